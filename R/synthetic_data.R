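#' Specification of a synthetic multi-batch stability study
#'
#' Describes the study conditions the generator emulates: several enzyme
#' concentrate batches (the sampling strata), vials stored at a set of
#' temperatures, first-order decay at known per-temperature rates, and
#' additive Gaussian measurement noise on the activity scale.
#'
#' Defaults reproduce a year-long laccase-concentrate study: three batches
#' at 16,575.50 +/- 268.92 U L^-1 initial activity, storage at the five
#' study temperatures with their fitted deactivation constants as ground
#' truth, measurement SD 96.6 U L^-1 (the pilot pooled estimate), and a
#' monthly-then-bimonthly schedule (1-6, 8, 10, 12 months).
#'
#' @param n_batches Number of batches (strata); default 3.
#' @param vials_per_batch Vials measured per batch at each
#'   (temperature, time); default 5.
#' @param initial_activity_mean Mean initial activity, U L^-1.
#' @param initial_activity_sd Between-batch SD of initial activity, U L^-1.
#' @param temperatures Storage temperatures, K (names of `true_kd`).
#' @param true_kd Named numeric map temperature -> k_d (month^-1), >= 0.
#' @param noise_sd Measurement SD on the activity scale, U L^-1, >= 0.
#' @param schedule_months Sampling months, strictly increasing.
#' @param seed Integer seed; the same spec and seed give an identical
#'   dataset.
#' @return An object of class `"study_spec"`.
#' @examples
#' study_spec(seed = 1)
#' @export
study_spec <- function(n_batches = 3,
                       vials_per_batch = 5,
                       initial_activity_mean = 16575.50,
                       initial_activity_sd = 268.92,
                       temperatures = c(240.98, 277.40, 297.53,
                                        303.27, 309.58),
                       true_kd = c(`240.98` = 0.003, `277.40` = 0.015,
                                   `297.53` = 0.055, `303.27` = 0.135,
                                   `309.58` = 0.400),
                       noise_sd = 96.6,
                       schedule_months = c(1:6, 8, 10, 12),
                       seed = 1L) {
  if (n_batches < 1 || vials_per_batch < 1)
    stop("batch and vial counts must be positive")
  if (noise_sd < 0 || initial_activity_sd < 0)
    stop("standard deviations must be non-negative")
  if (any(true_kd < 0)) stop("all true k_d must be non-negative")
  if (any(diff(schedule_months) <= 0))
    stop("schedule must be strictly increasing")
  key <- format(temperatures, trim = TRUE)
  if (!all(key %in% names(true_kd)))
    stop("every temperature needs an entry in 'true_kd' (named by format(T))")
  structure(list(n_batches = as.integer(n_batches),
                 vials_per_batch = as.integer(vials_per_batch),
                 initial_activity_mean = initial_activity_mean,
                 initial_activity_sd = initial_activity_sd,
                 temperatures = temperatures,
                 true_kd = true_kd,
                 noise_sd = noise_sd,
                 schedule_months = schedule_months,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Generate a synthetic stability-study measurement table
#'
#' One record per (batch, temperature, vial, month). Each batch draws an
#' initial activity E0_batch ~ N(mean, sd); each measurement is
#' E0_batch * exp(-k_d(T) * t) + N(0, noise_sd), truncated at zero (the
#' truncation count is recorded as an attribute). Vials form equal-size
#' strata per batch.
#'
#' @param spec A [study_spec()].
#' @return A data.frame with columns `batch`, `temperature_K`, `vial_id`,
#'   `month`, `activity_UL`, plus attributes `truth` (per-batch E0 and the
#'   k_d map), `n_truncated` and `seed`.
#' @examples
#' head(generate_study(study_spec(vials_per_batch = 2, seed = 7)))
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  E0_batch <- spec$initial_activity_mean +
    stats::rnorm(spec$n_batches, 0, spec$initial_activity_sd)
  key <- format(spec$temperatures, trim = TRUE)
  grid <- expand.grid(vial = seq_len(spec$vials_per_batch),
                      batch = seq_len(spec$n_batches),
                      month = spec$schedule_months,
                      ti = seq_along(spec$temperatures))
  kd <- spec$true_kd[key[grid$ti]]
  mu <- E0_batch[grid$batch] * exp(-kd * grid$month)
  act <- mu + stats::rnorm(nrow(grid), 0, spec$noise_sd)
  n_trunc <- sum(act < 0)
  act <- pmax(act, 0)
  out <- data.frame(batch = grid$batch,
                    temperature_K = spec$temperatures[grid$ti],
                    vial_id = grid$vial,
                    month = grid$month,
                    activity_UL = act)
  out <- out[order(out$temperature_K, out$month, out$batch, out$vial_id), ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(E0_batch = E0_batch, true_kd = spec$true_kd,
                             noise_sd = spec$noise_sd,
                             initial_activity_mean =
                               spec$initial_activity_mean)
  attr(out, "n_truncated") <- n_trunc
  attr(out, "seed") <- spec$seed
  out
}

#' Generate a synthetic Michaelis-Menten kinetics table
#'
#' V0 = Vmax S / (Km + S) + N(0, noise_sd) over a substrate grid. The
#' default grid is log-spaced over the 0.1-3 mM assay range; note that Km
#' values near 0.04 mM sit below this range, which limits Km
#' identifiability unless the grid is extended downward.
#'
#' @param vmax True maximum rate, mM min^-1, positive.
#' @param km True Michaelis constant, mM, positive.
#' @param s_grid Substrate concentrations, mM; default
#'   `exp(seq(log(0.1), log(3), length.out = 10))`.
#' @param noise_sd SD of additive velocity noise, mM min^-1; default 0.
#' @param replicates Replicate measurements per concentration; default 1.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `S_mM`, `V0_mM_min` and attribute
#'   `truth`.
#' @examples
#' generate_mm_dataset(0.0102, 0.0466, s_grid = c(0.1, 0.5, 1, 3))
#' @export
generate_mm_dataset <- function(vmax, km,
                                s_grid = exp(seq(log(0.1), log(3),
                                                 length.out = 10)),
                                noise_sd = 0, replicates = 1,
                                seed = NULL) {
  if (vmax <= 0 || km <= 0) stop("'vmax' and 'km' must be positive")
  if (any(s_grid < 0)) stop("substrate concentrations must be non-negative")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  S <- rep(s_grid, each = replicates)
  V0 <- vmax * S / (km + S)
  if (noise_sd > 0) V0 <- V0 + stats::rnorm(length(S), 0, noise_sd)
  out <- data.frame(S_mM = S, V0_mM_min = V0)
  attr(out, "truth") <- list(vmax = vmax, km = km, noise_sd = noise_sd)
  out
}

#' Specification of a synthetic Gaussian-fluctuation trajectory
#'
#' Describes a toy ensemble standing in for a molecular-dynamics
#' production run: frames are a reference structure plus independent
#' isotropic Gaussian displacements whose per-residue SD is the amplitude
#' profile. Optionally a random rigid-body rotation/translation is applied
#' per frame to exercise superposition machinery.
#'
#' @param n_residues Number of residues, >= 1.
#' @param n_frames Number of frames, >= 2; default 1000 (a typical
#'   production-snapshot count).
#' @param amplitude_profile Per-residue displacement SD per coordinate
#'   (Angstrom), length `n_residues`, >= 0. Default 0.5 everywhere.
#' @param atoms_per_residue Backbone atoms per residue; default 3
#'   (N, CA, C).
#' @param reference_coordinates Optional (n_residues *
#'   atoms_per_residue) x 3 matrix; default an extended-chain layout.
#' @param rigid_body Apply random global rotation + translation per frame;
#'   default `FALSE`.
#' @param seed Integer seed.
#' @return An object of class `"trajectory_spec"`.
#' @examples
#' trajectory_spec(n_residues = 10, n_frames = 50)
#' @export
trajectory_spec <- function(n_residues, n_frames = 1000,
                            amplitude_profile = rep(0.5, n_residues),
                            atoms_per_residue = 3,
                            reference_coordinates = NULL,
                            rigid_body = FALSE, seed = 1L) {
  if (n_residues < 1) stop("'n_residues' must be >= 1")
  if (n_frames < 2) stop("'n_frames' must be >= 2")
  if (length(amplitude_profile) != n_residues)
    stop("'amplitude_profile' must have one entry per residue")
  if (any(amplitude_profile < 0)) stop("amplitudes must be >= 0")
  n_atoms <- n_residues * atoms_per_residue
  if (is.null(reference_coordinates)) {
    # extended chain: residues 3.8 A apart along x, backbone atoms offset
    reference_coordinates <- cbind(
      rep(seq_len(n_residues) * 3.8, each = atoms_per_residue) +
        rep(seq_len(atoms_per_residue) - 1, n_residues) * 1.2,
      rep(c(0, 1.0, 0.5), length.out = n_atoms),
      rep(c(0.5, 0, 1.0), length.out = n_atoms))
  }
  stopifnot(nrow(reference_coordinates) == n_atoms,
            ncol(reference_coordinates) == 3)
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 amplitude_profile = amplitude_profile,
                 atoms_per_residue = as.integer(atoms_per_residue),
                 reference_coordinates = reference_coordinates,
                 rigid_body = rigid_body,
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Generate a synthetic Gaussian-fluctuation trajectory
#'
#' @param spec A [trajectory_spec()].
#' @return An [md_trajectory()] object with attributes recording the ground
#'   truth amplitude profile and seed.
#' @examples
#' traj <- generate_trajectory(trajectory_spec(5, n_frames = 10))
#' dim(traj$coords)
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n_atoms <- spec$n_residues * spec$atoms_per_residue
  sd_atom <- rep(spec$amplitude_profile, each = spec$atoms_per_residue)
  coords <- array(0, dim = c(spec$n_frames, n_atoms, 3))
  # all displacement noise is drawn before any rigid-body draws, so the
  # same seed yields identical internal motions with the jitter on or off
  for (f in seq_len(spec$n_frames)) {
    disp <- matrix(stats::rnorm(n_atoms * 3, 0, 1), n_atoms, 3) * sd_atom
    coords[f, , ] <- spec$reference_coordinates + disp
  }
  if (spec$rigid_body) {
    for (f in seq_len(spec$n_frames)) {
      R <- random_rotation()
      coords[f, , ] <- coords[f, , ] %*% t(R) +
        matrix(stats::runif(3, -20, 20), n_atoms, 3, byrow = TRUE)
    }
  }
  atom_names <- rep(c("N", "CA", "C"),
                    length.out = spec$atoms_per_residue)
  traj <- md_trajectory(
    coords = coords,
    residue = rep(seq_len(spec$n_residues),
                  each = spec$atoms_per_residue),
    atom_name = rep(atom_names, spec$n_residues))
  attr(traj, "truth") <- list(amplitude_profile = spec$amplitude_profile,
                              rigid_body = spec$rigid_body)
  attr(traj, "seed") <- spec$seed
  traj
}

# uniform random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
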