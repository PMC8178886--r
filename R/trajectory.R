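#' Construct a trajectory object
#'
#' A light container for an ensemble of conformations: a frames x atoms x 3
#' coordinate array (Angstrom) with a per-atom residue map and atom names.
#' Every frame must share the same atom count and order.
#'
#' @param coords Numeric array, dim = c(n_frames, n_atoms, 3).
#' @param residue Integer residue id per atom (length n_atoms). Residue
#'   numbering follows the input verbatim; no renumbering is attempted.
#' @param atom_name Atom name per atom (e.g. "N", "CA", "C", "H").
#' @param temperature Optional temperature label (K).
#' @return An object of class `"md_trajectory"`.
#' @examples
#' md_trajectory(array(0, c(2, 3, 3)), residue = c(1, 1, 1),
#'               atom_name = c("N", "CA", "C"))
#' @export
md_trajectory <- function(coords, residue, atom_name,
                          temperature = NA_real_) {
  stopifnot(is.array(coords), length(dim(coords)) == 3,
            dim(coords)[3] == 3)
  n_atoms <- dim(coords)[2]
  if (length(residue) != n_atoms || length(atom_name) != n_atoms)
    stop("'residue' and 'atom_name' must have one entry per atom")
  structure(list(coords = coords,
                 residue = as.integer(residue),
                 atom_name = as.character(atom_name),
                 temperature = temperature),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames, %d atoms, %d residues%s\n",
              d[1], d[2], length(unique(x$residue)),
              if (is.finite(x$temperature))
                sprintf(" (%.2f K)", x$temperature) else ""))
  invisible(x)
}

# atom-selection helper: non-hydrogen atoms with the requested names
select_atoms <- function(traj, atoms = NULL, drop_hydrogens = TRUE) {
  sel <- rep(TRUE, length(traj$atom_name))
  if (drop_hydrogens) sel <- sel & !grepl("^[0-9]*H", traj$atom_name)
  if (!is.null(atoms)) sel <- sel & traj$atom_name %in% atoms
  which(sel)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference coordinate set over a selection, via SVD of the
#' cross-covariance with the determinant sign corrected so no reflection is
#' introduced.
#'
#' @param mobile n_atoms x 3 coordinate matrix.
#' @param reference n_atoms x 3 coordinate matrix (same atoms).
#' @param selection Optional integer indices of the atoms used to compute
#'   the fit (the transform is applied to all atoms). Default: all.
#' @return A list with `coords` (transformed mobile), `rotation` (3 x 3),
#'   `translation` (length 3), and `rmsd` (Angstrom, over the selection).
#' @examples
#' m <- matrix(rnorm(12), 4, 3)
#' superpose(m, m)$rmsd # 0
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            all(dim(mobile) == dim(reference)), ncol(mobile) == 3)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3)
    stop("at least 3 atoms are required for superposition")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # degenerate selections (coincident or collinear points) have rank < 2
  if (qr(A0)$rank < 2 || qr(B0)$rank < 2)
    stop("degenerate selection: atoms are coincident or collinear")
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(mobile, 2, ca) %*% t(R)
  out <- sweep(out, 2, cb, `+`)
  fitted_sel <- out[selection, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted_sel - B)^2)))
  list(coords = out, rotation = R, translation = cb - c(R %*% ca),
       rmsd = rmsd)
}

#' RMSD of two conformations after superposition
#'
#' @param a,b n_atoms x 3 coordinate matrices.
#' @param selection Optional atom indices (fit and RMSD).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL) superpose(a, b, selection)$rmsd

# superpose every frame of a trajectory onto a reference conformation;
# returns the fitted coordinate array
fit_frames <- function(coords, reference, selection = NULL) {
  out <- coords
  for (f in seq_len(dim(coords)[1]))
    out[f, , ] <- superpose(coords[f, , ], reference, selection)$coords
  out
}

# iterative-mean reference: fit to the first frame, average, refit to the
# average (one pass); returns list(coords = fitted array, mean = reference)
mean_structure_fit <- function(coords, selection = NULL) {
  fitted <- fit_frames(coords, coords[1, , ], selection)
  avg <- apply(fitted, c(2, 3), mean)
  fitted <- fit_frames(fitted, avg, selection)
  list(coords = fitted, mean = apply(fitted, c(2, 3), mean))
}

#' Per-frame RMSD series of a trajectory
#'
#' Each frame is rigid-body superposed onto the reference (default: the
#' first frame) over the selection, then the RMSD over that selection is
#' reported — the standard equilibration/stability diagnostic of a
#' production run.
#'
#' @param traj An [md_trajectory()].
#' @param reference Optional n_atoms x 3 reference; default frame 1.
#' @param atoms Atom names to use; default `c("N", "CA", "C")` (backbone).
#'   Hydrogens are always excluded.
#' @return Numeric vector of per-frame RMSDs (Angstrom).
#' @examples
#' traj <- generate_trajectory(trajectory_spec(5, n_frames = 10))
#' rmsd_series(traj)
#' @export
rmsd_series <- function(traj, reference = NULL,
                        atoms = c("N", "CA", "C")) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj, atoms)
  if (length(sel) == 0) stop("selection matches no atoms")
  if (is.null(reference)) reference <- traj$coords[1, , ]
  vapply(seq_len(dim(traj$coords)[1]), function(f)
    superpose(traj$coords[f, , ], reference, sel)$rmsd, numeric(1))
}

#' Per-residue backbone RMSF
#'
#' Root-mean-square fluctuation about the time-average structure. All
#' frames are superposed (one iterative pass: fit to frame 1, average,
#' refit to the average), the per-atom RMSF is
#' sqrt(mean_t |x_t - xbar|^2), and each residue's value is the mean over
#' its backbone atoms (N, CA, C by default; hydrogens excluded).
#'
#' @param traj An [md_trajectory()].
#' @param atoms Backbone atom names averaged per residue; default
#'   `c("N", "CA", "C")`.
#' @return A data.frame with columns `residue` and `rmsf_A`, one row per
#'   residue in input order.
#' @examples
#' traj <- generate_trajectory(trajectory_spec(5, n_frames = 50))
#' rmsf_per_residue(traj)
#' @export
rmsf_per_residue <- function(traj, atoms = c("N", "CA", "C")) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj, atoms)
  if (length(sel) == 0) stop("selection matches no atoms")
  sub <- traj$coords[, sel, , drop = FALSE]
  fit <- mean_structure_fit(sub)
  dev2 <- sweep(fit$coords, c(2, 3), fit$mean)^2
  rmsf_atom <- sqrt(colMeans(dev2[, , 1] + dev2[, , 2] + dev2[, , 3]))
  res <- traj$residue[sel]
  agg <- tapply(rmsf_atom, res, mean)
  data.frame(residue = as.integer(names(agg)),
             rmsf_A = as.numeric(agg), row.names = NULL)
}

#' Per-residue RMSF difference against a base temperature
#'
#' Delta RMSF = RMSF(T) - RMSF(base), matched by residue id. Positive
#' values mean the residue fluctuates more than at the base temperature.
#'
#' @param profile,base Data frames from [rmsf_per_residue()] with identical
#'   residue sets.
#' @return A data.frame with columns `residue` and `delta_rmsf_A`.
#' @export
delta_rmsf <- function(profile, base) {
  stopifnot(all(c("residue", "rmsf_A") %in% names(profile)),
            all(c("residue", "rmsf_A") %in% names(base)))
  if (!identical(sort(profile$residue), sort(base$residue)))
    stop("profiles cover different residue sets")
  b <- base$rmsf_A[match(profile$residue, base$residue)]
  data.frame(residue = profile$residue,
             delta_rmsf_A = profile$rmsf_A - b)
}

#' Flag residues whose temperature response exceeds a cutoff
#'
#' Given the Delta-RMSF profiles of several temperatures against a common
#' base, computes for each residue the standard deviation across that set
#' of Delta-RMSF values and flags residues whose SD exceeds the cutoff
#' (default 0.5 Angstrom) — residues whose fluctuation changes strongly
#' and inconsistently with temperature.
#'
#' @param deltas A list of data frames from [delta_rmsf()] (at least two),
#'   or a residues x comparisons numeric matrix with residue ids as
#'   rownames.
#' @param cutoff SD cutoff in Angstrom; default 0.5.
#' @return A data.frame with columns `residue`, `sd_delta_A`, `flagged`.
#' @export
flag_fluctuating <- function(deltas, cutoff = 0.5) {
  if (is.list(deltas) && !is.matrix(deltas) && !is.data.frame(deltas)) {
    if (length(deltas) < 2)
      stop("at least two Delta-RMSF profiles are required for an SD")
    res <- deltas[[1]]$residue
    m <- vapply(deltas, function(d) {
      if (!identical(d$residue, res))
        stop("Delta-RMSF profiles cover different residue sets")
      d$delta_rmsf_A
    }, numeric(length(res)))
  } else {
    m <- as.matrix(deltas)
    if (ncol(m) < 2)
      stop("at least two Delta-RMSF profiles are required for an SD")
    res <- if (!is.null(rownames(m))) as.integer(rownames(m))
           else seq_len(nrow(m))
  }
  s <- apply(m, 1, stats::sd)
  data.frame(residue = res, sd_delta_A = as.numeric(s),
             flagged = as.numeric(s) > cutoff)
}

#' Merge flagged residues into fluctuating regions
#'
#' Maximal runs of flagged residues, allowing gaps of up to
#' `gap_tolerance` unflagged residues inside a run; runs spanning fewer
#' than `min_size` residues are dropped. This operationalizes "residues in
#' the vicinity of a peak form a fluctuating region".
#'
#' @param residues Integer ids of flagged residues.
#' @param gap_tolerance Largest allowed gap inside a region; default 2.
#' @param min_size Smallest reported region (residue span); default 2.
#' @return A data.frame with columns `start`, `end`, `n_flagged`.
#' @examples
#' find_regions(c(159, 160, 161, 300), min_size = 2)
#' @export
find_regions <- function(residues, gap_tolerance = 2, min_size = 2) {
  if (length(residues) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      n_flagged = integer(0)))
  r <- sort(unique(as.integer(residues)))
  brk <- c(0, which(diff(r) > gap_tolerance + 1), length(r))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    seg <- r[(brk[i] + 1):brk[i + 1]]
    data.frame(start = min(seg), end = max(seg), n_flagged = length(seg))
  }))
  out <- out[out$end - out$start + 1 >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Principal component analysis of C-alpha positional covariance
#'
#' Frames are superposed on the C-alpha selection (iterative-mean
#' reference), the 3N x 3N covariance matrix of the C-alpha coordinates is
#' eigendecomposed, and the leading k components are reported with their
#' variance proportions and per-residue contributions (squared norm of each
#' residue's three eigenvector components, normalized to sum to one per
#' component).
#'
#' @param traj An [md_trajectory()]; must contain CA atoms.
#' @param k Number of components to report; default 5.
#' @return An object of class `"ca_pca"`: `eigenvalues` (all),
#'   `proportion` (k), `vectors` (3N x k), `contributions` (residues x k),
#'   `residue` ids.
#' @examples
#' traj <- generate_trajectory(trajectory_spec(6, n_frames = 30))
#' pca_ca(traj, k = 2)
#' @export
pca_ca <- function(traj, k = 5) {
  stopifnot(inherits(traj, "md_trajectory"))
  sel <- select_atoms(traj, "CA")
  if (length(sel) == 0) stop("no CA atoms in the trajectory")
  n_frames <- dim(traj$coords)[1]
  if (n_frames < 2) stop("at least 2 frames are required")
  # RMS-fit on all heavy atoms (hydrogens excluded), then take the CA
  # coordinates for the covariance
  heavy <- select_atoms(traj)
  fit_all <- mean_structure_fit(traj$coords[, heavy, , drop = FALSE])
  fit <- list(coords = fit_all$coords[, match(sel, heavy), , drop = FALSE])
  # frames x 3N matrix, atom-major (x1 y1 z1 x2 y2 z2 ...)
  n <- length(sel)
  X <- matrix(0, n_frames, 3 * n)
  for (j in seq_len(n)) X[, (3 * j - 2):(3 * j)] <- fit$coords[, j, ]
  Xc <- sweep(X, 2, colMeans(X))
  C <- stats::cov(Xc)
  rank <- qr(Xc)$rank
  if (k > rank)
    stop(sprintf("k = %d exceeds the covariance rank (%d)", k, rank))
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  prop <- lambda[seq_len(k)] / sum(lambda)
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  contrib <- t(vapply(seq_len(n), function(j)
    colSums(vecs[(3 * j - 2):(3 * j), , drop = FALSE]^2), numeric(k)))
  contrib <- sweep(contrib, 2, colSums(contrib), `/`)
  structure(list(eigenvalues = lambda,
                 proportion = prop,
                 vectors = vecs,
                 contributions = contrib,
                 residue = traj$residue[sel],
                 k = k),
            class = "ca_pca")
}

#' @export
print.ca_pca <- function(x, ...) {
  cat(sprintf("C-alpha covariance PCA: %d residues, top %d components\n",
              length(x$residue), x$k))
  cat("  variance proportions:",
      paste(sprintf("%.3f", x$proportion), collapse = " "), "\n")
  invisible(x)
}

#' Per-residue contribution difference between two PCA results
#'
#' Delta PC = contribution(T) - contribution(base) for each of the first k
#' components, matched by residue.
#'
#' @param pca,base `"ca_pca"` objects over the same residues with the same
#'   k.
#' @return A residues x k matrix of contribution differences with residue
#'   ids as rownames.
#' @export
delta_pc <- function(pca, base) {
  stopifnot(inherits(pca, "ca_pca"), inherits(base, "ca_pca"))
  if (!identical(pca$residue, base$residue))
    stop("PCA results cover different residue sets")
  if (pca$k != base$k) stop("PCA results report different k")
  d <- pca$contributions - base$contributions
  rownames(d) <- pca$residue
  d
}
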