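# Independent brute-force oracles used across test files.

# exhaustive rotation-grid RMSD: best RMSD over a grid of Euler-angle
# rotations with optimal (centroid) translation; independent of the Kabsch
# route used by superpose()
grid_rmsd_oracle <- function(mobile, reference, n_angles = 36) {
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  ang_b <- seq(0, pi, length.out = n_angles / 2)
  A0 <- sweep(mobile, 2, colMeans(mobile))
  B0 <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  for (a in ang) for (b in ang_b) for (g in ang) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    R <- Rz1 %*% Ry %*% Rz2
    r <- sqrt(mean(rowSums((A0 %*% t(R) - B0)^2)))
    if (r < best) best <- r
  }
  best
}

# all size-k subsets of 1..n (small n only)
subsets_of <- function(n, k) utils::combn(n, k, simplify = FALSE)

# algebraic Michaelis-Menten inversion from two (S, V0) pairs on a
# noiseless curve: closed-form oracle for recovery tests
mm_invert_oracle <- function(S1, V1, S2, V2) {
  # V = Vmax S/(Km+S)  =>  Km = S1 S2 (V2 - V1) / (S2 V1 - S1 V2)
  Km <- S1 * S2 * (V2 - V1) / (S2 * V1 - S1 * V2)
  Vmax <- V1 * (Km + S1) / S1
  list(Vmax = Vmax, Km = Km)
}

# build a small 3-batch study data.frame directly (bypasses generate_study)
make_manual_study <- function(E0, kd_map, months, vials = 3,
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (Tk in names(kd_map)) for (m in months) for (b in 1:3)
    for (v in seq_len(vials)) {
      act <- E0 * exp(-kd_map[[Tk]] * m) + rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        batch = b, temperature_K = as.numeric(Tk), vial_id = v,
        month = m, activity_UL = max(act, 0))
    }
  do.call(rbind, rows)
}
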