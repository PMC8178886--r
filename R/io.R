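#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-column PDB ATOM records.
#' Residues are written as alanine ("ALA") unless residue names are
#' supplied; coordinates are truncated to the PDB's 3-decimal precision.
#'
#' @param traj An [md_trajectory()].
#' @param file Output path.
#' @param res_name Residue name per atom; default "ALA".
#' @return Invisibly, `file`.
#' @export
write_multimodel_pdb <- function(traj, file, res_name = "ALA") {
  stopifnot(inherits(traj, "md_trajectory"))
  n_atoms <- dim(traj$coords)[2]
  rn <- rep(res_name, length.out = n_atoms)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(n_atoms),
      ifelse(nchar(traj$atom_name) < 4, paste0(" ", traj$atom_name),
             traj$atom_name),
      rn, traj$residue, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL blocks of ATOM/HETATM records by fixed columns.
#' Every model must contain the same atoms in the same order.
#'
#' @param file Path to a PDB file.
#' @param temperature Optional temperature label (K) for the trajectory.
#' @return An [md_trajectory()].
#' @export
read_multimodel_pdb <- function(file, temperature = NA_real_) {
  lines <- readLines(file)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) model_starts <- 1L
  # assign each atom line to the preceding MODEL record
  model_of <- findInterval(which(is_atom), model_starts)
  atom_lines <- lines[is_atom]
  n_models <- max(model_of)
  per_model <- split(atom_lines, model_of)
  n_atoms <- length(per_model[[1]])
  if (!all(lengths(per_model) == n_atoms))
    stop("models contain different atom counts")
  first <- per_model[[1]]
  atom_name <- trimws(substr(first, 13, 16))
  residue <- as.integer(trimws(substr(first, 23, 26)))
  coords <- array(0, dim = c(n_models, n_atoms, 3))
  for (m in seq_len(n_models)) {
    ln <- per_model[[m]]
    coords[m, , 1] <- as.numeric(substr(ln, 31, 38))
    coords[m, , 2] <- as.numeric(substr(ln, 39, 46))
    coords[m, , 3] <- as.numeric(substr(ln, 47, 54))
  }
  md_trajectory(coords, residue, atom_name, temperature)
}

#' Write a trajectory as a whitespace XYZ file with a residue-map sidecar
#'
#' Standard XYZ: per frame, an atom-count line, a comment line, then
#' "name x y z" rows. The residue map (atom index, residue id, atom name)
#' goes to `<file>.map.csv` since plain XYZ carries no residue
#' information.
#'
#' @param traj An [md_trajectory()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_xyz_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "md_trajectory"))
  n_atoms <- dim(traj$coords)[2]
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(dim(traj$coords)[1])) {
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("frame %d", f), con)
    xyz <- traj$coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf("%-4s %12.6f %12.6f %12.6f", traj$atom_name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  utils::write.csv(data.frame(atom = seq_len(n_atoms),
                              residue = traj$residue,
                              atom_name = traj$atom_name),
                   paste0(file, ".map.csv"), row.names = FALSE)
  invisible(file)
}

#' Read a whitespace XYZ trajectory
#'
#' @param file Path to an XYZ file written by [write_xyz_trajectory()] (or
#'   any standard XYZ).
#' @param residue_map Optional data.frame with columns `atom`, `residue`,
#'   `atom_name`; defaults to reading `<file>.map.csv`, else atoms become
#'   one residue each.
#' @param temperature Optional temperature label (K).
#' @return An [md_trajectory()].
#' @export
read_xyz_trajectory <- function(file, residue_map = NULL,
                                temperature = NA_real_) {
  lines <- readLines(file)
  i <- 1L; frames <- list(); names_seen <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    names_seen <- vapply(parts, `[[`, character(1), 1)
    frames[[length(frames) + 1L]] <-
      t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    i <- i + 2L + n
  }
  n_atoms <- nrow(frames[[1]])
  coords <- array(0, dim = c(length(frames), n_atoms, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  if (is.null(residue_map)) {
    side <- paste0(file, ".map.csv")
    residue_map <- if (file.exists(side)) utils::read.csv(side)
                   else data.frame(atom = seq_len(n_atoms),
                                   residue = seq_len(n_atoms),
                                   atom_name = names_seen)
  }
  md_trajectory(coords, residue_map$residue, residue_map$atom_name,
                temperature)
}

#' Write a stability measurement table to CSV
#'
#' Columns: batch, temperature_K, vial_id, month, activity_UL (UTF-8,
#' comma-separated, '.' decimal). A JSON sidecar `<file>.truth.json`
#' records the generator ground truth and seed when present.
#'
#' @param study A data.frame from [generate_study()] (or with the same
#'   columns).
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_study_csv <- function(study, file) {
  utils::write.csv(study, file, row.names = FALSE)
  truth <- attr(study, "truth")
  if (!is.null(truth)) {
    truth$true_kd <- as.list(truth$true_kd)  # keep names in JSON
    jsonlite::write_json(
      c(truth, list(seed = attr(study, "seed"),
                    n_truncated = attr(study, "n_truncated"))),
      paste0(file, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read a stability measurement table from CSV
#'
#' @param file CSV path with at least columns `batch`, `temperature_K`,
#'   `month`, `activity_UL`.
#' @return A data.frame.
#' @export
read_study_csv <- function(file) {
  out <- utils::read.csv(file)
  need <- c("batch", "temperature_K", "month", "activity_UL")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0)
    stop("missing required columns: ", paste(miss, collapse = ", "))
  out
}

#' Read a run configuration from YAML
#'
#' Validates the fields used by [fit_stability_study()]: optional `seed`,
#' `confidence`, `precision`, `kd_unit`, `constants_mode`, `E0`,
#' `rmsf_cutoff`. Unknown fields are an error so typos fail loudly.
#'
#' @param file YAML path.
#' @return A named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  known <- c("seed", "confidence", "precision", "kd_unit",
             "constants_mode", "E0", "rmsf_cutoff")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  defaults <- list(seed = 1L, confidence = 0.95, precision = 21.8,
                   kd_unit = "month", constants_mode = "pinned",
                   E0 = NULL, rmsf_cutoff = 0.5)
  utils::modifyList(defaults, cfg)
}
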