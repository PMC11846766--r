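#' Write a point-cloud snapshot as legacy ASCII VTK
#'
#' Emits an unstructured-grid file with vertex cells and the per-point
#' arrays `cell_type` (integer codes, see [cell_type_codes]), `volume`,
#' `E`, `t_H`, and optionally the sampled concentrations.
#'
#' @param cloud an `mp_cloud`.
#' @param path output file path (.vtk).
#' @param field optional [chemical_field()] to sample `C_Ihh`, `C_PTHrP`.
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(cloud, path, field = NULL) {
  n <- n_points(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ossiforge material points", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(format(cloud$x, trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", n, 2 * n), con)
  writeLines(paste(1L, seq_len(n) - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", n), con)
  writeLines(rep("1", n), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  wr <- function(name, v, type = "float") {
    writeLines(c(sprintf("SCALARS %s %s 1", name, type),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(v, trim = TRUE), con)
  }
  wr("cell_type", cloud$type, "int")
  wr("volume", cloud$V)
  wr("E", cloud$E)
  wr("t_H", ifelse(is.na(cloud$t_H), -1, cloud$t_H))
  if (!is.null(field)) {
    wr("C_Ihh", chem_interp(field, cloud$x, field$C_ihh))
    wr("C_PTHrP", chem_interp(field, cloud$x, field$C_pthrp))
  }
  invisible(path)
}

#' Save / load a simulation checkpoint
#'
#' Serializes the full state of an `oss_sim` (or any state list) so a run
#' can be inspected or restarted.
#'
#' @param sim object to save.
#' @param path checkpoint file path (.rds).
#' @export
save_checkpoint <- function(sim, path) {
  saveRDS(sim, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# write the standard output set of a finished run
write_outputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$census, file.path(dir, "census.csv"), row.names = FALSE)
  if (!is.null(sim$divisions))
    write.csv(sim$divisions, file.path(dir, "divisions.csv"), row.names = FALSE)
  write_vtk_points(sim$cloud, file.path(dir, "final.vtk"), sim$field)
  save_checkpoint(sim, file.path(dir, "checkpoint.rds"))
  invisible(dir)
}
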