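#' Export a trajectory as plain text
#'
#' Writes the diagnostics series as TSV and (optionally) every stored
#' snapshot as long-format TSV (`t, x, y, B1, B2, W`), plus a JSON run
#' manifest carrying the full parameter set, grid, solver control, seed and
#' termination reason. Plain text is used for portability (no NetCDF
#' dependency); files are self-describing through the manifest.
#'
#' @param traj a [integrate_model] trajectory.
#' @param dir output directory (created if missing).
#' @param fields also write the field snapshots.
#' @return The directory, invisibly.
#' @export
export_trajectory <- function(traj, dir, fields = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(traj$diagnostics, file.path(dir, "diagnostics.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  if (fields) {
    snaps <- Filter(Negate(is.null), traj$snapshots)
    g <- traj$grid
    rows <- lapply(snaps, function(s) {
      data.frame(t = s$T,
                 x = rep(g$x, times = g$ny),
                 y = rep(g$y, each = g$nx),
                 B1 = as.vector(s$B1), B2 = as.vector(s$B2),
                 W = as.vector(s$W))
    })
    if (length(rows) > 0)
      write.table(do.call(rbind, rows), file.path(dir, "fields.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  man <- list(params = unclass(traj$params),
              grid = list(Lx = traj$grid$Lx, Ly = traj$grid$Ly,
                          nx = traj$grid$nx, ny = traj$grid$ny),
              control = unclass(traj$control),
              termination = traj$termination,
              clipped_mass = traj$clipped_mass,
              final_time = traj$final$T)
  man$control$census_threshold <- traj$control$census_threshold
  jsonlite::write_json(man, file.path(dir, "run.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
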