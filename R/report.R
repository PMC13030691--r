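#' Render the repeatability report to disk
#'
#' Writes the stratified repeatability table as CSV and JSON, one
#' Bland-Altman plot per supplied series, and a JSON manifest listing every
#' file written.
#'
#' @param results A [repeatability_table()].
#' @param series Optional named list of [bland_altman_series()] objects; each
#'   is plotted to `<name>.png`.
#' @param out_dir Output directory (created if absent).
#' @param make_plots Set `FALSE` to skip plot rendering.
#' @return Invisibly, the character vector of files written (also stored in
#'   `manifest.json`).
#' @export
render_report <- function(results, series = NULL, out_dir,
                          make_plots = TRUE) {
  if (!inherits(results, "repeatability_table")) {
    abort_structure("`results` must be a `repeatability_table`.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    abort(sprintf("output directory is not writable: %s", out_dir),
          class = "petrep_error_io")
  }
  files <- character()
  csv_path <- file.path(out_dir, "report.csv")
  readr::write_csv(results, csv_path)
  files <- c(files, csv_path)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(as.data.frame(results), json_path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  files <- c(files, json_path)
  if (make_plots && length(series) > 0) {
    nms <- names(series)
    if (is.null(nms) || any(nms == "")) {
      abort_structure("`series` must be a fully named list.")
    }
    for (nm in nms) {
      p <- ggplot2::autoplot(series[[nm]])
      plot_path <- file.path(out_dir, paste0(nm, ".png"))
      suppressMessages(ggplot2::ggsave(plot_path, p, width = 5, height = 4,
                                       dpi = 120))
      files <- c(files, plot_path)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(files = files), manifest_path, auto_unbox = FALSE)
  invisible(c(files, manifest_path))
}
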