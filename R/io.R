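#' Write / read a beam profile as CSV
#'
#' Fixed dialect: comma separator, '.' decimal, one header line
#' (`r_mm,intensity`), values formatted with 9 significant digits so a
#' written profile reads back identically to formatting precision.
#'
#' @param p A [beam_profile()].
#' @param path Output path.
#' @export
write_profile_csv <- function(p, path) {
  stopifnot(inherits(p, "beam_profile"))
  writeLines(c("r_mm,intensity",
               sprintf("%.9g,%.9g", p$positions, p$values)), path)
  invisible(path)
}

#' @rdname write_profile_csv
#' @return `read_profile_csv()` returns a [beam_profile()].
#' @export
read_profile_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2L) stop("expected two columns: r_mm, intensity")
  beam_profile(as.numeric(tab[[1]]), as.numeric(tab[[2]]))
}

#' Write profile metrics (or any metrics list) as JSON
#'
#' @param m A `"profile_metrics"` object or plain list.
#' @param path Output path.
#' @export
write_metrics_json <- function(m, path) {
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a 2D beam map as CSV + JSON sidecar
#'
#' Dense matrix CSV (rows indexed by x, columns by y) plus a small JSON
#' sidecar holding the grid metadata.
#'
#' @param map A `"beam_map"`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "beam_map"))
  utils::write.table(format(map$values, digits = 9, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(x_min = min(map$x), x_max = max(map$x),
         y_min = min(map$y), y_max = max(map$y),
         pixel = map$x[2] - map$x[1],
         nx = length(map$x), ny = length(map$y),
         source_integral = map$source_integral),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
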