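#' Gaussian sigma from FWHM
#'
#' @param fwhm Full width at half maximum (mm), positive.
#' @return Standard deviation `fwhm / (2 sqrt(2 ln 2))` (mm).
#' @examples
#' sigma_from_fwhm(1.5) # 0.637
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (!is.numeric(fwhm) || any(fwhm <= 0)) stop("fwhm must be > 0")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Focal-spot source models
#'
#' The focal spot is described by its one-dimensional intensity along a
#' diameter (slab approximation, consistent with treating each slice as a
#' line source and omitting the angular dependence of the emission).
#' `gaussian_source()` builds a Gaussian spot of given FWHM;
#' `tabulated_source()` accepts an arbitrary measured/tabulated intensity.
#'
#' Slice intensities carry a unit peak by convention; normalization
#' appropriate to a given comparison (e.g. equal total output across spot
#' sizes for dose-rate surrogates) is applied by the consuming functions.
#'
#' @param fwhm Full width at half maximum of the spot (mm).
#' @param center_offset Lateral displacement of the spot center (mm),
#'   for misalignment studies. Default 0.
#' @param slice_step Slice discretization step (mm). Default 0.002.
#' @param truncation Gaussian support half-width in units of sigma. Default 4.
#' @return An object of class `"source_model"`.
#' @examples
#' src <- gaussian_source(1.5)
#' @export
gaussian_source <- function(fwhm, center_offset = 0, slice_step = 0.002,
                            truncation = 4) {
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (slice_step <= 0) stop("slice_step must be > 0")
  if (truncation <= 0) stop("truncation must be > 0")
  structure(list(kind = "gaussian", fwhm = fwhm,
                 sigma = sigma_from_fwhm(fwhm),
                 center_offset = center_offset,
                 slice_step = slice_step, truncation = truncation),
            class = "source_model")
}

#' @rdname gaussian_source
#' @param positions,intensities Tabulated spot intensity: positions (mm,
#'   strictly increasing, at least 2) and non-negative intensities.
#' @export
tabulated_source <- function(positions, intensities, center_offset = 0,
                             slice_step = 0.002) {
  stopifnot(is.numeric(positions), is.numeric(intensities),
            length(positions) == length(intensities))
  if (length(positions) < 2L) stop("tabulated source needs >= 2 points")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be >= 0")
  if (slice_step <= 0) stop("slice_step must be > 0")
  structure(list(kind = "tabulated", positions = positions,
                 intensities = intensities, center_offset = center_offset,
                 slice_step = slice_step),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  if (x$kind == "gaussian")
    cat(sprintf(
      "Gaussian source: FWHM %g mm (sigma %.5f mm), center %g mm, slices %g mm, +/-%g sigma\n",
      x$fwhm, x$sigma, x$center_offset, x$slice_step, x$truncation))
  else
    cat(sprintf(
      "Tabulated source: %d points on [%g, %g] mm, center %g mm, slices %g mm\n",
      length(x$positions), min(x$positions), max(x$positions),
      x$center_offset, x$slice_step))
  invisible(x)
}

#' Discretize a source model into point-source slices
#'
#' The spot is divided into slices narrow enough to be treated as point
#' sources. Slice positions form a grid symmetric about the spot center with
#' spacing `slice_step`; each slice carries the distribution's intensity at
#' its position. Gaussian spots span `+/- truncation * sigma`; tabulated
#' spots span the table extent, with linear interpolation onto the slice
#' grid (clamped at zero).
#'
#' @param src A [gaussian_source()] or [tabulated_source()].
#' @return A data.frame with columns `r0` (slice position, mm) and
#'   `intensity` (>= 0, unit peak for a Gaussian).
#' @export
slice_source <- function(src) {
  stopifnot(inherits(src, "source_model"))
  if (src$kind == "gaussian") {
    half_span <- src$truncation * src$sigma
    n <- floor(half_span / src$slice_step)
    if (2 * half_span < src$slice_step || n < 1L)
      stop("degenerate source: span narrower than one slice_step")
    r0 <- src$center_offset + src$slice_step * (-n:n)
    intensity <- exp(-((r0 - src$center_offset)^2) / (2 * src$sigma^2))
  } else {
    lo <- min(src$positions); hi <- max(src$positions)
    half_span <- (hi - lo) / 2
    mid <- src$center_offset + (hi + lo) / 2
    n <- floor(half_span / src$slice_step)
    if (hi - lo < src$slice_step || 2 * n + 1 < 3L)
      stop("degenerate source: span narrower than one slice_step")
    r0 <- mid + src$slice_step * (-n:n)
    intensity <- stats::approx(src$positions + src$center_offset,
                               src$intensities, xout = r0, rule = 2)$y
    intensity <- pmax(intensity, 0)
  }
  if (length(r0) < 3L) stop("degenerate source: fewer than 3 slices")
  data.frame(r0 = r0, intensity = intensity)
}

#' Read a tabulated source from a two-column text file
#'
#' Accepts whitespace- or comma-delimited text with columns position (mm)
#' and intensity; a single header line is detected and skipped.
#'
#' @param path File path.
#' @param ... Passed on to [tabulated_source()].
#' @return A `"source_model"` of kind tabulated.
#' @export
read_source_table <- function(path, ...) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]][1])))
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           strip.white = TRUE)
  if (ncol(tab) < 2L) stop("expected two columns: position, intensity")
  tabulated_source(positions = as.numeric(tab[[1]]),
                   intensities = as.numeric(tab[[2]]), ...)
}
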