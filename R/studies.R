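#' Run configuration constructor
#'
#' Bundles everything needed to compute one profile: beamline geometry,
#' source model, aperture stack, metrics options and a seed for any
#' stochastic step (only the Monte-Carlo oracle uses randomness).
#'
#' @param geometry A [beamline()].
#' @param source A [gaussian_source()] or [tabulated_source()].
#' @param apertures List of [aperture()] objects.
#' @param metrics List of metric options; recognized: `detector_diameter`
#'   (mm or `NULL`).
#' @param seed Integer seed. Default 1.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(geometry, source, apertures,
                       metrics = list(detector_diameter = NULL), seed = 1L) {
  stopifnot(inherits(geometry, "beamline"), inherits(source, "source_model"))
  apertures <- .as_aperture_list(apertures)
  for (ap in apertures) magnification(geometry, ap)  # surfaces bad heights
  unknown <- setdiff(names(metrics), "detector_diameter")
  if (length(unknown))
    stop("unknown metrics option(s): ", paste(unknown, collapse = ", "))
  structure(list(geometry = geometry, source = source, apertures = apertures,
                 metrics = metrics, seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  print(x$geometry); print(x$source)
  for (ap in x$apertures) print(ap)
  if (!is.null(x$metrics$detector_diameter))
    cat(sprintf("Detector window: %g mm\n", x$metrics$detector_diameter))
  cat(sprintf("Seed: %d\n", x$seed))
  invisible(x)
}

#' Compute the profile of a run configuration
#'
#' @param config A [run_config()].
#' @return A [beam_profile()] (unnormalized; detector convolution applied
#'   when configured).
#' @export
config_profile <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- integrate_profile(config$source, config$apertures, config$geometry)
  if (!is.null(config$metrics$detector_diameter))
    p <- detector_convolve(p, config$metrics$detector_diameter)
  p
}

.with_source_fwhm <- function(src, fwhm) {
  gaussian_source(fwhm, center_offset = src$center_offset,
                  slice_step = src$slice_step,
                  truncation = if (!is.null(src$truncation)) src$truncation else 4)
}

# peak under the requested source-normalization convention
.conv_peak <- function(p, source_norm) {
  switch(source_norm,
         total = max(p$values) / p$source_integral,
         peak = max(p$values),
         stop("source_norm must be 'total' or 'peak'"))
}

.study_result <- function(rows, config, extra = list()) {
  structure(c(list(rows = rows,
                   provenance = list(config = config,
                                     timestamp = format(Sys.time(), tz = "UTC"))),
              extra),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study result: %d rows\n", nrow(x$rows)))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Beam-spot size sweep
#'
#' Recomputes the profile for each source FWHM with all other parameters
#' fixed, and reports the figures of merit plus the peak ratio against the
#' first row. Peak dose-rate surrogates compare sources of equal total
#' output by default (`source_norm = "total"`): the spot size changes the
#' clipping by the collimator, not the machine output. `"peak"` compares
#' sources of equal central slice intensity instead.
#'
#' @param config A [run_config()] with a gaussian source.
#' @param fwhm_values Vector of FWHM values (mm), at least one.
#' @param source_norm `"total"` (default) or `"peak"`.
#' @return A `"study_result"`; rows have fwhm, metrics, peak and
#'   `peak_ratio_vs_first`.
#' @export
sweep_source_fwhm <- function(config, fwhm_values, source_norm = "total") {
  stopifnot(inherits(config, "run_config"))
  if (length(fwhm_values) < 1L) stop("need at least one fwhm value")
  if (config$source$kind != "gaussian")
    stop("fwhm sweep requires a gaussian source")
  rows <- lapply(fwhm_values, function(f) {
    cfg <- config
    cfg$source <- .with_source_fwhm(config$source, f)
    p <- config_profile(cfg)
    m <- profile_metrics(normalize_profile(p))
    data.frame(fwhm = f, fwhm_mm = m$fwhm,
               penumbra_left = m$penumbra_left,
               penumbra_right = m$penumbra_right,
               peak = .conv_peak(p, source_norm))
  })
  rows <- do.call(rbind, rows)
  rows$peak_ratio_vs_first <- rows$peak / rows$peak[1]
  .study_result(rows, config)
}

#' Aperture parameter sweep
#'
#' Varies one parameter (radius, height or offset) of one aperture and
#' reports metrics per value. Values violating geometry invariants produce
#' per-row error records; the sweep continues.
#'
#' @param config A [run_config()].
#' @param parameter One of `"radius"`, `"height"`, `"offset"`.
#' @param values Parameter values to try (mm).
#' @param aperture_index Which aperture to vary (1-based). Default 1.
#' @param source_norm Peak convention, see [sweep_source_fwhm()].
#' @return A `"study_result"`; rows carry an `error` column (NA when the
#'   row succeeded).
#' @export
sweep_aperture <- function(config, parameter = c("radius", "height", "offset"),
                           values, aperture_index = 1L,
                           source_norm = "total") {
  stopifnot(inherits(config, "run_config"))
  parameter <- match.arg(parameter)
  if (length(values) < 1L) stop("need at least one value")
  if (aperture_index < 1L || aperture_index > length(config$apertures))
    stop("aperture_index out of range")
  rows <- lapply(values, function(v) {
    out <- tryCatch({
      cfg <- config
      ap <- cfg$apertures[[aperture_index]]
      ap[[parameter]] <- v
      cfg$apertures[[aperture_index]] <-
        aperture(ap$radius, ap$height, ap$offset)
      magnification(cfg$geometry, cfg$apertures[[aperture_index]])
      p <- config_profile(cfg)
      m <- profile_metrics(normalize_profile(p))
      data.frame(value = v, fwhm_mm = m$fwhm,
                 penumbra_left = m$penumbra_left,
                 penumbra_right = m$penumbra_right,
                 field_center = (m$edge50_left + m$edge50_right) / 2,
                 peak = .conv_peak(p, source_norm),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(value = v, fwhm_mm = NA_real_, penumbra_left = NA_real_,
                 penumbra_right = NA_real_, field_center = NA_real_,
                 peak = NA_real_, error = conditionMessage(e))
    })
    out
  })
  rows <- do.call(rbind, rows)
  ok <- is.na(rows$error)
  monotone <- function(x) {
    x <- x[ok]
    if (length(x) < 2L) return(NA)
    if (all(diff(x) >= 0)) return("non-decreasing")
    if (all(diff(x) <= 0)) return("non-increasing")
    "non-monotone"
  }
  .study_result(rows, config,
                extra = list(parameter = parameter,
                             monotonicity = list(fwhm = monotone(rows$fwhm_mm),
                                                 peak = monotone(rows$peak))))
}

#' Misalignment study
#'
#' Evaluates every combination of source center offset and aperture lateral
#' offset (applied to all apertures) and reports the resulting profile
#' asymmetry: penumbra difference and field-center shift.
#'
#' @param config A [run_config()].
#' @param source_offsets,aperture_offsets Offset values (mm), non-empty.
#' @return A `"study_result"` with one row per combination.
#' @export
misalignment_study <- function(config, source_offsets, aperture_offsets) {
  stopifnot(inherits(config, "run_config"))
  if (length(source_offsets) < 1L || length(aperture_offsets) < 1L)
    stop("offset lists must be non-empty")
  combos <- expand.grid(source_offset = source_offsets,
                        aperture_offset = aperture_offsets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    so <- combos$source_offset[i]; ao <- combos$aperture_offset[i]
    cfg <- config
    cfg$source$center_offset <- so
    cfg$apertures <- lapply(cfg$apertures, function(ap)
      aperture(ap$radius, ap$height, ao))
    p <- config_profile(cfg)
    m <- profile_metrics(normalize_profile(p))
    data.frame(source_offset = so, aperture_offset = ao,
               fwhm_mm = m$fwhm,
               penumbra_left = m$penumbra_left,
               penumbra_right = m$penumbra_right,
               asymmetry = m$penumbra_left - m$penumbra_right,
               field_center = (m$edge50_left + m$edge50_right) / 2)
  })
  .study_result(do.call(rbind, rows), config)
}

#' Write a study result to CSV + JSON
#'
#' @param study A `"study_result"`.
#' @param csv_path Path for the rows table.
#' @param json_path Optional path for a JSON summary (rows + provenance).
#' @export
write_study <- function(study, csv_path, json_path = NULL) {
  stopifnot(inherits(study, "study_result"))
  utils::write.csv(study$rows, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    summary <- list(rows = study$rows,
                    timestamp = study$provenance$timestamp)
    if (!is.null(study$monotonicity)) summary$monotonicity <- study$monotonicity
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}
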