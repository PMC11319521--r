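#' Oracle result container
#'
#' @param positions Grid (mm).
#' @param values Transmitted fraction of the source at each position.
#' @param standard_errors Binomial standard errors (Monte Carlo only).
#' @param sample_count Sample count (Monte Carlo only).
#' @param seed RNG seed (Monte Carlo only).
#' @return An object of class `"oracle_result"`.
#' @export
oracle_result <- function(positions, values, standard_errors = NULL,
                          sample_count = NULL, seed = NULL) {
  if (!is.null(standard_errors)) {
    stopifnot(length(standard_errors) == length(values))
    if (any(standard_errors < 0)) stop("standard_errors must be >= 0")
  }
  if (!is.null(sample_count) && sample_count <= 0)
    stop("sample_count must be > 0")
  structure(list(positions = positions, values = values,
                 standard_errors = standard_errors,
                 sample_count = sample_count, seed = seed),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  cat(sprintf("Oracle result: %d points, peak %.6g%s\n",
              length(x$positions), max(x$values),
              if (!is.null(x$sample_count))
                sprintf(" (MC, %g samples, seed %s)", x$sample_count,
                        format(x$seed)) else " (closed form)"))
  invisible(x)
}

#' Closed-form single-aperture profile for a Gaussian source
#'
#' Independent analytic validation of the projection integration: for one
#' circular aperture the slice-membership condition is linear in the slice
#' position, so the integral over a Gaussian spot collapses to a difference
#' of normal CDFs,
#' `value(r) = Phi((M Ra - r)/((M-1) sigma)) - Phi((-M Ra - r)/((M-1) sigma))`
#' for a centered system with magnification `M`. Aperture and source offsets
#' are handled by the general linear-inequality form. At `Ha = 0` (`M = 1`)
#' the geometry degenerates and the exact top-hat of the aperture is
#' returned.
#'
#' @param src A [gaussian_source()].
#' @param ap A single [aperture()].
#' @param geom A [beamline()].
#' @param grid Optional evaluation grid; defaults to the beamline grid.
#' @return An [oracle_result()] whose values are transmitted source
#'   fractions in `[0, 1]`.
#' @export
closed_form_single_aperture <- function(src, ap, geom, grid = NULL) {
  stopifnot(inherits(src, "source_model"), inherits(ap, "aperture"))
  if (src$kind != "gaussian")
    stop("closed form requires a gaussian source model")
  r <- if (is.null(grid)) grid_points(geom) else grid
  M <- magnification(geom, ap)
  if (ap$height == 0) {
    vals <- as.numeric(r >= ap$offset - ap$radius & r <= ap$offset + ap$radius)
    return(oracle_result(r, vals))
  }
  # slice r0 illuminates r  iff  (M(c-Ra)-r)/(M-1) <= r0 <= (M(c+Ra)-r)/(M-1)
  hi <- (M * (ap$offset + ap$radius) - r) / (M - 1)
  lo <- (M * (ap$offset - ap$radius) - r) / (M - 1)
  mu <- src$center_offset; s <- src$sigma
  vals <- stats::pnorm((hi - mu) / s) - stats::pnorm((lo - mu) / s)
  oracle_result(r, pmax(vals, 0))
}

#' Monte-Carlo ray-sampling oracle
#'
#' Independent geometric-transport check: source positions are drawn from
#' the (untruncated) source distribution; for each treatment-plane grid
#' point the straight ray from the sampled source position to that point is
#' tested against every aperture (`|x(Ha) - offset| <= Ra`, with
#' `x(h) = r0 h/Hbeam + r (1 - h/Hbeam)`). The value at a grid point is the
#' pass fraction, with its binomial standard error. One sample set is drawn
#' and reused across grid points; results are reproducible for a fixed seed.
#'
#' @param src A [gaussian_source()] or [tabulated_source()].
#' @param apertures A list of [aperture()] objects.
#' @param geom A [beamline()].
#' @param grid Optional evaluation grid; defaults to the beamline grid.
#' @param samples Number of rays (>= 1e4). Default 1e6.
#' @param seed RNG seed (integer).
#' @return An [oracle_result()] with values, standard errors, sample count
#'   and seed.
#' @export
mc_ray_oracle <- function(src, apertures, geom, grid = NULL,
                          samples = 1e6, seed = 1L) {
  stopifnot(inherits(src, "source_model"))
  apertures <- .as_aperture_list(apertures)
  if (samples < 1e4) stop("samples must be >= 1e4")
  r <- if (is.null(grid)) grid_points(geom) else grid
  set.seed(seed)
  r0 <- if (src$kind == "gaussian") {
    stats::rnorm(samples, mean = src$center_offset, sd = src$sigma)
  } else {
    .sample_tabulated(src, samples)
  }
  Hb <- geom$source_height
  a <- vapply(apertures, function(ap) ap$height / Hb, numeric(1))
  b <- 1 - a
  Ra <- vapply(apertures, function(ap) ap$radius, numeric(1))
  cc <- vapply(apertures, function(ap) ap$offset, numeric(1))
  vals <- numeric(length(r)); ses <- numeric(length(r))
  for (j in seq_along(r)) {
    pass <- rep(TRUE, samples)
    for (k in seq_along(a))
      pass <- pass & (abs(a[k] * r0 + b[k] * r[j] - cc[k]) <= Ra[k])
    p <- mean(pass)
    vals[j] <- p
    ses[j] <- sqrt(p * (1 - p) / samples)
  }
  oracle_result(r, vals, standard_errors = ses, sample_count = samples,
                seed = seed)
}

# exact inverse-CDF sampling of a piecewise-linear (trapezoid) density:
# within each table segment the quadratic cumulative is inverted analytically
.sample_tabulated <- function(src, n) {
  x <- src$positions + src$center_offset
  y <- pmax(src$intensities, 0)
  seg_w <- diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2
  cw <- c(0, cumsum(seg_w))
  total <- cw[length(cw)]
  if (total <= 0) stop("tabulated source has zero total intensity")
  u <- stats::runif(n) * total
  i <- findInterval(u, cw, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg_w))
  x0 <- x[i]; dx <- x[i + 1L] - x0
  y0 <- y[i]; dy <- y[i + 1L] - y0
  a <- (u - cw[i]) / dx                       # area to cover within segment
  lin <- abs(dy) < 1e-12 * (y0 + 1e-300)
  t <- ifelse(lin, a / pmax(y0, 1e-300),
              (-y0 + sqrt(pmax(y0^2 + 2 * dy * a, 0))) / ifelse(dy == 0, 1, dy))
  x0 + pmin(pmax(t, 0), 1) * dx
}

#' Agreement between integrator and oracle
#'
#' Compares a projection-integrated profile (expressed as transmitted source
#' fraction, `values / source_integral`) with an oracle on the same grid.
#' For a Monte-Carlo oracle, counts grid points whose discrepancy exceeds
#' `z` binomial standard errors (points with zero SE and zero discrepancy
#' count as agreeing).
#'
#' @param p A [beam_profile()] from [integrate_profile()].
#' @param orc An [oracle_result()] on the same grid.
#' @param z SE multiple for the MC band. Default 3.
#' @return A list with `max_abs_diff`, and for MC oracles `n_outside`,
#'   `fraction_outside`.
#' @export
oracle_agreement <- function(p, orc, z = 3) {
  stopifnot(inherits(p, "beam_profile"), inherits(orc, "oracle_result"))
  if (length(p$positions) != length(orc$positions) ||
      max(abs(p$positions - orc$positions)) > 1e-9)
    stop("profile and oracle grids differ")
  if (!is.finite(p$source_integral) || p$source_integral <= 0)
    stop("profile lacks a source_integral; run integrate_profile() first")
  trans <- p$values / p$source_integral
  d <- trans - orc$values
  out <- list(max_abs_diff = max(abs(d)))
  if (!is.null(orc$standard_errors)) {
    se <- orc$standard_errors
    outside <- abs(d) > z * se
    outside[se == 0 & abs(d) == 0] <- FALSE
    out$n_outside <- sum(outside)
    out$fraction_outside <- mean(outside)
  }
  out
}

#' Write an oracle result to CSV
#'
#' Same two-column dialect as [write_profile_csv()], with an extra
#' `standard_error` column for Monte-Carlo results.
#'
#' @param orc An [oracle_result()].
#' @param path Output path.
#' @export
write_oracle_csv <- function(orc, path) {
  stopifnot(inherits(orc, "oracle_result"))
  if (is.null(orc$standard_errors)) {
    lines <- c("r_mm,value",
               sprintf("%.9g,%.9g", orc$positions, orc$values))
  } else {
    lines <- c("r_mm,value,standard_error",
               sprintf("%.9g,%.9g,%.9g", orc$positions, orc$values,
                       orc$standard_errors))
  }
  writeLines(lines, path)
  invisible(path)
}
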