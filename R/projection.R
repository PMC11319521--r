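#' Beam profile container
#'
#' Integrated intensity versus signed position on the treatment plane.
#' Positions must form a strictly increasing, uniformly spaced grid.
#'
#' @param positions Grid of treatment-plane coordinates (mm).
#' @param values Non-negative intensities (arbitrary units).
#' @param normalized Logical: values are scaled to unit peak.
#' @param source_integral Total source intensity (sum of slice intensities
#'   times slice step); used to express values as transmitted fractions.
#' @return An object of class `"beam_profile"`.
#' @export
beam_profile <- function(positions, values, normalized = FALSE,
                         source_integral = NA_real_) {
  stopifnot(is.numeric(positions), is.numeric(values),
            length(positions) == length(values), length(positions) >= 2L)
  d <- diff(positions)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * max(d)) stop("positions must be uniformly spaced")
  if (any(values < -1e-12)) stop("profile values must be >= 0")
  structure(list(positions = positions, values = pmax(values, 0),
                 normalized = isTRUE(normalized),
                 source_integral = source_integral),
            class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf("Beam profile: %d points on [%g, %g] mm (step %g mm), peak %.6g%s\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$positions[2] - x$positions[1], max(x$values),
              if (x$normalized) " [normalized]" else ""))
  invisible(x)
}

#' @export
plot.beam_profile <- function(x, ...) {
  graphics::plot(x$positions, x$values, type = "l",
                 xlab = "position at treatment plane (mm)",
                 ylab = if (x$normalized) "relative intensity" else "intensity",
                 ...)
  invisible(x)
}

#' @export
as.data.frame.beam_profile <- function(x, ...) {
  data.frame(r_mm = x$positions, intensity = x$values)
}

#' Contribution of one slice through the collimation stack
#'
#' Projects a single point-source slice through every aperture and
#' intersects the per-aperture intervals. The slice illuminates the
#' resulting interval uniformly with its own intensity; an empty interval
#' contributes nothing.
#'
#' @param slice A list or one-row data.frame with fields `r0` and `intensity`.
#' @param apertures A list of [aperture()] objects (or a single one).
#' @param geom A [beamline()].
#' @return A list with components `interval` ([field_interval()]) and
#'   `intensity`.
#' @export
slice_contribution <- function(slice, apertures, geom) {
  apertures <- .as_aperture_list(apertures)
  ivs <- lapply(apertures, function(ap) project_edges(slice$r0, ap, geom))
  list(interval = intersect_intervals(ivs), intensity = slice$intensity)
}

.as_aperture_list <- function(apertures) {
  if (inherits(apertures, "aperture")) apertures <- list(apertures)
  if (!is.list(apertures) || length(apertures) == 0L ||
      !all(vapply(apertures, inherits, logical(1), "aperture")))
    stop("apertures must be a non-empty list of aperture objects")
  apertures
}

#' Integrate slice contributions into the treatment-plane profile
#'
#' The core projection-integration step: every source slice is projected
#' through the aperture stack onto the treatment plane; at each grid point
#' the profile is the sum over slices of the slice intensity times the
#' indicator of its illuminated interval, times the slice step, so the
#' result approximates the integral of the clipped source distribution.
#' Interval membership is closed on both ends.
#'
#' @param src A [gaussian_source()] or [tabulated_source()].
#' @param apertures A list of [aperture()] objects (or a single one).
#' @param geom A [beamline()]; its grid defines the profile positions.
#' @return A [beam_profile()] (unnormalized). Its `source_integral` field
#'   holds the total slice intensity times slice step, so
#'   `values / source_integral` is the transmitted fraction of the source.
#' @examples
#' geom <- beamline(457, -12, 12)
#' p <- integrate_profile(gaussian_source(1.5), aperture(0.9, 251.35), geom)
#' @export
integrate_profile <- function(src, apertures, geom) {
  apertures <- .as_aperture_list(apertures)
  slices <- slice_source(src)
  iv <- intersect_intervals(
    lapply(apertures, function(ap) project_edges(slices$r0, ap, geom)))
  r <- grid_points(geom)
  keep <- !iv$empty & slices$intensity > 0
  L <- iv$left[keep]; R <- iv$right[keep]; I <- slices$intensity[keep]
  values <- vapply(r, function(rj) sum(I[L <= rj & rj <= R]), numeric(1))
  values <- values * src$slice_step
  if (length(I) > 0L && all(values == 0))
    warning("evaluation grid excludes the entire illuminated field; profile is all zero")
  beam_profile(r, values,
               source_integral = sum(slices$intensity) * src$slice_step)
}

#' Orthogonal-plane profiles for rectangular fields
#'
#' Rectangular fields are handled by computing the two orthogonal planes
#' independently, each with its own aperture half-widths, using the same 1D
#' projection integration.
#'
#' @param src A source model (shared by both planes).
#' @param x_apertures,y_apertures Aperture lists for the two planes.
#' @param geom A [beamline()].
#' @return A list with components `x` and `y`, each a [beam_profile()].
#' @export
rectangular_profile <- function(src, x_apertures, y_apertures, geom) {
  list(x = integrate_profile(src, x_apertures, geom),
       y = integrate_profile(src, y_apertures, geom))
}

#' Two-dimensional pixel-based projection
#'
#' Divides an isotropic Gaussian focal spot into 2D pixels and accumulates,
#' for every treatment-plane pixel, the intensity of all source pixels whose
#' connecting ray passes inside every circular aperture (point-in-disc test
#' at each aperture height, the ray interpolated linearly between source and
#' target). This is the radial generalization of the 1D slab model; the two
#' agree on axis location and scale but differ in edge shape because a disc
#' and a slab weight the off-axis source differently.
#'
#' @param src A [gaussian_source()] (isotropic 2D interpretation).
#' @param apertures A list of [aperture()] objects.
#' @param geom A [beamline()]; its 1D grid bounds the target extent in both
#'   axes unless `target_extent` is given.
#' @param source_pixel Source-plane pixel size (mm). Default 0.1.
#' @param target_pixel Target-plane pixel size (mm). Default 0.1.
#' @param target_extent Half-extent of the square target grid (mm);
#'   defaults to `max(abs(grid))` of the beamline.
#' @return An object of class `"beam_map"`: list with `x`, `y` (pixel center
#'   coordinates), `values` (matrix, `values[i, j]` at `x[i], y[j]`) and
#'   `source_integral`.
#' @export
integrate_profile_2d <- function(src, apertures, geom, source_pixel = 0.1,
                                 target_pixel = 0.1, target_extent = NULL) {
  stopifnot(inherits(src, "source_model"))
  if (src$kind != "gaussian")
    stop("2D mode requires a gaussian source model")
  apertures <- .as_aperture_list(apertures)
  if (source_pixel > 0.5 || target_pixel > 0.5)
    warning("pixel grids coarser than 0.5 mm poorly resolve small fields")
  if (is.null(target_extent))
    target_extent <- max(abs(c(geom$grid_min, geom$grid_max)))
  half <- src$truncation * src$sigma
  ns <- floor(half / source_pixel)
  s <- source_pixel * (-ns:ns)
  sx <- s + src$center_offset
  nt <- floor(target_extent / target_pixel)
  tx <- target_pixel * (-nt:nt)
  ty <- tx
  Hb <- geom$source_height
  wx <- exp(-(s^2) / (2 * src$sigma^2))  # separable Gaussian pixel weights
  acc <- matrix(0, nrow = length(tx), ncol = length(ty))
  # per-aperture ray coefficients: position at height h is a*s + b*t
  a <- vapply(apertures, function(ap) ap$height / Hb, numeric(1))
  b <- 1 - a
  Ra <- vapply(apertures, function(ap) ap$radius, numeric(1))
  cc <- vapply(apertures, function(ap) ap$offset, numeric(1))
  tx2 <- tx; ty2 <- ty
  for (i in seq_along(sx)) {
    for (j in seq_along(s)) {
      w <- wx[i] * wx[j]
      ok <- NULL
      for (k in seq_along(a)) {
        dx <- a[k] * sx[i] + b[k] * tx2 - cc[k]
        dy <- a[k] * (s[j] + 0) + b[k] * ty2
        m <- outer(dx^2, dy^2, "+") <= Ra[k]^2
        ok <- if (is.null(ok)) m else ok & m
        if (!any(ok)) break
      }
      if (any(ok)) acc[ok] <- acc[ok] + w
    }
  }
  acc <- acc * source_pixel^2
  structure(list(x = tx, y = ty, values = acc,
                 source_integral = sum(outer(wx, wx)) * source_pixel^2),
            class = "beam_map")
}

#' @export
print.beam_map <- function(x, ...) {
  cat(sprintf("Beam map: %d x %d pixels on [%g, %g] mm, peak %.6g\n",
              length(x$x), length(x$y), min(x$x), max(x$x), max(x$values)))
  invisible(x)
}

#' Extract a row of a 2D beam map as a profile
#'
#' @param map A `"beam_map"`.
#' @param y Row coordinate (mm); nearest pixel row is used. Default 0.
#' @return A [beam_profile()].
#' @export
map_central_row <- function(map, y = 0) {
  j <- which.min(abs(map$y - y))
  beam_profile(map$x, map$values[, j], source_integral = map$source_integral)
}
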