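#' Beamline geometry
#'
#' Describes one beamline: the height of the focal spot (source) above the
#' treatment plane, and the evaluation grid on that plane. All lengths are in
#' millimetres; heights are measured from the treatment plane upward, so the
#' source sits at `source_height` and the treatment plane at 0.
#'
#' @param source_height Distance of the beam spot from the treatment plane
#'   (mm). Must be positive.
#' @param grid_min,grid_max Extent of the evaluation grid on the treatment
#'   plane (mm, signed coordinates).
#' @param grid_step Grid resolution (mm). Default 0.1.
#' @return An object of class `"beamline"`.
#' @examples
#' geom <- beamline(457, -12, 12)
#' @export
beamline <- function(source_height, grid_min, grid_max, grid_step = 0.1) {
  stopifnot(is.numeric(source_height), length(source_height) == 1L,
            is.numeric(grid_min), is.numeric(grid_max), is.numeric(grid_step))
  if (source_height <= 0) stop("source_height must be > 0")
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (grid_min >= grid_max) stop("grid_min must be < grid_max")
  structure(list(source_height = source_height,
                 grid_min = grid_min, grid_max = grid_max,
                 grid_step = grid_step),
            class = "beamline")
}

#' @export
print.beamline <- function(x, ...) {
  cat(sprintf("Beamline: source at %g mm; grid [%g, %g] mm, step %g mm\n",
              x$source_height, x$grid_min, x$grid_max, x$grid_step))
  invisible(x)
}

#' Evaluation grid of a beamline
#'
#' @param geom A [beamline()].
#' @return Numeric vector of treatment-plane coordinates (mm).
#' @export
grid_points <- function(geom) {
  n <- round((geom$grid_max - geom$grid_min) / geom$grid_step)
  # a grid symmetric about zero is built by mirroring, so that position pairs
  # (-r, r) are bitwise negatives and symmetric systems yield exactly
  # symmetric profiles even when slice edges land on grid points
  if (abs(geom$grid_min + geom$grid_max) < 1e-12 && n %% 2 == 0) {
    pos <- geom$grid_step * seq_len(n %/% 2)
    return(c(-rev(pos), 0, pos))
  }
  geom$grid_min + geom$grid_step * (0:n)
}

#' Circular collimation aperture
#'
#' One level of collimation: a circular opening of given radius at a given
#' height above the treatment plane, optionally displaced laterally.
#'
#' @param radius Opening radius (mm), positive.
#' @param height Height of the aperture plane above the treatment plane (mm),
#'   non-negative and below the source of any beamline it is used with.
#' @param offset Lateral displacement of the aperture center (mm). Default 0.
#' @return An object of class `"aperture"`.
#' @examples
#' aperture(radius = 0.9, height = 251.35)
#' @export
aperture <- function(radius, height, offset = 0) {
  stopifnot(is.numeric(radius), is.numeric(height), is.numeric(offset))
  if (radius <= 0) stop("aperture radius must be > 0")
  if (height < 0) stop("aperture height must be >= 0")
  structure(list(radius = radius, height = height, offset = offset),
            class = "aperture")
}

#' @export
print.aperture <- function(x, ...) {
  cat(sprintf("Aperture: radius %g mm at height %g mm (offset %g mm)\n",
              x$radius, x$height, x$offset))
  invisible(x)
}

#' Illuminated field interval on the treatment plane
#'
#' Signed interval `[left, right]` of treatment-plane coordinates illuminated
#' by one source slice. Stored with signed coordinates throughout; a
#' positive-magnitude "left edge" as used in reporting is simply `-left`.
#' `left` and `right` may be vectors (one interval per slice).
#'
#' @param left,right Signed interval bounds (mm).
#' @return An object of class `"field_interval"` with fields `left`, `right`
#'   and logical `empty` (`left > right`).
#' @export
field_interval <- function(left, right) {
  stopifnot(is.numeric(left), is.numeric(right), length(left) == length(right))
  structure(list(left = left, right = right, empty = left > right),
            class = "field_interval")
}

#' @export
print.field_interval <- function(x, ...) {
  if (length(x$left) == 1L) {
    if (x$empty) cat("Field interval: empty\n")
    else cat(sprintf("Field interval: [%g, %g] mm\n", x$left, x$right))
  } else {
    cat(sprintf("Field intervals: %d slices (%d empty)\n",
                length(x$left), sum(x$empty)))
  }
  invisible(x)
}

#' Projection magnification of an aperture level
#'
#' The factor `Hbeam / (Hbeam - Ha)` by which structure at the aperture
#' height projects onto the treatment plane from a point source at the
#' beamline source height. Always >= 1 for apertures between source and
#' treatment plane.
#'
#' @param geom A [beamline()].
#' @param ap An [aperture()].
#' @return Dimensionless magnification ratio.
#' @examples
#' magnification(beamline(457, -12, 12), aperture(0.9, 251.35)) # 2.2222
#' @export
magnification <- function(geom, ap) {
  if (ap$height >= geom$source_height)
    stop("invalid geometry: aperture height (", ap$height,
         " mm) must be below the source height (", geom$source_height, " mm)")
  geom$source_height / (geom$source_height - ap$height)
}

#' Project a source slice through one aperture
#'
#' Computes the illuminated interval on the treatment plane for a point
#' source at lateral position `r0` (at the source height) shining through a
#' single circular aperture. With magnification `M` and aperture center `c`,
#' the signed edges are
#' `left = r0 + M (c - Ra - r0)` and `right = r0 + M (c + Ra - r0)`,
#' i.e. the straight-line (pinhole) projection of the two physical aperture
#' edges from the slice position. Vectorized over `r0`.
#'
#' @param r0 Slice position(s) at the source plane (mm, signed).
#' @param ap An [aperture()].
#' @param geom A [beamline()].
#' @return A [field_interval()] (vector fields if `r0` is a vector).
#' @examples
#' geom <- beamline(457, -12, 12)
#' project_edges(0, aperture(0.9, 251.35), geom)     # [-2, 2]
#' project_edges(0.5, aperture(0.9, 251.35), geom)   # [-2.6111, 1.3889]
#' @export
project_edges <- function(r0, ap, geom) {
  M <- magnification(geom, ap)
  field_interval(left  = r0 + M * (ap$offset - ap$radius - r0),
                 right = r0 + M * (ap$offset + ap$radius - r0))
}

#' Intersect illuminated intervals across collimation levels
#'
#' With several collimation levels the field seen by one slice is bounded by
#' the innermost edge on each side: the intersection takes the maximum of the
#' left edges and the minimum of the right edges. An empty result means the
#' slice is fully blocked. Intervals with vector fields are intersected
#' component-wise.
#'
#' @param intervals A list of [field_interval()] objects (all the same
#'   length), or a single one.
#' @return A [field_interval()].
#' @export
intersect_intervals <- function(intervals) {
  if (inherits(intervals, "field_interval")) intervals <- list(intervals)
  if (!is.list(intervals) || length(intervals) == 0L)
    stop("intersect_intervals() needs at least one field_interval")
  eff_l <- lapply(intervals, function(iv) ifelse(iv$empty, Inf, iv$left))
  eff_r <- lapply(intervals, function(iv) ifelse(iv$empty, -Inf, iv$right))
  field_interval(left = do.call(pmax, eff_l), right = do.call(pmin, eff_r))
}

#' Aperture height tangent to the nominal field cone
#'
#' For a point source, an aperture of diameter `d` produces the nominal field
#' `F` exactly when it is tangent to the cone connecting the source to the
#' field edges, at height `Ha = Hbeam (1 - d/F)`. Used to reconstruct
#' collimator geometry when only diameters and the design field size are
#' known. `tangent_diameter()` is the inverse: the tangent diameter at a
#' given height.
#'
#' @param diameter Aperture diameter (mm), with `0 < diameter <= nominal_field`.
#' @param nominal_field Design field diameter at the treatment plane (mm).
#' @param geom A [beamline()].
#' @return Height (mm) for `cone_tangent_height()`; diameter (mm) for
#'   `tangent_diameter()`.
#' @examples
#' geom <- beamline(457, -12, 12)
#' cone_tangent_height(1.8, 4, geom)   # 251.35
#' cone_tangent_height(2.3, 4, geom)   # 194.225
#' @export
cone_tangent_height <- function(diameter, nominal_field, geom) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (diameter > nominal_field)
    stop("no tangent solution: diameter (", diameter,
         " mm) exceeds the nominal field (", nominal_field, " mm)")
  geom$source_height * (1 - diameter / nominal_field)
}

#' @rdname cone_tangent_height
#' @param height Aperture height above the treatment plane (mm).
#' @export
tangent_diameter <- function(height, nominal_field, geom) {
  if (height < 0 || height >= geom$source_height)
    stop("height must lie in [0, source_height)")
  nominal_field * (geom$source_height - height) / geom$source_height
}
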