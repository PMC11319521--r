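#' Normalize a profile to unit peak
#'
#' @param p A [beam_profile()] with a positive peak.
#' @return The profile scaled to peak 1, with the `normalized` flag set.
#'   Idempotent.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "beam_profile"))
  pk <- max(p$values)
  if (pk <= 0) stop("cannot normalize an all-zero profile")
  beam_profile(p$positions, p$values / pk, normalized = TRUE,
               source_integral = p$source_integral)
}

# Outermost crossing of `level` scanned from the grid boundary inward on the
# requested side, located by linear interpolation between bracketing points.
.edge_crossing <- function(p, level, side) {
  v <- p$values; r <- p$positions
  idx <- which(v >= level)
  if (length(idx) == 0L)
    stop(sprintf("undefined metric: profile never reaches %.3g on the %s side",
                 level, side))
  i <- if (side == "left") min(idx) else max(idx)
  if ((side == "left" && i == 1L) || (side == "right" && i == length(v)))
    stop(sprintf("undefined metric: level %.3g is not crossed on the %s side (grid too narrow?)",
                 level, side))
  j <- if (side == "left") i - 1L else i + 1L
  # v[j] < level <= v[i]
  r[j] + (level - v[j]) / (v[i] - v[j]) * (r[i] - r[j])
}

#' Full width at half maximum of a profile
#'
#' Distance between the outermost crossings of 50% of the profile peak,
#' scanned from the grid boundaries inward and located by linear
#' interpolation. Invariant under positive rescaling of the intensities.
#'
#' @param p A [beam_profile()] with positive peak.
#' @return FWHM (mm).
#' @export
profile_fwhm <- function(p) {
  stopifnot(inherits(p, "beam_profile"))
  level <- 0.5 * max(p$values)
  .edge_crossing(p, level, "right") - .edge_crossing(p, level, "left")
}

#' 20-80% penumbra of a profile edge
#'
#' Lateral distance over which the profile rises from 20% to 80% of its
#' peak on the requested side. Thresholds are relative to the actual profile
#' peak; crossings are the outermost ones, scanned from outside inward.
#'
#' @param p A [beam_profile()] with positive peak.
#' @param side `"left"` or `"right"`.
#' @return Penumbra width (mm), non-negative.
#' @export
profile_penumbra <- function(p, side = c("left", "right")) {
  stopifnot(inherits(p, "beam_profile"))
  side <- match.arg(side)
  pk <- max(p$values)
  abs(.edge_crossing(p, 0.8 * pk, side) - .edge_crossing(p, 0.2 * pk, side))
}

#' All figures of merit of a profile
#'
#' @param p A [beam_profile()] with positive peak.
#' @return An object of class `"profile_metrics"`: list with `fwhm`,
#'   `penumbra_left`, `penumbra_right`, `peak`, `edge50_left`,
#'   `edge50_right` (all lengths in mm).
#' @export
profile_metrics <- function(p) {
  stopifnot(inherits(p, "beam_profile"))
  pk <- max(p$values)
  if (pk <= 0) stop("profile has no positive peak")
  e50l <- .edge_crossing(p, 0.5 * pk, "left")
  e50r <- .edge_crossing(p, 0.5 * pk, "right")
  structure(list(fwhm = e50r - e50l,
                 penumbra_left = profile_penumbra(p, "left"),
                 penumbra_right = profile_penumbra(p, "right"),
                 peak = pk,
                 edge50_left = e50l, edge50_right = e50r),
            class = "profile_metrics")
}

#' @export
print.profile_metrics <- function(x, ...) {
  cat(sprintf("FWHM %.3f mm | penumbra L %.3f mm, R %.3f mm | peak %.6g | 50%% edges [%.3f, %.3f] mm\n",
              x$fwhm, x$penumbra_left, x$penumbra_right, x$peak,
              x$edge50_left, x$edge50_right))
  invisible(x)
}

#' Peak ratio of two unnormalized profiles
#'
#' Dose-rate surrogate comparison: the ratio of the raw peak intensities of
#' two profiles computed under the same source normalization convention.
#'
#' @param a,b Unnormalized [beam_profile()] objects.
#' @return `max(a) / max(b)`.
#' @export
peak_ratio <- function(a, b) {
  stopifnot(inherits(a, "beam_profile"), inherits(b, "beam_profile"))
  if (a$normalized || b$normalized)
    warning("peak_ratio on normalized profiles is always ~1; use raw profiles")
  pb <- max(b$values)
  if (pb <= 0) stop("denominator profile has zero peak")
  max(a$values) / pb
}

#' Emulate detector volume averaging
#'
#' Convolves the profile with a renormalized top-hat window of the detector
#' diameter (moving average), emulating the volume averaging of a detector
#' of finite active size: penumbras widen while straight edges keep their
#' 50% crossing. Window cells at the ends receive fractional weights so the
#' effective width is exactly `detector_diameter`. Boundary samples are
#' padded by edge replication, so constant profiles are unchanged.
#'
#' @param p A [beam_profile()].
#' @param detector_diameter Window width (mm), positive and smaller than the
#'   grid span.
#' @return The averaged [beam_profile()].
#' @export
detector_convolve <- function(p, detector_diameter) {
  stopifnot(inherits(p, "beam_profile"))
  if (detector_diameter <= 0) stop("detector_diameter must be > 0")
  h <- p$positions[2] - p$positions[1]
  span <- max(p$positions) - min(p$positions)
  if (detector_diameter > span)
    stop("detector window wider than the profile grid span")
  half <- detector_diameter / 2
  m <- ceiling(half / h - 0.5 + 1e-12)
  off <- -m:m
  w <- pmax(pmin(half, (off + 0.5) * h) - pmax(-half, (off - 0.5) * h), 0)
  w <- w / sum(w)
  n <- length(p$values)
  padded <- c(rep(p$values[1], m), p$values, rep(p$values[n], m))
  sm <- vapply(seq_len(n), function(i) sum(w * padded[i:(i + 2 * m)]),
               numeric(1))
  beam_profile(p$positions, sm, normalized = FALSE,
               source_integral = p$source_integral)
}

#' Compare beam profiles
#'
#' Normalizes both profiles, re-interpolates the second onto the first's
#' grid over their common range, and reports per-profile metrics, the FWHM
#' percent difference relative to the first (reference) profile, and the
#' max/mean absolute normalized difference.
#'
#' @param a Reference [beam_profile()] (e.g. a measurement).
#' @param b Comparison [beam_profile()].
#' @return An object of class `"profile_comparison"`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "beam_profile"), inherits(b, "beam_profile"))
  an <- normalize_profile(a); bn <- normalize_profile(b)
  lo <- max(min(a$positions), min(b$positions))
  hi <- min(max(a$positions), max(b$positions))
  if (lo >= hi) stop("profiles do not overlap in position")
  sel <- an$positions >= lo & an$positions <= hi
  if (sum(sel) < 2L) stop("fewer than 2 common grid points")
  bi <- stats::approx(bn$positions, bn$values, xout = an$positions[sel])$y
  d <- abs(an$values[sel] - bi)
  ma <- profile_metrics(an); mb <- profile_metrics(bn)
  structure(list(
    metrics_a = ma, metrics_b = mb,
    fwhm_pct_diff = abs(ma$fwhm - mb$fwhm) / ma$fwhm * 100,
    max_abs_diff = max(d), mean_abs_diff = mean(d),
    common_range = c(lo, hi)), class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Profile comparison (a = reference)\n  a: "); print(x$metrics_a)
  cat("  b: "); print(x$metrics_b)
  cat(sprintf("  FWHM difference: %.3f%% of reference\n", x$fwhm_pct_diff))
  cat(sprintf("  normalized difference on common grid: max %.4g, mean %.4g\n",
              x$max_abs_diff, x$mean_abs_diff))
  invisible(x)
}
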