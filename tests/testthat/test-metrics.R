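# helper: synthetic trapezoid profile with exact, known metrics
trapezoid_profile <- function(half_top = 1.5, ramp = 1, step = 0.1, lim = 6) {
  r <- seq(-lim, lim, by = step)
  v <- pmin(1, pmax(0, (half_top + ramp - abs(r)) / ramp))
  beam_profile(r, v)
}

test_that("normalization is idempotent and shape-preserving", {
  p <- trapezoid_profile()
  p$values <- p$values * 3.7
  n <- normalize_profile(p)
  expect_equal(max(n$values), 1.0)
  expect_true(n$normalized)
  n2 <- normalize_profile(n)
  expect_equal(n2$values, n$values)
  # value ratios unchanged at every pair of points
  pos <- p$values > 0
  expect_equal(n$values[pos] / n$values[pos][1],
               p$values[pos] / p$values[pos][1])
  zero <- beam_profile(c(0, 1, 2), c(0, 0, 0))
  expect_error(normalize_profile(zero), "all-zero")
})

test_that("FWHM of ideal and erf-edged profiles is exact", {
  # ideal top-hat of width 4.0 sampled at 0.1 mm (edge samples at the
  # half-maximum, the exact band-limited representation of the edge)
  r <- seq(-6, 6, 0.1)
  th <- beam_profile(r, as.numeric(abs(r) < 2) + 0.5 * (abs(r) == 2))
  expect_equal(profile_fwhm(th), 4.0)
  # symmetric erf edges cross 50% at +/- M Ra once the plateau is reached
  geom <- test_geom()
  p <- integrate_profile(gaussian_source(1.5), exit_ap(), geom)
  expect_equal(profile_fwhm(p), 4.0, tolerance = 1e-2)
  # scale invariance
  p2 <- p; p2$values <- p$values * 123.4
  expect_equal(profile_fwhm(p2), profile_fwhm(p))
  # trapezoid: 50% sits mid-ramp
  expect_equal(profile_fwhm(trapezoid_profile(1.5, 1)), 4.0)
})

test_that("20-80% penumbra matches straight-line and closed-form predictions", {
  # linear ramp of width w rises 20->80% over 0.6 w
  tp <- trapezoid_profile(half_top = 1.5, ramp = 1)
  expect_equal(profile_penumbra(tp, "left"), 0.6)
  expect_equal(profile_penumbra(tp, "right"), 0.6)
  # erf edge of a single aperture. In the sharp-plateau limit the penumbra
  # is 1.6832 * sigma_proj with sigma_proj = sigma * Ha / (Hbeam - Ha);
  # for a small field whose peak (2 Phi(M Ra / sigma_proj) - 1) sits below
  # the open plateau, the 20/80% thresholds refer to that actual peak:
  # pen = sigma_proj * (qnorm(0.8 peak) - qnorm(0.2 peak))
  geom <- test_geom()
  p <- integrate_profile(gaussian_source(1.5), exit_ap(), geom)
  sig <- sigma_from_fwhm(1.5)
  sp <- sig * 251.35 / (457 - 251.35)
  expect_equal((qnorm(0.8) - qnorm(0.2)) * sp, 1.310, tolerance = 1e-3)
  pk <- 2 * pnorm(2 / sp) - 1
  closed <- sp * (qnorm(0.8 * pk) - qnorm(0.2 * pk))
  expect_equal(profile_penumbra(p, "left"), closed, tolerance = 0.01)
  expect_equal(profile_penumbra(p, "right"), closed, tolerance = 0.01)
  # symmetric system: both sides equal within a grid step
  expect_lt(abs(profile_penumbra(p, "left") - profile_penumbra(p, "right")),
            geom$grid_step)
  # scale invariance
  p$values <- p$values * 55
  expect_equal(profile_penumbra(p, "left"), closed, tolerance = 0.01)
})

test_that("metrics error out when a level is never crossed", {
  r <- seq(-1, 1, 0.1)
  flat <- beam_profile(r, rep(1, length(r)))
  expect_error(profile_fwhm(flat), "undefined metric")
  expect_error(profile_penumbra(flat, "left"), "undefined metric")
})

test_that("profile_metrics bundles consistent figures of merit", {
  p <- trapezoid_profile(half_top = 2, ramp = 0.5)
  m <- profile_metrics(p)
  expect_s3_class(m, "profile_metrics")
  expect_equal(m$fwhm, m$edge50_right - m$edge50_left)
  expect_equal(m$fwhm, 4.5)
  expect_equal(m$penumbra_left, 0.3)
  expect_gt(m$edge50_right, m$edge50_left)
  expect_equal(m$peak, 1)
})

test_that("peak ratio compares unnormalized peaks", {
  p <- trapezoid_profile()
  q <- p; q$values <- 2 * p$values
  expect_equal(peak_ratio(p, p), 1.0)
  expect_equal(peak_ratio(p, q), 0.5)
  expect_error(peak_ratio(p, beam_profile(c(0, 1), c(0, 0))), "zero peak")
  # clipping strictly removes intensity: unclipped vs tightly clipped
  geom <- test_geom()
  src <- gaussian_source(1.5)
  open <- integrate_profile(src, exit_ap(), geom)
  clipped <- integrate_profile(src, list(exit_ap(), aperture(0.7, 407)), geom)
  expect_gt(peak_ratio(open, clipped), 1)
})

test_that("detector volume averaging behaves like a top-hat convolution", {
  r <- seq(-6, 6, 0.1)
  step_edge <- beam_profile(r, as.numeric(r <= 2))
  # one-grid-step window: identity
  same <- detector_convolve(step_edge, 0.1)
  expect_equal(same$values, step_edge$values, tolerance = 1e-12)
  # window w turns a sharp edge into a linear ramp: penumbra 0.6 w
  for (w in c(1, 1.5)) {
    sm <- detector_convolve(step_edge, w)
    expect_equal(profile_penumbra(sm, "right"), 0.6 * w, tolerance = 0.02)
  }
  # constant profile unchanged (edge replication padding)
  const <- beam_profile(r, rep(2, length(r)))
  expect_equal(detector_convolve(const, 1.5)$values, const$values)
  expect_error(detector_convolve(step_edge, 20), "wider")
  # volume averaging never sharpens a penumbra
  geom <- test_geom()
  p <- integrate_profile(gaussian_source(1.5), exit_ap(), geom)
  for (w in c(0.5, 1.0, 1.5)) {
    expect_gte(profile_penumbra(detector_convolve(p, w), "left"),
               profile_penumbra(p, "left"))
  }
})

test_that("profile comparison reports reference-relative FWHM differences", {
  # the canonical 25 mm field-size comparison pairs
  mk <- function(fwhm) {
    r <- seq(-20, 20, 0.1)
    beam_profile(r, pmin(1, pmax(0, fwhm / 2 + 0.5 - abs(r))))
  }
  a <- mk(25.56); b <- mk(24.5); c <- mk(24.92)
  expect_equal(compare_profiles(a, b)$fwhm_pct_diff, 4.147, tolerance = 1e-3)
  expect_equal(compare_profiles(a, c)$fwhm_pct_diff, 2.504, tolerance = 1e-3)
  # self comparison is exactly zero
  self <- compare_profiles(a, a)
  expect_equal(self$fwhm_pct_diff, 0)
  expect_equal(self$max_abs_diff, 0)
  expect_equal(self$mean_abs_diff, 0)
  # disjoint grids refuse
  d <- beam_profile(seq(100, 110, 0.1), rep(1, 101))
  expect_error(compare_profiles(a, d), "overlap")
})
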