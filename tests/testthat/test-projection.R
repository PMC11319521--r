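test_that("slice contributions intersect per-aperture intervals", {
  geom <- test_geom()
  sc <- slice_contribution(list(r0 = 0, intensity = 1), exit_ap(), geom)
  expect_equal(c(sc$interval$left, sc$interval$right), c(-2, 2),
               tolerance = 1e-9)
  expect_equal(sc$intensity, 1)
  # a slice blocked by crossed intervals from two offset apertures
  blocked <- slice_contribution(
    list(r0 = 0, intensity = 1),
    list(aperture(0.5, 251.35, offset = 2), aperture(0.5, 407, offset = -2)),
    geom)
  expect_true(blocked$interval$empty)
  # zero-intensity slice keeps its interval but carries nothing
  z <- slice_contribution(list(r0 = 0.3, intensity = 0), exit_ap(), geom)
  expect_false(z$interval$empty)
  expect_equal(z$intensity, 0)
})

test_that("integrated single-aperture profile matches the closed-form edge shape", {
  geom <- test_geom()
  src <- gaussian_source(1.5)
  p <- integrate_profile(src, exit_ap(), geom)
  cf <- closed_form_single_aperture(src, exit_ap(), geom)
  err <- max(abs(p$values / p$source_integral - cf$values)) / max(cf$values)
  expect_lt(err, 1e-3)
})

test_that("a point-like source projects to a top-hat of half-width M*Ra", {
  geom <- test_geom()
  p <- integrate_profile(gaussian_source(0.01), exit_ap(), geom)
  n <- normalize_profile(p)
  inside <- abs(n$positions) <= 2 - 0.1
  outside <- abs(n$positions) >= 2 + 0.1
  expect_true(all(n$values[inside] == 1))
  expect_true(all(n$values[outside] == 0))
  expect_equal(profile_fwhm(n), 4.0, tolerance = 0.1)
})

test_that("the profile is linear in the source intensities", {
  geom <- test_geom(6)
  s1 <- tabulated_source(c(-1, 0, 1), c(0.2, 1, 0.2), slice_step = 0.01)
  s2 <- tabulated_source(c(-1, 0, 1), 2 * c(0.2, 1, 0.2), slice_step = 0.01)
  p1 <- integrate_profile(s1, exit_ap(), geom)
  p2 <- integrate_profile(s2, exit_ap(), geom)
  expect_equal(p2$values, 2 * p1$values)
})

test_that("intensity is conserved up to grid discretization", {
  geom <- test_geom()
  src <- gaussian_source(1.5)
  for (aps in list(list(exit_ap()), list(entrance_ap(), exit_ap()))) {
    p <- integrate_profile(src, aps, geom)
    sl <- slice_source(src)
    iv <- intersect_intervals(lapply(aps, function(a)
      project_edges(sl$r0, a, geom)))
    len <- ifelse(iv$empty, 0, iv$right - iv$left)
    expected <- sum(sl$intensity * len) * src$slice_step
    got <- sum(p$values) * geom$grid_step
    expect_equal(got, expected, tolerance = 5e-3)
  }
})

test_that("adding an aperture never increases the profile anywhere", {
  geom <- test_geom()
  src <- gaussian_source(1.5)
  p1 <- integrate_profile(src, exit_ap(), geom)
  for (extra in list(entrance_ap(), aperture(1.5, 100), aperture(0.6, 300))) {
    p2 <- integrate_profile(src, list(exit_ap(), extra), geom)
    expect_true(all(p2$values <= p1$values + 1e-12))
  }
})

test_that("centered systems give symmetric profiles", {
  geom <- test_geom()
  p <- integrate_profile(gaussian_source(1.5),
                         list(entrance_ap(), exit_ap()), geom)
  expect_lt(max(abs(p$values - rev(p$values))), 1e-9 * max(p$values))
})

test_that("a grid that misses the field yields an all-zero profile with a warning", {
  geom <- beamline(457, 20, 30, 0.1)
  expect_warning(p <- integrate_profile(gaussian_source(1.5), exit_ap(), geom),
                 "excludes")
  expect_true(all(p$values == 0))
})

test_that("orthogonal planes are computed independently for rectangular fields", {
  geom <- test_geom(8)
  src <- gaussian_source(1.5)
  xa <- list(exit_ap()); ya <- list(aperture(3, 251.35))
  rp <- rectangular_profile(src, xa, ya, geom)
  expect_equal(rp$x$values, integrate_profile(src, xa, geom)$values)
  # identical aperture sets give identical planes
  same <- rectangular_profile(src, xa, xa, geom)
  expect_equal(same$x$values, same$y$values)
  # an unconstrained plane is a plateau: no 20% crossing inside the grid
  open <- rectangular_profile(src, xa, list(aperture(500, 251.35)), geom)
  nv <- normalize_profile(open$y)$values
  expect_true(all(nv > 0.99))
})

test_that("profile container enforces its grid and value invariants", {
  expect_error(beam_profile(c(0, 1, 1.5), c(1, 1, 1)), "uniformly")
  expect_error(beam_profile(c(1, 0), c(1, 1)), "increasing")
  expect_error(beam_profile(c(0, 1), c(-1, 1)), ">= 0")
  expect_error(beam_profile(c(0, 1), 1), "length")
})

test_that("2D pixel mode reproduces the exact disc-measure at the center and the system's symmetries", {
  geom <- beamline(457, -6, 6)
  src <- gaussian_source(1.5)
  map <- integrate_profile_2d(src, exit_ap(), geom, source_pixel = 0.05,
                              target_pixel = 0.1, target_extent = 6)
  # center value: Gaussian measure of the acceptance disc |s| <= Ra Hbeam / Ha
  Rlim <- 0.9 * 457 / 251.35
  sig <- sigma_from_fwhm(1.5)
  i0 <- which.min(abs(map$x))
  expect_equal(map$values[i0, i0] / map$source_integral,
               1 - exp(-Rlim^2 / (2 * sig^2)), tolerance = 1e-2)
  # invariant under 90 degree rotation (transpose for a symmetric system)
  expect_lt(max(abs(map$values - t(map$values))), 1e-12 * max(map$values))
  # central row tracks the 1D profile's field size; edge shapes differ
  # because the slab and radial source weightings differ
  row <- map_central_row(map)
  p1 <- integrate_profile(src, exit_ap(), geom)
  expect_lt(abs(profile_fwhm(row) - profile_fwhm(p1)), 0.4)
})

test_that("an off-center aperture shifts the 2D field centroid by M * offset", {
  geom <- beamline(457, -6, 6)
  ap <- aperture(0.9, 251.35, offset = 0.5)
  map <- integrate_profile_2d(gaussian_source(1.5), ap, geom,
                              source_pixel = 0.1, target_pixel = 0.1,
                              target_extent = 6)
  w <- rowSums(map$values)
  centroid <- sum(map$x * w) / sum(w)
  expect_equal(centroid, magnification(geom, ap) * 0.5, tolerance = 1e-2)
  expect_warning(
    integrate_profile_2d(gaussian_source(1.5), ap, geom, source_pixel = 0.6,
                         target_pixel = 0.6, target_extent = 3),
    "coarse")
})
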