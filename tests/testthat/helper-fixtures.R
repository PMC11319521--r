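# Shared small fixtures for the test suite. The canonical single-aperture
# system (exit aperture of the 4 mm collimator alone) has magnification
# 457 / (457 - 251.35) = 2.2222 and projected field half-width 2.0 mm.

test_geom <- function(lim = 12, step = 0.1) beamline(457, -lim, lim, step)

exit_ap <- function(offset = 0) aperture(0.9, 251.35, offset)

entrance_ap <- function(offset = 0) aperture(1.15, 407, offset)

# independent line-plane intersection: ray through (r0, Hbeam) and (e, Ha),
# evaluated at height 0 via explicit slope/intercept (no magnification algebra)
ray_at_plane <- function(r0, e, Hbeam, Ha) {
  slope <- (Hbeam - Ha) / (r0 - e)   # dh/dx along the ray
  r0 - Hbeam / slope
}
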