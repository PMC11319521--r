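# beamproj

Fast synthesis of radiotherapy beam profiles through multi-aperture
collimators from a finite focal spot, for small-field (SRS) collimator
design.

## What it computes

The lateral dose profile of a small photon field at the treatment plane is
set by the geometry of the collimation stack *and* by the finite size of
the X-ray focal spot: for millimetre fields the spot, not the aperture
edge, dominates the 20–80% penumbra. `beamproj` models the spot as an
intensity distribution $S(r_0)$, slices it into elements narrow enough to
act as point sources, and projects each slice through every circular
aperture (radius $R_a$, height $H_a$ above the treatment plane, source at
$H_\mathrm{beam}$). One slice at $r_0$ illuminates the signed interval

```
left  = r0 + M (c − Ra − r0)
right = r0 + M (c + Ra − r0)         M = Hbeam / (Hbeam − Ha)
```

per aperture (center `c`); with several collimation levels the slice sees
the innermost edges (max of lefts, min of rights). The profile is the sum
of slice intensities over all slices whose interval contains each grid
point — a sub-second computation that replaces hours of Monte-Carlo
transport for design iteration. On top of the integrator the package
provides:

* profile analytics: FWHM, per-side 20–80% penumbra, peak dose-rate
  surrogate, detector volume-averaging emulation, profile comparison
  against measured/simulated curves;
* independent validation oracles: a closed-form normal-CDF profile for
  single-aperture systems and a Monte-Carlo ray-sampling transport check;
* design studies: spot-size sweeps, aperture parameter sweeps,
  misalignment (off-center source/aperture) studies;
* rectangular fields (orthogonal planes) and a 2D pixel mode;
* YAML/JSON configurations, CSV/JSON outputs, and a `beamproj` command
  line (`inst/cli/beamproj`) with `profile`, `metrics`, `sweep`,
  `compare`, `oracle` and `fixtures` subcommands.

## Worked example

The bundled `collimator4` fixture is a 4 mm conical SRS collimator
(457 mm source-to-plane distance; entrance/exit aperture diameters
2.3/1.8 mm; aperture heights reconstructed as documented in the fixture
notes) with a 1.5 mm FWHM Gaussian focal spot:

```r
library(beamproj)

fx <- make_fixture("collimator4")
p  <- config_profile(fx$config)
profile_metrics(normalize_profile(p))
#> FWHM 4.055 mm | penumbra L 1.257 mm, R 1.257 mm | peak 1 | 50% edges [-2.028, 2.028] mm

sweep_source_fwhm(fx$config, c(1.5, 1.0))$rows
#>  fwhm fwhm_mm penumbra_left penumbra_right   peak peak_ratio_vs_first
#>   1.5   4.055        1.2572         1.2572 0.9574               1.000
#>   1.0   4.005        0.8756         0.8756 0.9977               1.042
```

Reading: the field is 4.06 mm wide at half maximum with a symmetric
1.26 mm penumbra. Shrinking the focal spot to 1.0 mm FWHM leaves the
field size essentially unchanged (4.01 mm) but sharpens the penumbra to
0.88 mm and raises the peak dose rate by 4.2% (the `peak` column is the
transmitted fraction of an equal-total-output source, so the ratio is the
dose-rate gain from reduced clipping at the entrance aperture). This is
the quantitative basis for matching collimator bores to the focal-spot
size.

The same run from the shell:

```sh
inst/cli/beamproj fixtures --dir cfg
inst/cli/beamproj profile --config cfg/collimator4.yaml --out p.csv
inst/cli/beamproj metrics --profile p.csv --out m.json
```

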