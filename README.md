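# qdimri — quasi-diffusion imaging of diffusion MRI signal decay

`qdimri` implements quasi-diffusion imaging (QDI), a two-parameter
representation of diffusion-weighted MRI signal decay for b-value ranges that
extend into the high-b power-law regime (up to ~25,000 s/mm² and beyond).
It is aimed at researchers who want ADC-like maps that remain valid far past
the Gaussian regime, plus the analytic machinery that comes with them.

The normalized, orientationally averaged signal is modelled by a stretched
Mittag–Leffler function

    S(b)/S0 = E_alpha( -(D12 * b)^alpha ),   E_alpha(z) = sum_k z^k / Gamma(alpha k + 1)

with the quasi-diffusion coefficient `D12` (mm²/s) and the fractional
exponent `alpha` in (0, 1] (`alpha = 1` is monoexponential Gaussian decay).
The curve interpolates between a stretched exponential at low b and a
negative power law `b^(-alpha)` at high b; the transition point — the zero
of `d² ln S / d(ln b)²`, the signal **inflection point (IP)** — is a derived
map with strong tissue contrast.

The package provides:

* robust evaluation of the one- and two-parameter Mittag–Leffler function on
  the negative real axis (`mlf`, `mlf_derivative`), with two independent
  test oracles (`mlf_series_oracle`, `mlf_integral_oracle`);
* the QDI forward model, its low/high-b asymptotics, log-log slope and
  curvature, and the classical intraneurite "stick" reference model;
* analytic inflection points (`find_ip`) and a fast lookup table
  (`build_ip_table`, `lookup_ip`);
* Rician noise estimation, floor correction and simulation
  (`estimate_sigma`, `correct_rician`, `add_rician_noise`);
* voxelwise bounded nonlinear least-squares mapping in log-signal space
  (`powder_average`, `fit_decay`, `fit_volume`);
* protocol evaluation: b_max truncation sweeps, short-vs-full protocol bias /
  uncertainty / ICC(2,1), ROI statistics (`bmax_sweep`, `compare_protocols`,
  `icc`, `roi_stats`);
* a synthetic multi-shell phantom with known ground truth (`make_scheme`,
  `make_phantom`) so the whole pipeline is testable without data downloads;
* minimal NIfTI-1 I/O, FSL-style bval/bvec handling, and a `qdi` command-line
  interface (`fit`, `simulate`, `ip-table`, `eval-protocol`).

## A worked example

```r
library(qdimri)

p <- qdi_params(0.8e-3, 0.88)        # typical cortical grey matter
qdi_attenuation(c(0, 1200, 5000, 15000), p)
#> [1] 1.0000000 0.3902010 0.0737633 0.0176561
log_slope(2e5, p)                    # tending to -alpha in the power-law tail
#> [1] -0.8965
find_ip(p)                           # inflection point, s/mm^2
#> [1] 5028.041
```

The signal at b = 5000 has fallen to 7.4% of S0; the log-log slope at
b = 2×10⁵ is already close to −0.88 (= −alpha); and the concave-to-convex
transition sits at b ≈ 5028 s/mm², consistent with reported grey-matter
IP medians.

A full phantom round trip — simulate a three-tissue slab phantom at
SNR(b=0) = 50 on the 302-volume ultra-high-b protocol, then fit maps with
the Rician floor correction:

```r
sch <- make_scheme("dataset1", seed = 1)
ph  <- make_phantom(default_phantom_spec(shape = c(6, 6, 1), snr_b0 = 50,
                                         seed = 42), sch)
maps <- fit_volume(ph$dwi, sch, mu_r = ph$sigma * sqrt(pi / 2))
roi_stats(maps$alpha, ph$spec$regions[[1]]$mask)
#> GM-slab fitted alpha: median 0.887 (IQR 0.884-0.891, n = 12)
```

The grey-matter slab (truth alpha = 0.88) is recovered with a median of
0.887.  A single-voxel fit prints as:

```
QDI fit: D1,2 = 0.000879 mm^2/s, alpha = 0.8368, IP = 4814 s/mm^2, MSE(ln) = 0.00869 (11 points)
```

## Command line

```sh
qdi simulate --preset dataset1 --snr 50 --seed 7 --shape 12,12,3 --out sim/
qdi fit --dwi sim/dwi.nii.gz --bvals sim/dwi.bval --bvecs sim/dwi.bvec --out maps/
qdi ip-table --d12 0.8e-3 --alpha 0.88     # prints 5028.040964
qdi eval-protocol --full maps/ --subset maps_short/ --out cmp.tsv
```

(`qdi` is installed to the package `exec/` directory; equivalently call
`qdimri::qdi_cli(c("simulate", ...))`.)

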