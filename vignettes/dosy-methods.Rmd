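---
title: "Models and methods behind dosytools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dosytools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dosytools)
```

# The measurement model

A pseudo-2D DOSY experiment acquires one FID per gradient amplitude
along a ramp. For a resonance with diffusion coefficient $D$ and
transverse relaxation time $T_2$, the signal surviving one increment at
gradient amplitude $g$ is modeled as

$$A(g) = \exp\{-D\,b(g)\}\;\exp\{-t_\perp/T_2\},\qquad
  b(g) = (\gamma\,\sigma\,g\,\delta)^2\left(\Delta-\tfrac{\delta}{3}-\tfrac{\tau}{2}\right),$$

the Stejskal–Tanner weighting with the bipolar-LED correction. Here
$\delta$ is the **summed** duration of a bipolar gradient pulse pair
(twice the per-lobe length usually quoted; `delta_is_per_lobe = TRUE`
converts), $\sigma$ a dimensionless shape factor for shaped gradient
pulses (default 1), $\tau$ the short gradient-recovery delay (≈3 µs;
its $\tau/2$ term is negligible but kept), and $t_\perp$ the time the
magnetization spends transverse.

Three sequence parameterizations are built in (`dosy_params()`):

* **traditional** — $\Delta$ = 50 ms, $\delta$ = 3.0 ms, ramp 5–95 %,
  8 increments × 8 scans. $t_\perp = 4\tau + 2\delta$ (the diffusion
  delay stores magnetization longitudinally), so relaxation barely
  touches it.
* **relaxation_edited** — a double spin–echo train repeated $n$ = 14
  times plus six bipolar gradient pulse pairs ($\delta$ = 1.6 ms) each
  separated by the unit diffusion time $\Delta$ = 30 ms. Diffusion
  weighting is modeled with a single effective diffusion time
  $n_\mathrm{eff}\,(\Delta-\delta/3-\tau/2)$ with
  $n_\mathrm{eff} = n_\mathrm{pairs}-1 = 5$ by default (the exact
  multi-pair expression is not published; $n_\mathrm{eff}$ is a config
  constant, and gradient calibration absorbs the choice on real data).
  The echo train adds $n\cdot 4\tau_\mathrm{echo}$ to $t_\perp$;
  $\tau_\mathrm{echo}$ defaults to 2.2 ms, i.e. $t_\perp \approx$
  126 ms, suppressing a $T_2$ = 20 ms macromolecule signal by >99.7 %
  while costing a $T_2$ = 0.5 s metabolite only ~22 %. This is the
  relaxation-editing filter; because the factor is
  gradient-independent it cancels exactly from every fit of $D$
  (property-tested).
* **diffusion_edited** — $\Delta$ = 350 ms with the ramp restricted to
  25–95 %: small molecules ($D\gtrsim7\times10^{-10}$ m²/s) retain only
  ~6 % of their signal at the first used increment while macromolecules
  retain >70 %, so the macromolecular envelope can be fitted without
  small-molecule interference.

The ramp design rule — signals of interest should decay from ≈95 % in
the first increment to ≈5 % in the last — is exposed as
`decay_fraction(decay_curve(...))`.

# Synthetic phantoms: the stated world

No public DOSY biofluid datasets accompany this problem, so the package
carries seeded generators whose defaults *are* the stated experimental
world; they were fixed before the acceptance runs and are not tuned.

**Urine** (`build_urine_phantom`): ≥30 small-molecule multiplets
(singlets/doublets/triplets, J = 6–7.5 Hz, linewidths 1–2.5 Hz) drawn
over 0.6–9 ppm avoiding the water region; $D \sim U(4,10)\times
10^{-10}$ m²/s, $T_2 \sim U(0.3, 1.5)$ s (plausible ranges — the
published per-metabolite tables are in supporting material not
available here); TSP reference singlet at 0.00 ppm (D = 5.0); residual
water at 4.7 ppm with a presaturation factor of 0.01. The per-scan
noise is anchored so that TSP in the first increment of the 8-scan
traditional experiment has SNR ≈ 681, the documented SNR convention of
the optimized urine experiment (measured 661 in the realized run).

**Plasma** (`build_plasma_phantom`): alanine (1.47 ppm), lactate (1.33,
4.14), valine (0.98, 1.03) and glucose — anomeric doublet at 5.23 ppm
plus six ring multiplets at 3.2–3.9 ppm, all sharing one ground-truth
$D = 7.20\times10^{-10}$ m²/s — over a macromolecular background: 21
broad protein components (linewidths 80–180 Hz) in 2.35–3.05,
3.70–4.10 and 6.8–8.3 ppm with $D\sim U(0.72,0.83)$ and
$T_2\sim U(10,20)$ ms; four lipid components at 5.15–5.40 ppm
($D\sim U(0.05,0.30)$, within the reported 0.01–0.45 band); lipoprotein
singlets at 0.84 and 1.25 ppm with $D$ = 0.05 and 0.08 (< 0.1, as
reported). Macromolecule $T_2 \ll$ metabolite $T_2$ is what makes
relaxation editing work, and is asserted by the tests. Noise anchors
the glucose anomeric line at SNR ≈ 400 (8 scans, unattenuated) — no
plasma SNR convention is printed, so this typical well-resolved
metabolite SNR was chosen once.

**Doped water** (`doped_water_phantom`): one dominant water resonance,
$D$ = 1.91, short $T_2$ (Gd doping), presaturation disabled — the
gradient-calibration sample.

What the phantoms deliberately do **not** emulate: J-modulation and
strong coupling, chemical exchange, lipoprotein subclass structure,
convection, eddy-current and spoil-gradient artifacts, temperature
effects (carried as metadata only), and baseline distortions. A green
test therefore establishes that the pipeline inverts its own forward
model under realistic noise, overlap and editing — not that it
reproduces every artifact of instrument data.

# Processing choices

* **Apodization**: $w(t)=\exp\{-(\pi\,\mathrm{gw}\,t)^2/(4\ln 2)\}$,
  i.e. `gw` is the Gaussian line broadening in Hz (the toolbox display
  convention "gw = 1" has no published formula; this mapping is
  documented, and fitted $D$ is invariant to `gw` — property-tested —
  so the convention cannot bias results). Zero-fill to 65536 points;
  first time-domain point halved.
* **Phasing**: one (φ0, φ1) pair per dataset minimizing the squared
  negative excursions of the real part over signal-bearing points.
  Minimizing the integrated |imaginary| — the first idea — is
  self-defeating: absorption has a *smaller* L1 norm than dispersion,
  so that criterion parks dispersion in the real channel. φ1 is off by
  default because simulated FIDs carry no first-order phase.
* **Chemical-shift calibration**: intensity-weighted centroid of the
  points above half the window maximum around the expected reference
  (glucose anomeric doublet → 5.23 ppm for plasma, TSP → 0.00 ppm for
  urine), so a symmetric doublet calibrates on its center. The
  diffusion-edited plasma spectrum suppresses glucose, so the pipeline
  applies no in-spectrum calibration there (the shift would be carried
  over from the companion small-molecule run on real data).
* **Water pruning**: 4.55–4.90 ppm masked, not zeroed — masked points
  are excluded from picking and extraction, but integrals elsewhere are
  untouched.
* **Noise**: MAD of the real part of the first increment in
  9.5–10.0 ppm (signal-free in both phantoms); SNR = height /
  noise_sd. On noiseless data the estimate is limited by Lorentzian
  tail curvature (~10⁻⁴ of the tallest peak), not zero.

# Fitting and peak extraction

Peaks are local maxima of the first increment above 5 × noise_sd that
additionally have a topographic prominence of 5 × noise_sd. The
prominence requirement is an addition to the plain threshold contract:
without it, noise bumps riding on the tails of strong resonances
produce hundreds of spurious picks (they exceed the threshold in
height while having ~2σ of structure), which would make retention
statistics meaningless. Per-increment intensity is the window maximum
(±0.0025 ppm) — matching the "peak intensity decay" definition —
with integrals available as an alternative.

Fits use log-linear initialization and `nls` refinement on raw
intensities; `stderr_D` comes from the covariance at the optimum, and
`relative_error = stderr_D / D` is the quantity the filter tool
thresholds (the reference tool's error metric is not published; this
one is documented and monotone in noise). Degenerate cases are flagged,
not dropped: <3 usable increments, non-positive first intensity,
negative $D$ (clamped to 0), `nls` failure (log-linear fallback),
masked-window truncation. Overlapping resonances legitimately fit to an
intensity-weighted average $D$; the tests assert the average lies
strictly between the component values rather than pretending overlap
resolves.

Ramp limits restrict which increments enter a fit (inclusive
endpoints); with limits 25–95 % on a 5–95 % acquisition, the
low-gradient increments are provably never used
(`ramp_indices_used`).

# Calibration

Every unknown multiplicative gradient constant (true g_max, shape
integral, per-lobe vs summed δ) enters $b$ through one factor on $g$,
so a doped-water fit determines a single scale
$\sqrt{D_\mathrm{fit}/1.91}$ per (spectrometer, sequence). The tests
verify the round-trip (deliberate 15 % mis-scaling → 1.91 within
0.5 %) and that calibrating under a wrong shape factor de-biases
subsequent metabolite fits.

# Numerical and design notes

* Diffusion coefficients are reported in 10⁻¹⁰ m²/s everywhere
  user-facing; fits run on that scale for conditioning (b × 10⁻¹⁰).
* Ramp spacing is linear in amplitude (acquisition default); squared
  spacing (uniform b steps) is available.
* Filter intervals are inclusive on both ends; the "noise" filter of
  the CSV extraction is interpreted as the intensity floor, since the
  fitting-error threshold is named separately.
* Peak-list files and CSVs are written with plain-decimal,
  locale-independent formatting and are byte-stable; binary pseudo-2D
  data round-trip bit-exactly (little-endian float64, interleaved
  re/im, row-major).
* Seeds: every stochastic step (phantom draw, noise) is an explicit
  argument; the pipeline refuses to simulate without one.

# Known limitations

* The printed per-experiment decay fractions (97.2 % TSP/traditional,
  91.5 % glucose/relaxation-edited, 84.2 % protein/diffusion-edited
  measured from 2 % to 95 % gradient) cannot all be reproduced with a
  single g_max: with the default 0.535 T/m and plausible D values the
  model computes 98.3 %, 99.3 % and 98.9 % respectively (the
  acceptance suite computes these; only the first matches within 5
  points). The absolute gradient amplitude and the exact multi-pair
  diffusion weighting of the editing sequence are not published; the
  calibration module exists precisely because such constants must be
  measured, not assumed. This consistency demonstration is therefore
  documented as deviating rather than gated on.
* Mono-exponential fits only; multi-component decays (lipoprotein
  subclasses, inverse-Laplace processing) are out of scope.
* The GNAT-style peak-list dialect here is self-defined; a converter
  hook (`load_peak_lists`) is the extension point for real toolbox
  exports, untested against them.
* Vendor raw-directory import is not implemented; the documented
  directory format is the interchange point.
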