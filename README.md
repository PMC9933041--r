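# dosytools

Diffusion-ordered ¹H NMR spectroscopy (DOSY) resolves the signals of a
mixture along two axes: chemical shift and translational diffusion
coefficient *D*. In biofluids this separates small metabolites
(*D* ≈ 4–10 × 10⁻¹⁰ m²/s) from proteins, lipids and lipoproteins
(*D* ≲ 1 × 10⁻¹⁰ m²/s), turning *D* into a usable readout for metabolic
phenotyping — but only if acquisition, processing and peak extraction
are standardized and automated. `dosytools` is that toolkit in R, aimed
at NMR metabolomics groups who want a tested, scriptable DOSY pipeline
and a fully synthetic test bed with known ground truth.

## What it implements

**Forward models of three optimized DOSY experiments** (8 gradient
increments × 8 scans each):

| kind | editing | Δ (diffusion delay) | gradient ramp |
|---|---|---|---|
| `traditional` | none (urine, simple mixtures) | 50 ms | 5–95 % |
| `relaxation_edited` | double spin–echo train (n = 14) suppresses short-T₂ macromolecules | 30 ms × 5 effective periods | 5–95 % |
| `diffusion_edited` | long delay decays small molecules first | 350 ms | 25–95 % |

Signal attenuation per increment follows the Stejskal–Tanner equation
with the bipolar-LED correction,

    I(g) = I₀ · exp(−D b(g)) · exp(−t⊥/T₂),
    b(g) = (γ σ g δ)² · (Δ − δ/3 − τ/2),

where δ is the summed bipolar gradient pulse length, σ a gradient shape
factor, and t⊥ the sequence's transverse-evolution time (the echo train
of the relaxation-edited experiment makes exp(−t⊥/T₂) the editing
filter). The T₂ factor is gradient-independent, so it cancels exactly
from any fit of *D*.

On top of the sequence models:

- `simulate` — urine-like (≥30 small-molecule multiplets + TSP) and
  plasma-like (alanine/lactate/valine/glucose over protein, lipid and
  lipoprotein envelopes) phantoms, seeded and fully ground-truthed;
  binary pseudo-2D dataset directory format (`meta.json` + `data.bin`).
- `process` — Gaussian apodization (gw in Hz), zero-fill to 64k, FFT,
  automatic phasing, chemical-shift calibration (glucose anomeric
  doublet → 5.23 ppm, or TSP → 0.00 ppm), water-region masking, robust
  noise estimation.
- `fitdosy` — peak picking (noise threshold + topographic prominence),
  per-peak decay extraction, Stejskal–Tanner fits with
  covariance-derived standard errors, DOSY peak lists, 2D display
  matrix.
- `peaktool` — multi-spectrum peak-list filtering by ppm ranges,
  relative fitting error and intensity floor; consolidated CSV export.
- `calibrate` — gradient calibration on a doped-water dataset against
  the reference D(H₂O) = 1.91 × 10⁻¹⁰ m²/s (since b ∝ g², the scale is
  √(D_fit/D_ref); it absorbs shape-factor and pulse-length conventions).
- `cli` / `pipeline` — `run_pipeline()` and a `dosy` command-line
  interface (`simulate`, `process`, `fit`, `filter`, `calibrate`,
  `run`) with reproducible JSON configs.

## Worked example

Relaxation-edited DOSY of a simulated plasma phantom, glucose
extraction:

```r
library(dosytools)
p  <- dosy_params("relaxation_edited")
ph <- build_plasma_phantom(seed = 1)
ds <- simulate_dataset(ph, p, seed = 1, sim = sim_options(temperature_k = 310))
sm <- process_dataset(ds, calibrate = "glucose")
pl <- build_peak_list(sm, "plasma01")
tab <- filter_peaks(pl, filter_spec(list(c(5.20, 5.26), c(3.20, 3.90)),
                                    max_relative_error = 0.2))
summarize_range(tab, c(3.20, 3.90))
```

prints

```
  spectrum_id range_low range_high n_peaks   mean_D       sd_D
1    plasma01       3.2        3.9      15 7.214577 0.04478265
```

15 glucose ring-proton peaks survive the error filter, with a mean
fitted D of 7.21 × 10⁻¹⁰ m²/s against a ground truth of 7.20 and a
spread of 0.04 — the relaxation-edited experiment recovers a consistent
glucose diffusion coefficient because the protein envelope underneath
(T₂ ≈ 10–20 ms) is suppressed by the echo train. Running the same
phantom through the `traditional` sequence instead biases the glucose
fits by several units of 10⁻¹⁰ m²/s: overlapping signals fit to an
intensity-weighted average of their components' D values.

The same pipeline from the shell:

```sh
Rscript inst/cli/dosy.R filter --lists 'peaklists/*.tsv' \
    --ranges 1.44:1.50,5.20:5.26 --max-error 0.2 --min-intensity 0 \
    --out table.csv
```

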