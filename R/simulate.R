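# Synthetic biofluid phantoms and pseudo-2D DOSY dataset simulation.
#
# A phantom is a ground-truth description of a biofluid: a set of species,
# each with one or more multiplets (center ppm, J coupling, number of
# lines with binomial intensity ratios), a diffusion coefficient (units
# 1e-10 m^2/s), a transverse relaxation time T2 (s), a Lorentzian
# linewidth (Hz) and an amplitude (arbitrary concentration units).
# Simulation produces time-domain FIDs: every line is an exponentially
# damped complex oscillation, scaled per gradient increment by the
# sequence attenuation model (seqmodel), with seeded complex Gaussian
# noise.

#' Digitization and spectrometer options for simulation
#'
#' Defaults: 16384 complex points over a 12 ppm spectral width at
#' 600.13 MHz with the carrier on water (4.7 ppm); spectra are
#' zero-filled to 64k during processing.
#'
#' @param points complex time-domain points per FID.
#' @param sw_ppm spectral width, ppm.
#' @param sfo1_mhz spectrometer frequency, MHz.
#' @param carrier_ppm transmitter offset, ppm.
#' @param temperature_k sample temperature, K (metadata only; 300 K for
#'   urine, 310 K for plasma by profiling convention).
#' @return a list of class `sim_options`.
#' @export
sim_options <- function(points = 16384L, sw_ppm = 12, sfo1_mhz = 600.13,
                        carrier_ppm = 4.7, temperature_k = 300) {
  structure(list(points = as.integer(points), sw_ppm = sw_ppm,
                 sfo1_mhz = sfo1_mhz, carrier_ppm = carrier_ppm,
                 temperature_k = temperature_k),
            class = "sim_options")
}

#' Construct a phantom species
#'
#' @param name species label.
#' @param multiplets data frame with columns `center` (ppm), `J`
#'   (coupling, Hz), `n` (number of lines; 1 = singlet) and `amp`
#'   (amplitude of this multiplet in concentration units).  Line
#'   intensities within a multiplet follow binomial ratios and sum to 1.
#' @param D diffusion coefficient, 1e-10 m^2/s.
#' @param T2 transverse relaxation time, s.
#' @param linewidth Lorentzian full width at half maximum, Hz.
#' @param presat multiplicative presaturation suppression factor applied
#'   at simulation time (1 = no suppression; the water species uses a
#'   small value such as 0.01).
#' @return an object of class `dosy_species`.
#' @export
species <- function(name, multiplets, D, T2, linewidth, presat = 1) {
  stopifnot(is.data.frame(multiplets),
            all(c("center", "J", "n", "amp") %in% names(multiplets)))
  if (D < 0) stop_invalid("species '%s': D must be >= 0", name)
  if (T2 <= 0) stop_invalid("species '%s': T2 must be > 0", name)
  if (linewidth <= 0) stop_invalid("species '%s': linewidth must be > 0", name)
  structure(list(name = name, multiplets = multiplets, D = D, T2 = T2,
                 linewidth = linewidth, presat = presat),
            class = "dosy_species")
}

#' Construct a phantom
#'
#' @param species_list list of [species()] objects (small molecules and
#'   macromolecule envelope components).
#' @param water a [species()] for the residual water resonance (near
#'   4.7 ppm) carrying a presaturation factor.
#' @param reference optional chemical-shift reference [species()] (TSP
#'   at 0.00 ppm for urine).
#' @param noise_sigma per-scan complex noise standard deviation in the
#'   time domain (each of the real and imaginary components).
#' @return an object of class `dosy_phantom`.
#' @export
phantom <- function(species_list, water, reference = NULL, noise_sigma = 0) {
  stopifnot(inherits(water, "dosy_species"))
  structure(list(species = species_list, water = water,
                 reference = reference, noise_sigma = noise_sigma),
            class = "dosy_phantom")
}

#' @export
print.dosy_phantom <- function(x, ...) {
  nmul <- sum(vapply(x$species, function(s) nrow(s$multiplets), integer(1)))
  cat(sprintf("<dosy_phantom: %d species, %d multiplets, noise_sigma = %g>\n",
              length(x$species), nmul, x$noise_sigma))
  invisible(x)
}

# Expand a phantom into a flat line table: one row per spectral line.
# Columns: ppm, amp (line amplitude after multiplet splitting and
# presaturation), lw (Hz), D (1e-10 m^2/s), T2 (s), species,
# class ("small", "macro", "water", "reference").
phantom_lines <- function(ph, sfo1_mhz) {
  expand <- function(sp, cls) {
    rows <- lapply(seq_len(nrow(sp$multiplets)), function(i) {
      m <- sp$multiplets[i, ]
      n <- m$n
      w <- choose(n - 1, 0:(n - 1)); w <- w / sum(w)
      # line positions: center +/- multiples of J (Hz -> ppm)
      off <- ((0:(n - 1)) - (n - 1) / 2) * m$J / sfo1_mhz
      data.frame(ppm = m$center + off, amp = m$amp * w * sp$presat,
                 lw = sp$linewidth, D = sp$D, T2 = sp$T2,
                 species = sp$name, class = cls,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  cls <- vapply(ph$species, function(s)
    if (s$T2 <= 0.1) "macro" else "small", character(1))
  tabs <- Map(expand, ph$species, cls)
  tabs <- c(tabs, list(expand(ph$water, "water")))
  if (!is.null(ph$reference))
    tabs <- c(tabs, list(expand(ph$reference, "reference")))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

singlet <- function(center, amp) data.frame(center = center, J = 0, n = 1L,
                                            amp = amp)
multiplet <- function(center, J, n, amp) data.frame(center = center, J = J,
                                                    n = as.integer(n),
                                                    amp = amp)

# Height of an on-resonance Lorentzian line in the processed spectrum
# (default Gaussian apodization gw, no zero-fill dependence), and the
# frequency-domain noise scale factor for a per-point time-domain sd of
# 1.  Used to anchor phantom noise levels to stated SNR conventions.
spectral_scale <- function(sim, lw, gw = 1) {
  t <- (0:(sim$points - 1)) / (sim$sw_ppm * sim$sfo1_mhz)
  w <- exp(-(pi * gw * t)^2 / (4 * log(2)))
  sig <- exp(-pi * lw * t) * w
  sig[1] <- sig[1] * 0.5
  list(height = sum(sig), noise_factor = sqrt(sum(w^2)))
}

#' Build the synthetic urine phantom
#'
#' A small-molecule-only biofluid: at least 30 randomly placed
#' metabolite multiplets spanning 0.5--9 ppm (avoiding the water
#' region), diffusion coefficients drawn in 4--10 x 1e-10 m^2/s, T2 in
#' 0.3--1.5 s, plus a TSP reference singlet at 0.00 ppm and residual
#' water at 4.7 ppm.  The noise level is anchored so that the TSP
#' signal in the first increment of the default 8-scan traditional DOSY
#' experiment has a signal-to-noise ratio of about 681, the SNR
#' convention of the optimized urine experiment.
#'
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @param n_metabolites number of random metabolite multiplets (>= 30).
#' @param sim [sim_options()] used for the SNR anchoring.
#' @return a [phantom()].
#' @export
build_urine_phantom <- function(seed, n_metabolites = 32L,
                                sim = sim_options()) {
  stopifnot(n_metabolites >= 30L)
  with_seed(seed, {
    sp <- vector("list", n_metabolites)
    for (i in seq_len(n_metabolites)) {
      # keep clear of the water pruning region (4.55-4.90) and the
      # noise-estimation region (>= 9.5 ppm)
      repeat {
        center <- runif(1, 0.6, 9.0)
        if (center < 4.40 || center > 5.05) break
      }
      n <- sample(c(1L, 2L, 3L), 1, prob = c(0.40, 0.45, 0.15))
      sp[[i]] <- species(
        name = sprintf("metab%02d", i),
        multiplets = multiplet(center, J = runif(1, 6, 7.5), n = n,
                               amp = runif(1, 0.2, 1.2)),
        D = runif(1, 4, 10), T2 = runif(1, 0.3, 1.5),
        linewidth = runif(1, 1.0, 2.5))
    }
    tsp <- species("TSP", singlet(0.00, 1.0), D = 5.0, T2 = 1.2,
                   linewidth = 1.2)
    water <- species("water", singlet(4.70, 150), D = 19.0, T2 = 0.1,
                     linewidth = 8, presat = 0.01)
    # SNR anchor: TSP height / effective noise sd = 681 in the first
    # increment (~98% intensity) of the 8-scan traditional experiment.
    sc <- spectral_scale(sim, lw = 1.2)
    a1 <- 0.98
    noise_sigma <- sc$height * 1.0 * a1 * sqrt(8) / (681 * sc$noise_factor)
    phantom(sp, water = water, reference = tsp, noise_sigma = noise_sigma)
  })
}

#' Build the synthetic plasma phantom
#'
#' Small metabolites (alanine doublet at 1.47 ppm, lactate doublet at
#' 1.33 ppm and quartet at 4.14 ppm, valine doublets at 0.98 and
#' 1.03 ppm, glucose ring multiplets at 3.2--3.9 ppm and the anomeric
#' doublet at 5.23 ppm, all glucose peaks sharing one diffusion
#' coefficient of 7.20 x 1e-10 m^2/s) over a macromolecular background:
#' a protein proton envelope (broad components near 2.4--3.0,
#' 3.7--4.1 ppm and the aromatic region; D in 0.72--0.83 x 1e-10, T2
#' 10--20 ms), broad lipid signals at 5.15--5.4 ppm (D in 0.05--0.30 x
#' 1e-10) and lipoprotein signals at 0.84 and 1.25 ppm (D < 0.1 x
#' 1e-10).  Macromolecule T2 values are far below small-molecule T2,
#' which is what relaxation editing exploits.  Noise is anchored so the
#' glucose anomeric line has SNR of about 400 in an unattenuated
#' 8-scan spectrum.
#'
#' @param seed integer seed.
#' @param sim [sim_options()] used for the SNR anchoring.
#' @return a [phantom()].
#' @export
build_plasma_phantom <- function(seed, sim = sim_options()) {
  with_seed(seed, {
    glc_D <- 7.20
    sp <- list(
      species("alanine", multiplet(1.47, 7.2, 2, 0.6),
              D = 7.3, T2 = 0.7, linewidth = 1.4),
      species("lactate", rbind(multiplet(1.33, 7.0, 2, 1.2),
                               multiplet(4.14, 7.0, 4, 0.4)),
              D = 8.0, T2 = 0.8, linewidth = 1.4),
      species("valine", rbind(multiplet(0.98, 7.0, 2, 0.35),
                              multiplet(1.03, 7.0, 2, 0.35)),
              D = 6.6, T2 = 0.6, linewidth = 1.4),
      species("glucose", rbind(multiplet(5.23, 3.8, 2, 0.30),
                               multiplet(3.25, 9.0, 3, 0.35),
                               multiplet(3.41, 9.0, 3, 0.40),
                               multiplet(3.48, 9.0, 2, 0.45),
                               multiplet(3.55, 9.0, 2, 0.40),
                               multiplet(3.72, 9.0, 3, 0.45),
                               multiplet(3.84, 9.0, 2, 0.40)),
              D = glc_D, T2 = 0.5, linewidth = 1.3))
    # protein proton envelope: many overlapping broad Lorentzians in the
    # regions the envelope occupies in plasma; one component per center
    protein_centers <- c(runif(7, 2.35, 3.05), runif(6, 3.70, 4.10),
                         runif(8, 6.80, 8.30))
    for (i in seq_along(protein_centers)) {
      sp[[length(sp) + 1L]] <- species(
        sprintf("protein%02d", i), singlet(protein_centers[i],
                                           amp = runif(1, 6, 12)),
        D = runif(1, 0.72, 0.83), T2 = runif(1, 0.010, 0.020),
        linewidth = runif(1, 80, 180))
    }
    # broad lipid olefinic/glyceryl signals at 5.15-5.4 ppm
    lipid_centers <- c(5.18, 5.24, 5.31, 5.37)
    for (i in seq_along(lipid_centers)) {
      sp[[length(sp) + 1L]] <- species(
        sprintf("lipid%02d", i), singlet(lipid_centers[i],
                                         amp = runif(1, 1.2, 2.0)),
        D = runif(1, 0.05, 0.30), T2 = runif(1, 0.025, 0.035),
        linewidth = runif(1, 30, 60))
    }
    # lipoprotein methyl/methylene signals
    sp[[length(sp) + 1L]] <- species("lipoprotein_CH3", singlet(0.84, 4.0),
                                     D = 0.05, T2 = 0.040, linewidth = 28)
    sp[[length(sp) + 1L]] <- species("lipoprotein_CH2", singlet(1.25, 4.5),
                                     D = 0.08, T2 = 0.040, linewidth = 32)
    water <- species("water", singlet(4.70, 200), D = 19.0, T2 = 0.08,
                     linewidth = 10, presat = 0.01)
    sc <- spectral_scale(sim, lw = 1.3)
    anomeric_line_height <- sc$height * (0.30 / 2)
    noise_sigma <- anomeric_line_height * sqrt(8) / (400 * sc$noise_factor)
    phantom(sp, water = water, reference = NULL, noise_sigma = noise_sigma)
  })
}

#' Build a doped-water calibration phantom
#'
#' A single dominant water resonance (1\% H2O in D2O doped with GdCl3,
#' measured at 298.15 K) with the reference diffusion coefficient of
#' 1.91 x 1e-10 m^2/s and the short relaxation times the Gd doping
#' produces.  Presaturation is disabled (factor 1), as required for
#' gradient calibration.
#'
#' @param D water diffusion coefficient, 1e-10 m^2/s.
#' @param noise_sigma per-scan time-domain noise sd.
#' @return a [phantom()].
#' @export
doped_water_phantom <- function(D = 1.91, noise_sigma = 0.002) {
  water <- species("water", singlet(4.70, 100), D = D, T2 = 0.12,
                   linewidth = 4, presat = 1)
  phantom(list(), water = water, reference = NULL,
          noise_sigma = noise_sigma)
}

#' Simulate a pseudo-2D DOSY dataset from a phantom
#'
#' Produces time-domain FIDs, one per gradient increment.  Every line of
#' every species contributes an exponentially damped complex oscillation
#' at its ppm offset (Lorentzian lineshape); increment `i` is scaled by
#' the sequence attenuation [attenuation()] at the i-th ramp amplitude,
#' which encodes both diffusion and T2 relaxation (editing).  Complex
#' Gaussian noise with per-component standard deviation
#' `noise_sigma / sqrt(n_scans)` is added to every increment.  The water
#' species is scaled by its presaturation factor.
#'
#' @param ph a [phantom()].
#' @param params a [dosy_params()] object.
#' @param seed integer seed for the noise.
#' @param sim a [sim_options()] object.
#' @return an object of class `pseudo2d`: list with `meta` (acquisition
#'   metadata including the sequence parameters and domain flag
#'   `"time"`), `matrix` (complex, `n_increments` x `points`), and
#'   `ground_truth` (the phantom, for testing).
#' @export
simulate_dataset <- function(ph, params, seed, sim = sim_options()) {
  stopifnot(inherits(ph, "dosy_phantom"))
  validate_dosy_params(params)
  lines <- phantom_lines(ph, sim$sfo1_mhz)
  lo <- sim$carrier_ppm - sim$sw_ppm / 2
  hi <- sim$carrier_ppm + sim$sw_ppm / 2
  if (any(lines$ppm < lo | lines$ppm > hi))
    stop_invalid("phantom line at %.3f ppm outside spectral width [%.2f, %.2f]",
                 lines$ppm[which(lines$ppm < lo | lines$ppm > hi)[1]], lo, hi)

  sw_hz <- sim$sw_ppm * sim$sfo1_mhz
  t <- (0:(sim$points - 1)) / sw_hz
  f_off <- (lines$ppm - sim$carrier_ppm) * sim$sfo1_mhz  # Hz
  # basis: one damped oscillation per line [n_lines x points]
  basis <- exp(outer(2i * pi * f_off - pi * lines$lw, t)) * lines$amp
  ramp <- gradient_ramp(params)
  # attenuation [n_increments x n_lines]
  att <- vapply(seq_len(nrow(lines)), function(l)
    attenuation(params, lines$D[l] * 1e-10, lines$T2[l], ramp$amplitudes),
    numeric(params$n_increments))
  if (params$n_increments == 1L) att <- matrix(att, nrow = 1L)
  mat <- att %*% basis
  if (ph$noise_sigma > 0) {
    sd_eff <- ph$noise_sigma / sqrt(params$n_scans)
    noise <- with_seed(seed, {
      n <- length(mat)
      complex(real = rnorm(n, sd = sd_eff), imaginary = rnorm(n, sd = sd_eff))
    })
    mat <- mat + matrix(noise, nrow = nrow(mat))
  }
  structure(list(
    meta = list(params = params, sw_ppm = sim$sw_ppm,
                sfo1_mhz = sim$sfo1_mhz, carrier_ppm = sim$carrier_ppm,
                points = sim$points, domain = "time",
                temperature_k = sim$temperature_k, seed = as.integer(seed)),
    matrix = mat,
    ground_truth = ph),
    class = "pseudo2d")
}

#' @export
print.pseudo2d <- function(x, ...) {
  cat(sprintf("<pseudo2d: %s-domain, %d increments x %d points, %s sequence>\n",
              x$meta$domain, nrow(x$matrix), ncol(x$matrix),
              x$meta$params$kind))
  invisible(x)
}
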