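# Apodization, transform, phasing, calibration, pruning, noise.

test_that("gw = 0 transform of a noiseless line gives the expected Lorentzian width", {
  lw <- 2.0
  ds <- simulate_dataset(single_species_phantom(lw = lw, T2 = 1e6),
                         dosy_params("traditional"), seed = 1,
                         sim = sim_options(points = 8192L))
  sm <- autophase(apodize_and_transform(ds, gw = 0, target_points = 65536L))
  y <- spectra(sm)[1, ]
  half <- max(y) / 2
  above <- range(which(y >= half))
  # linear interpolation of the half-height crossings
  interp <- function(i0, i1) {
    f <- (half - y[i0]) / (y[i1] - y[i0])
    sm$ppm_axis[i0] + f * (sm$ppm_axis[i1] - sm$ppm_axis[i0])
  }
  fwhm_hz <- abs(interp(above[1] - 1, above[1]) -
                 interp(above[2] + 1, above[2])) * sm$meta$sfo1_mhz
  expect_equal(fwhm_hz, lw, tolerance = 0.05)

  # gw = 1 broadens the line
  smg <- autophase(apodize_and_transform(ds, gw = 1, target_points = 65536L))
  yg <- spectra(smg)[1, ]
  wg <- abs(diff(smg$ppm_axis[range(which(yg >= max(yg) / 2))]))
  expect_gt(wg * sm$meta$sfo1_mhz, fwhm_hz)
})

test_that("degenerate inputs are handled: zero FID, frequency-domain input", {
  ds <- simulate_dataset(single_species_phantom(amp = 0),
                         dosy_params("traditional"), seed = 1,
                         sim = quick_sim())
  sm <- apodize_and_transform(ds, target_points = 16384L)
  expect_true(all(Mod(sm$signal) == 0))
  ds$meta$domain <- "frequency"
  expect_error(apodize_and_transform(ds), "time-domain")
})

test_that("autophase recovers known rotations and leaves phased data alone", {
  ds <- simulate_dataset(single_species_phantom(noise = 0.01),
                         dosy_params("traditional"), seed = 2,
                         sim = quick_sim())
  sm0 <- apodize_and_transform(ds, target_points = 16384L)
  ph0 <- attr(autophase(sm0), "phase_deg")
  expect_lt(abs(ph0[1]), 1)

  for (rot in c(30, -60, 135)) {
    smr <- sm0
    smr$signal <- smr$signal * exp(1i * rot * pi / 180)
    rec <- attr(autophase(smr), "phase_deg")
    expect_equal(rec[1], rot, tolerance = 1)
  }
  # the correction is a single pair applied to all increments: increment
  # ratios are preserved
  smp <- autophase(sm0)
  r1 <- spectra(smp)[2, ] / max(spectra(smp)[1, ])
  r2 <- spectra(sm0)[2, ] / max(Re(sm0$signal[1, ]))
  expect_equal(max(abs(r1)), max(abs(r2)), tolerance = 1e-6)
})

test_that("chemical-shift calibration finds doublet centers and injected offsets", {
  # glucose-like anomeric doublet deliberately simulated at 5.21 ppm
  ds <- simulate_dataset(doublet_phantom(ppm = 5.21, J = 3.8, lw = 1.3),
                         dosy_params("relaxation_edited"), seed = 1,
                         sim = quick_sim())
  sm <- autophase(apodize_and_transform(ds, target_points = 16384L))
  cal <- calibrate_ppm(sm, "glucose")
  expect_lt(abs(attr(cal, "shift_ppm") - 0.02), 0.002)

  # already calibrated: shift ~ 0
  cal2 <- calibrate_ppm(cal, "glucose")
  expect_lt(abs(attr(cal2, "shift_ppm")), 0.002)

  # tsp mode on a urine phantom puts TSP at 0.00
  u <- build_urine_phantom(3)
  dsu <- simulate_dataset(u, dosy_params("traditional"), seed = 3)
  smu <- process_dataset(dsu, calibrate = "tsp")
  picks <- pick_peaks(smu)
  expect_lt(min(abs(picks$ppm)), 0.002)

  # no reference peak in window -> calibration failure
  empty <- simulate_dataset(single_species_phantom(ppm = 2.0, noise = 0.01),
                            dosy_params("traditional"), seed = 1,
                            sim = quick_sim())
  sme <- estimate_noise(autophase(apodize_and_transform(empty, target_points = 16384L)))
  expect_error(calibrate_ppm(sme, "glucose"), "calibration failure")
})

test_that("water pruning masks picks without touching the data", {
  ph <- phantom(list(species("a", data.frame(center = 5.23, J = 0, n = 1L,
                                             amp = 1),
                             D = 7, T2 = 0.5, linewidth = 1.5)),
                water = species("water",
                                data.frame(center = 4.70, J = 0, n = 1L,
                                           amp = 5),
                                D = 19, T2 = 0.1, linewidth = 8,
                                presat = 1),
                noise_sigma = 0.002)
  ds <- simulate_dataset(ph, dosy_params("traditional"), seed = 1,
                         sim = quick_sim())
  sm <- estimate_noise(autophase(apodize_and_transform(ds, target_points = 16384L)))
  before <- pick_peaks(sm)
  expect_true(any(abs(before$ppm - 4.70) < 0.02))
  smp <- prune_water(sm)
  after <- pick_peaks(smp)
  expect_false(any(abs(after$ppm - 4.70) < 0.02))
  expect_true(any(abs(after$ppm - 5.23) < 0.005))   # untouched
  expect_identical(smp$signal, sm$signal)           # masked, not zeroed
  expect_error(prune_water(sm, c(20, 21)), "outside")
})

test_that("noise estimation matches the generated noise level", {
  ph <- single_species_phantom(amp = 0, noise = 0.5)
  ds <- simulate_dataset(ph, dosy_params("traditional", n_scans = 1),
                         seed = 9, sim = quick_sim())
  sm <- estimate_noise(apodize_and_transform(ds, target_points = 16384L))
  truth <- sd(Re(sm$signal[1, ]))    # pure-noise spectrum
  expect_equal(sm$noise_sd, truth, tolerance = 0.1)

  # noiseless: estimate negligible against the signal scale
  dsn <- simulate_dataset(single_species_phantom(ppm = 2.0),
                          dosy_params("traditional"), seed = 1,
                          sim = quick_sim())
  smn <- estimate_noise(autophase(apodize_and_transform(dsn, target_points = 16384L)))
  # residual Lorentzian-tail variation only: far below any real noise
  expect_lt(smn$noise_sd, 1e-4 * max(spectra(smn)))
  # an empty spectrum estimates exactly zero
  ds0 <- simulate_dataset(single_species_phantom(amp = 0),
                          dosy_params("traditional"), seed = 1,
                          sim = quick_sim())
  sm0 <- estimate_noise(apodize_and_transform(ds0, target_points = 16384L))
  expect_identical(sm0$noise_sd, 0)
  expect_error(estimate_noise(smn, c(30, 31)), "outside")
})

test_that("zero-fill level changes resolution but not integrated area", {
  ds <- simulate_dataset(single_species_phantom(),
                         dosy_params("traditional"), seed = 1,
                         sim = quick_sim())
  area <- function(tp) {
    sm <- autophase(apodize_and_transform(ds, target_points = tp))
    sum(spectra(sm)[1, ]) * abs(diff(sm$ppm_axis[1:2]))
  }
  expect_equal(area(16384L), area(65536L), tolerance = 1e-3)
})

test_that("fitted D is invariant to the apodization choice", {
  p <- dosy_params("traditional")
  ds <- simulate_dataset(single_species_phantom(D = 6.2),
                         p, seed = 1, sim = quick_sim())
  fitD <- function(gw) {
    sm <- autophase(apodize_and_transform(ds, gw = gw,
                                          target_points = 16384L))
    ramp <- gradient_ramp(p)
    fit_stejskal_tanner(extract_decay(sm, list(ppm = 2.0)),
                        b_value(p, ramp$amplitudes), ramp$fractions)$D
  }
  expect_equal(fitD(0), fitD(2), tolerance = 1e-6)
  expect_equal(fitD(1), 6.2, tolerance = 1e-6)
})
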