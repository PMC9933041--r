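# Peak picking, decay extraction, Stejskal-Tanner fitting, peak lists.

processed_single <- function(D = 7, T2 = 0.5, noise = 0, ppm = 2.0,
                             seed = 1) {
  ds <- simulate_dataset(single_species_phantom(ppm = ppm, D = D, T2 = T2,
                                                noise = noise),
                         dosy_params("traditional"), seed = seed,
                         sim = quick_sim())
  estimate_noise(autophase(apodize_and_transform(ds, target_points = 16384L)))
}

test_that("a noiseless doublet yields exactly two picks at the line positions", {
  ds <- simulate_dataset(doublet_phantom(ppm = 2.0, J = 7),
                         dosy_params("traditional"), seed = 1,
                         sim = quick_sim())
  sm <- estimate_noise(autophase(apodize_and_transform(ds, target_points = 16384L)))
  sm$noise_sd <- max(spectra(sm)) / 1000   # define a scale for thresholds
  picks <- pick_peaks(sm)
  expect_equal(nrow(picks), 2)
  expected <- 2.0 + c(-3.5, 3.5) / 600.13
  expect_equal(sort(picks$ppm), sort(expected), tolerance = 1e-3)

  # threshold above the maximum -> empty list
  expect_equal(nrow(pick_peaks(sm, threshold_multiple = 2000)), 0)
})

test_that("decay extraction reproduces the attenuation model and is additive", {
  p <- dosy_params("traditional")
  sm <- processed_single(D = 7, T2 = 0.5)
  dec <- as.numeric(extract_decay(sm, list(ppm = 2.0)))
  curve <- decay_curve(p, 7e-10, 0.5)
  expect_equal(dec / dec[1], curve / curve[1], tolerance = 1e-10)

  # D = 0 species -> constant decay
  sm0 <- processed_single(D = 0, T2 = 1e6)
  dec0 <- as.numeric(extract_decay(sm0, list(ppm = 2.0)))
  expect_equal(dec0 / dec0[1], rep(1, 8), tolerance = 1e-9)

  # two overlapping species -> sum of two exponentials
  ph2 <- phantom(list(
    species("s1", data.frame(center = 2.0, J = 0, n = 1L, amp = 1),
            D = 1.0, T2 = 1e6, linewidth = 1.5),
    species("s2", data.frame(center = 2.0, J = 0, n = 1L, amp = 1),
            D = 8.0, T2 = 1e6, linewidth = 1.5)),
    water = silent_water(), noise_sigma = 0)
  ds2 <- simulate_dataset(ph2, p, seed = 1, sim = quick_sim())
  sm2 <- autophase(apodize_and_transform(ds2, target_points = 16384L))
  dec2 <- as.numeric(extract_decay(sm2, list(ppm = 2.0)))
  expected <- decay_curve(p, 1.0e-10, Inf) + decay_curve(p, 8.0e-10, Inf)
  expect_equal(dec2 / dec2[1], expected / expected[1], tolerance = 1e-9)
})

test_that("noiseless fits recover D exactly and match the two-point oracle", {
  p <- dosy_params("traditional")
  ramp <- gradient_ramp(p)
  b <- b_value(p, ramp$amplitudes)
  for (D in c(0.08, 1.0, 7.20, 9.5)) {
    I <- 100 * exp(-D * b * 1e-10)
    f <- fit_stejskal_tanner(I, b, ramp$fractions)
    expect_rel_equal(f$D, D, 1e-6)
    # closed-form two-point oracle
    oracle <- log(I[1] / I[8]) / ((b[8] - b[1]) * 1e-10)
    expect_rel_equal(f$D, oracle, 1e-9)
    expect_equal(f$flags, "ok")
  }
})

test_that("overlapping signals fit to an intermediate averaged D", {
  p <- dosy_params("traditional")
  ramp <- gradient_ramp(p)
  b <- b_value(p, ramp$amplitudes)
  I <- exp(-1.0 * b * 1e-10) + exp(-8.0 * b * 1e-10)
  f <- fit_stejskal_tanner(I, b, ramp$fractions)
  expect_gt(f$D, 1.0)
  expect_lt(f$D, 8.0)
})

test_that("fit degeneracies are flagged, not hidden", {
  p <- dosy_params("traditional")
  ramp <- gradient_ramp(p)
  b <- b_value(p, ramp$amplitudes)
  # fewer than 3 usable points
  f1 <- fit_stejskal_tanner(c(1, 0.5), b[1:2], ramp$fractions[1:2])
  expect_equal(f1$flags, "too_few_points")
  expect_true(is.na(f1$D))
  # rising intensities -> negative D clamped to zero with flag
  f2 <- fit_stejskal_tanner(exp(0.5 * b * 1e-10), b, ramp$fractions)
  expect_equal(f2$D, 0)
  expect_true("clamped_negative_D" %in% f2$flags)
  # uniform scaling (a T2 factor) leaves D untouched
  I <- 10 * exp(-5 * b * 1e-10)
  expect_rel_equal(fit_stejskal_tanner(I, b, ramp$fractions)$D,
                   fit_stejskal_tanner(7.3 * I, b, ramp$fractions)$D, 1e-9)
})

test_that("ramp limits exclude low-gradient increments from the fit", {
  p <- dosy_params("traditional")   # acquisition ramp 5-95
  ramp <- gradient_ramp(p)
  b <- b_value(p, ramp$amplitudes)
  I <- exp(-0.5 * b * 1e-10)
  f <- fit_stejskal_tanner(I, b, ramp$fractions, ramp_limits_pct = c(25, 95))
  expect_true(all(ramp$fractions[f$ramp_indices_used] >= 0.25 - 1e-9))
  expect_lt(f$n_points_used, p$n_increments)
  expect_rel_equal(f$D, 0.5, 1e-6)
})

test_that("Monte-Carlo: mean fitted D is within the average stderr of truth", {
  p <- dosy_params("traditional")
  ramp <- gradient_ramp(p)
  b <- b_value(p, ramp$amplitudes)
  truth <- 7.2
  clean <- 100 * exp(-truth * b * 1e-10)
  fits <- withr::with_seed(11, lapply(1:100, function(i) {
    fit_stejskal_tanner(clean + rnorm(8, sd = 2), b, ramp$fractions)
  }))
  Ds <- vapply(fits, `[[`, numeric(1), "D")
  ses <- vapply(fits, `[[`, numeric(1), "stderr_D")
  expect_lt(abs(mean(Ds) - truth), mean(ses))
})

test_that("build_peak_list recovers ground truth on the urine phantom", {
  ph <- build_urine_phantom(42)
  ds <- simulate_dataset(ph, dosy_params("traditional"), seed = 42)
  sm <- process_dataset(ds, calibrate = "tsp")
  pl <- build_peak_list(sm, "urine42")
  expect_s3_class(pl, "dosy_peaklist")
  expect_gt(nrow(pl$peaks), 30)
  expect_false(any(pl$peaks$ppm >= 4.55 & pl$peaks$ppm <= 4.90))

  lines <- dosytools:::phantom_lines(ph, 600.13)
  lines <- lines[lines$class %in% c("small", "reference"), ]
  ok <- pl$peaks[pl$peaks$flags == "ok" & pl$peaks$rel_error <= 0.2, ]
  nearest <- vapply(ok$ppm, function(x) which.min(abs(lines$ppm - x)),
                    integer(1))
  # restrict to isolated lines: overlapping resonances legitimately fit
  # to an intensity-weighted average D, not their own
  isolated <- vapply(seq_along(ok$ppm), function(i) {
    d <- abs(lines$ppm - ok$ppm[i])
    j <- which.min(d)
    # multiplet partners share the species D, so only lines of *other*
    # species nearby make the averaged fit deviate from truth
    other <- lines$species != lines$species[j]
    d[j] < 0.005 && min(d[other]) > 0.02
  }, logical(1))
  dev <- abs(ok$D[isolated] - lines$D[nearest][isolated])
  se <- ok$D[isolated] * ok$rel_error[isolated]
  expect_gt(sum(isolated), 10)
  expect_gte(mean(dev <= 3 * se), 0.95)
})

test_that("empty spectra give empty, well-formed peak lists", {
  sm <- processed_single(noise = 0.02, seed = 3)
  pl <- build_peak_list(sm, "empty", threshold_multiple = 1e9)
  expect_equal(nrow(pl$peaks), 0)
  expect_identical(names(pl$peaks),
                   c("ppm", "D", "rel_error", "intensity", "flags"))
})

test_that("the display matrix places peaks and conserves intensity", {
  pl <- make_peaklist("s", ppm = c(3.0, 3.0), D = c(2.0, 8.0),
                      rel = c(0.02, 0.02), int = c(5, 5))
  m <- synthesize_dosy_matrix(pl, ppm_range = c(2.5, 3.5),
                              D_range = c(0, 12), n_D = 256L)
  # two separated maxima at the same ppm
  col <- which.min(abs(m$ppm - 3.0))
  prof <- m$matrix[, col]
  locmax <- which(prof[2:255] > prof[1:254] & prof[2:255] >= prof[3:256]) + 1
  expect_equal(length(locmax), 2)
  expect_equal(sort(m$D[locmax]), c(2.0, 8.0), tolerance = 0.1)
  # column integral over D equals summed intensity at the peak column
  dD <- m$D[2] - m$D[1]
  expect_equal(sum(prof) * dD, 10, tolerance = 0.01)

  one <- make_peaklist("s", 3.0, 5.0, 0.01, 7)
  m1 <- synthesize_dosy_matrix(one, ppm_range = c(2.8, 3.2))
  peak <- which(m1$matrix == max(m1$matrix), arr.ind = TRUE)[1, ]
  expect_equal(m1$D[peak[1]], 5.0, tolerance = 0.1)
  expect_equal(m1$ppm[peak[2]], 3.0, tolerance = 0.01)
  expect_error(synthesize_dosy_matrix(make_peaklist("s", numeric(), numeric(),
                                                    numeric(), numeric())),
               "empty")
})
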