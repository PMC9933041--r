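# Peak picking, per-peak decay extraction across the gradient ramp,
# Stejskal-Tanner fitting, and DOSY peak-list construction.
#
# The model is mono-exponential, I(b) = I0 * exp(-D b).  Overlapping
# resonances therefore yield an intensity-weighted average diffusion
# coefficient - an inherent property of intensity-decay DOSY, not a
# defect of the fitter.  Fits are initialized by log-linear regression
# of ln I on b and refined by nonlinear least squares on the raw
# intensities; the standard error of D comes from the parameter
# covariance at the optimum.  Diffusion coefficients are reported in
# units of 1e-10 m^2/s throughout.

#' Pick peaks on the first increment
#'
#' Local maxima of the real first-increment spectrum above
#' `threshold_multiple * noise_sd`, outside masked regions.  Each
#' maximum must additionally have a topographic prominence (height
#' above the highest saddle connecting it to taller spectrum) of at
#' least `prominence_multiple * noise_sd`, which rejects noise bumps
#' riding on the tails of strong resonances.
#'
#' @param sm a processed `spectrum_matrix` with `noise_sd` estimated.
#' @param threshold_multiple noise-multiple threshold (default 5).
#' @param prominence_multiple noise-multiple prominence requirement
#'   (default 5; 0 disables it).
#' @param regions optional list of `c(low, high)` ppm intervals; picks
#'   are restricted to their union.
#' @return data frame with columns `ppm`, `index`, `height` (possibly
#'   empty).
#' @export
pick_peaks <- function(sm, threshold_multiple = 5, prominence_multiple = 5,
                       regions = NULL) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  if (is.na(sm$noise_sd))
    stop_invalid("noise_sd not estimated; run estimate_noise() first")
  y <- Re(sm$signal[1, ])
  n <- length(y)
  thr <- threshold_multiple * sm$noise_sd
  cand <- which(y > thr)
  cand <- cand[cand > 1L & cand < n]
  is_max <- y[cand] > y[cand - 1L] & y[cand] >= y[cand + 1L]
  idx <- cand[is_max]
  idx <- idx[!sm$mask[idx]]
  if (prominence_multiple > 0 && length(idx)) {
    pmin_req <- prominence_multiple * sm$noise_sd
    keep <- vapply(idx, function(i) {
      h <- y[i]
      # walk each side until a higher point; track the deepest dip
      dipL <- h
      j <- i - 1L
      while (j >= 1L && y[j] <= h) {
        if (y[j] < dipL) dipL <- y[j]
        if (h - dipL >= pmin_req) break
        j <- j - 1L
      }
      dipR <- h
      j <- i + 1L
      while (j <= n && y[j] <= h) {
        if (y[j] < dipR) dipR <- y[j]
        if (h - dipR >= pmin_req) break
        j <- j + 1L
      }
      # the key saddle is the shallower dip: both sides must drop
      (h - dipL >= pmin_req) && (h - dipR >= pmin_req)
    }, logical(1))
    idx <- idx[keep]
  }
  if (!is.null(regions)) {
    keep <- rep(FALSE, length(idx))
    for (r in regions)
      keep <- keep | (sm$ppm_axis[idx] >= min(r) & sm$ppm_axis[idx] <= max(r))
    idx <- idx[keep]
  }
  data.frame(ppm = sm$ppm_axis[idx], index = idx, height = y[idx])
}

#' Extract the per-increment decay of one pick
#'
#' Intensity at each increment is the maximum of the real spectrum
#' within `window_ppm` (full width) of the pick position; the window
#' maximum tracks the peak top under small shifts and noise.
#'
#' @param sm a `spectrum_matrix`.
#' @param pick one row of [pick_peaks()] output (or a list with `ppm`).
#' @param window_ppm full window width, ppm.
#' @return numeric vector of length `n_increments`; attribute
#'   `"truncated"` is `TRUE` if the window overlapped a masked region
#'   and was truncated.
#' @export
extract_decay <- function(sm, pick, window_ppm = 0.005) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  p <- pick$ppm
  if (p < min(sm$ppm_axis) || p > max(sm$ppm_axis))
    stop_invalid("pick at %.4f ppm outside axis", p)
  sel <- which(sm$ppm_axis >= p - window_ppm / 2 &
               sm$ppm_axis <= p + window_ppm / 2)
  truncated <- any(sm$mask[sel])
  sel <- sel[!sm$mask[sel]]
  if (!length(sel)) stop_invalid("extraction window fully masked at %.4f ppm", p)
  v <- apply(Re(sm$signal[, sel, drop = FALSE]), 1, max)
  attr(v, "truncated") <- truncated
  v
}

#' Fit the Stejskal-Tanner decay model
#'
#' Fits \eqn{I(b) = I_0 \exp(-D b)} to one peak's intensity decay, using
#' only increments whose gradient fraction lies within
#' `ramp_limits_pct` (endpoints inclusive).  Initialization is by
#' log-linear regression of \eqn{\ln I} on \eqn{b} over the positive
#' intensities (grid search fallback when fewer than two are positive);
#' refinement is nonlinear least squares on the untransformed
#' intensities.  `stderr_D` is the standard error of D from the
#' covariance at the optimum.  Negative D estimates are clamped to zero
#' and flagged rather than rejected, preserving peak accounting.
#'
#' @param intensities numeric vector, one per increment.
#' @param b_values diffusion weightings, s m^-2 (SI), one per increment.
#' @param ramp_fractions gradient fractions (0-1) per increment; needed
#'   when `ramp_limits_pct` is given.
#' @param ramp_limits_pct optional `c(low, high)` percent limits
#'   restricting which increments enter the fit.
#' @return an object of class `decay_fit` with elements `D` (1e-10
#'   m^2/s), `I0`, `stderr_D`, `relative_error`, `residual_norm`,
#'   `n_points_used`, `ramp_indices_used`, `flags` (character vector;
#'   `"ok"` when clean).
#' @export
fit_stejskal_tanner <- function(intensities, b_values,
                                ramp_fractions = NULL,
                                ramp_limits_pct = NULL) {
  stopifnot(length(intensities) == length(b_values))
  use <- seq_along(intensities)
  if (!is.null(ramp_limits_pct)) {
    if (is.null(ramp_fractions))
      stop_invalid("ramp_fractions required with ramp_limits_pct")
    lo <- min(ramp_limits_pct) / 100 - 1e-9
    hi <- max(ramp_limits_pct) / 100 + 1e-9
    use <- which(ramp_fractions >= lo & ramp_fractions <= hi)
  }
  fail <- function(flag) structure(
    list(D = NA_real_, I0 = NA_real_, stderr_D = NA_real_,
         relative_error = NA_real_, residual_norm = NA_real_,
         n_points_used = length(use), ramp_indices_used = use,
         flags = flag),
    class = "decay_fit")
  if (length(use) < 3L) return(fail("too_few_points"))
  I <- intensities[use]
  if (I[1] <= 0) return(fail("nonpositive_first_intensity"))
  # work on the 1e-10 m^2/s scale for conditioning
  x <- b_values[use] * 1e-10
  flags <- character()

  pos <- I > 0
  if (sum(pos) >= 2L) {
    ll <- stats::lm(log(I[pos]) ~ x[pos])
    D0 <- -unname(stats::coef(ll)[2])
    I00 <- exp(unname(stats::coef(ll)[1]))
  } else {
    # grid-search fallback over decay rates
    grid <- 10^seq(-3, 2, length.out = 60)
    sse <- vapply(grid, function(d) {
      e <- exp(-d * x); a <- sum(I * e) / sum(e * e)
      sum((I - a * e)^2)
    }, numeric(1))
    D0 <- grid[which.min(sse)]
    I00 <- sum(I * exp(-D0 * x)) / sum(exp(-2 * D0 * x))
    flags <- c(flags, "grid_init")
  }
  if (!is.finite(D0)) D0 <- 1
  if (!is.finite(I00) || I00 <= 0) I00 <- max(I)

  dat <- data.frame(I = I, x = x)
  fit <- tryCatch(suppressWarnings(
    stats::nls(I ~ I0 * exp(-D * x), data = dat,
               start = list(I0 = I00, D = max(D0, 1e-6)),
               control = stats::nls.control(maxiter = 200, minFactor = 1e-10,
                                            scaleOffset = 1, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linear estimate with its own stderr
    if (sum(pos) >= 3L) {
      ll <- stats::lm(log(I[pos]) ~ x[pos])
      D <- -unname(stats::coef(ll)[2])
      se <- unname(sqrt(diag(stats::vcov(ll)))[2])
      I0 <- exp(unname(stats::coef(ll)[1]))
      res <- sqrt(sum((I - I0 * exp(-D * x))^2))
      flags <- c(flags, "nls_failed_loglinear")
    } else return(fail("fit_failed"))
  } else {
    cf <- stats::coef(fit)
    D <- unname(cf["D"]); I0 <- unname(cf["I0"])
    se <- tryCatch(unname(sqrt(diag(stats::vcov(fit)))["D"]),
                   error = function(e) NA_real_)
    res <- sqrt(sum(stats::resid(fit)^2))
  }
  if (D < 0) {
    D <- 0
    flags <- c(flags, "clamped_negative_D")
  }
  rel <- if (is.finite(se) && D > 0) se / D else Inf
  if (!length(flags)) flags <- "ok"
  structure(list(D = D, I0 = I0, stderr_D = se, relative_error = rel,
                 residual_norm = res, n_points_used = length(use),
                 ramp_indices_used = use, flags = flags),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit: D = %.4g x 1e-10 m^2/s (se %.3g, rel %.3g), %d points [%s]>\n",
              x$D, x$stderr_D, x$relative_error, x$n_points_used,
              paste(x$flags, collapse = ",")))
  invisible(x)
}

#' Build a DOSY peak list from a processed dataset
#'
#' Runs [pick_peaks()], [extract_decay()] and [fit_stejskal_tanner()]
#' for every pick.  Failed fits are flagged, never silently dropped.
#'
#' @param sm a processed `spectrum_matrix` whose metadata carries the
#'   acquisition [dosy_params()].
#' @param spectrum_id identifier recorded in the list.
#' @param threshold_multiple noise-multiple picking threshold.
#' @param prominence_multiple noise-multiple prominence requirement
#'   (see [pick_peaks()]).
#' @param window_ppm decay-extraction window, ppm.
#' @param ramp_limits_pct percent limits for the fit; defaults to the
#'   acquisition ramp limits.
#' @param regions optional ppm regions restricting the picks.
#' @return an object of class `dosy_peaklist`: `spectrum_id`, `peaks`
#'   (data frame `ppm`, `D`, `rel_error`, `intensity`, `flags`; D in
#'   1e-10 m^2/s) and `params_hash`.
#' @export
build_peak_list <- function(sm, spectrum_id = "spectrum",
                            threshold_multiple = 5, prominence_multiple = 5,
                            window_ppm = 0.005,
                            ramp_limits_pct = NULL, regions = NULL) {
  stopifnot(inherits(sm, "spectrum_matrix"))
  params <- sm$meta$params
  validate_dosy_params(params)
  ramp <- gradient_ramp(params)
  b <- b_value(params, ramp$amplitudes)
  limits <- ramp_limits_pct %||% c(params$ramp_min_pct, params$ramp_max_pct)
  picks <- pick_peaks(sm, threshold_multiple, prominence_multiple,
                      regions = regions)
  rows <- lapply(seq_len(nrow(picks)), function(i) {
    dec <- extract_decay(sm, picks[i, ], window_ppm)
    f <- fit_stejskal_tanner(dec, b, ramp$fractions, limits)
    flags <- f$flags
    if (isTRUE(attr(dec, "truncated"))) flags <- union(flags, "window_truncated")
    data.frame(ppm = picks$ppm[i], D = f$D, rel_error = f$relative_error,
               intensity = picks$height[i],
               flags = paste(setdiff(flags, if (length(flags) > 1) "ok" else character()),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  })
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ppm = numeric(), D = numeric(), rel_error = numeric(),
               intensity = numeric(), flags = character(),
               stringsAsFactors = FALSE)
  structure(list(spectrum_id = spectrum_id, peaks = peaks,
                 params_hash = str_hash(as.character(params_to_json(params)))),
            class = "dosy_peaklist")
}

#' @export
print.dosy_peaklist <- function(x, ...) {
  cat(sprintf("<dosy_peaklist '%s': %d peaks (params %s)>\n",
              x$spectrum_id, nrow(x$peaks), x$params_hash))
  invisible(x)
}

#' Render a peak list as a 2D DOSY display matrix
#'
#' Places every peak as a 2D Gaussian centered at (ppm, D), with the
#' diffusion-dimension width proportional to the fitting error (floored
#' so zero-error peaks remain visible).  Display only; never used for
#' quantification.  The integral of a peak's column over the D axis
#' equals its intensity.
#'
#' @param pl a `dosy_peaklist`.
#' @param ppm_range,D_range axis limits (`D_range` in 1e-10 m^2/s).
#' @param n_ppm,n_D grid sizes.
#' @param ppm_width Gaussian sigma in the ppm dimension.
#' @param D_width_scale multiplies `stderr_D` to give the D-dimension
#'   sigma.
#' @return list with `ppm`, `D` axes and `matrix` (`n_D` x `n_ppm`).
#' @export
synthesize_dosy_matrix <- function(pl, ppm_range = NULL, D_range = c(0, 12),
                                   n_ppm = 512L, n_D = 128L,
                                   ppm_width = 0.01, D_width_scale = 1) {
  stopifnot(inherits(pl, "dosy_peaklist"))
  pk <- pl$peaks[is.finite(pl$peaks$D), , drop = FALSE]
  if (!nrow(pk)) stop_invalid("peak list is empty")
  ppm_range <- ppm_range %||% range(pk$ppm) + c(-0.1, 0.1)
  ppm <- seq(ppm_range[1], ppm_range[2], length.out = n_ppm)
  Dax <- seq(D_range[1], D_range[2], length.out = n_D)
  dD <- Dax[2] - Dax[1]
  M <- matrix(0, n_D, n_ppm)
  for (i in seq_len(nrow(pk))) {
    wD <- max(D_width_scale * pk$D[i] * pk$rel_error[i], 2 * dD, na.rm = TRUE)
    gp <- exp(-(ppm - pk$ppm[i])^2 / (2 * ppm_width^2))
    gd <- exp(-(Dax - pk$D[i])^2 / (2 * wD^2))
    gd <- gd / (sum(gd) * dD)          # column integral = intensity
    M <- M + pk$intensity[i] * outer(gd, gp)
  }
  list(ppm = ppm, D = Dax, matrix = M)
}
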