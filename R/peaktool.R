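# Multi-spectrum peak filtering and CSV export: select reliable
# diffusion coefficients from many DOSY peak lists by chemical-shift
# ranges, a fitting-error ceiling and an intensity floor, then
# consolidate them into one table for cross-sample comparison.

#' Filter specification for peak extraction
#'
#' @param ppm_ranges list of `c(low, high)` ppm intervals; union
#'   semantics, endpoints inclusive on both ends.
#' @param max_relative_error maximum relative fitting error
#'   (stderr_D / D) a peak may carry; must be > 0 (`Inf` disables the
#'   criterion).
#' @param min_intensity intensity floor (absolute units of the peak
#'   lists).  The "noise" filter of the CSV extraction: low-intensity
#'   picks yield unreliable diffusion coefficients.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(ppm_ranges, max_relative_error = 0.2,
                        min_intensity = 0) {
  stopifnot(is.list(ppm_ranges))
  for (r in ppm_ranges)
    if (length(r) != 2 || r[1] >= r[2])
      stop_invalid("each ppm range must be c(low, high) with low < high")
  if (max_relative_error <= 0)
    stop_invalid("max_relative_error must be > 0")
  structure(list(ppm_ranges = ppm_ranges,
                 max_relative_error = max_relative_error,
                 min_intensity = min_intensity),
            class = "filter_spec")
}

in_ranges <- function(ppm, ranges) {
  keep <- rep(FALSE, length(ppm))
  for (r in ranges) keep <- keep | (ppm >= r[1] & ppm <= r[2])
  keep
}

#' Filter peak lists into a consolidated table
#'
#' Keeps exactly the peaks whose chemical shift lies in the union of
#' the ranges, whose relative fitting error is at most
#' `max_relative_error` and whose intensity is at least
#' `min_intensity`.  Peaks whose fit failed (non-finite D or error)
#' never pass.  Rows are sorted by (spectrum_id, ppm), so output is
#' deterministic.
#'
#' @param lists a list of `dosy_peaklist` objects (or a single one).
#' @param spec a [filter_spec()].
#' @return an object of class `dosy_table`: a data frame with columns
#'   `spectrum_id`, `ppm`, `D`, `rel_error`, `intensity`, carrying the
#'   spec as an attribute.  An empty result is an empty table, not an
#'   error.
#' @export
filter_peaks <- function(lists, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (inherits(lists, "dosy_peaklist")) lists <- list(lists)
  rows <- lapply(lists, function(pl) {
    pk <- pl$peaks
    if (!nrow(pk)) return(NULL)
    keep <- in_ranges(pk$ppm, spec$ppm_ranges) &
      is.finite(pk$D) &
      !is.na(pk$rel_error) & pk$rel_error <= spec$max_relative_error &
      pk$intensity >= spec$min_intensity
    if (!any(keep)) return(NULL)
    data.frame(spectrum_id = pl$spectrum_id, pk[keep, 1:4, drop = FALSE],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum_id = character(), ppm = numeric(), D = numeric(),
               rel_error = numeric(), intensity = numeric(),
               stringsAsFactors = FALSE)
  tab <- tab[order(tab$spectrum_id, tab$ppm), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("dosy_table", "data.frame"), filter_spec = spec)
}

#' Per-spectrum summary statistics over a chemical-shift range
#'
#' @param table a `dosy_table` from [filter_peaks()].
#' @param range `c(low, high)` ppm interval.
#' @return data frame with one row per spectrum: `spectrum_id`,
#'   `range_low`, `range_high`, `n_peaks`, `mean_D`, `sd_D` (`sd_D` is
#'   `NA` when `n_peaks` = 1).
#' @export
summarize_range <- function(table, range) {
  stopifnot(inherits(table, "dosy_table"), length(range) == 2)
  sel <- table$ppm >= min(range) & table$ppm <= max(range)
  sub <- table[sel, , drop = FALSE]
  ids <- unique(sub$spectrum_id)
  out <- lapply(ids, function(id) {
    d <- sub$D[sub$spectrum_id == id]
    data.frame(spectrum_id = id, range_low = min(range),
               range_high = max(range), n_peaks = length(d),
               mean_D = mean(d),
               sd_D = if (length(d) > 1) stats::sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(spectrum_id = character(), range_low = numeric(),
               range_high = numeric(), n_peaks = integer(),
               mean_D = numeric(), sd_D = numeric(),
               stringsAsFactors = FALSE)
}

#' Export a consolidated table as CSV
#'
#' Fixed header `spectrum_id,ppm,D_1e-10_m2s,rel_error,intensity`,
#' plain-decimal numbers, byte-stable for identical inputs.
#'
#' @param table a `dosy_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(table, path) {
  stopifnot(inherits(table, "dosy_table"))
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e)
                    stop_invalid("cannot write CSV to '%s': %s", path,
                                 conditionMessage(e)))
  on.exit(close(con))
  writeLines("spectrum_id,ppm,D_1e-10_m2s,rel_error,intensity", con)
  if (nrow(table)) {
    rows <- vapply(seq_len(nrow(table)), function(i)
      paste(table$spectrum_id[i], fmt_num(table$ppm[i], 8),
            fmt_num(table$D[i]), fmt_num(table$rel_error[i]),
            fmt_num(table$intensity[i]), sep = ","),
      character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Re-import a consolidated CSV
#'
#' Inverse of [export_csv()]; mainly used for round-trip verification.
#'
#' @param path CSV path.
#' @return a `dosy_table` (without a filter spec attribute).
#' @export
import_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("spectrum_id", "ppm", "D_1e.10_m2s", "rel_error", "intensity")
  if (!identical(names(df), expected))
    stop_invalid("'%s': unexpected CSV header", path)
  names(df) <- c("spectrum_id", "ppm", "D", "rel_error", "intensity")
  structure(df, class = c("dosy_table", "data.frame"))
}
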