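# Columnar text dialect for DOSY peak lists.  This is both the output
# of the fitting stage and the input dialect the filtering tool reads
# (a self-defined stand-in for toolbox peak-list exports; a converter
# for other dialects can be layered on load_peak_lists()).
#
#   # dosy_peak_list v1
#   # spectrum_id: <id>
#   # params_hash: <hash>
#   ppm<TAB>D_1e-10_m2s<TAB>rel_error<TAB>intensity<TAB>flags
#   <rows...>

PEAKLIST_HEADER <- "ppm\tD_1e-10_m2s\trel_error\tintensity\tflags"

#' Write a DOSY peak list to a text file
#'
#' @param pl a `dosy_peaklist`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(pl, path) {
  stopifnot(inherits(pl, "dosy_peaklist"))
  pk <- pl$peaks
  rows <- vapply(seq_len(nrow(pk)), function(i)
    paste(fmt_num(pk$ppm[i], 8), fmt_num(pk$D[i]), fmt_num(pk$rel_error[i]),
          fmt_num(pk$intensity[i]), pk$flags[i], sep = "\t"),
    character(1))
  writeLines(c("# dosy_peak_list v1",
               paste0("# spectrum_id: ", pl$spectrum_id),
               paste0("# params_hash: ", pl$params_hash),
               PEAKLIST_HEADER, rows), path)
  invisible(path)
}

parse_peak_list <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[1], "# dosy_peak_list"))
    stop_invalid("'%s': not a DOSY peak list (missing '# dosy_peak_list' header)",
                 path)
  hdr <- grep("^#", lines)
  get_field <- function(key) {
    m <- grep(paste0("^# ", key, ": "), lines, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, ": "), "", m[1]) else NA_character_
  }
  col_line <- setdiff(seq_along(lines), hdr)[1]
  if (is.na(col_line) || lines[col_line] != PEAKLIST_HEADER)
    stop_invalid("'%s': unparseable column header (expected '%s')",
                 path, PEAKLIST_HEADER)
  body <- lines[-c(hdr, col_line)]
  body <- body[nzchar(body)]
  rows <- vector("list", length(body))
  bad <- integer()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    nums <- suppressWarnings(as.numeric(f[1:4]))
    # rel_error may legitimately be Inf/NA for flagged fits; ppm and
    # intensity must parse
    if (length(f) != 5L || is.na(nums[1]) || is.na(nums[4])) {
      bad <- c(bad, i)
      next
    }
    rows[[i]] <- data.frame(ppm = nums[1], D = nums[2], rel_error = nums[3],
                            intensity = nums[4], flags = f[5],
                            stringsAsFactors = FALSE)
  }
  if (length(bad))
    warning(sprintf("'%s': skipped %d malformed line(s): data line %s",
                    path, length(bad), paste(bad, collapse = ", ")),
            call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  peaks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ppm = numeric(), D = numeric(), rel_error = numeric(),
               intensity = numeric(), flags = character(),
               stringsAsFactors = FALSE)
  structure(list(spectrum_id = get_field("spectrum_id") %||% basename(path),
                 peaks = peaks,
                 params_hash = get_field("params_hash")),
            class = "dosy_peaklist")
}

#' Load DOSY peak lists from files
#'
#' @param paths character vector of file paths (e.g. from
#'   `Sys.glob()`).  Malformed data lines are reported as warnings with
#'   their line numbers, not silently skipped.
#' @return a named list of `dosy_peaklist` objects (names =
#'   spectrum ids).
#' @export
load_peak_lists <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop_invalid("peak list file(s) not found: %s",
                 paste(missing, collapse = ", "))
  out <- lapply(paths, parse_peak_list)
  names(out) <- vapply(out, `[[`, character(1), "spectrum_id")
  out
}
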