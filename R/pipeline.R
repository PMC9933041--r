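# End-to-end pipeline: simulate (or import) -> process -> fit -> filter,
# with a single JSON-serializable configuration and reproducible,
# seed-driven artifacts.

#' Pipeline configuration
#'
#' A single JSON-serializable document driving [run_pipeline()].  Every
#' run writes the resolved configuration next to its outputs.
#'
#' @param kind sequence kind (see [dosy_params()]).
#' @param params_overrides named list of [dosy_params()] arguments
#'   overriding the kind defaults.
#' @param phantom `"urine"`, `"plasma"` or `"doped_water"`.
#' @param seeds integer vector; one simulated spectrum per seed
#'   (mandatory for simulation runs).
#' @param gw,target_points processing options.
#' @param calibrate `"none"`, `"glucose"` or `"tsp"` chemical-shift
#'   calibration mode; defaults to the convention for the phantom
#'   (glucose for plasma, tsp for urine).
#' @param water_region,noise_region ppm intervals.
#' @param threshold_multiple,window_ppm,ramp_limits_pct fit options.
#' @param filter a [filter_spec()], or `NULL` to keep every peak.
#' @param sim a [sim_options()] object.
#' @param out_dir output directory.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(kind = "traditional", params_overrides = list(),
                            phantom = c("urine", "plasma", "doped_water"),
                            seeds = 1L, gw = 1, target_points = 65536L,
                            calibrate = NULL,
                            water_region = c(4.55, 4.90),
                            noise_region = c(9.5, 10.0),
                            threshold_multiple = 5, window_ppm = 0.005,
                            ramp_limits_pct = NULL, filter = NULL,
                            sim = sim_options(), out_dir = tempfile("dosyrun")) {
  phantom <- match.arg(phantom)
  # glucose referencing needs visible glucose; the diffusion-edited
  # experiment suppresses it, so no in-spectrum calibration there
  calibrate <- calibrate %||%
    if (phantom == "plasma" && kind != "diffusion_edited") "glucose"
    else if (phantom == "urine") "tsp" else "none"
  structure(list(kind = kind, params_overrides = params_overrides,
                 phantom = phantom, seeds = as.integer(seeds), gw = gw,
                 target_points = as.integer(target_points),
                 calibrate = calibrate, water_region = water_region,
                 noise_region = noise_region,
                 threshold_multiple = threshold_multiple,
                 window_ppm = window_ppm, ramp_limits_pct = ramp_limits_pct,
                 filter = filter, sim = sim, out_dir = out_dir),
            class = "pipeline_config")
}

config_params <- function(config) {
  do.call(dosy_params, c(list(kind = config$kind), config$params_overrides))
}

config_phantom <- function(config, seed) {
  switch(config$phantom,
         urine = build_urine_phantom(seed, sim = config$sim),
         plasma = build_plasma_phantom(seed, sim = config$sim),
         doped_water = doped_water_phantom())
}

#' Run the DOSY pipeline
#'
#' Executes simulate -> process -> fit -> filter.  Stages are skippable:
#' a dataset or peak-list artifact that already exists on disk is reused
#' rather than recomputed, so a partially complete output directory can
#' be resumed.  All artifacts are reproducible bit-for-bit for a fixed
#' configuration and seed set.
#'
#' @param config a [pipeline_config()].
#' @param keep_spectra logical; also persist processed frequency-domain
#'   matrices under `spectra/`.
#' @return (invisibly) a list with the output directory and the paths of
#'   datasets, peak lists and the consolidated CSV.
#' @export
run_pipeline <- function(config, keep_spectra = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  logcon <- file(logf, "a")
  on.exit(close(logcon))
  say <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }
  cfg_json <- jsonlite::toJSON(
    c(unclass(config)[setdiff(names(config), c("filter", "sim"))],
      list(filter = if (!is.null(config$filter)) unclass(config$filter),
           sim = unclass(config$sim))),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  writeLines(cfg_json, file.path(out, "config.json"))

  params <- config_params(config)
  ids <- sprintf("%s_%s_seed%03d", config$phantom, config$kind, config$seeds)

  # stage 1: simulate
  ds_dirs <- file.path(out, "datasets", ids)
  for (i in seq_along(config$seeds)) {
    if (file.exists(file.path(ds_dirs[i], "data.bin"))) {
      say("simulate: reusing %s", ds_dirs[i])
      next
    }
    ph <- config_phantom(config, config$seeds[i])
    ds <- simulate_dataset(ph, params, seed = config$seeds[i],
                           sim = config$sim)
    write_dataset(ds, ds_dirs[i])
    say("simulate: wrote %s", ds_dirs[i])
  }

  # stages 2+3: process and fit
  pl_paths <- file.path(out, "peaklists", paste0(ids, ".tsv"))
  dir.create(file.path(out, "peaklists"), showWarnings = FALSE)
  if (keep_spectra) dir.create(file.path(out, "spectra"), showWarnings = FALSE)
  for (i in seq_along(ids)) {
    if (file.exists(pl_paths[i])) {
      say("fit: reusing %s", pl_paths[i])
      next
    }
    if (!file.exists(file.path(ds_dirs[i], "data.bin")))
      stop_invalid("stage failure (process): missing dataset artifact '%s'",
                   ds_dirs[i])
    ds <- read_dataset(ds_dirs[i])
    sm <- process_dataset(ds, gw = config$gw,
                          target_points = config$target_points,
                          calibrate = config$calibrate,
                          water_region = config$water_region,
                          noise_region = config$noise_region)
    if (keep_spectra)
      write_spectrum_matrix(sm, file.path(out, "spectra", ids[i]))
    pl <- build_peak_list(sm, spectrum_id = ids[i],
                          threshold_multiple = config$threshold_multiple,
                          window_ppm = config$window_ppm,
                          ramp_limits_pct = config$ramp_limits_pct)
    write_peak_list(pl, pl_paths[i])
    say("fit: wrote %s (%d peaks)", pl_paths[i], nrow(pl$peaks))
  }

  # stage 4: filter + consolidate
  lists <- load_peak_lists(pl_paths)
  fspec <- config$filter %||%
    filter_spec(list(c(min(vapply(lists, function(l)
      suppressWarnings(min(l$peaks$ppm, Inf)), numeric(1))) - 1,
      max(vapply(lists, function(l)
        suppressWarnings(max(l$peaks$ppm, -Inf)), numeric(1))) + 1)),
      max_relative_error = Inf)
  tab <- filter_peaks(lists, fspec)
  csv <- file.path(out, "table.csv")
  export_csv(tab, csv)
  say("filter: wrote %s (%d rows)", csv, nrow(tab))

  invisible(list(out_dir = out, datasets = ds_dirs, peak_lists = pl_paths,
                 table = csv))
}
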