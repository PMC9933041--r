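# Fixtures are built in code; no data files.

silent_water <- function()
  species("water", data.frame(center = 4.7, J = 0, n = 1L, amp = 0),
          D = 19, T2 = 0.1, linewidth = 8, presat = 1)

single_species_phantom <- function(ppm = 2.0, D = 7, T2 = 0.5, lw = 1.5,
                                   amp = 1, noise = 0) {
  phantom(list(species("x", data.frame(center = ppm, J = 0, n = 1L,
                                       amp = amp),
                       D = D, T2 = T2, linewidth = lw)),
          water = silent_water(), noise_sigma = noise)
}

doublet_phantom <- function(ppm = 2.0, J = 7, D = 7, T2 = 0.5, lw = 1.5,
                            amp = 1, noise = 0) {
  phantom(list(species("x", data.frame(center = ppm, J = J, n = 2L,
                                       amp = amp),
                       D = D, T2 = T2, linewidth = lw)),
          water = silent_water(), noise_sigma = noise)
}

# reduced digitization for speed: 4096 points, zero-fill to 16384
quick_sim <- function(...) sim_options(points = 4096L, ...)
process_quick <- function(ds, ...) process_dataset(ds, target_points = 16384L, ...)

# hand-built peak list for the filtering tool
make_peaklist <- function(id, ppm, D, rel, int,
                          flags = rep("ok", length(ppm))) {
  structure(list(spectrum_id = id,
                 peaks = data.frame(ppm = ppm, D = D, rel_error = rel,
                                    intensity = int, flags = flags,
                                    stringsAsFactors = FALSE),
                 params_hash = "deadbeef"),
            class = "dosy_peaklist")
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / abs(y), tol)
}
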