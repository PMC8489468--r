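# Shared fixtures. Everything is generated in code; nothing is read from
# disk except files the tests themselves write to tempdir().

# one centered lesion ellipse inside a healthy-tissue ellipse
fixture_spec <- function(grid = c(64L, 64L), lesion_adc = 0.8e-3,
                         tissue_adc = 1.4e-3, s0_tissue = 2000,
                         s0_lesion = 2800, background_s0 = 0, seed = 1L) {
  phantom_spec(grid, list(
    compartment("tissue", "ellipse", center = grid / 2,
                radii = grid * 0.38, s0 = s0_tissue, adc = tissue_adc),
    compartment("lesion1", "ellipse", center = grid / 2, radii = grid * 0.12,
                s0 = s0_lesion, adc = lesion_adc, is_lesion = TRUE)),
    background_s0 = background_s0, seed = seed)
}

fixture_gt <- function(...) generate_phantom(fixture_spec(...))

# small random stack for averaging oracles
fixture_random_stack <- function(seed = 1L, nb = 2L, nd = 3L, na = 3L,
                                 gs = c(8L, 8L)) {
  set.seed(seed)
  pr <- acquisition_protocol(b_values = seq_len(nb) * 100, n_directions = nd,
                             n_acquisitions = na, noise_sigma = 1,
                             intensity_ceiling = 4095L, seed = seed)
  dat <- array(runif(nb * nd * na * prod(gs), 0.1, 10),
               dim = c(nb, nd, na, gs))
  structure(list(data = dat, protocol = pr), class = "dwi_stack")
}

# desk-profile end-to-end run, computed once and cached for the session
desk_cache <- new.env(parent = emptyenv())
desk_pipeline_result <- function() {
  if (is.null(desk_cache$res)) {
    cfg <- pipeline_config("desk", global_seed = 1L)
    ws <- file.path(tempdir(), "quickdwi-desk-acceptance")
    desk_cache$res <- suppressMessages(run_pipeline(cfg, ws))
  }
  desk_cache$res
}
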