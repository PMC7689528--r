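# Shared fixtures: default bench objects built once per test run.
default_geom <- instrument_geometry()
default_spectrum <- kramers_spectrum()
default_qgrid <- q_grid()

# reduce one simulated measurement of a phantom in one call
simulate_and_reduce <- function(ph, mode = "noiseless", seed = NULL,
                                exposure = 600) {
  st <- simulate_stack(ph, default_geom, default_spectrum, exposure,
                       mode = mode, seed = seed)
  tr <- simulate_transmission(ph, default_spectrum)
  reduce_stack(st, tr, geometry = default_geom, grid = default_qgrid)
}

# a profile object with prescribed values on the default q grid
profile_of <- function(s, grid = default_qgrid) {
  structure(list(s = s, sd = rep(0, length(s)),
                 n_pixels = rep(1L, length(s)), q_grid = grid,
                 provenance = list(), metadata = list()),
            class = "ssaxs_profile")
}
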