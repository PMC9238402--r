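# Small fixtures shared across test files. Everything is generated in code;
# layouts are kept small so renders stay fast.

# compact plate: 2 x 5 grid on a 300 x 150 px raster, no edge exclusion
small_layout <- function(n_rows = 2, n_cols = 5, edge_margin = 0, ...) {
  plate_layout(n_rows = n_rows, n_cols = n_cols, edge_margin = edge_margin,
               width_px = 300, height_px = 150, origin_mm = c(8, 8), ...)
}

# noise-free rendered plate with uniform internal pH
render_uniform <- function(pH = 7.53, layout = small_layout(),
                           params = sensor_params_imager(),
                           instrument = instrument_imager(), L = 38000,
                           permeabilized = FALSE, noise = FALSE,
                           seed = 1) {
  colonies <- colony_grid(layout, pH_i = pH, permeabilized = permeabilized,
                          L = L)
  render_plate(layout, colonies, params, instrument, seed = seed,
               noise = noise)
}

# raw (unsubtracted) channel ratio of the forward model
raw_ratio <- function(pH, params, instrument, L = 38000) {
  I <- channel_intensities(cell_state(pH, L = L), params, instrument)
  I[["I_A"]] / I[["I_B"]]
}
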