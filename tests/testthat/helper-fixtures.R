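# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small rendered pair of a slanted plane, straight-ahead gaze, 63 px.
fx_pair63 <- function() fixture("pair63", function() {
  pl <- plane_stimulus(20, 60)
  tgt <- fixation_on_plane(pl, 0, 0)
  pose <- fixate(tgt, 60)
  render_stereo_pair(pl, pose, texture_seed = 11, px = 63)
})

fx_bank63 <- function() fixture("bank63", function() disparity_bank(px = 63))

fx_pop63 <- function() fixture("pop63", function() {
  population_response(fx_pair63(), fx_bank63(), pool_to = 43)
})

# Reduced-scale study: 6 x 6 orientation grid, 9 gazes, 63 px rendering.
# Used by the training, chance-level, scanpath and ring-ordering checks.
fx_config66 <- function() stereoslant_config(list(
  geometry = list(image_px = 63),
  grid = list(n_slant = 6, n_tilt = 6)))

fx_ds66 <- function() fixture("ds66", function() {
  generate_dataset(fx_config66())
})

fx_enc66 <- function() fixture("enc66", function() encode_dataset(fx_ds66()))

fx_model66 <- function() fixture("model66", function() {
  train_pipeline(fx_enc66())
})

# Synthetic linear vector fields (pure elementary components) on a grid.
linear_field <- function(type, n, c0 = 1) {
  ax <- seq_len(n) - (n + 1) / 2
  X1 <- matrix(ax, n, n); X2 <- matrix(ax, n, n, byrow = TRUE)
  switch(type,
         expansion = list(d1 = c0 * X1, d2 = c0 * X2),
         rotation = list(d1 = -c0 * X2, d2 = c0 * X1),
         shear = list(d1 = c0 * X2, d2 = c0 * X1),
         stretch = list(d1 = c0 * X1, d2 = -c0 * X2))
}
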