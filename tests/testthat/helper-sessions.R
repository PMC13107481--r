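# Shared fixtures, built once per test run and cached. Small sessions use
# block_size = 2 so every arm is visited even in short sessions; the
# acceptance session uses full task-scale parameters (10 simulated minutes).

.fixtures <- new.env(parent = emptyenv())

test_graph <- function() {
  if (is.null(.fixtures$graph)) .fixtures$graph <- build_xmaze_graph()
  .fixtures$graph
}

# ~130-s session with injected events and LFP, for module-level tests
small_event_session <- function() {
  if (is.null(.fixtures$small_ses)) {
    cfg <- sim_config(n_trials = 8, block_size = 2, n_mec = 40, n_ca1 = 8,
                      seed = 101)
    .fixtures$small_cfg <- cfg
    .fixtures$small_ses <- simulate_session(cfg, test_graph())
  }
  .fixtures$small_ses
}

small_event_decode <- function() {
  if (is.null(.fixtures$small_post)) {
    ses <- small_event_session()
    post <- crossval_decode(ses, test_graph(), k = 1)
    keep <- confidence_mask(post)
    .fixtures$small_post <- post
    .fixtures$small_keep <- keep
    .fixtures$small_lab <- label_nonlocal(post, ses$behavior, test_graph(),
                                          keep = keep)
  }
  list(post = .fixtures$small_post, keep = .fixtures$small_keep,
       lab = .fixtures$small_lab)
}

# event-free session for encoding / field tests
quiet_session <- function() {
  if (is.null(.fixtures$quiet_ses)) {
    cfg <- sim_config(n_trials = 12, block_size = 2, n_mec = 30, n_ca1 = 4,
                      event_rate = 0, seed = 202)
    .fixtures$quiet_ses <- simulate_session(cfg, test_graph(), lfp = FALSE)
  }
  .fixtures$quiet_ses
}

# open-field behavior shared by tuning-metric tests
open_field <- function() {
  if (is.null(.fixtures$of))
    .fixtures$of <- simulate_open_field(duration = 300, seed = 7)
  .fixtures$of
}

of_spikes <- function(params, seed = 1) {
  of <- open_field()
  set.seed(seed)
  rate <- tuning_rate_2d(params, of$x_cm, of$y_cm, of$hd_deg, of$speed_cm_s)
  mecnonlocal:::poisson_spikes(rate, of$time_s[2] - of$time_s[1])
}

# hand-built posterior from a MAP trace (for analysis-stage tests that do not
# need the decoder)
manual_posterior <- function(map_lin, dt = 0.002, spread = 0) {
  g <- test_graph()
  mb <- mecnonlocal:::nearest_grid_index(map_lin, g$bins$linear)
  structure(list(time = (seq_along(map_lin) - 0.5) * dt, dt = dt,
                 map_bin = mb, map_lin = map_lin,
                 spread_cm2 = rep(spread, length(map_lin)), bins = g$bins),
            class = "posterior")
}

# behavior trace of an immobile mouse parked at a linear position
parked_behavior <- function(lin, duration, fs = 500) {
  g <- test_graph()
  n <- duration * fs
  xy <- embed_linear(rep(lin, n), g)
  data.frame(time_s = (seq_len(n) - 1) / fs, x_cm = xy[, 1], y_cm = xy[, 2],
             linear_cm = lin, speed_cm_s = 0.5, hd_deg = 0)
}
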