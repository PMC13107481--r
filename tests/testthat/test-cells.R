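test_that("linear field detection recovers planted fields and rejects noise", {
  g <- test_graph()
  ses <- quiet_session()
  dur <- max(ses$behavior$time_s)
  # uniform-firing unit has no fields
  set.seed(16)
  f0 <- detect_linear_fields(runif(2000, 0, dur), ses$behavior, g,
                             n_shuffle = 200, seed = 1)
  expect_equal(nrow(f0), 0)
  # planted single-field cells: detected field contains the center (<= 1 bin)
  tun <- ses$ground_truth$tuning
  hits <- 0; tried <- 0
  for (u in seq_len(15)) {
    flds <- tun$fields[[u]]
    if (nrow(flds) != 1) next
    tried <- tried + 1
    f <- detect_linear_fields(ses$spikes$time_s[ses$spikes$unit_id == u],
                              ses$behavior, g, n_shuffle = 200, seed = 1)
    if (nrow(f) && any(f$start_lin - g$bin_size <= flds$center[1] &
                         f$end_lin + g$bin_size >= flds$center[1]))
      hits <- hits + 1
  }
  expect_gte(hits / tried, 0.7)
  # a narrow field (supra-null extent < 8 bins) is rejected by the length rule
  ctr <- 150
  set.seed(17)
  use <- ses$behavior$speed_cm_s > 2
  near <- abs(ses$behavior$linear_cm - ctr) < 3 & use
  narrow <- sort(ses$behavior$time_s[near][
    runif(sum(near, na.rm = TRUE)) < 0.15])
  fn <- detect_linear_fields(narrow, ses$behavior, g, n_shuffle = 200,
                             seed = 1)
  expect_true(nrow(fn) == 0 || all(fn$end_lin - fn$start_lin >= 16))
})

test_that("spatial information matches closed forms and sharpening order", {
  expect_equal(spatial_information(rep(3, 10), rep(1, 10)), 0)
  for (N in c(4, 8, 16))
    expect_equal(spatial_information(c(N, rep(0, N - 1)), rep(1, N)), log2(N))
  # monotone under field sharpening
  x <- seq(-10, 10, length.out = 101)
  si <- vapply(c(5, 3, 1.5), function(s)
    spatial_information(exp(-x^2 / (2 * s^2)), rep(1, 101)), 0)
  expect_true(all(diff(si) > 0))
  expect_equal(spatial_information(rep(0, 5), rep(1, 5)), 0)
})

test_that("active-cell composition reflects which ensembles carry a bout", {
  g <- test_graph()
  beh <- parked_behavior(2, duration = 2)
  map <- c(rep(2, 500), rep(220, 500))  # 1 s local, then 1 s nonlocal
  lab <- label_nonlocal(manual_posterior(map), beh, g)
  # two units: one with a field at the animal, one at the decoded target
  fields <- list(
    "1" = data.frame(bin0 = 1, bin1 = 9, start_lin = 0, end_lin = 18,
                     peak_lin = 2, peak_rate = 10),
    "2" = data.frame(bin0 = 99, bin1 = 107, start_lin = 212, end_lin = 228,
                     peak_lin = 220, peak_rate = 10))
  spikes <- data.frame(
    unit_id = rep(c(1, 2), each = 40),
    region = "MEC",
    time_s = c(runif(40, 0, 2), runif(40, 0, 2)))
  comp <- active_cell_composition(lab, spikes, fields, g)
  nl <- comp[comp$condition == "nonlocal", ]
  expect_equal(nl$frac_at_animal, 0.5)
  expect_equal(nl$frac_at_decoded, 0.5)
  expect_equal(nl$frac_at_both, 0)
  expect_true(all(comp$frac_at_both <=
                    pmin(comp$frac_at_animal, comp$frac_at_decoded)))
})

test_that("removing decoded-field spikes suppresses nonlocal coding", {
  g <- test_graph()
  ses <- small_event_session()
  out <- small_event_decode()
  # fields from ground truth (intervals center +/- 2 sigma)
  tun <- ses$ground_truth$tuning
  fields <- lapply(seq_len(nrow(tun$cells)), function(u) {
    f <- tun$fields[[u]]
    data.frame(bin0 = NA, bin1 = NA, start_lin = pmax(f$center - 2 * f$sigma, 0),
               end_lin = f$center + 2 * f$sigma, peak_lin = f$center,
               peak_rate = f$amp)
  })
  names(fields) <- as.character(tun$cells$unit_id)
  red <- remove_field_spikes_redecode(ses, out$lab, fields, g, k = 1)
  expect_equal(nrow(ses$spikes) - nrow(red$session$spikes), red$n_removed)
  expect_gt(red$n_removed, 0)
  before <- bout_statistics(out$lab)$summary$pct_immobile_time_nonlocal
  after <- bout_statistics(red$labels)$summary$pct_immobile_time_nonlocal
  expect_lt(after, 0.5 * before)
  # removing nothing leaves the spikes untouched
  none <- lapply(fields, function(f) f[0, ])
  red0 <- remove_field_spikes_redecode(ses, out$lab, none, g, k = 1)
  expect_equal(red0$n_removed, 0)
  expect_equal(nrow(red0$session$spikes), nrow(ses$spikes))
})

test_that("preferential recruitment flags event-locked units only", {
  dur <- 300
  bouts <- data.frame(t0 = seq(5, dur - 10, by = 9),
                      t1 = seq(5, dur - 10, by = 9) + 1)
  set.seed(18)
  inside <- unlist(lapply(seq_len(nrow(bouts)), function(k)
    runif(10, bouts$t0[k], bouts$t1[k])))
  expect_true(preferential_recruitment(inside, bouts, dur, n_shuffle = 199,
                                       seed = 2)$recruited)
  silent <- preferential_recruitment(numeric(0), bouts, dur,
                                     n_shuffle = 199, seed = 2)
  expect_false(silent$recruited)
  expect_error(preferential_recruitment(1:3, bouts[0, ], dur), "bouts")
})

test_that("tuning scores match their defining constructions", {
  of <- open_field()
  # rate proportional to speed: score near 1
  ts_speed <- of_spikes(list(class = "speed", slope = 0.5, base = 0.2), 21)
  sc <- tuning_scores(ts_speed, of)
  expect_gt(sc$speed_score, 0.9)
  # uniform HD tuning: score near 0; all mass in one 10-degree bin: score 1
  ts_unif <- of_spikes(list(class = "speed", slope = 0, base = 3), 22)
  expect_lt(tuning_scores(ts_unif, of)$hd_score, 0.1)
  one_bin <- of$time_s[of$hd_deg >= 40 & of$hd_deg < 50 & of$speed_cm_s > 2]
  sc1 <- tuning_scores(one_bin + 1e-4, of)
  expect_gt(sc1$hd_score, 0.98)
  # von Mises kappa = 4 ground truth: resultant near I1(4)/I0(4)
  ts_hd <- of_spikes(list(class = "hd", mu = 1.2, kappa = 4, peak = 12), 23)
  expect_equal(tuning_scores(ts_hd, of)$hd_score,
               besselI(4, 1) / besselI(4, 0), tolerance = 0.08)
})

test_that("grid and border scores separate their ground-truth classes", {
  of <- open_field()
  gsc <- grid_border_scores(tuning_scores(
    of_spikes(list(class = "grid", spacing = 35, angle = 0.3,
                   phase = c(15, 25), peak = 12), 24), of)$ratemap)
  expect_gt(gsc$grid_score, 0.5)
  bsc <- grid_border_scores(tuning_scores(
    of_spikes(list(class = "border", wall = 2, width = 6, peak = 10), 25),
    of)$ratemap)
  expect_gt(bsc$border_score, 0.5)
  blob <- grid_border_scores(tuning_scores(
    of_spikes(list(class = "aperiodic", cx = 37, cy = 37, sigma = 8,
                   peak = 10), 26), of)$ratemap)
  expect_lte(blob$grid_score, 0)
  expect_lt(blob$border_score, 0.5)
})

test_that("cell classification recovers classes and gates on stability", {
  of <- open_field()
  cl <- classify_cells(of_spikes(list(class = "grid", spacing = 35,
                                      angle = 0.3, phase = c(15, 25),
                                      peak = 12), 27),
                       of, n_shuffle = 60, seed = 5)
  expect_true(cl$flags[["spatial"]])
  expect_true(cl$flags[["grid"]])
  expect_false(cl$flags[["aperiodic"]])
  # unstable cell: field jumps between halves -> stability gate fails
  half <- max(of$time_s) / 2
  r1 <- tuning_rate_2d(list(class = "aperiodic", cx = 15, cy = 15, sigma = 6,
                            peak = 12), of$x_cm, of$y_cm, of$hd_deg,
                       of$speed_cm_s)
  r2 <- tuning_rate_2d(list(class = "aperiodic", cx = 60, cy = 60, sigma = 6,
                            peak = 12), of$x_cm, of$y_cm, of$hd_deg,
                       of$speed_cm_s)
  rate <- ifelse(of$time_s < half, r1, r2)
  set.seed(28)
  ts_unstable <- mecnonlocal:::poisson_spikes(rate, of$time_s[2] - of$time_s[1])
  cl2 <- classify_cells(ts_unstable, of, n_shuffle = 60, seed = 5)
  expect_false(cl2$flags[["spatial"]])
})

test_that("reward cells require a genuine rate increase on rewarded pokes", {
  set.seed(29)
  pokes <- data.frame(t0 = seq(1, 399, by = 4), t1 = seq(1, 399, by = 4) + 2)
  pokes$rewarded <- rep(c(TRUE, FALSE), 50)
  doubling <- unlist(lapply(seq_len(nrow(pokes)), function(i)
    runif(rpois(1, if (pokes$rewarded[i]) 12 else 6),
          pokes$t0[i], pokes$t1[i])))
  expect_true(reward_cells(sort(doubling), pokes)$flag)
  expect_false(reward_cells(numeric(0), pokes)$flag)
  expect_error(reward_cells(1:5, data.frame(t0 = 1, t1 = 2, rewarded = TRUE)),
               "rewarded")
})
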