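test_that("immobility detection applies the speed and merge rules", {
  g <- test_graph()
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  # constant running: no bouts
  none <- detect_immobility(rep(5, length(t)), t)
  expect_equal(nrow(none), 0)
  # two still periods separated by a 0.9-s gap and 1.5-cm displacement: merged
  speed <- rep(0.5, length(t))
  speed[t > 3 & t < 3.9] <- 5
  lin <- rep(100, length(t)); lin[t >= 3.9] <- 101.5
  m <- detect_immobility(speed, t, lin, g)
  expect_equal(nrow(m), 1)
  # a 1.5-s gap is never merged
  speed2 <- rep(0.5, length(t)); speed2[t > 3 & t < 4.5] <- 5
  m2 <- detect_immobility(speed2, t, lin, g)
  expect_equal(nrow(m2), 2)
  # sub-second gap with a large displacement is not merged either
  lin3 <- rep(100, length(t)); lin3[t >= 3.9] <- 110
  m3 <- detect_immobility(speed, t, lin3, g)
  expect_equal(nrow(m3), 2)
})

test_that("nonlocal labelling applies the 20-cm track-distance threshold", {
  g <- test_graph()
  beh <- parked_behavior(20, duration = 4)
  # MAP exactly at the animal: nothing nonlocal
  post <- manual_posterior(rep(20, 2000))
  lab <- label_nonlocal(post, beh, g)
  expect_equal(sum(lab$flags$nonlocal), 0)
  expect_equal(nrow(lab$bouts), 0)
  # 19.9 cm is local, 20.1 cm is nonlocal
  map <- rep(c(39.9, 40.1), each = 1000)
  lab2 <- label_nonlocal(manual_posterior(map), beh, g)
  fl2 <- lab2$flags
  expect_false(any(fl2$nonlocal[1:1000]))
  expect_true(all(fl2$local[1:1000]))
  # every kept immobile bin of the far half is nonlocal (the trace's final
  # bin can fall beyond the behavior samples and is excluded)
  far <- 1001:2000
  expect_true(all(fl2$nonlocal[far][fl2$immobile[far] & fl2$kept[far]]))
  expect_gte(sum(fl2$nonlocal), 999)
  # partition invariant: kept immobile bins are exactly local or nonlocal
  fl <- lab2$flags
  expect_true(all((fl$immobile & fl$kept) == (fl$local | fl$nonlocal)))
})

test_that("bout statistics compute exact fractions", {
  g <- test_graph()
  beh <- parked_behavior(20, duration = 1)
  map <- rep(20, 500); map[126:250] <- 140  # 250 ms nonlocal in a 1-s bout
  lab <- label_nonlocal(manual_posterior(map, dt = 0.002), beh, g)
  bs <- bout_statistics(lab)
  expect_equal(bs$summary$pct_bouts_with_nonlocal, 100)
  expect_equal(bs$per_bout$pct_nonlocal, 25, tolerance = 0.01)
  expect_equal(bs$summary$pct_immobile_time_nonlocal, 25, tolerance = 0.01)
})

test_that("distance-speed histogram is column-normalized with a far mode", {
  g <- test_graph()
  set.seed(12)
  n <- 5000
  speed <- runif(n, 0, 40)
  dist <- ifelse(speed < 2, sample(c(0, 115), n, TRUE, c(0.4, 0.6)),
                 abs(rnorm(n, 2, 1)))
  h <- distance_speed_histogram(dist, speed)
  cs <- colSums(h, na.rm = TRUE)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))
  # perfect decode: all mass in the first distance row
  h0 <- distance_speed_histogram(rep(0, 100), runif(100, 0, 30))
  expect_true(all(h0[1, ] == 1 | is.nan(h0[1, ])))
  # immobility columns show the far mode near 100-130 cm
  far_rows <- which(as.numeric(sub("^[(\\[]([0-9.]+),.*", "\\1",
                                   rownames(h))) >= 95)
  imm_cols <- 1
  expect_gt(sum(h[far_rows, imm_cols]), 0.3)
})

test_that("segment representation matches construction and sums to one", {
  g <- test_graph()
  # mouse parked at the N sample port; all events decode to choice rewards
  beh <- parked_behavior(2, duration = 10)
  map <- rep(2, 5000)
  map[1001:2000] <- 220   # N choice reward
  map[3001:4000] <- 285   # S choice reward
  lab <- label_nonlocal(manual_posterior(map), beh, g)
  sr <- segment_representation(lab, g)
  at_sr <- sr[sr$mouse_segment == "sample_reward", ]
  expect_equal(at_sr$fraction[at_sr$decoded_segment == "choice_reward"], 1)
  expect_equal(sum(at_sr$fraction, na.rm = TRUE), 1)
  # chance column reproduces the analytic geometry
  expect_equal(sr$chance[sr$mouse_segment == "sample_reward" &
                           sr$decoded_segment == "center"],
               chance_level("sample_reward", "center", g))
})

test_that("paired-reward fractions follow the rule and flip under nonmatch", {
  g <- test_graph()
  # construct: mouse at N sample port for 4 s then N choice port; trial table
  trials <- data.frame(trial = 1, sample_arm = "N", choice_arm = "N",
                       correct = TRUE, sample_poke_t = 0, choice_poke_t = 4)
  beh <- rbind(parked_behavior(2, 4), parked_behavior(223, 4))
  beh$time_s <- (seq_len(nrow(beh)) - 1) / 500
  # all nonlocal content at the sample port decodes to the N choice reward
  map <- c(rep(220, 2000), rep(7, 2000))
  lab <- label_nonlocal(manual_posterior(map), beh, g)
  pm <- paired_reward_analysis(lab, trials, "match", g)
  sm <- pm[pm$at == "sample" & pm$correct, ]
  expect_equal(sm$frac_paired, 1)   # match rule: same-side reward is paired
  cm <- pm[pm$at == "choice" & pm$correct, ]
  expect_equal(cm$frac_paired, 1)
  # nonmatch relabels the same events as unpaired
  pn <- paired_reward_analysis(lab, trials, "nonmatch", g)
  expect_equal(pn$frac_paired[pn$at == "sample" & pn$correct], 0)
})

test_that("generator paired targeting is recovered by the analysis", {
  g <- test_graph()
  cfg <- sim_config(n_trials = 40, block_size = 2, paired_frac = 0.7,
                    event_rate = 0.8, seed = 13)
  beh <- simulate_behavior(cfg, g)
  ev <- inject_nonlocal_events(beh$behavior, g, cfg, beh$trials)
  expect_gt(nrow(ev), 150)
  # ground-truth-driven posterior: actual position, event targets during events
  dt <- 0.002
  tt <- seq(dt / 2, max(beh$behavior$time_s), by = dt)
  idx <- pmin(pmax(round(tt * 500) + 1, 1), nrow(beh$behavior))
  map <- beh$behavior$linear_cm[idx]
  for (k in seq_len(nrow(ev)))
    map[tt >= ev$t0[k] & tt <= ev$t1[k]] <- ev$target_lin[k]
  lab <- label_nonlocal(manual_posterior(map), beh$behavior, g)
  pr <- paired_reward_analysis(lab, beh$trials, cfg$rule, g, seed = 1)
  pooled <- weighted.mean(pr$frac_paired, pr$n_bins, na.rm = TRUE)
  expect_equal(pooled, 0.7, tolerance = 0.08)
})

test_that("trial-accuracy prediction is calibrated", {
  # null calibration averages over independent datasets: within one finite
  # sample the train/test splits share that sample's accidental separation
  set.seed(14)
  accs <- vapply(1:10, function(i) {
    f <- data.frame(pct_nonlocal = rnorm(200),
                    correct = rep(c(TRUE, FALSE), 100))
    predict_trial_accuracy(f, n_rep = 60, seed = i)$mean_accuracy
  }, 0)
  expect_equal(mean(accs), 0.5, tolerance = 0.03)
  f_sep <- data.frame(pct_nonlocal = c(rnorm(150, 20), rnorm(150, -20)),
                      correct = rep(c(TRUE, FALSE), each = 150))
  a_sep <- predict_trial_accuracy(f_sep, n_rep = 100, seed = 15)
  expect_gt(a_sep$mean_accuracy, 0.99)
  expect_error(predict_trial_accuracy(
    data.frame(pct_nonlocal = 1:5, correct = rep(TRUE, 5))), "class")
})
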