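test_that("trial structure follows blocks and the task rule", {
  g <- test_graph()
  cfg <- sim_config(n_trials = 20, p_correct = 1, rule = "match", seed = 31,
                    dwell_mean = 1.5)
  beh <- simulate_behavior(cfg, g)
  # blocks of ten, southwest (S) sample arm first
  expect_equal(beh$trials$sample_arm, rep(c("S", "N"), each = 10))
  # p_correct = 1 under match: choice side equals sample side
  expect_equal(beh$trials$choice_arm, beh$trials$sample_arm)
  expect_true(all(beh$trials$correct))
  # nonmatch rule pairs opposite sides
  cfgn <- sim_config(n_trials = 6, block_size = 2, p_correct = 1,
                     rule = "nonmatch", seed = 31, dwell_mean = 1.5)
  behn <- simulate_behavior(cfgn, g)
  expect_true(all(behn$trials$choice_arm != behn$trials$sample_arm))
})

test_that("behavior trace has port dwells below the immobility threshold", {
  ses <- small_event_session()
  g <- test_graph()
  imm <- detect_immobility(ses$behavior$speed_cm_s, ses$behavior$time_s,
                           ses$behavior$linear_cm, g)
  # one dwell at the sample port and one at the choice port per trial
  expect_gte(nrow(imm), nrow(ses$trials))
  frac <- sum(imm$t1 - imm$t0) / max(ses$behavior$time_s)
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.7)
  # dwells happen at reward ports
  seg <- segment_of(ses$behavior$linear_cm[imm$i0], g)$segment
  expect_true(all(seg %in% c("sample_reward", "choice_reward")))
})

test_that("injected events respect rate, distance and target distribution", {
  g <- test_graph()
  cfg0 <- sim_config(n_trials = 4, block_size = 2, event_rate = 0, seed = 41)
  beh0 <- simulate_behavior(cfg0, g)
  expect_equal(nrow(inject_nonlocal_events(beh0$behavior, g, cfg0)), 0)

  probs <- c(sample_reward = 0.4, sample_arm = 0.05, center = 0.05,
             choice_arm = 0.1, choice_reward = 0.4)  # 80% rewards
  cfg <- sim_config(n_trials = 30, block_size = 2, event_rate = 2,
                    event_target_probs = probs, dwell_mean = 5, seed = 42)
  beh <- simulate_behavior(cfg, g)
  ev <- inject_nonlocal_events(beh$behavior, g, cfg)
  expect_gt(nrow(ev), 300)
  d <- track_distance(ev$target_lin, ev$mouse_lin, g)
  expect_true(all(d >= 20))
  frac_reward <- mean(ev$target_segment %in% c("sample_reward", "choice_reward"))
  expect_equal(frac_reward, 0.8, tolerance = 0.06)
  # events sit inside immobility
  imm <- detect_immobility(beh$behavior$speed_cm_s, beh$behavior$time_s,
                           beh$behavior$linear_cm, g)
  inside <- vapply(seq_len(nrow(ev)), function(k)
    any(ev$t0[k] >= imm$t0 & ev$t1[k] <= imm$t1 + 0.01), TRUE)
  expect_true(all(inside))
})

test_that("spike generation matches Poisson expectations and event drive", {
  g <- test_graph()
  ses <- small_event_session()
  cfg <- .fixtures$small_cfg
  tun <- ses$ground_truth$tuning
  # total count per cell ~ integral of the rate +/- 3 sqrt
  dt <- ses$behavior$time_s[2] - ses$behavior$time_s[1]
  idx <- mecnonlocal:::nearest_grid_index(ses$behavior$linear_cm, tun$grid)
  for (u in c(2, 17)) {
    lam <- sum(tun$rate_grid[u, idx]) * dt
    n_obs <- sum(ses$spikes$unit_id == u)
    # events add extra spikes for participating cells; allow upward slack
    extra <- 3 * cfg$event_gain * max(tun$fields[[u]]$amp) *
      sum(ses$ground_truth$events$t1 - ses$ground_truth$events$t0)
    expect_gt(n_obs, lam - 4 * sqrt(lam))
    expect_lt(n_obs, lam + 4 * sqrt(lam) + extra)
  }
  # during events, participating cells fire near gain x in-field rate
  ev <- ses$ground_truth$events
  long <- which(ev$t1 - ev$t0 > 0.2)
  rates <- unlist(lapply(long, function(k) {
    parts <- ses$ground_truth$participants[[k]]
    if (!length(parts)) return(NULL)
    n <- sum(ses$spikes$time_s >= ev$t0[k] & ses$spikes$time_s <= ev$t1[k] &
               ses$spikes$unit_id %in% parts)
    n / (ev$t1[k] - ev$t0[k]) / length(parts)
  }))
  expect_equal(mean(rates), cfg$event_gain * cfg$peak_rate,
               tolerance = 0.35)
  # zero-rate process produces no spikes
  expect_length(mecnonlocal:::poisson_spikes(rep(0, 1000), 0.002), 0)
})

test_that("tuning curves peak at their field centers and tile the track", {
  g <- test_graph()
  cfg <- sim_config(n_mec = 100, n_ca1 = 10, seed = 51)
  tun <- simulate_tuning(cfg, g)
  for (u in c(1, 30, 77)) {
    ctr <- tun$fields[[u]]$center[1]
    pk <- tun$grid[which.max(tun$rate_grid[u, ])]
    expect_lte(track_distance(pk, ctr, g), 2)
  }
  # every 2-cm bin covered by at least one MEC field (stated density)
  mec <- which(tun$cells$region == "MEC")
  covered <- vapply(test_graph()$bins$linear, function(p)
    any(vapply(mec, function(u)
      any(track_distance(rep(p, nrow(tun$fields[[u]])),
                         tun$fields[[u]]$center, g) <
            2 * tun$fields[[u]]$sigma), TRUE)), TRUE)
  expect_true(all(covered))
})

test_that("simulated LFP carries ripples during immobility and theta during movement", {
  ses <- small_event_session()
  lf <- ses$lfp
  expect_gt(nrow(lf$swr), 0)
  # ripple-band envelope exceeds 2 SD inside injected bursts
  b <- mecnonlocal:::bandpass_fir(lf$fs, 125, 200)
  env <- Mod(mecnonlocal:::analytic_signal(mecnonlocal:::fir_filtfilt(b, lf$ca1)))
  z <- (env - mean(env)) / sd(env)
  peak_z <- vapply(seq_len(nrow(lf$swr)), function(k)
    max(z[lf$t >= lf$swr$t0[k] & lf$t <= lf$swr$t1[k]]), 0)
  expect_true(all(peak_z > 2))
  # movement-epoch spectrum peaks in the 7-11 Hz theta band
  mov <- approx(ses$behavior$time_s, ses$behavior$speed_cm_s, lf$t, rule = 2)$y > 2
  runs <- mecnonlocal:::logical_runs(mov)
  longest <- which.max(runs$i1 - runs$i0)
  seg <- lf$mec[runs$i0[longest]:runs$i1[longest]]
  sm <- spectral_measures(seg, seg, lf$fs, window = 1)
  sel <- sm$freq > 2 & sm$freq < 30
  pk <- sm$freq[sel][which.max(sm$psd_x[sel])]
  expect_gte(pk, 7); expect_lte(pk, 11)
  # no-amplitude config injects nothing
  cfg0 <- sim_config(n_trials = 4, block_size = 2, ripple_amp = 0, seed = 61)
  beh0 <- simulate_behavior(cfg0, test_graph())
  expect_equal(nrow(simulate_lfp(beh0$behavior, cfg0)$swr), 0)
})

test_that("a session is reproducible from its master seed", {
  cfg <- sim_config(n_trials = 4, block_size = 2, n_mec = 10, n_ca1 = 3,
                    seed = 71)
  s1 <- simulate_session(cfg, test_graph())
  s2 <- simulate_session(cfg, test_graph())
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$lfp$ca1, s2$lfp$ca1)
  expect_identical(s1$ground_truth$events, s2$ground_truth$events)
})
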