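test_that("spike binning conserves counts and places spikes correctly", {
  empty <- bin_spikes(list(numeric(0)), 0, 1, 0.002)
  expect_true(all(empty == 0))
  one <- bin_spikes(list(0.0031), 0, 1, 0.002)
  expect_equal(which(one[, 1] == 1), 2)  # floor(t / dt) -> second bin
  set.seed(8)
  trains <- list(sort(runif(200, 0, 10)), sort(runif(50, 0, 10)))
  m <- bin_spikes(trains, 0, 10, 0.002)
  expect_equal(sum(m), 250)
})

test_that("encoding model recovers rate maps from simulated spiking", {
  g <- test_graph()
  ses <- quiet_session()
  sp <- ses$spikes[ses$spikes$region == "MEC", ]
  enc <- fit_encoding(sp, ses$behavior, g)
  # occupancy equals total movement time
  dt <- ses$behavior$time_s[2] - ses$behavior$time_s[1]
  mv_time <- sum(ses$behavior$speed_cm_s > 2 & !is.na(ses$behavior$linear_cm)) * dt
  expect_equal(sum(enc$occupancy), mv_time, tolerance = 1e-9)
  # fitted peak within 1 bin of the true field center for well-sampled cells
  tun <- ses$ground_truth$tuning
  hits <- 0; tried <- 0
  for (u in seq_len(20)) {
    flds <- tun$fields[[u]]
    if (nrow(flds) != 1) next
    tried <- tried + 1
    pk <- enc$bins$linear[which.max(enc$lambda[as.character(u), ])]
    if (track_distance(pk, flds$center[1], g) <= 2 * g$bin_size) hits <- hits + 1
  }
  expect_gte(hits / tried, 0.8)
  expect_error(fit_encoding(sp, ses$behavior, g, v_thr = 1e6), "movement")
})

test_that("transition kernels are stochastic and respect graph topology", {
  g <- test_graph()
  tr <- transition_model(g)
  for (K in tr$kernels) expect_equal(rowSums(K), rep(1, nrow(K)))
  expect_equal(tr$kernels$stationary, diag(115))
  expect_true(all(tr$kernels$fragmented == 1 / 115))
  expect_equal(rowSums(tr$switch), rep(1, 3))
  expect_equal(diag(tr$switch), rep(0.98, 3))
  # continuous kernel follows track distance, not layout distance: the last
  # bin of the N-sample arm is near the junction, so transition mass to the
  # first center-arm bin exceeds mass to the layout-adjacent S-port bin
  b_arm_end <- 25   # lin 49, 1 cm from the sample junction
  b_s_port <- 26    # lin 66, layout-adjacent but 50 cm away on the track
  b_center <- which.min(abs(g$bins$linear - 131))
  K <- tr$kernels$continuous
  expect_gt(K[b_arm_end, b_center], K[b_arm_end, b_s_port])
})

test_that("acausal posterior matches brute-force path enumeration", {
  set.seed(9)
  B <- 3; TT <- 4
  bindist <- abs(outer(1:B, 1:B, "-")) * 2
  cont <- exp(-bindist^2 / 8); cont <- cont / rowSums(cont)
  kernels <- list(diag(B), cont, matrix(1 / B, B, B))
  sw <- matrix(0.01, 3, 3); diag(sw) <- 0.98
  logemit <- matrix(rnorm(B * TT), B, TT)
  res <- mecnonlocal:::fb_smoother(logemit, kernels, sw, bindist, TRUE, TRUE)
  # oracle: enumerate all (3B)^T latent paths
  S <- 3 * B
  states <- expand.grid(d = 1:3, x = 1:B)
  trans <- matrix(0, S, S)
  for (i in 1:S) for (j in 1:S)
    trans[i, j] <- sw[states$d[i], states$d[j]] *
      kernels[[states$d[j]]][states$x[i], states$x[j]]
  e <- exp(logemit)
  paths <- as.matrix(expand.grid(rep(list(1:S), TT)))
  pp <- apply(paths, 1, function(p) {
    w <- (1 / S) * e[states$x[p[1]], 1]
    for (t in 2:TT) w <- w * trans[p[t - 1], p[t]] * e[states$x[p[t]], t]
    w
  })
  pp <- pp / sum(pp)
  marg_bf <- sapply(1:TT, function(t) sapply(1:B, function(x)
    sum(pp[states$x[paths[, t]] == x])))
  expect_equal(res$marginal, t(marg_bf), tolerance = 1e-12)
  joint_bf <- sapply(1:TT, function(t) sapply(1:S, function(s)
    sum(pp[paths[, t] == s])))
  ord <- order((states$d - 1) * B + states$x)
  expect_equal(res$joint, t(joint_bf[ord, ]), tolerance = 1e-12)
})

test_that("flat encoding and uniform transitions give a uniform posterior", {
  g <- test_graph()
  B <- nrow(g$bins)
  enc <- structure(list(
    lambda = matrix(5, 1, B, dimnames = list("1", NULL)),
    occupancy = rep(1, B), bins = g$bins, unit_ids = 1,
    sigma_bins = 1, rate_floor = 1e-3), class = "encoding")
  tr <- transition_model(g)
  tr$kernels <- list(matrix(1 / B, B, B), matrix(1 / B, B, B),
                     matrix(1 / B, B, B))
  counts <- bin_spikes(list(c(0.001, 0.005, 0.02)), 0, 0.03, 0.002)
  post <- decode_acausal(counts, enc, tr, g, return_marginal = TRUE)
  expect_true(all(abs(post$marginal - 1 / B) < 1e-12))
})

test_that("with p_switch = 0 and one dynamic the decoder is a plain HMM", {
  set.seed(10)
  B <- 5; TT <- 20
  bindist <- abs(outer(1:B, 1:B, "-")) * 2
  cont <- exp(-bindist^2 / 8); cont <- cont / rowSums(cont)
  logemit <- matrix(rnorm(B * TT), B, TT)
  res <- mecnonlocal:::fb_smoother(logemit, list(cont), matrix(1, 1, 1),
                                   bindist, TRUE, FALSE)
  # reference: textbook scaled forward-backward in R
  e <- exp(sweep(logemit, 2, apply(logemit, 2, max)))
  alpha <- matrix(0, B, TT)
  alpha[, 1] <- e[, 1] / sum(e[, 1])
  for (t in 2:TT) {
    a <- (t(cont) %*% alpha[, t - 1]) * e[, t]
    alpha[, t] <- a / sum(a)
  }
  beta <- matrix(1, B, TT)
  for (t in (TT - 1):1) {
    b <- cont %*% (e[, t + 1] * beta[, t + 1])
    beta[, t] <- b / sum(b)
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  expect_equal(res$marginal, t(gamma), tolerance = 1e-12)
})

test_that("posterior is normalized and movement decoding is accurate", {
  out <- small_event_decode()
  ses <- small_event_session()
  g <- test_graph()
  err <- decode_error(out$post, ses$behavior, g)
  mv <- err$speed > 2 & !is.na(err$dist_cm)
  expect_lt(median(err$dist_cm[mv]), 4)
  # dynamic marginal rows are probabilities
  expect_true(all(abs(rowSums(out$post$dyn) - 1) < 1e-9))
})

test_that("cross-validated decoding partitions time and stays accurate", {
  ses <- quiet_session()
  g <- test_graph()
  post_cv <- crossval_decode(ses, g, k = 5)
  post_full <- crossval_decode(ses, g, k = 1)
  expect_equal(length(post_cv$time), length(post_full$time))
  expect_equal(post_cv$time, post_full$time)  # exact fold partition
  err_cv <- decode_error(post_cv, ses$behavior, g)
  err_f <- decode_error(post_full, ses$behavior, g)
  mv <- err_cv$speed > 2 & !is.na(err_cv$dist_cm)
  m_cv <- median(err_cv$dist_cm[mv]); m_f <- median(err_f$dist_cm[mv])
  expect_lt(m_cv, 1.25 * m_f + 1)
  expect_error(crossval_decode(ses, g, k = 0), "k")
})

test_that("confidence mask keeps sharp posteriors and drops diffuse ones", {
  g <- test_graph()
  B <- nrow(g$bins)
  post <- manual_posterior(rep(100, 1000))
  post$spread_cm2 <- rep(0, 1000)
  expect_true(all(confidence_mask(post)))           # delta posterior kept
  post$spread_cm2 <- rep(5000, 1000)
  expect_false(any(confidence_mask(post)))          # uniform-like excluded
  set.seed(11)
  post$spread_cm2 <- runif(1000, 0, 1000)
  keep <- confidence_mask(post, mode = "percentile", threshold = 92.8)
  expect_equal(mean(!keep), 0.072, tolerance = 0.001)
})

test_that("naive-Bayes decoder handles degenerate and simulated inputs", {
  g <- test_graph()
  B <- nrow(g$bins)
  lam <- matrix(1e-3, 1, B, dimnames = list("1", NULL))
  lam[1, 40] <- 20
  enc <- structure(list(lambda = lam, occupancy = rep(1, B), bins = g$bins,
                        unit_ids = 1, sigma_bins = 1, rate_floor = 1e-3),
                   class = "encoding")
  nb <- naive_bayes_decode(list(seq(2, 8, by = 0.05)), enc, 0, 10)
  spiking <- nb$time > 2.5 & nb$time < 7.5
  expect_true(all(nb$map_bin[spiking] == 40))
  # uniform rates: all positions tied, deterministic lowest-index pick
  enc$lambda <- matrix(2, 1, B, dimnames = list("1", NULL))
  nb2 <- naive_bayes_decode(list(seq(0.05, 9.95, by = 0.1)), enc, 0, 10)
  expect_true(all(nb2$map_bin == 1))
  # agreement with the state-space MAP during simulated movement
  ses <- quiet_session()
  sp <- ses$spikes[ses$spikes$region == "MEC", ]
  enc3 <- fit_encoding(sp, ses$behavior, g)
  nb3 <- naive_bayes_decode(sp, enc3, 0, max(ses$behavior$time_s))
  ss <- crossval_decode(ses, g, k = 1)
  ssi <- pmin(pmax(round(nb3$time / ss$dt), 1), length(ss$map_lin))
  spd <- approx(ses$behavior$time_s, ses$behavior$speed_cm_s, nb3$time,
                rule = 2)$y
  mv <- spd > 2
  agree <- track_distance(nb3$map_lin[mv], ss$map_lin[ssi][mv], g) <= 10
  expect_gt(mean(agree), 0.8)
})

test_that("temporally shuffled control model loses position information", {
  ses <- quiet_session()
  g <- test_graph()
  shm <- shuffled_spike_model(ses, g, seed = 3, k = 2)
  expect_equal(nrow(shm$session$spikes), nrow(ses$spikes))  # counts preserved
  err_s <- decode_error(shm$posterior, ses$behavior, g)
  post <- crossval_decode(ses, g, k = 2)
  err <- decode_error(post, ses$behavior, g)
  mv <- err$speed > 2 & !is.na(err$dist_cm)
  expect_gt(median(err_s$dist_cm[mv], na.rm = TRUE),
            5 * median(err$dist_cm[mv]))
})
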