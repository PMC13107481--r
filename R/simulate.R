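#' Simulation configuration
#'
#' Parameters of the synthetic-session generator. Defaults emulate the task
#' conditions: 100 trials in alternating blocks of ten (southwest sample arm
#' first), immobility dwells at reward ports, Poisson place-cell spiking with
#' Gaussian fields tiling the 230-cm linearized track, discrete remote
#' reactivation events injected during immobility (remote-field cells fire at
#' a gain times their in-field rate while local-field cells keep firing),
#' CA1 units lag-coupled to MEC partners at 1-10 ms during local immobility
#' only, and LFP with movement theta and immobility ripple bursts.
#'
#' @param n_trials number of trials (default 100).
#' @param block_size trials per sample-arm block (default 10).
#' @param rule task rule, "match" or "nonmatch".
#' @param p_correct probability a trial's choice is correct.
#' @param run_speed,run_speed_sd mean and SD of running speed, cm/s.
#' @param dwell_mean,dwell_shape gamma mean (s) and shape of port dwells.
#' @param frame_rate camera frame rate, Hz; behavior is generated here and
#'   upsampled.
#' @param fs_pos position/analysis sampling rate, Hz.
#' @param n_mec,n_ca1 unit counts per region.
#' @param field_sigma Gaussian field width sigma, cm.
#' @param peak_rate,baseline_rate in-field peak and out-of-field rates, Hz.
#' @param event_rate nonlocal events per second of immobility.
#' @param event_dur_mean,event_dur_shape gamma mean (s) and shape of event
#'   durations.
#' @param event_gain multiplier on the in-field rate of remote-field cells
#'   during an event.
#' @param event_target_probs named probabilities over the five segments for
#'   event targets (default enriched at reward segments).
#' @param paired_frac if non-NULL, events during reward-port dwells target the
#'   paired (vs unpaired) opposite-end reward with this probability, instead
#'   of drawing from \code{event_target_probs}.
#' @param n_coupled_pairs number of truly coupled MEC-CA1 pairs.
#' @param coupling_gain probability an MEC spike evokes a lagged CA1 spike
#'   during local (non-event) immobility.
#' @param coupling_lag two-element range of the coupling lag, s.
#' @param fs_lfp LFP sampling rate, Hz.
#' @param ripple_rate ripples per second of immobility.
#' @param ripple_amp ripple amplitude in SDs of the background.
#' @param ripple_dur ripple duration, s.
#' @param ripple_freq ripple carrier frequency, Hz.
#' @param theta_freq,theta_amp movement theta frequency (Hz) and amplitude
#'   (SD units).
#' @param seed master seed; each stage derives its own child seed from it.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_trials = 100, block_size = 10, rule = c("match", "nonmatch"),
                       p_correct = 0.8, run_speed = 25, run_speed_sd = 4,
                       dwell_mean = 4, dwell_shape = 4,
                       frame_rate = 60, fs_pos = 500,
                       n_mec = 100, n_ca1 = 15,
                       field_sigma = 5, peak_rate = 10, baseline_rate = 0.5,
                       event_rate = 0.5, event_dur_mean = 0.25,
                       event_dur_shape = 4, event_gain = 2,
                       event_target_probs = c(sample_reward = 0.3, sample_arm = 0.1,
                                              center = 0.1, choice_arm = 0.1,
                                              choice_reward = 0.4),
                       paired_frac = NULL,
                       n_coupled_pairs = 10, coupling_gain = 0.3,
                       coupling_lag = c(0.001, 0.010),
                       fs_lfp = 625, ripple_rate = 0.3, ripple_amp = 5,
                       ripple_dur = 0.070, ripple_freq = 165,
                       theta_freq = 8, theta_amp = 1.5,
                       seed = 1) {
  rule <- match.arg(rule)
  cfg <- as.list(environment())
  stopifnot(p_correct >= 0, p_correct <= 1, event_rate >= 0, ripple_rate >= 0,
            all(event_target_probs >= 0))
  cfg$event_target_probs <- event_target_probs / sum(event_target_probs)
  structure(cfg, class = "sim_config")
}

# deterministic per-stage child seeds below 2^31
child_seed <- function(master, stage) {
  (as.integer(master) * 48271L + utf8ToInt(stage)[1] * 1009L +
     sum(utf8ToInt(stage))) %% 2147483629L
}

# nearest index into a sorted grid of centers (on-track points only)
nearest_grid_index <- function(lin, grid) {
  mid <- grid[-1] - diff(grid) / 2
  findInterval(lin, mid) + 1L
}

# node sequence of the port-to-port path as an arc-length -> linear map
port_path <- function(graph, from, to) {
  vp <- igraph::shortest_paths(graph$graph, from, to)$vpath[[1]]
  ids <- names(vp)
  steps <- list(); total <- 0
  for (k in seq_len(length(ids) - 1)) {
    a <- ids[k]; b <- ids[k + 1]
    ei <- which((graph$edges$from == a & graph$edges$to == b) |
                  (graph$edges$from == b & graph$edges$to == a))
    len <- graph$edges$length[ei]
    steps[[k]] <- list(edge = ei, fwd = graph$edges$from[ei] == a,
                       s0 = total, len = len)
    total <- total + len
  }
  list(total = total, to_linear = function(s) {
    s <- pmin(pmax(s, 0), total - 1e-9)
    out <- numeric(length(s))
    for (st in steps) {
      inb <- s >= st$s0 & s < st$s0 + st$len
      off <- s[inb] - st$s0
      if (!st$fwd) off <- st$len - off
      out[inb] <- graph$layout$lin_start[st$edge] + off
    }
    out
  })
}

port_linear <- function(graph, side, kind) {
  lay <- graph$layout
  nm <- paste0(side, "_", kind)
  i <- match(nm, graph$edges$id)
  # sample ports sit at the from-end (layout start), choice ports at the to-end
  if (kind == "sample") lay$lin_start[i] else lay$lin_end[i]
}
port_node <- function(side, kind) paste0(side, "_", kind, "_port")

#' Simulate X-maze behavior
#'
#' Generates a trial table and a position/speed/head-direction trace. Trials
#' run in blocks of \code{block_size} with the southwest (S) sample arm first;
#' the choice arm is correct with probability \code{p_correct} under the
#' configured rule (match: same side as the sample; nonmatch: opposite).
#' Behavior is generated at the camera frame rate with gamma-distributed
#' immobility dwells at the ports and near-constant running speed between
#' them, smoothed with a 15-frame Hanning window, then linearly upsampled to
#' \code{fs_pos}.
#'
#' @param config a \code{sim_config}.
#' @param graph a \code{track_graph}.
#' @param seed stage seed; defaults to a child of the config master seed.
#' @return list with \code{behavior} (data.frame time_s, x_cm, y_cm,
#'   linear_cm, speed_cm_s, hd_deg at \code{fs_pos}) and \code{trials}
#'   (data.frame trial, sample_arm, choice_arm, correct, sample_poke_t,
#'   choice_poke_t).
#' @export
simulate_behavior <- function(config, graph,
                              seed = child_seed(config$seed, "behavior")) {
  set.seed(seed)
  nt <- config$n_trials
  block <- rep(c("S", "N"), length.out = ceiling(nt / config$block_size))
  sample_arm <- rep(block, each = config$block_size)[seq_len(nt)]
  correct <- stats::runif(nt) < config$p_correct
  match_side <- if (config$rule == "match") sample_arm else ifelse(sample_arm == "N", "S", "N")
  choice_arm <- ifelse(correct, match_side, ifelse(match_side == "N", "S", "N"))

  fr <- config$frame_rate
  frames_x <- list(); frames_hd <- list()
  sample_poke <- choice_poke <- numeric(nt)
  t_now <- 0
  jitter_walk <- function(n, port_lin, lo, hi) {
    # reflected random walk along the reward zone; stays < 2 cm/s at 60 Hz
    p <- port_lin + cumsum(stats::rnorm(n, 0, 0.015))
    lo2 <- min(lo, hi); hi2 <- max(lo, hi)
    pmin(pmax(p, lo2 + 0.2), hi2 - 0.2)
  }
  dwell_frames <- function() {
    max(round(fr * stats::rgamma(1, shape = config$dwell_shape,
                                 scale = config$dwell_mean / config$dwell_shape)),
        round(fr * 0.5))
  }
  run_lin <- function(from_node, to_node) {
    v <- max(8, stats::rnorm(1, config$run_speed, config$run_speed_sd))
    pp <- port_path(graph, from_node, to_node)
    n <- ceiling(pp$total / v * fr)
    pp$to_linear(seq_len(n) / n * pp$total)
  }
  for (i in seq_len(nt)) {
    sp <- port_linear(graph, sample_arm[i], "sample")
    cp <- port_linear(graph, choice_arm[i], "choice")
    sample_poke[i] <- t_now
    nd <- dwell_frames()
    frames_x[[length(frames_x) + 1]] <-
      jitter_walk(nd, sp, sp, sp + graph$reward_length)
    t_now <- t_now + nd / fr
    r1 <- run_lin(port_node(sample_arm[i], "sample"), port_node(choice_arm[i], "choice"))
    frames_x[[length(frames_x) + 1]] <- r1
    t_now <- t_now + length(r1) / fr
    choice_poke[i] <- t_now
    nd <- dwell_frames()
    frames_x[[length(frames_x) + 1]] <- jitter_walk(nd, cp, cp - graph$reward_length, cp)
    t_now <- t_now + nd / fr
    if (i < nt) {
      r2 <- run_lin(port_node(choice_arm[i], "choice"), port_node(sample_arm[i + 1], "sample"))
      frames_x[[length(frames_x) + 1]] <- r2
      t_now <- t_now + length(r2) / fr
    }
  }
  lin60 <- unlist(frames_x)
  n60 <- length(lin60)
  t60 <- (seq_len(n60) - 1) / fr
  xy60 <- embed_linear(lin60, graph)
  han <- function(x, n = 15) {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n)); w <- w / sum(w)
    stats::filter(c(rep(x[1], n), x, rep(x[length(x)], n)), w,
                  sides = 2)[(n + 1):(n + length(x))]
  }
  x60 <- han(xy60[, 1]); y60 <- han(xy60[, 2])
  sp60 <- c(0, sqrt(diff(x60)^2 + diff(y60)^2)) * fr
  sp60 <- han(sp60)
  hd60 <- atan2(c(0, diff(y60)), c(1e-9, diff(x60)))
  still <- sp60 < 3
  for (k in which(still)) if (k > 1) hd60[k] <- hd60[k - 1]
  hd60 <- hd60 + stats::rnorm(n60, 0, 0.05)

  t500 <- seq(0, t60[n60], by = 1 / config$fs_pos)
  li <- function(v) stats::approx(t60, v, t500, rule = 2)$y
  x500 <- li(x60); y500 <- li(y60)
  behavior <- data.frame(
    time_s = t500, x_cm = x500, y_cm = y500,
    linear_cm = linearize(x500, y500, graph),
    speed_cm_s = pmax(li(sp60), 0),
    hd_deg = (li(hd60 * 180 / pi) + 360) %% 360
  )
  trials <- data.frame(trial = seq_len(nt), sample_arm = sample_arm,
                       choice_arm = choice_arm, correct = correct,
                       sample_poke_t = sample_poke, choice_poke_t = choice_poke,
                       stringsAsFactors = FALSE)
  list(behavior = behavior, trials = trials)
}

#' Simulate ground-truth tuning curves
#'
#' Assigns each unit Gaussian place fields on the linearized track
#' (field centers tile the track; a fraction of cells get a second field) and,
#' for MEC units, a 2D open-field tuning class (grid, border, head-direction,
#' speed or aperiodic-spatial) with parametric ground truth.
#'
#' @param config a \code{sim_config}.
#' @param graph a \code{track_graph}.
#' @param seed stage seed.
#' @return list of class \code{sim_tuning}: \code{cells} (unit table),
#'   \code{fields} (per-unit data.frame center/sigma/amp), \code{rate_grid}
#'   (units x 1-cm grid rates, Hz), \code{grid} (1-cm centers), and
#'   \code{class2d} parameters.
#' @export
simulate_tuning <- function(config, graph,
                            seed = child_seed(config$seed, "tuning")) {
  set.seed(seed)
  n <- config$n_mec + config$n_ca1
  region <- c(rep("MEC", config$n_mec), rep("CA1", config$n_ca1))
  grid <- chance_grid(graph)
  L <- graph$total_length
  # stratified centers per region guarantee both populations tile the track
  strat <- function(m) ((sample(m) - 0.5) / m * L +
                          stats::runif(m, -L / m / 2, L / m / 2)) %% L
  centers1 <- c(strat(config$n_mec), strat(config$n_ca1))
  # map arc position (0..230) onto layout coordinates via the 1-cm grid
  arc_to_lin <- function(a) grid[pmin(length(grid), pmax(1, ceiling(a)))]
  fields <- vector("list", n)
  for (c_i in seq_len(n)) {
    ctr <- arc_to_lin(centers1[c_i])
    if (stats::runif(1) < 0.3) ctr <- c(ctr, sample(grid, 1))
    fields[[c_i]] <- data.frame(
      center = ctr, sigma = config$field_sigma,
      amp = config$peak_rate * stats::runif(length(ctr), 0.7, 1.3))
  }
  rate_grid <- matrix(config$baseline_rate, n, length(grid))
  for (c_i in seq_len(n)) {
    for (k in seq_len(nrow(fields[[c_i]]))) {
      f <- fields[[c_i]][k, ]
      d <- track_distance(rep(f$center, length(grid)), grid, graph)
      rate_grid[c_i, ] <- rate_grid[c_i, ] + f$amp * exp(-d^2 / (2 * f$sigma^2))
    }
  }
  classes <- c("grid", "border", "hd", "speed", "aperiodic")
  class2d <- lapply(seq_len(n), function(c_i) {
    cl <- if (region[c_i] == "MEC") classes[1 + (c_i - 1) %% length(classes)] else "aperiodic"
    switch(cl,
      grid = list(class = "grid", spacing = stats::runif(1, 30, 50),
                  angle = stats::runif(1, 0, pi / 3),
                  phase = stats::runif(2, 0, 50), peak = config$peak_rate),
      border = list(class = "border", wall = sample(1:4, 1), width = 6,
                    peak = config$peak_rate),
      hd = list(class = "hd", mu = stats::runif(1, 0, 2 * pi), kappa = 4,
                peak = config$peak_rate),
      speed = list(class = "speed", slope = 0.3, base = 1),
      list(class = "aperiodic", cx = stats::runif(1, 10, 65),
           cy = stats::runif(1, 10, 65), sigma = 8, peak = config$peak_rate))
  })
  structure(list(
    cells = data.frame(unit_id = seq_len(n), region = region,
                       depth_um = round(stats::runif(n, 0, 2000)),
                       class2d = vapply(class2d, `[[`, "", "class"),
                       stringsAsFactors = FALSE),
    fields = fields, rate_grid = rate_grid, grid = grid, class2d = class2d
  ), class = "sim_tuning")
}

#' Inject ground-truth nonlocal events
#'
#' Places discrete remote-reactivation events inside immobility bouts as a
#' Poisson process at \code{event_rate}. Each event has a single constant
#' target position at least 20 cm of track distance from the concurrent animal
#' position, drawn from the configured distribution over segments (or, in
#' paired mode, from the paired/unpaired opposite-end reward of the current
#' trial).
#'
#' @param behavior behavior data.frame from \code{simulate_behavior}.
#' @param graph a \code{track_graph}.
#' @param config a \code{sim_config}.
#' @param trials trial table (required for paired mode).
#' @param seed stage seed.
#' @return data.frame with t0, t1, target_lin, mouse_lin, target_segment,
#'   paired (logical or NA).
#' @export
inject_nonlocal_events <- function(behavior, graph, config, trials = NULL,
                                   seed = child_seed(config$seed, "events")) {
  set.seed(seed)
  bouts <- detect_immobility(behavior$speed_cm_s, behavior$time_s,
                             behavior$linear_cm, graph)
  empty <- data.frame(t0 = numeric(0), t1 = numeric(0), target_lin = numeric(0),
                      mouse_lin = numeric(0), target_segment = character(0),
                      paired = logical(0))
  if (config$event_rate == 0 || nrow(bouts) == 0) return(empty)
  grid <- chance_grid(graph)
  gseg <- segment_of(grid, graph)$segment
  out <- list()
  for (b in seq_len(nrow(bouts))) {
    dur <- bouts$t1[b] - bouts$t0[b]
    if (dur < 0.3) next
    ne <- stats::rpois(1, config$event_rate * dur)
    if (ne == 0) next
    t0s <- sort(stats::runif(ne, bouts$t0[b], bouts$t1[b]))
    durs <- pmax(0.06, stats::rgamma(ne, shape = config$event_dur_shape,
                                     scale = config$event_dur_mean / config$event_dur_shape))
    last_end <- -Inf
    for (k in seq_len(ne)) {
      t0 <- max(t0s[k], last_end + 0.01)
      t1 <- min(t0 + durs[k], bouts$t1[b])
      if (t1 - t0 < 0.06) next
      idx <- findInterval(t0, behavior$time_s)
      mouse <- behavior$linear_cm[idx]
      if (is.na(mouse)) next
      d <- track_distance(rep(mouse, length(grid)), grid, graph)
      paired <- NA
      if (!is.null(config$paired_frac) && !is.null(trials)) {
        tinfo <- current_trial_side(t0, trials)
        if (is.null(tinfo)) next
        paired <- stats::runif(1) < config$paired_frac
        side <- paired_reward_side(tinfo$at, tinfo$side, trials$sample_arm[tinfo$trial],
                                   trials$choice_arm[tinfo$trial], config$rule,
                                   paired = paired)
        kind <- if (tinfo$at == "sample") "choice" else "sample"
        ok <- which(d >= 20 & gseg == paste0(kind, "_reward") &
                      segment_of(grid, graph)$side == side)
      } else {
        seg <- sample(names(config$event_target_probs), 1,
                      prob = config$event_target_probs)
        ok <- which(d >= 20 & gseg == seg)
        tries <- 0
        while (length(ok) == 0 && tries < 20) {
          seg <- sample(names(config$event_target_probs), 1,
                        prob = config$event_target_probs)
          ok <- which(d >= 20 & gseg == seg)
          tries <- tries + 1
        }
      }
      if (length(ok) == 0) next
      target <- grid[sample(rep(ok, 2), 1)]
      out[[length(out) + 1]] <- data.frame(
        t0 = t0, t1 = t1, target_lin = target, mouse_lin = mouse,
        target_segment = segment_of(target, graph)$segment, paired = paired)
      last_end <- t1
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# which trial phase contains time t: at the sample or choice reward port
current_trial_side <- function(t, trials) {
  i <- findInterval(t, trials$sample_poke_t)
  if (i < 1) return(NULL)
  if (t >= trials$choice_poke_t[i])
    list(trial = i, at = "choice", side = trials$choice_arm[i])
  else list(trial = i, at = "sample", side = trials$sample_arm[i])
}

# side of the paired (or unpaired) opposite-end reward under the task rule
paired_reward_side <- function(at, side, sample_arm, choice_arm, rule,
                               paired = TRUE) {
  flip <- function(s) ifelse(s == "N", "S", "N")
  base <- if (rule == "match") side else flip(side)
  if (paired) base else flip(base)
}

# inhomogeneous Poisson spikes from a rate vector on a uniform time grid
poisson_spikes <- function(rate, dt, t0 = 0) {
  n <- stats::rpois(length(rate), pmax(rate, 0) * dt)
  idx <- rep(seq_along(rate), n)
  if (!length(idx)) return(numeric(0))
  sort(t0 + (idx - 1) * dt + stats::runif(length(idx), 0, dt))
}

#' Generate spike trains for a session
#'
#' Inhomogeneous Poisson spiking driven by each unit's tuning evaluated at the
#' animal's current position. During an injected nonlocal event, units with a
#' field at the event target additionally fire at \code{event_gain} times
#' their rate at the target, while units with fields at the animal's position
#' keep firing at their local rate (local cells are not silenced). CA1 units
#' in coupled pairs receive an extra spike with probability
#' \code{coupling_gain} at a 1-10-ms lag after each partner MEC spike, during
#' non-event immobility only.
#'
#' @param tuning a \code{sim_tuning}.
#' @param behavior behavior data.frame.
#' @param events injected event table.
#' @param config a \code{sim_config}.
#' @param graph a \code{track_graph}.
#' @param seed stage seed.
#' @return list: \code{spikes} (data.frame unit_id, region, time_s, sorted per
#'   unit), \code{coupled_pairs} (data.frame mec, ca1, lag),
#'   \code{participants} (per-event unit-id lists).
#' @export
generate_spikes <- function(tuning, behavior, events, config, graph,
                            seed = child_seed(config$seed, "spikes")) {
  set.seed(seed)
  dt <- behavior$time_s[2] - behavior$time_s[1]
  nT <- nrow(behavior)
  pos_idx <- nearest_grid_index(behavior$linear_cm, tuning$grid)
  n <- nrow(tuning$cells)
  immobile <- behavior$speed_cm_s < 2
  ev_bin <- rep(0L, nT)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      i0 <- findInterval(events$t0[k], behavior$time_s)
      i1 <- findInterval(events$t1[k], behavior$time_s)
      ev_bin[i0:i1] <- k
    }
  }
  participants <- vector("list", nrow(events))
  spk <- vector("list", n)
  for (c_i in seq_len(n)) {
    rate <- tuning$rate_grid[c_i, pos_idx]
    if (nrow(events) && tuning$cells$region[c_i] == "MEC") {
      flds <- tuning$fields[[c_i]]
      # remote-field cells fire at their in-field rate (times the event gain)
      has_field <- vapply(seq_len(nrow(events)), function(k) {
        d <- track_distance(rep(events$target_lin[k], nrow(flds)),
                            flds$center, graph)
        any(d < 2 * flds$sigma)
      }, TRUE)
      for (k in which(has_field)) {
        sel <- ev_bin == k
        d <- track_distance(rep(events$target_lin[k], nrow(flds)),
                            flds$center, graph)
        rate[sel] <- rate[sel] +
          config$event_gain * max(flds$amp[d < 2 * flds$sigma])
        participants[[k]] <- c(participants[[k]], c_i)
      }
    }
    spk[[c_i]] <- poisson_spikes(rate, dt, behavior$time_s[1])
  }
  # MEC -> CA1 coupling during non-event immobility
  mec_ids <- which(tuning$cells$region == "MEC")
  ca1_ids <- which(tuning$cells$region == "CA1")
  np <- min(config$n_coupled_pairs, length(mec_ids) * length(ca1_ids))
  coupled <- data.frame(mec = integer(0), ca1 = integer(0), lag = numeric(0))
  if (np > 0 && length(ca1_ids)) {
    coupled <- data.frame(
      mec = sample(mec_ids, np, replace = np > length(mec_ids)),
      ca1 = sample(ca1_ids, np, replace = np > length(ca1_ids)),
      lag = stats::runif(np, config$coupling_lag[1], config$coupling_lag[2]))
    for (p in seq_len(np)) {
      ms <- spk[[coupled$mec[p]]]
      if (!length(ms)) next
      bi <- pmin(pmax(findInterval(ms, behavior$time_s), 1L), nT)
      ok <- immobile[bi] & ev_bin[bi] == 0L
      evoke <- ms[ok][stats::runif(sum(ok)) < config$coupling_gain]
      if (length(evoke))
        spk[[coupled$ca1[p]]] <- sort(c(spk[[coupled$ca1[p]]],
                                        evoke + coupled$lag[p]))
    }
  }
  spikes <- data.frame(
    unit_id = rep(seq_len(n), lengths(spk)),
    region = rep(tuning$cells$region, lengths(spk)),
    time_s = unlist(spk))
  list(spikes = spikes, coupled_pairs = coupled, participants = participants)
}

# pink (1/f) noise with unit variance via FFT spectral shaping
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1)
  shaped <- Re(stats::fft(f / sqrt(freq), inverse = TRUE)) / n
  as.numeric(scale(shaped))
}

#' Simulate LFP traces with ripples and theta
#'
#' CA1 trace: pink-noise background, plus 125-200-Hz-band ripple bursts of
#' configured amplitude injected during immobility at \code{ripple_rate}, plus
#' movement theta. MEC trace: background plus theta. Ground-truth ripple
#' intervals are returned.
#'
#' @param behavior behavior data.frame.
#' @param config a \code{sim_config}.
#' @param seed stage seed.
#' @return list: \code{fs}, \code{t}, \code{ca1}, \code{mec}, \code{swr}
#'   (data.frame t0, t1).
#' @export
simulate_lfp <- function(behavior, config,
                         seed = child_seed(config$seed, "lfp")) {
  set.seed(seed)
  fs <- config$fs_lfp
  dur <- max(behavior$time_s)
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  bg_ca1 <- pink_noise(n)
  bg_mec <- pink_noise(n)
  mov <- stats::approx(behavior$time_s, as.numeric(behavior$speed_cm_s >= 2),
                       t, rule = 2)$y
  theta <- config$theta_amp * sin(2 * pi * config$theta_freq * t) * mov
  ca1 <- bg_ca1 + theta * 0.5
  mec <- bg_mec + theta
  swr <- data.frame(t0 = numeric(0), t1 = numeric(0))
  if (config$ripple_rate > 0 && config$ripple_amp > 0) {
    bouts <- detect_immobility(behavior$speed_cm_s, behavior$time_s,
                               behavior$linear_cm)
    for (b in seq_len(nrow(bouts))) {
      durb <- bouts$t1[b] - bouts$t0[b]
      if (durb < 0.5) next
      nr <- stats::rpois(1, config$ripple_rate * durb)
      if (nr == 0) next
      starts <- sort(stats::runif(nr, bouts$t0[b],
                                  max(bouts$t0[b], bouts$t1[b] - config$ripple_dur)))
      starts <- starts[c(TRUE, diff(starts) > config$ripple_dur + 0.05)]
      for (s in starts) {
        i0 <- findInterval(s, t); i1 <- min(findInterval(s + config$ripple_dur, t), n)
        k <- i0:i1
        env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(k)))
        ca1[k] <- ca1[k] + config$ripple_amp * env *
          sin(2 * pi * config$ripple_freq * (t[k] - s))
        swr <- rbind(swr, data.frame(t0 = s, t1 = s + config$ripple_dur))
      }
    }
  }
  list(fs = fs, t = t, ca1 = ca1, mec = mec, swr = swr)
}

#' Simulate a complete session with ground truth
#'
#' Runs every generator stage under per-stage child seeds of the master seed
#' and assembles a session bundle.
#'
#' @param config a \code{sim_config}.
#' @param graph a \code{track_graph}; built with defaults if missing.
#' @param lfp generate LFP traces (default TRUE).
#' @return list of class \code{session}: meta, behavior, trials, spikes,
#'   units, lfp, and \code{ground_truth} (fields, events, swr, coupled_pairs).
#' @export
simulate_session <- function(config = sim_config(), graph = build_xmaze_graph(),
                             lfp = TRUE) {
  beh <- simulate_behavior(config, graph)
  tun <- simulate_tuning(config, graph)
  ev <- inject_nonlocal_events(beh$behavior, graph, config, beh$trials)
  sp <- generate_spikes(tun, beh$behavior, ev, config, graph)
  lf <- if (lfp) simulate_lfp(beh$behavior, config) else NULL
  units <- tun$cells
  structure(list(
    meta = list(animal = "synthetic", session = sprintf("sim%06d", config$seed),
                rule = config$rule, seed = config$seed,
                duration = max(beh$behavior$time_s),
                config_hash = config_hash(config)),
    behavior = beh$behavior, trials = beh$trials,
    spikes = sp$spikes, units = units, lfp = lf,
    ground_truth = list(tuning = tun, events = ev,
                        swr = if (lfp) lf$swr else NULL,
                        coupled_pairs = sp$coupled_pairs,
                        participants = sp$participants),
    config = config
  ), class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("session %s: %.0f s, %d trials, %d units (%d MEC / %d CA1), %d spikes\n",
              x$meta$session, x$meta$duration, nrow(x$trials), nrow(x$units),
              sum(x$units$region == "MEC"), sum(x$units$region == "CA1"),
              nrow(x$spikes)))
  invisible(x)
}

#' Simulate open-field foraging behavior
#'
#' Smooth random-walk (Ornstein-Uhlenbeck velocity) trajectory in a square
#' box, used for 2D tuning-metric ground truth.
#'
#' @param duration seconds.
#' @param box box side, cm.
#' @param fs sampling rate, Hz.
#' @param seed RNG seed.
#' @return data.frame time_s, x_cm, y_cm, hd_deg, speed_cm_s.
#' @export
simulate_open_field <- function(duration = 600, box = 75, fs = 50, seed = 1) {
  set.seed(seed)
  n <- duration * fs
  vx <- vy <- numeric(n)
  x <- y <- numeric(n)
  x[1] <- box / 2; y[1] <- box / 2
  th <- exp(-1 / (fs * 0.7)); sd_v <- 12 * sqrt(1 - th^2)
  for (i in 2:n) {
    vx[i] <- th * vx[i - 1] + stats::rnorm(1, 0, sd_v)
    vy[i] <- th * vy[i - 1] + stats::rnorm(1, 0, sd_v)
    x[i] <- x[i - 1] + vx[i] / fs
    y[i] <- y[i - 1] + vy[i] / fs
    if (x[i] < 0) { x[i] <- -x[i]; vx[i] <- -vx[i] }
    if (x[i] > box) { x[i] <- 2 * box - x[i]; vx[i] <- -vx[i] }
    if (y[i] < 0) { y[i] <- -y[i]; vy[i] <- -vy[i] }
    if (y[i] > box) { y[i] <- 2 * box - y[i]; vy[i] <- -vy[i] }
  }
  data.frame(time_s = (seq_len(n) - 1) / fs, x_cm = x, y_cm = y,
             hd_deg = (atan2(vy, vx) * 180 / pi + 360) %% 360,
             speed_cm_s = sqrt(vx^2 + vy^2))
}

#' Parametric 2D tuning rate
#'
#' Evaluates a ground-truth open-field tuning class at behavioral samples:
#' hexagonal-lattice grid, wall-adjacent border band, von Mises head
#' direction, linear speed gain, or a single aperiodic Gaussian blob.
#'
#' @param params a class-parameter list as produced by
#'   \code{simulate_tuning} (element of \code{class2d}), or built by hand with
#'   a \code{class} field.
#' @param x,y,hd_deg,speed behavioral samples; \code{box} the box side (cm).
#' @return rate vector, Hz.
#' @export
tuning_rate_2d <- function(params, x, y, hd_deg, speed, box = 75) {
  switch(params$class,
    grid = {
      k <- 4 * pi / (sqrt(3) * params$spacing)
      ang <- params$angle + c(0, pi / 3, 2 * pi / 3)
      z <- 0
      for (a in ang)
        z <- z + cos(k * (cos(a) * (x - params$phase[1]) +
                            sin(a) * (y - params$phase[2])))
      params$peak * pmax(z + 1.5, 0) / 4.5
    },
    border = {
      dwall <- switch(params$wall, y, box - y, x, box - x)
      params$peak * exp(-dwall^2 / (2 * params$width^2))
    },
    hd = {
      th <- hd_deg * pi / 180
      params$peak * exp(params$kappa * (cos(th - params$mu) - 1))
    },
    speed = params$base + params$slope * speed,
    aperiodic = params$peak *
      exp(-((x - params$cx)^2 + (y - params$cy)^2) / (2 * params$sigma^2)),
    stop("unknown tuning class"))
}
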