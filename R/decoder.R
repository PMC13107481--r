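#' Bin spike trains onto a uniform time grid
#'
#' @param spikes data.frame with unit_id and time_s, or a list of spike-time
#'   vectors.
#' @param t_start,t_end session span, s; bins are \code{[t_start + (i-1) dt,
#'   t_start + i dt)}.
#' @param dt bin width, s (default 0.002).
#' @param unit_ids units (columns) to include; defaults to all units present.
#' @return integer count matrix, time bins x units.
#' @export
bin_spikes <- function(spikes, t_start, t_end, dt = 0.002, unit_ids = NULL) {
  if (is.data.frame(spikes)) {
    if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
    spikes <- split(spikes$time_s, factor(spikes$unit_id, levels = unit_ids))
  } else if (is.null(unit_ids)) unit_ids <- seq_along(spikes)
  nT <- ceiling((t_end - t_start) / dt - 1e-9)
  counts <- matrix(0L, nT, length(spikes))
  for (j in seq_along(spikes)) {
    ts <- spikes[[j]]
    ts <- ts[ts >= t_start & ts < t_start + nT * dt]
    if (length(ts))
      counts[, j] <- tabulate(floor((ts - t_start) / dt) + 1L, nbins = nT)
  }
  colnames(counts) <- as.character(unit_ids)
  attr(counts, "t_start") <- t_start
  attr(counts, "dt") <- dt
  counts
}

# Gaussian smoothing within contiguous layout blocks (never across buffers)
smooth_blocks <- function(v, block, sigma) {
  if (sigma <= 0) return(v)
  half <- ceiling(4 * sigma)
  kern <- exp(-(-half:half)^2 / (2 * sigma^2))
  out <- v
  for (b in unique(block)) {
    idx <- which(block == b)
    x <- v[idx]
    n <- length(x)
    sm <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      w <- kern[(lo - i + half + 1):(hi - i + half + 1)]
      sm[i] <- sum(w * x[lo:hi]) / sum(w)
    }
    out[idx] <- sm
  }
  out
}

# layout block (edge index) of each decoder bin
bin_block <- function(graph) linear_to_edge(graph$bins$linear, graph)$edge

#' Fit the encoding model (per-unit rate maps)
#'
#' Mean firing rate of each unit in 2-cm linearized position bins over
#' movement samples (speed > \code{v_thr}), smoothed with a 1D Gaussian
#' (sigma = 1 bin) within each track block. Bins never visited keep the
#' smoothed estimate, floored at \code{rate_floor}.
#'
#' @param spikes data.frame (unit_id, time_s) or list of spike-time vectors.
#' @param behavior behavior data.frame (time_s, linear_cm, speed_cm_s).
#' @param graph a \code{track_graph}.
#' @param v_thr movement speed threshold, cm/s (default 2).
#' @param sigma_bins Gaussian smoothing sigma in bins (default 1).
#' @param rate_floor minimum rate, Hz (default 1e-3).
#' @param sample_mask optional logical mask over behavior samples; only masked
#'   samples are used for training (on top of the movement criterion).
#' @param unit_ids units to fit.
#' @return list of class \code{encoding}: \code{lambda} (units x bins, Hz),
#'   \code{occupancy} (s per bin), \code{bins}, \code{unit_ids}.
#' @export
fit_encoding <- function(spikes, behavior, graph, v_thr = 2, sigma_bins = 1,
                         rate_floor = 1e-3, sample_mask = NULL,
                         unit_ids = NULL) {
  if (is.data.frame(spikes)) {
    if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
    spikes <- split(spikes$time_s, factor(spikes$unit_id, levels = unit_ids))
  } else if (is.null(unit_ids)) unit_ids <- seq_along(spikes)
  dt_pos <- behavior$time_s[2] - behavior$time_s[1]
  use <- behavior$speed_cm_s > v_thr & !is.na(behavior$linear_cm)
  if (!is.null(sample_mask)) use <- use & sample_mask
  if (!any(use)) stop("no movement samples to train the encoding model on")
  bins <- graph$bins
  B <- nrow(bins)
  pos_bin <- nearest_grid_index(behavior$linear_cm, bins$linear)
  occ_counts <- tabulate(pos_bin[use], nbins = B)
  occupancy <- occ_counts * dt_pos
  block <- bin_block(graph)
  occ_s <- smooth_blocks(occupancy, block, sigma_bins)
  lambda <- matrix(rate_floor, length(spikes), B)
  # spike -> nearest behavior sample; kept only if that sample is usable
  t0 <- behavior$time_s[1]
  nS <- nrow(behavior)
  for (j in seq_along(spikes)) {
    ts <- spikes[[j]]
    if (!length(ts)) next
    si <- pmin(pmax(round((ts - t0) / dt_pos) + 1L, 1L), nS)
    si <- si[use[si]]
    if (!length(si)) next
    cnt <- tabulate(pos_bin[si], nbins = B)
    lam <- smooth_blocks(cnt, block, sigma_bins) / pmax(occ_s, 1e-12)
    lam[occ_s <= 0] <- rate_floor
    lambda[j, ] <- pmax(lam, rate_floor)
  }
  rownames(lambda) <- as.character(unit_ids)
  structure(list(lambda = lambda, occupancy = occupancy, bins = bins,
                 unit_ids = unit_ids, sigma_bins = sigma_bins,
                 rate_floor = rate_floor, v_thr = v_thr),
            class = "encoding")
}

#' Transition model of the switching decoder
#'
#' Three latent movement dynamics, each with its own position kernel:
#' stationary (identity), continuous (Gaussian in track distance with
#' \code{sigma_cont} bins), fragmented (uniform). The dynamic-switch matrix
#' keeps 1 - p_switch on the diagonal and splits p_switch equally between the
#' other two dynamics.
#'
#' @param graph a \code{track_graph}.
#' @param sigma_cont continuous-kernel sigma in position bins per time step
#'   (default 1.0, with 6.0 as the broad alternative).
#' @param p_switch total per-step probability of leaving the current dynamic
#'   (default 0.02).
#' @return list of class \code{transition_model}: \code{kernels} (list of
#'   B x B row-stochastic matrices, order stationary / continuous /
#'   fragmented), \code{switch} (3 x 3), \code{bindist}.
#' @export
transition_model <- function(graph, sigma_cont = 1.0, p_switch = 0.02) {
  bindist <- bin_distance_matrix(graph)
  B <- nrow(bindist)
  cont <- exp(-(bindist / graph$bin_size)^2 / (2 * sigma_cont^2))
  cont <- cont / rowSums(cont)
  kernels <- list(stationary = diag(B), continuous = cont,
                  fragmented = matrix(1 / B, B, B))
  sw <- matrix(p_switch / 2, 3, 3)
  diag(sw) <- 1 - p_switch
  structure(list(kernels = kernels, switch = sw, bindist = bindist,
                 sigma_cont = sigma_cont, p_switch = p_switch),
            class = "transition_model")
}

# position log-likelihood under independent-Poisson emissions, B x T
poisson_logemission <- function(counts, encoding, dt) {
  lam <- pmax(encoding$lambda, encoding$rate_floor)  # units x bins
  ll <- counts %*% log(lam)                          # T x B
  ll <- sweep(ll, 2, dt * colSums(lam))
  t(ll)
}

#' Acausal switching-dynamics decoding
#'
#' Runs the forward-backward smoother over the joint (dynamic x position)
#' state with independent-Poisson emissions, returning the acausal posterior
#' summaries: MAP position per time bin (argmax of the position marginal
#' summed across dynamics; lowest bin on ties), the dynamic marginal, and the
#' posterior spread (mean squared track distance from the MAP bin, cm^2) used
#' for confidence masking.
#'
#' @param counts spike count matrix from \code{bin_spikes} (time x units).
#' @param encoding an \code{encoding} fit on the same units, same column
#'   order.
#' @param transitions a \code{transition_model}.
#' @param graph a \code{track_graph}.
#' @param return_marginal,return_joint also return the full position marginal
#'   (time x bins) / joint posterior (time x 3 bins) - memory-heavy for long
#'   sessions.
#' @return list of class \code{posterior}: \code{time} (bin centers, s),
#'   \code{map_bin}, \code{map_lin}, \code{dyn} (time x 3), \code{spread_cm2},
#'   optionally \code{marginal} and \code{joint}.
#' @export
decode_acausal <- function(counts, encoding, transitions, graph,
                           return_marginal = FALSE, return_joint = FALSE) {
  dt <- attr(counts, "dt")
  t_start <- attr(counts, "t_start")
  if (is.null(dt)) stop("counts must come from bin_spikes (dt attribute missing)")
  le <- poisson_logemission(counts, encoding, dt)
  res <- fb_smoother(le, transitions$kernels, transitions$switch,
                     transitions$bindist, return_marginal, return_joint)
  out <- list(time = t_start + (seq_len(ncol(le)) - 0.5) * dt, dt = dt,
              map_bin = res$map_bin,
              map_lin = graph$bins$linear[res$map_bin],
              dyn = res$dyn, spread_cm2 = res$spread,
              bins = graph$bins)
  if (return_marginal) out$marginal <- res$marginal
  if (return_joint) {
    out$joint <- array(res$joint,
                       dim = c(nrow(res$joint), nrow(graph$bins), 3))
    out$joint <- aperm(out$joint, c(1, 3, 2))  # time x dynamic x bin
  }
  structure(out, class = "posterior")
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf("posterior: %d time bins of %g ms, %d position bins\n",
              length(x$time), x$dt * 1000, nrow(x$bins)))
  invisible(x)
}

#' Cross-validated decoding of a session
#'
#' Splits the session into \code{k} contiguous time folds; each fold is
#' decoded with an encoding model trained on the movement samples of the other
#' folds, and the posteriors are concatenated. With \code{k = 1} the model is
#' trained on all movement samples and used to decode the entire session
#' (the immobility-decoding mode).
#'
#' @param session a \code{session} bundle (or any list with spikes, behavior).
#' @param graph a \code{track_graph}.
#' @param k number of contiguous folds (default 5); \code{k = 1} trains on
#'   everything.
#' @param region decode units of this region (default "MEC").
#' @param dt decoding bin width, s.
#' @param transitions a \code{transition_model}; defaults built from
#'   \code{graph}.
#' @param ... passed to \code{fit_encoding}.
#' @return a \code{posterior} spanning the whole session.
#' @export
crossval_decode <- function(session, graph, k = 5, region = "MEC", dt = 0.002,
                            transitions = transition_model(graph), ...) {
  if (k < 1) stop("k must be >= 1")
  spikes <- session$spikes[session$spikes$region == region, ]
  unit_ids <- sort(unique(spikes$unit_id))
  beh <- session$behavior
  t_end <- max(beh$time_s)
  counts <- bin_spikes(spikes, 0, t_end, dt, unit_ids)
  nT <- nrow(counts)
  if (k == 1) {
    enc <- fit_encoding(spikes, beh, graph, unit_ids = unit_ids, ...)
    return(decode_acausal(counts, enc, transitions, graph))
  }
  fold_of_bin <- pmin(floor((seq_len(nT) - 1) / (nT / k)) + 1L, k)
  bin_time <- (seq_len(nT) - 0.5) * dt
  pieces <- vector("list", k)
  for (f in seq_len(k)) {
    keep <- fold_of_bin != f
    # train-sample mask on the behavior grid
    tmin <- min(bin_time[!keep]); tmax <- max(bin_time[!keep])
    mask <- beh$time_s < tmin - dt / 2 | beh$time_s > tmax + dt / 2
    enc <- fit_encoding(spikes, beh, graph, sample_mask = mask,
                        unit_ids = unit_ids, ...)
    sub <- counts[fold_of_bin == f, , drop = FALSE]
    attr(sub, "dt") <- dt
    attr(sub, "t_start") <- (which(fold_of_bin == f)[1] - 1) * dt
    pieces[[f]] <- decode_acausal(sub, enc, transitions, graph)
  }
  out <- pieces[[1]]
  for (f in 2:k) {
    out$time <- c(out$time, pieces[[f]]$time)
    out$map_bin <- c(out$map_bin, pieces[[f]]$map_bin)
    out$map_lin <- c(out$map_lin, pieces[[f]]$map_lin)
    out$dyn <- rbind(out$dyn, pieces[[f]]$dyn)
    out$spread_cm2 <- c(out$spread_cm2, pieces[[f]]$spread_cm2)
  }
  out
}

#' Confidence mask over decoded time bins
#'
#' Flags time bins where the acausal posterior is concentrated enough to
#' trust. The spread statistic is the posterior-weighted mean squared track
#' distance from the MAP bin. The default absolute mode keeps bins whose
#' spread is at most 400 cm^2 - a posterior SD of 20 cm, the same radius that
#' defines nonlocal coding, so a kept bin's position call is meaningful at the
#' scale of the nonlocal threshold. Percentile mode instead excludes a fixed
#' fraction of the session (e.g. 92.8 keeps all but the most diffuse 7.2%).
#'
#' @param posterior a \code{posterior}.
#' @param mode "absolute" or "percentile".
#' @param threshold spread in cm^2 (absolute mode, default 400) or percentile
#'   0-100 (percentile mode, default 92.8).
#' @return logical keep-mask per time bin.
#' @export
confidence_mask <- function(posterior, mode = c("absolute", "percentile"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "absolute") 400 else 92.8
  thr <- if (mode == "percentile")
    stats::quantile(posterior$spread_cm2, threshold / 100, names = FALSE)
  else threshold
  posterior$spread_cm2 <= thr
}

#' Naive-Bayes position decoding (validation decoder)
#'
#' Memoryless Poisson decoder at 100-ms bins: spike counts are summed over a
#' sliding 1-s window centered on each bin and the decoded position is the
#' argmax over bins of the product of per-unit Poisson likelihoods under the
#' encoding rate maps, with a uniform prior (lowest bin index on ties).
#'
#' @param spikes spikes data.frame or list.
#' @param encoding an \code{encoding}.
#' @param t_start,t_end span to decode, s.
#' @param bin decoding bin, s (default 0.1).
#' @param window sliding summation window, s (default 1).
#' @return list: \code{time}, \code{map_bin}, \code{map_lin}.
#' @export
naive_bayes_decode <- function(spikes, encoding, t_start, t_end,
                               bin = 0.1, window = 1) {
  counts <- bin_spikes(spikes, t_start, t_end, bin,
                       unit_ids = encoding$unit_ids)
  half <- round(window / bin / 2)
  csum <- apply(counts, 2, function(v) {
    cs <- cumsum(v)
    n <- length(v)
    hi <- pmin(seq_len(n) + half, n)
    lo <- pmax(seq_len(n) - half - 1, 0)
    cs[hi] - c(0, cs)[lo + 1]
  })
  lam <- pmax(encoding$lambda, encoding$rate_floor)
  ll <- csum %*% log(lam)
  ll <- sweep(ll, 2, window * colSums(lam))
  mb <- max.col(ll, ties.method = "first")
  list(time = t_start + (seq_len(nrow(counts)) - 0.5) * bin,
       map_bin = mb, map_lin = encoding$bins$linear[mb])
}

#' Decode with a temporally shuffled control model
#'
#' Circularly shifts each unit's spike train by an independent uniform offset
#' (spike counts preserved), refits the encoding model on the shifted trains
#' and reruns the full decode - the negative-control model for the nonlocal
#' analyses. When evaluating movement decoding error, use cross-validation
#' (k >= 2, the same rule as for the standard model when training and decoding
#' share time bins): a full-train control can partially memorize its own
#' shuffled spikes.
#'
#' @param session a \code{session}.
#' @param graph a \code{track_graph}.
#' @param seed RNG seed for the per-unit offsets.
#' @param ... passed to \code{crossval_decode}.
#' @return list: \code{posterior} (control decode), \code{session} (with
#'   shifted spikes), \code{offsets}.
#' @export
shuffled_spike_model <- function(session, graph, seed = 1, ...) {
  set.seed(seed)
  dur <- session$meta$duration
  shuffled <- session
  sp <- split(seq_len(nrow(session$spikes)), session$spikes$unit_id)
  offsets <- stats::runif(length(sp), 0, dur)
  names(offsets) <- names(sp)
  for (j in seq_along(sp)) {
    idx <- sp[[j]]
    shuffled$spikes$time_s[idx] <-
      (session$spikes$time_s[idx] + offsets[j]) %% dur
  }
  o <- order(shuffled$spikes$unit_id, shuffled$spikes$time_s)
  shuffled$spikes <- shuffled$spikes[o, ]
  post <- crossval_decode(shuffled, graph, ...)
  list(posterior = post, session = shuffled, offsets = offsets)
}

#' Decode error against actual position
#'
#' Track distance between the MAP decoded position and the animal's actual
#' position at each decoded time bin.
#'
#' @param posterior a \code{posterior} (or naive-Bayes result).
#' @param behavior behavior data.frame.
#' @param graph a \code{track_graph}.
#' @return list: \code{dist_cm}, \code{actual_lin}, \code{speed}.
#' @export
decode_error <- function(posterior, behavior, graph) {
  dtb <- behavior$time_s[2] - behavior$time_s[1]
  idx <- pmin(pmax(round(posterior$time / dtb) + 1L, 1L), nrow(behavior))
  actual <- behavior$linear_cm[idx]
  ok <- !is.na(actual)
  d <- rep(NA_real_, length(actual))
  d[ok] <- track_distance(posterior$map_lin[ok], actual[ok], graph)
  list(dist_cm = d, actual_lin = actual, speed = behavior$speed_cm_s[idx])
}
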