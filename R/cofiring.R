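# union of intervals, sorted and merged
interval_union <- function(t0, t1) {
  if (!length(t0)) return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  o <- order(t0)
  t0 <- t0[o]; t1 <- t1[o]
  out0 <- t0[1]; out1 <- t1[1]
  for (k in seq_along(t0)[-1]) {
    last <- length(out0)
    if (t0[k] <= out1[last]) out1[last] <- max(out1[last], t1[k])
    else { out0 <- c(out0, t0[k]); out1 <- c(out1, t1[k]) }
  }
  data.frame(t0 = out0, t1 = out1)
}

# intersection of two interval sets (each sorted, disjoint)
interval_intersect <- function(a, b) {
  out0 <- numeric(0); out1 <- numeric(0)
  for (k in seq_len(nrow(a))) {
    j <- which(b$t1 > a$t0[k] & b$t0 < a$t1[k])
    if (length(j)) {
      out0 <- c(out0, pmax(b$t0[j], a$t0[k]))
      out1 <- c(out1, pmin(b$t1[j], a$t1[k]))
    }
  }
  data.frame(t0 = out0, t1 = out1)
}

# (1 ms, 10 ms] windows after MEC spikes, clipped to the condition bouts
cofire_windows <- function(mec_times, bouts, w_lo = 0.001, w_hi = 0.010) {
  if (!nrow(bouts) || !length(mec_times))
    return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  inb <- vapply(mec_times, function(s)
    any(s >= bouts$t0 & s <= bouts$t1), TRUE)
  s <- mec_times[inb]
  if (!length(s)) return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  win <- interval_union(s + w_lo, s + w_hi)
  interval_intersect(win, interval_union(bouts$t0, bouts$t1))
}

#' MEC-CA1 co-firing test for one pair
#'
#' Observed statistic per condition (local / nonlocal coding bouts): the CA1
#' unit's firing rate within the (1 ms, 10 ms] window following every MEC
#' spike in that condition, windows truncated at bout edges and normalized by
#' actual window time. Null: each CA1 spike is moved to a random time within a
#' random immobility bout and the windowed rate recomputed (1000 iterations);
#' a condition is significant when the observed rate exceeds the null's 95th
#' percentile.
#'
#' @param mec_times,ca1_times spike times of the pair, s.
#' @param bouts_local,bouts_nonlocal condition bout tables (t0, t1).
#' @param immobility immobility bout table for the shuffle.
#' @param n_shuffle iterations (default 1000).
#' @param pctile null percentile (default 95).
#' @param seed RNG seed.
#' @return one-row data.frame: rate and significance per condition, window
#'   spike counts, and the combined significance category.
#' @export
cofire_test <- function(mec_times, ca1_times, bouts_local, bouts_nonlocal,
                        immobility, n_shuffle = 1000, pctile = 95, seed = 1) {
  set.seed(seed)
  nb <- nrow(immobility)
  if (!nb) stop("no immobility bouts")
  one_condition <- function(bouts) {
    win <- cofire_windows(mec_times, bouts)
    wt <- sum(win$t1 - win$t0)
    if (wt <= 0)
      return(list(rate = NA_real_, n = NA_integer_, sig = NA))
    nobs <- count_in_intervals(ca1_times, win$t0, win$t1)
    null <- vapply(seq_len(n_shuffle), function(i) {
      bi <- sample.int(nb, length(ca1_times), replace = TRUE)
      sh <- stats::runif(length(ca1_times), immobility$t0[bi],
                         immobility$t1[bi])
      count_in_intervals(sh, win$t0, win$t1) / wt
    }, 0)
    list(rate = nobs / wt, n = nobs,
         sig = nobs / wt > stats::quantile(null, pctile / 100, names = FALSE))
  }
  loc <- one_condition(bouts_local)
  nl <- one_condition(bouts_nonlocal)
  category <- if (isTRUE(loc$sig) && isTRUE(nl$sig)) "both"
  else if (isTRUE(loc$sig)) "local_only"
  else if (isTRUE(nl$sig)) "nonlocal_only"
  else "neither"
  data.frame(rate_local = loc$rate, rate_nonlocal = nl$rate,
             n_local = loc$n, n_nonlocal = nl$n,
             sig_local = loc$sig, sig_nonlocal = nl$sig,
             category = category)
}

#' Co-firing tests over all MEC-CA1 pairs of a session
#'
#' @param session a \code{session}.
#' @param labels a \code{nonlocal_labels} (supplies local / nonlocal bouts and
#'   immobility).
#' @param max_pairs cap on the number of pairs tested (all by default).
#' @param ... passed to \code{cofire_test}.
#' @param seed base seed; each pair uses seed + pair index.
#' @return data.frame with mec, ca1 and the \code{cofire_test} columns.
#' @export
cofire_all_pairs <- function(session, labels, max_pairs = Inf, seed = 1, ...) {
  mec_ids <- session$units$unit_id[session$units$region == "MEC"]
  ca1_ids <- session$units$unit_id[session$units$region == "CA1"]
  bouts_local <- {
    runs <- logical_runs(labels$flags$local)
    data.frame(t0 = labels$flags$time[runs$i0],
               t1 = labels$flags$time[runs$i1])
  }
  pairs <- expand.grid(mec = mec_ids, ca1 = ca1_ids)
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), ]
  sp <- split(session$spikes$time_s, session$spikes$unit_id)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    r <- cofire_test(sp[[as.character(pairs$mec[k])]],
                     sp[[as.character(pairs$ca1[k])]],
                     bouts_local, labels$bouts[, c("t0", "t1")],
                     labels$immobility, seed = seed + k, ...)
    cbind(pairs[k, ], r)
  })
  do.call(rbind, out)
}

#' Population summary of pair co-firing
#'
#' @param pairs data.frame from \code{cofire_all_pairs}.
#' @return list: pct_sig_local, pct_sig_nonlocal, pct_local_only,
#'   pct_nonlocal_only, pct_both, n_pairs.
#' @export
pair_population_summary <- function(pairs) {
  ok <- !is.na(pairs$sig_local) | !is.na(pairs$sig_nonlocal)
  p <- pairs[ok, ]
  n <- nrow(p)
  list(pct_sig_local = 100 * mean(p$sig_local %in% TRUE),
       pct_sig_nonlocal = 100 * mean(p$sig_nonlocal %in% TRUE),
       pct_local_only = 100 * mean(p$category == "local_only"),
       pct_nonlocal_only = 100 * mean(p$category == "nonlocal_only"),
       pct_both = 100 * mean(p$category == "both"),
       n_pairs = n)
}

#' MEC / CA1 decoded-position coincidence
#'
#' Fraction of confidence-kept time bins where the MEC and CA1 decoders agree
#' on the position bin, split by the MEC local / nonlocal condition.
#'
#' @param mec_map,ca1_map MAP bin indices on the same 2-ms grid.
#' @param mec_local,mec_nonlocal logical condition flags per bin.
#' @param keep joint confidence mask.
#' @return list: coincidence_local, coincidence_nonlocal, n_local,
#'   n_nonlocal.
#' @export
decode_coincidence <- function(mec_map, ca1_map, mec_local, mec_nonlocal,
                               keep = NULL) {
  if (length(mec_map) != length(ca1_map))
    stop("decoder grids are misaligned (different lengths)")
  if (is.null(keep)) keep <- rep(TRUE, length(mec_map))
  same <- mec_map == ca1_map
  sl <- keep & mec_local
  sn <- keep & mec_nonlocal
  list(coincidence_local = if (any(sl)) mean(same[sl]) else NA_real_,
       coincidence_nonlocal = if (any(sn)) mean(same[sn]) else NA_real_,
       n_local = sum(sl), n_nonlocal = sum(sn))
}

#' Spike cross-correlogram
#'
#' Histogram of CA1 spike lags relative to MEC spikes, 1-ms bins over
#' +/- 50 ms, optionally restricted to MEC spikes inside given bouts.
#'
#' @param mec_times,ca1_times spike times, s.
#' @param bouts optional bout table restricting the reference spikes.
#' @param max_lag window half-width, s (default 0.05).
#' @param bin bin width, s (default 0.001).
#' @return data.frame lag_s (bin centers), count.
#' @export
cross_correlogram <- function(mec_times, ca1_times, bouts = NULL,
                              max_lag = 0.05, bin = 0.001) {
  if (!is.null(bouts) && nrow(bouts)) {
    inb <- vapply(mec_times, function(s)
      any(s >= bouts$t0 & s <= bouts$t1), TRUE)
    mec_times <- mec_times[inb]
  }
  edges <- seq(-max_lag, max_lag, by = bin)
  counts <- numeric(length(edges) - 1)
  ca1_sorted <- sort(ca1_times)
  for (s in mec_times) {
    lo <- findInterval(s - max_lag, ca1_sorted) + 1
    hi <- findInterval(s + max_lag, ca1_sorted)
    if (hi >= lo) {
      lags <- ca1_sorted[lo:hi] - s
      idx <- pmin(pmax(floor((lags + max_lag) / bin) + 1, 1), length(counts))
      for (i in idx) counts[i] <- counts[i] + 1
    }
  }
  data.frame(lag_s = edges[-length(edges)] + bin / 2, count = counts)
}
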