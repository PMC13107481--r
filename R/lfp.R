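# analytic signal via FFT (no installed R package exposes a Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Gaussian smoothing of a regularly sampled trace, sigma in samples
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- ceiling(4 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2)); k <- k / sum(k)
  out <- stats::filter(c(rep(x[1], half), x, rep(x[length(x)], half)),
                       k, sides = 2)
  as.numeric(out[(half + 1):(half + length(x))])
}

# bandpass FIR: equiripple (Parks-McClellan) with 5-Hz transitions, falling
# back to a long windowed-sinc design if remez fails to converge
bandpass_fir <- function(fs, f_lo, f_hi, transition = 5, order = 300) {
  nyq <- fs / 2
  b <- tryCatch({
    f <- c(0, f_lo - transition, f_lo, f_hi,
           min(f_hi + transition, nyq * 0.999), nyq) / nyq
    signal::remez(order, f, c(0, 0, 1, 1, 0, 0))
  }, error = function(e)
    signal::fir1(order, c(f_lo, f_hi) / nyq, type = "pass"))
  as.numeric(b)
}

# zero-phase filtering with a symmetric (linear-phase) FIR: single convolution
# with group-delay compensation and mirrored edge padding
fir_filtfilt <- function(b, x) {
  n <- length(x)
  half <- (length(b) - 1) %/% 2
  pad <- min(half, n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  y <- stats::convolve(xp, rev(b), type = "open")
  y[(pad + half + 1):(pad + half + n)]
}

#' Sharp-wave-ripple detection from the CA1 LFP envelope
#'
#' Equiripple-bandpasses the trace at 125-200 Hz (5-Hz transition bands),
#' takes the Hilbert envelope, smooths it with a Gaussian (sigma = 4 ms) and
#' detects events where the envelope exceeds \code{thr_sd} SDs above the
#' session baseline for at least \code{min_dur}. Event boundaries are extended
#' outward to where the envelope falls back to the baseline mean.
#'
#' @param lfp CA1 trace, uniformly sampled.
#' @param fs sampling rate, Hz (default 625).
#' @param thr_sd detection threshold in baseline SDs (default 2).
#' @param min_dur minimum supra-threshold duration, s (default 0.015).
#' @param sigma_env envelope smoothing sigma, s (default 0.004).
#' @param band ripple band, Hz.
#' @param baseline_mask optional logical mask (e.g. immobility-only) over
#'   samples for the baseline mean/SD; default whole session.
#' @param extend_to_mean extend boundaries to the mean crossing (default TRUE).
#' @return data.frame of class SWR events: t0, t1, peak_t, peak_sd, mode.
#' @export
detect_swr_envelope <- function(lfp, fs = 625, thr_sd = 2, min_dur = 0.015,
                                sigma_env = 0.004, band = c(125, 200),
                                baseline_mask = NULL, extend_to_mean = TRUE) {
  if (length(lfp) < 2 * fs)
    stop("LFP trace shorter than the filter warm-up (need >= 2 s)")
  b <- bandpass_fir(fs, band[1], band[2])
  filt <- fir_filtfilt(b, lfp)
  env_raw <- Mod(analytic_signal(filt))
  env <- gauss_smooth(env_raw, sigma_env * fs)
  if (is.null(baseline_mask)) baseline_mask <- rep(TRUE, length(env))
  # baseline statistics come from the unsmoothed envelope; smoothing is only
  # for detection stability (keeps the null false-positive rate low)
  mu <- mean(env_raw[baseline_mask]); sdv <- stats::sd(env_raw[baseline_mask])
  detect_events_from_envelope(env, fs, mu, sdv, thr_sd, min_dur,
                              extend_to_mean, mode = "envelope")
}

detect_events_from_envelope <- function(env, fs, mu, sdv, thr_sd, min_dur,
                                        extend_to_mean, mode) {
  z <- (env - mu) / sdv
  runs <- logical_runs(z > thr_sd)
  runs <- runs[(runs$i1 - runs$i0 + 1) / fs >= min_dur, , drop = FALSE]
  if (!nrow(runs))
    return(data.frame(t0 = numeric(0), t1 = numeric(0), peak_t = numeric(0),
                      peak_sd = numeric(0), mode = character(0)))
  n <- length(env)
  if (extend_to_mean) {
    below <- z <= 0
    for (k in seq_len(nrow(runs))) {
      i <- runs$i0[k]
      while (i > 1 && !below[i - 1]) i <- i - 1
      runs$i0[k] <- i
      j <- runs$i1[k]
      while (j < n && !below[j + 1]) j <- j + 1
      runs$i1[k] <- j
    }
    # merge events that grew into each other
    keep <- c(TRUE, runs$i0[-1] > utils::head(runs$i1, -1))
    merged <- runs[keep, , drop = FALSE]
    gi <- cumsum(keep)
    merged$i1 <- as.integer(vapply(seq_len(nrow(merged)), function(g)
      max(runs$i1[gi == g]), numeric(1)))
    runs <- merged
  }
  out <- data.frame(
    t0 = (runs$i0 - 1) / fs, t1 = (runs$i1 - 1) / fs,
    peak_t = NA_real_, peak_sd = NA_real_, mode = mode)
  for (k in seq_len(nrow(runs))) {
    seg <- runs$i0[k]:runs$i1[k]
    pk <- seg[which.max(z[seg])]
    out$peak_t[k] <- (pk - 1) / fs
    out$peak_sd[k] <- z[pk]
  }
  out
}

#' Sharp-wave-ripple detection from multi-unit activity
#'
#' Sums the population firing rate of all units in 1-ms bins, smooths it with
#' a Gaussian (sigma = 15 ms) and applies the same threshold rule as the
#' envelope detector (2 SD above baseline for at least 15 ms).
#'
#' @param spike_times vector of all units' spike times pooled, s.
#' @param t_end session end, s.
#' @param thr_sd,min_dur detection rule (defaults 2 SD, 15 ms).
#' @param sigma_rate rate smoothing sigma, s (default 0.015).
#' @param bin rate bin, s (default 0.001).
#' @param extend_to_mean extend boundaries to the mean crossing.
#' @return SWR event data.frame as in \code{detect_swr_envelope}.
#' @export
detect_swr_mua <- function(spike_times, t_end, thr_sd = 2, min_dur = 0.015,
                           sigma_rate = 0.015, bin = 0.001,
                           extend_to_mean = TRUE) {
  if (!length(spike_times))
    return(data.frame(t0 = numeric(0), t1 = numeric(0), peak_t = numeric(0),
                      peak_sd = numeric(0), mode = character(0)))
  nT <- ceiling(t_end / bin)
  cnt <- tabulate(pmin(floor(spike_times / bin) + 1L, nT), nbins = nT)
  rate <- gauss_smooth(cnt / bin, sigma_rate / bin)
  detect_events_from_envelope(rate, 1 / bin, mean(rate), stats::sd(rate),
                              thr_sd, min_dur, extend_to_mean, mode = "mua")
}

# total overlap time between two sets of intervals
interval_overlap <- function(a0, a1, b0, b1) {
  if (!length(a0) || !length(b0)) return(0)
  tot <- 0
  o <- order(b0); b0 <- b0[o]; b1 <- b1[o]
  for (k in seq_along(a0)) {
    j <- which(b1 > a0[k] & b0 < a1[k])
    if (length(j))
      tot <- tot + sum(pmin(b1[j], a1[k]) - pmax(b0[j], a0[k]))
  }
  tot
}

#' SWR / nonlocal-coding overlap with a temporal-shuffle null
#'
#' Observed overlap in both directions (percentage of SWRs containing any
#' nonlocal coding; percentage of nonlocal time inside SWRs), against a null
#' in which each SWR is moved to a random time within a random immobility bout
#' (1000 iterations). The session is significant when the observed
#' events-with-nonlocal percentage exceeds the null's 95th percentile.
#'
#' @param events SWR event table (t0, t1).
#' @param nonlocal_bouts nonlocal bout table (t0, t1).
#' @param immobility immobility bout table (t0, t1).
#' @param n_shuffle iterations (default 1000).
#' @param pctile null percentile (default 95).
#' @param seed RNG seed.
#' @return list: pct_events_with_nonlocal, pct_nonlocal_in_events,
#'   null (vector), significant.
#' @export
overlap_shuffle <- function(events, nonlocal_bouts, immobility,
                            n_shuffle = 1000, pctile = 95, seed = 1) {
  if (!nrow(immobility)) stop("no immobility bouts to shuffle into")
  nl_t <- sum(nonlocal_bouts$t1 - nonlocal_bouts$t0)
  obs_pct <- function(e0, e1) {
    with_nl <- vapply(seq_along(e0), function(k)
      interval_overlap(e0[k], e1[k], nonlocal_bouts$t0, nonlocal_bouts$t1) > 0,
      TRUE)
    100 * mean(with_nl)
  }
  obs <- obs_pct(events$t0, events$t1)
  in_events <- if (nl_t > 0)
    100 * interval_overlap(events$t0, events$t1,
                           nonlocal_bouts$t0, nonlocal_bouts$t1) / nl_t else 0
  set.seed(seed)
  dur <- events$t1 - events$t0
  nb <- nrow(immobility)
  null <- vapply(seq_len(n_shuffle), function(i) {
    bi <- sample.int(nb, length(dur), replace = TRUE)
    lo <- immobility$t0[bi]
    hi <- pmax(immobility$t1[bi] - dur, lo)
    s <- stats::runif(length(dur), lo, hi)
    obs_pct(s, s + dur)
  }, 0)
  list(pct_events_with_nonlocal = obs,
       pct_nonlocal_in_events = in_events,
       null = null,
       significant = obs > stats::quantile(null, pctile / 100, names = FALSE))
}

# Welch spectra: averaged Hanning-windowed periodograms; returns per-segment
# FFTs so callers can form cross-spectra
welch_fft <- function(x, fs, window = 1, overlap = 0.5) {
  nw <- round(window * fs)
  if (nw > length(x)) stop("window longer than trace")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / (nw - 1))
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + nw - 1)]
    stats::fft((seg - mean(seg)) * w)
  }, complex(nw))
  freq <- (seq_len(nw) - 1) * fs / nw
  keep <- seq_len(floor(nw / 2) + 1)
  list(fft = segs[keep, , drop = FALSE], freq = freq[keep],
       starts_t = (starts - 1) / fs, norm = sum(w^2) * fs)
}

#' Spectral measures of an LFP pair
#'
#' Welch power spectral density of each trace (Hanning-windowed segment
#' averaging with a 1-s sliding window), magnitude-squared coherence from the
#' segment-averaged cross-spectrum, band power per canonical band (type II
#' theta 3-7 Hz, type I theta 7-11 Hz, fast gamma 50-110 Hz, ripple
#' 125-200 Hz), and the instantaneous frequency of a chosen band (bandpass,
#' 15-sample Hanning smoothing, Hilbert phase derivative).
#'
#' @param x,y the two traces (e.g. MEC and CA1).
#' @param fs sampling rate, Hz.
#' @param window Welch window, s (default 1).
#' @param bands named list of band edges, Hz.
#' @param if_band band for the instantaneous frequency (default type I theta).
#' @return list: freq, psd_x, psd_y, coherence, band_power (matrix bands x
#'   traces), inst_freq (vector at fs).
#' @export
spectral_measures <- function(x, y, fs, window = 1,
                              bands = list(theta2 = c(3, 7), theta1 = c(7, 11),
                                           fast_gamma = c(50, 110),
                                           ripple = c(125, 200)),
                              if_band = c(7, 11)) {
  wx <- welch_fft(x, fs, window)
  wy <- welch_fft(y, fs, window)
  sxx <- rowMeans(Mod(wx$fft)^2) / wx$norm
  syy <- rowMeans(Mod(wy$fft)^2) / wy$norm
  sxy <- rowMeans(wx$fft * Conj(wy$fft)) / wx$norm
  coh <- Mod(sxy)^2 / (sxx * syy)
  bp <- t(vapply(bands, function(b) {
    sel <- wx$freq >= b[1] & wx$freq <= b[2]
    c(x = sum(sxx[sel]), y = sum(syy[sel]))
  }, c(x = 0, y = 0)))
  inst <- instantaneous_frequency(x, fs, if_band)
  list(freq = wx$freq, psd_x = sxx, psd_y = syy, coherence = coh,
       band_power = bp, inst_freq = inst)
}

#' Instantaneous frequency within a band
#'
#' Bandpasses the trace, smooths with a 15-sample Hanning window and
#' differentiates the Hilbert phase (cycle-to-cycle peak-to-peak frequency).
#'
#' @param x trace.
#' @param fs sampling rate, Hz.
#' @param band two-element band, Hz.
#' @return per-sample frequency, Hz.
#' @export
instantaneous_frequency <- function(x, fs, band) {
  b <- bandpass_fir(fs, band[1], band[2],
                    transition = max(2, diff(band) / 4),
                    order = min(300, floor(length(x) / 3) * 2))
  filt <- fir_filtfilt(b, x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 14) / 14); w <- w / sum(w)
  sm <- as.numeric(stats::filter(c(rep(filt[1], 15), filt,
                                   rep(filt[length(filt)], 15)),
                                 w, sides = 2))[16:(15 + length(filt))]
  ph <- Arg(analytic_signal(sm))
  dph <- diff(ph)
  dph[dph < -pi] <- dph[dph < -pi] + 2 * pi
  dph[dph > pi] <- dph[dph > pi] - 2 * pi
  c(dph, dph[length(dph)]) * fs / (2 * pi)
}
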