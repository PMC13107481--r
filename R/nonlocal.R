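# run-length intervals of a logical vector
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(i0 = starts[r$values], i1 = ends[r$values])
}

#' Detect immobility bouts
#'
#' Maximal intervals with speed below \code{v_thr}; neighboring bouts are
#' concatenated when the gap between them is shorter than \code{merge_gap_s}
#' AND the net displacement across the gap (track distance) is less than
#' \code{merge_gap_cm}.
#'
#' @param speed speed trace, cm/s, uniformly sampled.
#' @param time sample times, s.
#' @param linear linearized positions (needed for the displacement rule; if
#'   NULL only the time rule applies).
#' @param graph a \code{track_graph} (required with \code{linear}).
#' @param v_thr immobility threshold, cm/s (default 2).
#' @param merge_gap_s,merge_gap_cm merge rule bounds (default 1 s, 2 cm).
#' @return data.frame t0, t1, i0, i1 (sample indices).
#' @export
detect_immobility <- function(speed, time, linear = NULL, graph = NULL,
                              v_thr = 2, merge_gap_s = 1, merge_gap_cm = 2) {
  runs <- logical_runs(speed < v_thr)
  if (!nrow(runs))
    return(data.frame(t0 = numeric(0), t1 = numeric(0),
                      i0 = integer(0), i1 = integer(0)))
  b <- data.frame(t0 = time[runs$i0], t1 = time[runs$i1],
                  i0 = runs$i0, i1 = runs$i1)
  merged <- b[1, ]
  for (k in seq_len(nrow(b) - 1) + 1) {
    last <- nrow(merged)
    gap_s <- b$t0[k] - merged$t1[last]
    gap_cm <- if (!is.null(linear) && !is.null(graph) &&
                  !is.na(linear[merged$i1[last]]) && !is.na(linear[b$i0[k]]))
      track_distance(linear[merged$i1[last]], linear[b$i0[k]], graph)
    else 0
    if (gap_s < merge_gap_s && gap_cm < merge_gap_cm) {
      merged$t1[last] <- b$t1[k]
      merged$i1[last] <- b$i1[k]
    } else merged <- rbind(merged, b[k, ])
  }
  merged
}

#' Label nonlocal coding bins and bouts
#'
#' A decoded time bin is nonlocal when the track distance between the MAP
#' decoded position and the animal's position is at least \code{d_thr}
#' (20 cm), restricted to immobility and to confidence-kept bins; local bins
#' are the remaining kept immobile bins. Contiguous nonlocal bins form bouts;
#' by default a single non-nonlocal bin splits a bout (\code{gap_bins = 0}).
#'
#' @param posterior a \code{posterior}.
#' @param behavior behavior data.frame.
#' @param graph a \code{track_graph}.
#' @param immobility immobility bout table from \code{detect_immobility};
#'   computed from behavior when NULL.
#' @param keep confidence mask (default: all kept).
#' @param d_thr nonlocal distance threshold, cm (default 20).
#' @param gap_bins tolerated in-bout gap, bins (default 0).
#' @return list of class \code{nonlocal_labels}: \code{flags} (data.frame per
#'   decoded bin: time, dist_cm, immobile, kept, nonlocal, local, map_lin,
#'   actual_lin), \code{bouts} (nonlocal bout table with mouse position and
#'   segment), \code{immobility}.
#' @export
label_nonlocal <- function(posterior, behavior, graph, immobility = NULL,
                           keep = NULL, d_thr = 20, gap_bins = 0) {
  if (is.null(immobility))
    immobility <- detect_immobility(behavior$speed_cm_s, behavior$time_s,
                                    behavior$linear_cm, graph)
  if (is.null(keep)) keep <- rep(TRUE, length(posterior$time))
  err <- decode_error(posterior, behavior, graph)
  nT <- length(posterior$time)
  immobile <- rep(FALSE, nT)
  for (b in seq_len(nrow(immobility))) {
    sel <- posterior$time >= immobility$t0[b] & posterior$time <= immobility$t1[b]
    immobile[sel] <- TRUE
  }
  ok <- !is.na(err$dist_cm)
  nonlocal <- ok & immobile & keep & err$dist_cm >= d_thr
  local <- ok & immobile & keep & err$dist_cm < d_thr
  nl <- nonlocal
  if (gap_bins > 0) {  # bridge short gaps inside nonlocal stretches
    gaps <- logical_runs(!nl)
    for (g in seq_len(nrow(gaps))) {
      if (gaps$i1[g] - gaps$i0[g] + 1 <= gap_bins &&
          gaps$i0[g] > 1 && gaps$i1[g] < nT)
        nl[gaps$i0[g]:gaps$i1[g]] <- TRUE
    }
  }
  runs <- logical_runs(nl)
  bouts <- if (nrow(runs)) {
    t0 <- posterior$time[runs$i0] - posterior$dt / 2
    t1 <- posterior$time[runs$i1] + posterior$dt / 2
    mouse <- err$actual_lin[runs$i0]
    seg <- segment_of(mouse, graph)
    data.frame(t0 = t0, t1 = t1, i0 = runs$i0, i1 = runs$i1,
               duration = t1 - t0, mouse_lin = mouse,
               mouse_segment = seg$segment, mouse_side = seg$side,
               map_lin = vapply(seq_len(nrow(runs)), function(k)
                 stats::median(posterior$map_lin[runs$i0[k]:runs$i1[k]]), 0))
  } else data.frame(t0 = numeric(0), t1 = numeric(0), i0 = integer(0),
                    i1 = integer(0), duration = numeric(0),
                    mouse_lin = numeric(0), mouse_segment = character(0),
                    mouse_side = character(0), map_lin = numeric(0))
  structure(list(
    flags = data.frame(time = posterior$time, dist_cm = err$dist_cm,
                       immobile = immobile, kept = keep,
                       nonlocal = nonlocal, local = local,
                       map_lin = posterior$map_lin,
                       actual_lin = err$actual_lin),
    bouts = bouts, immobility = immobility, d_thr = d_thr),
    class = "nonlocal_labels")
}

#' Per-session bout statistics
#'
#' Summaries over immobility bouts: per-bout percentage of kept bins that are
#' nonlocal, percentage of bouts with any nonlocal content, percentage of all
#' kept immobile time that is nonlocal, mean nonlocal bout duration, and the
#' mean durations of local-only versus any-nonlocal immobility bouts.
#'
#' @param labels a \code{nonlocal_labels}.
#' @return list: \code{per_bout} data.frame and \code{summary} one-row
#'   data.frame.
#' @export
bout_statistics <- function(labels) {
  fl <- labels$flags
  imm <- labels$immobility
  if (!nrow(imm)) {
    return(list(per_bout = data.frame(),
                summary = data.frame(empty = TRUE)))
  }
  per <- do.call(rbind, lapply(seq_len(nrow(imm)), function(b) {
    sel <- fl$time >= imm$t0[b] & fl$time <= imm$t1[b]
    kept <- sel & fl$kept & !is.na(fl$dist_cm)
    nl <- sum(fl$nonlocal[sel])
    data.frame(bout = b, t0 = imm$t0[b], t1 = imm$t1[b],
               duration = imm$t1[b] - imm$t0[b],
               n_kept = sum(kept), n_nonlocal = nl,
               pct_nonlocal = if (sum(kept)) 100 * nl / sum(kept) else NA_real_,
               any_nonlocal = nl > 0)
  }))
  nlb <- labels$bouts
  summary <- data.frame(
    n_immobility_bouts = nrow(per),
    mean_nonlocal_duration_ms =
      if (nrow(nlb)) 1000 * mean(nlb$duration) else NA_real_,
    pct_bouts_with_nonlocal = 100 * mean(per$any_nonlocal, na.rm = TRUE),
    pct_immobile_time_nonlocal =
      100 * sum(per$n_nonlocal) / max(sum(per$n_kept), 1),
    mean_duration_local_only = mean(per$duration[!per$any_nonlocal]),
    mean_duration_any_nonlocal = mean(per$duration[per$any_nonlocal]))
  list(per_bout = per, summary = summary)
}

#' Decoded-distance by speed histogram
#'
#' 2D histogram of the distance between decoded and actual positions against
#' running speed, normalized so every speed column sums to 1.
#'
#' @param dist_cm decode distances per time bin.
#' @param speed speed per time bin, cm/s.
#' @param dist_breaks,speed_breaks histogram bin edges.
#' @return matrix distance bins x speed bins; columns sum to 1 (NaN for empty
#'   speed columns).
#' @export
distance_speed_histogram <- function(dist_cm, speed,
                                     dist_breaks = seq(0, 230, by = 5),
                                     speed_breaks = c(seq(0, 60, by = 2), Inf)) {
  ok <- !is.na(dist_cm) & !is.na(speed)
  di <- cut(pmin(dist_cm[ok], max(dist_breaks) - 1e-9), dist_breaks,
            include.lowest = TRUE)
  si <- cut(pmin(speed[ok], 1e9), speed_breaks, include.lowest = TRUE)
  h <- table(di, si)
  sweep(unclass(h), 2, colSums(h), "/")
}

#' Segment representation of nonlocal content
#'
#' For each of the five maze segments the mouse can occupy, the distribution
#' over segments of the nonlocally decoded positions, paired with the
#' analytic segment-mode chance levels.
#'
#' @param labels a \code{nonlocal_labels}.
#' @param graph a \code{track_graph}.
#' @param local_radius chance-geometry exclusion radius (default
#'   \code{labels$d_thr}).
#' @return data.frame mouse_segment x decoded_segment with observed fraction
#'   and chance.
#' @export
segment_representation <- function(labels, graph,
                                   local_radius = labels$d_thr) {
  fl <- labels$flags[labels$flags$nonlocal, ]
  segs <- segment_levels()
  out <- expand.grid(mouse_segment = segs, decoded_segment = segs,
                     stringsAsFactors = FALSE)
  out$fraction <- NA_real_
  out$chance <- NA_real_
  if (nrow(fl)) {
    ms <- segment_of(fl$actual_lin, graph)$segment
    ds <- segment_of(fl$map_lin, graph)$segment
    for (m in segs) {
      sel <- ms == m
      if (!any(sel)) next
      for (d in segs)
        out$fraction[out$mouse_segment == m & out$decoded_segment == d] <-
          mean(ds[sel] == d)
    }
  }
  for (m in segs) for (d in segs)
    out$chance[out$mouse_segment == m & out$decoded_segment == d] <-
      chance_level(m, d, graph, local_radius)
  out
}

#' Paired versus unpaired reward representation
#'
#' Among nonlocal bins recorded while the mouse pauses at a reward port and
#' decoding to a reward zone at the other end of the maze, the fraction
#' representing the paired versus the unpaired reward, split by trial
#' correctness. The paired reward of a bout is the opposite-end reward
#' associated with the animal's current arm under the task rule (match: same
#' side; nonmatch: opposite side). Bouts at the choice reward are counted from
#' the choice poke onward. Incorrect-trial bins are duration-matched to the
#' correct-trial total by seeded random subsampling, averaged over
#' \code{n_match_rep} repetitions.
#'
#' @param labels a \code{nonlocal_labels}.
#' @param trials trial table.
#' @param rule "match" or "nonmatch".
#' @param graph a \code{track_graph}.
#' @param seed RNG seed for duration matching.
#' @param n_match_rep subsampling repetitions (default 100).
#' @return data.frame: at (sample/choice), correct, n_bins, frac_paired,
#'   frac_unpaired.
#' @export
paired_reward_analysis <- function(labels, trials, rule, graph, seed = 1,
                                   n_match_rep = 100) {
  fl <- labels$flags[labels$flags$nonlocal, ]
  grid_cases <- expand.grid(at = c("sample", "choice"),
                            correct = c(TRUE, FALSE),
                            stringsAsFactors = FALSE)
  empty <- cbind(grid_cases, n_bins = 0L, frac_paired = NA_real_,
                 frac_unpaired = NA_real_)
  if (!nrow(fl)) return(empty)
  ms <- segment_of(fl$actual_lin, graph)
  ds <- segment_of(fl$map_lin, graph)
  rows <- list()
  for (i in seq_len(nrow(fl))) {
    if (!ms$segment[i] %in% c("sample_reward", "choice_reward")) next
    at <- sub("_reward", "", ms$segment[i])
    opp <- if (at == "sample") "choice_reward" else "sample_reward"
    if (ds$segment[i] != opp) next
    ti <- current_trial_side(fl$time[i], trials)
    if (is.null(ti) || ti$at != at) next
    if (at == "choice" && fl$time[i] < trials$choice_poke_t[ti$trial]) next
    pside <- paired_reward_side(at, ti$side, trials$sample_arm[ti$trial],
                                trials$choice_arm[ti$trial], rule)
    rows[[length(rows) + 1]] <- data.frame(
      at = at, trial = ti$trial, correct = trials$correct[ti$trial],
      paired = ds$side[i] == pside)
  }
  if (!length(rows)) return(empty)
  dat <- do.call(rbind, rows)
  set.seed(seed)
  out <- lapply(seq_len(nrow(grid_cases)), function(k) {
    at <- grid_cases$at[k]; corr <- grid_cases$correct[k]
    d <- dat[dat$at == at & dat$correct == corr, ]
    n <- nrow(d)
    if (!n) return(cbind(grid_cases[k, ], n_bins = 0L,
                         frac_paired = NA_real_, frac_unpaired = NA_real_))
    if (!corr) {
      n_corr <- sum(dat$at == at & dat$correct)
      if (n_corr > 0 && n > n_corr) {
        fp <- mean(vapply(seq_len(n_match_rep), function(r)
          mean(d$paired[sample.int(n, n_corr)]), 0))
        return(cbind(grid_cases[k, ], n_bins = n_corr,
                     frac_paired = fp, frac_unpaired = 1 - fp))
      }
    }
    cbind(grid_cases[k, ], n_bins = n, frac_paired = mean(d$paired),
          frac_unpaired = 1 - mean(d$paired))
  })
  do.call(rbind, out)
}

#' Predict trial accuracy from nonlocal content
#'
#' Logistic regression of trial correctness on the percentage of nonlocal
#' content in the post-choice-poke immobility bout (plus animal identity when
#' several animals are pooled). Classes are balanced 50/50 by subsampling;
#' the data are split 80/20 into train and test, and the test classification
#' accuracy is averaged over \code{n_rep} random splits.
#'
#' @param features data.frame with columns \code{pct_nonlocal},
#'   \code{correct} (logical) and optionally \code{animal}.
#' @param n_rep number of random splits (default 1000).
#' @param seed RNG seed.
#' @return list: \code{mean_accuracy}, \code{sem_accuracy}, \code{n_per_class}.
#' @export
predict_trial_accuracy <- function(features, n_rep = 1000, seed = 1) {
  stopifnot(all(c("pct_nonlocal", "correct") %in% names(features)))
  features <- features[!is.na(features$pct_nonlocal), ]
  n1 <- sum(features$correct); n0 <- sum(!features$correct)
  if (n1 < 2 || n0 < 2) stop("need at least two bouts per class")
  n_bal <- min(n1, n0)
  use_animal <- !is.null(features$animal) &&
    length(unique(features$animal)) > 1
  idx1 <- which(features$correct); idx0 <- which(!features$correct)
  set.seed(seed)
  acc <- vapply(seq_len(n_rep), function(r) {
    s1 <- sample(idx1, n_bal); s0 <- sample(idx0, n_bal)
    n_tr <- max(1, round(0.8 * n_bal))
    tr <- c(s1[seq_len(n_tr)], s0[seq_len(n_tr)])
    te <- c(s1[-seq_len(n_tr)], s0[-seq_len(n_tr)])
    if (!length(te)) return(NA_real_)
    f <- if (use_animal) correct ~ pct_nonlocal + animal else correct ~ pct_nonlocal
    fit <- suppressWarnings(stats::glm(f, binomial(), features[tr, ]))
    pred <- stats::predict(fit, features[te, ], type = "response") > 0.5
    mean(pred == features$correct[te])
  }, 0)
  acc <- acc[!is.na(acc)]
  list(mean_accuracy = mean(acc),
       sem_accuracy = stats::sd(acc) / sqrt(length(acc)),
       n_per_class = n_bal)
}
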