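# spikes -> nearest behavior-sample indices
spike_sample_index <- function(ts, time) {
  dt <- time[2] - time[1]
  pmin(pmax(round((ts - time[1]) / dt) + 1L, 1L), length(time))
}

# count spikes falling inside a set of disjoint sorted intervals
count_in_intervals <- function(ts, t0, t1) {
  if (!length(t0) || !length(ts)) return(0L)
  o <- order(t0)
  edges <- as.vector(rbind(t0[o], t1[o]))
  sum(findInterval(ts, edges) %% 2L == 1L)
}

#' Detect linear place fields of one unit
#'
#' Rate map during movement in 2-cm bins (Gaussian-smoothed, sigma = 1 bin),
#' compared against a null built by circularly shifting the animal's position
#' series relative to the spikes. A field is a run of at least
#' \code{min_bins} consecutive bins (within one track block) whose rate
#' exceeds that bin's 95th-percentile null rate.
#'
#' @param spike_times one unit's spike times, s.
#' @param behavior behavior data.frame.
#' @param graph a \code{track_graph}.
#' @param v_thr movement threshold, cm/s.
#' @param n_shuffle number of circular shifts (default 1000).
#' @param min_bins minimum field extent in bins (default 8 = 16 cm).
#' @param sigma_bins rate-map smoothing sigma (default 1).
#' @param pctile null percentile (default 95).
#' @param seed RNG seed.
#' @return data.frame of fields: bin0, bin1, start_lin, end_lin, peak_lin,
#'   peak_rate; attribute \code{ratemap} carries the observed rates.
#' @export
detect_linear_fields <- function(spike_times, behavior, graph, v_thr = 2,
                                 n_shuffle = 1000, min_bins = 8,
                                 sigma_bins = 1, pctile = 95, seed = 1) {
  bins <- graph$bins
  B <- nrow(bins)
  block <- bin_block(graph)
  use <- behavior$speed_cm_s > v_thr & !is.na(behavior$linear_cm)
  mv <- which(use)
  dt_pos <- behavior$time_s[2] - behavior$time_s[1]
  pos_bin <- nearest_grid_index(behavior$linear_cm, bins$linear)
  occ_s <- smooth_blocks(tabulate(pos_bin[mv], nbins = B) * dt_pos,
                         block, sigma_bins)
  si <- spike_sample_index(spike_times, behavior$time_s)
  # rank of each spike's sample within the movement-sample sequence;
  # spikes outside movement samples are dropped
  rk <- findInterval(si, mv)
  rk <- rk[rk >= 1 & mv[pmax(rk, 1)] == si]
  n_mv <- length(mv)
  ratemap_at <- function(shift) {
    r2 <- ((rk - 1 + shift) %% n_mv) + 1
    cnt <- tabulate(pos_bin[mv[r2]], nbins = B)
    smooth_blocks(cnt, block, sigma_bins) / pmax(occ_s, 1e-12)
  }
  obs <- ratemap_at(0L)
  empty <- data.frame(bin0 = integer(0), bin1 = integer(0),
                      start_lin = numeric(0), end_lin = numeric(0),
                      peak_lin = numeric(0), peak_rate = numeric(0))
  attr(empty, "ratemap") <- obs
  if (!length(rk)) return(empty)
  set.seed(seed)
  shifts <- sample.int(n_mv - 1L, n_shuffle, replace = n_shuffle > n_mv - 1L)
  null <- vapply(shifts, ratemap_at, numeric(B))
  thr <- apply(null, 1, stats::quantile, probs = pctile / 100, names = FALSE)
  above <- obs > thr
  fields <- list()
  for (b in unique(block)) {
    idx <- which(block == b)
    runs <- logical_runs(above[idx])
    runs <- runs[runs$i1 - runs$i0 + 1 >= min_bins, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      gi <- idx[runs$i0[r]:runs$i1[r]]
      fields[[length(fields) + 1]] <- data.frame(
        bin0 = gi[1], bin1 = gi[length(gi)],
        start_lin = bins$linear[gi[1]] - graph$bin_size / 2,
        end_lin = bins$linear[gi[length(gi)]] + graph$bin_size / 2,
        peak_lin = bins$linear[gi[which.max(obs[gi])]],
        peak_rate = max(obs[gi]))
    }
  }
  out <- if (length(fields)) do.call(rbind, fields) else empty
  attr(out, "ratemap") <- obs
  out
}

# does any field interval contain the linearized position?
field_contains <- function(fields, lin) {
  if (is.null(fields) || !nrow(fields)) return(FALSE)
  any(lin >= fields$start_lin & lin <= fields$end_lin)
}

#' Active-cell composition of local and nonlocal bouts
#'
#' For each coding bout (local and nonlocal), among units active in the bout
#' (at least one spike), the fraction with a field at the animal's position,
#' at the decoded position, and at both.
#'
#' @param labels a \code{nonlocal_labels}.
#' @param spikes spikes data.frame (MEC units are used).
#' @param fields named list of per-unit field tables (names = unit ids).
#' @param graph a \code{track_graph}.
#' @param min_duration drop bouts shorter than this, s (default 0.02).
#' @return data.frame: condition, bout, t0, t1, n_active, frac_at_animal,
#'   frac_at_decoded, frac_at_both.
#' @export
active_cell_composition <- function(labels, spikes, fields, graph,
                                    min_duration = 0.02) {
  mec <- spikes[spikes$region == "MEC" &
                  spikes$unit_id %in% names(fields), ]
  sp_by_unit <- split(mec$time_s, mec$unit_id)
  bout_tables <- list(
    nonlocal = labels$bouts,
    local = {
      runs <- logical_runs(labels$flags$local)
      if (nrow(runs)) {
        data.frame(t0 = labels$flags$time[runs$i0],
                   t1 = labels$flags$time[runs$i1],
                   mouse_lin = labels$flags$actual_lin[runs$i0],
                   map_lin = vapply(seq_len(nrow(runs)), function(k)
                     stats::median(labels$flags$map_lin[runs$i0[k]:runs$i1[k]]), 0))
      } else data.frame(t0 = numeric(0), t1 = numeric(0),
                        mouse_lin = numeric(0), map_lin = numeric(0))
    })
  out <- list()
  for (cond in names(bout_tables)) {
    bt <- bout_tables[[cond]]
    for (b in seq_len(nrow(bt))) {
      if (bt$t1[b] - bt$t0[b] < min_duration) next
      active <- names(sp_by_unit)[vapply(sp_by_unit, function(ts)
        any(ts >= bt$t0[b] & ts <= bt$t1[b]), TRUE)]
      if (!length(active)) next
      at_a <- vapply(active, function(u)
        field_contains(fields[[u]], bt$mouse_lin[b]), TRUE)
      at_d <- vapply(active, function(u)
        field_contains(fields[[u]], bt$map_lin[b]), TRUE)
      out[[length(out) + 1]] <- data.frame(
        condition = cond, bout = b, t0 = bt$t0[b], t1 = bt$t1[b],
        n_active = length(active),
        frac_at_animal = mean(at_a), frac_at_decoded = mean(at_d),
        frac_at_both = mean(at_a & at_d))
    }
  }
  if (!length(out))
    return(data.frame(condition = character(0), bout = integer(0),
                      t0 = numeric(0), t1 = numeric(0), n_active = integer(0),
                      frac_at_animal = numeric(0), frac_at_decoded = numeric(0),
                      frac_at_both = numeric(0)))
  do.call(rbind, out)
}

#' Re-decode after removing decoded-field spikes
#'
#' Within each nonlocal bout, deletes the spikes of units that have a field at
#' that bout's decoded position, reruns the full-train decode and relabels
#' nonlocal coding - the ablation that tests whether nonlocal content is
#' carried by remote-field cells.
#'
#' @param session a \code{session}.
#' @param labels a \code{nonlocal_labels} from the standard decode.
#' @param fields named list of per-unit field tables.
#' @param graph a \code{track_graph}.
#' @param ... passed to \code{crossval_decode}.
#' @return list: \code{labels} (re-decoded), \code{n_removed} (spikes
#'   deleted), \code{session} (with spikes removed).
#' @export
remove_field_spikes_redecode <- function(session, labels, fields, graph, ...) {
  sp <- session$spikes
  drop <- rep(FALSE, nrow(sp))
  for (b in seq_len(nrow(labels$bouts))) {
    bt <- labels$bouts[b, ]
    in_bout <- sp$time_s >= bt$t0 & sp$time_s <= bt$t1
    if (!any(in_bout)) next
    for (u in unique(sp$unit_id[in_bout])) {
      if (field_contains(fields[[as.character(u)]], bt$map_lin))
        drop[in_bout & sp$unit_id == u] <- TRUE
    }
  }
  ses2 <- session
  ses2$spikes <- sp[!drop, ]
  post <- crossval_decode(ses2, graph, ...)
  keep <- confidence_mask(post)
  list(labels = label_nonlocal(post, ses2$behavior, graph, keep = keep),
       n_removed = sum(drop), session = ses2)
}

#' Preferential recruitment to nonlocal coding
#'
#' One-sided shuffle test per unit: the unit's mean firing rate over all
#' nonlocal periods against a null built by circularly shifting its spike
#' train (1000 iterations); recruited if the observed rate exceeds the null's
#' 95th percentile.
#'
#' @param spike_times one unit's spike times, s.
#' @param bouts nonlocal bout table (t0, t1).
#' @param duration session duration, s.
#' @param n_shuffle shuffles (default 1000).
#' @param pctile null percentile (default 95).
#' @param seed RNG seed.
#' @return list: \code{rate}, \code{null} (vector), \code{recruited},
#'   \code{pctile_rank}.
#' @export
preferential_recruitment <- function(spike_times, bouts, duration,
                                     n_shuffle = 1000, pctile = 95, seed = 1) {
  if (!nrow(bouts)) stop("no nonlocal bouts")
  total <- sum(bouts$t1 - bouts$t0)
  obs <- count_in_intervals(spike_times, bouts$t0, bouts$t1) / total
  if (!length(spike_times))
    return(list(rate = 0, null = rep(0, n_shuffle), recruited = FALSE,
                pctile_rank = 0))
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) {
    shifted <- (spike_times + stats::runif(1, 0, duration)) %% duration
    count_in_intervals(shifted, bouts$t0, bouts$t1) / total
  }, 0)
  thr <- stats::quantile(null, pctile / 100, names = FALSE)
  list(rate = obs, null = null, recruited = obs > thr,
       pctile_rank = mean(obs > null))
}

#' Spatial information of a rate map
#'
#' Rate-map mutual information between firing and position (bits per spike):
#' sum over occupied bins of p(x) (lambda(x)/mean) log2(lambda(x)/mean).
#'
#' @param rate per-bin firing rate, Hz.
#' @param occupancy per-bin occupancy, s (or any weights).
#' @return bits per spike; 0 for a silent unit.
#' @export
spatial_information <- function(rate, occupancy) {
  ok <- !is.na(rate) & !is.na(occupancy) & occupancy > 0
  if (!any(ok)) stop("no occupied bins")
  p <- occupancy[ok] / sum(occupancy[ok])
  lam <- rate[ok]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(0)
  rel <- lam / lbar
  sum(p[rel > 0] * rel[rel > 0] * log2(rel[rel > 0]))
}

# 2D ratemap in square bins with Gaussian smoothing of counts and occupancy
ratemap_2d <- function(spike_times, behavior, box = 75, bin_cm = 2.5,
                       sigma_bins = 1.5, v_thr = 2) {
  use <- behavior$speed_cm_s > v_thr
  nb <- ceiling(box / bin_cm)
  dt <- behavior$time_s[2] - behavior$time_s[1]
  bx <- pmin(pmax(ceiling(behavior$x_cm / bin_cm), 1), nb)
  by <- pmin(pmax(ceiling(behavior$y_cm / bin_cm), 1), nb)
  occ <- matrix(0, nb, nb)
  tab <- table(factor(bx[use], 1:nb), factor(by[use], 1:nb))
  occ[] <- as.numeric(tab) * dt
  si <- spike_sample_index(spike_times, behavior$time_s)
  si <- si[use[si]]
  cnt <- matrix(0, nb, nb)
  if (length(si)) {
    tabs <- table(factor(bx[si], 1:nb), factor(by[si], 1:nb))
    cnt[] <- as.numeric(tabs)
  }
  sm <- function(m) {
    half <- ceiling(3 * sigma_bins)
    k <- exp(-(-half:half)^2 / (2 * sigma_bins^2))
    k <- k / sum(k)
    pad <- function(mm) mm
    m1 <- apply(m, 2, function(v) stats::filter(c(rep(0, half), v, rep(0, half)),
                                                k, sides = 2)[(half + 1):(half + nb)])
    t(apply(t(m1), 2, function(v) stats::filter(c(rep(0, half), v, rep(0, half)),
                                                k, sides = 2)[(half + 1):(half + nb)]))
  }
  occ_s <- sm(occ); cnt_s <- sm(cnt)
  rate <- cnt_s / pmax(occ_s, 1e-12)
  rate[occ_s < 1e-6] <- NA
  list(rate = rate, occupancy = occ, bin_cm = bin_cm, box = box)
}

#' Open-field tuning scores of one unit
#'
#' Computed over movement samples (speed > 2 cm/s): speed score (Pearson
#' correlation between firing rate and speed across 2-cm/s bins), head
#' direction score (resultant vector length of firing rate across 10-degree
#' bins), the 2.5-cm smoothed 2D ratemap (Gaussian sigma = 1.5 bins), spatial
#' stability (ratemap correlation between epoch halves over bins visited in
#' both) and 2D spatial information.
#'
#' @param spike_times one unit's spike times, s.
#' @param behavior open-field behavior data.frame (time_s, x_cm, y_cm,
#'   hd_deg, speed_cm_s).
#' @param box box side, cm.
#' @param v_thr movement threshold.
#' @return list: speed_score, speed_defined, hd_score, spatial_info,
#'   stability, ratemap (list from the 2D binner).
#' @export
tuning_scores <- function(spike_times, behavior, box = 75, v_thr = 2) {
  use <- behavior$speed_cm_s > v_thr
  dt <- behavior$time_s[2] - behavior$time_s[1]
  si <- spike_sample_index(spike_times, behavior$time_s)
  si <- si[use[si]]
  # speed score over 2-cm/s bins
  sb_edges <- seq(v_thr, max(behavior$speed_cm_s[use]) + 2, by = 2)
  sb <- cut(behavior$speed_cm_s[use], sb_edges, include.lowest = TRUE)
  occ_sb <- tabulate(sb, nbins = nlevels(sb)) * dt
  cnt_sb <- tabulate(cut(behavior$speed_cm_s[si], sb_edges,
                         include.lowest = TRUE), nbins = nlevels(sb))
  okb <- occ_sb > 0.5
  speed_defined <- sum(okb) >= 2
  speed_score <- if (speed_defined) {
    ctrs <- (sb_edges[-1] + sb_edges[-length(sb_edges)]) / 2
    suppressWarnings(stats::cor(ctrs[okb], cnt_sb[okb] / occ_sb[okb]))
  } else 0
  if (is.na(speed_score)) { speed_score <- 0; speed_defined <- FALSE }
  # HD score: resultant vector of rates across 10-degree bins
  hb <- floor(behavior$hd_deg / 10) %% 36 + 1
  occ_hb <- tabulate(hb[use], nbins = 36) * dt
  cnt_hb <- tabulate(hb[si], nbins = 36)
  r_hb <- ifelse(occ_hb > 0, cnt_hb / occ_hb, 0)
  th <- (seq_len(36) - 0.5) * 10 * pi / 180
  hd_score <- if (sum(r_hb) > 0)
    Mod(sum(r_hb * exp(1i * th))) / sum(r_hb) else 0
  # ratemap, spatial information, stability
  rm_all <- ratemap_2d(spike_times, behavior, box, v_thr = v_thr)
  half_t <- behavior$time_s[round(nrow(behavior) / 2)]
  rm1 <- ratemap_2d(spike_times[spike_times < half_t],
                    behavior[behavior$time_s < half_t, ], box, v_thr = v_thr)
  rm2 <- ratemap_2d(spike_times[spike_times >= half_t],
                    behavior[behavior$time_s >= half_t, ], box, v_thr = v_thr)
  both <- !is.na(rm1$rate) & !is.na(rm2$rate)
  stability <- if (sum(both) > 10)
    suppressWarnings(stats::cor(rm1$rate[both], rm2$rate[both])) else 0
  if (is.na(stability)) stability <- 0
  ok <- !is.na(rm_all$rate)
  s_info <- spatial_information(rm_all$rate[ok], rm_all$occupancy[ok] + 1e-12)
  list(speed_score = speed_score, speed_defined = speed_defined,
       hd_score = hd_score, spatial_info = s_info, stability = stability,
       ratemap = rm_all)
}

# Pearson spatial autocorrelogram of a ratemap (NA-aware)
ratemap_autocorr <- function(rate, min_overlap = 20) {
  n <- nrow(rate); m <- ncol(rate)
  ac <- matrix(NA_real_, 2 * n - 1, 2 * m - 1)
  for (dx in -(n - 1):(n - 1)) {
    xi <- max(1, 1 + dx):min(n, n + dx)
    xj <- xi - dx
    for (dy in -(m - 1):(m - 1)) {
      yi <- max(1, 1 + dy):min(m, m + dy)
      yj <- yi - dy
      a <- rate[xi, yi]; b <- rate[xj, yj]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) >= min_overlap)
        ac[n + dx, m + dy] <- suppressWarnings(stats::cor(a[ok], b[ok]))
    }
  }
  ac
}

# bilinear interpolation into a matrix (NA outside)
bilin <- function(m, x, y) {
  n <- nrow(m); p <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  ok <- x0 >= 1 & x0 < n & y0 >= 1 & y0 < p
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  fx <- x[ok] - x0[ok]; fy <- y[ok] - y0[ok]
  i <- x0[ok]; j <- y0[ok]
  out[ok] <- (1 - fx) * (1 - fy) * m[cbind(i, j)] +
    fx * (1 - fy) * m[cbind(i + 1, j)] +
    (1 - fx) * fy * m[cbind(i, j + 1)] +
    fx * fy * m[cbind(i + 1, j + 1)]
  out
}

#' Grid and border scores of a 2D ratemap
#'
#' Grid score: mean Pearson correlation between the ratemap autocorrelogram
#' and itself rotated by 60 and 120 degrees, minus the mean at 30, 90 and 150
#' degrees, evaluated on an annulus that excludes the central peak (inner
#' radius = first zero crossing of the radial profile). Border score: the
#' longest fraction of a wall adjacent to a single field minus the mean
#' (rate-weighted, half-box-normalized) distance of field bins from their
#' nearest wall, divided by their sum; 2D fields are connected components of
#' at least \code{min_bins} bins above \code{rate_thr}.
#'
#' @param ratemap list from the 2D binner (rate, bin_cm, box) or a plain rate
#'   matrix.
#' @param rate_thr field threshold, Hz (default 0.25).
#' @param min_bins minimum field size in bins (default 10).
#' @return list: grid_score, border_score, border_defined, n_fields.
#' @export
grid_border_scores <- function(ratemap, rate_thr = 0.25, min_bins = 10) {
  rate <- if (is.list(ratemap)) ratemap$rate else ratemap
  ac <- ratemap_autocorr(rate)
  cx <- (nrow(ac) + 1) / 2; cy <- (ncol(ac) + 1) / 2
  rmax <- min(cx, cy) - 1
  # radial profile to find the central peak's first zero crossing
  rr <- seq(1, rmax, by = 0.5)
  prof <- vapply(rr, function(r) {
    th <- seq(0, 2 * pi, length.out = 24)[-24]
    mean(bilin(ac, cx + r * cos(th), cy + r * sin(th)), na.rm = TRUE)
  }, 0)
  zc <- which(prof < 0)[1]
  r_in <- if (is.na(zc)) rmax / 3 else rr[zc]
  th <- seq(0, 2 * pi, length.out = 90)[-90]
  rads <- seq(r_in + 0.5, rmax, by = 0.5)
  px <- as.vector(outer(rads, cos(th))); py <- as.vector(outer(rads, sin(th)))
  base <- bilin(ac, cx + px, cy + py)
  rotcor <- vapply(c(30, 60, 90, 120, 150) * pi / 180, function(a) {
    rot <- bilin(ac, cx + px * cos(a) - py * sin(a),
                 cy + px * sin(a) + py * cos(a))
    ok <- !is.na(base) & !is.na(rot)
    if (sum(ok) < 20) return(NA_real_)
    suppressWarnings(stats::cor(base[ok], rot[ok]))
  }, 0)
  grid_score <- mean(rotcor[c(2, 4)]) - mean(rotcor[c(1, 3, 5)])

  # 2D fields: 4-connected components above threshold
  nb <- nrow(rate)
  above <- !is.na(rate) & rate > rate_thr
  lab <- matrix(0L, nb, ncol(rate))
  nf <- 0L
  for (i0 in seq_len(nb)) for (j0 in seq_len(ncol(rate))) {
    if (!above[i0, j0] || lab[i0, j0]) next
    nf <- nf + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- nf
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- q[1] + d[1]; jj <- q[2] + d[2]
        if (ii >= 1 && ii <= nb && jj >= 1 && jj <= ncol(rate) &&
            above[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- nf
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0], nbins = nf)
  keep_f <- which(sizes >= min_bins)
  if (!length(keep_f))
    return(list(grid_score = grid_score, border_score = NA_real_,
                border_defined = FALSE, n_fields = 0L))
  bin_cm <- if (is.list(ratemap)) ratemap$bin_cm else 1
  box <- if (is.list(ratemap)) ratemap$box else nb * bin_cm
  # cM: longest fraction of one wall adjacent to a single field
  cM <- 0
  for (f in keep_f) {
    msk <- lab == f
    cM <- max(cM,
              mean(msk[1, ]), mean(msk[nb, ]),
              mean(msk[, 1]), mean(msk[, ncol(rate)]))
  }
  # dm: rate-weighted mean distance of field bins from the nearest wall,
  # normalized by half the box
  fid <- which(array(lab %in% keep_f, dim(lab)), arr.ind = TRUE)
  dwall <- pmin(fid[, 1] - 1, nb - fid[, 1], fid[, 2] - 1,
                ncol(rate) - fid[, 2]) * bin_cm
  w <- rate[fid]
  dm <- sum(dwall * w) / sum(w) / (box / 2)
  border <- (cM - dm) / (cM + dm)
  list(grid_score = grid_score, border_score = border,
       border_defined = TRUE, n_fields = length(keep_f))
}

#' Classify a unit from shuffle nulls of its tuning scores
#'
#' Circularly shifts the spike train \code{n_shuffle} times, recomputes every
#' tuning score, and flags the unit for a variable when its observed score
#' exceeds the 95th percentile of its own null. Spatial, grid, border and
#' aperiodic flags additionally require spatial stability above its own null
#' threshold; aperiodic = spatial and neither grid nor border.
#'
#' @param spike_times one unit's spike times, s.
#' @param behavior open-field behavior data.frame.
#' @param box box side, cm.
#' @param n_shuffle shuffles (default 1000).
#' @param min_shift minimum circular shift, s (default 20).
#' @param pctile null percentile (default 95).
#' @param seed RNG seed.
#' @param scores_fn computes the score list (default computes all; swap in a
#'   cheaper one for calibration studies).
#' @return list: \code{scores} (observed), \code{flags} (logical: spatial,
#'   grid, border, aperiodic, hd, speed), \code{null_thr}.
#' @export
classify_cells <- function(spike_times, behavior, box = 75, n_shuffle = 1000,
                           min_shift = 20, pctile = 95, seed = 1,
                           scores_fn = NULL) {
  duration <- max(behavior$time_s)
  all_scores <- function(ts) {
    sc <- tuning_scores(ts, behavior, box)
    gb <- grid_border_scores(sc$ratemap)
    c(spatial = sc$spatial_info, speed = sc$speed_score, hd = sc$hd_score,
      stability = sc$stability, grid = gb$grid_score,
      border = if (gb$border_defined) gb$border_score else -1)
  }
  if (is.null(scores_fn)) scores_fn <- all_scores
  obs <- scores_fn(spike_times)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffle), function(i) {
    sh <- stats::runif(1, min_shift, duration - min_shift)
    scores_fn((spike_times + sh) %% duration)
  }, obs)
  if (is.null(dim(null)))
    null <- matrix(null, nrow = 1, dimnames = list(names(obs)))
  thr <- apply(null, 1, stats::quantile, probs = pctile / 100, names = FALSE)
  sig <- obs > thr
  flags <- c(spatial = FALSE, grid = FALSE, border = FALSE,
             aperiodic = FALSE, hd = FALSE, speed = FALSE)
  if ("hd" %in% names(sig)) flags["hd"] <- sig[["hd"]]
  if ("speed" %in% names(sig)) flags["speed"] <- sig[["speed"]]
  if (all(c("spatial", "stability") %in% names(sig))) {
    spatial <- sig[["spatial"]] && sig[["stability"]]
    flags["spatial"] <- spatial
    flags["grid"] <- spatial && isTRUE(sig[["grid"]])
    flags["border"] <- spatial && isTRUE(sig[["border"]])
    flags["aperiodic"] <- spatial && !flags["grid"] && !flags["border"]
  }
  list(scores = obs, flags = flags, null_thr = thr)
}

#' Reward-cell test
#'
#' One-sided rank test of whether a unit fires more during rewarded than
#' unrewarded reward-port visits (consumption periods).
#'
#' @param spike_times one unit's spike times, s.
#' @param pokes data.frame t0, t1, rewarded (logical): consumption periods.
#' @param alpha significance level (default 0.05).
#' @return list: \code{flag}, \code{p}, per-poke \code{rates}.
#' @export
reward_cells <- function(spike_times, pokes, alpha = 0.05) {
  if (!any(pokes$rewarded) || !any(!pokes$rewarded))
    stop("need both rewarded and unrewarded pokes")
  rates <- vapply(seq_len(nrow(pokes)), function(i)
    sum(spike_times >= pokes$t0[i] & spike_times <= pokes$t1[i]) /
      (pokes$t1[i] - pokes$t0[i]), 0)
  if (all(rates == 0))
    return(list(flag = FALSE, p = 1, rates = rates))
  p <- suppressWarnings(stats::wilcox.test(
    rates[pokes$rewarded], rates[!pokes$rewarded],
    alternative = "greater", exact = FALSE)$p.value)
  list(flag = p < alpha, p = p, rates = rates)
}
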