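#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; embedded in session metadata and
#' result tables so derived artifacts can be matched to the configuration that
#' produced them.
#'
#' @param config any list-like configuration.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

read_tsv <- function(path, ...)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)

#' Save / load a session bundle
#'
#' A session is persisted as a directory of plain-text tables: meta.json,
#' spikes.tsv (unit_id, region, depth_um, time_s), behavior.tsv, trials.tsv,
#' lfp.tsv (fs in meta; one column per region) and ground_truth.json when
#' present.
#'
#' @param session a \code{session}.
#' @param path directory to write to / read from.
#' @return \code{save_session}: the path, invisibly. \code{load_session}: a
#'   \code{session} (without the generator closures of the in-memory ground
#'   truth; fields, events and pairs are preserved).
#' @export
save_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- session$meta
  meta$has_lfp <- !is.null(session$lfp)
  if (meta$has_lfp) meta$fs_lfp <- session$lfp$fs
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  sp <- session$spikes
  if (is.null(sp$depth_um))
    sp$depth_um <- session$units$depth_um[match(sp$unit_id, session$units$unit_id)]
  write_tsv(sp[, c("unit_id", "region", "depth_um", "time_s")],
            file.path(path, "spikes.tsv"))
  write_tsv(session$behavior, file.path(path, "behavior.tsv"))
  write_tsv(session$trials, file.path(path, "trials.tsv"))
  write_tsv(session$units, file.path(path, "units.tsv"))
  if (!is.null(session$lfp))
    write_tsv(data.frame(ca1 = round(session$lfp$ca1, 4),
                         mec = round(session$lfp$mec, 4)),
              file.path(path, "lfp.tsv"))
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth
    jsonlite::write_json(
      list(events = gt$events, swr = gt$swr, coupled_pairs = gt$coupled_pairs,
           fields = lapply(gt$tuning$fields, identity)),
      file.path(path, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  need <- c("meta.json", "spikes.tsv", "behavior.tsv", "trials.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session bundle is missing required file(s): ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  spikes <- read_tsv(file.path(path, "spikes.tsv"))
  bad <- which(spikes$time_s < 0 | spikes$time_s > meta$duration + 1)
  if (length(bad))
    stop("spikes.tsv: time out of session range at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  unsorted <- which(diff(spikes$time_s) < 0 &
                      diff(spikes$unit_id) == 0)
  if (length(unsorted))
    stop("spikes.tsv: unsorted spike times within unit at row ", unsorted[1] + 1)
  behavior <- read_tsv(file.path(path, "behavior.tsv"))
  trials <- read_tsv(file.path(path, "trials.tsv"))
  units <- if (file.exists(file.path(path, "units.tsv")))
    read_tsv(file.path(path, "units.tsv")) else NULL
  lfp <- NULL
  if (isTRUE(meta$has_lfp) && file.exists(file.path(path, "lfp.tsv"))) {
    lf <- read_tsv(file.path(path, "lfp.tsv"))
    lfp <- list(fs = meta$fs_lfp,
                t = (seq_len(nrow(lf)) - 1) / meta$fs_lfp,
                ca1 = lf$ca1, mec = lf$mec)
  } else if (isTRUE(meta$has_lfp)) {
    message("lfp.tsv missing: LFP stages will be disabled for this session")
  }
  gt <- NULL
  gtp <- file.path(path, "ground_truth.json")
  if (file.exists(gtp)) {
    gt <- jsonlite::read_json(gtp, simplifyVector = TRUE)
    if (length(gt$events) == 0)
      gt$events <- data.frame(t0 = numeric(0), t1 = numeric(0),
                              target_lin = numeric(0), mouse_lin = numeric(0),
                              target_segment = character(0), paired = logical(0))
  }
  structure(list(meta = meta, behavior = behavior, trials = trials,
                 spikes = spikes, units = units, lfp = lfp,
                 ground_truth = gt), class = "session")
}

#' Run the full analysis pipeline on one synthetic session
#'
#' Ordered execution of every stage: simulate, cross-validated decode,
#' confidence mask, immobility and nonlocal labelling, bout and segment
#' statistics, paired-reward analysis, linear fields and preferential
#' recruitment, SWR detection and overlap, MEC-CA1 co-firing and decode
#' coincidence, and trial-accuracy prediction. Result tables are written as
#' TSV under \code{out_dir}, each stamped with the config hash; runs are
#' deterministic per seed.
#'
#' @param config a \code{sim_config}; the seed inside it drives everything.
#' @param out_dir output directory (default "results").
#' @param k cross-validation folds for movement decoding; immobility is
#'   decoded with the full-train model (k = 1).
#' @param stages character vector of stages to run (default all): subset of
#'   decode, nonlocal, cells, lfp, cofiring, accuracy.
#' @param n_shuffle shuffle count for the single-unit and overlap statistics.
#' @return invisible list of the main results.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "results",
                         k = 1, stages = c("decode", "nonlocal", "cells",
                                           "lfp", "cofiring", "accuracy"),
                         n_shuffle = 1000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- function(df) { df$config_hash <- hash; df }
  logf <- file.path(out_dir, "pipeline.log")
  logit <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                     sprintf(...)), file = logf, append = TRUE)
  cat(sprintf("pipeline seed=%d hash=%s\n", config$seed, hash), file = logf)

  graph <- build_xmaze_graph()
  session <- simulate_session(config, graph)
  logit("simulated session: %.0f s, %d spikes", session$meta$duration,
        nrow(session$spikes))
  res <- list(session = session)
  if (!"decode" %in% stages) return(invisible(res))

  post <- crossval_decode(session, graph, k = k)
  keep <- confidence_mask(post)
  logit("decoded %d bins, %.1f%% excluded by confidence",
        length(post$time), 100 * mean(!keep))
  res$posterior <- post

  if ("nonlocal" %in% stages) {
    labels <- label_nonlocal(post, session$behavior, graph, keep = keep)
    bs <- bout_statistics(labels)
    write_tsv(stamp(bs$per_bout), file.path(out_dir, "fig2_bouts.tsv"))
    write_tsv(stamp(bs$summary), file.path(out_dir, "fig2_summary.tsv"))
    segrep <- segment_representation(labels, graph)
    write_tsv(stamp(segrep), file.path(out_dir, "fig5_segments.tsv"))
    paired <- paired_reward_analysis(labels, session$trials, config$rule,
                                     graph, seed = config$seed)
    write_tsv(stamp(paired), file.path(out_dir, "fig5_paired.tsv"))
    logit("nonlocal: %d bouts, %.1f%% of immobile time",
          nrow(labels$bouts), bs$summary$pct_immobile_time_nonlocal)
    res$labels <- labels; res$bouts <- bs; res$segments <- segrep
    res$paired <- paired
  }

  if ("cells" %in% stages && !is.null(res$labels)) {
    enc <- fit_encoding(session$spikes[session$spikes$region == "MEC", ],
                        session$behavior, graph)
    fields <- lapply(enc$unit_ids, function(u)
      detect_linear_fields(session$spikes$time_s[session$spikes$unit_id == u],
                           session$behavior, graph,
                           n_shuffle = min(n_shuffle, 200),
                           seed = child_seed(config$seed, "fields")))
    names(fields) <- as.character(enc$unit_ids)
    comp <- active_cell_composition(res$labels, session$spikes, fields, graph)
    write_tsv(stamp(comp), file.path(out_dir, "fig3_composition.tsv"))
    recr <- vapply(enc$unit_ids, function(u)
      preferential_recruitment(
        session$spikes$time_s[session$spikes$unit_id == u],
        res$labels$bouts, session$meta$duration,
        n_shuffle = min(n_shuffle, 500),
        seed = child_seed(config$seed, "recruit"))$recruited, TRUE)
    write_tsv(stamp(data.frame(unit_id = enc$unit_ids, recruited = recr)),
              file.path(out_dir, "fig3_recruitment.tsv"))
    logit("cells: %d units, %d preferentially recruited",
          length(enc$unit_ids), sum(recr))
    res$fields <- fields
  }

  if ("lfp" %in% stages) {
    if (is.null(session$lfp)) {
      logit("lfp stage skipped: no LFP in session")
    } else {
      swr <- detect_swr_envelope(session$lfp$ca1, session$lfp$fs)
      write_tsv(stamp(swr), file.path(out_dir, "swr_events.tsv"))
      if (!is.null(res$labels) && nrow(swr)) {
        ov <- overlap_shuffle(swr, res$labels$bouts, res$labels$immobility,
                              n_shuffle = n_shuffle,
                              seed = child_seed(config$seed, "overlap"))
        write_tsv(stamp(data.frame(pct_swr_with_nonlocal = ov$pct_events_with_nonlocal,
                                   pct_nonlocal_in_swr = ov$pct_nonlocal_in_events,
                                   significant = ov$significant)),
                  file.path(out_dir, "swr_overlap.tsv"))
      }
      logit("lfp: %d SWRs detected", nrow(swr))
      res$swr <- swr
    }
  }

  if ("cofiring" %in% stages && !is.null(res$labels)) {
    if (!any(session$units$region == "CA1")) {
      logit("cofiring stage skipped: no CA1 units in session")
    } else {
      pairs <- cofire_all_pairs(session, res$labels,
                                n_shuffle = min(n_shuffle, 200),
                                seed = child_seed(config$seed, "cofire"))
      write_tsv(stamp(pairs), file.path(out_dir, "fig4_pairs.tsv"))
      res$pairs <- pairs
      logit("cofiring: %d pairs tested", nrow(pairs))
    }
  }

  if ("accuracy" %in% stages && !is.null(res$bouts)) {
    feats <- choice_reward_features(res$labels, session$trials, graph)
    if (sum(feats$correct) >= 5 && sum(!feats$correct) >= 5) {
      acc <- predict_trial_accuracy(feats, n_rep = 1000,
                                    seed = child_seed(config$seed, "accuracy"))
      write_tsv(stamp(data.frame(mean_accuracy = acc$mean_accuracy,
                                 sem_accuracy = acc$sem_accuracy,
                                 n_per_class = acc$n_per_class)),
                file.path(out_dir, "fig5_accuracy.tsv"))
      logit("accuracy: %.3f +/- %.3f", acc$mean_accuracy, acc$sem_accuracy)
      res$accuracy <- acc
    } else logit("accuracy stage skipped: fewer than 5 bouts per class")
  }
  invisible(res)
}

#' Per-trial nonlocal content at the choice reward
#'
#' Feature table for \code{predict_trial_accuracy}: for each trial, the
#' percentage of kept immobile bins after the choice poke (while the mouse is
#' at the choice reward) that are nonlocal.
#'
#' @param labels a \code{nonlocal_labels}.
#' @param trials trial table.
#' @param graph a \code{track_graph}.
#' @return data.frame trial, pct_nonlocal, correct.
#' @export
choice_reward_features <- function(labels, trials, graph) {
  fl <- labels$flags
  seg <- segment_of(fl$actual_lin, graph)$segment
  out <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    t_hi <- if (i < nrow(trials)) trials$sample_poke_t[i + 1] else Inf
    sel <- fl$time >= trials$choice_poke_t[i] & fl$time < t_hi &
      fl$immobile & fl$kept & !is.na(fl$dist_cm) & seg == "choice_reward"
    data.frame(trial = i,
               pct_nonlocal = if (any(sel)) 100 * mean(fl$nonlocal[sel]) else NA_real_,
               correct = trials$correct[i])
  }))
  out[!is.na(out$pct_nonlocal), ]
}
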