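#!/usr/bin/env Rscript
# Stage 5: CA1 LFP ripple detection (envelope and multi-unit variants), the
# SWR / nonlocal temporal-shuffle overlap test, and MEC->CA1 spike-timing
# coordination during local versus nonlocal coding.

suppressPackageStartupMessages(library(mecnonlocal))
seed <- as.integer(Sys.getenv("MECNL_SEED", "1"))

graph <- build_xmaze_graph()
session <- load_session("results/session")
lab_cache <- readRDS("scratch/labels.rds")
if (!identical(lab_cache$config_hash, session$meta$config_hash))
  stop("cached labels were produced under a different config; rerun 03_nonlocal.R")
labels <- lab_cache$labels

swr <- detect_swr_envelope(session$lfp$ca1, session$lfp$fs)
true_swr <- session$ground_truth$swr
rec <- mean(vapply(seq_len(nrow(true_swr)), function(k)
  any(swr$t1 > true_swr$t0[k] & swr$t0 < true_swr$t1[k]), TRUE))
mua <- detect_swr_mua(session$spikes$time_s[session$spikes$region == "CA1"],
                      session$meta$duration)
write.table(swr, "results/05_swr_events.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ov <- overlap_shuffle(swr, labels$bouts, labels$immobility,
                      n_shuffle = 1000, seed = seed)
write.table(data.frame(pct_swr_with_nonlocal = round(ov$pct_events_with_nonlocal, 1),
                       pct_nonlocal_in_swr = round(ov$pct_nonlocal_in_events, 1),
                       null_95 = round(quantile(ov$null, 0.95), 1),
                       significant = ov$significant),
            "results/05_swr_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pairs <- cofire_all_pairs(session, labels, n_shuffle = 200, seed = seed)
write.table(pairs, "results/05_fig4_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ps <- pair_population_summary(pairs)
truth_pairs <- session$ground_truth$coupled_pairs
hit <- mean(vapply(seq_len(nrow(truth_pairs)), function(k) {
  r <- pairs[pairs$mec == truth_pairs$mec[k] & pairs$ca1 == truth_pairs$ca1[k], ]
  nrow(r) > 0 && isTRUE(r$sig_local)
}, TRUE))

cat(sprintf("SWR: %d detected (recall %.2f vs injected), %d by MUA; overlap with nonlocal %s; cofiring: %.1f%% pairs sig local, %.1f%% sig nonlocal (%.0f%% of truly coupled pairs recovered)\n",
            nrow(swr), rec, nrow(mua),
            if (ov$significant) "significant" else "at chance",
            ps$pct_sig_local, ps$pct_sig_nonlocal, 100 * hit))
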