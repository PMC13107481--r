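#!/usr/bin/env Rscript
# Stage 1: generate one synthetic X-maze session with known ground truth.
#
# The generator emulates the task conditions: trial blocks of ten starting
# with the southwest sample arm, immobility dwells at reward ports, 100 MEC +
# 15 CA1 units with Gaussian fields tiling the 230-cm linearized track,
# discrete remote-reactivation events injected during immobility (targets
# enriched at reward segments), lag-coupled CA1 spiking during local
# immobility, and LFP with movement theta and immobility ripples. Here we run
# 30 trials (about 8-9 simulated minutes) so the full workflow stays desk
# sized; the per-trial structure is unchanged.

suppressPackageStartupMessages(library(mecnonlocal))
seed <- as.integer(Sys.getenv("MECNL_SEED", "1"))

graph <- build_xmaze_graph()
config <- sim_config(n_trials = 30, seed = seed)
session <- simulate_session(config, graph)
print(session)

dir.create("results", showWarnings = FALSE)
save_session(session, "results/session")
track_to_json(graph, "results/track_graph.json")

gt <- session$ground_truth
ev <- gt$events
imm <- detect_immobility(session$behavior$speed_cm_s, session$behavior$time_s,
                         session$behavior$linear_cm, graph)
summary <- data.frame(
  n_trials = nrow(session$trials),
  duration_s = round(session$meta$duration, 1),
  n_units = nrow(session$units),
  n_spikes = nrow(session$spikes),
  n_immobility_bouts = nrow(imm),
  pct_time_immobile = round(100 * sum(imm$t1 - imm$t0) /
                              session$meta$duration, 1),
  n_injected_events = nrow(ev),
  pct_immobile_time_in_events = round(100 * sum(ev$t1 - ev$t0) /
                                        sum(imm$t1 - imm$t0), 1),
  n_injected_swr = nrow(gt$swr),
  n_coupled_pairs = nrow(gt$coupled_pairs))
write.table(summary, "results/01_ground_truth_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("session written to results/session: %d injected events over %.0f s (%s%% of immobility)\n",
            nrow(ev), session$meta$duration,
            summary$pct_immobile_time_in_events))
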