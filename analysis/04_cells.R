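#!/usr/bin/env Rscript
# Stage 4: single-unit analyses on the X-maze - linear field detection with a
# position-shuffle null, the composition of active ensembles during local
# versus nonlocal coding, the decoded-field spike-removal ablation, and
# preferential recruitment. Shuffle counts are reduced from the canonical
# 1000 to keep the stage desk sized; the test suite calibrates the full rule.

suppressPackageStartupMessages(library(mecnonlocal))
seed <- as.integer(Sys.getenv("MECNL_SEED", "1"))

graph <- build_xmaze_graph()
session <- load_session("results/session")
lab_cache <- readRDS("scratch/labels.rds")
if (!identical(lab_cache$config_hash, session$meta$config_hash))
  stop("cached labels were produced under a different config; rerun 03_nonlocal.R")
labels <- lab_cache$labels

mec <- session$spikes[session$spikes$region == "MEC", ]
unit_ids <- sort(unique(mec$unit_id))
fields <- lapply(unit_ids, function(u)
  detect_linear_fields(mec$time_s[mec$unit_id == u], session$behavior, graph,
                       n_shuffle = 200, seed = seed))
names(fields) <- as.character(unit_ids)
n_fields <- vapply(fields, nrow, 0L)
write.table(data.frame(unit_id = unit_ids, n_fields = n_fields),
            "results/04_fields.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

comp <- active_cell_composition(labels, session$spikes, fields, graph)
write.table(comp, "results/04_fig3_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
agg <- aggregate(cbind(frac_at_animal, frac_at_decoded) ~ condition, comp, mean)

recr <- vapply(unit_ids, function(u)
  preferential_recruitment(mec$time_s[mec$unit_id == u],
                           labels$bouts, session$meta$duration,
                           n_shuffle = 500, seed = seed)$recruited, TRUE)
write.table(data.frame(unit_id = unit_ids, recruited = recr),
            "results/04_fig3_recruitment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

red <- remove_field_spikes_redecode(session, labels, fields, graph, k = 1)
before <- bout_statistics(labels)$summary$pct_immobile_time_nonlocal
after <- bout_statistics(red$labels)$summary$pct_immobile_time_nonlocal
write.table(data.frame(n_spikes_removed = red$n_removed,
                       pct_nonlocal_before = round(before, 2),
                       pct_nonlocal_after = round(after, 2)),
            "results/04_fig3_removal.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("fields: %d/%d units with >=1 field; active-at-animal fraction local %.2f vs nonlocal %.2f; %d/%d recruited; removing decoded-field spikes drops nonlocal %.1f%% -> %.1f%%\n",
            sum(n_fields > 0), length(unit_ids),
            agg$frac_at_animal[agg$condition == "local"],
            agg$frac_at_animal[agg$condition == "nonlocal"],
            sum(recr), length(unit_ids), before, after))
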