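#!/usr/bin/env Rscript
# Stage 6: collect the headline quantities from every stage into one table
# and restate the analytic chance geometry they are compared against.

suppressPackageStartupMessages(library(mecnonlocal))

graph <- build_xmaze_graph()
rd <- function(f) read.table(file.path("results", f), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
gt <- rd("01_ground_truth_summary.tsv")
dec <- rd("02_decode_summary.tsv")
nl <- rd("03_fig2_summary.tsv")
rec <- rd("03_event_recovery.tsv")

chance <- data.frame(
  target = segment_levels(),
  chance_at_port = vapply(segment_levels(), function(s)
    chance_level(0, s, graph), 0))

report <- data.frame(
  quantity = c("median movement decode error (cm)",
               "shuffled-control decode error (cm)",
               "pct immobile time nonlocal",
               "pct immobility bouts with nonlocal",
               "mean nonlocal duration (ms)",
               "event recall", "event precision",
               "sample-sample port distance (cm)",
               "sample-choice port distance (cm)",
               "chance denominator at port (cm)"),
  value = c(dec$median_movement_error_cm,
            dec$median_shuffled_control_error_cm,
            round(nl$pct_immobile_time_nonlocal, 1),
            round(nl$pct_bouts_with_nonlocal, 1),
            round(nl$mean_nonlocal_duration_ms, 0),
            rec$recall, rec$precision,
            track_distance(0, 65, graph),
            track_distance(0, 225, graph),
            nonlocal_denominator(0, graph)))
write.table(report, "results/06_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(chance, "results/06_chance_geometry.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report, row.names = FALSE)
cat("\nchance geometry at a sample port (fractions of 210 cm):\n")
print(chance, row.names = FALSE)
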