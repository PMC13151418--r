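#!/usr/bin/env Rscript
# Apply the cohort exclusion rules to the per-participant summaries:
# an ROI channel is available iff both conditions have >= 3 valid blocks;
# a participant is retained iff >= 5 of the 6 ROI channels are available.
# Writes the tidy cohort table (the inference module's input) and the
# exclusion report.

library(nirsblock)

flat <- utils::read.csv(file.path("results", "participant_summaries.csv"))
ids <- unique(flat$participant)
summaries <- lapply(ids, function(id) {
  s <- flat[flat$participant == id, c("channel", "condition", "hb",
                                      "mean_change", "n_valid_blocks")]
  structure(list(summary = s), class = "participant_summary")
})

exc <- apply_exclusions(summaries, exclusion_params(), probe_layout(),
                        participant_ids = ids, age_group = "5-month")

utils::write.csv(exc$cohort, file.path("results", "cohort.csv"),
                 row.names = FALSE)
utils::write.csv(exc$report, file.path("results", "exclusions.csv"),
                 row.names = FALSE)

cat(sprintf("retained %d of %d participants\n",
            sum(exc$report$included), length(ids)))
if (any(!exc$report$included)) {
  bad <- exc$report[!exc$report$included, ]
  for (r in seq_len(nrow(bad)))
    cat(sprintf("  excluded %s: %s\n", bad$participant[r], bad$reason[r]))
}
cat("wrote results/cohort.csv and results/exclusions.csv\n")
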