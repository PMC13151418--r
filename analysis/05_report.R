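#!/usr/bin/env Rscript
# Render the human-readable report from the results table: grouped by
# hemoglobin species, age group and family, significance flagged at
# alpha = 0.05, with the sign-convention footnote.

library(nirsblock)

results <- utils::read.csv(file.path("results", "results.csv"))
class(results) <- c("group_test_result", class(results))

lines <- render_report(results, alpha = 0.05,
                       file = file.path("results", "report.txt"))
cat(lines, sep = "\n")
cat("\nwrote results/report.txt\n")
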