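#!/usr/bin/env Rscript
# Stage 5 — descriptive and summary reporting.
#
# Renders the population-characteristics table (by sex and case status) for
# the post-QC cohort and collates a short plain-text run summary.

library(heightMR)

cohort <- read_cohort("results/cohort_qc")
tab1 <- descriptive_table(cohort$phenotypes)
wide <- format(tab1)
write.table(wide, "results/table1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(wide, row.names = FALSE)

sbs <- tab1$sex_by_status
lines <- c(
  sprintf("males among cases: %.1f%%; among controls: %.1f%%",
          sbs$pct[sbs$status == "case" & sbs$sex == "male"],
          sbs$pct[sbs$status == "control" & sbs$sex == "male"]),
  readLines("results/power.txt"))
writeLines(lines, "results/run_summary.txt")
cat("written: table1.tsv, run_summary.txt -> results/\n")
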