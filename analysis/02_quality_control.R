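#!/usr/bin/env Rscript
# Stage 2 — genotype quality control and principal components.
#
# Applies the instrument-selection filters in their analysis order: call
# rate >= 95% (variants, then individuals), Hardy-Weinberg exact test in
# controls at P < 1e-7, imputation quality R2 > 0.7, and greedy LD pruning
# at pairwise R2 < 0.01 prioritised by GWAS p-value; then computes 15
# genetic principal components on the surviving set.

library(heightMR)

cohort <- read_cohort("results/cohort")
qc <- run_qc(cohort$genotypes, cohort$panel, cohort$phenotypes,
             call_rate = 0.95, hwe_p = 1e-7, impute_r2 = 0.7,
             r2_prune = 0.01, k_pcs = 15L)

for (nm in names(qc$reports)) {
  r <- qc$reports[[nm]]
  cat(sprintf("%-12s variants %4d -> %4d (removed %d)\n", r$filter,
              r$n_variants_in, r$n_variants_out, nrow(r$removed_variants)))
}
cat(sprintf("post-QC: %d variants, %d individuals; PC1 explains %.1f%% of genotype variance\n",
            ncol(qc$genotypes), nrow(qc$genotypes),
            100 * qc$pcs$explained_variance[1]))

heightMR:::qc_reports_to_json(qc$reports, "results/qc_report.json")
write_cohort(qc$genotypes, qc$panel, qc$phenotypes, "results/cohort_qc")
pcs_df <- data.frame(individual_id = rownames(qc$pcs$scores),
                     qc$pcs$scores, check.names = FALSE)
write.table(pcs_df, "results/pcs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("written: qc_report.json, cohort_qc/, pcs.tsv -> results/\n")
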