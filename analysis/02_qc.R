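#!/usr/bin/env Rscript

# Stage 2: marker/sample quality control on the simulated cohort.
# Filters: sample missingness > 10%, then sex-chromosome markers, call rate
# < 95%, MAF < 5%, exact-test HWE p < 1e-5. Writes the exclusion ledger and
# the filtered fileset.

library(rohsel)

g <- read_plink("results/simdata/cohort")
out <- apply_filters(g, qc_params())
print(out$report)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
write_plink(out$genotypes, "results/qc/cohort_qc", "binary")
led <- out$report
write.table(
  data.frame(filter = c("initial", names(led$removed), "total_removed",
                        "remaining"),
             markers = c(led$initial_markers, led$removed,
                         led$total_removed, led$remaining_markers)),
  "results/qc/ledger.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat("QC survivors written to results/qc/cohort_qc.*\n")
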