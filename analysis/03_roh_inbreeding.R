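#!/usr/bin/env Rscript

# Stage 3: runs of homozygosity, inbreeding coefficients and ROH islands.
# Consecutive-run criteria: >= 15 SNPs, >= 1 Mb, at most one heterozygote
# and one missing call per run. F_ROH uses the simulated autosome length
# (200 Mb); F_HOM is the excess-homozygosity coefficient; islands flag SNPs
# covered by ROH in > 45% of individuals.

library(rohsel)

g <- read_plink("results/qc/cohort_qc")
l_auto_mb <- sum(tapply(g$map$bp, g$map$chr, max)) / 1e6
dir.create("results/roh", showWarnings = FALSE, recursive = TRUE)

segs <- detect_roh(g, roh_params())
inb <- merge(froh(segs, rownames(g$geno), l_auto = l_auto_mb), fhom(g),
             by = "sample")
summ <- roh_summary(segs, setNames(g$pop, rownames(g$geno)),
                    tapply(g$map$bp, g$map$chr, max) / 1e6)
isl <- roh_islands(segs, g, threshold = 0.45)

write.table(segs, "results/roh/segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(inb, "results/roh/inbreeding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summ$by_breed, "results/roh/summary_by_breed.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$by_class, "results/roh/summary_by_class.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(summ$by_chromosome, "results/roh/summary_by_chromosome.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(isl$per_snp, "results/roh/snp_occurrence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(isl$islands)) {
  bed <- to_bed(isl$islands$start_bp, isl$islands$end_bp)
  write.table(data.frame(isl$islands$chr, bed, isl$islands$peak_pct),
              "results/roh/islands.bed", sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

inb$pop <- g$pop[match(inb$sample, rownames(g$geno))]
cat("total ROH:", nrow(segs), "| mean per individual:",
    round(nrow(segs) / n_samples(g), 2), "\n")
cat("mean F_ROH by population:\n")
print(round(tapply(inb$froh, inb$pop, mean), 4))
cat("F_ROH vs F_HOM correlation:",
    round(cor(inb$froh, inb$fhom, use = "complete.obs"), 3), "\n")
cat("ROH islands called:", nrow(isl$islands), "\n")
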