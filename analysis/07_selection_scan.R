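#!/usr/bin/env Rscript

# Stage 7: selection scan between the high-fecundity group (GF, JG, NJ, LP)
# and the low-fecundity group (LN, QG): per-SNP Weir-Cockerham FST with its
# Z-score, pi_low/pi_high ratio, and XP-EHH from the phased haplotypes with
# the high group as test population. Outliers: top 1% FST, top 1% pi-ratio,
# top 0.1% XP-EHH; candidates (FST-and-pi, or XP-EHH) extended +/- 100 kb,
# merged, and intersected with the toy gene annotation around the planted
# sweep core.

library(rohsel)

g <- read_plink("results/qc/cohort_qc")
haps <- read_haplotypes("results/simdata/cohort.haps", format = "haps")
haps$pop <- g$pop[match(haps$samples, rownames(g$geno))]
## restrict haplotypes to QC-surviving markers
keep <- haps$map$id %in% g$map$id
haps <- haplotype_set(haps$hap[, keep], haps$map[keep, ],
                      samples = haps$samples, pop = haps$pop)

dir.create("results/scan", showWarnings = FALSE, recursive = TRUE)
high <- c("GF", "JG", "NJ", "LP"); low <- c("LN", "QG")
rows <- selection_scan(g, high, low, haps = haps, xpehh_step = 4)

genes <- data.frame(chr = "1",
                    start_bp = c(49.5e6, 70e6),
                    end_bp = c(50.5e6, 70.5e6),
                    gene = c("SWEPT_LOCUS", "CONTROL_LOCUS"))
cc <- call_candidates(rows, q_fst = 0.01, q_pi = 0.01, q_xpehh = 0.001,
                      extend_bp = 1e5, annotation = genes,
                      chrom_lengths_bp = tapply(g$map$bp, g$map$chr, max))

write.table(cc$rows, "results/scan/scan_rows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(set = names(cc$venn), count = cc$venn),
            "results/scan/venn_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cc$regions, "results/scan/candidate_regions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("outliers:", cc$venn["fst"], "FST,", cc$venn["pi"], "pi-ratio,",
    cc$venn["xpehh"], "XP-EHH;",
    cc$venn["fst_pi_xpehh"], "in the three-way intersection\n")
core <- cc$rows[cc$rows$chr == "1" & abs(cc$rows$bp - 50e6) < 5e5, ]
cat(sprintf("planted core region: max ZFst %.2f, max pi-ratio %.2f, max XP-EHH z %.2f\n",
            max(core$zfst, na.rm = TRUE), max(core$pi_ratio, na.rm = TRUE),
            max(core$xpehh_std, na.rm = TRUE)))
hit <- cc$regions[cc$regions$genes != "", ]
cat("annotated candidate regions:\n")
print(hit)
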