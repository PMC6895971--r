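#!/usr/bin/env Rscript

# Stage 6: population differentiation and structure.
# Reynolds distances (upper triangle) with pairwise Weir-Cockerham theta
# (lower), AMOVA with permutation test, LD pruning (50-SNP windows, step 10,
# r2 < 0.1) feeding PCA, and a neighbour-joining tree on population-level
# 1-IBS distances. Also exports the pruned fileset for external model-based
# clustering tools.

library(rohsel)

g <- read_plink("results/qc/cohort_qc")
dir.create("results/structure", showWarnings = FALSE, recursive = TRUE)

pd <- population_distances(g)
write.table(round(pd$combined, 5), "results/structure/distances.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
cat("Reynolds D_R above diagonal, pairwise theta below:\n")
print(round(pd$combined, 4))

set.seed(20260929)
am <- amova(g, n_perm = 100)
print(am)
writeLines(sprintf("%s\t%s", c("pct_among", "pct_within", "phi", "p_value"),
                   c(am$pct_among, am$pct_within, am$phi, am$p_value)),
           "results/structure/amova.tsv")

keep <- ld_prune(g, window = 50, step = 10, r2 = 0.1)
cat("LD pruning kept", length(keep), "of", n_markers(g), "markers\n")
gp <- g[, keep]
write_plink(gp, "results/structure/cohort_pruned", "binary")

pc <- pca_genotypes(gp)
write.table(data.frame(sample = rownames(pc$scores), pop = pc$pop,
                       pc$scores),
            "results/structure/pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("PC1 %.2f%%, PC2 %.2f%% of variance\n",
            100 * pc$varprop[1], 100 * pc$varprop[2]))

nj <- nj_tree(ibs_distance(g, by = "population"))
writeLines(nj$newick, "results/structure/nj_tree.nwk")
cat("NJ tree:", nj$newick, "\n")
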