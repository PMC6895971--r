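#!/usr/bin/env Rscript

# Stage 1: build the synthetic study cohort.
#
# The study design this emulates: six populations genotyped on a ~50K chip,
# two fecundity groups, one population carrying a hard sweep near a known
# core, and a handful of individuals with substantial recent inbreeding.
# Everything downstream (QC, ROH, HBD, Ne, structure, selection scan) runs
# off the files this writes, and the planted truth is kept alongside so each
# stage's recovery can be judged.

library(rohsel)

seed <- 20260929L
out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

map <- sim_map(n_chr = 2, chr_length_bp = 100e6, spacing_bp = 50e3)

## six populations as two divergence tiers around a shared ancestor
pops <- c(GF = 35, JG = 35, LN = 35, LP = 35, NJ = 35, QG = 35)
Fdiv <- c(GF = 0.06, JG = 0.05, LN = 0.12, LP = 0.10, NJ = 0.04, QG = 0.05)
bn <- simulate_balding_nichols(pops, F_div = Fdiv, map = map,
                               error = 0.001, missing = 0.01, seed = seed)
g <- bn$genotypes

## phased haplotypes for the scan populations (drawn at the population
## frequencies of the divergence model), with a sweep planted in GF
haps <- local({
  hap <- NULL
  for (k in seq_along(pops)) {
    set.seed(seed + k)
    m <- nrow(map)
    p <- bn$truth$pop_freq[, k]
    hk <- matrix(stats::rbinom(2 * pops[k] * m, 1, rep(p, each = 2 * pops[k])),
                 nrow = 2 * pops[k])
    hap <- rbind(hap, hk)
  }
  haplotype_set(hap, map,
                samples = rownames(g$geno),
                pop = g$pop)
})
## the sweep is a group-level signal: every high-fecundity population carries
## a swept haplotype at the same core (its own founder, as after selection on
## standing variation)
for (b in c("GF", "JG", "NJ", "LP")) {
  sw <- plant_sweep(haps, b, core_bp = 50e6, chr = "1", fraction = 0.8,
                    window_cm = 2.5, seed = seed + 10 + match(b, c("GF", "JG", "NJ", "LP")))
  haps <- sw$haplotypes
}

## recent inbreeding: strong in GF and LN, mild in LP
planted <- list(GF = 0.20, LN = 0.12, LP = 0.06)
hap_in <- haps
tracts <- list()
for (b in names(planted)) {
  idx <- which(hap_in$pop == b)[1:10]
  pa <- plant_autozygosity(hap_in, idx, fraction = planted[[b]],
                           tract_mean_cm = 6, error = 0.001, missing = 0.01,
                           seed = seed + 100 + match(b, names(planted)))
  hap_in <- pa$haplotypes
  tracts[[b]] <- pa$truth$tracts
}
## genotype view comes from the final haplotypes plus chip noise
g_final <- genotypes_from_haplotypes(hap_in)
set.seed(seed + 999)
g_final$geno <- rohsel:::corrupt_genotypes(g_final$geno, 0.001, 0.01)

write_plink(g_final, file.path(out, "cohort"), "binary")
write_haplotypes(hap_in, file.path(out, "cohort"))
truth <- do.call(rbind, tracts)
write.table(truth, file.path(out, "planted_tracts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(c(sprintf("sweep_core_bp\t%d", 50e6),
             sprintf("sweep_chr\t%s", "1"),
             sprintf("sweep_population\t%s", "GF")),
           file.path(out, "sweep_truth.tsv"))

cat("cohort:", n_samples(g_final), "individuals x", n_markers(g_final),
    "markers;", length(unique(g_final$pop)), "populations\n")
cat("planted inbreeding tracts:", nrow(truth), "across",
    length(unique(truth$sample)), "individuals\n")
cat("files under", out, "\n")
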