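#' Synthetic chip-like marker map
#'
#' Evenly spaced markers on equally sized chromosomes with a constant
#' recombination rate — the default emulates a 50K-style panel scaled to a
#' small test genome: 2 chromosomes of 100 Mb (100 cM at 1 cM/Mb) with one
#' marker per 50 kb, about 4,000 markers.
#'
#' @param n_chr number of chromosomes.
#' @param chr_length_bp chromosome length in bp.
#' @param spacing_bp distance between adjacent markers.
#' @param cm_per_mb recombination rate.
#' @return a marker-map data.frame (`chr`, `id`, `cM`, `bp`).
#' @export
sim_map <- function(n_chr = 2, chr_length_bp = 100e6, spacing_bp = 50e3,
                    cm_per_mb = 1) {
  bp <- seq(spacing_bp, chr_length_bp, by = spacing_bp)
  do.call(rbind, lapply(seq_len(n_chr), function(ch) {
    data.frame(chr = as.character(ch),
               id = paste0("snp", ch, "_", seq_along(bp)),
               cM = bp * 1e-6 * cm_per_mb, bp = bp,
               stringsAsFactors = FALSE)
  }))
}

## apply genotyping error (random re-draw of the genotype) and missingness
corrupt_genotypes <- function(geno, error = 0, missing = 0) {
  if (error > 0) {
    flip <- which(matrix(stats::runif(length(geno)) < error, nrow(geno)))
    geno[flip] <- sample(0:2, length(flip), replace = TRUE)
  }
  if (missing > 0) {
    geno[matrix(stats::runif(length(geno)) < missing, nrow(geno))] <- NA_integer_
  }
  geno
}

#' Simulate outbred (independent-sites) haplotypes
#'
#' Haplotype alleles are independent Bernoulli draws at per-marker
#' frequencies uniform on `maf_range` — an idealized infinite-Ne panmictic
#' population with no linkage disequilibrium and no autozygosity. This is
#' the clean background for planted-truth recovery tests
#' ([plant_autozygosity()], [plant_sweep()]): every homozygous run or EHH
#' signal beyond chance is the planted one.
#'
#' @param n number of individuals.
#' @param map marker map.
#' @param freq_range range of counted-allele frequencies.
#' @param pop_label population label.
#' @param seed RNG seed (mandatory).
#' @return a [haplotype_set()].
#' @export
simulate_haplotypes_iid <- function(n, map = sim_map(),
                                    freq_range = c(0.2, 0.8),
                                    pop_label = "POP1", seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  m <- nrow(map)
  p <- stats::runif(m, freq_range[1], freq_range[2])
  hap <- matrix(stats::rbinom(2 * n * m, 1, rep(p, each = 2 * n)), nrow = 2 * n)
  haplotype_set(hap, map, samples = paste0(pop_label, "_", seq_len(n)),
                pop = rep(pop_label, n))
}

#' Simulate genotypes under the Balding-Nichols divergence model
#'
#' Ancestral frequencies are uniform on `[0.05, 0.95]`; each population draws
#' its marker frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean `p`,
#' variance `F p (1-p)`) and genotypes are `Binomial(2, p_pop)`. `F = 0`
#' collapses to identical frequencies. Backs the FST / PCA / Reynolds tests
#' with known divergence truth.
#'
#' @param n_per_pop integer vector (one entry per population) of sample
#'   counts; names become population labels.
#' @param F_div divergence parameter per population (recycled).
#' @param map marker map (default [sim_map()]).
#' @param error,missing genotyping-error and missingness rates.
#' @param seed RNG seed (mandatory: simulations are always reproducible).
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (`F_div`, `ancestral_freq`, `pop_freq`).
#' @export
simulate_balding_nichols <- function(n_per_pop = c(A = 50, B = 50),
                                     F_div = 0.1, map = sim_map(),
                                     error = 0, missing = 0, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (is.null(names(n_per_pop)))
    names(n_per_pop) <- paste0("POP", seq_along(n_per_pop))
  F_div <- rep_len(F_div, length(n_per_pop))
  m <- nrow(map)
  p_anc <- stats::runif(m, 0.05, 0.95)
  pop_freq <- vapply(seq_along(n_per_pop), function(k) {
    Fk <- F_div[k]
    if (Fk <= 0) p_anc else {
      a <- p_anc * (1 - Fk) / Fk
      b <- (1 - p_anc) * (1 - Fk) / Fk
      stats::rbeta(m, a, b)
    }
  }, numeric(m))
  geno <- do.call(rbind, lapply(seq_along(n_per_pop), function(k) {
    matrix(stats::rbinom(n_per_pop[k] * m, 2, rep(pop_freq[, k],
                                                  each = n_per_pop[k])),
           nrow = n_per_pop[k])
  }))
  geno <- corrupt_genotypes(geno, error, missing)
  pop <- rep(names(n_per_pop), n_per_pop)
  rownames(geno) <- paste0(pop, "_", unlist(lapply(n_per_pop, seq_len)))
  g <- genotype_matrix(geno, map, pop = pop)
  list(genotypes = g,
       truth = list(F_div = stats::setNames(F_div, names(n_per_pop)),
                    ancestral_freq = p_anc, pop_freq = pop_freq))
}

#' Simulate a population forward in time (Wright-Fisher with recombination)
#'
#' Discrete non-overlapping generations of random mating at diploid size
#' `n_traj[g]` per generation; gametes recombine with a Poisson number of
#' crossovers per Morgan. Founder haplotype alleles are independent Bernoulli
#' draws at uniform `[0.2, 0.8]` frequencies; the final generation (or a
#' sample of it) is returned with its realized LD. Markers that drifted to
#' fixation can be filtered downstream by MAF.
#'
#' @param n_traj diploid population size per generation, e.g. `rep(100, 200)`
#'   (a vector with a step change simulates a bottleneck).
#' @param n_sample individuals sampled from the final generation.
#' @param map marker map.
#' @param pop_label population label for the sample.
#' @param seed RNG seed (mandatory).
#' @return list with `haplotypes` ([haplotype_set()]), `genotypes`
#'   ([genotype_matrix()]) and `truth` (`n_traj`).
#' @export
simulate_wright_fisher <- function(n_traj = rep(100, 200), n_sample = 50,
                                   map = sim_map(), pop_label = "WF", seed) {
  stopifnot(!missing(seed), all(n_traj >= 2))
  set.seed(seed)
  m <- nrow(map)
  n0 <- n_traj[1]
  p0 <- stats::runif(m, 0.2, 0.8)
  founders <- matrix(stats::rbinom(2 * n0 * m, 1, rep(p0, each = 2 * n0)),
                     nrow = 2 * n0)
  chr_int <- as.integer(factor(map$chr, levels = unique(map$chr)))
  fin <- wf_evolve(founders, map$cM, chr_int, as.integer(n_traj))
  n_fin <- nrow(fin) / 2
  n_sample <- min(n_sample, n_fin)
  pick <- sort(sample.int(n_fin, n_sample))
  rows <- as.vector(rbind(2 * pick - 1, 2 * pick))
  hap <- fin[rows, , drop = FALSE]
  h <- haplotype_set(hap, map,
                     samples = paste0(pop_label, "_", seq_len(n_sample)),
                     pop = rep(pop_label, n_sample))
  list(haplotypes = h, genotypes = genotypes_from_haplotypes(h),
       truth = list(n_traj = n_traj))
}

#' Plant autozygous (IBD) tracts into phased haplotypes
#'
#' For each chosen individual, tracts are drawn (exponential lengths, uniform
#' starts, non-overlapping) until the requested fraction of the genetic map
#' is covered, and haplotype 1 is copied over haplotype 2 inside each tract —
#' creating true homozygosity-by-descent of known location and age proxy
#' (tract length). Genotyping error and missingness are then applied to the
#' derived genotypes. Backs the ROH and HBD parameter-recovery tests.
#'
#' @param h a [haplotype_set()].
#' @param individuals indices (or ids) of individuals to modify.
#' @param fraction target autozygous fraction of the genome per individual.
#' @param tract_mean_cm mean tract length (centiMorgan).
#' @param error,missing genotype corruption rates for the genotype view.
#' @param seed RNG seed (mandatory).
#' @return list with `haplotypes` (modified), `genotypes` (corrupted view)
#'   and `truth` (data.frame of planted tracts: sample, chr, start/end bp and
#'   cM, plus realized per-individual fraction).
#' @export
plant_autozygosity <- function(h, individuals, fraction, tract_mean_cm = 5,
                               error = 0.001, missing = 0.01, seed) {
  stopifnot(!missing(seed), inherits(h, "haplotype_set"),
            fraction >= 0, fraction <= 1)
  set.seed(seed)
  if (is.character(individuals)) individuals <- match(individuals, h$samples)
  map <- h$map
  chroms <- unique(map$chr)
  cm_lo <- vapply(chroms, function(ch) min(map$cM[map$chr == ch]), 0)
  cm_hi <- vapply(chroms, function(ch) max(map$cM[map$chr == ch]), 0)
  total_cm <- sum(cm_hi - cm_lo)
  truth <- list()
  for (i in individuals) {
    covered <- 0
    tracts <- list()   # per chrom: matrix of (start, end) in cM
    guard <- 0
    while (fraction > 0 && covered < fraction * total_cm && guard < 10000) {
      guard <- guard + 1
      ch <- sample(chroms, 1, prob = cm_hi - cm_lo)
      len <- stats::rexp(1, 1 / tract_mean_cm)
      st <- stats::runif(1, cm_lo[[ch]], cm_hi[[ch]])
      en <- min(st + len, cm_hi[[ch]])
      if (en <= st) next
      prev <- tracts[[ch]]
      if (!is.null(prev) &&
          any(st <= prev[, 2] & en >= prev[, 1])) next  # keep disjoint
      tracts[[ch]] <- rbind(prev, c(st, en))
      covered <- covered + (en - st)
      jj <- which(map$chr == ch & map$cM >= st & map$cM <= en)
      if (length(jj))
        h$hap[2 * i, jj] <- h$hap[2 * i - 1, jj]
      truth[[length(truth) + 1]] <-
        data.frame(sample = h$samples[i], chr = ch,
                   start_cm = st, end_cm = en,
                   start_bp = if (length(jj)) min(map$bp[jj]) else NA,
                   end_bp = if (length(jj)) max(map$bp[jj]) else NA)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(), chr = character(), start_cm = numeric(),
               end_cm = numeric(), start_bp = numeric(), end_bp = numeric())
  realized <- vapply(h$samples, function(s)
    sum(truth$end_cm[truth$sample == s] - truth$start_cm[truth$sample == s]) /
      total_cm, 0)
  g <- genotypes_from_haplotypes(h)
  g$geno <- corrupt_genotypes(g$geno, error, missing)
  list(haplotypes = h, genotypes = g,
       truth = list(tracts = truth, realized_fraction = realized))
}

#' Plant a hard selective sweep into one population's haplotypes
#'
#' In the target population, a configured fraction of haplotypes is replaced
#' by copies of one founder haplotype within a window around the core, with
#' per-marker copy fidelity decaying exponentially with genetic distance
#' (`exp(-d / decay_cm)`; `decay_cm = Inf` copies faithfully across the whole
#' window). This creates the extended haplotype homozygosity of a recent hard
#' sweep and backs the XP-EHH positive control.
#'
#' @param h a [haplotype_set()].
#' @param pop population whose haplotypes sweep.
#' @param core_bp sweep core physical position (nearest marker is used).
#' @param chr chromosome of the core (defaults to the first).
#' @param fraction fraction of the population's haplotypes carrying the swept
#'   haplotype.
#' @param window_cm half-width of the affected window (centiMorgan).
#' @param decay_cm fidelity decay scale.
#' @param seed RNG seed (mandatory).
#' @return list with `haplotypes` (modified) and `truth` (`core_bp`,
#'   `core_marker`, `carriers`).
#' @export
plant_sweep <- function(h, pop, core_bp, chr = NULL, fraction = 0.8,
                        window_cm = 25, decay_cm = Inf, seed) {
  stopifnot(!missing(seed), inherits(h, "haplotype_set"),
            fraction >= 0, fraction <= 1)
  set.seed(seed)
  map <- h$map
  if (is.null(chr)) chr <- map$chr[1]
  jj <- which(map$chr == chr)
  core <- jj[which.min(abs(map$bp[jj] - core_bp))]
  win <- jj[abs(map$cM[jj] - map$cM[core]) <= window_cm]
  rows <- which(rep(h$pop == pop, each = 2))
  if (!length(rows)) stop("no haplotypes in population ", pop)
  n_carrier <- round(fraction * length(rows))
  carriers <- sample(rows, n_carrier)
  founder <- h$hap[rows[1], win]
  d <- abs(map$cM[win] - map$cM[core])
  fid <- if (is.infinite(decay_cm)) rep(1, length(win)) else exp(-d / decay_cm)
  for (r in carriers) {
    copy <- stats::runif(length(win)) < fid
    h$hap[r, win[copy]] <- founder[copy]
  }
  list(haplotypes = h,
       truth = list(core_bp = map$bp[core], core_marker = map$id[core],
                    chr = chr, carriers = carriers))
}
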