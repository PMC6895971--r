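#' QC filter parameters
#'
#' Defaults follow the standard 50K-chip panel filters: SNP call rate >= 0.95,
#' minor allele frequency >= 0.05, per-sample missingness <= 0.10, exact
#' Hardy-Weinberg test exclusion at p < 1e-5, and removal of sex-chromosome
#' markers.
#'
#' @param min_call_rate minimum per-marker call rate.
#' @param min_maf minimum minor allele frequency.
#' @param max_sample_missing maximum per-sample missing fraction.
#' @param hwe_p exclusion threshold: markers with exact-test p below this are
#'   removed.
#' @param drop_sex_chromosomes remove markers on non-autosomal chromosomes.
#' @param sex_chromosomes labels treated as sex chromosomes.
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate = 0.95, min_maf = 0.05,
                      max_sample_missing = 0.10, hwe_p = 1e-5,
                      drop_sex_chromosomes = TRUE,
                      sex_chromosomes = c("X", "Y", "XY", "MT")) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            hwe_p >= 0, hwe_p <= 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_sample_missing = max_sample_missing, hwe_p = hwe_p,
                 drop_sex_chromosomes = drop_sex_chromosomes,
                 sex_chromosomes = sex_chromosomes),
            class = "qc_params")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test for a biallelic marker: conditioning on
#' the observed allele counts, the p-value is the summed probability of all
#' heterozygote counts no more probable than the observed one (no mid-p
#' correction). Probabilities follow the hypergeometric-type recurrence over
#' heterozygote counts of matching parity.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (either homozygote first).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("HWE test undefined for a marker with no called genotypes")
  n_r <- 2 * min(n_hom1, n_hom2) + n_het     # rare allele count
  if (n_r == 0) return(1.0)                  # monomorphic: single outcome
  hets <- seq(n_r %% 2, n_r, by = 2)
  ## unnormalized probabilities via the recurrence
  ## P(h+2)/P(h) = 4 * n_rare_hom(h) * n_common_hom(h) / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_r <- (n_r - h) / 2
    hom_c <- n - (h + hom_r)                 # common homozygotes at h hets
    lp[k] <- lp[k - 1] + log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele count")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

## vectorized over markers: counts is a 3-column matrix (hom2, het, hom0)
hwe_exact_vec <- function(counts) {
  apply(counts, 1, function(x) {
    if (sum(x) == 0) return(NA_real_)
    hwe_exact_test(x[1], x[2], x[3])
  })
}

#' Assemble a QC exclusion ledger
#'
#' The ledger's arithmetic invariant: total removed equals the sum of the
#' per-filter marker removals (each marker counted in exactly one category),
#' and remaining = initial - total removed.
#'
#' @param initial_markers marker count before filtering.
#' @param removed named numeric vector with entries `sex`, `call_rate`, `maf`,
#'   `hwe` (markers removed by each filter, mutually exclusive).
#' @param initial_samples,removed_samples sample counts (optional).
#' @param genotyping_rate post-QC overall call rate (optional).
#' @return a list of class `qc_report`.
#' @export
qc_ledger <- function(initial_markers, removed,
                      initial_samples = NA, removed_samples = NA,
                      genotyping_rate = NA) {
  need <- c("sex", "call_rate", "maf", "hwe")
  stopifnot(all(need %in% names(removed)))
  removed <- removed[need]
  total <- sum(removed)
  structure(list(initial_markers = initial_markers,
                 removed = removed,
                 total_removed = total,
                 remaining_markers = initial_markers - total,
                 initial_samples = initial_samples,
                 removed_samples = removed_samples,
                 remaining_samples = if (is.na(initial_samples)) NA
                                     else initial_samples - removed_samples,
                 genotyping_rate = genotyping_rate),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat("  initial markers:  ", x$initial_markers, "\n")
  cat("  removed: sex", x$removed["sex"], "| call rate", x$removed["call_rate"],
      "| MAF", x$removed["maf"], "| HWE", x$removed["hwe"], "\n")
  cat("  total removed:    ", x$total_removed, "\n")
  cat("  remaining markers:", x$remaining_markers, "\n")
  if (!is.na(x$initial_samples))
    cat("  samples: ", x$initial_samples, "->", x$remaining_samples,
        "(", x$removed_samples, "removed )\n")
  if (!is.na(x$genotyping_rate))
    cat(sprintf("  genotyping rate:   %.5f\n", x$genotyping_rate))
  invisible(x)
}

#' Apply marker and sample QC filters
#'
#' Samples failing the missingness bound are removed first; markers are then
#' filtered in the fixed order sex-chromosome, call rate, MAF, HWE (each
#' marker attributed to the first filter that catches it, so ledger categories
#' are mutually exclusive). Marker statistics are computed on the
#' post-sample-removal data.
#'
#' @param g a [genotype_matrix()].
#' @param params a [qc_params()].
#' @return list with elements `genotypes` (the filtered matrix) and `report`
#'   (a [qc_ledger()] plus attribute `marker_fate`, the per-marker category).
#' @export
apply_filters <- function(g, params = qc_params()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(params, "qc_params"))
  n0 <- n_samples(g); m0 <- n_markers(g)

  smiss <- missing_rate(g, "sample")
  keep_s <- smiss <= params$max_sample_missing
  if (!any(keep_s)) stop("all samples removed by the missingness filter")
  g <- g[keep_s, ]

  fate <- rep("kept", n_markers(g))
  is_sex <- params$drop_sex_chromosomes & g$map$chr %in% params$sex_chromosomes
  fate[is_sex] <- "sex"

  call_rate <- 1 - missing_rate(g, "marker")
  low_call <- fate == "kept" & call_rate < params$min_call_rate
  fate[low_call] <- "call_rate"

  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  low_maf <- fate == "kept" & (is.nan(maf) | maf < params$min_maf)
  fate[low_maf] <- "maf"

  idx <- which(fate == "kept")
  if (length(idx)) {
    cnt <- cbind(colSums(g$geno[, idx, drop = FALSE] == 2L, na.rm = TRUE),
                 colSums(g$geno[, idx, drop = FALSE] == 1L, na.rm = TRUE),
                 colSums(g$geno[, idx, drop = FALSE] == 0L, na.rm = TRUE))
    pv <- hwe_exact_vec(cnt)
    bad <- idx[!is.na(pv) & pv < params$hwe_p]
    fate[bad] <- "hwe"
  }

  keep_m <- fate == "kept"
  out <- g[, keep_m]
  report <- qc_ledger(
    initial_markers = m0,
    removed = c(sex = sum(fate == "sex"),
                call_rate = sum(fate == "call_rate"),
                maf = sum(fate == "maf"),
                hwe = sum(fate == "hwe")),
    initial_samples = n0,
    removed_samples = sum(!keep_s),
    genotyping_rate = if (n_markers(out)) 1 - missing_rate(out) else NA)
  attr(report, "marker_fate") <- stats::setNames(fate, g$map$id)
  list(genotypes = out, report = report)
}
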