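#' Squared dosage correlation between two markers
#'
#' Composite (unphased) linkage disequilibrium: the squared Pearson
#' correlation of the 0/1/2 genotype dosages over samples non-missing at both
#' markers. Undefined (`NA`) with fewer than two complete pairs or zero
#' variance at either marker.
#'
#' @param g a [genotype_matrix()].
#' @param i,j marker indices or ids.
#' @return r-squared, or `NA` when undefined.
#' @export
pairwise_r2 <- function(g, i, j) {
  if (is.character(i)) i <- match(i, g$map$id)
  if (is.character(j)) j <- match(j, g$map$id)
  x <- g$geno[, i]; y <- g$geno[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

#' Invert Sved's relation
#'
#' Sved's drift-recombination relation `E(r2) = 1 / (1 + 4 Ne c)` gives, for
#' an (adjusted) r-squared at genetic distance `c` Morgans,
#' `Ne = (1/r2 - 1) / (4c)` and the corresponding time depth `T = 1/(2c)`
#' generations.
#'
#' @param r2_adj sample-size-adjusted r-squared in (0, 1).
#' @param c_morgan genetic distance in Morgans.
#' @return list with `ne` and `generation`.
#' @export
sved_ne <- function(r2_adj, c_morgan) {
  stopifnot(all(c_morgan > 0))
  ne <- ifelse(r2_adj > 0 & r2_adj < 1, (1 / r2_adj - 1) / (4 * c_morgan),
               NA_real_)
  list(ne = ne, generation = 1 / (2 * c_morgan))
}

#' Historical effective population size from binned LD decay
#'
#' Within-chromosome marker pairs are assigned to genetic-distance bins; each
#' bin's mean r-squared, corrected for sample size (`r2 - 1/(2n)` by
#' default), is inverted through Sved's relation at the bin midpoint `c`,
#' giving one `(T = 1/(2c), Ne)` point per bin. Markers below the MAF floor
#' are excluded; bins are returned ordered by generation (most recent first,
#' i.e. largest `c`).
#'
#' @param g a [genotype_matrix()] for one population.
#' @param bins numeric vector of bin edges in Morgans (default log-spaced on
#'   `[0.0005, 0.25]`).
#' @param adjust `"1/(2n)"` (default) or `"none"`.
#' @param min_maf minimum minor allele frequency within the population.
#' @param min_pairs bins with fewer pairs are dropped.
#' @return data.frame of class bins: `c_lo`, `c_hi`, `c_mid`, `n_pairs`,
#'   `mean_r2`, `r2_adj`, `ne`, `generation` (`Ne` is `NA` where
#'   `r2_adj >= 1` or `<= 0`).
#' @export
estimate_ne <- function(g, bins = NULL, adjust = c("1/(2n)", "none"),
                        min_maf = 0.05, min_pairs = 10) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(bins)) bins <- exp(seq(log(5e-4), log(0.25), length.out = 21))
  map <- impute_cm(g$map)
  p <- allele_freq(g)
  keep <- !is.nan(p) & pmin(p, 1 - p) >= min_maf
  n <- n_samples(g)
  nb <- length(bins) - 1
  sum_r2 <- numeric(nb); n_pairs <- integer(nb)
  for (ch in unique(map$chr)) {
    jj <- which(map$chr == ch & keep)
    if (length(jj) < 2) next
    cm <- map$cM[jj]
    r2m <- suppressWarnings(
      stats::cor(g$geno[, jj, drop = FALSE],
                 use = "pairwise.complete.obs")^2)
    dm <- abs(outer(cm, cm, "-")) / 100       # Morgans
    ut <- upper.tri(dm)
    d <- dm[ut]; r2 <- r2m[ut]
    ok <- !is.na(r2)
    b <- findInterval(d[ok], bins, rightmost.closed = FALSE)
    valid <- b >= 1 & b <= nb
    sum_r2 <- sum_r2 + as.numeric(tapply(r2[ok][valid],
                                         factor(b[valid], levels = seq_len(nb)),
                                         sum, default = 0))
    n_pairs <- n_pairs + as.integer(table(factor(b[valid],
                                                 levels = seq_len(nb))))
  }
  mean_r2 <- ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_)
  corr <- if (adjust == "1/(2n)") 1 / (2 * n) else 0
  r2_adj <- mean_r2 - corr
  c_mid <- (bins[-length(bins)] + bins[-1]) / 2
  sv <- sved_ne(r2_adj, c_mid)
  out <- data.frame(c_lo = bins[-length(bins)], c_hi = bins[-1],
                    c_mid = c_mid, n_pairs = n_pairs, mean_r2 = mean_r2,
                    r2_adj = r2_adj, ne = sv$ne, generation = sv$generation)
  out <- out[out$n_pairs >= min_pairs, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$generation), , drop = FALSE]
}
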