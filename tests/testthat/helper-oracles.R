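# Independent brute-force oracles used to validate the fast implementations.

# toy genotype matrix on one chromosome, evenly spaced markers
toy_gmat <- function(codes, spacing_bp = 1e5, chr = "1", pop = NULL) {
  codes <- rbind(codes)
  m <- ncol(codes)
  map <- data.frame(chr = chr, id = paste0("m", seq_len(m)),
                    cM = seq_len(m) * spacing_bp * 1e-6,
                    bp = seq_len(m) * spacing_bp)
  genotype_matrix(codes, map, pop = pop)
}

# O(n^2) enumeration of maximal het/missing-bounded windows, then the same
# published filtering and greedy overlap rule as the scanner
roh_oracle_one <- function(x, bp, params) {
  n <- length(x)
  het <- cumsum(c(0, !is.na(x) & x == 1))
  mis <- cumsum(c(0, is.na(x)))
  ok <- function(i, j) {
    (het[j + 1] - het[i]) <= params$max_het &&
      (mis[j + 1] - mis[i]) <= params$max_missing
  }
  starts <- integer(0); ends <- integer(0)
  for (i in seq_len(n)) for (j in i:n) {
    if (!ok(i, j)) next
    if (i > 1 && ok(i - 1, j)) next
    if (j < n && ok(i, j + 1)) next
    starts <- c(starts, i); ends <- c(ends, j)
  }
  if (!length(starts)) return(NULL)
  len_mb <- (bp[ends] - bp[starts]) / 1e6
  keep <- (ends - starts + 1) >= params$min_snps & len_mb >= params$min_length_mb
  starts <- starts[keep]; ends <- ends[keep]; len_mb <- len_mb[keep]
  if (!length(starts)) return(NULL)
  ord <- order(-len_mb, starts)
  sel <- integer(0)
  for (k in ord) {
    clash <- any(vapply(sel, function(s)
      starts[k] <= ends[s] && ends[k] >= starts[s], TRUE))
    if (!clash) sel <- c(sel, k)
  }
  sel <- sort(sel)
  cbind(start = starts[sel], end = ends[sel])
}

# exact HWE p-value from direct log-factorial probabilities of each
# heterozygote count given the allele count (independent of the recurrence)
hwe_pvalue_direct <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n_het, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# per-marker Reynolds coancestry components, aggregated here rather than in
# the implementation (second independent coding of the same estimator)
reynolds_oracle <- function(p1, p2, n1, n2) {
  h1 <- 2 * p1 * (1 - p1); h2 <- 2 * p2 * (1 - p2)
  a <- 2 * (p1 - p2)^2 - h1 / (2 * n1 - 1) - h2 / (2 * n2 - 1)
  b <- (2 * n1 * h1 / (2 * n1 - 1) + 2 * n2 * h2 / (2 * n2 - 1)) / 2
  sum(a) / sum(a + b)
}

# all-pairs mean difference oracle for site pi
pi_allpairs <- function(alleles) {
  n <- length(alleles)
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + (alleles[i] != alleles[j])
    cnt <- cnt + 1
  }
  tot / cnt
}

# exhaustive path-sum likelihood of the HBD HMM (K^L paths)
hbd_loglik_enum <- function(geno, freq, d_morgan, spec, M) {
  K <- spec$K; L <- length(geno)
  emis <- vapply(seq_len(K),
                 function(k) hbd_emission(geno, freq, spec$hbd[k], spec$err),
                 numeric(L))
  emis <- matrix(emis, L, K)
  Ts <- lapply(d_morgan, hbd_transition, spec = spec, M = M)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pr <- M[paths[r, 1]] * emis[1, paths[r, 1]]
    for (t in seq_len(L - 1))
      pr <- pr * Ts[[t]][paths[r, t], paths[r, t + 1]] * emis[t + 1, paths[r, t + 1]]
    tot <- tot + pr
  }
  log(tot)
}

# EHH by hand: probability two distinct haplotypes agree on a marker set
ehh_by_hand <- function(hap, markers) {
  key <- apply(hap[, markers, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(key)
  n <- nrow(hap)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}
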