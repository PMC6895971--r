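#' Reynolds coancestry distance between populations
#'
#' Per-marker coancestry components: the between-population component is the
#' squared allele-frequency difference summed over the two alleles, minus its
#' sampling bias (`h_i / (2 n_i - 1)` per population, `h_i` the sample
#' heterozygosity `2 p q`); the within component is the average unbiased
#' heterozygosity. Components are aggregated over markers as a ratio of sums,
#' `theta = sum(a) / sum(a + b)`, and the distance is
#' `D_R = -ln(1 - theta)`. Identical populations give `theta ~ 0`; fixed
#' alternative alleles give `theta = 1`.
#'
#' @param g a [genotype_matrix()] with at least two populations.
#' @return list with `theta` and `d` (both symmetric population matrices of
#'   class; the distance matrix carries attribute `metric = "reynolds"`).
#' @export
reynolds_distance <- function(g) {
  pops <- sort(unique(g$pop))
  if (length(pops) < 2) stop("need at least two populations")
  P <- vapply(pops, function(b) allele_freq(g, which(g$pop == b)),
              numeric(n_markers(g)))
  N <- vapply(pops, function(b)
    colSums(!is.na(g$geno[g$pop == b, , drop = FALSE])),
    numeric(n_markers(g)))
  if (any(colSums(N) == 0)) stop("population with zero typed markers")
  r <- length(pops)
  theta <- matrix(0, r, r, dimnames = list(pops, pops))
  for (i in seq_len(r - 1)) for (j in (i + 1):r) {
    ok <- N[, i] > 1 & N[, j] > 1 & !is.nan(P[, i]) & !is.nan(P[, j])
    p1 <- P[ok, i]; p2 <- P[ok, j]
    n1 <- N[ok, i]; n2 <- N[ok, j]
    h1 <- 2 * p1 * (1 - p1); h2 <- 2 * p2 * (1 - p2)
    a <- 2 * (p1 - p2)^2 - h1 / (2 * n1 - 1) - h2 / (2 * n2 - 1)
    b <- (2 * n1 * h1 / (2 * n1 - 1) + 2 * n2 * h2 / (2 * n2 - 1)) / 2
    th <- sum(a) / sum(a + b)
    theta[i, j] <- theta[j, i] <- th
  }
  d <- -log(1 - pmin(theta, 1 - 1e-12))
  diag(d) <- 0
  attr(d, "metric") <- "reynolds"
  list(theta = theta, d = d)
}

#' Weir-Cockerham FST (theta) estimator
#'
#' The variance-component estimator for biallelic markers over two or more
#' populations: per marker `theta = a / (a + b + c)` with `a`, `b`, `c` the
#' among-population, among-individual and within-individual components;
#' globally the components are summed over markers before the ratio. Markers
#' monomorphic across all populations are undefined (`NA` per marker,
#' excluded from the global sum and from any downstream Z-standardization).
#'
#' @param g a [genotype_matrix()].
#' @param pops optional subset of population labels to contrast.
#' @param mode `"global"` (ratio of sums) or `"per-marker"`.
#' @return a single theta for `"global"`; for `"per-marker"` a data.frame
#'   `chr`, `bp`, `id`, `fst`, plus attribute `global`.
#' @export
weir_cockerham_fst <- function(g, pops = NULL, mode = c("global", "per-marker")) {
  mode <- match.arg(mode)
  if (!is.null(pops)) g <- g[g$pop %in% pops, ]
  labs <- sort(unique(g$pop))
  r <- length(labs)
  if (r < 2) stop("need at least two populations")
  m <- n_markers(g)
  ni <- vapply(labs, function(b)
    colSums(!is.na(g$geno[g$pop == b, , drop = FALSE])), numeric(m))
  pi_ <- vapply(labs, function(b) {
    gi <- g$geno[g$pop == b, , drop = FALSE]
    colMeans(gi, na.rm = TRUE) / 2
  }, numeric(m))
  hi <- vapply(labs, function(b) {
    gi <- g$geno[g$pop == b, , drop = FALSE]
    colMeans(gi == 1L, na.rm = TRUE)
  }, numeric(m))
  ni <- matrix(ni, m, r); pi_ <- matrix(pi_, m, r); hi <- matrix(hi, m, r)
  usable <- rowSums(ni >= 2) == r
  nbar <- rowMeans(ni)
  nsum <- rowSums(ni)
  nc <- (nsum - rowSums(ni^2) / nsum) / (r - 1)
  pbar <- rowSums(ni * pi_) / nsum
  s2 <- rowSums(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  a[!usable | mono] <- NA; b[!usable | mono] <- NA; cc[!usable | mono] <- NA
  denom <- a + b + cc
  fst <- ifelse(is.na(denom) | denom == 0, NA_real_, a / denom)
  global <- sum(a, na.rm = TRUE) / sum(denom, na.rm = TRUE)
  if (mode == "global") return(global)
  out <- data.frame(chr = g$map$chr, bp = g$map$bp, id = g$map$id, fst = fst,
                    stringsAsFactors = FALSE)
  attr(out, "global") <- global
  out
}

#' Pairwise population distance matrices
#'
#' Upper-triangle Reynolds distances and lower-triangle pairwise
#' differentiation (global Weir-Cockerham theta between each pair) as used to
#' tabulate between-breed divergence.
#'
#' @param g a [genotype_matrix()].
#' @return list with `reynolds` (D_R matrix), `pairwise_fst` (theta matrix),
#'   and `combined` (Reynolds above, theta below the diagonal).
#' @export
population_distances <- function(g) {
  rd <- reynolds_distance(g)
  pops <- rownames(rd$d)
  fst <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    fst[i, j] <- fst[j, i] <- weir_cockerham_fst(g, pops = pops[c(i, j)])
  }
  comb <- rd$d
  comb[lower.tri(comb)] <- fst[lower.tri(fst)]
  list(reynolds = rd$d, pairwise_fst = fst, combined = comb)
}

#' Analysis of molecular variance (two-level)
#'
#' Partitions genotypic variance among and within populations from pairwise
#' squared genotype distances (`d2 = sum over markers of (g_i - g_j)^2 / 2`,
#' scaled to the full marker count when pairs have missing data). The
#' Phi-statistic's significance is assessed by permuting sample labels among
#' populations: `p = (# permutation Phi >= observed + 1) / (n_perm + 1)`.
#'
#' @param g a [genotype_matrix()] with >= 2 populations.
#' @param n_perm number of label permutations (>= 99 recommended).
#' @return list of class `amova_result`: `sigma_among`, `sigma_within`,
#'   `pct_among`, `pct_within`, `phi`, `p_value`, `n_perm`.
#' @export
amova <- function(g, n_perm = 100) {
  stopifnot(inherits(g, "genotype_matrix"))
  labs <- as.character(g$pop)
  if (length(unique(labs)) < 2) stop("need at least two populations")
  X <- g$geno
  m <- ncol(X)
  ## pairwise squared distances; missing pairs rescaled to m markers
  D2 <- matrix(0, nrow(X), nrow(X))
  obs <- !is.na(X)
  Xz <- X; Xz[!obs] <- 0L
  gg <- tcrossprod(Xz)                    # sum x_i x_j over shared markers
  sq <- tcrossprod(Xz^2, obs)             # sum x_i^2 over j-observed markers
  shared <- tcrossprod(obs * 1)
  D2 <- (sq + t(sq) - 2 * gg) / 2
  D2 <- D2 * ifelse(shared > 0, m / shared, 0)
  phi_of <- function(lab) {
    N <- length(lab)
    G <- unique(lab)
    ssd_t <- sum(D2[upper.tri(D2)]) / N
    ssd_w <- 0; ngs <- integer(length(G))
    for (k in seq_along(G)) {
      idx <- which(lab == G[k])
      ngs[k] <- length(idx)
      Dg <- D2[idx, idx, drop = FALSE]
      ssd_w <- ssd_w + sum(Dg[upper.tri(Dg)]) / length(idx)
    }
    ssd_a <- ssd_t - ssd_w
    df_a <- length(G) - 1; df_w <- N - length(G)
    ms_a <- ssd_a / df_a; ms_w <- ssd_w / df_w
    n0 <- (N - sum(ngs^2) / N) / df_a
    s2_w <- ms_w
    s2_a <- (ms_a - ms_w) / n0
    c(phi = s2_a / (s2_a + s2_w), s2_a = s2_a, s2_w = s2_w)
  }
  obs_stat <- phi_of(labs)
  perm <- vapply(seq_len(n_perm),
                 function(k) phi_of(sample(labs))["phi"], 0)
  p <- (sum(perm >= obs_stat["phi"]) + 1) / (n_perm + 1)
  tot <- obs_stat["s2_a"] + obs_stat["s2_w"]
  structure(list(sigma_among = unname(obs_stat["s2_a"]),
                 sigma_within = unname(obs_stat["s2_w"]),
                 pct_among = unname(100 * obs_stat["s2_a"] / tot),
                 pct_within = unname(100 * obs_stat["s2_w"] / tot),
                 phi = unname(obs_stat["phi"]),
                 p_value = p, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (two-level)\n")
  cat(sprintf("  among populations:  %6.2f%%  (sigma2 = %.4f)\n",
              x$pct_among, x$sigma_among))
  cat(sprintf("  within populations: %6.2f%%  (sigma2 = %.4f)\n",
              x$pct_within, x$sigma_within))
  cat(sprintf("  Phi_ST = %.4f, p = %.4g (%d permutations)\n",
              x$phi, x$p_value, x$n_perm))
  invisible(x)
}

#' Greedy window LD pruning
#'
#' PLINK-style `indep-pairwise` pruning: within each window of `window`
#' markers, pairs of still-present markers with dosage r-squared above `r2`
#' are visited in order and the later marker of each offending pair is
#' removed; the window then slides by `step` markers. Deterministic.
#'
#' @param g a [genotype_matrix()].
#' @param window window size in markers.
#' @param step slide in markers.
#' @param r2 r-squared threshold.
#' @return integer vector of surviving marker indices (use `g[, idx]`).
#' @export
ld_prune <- function(g, window = 50, step = 10, r2 = 0.1) {
  keep <- rep(TRUE, n_markers(g))
  for (ch in unique(g$map$chr)) {
    jj <- which(g$map$chr == ch)
    start <- 1
    repeat {
      win <- jj[start:min(start + window - 1, length(jj))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2m <- suppressWarnings(
          stats::cor(g$geno[, win, drop = FALSE],
                     use = "pairwise.complete.obs")^2)
        for (a in seq_len(length(win) - 1)) {
          if (!keep[win[a]]) next
          for (b in (a + 1):length(win)) {
            if (!keep[win[b]]) next
            if (!is.na(r2m[a, b]) && r2m[a, b] > r2) keep[win[b]] <- FALSE
          }
        }
      }
      if (start + window - 1 >= length(jj)) break
      start <- start + step
    }
  }
  which(keep)
}

#' Principal component analysis of genotypes
#'
#' Markers are centered at twice their allele frequency and scaled by
#' `sqrt(p (1 - p))`; missing genotypes sit at the marker mean. Sample
#' coordinates come from the eigendecomposition of the sample covariance of
#' the standardized matrix; variance-explained fractions are eigenvalues over
#' their total.
#'
#' @param g a [genotype_matrix()] (typically LD-pruned).
#' @param n_pc number of components to return.
#' @return list with `scores` (samples x n_pc), `varprop` (fractions),
#'   `pop` labels.
#' @export
pca_genotypes <- function(g, n_pc = 10) {
  p <- allele_freq(g)
  use <- !is.nan(p) & p > 0 & p < 1
  X <- g$geno[, use, drop = FALSE]
  p <- p[use]
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  C <- tcrossprod(Z) / ncol(Z)
  ei <- eigen(C, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  n_pc <- min(n_pc, sum(ev > 1e-12))
  scores <- ei$vectors[, seq_len(n_pc), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_pc)]), n_pc)
  rownames(scores) <- rownames(g$geno)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  list(scores = scores, varprop = ev / sum(ev), pop = g$pop)
}

#' Allele-sharing (1 - IBS) distance
#'
#' Mean per-marker allele-sharing dissimilarity `|g_i - g_j| / 2` over
#' non-missing marker pairs; optionally averaged to population level for
#' breed-level trees.
#'
#' @param g a [genotype_matrix()].
#' @param by `"sample"` or `"population"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
ibs_distance <- function(g, by = c("sample", "population")) {
  by <- match.arg(by)
  X <- g$geno
  obs <- !is.na(X)
  Xz <- X; Xz[!obs] <- 0L
  ## sum |gi - gj| decomposed through genotype indicator products
  levs <- 0:2
  ind <- lapply(levs, function(v) (Xz == v & obs) * 1)
  num <- matrix(0, nrow(X), nrow(X))
  for (a in 1:3) for (b in 1:3)
    num <- num + abs(levs[a] - levs[b]) * tcrossprod(ind[[a]], ind[[b]])
  shared <- tcrossprod(obs * 1)
  d <- ifelse(shared > 0, num / (2 * shared), 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  if (by == "population") {
    pops <- sort(unique(g$pop))
    dp <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)) for (j in seq_along(pops)) {
      if (i == j) next
      dp[i, j] <- mean(d[g$pop == pops[i], g$pop == pops[j], drop = FALSE])
    }
    d <- dp
  }
  attr(d, "metric") <- "1-IBS"
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via ape). Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero with the deficit
#' transferred to the adjacent branch so pairwise path lengths through the
#' parent are preserved.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @return list with `tree` (an ape `phylo`) and `newick` (string).
#' @export
nj_tree <- function(d) {
  stopifnot(nrow(d) >= 3, isSymmetric(unname(as.matrix(d)), tol = 1e-8))
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    node <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == node & seq_along(tr$edge.length) != e)
    tr$edge.length[e] <- 0
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
  }
  list(tree = tr, newick = ape::write.tree(tr))
}
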