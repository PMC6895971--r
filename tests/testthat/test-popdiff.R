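test_that("Reynolds distance behaves at its anchors", {
  ## identical populations: |D_R| < 0.01 at 1,000 markers
  sim <- simulate_balding_nichols(c(A = 40, B = 40), F_div = 0,
                                  map = sim_map(1, 50e6, 50e3), seed = 2)
  rd <- reynolds_distance(sim$genotypes)
  expect_lt(abs(rd$d["A", "B"]), 0.01)
  ## fully fixed alternative alleles: theta -> 1
  g <- toy_gmat(rbind(matrix(2L, 5, 50), matrix(0L, 5, 50)),
                pop = rep(c("A", "B"), each = 5))
  rd2 <- reynolds_distance(g)
  expect_gt(rd2$theta["A", "B"], 0.99)
  expect_gt(rd2$d["A", "B"], 4)
})

test_that("ratio-of-sums aggregation matches the independently coded oracle", {
  sim <- simulate_balding_nichols(c(A = 30, B = 45), F_div = 0.08,
                                  map = sim_map(1, 40e6, 50e3),
                                  missing = 0.02, seed = 9)
  g <- sim$genotypes
  rd <- reynolds_distance(g)
  p1 <- allele_freq(g, which(g$pop == "A"))
  p2 <- allele_freq(g, which(g$pop == "B"))
  n1 <- colSums(!is.na(g$geno[g$pop == "A", ]))
  n2 <- colSums(!is.na(g$geno[g$pop == "B", ]))
  ok <- n1 > 1 & n2 > 1 & !is.nan(p1) & !is.nan(p2)
  expect_equal(rd$theta["A", "B"],
               reynolds_oracle(p1[ok], p2[ok], n1[ok], n2[ok]),
               tolerance = 1e-12)
})

test_that("both distances grow monotonically with simulated divergence", {
  th <- dr <- fst <- numeric(0)
  for (Fd in c(0.02, 0.05, 0.1, 0.2)) {
    sim <- simulate_balding_nichols(c(A = 40, B = 40), F_div = Fd,
                                    map = sim_map(1, 60e6, 50e3),
                                    seed = 100 + round(1000 * Fd))
    rd <- reynolds_distance(sim$genotypes)
    th <- c(th, rd$theta["A", "B"])
    dr <- c(dr, rd$d["A", "B"])
    fst <- c(fst, weir_cockerham_fst(sim$genotypes))
  }
  expect_true(all(diff(th) > 0))
  expect_true(all(diff(dr) > 0))
  expect_true(all(diff(fst) > 0))
})

test_that("Weir-Cockerham components match a hand-worked example", {
  ## two pops of 10, counted-allele freq 0.9 vs 0.1, all heterozygotes
  ## arranged to give h1 = 0.2, h2 = 0.2
  g1 <- c(rep(2L, 8), 1L, 1L)  # p = 18/20 = 0.9, het fraction 0.2
  g2 <- c(rep(0L, 8), 1L, 1L)  # p = 2/20  = 0.1
  g <- toy_gmat(cbind(c(g1, g2)), pop = rep(c("A", "B"), each = 10))
  got <- weir_cockerham_fst(g)
  ## hand evaluation of the variance components
  r <- 2; n1 <- 10; n2 <- 10
  nbar <- 10; nc <- (20 - (100 + 100) / 20) / 1
  p1 <- 0.9; p2 <- 0.1; pbar <- 0.5
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- 0.2
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  expect_equal(got, a / (a + b + cc), tolerance = 1e-12)
})

test_that("identical populations give near-zero global theta", {
  sim <- simulate_balding_nichols(c(A = 50, B = 50), F_div = 0,
                                  map = sim_map(1, 100e6, 50e3), seed = 3)
  expect_lte(abs(weir_cockerham_fst(sim$genotypes)), 0.01)
})

test_that("theta tracks Balding-Nichols truth across F", {
  for (Fd in c(0.05, 0.1, 0.2)) {
    sim <- simulate_balding_nichols(c(A = 60, B = 60), F_div = Fd,
                                    map = sim_map(2, 125e6, 25e3),
                                    seed = 7000 + round(1000 * Fd))
    expect_lt(abs(weir_cockerham_fst(sim$genotypes) - Fd), 0.02)
  }
})

test_that("AMOVA finds no structure in shuffled labels, full in fixed ones", {
  sim <- simulate_balding_nichols(c(A = 20, B = 20), F_div = 0,
                                  map = sim_map(1, 10e6, 1e5), seed = 11)
  hits <- 0
  for (s in 1:10) {
    g <- sim$genotypes
    set.seed(s)
    g$pop <- sample(g$pop)
    am <- amova(g, n_perm = 99)
    if (am$p_value > 0.05) hits <- hits + 1
    expect_equal(am$pct_among + am$pct_within, 100, tolerance = 1e-9)
  }
  expect_gte(hits, 8)
  ## two fully fixed divergent populations: among ~ 100%
  gf <- toy_gmat(rbind(matrix(2L, 6, 40), matrix(0L, 6, 40)),
                 pop = rep(c("A", "B"), each = 6))
  amf <- amova(gf, n_perm = 99)
  expect_gt(amf$pct_among, 95)
})

test_that("structured data yields significant AMOVA with sane partition", {
  sim <- simulate_balding_nichols(c(A = 25, B = 25, C = 25), F_div = 0.1,
                                  map = sim_map(1, 25e6, 50e3), seed = 13)
  am <- amova(sim$genotypes, n_perm = 99)
  expect_lt(am$p_value, 0.05)
  expect_gt(am$pct_among, 5)
  expect_lt(am$pct_among, 40)
})

test_that("LD pruning is greedy, windowed and deterministic", {
  ## duplicated marker pair: exactly one survives
  set.seed(21)
  x <- sample(0:2, 30, TRUE)
  g <- toy_gmat(cbind(x, x))
  expect_equal(ld_prune(g, r2 = 0.1), 1L)
  ## independent markers: none removed
  sim <- simulate_balding_nichols(c(A = 60), F_div = 0,
                                  map = sim_map(1, 3e6, 1e5), seed = 22)
  expect_equal(ld_prune(sim$genotypes, r2 = 0.99), seq_len(30))
  ## known correlated triplet traced by hand: markers 2,3,4 identical;
  ## greedy visit (2,3) removes 3, (2,4) removes 4 -> survivors all but 3,4
  set.seed(23)
  base <- sample(0:2, 40, TRUE)
  noise <- function() sample(0:2, 40, TRUE)
  codes <- cbind(noise(), base, base, base, noise(), noise())
  g3 <- toy_gmat(codes)
  expect_equal(ld_prune(g3, window = 6, step = 2, r2 = 0.2),
               c(1L, 2L, 5L, 6L))
})

test_that("PCA separates diverged populations and keeps its invariants", {
  sim <- simulate_balding_nichols(c(A = 50, B = 50), F_div = 0.2,
                                  map = sim_map(1, 125e6, 25e3), seed = 29)
  g <- sim$genotypes[, ld_prune(sim$genotypes)]
  pc <- pca_genotypes(g)
  a <- pc$scores[pc$pop == "A", 1]; b <- pc$scores[pc$pop == "B", 1]
  expect_true(max(a) < min(b) || max(b) < min(a))   # zero overlap on PC1
  expect_true(all(diff(pc$varprop) <= 1e-12))        # non-increasing
  expect_lte(sum(pc$varprop), 1 + 1e-9)
  ## duplicating every sample leaves variance fractions unchanged
  gd <- genotype_matrix(rbind(g$geno,
                              `rownames<-`(g$geno,
                                           paste0(rownames(g$geno), "_d"))),
                        g$map, pop = c(g$pop, g$pop),
                        counted = g$counted, other = g$other)
  pcd <- pca_genotypes(gd)
  expect_equal(pcd$varprop[1:5], pc$varprop[1:5], tolerance = 1e-6)
})

test_that("neighbour-joining recovers additive matrices exactly", {
  set.seed(37)
  for (ntax in 4:8) {
    tr <- ape::rtree(ntax, br = function(n) stats::runif(n, 0.1, 1))
    tr <- ape::unroot(tr)
    D <- stats::cophenetic(tr)
    out <- nj_tree(D)
    expect_equal(ape::dist.topo(out$tree, tr), 0, ignore_attr = TRUE)
    D2 <- stats::cophenetic(out$tree)[rownames(D), colnames(D)]
    expect_equal(D2, D, tolerance = 1e-10)
    expect_match(out$newick, ";$")
  }
  ## three taxa have a unique unrooted topology
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ape::Ntip(nj_tree(D3)$tree), 3)
})

test_that("NJ matches UPGMA topology on ultrametric input", {
  set.seed(41)
  tr <- ape::rcoal(6)                       # ultrametric by construction
  D <- stats::cophenetic(tr)
  nj_out <- nj_tree(D)$tree
  up <- ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
  expect_equal(ape::dist.topo(ape::unroot(nj_out), ape::unroot(up)), 0,
               ignore_attr = TRUE)
})

test_that("population distance table carries both metrics", {
  sim <- simulate_balding_nichols(c(A = 30, B = 30, C = 30),
                                  F_div = c(0.05, 0.1, 0.15),
                                  map = sim_map(1, 50e6, 50e3), seed = 43)
  pd <- population_distances(sim$genotypes)
  expect_true(isSymmetric(pd$reynolds))
  expect_true(isSymmetric(pd$pairwise_fst))
  expect_equal(diag(pd$combined), rep(0, 3), ignore_attr = TRUE)
  expect_equal(pd$combined["A", "B"], pd$reynolds["A", "B"])
  expect_equal(pd$combined["B", "A"], pd$pairwise_fst["A", "B"])
})
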