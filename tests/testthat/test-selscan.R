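test_that("site pi matches counting and the all-pairs oracle", {
  ## fixed site -> 0
  g <- toy_gmat(rbind(c(2L, 2L), c(2L, 0L)))
  expect_equal(unname(site_pi(g)[1]), 0)
  ## k = 2 of 2n = 4 alleles: 2*2*2 / (4*3) = 2/3
  g2 <- toy_gmat(cbind(c(1L, 1L)))
  expect_equal(site_pi(g2), 2 / 3, ignore_attr = TRUE)
  ## equals mean pairwise allele difference enumerated over all 2n alleles
  set.seed(4)
  for (rep in 1:10) {
    codes <- cbind(sample(0:2, 7, TRUE))
    g3 <- toy_gmat(codes)
    alleles <- unlist(lapply(codes, function(x) c(rep(1, x), rep(0, 2 - x))))
    expect_equal(unname(site_pi(g3)), pi_allpairs(alleles))
  }
})

test_that("ZFst standardizes to mean 0 sd 1 with the population sd", {
  z <- zfst(c(0.1, 0.3))
  expect_equal(z, c(-1, 1))   # population sd of {0.1, 0.3} is 0.1
  set.seed(5)
  x <- stats::runif(50)
  z2 <- zfst(x)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-12)
  expect_error(zfst(rep(0.2, 10)), "sd = 0")
  ## NA values pass through without poisoning the moments
  z3 <- zfst(c(0.1, NA, 0.3))
  expect_equal(z3, c(-1, NA, 1))
})

test_that("EHH is 1 at the core, monotone, and matches hand grouping", {
  ## all haplotypes identical -> EHH = 1 everywhere
  h1 <- matrix(1L, 6, 9)
  e1 <- ehh(h1, 5)
  expect_true(all(e1$right$ehh == 1) && all(e1$left$ehh == 1))
  ## all haplotypes distinct at the adjacent marker -> EHH drops to 0
  h2 <- rbind(c(1L, 0L), c(1L, 1L))
  h2 <- h2[c(1, 2), ]
  e2 <- ehh(rbind(c(1L, 0L), c(1L, 1L)), 1)
  expect_equal(e2$right$ehh, c(1, 0))
  ## 6-haplotype toy vs the homozygosity count formula per extension
  set.seed(6)
  hap <- matrix(sample(0:1, 6 * 7, TRUE), 6, 7)
  core <- 4
  e <- ehh(hap, core)
  for (k in 2:nrow(e$right))
    expect_equal(e$right$ehh[k], ehh_by_hand(hap, core:e$right$marker[k]))
  for (k in 2:nrow(e$left))
    expect_equal(e$left$ehh[k], ehh_by_hand(hap, e$left$marker[k]:core))
  expect_true(all(diff(e$right$ehh) <= 1e-12))
  expect_true(all(diff(e$left$ehh) <= 1e-12))
  expect_error(ehh(hap[1, , drop = FALSE], 1), "two haplotypes")
})

test_that("XP-EHH is zero on identical sets and antisymmetric under swap", {
  set.seed(7)
  map1 <- sim_map(1, 10e6, 1e5)
  hA <- simulate_haplotypes_iid(15, map1, seed = 71)
  hB <- simulate_haplotypes_iid(15, map1, seed = 72)
  hA_copy <- hA
  core <- 50
  expect_equal(xpehh(hA, hA_copy, core), 0)
  s1 <- xpehh(hA, hB, core)
  s2 <- xpehh(hB, hA, core)
  expect_equal(s1, -s2, tolerance = 1e-12)
})

test_that("standardized XP-EHH has unit moments and affine invariance", {
  set.seed(8)
  x <- stats::rnorm(100)
  z <- standardize_xpehh(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  expect_equal(standardize_xpehh(3 * x + 2), z, tolerance = 1e-12)
  expect_error(standardize_xpehh(5), "two scores")
})

test_that("neutral two-population data rarely exceeds |z| = 2", {
  map1 <- sim_map(1, 30e6, 50e3)
  h <- simulate_haplotypes_iid(40, map1, seed = 91)
  h$pop <- rep(c("HI", "LO"), each = 20)
  g <- genotypes_from_haplotypes(h)
  sc <- selection_scan(g, "HI", "LO", haps = h, xpehh_step = 6)
  z <- sc$xpehh_std[!is.na(sc$xpehh_std)]
  expect_lte(mean(abs(z) > 2), 0.10)
})

test_that("outlier flags use the ceiling quantile rule exactly", {
  set.seed(10)
  n <- 250
  rows <- data.frame(chr = "1", bp = seq_len(n) * 1e5, id = paste0("s", 1:n),
                     fst = seq_len(n) / n, pi_ratio = rev(seq_len(n)) / n,
                     xpehh_std = stats::rnorm(n))
  cc <- call_candidates(rows)
  expect_equal(sum(cc$rows$out_fst), ceiling(0.01 * n))
  expect_equal(sum(cc$rows$out_pi), ceiling(0.01 * n))
  expect_equal(sum(cc$rows$out_xpehh), ceiling(0.001 * n))
  ## constructed ranks: fst top at the end, pi top at the start -> no overlap
  expect_equal(unname(cc$venn["fst_pi"]), 0)
  ## aligned ranks -> full overlap
  rows2 <- rows; rows2$pi_ratio <- rows2$fst
  cc2 <- call_candidates(rows2)
  expect_equal(unname(cc2$venn["fst_pi"]), ceiling(0.01 * n))
  ## regions come with empty gene lists when no annotation is given
  expect_true(all(cc2$regions$genes == ""))
  ## region geometry: a single isolated candidate spans exactly +/- extension
  rows3 <- rows
  rows3$fst <- rows3$pi_ratio <- c(rep(0.1, 99), 0.9, rep(0.1, n - 100))
  rows3$xpehh_std <- 0.5
  cc3 <- call_candidates(rows3, q_fst = 0.001, q_pi = 0.001, q_xpehh = 0.001)
  r <- cc3$regions[cc3$regions$n_snps == 1 & cc3$regions$stats == "FP", ]
  expect_equal(nrow(r), 1)
  expect_equal(r$end_bp - r$start_bp, 2e5)
  expect_equal((r$start_bp + r$end_bp) / 2, 100 * 1e5)
})

test_that("candidate regions merge overlaps and pick up gene annotation", {
  rows <- data.frame(chr = "1", bp = c(1e6, 1.05e6, 5e6),
                     id = c("a", "b", "c"),
                     fst = c(0.9, 0.95, 0.99), pi_ratio = c(5, 6, 7),
                     xpehh_std = c(0, 0, 3))
  ## with q = 0.34 the top ceiling(0.34*3) = 2 of each flag
  cc <- call_candidates(rows, q_fst = 0.5, q_pi = 0.5, q_xpehh = 0.4,
                        extend_bp = 1e5,
                        annotation = data.frame(chr = "1",
                                                start_bp = 1.1e6,
                                                end_bp = 1.2e6,
                                                gene = "GENE1"))
  ## cores 1.05e6 and 5e6 are flagged on fst&pi; 5e6 also on xpehh
  expect_equal(nrow(cc$regions), 2)
  expect_equal(cc$regions$genes[1], "GENE1")
  expect_equal(cc$regions$genes[2], "")
})

test_that("a planted sweep plus divergence lands in the 3-way intersection", {
  map2 <- sim_map(2, 100e6, 50e3)
  h <- simulate_haplotypes_iid(60, map2, seed = 9)
  h$pop <- rep(c("HI", "LO"), each = 30)
  sw <- plant_sweep(h, "HI", core_bp = 50e6, chr = "1", fraction = 0.85,
                    window_cm = 2.5, seed = 10)
  g <- genotypes_from_haplotypes(sw$haplotypes)
  sc <- selection_scan(g, "HI", "LO", haps = sw$haplotypes, xpehh_step = 4)
  cc <- call_candidates(sc, q_xpehh = 0.005)
  expect_gt(unname(cc$venn["fst_pi_xpehh"]), 0)
  hit <- cc$rows[cc$rows$out_fst & cc$rows$out_pi & cc$rows$out_xpehh, ]
  expect_true(any(hit$chr == "1" & abs(hit$bp - 50e6) < 2.5e6))
})

test_that("BED genes convert coordinates through the central function", {
  d <- withr::local_tempdir()
  writeLines("1\t999\t2000\tGENEA\n2\t0\t100\tGENEB",
             file.path(d, "genes.bed"))
  gn <- read_genes(file.path(d, "genes.bed"))
  expect_equal(gn$start_bp, c(1000, 1))
  expect_equal(gn$end_bp, c(2000, 100))
  expect_equal(gn$gene, c("GENEA", "GENEB"))
})
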