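test_that("an all-heterozygous chromosome yields no runs", {
  g <- toy_gmat(matrix(1L, 1, 40))
  expect_equal(nrow(detect_roh(g)), 0)
})

test_that("one interior heterozygote is tolerated inside a run", {
  x <- rep(2L, 20); x[10] <- 1L
  g <- toy_gmat(x)      # 20 markers spanning 1.9 Mb at 100 kb spacing
  segs <- detect_roh(g, roh_params(min_snps = 15, min_length_mb = 1))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 20)
  expect_equal(segs$n_het, 1)
})

test_that("scanner equals the brute-force maximal-window oracle", {
  set.seed(99)
  params <- roh_params(min_snps = 10, min_length_mb = 0.5)
  for (rep in 1:200) {
    n <- 200
    x <- sample(c(0L, 1L, 2L, NA), n, TRUE, prob = c(.44, .08, .44, .04))
    bp <- sort(sample(1:(n * 60000), n))
    map <- data.frame(chr = "1", id = paste0("m", 1:n), cM = bp * 1e-6,
                      bp = bp)
    g <- genotype_matrix(rbind(x), map)
    segs <- detect_roh(g, params)
    orc <- roh_oracle_one(x, bp, params)
    if (is.null(orc)) {
      expect_equal(nrow(segs), 0)
    } else {
      expect_equal(segs$start_bp, bp[orc[, "start"]])
      expect_equal(segs$end_bp, bp[orc[, "end"]])
    }
  }
})

test_that("froh follows its definition and decomposes over length classes", {
  segs <- data.frame(sample = "s1", pop = "P", chr = "1",
                     start_bp = c(1e6, 10e6), end_bp = c(3.5e6, 14e6),
                     n_snps = c(30, 50), n_het = 0, n_missing = 0,
                     length_mb = c(2.5, 4), class = c("0-3", "3-5"))
  f <- froh(segs, samples = c("s1", "s2"), l_auto = 100)
  expect_equal(f$froh[f$sample == "s1"], 6.5 / 100)
  expect_equal(f$froh[f$sample == "s2"], 0)
  class_cols <- grep("^froh_", names(f))
  expect_equal(rowSums(f[, class_cols]), f$froh, tolerance = 1e-9,
               ignore_attr = TRUE)
  ## the stated arithmetic anchors
  expect_equal(froh(segs[0, ], "s", 2399.4)$froh, 0)
  segs2 <- segs[1, ]; segs2$length_mb <- 239.94
  expect_equal(froh(segs2, "s1", 2399.4)$froh, 0.1)
  segs2$length_mb <- 2399.4
  expect_equal(froh(segs2, "s1", 2399.4)$froh, 1)
})

test_that("fhom matches a hand computation and its edge cases", {
  ## 2 markers x 2 samples: s1 = (2, 2), s2 = (0, 1)
  g <- toy_gmat(rbind(c(2L, 2L), c(0L, 1L)))
  ## freq p = (0.5, 0.75); h = 2pq * 2n/(2n-1) with n = 2 -> 4/3 * 2pq
  h1 <- 2 * .5 * .5 * 4 / 3; h2 <- 2 * .75 * .25 * 4 / 3
  E <- (1 - h1) + (1 - h2)
  f <- fhom(g)
  expect_equal(f$E, c(E, E))
  expect_equal(f$O, c(2, 1))
  expect_equal(f$N, c(2, 2))
  expect_equal(f$fhom, (c(2, 1) - E) / (2 - E))
  ## a fully homozygous sample scores F_HOM = 1
  expect_equal(f$fhom[1], 1)
  ## frequency invariance: duplicating the population leaves F_HOM unchanged
  g2 <- toy_gmat(rbind(c(2L, 2L), c(0L, 1L), c(2L, 2L), c(0L, 1L)))
  f2 <- fhom(g2)
  ## same O and N; E changes only through the 2n/(2n-1) correction
  expect_equal(f2$O[1:2], f$O)
  ## all-monomorphic matrix has N = E, undefined
  g3 <- toy_gmat(rbind(c(2L, 2L), c(2L, 2L)))
  expect_true(all(is.na(fhom(g3)$fhom)))
})

test_that("chromosome coverage uses the carrier denominator", {
  seg <- function(s, len_mb) data.frame(sample = s, pop = "P", chr = "1",
                                        start_bp = 1e6,
                                        end_bp = 1e6 + len_mb * 1e6,
                                        n_snps = 20, n_het = 0, n_missing = 0,
                                        length_mb = len_mb,
                                        class = roh_class_of(len_mb))
  pop <- c(s1 = "P", s2 = "P")
  ## one individual, one 5-Mb ROH on a 100-Mb chromosome -> 5%
  s <- roh_summary(seg("s1", 5), pop, c("1" = 100))
  expect_equal(s$by_chromosome$coverage_pct, 5)
  ## two individuals, only one carries (4 Mb) -> still 4% (carriers only)
  s2 <- roh_summary(seg("s1", 4), pop, c("1" = 100))
  expect_equal(s2$by_chromosome$coverage_pct, 4)
  ## empty input -> all-zero summary
  s3 <- roh_summary(seg("s1", 4)[0, ], pop, c("1" = 100))
  expect_equal(s3$by_chromosome$coverage_pct, 0)
  expect_equal(s3$by_breed$n_roh, 0)
})

test_that("per-class means divide by breed size, not carrier count", {
  segs <- rbind(
    data.frame(sample = "s1", pop = "P", chr = "1", start_bp = 1e6,
               end_bp = 3e6, n_snps = 20, n_het = 0, n_missing = 0,
               length_mb = 2, class = "0-3"),
    data.frame(sample = "s1", pop = "P", chr = "1", start_bp = 5e6,
               end_bp = 9e6, n_snps = 30, n_het = 0, n_missing = 0,
               length_mb = 4, class = "3-5"))
  pop <- c(s1 = "P", s2 = "P", s3 = "P", s4 = "P")
  s <- roh_summary(segs, pop, c("1" = 100))
  bc <- s$by_class[s$by_class$pop == "P", ]
  expect_equal(bc$mean_sum_mb[bc$class == "0-3"], 2 / 4)
  expect_equal(bc$mean_sum_mb[bc$class == "3-5"], 4 / 4)
  expect_equal(sum(bc$count), 2)
  expect_equal(sum(bc$frequency), 1)
})

test_that("islands recover a shared segment and respect the threshold", {
  ## all samples share one identical ROH -> one island spanning it at 100%
  set.seed(123)
  n <- 6
  codes <- matrix(sample(c(0L, 1L, 2L), n * 60, TRUE), n, 60)
  codes[, 21:40] <- 2L
  ## heterozygous barriers: the single allowed heterozygote lets a run grow
  ## by at most one marker beyond the shared segment
  codes[, c(19, 20, 41, 42)] <- 1L
  g <- toy_gmat(codes)
  segs <- detect_roh(g, roh_params(min_snps = 15, min_length_mb = 1))
  isl <- roh_islands(segs, g, threshold = 0.45)
  expect_gte(nrow(isl$islands), 1)
  main <- isl$islands[which.max(isl$islands$n_snps), ]
  expect_equal(main$peak_pct, 100)
  expect_lte(abs(main$start_bp - 21 * 1e5), 1e5)
  expect_lte(abs(main$end_bp - 40 * 1e5), 1e5)
  ## no ROH -> no islands
  empty <- roh_islands(segs[0, ], g, threshold = 0.45)
  expect_equal(nrow(empty$islands), 0)
  expect_true(all(empty$per_snp$occurrence_pct == 0))
})

test_that("a 60%-carrier planted segment is recovered within one marker", {
  set.seed(31)
  h <- simulate_haplotypes_iid(20, sim_map(1, 30e6, 50e3), seed = 77)
  ## plant the same 3-Mb autozygous tract in 12/20 individuals (60%)
  jj <- which(h$map$bp >= 10e6 & h$map$bp <= 13e6)
  for (i in 1:12) h$hap[2 * i, jj] <- h$hap[2 * i - 1, jj]
  g <- genotypes_from_haplotypes(h)
  segs <- detect_roh(g)
  isl <- roh_islands(segs, g, threshold = 0.45)
  expect_equal(nrow(isl$islands), 1)
  expect_lte(abs(isl$islands$start_bp - 10e6), 1e5)
  expect_lte(abs(isl$islands$end_bp - 13e6), 1e5)
})

test_that("F_ROH recovers planted autozygous fractions within 0.02", {
  h <- simulate_haplotypes_iid(12, sim_map(2, 100e6, 50e3), seed = 5)
  pa <- plant_autozygosity(h, 1:6, fraction = 0.3, tract_mean_cm = 5,
                           seed = 7)
  segs <- detect_roh(pa$genotypes)
  fr <- froh(segs, rownames(pa$genotypes$geno), l_auto = 200)
  err <- fr$froh - pa$truth$realized_fraction
  expect_lt(max(abs(err[1:6])), 0.02)
  expect_lt(max(abs(err[7:12])), 0.02)   # unplanted stay near zero
})

test_that("F_ROH and F_HOM correlate strongly across varied inbreeding", {
  h <- simulate_haplotypes_iid(24, sim_map(2, 100e6, 50e3), seed = 15)
  fracs <- rep(c(0, 0.05, 0.15, 0.3), each = 6)
  ## plant individual-specific fractions
  hap <- h
  for (i in seq_along(fracs)) {
    if (fracs[i] == 0) next
    hap <- plant_autozygosity(hap, i, fraction = fracs[i], tract_mean_cm = 4,
                              seed = 100 + i)$haplotypes
  }
  g <- genotypes_from_haplotypes(hap)
  segs <- detect_roh(g)
  fr <- froh(segs, rownames(g$geno), l_auto = 200)
  fh <- fhom(g)
  expect_gt(stats::cor(fr$froh, fh$fhom), 0.9)
})

test_that("region-gene distance keeps sign and units", {
  expect_equal(region_gene_distance(5e6, 5e6), 0)
  expect_equal(region_gene_distance(5e6, 7.57e6), 2.57)
  expect_lt(region_gene_distance(5e6, 3e6), 0)
})
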