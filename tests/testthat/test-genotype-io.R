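test_that("hand-written ped/map decodes to the expected codes", {
  d <- withr::local_tempdir()
  writeLines(c("1\tm1\t0\t100",
               "1\tm2\t0\t200",
               "1\tm3\t0\t300"), file.path(d, "toy.map"))
  ## sample1: A/A  A/G  0/0 ; sample2: A/G  G/G  G/G
  writeLines(c("FAM1 ind1 0 0 0 -9 A A A G 0 0",
               "FAM2 ind2 0 0 0 -9 A G G G G G"),
             file.path(d, "toy.ped"))
  g <- read_plink(file.path(d, "toy"), dialect = "text")
  expect_equal(dim(g$geno), c(2L, 3L))
  ## counted allele is the lexicographically smaller: A, A, G
  expect_equal(g$counted, c("A", "A", "G"))
  expect_equal(unname(g$geno[1, ]), c(2L, 1L, NA))
  expect_equal(unname(g$geno[2, ]), c(1L, 0L, 2L))
  expect_equal(g$pop, c("FAM1", "FAM2"))
  expect_equal(rownames(g$geno), c("ind1", "ind2"))
  expect_equal(g$map$bp, c(100, 200, 300))
})

test_that("a .bed without the magic bytes is a format error", {
  d <- withr::local_tempdir()
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0xff)), file.path(d, "bad.bed"))
  write.table(data.frame("1", "m1", 0, 100, "A", "B"),
              file.path(d, "bad.bim"), row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  write.table(data.frame("F", "i1", 0, 0, 0, -9),
              file.path(d, "bad.fam"), row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  expect_error(read_plink(file.path(d, "bad"), "binary"), "magic")
})

test_that("ped rows with the wrong field count raise a parse error", {
  d <- withr::local_tempdir()
  writeLines("1\tm1\t0\t100\n1\tm2\t0\t200", file.path(d, "p.map"))
  writeLines("F i 0 0 0 -9 A A G", file.path(d, "p.ped"))
  expect_error(read_plink(file.path(d, "p"), "text"), "parse error")
})

test_that("binary round trip is bit-exact for codes, map, labels and alleles", {
  d <- withr::local_tempdir()
  set.seed(42)
  for (n in c(1, 4, 5, 17)) {
    m <- 13
    codes <- matrix(sample(c(0:2, NA), n * m, TRUE, prob = c(.3, .3, .3, .1)),
                    n, m)
    rownames(codes) <- paste0("id", seq_len(n))
    map <- data.frame(chr = rep(c("1", "2"), c(7, 6)),
                      id = paste0("mk", seq_len(m)),
                      cM = seq_len(m),
                      bp = c(1:7 * 1000, 1:6 * 1000))
    g <- genotype_matrix(codes, map, pop = rep(c("P1", "P2"), length.out = n),
                         counted = sample(c("A", "C"), m, TRUE),
                         other = rep("G", m))
    write_plink(g, file.path(d, paste0("rt", n)), "binary")
    g2 <- read_plink(file.path(d, paste0("rt", n)), "binary")
    expect_identical(g2$geno, g$geno)
    expect_equal(g2$map$bp, g$map$bp)   # read.table may narrow to integer
    expect_identical(g2$map$id, g$map$id)
    expect_identical(g2$pop, g$pop)
    expect_identical(g2$counted, g$counted)  # writer never re-polarizes
    expect_identical(g2$other, g$other)
  }
})

test_that("text round trip preserves the genotype information", {
  d <- withr::local_tempdir()
  sim <- simulate_balding_nichols(c(A = 10, B = 10), F_div = 0.05,
                                  map = sim_map(1, 3e6, 1e5),
                                  missing = 0.05, seed = 7)
  g <- sim$genotypes
  write_plink(g, file.path(d, "t"), "text")
  g2 <- read_plink(file.path(d, "t"), "text")
  same <- g2$counted == g$counted
  codes <- g2$geno
  codes[, !same] <- 2L - codes[, !same]
  expect_identical(unname(codes), unname(g$geno))
  expect_identical(g2$pop, g$pop)
})

test_that("one sample, one marker gives a 4-byte .bed", {
  d <- withr::local_tempdir()
  g <- toy_gmat(matrix(1L, 1, 1))
  write_plink(g, file.path(d, "tiny"), "binary")
  expect_equal(file.size(file.path(d, "tiny.bed")), 4)
})

test_that("an empty matrix writes valid header-only files", {
  d <- withr::local_tempdir()
  g <- genotype_matrix(matrix(integer(), 0, 0),
                       data.frame(chr = character(), id = character(),
                                  cM = numeric(), bp = numeric()),
                       pop = character())
  write_plink(g, file.path(d, "empty"), "binary")
  expect_equal(file.size(file.path(d, "empty.bed")), 3)  # just the magic
  write_plink(g, file.path(d, "emptx"), "text")
  g2 <- read_plink(file.path(d, "emptx"), "text")
  expect_equal(dim(g2$geno), c(0L, 0L))
})

test_that("phased VCF decodes to two haplotype rows per sample", {
  skip_if_not_installed("vcfR")
  d <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
           "1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0|1\t1|1\t0|0",
           "1\t200\tv2\tC\tT\t.\t.\t.\tGT\t1|0\t0|1\t1|1",
           "1\t300\tv3\tG\tA\t.\t.\t.\tGT\t0|0\t1|0\t0|1")
  writeLines(vcf, file.path(d, "p.vcf"))
  h <- read_haplotypes(file.path(d, "p.vcf"))
  expect_equal(nrow(h$hap), 6)
  ## hand decoding, rows = (s1.h1, s1.h2, s2.h1, s2.h2, s3.h1, s3.h2)
  expect_equal(unname(h$hap),
               rbind(c(0L, 1L, 0L), c(1L, 0L, 0L),
                     c(1L, 0L, 1L), c(1L, 1L, 0L),
                     c(0L, 1L, 0L), c(0L, 1L, 1L)))
  expect_equal(h$samples, c("s1", "s2", "s3"))
})

test_that("an unphased GT is rejected with the offending site named", {
  skip_if_not_installed("vcfR")
  d <- withr::local_tempdir()
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
           "1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0|1",
           "1\t250\tv2\tC\tT\t.\t.\t.\tGT\t0/1")
  writeLines(vcf, file.path(d, "u.vcf"))
  expect_error(read_haplotypes(file.path(d, "u.vcf")), "250")
})

test_that("haps/sample round trip through the writer is exact", {
  d <- withr::local_tempdir()
  h <- simulate_haplotypes_iid(5, sim_map(1, 1e6, 1e5), seed = 3)
  write_haplotypes(h, file.path(d, "h"))
  h2 <- read_haplotypes(file.path(d, "h.haps"), format = "haps")
  expect_equal(unname(h2$hap), unname(h$hap))
  expect_equal(h2$samples, h$samples)
  expect_equal(h2$map$bp, h$map$bp)
})

test_that("coordinate conversion round-trips and matches BED convention", {
  b <- to_bed(101, 200)
  expect_equal(unname(b), cbind(100, 200))
  back <- from_bed(b[, 1], b[, 2])
  expect_equal(unname(back), cbind(101, 200))
})
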