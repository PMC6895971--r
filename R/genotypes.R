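#' Genotype matrix with marker map
#'
#' The shared data model for all pipeline stages: a diploid genotype code
#' matrix (samples x markers, each entry the number of copies of the per-marker
#' *counted* allele: 0, 1, 2 or `NA` for missing), a marker map, a population
#' label per sample and the counted/other allele per marker.
#'
#' Markers are stored sorted by (chromosome, physical position); physical
#' positions must be strictly increasing within a chromosome and marker ids
#' unique.
#'
#' @param geno integer matrix, samples in rows (rownames = sample ids),
#'   markers in columns, values in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `chr` (chromosome label; autosome
#'   integers or `"X"`/`"Y"`), `id` (marker id), `cM` (genetic position,
#'   centiMorgan; may be 0/NA, see [impute_cm()]), `bp` (physical position,
#'   1-based).
#' @param pop character/factor of population labels, one per sample.
#' @param counted,other per-marker allele labels; the genotype code counts
#'   copies of `counted`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, pop = NULL,
                            counted = NULL, other = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(is.data.frame(map), all(c("chr", "id", "bp") %in% names(map)))
  if (is.null(map$cM)) map$cM <- 0
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " markers but map has ", nrow(map), " rows")
  ok <- geno[!is.na(geno)]
  if (length(ok) && (min(ok) < 0L || max(ok) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(map$id)) stop("marker ids must be unique")
  if (is.null(rownames(geno)) && nrow(geno) > 0)
    rownames(geno) <- paste0("S", seq_len(nrow(geno)))
  if (anyDuplicated(rownames(geno))) stop("sample ids must be unique")
  if (is.null(pop)) pop <- rep("POP1", nrow(geno))
  pop <- as.character(pop)
  if (length(pop) != nrow(geno)) stop("one population label per sample required")
  if (is.null(counted)) counted <- rep("A", nrow(map))
  if (is.null(other)) other <- rep("B", nrow(map))

  map$chr <- as.character(map$chr)
  ord <- order(chrom_rank(map$chr), map$bp)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  counted <- counted[ord]
  other <- other[ord]
  rownames(map) <- NULL
  for (ch in unique(map$chr)) {
    bp <- map$bp[map$chr == ch]
    if (any(diff(bp) <= 0))
      stop("physical positions must be strictly increasing on chromosome ", ch)
  }
  colnames(geno) <- map$id
  structure(list(geno = geno, map = map, pop = pop,
                 counted = as.character(counted), other = as.character(other)),
            class = "genotype_matrix")
}

## internal: sortable rank for chromosome labels (integers first, then X, Y, ...)
chrom_rank <- function(chr) {
  n <- suppressWarnings(as.numeric(chr))
  r <- ifelse(is.na(n), 1e6 + as.numeric(factor(chr)), n)
  r
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "markers\n")
  cat("  chromosomes:", paste(unique(x$map$chr), collapse = ", "), "\n")
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$pop)),
                                      table(x$pop)), collapse = ", "), "\n")
  cat(sprintf("  missing rate: %.4f\n", missing_rate(x)))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (logical, integer or sample ids).
#' @param j marker index (logical, integer or marker ids).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(i)) i <- match(i, rownames(x$geno))
  if (is.character(j)) j <- match(j, x$map$id)
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  structure(list(geno = x$geno[i, j, drop = FALSE],
                 map = {m <- x$map[j, , drop = FALSE]; rownames(m) <- NULL; m},
                 pop = x$pop[i],
                 counted = x$counted[j], other = x$other[j]),
            class = "genotype_matrix")
}

#' Number of samples / markers
#' @param g a [genotype_matrix()].
#' @export
n_samples <- function(g) nrow(g$geno)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$geno)

#' Counted-allele frequency per marker
#'
#' @param g a [genotype_matrix()].
#' @param samples optional sample subset (index or ids) over which to compute.
#' @return numeric vector of counted-allele frequencies (`NaN` where all
#'   genotypes are missing).
#' @export
allele_freq <- function(g, samples = NULL) {
  geno <- g$geno
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(geno))
    geno <- geno[samples, , drop = FALSE]
  }
  colMeans(geno, na.rm = TRUE) / 2
}

#' Overall or per-marker/per-sample missing fraction
#'
#' @param g a [genotype_matrix()].
#' @param by one of `"overall"`, `"marker"`, `"sample"`.
#' @export
missing_rate <- function(g, by = c("overall", "marker", "sample")) {
  by <- match.arg(by)
  m <- is.na(g$geno)
  switch(by,
         overall = mean(m),
         marker = colMeans(m),
         sample = rowMeans(m))
}

#' Phased haplotype set
#'
#' Binary haplotypes (0 = other allele, 1 = counted allele), two rows per
#' sample, no missing values, sharing a marker map with the genotype model.
#'
#' @param hap binary matrix with `2 * n_samples` rows and one column per
#'   marker; rows `2i - 1` and `2i` are the two haplotypes of sample `i`.
#' @param map marker map as in [genotype_matrix()].
#' @param samples character vector of sample ids (length `nrow(hap) / 2`).
#' @param pop population label per sample.
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(hap, map, samples = NULL, pop = NULL) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (nrow(hap) %% 2L != 0L) stop("haplotype rows must pair: 2 per sample")
  if (anyNA(hap) || !all(hap %in% c(0L, 1L)))
    stop("haplotypes must be binary with no missing values")
  n <- nrow(hap) / 2L
  stopifnot(is.data.frame(map), nrow(map) == ncol(hap))
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  if (length(samples) != n) stop("need one sample id per haplotype pair")
  if (is.null(pop)) pop <- rep("POP1", n)
  map$chr <- as.character(map$chr)
  structure(list(hap = hap, map = map, samples = as.character(samples),
                 pop = as.character(pop)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$samples), "samples (",
      nrow(x$hap), "haplotypes ) x", ncol(x$hap), "markers\n")
  invisible(x)
}

#' Collapse phased haplotypes to genotype codes
#'
#' @param h a [haplotype_set()].
#' @return a [genotype_matrix()] whose codes count the `1` allele.
#' @export
genotypes_from_haplotypes <- function(h) {
  stopifnot(inherits(h, "haplotype_set"))
  n <- length(h$samples)
  g <- h$hap[seq(1, 2 * n, by = 2), , drop = FALSE] +
       h$hap[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(g) <- h$samples
  genotype_matrix(g, h$map, pop = h$pop)
}

#' Impute genetic positions at 1 cM/Mb where absent
#'
#' If the map's cM column is entirely zero or missing, genetic positions are
#' imputed as `bp * 1e-6` (a constant 1 cM/Mb recombination rate) and the map
#' gains the attribute `cM_imputed = TRUE`. Stages needing genetic distances
#' (HBD model, LD-based Ne, XP-EHH) call this on entry.
#'
#' @param map a marker-map data.frame (`chr`, `id`, `cM`, `bp`).
#' @param rate centiMorgan per megabase used for imputation.
#' @return the map, with usable `cM`.
#' @export
impute_cm <- function(map, rate = 1.0) {
  cm <- map$cM
  if (is.null(cm) || all(is.na(cm) | cm == 0)) {
    map$cM <- map$bp * 1e-6 * rate
    attr(map, "cM_imputed") <- TRUE
    message("genetic positions absent; imputed at ", rate, " cM/Mb")
  }
  map
}

#' Override population labels from a two-column table
#'
#' @param g a [genotype_matrix()].
#' @param path TSV file with columns sample id, population (no header).
#' @return `g` with replaced labels; samples absent from the table keep theirs.
#' @export
assign_populations <- function(g, path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  idx <- match(rownames(g$geno), tab[[1]])
  hit <- !is.na(idx)
  g$pop[hit] <- tab[[2]][idx[hit]]
  g
}
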