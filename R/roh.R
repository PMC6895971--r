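#' ROH detection parameters
#'
#' Defaults are the consecutive-run criteria used for 50K-chip data: at least
#' 15 SNPs and 1 Mb per run, with at most one heterozygote and one missing
#' genotype allowed inside a run.
#'
#' @param min_snps minimum number of SNPs in a run.
#' @param min_length_mb minimum run length (Mb, end - start).
#' @param max_het maximum heterozygous genotypes allowed in a run.
#' @param max_missing maximum missing genotypes allowed in a run.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 15, min_length_mb = 1,
                       max_het = 1, max_missing = 1) {
  stopifnot(min_snps >= 1, min_length_mb > 0, max_het >= 0, max_missing >= 0)
  structure(list(min_snps = min_snps, min_length_mb = min_length_mb,
                 max_het = max_het, max_missing = max_missing),
            class = "roh_params")
}

## ROH length classes (Mb), half-open [lo, hi)
roh_classes <- function() {
  data.frame(class = c("0-3", "3-5", "5-10", "10-20", "20-30", ">30"),
             lo = c(0, 3, 5, 10, 20, 30),
             hi = c(3, 5, 10, 20, 30, Inf))
}

roh_class_of <- function(length_mb) {
  cl <- roh_classes()
  cl$class[findInterval(length_mb, cl$lo)]
}

#' Detect runs of homozygosity
#'
#' Scans each sample and chromosome for maximal runs of consecutive markers
#' containing at most `max_het` heterozygotes and `max_missing` missing
#' genotypes, then keeps runs with at least `min_snps` markers spanning at
#' least `min_length_mb` (length = end bp - start bp). Where two maximal runs
#' overlap (possible around an allowed heterozygote), overlap is resolved
#' greedily by keeping the longer run (ties to the leftmost), so the reported
#' segments of one sample never overlap. Deterministic for fixed input.
#'
#' @param g a [genotype_matrix()], markers sorted by position (guaranteed by
#'   the constructor).
#' @param params a [roh_params()].
#' @return data.frame with columns `sample`, `pop`, `chr`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_mb`, `class`.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(params, "roh_params"))
  out <- vector("list", 0)
  chroms <- unique(g$map$chr)
  for (ch in chroms) {
    jj <- which(g$map$chr == ch)
    bp <- g$map$bp[jj]
    for (i in seq_len(n_samples(g))) {
      x <- g$geno[i, jj]
      segs <- roh_scan_one(x, bp, params)
      if (is.null(segs)) next
      segs$sample <- rownames(g$geno)[i]
      segs$pop <- g$pop[i]
      segs$chr <- ch
      out[[length(out) + 1]] <- segs
    }
  }
  if (!length(out)) {
    return(data.frame(sample = character(), pop = character(),
                      chr = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      n_het = integer(), n_missing = integer(),
                      length_mb = numeric(), class = character()))
  }
  res <- do.call(rbind, out)
  res$length_mb <- (res$end_bp - res$start_bp) / 1e6
  res$class <- roh_class_of(res$length_mb)
  res[, c("sample", "pop", "chr", "start_bp", "end_bp", "n_snps",
          "n_het", "n_missing", "length_mb", "class")]
}

## single genotype vector scan: two-pointer maximal windows + greedy overlap
## resolution; returns NULL or a data.frame of runs
roh_scan_one <- function(x, bp, params) {
  n <- length(x)
  if (n == 0) return(NULL)
  het <- !is.na(x) & x == 1L
  mis <- is.na(x)
  ch <- cumsum(het); cm <- cumsum(mis)
  nh <- function(i, j) ch[j] - if (i > 1) ch[i - 1] else 0
  nm <- function(i, j) cm[j] - if (i > 1) cm[i - 1] else 0
  ## two-pointer: e[s] = furthest end with constraints satisfied
  starts <- integer(0); ends <- integer(0)
  e <- 0L
  prev_e <- 0L
  for (s in seq_len(n)) {
    if (e < s) e <- s - 1L
    while (e < n && nh(s, e + 1L) <= params$max_het &&
           nm(s, e + 1L) <= params$max_missing) e <- e + 1L
    ## window [s, e]; left-maximal iff s == 1 or previous window ended earlier
    if (e >= s && (s == 1L || e > prev_e)) {
      starts <- c(starts, s); ends <- c(ends, e)
    }
    prev_e <- e
  }
  if (!length(starts)) return(NULL)
  len_mb <- (bp[ends] - bp[starts]) / 1e6
  nsnp <- ends - starts + 1L
  keep <- nsnp >= params$min_snps & len_mb >= params$min_length_mb
  starts <- starts[keep]; ends <- ends[keep]; len_mb <- len_mb[keep]
  if (!length(starts)) return(NULL)
  ## greedy overlap resolution: longer first, ties leftmost
  ord <- order(-len_mb, starts)
  acc <- logical(0); a_s <- integer(0); a_e <- integer(0)
  sel <- integer(0)
  for (k in ord) {
    if (!any(starts[k] <= a_e & ends[k] >= a_s)) {
      sel <- c(sel, k); a_s <- c(a_s, starts[k]); a_e <- c(a_e, ends[k])
    }
  }
  sel <- sort(sel)
  data.frame(start_bp = bp[starts[sel]], end_bp = bp[ends[sel]],
             n_snps = ends[sel] - starts[sel] + 1L,
             n_het = vapply(sel, function(k) nh(starts[k], ends[k]), 0),
             n_missing = vapply(sel, function(k) nm(starts[k], ends[k]), 0))
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' `F_ROH = L_ROH / L_AUTO`: the summed ROH length of an individual divided by
#' the autosomal genome length. The default `l_auto` is the goat autosome
#' length of 2399.4 Mb; pass the simulated genome length when working with
#' synthetic data. Also returns the per-length-class decomposition, which sums
#' to the total.
#'
#' @param segments ROH table from [detect_roh()].
#' @param samples character vector of all sample ids (samples without ROH get
#'   F_ROH = 0).
#' @param l_auto autosomal genome length in Mb.
#' @return data.frame with `sample`, `l_roh_mb`, `froh` and one `froh_<class>`
#'   column per length class.
#' @export
froh <- function(segments, samples, l_auto = 2399.4) {
  stopifnot(l_auto > 0)
  cl <- roh_classes()
  out <- data.frame(sample = samples,
                    l_roh_mb = 0, froh = 0, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cl))) out[[paste0("froh_", cl$class[k])]] <- 0
  if (nrow(segments)) {
    tot <- tapply(segments$length_mb, segments$sample, sum)
    idx <- match(names(tot), samples)
    out$l_roh_mb[idx] <- as.numeric(tot)
    out$froh[idx] <- as.numeric(tot) / l_auto
    for (k in seq_len(nrow(cl))) {
      sk <- segments[segments$class == cl$class[k], ]
      if (!nrow(sk)) next
      tk <- tapply(sk$length_mb, sk$sample, sum)
      out[[paste0("froh_", cl$class[k])]][match(names(tk), samples)] <-
        as.numeric(tk) / l_auto
    }
  }
  out
}

#' Excess-homozygosity inbreeding coefficient F_HOM
#'
#' Per sample, `F_HOM = (O - E) / (N - E)` where `O` is the observed number of
#' homozygous genotypes, `N` the number of non-missing genotypes, and `E` the
#' expected homozygote count under Hardy-Weinberg using the small-sample
#' corrected heterozygosity `2pq * 2n/(2n - 1)` per marker (`n` = non-missing
#' samples at the marker), summed over the sample's non-missing markers.
#' Frequencies are computed from all samples in `g`.
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with `sample`, `O`, `E`, `N`, `fhom` (`NA` where
#'   `N = E`, i.e. nothing informative).
#' @export
fhom <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- allele_freq(g)
  nonmiss <- colSums(!is.na(g$geno))
  h_exp <- 2 * p * (1 - p) * ifelse(nonmiss > 1,
                                    2 * nonmiss / (2 * nonmiss - 1), 0)
  obs_mat <- !is.na(g$geno)
  O <- rowSums(g$geno != 1L, na.rm = TRUE)
  N <- rowSums(obs_mat)
  E <- as.numeric(obs_mat %*% (1 - h_exp))
  f <- ifelse(abs(N - E) < 1e-12, NA_real_, (O - E) / (N - E))
  data.frame(sample = rownames(g$geno), O = O, E = E, N = N, fhom = f,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize ROH by breed, length class and chromosome
#'
#' Per-chromosome coverage follows the carrier convention: summed ROH length
#' on the chromosome divided by the number of individuals carrying at least
#' one ROH there (the mean carrier ROH length), then divided by the
#' chromosome length and expressed as a percentage. Per-class per-breed means
#' divide the class length sum by the total number of individuals of the
#' breed (carriers or not).
#'
#' @param segments ROH table from [detect_roh()].
#' @param pop named character vector: population label per sample id (all
#'   samples, so breed sizes count non-carriers).
#' @param chrom_lengths_mb named numeric vector of chromosome lengths (Mb).
#' @return list with data.frames `by_breed`, `by_class`, `by_chromosome`,
#'   `per_individual`.
#' @export
roh_summary <- function(segments, pop, chrom_lengths_mb) {
  breeds <- sort(unique(as.character(pop)))
  cl <- roh_classes()
  per_ind <- data.frame(sample = names(pop), pop = as.character(pop),
                        n_roh = 0L, sum_mb = 0, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    cnt <- table(segments$sample)
    smb <- tapply(segments$length_mb, segments$sample, sum)
    i <- match(names(cnt), per_ind$sample)
    per_ind$n_roh[i] <- as.integer(cnt)
    per_ind$sum_mb[match(names(smb), per_ind$sample)] <- as.numeric(smb)
  }
  by_breed <- do.call(rbind, lapply(breeds, function(b) {
    sb <- segments[segments$pop == b, , drop = FALSE]
    ind <- per_ind[per_ind$pop == b, ]
    data.frame(pop = b, n_ind = nrow(ind), n_roh = nrow(sb),
               mean_n_roh = mean(ind$n_roh),
               min_n_roh = min(ind$n_roh), max_n_roh = max(ind$n_roh),
               mean_length_mb = if (nrow(sb)) mean(sb$length_mb) else NA,
               min_length_mb = if (nrow(sb)) min(sb$length_mb) else NA,
               max_length_mb = if (nrow(sb)) max(sb$length_mb) else NA,
               mean_sum_mb = mean(ind$sum_mb))
  }))
  by_class <- do.call(rbind, lapply(breeds, function(b) {
    sb <- segments[segments$pop == b, , drop = FALSE]
    nb <- sum(pop == b)
    cc <- vapply(cl$class, function(k) sum(sb$class == k), 0)
    data.frame(pop = b, class = cl$class, count = cc,
               frequency = if (nrow(sb)) cc / nrow(sb) else 0,
               mean_sum_mb = vapply(cl$class, function(k)
                 sum(sb$length_mb[sb$class == k]) / nb, 0))
  }))
  chroms <- names(chrom_lengths_mb)
  by_chromosome <- do.call(rbind, lapply(chroms, function(ch) {
    sc <- segments[segments$chr == ch, , drop = FALSE]
    carriers <- length(unique(sc$sample))
    cov <- if (carriers > 0)
      (sum(sc$length_mb) / carriers) / chrom_lengths_mb[[ch]] * 100 else 0
    data.frame(chr = ch, n_roh = nrow(sc), n_carriers = carriers,
               coverage_pct = cov)
  }))
  list(by_breed = by_breed, by_class = by_class,
       by_chromosome = by_chromosome, per_individual = per_ind)
}

#' Per-SNP ROH occurrence and ROH islands
#'
#' For every SNP, the occurrence is the share of samples whose ROH covers its
#' position. Islands are maximal runs of consecutive SNPs whose occurrence
#' exceeds `threshold`; they flag genomic regions of shared homozygosity
#' (putative selection footprints).
#'
#' @param segments ROH table from [detect_roh()].
#' @param g the [genotype_matrix()] the segments came from (defines the SNP
#'   grid and the sample universe).
#' @param threshold occurrence fraction above which a SNP belongs to an
#'   island, in (0, 1).
#' @return list with `per_snp` (chr, bp, id, occurrence_pct) and `islands`
#'   (chr, start_bp, end_bp, n_snps, peak_pct).
#' @export
roh_islands <- function(segments, g, threshold = 0.45) {
  stopifnot(threshold > 0, threshold < 1)
  n <- n_samples(g)
  per_snp <- data.frame(chr = g$map$chr, bp = g$map$bp, id = g$map$id,
                        occurrence_pct = 0, stringsAsFactors = FALSE)
  islands <- list()
  for (ch in unique(g$map$chr)) {
    jj <- which(g$map$chr == ch)
    bp <- g$map$bp[jj]
    cover <- numeric(length(jj))
    sc <- segments[segments$chr == ch, , drop = FALSE]
    for (k in seq_len(nrow(sc)))
      cover <- cover + (bp >= sc$start_bp[k] & bp <= sc$end_bp[k])
    occ <- cover / n
    per_snp$occurrence_pct[jj] <- occ * 100
    above <- occ > threshold
    if (any(above)) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        islands[[length(islands) + 1]] <-
          data.frame(chr = ch, start_bp = bp[starts[k]], end_bp = bp[ends[k]],
                     n_snps = r$lengths[k],
                     peak_pct = max(occ[starts[k]:ends[k]]) * 100)
      }
    }
  }
  islands <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chr = character(), start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), peak_pct = numeric())
  list(per_snp = per_snp, islands = islands)
}

#' Signed distance from a region start to a gene start
#'
#' Convention for reporting how far a gene lies from an ROH region on the
#' same chromosome: gene start minus region start, in Mb, sign preserved
#' (negative when the gene precedes the region).
#'
#' @param region_start_bp,gene_start_bp 1-based positions on one chromosome.
#' @return distance in Mb.
#' @export
region_gene_distance <- function(region_start_bp, gene_start_bp) {
  (gene_start_bp - region_start_bp) / 1e6
}
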