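#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: with `k` copies of the counted allele
#' among `2n` non-missing alleles, `pi = 2 k (2n - k) / (2n (2n - 1))` — the
#' proportion of pairwise allele differences at the site.
#'
#' @param g a [genotype_matrix()] subset to one population/group.
#' @return numeric vector of per-marker pi (`NA` with < 2 called samples).
#' @export
site_pi <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  k <- colSums(g$geno, na.rm = TRUE)
  an <- 2 * colSums(!is.na(g$geno))
  ifelse(an >= 4, 2 * k * (an - k) / (an * (an - 1)), NA_real_)
}

#' Z-standardize FST values
#'
#' `Z = (fst - mean) / sd` over all scanned SNPs, using the population
#' (n-denominator) standard deviation. `NA` values are ignored for the
#' moments and propagate through.
#'
#' @param fst numeric vector of per-SNP FST.
#' @return numeric vector with sample mean 0 and sd 1 over non-missing SNPs.
#' @export
zfst <- function(fst) {
  x <- fst[!is.na(fst)]
  if (length(x) < 2) stop("need at least two FST values to standardize")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("constant FST values cannot be standardized (sd = 0)")
  (fst - mean(x)) / s
}

#' Extended haplotype homozygosity from a core marker
#'
#' `EHH(x)` is the probability that two random distinct haplotypes are
#' identical over the markers from the core out to `x` (inclusive; the core
#' itself enters the comparison at the first extension step, so
#' `EHH(core) = 1` and the curve is non-increasing with distance). Computed
#' over all haplotypes of the set jointly — the unstandardized
#' cross-population variant.
#'
#' @param hap binary haplotype matrix (haplotypes x markers) on one
#'   chromosome, markers in map order.
#' @param core core marker column index.
#' @return list with `left` and `right`: data.frames of `marker` (column
#'   index) and `ehh`, ordered outward from the core; both include the core
#'   itself with `ehh = 1`.
#' @export
ehh <- function(hap, core) {
  n <- nrow(hap)
  if (n < 2) stop("EHH needs at least two haplotypes")
  m <- ncol(hap)
  stopifnot(core >= 1, core <= m)
  one_side <- function(idx) {
    grp <- rep(1L, n)
    out <- numeric(length(idx))
    for (t in seq_along(idx)) {
      key <- grp * 2L + hap[, idx[t]]
      grp <- match(key, unique(key))
      cnt <- tabulate(grp)
      out[t] <- sum(cnt * (cnt - 1)) / (n * (n - 1))
    }
    out
  }
  right_idx <- if (core < m) (core + 1):m else integer(0)
  left_idx <- if (core > 1) (core - 1):1 else integer(0)
  ## the core allele joins the prefix at the first step outward
  right <- one_side(c(core, right_idx))[-1]
  left <- one_side(c(core, left_idx))[-1]
  list(left = data.frame(marker = c(core, left_idx),
                         ehh = c(1, left)),
       right = data.frame(marker = c(core, right_idx),
                          ehh = c(1, right)))
}

## EHH stepper used by the XP-EHH integral: walks outward refining the
## identity partition of several haplotype groups at once, integrating by
## trapezoid over Morgans until the pooled EHH drops below `min_ehh` or the
## physical extension exceeds `max_ext_bp`.
xpehh_integrate <- function(hapA, hapB, cm, bp, core,
                            min_ehh = 0.05, max_ext_bp = 2.5e6) {
  nA <- nrow(hapA); nB <- nrow(hapB)
  pool <- rbind(hapA, hapB)
  np <- nrow(pool)
  homo <- function(grp, n) {
    cnt <- tabulate(grp)
    sum(cnt * (cnt - 1)) / (n * (n - 1))
  }
  refine <- function(grp, al) {
    key <- grp * 2L + al
    match(key, unique(key))
  }
  walk <- function(idx) {
    gA <- rep(1L, nA); gB <- rep(1L, nB); gP <- rep(1L, np)
    eA <- 1; eB <- 1
    iA <- 0; iB <- 0
    prev_cm <- cm[core]
    for (t in seq_along(idx)) {
      x <- idx[t]
      al <- pool[, x]
      gP <- refine(gP, al)
      gA <- refine(gA, al[seq_len(nA)])
      gB <- refine(gB, al[nA + seq_len(nB)])
      if (t == 1) next   # the core is the origin: EHH = 1, zero extension
      eP <- homo(gP, np)
      eA_new <- homo(gA, nA)
      eB_new <- homo(gB, nB)
      if (eP < min_ehh || abs(bp[x] - bp[core]) > max_ext_bp) break
      step <- abs(cm[x] - prev_cm) / 100
      iA <- iA + step * (eA + eA_new) / 2
      iB <- iB + step * (eB + eB_new) / 2
      eA <- eA_new; eB <- eB_new
      prev_cm <- cm[x]
    }
    c(iA, iB)
  }
  right_idx <- if (core < length(cm)) core:length(cm) else core
  left_idx <- if (core > 1) core:1 else core
  r <- walk(right_idx)
  l <- walk(left_idx)
  c(iA = r[1] + l[1], iB = r[2] + l[2])
}

#' Raw XP-EHH score at one core marker
#'
#' `XP-EHH = ln(I_A / I_B)` where `I` is the trapezoid integral of EHH over
#' genetic distance in both directions from the core, truncated where the
#' combined-population EHH falls below `min_ehh` (and at a physical extension
#' bound). Positive scores indicate longer haplotype homozygosity — a sweep —
#' in population A; swapping the populations flips the sign.
#'
#' @param hA,hB [haplotype_set()]s of the two populations over the same
#'   markers (one chromosome at a time).
#' @param core core marker index.
#' @param min_ehh truncation level for the combined-population EHH.
#' @param max_ext_bp maximal physical extension either side of the core.
#' @return raw score (`NA` with a log entry when either integral is 0).
#' @export
xpehh <- function(hA, hB, core, min_ehh = 0.05, max_ext_bp = 2.5e6) {
  stopifnot(inherits(hA, "haplotype_set"), inherits(hB, "haplotype_set"))
  if (!identical(hA$map$id, hB$map$id))
    stop("the two populations must be phased over the same markers")
  if (length(unique(hA$map$chr)) != 1)
    stop("xpehh expects markers from a single chromosome")
  mapA <- impute_cm(hA$map)
  ii <- xpehh_integrate(hA$hap, hB$hap, mapA$cM, mapA$bp, core,
                        min_ehh, max_ext_bp)
  if (ii["iA"] <= 0 || ii["iB"] <= 0) {
    message("EHH integral is zero at core ", core, "; site skipped")
    return(NA_real_)
  }
  unname(log(ii["iA"] / ii["iB"]))
}

#' Standardize raw XP-EHH scores
#'
#' Centers and scales the raw scores to mean 0, unit variance over all
#' scanned cores (population sd). Affine-invariant: positively rescaled and
#' shifted inputs standardize identically.
#'
#' @param raw numeric vector of raw scores.
#' @return standardized scores.
#' @export
standardize_xpehh <- function(raw) {
  x <- raw[!is.na(raw)]
  if (length(x) < 2) stop("need at least two scores to standardize")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("constant scores cannot be standardized (sd = 0)")
  (raw - mean(x)) / s
}

#' Three-statistic selection scan between two population groups
#'
#' Contrasts a high and a low group per SNP: Weir-Cockerham FST (and its
#' Z-score), nucleotide diversity in each group with the ratio oriented as
#' `pi_low / pi_high` (elevated values flag diversity loss in the high
#' group), and — when phased haplotypes are supplied — XP-EHH with the high
#' group as test population A.
#'
#' @param g a [genotype_matrix()].
#' @param high,low character vectors of population labels forming the two
#'   groups.
#' @param haps optional [haplotype_set()] covering the same markers.
#' @param xpehh_step compute XP-EHH at every `xpehh_step`-th marker (cost
#'   control; 1 scans all markers).
#' @param min_ehh,max_ext_bp truncation controls passed to [xpehh()].
#' @return data.frame (one row per SNP): `chr`, `bp`, `id`, `fst`, `zfst`,
#'   `pi_high`, `pi_low`, `pi_ratio`, `log2_pi_ratio`, `xpehh_raw`,
#'   `xpehh_std`.
#' @export
selection_scan <- function(g, high, low, haps = NULL, xpehh_step = 1,
                           min_ehh = 0.05, max_ext_bp = 2.5e6) {
  stopifnot(all(c(high, low) %in% g$pop))
  grp <- ifelse(g$pop %in% high, "high", ifelse(g$pop %in% low, "low", NA))
  gg <- g[!is.na(grp), ]
  gg$pop <- grp[!is.na(grp)]
  per <- weir_cockerham_fst(gg, mode = "per-marker")
  pi_h <- site_pi(gg[gg$pop == "high", ])
  pi_l <- site_pi(gg[gg$pop == "low", ])
  ratio <- ifelse(pi_h > 0, pi_l / pi_h, NA_real_)
  out <- data.frame(chr = gg$map$chr, bp = gg$map$bp, id = gg$map$id,
                    fst = per$fst, zfst = zfst(per$fst),
                    pi_high = pi_h, pi_low = pi_l,
                    pi_ratio = ratio, log2_pi_ratio = log2(ratio),
                    xpehh_raw = NA_real_, xpehh_std = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(haps)) {
    stopifnot(inherits(haps, "haplotype_set"))
    hmap <- impute_cm(haps$map)
    hi_rows <- rep(haps$pop %in% high, each = 2)
    lo_rows <- rep(haps$pop %in% low, each = 2)
    raw <- rep(NA_real_, nrow(hmap))
    for (ch in unique(hmap$chr)) {
      jj <- which(hmap$chr == ch)
      cores <- jj[seq(1, length(jj), by = xpehh_step)]
      hapA <- haps$hap[hi_rows, jj, drop = FALSE]
      hapB <- haps$hap[lo_rows, jj, drop = FALSE]
      for (cix in seq_along(cores)) {
        loc <- match(cores[cix], jj)
        ii <- xpehh_integrate(hapA, hapB, hmap$cM[jj], hmap$bp[jj], loc,
                              min_ehh, max_ext_bp)
        raw[cores[cix]] <-
          if (ii["iA"] > 0 && ii["iB"] > 0) log(ii["iA"] / ii["iB"]) else NA
      }
    }
    idx <- match(hmap$id, out$id)
    ok <- !is.na(idx)
    out$xpehh_raw[idx[ok]] <- raw[ok]
    if (sum(!is.na(out$xpehh_raw)) >= 2)
      out$xpehh_std <- ifelse(is.na(out$xpehh_raw), NA,
                              standardize_xpehh(out$xpehh_raw))
  }
  out
}

## top-k outlier flag: the ceiling(q * n_valid) largest values
top_flag <- function(x, q) {
  flag <- rep(FALSE, length(x))
  valid <- which(!is.na(x))
  if (!length(valid)) return(flag)
  k <- ceiling(q * length(valid))
  flag[valid[order(-x[valid])[seq_len(k)]]] <- TRUE
  flag
}

#' Call candidate selection regions by outlier intersection
#'
#' Flags the empirical top `q_fst` of FST, top `q_pi` of the pi-ratio and top
#' `q_xpehh` of standardized XP-EHH (each as the `ceiling(q * n)` largest
#' values), reports the two-way (FST and pi) and three-way intersection
#' counts, and turns candidate SNPs — those in the FST-and-pi intersection or
#' in the XP-EHH outlier set — into regions of core position +/- `extend_bp`,
#' merged when overlapping and clipped at chromosome ends when lengths are
#' supplied. Genes are attached by interval intersection when an annotation
#' table is given.
#'
#' @param rows scan table from [selection_scan()].
#' @param q_fst,q_pi,q_xpehh empirical tail fractions.
#' @param extend_bp extension either side of a candidate SNP.
#' @param annotation optional gene table (`chr`, `start_bp`, `end_bp`,
#'   `gene`), e.g. from [read_genes()].
#' @param chrom_lengths_bp optional named vector for clipping.
#' @return list with `rows` (input plus `out_fst`, `out_pi`, `out_xpehh`
#'   flags), `venn` (named counts), `regions` (chr, start_bp, end_bp, n_snps,
#'   stats, genes).
#' @export
call_candidates <- function(rows, q_fst = 0.01, q_pi = 0.01, q_xpehh = 0.001,
                            extend_bp = 1e5, annotation = NULL,
                            chrom_lengths_bp = NULL) {
  rows$out_fst <- top_flag(rows$fst, q_fst)
  rows$out_pi <- top_flag(rows$pi_ratio, q_pi)
  rows$out_xpehh <- top_flag(rows$xpehh_std, q_xpehh)
  venn <- c(fst = sum(rows$out_fst), pi = sum(rows$out_pi),
            xpehh = sum(rows$out_xpehh),
            fst_pi = sum(rows$out_fst & rows$out_pi),
            fst_xpehh = sum(rows$out_fst & rows$out_xpehh),
            pi_xpehh = sum(rows$out_pi & rows$out_xpehh),
            fst_pi_xpehh = sum(rows$out_fst & rows$out_pi & rows$out_xpehh))
  cand <- rows[(rows$out_fst & rows$out_pi) | rows$out_xpehh, , drop = FALSE]
  regions <- merge_candidate_regions(cand, extend_bp, chrom_lengths_bp)
  if (nrow(regions) && !is.null(annotation)) {
    regions$genes <- vapply(seq_len(nrow(regions)), function(k) {
      hit <- annotation$chr == regions$chr[k] &
        annotation$start_bp <= regions$end_bp[k] &
        annotation$end_bp >= regions$start_bp[k]
      paste(annotation$gene[hit], collapse = ",")
    }, "")
  } else if (nrow(regions)) {
    regions$genes <- ""
  }
  list(rows = rows, venn = venn, regions = regions)
}

merge_candidate_regions <- function(cand, extend_bp, chrom_lengths_bp) {
  if (!nrow(cand))
    return(data.frame(chr = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      stats = character()))
  cand$stat <- paste0(ifelse(cand$out_fst, "F", ""),
                      ifelse(cand$out_pi, "P", ""),
                      ifelse(cand$out_xpehh, "X", ""))
  out <- list()
  for (ch in unique(cand$chr)) {
    cc <- cand[cand$chr == ch, ]
    cc <- cc[order(cc$bp), ]
    s <- pmax(cc$bp - extend_bp, 1)
    e <- cc$bp + extend_bp
    if (!is.null(chrom_lengths_bp) && ch %in% names(chrom_lengths_bp))
      e <- pmin(e, chrom_lengths_bp[[ch]])
    cur_s <- s[1]; cur_e <- e[1]; n <- 1L; st <- cc$stat[1]
    flush <- function() data.frame(chr = ch, start_bp = cur_s, end_bp = cur_e,
                                   n_snps = n, stats = st)
    for (k in seq_len(nrow(cc))[-1]) {
      if (s[k] <= cur_e) {
        cur_e <- max(cur_e, e[k]); n <- n + 1L
        st <- paste(unique(c(strsplit(st, ";")[[1]], cc$stat[k])),
                    collapse = ";")
      } else {
        out[[length(out) + 1]] <- flush()
        cur_s <- s[k]; cur_e <- e[k]; n <- 1L; st <- cc$stat[k]
      }
    }
    out[[length(out) + 1]] <- flush()
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a gene-interval annotation table
#'
#' BED input (0-based half-open) is converted to 1-based inclusive through
#' [from_bed()]; GFF/GTF goes through rtracklayer when installed.
#'
#' @param path BED (3+ columns, optional 4th = name) or GFF/GTF file.
#' @param format `"auto"` by extension, `"bed"` or `"gff"`.
#' @return data.frame `chr`, `start_bp`, `end_bp`, `gene`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE))
      "gff" else "bed"
  if (format == "bed") {
    b <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    coords <- from_bed(b[[2]], b[[3]])
    data.frame(chr = as.character(b[[1]]),
               start_bp = coords[, 1], end_bp = coords[, 2],
               gene = if (ncol(b) >= 4) as.character(b[[4]])
                      else paste0("feature", seq_len(nrow(b))),
               stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GFF annotation requires the 'rtracklayer' package")
    gr <- rtracklayer::import(path)
    nm <- if (!is.null(gr$Name)) gr$Name else
      if (!is.null(gr$ID)) gr$ID else paste0("feature", seq_along(gr))
    data.frame(chr = as.character(GenomeInfoDb::seqnames(gr)),
               start_bp = BiocGenerics::start(gr),
               end_bp = BiocGenerics::end(gr),
               gene = as.character(nm), stringsAsFactors = FALSE)
  }
}
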