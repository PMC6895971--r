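#' Read PLINK genotype files
#'
#' Reads a PLINK fileset (text `.ped`/`.map` or binary SNP-major
#' `.bed`/`.bim`/`.fam`) into a [genotype_matrix()]. The family-id column is
#' used as the population label (override with [assign_populations()]).
#'
#' For binary input the counted allele is the `.bim` allele-1 column, with no
#' re-polarization. Text input carries no allele-1 designation, so the counted
#' allele of each marker is the lexicographically smaller of its two observed
#' alleles, and the unobservable second allele of a monomorphic marker is
#' recorded as `"0"` (deterministic; a binary round trip is always
#' code-exact, a text round trip preserves the genotype information exactly
#' but re-expresses codes relative to its own counted allele — align via the
#' allele labels to compare).
#'
#' @param prefix path prefix (without extension).
#' @param dialect `"auto"` (binary if a `.bed` exists), `"binary"` or `"text"`.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix, dialect = c("auto", "binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (file.exists(paste0(prefix, ".bed"))) "binary" else "text"
  if (dialect == "binary") read_plink_bed(prefix) else read_plink_ped(prefix)
}

read_map_file <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chr = character(), id = character(),
                      cM = numeric(), bp = numeric()))
  m <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("chr", "id", "cM", "bp"))
  m$chr <- as.character(m$chr)
  m
}

read_plink_ped <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map <- read_map_file(paste0(prefix, ".map"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0)
    return(genotype_matrix(matrix(integer(), 0, m), map, pop = character()))
  tok <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(tok)
  bad <- which(len != 6 + 2 * m)
  if (length(bad))
    stop("parse error in .ped line ", bad[1], ": expected ", 6 + 2 * m,
         " fields, found ", len[bad[1]],
         " (marker index ", (len[bad[1]] - 6) %/% 2 + 1, ")")
  tok <- do.call(rbind, tok)
  fam <- tok[, 1]
  iid <- tok[, 2]
  a1 <- tok[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(m), drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  counted <- character(m); other <- character(m)
  for (j in seq_len(m)) {
    als <- c(a1[, j], a2[, j])
    obs <- sort(unique(als[als != "0"]))
    if (length(obs) > 2)
      stop("marker ", map$id[j], " has more than two alleles")
    ## monomorphic / all-missing: the second allele is unobservable in text
    ## input; PLINK marks it "0"
    if (length(obs) == 0) obs <- c("0", "0")
    if (length(obs) == 1) obs <- c(obs, "0")
    counted[j] <- obs[1]; other[j] <- obs[2]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == obs[1]) + (a2[, j] == obs[1])
    geno[miss, j] <- NA_integer_
  }
  rownames(geno) <- iid
  genotype_matrix(geno, map, pop = fam, counted = counted, other = other)
}

read_plink_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cM", "bp", "A1", "A2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: ", bed_path, " lacks the PLINK .bed magic bytes")
  if (raw[3] != as.raw(0x01))
    stop("format error: ", bed_path, " is not SNP-major")
  bpm <- ceiling(n / 4)   # bytes per marker
  if (length(raw) - 3 != bpm * m)
    stop("parse error: .bed payload is ", length(raw) - 3,
         " bytes, expected ", bpm * m)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpm, ncol = m)
  ## unpack 2-bit genotypes, sample-fastest within each marker
  pair_shift <- c(0L, 2L, 4L, 6L)
  codes <- matrix(NA_integer_, n, m)
  lookup <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11 -> copies of A1
  for (s in if (n > 0) 1:4 else integer()) {
    idx <- which((seq_len(n) - 1L) %% 4L == s - 1L)  # byte slot s samples
    if (!length(idx)) next
    byte_rows <- (idx - 1) %/% 4 + 1
    bytes <- body[byte_rows, , drop = FALSE]
    two_bits <- (bytes %/% bitwShiftL(1L, pair_shift[s])) %% 4L
    codes[idx, ] <- lookup[two_bits + 1L]
  }
  rownames(codes) <- as.character(fam[[2]])
  map <- bim[, c("chr", "id", "cM", "bp")]
  map$chr <- as.character(map$chr)
  genotype_matrix(codes, map, pop = as.character(fam[[1]]),
                  counted = as.character(bim$A1), other = as.character(bim$A2))
}

#' Write PLINK genotype files
#'
#' Writes a [genotype_matrix()] as a PLINK fileset, re-readable by
#' [read_plink()] to an identical matrix. The counted allele is written as
#' allele 1 (`.bim` A1 / first allele of each text pair), so writing never
#' changes the counted-allele designation. Binary output is SNP-major with the
#' standard three magic bytes. This is also the export path for external
#' model-based clustering tools that consume PLINK input.
#'
#' @param g a [genotype_matrix()].
#' @param prefix output path prefix.
#' @param dialect `"binary"` or `"text"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  if (dialect == "binary") write_plink_bed(g, prefix) else write_plink_ped(g, prefix)
  invisible(prefix)
}

write_plink_ped <- function(g, prefix) {
  n <- n_samples(g); m <- n_markers(g)
  utils::write.table(g$map[, c("chr", "id", "cM", "bp")],
                     paste0(prefix, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  con <- file(paste0(prefix, ".ped"), "w"); on.exit(close(con))
  if (n == 0) return(invisible(prefix))
  for (i in seq_len(n)) {
    gi <- g$geno[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, g$counted, g$other))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, g$counted, g$other))
    alle <- character(2 * m)
    if (m > 0) { alle[c(TRUE, FALSE)] <- a1; alle[c(FALSE, TRUE)] <- a2 }
    writeLines(paste(c(g$pop[i], rownames(g$geno)[i], "0", "0", "0", "-9",
                       alle), collapse = " "), con)
  }
  invisible(prefix)
}

write_plink_bed <- function(g, prefix) {
  n <- n_samples(g); m <- n_markers(g)
  bim <- cbind(g$map[, c("chr", "id", "cM", "bp")], A1 = g$counted, A2 = g$other)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  rn <- rownames(g$geno); if (is.null(rn)) rn <- character(0)
  fam <- data.frame(g$pop, rn, rep(0, n), rep(0, n), rep(0, n), rep(-9, n))
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  bpm <- ceiling(n / 4)
  payload <- raw(0)
  if (m > 0 && n > 0) {
    code2bits <- function(x) {           # copies of A1 -> 2-bit code
      b <- integer(length(x))
      b[is.na(x)] <- 1L
      b[!is.na(x) & x == 2L] <- 0L
      b[!is.na(x) & x == 1L] <- 2L
      b[!is.na(x) & x == 0L] <- 3L
      b
    }
    bits <- matrix(0L, 4 * bpm, m)
    bits[seq_len(n), ] <- apply(g$geno, 2, code2bits)
    ## pad slots beyond n are 0 (= hom A1) per the format's ignore convention
    bytes <- bits[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
             4L * bits[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
             16L * bits[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
             64L * bits[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
    payload <- as.raw(as.vector(bytes))
  } else if (m > 0) {
    payload <- raw(0)
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), payload), paste0(prefix, ".bed"))
  invisible(prefix)
}
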