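#' Read phased haplotypes
#'
#' Reads externally phased haplotypes into a [haplotype_set()], either from a
#' VCF whose GT fields are all phased (`0|1` style, parsed with the vcfR
#' package) or from an Oxford `haps`/`sample` file pair. Any unphased GT in a
#' VCF is an error naming the offending site: downstream extended-haplotype
#' statistics are meaningless on unphased data.
#'
#' Haplotype alleles are stored as 0/1 where 1 is the VCF ALT (respectively
#' the `haps` second allele), which becomes the counted allele.
#'
#' @param path VCF file, or the `.haps` file of a haps/sample pair.
#' @param format `"auto"` (by extension), `"vcf"` or `"haps"`.
#' @param sample_path the `sample` file; defaults to `path` with a `.sample`
#'   extension.
#' @return a [haplotype_set()], two rows per sample in file order.
#' @export
read_haplotypes <- function(path, format = c("auto", "vcf", "haps"),
                            sample_path = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "haps"
  if (format == "vcf") read_haps_vcf(path) else read_haps_oxford(path, sample_path)
}

read_haps_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF haplotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (anyNA(gt)) stop("missing GT not allowed in phased haplotype input")
  bad <- !grepl("^[01]\\|[01]$", gt)
  dim(bad) <- dim(gt)
  unph <- which(bad, arr.ind = TRUE)
  if (nrow(unph) > 0) {
    fx <- v@fix[unph[1, "row"], ]
    stop("unphased or non-biallelic GT '", gt[unph[1, , drop = FALSE]],
         "' at site ", fx["CHROM"], ":", fx["POS"],
         " sample ", colnames(gt)[unph[1, "col"]])
  }
  n <- ncol(gt); m <- nrow(gt)
  hap <- matrix(0L, 2 * n, m)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), m, n)
  a2 <- matrix(as.integer(substr(gt, 3, 3)), m, n)
  hap[seq(1, 2 * n, 2), ] <- t(a1)
  hap[seq(2, 2 * n, 2), ] <- t(a2)
  pos <- as.numeric(v@fix[, "POS"])
  map <- data.frame(chr = as.character(v@fix[, "CHROM"]),
                    id = ifelse(is.na(v@fix[, "ID"]) | v@fix[, "ID"] == ".",
                                paste0(v@fix[, "CHROM"], ":", pos),
                                v@fix[, "ID"]),
                    cM = 0, bp = pos, stringsAsFactors = FALSE)
  haplotype_set(hap, map, samples = colnames(gt))
}

read_haps_oxford <- function(path, sample_path = NULL) {
  if (is.null(sample_path))
    sample_path <- sub("\\.haps$", ".sample", path)
  h <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  smp <- utils::read.table(sample_path, header = TRUE,
                           stringsAsFactors = FALSE)[-1, , drop = FALSE]
  ids <- as.character(smp[[2]])
  m <- nrow(h)
  hap <- t(as.matrix(h[, -(1:5), drop = FALSE]))
  if (nrow(hap) != 2 * length(ids))
    stop("haps file has ", nrow(hap), " haplotype columns but sample file has ",
         length(ids), " samples")
  storage.mode(hap) <- "integer"
  map <- data.frame(chr = as.character(h[[1]]), id = as.character(h[[2]]),
                    cM = 0, bp = as.numeric(h[[3]]), stringsAsFactors = FALSE)
  rownames(hap) <- NULL
  haplotype_set(hap, map, samples = ids)
}

#' Write haplotypes as an Oxford haps/sample pair
#'
#' @param h a [haplotype_set()].
#' @param prefix output path prefix (writes `prefix.haps`, `prefix.sample`).
#' @return `prefix`, invisibly.
#' @export
write_haplotypes <- function(h, prefix) {
  stopifnot(inherits(h, "haplotype_set"))
  tab <- cbind(h$map$chr, h$map$id, h$map$bp, "A", "B", t(h$hap))
  utils::write.table(tab, paste0(prefix, ".haps"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  smp <- rbind(c("0", "0", "0"),
               cbind(h$samples, h$samples, "0"))
  colnames(smp) <- c("ID_1", "ID_2", "missing")
  utils::write.table(smp, paste0(prefix, ".sample"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = TRUE)
  invisible(prefix)
}
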