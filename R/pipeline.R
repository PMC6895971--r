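#' Pipeline run configuration
#'
#' Collects every stage's parameters. Stages run in dependency order
#' (QC first; ROH, HBD, Ne, structure and the selection scan all consume the
#' QC survivors). Unknown configuration keys are rejected.
#'
#' @param genotypes a [genotype_matrix()], or `NULL` with `plink_prefix`.
#' @param plink_prefix PLINK fileset to load when `genotypes` is `NULL`.
#' @param haplotypes optional [haplotype_set()] for XP-EHH.
#' @param stages character subset of
#'   `c("qc", "roh", "hbd", "ne", "structure", "scan")`.
#' @param qc a [qc_params()].
#' @param roh a [roh_params()].
#' @param hbd an [hbd_model()].
#' @param l_auto autosome length (Mb) for F_ROH.
#' @param island_threshold ROH-island occurrence threshold.
#' @param ne_bins Morgan bin edges for [estimate_ne()] (NULL = default).
#' @param scan_high,scan_low population groups for the selection scan.
#' @param scan_q quantiles `c(fst, pi, xpehh)`.
#' @param extend_bp candidate-region extension.
#' @param annotation optional gene table for region annotation.
#' @param amova_perm AMOVA permutation count.
#' @param out_dir optional directory for TSV outputs.
#' @param seed seed for the stochastic stages (AMOVA permutations).
#' @param ... rejected (catches unknown keys).
#' @return list of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, plink_prefix = NULL,
                       haplotypes = NULL,
                       stages = c("qc", "roh", "hbd", "ne", "structure",
                                  "scan"),
                       qc = qc_params(), roh = roh_params(),
                       hbd = hbd_model(), l_auto = 2399.4,
                       island_threshold = 0.45, ne_bins = NULL,
                       scan_high = NULL, scan_low = NULL,
                       scan_q = c(fst = 0.01, pi = 0.01, xpehh = 0.001),
                       extend_bp = 1e5, annotation = NULL,
                       amova_perm = 100, out_dir = NULL, seed = 1, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  if (is.null(genotypes) && is.null(plink_prefix))
    stop("either genotypes or plink_prefix is required")
  if (!is.null(plink_prefix) && is.null(genotypes) &&
      !file.exists(paste0(plink_prefix, ".bed")) &&
      !file.exists(paste0(plink_prefix, ".ped")))
    stop("no PLINK fileset at prefix ", plink_prefix)
  structure(list(genotypes = genotypes, plink_prefix = plink_prefix,
                 haplotypes = haplotypes, stages = stages, qc = qc,
                 roh = roh, hbd = hbd, l_auto = l_auto,
                 island_threshold = island_threshold, ne_bins = ne_bins,
                 scan_high = scan_high, scan_low = scan_low,
                 scan_q = scan_q, extend_bp = extend_bp,
                 annotation = annotation, amova_perm = amova_perm,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order. A stage failure is
#' recorded and aborts its dependents, not independent stages. With a
#' fixed seed and config the report bundle is fully reproducible.
#'
#' @param cfg a [run_config()].
#' @return list of class `pipeline_result` with one element per stage
#'   (`NULL` where disabled) plus `status` (per-stage "ok" / "skipped" /
#'   error message).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  status <- c(qc = "skipped", roh = "skipped", hbd = "skipped",
              ne = "skipped", structure = "skipped", scan = "skipped")
  res <- list(status = status)
  g <- cfg$genotypes
  if (is.null(g)) g <- read_plink(cfg$plink_prefix)

  run_stage <- function(name, expr) {
    if (!(name %in% cfg$stages)) return(NULL)
    tryCatch({
      v <- force(expr())
      res$status[name] <<- "ok"
      v
    }, error = function(e) {
      res$status[name] <<- paste("error:", conditionMessage(e))
      NULL
    })
  }

  res$qc <- run_stage("qc", function() apply_filters(g, cfg$qc))
  gq <- if (!is.null(res$qc)) res$qc$genotypes else g
  if ("qc" %in% cfg$stages && is.null(res$qc)) {
    res$status[setdiff(names(status), "qc")] <- "skipped (qc failed)"
    res$status <- res$status
    class(res) <- "pipeline_result"
    return(res)
  }

  res$roh <- run_stage("roh", function() {
    segs <- detect_roh(gq, cfg$roh)
    chrlen <- tapply(gq$map$bp, gq$map$chr, max) / 1e6
    list(segments = segs,
         inbreeding = merge(froh(segs, rownames(gq$geno), cfg$l_auto),
                            fhom(gq), by = "sample"),
         summary = roh_summary(segs, stats::setNames(gq$pop,
                                                     rownames(gq$geno)),
                               chrlen),
         islands = roh_islands(segs, gq, cfg$island_threshold))
  })
  res$hbd <- run_stage("hbd", function() {
    fit <- fit_hbd(gq, cfg$hbd)
    list(fit = fit, fgt = fgt_curve(fit))
  })
  res$ne <- run_stage("ne", function() {
    pops <- unique(gq$pop)
    stats::setNames(lapply(pops, function(b)
      estimate_ne(gq[gq$pop == b, ], bins = cfg$ne_bins)), pops)
  })
  res$structure <- run_stage("structure", function() {
    multi <- length(unique(gq$pop)) >= 2
    pruned <- gq[, ld_prune(gq)]
    out <- list(pca = pca_genotypes(pruned))
    if (multi) {
      out$distances <- population_distances(gq)
      out$amova <- amova(gq, n_perm = cfg$amova_perm)
      if (length(unique(gq$pop)) >= 3)
        out$nj <- nj_tree(ibs_distance(gq, by = "population"))
    }
    out
  })
  res$scan <- run_stage("scan", function() {
    if (is.null(cfg$scan_high) || is.null(cfg$scan_low))
      stop("scan requires scan_high and scan_low population groups")
    rows <- selection_scan(gq, cfg$scan_high, cfg$scan_low,
                           haps = cfg$haplotypes)
    call_candidates(rows, q_fst = cfg$scan_q[["fst"]],
                    q_pi = cfg$scan_q[["pi"]],
                    q_xpehh = cfg$scan_q[["xpehh"]],
                    extend_bp = cfg$extend_bp,
                    annotation = cfg$annotation)
  })
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  for (s in names(x$status)) cat(sprintf("  %-10s %s\n", s, x$status[s]))
  invisible(x)
}

## write the tabular report bundle (one TSV per product)
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                          quote = FALSE, sep = "\t",
                                          row.names = FALSE)
  if (!is.null(res$roh)) {
    wt(res$roh$segments, "roh_segments.tsv")
    wt(res$roh$inbreeding, "inbreeding.tsv")
    wt(res$roh$islands$per_snp, "roh_snp_occurrence.tsv")
    isl <- res$roh$islands$islands
    if (nrow(isl)) {
      bed <- to_bed(isl$start_bp, isl$end_bp)
      wt(data.frame(chr = isl$chr, start = bed[, 1], end = bed[, 2],
                    peak_pct = isl$peak_pct), "roh_islands.bed")
    }
  }
  if (!is.null(res$hbd)) wt(res$hbd$fgt, "fgt_curve.tsv")
  if (!is.null(res$ne))
    wt(do.call(rbind, Map(cbind, pop = names(res$ne), res$ne)), "ne_bins.tsv")
  if (!is.null(res$structure)) {
    wt(data.frame(sample = rownames(res$structure$pca$scores),
                  pop = res$structure$pca$pop, res$structure$pca$scores),
       "pca.tsv")
    if (!is.null(res$structure$nj))
      writeLines(res$structure$nj$newick, file.path(out_dir, "nj_tree.nwk"))
  }
  if (!is.null(res$scan)) {
    wt(res$scan$rows, "scan_rows.tsv")
    wt(data.frame(set = names(res$scan$venn), count = res$scan$venn),
       "venn_counts.tsv")
    if (nrow(res$scan$regions)) wt(res$scan$regions, "candidate_regions.tsv")
  }
  invisible(out_dir)
}
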