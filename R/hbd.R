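#' Homozygosity-by-descent mixture-HMM specification
#'
#' A K-class model: `K - 1` HBD classes whose segment lengths are exponential
#' with rates `2^1 ... 2^(K-1)` (in 1/Morgan, so class k has mean segment
#' length `1/R_k` Morgans and corresponds to ancestors roughly `R_k / 2`
#' generations back) and one non-HBD class sharing the most ancient rate
#' `2^(K-1)`. Class mixing coefficients `M_k` are estimated per individual by
#' EM; the rates stay fixed.
#'
#' @param K total number of classes (K - 1 HBD + 1 non-HBD).
#' @param rates optional rate vector of length `K` (default `2^(1:(K-1))`
#'   plus the last rate repeated for the non-HBD class).
#' @param err genotyping-error probability used by the HBD emission.
#' @return a list of class `hbd_model`.
#' @export
hbd_model <- function(K = 10, rates = NULL, err = 0.001) {
  stopifnot(K >= 2, err >= 0, err <= 0.1)
  if (is.null(rates)) rates <- c(2^seq_len(K - 1), 2^(K - 1))
  stopifnot(length(rates) == K, all(rates > 0),
            all(diff(rates[seq_len(K - 1)]) >= 0))
  structure(list(K = K, rates = rates, err = err,
                 hbd = c(rep(TRUE, K - 1), FALSE)),
            class = "hbd_model")
}

#' HBD / non-HBD emission probabilities
#'
#' An HBD class emits homozygotes: the counted-allele homozygote with
#' probability `(1 - err) * p`, the other homozygote with `(1 - err) * (1-p)`,
#' and a heterozygote only through genotyping error (`err`). The non-HBD
#' class emits Hardy-Weinberg genotype frequencies `p^2, 2pq, q^2`. Missing
#' genotypes emit 1 in every class (no information).
#'
#' @param geno genotype code 0, 1, 2 or `NA`.
#' @param p counted-allele frequency in (0, 1).
#' @param hbd `TRUE` for an HBD class.
#' @param err genotyping-error probability.
#' @return emission probability.
#' @export
hbd_emission <- function(geno, p, hbd, err = 0.001) {
  stopifnot(all(p > 0 & p < 1))
  out <- rep(1, length(geno))
  q <- 1 - p
  if (hbd) {
    out[!is.na(geno) & geno == 2] <- ((1 - err) * p)[!is.na(geno) & geno == 2]
    out[!is.na(geno) & geno == 1] <- err
    out[!is.na(geno) & geno == 0] <- ((1 - err) * q)[!is.na(geno) & geno == 0]
  } else {
    out[!is.na(geno) & geno == 2] <- (p^2)[!is.na(geno) & geno == 2]
    out[!is.na(geno) & geno == 1] <- (2 * p * q)[!is.na(geno) & geno == 1]
    out[!is.na(geno) & geno == 0] <- (q^2)[!is.na(geno) & geno == 0]
  }
  out
}

#' HBD transition matrix over a genetic distance
#'
#' Between two markers separated by `d` Morgans the chain stays in class `k`
#' with probability `exp(-R_k d)`; otherwise the current segment ends and a
#' new class is drawn from the mixing coefficients `M`. Rows sum to 1; at
#' `d = 0` the matrix is the identity, and as `d` grows every row tends to
#' `M` (the stationary mixture).
#'
#' @param d genetic distance in Morgans (>= 0).
#' @param spec an [hbd_model()].
#' @param M mixing coefficients (length K, summing to 1).
#' @return a `K x K` transition matrix.
#' @export
hbd_transition <- function(d, spec, M) {
  stopifnot(d >= 0, length(M) == spec$K, abs(sum(M) - 1) < 1e-8)
  stay <- exp(-spec$rates * d)
  diag(stay, spec$K) + (1 - stay) %o% M
}

#' Fit the HBD mixture HMM to each individual
#'
#' Per individual: mixing coefficients are estimated by EM (scaled
#' forward-backward E-step), rates stay on the fixed grid; posterior decoding
#' gives the per-marker class probabilities, whose genome averages are the
#' realized per-class autozygosities. Monomorphic markers carry no
#' information and are dropped before fitting. Allele frequencies default to
#' the sample in `g`.
#'
#' @param g a [genotype_matrix()] (cM positions used; imputed at 1 cM/Mb when
#'   absent).
#' @param spec an [hbd_model()].
#' @param freq optional per-marker counted-allele frequencies.
#' @param max_iter,tol EM stopping rule (log-likelihood gain below `tol`).
#' @param keep_posterior return the per-marker posterior matrices.
#' @return list of class `hbd_result`: `autozygosity` (samples x K matrix of
#'   genome-averaged class posteriors), `mixing` (fitted M per sample),
#'   `loglik`, `converged`, `spec`, and optionally `posterior`.
#' @export
fit_hbd <- function(g, spec = hbd_model(), freq = NULL,
                    max_iter = 1000, tol = 1e-6, keep_posterior = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(spec, "hbd_model"))
  map <- impute_cm(g$map)
  if (is.null(freq)) freq <- allele_freq(g)
  poly <- !is.nan(freq) & freq > 0 & freq < 1
  if (!all(poly))
    message(sum(!poly), " monomorphic/all-missing markers dropped from HBD fit")
  map <- map[poly, , drop = FALSE]
  freq <- freq[poly]
  geno <- g$geno[, poly, drop = FALSE]
  K <- spec$K
  n <- nrow(geno)
  ## per-chromosome marker blocks and Morgan distances
  blocks <- lapply(unique(map$chr), function(ch) which(map$chr == ch))
  dists <- lapply(blocks, function(jj) diff(map$cM[jj]) / 100)
  auto <- matrix(NA_real_, n, K,
                 dimnames = list(rownames(geno),
                                 paste0("R", spec$rates,
                                        ifelse(spec$hbd, "", "_nonHBD"))))
  mix <- matrix(NA_real_, n, K)
  ll <- numeric(n); conv <- logical(n)
  posts <- if (keep_posterior) vector("list", n) else NULL
  for (i in seq_len(n)) {
    fit <- fit_hbd_one(geno[i, ], freq, blocks, dists, spec,
                       max_iter, tol, keep_posterior)
    auto[i, ] <- fit$auto
    mix[i, ] <- fit$M
    ll[i] <- fit$ll
    conv[i] <- fit$converged
    if (keep_posterior) posts[[i]] <- fit$post
  }
  if (!all(conv)) warning(sum(!conv), " individual(s) hit max_iter in EM")
  structure(list(autozygosity = auto, mixing = mix, loglik = ll,
                 converged = conv, spec = spec,
                 markers = map, posterior = posts),
            class = "hbd_result")
}

## EM for one individual; the scaled forward-backward E-step runs in C++
fit_hbd_one <- function(geno, freq, blocks, dists, spec, max_iter, tol,
                        keep_posterior) {
  K <- spec$K
  m <- length(geno)
  emis <- matrix(1, m, K)
  for (k in seq_len(K))
    emis[, k] <- hbd_emission(geno, freq, spec$hbd[k], spec$err)
  stays <- lapply(dists, function(d) exp(-outer(d, spec$rates)))
  M <- rep(1 / K, K)
  ll_old <- -Inf; converged <- FALSE
  post <- NULL; gamma_sum <- numeric(K); ll <- -Inf
  for (iter in seq_len(max_iter)) {
    ll <- 0
    gamma_sum <- numeric(K)
    jump_to <- numeric(K)   # expected landings in class k after a jump
    jump_n <- 0             # expected jumps (+1 initial draw per chromosome)
    post_blocks <- if (keep_posterior) list() else NULL
    for (b in seq_along(blocks)) {
      fb <- hbd_fb(emis[blocks[[b]], , drop = FALSE], stays[[b]], M)
      ll <- ll + fb$ll
      gamma_sum <- gamma_sum + colSums(fb$gamma)
      ## the initial class of each chromosome is also a draw from M
      jump_to <- jump_to + fb$jump_to + fb$gamma[1, ]
      jump_n <- jump_n + fb$jump_n + 1
      if (keep_posterior) post_blocks[[b]] <- fb$gamma
    }
    M_new <- jump_to / jump_n
    M_new <- pmax(M_new, 1e-12); M_new <- M_new / sum(M_new)
    if (keep_posterior) post <- do.call(rbind, post_blocks)
    if (is.finite(ll) && ll - ll_old < tol && iter > 1) {
      converged <- TRUE
      M <- M_new
      break
    }
    ll_old <- ll
    M <- M_new
  }
  gamma_mean <- gamma_sum / length(geno)   # genome-averaged class posterior
  list(M = M, ll = ll, converged = converged,
       auto = gamma_mean, post = post)
}

#' Forward-algorithm log-likelihood of one genotype vector
#'
#' Exposed for verification: on tiny marker sets the value can be compared
#' with an exhaustive sum over all `K^L` state paths.
#'
#' @param geno genotype codes.
#' @param freq counted-allele frequencies.
#' @param d_morgan distances between consecutive markers (length
#'   `length(geno) - 1`).
#' @param spec an [hbd_model()].
#' @param M mixing coefficients.
#' @return log-likelihood.
#' @export
hbd_forward_loglik <- function(geno, freq, d_morgan, spec, M) {
  K <- spec$K
  L <- length(geno)
  stopifnot(length(d_morgan) == L - 1)
  emis <- vapply(seq_len(K),
                 function(k) hbd_emission(geno, freq, spec$hbd[k], spec$err),
                 numeric(L))
  emis <- matrix(emis, L, K)
  a <- M * emis[1, ]
  ll <- log(sum(a)); a <- a / sum(a)
  if (L > 1) for (t in 2:L) {
    P <- hbd_transition(d_morgan[t - 1], spec, M)
    a <- as.numeric(a %*% P) * emis[t, ]
    ll <- ll + log(sum(a)); a <- a / sum(a)
  }
  ll
}

#' Cumulative inbreeding coefficient F_G-T
#'
#' `F_G-T(T)` sums the realized autozygosity of all HBD classes with rate
#' `R_k <= T`: larger thresholds include older ancestors, so the curve is
#' non-decreasing in `T` and plateaus at the total HBD autozygosity.
#'
#' @param result an `hbd_result` from [fit_hbd()].
#' @param thresholds rate thresholds `T` (default the HBD rate grid).
#' @return data.frame: `T`, then one column per sample.
#' @export
fgt_curve <- function(result, thresholds = NULL) {
  spec <- result$spec
  if (is.null(thresholds)) thresholds <- sort(unique(spec$rates[spec$hbd]))
  auto <- result$autozygosity
  out <- data.frame(T = thresholds)
  vals <- vapply(thresholds, function(Tt) {
    keep <- spec$hbd & spec$rates <= Tt
    if (!any(keep)) rep(0, nrow(auto)) else
      rowSums(auto[, keep, drop = FALSE])
  }, numeric(nrow(auto)))
  vals <- matrix(vals, nrow = nrow(auto), ncol = length(thresholds))
  cbind(out, stats::setNames(as.data.frame(t(vals)), rownames(auto)))
}
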