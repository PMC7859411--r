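# Tumor purity from copy-neutral SNVs.
#
# Alt-allele counts x_i at depth N_i for SNVs inside copy-neutral segments
# (tcn = 2, minor = 1) follow an ordered binomial mixture
#   x_i ~ sum_k pi_k Binom(N_i, theta_k),   theta_K < ... < theta_1 <= 0.5,
# one component per (sub)clone.  EM maximizes the likelihood, BIC picks K,
# and purity = 2 * theta_1 because a clonal heterozygous variant in a
# copy-neutral region has expected VAF purity/2.

#' Select variants in copy-neutral regions
#'
#' Keeps variants whose position lies in a segment with total copy number 2
#' and minor copy number 1 (one copy of each allele).  Variants falling in
#' coverage gaps of the profile are dropped with a warning; variants in
#' non-neutral segments (including copy-neutral LOH, tcn 2 / minor 0) are
#' dropped silently.
#'
#' @param variants variant data.frame for one sample (1-based \code{pos}).
#' @param profile the sample's \linkS4class{CNProfile}.
#' @return the copy-neutral subset of \code{variants}.
#' @export
selectNeutralVariants <- function(variants, profile) {
  if (nrow(variants) == 0L) return(variants)
  gr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  seg <- segments(profile)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, seg, select = "first"))
  uncovered <- is.na(hits)
  if (any(uncovered))
    warning(sum(uncovered), " variant(s) fall in coverage gaps and were dropped")
  mc <- S4Vectors::mcols(seg)
  neutral <- !uncovered & mc$tcn[hits] == 2L & mc$mcnMinor[hits] == 1L
  neutral[is.na(neutral)] <- FALSE
  variants[neutral, , drop = FALSE]
}

#' Fit an ordered binomial mixture by EM
#'
#' E-step computes binomial responsibilities; M-step sets
#' \eqn{\theta_k = \sum_i \gamma_{ik} x_i / \sum_i \gamma_{ik} N_i} and
#' \eqn{\pi_k = \mathrm{mean}_i\,\gamma_{ik}}.  After each M-step the
#' components are sorted by descending \eqn{\theta} and any \eqn{\theta}
#' above 0.5 is projected back to 0.5.  The log-likelihood is asserted to be
#' non-decreasing (up to numerical jitter from the projection) and EM stops
#' when its change falls below \code{tol}.
#'
#' @param x alt-allele counts.
#' @param n read depths (all > 0).
#' @param K number of components (>= 1; must not exceed length(x)).
#' @param thetaInit optional initial theta (length K); defaults to K
#'   quantiles of x/n.
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxIter maximum EM iterations (default 500).
#' @return a \linkS4class{PurityFit} (with \code{converged = FALSE} when
#'   \code{maxIter} is reached).
#' @export
emFitBinomial <- function(x, n, K, thetaInit = NULL, tol = 1e-8,
                          maxIter = 500L) {
  stopifnot(K >= 1L, length(x) == length(n))
  if (any(n <= 0)) stop("all depths must be > 0")
  nv <- length(x)
  if (K > nv) stop("K must not exceed the number of variants")
  K <- as.integer(K)
  if (is.null(thetaInit)) {
    probs <- (seq_len(K) - 0.5) / K
    thetaInit <- rev(sort(stats::quantile(x / n, probs = probs, names = FALSE)))
  }
  theta <- pmin(pmax(thetaInit, 1e-6), 0.5)
  theta <- rev(sort(theta))
  piw <- rep(1 / K, K)
  # aggregate duplicate (x, N) pairs: the likelihood only depends on the
  # multiset of counts, so EM runs on unique pairs with multiplicities
  key <- paste(x, n)
  first <- !duplicated(key)
  xu <- x[first]; nu <- n[first]
  wts <- as.numeric(table(factor(key, levels = key[first])))
  lch <- lchoose(nu, xu)
  res <- .emBinomCore(as.numeric(xu), as.numeric(nu), wts, lch,
                      as.numeric(theta), tol, as.integer(maxIter))
  if (res$decreased)
    stop(sprintf("EM log-likelihood decreased (at %.10g)", res$loglik))
  ll <- res$loglik
  new("PurityFit", K = K, theta = as.numeric(res$theta),
      pi = as.numeric(res$pi), loglik = ll,
      bic = -2 * ll + (2 * K - 1) * log(nv),
      purity = min(1, 2 * res$theta[1L]), nVariants = nv,
      converged = res$converged, nIter = as.integer(res$iter))
}

.emMultiStart <- function(x, n, K, nStarts = 10L, tol = 1e-8,
                          maxIter = 500L) {
  probs <- (seq_len(K) - 0.5) / K
  base <- rev(sort(stats::quantile(x / n, probs = probs, names = FALSE)))
  if (K == 1L) nStarts <- 1L   # K = 1 EM is globally convergent
  best <- NULL
  for (s in seq_len(nStarts)) {
    init <- if (s == 1L) base else
      pmin(pmax(base + stats::rnorm(K, 0, 0.05), 1e-4), 0.5)
    fit <- emFitBinomial(x, n, K, thetaInit = init, tol = tol,
                         maxIter = maxIter)
    if (is.null(best) || fit@loglik > best@loglik) best <- fit
  }
  best
}

#' Choose the number of clones by BIC
#'
#' Fits the ordered binomial mixture for K = 1..\code{kMax} with multi-start
#' EM and returns the fit minimizing
#' \eqn{\mathrm{BIC} = -2\ell + (2K-1)\log n} (K thetas plus K-1 free
#' weights).  Ties break toward smaller K.  \code{kMax} is truncated so that
#' the parameter count stays below the number of variants, with a warning.
#'
#' @inheritParams emFitBinomial
#' @param kMax largest number of components to consider (default 4).
#' @param nStarts EM restarts per K (default 10; the first uses quantile
#'   initialization, the rest jitter it).
#' @return the BIC-selected \linkS4class{PurityFit}.
#' @export
selectK <- function(x, n, kMax = 4L, nStarts = 10L, tol = 1e-8,
                    maxIter = 500L) {
  stopifnot(kMax >= 1L)
  nv <- length(x)
  kEff <- max(1L, min(as.integer(kMax), nv %/% 2L))
  if (kEff < kMax)
    warning(sprintf("kMax truncated to %d so that 2K-1 < n = %d", kEff, nv))
  fits <- lapply(seq_len(kEff), function(K)
    .emMultiStart(x, n, K, nStarts = nStarts, tol = tol, maxIter = maxIter))
  bics <- vapply(fits, function(f) f@bic, numeric(1))
  fits[[which.min(bics)]]   # which.min takes the first (smallest K) on ties
}

#' Estimate tumor purity for one sample
#'
#' Restricts the variants to copy-neutral regions, fits the ordered binomial
#' mixture with BIC-selected K, and reports purity \eqn{2\theta_1} (capped
#' at 1).  With fewer than \code{minVariants} copy-neutral SNVs no call is
#' made.
#'
#' @param variants retained somatic variant data.frame for the sample.
#' @param profile the sample's \linkS4class{CNProfile}.
#' @param kMax largest number of clones considered (default 4).
#' @param minVariants minimum copy-neutral SNV count for a call (default 20).
#' @param ... passed to [selectK()].
#' @return list with \code{purity} (NA for a no-call), \code{fit} (a
#'   \linkS4class{PurityFit} or NULL), \code{nNeutral} and \code{reason}.
#' @export
estimatePurity <- function(variants, profile, kMax = 4L, minVariants = 20L,
                           ...) {
  neutral <- selectNeutralVariants(variants, profile)
  if (nrow(neutral) < minVariants) {
    return(list(purity = NA_real_, fit = NULL, nNeutral = nrow(neutral),
                reason = sprintf("only %d copy-neutral SNVs (< %d)",
                                 nrow(neutral), minVariants)))
  }
  keep <- neutral$t_depth > 0
  fit <- selectK(neutral$t_alt[keep], neutral$t_depth[keep], kMax = kMax, ...)
  if (fit@theta[1L] < 0.01)
    warning("theta1 ~ 0: purity estimate is near zero (low-purity sample?)")
  list(purity = fit@purity, fit = fit, nNeutral = nrow(neutral),
       reason = NA_character_)
}
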