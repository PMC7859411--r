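#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

#' Genome build with chromosome-arm geometry
#'
#' Holds the chromosome names, lengths, p/q-arm boundaries and autosome flags
#' against which all segment, variant and structural-variant coordinates are
#' validated.  Arm boundaries are stored 0-based half-open; the gap between a
#' p arm's end and the q arm's start is the (acro)centromeric region, which
#' belongs to neither arm.
#'
#' @slot chroms ordered chromosome names (with "chr" prefix).
#' @slot lengths named numeric vector of chromosome lengths in bp.
#' @slot arms data.frame with columns \code{chrom}, \code{arm} ("p"/"q"),
#'   \code{start}, \code{end} (0-based half-open bp).
#' @slot autosome named logical vector; \code{TRUE} for autosomes.
#'
#' @seealso [readGenome()], [hg19Genome()], [armRanges()]
#' @export
setClass("GenomeBuild",
  representation(
    chroms = "character",
    lengths = "numeric",
    arms = "data.frame",
    autosome = "logical"
  )
)

setValidity("GenomeBuild", function(object) {
  msgs <- character()
  if (length(object@chroms) == 0L) msgs <- c(msgs, "no chromosomes defined")
  if (!identical(names(object@lengths), object@chroms))
    msgs <- c(msgs, "lengths must be named by chroms, in order")
  if (!identical(names(object@autosome), object@chroms))
    msgs <- c(msgs, "autosome flags must be named by chroms, in order")
  a <- object@arms
  need <- c("chrom", "arm", "start", "end")
  if (!all(need %in% names(a))) {
    msgs <- c(msgs, "arms table needs columns chrom, arm, start, end")
  } else {
    if (!all(a$chrom %in% object@chroms))
      msgs <- c(msgs, "arms table names unknown chromosomes")
    if (any(a$start >= a$end)) msgs <- c(msgs, "arm start must be < end")
    if (any(a$start < 0) || any(a$end > object@lengths[a$chrom]))
      msgs <- c(msgs, "arms must lie within [0, chromosome length)")
    for (ch in unique(a$chrom)) {
      sub <- a[a$chrom == ch, , drop = FALSE]
      if (nrow(sub) == 2L) {
        p <- sub[sub$arm == "p", ]; q <- sub[sub$arm == "q", ]
        if (nrow(p) == 1L && nrow(q) == 1L && p$end > q$start)
          msgs <- c(msgs, sprintf("arms of %s overlap", ch))
      }
    }
    if (sum(object@lengths[object@autosome]) <= 0)
      msgs <- c(msgs, "total autosomal length must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-sample allele-specific copy-number profile
#'
#' Wraps a \linkS4class{GRanges} of allele-specific copy-number segments
#' (metadata columns \code{tcn}, total copy number, and \code{mcnMinor},
#' minor-allele copy number).  Internal coordinates are 0-based half-open,
#' carried as GRanges 1-based starts minus one on I/O.  Segments of one
#' chromosome must not overlap; coverage gaps are allowed and are excluded
#' from all denominators downstream.
#'
#' @slot sampleId sample identifier.
#' @slot segments \code{GRanges} with integer columns \code{tcn} and
#'   \code{mcnMinor}, sorted by (chrom, start).
#'
#' @seealso [readSegments()], [classifyState()], [callArmEvents()], [callWGD()]
#' @export
setClass("CNProfile",
  representation(sampleId = "character", segments = "GRanges")
)

setValidity("CNProfile", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msgs <- c(msgs, "sampleId must be a single string")
  seg <- object@segments
  mc <- S4Vectors::mcols(seg)
  if (!all(c("tcn", "mcnMinor") %in% names(mc))) {
    msgs <- c(msgs, "segments need metadata columns tcn and mcnMinor")
  } else {
    tcn <- mc$tcn; mn <- mc$mcnMinor
    if (any(is.na(tcn)) || any(is.na(mn)) || any(tcn < 0) || any(mn < 0))
      msgs <- c(msgs, "tcn and mcnMinor must be non-negative")
    if (any(tcn - mn < mn))
      msgs <- c(msgs, "mcnMinor must not exceed tcn/2 (minor <= major)")
    if (length(seg) > 1L) {
      hits <- GenomicRanges::findOverlaps(seg, drop.self = TRUE,
                                          drop.redundant = TRUE)
      if (length(hits) > 0L)
        msgs <- c(msgs, "segments overlap within a chromosome")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted ordered binomial mixture for tumor purity
#'
#' Result of fitting \eqn{x_i \sim \sum_k \pi_k \mathrm{Binom}(N_i, \theta_k)}
#' with \eqn{\theta_K < \dots < \theta_1 \le 0.5} to alt-allele counts of SNVs
#' in copy-neutral regions.  Purity is \eqn{2\theta_1}: in a copy-neutral
#' region a clonal heterozygous somatic variant has expected VAF purity/2.
#'
#' @slot K number of mixture components (clones).
#' @slot theta success probabilities, descending, \code{theta[1] <= 0.5}.
#' @slot pi mixture weights summing to 1.
#' @slot loglik maximized log-likelihood.
#' @slot bic \eqn{-2\ell + (2K-1)\log n}.
#' @slot purity \eqn{\min(1, 2\theta_1)}.
#' @slot nVariants number of variants used.
#' @slot converged whether EM reached the loglik tolerance.
#' @slot nIter EM iterations used.
#'
#' @seealso [emFitBinomial()], [selectK()], [estimatePurity()]
#' @export
setClass("PurityFit",
  representation(
    K = "integer", theta = "numeric", pi = "numeric",
    loglik = "numeric", bic = "numeric", purity = "numeric",
    nVariants = "integer", converged = "logical", nIter = "integer"
  )
)

setValidity("PurityFit", function(object) {
  msgs <- character()
  if (length(object@theta) != object@K || length(object@pi) != object@K)
    msgs <- c(msgs, "theta and pi must have length K")
  if (object@K >= 1L) {
    if (is.unsorted(rev(object@theta), strictly = FALSE))
      msgs <- c(msgs, "theta must be in descending order")
    if (object@theta[1L] > 0.5 + 1e-12)
      msgs <- c(msgs, "theta[1] must be <= 0.5")
    if (abs(sum(object@pi) - 1) > 1e-8)
      msgs <- c(msgs, "mixture weights must sum to 1")
    if (object@purity < 0 || object@purity > 1 + 1e-12)
      msgs <- c(msgs, "purity must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GenomeBuild", function(object) {
  cat("GenomeBuild:", length(object@chroms), "chromosomes,",
      sum(object@autosome), "autosomes\n")
  cat("  total length:", format(sum(object@lengths), big.mark = ","), "bp;",
      nrow(object@arms), "arms\n")
})

setMethod("show", "CNProfile", function(object) {
  seg <- object@segments
  cat("CNProfile for sample", object@sampleId, "\n")
  cat(" ", length(seg), "segments on",
      length(unique(as.character(GenomicRanges::seqnames(seg)))),
      "chromosomes;", format(sum(GenomicRanges::width(seg)), big.mark = ","),
      "bp covered\n")
})

setMethod("show", "PurityFit", function(object) {
  cat(sprintf("PurityFit: K = %d, purity = %.3f (2*theta1)\n",
              object@K, object@purity))
  cat("  theta:", paste(sprintf("%.4f", object@theta), collapse = ", "), "\n")
  cat("  pi:   ", paste(sprintf("%.4f", object@pi), collapse = ", "), "\n")
  cat(sprintf("  loglik = %.4f, BIC = %.4f, n = %d, %s in %d iterations\n",
              object@loglik, object@bic, object@nVariants,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
})

#' @describeIn CNProfile-class sample identifier.
#' @param object a \code{CNProfile} (or \code{PurityFit} for its accessors).
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname CNProfile-class
#' @export
setMethod("sampleId", "CNProfile", function(object) object@sampleId)

#' @describeIn CNProfile-class segment \code{GRanges} (tcn, mcnMinor columns).
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))

#' @rdname CNProfile-class
#' @export
setMethod("segments", "CNProfile", function(object) object@segments)

#' @describeIn PurityFit-class estimated purity (\eqn{2\theta_1}, capped at 1).
#' @param object a \code{PurityFit}.
#' @export
setGeneric("purity", function(object) standardGeneric("purity"))

#' @rdname PurityFit-class
#' @export
setMethod("purity", "PurityFit", function(object) object@purity)

#' @describeIn PurityFit-class Bayesian information criterion of the fit.
#' @export
setGeneric("bic", function(object) standardGeneric("bic"))

#' @rdname PurityFit-class
#' @export
setMethod("bic", "PurityFit", function(object) object@bic)

#' @describeIn PurityFit-class maximized log-likelihood.
#' @export
setGeneric("fitLogLik", function(object) standardGeneric("fitLogLik"))

#' @rdname PurityFit-class
#' @export
setMethod("fitLogLik", "PurityFit", function(object) object@loglik)

#' @describeIn PurityFit-class number of mixture components.
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname PurityFit-class
#' @export
setMethod("nComponents", "PurityFit", function(object) object@K)

#' Construct a CNProfile
#'
#' @param sampleId sample identifier.
#' @param segments either a \code{GRanges} with \code{tcn}/\code{mcnMinor}
#'   metadata columns, or a data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{tcn},
#'   \code{mcnMinor}.
#' @return a validated \linkS4class{CNProfile}.
#' @export
CNProfile <- function(sampleId, segments) {
  if (is.data.frame(segments)) {
    segments <- GenomicRanges::GRanges(
      seqnames = segments$chrom,
      ranges = IRanges::IRanges(start = segments$start + 1L,
                                end = segments$end),
      tcn = as.integer(segments$tcn),
      mcnMinor = as.integer(segments$mcnMinor)
    )
  }
  segments <- GenomicRanges::sort(segments)
  new("CNProfile", sampleId = as.character(sampleId), segments = segments)
}
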