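# High-confidence chromothripsis calling from structural variants and
# allele-specific segments.  A region qualifies under criteria set 1
# (>= 6 interleaved intra-chromosomal SVs, >= 7 adjacent segments
# oscillating between two total-CN states, fragment-joins test p < 0.05,
# and chromosomal enrichment OR exponential breakpoint-spacing p < 0.05)
# or set 2 (>= 3 interleaved intra-chromosomal SVs, >= 4 inter-chromosomal
# SVs, the same oscillation and fragment-joins requirements).

.INTRA_CLASSES <- c("DEL", "DUP", "h2hINV", "t2tINV")

.unionFind <- function(m) {
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  list(find = find, union = union)
}

#' Clusters of interleaved intra-chromosomal SVs
#'
#' Two intra-chromosomal SVs interleave when their breakpoint intervals
#' [pos1, pos2] overlap and neither contains the other.  Clusters are the
#' connected components of the interleaving graph, computed per chromosome.
#'
#' @param svs SV data.frame for one sample (see [readSVBedpe()]).
#' @param chrom optional chromosome to restrict to.
#' @return list of data.frames, one per cluster (clusters of size 1 are
#'   singletons with no interleaving partner), ordered by chromosome and
#'   leftmost breakpoint.
#' @export
interleavedClusters <- function(svs, chrom = NULL) {
  intra <- svs[svs$chrom1 == svs$chrom2, , drop = FALSE]
  if (!is.null(chrom)) intra <- intra[intra$chrom1 == chrom, , drop = FALSE]
  out <- list()
  for (ch in unique(intra$chrom1)) {
    sub <- intra[intra$chrom1 == ch, , drop = FALSE]
    sub <- sub[order(sub$pos1, sub$pos2), , drop = FALSE]
    m <- nrow(sub)
    uf <- .unionFind(m)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        for (j in (i + 1L):m) {
          a1 <- sub$pos1[i]; a2 <- sub$pos2[i]
          b1 <- sub$pos1[j]; b2 <- sub$pos2[j]
          overlaps <- a1 < b2 && b1 < a2
          nested <- (a1 <= b1 && a2 >= b2) || (b1 <= a1 && b2 >= a2)
          if (overlaps && !nested) uf$union(i, j)
        }
      }
    }
    roots <- vapply(seq_len(m), uf$find, integer(1))
    for (r in unique(roots))
      out[[length(out) + 1L]] <- sub[roots == r, , drop = FALSE]
  }
  out
}

#' Longest alternating run in a copy-number sequence
#'
#' Longest run of consecutive values that alternate strictly between
#' exactly two distinct values (ABAB...).  A constant sequence has run
#' length 1.
#'
#' @param v numeric/integer vector (e.g. per-segment total copy numbers).
#' @return the maximal run length (0 for an empty vector).
#' @export
maxAlternatingRun <- function(v) {
  n <- length(v)
  if (n == 0L) return(0L)
  best <- 1L
  s <- 1L
  for (i in seq_len(n)[-1L]) {
    if (v[i] == v[i - 1L]) {
      s <- i
    } else if (i - s >= 2L && v[i] != v[i - 2L]) {
      s <- i - 1L
    }
    best <- max(best, i - s + 1L)
  }
  as.integer(best)
}

#' Maximal CN oscillation within a region
#'
#' Takes the total copy numbers of the profile's segments overlapping the
#' region, in genomic order, and returns the longest run oscillating
#' between two CN states (see [maxAlternatingRun()]).
#'
#' @param profile a \linkS4class{CNProfile}.
#' @param chrom chromosome of the region.
#' @param start,end region bounds, 0-based half-open bp.
#' @return integer run length (0 when no segment overlaps the region).
#' @export
maxOscillation <- function(profile, chrom, start, end) {
  seg <- segments(profile)
  region <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  hits <- S4Vectors::queryHits(
    suppressWarnings(GenomicRanges::findOverlaps(seg, region)))
  if (length(hits) == 0L) return(0L)
  maxAlternatingRun(S4Vectors::mcols(seg)$tcn[sort(hits)])
}

#' Fragment-joins test
#'
#' Goodness-of-fit of the intra-chromosomal join-class counts (deletion-
#' like, duplication-like, head-to-head inverted, tail-to-tail inverted)
#' against equal proportions.  Chi-square with 3 df for n >=
#' \code{exactBelow}; an exact multinomial test (summing the probability of
#' every outcome at most as probable as the observed one) for smaller n.
#'
#' @param classes character vector of intra-chromosomal SV classes
#'   (values among "DEL", "DUP", "h2hINV", "t2tINV"; length >= 3).
#' @param exactBelow use the exact test when n < this bound (default 20).
#' @return p-value.
#' @export
fragmentJoinsTest <- function(classes, exactBelow = 20L) {
  if (length(classes) < 3L)
    stop("fragment-joins test requires at least 3 SVs")
  counts <- as.integer(table(factor(classes, levels = .INTRA_CLASSES)))
  n <- sum(counts)
  if (n >= exactBelow)
    return(suppressWarnings(
      stats::chisq.test(counts, p = rep(0.25, 4))$p.value))
  # exact multinomial: enumerate all 4-cell outcomes of size n
  grid <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
  grid <- grid[grid$a + grid$b + grid$c <= n, , drop = FALSE]
  grid$d <- n - grid$a - grid$b - grid$c
  lp <- lgamma(n + 1) -
    (lgamma(grid$a + 1) + lgamma(grid$b + 1) +
     lgamma(grid$c + 1) + lgamma(grid$d + 1)) + n * log(0.25)
  lpObs <- lgamma(n + 1) - sum(lgamma(counts + 1)) + n * log(0.25)
  sum(exp(lp[lp <= lpObs + 1e-9]))
}

#' Chromosomal breakpoint-enrichment test
#'
#' One-sided binomial tail for the number of the sample's SV breakends on
#' one chromosome: \eqn{P(X \ge obs)} with
#' \eqn{X \sim Binom(total\;breakends, L_{chrom}/L_{genome})}.
#'
#' @param svs the sample's full SV data.frame.
#' @param chrom chromosome tested.
#' @param genome a \linkS4class{GenomeBuild}.
#' @return p-value (1 when the chromosome has no breakend).
#' @export
breakpointEnrichmentTest <- function(svs, chrom, genome) {
  chroms <- c(svs$chrom1, svs$chrom2)
  total <- length(chroms)
  if (total == 0L) return(1)
  obs <- sum(chroms == chrom)
  q <- chromLengths(genome)[[chrom]] / sum(chromLengths(genome))
  stats::pbinom(obs - 1, total, q, lower.tail = FALSE)
}

#' Exponential breakpoint-spacing test
#'
#' One-sample Kolmogorov-Smirnov test of the successive inter-breakpoint
#' gaps within a region against Exponential(rate = (n-1)/span), i.e.
#' against the spacing distribution of uniformly scattered breakpoints.
#' Small p rejects the exponential-spacing (random scatter) model, as for a
#' regular grid of breakpoints.
#'
#' @param breakpoints breakpoint positions (bp).
#' @return list with \code{p} and \code{tested}; fewer than 3 breakpoints
#'   is a no-test (\code{p = 1}, \code{tested = FALSE}).
#' @export
exponentialSpacingTest <- function(breakpoints) {
  n <- length(breakpoints)
  if (n < 3L) return(list(p = 1, tested = FALSE))
  gaps <- diff(sort(breakpoints))
  rate <- (n - 1) / (max(breakpoints) - min(breakpoints))
  p <- suppressWarnings(stats::ks.test(gaps, "pexp", rate))$p.value
  list(p = p, tested = TRUE)
}

#' Call high-confidence chromothripsis regions for one sample
#'
#' Builds interleaved-SV clusters per chromosome, takes each cluster's
#' breakpoint hull as the candidate region, and evaluates both criteria
#' sets: (1) at least \code{minIntra} interleaved intra-chromosomal SVs,
#' an oscillation of at least \code{minOsc} adjacent segments between two
#' CN states, fragment-joins p < \code{alpha}, and chromosomal enrichment
#' or exponential-spacing p < \code{alpha}; (2) at least
#' \code{minIntraSet2} interleaved intra-chromosomal SVs plus at least
#' \code{minInter} inter-chromosomal SVs with a breakend inside the region,
#' with the same oscillation and fragment-joins requirements.
#'
#' @param svs the sample's SV data.frame (see [readSVBedpe()]).
#' @param profile the sample's \linkS4class{CNProfile}.
#' @param genome a \linkS4class{GenomeBuild}.
#' @param minIntra,minOsc,minIntraSet2,minInter,alpha criteria thresholds
#'   (defaults 6, 7, 3, 4, 0.05).
#' @param joinsDirection "below" (default) qualifies regions with
#'   fragment-joins p < alpha, as printed in the criteria; "above" flips
#'   the direction (p >= alpha qualifies) for users who read the joins test
#'   as a uniformity requirement.
#' @return data.frame with one row per evaluated cluster (clusters of at
#'   least \code{minIntraSet2} SVs): sample, chrom, region bounds (0-based
#'   half-open), counts, oscillation run, the three p-values,
#'   \code{criteria_set} (1, 2 or NA) and \code{high_confidence}.
#' @export
callChromothripsis <- function(svs, profile, genome, minIntra = 6L,
                               minOsc = 7L, minIntraSet2 = 3L,
                               minInter = 4L, alpha = 0.05,
                               joinsDirection = c("below", "above")) {
  joinsDirection <- match.arg(joinsDirection)
  sid <- sampleId(profile)
  clusters <- interleavedClusters(svs)
  clusters <- Filter(function(cl) nrow(cl) >= minIntraSet2, clusters)
  tra <- svs[svs$chrom1 != svs$chrom2, , drop = FALSE]
  rows <- lapply(clusters, function(cl) {
    ch <- cl$chrom1[1L]
    bp <- c(cl$pos1, cl$pos2)
    regionStart <- min(bp) - 1
    regionEnd <- max(bp)
    nIntra <- nrow(cl)
    nInter <- sum((tra$chrom1 == ch & tra$pos1 >= regionStart + 1 &
                     tra$pos1 <= regionEnd) |
                  (tra$chrom2 == ch & tra$pos2 >= regionStart + 1 &
                     tra$pos2 <= regionEnd))
    osc <- maxOscillation(profile, ch, regionStart, regionEnd)
    pJoins <- fragmentJoinsTest(cl$sv_class)
    pEnrich <- breakpointEnrichmentTest(svs, ch, genome)
    spacing <- exponentialSpacingTest(bp)
    joinsOK <- if (joinsDirection == "below") pJoins < alpha else
      pJoins >= alpha
    set1 <- nIntra >= minIntra && osc >= minOsc && joinsOK &&
      (pEnrich < alpha || (spacing$tested && spacing$p < alpha))
    set2 <- nIntra >= minIntraSet2 && nInter >= minInter &&
      osc >= minOsc && joinsOK
    data.frame(sample = sid, chrom = ch, start = regionStart,
               end = regionEnd, n_intra_interleaved = nIntra,
               n_inter_sv = nInter, max_oscillation_run = osc,
               p_fragment_joins = pJoins, p_enrichment = pEnrich,
               p_exponential = spacing$p,
               criteria_set = if (set1) 1L else if (set2) 2L else NA_integer_,
               high_confidence = set1 || set2,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = character(), start = numeric(),
               end = numeric(), n_intra_interleaved = integer(),
               n_inter_sv = integer(), max_oscillation_run = integer(),
               p_fragment_joins = numeric(), p_enrichment = numeric(),
               p_exponential = numeric(), criteria_set = integer(),
               high_confidence = logical())
}
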