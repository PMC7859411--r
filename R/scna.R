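# Allele-specific SCNA landscape: five-state classification, arm-level
# event calls (>= 90% of an arm), whole-genome doubling (MCN >= 2 over more
# than half of the covered autosomal genome), a length-weighted CN-state
# distance between tumors, and hierarchical clustering with an
# elbow-selected group count.

.CN_STATES <- c("HOMDEL", "HEMIDEL", "NEUTRAL", "LOH", "AMP")

#' Classify a segment's copy-number state
#'
#' Total function of (tcn, minor): HOMDEL when tcn = 0, HEMIDEL when
#' tcn = 1, AMP when tcn >= 3, LOH when tcn = 2 and minor = 0, NEUTRAL when
#' tcn = 2 and minor >= 1.  Amplification takes precedence over LOH for
#' tcn >= 3 with minor 0.
#'
#' @param tcn total copy number (vectorized).
#' @param minor minor-allele copy number (vectorized).
#' @return character vector of states.
#' @export
classifyState <- function(tcn, minor) {
  ifelse(tcn == 0L, "HOMDEL",
  ifelse(tcn == 1L, "HEMIDEL",
  ifelse(tcn >= 3L, "AMP",
  ifelse(minor == 0L, "LOH", "NEUTRAL"))))
}

.armOverlapWidths <- function(seg, armGr) {
  hits <- suppressWarnings(GenomicRanges::findOverlaps(seg, armGr))
  if (length(hits) == 0L)
    return(data.frame(seg = integer(), arm = integer(), w = numeric()))
  inter <- IRanges::pintersect(seg[S4Vectors::queryHits(hits)],
                               armGr[S4Vectors::subjectHits(hits)])
  data.frame(seg = S4Vectors::queryHits(hits),
             arm = S4Vectors::subjectHits(hits),
             w = GenomicRanges::width(inter))
}

#' Call arm-level SCNA events
#'
#' An arm-level gain (loss) is emitted when segments with total copy number
#' above (below) 2 cover at least \code{minFraction} of the p or q arm.
#' Fractions are taken over the full arm length, so uncovered bp count
#' against the event.  Fully uncovered arms yield no call (with a single
#' summarizing warning when \code{warnUncovered}).
#'
#' @param profile a \linkS4class{CNProfile}.
#' @param genome a \linkS4class{GenomeBuild}.
#' @param minFraction coverage fraction required (default 0.9).
#' @param warnUncovered warn about fully uncovered arms (default TRUE).
#' @return data.frame with columns \code{sample}, \code{chrom}, \code{arm},
#'   \code{direction} ("gain"/"loss"), \code{covered_fraction}.
#' @export
callArmEvents <- function(profile, genome, minFraction = 0.9,
                          warnUncovered = TRUE) {
  seg <- segments(profile)
  armGr <- armRanges(genome)
  armKey <- paste0(as.character(GenomicRanges::seqnames(armGr)),
                   S4Vectors::mcols(armGr)$arm)
  armLen <- GenomicRanges::width(armGr)
  ov <- .armOverlapWidths(seg, armGr)
  tcn <- S4Vectors::mcols(seg)$tcn[ov$seg]
  gainBp <- vapply(seq_along(armGr), function(i)
    sum(ov$w[ov$arm == i & tcn > 2L]), numeric(1))
  lossBp <- vapply(seq_along(armGr), function(i)
    sum(ov$w[ov$arm == i & tcn < 2L]), numeric(1))
  covBp <- vapply(seq_along(armGr), function(i)
    sum(ov$w[ov$arm == i]), numeric(1))
  if (warnUncovered && any(covBp == 0))
    warning(sum(covBp == 0), " arm(s) fully uncovered, no call: ",
            paste(armKey[covBp == 0], collapse = ", "))
  rows <- list()
  for (i in seq_along(armGr)) {
    if (covBp[i] == 0) next
    for (dir in c("gain", "loss")) {
      f <- (if (dir == "gain") gainBp[i] else lossBp[i]) / armLen[i]
      if (f >= minFraction)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sampleId(profile),
          chrom = as.character(GenomicRanges::seqnames(armGr))[i],
          arm = S4Vectors::mcols(armGr)$arm[i],
          direction = dir, covered_fraction = f,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), chrom = character(), arm = character(),
               direction = character(), covered_fraction = numeric())
}

#' Call whole-genome doubling
#'
#' A tumor is flagged as whole-genome doubled when more than 50% (strict)
#' of the covered autosomal genome has major copy number (tcn - minor) of
#' at least 2.
#'
#' @param profile a \linkS4class{CNProfile}.
#' @param genome a \linkS4class{GenomeBuild}.
#' @return list with \code{wgd} (logical) and \code{mcn_ge2_fraction}.
#' @export
callWGD <- function(profile, genome) {
  seg <- segments(profile)
  auto <- GenomicRanges::GRanges(
    seqnames = chromNames(genome, autosomesOnly = TRUE),
    ranges = IRanges::IRanges(1, chromLengths(genome, autosomesOnly = TRUE)))
  ov <- .armOverlapWidths(seg, auto)
  if (nrow(ov) == 0L) return(list(wgd = FALSE, mcn_ge2_fraction = 0))
  mc <- S4Vectors::mcols(seg)
  mcn <- (mc$tcn - mc$mcnMinor)[ov$seg]
  frac <- sum(ov$w[mcn >= 2L]) / sum(ov$w)
  list(wgd = frac > 0.5, mcn_ge2_fraction = frac)
}

.stateMatrix <- function(profiles, genome) {
  allSeg <- lapply(profiles, segments)
  pieces <- GenomicRanges::disjoin(
    suppressWarnings(do.call(c, unname(allSeg))))
  keep <- as.character(GenomicRanges::seqnames(pieces)) %in% genome@chroms
  pieces <- pieces[keep]
  S <- matrix(NA_integer_, nrow = length(profiles), ncol = length(pieces))
  for (i in seq_along(profiles)) {
    seg <- allSeg[[i]]
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(pieces, seg, select = "first",
                                  type = "within"))
    mc <- S4Vectors::mcols(seg)
    st <- match(classifyState(mc$tcn, mc$mcnMinor), .CN_STATES)
    S[i, ] <- st[hit]
  }
  list(S = S, w = GenomicRanges::width(pieces))
}

#' Length-weighted CN-state distance between tumors
#'
#' At each base pair two tumors are at distance 0 if their five-state CN
#' classification agrees and 1 otherwise; the distance between two profiles
#' is the length-weighted sum over the genome, computed interval-wise on the
#' disjoint pieces induced by all segment boundaries.  With
#' \code{normalize = TRUE} (default) the sum is divided by the number of bp
#' jointly covered by both samples, so cohorts with coverage gaps remain
#' comparable; \code{normalize = FALSE} returns the raw differing-bp count.
#' Base pairs covered by only one of the two samples are excluded.
#'
#' @param profiles list of \linkS4class{CNProfile} (>= 2).
#' @param genome a \linkS4class{GenomeBuild}.
#' @param normalize divide by jointly covered bp (default TRUE).
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
pairwiseDistance <- function(profiles, genome, normalize = TRUE) {
  stopifnot(length(profiles) >= 2L)
  ids <- vapply(profiles, sampleId, character(1))
  sm <- .stateMatrix(profiles, genome)
  S <- sm$S; w <- sm$w
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(S[i, ]) & !is.na(S[j, ])
      denom <- sum(w[both])
      if (denom == 0)
        stop(sprintf("samples %s and %s have disjoint coverage; %s",
                     ids[i], ids[j], "distance undefined"))
      d <- sum(w[both & S[i, ] != S[j, ]])
      D[i, j] <- D[j, i] <- if (normalize) d / denom else d
    }
  }
  D
}

#' Cluster a cohort on the CN-state distance
#'
#' Agglomerative clustering of the distance matrix (average linkage by
#' default).  For each candidate k the within-cluster dispersion
#' W(k) — the mean pairwise distance restricted to within-cluster pairs,
#' hence monotone non-increasing in k — is computed from cutting the tree;
#' the number of groups is the
#' maximum-curvature elbow: the k maximizing the second difference of
#' log W(k) (ties toward smaller k), i.e. the point where the relative
#' decay of the dispersion flattens.  A cohort of
#' (near-)identical profiles degenerates to a single group.  Group labels
#' are assigned deterministically in order of decreasing group size.
#'
#' @param D distance matrix from [pairwiseDistance()].
#' @param kMax largest group count considered (must be < number of samples
#'   and is only informative when above the expected group count).
#' @param linkage "average" (default), "complete", or "ward" (Ward.D2 on a
#'   classical MDS embedding of the distance).
#' @return list of class \code{cohortClustering} with elements
#'   \code{distance}, \code{tree}, \code{W}, \code{chosenK},
#'   \code{labels} (named integer vector in 1..chosenK).
#' @export
clusterCohort <- function(D, kMax = 8L,
                          linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  n <- nrow(D)
  if (kMax >= n) stop("kMax must be smaller than the number of samples")
  tree <- if (linkage == "ward") {
    emb <- stats::cmdscale(stats::as.dist(D), k = min(n - 1L, 10L))
    stats::hclust(stats::dist(emb), method = "ward.D2")
  } else {
    stats::hclust(stats::as.dist(D), method = linkage)
  }
  nPairs <- n * (n - 1) / 2
  W <- vapply(seq_len(kMax), function(k) {
    lab <- stats::cutree(tree, k = k)
    sum(vapply(split(seq_len(n), lab), function(idx) {
      if (length(idx) < 2L) return(0)
      sum(D[idx, idx][upper.tri(D[idx, idx])])
    }, numeric(1))) / nPairs
  }, numeric(1))
  chosenK <- if (W[1L] < 1e-12 || kMax < 3L) 1L else {
    # curvature on the log scale: scale-invariant, so the elbow is where
    # the relative decay of W flattens rather than where its absolute
    # drops are largest
    lw <- log(pmax(W, W[1L] * 1e-9))
    ks <- 2:(kMax - 1L)
    curv <- lw[ks - 1L] - 2 * lw[ks] + lw[ks + 1L]
    ks[which.max(curv)]
  }
  lab <- stats::cutree(tree, k = chosenK)
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- stats::setNames(as.integer(relab[as.character(lab)]),
                            rownames(D))
  structure(list(distance = D, tree = tree, W = W, chosenK = chosenK,
                 labels = labels),
            class = "cohortClustering")
}

#' @export
print.cohortClustering <- function(x, ...) {
  cat("cohortClustering:", length(x$labels), "samples in", x$chosenK,
      "groups (elbow over k = 1..", length(x$W), ")\n", sep = " ")
  print(table(group = x$labels))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples
#' (1 = identical partitions, ~0 = random agreement).
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumA <- sum(comb2(rowSums(tab)))
  sumB <- sum(comb2(colSums(tab)))
  nPairs <- comb2(length(a))
  expected <- sumA * sumB / nPairs
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}
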