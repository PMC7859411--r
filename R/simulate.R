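# Synthetic chordoma-like cohort generator.  Emulates the statistical
# structure the analysis assumes -- ~80 tumors with low mutation burden,
# purity 0.2-0.9, five SCNA archetype groups, sparse SVs (~38 per tumor)
# with occasional chromothripsis, clonal SNV VAFs of purity*CCF/2 at ~76x
# depth, and marker-dependent survival -- and emits the generating truth
# alongside the data so every stage can be tested without controlled-access
# patient data.  Truth is written under a separate truth/ directory and is
# never read by analysis stages.

# arm-level events recurrently gained/lost in this tumor type
.GAIN_ARMS <- c("chr1q", "chr7p", "chr7q")
.LOSS_ARMS <- c("chr1p", "chr3p", "chr3q", "chr4p", "chr4q", "chr9p",
                "chr9q", "chr10p", "chr10q", "chr13q", "chr14q", "chr18p",
                "chr18q", "chr22q")

#' Synthetic-cohort configuration
#'
#' Defaults mirror the cohort the analysis is designed for: 80 tumors,
#' purity uniform on 0.2-0.9, 76x tumor / 41x normal depth, five SCNA
#' archetype groups in proportions 16:25:13:19:7, a mean of 38 background
#' SVs per tumor, chromothripsis in ~9% of tumors, ~300 somatic SNVs per
#' genome of which ~7% are coding (about 18 retained coding mutations, TMB
#' ~0.5/Mb over 35 Mb), and exponential proportional-hazards survival with
#' marker log-hazard-ratios taken from the driver-marker effect sizes the
#' package is meant to recover.
#'
#' @param nSamples cohort size.
#' @param purityRange uniform range for true purity.
#' @param depthMean,normalDepthMean Poisson mean sequencing depths.
#' @param snvsPerSample somatic variants drawn per sample.
#' @param codingFraction fraction of variants that are coding.
#' @param subclonalFraction fraction of variants with CCF < 1.
#' @param failFraction fraction of variants planted to fail one retention
#'   rule.
#' @param groupProportions proportions of the five SCNA archetypes (sum 1).
#' @param armInclusion per-arm probability that an archetype's signature
#'   arm event is present.
#' @param chromothripsisRate per-sample probability of a planted
#'   chromothripsis event.
#' @param svBackgroundRate Poisson mean of background SVs per tumor.
#' @param markerRates named rates for planted driver markers (pbrm1, setd2,
#'   cdkn2ab, tbxt, lyst, focal9q21).
#' @param h0Css,h0Rfs exponential baseline hazards per month.
#' @param logHRCss,logHRRfs named log hazard ratios applied to marker flags
#'   for each endpoint.
#' @param censorRange uniform censoring window (months).
#' @param seed integer seed fixing all randomness.
#' @return list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(nSamples = 80L,
                             purityRange = c(0.2, 0.9),
                             depthMean = 76, normalDepthMean = 41,
                             snvsPerSample = 300L,
                             codingFraction = 0.07,
                             subclonalFraction = 0.15,
                             failFraction = 0.10,
                             groupProportions = c(16, 25, 13, 19, 7) / 80,
                             armInclusion = 0.95,
                             chromothripsisRate = 7 / 80,
                             svBackgroundRate = 38,
                             markerRates = c(pbrm1 = 0.125, setd2 = 0.0375,
                                             cdkn2ab = 0.1375, tbxt = 0.05,
                                             lyst = 0.0375,
                                             focal9q21 = 0.15),
                             h0Css = 0.0025, h0Rfs = 0.015,
                             logHRCss = c(pbrm1 = log(4.79),
                                          del22q = log(5.88)),
                             logHRRfs = c(pbrm1 = log(5.72),
                                          del22q = log(3.74),
                                          del9q21 = log(3.63)),
                             censorRange = c(24, 120),
                             seed = 1L) {
  stopifnot(abs(sum(groupProportions) - 1) < 1e-8,
            length(groupProportions) == 5L,
            chromothripsisRate >= 0, svBackgroundRate >= 0,
            all(is.finite(c(logHRCss, logHRRfs))))
  structure(as.list(environment()), class = c("simulationConfig", "list"))
}

.armSet <- function(genome) {
  a <- genome@arms
  a <- a[genome@autosome[a$chrom], , drop = FALSE]
  a$key <- paste0(a$chrom, a$arm)
  a
}

# archetype arm assignment -> data.frame(key, direction)
.drawArmEvents <- function(group, arms, armInclusion) {
  gains <- character(); losses <- character()
  if (group == 1L) {
    block <- c("chr4p", "chr4q", "chr9p", "chr9q", "chr14q")
    losses <- .LOSS_ARMS[!(.LOSS_ARMS %in% block)]
    losses <- losses[stats::runif(length(losses)) < armInclusion]
    gains <- .GAIN_ARMS[stats::runif(length(.GAIN_ARMS)) < armInclusion]
  } else if (group == 2L) {
    losses <- .LOSS_ARMS[stats::runif(length(.LOSS_ARMS)) < armInclusion]
  } else if (group == 3L) {
    # scattered, mostly deletions: a small signature of the recurrently
    # deleted arms, shared across the group, plus rare extras
    sig <- c("chr1p", "chr3p", "chr9p", "chr9q", "chr10p", "chr10q",
             "chr22q")
    losses <- sig[stats::runif(length(sig)) < armInclusion]
    extra <- setdiff(.LOSS_ARMS, sig)
    losses <- c(losses, extra[stats::runif(length(extra)) < 0.05])
    gains <- .GAIN_ARMS[stats::runif(length(.GAIN_ARMS)) < 0.05]
  } else if (group == 4L) {
    losses <- arms$key[stats::runif(nrow(arms)) < 0.01]
  }
  rbind(
    if (length(gains)) data.frame(key = gains, direction = "gain"),
    if (length(losses)) data.frame(key = losses, direction = "loss")
  )
}

.simulateCN <- function(group, genome, cfg) {
  arms <- .armSet(genome)
  seg <- data.frame(chrom = arms$chrom, start = arms$start, end = arms$end,
                    tcn = 2L, mcnMinor = 1L, key = arms$key,
                    stringsAsFactors = FALSE)
  wgdFraction <- NA_real_
  events <- NULL
  if (group == 5L) {
    # double whole arms until just below the target MCN>=2 fraction, then
    # split the next arm so the fraction lands on the target exactly
    # doubled fraction concentrated around ~0.73 on support (0.55, 0.9):
    # doubled genomes are extensively, not marginally, doubled
    target <- 0.55 + 0.35 * stats::rbeta(1, 8, 6)
    # canonical arm order: profiles of doubled tumors are nested (WGD of
    # the full genome followed by progressively ordered arm losses), which
    # keeps the archetype internally coherent
    ord <- seq_len(nrow(seg))
    widths <- (seg$end - seg$start)[ord]
    total <- sum(seg$end - seg$start)
    cum <- cumsum(widths) / total
    last <- which(cum >= target)[1L]
    full <- ord[seq_len(last - 1L)]
    seg$tcn[full] <- 4L; seg$mcnMinor[full] <- 2L
    needBp <- round(target * total - sum(widths[seq_len(last - 1L)]))
    if (needBp > 0) {
      i <- ord[last]
      part <- seg[i, ]; part$end <- part$start + needBp
      part$tcn <- 4L; part$mcnMinor <- 2L
      seg[i, "start"] <- seg[i, "start"] + needBp
      seg <- rbind(seg, part)
      seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    }
    wgdFraction <- target
    events <- data.frame(key = seg$key[seg$tcn == 4L], direction = "gain")
  } else {
    events <- .drawArmEvents(group, arms, cfg$armInclusion)
    if (!is.null(events) && nrow(events)) {
      i <- match(events$key, seg$key)
      loss <- events$direction == "loss"
      seg$tcn[i[loss]] <- 1L; seg$mcnMinor[i[loss]] <- 0L
      seg$tcn[i[!loss]] <- 3L; seg$mcnMinor[i[!loss]] <- 1L
    }
  }
  list(segments = seg, events = events, wgdFraction = wgdFraction)
}

#' Simulate an archetype copy-number profile
#'
#' Draws one profile from the five-group SCNA archetype model: Group 1,
#' extensive arm events but no deletions of chromosomes 4, 9 or 14;
#' Group 2, extensive deletions and no gains; Group 3, scattered (mostly
#' deletion) events; Group 4, near-diploid; Group 5, whole-genome doubled
#' by construction (a fraction drawn in (0.55, 0.9) of the autosomal genome
#' at major copy number 2).
#'
#' @param group archetype 1..5.
#' @param genome a \linkS4class{GenomeBuild}.
#' @param config a [simulationConfig()].
#' @param sampleId sample identifier.
#' @return a \linkS4class{CNProfile} covering the autosomal arms.
#' @export
simulateCNProfile <- function(group, genome, config = simulationConfig(),
                              sampleId = "S1") {
  stopifnot(group %in% 1:5)
  cn <- .simulateCN(group, genome, config)
  CNProfile(sampleId, cn$segments[, c("chrom", "start", "end", "tcn",
                                      "mcnMinor")])
}

# carve [start,end) out of a segment data.frame and insert replacement rows
.applyFocal <- function(seg, chrom, start, end, tcn, mcnMinor) {
  keep <- list(); add <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    if (s$chrom != chrom || s$end <= start || s$start >= end) {
      keep[[length(keep) + 1L]] <- s
      next
    }
    if (s$start < start) {
      left <- s; left$end <- start
      keep[[length(keep) + 1L]] <- left
    }
    if (s$end > end) {
      right <- s; right$start <- end
      keep[[length(keep) + 1L]] <- right
    }
  }
  add <- data.frame(chrom = chrom, start = start, end = end, tcn = tcn,
                    mcnMinor = mcnMinor, key = NA_character_,
                    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, keep), add)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Simulate somatic variants for one tumor
#'
#' Variant positions are uniform over the profile's covered genome; tumor
#' depth is Poisson(\code{depthMean}) and the alt count of a variant with
#' cancer-cell fraction c is Binomial(depth, purity * c / 2) — the VAF
#' model for a heterozygous somatic variant in a copy-neutral region (local
#' copy number is deliberately ignored elsewhere; purity estimation only
#' consumes copy-neutral variants).  A configurable fraction is subclonal
#' (c ~ U(0.2, 0.8)); normal-tissue counts are near zero; a configurable
#' fraction of records is planted to fail exactly one retention rule.
#'
#' @param profile the tumor's \linkS4class{CNProfile}.
#' @param purity true purity in (0, 1].
#' @param config a [simulationConfig()].
#' @param n number of variants (default \code{config$snvsPerSample}).
#' @return variant data.frame in the [readVariants()] schema.
#' @export
simulateVariants <- function(profile, purity, config = simulationConfig(),
                             n = config$snvsPerSample) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  seg <- segments(profile)
  w <- GenomicRanges::width(seg)
  idx <- sample.int(length(seg), n, replace = TRUE, prob = w)
  pos <- GenomicRanges::start(seg)[idx] +
    floor(stats::runif(n) * w[idx])
  chrom <- as.character(GenomicRanges::seqnames(seg))[idx]
  ccf <- ifelse(stats::runif(n) < config$subclonalFraction,
                stats::runif(n, 0.2, 0.8), 1)
  tDepth <- pmax(1L, stats::rpois(n, config$depthMean))
  tAlt <- stats::rbinom(n, tDepth, pmin(1, purity * ccf / 2))
  nDepth <- pmax(1L, stats::rpois(n, config$normalDepthMean))
  nAlt <- stats::rbinom(n, nDepth, 0.001)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  indel <- stats::runif(n) < 0.05
  alt[indel] <- paste0(alt[indel], sample(bases, sum(indel), replace = TRUE))
  df <- data.frame(
    sample = sampleId(profile), chrom = chrom, pos = pos, ref = ref,
    alt = alt,
    t_alt = tAlt, t_depth = tDepth, n_alt = nAlt, n_depth = nDepth,
    n_callers = sample(2:5, n, replace = TRUE,
                       prob = c(0.3, 0.3, 0.25, 0.15)),
    pop_maf = 0,
    is_coding = stats::runif(n) < config$codingFraction,
    is_nonsynonymous = FALSE, gene = "", stringsAsFactors = FALSE
  )
  df$is_nonsynonymous <- df$is_coding & stats::runif(n) < 0.75
  fail <- which(stats::runif(n) < config$failFraction)
  if (length(fail)) {
    mode <- sample(c("n_callers", "t_vaf", "n_vaf", "t_alt", "t_depth",
                     "n_depth", "pop_maf"), length(fail), replace = TRUE)
    for (j in seq_along(fail)) {
      i <- fail[j]
      switch(mode[j],
        n_callers = { df$n_callers[i] <- 1L },
        t_vaf = { df$t_depth[i] <- 120L; df$t_alt[i] <- 6L },
        n_vaf = { df$n_depth[i] <- 40L; df$n_alt[i] <- 2L },
        t_alt = { df$t_depth[i] <- 20L; df$t_alt[i] <- 2L },
        t_depth = { df$t_depth[i] <- 6L; df$t_alt[i] <- 3L },
        n_depth = { df$n_depth[i] <- 4L; df$n_alt[i] <- 0L },
        pop_maf = { df$pop_maf[i] <- 0.01 })
    }
  }
  df
}

.strandsForClass <- function(cls) {
  switch(cls,
         DEL = c("+", "-"), DUP = c("-", "+"),
         h2hINV = c("+", "+"), t2tINV = c("-", "-"),
         TRA = sample(c("+", "-"), 2L, replace = TRUE))
}

.inAvoid <- function(chrom, pos, avoid) {
  if (is.null(avoid) || nrow(avoid) == 0L) return(FALSE)
  any(avoid$chrom == chrom & pos > avoid$start & pos <= avoid$end)
}

.randomBreakend <- function(genome, avoid, chroms = NULL) {
  lens <- chromLengths(genome, autosomesOnly = TRUE)
  if (!is.null(chroms)) lens <- lens[chroms]
  for (try in 1:50) {
    ch <- sample(names(lens), 1L, prob = lens)
    pos <- 1 + floor(stats::runif(1) * (lens[[ch]] - 1))
    if (!.inAvoid(ch, pos, avoid)) return(list(chrom = ch, pos = pos))
  }
  list(chrom = ch, pos = pos)
}

#' Simulate a tumor's structural variants
#'
#' Background rearrangements are scattered uniformly over the autosomes
#' (about a quarter inter-chromosomal, intra-chromosomal spans log-uniform
#' between 10 kb and 10 Mb) with classes drawn at random.  Optionally one
#' chromothripsis event is planted: 12 mutually interleaved SVs over a
#' ~30 Mb window with a deletion-dominated join-class mix (9 DEL-like, one
#' each of the other classes — the signature of fragment loss during
#' shattering), and the window's segments rewritten to oscillate between
#' total copy numbers 2 and 1 across 11 adjacent segments.
#'
#' @param profile the tumor's \linkS4class{CNProfile} (rewritten in the
#'   returned copy when an event is planted).
#' @param config a [simulationConfig()].
#' @param genome a \linkS4class{GenomeBuild}.
#' @param plantChromothripsis plant one event (default FALSE).
#' @param avoid optional data.frame (chrom, start, end; 0-based half-open)
#'   of loci breakends must not hit.
#' @param eventChroms candidate chromosomes for the planted event (default:
#'   autosomes longer than 80 Mb not on chr9/chr22).
#' @return list with \code{svs} (data.frame), \code{profile} (possibly
#'   rewritten) and \code{event} (NULL or list(chrom, start, end)).
#' @export
simulateSVSet <- function(profile, config = simulationConfig(), genome,
                          plantChromothripsis = FALSE, avoid = NULL,
                          eventChroms = NULL) {
  sid <- sampleId(profile)
  nBg <- stats::rpois(1, config$svBackgroundRate)
  rows <- vector("list", nBg)
  lens <- chromLengths(genome, autosomesOnly = TRUE)
  for (i in seq_len(nBg)) {
    if (stats::runif(1) < 0.25) {
      b1 <- .randomBreakend(genome, avoid)
      repeat {
        b2 <- .randomBreakend(genome, avoid)
        if (b2$chrom != b1$chrom) break
      }
      s <- .strandsForClass("TRA")
      rows[[i]] <- data.frame(sample = sid, chrom1 = b1$chrom, pos1 = b1$pos,
                              strand1 = s[1], chrom2 = b2$chrom,
                              pos2 = b2$pos, strand2 = s[2],
                              sv_class = "TRA", stringsAsFactors = FALSE)
    } else {
      cls <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), 1L)
      span <- 10^stats::runif(1, 4, 7)
      repeat {
        ch <- sample(names(lens), 1L, prob = lens)
        p1 <- 1 + floor(stats::runif(1) * (lens[[ch]] - span - 1))
        p2 <- round(p1 + span)
        if (!.inAvoid(ch, p1, avoid) && !.inAvoid(ch, p2, avoid)) break
      }
      s <- .strandsForClass(cls)
      rows[[i]] <- data.frame(sample = sid, chrom1 = ch, pos1 = p1,
                              strand1 = s[1], chrom2 = ch, pos2 = p2,
                              strand2 = s[2], sv_class = cls,
                              stringsAsFactors = FALSE)
    }
  }
  svs <- if (nBg) do.call(rbind, rows) else
    data.frame(sample = character(), chrom1 = character(), pos1 = numeric(),
               strand1 = character(), chrom2 = character(), pos2 = numeric(),
               strand2 = character(), sv_class = character())
  event <- NULL
  if (plantChromothripsis) {
    if (is.null(eventChroms)) {
      cand <- names(lens)[lens > 8e7 & !(names(lens) %in% c("chr9", "chr22"))]
    } else cand <- eventChroms
    ch <- sample(cand, 1L)
    width <- 3e7
    lo <- floor(stats::runif(1) * (lens[[ch]] - width - 2e6)) + 1e6
    hi <- lo + width
    nSV <- 12L
    pts <- sort(floor(stats::runif(2 * nSV, lo + 1, hi)))
    while (anyDuplicated(pts))
      pts <- sort(floor(stats::runif(2 * nSV, lo + 1, hi)))
    classes <- sample(c(rep("DEL", 9L), "DUP", "h2hINV", "t2tINV"))
    ev <- do.call(rbind, lapply(seq_len(nSV), function(i) {
      s <- .strandsForClass(classes[i])
      data.frame(sample = sid, chrom1 = ch, pos1 = pts[i], strand1 = s[1],
                 chrom2 = ch, pos2 = pts[i + nSV], strand2 = s[2],
                 sv_class = classes[i], stringsAsFactors = FALSE)
    }))
    svs <- rbind(svs, ev)
    # rewrite the window to oscillate between total CN 2 and 1
    segDf <- segmentTable(profile)
    segDf <- data.frame(chrom = segDf$chrom, start = segDf$start - 1,
                        end = segDf$end, tcn = segDf$tcn,
                        mcnMinor = segDf$mcn_minor, key = NA_character_,
                        stringsAsFactors = FALSE)
    bounds <- round(seq(lo, hi, length.out = 12L))
    for (i in seq_len(11L)) {
      segDf <- .applyFocal(segDf, ch, bounds[i], bounds[i + 1L],
                           tcn = if (i %% 2L == 1L) 2L else 1L,
                           mcnMinor = if (i %% 2L == 1L) 1L else 0L)
    }
    profile <- CNProfile(sid, segDf[, c("chrom", "start", "end", "tcn",
                                        "mcnMinor")])
    event <- list(chrom = ch, start = lo, end = hi)
  }
  list(svs = svs, profile = profile, event = event)
}

#' Simulate survival times under an exponential proportional-hazards model
#'
#' Event times are exponential with hazard
#' \eqn{h_0 \exp(\beta^T x)}; censoring is independent uniform on
#' \code{censorRange}.
#'
#' @param X design matrix (or data.frame) of marker/covariate columns.
#' @param beta named log hazard ratios for (a subset of) X's columns.
#' @param h0 baseline hazard per month.
#' @param censorRange uniform censoring window in months.
#' @return data.frame with \code{time} and \code{event}.
#' @export
simulateSurvival <- function(X, beta, h0, censorRange = c(24, 120)) {
  stopifnot(all(is.finite(beta)), h0 > 0)
  X <- as.matrix(as.data.frame(X)[, names(beta), drop = FALSE])
  n <- nrow(X)
  lp <- as.numeric(X %*% beta)
  t <- stats::rexp(n, rate = h0 * exp(lp))
  cens <- stats::runif(n, censorRange[1], censorRange[2])
  data.frame(time = pmin(t, cens), event = t <= cens)
}

#' Simulate a full cohort bundle on disk
#'
#' Generates the cohort (profiles, variants, SVs, clinical metadata) and
#' writes \code{segments.tsv}, \code{variants.tsv}, \code{svs.bedpe},
#' \code{metadata.tsv} under \code{outDir}, plus the generating truth under
#' \code{outDir/truth/truth.tsv}.  Analysis stages must read only the data
#' files, never the truth directory.  The same seed yields a byte-identical
#' bundle.
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory (created; must be empty unless
#'   \code{force}).
#' @param force overwrite a non-empty directory (default FALSE).
#' @param genome a \linkS4class{GenomeBuild} (default [hg19Genome()]).
#' @return (invisibly) list with \code{paths}, \code{truth},
#'   \code{profiles}, \code{variants}, \code{svs}, \code{metadata}.
#' @export
simulateCohort <- function(config = simulationConfig(), outDir,
                           force = FALSE, genome = hg19Genome()) {
  if (dir.exists(outDir) && length(dir(outDir)) > 0L && !force)
    stop("output directory exists and is not empty (use force = TRUE)")
  dir.create(file.path(outDir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$nSamples
  ids <- sprintf("S%03d", seq_len(n))
  groups <- sample(1:5, n, replace = TRUE, prob = config$groupProportions)
  # mutually exclusive driver assignment for pbrm1/setd2/cdkn2ab
  rates <- config$markerRates
  shuffled <- sample(n)
  nP <- round(rates[["pbrm1"]] * n)
  nS <- round(rates[["setd2"]] * n)
  nC <- round(rates[["cdkn2ab"]] * n)
  pbrm1 <- seq_len(n) %in% shuffled[seq_len(nP)]
  setd2 <- seq_len(n) %in% shuffled[nP + seq_len(nS)]
  cdkn2ab <- seq_len(n) %in% shuffled[nP + nS + seq_len(nC)]
  tbxt <- stats::runif(n) < rates[["tbxt"]]
  lyst <- stats::runif(n) < rates[["lyst"]]
  focal9q <- stats::runif(n) < rates[["focal9q21"]]
  purityTruth <- stats::runif(n, config$purityRange[1], config$purityRange[2])
  ctPlanted <- stats::runif(n) < config$chromothripsisRate
  loci <- defaultGeneLoci()
  locus <- function(g) loci[loci$gene == g, , drop = FALSE]
  profiles <- vector("list", n); names(profiles) <- ids
  variantList <- vector("list", n)
  svList <- vector("list", n)
  truthRows <- vector("list", n)
  for (i in seq_len(n)) {
    cn <- .simulateCN(groups[i], genome, config)
    seg <- cn$segments
    lostArms <- if (!is.null(cn$events))
      cn$events$key[cn$events$direction == "loss"] else character()
    # planted focal events
    cdknMut <- FALSE
    if (cdkn2ab[i]) {
      if (stats::runif(1) < 0.8) {
        lc <- locus("CDKN2A"); lc2 <- locus("CDKN2B")
        seg <- .applyFocal(seg, "chr9", lc$start, lc2$end, 0L, 0L)
      } else cdknMut <- TRUE
    }
    if (focal9q[i]) {
      w <- locus("win9q21")
      seg <- .applyFocal(seg, "chr9", w$start, w$end, 1L, 0L)
    }
    profile <- CNProfile(ids[i], seg[, c("chrom", "start", "end", "tcn",
                                         "mcnMinor")])
    # SVs (background avoids all driver loci so truth stays identifiable)
    sv <- simulateSVSet(profile, config, genome,
                        plantChromothripsis = ctPlanted[i], avoid = loci)
    profile <- sv$profile
    svs <- sv$svs
    # marker realizations
    plantVar <- function(gene, nonsyn = TRUE) {
      l <- locus(gene)
      td <- max(stats::rpois(1, config$depthMean), 10L)
      ta <- max(stats::rbinom(1, td, purityTruth[i] / 2),
                ceiling(0.07 * td), 3L)
      data.frame(sample = ids[i], chrom = l$chrom,
                 pos = l$start + 1 + floor(stats::runif(1) * (l$end - l$start)),
                 ref = "C", alt = "T", t_alt = ta, t_depth = td, n_alt = 0L,
                 n_depth = max(stats::rpois(1, config$normalDepthMean), 6L),
                 n_callers = 3L, pop_maf = 0, is_coding = TRUE,
                 is_nonsynonymous = nonsyn, gene = gene,
                 stringsAsFactors = FALSE)
    }
    plantSV <- function(gene, cls = "TRA") {
      l <- locus(gene)
      p1 <- l$start + 1 + floor(stats::runif(1) * (l$end - l$start))
      b2 <- .randomBreakend(genome, loci)
      s <- .strandsForClass(cls)
      if (cls != "TRA") {
        p2 <- min(p1 + round(10^stats::runif(1, 4, 5)),
                  chromLengths(genome)[[l$chrom]])
        data.frame(sample = ids[i], chrom1 = l$chrom, pos1 = p1,
                   strand1 = s[1], chrom2 = l$chrom, pos2 = p2,
                   strand2 = s[2], sv_class = cls, stringsAsFactors = FALSE)
      } else {
        data.frame(sample = ids[i], chrom1 = l$chrom, pos1 = p1,
                   strand1 = s[1], chrom2 = b2$chrom, pos2 = b2$pos,
                   strand2 = s[2], sv_class = "TRA", stringsAsFactors = FALSE)
      }
    }
    vars <- simulateVariants(profile, purityTruth[i], config)
    if (pbrm1[i]) {
      if (stats::runif(1) < 0.5) vars <- rbind(vars, plantVar("PBRM1"))
      else svs <- rbind(svs, plantSV("PBRM1"))
    }
    if (setd2[i]) vars <- rbind(vars, plantVar("SETD2"))
    if (cdknMut) vars <- rbind(vars, plantVar("CDKN2A"))
    if (tbxt[i]) svs <- rbind(svs, plantSV("TBXT", cls = "DUP"))
    if (lyst[i]) vars <- rbind(vars, plantVar("LYST"))
    profiles[[i]] <- profile
    variantList[[i]] <- vars
    svList[[i]] <- svs
    truthRows[[i]] <- data.frame(
      sample = ids[i], purity = round(purityTruth[i], 6),
      group = groups[i], wgd = groups[i] == 5L,
      pbrm1_plus = pbrm1[i], setd2_plus = setd2[i],
      cdkn2ab_plus = cdkn2ab[i], tbxt_plus = tbxt[i], lyst_plus = lyst[i],
      del22q = "chr22q" %in% lostArms,
      del9q21_focal = focal9q[i] || ("chr9q" %in% lostArms),
      chromothripsis = if (is.null(sv$event)) "" else
        sprintf("%s:%d-%d", sv$event$chrom, sv$event$start, sv$event$end),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truthRows)
  # survival from the true marker flags
  Xcss <- data.frame(pbrm1 = as.numeric(truth$pbrm1_plus),
                     del22q = as.numeric(truth$del22q))
  Xrfs <- cbind(Xcss, del9q21 = as.numeric(truth$del9q21_focal))
  os <- simulateSurvival(Xcss, config$logHRCss, config$h0Css,
                         config$censorRange)
  rfsRaw <- simulateSurvival(Xrfs, config$logHRRfs, config$h0Rfs,
                             config$censorRange)
  rfsTime <- pmin(rfsRaw$time, os$time)
  rfsEvent <- rfsRaw$event & rfsRaw$time <= os$time
  metadata <- data.frame(
    sample = ids,
    age = round(pmin(pmax(stats::rnorm(n, 44.7, 16), 7), 79), 1),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.625, 0.375)),
    histology = sample(c("classic", "chondroid", "dedifferentiated"), n,
                       replace = TRUE, prob = c(0.80, 0.175, 0.025)),
    pre_rt = stats::runif(n) < 0.15,
    post_rt = stats::runif(n) < 0.525,
    recurred = rfsEvent,
    rfs_months = round(pmax(rfsTime, 0.1), 3),
    died = os$event,
    os_months = round(pmax(os$time, 0.1), 3),
    stringsAsFactors = FALSE
  )
  metadata$rfs_months <- pmin(metadata$rfs_months, metadata$os_months)
  paths <- list(
    segments = file.path(outDir, "segments.tsv"),
    variants = file.path(outDir, "variants.tsv"),
    svs = file.path(outDir, "svs.bedpe"),
    metadata = file.path(outDir, "metadata.tsv"),
    truth = file.path(outDir, "truth", "truth.tsv")
  )
  writeSegments(profiles, paths$segments)
  writeTable(do.call(rbind, variantList), paths$variants)
  writeSVBedpe(do.call(rbind, svList), paths$svs)
  writeTable(metadata, paths$metadata)
  writeTable(truth, paths$truth)
  invisible(list(paths = paths, truth = truth, profiles = profiles,
                 variants = do.call(rbind, variantList),
                 svs = do.call(rbind, svList), metadata = metadata))
}
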