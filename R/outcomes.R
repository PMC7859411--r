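# Driver-marker assembly and outcome models: per-sample alteration flags
# for the recurrent chordoma drivers, mutual-exclusivity testing,
# covariate-adjusted Cox proportional-hazards fits for chordoma-specific
# (CSS) and recurrence-free (RFS) survival, a Bonferroni-corrected scan of
# arm-level events, and paired primary/recurrence shared-alteration
# fractions.

#' Default driver-gene loci (hg19)
#'
#' Genomic intervals (0-based half-open) for the genes used in marker
#' assembly: PBRM1 and SETD2 (chromatin remodeling, chr3p21), CDKN2A/B
#' (chr9p21.3), SMARCB1 (chr22q), TBXT (the brachyury gene T, chr6q27) and
#' LYST (chr1q42), plus the focal 9q21.11 deletion window.
#'
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{start},
#'   \code{end}.
#' @export
defaultGeneLoci <- function() {
  data.frame(
    gene = c("PBRM1", "SETD2", "CDKN2A", "CDKN2B", "SMARCB1", "TBXT",
             "LYST", "win9q21"),
    chrom = c("chr3", "chr3", "chr9", "chr9", "chr22", "chr6", "chr1",
              "chr9"),
    start = c(52579367, 47057897, 21967750, 22002901, 24129149, 166571144,
              235824345, 71000000),
    end = c(52719866, 47205467, 21995300, 22009280, 24176705, 166582804,
            236030227, 71700000),
    stringsAsFactors = FALSE
  )
}

.lociRanges <- function(loci) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(loci$start + 1, loci$end),
                         gene = loci$gene)
}

.breakendInLocus <- function(svs, locus) {
  (svs$chrom1 == locus$chrom & svs$pos1 > locus$start &
     svs$pos1 <= locus$end) |
  (svs$chrom2 == locus$chrom & svs$pos2 > locus$start &
     svs$pos2 <= locus$end)
}

.segOverLocus <- function(seg, locus, predicate) {
  gr <- GenomicRanges::GRanges(locus$chrom,
                               IRanges::IRanges(locus$start + 1, locus$end))
  hits <- S4Vectors::queryHits(
    suppressWarnings(GenomicRanges::findOverlaps(seg, gr)))
  any(predicate(S4Vectors::mcols(seg)[hits, , drop = FALSE]))
}

#' Assemble per-sample driver-marker flags
#'
#' A gene is flagged altered ("gene+") when the sample carries a retained
#' nonsynonymous variant annotated to the gene, or an SV breakend inside
#' the gene's interval; for CDKN2A/B a homozygously deleted segment
#' (tcn = 0) overlapping either locus also qualifies.  \code{del22q} is an
#' arm-level 22q loss from [callArmEvents()]; \code{del9q21_focal} is any
#' deletion segment (tcn < 2) overlapping the configured 9q21.11 window.
#' The combined markers are exact ORs: \code{combined_css} =
#' PBRM1+ OR del22q; \code{combined_rfs} = PBRM1+ OR del9q21_focal OR
#' del22q.
#'
#' @param variants retained (filtered) variant data.frame for the cohort.
#' @param svs cohort SV data.frame.
#' @param profiles named list of \linkS4class{CNProfile}.
#' @param genome a \linkS4class{GenomeBuild}.
#' @param loci gene-locus table (default [defaultGeneLoci()]); must contain
#'   PBRM1, SETD2, CDKN2A, CDKN2B, TBXT, LYST and win9q21.
#' @return data.frame with one row per profile: \code{sample},
#'   \code{pbrm1_plus}, \code{setd2_plus}, \code{cdkn2ab_plus},
#'   \code{tbxt_plus}, \code{lyst_plus}, \code{del22q},
#'   \code{del9q21_focal}, \code{combined_css}, \code{combined_rfs}.
#' @export
assembleMarkers <- function(variants, svs, profiles, genome,
                            loci = defaultGeneLoci()) {
  need <- c("PBRM1", "SETD2", "CDKN2A", "CDKN2B", "TBXT", "LYST", "win9q21")
  miss <- setdiff(need, loci$gene)
  if (length(miss))
    stop("missing locus definition for: ", paste(miss, collapse = ", "))
  locus <- function(g) loci[loci$gene == g, , drop = FALSE]
  rows <- lapply(profiles, function(prof) {
    sid <- sampleId(prof)
    v <- variants[variants$sample == sid & variants$is_nonsynonymous, ,
                  drop = FALSE]
    sv <- svs[svs$sample == sid, , drop = FALSE]
    seg <- segments(prof)
    genePlus <- function(g) {
      any(v$gene == g) || any(.breakendInLocus(sv, locus(g)))
    }
    cdkn <- genePlus("CDKN2A") || genePlus("CDKN2B") ||
      .segOverLocus(seg, locus("CDKN2A"), function(m) m$tcn == 0L) ||
      .segOverLocus(seg, locus("CDKN2B"), function(m) m$tcn == 0L)
    arm <- callArmEvents(prof, genome, warnUncovered = FALSE)
    del22q <- any(arm$chrom == "chr22" & arm$arm == "q" &
                    arm$direction == "loss")
    del9q21 <- .segOverLocus(seg, locus("win9q21"),
                             function(m) m$tcn < 2L)
    pbrm1 <- genePlus("PBRM1")
    data.frame(
      sample = sid,
      pbrm1_plus = pbrm1,
      setd2_plus = genePlus("SETD2"),
      cdkn2ab_plus = cdkn,
      tbxt_plus = genePlus("TBXT"),
      lyst_plus = genePlus("LYST"),
      del22q = del22q,
      del9q21_focal = del9q21,
      combined_css = pbrm1 || del22q,
      combined_rfs = pbrm1 || del9q21 || del22q,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample), , drop = FALSE]
}

#' Mutual-exclusivity test for two marker flags
#'
#' One-sided Fisher's exact test on the 2x2 co-occurrence table with
#' alternative "fewer co-occurrences than expected under independence".
#'
#' @param flagsA,flagsB equal-length logical vectors.
#' @return list with \code{overlap} (co-occurrence count), \code{p} and
#'   \code{degenerate} (TRUE when either flag never occurs, in which case
#'   p = 1).
#' @export
mutualExclusivity <- function(flagsA, flagsB) {
  stopifnot(length(flagsA) == length(flagsB))
  overlap <- sum(flagsA & flagsB)
  if (!any(flagsA) || !any(flagsB))
    return(list(overlap = overlap, p = 1, degenerate = TRUE))
  tab <- table(factor(flagsA, c(FALSE, TRUE)), factor(flagsB, c(FALSE, TRUE)))
  p <- stats::fisher.test(tab, alternative = "less")$p.value
  list(overlap = overlap, p = p, degenerate = FALSE)
}

.endpointSurv <- function(metadata, endpoint) {
  if (endpoint == "css")
    survival::Surv(metadata$os_months, metadata$died)
  else
    survival::Surv(metadata$rfs_months, metadata$recurred)
}

#' Covariate-adjusted proportional-hazards fit for one marker
#'
#' Cox model (Efron tie handling) of the endpoint on the marker with
#' adjustment for age, sex, and pre-/post-surgery radiation therapy.
#' Chordoma-specific survival ("css") uses (os_months, died); recurrence-
#' free survival ("rfs") uses (rfs_months, recurred).
#'
#' @param metadata clinical data.frame (see [readMetadata()]).
#' @param markers marker data.frame (see [assembleMarkers()]); joined to
#'   metadata by \code{sample}.
#' @param marker marker column name.
#' @param endpoint "css" or "rfs".
#' @param adjust covariate column names (default age, sex, pre_rt,
#'   post_rt); set \code{character()} for an unadjusted fit.
#' @return data.frame with endpoint, marker, \code{hr}, \code{ci_lo},
#'   \code{ci_hi}, \code{p}, \code{n}, \code{n_events}, \code{fitted},
#'   \code{reason}.  A marker that is constant, or with an event-free
#'   stratum, yields a no-fit row with the reason.
#' @export
fitPH <- function(metadata, markers, marker, endpoint = c("css", "rfs"),
                  adjust = c("age", "sex", "pre_rt", "post_rt")) {
  endpoint <- match.arg(endpoint)
  df <- merge(metadata, markers, by = "sample")
  noFit <- function(reason) data.frame(
    endpoint = endpoint, marker = marker, hr = NA_real_, ci_lo = NA_real_,
    ci_hi = NA_real_, p = NA_real_, n = nrow(df),
    n_events = sum(if (endpoint == "css") df$died else df$recurred),
    fitted = FALSE, reason = reason, stringsAsFactors = FALSE)
  x <- df[[marker]]
  if (length(unique(x)) < 2L)
    return(noFit("marker constant across cohort"))
  ev <- if (endpoint == "css") df$died else df$recurred
  if (any(tapply(ev, x, sum) < 1L))
    return(noFit("a marker stratum has no events"))
  df$.marker <- as.logical(x)
  fml <- stats::reformulate(c(".marker", adjust),
                            response = ".surv")
  df$.surv <- .endpointSurv(df, endpoint)
  fit <- try(survival::coxph(fml, data = df, ties = "efron"), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(noFit("coxph failed to converge"))
  sm <- summary(fit)
  i <- grep("^\\.marker", rownames(sm$coefficients))[1L]
  data.frame(
    endpoint = endpoint, marker = marker,
    hr = unname(sm$coefficients[i, "exp(coef)"]),
    ci_lo = unname(sm$conf.int[i, "lower .95"]),
    ci_hi = unname(sm$conf.int[i, "upper .95"]),
    p = unname(sm$coefficients[i, "Pr(>|z|)"]),
    n = sm$n, n_events = sm$nevent, fitted = TRUE,
    reason = NA_character_, stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier curves per marker stratum
#'
#' @inheritParams fitPH
#' @return data.frame with \code{stratum}, \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event} — plot-ready KM step data.
#' @export
kmCurves <- function(metadata, markers, marker, endpoint = c("css", "rfs")) {
  endpoint <- match.arg(endpoint)
  df <- merge(metadata, markers, by = "sample")
  df$.marker <- factor(ifelse(df[[marker]], paste0(marker, "+"),
                              paste0(marker, "-")))
  df$.surv <- .endpointSurv(df, endpoint)
  sf <- survival::survfit(.surv ~ .marker, data = df)
  strata <- rep(names(sf$strata), sf$strata)
  data.frame(stratum = sub("^\\.marker=", "", strata), time = sf$time,
             surv = sf$surv, n_risk = sf$n.risk, n_event = sf$n.event,
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected survival scan over arm-level events
#'
#' Fits the adjusted proportional-hazards model for each arm event flag and
#' applies Bonferroni correction \eqn{p_{adj} = \min(1, m \cdot p)} over
#' the \code{m} events tested.
#'
#' @param metadata clinical data.frame.
#' @param armFlags data.frame with \code{sample} plus one logical column
#'   per arm event.
#' @param endpoint "css" or "rfs".
#' @param m number of tests for the correction (default: number of arm
#'   event columns).
#' @param alpha significance level on the corrected p (default 0.05).
#' @return data.frame of per-event fits with \code{p_adj},
#'   \code{bonferroni_m} and \code{significant}.
#' @export
armScan <- function(metadata, armFlags, endpoint = c("css", "rfs"),
                    m = NULL, alpha = 0.05) {
  endpoint <- match.arg(endpoint)
  events <- setdiff(names(armFlags), "sample")
  if (is.null(m)) m <- length(events)
  fits <- do.call(rbind, lapply(events, function(ev)
    fitPH(metadata, armFlags[, c("sample", ev)], ev, endpoint)))
  fits$bonferroni_m <- m
  fits$p_adj <- pmin(1, m * fits$p)
  fits$significant <- !is.na(fits$p_adj) & fits$p_adj < alpha
  fits
}

.propShared <- function(keysP, keysR) {
  shared <- length(intersect(keysP, keysR))
  pOnly <- length(setdiff(keysP, keysR))
  rOnly <- length(setdiff(keysR, keysP))
  total <- shared + pOnly + rOnly
  if (total == 0L) return(c(shared = NA_real_, primary_only = NA_real_,
                            recurrence_only = NA_real_))
  c(shared = shared / total, primary_only = pOnly / total,
    recurrence_only = rOnly / total)
}

#' Shared-alteration fractions for a paired primary/recurrence sample
#'
#' For SNVs and indels, identity is (chrom, pos, ref, alt) and the three
#' proportions (shared, primary-only, recurrence-only) are taken over the
#' union of the pair's alterations.  For SCNAs, sharing is measured in
#' base pairs: over the jointly covered genome, bp whose five-state CN
#' classification is identical and non-neutral in both samples are shared,
#' and bp altered in only one sample (or discordantly altered) count
#' toward that sample's exclusive fraction.
#'
#' @param variantsP,variantsR retained variant data.frames of the primary
#'   and recurrence samples.
#' @param profileP,profileR their \linkS4class{CNProfile}s.
#' @param genome a \linkS4class{GenomeBuild}.
#' @return data.frame with columns \code{class} ("SCNA", "SNV", "indel"),
#'   \code{shared}, \code{primary_only}, \code{recurrence_only} (each row
#'   sums to 1; NA when the pair has no alteration of that class).
#' @export
sharedFraction <- function(variantsP, variantsR, profileP, profileR,
                           genome) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  isIndel <- function(v) nchar(v$ref) != nchar(v$alt)
  snvP <- key(variantsP[!isIndel(variantsP), , drop = FALSE])
  snvR <- key(variantsR[!isIndel(variantsR), , drop = FALSE])
  indP <- key(variantsP[isIndel(variantsP), , drop = FALSE])
  indR <- key(variantsR[isIndel(variantsR), , drop = FALSE])
  sm <- .stateMatrix(list(profileP, profileR), genome)
  both <- !is.na(sm$S[1L, ]) & !is.na(sm$S[2L, ])
  neutral <- match("NEUTRAL", .CN_STATES)
  aP <- both & sm$S[1L, ] != neutral
  aR <- both & sm$S[2L, ] != neutral
  sharedBp <- sum(sm$w[aP & aR & sm$S[1L, ] == sm$S[2L, ]])
  pBp <- sum(sm$w[aP]) - sharedBp
  rBp <- sum(sm$w[aR]) - sharedBp
  totBp <- sharedBp + pBp + rBp
  scna <- if (totBp == 0) c(NA_real_, NA_real_, NA_real_) else
    c(sharedBp, pBp, rBp) / totBp
  out <- rbind(
    data.frame(class = "SCNA", shared = scna[1L], primary_only = scna[2L],
               recurrence_only = scna[3L], stringsAsFactors = FALSE),
    data.frame(class = "SNV", t(.propShared(snvP, snvR)),
               stringsAsFactors = FALSE),
    data.frame(class = "indel", t(.propShared(indP, indR)),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}
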