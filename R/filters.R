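#' Ensemble variant-retention filter configuration
#'
#' Thresholds of the somatic retention filter: variants are kept only when
#' supported by two or more callers, with tumor VAF >= 0.07, normal VAF
#' <= 0.02, at least 3 alt reads and depth >= 8 in tumor, depth >= 6 in
#' normal, and population minor-allele frequency <= 0.1%.  Values below the
#' tumor-VAF bound (and symmetric boundaries elsewhere) are excluded; the
#' boundary itself is kept.
#'
#' @param min_callers minimum ensemble caller support (default 2).
#' @param min_t_vaf minimum tumor VAF (default 0.07; kept at exactly 0.07).
#' @param max_n_vaf maximum normal VAF (default 0.02).
#' @param min_t_alt minimum tumor alt read count (default 3).
#' @param min_t_depth minimum tumor depth (default 8).
#' @param min_n_depth minimum normal depth (default 6).
#' @param max_pop_maf maximum population MAF (default 0.001).
#' @param coding_mb coding territory in Mb used as the TMB denominator
#'   (default 35).
#' @return a list of class \code{filterConfig}.
#' @export
filterConfig <- function(min_callers = 2L, min_t_vaf = 0.07,
                         max_n_vaf = 0.02, min_t_alt = 3L,
                         min_t_depth = 8L, min_n_depth = 6L,
                         max_pop_maf = 0.001, coding_mb = 35.0) {
  stopifnot(min_callers >= 0, min_t_vaf >= 0, max_n_vaf >= 0,
            min_t_alt >= 0, min_t_depth >= 0, min_n_depth >= 0,
            max_pop_maf >= 0, coding_mb > 0)
  structure(list(min_callers = min_callers, min_t_vaf = min_t_vaf,
                 max_n_vaf = max_n_vaf, min_t_alt = min_t_alt,
                 min_t_depth = min_t_depth, min_n_depth = min_n_depth,
                 max_pop_maf = max_pop_maf, coding_mb = coding_mb),
            class = c("filterConfig", "list"))
}

#' Apply the ensemble retention filter
#'
#' A variant is kept iff it passes every rule; a rejected variant is labeled
#' with the first failing rule in the fixed order
#' \code{n_callers, t_vaf, n_vaf, t_alt, t_depth, n_depth, pop_maf}.
#' VAF rules with zero read depth pass vacuously, so that zero-depth records
#' are rejected by the count/depth rules rather than raising a division
#' error.
#'
#' @param variants validated variant data.frame (see [readVariants()]).
#' @param cfg a [filterConfig()].
#' @return list with elements \code{kept} (data.frame) and \code{rejected}
#'   (data.frame with an extra \code{reason} column).
#' @export
applyFilters <- function(variants, cfg = filterConfig()) {
  v <- variants
  n <- nrow(v)
  tVaf <- ifelse(v$t_depth > 0, v$t_alt / v$t_depth, NA_real_)
  nVaf <- ifelse(v$n_depth > 0, v$n_alt / v$n_depth, NA_real_)
  rules <- list(
    n_callers = v$n_callers < cfg$min_callers,
    t_vaf = !is.na(tVaf) & tVaf < cfg$min_t_vaf,
    n_vaf = !is.na(nVaf) & nVaf > cfg$max_n_vaf,
    t_alt = v$t_alt < cfg$min_t_alt,
    t_depth = v$t_depth < cfg$min_t_depth,
    n_depth = v$n_depth < cfg$min_n_depth,
    pop_maf = v$pop_maf > cfg$max_pop_maf
  )
  reason <- rep(NA_character_, n)
  for (nm in rev(names(rules))) reason[rules[[nm]]] <- nm
  kept <- v[is.na(reason), , drop = FALSE]
  rejected <- v[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = kept, rejected = rejected)
}

#' Tumor mutational burden per sample
#'
#' TMB is the number of retained coding mutations (SNVs and indels) per
#' megabase of coding territory.
#'
#' @param kept data.frame of retained variants with an \code{is_coding}
#'   column.
#' @param cfg a [filterConfig()] supplying \code{coding_mb}.
#' @param samples optional sample ids to report (defaults to those present);
#'   samples with no retained coding variant report TMB 0.
#' @return data.frame with columns \code{sample}, \code{n_coding},
#'   \code{tmb}.
#' @export
computeTMB <- function(kept, cfg = filterConfig(), samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(kept$sample))
  coding <- kept[kept$is_coding, , drop = FALSE]
  counts <- table(factor(coding$sample, levels = samples))
  data.frame(
    sample = samples,
    n_coding = as.integer(counts),
    tmb = as.numeric(counts) / cfg$coding_mb,
    stringsAsFactors = FALSE
  )
}
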