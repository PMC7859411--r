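# Readers/writers for the package's plain-text interchange formats.
# Conventions: SEG-like segment TSV is 1-based inclusive on disk, BEDPE is
# 0-based half-open on disk, and everything is 0-based half-open internally
# (a CNProfile GRanges in 1-based closed form encodes the same intervals).

.requireCols <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

.checkChroms <- function(chrom, genome, what) {
  bad <- which(!(chrom %in% genome@chroms))
  if (length(bad))
    stop(sprintf("%s: unknown chromosome '%s' at data line %d",
                 what, chrom[bad[1L]], bad[1L]), call. = FALSE)
}

#' Read allele-specific copy-number segments
#'
#' Reads a SEG-like TSV with columns \code{sample}, \code{chrom},
#' \code{start}, \code{end}, \code{tcn}, \code{mcn_minor} (coordinates
#' 1-based inclusive on disk) and returns one validated
#' \linkS4class{CNProfile} per sample.  Overlapping segments within a
#' sample/chromosome, unknown chromosomes, or \code{tcn < mcn_minor} are
#' rejected.
#'
#' @param path path to the TSV.
#' @param genome a \linkS4class{GenomeBuild} used to validate chromosomes.
#' @return named list of \linkS4class{CNProfile}, one per sample.
#' @export
readSegments <- function(path, genome) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .requireCols(df, c("sample", "chrom", "start", "end", "tcn", "mcn_minor"),
               "segment table")
  if (nrow(df) == 0L) return(list())
  df$chrom <- normalizeChrom(df$chrom)
  .checkChroms(df$chrom, genome, "segment table")
  if (any(df$end <= df$start - 1L))
    stop("segment table: end must be >= start (1-based inclusive)")
  if (any(df$tcn < df$mcn_minor))
    stop(sprintf("segment table: tcn < mcn_minor at data line %d",
                 which(df$tcn < df$mcn_minor)[1L]))
  over <- df$end > genome@lengths[df$chrom]
  if (any(over))
    stop(sprintf("segment table: segment beyond chromosome end at data line %d",
                 which(over)[1L]))
  out <- lapply(split(df, df$sample), function(sub) {
    prof <- try(CNProfile(sub$sample[1L], data.frame(
      chrom = sub$chrom, start = sub$start - 1, end = sub$end,
      tcn = sub$tcn, mcnMinor = sub$mcn_minor)), silent = TRUE)
    if (inherits(prof, "try-error"))
      stop("segment table: invalid profile for sample ", sub$sample[1L],
           ": ", attr(prof, "condition")$message, call. = FALSE)
    prof
  })
  out[order(names(out))]
}

#' Write CNProfiles as a SEG-like TSV
#'
#' Inverse of [readSegments()]; coordinates written 1-based inclusive,
#' rows sorted by (sample, chrom, start).
#'
#' @param profiles list of \linkS4class{CNProfile}.
#' @param path output path.
#' @return (invisibly) the written data.frame.
#' @export
writeSegments <- function(profiles, path) {
  df <- segmentTable(profiles)
  writeTable(df, path)
}

#' Flatten CNProfiles to a segment data.frame (1-based inclusive)
#' @param profiles list of \linkS4class{CNProfile}.
#' @return data.frame with sample, chrom, start, end, tcn, mcn_minor.
#' @export
segmentTable <- function(profiles) {
  if (is(profiles, "CNProfile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    seg <- segments(p)
    data.frame(
      sample = sampleId(p),
      chrom = as.character(GenomicRanges::seqnames(seg)),
      start = GenomicRanges::start(seg),
      end = GenomicRanges::end(seg),
      tcn = S4Vectors::mcols(seg)$tcn,
      mcn_minor = S4Vectors::mcols(seg)$mcnMinor,
      stringsAsFactors = FALSE
    )
  }))
}

.svClassFromStrands <- function(chrom1, chrom2, strand1, strand2) {
  cls <- ifelse(chrom1 != chrom2, "TRA",
         ifelse(strand1 == "+" & strand2 == "-", "DEL",
         ifelse(strand1 == "-" & strand2 == "+", "DUP",
         ifelse(strand1 == "+" & strand2 == "+", "h2hINV", "t2tINV"))))
  cls
}

#' Read structural variants from BEDPE
#'
#' BEDPE is 0-based half-open on disk; the breakend position is taken as the
#' interval start + 1 (1-based).  The 7th (name) column carries the sample
#' identifier.  The rearrangement class is derived from strand orientation
#' and chromosome equality: intra-chromosomal +/- is deletion-like (DEL),
#' -/+ duplication-like (DUP), +/+ head-to-head inverted (h2hINV), -/-
#' tail-to-tail inverted (t2tINV); inter-chromosomal records are
#' translocations (TRA).  Intra-chromosomal breakends are ordered so that
#' pos1 < pos2.
#'
#' @param path path to the BEDPE file (with header or not; 10 columns:
#'   chrom1, start1, end1, chrom2, start2, end2, name, score, strand1,
#'   strand2).
#' @return data.frame with columns sample, chrom1, pos1, strand1, chrom2,
#'   pos2, strand2, sv_class.
#' @export
readSVBedpe <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- length(first) > 0L && grepl("chrom1|#", first)
  df <- utils::read.delim(path, header = hasHeader, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df) == 0L && ncol(df) < 10L) {
    return(data.frame(sample = character(), chrom1 = character(),
                      pos1 = numeric(), strand1 = character(),
                      chrom2 = character(), pos2 = numeric(),
                      strand2 = character(), sv_class = character()))
  }
  if (ncol(df) < 10L) stop("BEDPE must have at least 10 columns")
  df <- df[, 1:10]
  names(df) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                 "name", "score", "strand1", "strand2")
  if (!all(df$strand1 %in% c("+", "-")) || !all(df$strand2 %in% c("+", "-")))
    stop("BEDPE: malformed strand (must be '+' or '-')")
  out <- data.frame(
    sample = as.character(df$name),
    chrom1 = normalizeChrom(df$chrom1),
    pos1 = df$start1 + 1,
    strand1 = df$strand1,
    chrom2 = normalizeChrom(df$chrom2),
    pos2 = df$start2 + 1,
    strand2 = df$strand2,
    stringsAsFactors = FALSE
  )
  # order intra-chromosomal breakends by position, carrying strands along
  swap <- out$chrom1 == out$chrom2 & out$pos1 > out$pos2
  if (any(swap)) {
    tmp <- out[swap, ]
    out[swap, c("pos1", "pos2")] <- tmp[, c("pos2", "pos1")]
    out[swap, c("strand1", "strand2")] <- tmp[, c("strand2", "strand1")]
  }
  if (any(out$chrom1 == out$chrom2 & out$pos1 == out$pos2))
    stop("BEDPE: intra-chromosomal record with identical breakend positions")
  out$sv_class <- .svClassFromStrands(out$chrom1, out$chrom2,
                                      out$strand1, out$strand2)
  out
}

#' Write structural variants as BEDPE
#'
#' Inverse of [readSVBedpe()] (0-based half-open on disk, breakends written
#' as 1-bp intervals), sorted by (sample, chrom1, pos1).
#'
#' @param svs data.frame as returned by [readSVBedpe()].
#' @param path output path.
#' @return (invisibly) the written data.frame.
#' @export
writeSVBedpe <- function(svs, path) {
  o <- order(svs$sample, svs$chrom1, svs$pos1, svs$chrom2, svs$pos2)
  svs <- svs[o, , drop = FALSE]
  bed <- data.frame(
    chrom1 = svs$chrom1, start1 = svs$pos1 - 1, end1 = svs$pos1,
    chrom2 = svs$chrom2, start2 = svs$pos2 - 1, end2 = svs$pos2,
    name = svs$sample, score = ".", strand1 = svs$strand1,
    strand2 = svs$strand2, stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(bed)
}

#' Read a somatic variant table
#'
#' TSV with columns \code{sample}, \code{chrom}, \code{pos} (1-based),
#' \code{ref}, \code{alt}, \code{t_alt}, \code{t_depth}, \code{n_alt},
#' \code{n_depth}, \code{n_callers}, \code{pop_maf}, \code{is_coding},
#' \code{is_nonsynonymous}, \code{gene}.  A missing \code{pop_maf} column is
#' imputed as 0 with a warning.  Count invariants
#' (\code{0 <= t_alt <= t_depth} etc.) are enforced.
#'
#' @param path path to the TSV.
#' @return data.frame of validated variant records.
#' @export
readVariants <- function(path) {
  # ref/alt must never be parsed as logical (an all-"T" column would be)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ref = "character",
                                         alt = "character",
                                         gene = "character"))
  .requireCols(df, c("sample", "chrom", "pos", "ref", "alt", "t_alt",
                     "t_depth", "n_alt", "n_depth", "n_callers",
                     "is_coding", "is_nonsynonymous", "gene"),
               "variant table")
  if (!"pop_maf" %in% names(df)) {
    warning("variant table has no pop_maf column; imputing pop_maf = 0")
    df$pop_maf <- 0
  }
  df$chrom <- normalizeChrom(df$chrom)
  df$gene <- ifelse(is.na(df$gene), "", as.character(df$gene))
  df$is_coding <- as.logical(df$is_coding)
  df$is_nonsynonymous <- as.logical(df$is_nonsynonymous)
  bad <- df$t_alt > df$t_depth | df$n_alt > df$n_depth |
    df$t_alt < 0 | df$n_alt < 0
  if (any(bad))
    stop(sprintf("variant table: allele count exceeds depth at data line %d",
                 which(bad)[1L]))
  if (any(df$pop_maf < 0 | df$pop_maf > 1))
    stop("variant table: pop_maf must lie in [0, 1]")
  df
}

#' Read cohort clinical metadata
#'
#' TSV with columns \code{sample}, \code{age}, \code{sex},
#' \code{histology}, \code{pre_rt}, \code{post_rt}, \code{recurred},
#' \code{rfs_months}, \code{died}, \code{os_months}.  Follow-up times must
#' be positive and event times cannot exceed follow-up by convention
#' (rfs_months <= os_months).
#'
#' @param path path to the TSV.
#' @return data.frame of validated sample metadata.
#' @export
readMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sex = "character"))
  .requireCols(df, c("sample", "age", "sex", "histology", "pre_rt",
                     "post_rt", "recurred", "rfs_months", "died",
                     "os_months"), "metadata table")
  for (cl in c("pre_rt", "post_rt", "recurred", "died"))
    df[[cl]] <- as.logical(df[[cl]])
  if (any(df$rfs_months <= 0 | df$os_months <= 0))
    stop("metadata table: follow-up times must be > 0")
  if (any(df$rfs_months > df$os_months))
    stop("metadata table: rfs_months must not exceed os_months")
  df
}

#' Write a data.frame as a deterministic TSV
#'
#' Rows are sorted by (sample, chrom, pos) — falling back to whichever of
#' those columns exist — so outputs are diffable across runs.
#'
#' @param df data.frame.
#' @param path output path.
#' @return (invisibly) the sorted data.frame.
#' @export
writeTable <- function(df, path) {
  keys <- intersect(c("sample", "chrom", "chrom1", "start", "pos", "pos1"),
                    names(df))
  if (length(keys))
    df <- df[do.call(order, df[keys]), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}
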