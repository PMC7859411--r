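#' Normalize chromosome names
#'
#' Accepts names with or without the "chr" prefix and returns them with the
#' prefix; "23"/"24" are not special-cased (sex chromosomes must be named
#' X/Y).
#'
#' @param x character vector of chromosome names.
#' @return normalized names ("chr1", ..., "chrX").
#' @export
normalizeChrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Build a GenomeBuild from an arm table
#'
#' The arm table is the genome model: chromosome lengths are the end of each
#' q arm, and autosomes are every chromosome except chrX/chrY.
#'
#' @param arms data.frame with columns \code{chrom}, \code{arm} ("p"/"q"),
#'   \code{start}, \code{end}; coordinates 0-based half-open bp.
#' @return a validated \linkS4class{GenomeBuild}.
#' @export
GenomeBuild <- function(arms) {
  need <- c("chrom", "arm", "start", "end")
  miss <- setdiff(need, names(arms))
  if (length(miss))
    stop("arm table is missing required columns: ", paste(miss, collapse = ", "))
  arms$chrom <- normalizeChrom(arms$chrom)
  arms$start <- as.numeric(arms$start)
  arms$end <- as.numeric(arms$end)
  chroms <- unique(arms$chrom)
  lengths <- vapply(chroms, function(ch) max(arms$end[arms$chrom == ch]),
                    numeric(1))
  autosome <- !(chroms %in% c("chrX", "chrY", "chrM"))
  names(autosome) <- chroms
  new("GenomeBuild", chroms = chroms, lengths = lengths,
      arms = arms[order(match(arms$chrom, chroms), arms$arm), , drop = FALSE],
      autosome = autosome)
}

#' Read a genome arm table
#'
#' @param path TSV with columns \code{chrom}, \code{arm}, \code{start},
#'   \code{end} (0-based half-open bp).
#' @return a \linkS4class{GenomeBuild}.
#' @export
readGenome <- function(path) {
  arms <- utils::read.delim(path, stringsAsFactors = FALSE)
  GenomeBuild(arms)
}

#' The packaged hg19 genome model
#'
#' Chromosome-arm boundaries for GRCh37/hg19 derived from the assembly's
#' centromeric gap coordinates; the centromere belongs to neither arm.
#'
#' @return a \linkS4class{GenomeBuild} for hg19 (chr1-22, X, Y).
#' @export
hg19Genome <- function() {
  readGenome(system.file("extdata", "hg19_arms.tsv", package = "chordomics",
                         mustWork = TRUE))
}

#' Chromosome arms as GRanges
#'
#' @param genome a \linkS4class{GenomeBuild}.
#' @param autosomesOnly drop chrX/chrY arms.
#' @return \code{GRanges} with an \code{arm} metadata column ("p"/"q").
#' @export
armRanges <- function(genome, autosomesOnly = FALSE) {
  a <- genome@arms
  if (autosomesOnly) a <- a[genome@autosome[a$chrom], , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = a$chrom,
    ranges = IRanges::IRanges(start = a$start + 1L, end = a$end),
    arm = a$arm
  )
}

#' Chromosome names of a genome model
#' @param genome a \linkS4class{GenomeBuild}.
#' @param autosomesOnly restrict to autosomes.
#' @return character vector of chromosome names.
#' @export
chromNames <- function(genome, autosomesOnly = FALSE) {
  if (autosomesOnly) genome@chroms[genome@autosome] else genome@chroms
}

#' Chromosome lengths of a genome model
#' @inheritParams chromNames
#' @return named numeric vector of lengths in bp.
#' @export
chromLengths <- function(genome, autosomesOnly = FALSE) {
  if (autosomesOnly) genome@lengths[genome@autosome] else genome@lengths
}
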