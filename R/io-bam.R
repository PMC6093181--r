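#' Count reads in peaks from an indexed BAM file
#'
#' Assigns each aligned read to every peak whose interval contains the read's
#' strand-aware 5' end (leftmost aligned base for forward reads, rightmost for
#' reverse reads), so a read contributes at most once per peak and exactly one
#' peak in a non-overlapping peak set. Reads with mapping quality below
#' `min_mapq`, unmapped reads, and secondary/supplementary alignments are
#' excluded. An optional blacklist removes reads whose 5' end falls in a
#' blacklisted interval before counting.
#'
#' @param alignment path to a coordinate-sorted, indexed BAM file.
#' @param peaks a non-empty `refchip_peaks` object.
#' @param min_mapq minimum mapping quality (default 15); reads with missing
#'   mapping quality are excluded.
#' @param blacklist optional `refchip_peaks` of regions whose reads are
#'   discarded (e.g. the ENCODE blacklist read from BED).
#' @return Named integer vector of counts, one per peak, in peak-set order.
#'   Peaks on chromosomes absent from the BAM header get count 0 with a
#'   warning.
#' @export
count_reads_in_peaks <- function(alignment, peaks, min_mapq = 15L,
                                 blacklist = NULL) {
  stopifnot(is_peak_set(peaks))
  if (nrow(peaks) == 0) stop("peaks must be non-empty", call. = FALSE)
  if (!file.exists(alignment)) {
    stop("alignment file not found: ", alignment, call. = FALSE)
  }
  index <- paste0(alignment, ".bai")
  if (!file.exists(index) && !file.exists(sub("\\.bam$", ".bai", alignment))) {
    stop("missing BAM index (.bai) for ", alignment, call. = FALSE)
  }
  bf <- Rsamtools::BamFile(alignment)
  header_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  absent <- setdiff(unique(peaks$chrom), header_chroms)
  if (length(absent)) {
    warning("chromosome(s) in peaks absent from BAM header (count 0): ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "mapq", "cigar"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  rec <- Rsamtools::scanBam(bf, param = param)[[1]]
  counts <- stats::setNames(integer(nrow(peaks)), peaks$name)
  if (!length(rec$pos)) return(counts)
  keep <- !is.na(rec$mapq) & rec$mapq >= min_mapq & !is.na(rec$pos)
  if (!any(keep)) return(counts)
  chrom <- as.character(rec$rname)[keep]
  pos <- rec$pos[keep]                      # 1-based leftmost
  rev <- as.character(rec$strand)[keep] == "-"
  width <- cigar_ref_width(rec$cigar[keep])
  five_prime0 <- ifelse(rev, pos + width - 1L, pos) - 1L   # 0-based 5' end
  pts <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(five_prime0 + 1L, width = 1L))
  if (!is.null(blacklist) && nrow(blacklist)) {
    drop <- suppressWarnings(
      GenomicRanges::countOverlaps(pts, peaks_to_granges(blacklist))) > 0
    pts <- pts[!drop]
    if (!length(pts)) return(counts)
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, peaks_to_granges(peaks)))
  tab <- tabulate(S4Vectors::subjectHits(hits), nbins = nrow(peaks))
  counts[] <- as.integer(tab)
  counts
}

# reference-space width of a CIGAR string: sum of M/D/N/=/X op lengths
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
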