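#' Partition combined-genome peaks by species
#'
#' Peaks called against a combined multi-species reference carry
#' species-prefixed chromosome names (e.g. `dm3_chr2L`). This splits a peak
#' set into one set per species by the longest matching chromosome-name
#' prefix.
#'
#' @param peaks a `refchip_peaks` object.
#' @param rule named character vector mapping chromosome-name prefix to
#'   species tag, e.g. `stats::setNames(c("Dm", "Hs"), c("dm3_", ""))`. At most one empty prefix
#'   (the default species) is allowed; chromosomes matching no prefix fall to
#'   it, or raise an error when it is absent.
#' @return Named list of `refchip_peaks`, one per species tag (possibly
#'   empty sets), each sorted and tagged with its species.
#' @examples
#' p <- peak_set(c("chr1", "dm3_chr2L"), c(0L, 10L), c(100L, 60L))
#' partition_by_genome(p, stats::setNames(c("Dm", "Hs"), c("dm3_", "")))
#' @export
partition_by_genome <- function(peaks, rule) {
  stopifnot(is_peak_set(peaks))
  if (!length(rule) || is.null(names(rule))) {
    stop("rule must be a non-empty named character vector (prefix -> species)",
         call. = FALSE)
  }
  prefixes <- names(rule)
  if (anyDuplicated(prefixes)) stop("prefixes must be unique", call. = FALSE)
  if (sum(prefixes == "") > 1L) stop("at most one empty prefix", call. = FALSE)
  # longest matching prefix wins
  ord <- order(nchar(prefixes), decreasing = TRUE)
  assigned <- rep(NA_character_, nrow(peaks))
  for (i in ord) {
    pf <- prefixes[i]
    hit <- if (nzchar(pf)) startsWith(peaks$chrom, pf) else rep(TRUE, nrow(peaks))
    assigned[is.na(assigned) & hit] <- rule[[i]]
  }
  if (anyNA(assigned)) {
    stop("chromosome(s) match no prefix and no default species is defined: ",
         paste(unique(peaks$chrom[is.na(assigned)]), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(stats::setNames(unique(unname(rule)), unique(unname(rule))),
    function(sp) {
      keep <- peaks[!is.na(assigned) & assigned == sp, , drop = FALSE]
      peak_set(keep$chrom, keep$start, keep$end, keep$name, keep$score,
               channel = attr(peaks, "channel"), species_tag = sp)
    })
  out
}

#' Derive a clean control reference peak set
#'
#' Retains the control-factor peaks that lie strictly more than
#' `min_distance` bp from every target-factor peak, removing control peaks
#' whose signal could be contaminated by overlapping or adjacent target
#' binding. Distance is the edge-to-edge gap between half-open intervals
#' (overlapping or abutting peaks have gap 0), measured per chromosome;
#' control peaks on chromosomes with no target peak are always retained.
#'
#' @param control,target `refchip_peaks` on the same coordinate system.
#' @param min_distance exclusion radius in bp (default 500): control peaks
#'   with gap `<= min_distance` to any target peak are removed.
#' @return A `refchip_peaks` that is a sorted subset of `control`.
#' @export
filter_control_peaks <- function(control, target, min_distance = 500L) {
  stopifnot(is_peak_set(control), is_peak_set(target))
  if (nrow(control) == 0 || nrow(target) == 0) return(control)
  gr_c <- peaks_to_granges(control)
  gr_t <- peaks_to_granges(target)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(gr_c, gr_t, ignore.strand = TRUE))
  gap <- rep(Inf, nrow(control))
  gap[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  keep <- control[gap > min_distance, , drop = FALSE]
  peak_set(keep$chrom, keep$start, keep$end, keep$name, keep$score,
           channel = attr(control, "channel"),
           species_tag = attr(control, "species_tag"))
}

#' Build consensus peaks from replicate peak sets
#'
#' A genomic base is supported by a replicate when any of that replicate's
#' intervals covers it (multiple intervals in one replicate count once).
#' Maximal runs of bases supported by at least `min_occurrence` replicates
#' are merged and emitted as consensus peaks with generated names
#' (`consensus_1`, ...); the score of each consensus peak is the maximum
#' number of supporting replicates along the run. This per-base definition
#' behaves identically for narrow transcription-factor peaks and broad
#' histone-mark domains.
#'
#' @param peaksets list of `refchip_peaks` (>= 1).
#' @param min_occurrence minimum number of supporting replicate sets,
#'   `1 <= min_occurrence <= length(peaksets)`.
#' @inheritParams peak_set
#' @return A `refchip_peaks` of merged consensus intervals.
#' @export
consensus_peaks <- function(peaksets, min_occurrence,
                            channel = "target", species_tag = "") {
  if (!length(peaksets) || !all(vapply(peaksets, is_peak_set, logical(1)))) {
    stop("peaksets must be a non-empty list of peak sets", call. = FALSE)
  }
  if (min_occurrence < 1L || min_occurrence > length(peaksets)) {
    stop("min_occurrence must be between 1 and the number of peak sets",
         call. = FALSE)
  }
  # reduce within each replicate so one replicate supports a base at most once,
  # then a combined coverage counts supporting replicates per base
  grl <- lapply(peaksets, function(p)
    GenomicRanges::reduce(peaks_to_granges(p)))
  combined <- suppressWarnings(do.call(c, unname(grl)))
  cov <- GenomicRanges::coverage(combined)
  views <- IRanges::slice(cov, lower = min_occurrence)
  chroms <- rep(names(views), vapply(views, length, integer(1)))
  starts1 <- unlist(lapply(views, IRanges::start), use.names = FALSE)
  ends1 <- unlist(lapply(views, IRanges::end), use.names = FALSE)
  support <- unlist(lapply(views, IRanges::viewMaxs), use.names = FALSE)
  n <- length(chroms)
  if (n) {
    ord <- order(chroms, starts1, method = "radix")
    chroms <- chroms[ord]; starts1 <- starts1[ord]
    ends1 <- ends1[ord]; support <- support[ord]
  }
  peak_set(
    chrom = if (n) chroms else character(0),
    start = if (n) starts1 - 1L else integer(0),
    end = if (n) ends1 else integer(0),
    name = if (n) paste0("consensus_", seq_len(n)) else character(0),
    score = if (n) as.numeric(support) else numeric(0),
    channel = channel, species_tag = species_tag
  )
}
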