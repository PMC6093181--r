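#' Construct a peak set
#'
#' A `refchip_peaks` object is an ordered table of genomic intervals in
#' BED/narrowPeak convention (0-based, half-open), carrying a factor channel
#' (`"target"`, `"control"` or `"spike_in"`) and an optional species tag for
#' peaks called against a combined multi-species reference genome.
#'
#' @param chrom character vector of sequence names; combined-genome
#'   chromosomes may carry a species prefix such as `"dm3_"`.
#' @param start,end integer vectors; 0-based half-open coordinates with
#'   `0 <= start < end`.
#' @param name peak identifiers, unique within the set. Generated
#'   (`peak_1`, ...) when `NULL`.
#' @param score numeric peak scores (recycled).
#' @param channel one of `"target"`, `"control"`, `"spike_in"`.
#' @param species_tag species label, `""` for the default species.
#' @return A `refchip_peaks` data frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`, sorted by `(chrom, start)`.
#' @examples
#' peak_set(c("chr1", "chr1"), c(100L, 500L), c(200L, 700L))
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     channel = c("target", "control", "spike_in"),
                     species_tag = "") {
  channel <- match.arg(channel)
  n <- length(chrom)
  if (is.null(name)) {
    name <- if (n) paste0("peak_", seq_len(n)) else character(0)
  }
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_peak_set(df)
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            channel = channel, species_tag = as.character(species_tag),
            class = c("refchip_peaks", "data.frame"))
}

validate_peak_set <- function(df) {
  if (anyNA(df$start) || anyNA(df$end)) {
    stop("peak coordinates must be integral and non-missing", call. = FALSE)
  }
  bad <- df$start < 0L | df$start >= df$end
  if (any(bad)) {
    stop("invalid interval(s): require 0 <= start < end (peaks ",
         paste(utils::head(df$name[bad], 5), collapse = ", "), ")",
         call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("peak names must be unique within a peak set", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.refchip_peaks <- function(x, ...) {
  cat(sprintf("refchip peak set: %d peaks, channel=%s%s\n", nrow(x),
              attr(x, "channel"),
              if (nzchar(attr(x, "species_tag")))
                paste0(", species=", attr(x, "species_tag")) else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @rdname peak_set
#' @param x object to test or convert.
#' @export
is_peak_set <- function(x) inherits(x, "refchip_peaks")

#' Convert between peak sets and GRanges
#'
#' `peaks_to_granges()` lifts the 0-based half-open BED intervals into the
#' 1-based closed convention of [GenomicRanges::GRanges];
#' `granges_to_peaks()` is its inverse. Round-tripping preserves coordinates
#' exactly.
#'
#' @param peaks a `refchip_peaks` object.
#' @return A `GRanges` with `name` and `score` metadata columns.
#' @export
peaks_to_granges <- function(peaks) {
  stopifnot(is_peak_set(peaks))
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  S4Vectors::mcols(gr)$name <- peaks$name
  S4Vectors::mcols(gr)$score <- peaks$score
  gr
}

#' @rdname peaks_to_granges
#' @param gr a `GRanges`; metadata columns `name`/`score` are used if present.
#' @inheritParams peak_set
#' @export
granges_to_peaks <- function(gr, channel = "target", species_tag = "") {
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% names(mc)) as.character(mc$name) else NULL
  sc <- if ("score" %in% names(mc)) as.numeric(mc$score) else 0
  peak_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm, score = sc,
    channel = channel, species_tag = species_tag
  )
}

#' Subset a peak set by peak name
#'
#' @param peaks a `refchip_peaks` object.
#' @param names character vector of peak names to keep (all must exist).
#' @return A `refchip_peaks` containing the named peaks, order preserved.
#' @export
subset_peaks <- function(peaks, names) {
  stopifnot(is_peak_set(peaks))
  missing <- setdiff(names, peaks$name)
  if (length(missing)) {
    stop("unknown peak name(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  keep <- peaks[peaks$name %in% names, , drop = FALSE]
  peak_set(keep$chrom, keep$start, keep$end, keep$name, keep$score,
           channel = attr(peaks, "channel"),
           species_tag = attr(peaks, "species_tag"))
}
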