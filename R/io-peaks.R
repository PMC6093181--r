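#' Read a narrowPeak or BED peak file
#'
#' Parses MACS2-style narrowPeak (BED6+4) or plain BED files into a peak set.
#' Coordinates are kept exactly as in the file (0-based, half-open). Lines
#' beginning with `track`, `browser` or `#` are skipped. Peaks on any
#' chromosome are retained; species partitioning and chromosome filtering are
#' separate operations (see [partition_by_genome()]).
#'
#' @param path path to the file.
#' @param species_tag species label to attach (`""` for the default species).
#' @inheritParams peak_set
#' @param min_fields minimum number of tab-separated fields required per line
#'   (default 6, the BED6 core shared with narrowPeak).
#' @return A `refchip_peaks` object (empty for an empty file).
#' @seealso [write_bed()]
#' @export
read_narrowpeak <- function(path, species_tag = "", channel = "target",
                            min_fields = 6L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  idx <- which(!skip)
  if (!length(idx)) {
    return(peak_set(character(0), integer(0), integer(0),
                    channel = channel, species_tag = species_tag))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- idx[which(nf < min_fields)[1]]
    stop(sprintf("%s:%d: expected >= %d tab-separated fields, found %d",
                 path, bad, min_fields, nf[which(nf < min_fields)[1]]),
         call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  malformed <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(malformed)) {
    bad <- which(malformed)[1]
    stop(sprintf("%s:%d: malformed interval '%s' (need integer 0 <= start < end)",
                 path, idx[bad], lines[idx[bad]]), call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(get(5)))
  score[is.na(score)] <- 0
  nm <- get(4)
  if (anyDuplicated(nm)) {
    stop(path, ": duplicate peak name(s): ",
         paste(utils::head(unique(nm[duplicated(nm)]), 5), collapse = ", "),
         call. = FALSE)
  }
  peak_set(get(1), start, end, nm, score,
           channel = channel, species_tag = species_tag)
}

#' @rdname read_narrowpeak
#' @export
read_bed <- function(path, species_tag = "", channel = "target") {
  read_narrowpeak(path, species_tag = species_tag, channel = channel,
                  min_fields = 6L)
}

#' Write a peak set as BED6
#'
#' Emits the six core BED columns (chrom, start, end, name, score, strand
#' `.`), preserving the stored 0-based half-open coordinates so that
#' `read_bed(write_bed(p))` reproduces `p` exactly.
#'
#' @param peaks a `refchip_peaks` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(is_peak_set(peaks))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format(peaks$score, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
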