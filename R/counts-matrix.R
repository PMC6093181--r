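#' Construct a peaks-by-samples counts matrix
#'
#' Wraps a non-negative numeric matrix of read counts (rows = peaks,
#' columns = samples). Counts are integers on ingest but may become
#' non-integer after normalization or coefficient scaling. Optionally carries
#' per-sample total aligned read counts (`library_totals`) for
#' library-size-based normalization modes.
#'
#' @param counts numeric matrix with unique rownames (peak names) and
#'   colnames (sample ids); all values finite and `>= 0`.
#' @param library_totals optional numeric vector of per-sample totals, in
#'   column order or named by sample id.
#' @return A `refchip_counts` object (a matrix subclass).
#' @export
counts_matrix <- function(counts, library_totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    stop("counts matrix must have peak names as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("counts matrix must have sample ids as colnames", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("counts must be finite and non-missing", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicate peak names", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (!is.null(library_totals)) {
    if (!is.null(names(library_totals))) {
      if (!setequal(names(library_totals), colnames(counts))) {
        stop("library_totals names must match sample ids", call. = FALSE)
      }
      library_totals <- library_totals[colnames(counts)]
    } else if (length(library_totals) != ncol(counts)) {
      stop("library_totals length must equal the number of samples", call. = FALSE)
    }
    library_totals <- stats::setNames(as.numeric(library_totals), colnames(counts))
    if (any(library_totals <= 0)) stop("library_totals must be positive", call. = FALSE)
  }
  structure(counts, library_totals = library_totals,
            class = c("refchip_counts", class(counts)))
}

#' @rdname counts_matrix
#' @param x object to test.
#' @export
is_counts_matrix <- function(x) inherits(x, "refchip_counts")

#' @rdname counts_matrix
#' @export
library_totals <- function(x) attr(x, "library_totals")

# rebuild the class after arithmetic that strips attributes
as_counts <- function(m, library_totals = NULL) counts_matrix(m, library_totals)

#' @export
print.refchip_counts <- function(x, ...) {
  cat(sprintf("refchip counts matrix: %d peaks x %d samples%s\n",
              nrow(x), ncol(x),
              if (is.null(library_totals(x))) "" else " (+library totals)"))
  print(utils::head(unclass(x)[, , drop = FALSE], 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Sample sheet describing an experiment
#'
#' Assigns each sequencing library to a condition and replicate; optional
#' columns point at alignment and peak files for count-from-BAM workflows.
#'
#' @param sample_id unique sample identifiers.
#' @param condition condition label per sample (e.g. `"control"`, `"treated"`).
#' @param replicate positive integer replicate index per sample.
#' @param alignment_path,peaks_path optional file paths (NA when absent).
#' @return A `refchip_samples` data frame.
#' @export
sample_sheet <- function(sample_id, condition, replicate,
                         alignment_path = NA_character_,
                         peaks_path = NA_character_) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    alignment_path = rep_len(as.character(alignment_path), length(sample_id)),
    peaks_path = rep_len(as.character(peaks_path), length(sample_id)),
    stringsAsFactors = FALSE
  )
  if (nrow(df) == 0) stop("sample sheet must have at least one sample", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique", call. = FALSE)
  if (any(is.na(df$replicate) | df$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  structure(df, class = c("refchip_samples", "data.frame"))
}

#' @rdname sample_sheet
#' @param x object to test.
#' @export
is_sample_sheet <- function(x) inherits(x, "refchip_samples")

# sample ids belonging to one condition, in sheet order
samples_for <- function(sheet, condition) {
  ids <- sheet$sample_id[sheet$condition == condition]
  if (!length(ids)) {
    stop("no samples with condition '", condition, "' in the sample sheet",
         call. = FALSE)
  }
  ids
}

check_contrast <- function(sheet, contrast) {
  if (length(contrast) != 2L || anyDuplicated(contrast)) {
    stop("contrast must name two distinct conditions (control, treated)",
         call. = FALSE)
  }
  list(control = samples_for(sheet, contrast[[1]]),
       treated = samples_for(sheet, contrast[[2]]))
}
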