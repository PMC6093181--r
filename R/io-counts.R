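#' Read and write counts matrices as TSV
#'
#' Tab-separated, UTF-8, `.`-decimal. The header row holds the sample ids
#' (first cell `peak_id`), subsequent rows one peak each. When library totals
#' are attached they are stored in a `#library_totals` comment line above the
#' header so that `read_counts_tsv(write_counts_tsv(m))` reproduces `m`
#' exactly, totals included.
#'
#' @param path file path.
#' @return `read_counts_tsv()` returns a `refchip_counts` object.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  totals <- NULL
  if (length(lines) && startsWith(lines[1], "#library_totals")) {
    totals <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1])
    lines <- lines[-1]
  }
  if (!length(lines)) stop(path, ": missing header row", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop(sprintf("%s:%d: ragged row (%d fields, expected %d)",
                 path, bad + 1L + !is.null(totals), nf[bad], length(header)),
         call. = FALSE)
  }
  peak_names <- vapply(fields, `[[`, character(1), 1L)
  vals <- if (length(body)) {
    m <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(fields, `[`, -1L), use.names = FALSE))),
      nrow = length(body), ncol = length(samples), byrow = TRUE)
    m
  } else {
    matrix(numeric(0), nrow = 0, ncol = length(samples))
  }
  if (anyNA(vals)) stop(path, ": non-numeric count value", call. = FALSE)
  if (any(vals < 0)) stop(path, ": negative count value", call. = FALSE)
  dimnames(vals) <- list(peak_names, samples)
  counts_matrix(vals, library_totals = totals)
}

#' @rdname read_counts_tsv
#' @param matrix a `refchip_counts` object.
#' @export
write_counts_tsv <- function(matrix, path) {
  stopifnot(is_counts_matrix(matrix))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  lt <- library_totals(matrix)
  if (!is.null(lt)) {
    writeLines(paste(c("#library_totals",
                       format(lt, trim = TRUE, scientific = FALSE)),
                     collapse = "\t"), con)
  }
  writeLines(paste(c("peak_id", colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix)) {
    body <- apply(unclass(matrix), 1, function(v)
      paste(format(v, trim = TRUE, scientific = FALSE, digits = 15),
            collapse = "\t"))
    writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Expects a header `sample_id,condition,replicate,alignment_path,peaks_path`
#' (the two path columns optional).
#'
#' @param path CSV file path.
#' @return A `refchip_samples` data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_sheet(df$sample_id, df$condition, df$replicate,
               alignment_path = if ("alignment_path" %in% names(df))
                 df$alignment_path else NA_character_,
               peaks_path = if ("peaks_path" %in% names(df))
                 df$peaks_path else NA_character_)
}

#' @rdname read_sample_sheet
#' @param sheet a `refchip_samples` data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(is_sample_sheet(sheet))
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
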