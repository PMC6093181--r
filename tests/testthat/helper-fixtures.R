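# small in-code fixtures shared across test files

make_counts <- function(values, peaks = NULL, samples = NULL, totals = NULL) {
  m <- matrix(values, nrow = if (is.null(peaks)) 2 else length(peaks),
              byrow = TRUE)
  rownames(m) <- if (is.null(peaks)) paste0("p", seq_len(nrow(m))) else peaks
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  counts_matrix(m, library_totals = totals)
}

make_sheet <- function(reps = 3L) {
  sample_sheet(c(paste0("c", seq_len(reps)), paste0("t", seq_len(reps))),
               condition = rep(c("control", "treated"), each = reps),
               replicate = rep(seq_len(reps), 2))
}

# 2x(2*reps) sheet whose sample ids match generate_experiment() output
sim_contrast <- c("control", "treated")

unit_factors <- function(ids) size_factors(stats::setNames(rep(1, length(ids)), ids))

write_lines_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force per-base consensus oracle for instances spanning <= 10 kb
consensus_oracle <- function(peaksets, min_occurrence) {
  chroms <- unique(unlist(lapply(peaksets, function(p) p$chrom)))
  out <- NULL
  for (ch in sort(chroms)) {
    span <- max(unlist(lapply(peaksets, function(p) p$end[p$chrom == ch]), 0))
    cov <- integer(span)
    for (p in peaksets) {
      sel <- p[p$chrom == ch, , drop = FALSE]
      covered <- logical(span)
      for (i in seq_len(nrow(sel))) {
        covered[(sel$start[i] + 1):sel$end[i]] <- TRUE  # 1-indexed base b-1
      }
      cov <- cov + covered
    }
    ok <- cov >= min_occurrence
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out <- rbind(out, data.frame(chrom = ch, start = starts[keep] - 1L,
                                 end = ends[keep]))
  }
  out
}

# brute-force (read x peak) counting oracle on 0-based 5' end positions
counting_oracle <- function(chrom, five_prime0, peaks) {
  vapply(seq_len(nrow(peaks)), function(i) {
    sum(chrom == peaks$chrom[i] &
          five_prime0 >= peaks$start[i] & five_prime0 < peaks$end[i])
  }, numeric(1))
}

# exhaustive BH step-up: q_(i) = min over j >= i of m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}
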