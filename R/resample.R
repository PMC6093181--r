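#' Subsampling stability of the normalization coefficient
#'
#' Quantifies how many control peaks the coefficient actually needs: for each
#' fraction `f`, `ceiling(f * N)` control peaks are drawn uniformly without
#' replacement, the through-origin coefficient is recomputed on the draw, and
#' the relative error `c_sub / c_full - 1` against the full-set coefficient
#' is recorded over `n_reps` repetitions. Each `(fraction, rep)` pair uses
#' its own RNG stream derived deterministically from the master seed, so the
#' report is reproducible and independent of evaluation order.
#'
#' @inheritParams normalization_coefficient
#' @param fractions numeric vector of subsampling fractions in `(0, 1]`;
#'   every fraction must yield at least 2 peaks.
#' @param n_reps repetitions per fraction (>= 1).
#' @param seed master seed (mandatory).
#' @return A `refchip_stability` data frame with one row per fraction:
#'   `fraction`, `n_peaks`, `n_reps`, `median_abs_rel_err`,
#'   `max_abs_rel_err`; attribute `full_coefficient` holds `c_full` and
#'   attribute `errors` the per-repetition signed relative errors (a list,
#'   one vector per fraction).
#' @export
subsample_coefficient_stability <- function(matrix, control_peaks, sheet,
                                            contrast, fractions, n_reps,
                                            seed) {
  stopifnot(is_counts_matrix(matrix), is_sample_sheet(sheet))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  nm <- control_peak_names(matrix, control_peaks)
  N <- length(nm)
  sizes <- as.integer(ceiling(fractions * N))
  if (any(sizes < 2L)) {
    stop("fraction(s) ", paste(fractions[sizes < 2L], collapse = ", "),
         " yield fewer than 2 control peaks", call. = FALSE)
  }
  c_full <- normalization_coefficient(matrix, nm, sheet, contrast)$coefficient
  errs <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    e <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      set.seed(stream_seed(seed, i, r))
      idx <- sample.int(N, sizes[i])
      c_sub <- normalization_coefficient(matrix, nm[idx], sheet,
                                         contrast)$coefficient
      e[r] <- c_sub / c_full - 1
    }
    errs[[i]] <- e
  }
  out <- data.frame(
    fraction = fractions,
    n_peaks = sizes,
    n_reps = as.integer(n_reps),
    median_abs_rel_err = vapply(errs, function(e) stats::median(abs(e)),
                                numeric(1)),
    max_abs_rel_err = vapply(errs, function(e) max(abs(e)), numeric(1))
  )
  structure(out, full_coefficient = c_full, errors = errs,
            class = c("refchip_stability", "data.frame"))
}

# deterministic per-(fraction, rep) stream; kept below 2^31
stream_seed <- function(seed, i_fraction, i_rep) {
  as.integer((as.numeric(seed) + 97771 * i_fraction + 131 * i_rep) %%
               2147483647)
}

#' Cross-normalize a single-factor experiment to a parallel-factor one
#'
#' Relative binding within one pull-down is intrinsically accurate, so a
#' single-factor (target-only) experiment can inherit the normalization of a
#' parallel-factor experiment through peaks measured in both. Over the
#' matched peaks (consensus sites that pass the control-proximity filter),
#' the per-peak offset `delta_i = M_single_i - M_parallel_i` between the raw
#' single-factor fold-changes and the normalized parallel-factor
#' fold-changes is summarized by its median (robust to residual true-change
#' outliers), and the single experiment's treated condition is corrected by
#' the multiplicative constant `2^(-median(delta))`. After applying the
#' correction the median offset over matched peaks is exactly zero.
#'
#' @param single_ma `refchip_ma` of the single-factor experiment (raw, i.e.
#'   unit size factors).
#' @param parallel_ma `refchip_ma` of the normalized parallel-factor
#'   experiment.
#' @param matched_peaks character vector of peak names present in both
#'   tables (>= 1); typically consensus peaks distant from the control
#'   factor's sites (see [filter_control_peaks()]).
#' @return A list: `scale` (multiplier for the single experiment's treated
#'   counts, usable with [apply_coefficient()]), `median_delta`, `n_matched`,
#'   and `corrected_ma` (the single-factor table with
#'   `M - median(delta)`).
#' @export
cross_normalize <- function(single_ma, parallel_ma, matched_peaks) {
  stopifnot(inherits(single_ma, "refchip_ma"),
            inherits(parallel_ma, "refchip_ma"))
  matched_peaks <- as.character(matched_peaks)
  miss <- setdiff(matched_peaks,
                  intersect(single_ma$name, parallel_ma$name))
  if (!length(matched_peaks) || length(miss)) {
    stop("matched peaks must be non-empty and present in both MA tables",
         call. = FALSE)
  }
  ms <- single_ma$M[match(matched_peaks, single_ma$name)]
  mp <- parallel_ma$M[match(matched_peaks, parallel_ma$name)]
  delta <- ms - mp
  med <- stats::median(delta)
  corrected <- single_ma
  corrected$M <- single_ma$M - med
  list(scale = 2^(-med), median_delta = med,
       n_matched = length(matched_peaks), corrected_ma = corrected)
}
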