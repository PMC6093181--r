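#' Baseline reads-per-million normalization
#'
#' The three analytical baselines the reference-peak method is compared
#' against: each sample's counts are divided by a per-sample total and
#' multiplied by one million. `reads_in_peaks` uses the column sums of the
#' counts matrix; `total_reads` and `aligned_reads` use the attached
#' `library_totals` (whichever totals the user supplied). These baselines
#' recenter unchanged peaks incorrectly when occupancy changes genome-wide;
#' they are provided for comparison, not as the recommended method.
#'
#' @param matrix a `refchip_counts` object.
#' @param mode one of `"reads_in_peaks"`, `"total_reads"`, `"aligned_reads"`.
#' @return A rescaled `refchip_counts` (non-integer).
#' @export
normalize_rpm <- function(matrix,
                          mode = c("reads_in_peaks", "total_reads",
                                   "aligned_reads")) {
  stopifnot(is_counts_matrix(matrix))
  mode <- match.arg(mode)
  totals <- if (mode == "reads_in_peaks") {
    colSums(matrix)
  } else {
    lt <- library_totals(matrix)
    if (is.null(lt)) {
      stop("mode '", mode, "' requires library_totals on the counts matrix",
           call. = FALSE)
    }
    lt
  }
  if (any(totals <= 0)) {
    stop("zero total for sample(s): ",
         paste(colnames(matrix)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(unclass(matrix), 2, totals, "/") * 1e6
  as_counts(scaled, library_totals(matrix))
}

#' Size factors from control-peak counts
#'
#' Estimates per-sample size factors from the counts in an unchanged
#' reference (control) peak subset only, then applies them to all peaks.
#' `method = "sum"` scales by the control-peak column sums (total reference
#' signal per sample); `method = "median_ratio"` is the median-of-ratios
#' estimator computed on the control submatrix: each control peak's counts
#' are divided by the peak's geometric mean across samples and the per-sample
#' median ratio is taken (peaks with a zero count in any sample are skipped,
#' as their geometric-mean reference is degenerate). Factors are rescaled to
#' geometric mean 1 so the two methods are on a common scale.
#'
#' @param matrix a `refchip_counts` object.
#' @param control_peaks character vector of control peak names (or a
#'   `refchip_peaks` whose names are used); must be non-empty and present in
#'   `matrix`.
#' @param method `"sum"` or `"median_ratio"`.
#' @return A `refchip_size_factors`: named positive numeric vector with
#'   geometric mean 1 (attribute `method` records the estimator).
#' @export
control_size_factors <- function(matrix, control_peaks,
                                 method = c("sum", "median_ratio")) {
  stopifnot(is_counts_matrix(matrix))
  method <- match.arg(method)
  nm <- control_peak_names(matrix, control_peaks)
  sub <- unclass(matrix)[nm, , drop = FALSE]
  if (method == "sum") {
    s <- colSums(sub)
    if (any(s <= 0)) {
      stop("zero control-peak counts for sample(s): ",
           paste(colnames(sub)[s <= 0], collapse = ", "), call. = FALSE)
    }
  } else {
    pos <- rowSums(sub > 0) == ncol(sub)
    if (!any(pos)) {
      stop("median_ratio requires at least one control peak with non-zero ",
           "counts in every sample", call. = FALSE)
    }
    logs <- log(sub[pos, , drop = FALSE])
    ref <- rowMeans(logs)                       # log geometric mean per peak
    s <- apply(exp(logs - ref), 2, stats::median)
    if (any(s <= 0)) stop("degenerate median ratio", call. = FALSE)
  }
  size_factors(s, method = method)
}

#' @rdname control_size_factors
#' @param s positive numeric vector of per-sample scales (rescaled to
#'   geometric mean 1 on construction).
#' @export
size_factors <- function(s, method = "sum") {
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  s <- s / exp(mean(log(s)))
  structure(s, method = method, class = "refchip_size_factors")
}

#' @export
print.refchip_size_factors <- function(x, ...) {
  cat("refchip size factors (method=", attr(x, "method"), "):\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

control_peak_names <- function(matrix, control_peaks) {
  nm <- if (is_peak_set(control_peaks)) control_peaks$name else
    as.character(control_peaks)
  if (!length(nm)) stop("control peak subset is empty", call. = FALSE)
  missing <- setdiff(nm, rownames(matrix))
  if (length(missing)) {
    stop("control peak(s) absent from counts matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  nm
}

#' Between-condition normalization coefficient from control peaks
#'
#' The core of the reference-peak method. For each control peak, the mean
#' raw count over the control-condition replicates (`x`) is regressed against
#' the mean over the treated replicates (`y`) through the origin
#' (`m = sum(x*y) / sum(x^2)`). With no systematic bias between conditions
#' the unchanged control peaks satisfy `y = x`, so the fitted gradient `m`
#' should be 1; a gradient below 1 reveals a multiplicative efficiency bias.
#' The normalization coefficient `c = 1/m` is the constant that rescales the
#' treated counts so a refit gradient equals 1 exactly (before any integer
#' rounding).
#'
#' With `space = "log"` the multiplicative offset is instead estimated as
#' the mean of `log2(y/x)` over control peaks with positive means, and
#' `c = 2^(-offset)`; the reported `slope` is then `1/c` so the
#' `c == 1/slope` relation is preserved.
#'
#' @param matrix a `refchip_counts` of raw counts.
#' @param control_peaks control peak names (or a `refchip_peaks`), >= 2 peaks.
#' @param sheet a `refchip_samples` sample sheet.
#' @param contrast length-2 character vector
#'   `c(control_condition, treated_condition)`.
#' @param space `"linear"` (through-origin fit on replicate-mean counts, the
#'   default) or `"log"`.
#' @return A `refchip_norm` list: `coefficient` (`c`), `slope` (`m`),
#'   `n_control_peaks`, `residual_se` (SD of `y - m*x` residuals), `contrast`
#'   and `space`.
#' @export
normalization_coefficient <- function(matrix, control_peaks, sheet, contrast,
                                      space = c("linear", "log")) {
  stopifnot(is_counts_matrix(matrix), is_sample_sheet(sheet))
  space <- match.arg(space)
  nm <- control_peak_names(matrix, control_peaks)
  if (length(nm) < 2L) stop("need >= 2 control peaks", call. = FALSE)
  grp <- check_contrast(sheet, contrast)
  sub <- unclass(matrix)[nm, , drop = FALSE]
  x <- rowMeans(sub[, grp$control, drop = FALSE])
  y <- rowMeans(sub[, grp$treated, drop = FALSE])
  if (space == "linear") {
    sxx <- sum(x * x)
    if (sxx == 0) stop("all control-condition counts are zero", call. = FALSE)
    m <- sum(x * y) / sxx
    if (m <= 0) stop("non-positive gradient: treated control-peak counts are all zero",
                     call. = FALSE)
    rse <- if (length(nm) > 1L) stats::sd(y - m * x) else NA_real_
  } else {
    ok <- x > 0 & y > 0
    if (sum(ok) < 2L) stop("need >= 2 control peaks with positive means",
                           call. = FALSE)
    offset <- mean(log2(y[ok] / x[ok]))
    m <- 2^offset
    rse <- stats::sd(log2(y[ok] / x[ok]))
  }
  structure(list(coefficient = 1 / m, slope = m,
                 n_control_peaks = length(nm), residual_se = rse,
                 contrast = as.character(contrast), space = space),
            class = "refchip_norm")
}

#' @export
print.refchip_norm <- function(x, ...) {
  cat(sprintf(paste0("refchip normalization coefficient (%s space)\n",
                     "  gradient m = %.6g  coefficient c = 1/m = %.6g\n",
                     "  control peaks: %d   residual SE: %.4g\n"),
              x$space, x$slope, x$coefficient, x$n_control_peaks,
              x$residual_se))
  invisible(x)
}

#' Apply a normalization coefficient to the treated samples
#'
#' Multiplies the treated-condition columns by the coefficient `c`, leaving
#' other columns untouched. `rounding = "nearest_int"` rounds half away from
#' zero to restore integer counts for count-model compatibility;
#' `rounding = "none"` keeps exact scaled values (required for the
#' gradient-restoration identity).
#'
#' @param matrix a `refchip_counts` object.
#' @param result a `refchip_norm` from [normalization_coefficient()], or a
#'   single positive number used as the coefficient directly.
#' @param treated_samples character vector of sample ids to scale.
#' @param rounding `"none"` or `"nearest_int"`.
#' @return The rescaled `refchip_counts`.
#' @export
apply_coefficient <- function(matrix, result, treated_samples,
                              rounding = c("none", "nearest_int")) {
  stopifnot(is_counts_matrix(matrix))
  rounding <- match.arg(rounding)
  cc <- if (inherits(result, "refchip_norm")) result$coefficient else
    as.numeric(result)
  if (!is.finite(cc) || cc <= 0) stop("coefficient must be positive", call. = FALSE)
  missing <- setdiff(treated_samples, colnames(matrix))
  if (length(missing)) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- unclass(matrix)
  out[, treated_samples] <- out[, treated_samples, drop = FALSE] * cc
  if (rounding == "nearest_int") {
    v <- out[, treated_samples, drop = FALSE]
    out[, treated_samples] <- sign(v) * floor(abs(v) + 0.5)  # half away from zero
  }
  as_counts(out, library_totals(matrix))
}

#' MA table of per-peak intensity and fold-change
#'
#' Computes, per peak, the mean size-factor-normalized count within each
#' condition of the contrast, then
#' `A = log2((mean_control + mean_treated)/2 + pseudocount)` and
#' `M = log2((mean_treated + pseudocount) / (mean_control + pseudocount))`.
#' In a correctly normalized experiment the unchanged peaks center on
#' `M = 0`. The pseudocount only stabilizes display values; it is never used
#' inside the count-model test.
#'
#' @inheritParams normalization_coefficient
#' @param factors a `refchip_size_factors` (or named positive vector) per
#'   sample; use `size_factors(rep(1, n))` for raw counts.
#' @param pseudocount positive value added inside the logs (default 0.5).
#' @param channels optional channel label per peak: a named character vector
#'   (by peak name) or a single label (default `"target"`).
#' @return A `refchip_ma` data frame: `name`, `channel`, `A`, `M`.
#' @export
ma_transform <- function(matrix, factors, sheet, contrast, pseudocount = 0.5,
                         channels = "target") {
  stopifnot(is_counts_matrix(matrix), is_sample_sheet(sheet))
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  s <- normalize_factors_arg(factors, colnames(matrix))
  grp <- check_contrast(sheet, contrast)
  norm <- sweep(unclass(matrix), 2, s, "/")
  mc <- rowMeans(norm[, grp$control, drop = FALSE])
  mt <- rowMeans(norm[, grp$treated, drop = FALSE])
  ch <- if (length(channels) == 1L && is.null(names(channels))) {
    rep(channels, nrow(matrix))
  } else {
    unname(channels[rownames(matrix)])
  }
  out <- data.frame(
    name = rownames(matrix),
    channel = as.character(ch),
    A = log2((mc + mt) / 2 + pseudocount),
    M = log2((mt + pseudocount) / (mc + pseudocount)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("refchip_ma", "data.frame"))
}

normalize_factors_arg <- function(factors, sample_ids) {
  s <- unclass(factors)
  if (!is.null(names(s))) {
    missing <- setdiff(sample_ids, names(s))
    if (length(missing)) {
      stop("size factors missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    s <- s[sample_ids]
  } else if (length(s) != length(sample_ids)) {
    stop("size factors length must match the number of samples", call. = FALSE)
  }
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("size factors must be positive", call. = FALSE)
  }
  stats::setNames(as.numeric(s), sample_ids)
}

#' Correct fold-changes by a linear fit to control-peak log fold-changes
#'
#' Treats the control channel (spike-in or parallel-factor peaks) as ground
#' truth for zero fold-change: an ordinary least-squares fit of `M` on `A`
#' (intercept and slope by default, or a constant-only fit) over the
#' control-channel rows is subtracted from every row's `M`. After
#' correction the control rows' `M` has mean zero by construction.
#'
#' @param table a `refchip_ma` from [ma_transform()].
#' @param control_channel the channel label of the reference rows.
#' @param fit `"linear"` (intercept + slope on `A`) or `"constant"`
#'   (intercept only).
#' @return The corrected `refchip_ma`, with attributes `fit_intercept` and
#'   `fit_slope` recording the removed trend.
#' @export
lfc_fit_correction <- function(table, control_channel = "control",
                               fit = c("linear", "constant")) {
  stopifnot(inherits(table, "refchip_ma"))
  fit <- match.arg(fit)
  ctrl <- table$channel == control_channel
  if (sum(ctrl) < 2L) {
    stop("need >= 2 control-channel rows for the fit", call. = FALSE)
  }
  if (fit == "linear") {
    if (stats::var(table$A[ctrl]) == 0) {
      stop("control-channel A values have zero variance; use fit='constant'",
           call. = FALSE)
    }
    co <- stats::coef(stats::lm(M ~ A, data = table[ctrl, , drop = FALSE]))
    b0 <- co[[1]]; b1 <- co[[2]]
  } else {
    b0 <- mean(table$M[ctrl]); b1 <- 0
  }
  out <- table
  out$M <- table$M - (b0 + b1 * table$A)
  attr(out, "fit_intercept") <- b0
  attr(out, "fit_slope") <- b1
  out
}
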