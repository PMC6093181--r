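#' Per-peak negative-binomial dispersion estimates
#'
#' Method-of-moments estimator on size-factor-normalized counts under the
#' `variance = mu + alpha * mu^2` parameterization. For each peak the
#' within-condition variance is pooled over all conditions with at least two
#' replicates and combined with the overall normalized mean `mu` as
#' `alpha_hat = max((v - mu) / mu^2, alpha_min)` (Poisson-like peaks hit the
#' floor). A mean-dispersion trend `alpha_tr(mu) = a0 / mu + a1` is then fit
#' by least squares over all peaks with positive mean, and the final
#' per-peak dispersion is the conservative maximum
#' `max(alpha_hat, alpha_tr(mu))`.
#'
#' @inheritParams ma_transform
#' @param alpha_min dispersion floor (default `1e-8`).
#' @return Named numeric vector of dispersions (one per peak), with the
#'   fitted trend coefficients in attribute `trend`.
#' @export
estimate_dispersions <- function(matrix, factors, sheet, alpha_min = 1e-8) {
  stopifnot(is_counts_matrix(matrix), is_sample_sheet(sheet))
  s <- normalize_factors_arg(factors, colnames(matrix))
  sheet <- sheet[sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  conds <- split(sheet$sample_id, sheet$condition)
  conds <- conds[lengths(conds) >= 2L]
  if (!length(conds)) {
    stop("no condition has >= 2 replicates; supply per-peak dispersions ",
         "directly to nb_wald_test()", call. = FALSE)
  }
  norm <- sweep(unclass(matrix)[, sheet$sample_id, drop = FALSE], 2,
                s[sheet$sample_id], "/")
  mu <- rowMeans(norm)
  ss <- 0; df <- 0
  for (ids in conds) {
    sub <- norm[, ids, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(ids) - 1L
  }
  v <- ss / df
  alpha_hat <- ifelse(mu > 0, pmax((v - mu) / mu^2, alpha_min), alpha_min)
  ok <- mu > 0
  trend <- c(a0 = 0, a1 = alpha_min)
  if (sum(ok) >= 2L && stats::var(1 / mu[ok]) > 0) {
    co <- stats::coef(stats::lm(alpha_hat[ok] ~ I(1 / mu[ok])))
    trend <- c(a0 = unname(co[2]), a1 = unname(co[1]))
  } else if (sum(ok) >= 1L) {
    trend <- c(a0 = 0, a1 = mean(alpha_hat[ok]))
  }
  alpha_tr <- ifelse(mu > 0,
                     pmax(trend[["a0"]] / mu + trend[["a1"]], alpha_min),
                     alpha_min)
  alpha <- pmax(alpha_hat, alpha_tr)
  structure(stats::setNames(alpha, rownames(matrix)), trend = trend)
}

#' Negative-binomial Wald test of differential binding
#'
#' Fits, per peak, the two-condition NB generalized linear model
#' `log mu_ij = beta0 + beta1 * treated_j + log s_j` with known per-peak
#' dispersion, by iteratively reweighted least squares (Fisher weights
#' `w = mu / (1 + alpha * mu)`, convergence tolerance `1e-8` on the
#' coefficients, at most 100 iterations). The condition effect `beta1` is
#' reported in log2 units with its Wald standard error; the two-sided p-value
#' uses the standard-normal reference for `z = beta1 / SE`. Peaks whose
#' counts are all zero get `log2FC = 0`, `p = 1`. On the rare non-converged
#' peak the coefficient falls back to the moment estimate
#' `log(mean_treated / mean_control)` of the normalized means (flagged in
#' the `converged` column). Fitted means are floored at `1e-8`, which bounds
#' the estimate and inflates the SE when one condition is entirely zero.
#'
#' @inheritParams ma_transform
#' @param dispersions named per-peak dispersion vector (e.g. from
#'   [estimate_dispersions()]), all `> 0`.
#' @param tol,max_iter IRLS convergence controls.
#' @return A `refchip_diff` data frame: `name`, `baseMean`, `log2FC`, `SE`,
#'   `stat`, `pvalue`, `dispersion`, `converged` (no multiplicity adjustment;
#'   see [bh_adjust()] and [differential_pipeline()]).
#' @export
nb_wald_test <- function(matrix, factors, sheet, contrast, dispersions,
                         tol = 1e-8, max_iter = 100L) {
  stopifnot(is_counts_matrix(matrix), is_sample_sheet(sheet))
  grp <- check_contrast(sheet, contrast)
  ids <- c(grp$control, grp$treated)
  s <- normalize_factors_arg(factors, colnames(matrix))[ids]
  alpha <- dispersions[rownames(matrix)]
  if (anyNA(alpha) || any(alpha <= 0)) {
    stop("dispersions must be positive and cover every peak", call. = FALSE)
  }
  y <- unclass(matrix)[, ids, drop = FALSE]
  n <- nrow(y)
  if (n == 0L) {
    return(structure(data.frame(name = character(0), baseMean = numeric(0),
                                log2FC = numeric(0), SE = numeric(0),
                                stat = numeric(0), pvalue = numeric(0),
                                dispersion = numeric(0), converged = logical(0),
                                stringsAsFactors = FALSE),
                     class = c("refchip_diff", "data.frame")))
  }
  treated <- ids %in% grp$treated
  off <- matrix(log(s), n, length(ids), byrow = TRUE)
  norm <- sweep(y, 2, s, "/")
  mc <- rowMeans(norm[, !treated, drop = FALSE])
  mt <- rowMeans(norm[, treated, drop = FALSE])
  mu_floor <- 1e-8
  # moment initialization (also the documented non-convergence fallback)
  b0 <- log(pmax(mc, mu_floor))
  b1 <- log(pmax(mt, mu_floor)) - b0
  conv <- rep(FALSE, n)
  active <- rep(TRUE, n)
  for (iter in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- matrix(b0, n, length(ids)) + outer(b1, as.numeric(treated)) + off
    mu <- pmax(exp(eta), mu_floor)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    a <- rowSums(w)
    b <- rowSums(w[, treated, drop = FALSE])
    S1 <- rowSums(w * z)
    St <- rowSums((w * z)[, treated, drop = FALSE])
    b0_new <- (S1 - St) / (a - b)
    b1_new <- St / b - b0_new
    # keep estimates finite when one group is numerically extinguished
    b0_new <- pmin(pmax(b0_new, log(mu_floor)), 50)
    b1_new <- pmin(pmax(b1_new, 2 * log(mu_floor)), -2 * log(mu_floor))
    delta <- pmax(abs(b0_new - b0), abs(b1_new - b1))
    newly <- active & delta < tol
    conv[newly] <- TRUE
    active <- active & !newly
    b0 <- b0_new; b1 <- b1_new
  }
  if (any(!conv)) {
    # moment fallback for non-converged fits
    b1[!conv] <- log(pmax(mt[!conv], mu_floor)) - log(pmax(mc[!conv], mu_floor))
    b0[!conv] <- log(pmax(mc[!conv], mu_floor))
  }
  eta <- matrix(b0, n, length(ids)) + outer(b1, as.numeric(treated)) + off
  mu <- pmax(exp(eta), mu_floor)
  w <- mu / (1 + alpha * mu)
  a <- rowSums(w)
  b <- rowSums(w[, treated, drop = FALSE])
  se <- sqrt(a / (b * (a - b)))
  stat <- b1 / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  all_zero <- rowSums(y) == 0
  b1[all_zero] <- 0; stat[all_zero] <- 0; pvalue[all_zero] <- 1
  se[all_zero] <- NA_real_
  res <- data.frame(
    name = rownames(y),
    baseMean = rowMeans(norm),
    log2FC = b1 / log(2),
    SE = se / log(2),
    stat = stat,
    pvalue = pvalue,
    dispersion = unname(alpha),
    converged = conv | all_zero,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("refchip_diff", "data.frame"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, mapped back to the
#' input order (ties resolved stably by input position).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of BH-adjusted q-values (FDR), same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p, seq_along(p), method = "radix")  # stable in input order
  q_sorted <- pmin(rev(cummin(rev(m * p[ord] / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  pmax(q, p)  # q >= p holds mathematically; guard against float rounding
}

#' Differential-binding pipeline with reference-peak normalization
#'
#' End-to-end test: derive the normalization from the control (reference)
#' peaks, exclude those peaks from the tested set, fit per-peak dispersions,
#' run the NB Wald test on the remaining (target) peaks of the contrast, and
#' BH-adjust. Three normalization modes mirror the comparison the method was
#' designed around:
#' \describe{
#'   \item{`library_total`}{size factors proportional to the attached
#'     per-sample library totals (total-read-depth normalization; fails under
#'     genome-wide occupancy changes).}
#'   \item{`control_size_factors`}{median-of-ratios size factors estimated on
#'     the control-peak submatrix only.}
#'   \item{`coefficient`}{through-origin regression coefficient from the
#'     control peaks, applied to the treated columns (rounded to integers)
#'     with unit size factors.}
#' }
#'
#' @inheritParams normalization_coefficient
#' @param normalization_mode one of `"library_total"`,
#'   `"control_size_factors"`, `"coefficient"`.
#' @param test_peaks optional character vector restricting which peaks are
#'   tested (default: all peaks not in `control_peaks`; control peaks are
#'   always excluded).
#' @param alpha_min dispersion floor passed to [estimate_dispersions()].
#' @return A `refchip_diff` data frame for the tested peaks only, with
#'   columns of [nb_wald_test()] plus `padj`; attributes `size_factors` and
#'   (for `"coefficient"`) `normalization` record how the data were scaled.
#' @export
differential_pipeline <- function(matrix, control_peaks, sheet, contrast,
                                  normalization_mode = c("control_size_factors",
                                                         "library_total",
                                                         "coefficient"),
                                  test_peaks = NULL, alpha_min = 1e-8) {
  stopifnot(is_counts_matrix(matrix), is_sample_sheet(sheet))
  normalization_mode <- match.arg(normalization_mode)
  ctrl <- control_peak_names(matrix, control_peaks)
  keep <- if (is.null(test_peaks)) setdiff(rownames(matrix), ctrl) else
    setdiff(test_peaks, ctrl)
  norm_result <- NULL
  work <- matrix
  if (normalization_mode == "library_total") {
    lt <- library_totals(matrix)
    if (is.null(lt)) {
      stop("library_total mode requires library_totals on the counts matrix",
           call. = FALSE)
    }
    factors <- size_factors(lt, method = "library_total")
  } else if (normalization_mode == "control_size_factors") {
    factors <- control_size_factors(matrix, ctrl, method = "median_ratio")
  } else {
    grp <- check_contrast(sheet, contrast)
    norm_result <- normalization_coefficient(matrix, ctrl, sheet, contrast)
    work <- apply_coefficient(matrix, norm_result, grp$treated,
                              rounding = "nearest_int")
    factors <- size_factors(stats::setNames(rep(1, ncol(matrix)),
                                            colnames(matrix)),
                            method = "coefficient")
  }
  disp <- estimate_dispersions(work, factors, sheet, alpha_min = alpha_min)
  target <- as_counts(unclass(work)[keep, , drop = FALSE],
                      library_totals(work))
  res <- nb_wald_test(target, factors, sheet, contrast, disp[keep])
  res$padj <- bh_adjust(res$pvalue)
  attr(res, "size_factors") <- factors
  attr(res, "normalization") <- norm_result
  res
}
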