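test_that("RPM baselines divide by the requested totals", {
  m <- make_counts(c(200, 50, 1999800, 999950), totals = c(4e6, 2e6))
  rpm <- normalize_rpm(m, "reads_in_peaks")   # column sums 2e6 and 1e6
  expect_equal(rpm["p1", "s1"], 100)
  expect_equal(rpm["p1", "s2"], 50)
  rpm_tot <- normalize_rpm(m, "total_reads")
  expect_equal(rpm_tot["p1", "s1"], 50)

  # equal totals leave relative values unchanged
  eq <- make_counts(c(10, 20, 90, 80))
  r <- normalize_rpm(eq, "reads_in_peaks")
  expect_equal(r[, "s1"] / r[, "s2"], unclass(eq)[, "s1"] / unclass(eq)[, "s2"])

  no_totals <- make_counts(c(1, 2, 3, 4))
  expect_error(normalize_rpm(no_totals, "total_reads"), "library_totals")
  zero <- make_counts(c(0, 1, 0, 1))
  expect_error(normalize_rpm(zero, "reads_in_peaks"), "zero total")
})

test_that("sum-method size factors equal the column-sum ratio oracle", {
  m <- make_counts(c(40, 80, 60, 120), peaks = c("k1", "k2"))
  s <- control_size_factors(m, c("k1", "k2"), method = "sum")
  expect_equal(unclass(s), c(s1 = 1 / sqrt(2), s2 = sqrt(2)), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)

  # oracle property on random instances: factors proportional to column sums
  set.seed(8)
  for (trial in 1:5) {
    n <- sample(3:20, 1); k <- sample(2:6, 1)
    mm <- counts_matrix(matrix(rpois(n * k, 50) + 1, n, k,
                               dimnames = list(paste0("p", 1:n),
                                               paste0("s", 1:k))))
    ctrl <- sample(rownames(mm), sample(2:n, 1))
    got <- control_size_factors(mm, ctrl, method = "sum")
    cs <- colSums(unclass(mm)[ctrl, , drop = FALSE])
    expect_equal(unclass(got), cs / exp(mean(log(cs))), tolerance = 1e-12, ignore_attr = TRUE)
  }

  ident <- make_counts(c(5, 5, 9, 9))
  expect_equal(unname(unclass(control_size_factors(ident, c("p1", "p2"), "sum"))), ignore_attr = TRUE,
               c(1, 1))
})

test_that("median-ratio factors reproduce the hand-computed example", {
  m <- counts_matrix(matrix(c(10, 20, 20, 40, 40, 80), 3, 2, byrow = TRUE,
                            dimnames = list(paste0("p", 1:3), c("a", "b"))))
  s <- control_size_factors(m, paste0("p", 1:3), method = "median_ratio")
  expect_equal(unclass(s), c(a = 1 / sqrt(2), b = sqrt(2)), tolerance = 1e-12, ignore_attr = TRUE)

  zero_sample <- make_counts(c(0, 5, 0, 7), peaks = c("k1", "k2"))
  expect_error(control_size_factors(zero_sample, c("k1", "k2"), "sum"),
               "zero control")
  all_zero_rows <- make_counts(c(0, 5, 3, 0), peaks = c("k1", "k2"))
  expect_error(control_size_factors(all_zero_rows, c("k1", "k2"),
                                    "median_ratio"), "non-zero")
  expect_error(control_size_factors(m, character(0)), "empty")
  expect_error(control_size_factors(m, "nope"), "absent")
})

test_that("through-origin coefficient inverts exact proportional bias", {
  sheet <- make_sheet(1)
  m <- counts_matrix(matrix(c(10, 5, 20, 10, 30, 15), 3, 2, byrow = TRUE,
                            dimnames = list(paste0("p", 1:3), c("c1", "t1"))))
  r <- normalization_coefficient(m, paste0("p", 1:3), sheet, sim_contrast)
  expect_equal(r$slope, 0.5)
  expect_equal(r$coefficient, 2)
  expect_equal(r$n_control_peaks, 3L)

  same <- counts_matrix(matrix(c(10, 10, 20, 20), 2, 2, byrow = TRUE,
                               dimnames = list(c("p1", "p2"), c("c1", "t1"))))
  expect_equal(normalization_coefficient(same, c("p1", "p2"), sheet,
                                         sim_contrast)$coefficient, 1)

  zero_y <- counts_matrix(matrix(c(10, 0, 20, 0), 2, 2, byrow = TRUE,
                                 dimnames = list(c("p1", "p2"), c("c1", "t1"))))
  expect_error(normalization_coefficient(zero_y, c("p1", "p2"), sheet,
                                         sim_contrast), "zero")
  expect_error(normalization_coefficient(m, "p1", sheet, sim_contrast), ">= 2")
})

test_that("coefficient recovery on NB counts matches the brute-force oracle", {
  cfg <- simulation_config(n_target_peaks = 0L, n_control_peaks = 5000L,
                           n_spikein_peaks = 0L, true_treated_scaling = 0.8,
                           dispersion = 0.05, seed = 101)
  sim <- generate_experiment(cfg)
  r <- normalization_coefficient(sim$counts, sim$truth$name, sim$samples,
                                 sim_contrast)
  # independent brute-force loop over peaks for the closed form sum(xy)/sum(xx)
  raw <- unclass(sim$counts)
  sxy <- sxx <- 0
  for (i in seq_len(nrow(raw))) {
    x <- mean(raw[i, 1:3]); y <- mean(raw[i, 4:6])
    sxy <- sxy + x * y; sxx <- sxx + x * x
  }
  expect_equal(r$slope, sxy / sxx, tolerance = 1e-12)
  expect_lt(abs(r$coefficient * 0.8 - 1), 0.02)
})

test_that("applying the coefficient restores a unit gradient", {
  sheet <- make_sheet(2)
  set.seed(14)
  for (trial in 1:5) {
    n <- sample(5:50, 1)
    raw <- matrix(runif(n * 4, 1, 500), n, 4,
                  dimnames = list(paste0("p", 1:n), sheet$sample_id))
    m <- counts_matrix(raw)
    r <- normalization_coefficient(m, rownames(raw), sheet, sim_contrast)
    fixed <- apply_coefficient(m, r, c("t1", "t2"), rounding = "none")
    refit <- normalization_coefficient(fixed, rownames(raw), sheet,
                                       sim_contrast)
    expect_equal(refit$slope, 1, tolerance = 1e-9)
  }
})

test_that("gradient is scale-equivariant in the treated columns", {
  sheet <- make_sheet(1)
  m <- counts_matrix(matrix(c(12, 30, 44, 10, 7, 99), 3, 2,
                            dimnames = list(paste0("p", 1:3), c("c1", "t1"))))
  base <- normalization_coefficient(m, paste0("p", 1:3), sheet, sim_contrast)
  for (k in c(0.25, 2, 10)) {
    scaled <- apply_coefficient(m, k, "t1", rounding = "none")
    r <- normalization_coefficient(scaled, paste0("p", 1:3), sheet,
                                   sim_contrast)
    expect_equal(r$slope, base$slope * k, tolerance = 1e-12)
    expect_equal(r$coefficient, base$coefficient / k, tolerance = 1e-12)
  }
})

test_that("coefficient application scales, rounds half-away, and is identity at 1", {
  m <- make_counts(c(7, 3.7, 2, 2.5), samples = c("c1", "t1"))
  doubled <- apply_coefficient(m, 2, "t1", rounding = "none")
  expect_equal(doubled["p1", "t1"], 7.4)
  expect_equal(doubled["p1", "c1"], 7)
  rounded <- apply_coefficient(m, 2, "t1", rounding = "nearest_int")
  expect_equal(rounded["p1", "t1"], 7)   # 7.4 -> 7
  expect_equal(rounded["p2", "t1"], 5)   # 5.0 stays 5, half away from zero
  ident <- apply_coefficient(m, 1, "t1", rounding = "none")
  expect_equal(unclass(ident), unclass(m))
})

test_that("MA transform computes A and M with pseudocount handling", {
  sheet <- make_sheet(1)
  m <- counts_matrix(matrix(c(16, 4, 8, 8, 0, 0), 3, 2, byrow = TRUE,
                            dimnames = list(paste0("p", 1:3), c("c1", "t1"))))
  ma <- ma_transform(m, unit_factors(c("c1", "t1")), sheet, sim_contrast,
                     pseudocount = 1e-9)
  expect_equal(ma$M[1], -2, tolerance = 1e-6)
  expect_equal(ma$A[1], log2(10), tolerance = 1e-6)
  expect_equal(ma$M[2], 0, tolerance = 1e-6)

  ma2 <- ma_transform(m, unit_factors(c("c1", "t1")), sheet, sim_contrast,
                      pseudocount = 0.5)
  expect_equal(ma2$M[3], 0)
  expect_equal(ma2$A[3], log2(0.5))
  expect_error(ma_transform(m, unit_factors(c("c1", "t1")), sheet,
                            sim_contrast, pseudocount = 0), "pseudocount")
})

test_that("control-channel linear fit correction recenters fold-changes", {
  mk_ma <- function(A, M, channel) {
    structure(data.frame(name = paste0("x", seq_along(A)), channel = channel,
                         A = A, M = M, stringsAsFactors = FALSE),
              class = c("refchip_ma", "data.frame"))
  }
  # constant control offset of 1 is subtracted everywhere
  tab <- mk_ma(c(1, 5, 9, 2, 7), c(1, 1, 1, 3, 0.5),
               c("control", "control", "control", "target", "target"))
  fixed <- lfc_fit_correction(tab)
  expect_equal(fixed$M, c(0, 0, 0, 2, -0.5), tolerance = 1e-9)

  # zero control M leaves the table unchanged
  null_tab <- mk_ma(c(1, 4, 6), c(0, 0, 2), c("control", "control", "target"))
  expect_equal(lfc_fit_correction(null_tab)$M, c(0, 0, 2), tolerance = 1e-9)

  # control M = 0.1*A exactly: every row corrected by 0.1*A
  A <- c(2, 4, 8, 16, 5)
  tab3 <- mk_ma(A, c(0.1 * A[1:4], 1),
                c(rep("control", 4), "target"))
  fixed3 <- lfc_fit_correction(tab3)
  expect_equal(fixed3$M, c(0, 0, 0, 0, 1 - 0.1 * 5), tolerance = 1e-9)
  # control rows' corrected M has mean zero
  expect_equal(mean(fixed3$M[fixed3$channel == "control"]), 0,
               tolerance = 1e-9)

  expect_error(lfc_fit_correction(mk_ma(1, 1, "control")), ">= 2")
  same_A <- mk_ma(c(3, 3, 5), c(1, 2, 0), c("control", "control", "target"))
  expect_error(lfc_fit_correction(same_A), "variance")
  expect_equal(lfc_fit_correction(same_A, fit = "constant")$M,
               c(-0.5, 0.5, -1.5))
})

test_that("control peaks center on M = 0 after size-factor normalization", {
  cfg <- simulation_config(n_target_peaks = 400L, n_control_peaks = 800L,
                           n_spikein_peaks = 0L, true_treated_scaling = 0.7,
                           seed = 55)
  sim <- generate_experiment(cfg)
  ctrl <- sim$truth$name[sim$truth$channel == "control"]
  s <- control_size_factors(sim$counts, ctrl, method = "median_ratio")
  ma <- ma_transform(sim$counts, s, sim$samples, sim_contrast,
                     channels = sim$channels)
  mc <- ma$M[ma$channel == "control"]
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc)), 3 * se)
})
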