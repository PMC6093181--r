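test_that("method-of-moments dispersion matches sample moments and floors", {
  sheet <- make_sheet(3)
  ids <- sheet$sample_id
  # identical replicates: variance 0 < mean, so the floor is hit
  flat <- counts_matrix(matrix(rep(c(10, 10, 10, 10, 10, 10), 2), 2, 6,
                               byrow = TRUE,
                               dimnames = list(c("p1", "p2"), ids)))
  d <- estimate_dispersions(flat, unit_factors(ids), sheet, alpha_min = 1e-8)
  expect_equal(unname(d), c(1e-8, 1e-8), ignore_attr = TRUE)

  # single peak: alpha_hat = (v - mu) / mu^2 with v, mu the sample moments
  y <- matrix(c(80, 100, 120, 70, 100, 130), 1, 6,
              dimnames = list("pk", ids))
  m <- counts_matrix(y)
  v <- (var(y[1, 1:3]) + var(y[1, 4:6])) / 2
  mu <- mean(y)
  expect_equal(unname(estimate_dispersions(m, unit_factors(ids), sheet)),
               (v - mu) / mu^2, ignore_attr = TRUE)

  one_rep <- make_sheet(1)
  m2 <- counts_matrix(matrix(c(5, 6), 1, 2,
                             dimnames = list("pk", one_rep$sample_id)))
  expect_error(estimate_dispersions(m2, unit_factors(one_rep$sample_id),
                                    one_rep), "replicates")
})

test_that("dispersion estimates recover the simulated truth in order of magnitude", {
  cfg <- simulation_config(n_target_peaks = 5000L, n_control_peaks = 0L,
                           n_spikein_peaks = 0L, true_treated_scaling = 1,
                           fraction_changed = 0, dispersion = 0.1, seed = 77)
  sim <- generate_experiment(cfg)
  d <- estimate_dispersions(sim$counts, unit_factors(colnames(sim$counts)),
                            sim$samples)
  expect_gt(median(d), 0.05)
  expect_lt(median(d), 0.2)
})

test_that("NB Wald test recovers saturated group means and null boundaries", {
  sheet <- make_sheet(3)
  ids <- sheet$sample_id
  m <- counts_matrix(matrix(c(10, 20, 30, 20, 40, 60,
                              15, 15, 15, 15, 15, 15,
                              0, 0, 0, 0, 0, 0), 3, 6, byrow = TRUE,
                            dimnames = list(c("dbl", "flat", "zero"), ids)))
  disp <- setNames(rep(0.1, 3), rownames(m))
  r <- nb_wald_test(m, unit_factors(ids), sheet, sim_contrast, disp)
  expect_equal(r$log2FC[r$name == "dbl"], 1, tolerance = 1e-6)
  expect_equal(r$log2FC[r$name == "flat"], 0, tolerance = 1e-8)
  expect_equal(r$pvalue[r$name == "flat"], 1, tolerance = 1e-6)
  expect_equal(r$log2FC[r$name == "zero"], 0)
  expect_equal(r$pvalue[r$name == "zero"], 1)
  expect_true(all(r$converged))
  # size factors fold into the offset: doubling every treated count together
  # with the treated factors leaves the fold-change estimate unchanged
  m2 <- unclass(m); m2[, 4:6] <- m2[, 4:6] * 2
  r2 <- nb_wald_test(counts_matrix(m2),
                     stats::setNames(c(1, 1, 1, 2, 2, 2), ids), sheet,
                     sim_contrast, disp)
  expect_equal(r2$log2FC[r2$name == "dbl"], 1, tolerance = 1e-6)
})

test_that("the null NB test is calibrated near the nominal level", {
  fp <- vapply(1:3, function(sd) {
    cfg <- simulation_config(n_target_peaks = 2000L, n_control_peaks = 0L,
                             n_spikein_peaks = 0L, true_treated_scaling = 1,
                             fraction_changed = 0, dispersion = 0.05,
                             seed = sd)
    sim <- generate_experiment(cfg)
    s <- unit_factors(colnames(sim$counts))
    d <- estimate_dispersions(sim$counts, s, sim$samples)
    r <- nb_wald_test(sim$counts, s, sim$samples, sim_contrast, d)
    mean(r$pvalue < 0.05)
  }, numeric(1))
  expect_gt(mean(fp), 0.03)
  expect_lt(mean(fp), 0.07)
})

test_that("detection power is nondecreasing in the true effect size", {
  set.seed(99)
  n <- 400L; reps <- 3L
  sheet <- make_sheet(reps)
  rates <- vapply(c(0.5, 1, 2), function(lfc) {
    mu <- rep(100, n)
    y <- cbind(matrix(rnbinom(n * reps, mu = mu, size = 20), n, reps),
               matrix(rnbinom(n * reps, mu = mu * 2^-lfc, size = 20), n, reps))
    dimnames(y) <- list(paste0("p", 1:n), sheet$sample_id)
    m <- counts_matrix(y)
    d <- setNames(rep(0.05, n), rownames(y))
    r <- nb_wald_test(m, unit_factors(sheet$sample_id), sheet, sim_contrast, d)
    mean(r$pvalue < 0.05)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})

test_that("BH step-up matches closed forms, p.adjust and exhaustive oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.001, 0.5, 1.0)), c(0.003, 0.75, 1.0))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")

  set.seed(6)
  for (n in 1:8) {
    for (trial in 1:10) {
      p <- round(runif(n), 3)  # rounding induces ties
      q <- bh_adjust(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
      expect_true(all(q >= p))
    }
  }
})

test_that("pipeline excludes control peaks and calls no spurious increases", {
  cfg <- simulation_config(n_target_peaks = 300L, n_control_peaks = 400L,
                           n_spikein_peaks = 0L, true_treated_scaling = 0.8,
                           fraction_changed = 0.8, seed = 12)
  sim <- generate_experiment(cfg)
  ctrl <- sim$truth$name[sim$truth$channel == "control"]
  res <- differential_pipeline(sim$counts, ctrl, sim$samples, sim_contrast,
                               normalization_mode = "control_size_factors")
  expect_equal(sort(res$name),
               sort(sim$truth$name[sim$truth$channel == "target"]))
  expect_length(intersect(res$name, ctrl), 0)
  expect_true(all(res$padj >= res$pvalue))
  # generator truth holds no increases; none should be called
  expect_equal(sum(res$padj < 0.05 & res$log2FC > 0), 0)
})

test_that("library-total normalization admits spurious increases that control-derived factors remove", {
  # constant sequencing depth with collapsing target signal inflates the
  # surviving peaks' treated counts (scaling > 1); library totals are
  # background-dominated and blind to it
  n_inc <- vapply(1:50, function(sd) {
    cfg <- simulation_config(n_target_peaks = 150L, n_control_peaks = 150L,
                             n_spikein_peaks = 0L, true_treated_scaling = 1.5,
                             fraction_changed = 0.6, seed = 1000 + sd)
    sim <- generate_experiment(cfg)
    ctrl <- sim$truth$name[sim$truth$channel == "control"]
    lib <- differential_pipeline(sim$counts, ctrl, sim$samples, sim_contrast,
                                 normalization_mode = "library_total")
    ref <- differential_pipeline(sim$counts, ctrl, sim$samples, sim_contrast,
                                 normalization_mode = "control_size_factors")
    unchanged <- sim$truth$name[sim$truth$channel == "target" &
                                  sim$truth$true_log2fc == 0]
    c(lib = sum(lib$padj < 0.05 & lib$log2FC > 0 & lib$name %in% unchanged),
      ref = sum(ref$padj < 0.05 & ref$log2FC > 0 & ref$name %in% unchanged))
  }, numeric(2))
  expect_gt(mean(n_inc["lib", ]), mean(n_inc["ref", ]))
  expect_gt(mean(n_inc["lib", ]), 1)
})

test_that("empty target sets give empty results", {
  cfg <- simulation_config(n_target_peaks = 0L, n_control_peaks = 50L,
                           n_spikein_peaks = 0L, seed = 3)
  sim <- generate_experiment(cfg)
  res <- differential_pipeline(sim$counts, sim$truth$name, sim$samples,
                               sim_contrast)
  expect_equal(nrow(res), 0L)
})
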