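# QC metrics sit on the median-ratio (linear relative abundance) stage;
# fixtures here build that stage directly
linear_qc_matrix <- function(values, groups, batches) {
  n <- ncol(values)
  samples <- data.frame(sample_id = paste0("S", seq_len(n)), group = groups,
                        batch = batches, channel = paste0("ch", seq_len(n)),
                        stringsAsFactors = FALSE)
  proteins <- data.frame(accession = sprintf("P%03d", seq_len(nrow(values))),
                         gene = sprintf("G%d", seq_len(nrow(values))),
                         stringsAsFactors = FALSE)
  x <- tmt_abundance(values, proteins, samples, scale = "log2")
  x$scale <- "median_ratio"  # no MP channel: built past the MP stage
  x
}

test_that("QC CV matches hand arithmetic and is scale-invariant", {
  vals <- rbind(c(1, 1, 1, 1, 2), c(3, 3, 3, 3, 3))
  x <- linear_qc_matrix(vals, groups = rep("QC", 5), batches = 1:5)
  cv <- qc_cv(x)
  expect_equal(unname(cv[1]), 0.4472136 / 1.2, tolerance = 1e-6)  # 0.3727
  expect_equal(unname(cv[2]), 0)
  x10 <- x; x10$values <- x$values * 10
  expect_equal(qc_cv(x10), cv, tolerance = 1e-12)
  expect_error(qc_cv(linear_qc_matrix(vals[, 1, drop = FALSE], "QC", 1)),
               ">= 2 QC")
})

test_that("S/N is the subject-to-QC SD ratio on the log2 scale", {
  # subjects (0,2), QCs (0,1) on the log2 scale: SD ratio = 2
  vals <- rbind(2^c(0, 2, 0, 1))
  x <- linear_qc_matrix(vals, groups = c("PSP", "HC", "QC", "QC"),
                        batches = c(1, 1, 1, 2))
  expect_equal(unname(qc_sn(x)), 1.4142136 / 0.7071068, tolerance = 1e-6)

  # identical spreads give exactly 1
  vals2 <- rbind(2^c(0, 1, 0, 1))
  x2 <- linear_qc_matrix(vals2, groups = c("PSP", "HC", "QC", "QC"),
                         batches = c(1, 1, 1, 2))
  expect_equal(unname(qc_sn(x2)), 1)

  # zero QC SD reported as Inf
  vals3 <- rbind(c(1, 2, 1, 1))
  x3 <- linear_qc_matrix(vals3, groups = c("PSP", "HC", "QC", "QC"),
                         batches = c(1, 1, 1, 2))
  expect_equal(unname(qc_sn(x3)), Inf)
})

test_that("biological variance above technical noise gives median S/N > 1", {
  sim <- simulate_tmt(simulation_config(n_proteins = 400, sigma = 0.208,
                                        sigma_tech = 0.10, seed = 23))
  linear <- filter_missing(median_scale(mp_normalize(sim$matrix)))
  sn <- qc_sn(linear)
  expect_gt(median(sn, na.rm = TRUE), 1)
})

test_that("PCA quantifies batch structure before and after correction", {
  sim <- simulate_tmt(simulation_config(n_proteins = 300, frac_de = 0,
                                        batch_shift_sd = 1.0,
                                        batch_scale_sd = 0, seed = 29))
  # strong shifts on the log2 stage: z-scoring rescales rows, so assess the
  # log2 matrix directly by skipping the z step through the sim's own chain
  zs <- normalize_chain(sim$matrix)
  eta_before <- pca_batch_check(zs)$batch_eta2
  expect_gt(eta_before, 0.5)
  fit <- combat_correct(zs)
  eta_after <- pca_batch_check(fit$matrix)$batch_eta2
  expect_lt(eta_after, eta_before)
})

test_that("degenerate PCA input warns instead of failing", {
  vals <- matrix(1, 4, 6)
  x <- zscore_matrix(vals, groups = rep(c("PSP", "HC"), 3),
                     batches = rep(1:2, each = 3))
  expect_warning(p <- pca_batch_check(x), "zero variance")
  expect_true(is.na(p$batch_eta2))
})

test_that("PCA rejects incomplete or too-small inputs", {
  vals <- matrix(rnorm(12), 3, 4)
  vals[1, 1] <- NA
  x <- zscore_matrix(vals, groups = rep("HC", 4), batches = rep(1, 4))
  expect_error(pca_batch_check(x), "complete")
  x2 <- zscore_matrix(matrix(rnorm(6), 3, 2), groups = rep("HC", 2),
                      batches = rep(1, 2))
  expect_error(pca_batch_check(x2), "3 samples")
})

test_that("qc_report aggregates headline fractions", {
  sim <- simulate_tmt(simulation_config(n_proteins = 200, seed = 31))
  linear <- filter_missing(median_scale(mp_normalize(sim$matrix)))
  rep <- qc_report(linear)
  expect_true(rep$frac_cv_below >= 0 && rep$frac_cv_below <= 1)
  expect_true(rep$frac_sn_above >= 0 && rep$frac_sn_above <= 1)
  # the simulated technical noise is well below biological spread
  expect_gt(rep$frac_sn_above, 0.5)
})
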