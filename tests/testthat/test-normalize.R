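test_that("MP normalization divides by the batch reference and drops MP", {
  vals <- matrix(c(8, 2, 4,    # S1 (PSP)
                   8, 4, 4,    # S2 (HC)
                   8, 2, 2,    # QC
                   8, 2, 4),   # MP
                 nrow = 3)
  x <- tiny_raw(values = vals)
  y <- mp_normalize(x)
  expect_equal(y$scale, "mp_ratio")
  expect_false("MP" %in% y$samples$group)
  expect_equal(unname(y$values[1, ]), c(1, 1, 1))      # value 8 / MP 8
  expect_equal(unname(y$values[2, c("PSP1", "HC1")]), c(1, 2))  # (2,4)/2
})

test_that("missing or zero MP propagates to the whole batch", {
  x <- tiny_raw(n_proteins = 2, n_batches = 2)
  x$values[1, x$samples$batch == 2 & x$samples$group == "MP"] <- NA
  x$values[2, x$samples$batch == 1 & x$samples$group == "MP"] <- 0
  y <- mp_normalize(x)
  b2 <- y$samples$batch == 2
  expect_true(all(is.na(y$values[1, b2])))
  expect_true(all(!is.na(y$values[1, !b2])))
  expect_true(all(is.na(y$values[2, !b2])))
})

test_that("MP normalization is equivariant to batch-wide rescaling", {
  set.seed(7)
  x <- tiny_raw(values = matrix(exp(rnorm(16)), 2), n_batches = 2)
  y1 <- mp_normalize(x)
  x$values[, x$samples$batch == 2] <- x$values[, x$samples$batch == 2] * 37
  y2 <- mp_normalize(x)
  expect_equal(y1$values, y2$values, tolerance = 1e-12)
})

test_that("median scaling gives every row median 1", {
  x <- tiny_raw(values = matrix(c(0.5, 2, 3,  1, 4, 3,  2, 8, 3,  1, 1, 1),
                                nrow = 3))
  y <- median_scale(mp_normalize(x))
  expect_equal(y$scale, "median_ratio")
  expect_equal(unname(y$values[1, ]), c(0.5, 1, 2))   # median already 1
  expect_equal(unname(y$values[2, ]), c(0.5, 1, 2))   # (2,4,8)/4
  expect_equal(unname(y$values[3, ]), c(1, 1, 1))     # constant row
  meds <- apply(y$values, 1, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(1, 3))
})

test_that("log2 + z-score yields row mean 0 and sample SD 1", {
  x <- tiny_raw(values = matrix(c(0.5, 2, 1, 4, 2, 8, 1, 1), nrow = 2))
  y <- median_scale(mp_normalize(x))
  z <- log2_zscore(y)
  expect_equal(z$scale, "zscore")
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))   # (0.5,1,2) exact case
  expect_equal(unname(rowMeans(z$values)), rep(0, 2), tolerance = 1e-12)
  sds <- apply(z$values, 1, sd)
  expect_equal(unname(sds), rep(1, 2), tolerance = 1e-12)
})

test_that("constant rows and non-positive cells are handled with warnings", {
  x <- tiny_raw(values = matrix(c(2, 1, 2, 1, 2, 1, 2, 1), nrow = 2))
  y <- median_scale(mp_normalize(x))
  expect_warning(z <- log2_zscore(y), "constant row")
  expect_equal(unname(z$values[1, ]), rep(0, 3))

  y2 <- median_scale(mp_normalize(tiny_raw(
    values = matrix(c(0, 2, 1, 4, 2, 8, 1, 1), nrow = 2))))
  expect_warning(z2 <- log2_zscore(y2), "non-positive")
  expect_true(is.na(z2$values[1, 1]))
})

test_that("filtering keeps exactly the complete rows, order preserved", {
  x <- tiny_raw(n_proteins = 3)
  x$values[2, 2] <- NA
  y <- filter_missing(x)
  expect_equal(y$proteins$accession, c("P001", "P003"))

  complete <- tiny_raw(n_proteins = 4)
  expect_identical(filter_missing(complete)$values, complete$values)
})

test_that("filtering recovers the batch-dropout survivor set", {
  sim <- simulate_tmt(simulation_config(n_proteins = 300,
                                        p_batch_dropout = 0.15, seed = 13))
  zs <- suppressWarnings(normalize_chain(sim$matrix))
  survivors <- rownames(sim$truth$dropout)[rowSums(sim$truth$dropout) == 0]
  expect_setequal(zs$proteins$accession, survivors)
})

test_that("scale transitions only compose in the legal order", {
  x <- tiny_raw()
  expect_error(median_scale(x), "mp_ratio")
  expect_error(log2_zscore(x), "median_ratio")
  expect_error(mp_normalize(mp_normalize(x)), "raw")
  expect_error(ttest_fc(mp_normalize(x), c("PSP", "HC")), "zscore")
})
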