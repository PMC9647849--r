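# 3-vs-3 toy instance used across the SAM tests
toy_de_matrix <- function(P = 12, seed = 91, shift = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(P * 6), P, 6)
  vals[1, 1:3] <- vals[1, 1:3] + shift
  zscore_matrix(vals, groups = rep(c("PSP", "HC"), each = 3))
}

test_that("t statistic and fold change match the textbook formula", {
  x <- zscore_matrix(rbind(c(1, 2, 3, 4, 5, 6)),
                     groups = rep(c("PSP", "HC"), each = 3))
  tf <- ttest_fc(x, c("PSP", "HC"))
  expect_equal(tf$log2fc, -3)
  expect_equal(tf$tstat, -3 / sqrt(2 / 3), tolerance = 1e-6)  # -3.674
  expect_equal(tf$df, 4)
  # swapping the contrast negates both
  tf2 <- ttest_fc(x, c("HC", "PSP"))
  expect_equal(tf2$tstat, -tf$tstat)
  expect_equal(tf2$log2fc, -tf$log2fc)
})

test_that("identical groups give t = 0 and degenerate variance warns", {
  x <- zscore_matrix(rbind(c(1, 2, 3, 1, 2, 3), rep(2, 6)),
                     groups = rep(c("PSP", "HC"), each = 3))
  expect_warning(tf <- ttest_fc(x, c("PSP", "HC")), "zero pooled variance")
  expect_equal(tf$tstat, c(0, 0))
  expect_equal(tf$pvalue[2], 1)
})

test_that("d-score limits: s0 = 0 is the t statistic, s0 large kills d", {
  x <- toy_de_matrix()
  tf <- ttest_fc(x, c("PSP", "HC"))
  expect_equal(sam_statistic(x, c("PSP", "HC"), s0 = 0), tf$tstat,
               tolerance = 1e-12)
  expect_true(all(abs(sam_statistic(x, c("PSP", "HC"), s0 = 1e6)) < 1e-4))
  # direct evaluation of the moderated formula on one protein
  a <- x$values[1, 1:3]; b <- x$values[1, 4:6]
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  d_hand <- (mean(a) - mean(b)) / (sqrt(sp2 * 2 / 3) + 0.1)
  expect_equal(sam_statistic(x, c("PSP", "HC"), s0 = 0.1)[1], d_hand,
               tolerance = 1e-12)
})

test_that("q-values are monotone non-increasing in |d| and in [0,1]", {
  x <- toy_de_matrix(P = 40, shift = 4)
  res <- suppressWarnings(
    sam_qvalues(x, c("PSP", "HC"), sam_config(n_permutations = 50,
                                              seed = 3)))
  expect_true(all(res$q_sam >= 0 & res$q_sam <= 1))
  ord <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q_sam[ord]) >= -1e-12))
  # determinism
  res2 <- suppressWarnings(
    sam_qvalues(x, c("PSP", "HC"), sam_config(n_permutations = 50,
                                              seed = 3)))
  expect_identical(res$q_sam, res2$q_sam)
})

test_that("permutation FDR equals exhaustive enumeration on a 3-vs-3 toy", {
  x <- toy_de_matrix(P = 15, seed = 55, shift = 5)
  cfg <- sam_config(s0 = 0, n_permutations = 1000, seed = 1)
  expect_warning(res <- sam_qvalues(x, c("PSP", "HC"), cfg),
                 "distinct relabelings")

  # independent oracle: enumerate all C(6,3) = 20 relabelings directly
  absd_of <- function(ia) {
    ib <- setdiff(1:6, ia)
    abs(apply(x$values, 1, function(v) t_brute(v[ia], v[ib])))
  }
  obs <- absd_of(1:3)
  relabels <- combn(1:6, 3, simplify = FALSE)
  null_mat <- vapply(relabels, absd_of, numeric(nrow(x$values)))
  q_expect <- vapply(obs, function(di) {
    thetas <- sort(obs[obs <= di], decreasing = TRUE)
    fdrs <- vapply(thetas, function(th) {
      n_obs <- sum(obs >= th)
      med_null <- median(apply(null_mat, 2, function(z) sum(z >= th)))
      min(max(med_null / n_obs, 0), 1)
    }, numeric(1))
    min(fdrs)
  }, numeric(1))
  expect_equal(res$q_sam, unname(q_expect), tolerance = 1e-12)
})

test_that("an extreme planted effect is significant and nulls are not", {
  set.seed(77)
  P <- 200
  vals <- matrix(rnorm(P * 30), P, 30)
  vals[1, 1:15] <- vals[1, 1:15] + 5   # |effect| = 5 sigma
  x <- zscore_matrix(vals, groups = rep(c("PSP", "HC"), each = 15))
  res <- sam_qvalues(x, c("PSP", "HC"),
                     sam_config(n_permutations = 150, seed = 5))
  expect_lt(res$q_sam[1], 0.05)
  expect_lt(mean(res$q_sam < 0.05), 0.06)
})

test_that("the volcano boundary sits at the significance frontier", {
  set.seed(78)
  P <- 100
  vals <- matrix(rnorm(P * 20), P, 20)
  vals[1:10, 1:10] <- vals[1:10, 1:10] + 3
  x <- zscore_matrix(vals, groups = rep(c("PSP", "HC"), each = 10))
  res <- sam_qvalues(x, c("PSP", "HC"),
                     sam_config(n_permutations = 100, seed = 6))
  bnd <- sam_boundary(res)
  expect_true(all(c("se", "log2fc", "neg_log10_p", "side") %in% names(bnd)))
  expect_setequal(unique(bnd$side), c("up", "down"))
  # boundary |fc| at each se equals d_cut * (se + s0)
  up <- bnd[bnd$side == "up", ]
  expect_equal(up$log2fc, attr(res, "d_cut") * (up$se + attr(res, "s0")),
               tolerance = 1e-12)
  # no significant boundary when nothing is significant
  null_res <- sam_qvalues(toy_de_matrix(P = 10),
                          c("PSP", "HC"),
                          sam_config(n_permutations = 10, seed = 2))
  if (is.na(attr(null_res, "d_cut")))
    expect_equal(nrow(sam_boundary(null_res)), 0)
})
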