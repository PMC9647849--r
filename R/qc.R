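#' Coefficient of variation of the QC replicates
#'
#' Per protein, the CV (SD / mean) across the pooled-QC replicate channels,
#' one per batch. Computed on linear-scale relative abundances (the
#' `median_ratio` stage): a CV of log-scale or z-scored data is not
#' meaningful because the mean is near zero.
#'
#' @param x A `tmt_abundance`; the `median_ratio` scale is expected, other
#'   linear scales are accepted with a warning.
#' @return Named numeric vector of per-protein CVs (fractions; `NA` where
#'   fewer than 2 QC values are observed).
#' @export
qc_cv <- function(x) {
  stopifnot(inherits(x, "tmt_abundance"))
  if (!x$scale %in% c("median_ratio", "mp_ratio", "raw"))
    warning("CV computed on '", x$scale, "' scale data; ",
            "a linear relative-abundance scale (median_ratio) is expected")
  qc <- x$values[, x$samples$group == "QC", drop = FALSE]
  if (ncol(qc) < 2) stop("need >= 2 QC samples to compute CV")
  row_sds(qc) / rowMeans(qc, na.rm = TRUE)
}

#' Signal-to-noise ratio of subjects over QC replicates
#'
#' Per protein, SD of the subject samples divided by SD of the QC
#' replicates. Computed on the log2 scale, where SDs are
#' variance-stabilized; `median_ratio` input is log2-transformed
#' internally, and z-scored input is accepted unchanged (row-wise scaling
#' cancels in the ratio).
#'
#' @param x A `tmt_abundance` on the `median_ratio`, `log2`, `zscore` or
#'   `batch_corrected` scale containing QC columns.
#' @return Named numeric vector of per-protein S/N ratios; `Inf` where the
#'   QC SD is zero.
#' @export
qc_sn <- function(x) {
  stopifnot(inherits(x, "tmt_abundance"))
  vals <- x$values
  if (x$scale %in% c("raw", "mp_ratio", "median_ratio")) {
    vals[!is.na(vals) & vals <= 0] <- NA_real_
    vals <- log2(vals)
  }
  qc <- vals[, x$samples$group == "QC", drop = FALSE]
  subj <- vals[, subject_cols(x), drop = FALSE]
  if (ncol(qc) < 2) stop("need >= 2 QC samples to compute S/N")
  if (ncol(subj) < 2) stop("need >= 2 subject samples to compute S/N")
  sn <- row_sds(subj) / row_sds(qc)
  sn[row_sds(qc) == 0] <- Inf
  sn
}

#' PCA-based batch-effect assessment
#'
#' Principal-component analysis over samples (proteins as features,
#' centered, unscaled), returning the first two PC scores, the variance
#' they explain, and `batch_eta2`: the fraction of the PC1–PC2 score
#' variance attributable to batch (between-batch sum of squares over total
#' sum of squares, pooled over the two PCs). Values near 1 mean the 2D PCA
#' separates by batch, near 0 that batch structure is absent — the
#' before/after contrast a ComBat correction should produce.
#'
#' @param x A complete `tmt_abundance` (no missing cells), at least 3
#'   samples.
#' @param use_qc Include QC columns in the PCA (default `FALSE`: subjects
#'   only, matching the design used for correction).
#' @return A list of class `tmt_pca`: `scores` (samples x 2), `var_explained`
#'   (length 2), `batch_eta2`, `batch` (factor), `group` (factor).
#' @export
pca_batch_check <- function(x, use_qc = FALSE) {
  stopifnot(inherits(x, "tmt_abundance"))
  cols <- if (use_qc) which(x$samples$group != "MP") else subject_cols(x)
  vals <- x$values[, cols, drop = FALSE]
  if (anyNA(vals)) stop("PCA needs a complete matrix; run filter_missing()")
  if (ncol(vals) < 3) stop("need at least 3 samples for PCA")
  tv <- t(vals)
  if (all(apply(tv, 2, var) == 0)) {
    warning("all proteins have zero variance across samples; PCA degenerate")
    scores <- matrix(0, nrow(tv), 2,
                     dimnames = list(rownames(tv), c("PC1", "PC2")))
    return(structure(list(scores = scores, var_explained = c(0, 0),
                          batch_eta2 = NA_real_,
                          batch = factor(x$samples$batch[cols]),
                          group = factor(x$samples$group[cols])),
                     class = "tmt_pca"))
  }
  pc <- prcomp(tv, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2) scores <- cbind(scores, PC2 = 0)
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  ve[is.na(ve)] <- 0

  batch <- factor(x$samples$batch[cols])
  centered <- sweep(scores, 2, colMeans(scores))
  ss_tot <- sum(centered^2)
  ss_between <- 0
  for (b in levels(batch)) {
    sel <- batch == b
    ss_between <- ss_between + sum(sel) * sum(colMeans(centered[sel, ,
                                                       drop = FALSE])^2)
  }
  eta2 <- if (ss_tot > 0) ss_between / ss_tot else NA_real_
  structure(list(scores = scores, var_explained = ve, batch_eta2 = eta2,
                 batch = batch, group = factor(x$samples$group[cols])),
            class = "tmt_pca")
}

#' @export
print.tmt_pca <- function(x, ...) {
  cat("PCA batch check: ", nrow(x$scores), " samples, PC1/PC2 explain ",
      sprintf("%.1f%% / %.1f%%", 100 * x$var_explained[1],
              100 * x$var_explained[2]),
      "; batch eta^2 = ", sprintf("%.3f", x$batch_eta2), "\n", sep = "")
  invisible(x)
}

#' Assemble a QC report
#'
#' Computes per-protein QC CVs and S/N ratios on the linear relative
#' abundance matrix, the summary fractions used as data-quality headlines
#' (proteins with CV < 30%; proteins with S/N > 1), and a PCA batch check
#' on the corrected matrix when supplied.
#'
#' @param x_linear A `tmt_abundance` on the `median_ratio` scale (with QC
#'   columns).
#' @param x_corrected Optional complete matrix (e.g. z-scored or
#'   batch-corrected) for the PCA; defaults to a complete-case version of
#'   the log2 of `x_linear`.
#' @param cv_threshold CV headline threshold (default 0.30).
#' @param sn_threshold S/N headline threshold (default 1).
#' @return A list of class `qc_report`: per-protein `cv` and `sn`, headline
#'   `frac_cv_below` / `frac_sn_above`, and `pca` (a `tmt_pca` or `NULL`).
#' @export
qc_report <- function(x_linear, x_corrected = NULL, cv_threshold = 0.30,
                      sn_threshold = 1) {
  cv <- qc_cv(x_linear)
  sn <- qc_sn(x_linear)
  pca <- if (!is.null(x_corrected)) pca_batch_check(x_corrected) else NULL
  structure(list(cv = cv, sn = sn,
                 frac_cv_below = mean(cv < cv_threshold, na.rm = TRUE),
                 frac_sn_above = mean(sn > sn_threshold, na.rm = TRUE),
                 cv_threshold = cv_threshold, sn_threshold = sn_threshold,
                 pca = pca),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  %.1f%% of proteins with QC CV < %d%%\n",
              100 * x$frac_cv_below, round(100 * x$cv_threshold)))
  cat(sprintf("  %.1f%% of proteins with S/N > %g\n",
              100 * x$frac_sn_above, x$sn_threshold))
  if (!is.null(x$pca)) print(x$pca)
  invisible(x)
}
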