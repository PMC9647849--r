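#' Normalize against the master-pool reference channel
#'
#' Divides every subject and QC value by its own batch's master-pool (MP)
#' value for the same protein, then drops the MP columns. Division by a
#' missing or zero MP value yields a missing cell. This is the bridging
#' step that puts reporter abundances from different TMT batches on a
#' common relative scale.
#'
#' @param x A `tmt_abundance` on the `raw` scale with one MP per batch.
#' @return A `tmt_abundance` on the `mp_ratio` scale, MP columns removed.
#' @export
mp_normalize <- function(x) {
  assert_scale(x, "raw")
  mp_idx <- which(x$samples$group == "MP")
  mp_batch <- x$samples$batch[mp_idx]
  if (!all(unique(x$samples$batch) %in% mp_batch))
    stop("batch without MP: ",
         paste(setdiff(unique(x$samples$batch), mp_batch), collapse = ", "))
  keep <- which(x$samples$group != "MP")
  vals <- x$values[, keep, drop = FALSE]
  for (j in seq_along(keep)) {
    b <- x$samples$batch[keep[j]]
    mp <- x$values[, mp_idx[match(b, mp_batch)]]
    mp[!is.na(mp) & mp == 0] <- NA_real_
    vals[, j] <- vals[, j] / mp
  }
  tmt_abundance(vals, x$proteins, x$samples[keep, ], scale = "mp_ratio")
}

#' Scale each protein by its median relative abundance
#'
#' Divides each protein row by the median of its non-missing values across
#' all retained samples, so every row has median 1. Rows with no observed
#' values are left all-missing.
#'
#' @param x A `tmt_abundance` on the `mp_ratio` scale.
#' @return A `tmt_abundance` on the `median_ratio` scale.
#' @export
median_scale <- function(x) {
  assert_scale(x, "mp_ratio")
  med <- apply(x$values, 1, median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_  # all-missing rows stay all-missing
  vals <- x$values / med
  vals[is.na(med), ] <- NA_real_
  out <- x
  out$values <- vals
  out$scale <- "median_ratio"
  out
}

#' Log2-transform and z-score each protein
#'
#' Takes log2 of each cell, then centers and scales each protein row to
#' mean 0 and sample SD 1 (denominator n - 1, Perseus convention), computed
#' over non-missing entries. Non-positive cells cannot be log-transformed
#' and become missing with a warning; constant rows (SD 0) are set to
#' all-zero with a warning.
#'
#' @param x A `tmt_abundance` on the `median_ratio` scale.
#' @return A `tmt_abundance` on the `zscore` scale.
#' @export
log2_zscore <- function(x) {
  assert_scale(x, "median_ratio")
  vals <- x$values
  bad <- !is.na(vals) & vals <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive cell(s) set to missing before log2")
    vals[bad] <- NA_real_
  }
  vals <- log2(vals)
  mu <- rowMeans(vals, na.rm = TRUE)
  s <- row_sds(vals)
  const <- !is.na(s) & s == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) z-scored to all-zero")
    s[const] <- 1
  }
  vals <- (vals - mu) / s
  out <- x
  out$values <- vals
  out$scale <- "zscore"
  out
}

#' Drop proteins with any missing value
#'
#' Retains exactly the proteins observed in every sample column (subjects
#' and QC alike), preserving order. This is the complete-case filter
#' applied before batch correction; no imputation is performed anywhere in
#' the pipeline.
#'
#' @param x A `tmt_abundance` on any scale.
#' @return A `tmt_abundance` containing only complete rows.
#' @export
filter_missing <- function(x) {
  stopifnot(inherits(x, "tmt_abundance"))
  keep <- rowSums(is.na(x$values)) == 0
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$proteins <- x$proteins[keep, , drop = FALSE]
  rownames(out$proteins) <- NULL
  out
}

#' Run the full pre-correction normalization chain
#'
#' Convenience composition `mp_normalize |> median_scale |> log2_zscore |>
#' filter_missing`, the fixed legal order of scale transitions.
#'
#' @param x A `tmt_abundance` on the `raw` scale.
#' @return A complete (no missing cells) `tmt_abundance` on the `zscore`
#'   scale, MP columns removed, QC columns retained.
#' @export
normalize_chain <- function(x) {
  filter_missing(log2_zscore(median_scale(mp_normalize(x))))
}
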