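# pooled-variance two-sample statistics for every row of vals
two_sample_stats <- function(vals, ia, ib) {
  na <- length(ia); nb <- length(ib)
  a <- vals[, ia, drop = FALSE]; b <- vals[, ib, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  ssa <- rowSums((a - ma)^2); ssb <- rowSums((b - mb)^2)
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  list(diff = unname(ma - mb), se = unname(se), df = df)
}

#' Two-sample t-test and fold change per protein
#'
#' Student's pooled-variance two-sided t-test of `contrast[1]` against
#' `contrast[2]` for every protein, with the group-mean difference as the
#' fold change (on the log2-consistent scale of the input: a mean
#' difference of z-scored log2 abundances). Proteins with zero pooled
#' variance get `t = 0`, `p = 1` with a warning.
#'
#' @param x A `tmt_abundance` on the `zscore` or `batch_corrected` scale.
#' @param contrast Character 2-vector `c(groupA, groupB)`.
#' @return Data frame with `accession`, `gene`, `log2fc`, `tstat`,
#'   `pvalue`, `se`, `df`.
#' @export
ttest_fc <- function(x, contrast) {
  assert_scale(x, c("zscore", "batch_corrected"))
  idx <- contrast_idx(x, contrast)
  if (length(idx$a) < 2 || length(idx$b) < 2)
    stop("need >= 2 samples per group")
  if (anyNA(x$values[, c(idx$a, idx$b)]))
    stop("differential testing needs complete rows; run filter_missing()")
  st <- two_sample_stats(x$values, idx$a, idx$b)
  tstat <- st$diff / st$se
  p <- 2 * pt(-abs(tstat), st$df)
  degen <- st$se == 0
  if (any(degen)) {
    warning(sum(degen), " protein(s) with zero pooled variance: t = 0, p = 1")
    tstat[degen] <- 0; p[degen] <- 1
  }
  data.frame(accession = x$proteins$accession, gene = x$proteins$gene,
             log2fc = st$diff, tstat = tstat, pvalue = p, se = st$se,
             df = st$df, stringsAsFactors = FALSE)
}

#' SAM moderated d-statistic
#'
#' The SAM test statistic: the group-mean difference divided by the pooled
#' standard error plus a small fudge factor `s0` that stabilizes
#' low-variance proteins. With `s0 = 0` it reduces exactly to the ordinary
#' pooled-variance t statistic.
#'
#' @param x A `tmt_abundance` on the `zscore` or `batch_corrected` scale.
#' @param contrast Character 2-vector `c(groupA, groupB)`.
#' @param s0 Fudge factor, >= 0.
#' @return Numeric vector of per-protein d-scores.
#' @export
sam_statistic <- function(x, contrast, s0 = 0.1) {
  stopifnot(s0 >= 0)
  idx <- contrast_idx(x, contrast)
  st <- two_sample_stats(x$values, idx$a, idx$b)
  st$diff / (st$se + s0)
}

#' SAM configuration
#'
#' @param s0 Fudge factor added to the pooled standard error (default 0.1,
#'   the common volcano-plot default).
#' @param n_permutations Number of random group relabelings for the null
#'   (default 250).
#' @param q_threshold Significance cut on the q-value (default 0.05).
#' @param seed Integer seed for the permutation draws.
#' @return A list of class `sam_config`.
#' @export
sam_config <- function(s0 = 0.1, n_permutations = 250L, q_threshold = 0.05,
                       seed = 1L) {
  stopifnot(s0 >= 0, n_permutations >= 1, q_threshold > 0, q_threshold < 1)
  structure(list(s0 = s0, n_permutations = as.integer(n_permutations),
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "sam_config")
}

# count, for each threshold in `thr` (sorted descending), how many values
# of `v` are >= that threshold
count_ge <- function(v, thr) {
  sv <- sort(v)
  length(v) - findInterval(thr, sv, left.open = TRUE)
}
count_le <- function(v, thr) findInterval(thr, sort(v))

#' SAM permutation q-values
#'
#' Computes the per-protein SAM d-scores on the observed labels and on
#' `n_permutations` random relabelings of the pooled samples, then for
#' every observed |d| threshold estimates
#' \deqn{FDR(\theta) = \mathrm{median}_{perm}\,\#\{|d^*| \ge \theta\} /
#'       \#\{|d| \ge \theta\}}
#' clipped to \[0, 1\]. A protein's q-value is the minimum FDR over all
#' thresholds at or below its own |d|, which makes q monotone
#' non-increasing in |d|. If more permutations are requested than distinct
#' relabelings exist, all distinct relabelings are enumerated instead, with
#' a warning.
#'
#' @param x A complete `tmt_abundance` on the `zscore` or `batch_corrected`
#'   scale.
#' @param contrast Character 2-vector `c(groupA, groupB)`.
#' @param config A [sam_config()].
#' @return Data frame of class `sam_result` with `accession`, `gene`,
#'   `log2fc`, `tstat`, `pvalue`, `se`, `df`, `d`, `q_sam`, `sig_sam`;
#'   attributes `s0`, `df`, `d_cut` (smallest significant |d|, `NA` if
#'   none) and `q_threshold` for the volcano boundary.
#' @export
sam_qvalues <- function(x, contrast, config = sam_config()) {
  stopifnot(inherits(config, "sam_config"))
  base <- ttest_fc(x, contrast)
  idx <- contrast_idx(x, contrast)
  pool <- c(idx$a, idx$b)
  na <- length(idx$a)
  if (length(pool) < 4) stop("combined group size must be >= 4")
  d_obs <- base$log2fc / (base$se + config$s0)
  absd <- abs(d_obs)

  n_distinct <- choose(length(pool), na)
  perms <- with_local_seed(config$seed, {
    if (config$n_permutations >= n_distinct && n_distinct <= 1e5) {
      warning("requested ", config$n_permutations, " permutations but only ",
              n_distinct, " distinct relabelings exist; using all of them")
      combn(pool, na, simplify = FALSE)
    } else {
      lapply(seq_len(config$n_permutations),
             function(k) sample(pool, na))
    }
  })

  thr <- sort(unique(absd), decreasing = TRUE)
  obs_ge <- count_ge(absd, thr)
  null_ge <- vapply(perms, function(pa) {
    pb <- setdiff(pool, pa)
    # relabelings may be unbalanced only if groups differ in size; pa is
    # always drawn with the original size of group A
    st <- two_sample_stats(x$values, pa, pb)
    count_ge(abs(st$diff / (st$se + config$s0)), thr)
  }, numeric(length(thr)))
  med_null <- apply(matrix(null_ge, nrow = length(thr)), 1, median)
  fdr <- pmin(pmax(med_null / obs_ge, 0), 1)
  # q(protein) = min FDR over thresholds at or below its own |d| (the
  # thresholds that call it significant); monotone non-increasing in |d|
  qthr <- rev(cummin(rev(fdr)))
  q <- qthr[match(absd, thr)]

  out <- base
  out$d <- d_obs
  out$q_sam <- q
  out$sig_sam <- q < config$q_threshold
  sig_d <- absd[out$sig_sam]
  attr(out, "s0") <- config$s0
  attr(out, "t_df") <- base$df[1]
  attr(out, "d_cut") <- if (length(sig_d)) min(sig_d) else NA_real_
  attr(out, "q_threshold") <- config$q_threshold
  class(out) <- c("sam_result", "data.frame")
  out
}

#' Curved volcano significance boundary
#'
#' Exports the locus in (log2fc, -log10 p) space where the SAM q-value
#' crosses the significance threshold: the curve traced by
#' `|fc| = d_cut * (se + s0)` as the per-protein standard error varies,
#' i.e. the curved boundary drawn on SAM-style volcano plots.
#'
#' @param fit A `sam_result` from [sam_qvalues()].
#' @param n_points Number of points per branch.
#' @return Data frame with `se`, `log2fc`, `neg_log10_p` and `side`
#'   (`"up"`/`"down"`); zero rows if no protein reached significance.
#' @export
sam_boundary <- function(fit, n_points = 200L) {
  stopifnot(inherits(fit, "sam_result"))
  d_cut <- attr(fit, "d_cut"); s0 <- attr(fit, "s0")
  dfree <- attr(fit, "t_df")
  if (is.na(d_cut))
    return(data.frame(se = numeric(0), log2fc = numeric(0),
                      neg_log10_p = numeric(0), side = character(0)))
  se_grid <- seq(max(min(fit$se), 1e-6), max(fit$se), length.out = n_points)
  fc <- d_cut * (se_grid + s0)
  tt <- fc / se_grid
  nlp <- -log10(2 * pt(-tt, dfree))
  rbind(data.frame(se = se_grid, log2fc = fc, neg_log10_p = nlp,
                   side = "up", stringsAsFactors = FALSE),
        data.frame(se = se_grid, log2fc = -fc, neg_log10_p = nlp,
                   side = "down", stringsAsFactors = FALSE))
}
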