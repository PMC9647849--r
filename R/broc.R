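#' Mann-Whitney AUC with midrank tie handling
#'
#' The area under the ROC curve for separating `values_a` (cases) from
#' `values_b` (controls): the probability that a random case exceeds a
#' random control, ties counted half,
#' `AUC = (#\{a > b\} + 0.5 #\{a = b\}) / (|A| |B|)`.
#'
#' @param values_a Numeric vector, group A (higher values push AUC above
#'   0.5).
#' @param values_b Numeric vector, group B.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (!na || !nb) stop("both groups must be non-empty")
  r <- rank(c(values_a, values_b))
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nb)
}

#' Bootstrap distribution of the AUC
#'
#' Resamples each group with replacement (stratified: group sizes are
#' preserved) `n_bootstrap` times, computes the Mann-Whitney AUC for each
#' resample, and returns the mean and SD of the bootstrap AUCs.
#'
#' @param values_a Numeric vector, group A (size >= 2).
#' @param values_b Numeric vector, group B (size >= 2).
#' @param n_bootstrap Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return Named numeric vector `c(auc_mean, auc_sd)`.
#' @export
bootstrap_auc <- function(values_a, values_b, n_bootstrap = 1000L,
                          seed = 1L) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2, n_bootstrap >= 1)
  aucs <- with_local_seed(seed, vapply(seq_len(n_bootstrap), function(k) {
    auc_mw(sample(values_a, replace = TRUE),
           sample(values_b, replace = TRUE))
  }, numeric(1)))
  c(auc_mean = mean(aucs), auc_sd = sd(aucs))
}

#' Bootstrap-ROC configuration
#'
#' @param n_bootstrap Bootstrap resamples per protein (default 1000).
#' @param n_permutation_passes Independent label permutations building the
#'   null (default 1; counts are averaged over passes).
#' @param q_threshold Significance cut on the q-value (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `broc_config`.
#' @export
broc_config <- function(n_bootstrap = 1000L, n_permutation_passes = 1L,
                        q_threshold = 0.05, seed = 1L) {
  stopifnot(n_bootstrap >= 1, n_permutation_passes >= 1,
            q_threshold > 0, q_threshold < 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 n_permutation_passes = as.integer(n_permutation_passes),
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "broc_config")
}

# bootstrap mean/SD AUC for every row of vals at once; one stratified
# resample of the sample columns per iteration is shared across proteins
# (each protein's marginal bootstrap distribution is unchanged; sharing
# makes the matrix-wide sweep feasible)
matrix_bootstrap_auc <- function(vals, ia, ib, n_bootstrap) {
  na <- length(ia); nb <- length(ib)
  P <- nrow(vals)
  s <- s2 <- numeric(P)
  off <- na * (na + 1) / 2
  for (k in seq_len(n_bootstrap)) {
    cols <- c(sample(ia, replace = TRUE), sample(ib, replace = TRUE))
    rr <- t(apply(vals[, cols, drop = FALSE], 1, rank))
    aucs <- (rowSums(rr[, seq_len(na), drop = FALSE]) - off) / (na * nb)
    s <- s + aucs
    s2 <- s2 + aucs^2
  }
  m <- s / n_bootstrap
  v <- pmax(s2 / n_bootstrap - m^2, 0) * n_bootstrap / max(n_bootstrap - 1, 1)
  list(mean = m, sd = sqrt(v))
}

# q-values for one direction: thr are the observed auc_means of that list,
# swept from most extreme inward; ge = TRUE for the up-list
direction_q <- function(obs_all, null_mat, thr, ge) {
  if (!length(thr)) return(numeric(0))
  ord <- order(thr, decreasing = ge)
  tsort <- thr[ord]
  n_obs <- if (ge) count_ge(obs_all, tsort) else count_le(obs_all, tsort)
  n_null <- rowMeans(vapply(seq_len(ncol(null_mat)), function(p) {
    if (ge) count_ge(null_mat[, p], tsort) else count_le(null_mat[, p], tsort)
  }, numeric(length(tsort))))
  q <- pmin(pmax(n_null / n_obs, 0), 1)
  q <- cummax(q)          # monotone non-decreasing toward AUC = 0.5
  q[order(ord)]           # back to input order
}

#' Bootstrap-ROC q-values
#'
#' The bootstrap-ROC differential-abundance procedure: (1) per-protein
#' bootstrap mean and SD of the AUC on the observed labels; (2) the same
#' bootstrap procedure after permuting the group labels
#' (`n_permutation_passes` independent shuffles, null counts averaged);
#' (3) proteins split into an up-list (mean AUC > 0.5) and a down-list
#' (mean AUC < 0.5); (4) sweeping the threshold from the most extreme AUC
#' inward, `q(theta) = N_null(theta) / N_obs(theta)` with counts of
#' proteins at or beyond the threshold; (5) q clipped to \[0, 1\] and made
#' monotone non-decreasing toward 0.5. Proteins with mean AUC exactly 0.5
#' get q = 1.
#'
#' @param x A complete `tmt_abundance` on the `zscore` or `batch_corrected`
#'   scale.
#' @param contrast Character 2-vector `c(groupA, groupB)`; AUC > 0.5 means
#'   higher in `groupA`.
#' @param config A [broc_config()].
#' @return Data frame of class `broc_result` with `accession`, `gene`,
#'   `auc_mean`, `auc_sd`, `q_broc`, `sig_broc`; attribute `q_threshold`.
#' @export
broc_qvalues <- function(x, contrast, config = broc_config()) {
  stopifnot(inherits(config, "broc_config"))
  assert_scale(x, c("zscore", "batch_corrected"))
  idx <- contrast_idx(x, contrast)
  if (length(idx$a) < 2 || length(idx$b) < 2)
    stop("need >= 2 samples per group")
  vals <- x$values[, c(idx$a, idx$b), drop = FALSE]
  if (anyNA(vals))
    stop("differential testing needs complete rows; run filter_missing()")
  na <- length(idx$a)
  ia <- seq_len(na); ib <- na + seq_along(idx$b)

  res <- with_local_seed(config$seed, {
    obs <- matrix_bootstrap_auc(vals, ia, ib, config$n_bootstrap)
    null_means <- vapply(seq_len(config$n_permutation_passes), function(p) {
      perm <- sample(ncol(vals))
      matrix_bootstrap_auc(vals[, perm, drop = FALSE], ia, ib,
                           config$n_bootstrap)$mean
    }, numeric(nrow(vals)))
    list(obs = obs, null = matrix(null_means, nrow = nrow(vals)))
  })

  am <- res$obs$mean
  q <- rep(1, length(am))
  up <- am > 0.5; down <- am < 0.5
  q[up] <- direction_q(am, res$null, am[up], ge = TRUE)
  q[down] <- direction_q(am, res$null, am[down], ge = FALSE)

  out <- data.frame(accession = x$proteins$accession, gene = x$proteins$gene,
                    auc_mean = am, auc_sd = res$obs$sd, q_broc = q,
                    sig_broc = q < config$q_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "q_threshold") <- config$q_threshold
  class(out) <- c("broc_result", "data.frame")
  out
}
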