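#' Parametric empirical-Bayes batch correction
#'
#' Location-scale batch correction of a complete (no missing values)
#' normalized abundance matrix, following the parametric empirical-Bayes
#' scheme of Johnson et al.: each protein is standardized under a grand
#' model (optionally preserving group means through a covariate design),
#' per-batch per-protein additive effects (gamma) and variance scale
#' factors (delta squared) are estimated, shrunk toward batch-level normal
#' and inverse-gamma priors by iterating the conditional posterior means to
#' convergence, and the data are adjusted by removing the shrunken effects
#' and restoring the grand model.
#'
#' QC channels are diagnostics, not biology: they are excluded from
#' estimation and dropped from the corrected output, which therefore
#' contains subject samples only.
#'
#' @param x A complete `tmt_abundance` on the `zscore` (or `log2`) scale,
#'   e.g. the output of [normalize_chain()].
#' @param preserve_groups Keep the biological group means in the model so
#'   group signal is not absorbed into the batch terms (default `TRUE`).
#' @param tol Convergence tolerance: iteration stops when the largest
#'   absolute change of any posterior estimate falls below `tol`.
#' @param max_iter Iteration cap for the EB update.
#' @return A list of class `combat_fit` with elements `matrix` (the
#'   corrected `tmt_abundance`, `scale = "batch_corrected"`) and `model`
#'   (per-batch `gamma_hat`, `delta2_hat`, shrunken `gamma_star`,
#'   `delta2_star`, the EB hyperparameters, the pooled variance, and the
#'   iteration counts).
#' @export
combat_correct <- function(x, preserve_groups = TRUE, tol = 1e-6,
                           max_iter = 1000L) {
  assert_scale(x, c("zscore", "log2"))
  keep <- which(x$samples$group != "QC")
  samples <- x$samples[keep, , drop = FALSE]
  dat <- x$values[, keep, drop = FALSE]
  if (anyNA(dat))
    stop("batch correction needs a complete matrix; run filter_missing()")
  batch <- factor(samples$batch)
  nb <- table(batch)
  if (any(nb < 2))
    stop("batch(es) with a single sample, variance inestimable: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  P <- nrow(dat); N <- ncol(dat); B <- nlevels(batch)

  out_mat <- function(vals) tmt_abundance(vals, x$proteins, samples,
                                          scale = "batch_corrected")

  if (B == 1L) {
    # single batch: nothing to correct
    model <- list(batches = levels(batch),
                  gamma_hat = matrix(0, P, 1), delta2_hat = matrix(1, P, 1),
                  gamma_star = matrix(0, P, 1), delta2_star = matrix(1, P, 1),
                  hyper = data.frame(batch = levels(batch), gamma_bar = 0,
                                     t2 = 0, a_prior = NA, b_prior = NA),
                  var_pooled = row_sds(dat)^2, iterations = 0L)
    return(structure(list(matrix = out_mat(dat), model = model),
                     class = "combat_fit"))
  }

  batch_design <- stats::model.matrix(~ 0 + batch)
  design <- batch_design
  if (preserve_groups) {
    grp <- factor(samples$group)
    if (nlevels(grp) > 1) {
      grp_design <- stats::model.matrix(~ grp)[, -1, drop = FALSE]
      design <- cbind(batch_design, grp_design)
    }
  }
  if (qr(design)$rank < ncol(design))
    stop("batch and group are confounded; cannot preserve group effects")

  # grand model fit and per-protein standardization
  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(as.numeric(nb) / N, B_hat[seq_len(B), , drop = FALSE])
  var_pooled <- as.numeric(
    ((dat - t(design %*% B_hat))^2) %*% rep(1 / N, N))
  if (any(var_pooled <= 0))
    stop("zero pooled variance for ", sum(var_pooled <= 0), " protein(s)")
  stand_mean <- t(grand_mean)[, rep(1, N), drop = FALSE]
  if (ncol(design) > B) {
    tmp <- design; tmp[, seq_len(B)] <- 0
    stand_mean <- stand_mean + t(tmp %*% B_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  # per-batch location/scale estimates and EB hyperpriors
  gamma_hat <- delta2_hat <- matrix(NA_real_, P, B,
                                    dimnames = list(rownames(dat),
                                                    levels(batch)))
  for (i in seq_len(B)) {
    cols <- which(batch == levels(batch)[i])
    gamma_hat[, i] <- rowMeans(s_data[, cols, drop = FALSE])
    delta2_hat[, i] <- row_sds(s_data[, cols, drop = FALSE])^2
  }
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, var)
  a_prior <- apply(delta2_hat, 2, function(d) {
    m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta2_hat, 2, function(d) {
    m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- delta2_star <- matrix(NA_real_, P, B,
                                      dimnames = dimnames(gamma_hat))
  iterations <- integer(B)
  for (i in seq_len(B)) {
    cols <- which(batch == levels(batch)[i])
    n_i <- length(cols)
    sd_i <- s_data[, cols, drop = FALSE]
    g_old <- gamma_hat[, i]; d_old <- delta2_hat[, i]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (t2[i] * n_i * gamma_hat[, i] + d_old * gamma_bar[i]) /
        (t2[i] * n_i + d_old)
      sum2 <- rowSums((sd_i - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
      delta <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new; d_old <- d_new
      if (delta < tol || it >= max_iter) break
    }
    gamma_star[, i] <- g_old
    delta2_star[, i] <- d_old
    iterations[i] <- it
  }

  # adjust: remove shrunken batch effects, restore the grand model
  adj <- s_data
  for (i in seq_len(B)) {
    cols <- which(batch == levels(batch)[i])
    adj[, cols] <- (adj[, cols, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta2_star[, i])
  }
  adj <- adj * sqrt(var_pooled) + stand_mean

  model <- list(batches = levels(batch), gamma_hat = gamma_hat,
                delta2_hat = delta2_hat, gamma_star = gamma_star,
                delta2_star = delta2_star,
                hyper = data.frame(batch = levels(batch),
                                   gamma_bar = gamma_bar, t2 = t2,
                                   a_prior = a_prior, b_prior = b_prior),
                var_pooled = var_pooled, preserve_groups = preserve_groups,
                iterations = iterations)
  structure(list(matrix = out_mat(adj), model = model),
            class = "combat_fit")
}

#' @export
print.combat_fit <- function(x, ...) {
  m <- x$model
  cat("Empirical-Bayes batch correction over ", length(m$batches),
      " batch(es), ", nrow(x$matrix$values), " proteins\n", sep = "")
  cat("  EB iterations per batch: ", paste(m$iterations, collapse = ", "),
      "\n", sep = "")
  cat("  mean |gamma_star| per batch: ",
      paste(sprintf("%.3f", colMeans(abs(m$gamma_star))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Dump a batch-correction model to TSV
#'
#' Writes the per-protein per-batch location and scale estimates (raw and
#' shrunken) for inspection.
#'
#' @param fit A `combat_fit` from [combat_correct()].
#' @param path Output TSV path.
#' @return `fit`, invisibly.
#' @export
write_combat_model <- function(fit, path) {
  stopifnot(inherits(fit, "combat_fit"))
  m <- fit$model
  df <- data.frame(accession = rownames(m$gamma_hat),
                   stringsAsFactors = FALSE)
  for (i in seq_along(m$batches)) {
    b <- m$batches[i]
    df[[paste0("gamma_hat_", b)]] <- m$gamma_hat[, i]
    df[[paste0("delta2_hat_", b)]] <- m$delta2_hat[, i]
    df[[paste0("gamma_star_", b)]] <- m$gamma_star[, i]
    df[[paste0("delta2_star_", b)]] <- m$delta2_star[, i]
  }
  write_tsv(df, path)
  invisible(fit)
}
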