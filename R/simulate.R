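#' Simulation configuration for a multi-batch 11-plex TMT study
#'
#' Defaults emulate a 3-group, 15-subjects-per-group case-control design run
#' as 5 batches of 11-plex TMT, each batch carrying one master-pool (MP)
#' reference channel and one pooled QC channel alongside 9 subject channels.
#'
#' The generative model, per protein i and subject j in batch b, on the log2
#' scale, is
#' \deqn{y_{ij} = \mu_i + \beta_i(g_j) + \gamma_{ib} + \delta_b e_{ij},
#'       \quad e_{ij} \sim N(0, \sigma^2)}
#' with \eqn{\mu_i \sim N(3, 1)} the baseline log2 abundance,
#' \eqn{\beta_i(g)} a planted group effect of magnitude `delta` (present with
#' probability `frac_de` per non-reference group, random sign; the last group
#' listed is the reference with effect 0), \eqn{\gamma_{ib} \sim N(0,
#' \code{batch_shift_sd}^2)} a protein-specific additive batch effect (the
#' location part of the ComBat generative model) and \eqn{\delta_b =
#' \exp(N(0, \code{batch_scale_sd}^2))} a multiplicative batch noise scale.
#' The MP channel is the exact linear-scale mean of all subjects'
#' noise-free values, so dividing by it bridges batches without cancelling
#' the protein-level batch effects — the residual batch structure that the
#' correction stage exists to remove; the QC channel is the same pooled
#' value subject to the batch effect plus technical noise of SD
#' `sigma_tech`. With probability `p_batch_dropout` a protein is unobserved
#' in an entire batch (all 11 channels missing), the batch-level missingness
#' mechanism characteristic of multiplexed TMT.
#'
#' @param n_proteins Number of simulated proteins.
#' @param n_per_group Subjects per biological group (>= 2).
#' @param groups Biological group labels; the last is the null reference.
#' @param n_batches Number of TMT batches.
#' @param frac_de Fraction of proteins carrying a planted effect per
#'   non-reference group.
#' @param delta Planted absolute log2 fold change (default 0.585 = log2 1.5).
#' @param sigma Residual SD of subject measurements on the log2 scale
#'   (default 0.208).
#' @param batch_shift_sd SD of the additive per-batch shifts (log2 scale).
#' @param batch_scale_sd SD of the log multiplicative batch scale factors.
#' @param p_batch_dropout Probability a protein is missing from a whole
#'   batch.
#' @param sigma_tech Technical SD of the QC replicate channel (log2 scale).
#' @param seed Integer seed; the whole simulation is driven by one RNG
#'   stream so identical configs give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_proteins = 2000L, n_per_group = 15L,
                              groups = c("PSP", "PD", "HC"),
                              n_batches = 5L, frac_de = 0.1, delta = 0.585,
                              sigma = 0.208, batch_shift_sd = 0.3,
                              batch_scale_sd = 0.1, p_batch_dropout = 0.05,
                              sigma_tech = 0.10, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_per_group = as.integer(n_per_group),
              groups = as.character(groups),
              n_batches = as.integer(n_batches),
              frac_de = frac_de, delta = delta, sigma = sigma,
              batch_shift_sd = batch_shift_sd,
              batch_scale_sd = batch_scale_sd,
              p_batch_dropout = p_batch_dropout,
              sigma_tech = sigma_tech, seed = as.integer(seed))
  stopifnot(cfg$n_proteins >= 1, cfg$n_per_group >= 2, cfg$n_batches >= 1,
            cfg$frac_de >= 0, cfg$frac_de <= 1, cfg$sigma > 0,
            cfg$p_batch_dropout >= 0, cfg$p_batch_dropout <= 1,
            cfg$batch_shift_sd >= 0, cfg$batch_scale_sd >= 0,
            cfg$sigma_tech >= 0, length(cfg$groups) >= 2,
            !anyDuplicated(cfg$groups))
  if (any(cfg$groups %in% c("QC", "MP")))
    stop("QC and MP are reserved labels, not biological groups")
  # 9 free channels per batch: 11 minus one MP and one QC
  n_sub <- cfg$n_per_group * length(cfg$groups)
  per_batch <- subjects_per_batch(cfg)
  if (any(per_batch > 9L))
    stop("config error: ", n_sub, " subjects are not distributable over ",
         cfg$n_batches, " batches x 9 free channels")
  structure(cfg, class = "sim_config")
}

# per-group round-robin assignment of subjects to batches; returns the
# resulting per-batch subject counts
subjects_per_batch <- function(cfg) {
  b <- rep(seq_len(cfg$n_batches), length.out = cfg$n_per_group)
  tab <- tabulate(b, cfg$n_batches) * length(cfg$groups)
  tab
}

.TMT_CHANNELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                   "130N", "130C", "131N", "131C")

#' Simulate a multi-batch TMT dataset with ground truth
#'
#' Draws a full reporter-abundance matrix (linear scale, `scale = "raw"`)
#' under the generative model documented in [simulation_config()], together
#' with the planted truth needed for recovery tests: per-protein group
#' effects and per-contrast true log2 fold changes, the per-batch additive
#' shifts and noise scale factors, and the batch-level dropout mask.
#' Channel-to-sample assignment is randomized per batch (the MP reference
#' always occupies the 11th channel); all randomness comes from one stream
#' keyed by `config$seed`, so the same config yields bit-identical output.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list of class `tmt_simulation` with elements `matrix` (a
#'   `tmt_abundance`, raw scale) and `truth` (list: `effects` data frame of
#'   per-protein group effects and per-contrast `lfc_*` / `de_*` columns,
#'   `batch` data frame of per-batch noise scale factors, `gamma`
#'   proteins-by-batches matrix of additive batch effects, `dropout` logical
#'   proteins-by-batches matrix, and the `config`).
#' @export
simulate_tmt <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, simulate_tmt_impl(config))
}

simulate_tmt_impl <- function(cfg) {
  P <- cfg$n_proteins
  G <- cfg$groups
  ref <- G[length(G)]
  acc <- sprintf("P%05d", seq_len(P))
  genes <- sprintf("GENE%d", seq_len(P))

  # --- RNG draw order is fixed: baselines, effects, batch params, channel
  # shuffles, subject noise, QC noise, dropout ---
  mu <- rnorm(P, mean = 3, sd = 1)

  eff <- matrix(0, P, length(G), dimnames = list(acc, G))
  for (g in setdiff(G, ref)) {
    is_de <- runif(P) < cfg$frac_de
    sgn <- sample(c(-1, 1), P, replace = TRUE)
    eff[, g] <- ifelse(is_de, sgn * cfg$delta, 0)
  }

  gamma_ib <- matrix(rnorm(P * cfg$n_batches, 0, cfg$batch_shift_sd),
                     P, cfg$n_batches,
                     dimnames = list(acc, seq_len(cfg$n_batches)))
  scale_b <- exp(rnorm(cfg$n_batches, 0, cfg$batch_scale_sd))

  # subjects: per-group round-robin over batches
  subj <- do.call(rbind, lapply(G, function(g) {
    data.frame(sample_id = sprintf("%s%02d", g, seq_len(cfg$n_per_group)),
               group = g,
               batch = rep(seq_len(cfg$n_batches),
                           length.out = cfg$n_per_group),
               stringsAsFactors = FALSE)
  }))

  # per-batch channel assignment: MP fixed in the 11th channel, the other
  # 10 shuffled; QC takes the first free channel, subjects the rest
  ann <- NULL
  for (b in seq_len(cfg$n_batches)) {
    sb <- subj[subj$batch == b, ]
    free <- sample(.TMT_CHANNELS[1:10])
    sb <- sb[sample(nrow(sb)), ]  # randomized labelling order
    sb$channel <- free[seq_len(nrow(sb)) + 1L]
    qc <- data.frame(sample_id = sprintf("QC%d", b), group = "QC", batch = b,
                     channel = free[1], stringsAsFactors = FALSE)
    mp <- data.frame(sample_id = sprintf("MP%d", b), group = "MP", batch = b,
                     channel = .TMT_CHANNELS[11], stringsAsFactors = FALSE)
    ann <- rbind(ann, sb, qc, mp)
  }
  rownames(ann) <- NULL

  is_subj <- !ann$group %in% c("QC", "MP")
  n_samp <- nrow(ann)

  # noise-free subject log2 values and the exact pooled reference
  t_subj <- mu + eff[, ann$group[is_subj], drop = FALSE]
  pool_log2 <- log2(rowMeans(2^t_subj))

  log2m <- matrix(NA_real_, P, n_samp, dimnames = list(acc, ann$sample_id))
  noise <- matrix(rnorm(P * sum(is_subj), 0, cfg$sigma), P, sum(is_subj))
  bsub <- ann$batch[is_subj]
  log2m[, is_subj] <- t_subj + gamma_ib[, bsub] +
    noise * rep(scale_b[bsub], each = P)
  for (j in which(ann$group == "QC")) {
    b <- ann$batch[j]
    log2m[, j] <- pool_log2 + gamma_ib[, b] +
      scale_b[b] * rnorm(P, 0, cfg$sigma_tech)
  }
  for (j in which(ann$group == "MP"))
    log2m[, j] <- pool_log2

  # batch-level dropout: a protein missing from a batch loses all channels
  drop_mask <- matrix(runif(P * cfg$n_batches) < cfg$p_batch_dropout,
                      P, cfg$n_batches,
                      dimnames = list(acc, seq_len(cfg$n_batches)))
  for (b in seq_len(cfg$n_batches))
    log2m[drop_mask[, b], ann$batch == b] <- NA_real_

  mat <- tmt_abundance(2^log2m,
                       proteins = data.frame(accession = acc, gene = genes,
                                             stringsAsFactors = FALSE),
                       samples = ann, scale = "raw")

  effects <- data.frame(accession = acc, mu = mu, check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (g in G) effects[[paste0("eff_", g)]] <- eff[, g]
  for (pair in utils::combn(G, 2, simplify = FALSE)) {
    lfc <- eff[, pair[1]] - eff[, pair[2]]
    tag <- paste0(pair[1], "_", pair[2])
    effects[[paste0("lfc_", tag)]] <- lfc
    effects[[paste0("de_", tag)]] <- lfc != 0
  }

  truth <- list(effects = effects,
                batch = data.frame(batch = seq_len(cfg$n_batches),
                                   scale = scale_b),
                gamma = gamma_ib, dropout = drop_mask, config = cfg)
  structure(list(matrix = mat, truth = truth), class = "tmt_simulation")
}

#' @export
print.tmt_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat("Simulated TMT dataset: ", cfg$n_proteins, " proteins, ",
      cfg$n_batches, " batches, ", cfg$n_per_group, " per group (",
      paste(cfg$groups, collapse = "/"), ")\n", sep = "")
  de_cols <- grep("^de_", names(x$truth$effects), value = TRUE)
  for (cn in de_cols)
    cat("  planted DE ", sub("^de_", "", cn), ": ",
        sum(x$truth$effects[[cn]]), "\n", sep = "")
  invisible(x)
}

#' True log2 fold change and DE status for a contrast
#'
#' @param truth The `truth` element of a [simulate_tmt()] result.
#' @param contrast Character 2-vector `c(groupA, groupB)`.
#' @return Data frame with `accession`, `true_log2fc`, `is_de`.
#' @export
truth_contrast <- function(truth, contrast) {
  eff <- truth$effects
  a <- eff[[paste0("eff_", contrast[1])]]
  b <- eff[[paste0("eff_", contrast[2])]]
  if (is.null(a) || is.null(b))
    stop("contrast groups not present in the simulation: ",
         paste(contrast, collapse = " vs "))
  lfc <- a - b
  data.frame(accession = eff$accession, true_log2fc = lfc, is_de = lfc != 0,
             stringsAsFactors = FALSE)
}

#' Export a simulated dataset as plain-text fixture files
#'
#' Writes `abundance.tsv`, `annotation.tsv` and `truth.tsv` into `dir` so a
#' simulation can be re-read with [read_abundance_table()].
#'
#' @param sim A `tmt_simulation`.
#' @param dir Output directory (created if absent).
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return The directory path, invisibly.
#' @export
export_fixture <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "tmt_simulation"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " exists and is not empty; ",
         "use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(sim$matrix, file.path(dir, "abundance.tsv"),
                        file.path(dir, "annotation.tsv"))
  write_tsv(sim$truth$effects, file.path(dir, "truth.tsv"))
  invisible(dir)
}
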