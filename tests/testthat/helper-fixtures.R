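# small deterministic fixtures built in code

# minimal raw matrix: `n_batches` batches, each with 2 subjects (PSP, HC),
# one QC and one MP channel; values supplied per column or defaulted
tiny_raw <- function(values = NULL, n_proteins = 3, n_batches = 1) {
  samples <- do.call(rbind, lapply(seq_len(n_batches), function(b) {
    data.frame(
      sample_id = paste0(c("PSP", "HC", "QC", "MP"), b),
      group = c("PSP", "HC", "QC", "MP"),
      batch = b,
      channel = c("126", "127N", "127C", "131C"),
      stringsAsFactors = FALSE)
  }))
  if (is.null(values)) {
    values <- matrix(seq_len(n_proteins * nrow(samples)),
                     n_proteins, nrow(samples))
  } else {
    n_proteins <- nrow(values)
  }
  proteins <- data.frame(accession = sprintf("P%03d", seq_len(n_proteins)),
                         gene = sprintf("G%d", seq_len(n_proteins)),
                         stringsAsFactors = FALSE)
  tmt_abundance(values, proteins, samples, scale = "raw")
}

# bare two-group matrix on the zscore scale (no QC/MP), for DE-level tests
zscore_matrix <- function(values, groups, batches = NULL) {
  n <- ncol(values)
  if (is.null(batches)) batches <- rep(1L, n)
  samples <- data.frame(sample_id = paste0("S", seq_len(n)), group = groups,
                        batch = batches,
                        channel = paste0("ch", seq_len(n)),
                        stringsAsFactors = FALSE)
  proteins <- data.frame(accession = sprintf("P%03d", seq_len(nrow(values))),
                         gene = sprintf("G%d", seq_len(nrow(values))),
                         stringsAsFactors = FALSE)
  tmt_abundance(values, proteins, samples, scale = "zscore")
}

# normalized + batch-corrected matrix from a simulation, warnings silenced
corrected_from_sim <- function(sim) {
  combat_correct(normalize_chain(sim$matrix))$matrix
}

# brute-force AUC by pair enumeration (independent oracle)
auc_brute <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# pooled-variance t by the textbook formula (independent oracle)
t_brute <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
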