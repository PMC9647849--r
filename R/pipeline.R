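#' Pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: the data
#' source (a simulation config, or paths to an abundance/annotation TSV
#' pair), the contrasts, the two DE configurations, enrichment options and
#' the output directory. One master `seed` is propagated to every
#' stochastic stage through independent per-stage substreams, so stage
#' re-runs do not depend on execution order.
#'
#' @param out_dir Output directory for all run artifacts.
#' @param sim A [simulation_config()] used when no input files are given.
#' @param abundance_path,annotation_path Optional input TSV paths; when
#'   supplied the simulation config is ignored.
#' @param contrasts List of character 2-vectors (default the three
#'   pairwise contrasts PSP/HC, PSP/PD, PD/HC).
#' @param sam A [sam_config()].
#' @param broc A [broc_config()].
#' @param gmt Optional GMT path or `gene_sets` collection for
#'   overrepresentation of the consensus sets.
#' @param ease Use the EASE variant of the enrichment test.
#' @param q_threshold Consensus significance cut.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, sim = simulation_config(),
                            abundance_path = NULL, annotation_path = NULL,
                            contrasts = list(c("PSP", "HC"), c("PSP", "PD"),
                                             c("PD", "HC")),
                            sam = sam_config(), broc = broc_config(),
                            gmt = NULL, ease = FALSE, q_threshold = 0.05,
                            seed = 7L) {
  stopifnot(inherits(sim, "sim_config"), inherits(sam, "sam_config"),
            inherits(broc, "broc_config"))
  groups <- if (is.null(abundance_path)) sim$groups else NULL
  for (ct in contrasts) {
    stopifnot(length(ct) == 2, is.character(ct))
    if (!is.null(groups) && !all(ct %in% groups))
      stop("contrast ", paste(ct, collapse = " vs "),
           " references undeclared group(s)")
  }
  structure(list(out_dir = out_dir, sim = sim,
                 abundance_path = abundance_path,
                 annotation_path = annotation_path, contrasts = contrasts,
                 sam = sam, broc = broc, gmt = gmt, ease = ease,
                 q_threshold = q_threshold, seed = as.integer(seed)),
            class = "run_config")
}

# cheap deterministic config fingerprint for the run log
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97)) %% 4294967291)
}

run_stage <- function(name, log_lines, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  cat(sprintf("stage %-12s %.2fs\n", name, proc.time()[["elapsed"]] - t0),
      file = log_lines, append = TRUE)
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> normalize -> QC -> batch correction ->
#' SAM -> bootstrap-ROC -> consensus -> enrichment in order, writing every
#' intermediate table into the run directory together with a
#' machine-readable `summary.json` (per-contrast DE counts, QC headline
#' fractions, PCA batch eta-squared before/after correction, enrichment
#' tables) and a `run.log` with stage timings, package version, seed and a
#' config fingerprint. Identical config and seed give byte-identical
#' summaries. A failing stage aborts with the stage name; tables already
#' written are left in place.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `tmt_run` (`dir`, `summary`, per-contrast
#'   `results`, the `qc_report`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("tmtpipe ", as.character(utils::packageVersion("tmtpipe")),
      " | R ", paste(R.version$major, R.version$minor, sep = "."),
      " | seed ", config$seed, " | config ", config_hash(config), "\n",
      sep = "", file = log_path)

  input <- run_stage("input", log_path, {
    if (!is.null(config$abundance_path)) {
      list(matrix = read_abundance_table(config$abundance_path,
                                         config$annotation_path),
           truth = NULL)
    } else {
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_tmt(sim_cfg)
      write_tsv(sim$truth$effects, file.path(config$out_dir, "truth.tsv"))
      sim
    }
  })
  raw <- input$matrix
  truth <- input$truth
  write_abundance_table(raw, file.path(config$out_dir, "abundance_raw.tsv"),
                        file.path(config$out_dir, "annotation.tsv"))

  linear <- run_stage("normalize", log_path,
                      median_scale(mp_normalize(raw)))
  zs <- run_stage("zscore", log_path,
                  filter_missing(suppressWarnings(log2_zscore(linear))))
  write_abundance_table(zs, file.path(config$out_dir, "normalized.tsv"))

  qc <- run_stage("qc", log_path, {
    rep <- qc_report(filter_missing(linear), x_corrected = zs)
    write_tsv(data.frame(accession = names(rep$cv), cv_qc = rep$cv,
                         sn_ratio = rep$sn[names(rep$cv)]),
              file.path(config$out_dir, "qc.tsv"))
    rep
  })

  fit <- run_stage("combat", log_path, combat_correct(zs))
  corrected <- fit$matrix
  write_abundance_table(corrected,
                        file.path(config$out_dir, "corrected.tsv"))
  write_combat_model(fit, file.path(config$out_dir, "combat_model.tsv"))
  pca_after <- pca_batch_check(corrected)

  gmt <- config$gmt
  if (is.character(gmt)) gmt <- read_gmt(gmt)
  universe <- unique(toupper(corrected$proteins$gene))

  results <- list(); contrast_summaries <- list()
  for (ct in config$contrasts) {
    tag <- paste0(ct[1], "_vs_", ct[2])
    sam_cfg <- config$sam
    sam_cfg$seed <- stage_seed(config$seed, paste0("sam_", tag))
    broc_cfg <- config$broc
    broc_cfg$seed <- stage_seed(config$seed, paste0("broc_", tag))

    sam_res <- run_stage(paste0("sam:", tag), log_path,
                         sam_qvalues(corrected, ct, sam_cfg))
    write_tsv(sam_boundary(sam_res),
              file.path(config$out_dir, paste0("boundary_", tag, ".tsv")))
    broc_res <- run_stage(paste0("broc:", tag), log_path,
                          broc_qvalues(corrected, ct, broc_cfg))
    cons <- run_stage(paste0("consensus:", tag), log_path,
                      consensus_select(sam_res, broc_res,
                                       config$q_threshold))
    write_results(cons$table,
                  file.path(config$out_dir, paste0("de_", tag, ".tsv")))

    enr <- NULL
    if (!is.null(gmt)) {
      de_genes <- cons$table$gene[cons$table$sig_consensus]
      enr <- run_stage(paste0("enrich:", tag), log_path,
                       suppressWarnings(
                         enrich(de_genes, gmt, universe = universe,
                                ease = config$ease)))
      write_tsv(enr, file.path(config$out_dir,
                               paste0("enrichment_", tag, ".tsv")))
    }
    results[[tag]] <- list(sam = sam_res, broc = broc_res, consensus = cons,
                           enrichment = enr)
    contrast_summaries[[tag]] <- list(
      n_sig_sam = sum(cons$table$sig_sam),
      n_sig_broc = sum(cons$table$sig_broc),
      n_sig_consensus = sum(cons$table$sig_consensus),
      venn = as.list(cons$venn))
  }

  summary <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    n_proteins_input = nrow(raw$values),
    n_proteins_quantified = nrow(corrected$values),
    qc = list(frac_cv_below_030 = qc$frac_cv_below,
              frac_sn_above_1 = qc$frac_sn_above),
    pca = list(batch_eta2_before = qc$pca$batch_eta2,
               batch_eta2_after = pca_after$batch_eta2),
    contrasts = contrast_summaries)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(dir = config$out_dir, summary = summary,
                           results = results, qc = qc, truth = truth,
                           combat = fit),
                      class = "tmt_run"))
}

#' @export
print.tmt_run <- function(x, ...) {
  cat("tmtpipe run: ", x$dir, "\n", sep = "")
  cat("  proteins quantified (complete cases): ",
      x$summary$n_proteins_quantified, " of ", x$summary$n_proteins_input,
      "\n", sep = "")
  cat(sprintf("  QC: %.1f%% proteins CV<30%%, %.1f%% S/N>1\n",
              100 * x$summary$qc$frac_cv_below_030,
              100 * x$summary$qc$frac_sn_above_1))
  cat(sprintf("  batch eta2 PC1-2: %.3f -> %.3f\n",
              x$summary$pca$batch_eta2_before,
              x$summary$pca$batch_eta2_after))
  for (tag in names(x$summary$contrasts)) {
    s <- x$summary$contrasts[[tag]]
    cat(sprintf("  %-12s SAM %4d | bROC %4d | consensus %4d\n", tag,
                s$n_sig_sam, s$n_sig_broc, s$n_sig_consensus))
  }
  invisible(x)
}
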