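#' @importFrom stats median sd var prcomp pt qt phyper dhyper fisher.test
#'   p.adjust rnorm rbinom runif uniroot complete.cases setNames quantile
#' @importFrom utils read.delim write.table combn head
NULL

# legal order of abundance-scale transitions; each op asserts its input scale
.SCALES <- c("raw", "mp_ratio", "median_ratio", "log2", "zscore",
             "batch_corrected")

.GROUPS <- c("PSP", "PD", "HC", "QC", "MP")

#' Construct a TMT abundance matrix
#'
#' Bundles a proteins-by-samples reporter-abundance matrix with its protein
#' and sample annotations and a scale tag tracking the normalization state.
#' Missing measurements are `NA`; a zero abundance is a valid measured value,
#' distinct from missing.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#'   Row names must be protein accessions and column names sample ids.
#' @param proteins Data frame with columns `accession` and `gene`, one row
#'   per matrix row, in matrix order.
#' @param samples Data frame with columns `sample_id`, `group` (one of
#'   `"PSP"`, `"PD"`, `"HC"`, `"QC"`, `"MP"`), `batch` (integer index) and
#'   `channel` (TMT channel label), one row per matrix column, in matrix
#'   order.
#' @param scale Character scalar naming the normalization state, one of
#'   `"raw"`, `"mp_ratio"`, `"median_ratio"`, `"log2"`, `"zscore"`,
#'   `"batch_corrected"`.
#' @return An object of class `tmt_abundance`.
#' @export
tmt_abundance <- function(values, proteins, samples, scale = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  scale <- match.arg(scale, .SCALES)

  stopifnot(all(c("accession", "gene") %in% names(proteins)),
            all(c("sample_id", "group", "batch", "channel") %in%
                  names(samples)))
  if (nrow(values) != nrow(proteins))
    stop("matrix has ", nrow(values), " rows but ", nrow(proteins),
         " protein records")
  if (ncol(values) != nrow(samples))
    stop("matrix has ", ncol(values), " columns but ", nrow(samples),
         " sample records")
  if (anyDuplicated(proteins$accession))
    stop("duplicate accession: ",
         paste(unique(proteins$accession[duplicated(proteins$accession)]),
               collapse = ", "))
  samples$batch <- as.integer(samples$batch)
  validate_annotation(samples, require_mp = (scale == "raw"))
  if (scale %in% c("raw", "mp_ratio", "median_ratio") &&
      any(values < 0, na.rm = TRUE))
    stop("negative abundances are not allowed on the ", scale, " scale")

  rownames(values) <- proteins$accession
  colnames(values) <- samples$sample_id
  structure(list(values = values, proteins = proteins, samples = samples,
                 scale = scale),
            class = "tmt_abundance")
}

#' Validate a sample-annotation table
#'
#' Checks the design invariants of a multi-batch TMT annotation: unique
#' sample ids, known group labels, channels unique within a batch, exactly
#' one master-pool (MP) channel per batch when `require_mp` is set, and at
#' most one QC channel per batch.
#'
#' @param samples Annotation data frame (see [tmt_abundance()]).
#' @param require_mp Require one MP sample in every batch (true for raw
#'   data; MP channels are consumed by [mp_normalize()]).
#' @return The validated data frame, invisibly.
#' @export
validate_annotation <- function(samples, require_mp = TRUE) {
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(samples$group), .GROUPS)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (b in sort(unique(samples$batch))) {
    sb <- samples[samples$batch == b, ]
    if (anyDuplicated(sb$channel))
      stop("duplicate channel within batch ", b)
    n_mp <- sum(sb$group == "MP")
    if (require_mp && n_mp != 1)
      stop("batch without MP" , if (n_mp > 1) " (or more than one MP)",
           ": batch ", b, " has ", n_mp)
    if (sum(sb$group == "QC") > 1)
      stop("batch ", b, " has more than one QC sample")
  }
  invisible(samples)
}

#' @export
print.tmt_abundance <- function(x, ...) {
  cat("TMT abundance matrix (", x$scale, " scale)\n", sep = "")
  cat("  proteins: ", nrow(x$values), "   samples: ", ncol(x$values),
      "   missing cells: ", sum(is.na(x$values)), "\n", sep = "")
  tab <- table(factor(x$samples$group, levels = .GROUPS))
  cat("  groups:  ", paste(names(tab), tab, sep = "=", collapse = "  "),
      "\n", sep = "")
  cat("  batches: ", length(unique(x$samples$batch)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.tmt_abundance <- function(x) dim(x$values)

# columns belonging to biological subjects (PSP/PD/HC)
subject_cols <- function(x) which(!x$samples$group %in% c("QC", "MP"))

#' Read an abundance table with its sample annotation
#'
#' Reads a tab-separated proteins-by-samples abundance export (columns:
#' `accession`, `gene`, then one reporter-abundance column per sample) and a
#' sample-annotation TSV (columns `sample_id`, `group`, `batch`, `channel`).
#' Sample order is taken from the annotation file. Empty cells, `NA` and
#' `NaN` are read as missing.
#'
#' @param path Abundance TSV path.
#' @param annotation_path Annotation TSV path.
#' @return A `tmt_abundance` with `scale = "raw"`.
#' @export
read_abundance_table <- function(path, annotation_path) {
  tab <- read.delim(path, check.names = FALSE, na.strings = c("", "NA", "NaN"),
                    stringsAsFactors = FALSE)
  if (!all(c("accession", "gene") %in% names(tab)))
    stop("abundance table must start with 'accession' and 'gene' columns")
  ann <- read.delim(annotation_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group", "batch", "channel") %in% names(ann)))
    stop("annotation must have columns sample_id, group, batch, channel")
  value_cols <- setdiff(names(tab), c("accession", "gene"))
  missing_ann <- setdiff(value_cols, ann$sample_id)
  if (length(missing_ann))
    stop("abundance column(s) without annotation: ",
         paste(missing_ann, collapse = ", "))
  missing_col <- setdiff(ann$sample_id, value_cols)
  if (length(missing_col))
    stop("annotated sample(s) absent from abundance table: ",
         paste(missing_col, collapse = ", "))
  vals <- as.matrix(tab[, ann$sample_id, drop = FALSE])
  tmt_abundance(vals,
                proteins = tab[, c("accession", "gene")],
                samples = ann, scale = "raw")
}

#' Write an abundance matrix and its annotation to TSV
#'
#' Inverse of [read_abundance_table()]. Values are written with full double
#' precision (15 significant digits); missing cells are written as `NA`.
#'
#' @param x A `tmt_abundance`.
#' @param path Abundance TSV path to write.
#' @param annotation_path Optional annotation TSV path to write.
#' @return `x`, invisibly.
#' @export
write_abundance_table <- function(x, path, annotation_path = NULL) {
  stopifnot(inherits(x, "tmt_abundance"))
  out <- data.frame(accession = x$proteins$accession, gene = x$proteins$gene,
                    stringsAsFactors = FALSE, check.names = FALSE)
  vals <- x$values
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  write_tsv(out, path)
  if (!is.null(annotation_path)) write_tsv(x$samples, annotation_path)
  invisible(x)
}

# deterministic TSV writer: tab-separated, no quoting of numerics, NA for
# missing, 15 significant digits
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    v <- df[[j]]
    if (is.integer(v)) next
    s <- formatC(v, format = "g", digits = 15)
    s[is.na(v)] <- NA_character_
    df[[j]] <- s
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term TAB description TAB gene1 TAB ...`.
#' Gene symbols are upper-cased and deduplicated within a set; empty lines
#' are skipped.
#'
#' @param path GMT file path.
#' @param universe Optional character vector of background gene symbols. If
#'   omitted it must be supplied to [enrich()] instead.
#' @return An object of class `gene_sets`: a list with elements `sets`
#'   (named list of character vectors), `descriptions`, and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  sets <- list(); descs <- character(0)
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated ",
           "fields, got ", length(f))
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, ": empty gene set '", f[1], "'")
    sets[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  gene_sets(sets, descriptions = descs, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional named character vector of set descriptions.
#' @param universe Optional background universe of gene symbols.
#' @return An object of class `gene_sets`.
#' @export
gene_sets <- function(sets, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("every gene set must be non-empty")
  # genes outside a supplied universe are intersected away at enrich() time
  if (!is.null(universe)) universe <- unique(toupper(universe))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sizes <- vapply(x$sets, length, integer(1))
  cat("Gene-set collection: ", length(x$sets), " sets (sizes ",
      min(sizes), "-", max(sizes), ")",
      if (!is.null(x$universe)) paste0("; universe of ", length(x$universe)),
      "\n", sep = "")
  invisible(x)
}

# fixed column order of the per-protein differential-expression table
.DE_COLS <- c("accession", "gene", "log2fc", "tstat", "pvalue", "d", "q_sam",
              "auc_mean", "auc_sd", "q_broc", "sig_sam", "sig_broc",
              "sig_consensus")

#' Write a differential-expression result table to TSV
#'
#' One row per protein, fixed column order; statistics that were not
#' computed are written as `NA`.
#'
#' @param results Data frame as returned by [consensus_select()] (or any
#'   subset of its columns plus `accession`).
#' @param path Output TSV path.
#' @return `results`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), "accession" %in% names(results))
  for (cn in .DE_COLS)
    if (!cn %in% names(results)) results[[cn]] <- rep(NA, nrow(results))
  write_tsv(results[, .DE_COLS], path)
  invisible(results)
}

#' Read back a differential-expression result table
#'
#' @param path TSV path written by [write_results()].
#' @return Data frame with the fixed result columns.
#' @export
read_results <- function(path) {
  df <- read.delim(path, na.strings = c("", "NA", "NaN"),
                   stringsAsFactors = FALSE)
  for (cn in c("sig_sam", "sig_broc", "sig_consensus"))
    if (cn %in% names(df)) df[[cn]] <- as.logical(df[[cn]])
  df
}
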