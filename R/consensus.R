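#' Consensus of the SAM and bootstrap-ROC calls
#'
#' Merges the two per-protein result tables over the same protein universe
#' and flags the consensus set: proteins significant in both procedures
#' (`sig_consensus = sig_sam & sig_broc`), the intersection used to guard
#' against type-I error of any single method.
#'
#' @param sam_results A `sam_result` from [sam_qvalues()].
#' @param broc_results A `broc_result` from [broc_qvalues()] over the same
#'   proteins.
#' @param q_threshold Significance cut applied to both q-values (default
#'   0.05).
#' @return A list of class `consensus_result`: `table` (merged per-protein
#'   data frame with both q-values and all three significance flags) and
#'   `venn` (named counts `sam_only`, `both`, `broc_only`).
#' @export
consensus_select <- function(sam_results, broc_results, q_threshold = 0.05) {
  stopifnot(is.data.frame(sam_results), is.data.frame(broc_results))
  sdiff <- c(setdiff(sam_results$accession, broc_results$accession),
             setdiff(broc_results$accession, sam_results$accession))
  if (length(sdiff))
    stop("result tables cover different protein universes; ",
         "symmetric difference: ", paste(head(sdiff, 10), collapse = ", "),
         if (length(sdiff) > 10) ", ...")
  b <- broc_results[match(sam_results$accession, broc_results$accession), ]
  tab <- data.frame(sam_results[, c("accession", "gene", "log2fc", "tstat",
                                    "pvalue", "d", "q_sam")],
                    b[, c("auc_mean", "auc_sd", "q_broc")],
                    stringsAsFactors = FALSE)
  tab$sig_sam <- tab$q_sam < q_threshold
  tab$sig_broc <- tab$q_broc < q_threshold
  tab$sig_consensus <- tab$sig_sam & tab$sig_broc
  venn <- c(sam_only = sum(tab$sig_sam & !tab$sig_broc),
            both = sum(tab$sig_consensus),
            broc_only = sum(tab$sig_broc & !tab$sig_sam))
  structure(list(table = tab, venn = venn, q_threshold = q_threshold),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus differential expression at q < ", x$q_threshold, "\n",
      sep = "")
  cat("  SAM only: ", x$venn["sam_only"], "   both: ", x$venn["both"],
      "   bROC only: ", x$venn["broc_only"], "\n", sep = "")
  invisible(x)
}

#' Gene-set overrepresentation test
#'
#' For each set in the collection: `count`, the number of differential
#' genes in the set; `ph`, the total number of the set's genes present in
#' the background universe; `percent = 100 * count / ph`; a one-sided
#' Fisher exact p-value on the 2x2 table (DE-in-set, DE-not-in-set,
#' set-not-DE, rest); and the fold enrichment over the expected overlap.
#' With `ease = TRUE` the overlap is decremented by one before testing
#' (the conservative EASE variant). Rows are sorted by p ascending. No
#' multiple-testing correction is applied unless `p_adjust = TRUE`
#' (Benjamini-Hochberg, extra column `p_bh`).
#'
#' @param de_genes Character vector of differential gene symbols (matched
#'   case-insensitively).
#' @param collection A `gene_sets` collection; its `universe` (or the
#'   `universe` argument) defines the background of quantified genes.
#' @param universe Optional background overriding the collection's.
#' @param ease Use the EASE (count - 1) variant (default `FALSE`).
#' @param p_adjust Add Benjamini-Hochberg adjusted p-values.
#' @return Data frame with `term`, `description`, `count`, `ph`, `percent`,
#'   `pvalue`, `fold_enrichment` (and `p_bh` if requested).
#' @export
enrich <- function(de_genes, collection, universe = NULL, ease = FALSE,
                   p_adjust = FALSE) {
  stopifnot(inherits(collection, "gene_sets"))
  universe <- unique(toupper(if (is.null(universe)) collection$universe
                             else universe))
  if (!length(universe)) stop("a background universe must be supplied")
  de <- intersect(unique(toupper(de_genes)), universe)
  if (!length(de)) {
    warning("empty DE gene list (after intersecting with the universe)")
    return(data.frame(term = character(0), description = character(0),
                      count = integer(0), ph = integer(0),
                      percent = numeric(0), pvalue = numeric(0),
                      fold_enrichment = numeric(0)))
  }
  n_u <- length(universe); n_de <- length(de)
  rows <- lapply(names(collection$sets), function(term) {
    set <- intersect(collection$sets[[term]], universe)
    ph <- length(set)
    if (!ph) return(NULL)
    count <- length(intersect(de, set))
    if (ease) {
      # EASE: decrement the overlap by one under the same margins
      k <- max(count - 1L, 0L)
      p <- phyper(k - 1L, n_de, n_u - n_de, ph, lower.tail = FALSE)
    } else {
      p <- fisher.test(matrix(c(count, n_de - count, ph - count,
                                n_u - n_de - ph + count), 2, 2),
                       alternative = "greater")$p.value
    }
    data.frame(term = term,
               description = unname(collection$descriptions[term]),
               count = count, ph = ph, percent = 100 * count / ph,
               pvalue = p,
               fold_enrichment = (count / n_de) / (ph / n_u),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    warning("no gene set overlaps the universe")
    return(data.frame(term = character(0), description = character(0),
                      count = integer(0), ph = integer(0),
                      percent = numeric(0), pvalue = numeric(0),
                      fold_enrichment = numeric(0)))
  }
  if (p_adjust) out$p_bh <- p.adjust(out$pvalue, "BH")
  out <- out[order(out$pvalue, out$term), ]
  rownames(out) <- NULL
  out
}
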