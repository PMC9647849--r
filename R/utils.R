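# run expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a per-stage 32-bit seed from a master seed and a stage tag so stage
# re-runs are independent of execution order
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
}

assert_scale <- function(x, expected) {
  stopifnot(inherits(x, "tmt_abundance"))
  if (!x$scale %in% expected)
    stop("expected matrix on scale ", paste(expected, collapse = "/"),
         ", got '", x$scale, "' (the normalization chain is ",
         "raw -> mp_ratio -> median_ratio -> log2 -> zscore -> ",
         "batch_corrected)")
  invisible(x)
}

# group labels of two contrast sides, validated against the annotation
contrast_idx <- function(x, contrast) {
  stopifnot(length(contrast) == 2, is.character(contrast))
  g <- x$samples$group
  ia <- which(g == contrast[1]); ib <- which(g == contrast[2])
  if (!length(ia) || !length(ib))
    stop("contrast group(s) absent from annotation: ",
         paste(contrast[c(!length(ia), !length(ib))], collapse = ", "))
  list(a = ia, b = ib)
}

row_sds <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- sqrt(ss / pmax(n - 1, 1))
  out[n < 2] <- NA_real_
  out
}
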