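fake_results <- function(acc, q_sam, q_broc) {
  sam <- data.frame(accession = acc, gene = paste0("G", acc),
                    log2fc = 0, tstat = 0, pvalue = 1, d = 0,
                    q_sam = q_sam, stringsAsFactors = FALSE)
  broc <- data.frame(accession = acc, gene = paste0("G", acc),
                     auc_mean = 0.5, auc_sd = 0, q_broc = q_broc,
                     stringsAsFactors = FALSE)
  list(sam = sam, broc = broc)
}

test_that("consensus is the intersection with correct Venn counts", {
  # SAM set {A,B,C}, bROC set {B,C,D} over universe A..E
  acc <- LETTERS[1:5]
  r <- fake_results(acc,
                    q_sam = c(0.01, 0.01, 0.01, 0.5, 0.5),
                    q_broc = c(0.5, 0.01, 0.01, 0.01, 0.5))
  cons <- consensus_select(r$sam, r$broc)
  expect_equal(unname(cons$venn), c(1, 2, 1))
  expect_equal(cons$table$accession[cons$table$sig_consensus], c("B", "C"))
  # Venn parts sum to the union
  union_n <- sum(cons$table$sig_sam | cons$table$sig_broc)
  expect_equal(sum(cons$venn), union_n)

  # disjoint and identical sets
  r2 <- fake_results(acc, q_sam = c(0.01, 0.5, 0.5, 0.5, 0.5),
                     q_broc = c(0.5, 0.01, 0.5, 0.5, 0.5))
  expect_equal(unname(consensus_select(r2$sam, r2$broc)$venn), c(1, 0, 1))
  r3 <- fake_results(acc, q_sam = c(0.01, 0.01, 0.5, 0.5, 0.5),
                     q_broc = c(0.01, 0.01, 0.5, 0.5, 0.5))
  expect_equal(unname(consensus_select(r3$sam, r3$broc)$venn), c(0, 2, 0))
})

test_that("mismatched universes are rejected with the difference listed", {
  r <- fake_results(LETTERS[1:3], rep(1, 3), rep(1, 3))
  r2 <- fake_results(LETTERS[2:4], rep(1, 3), rep(1, 3))
  expect_error(consensus_select(r$sam, r2$broc), "A")
})

test_that("consensus respects the ordering of results tables", {
  r <- fake_results(LETTERS[1:4], c(0.01, 0.5, 0.01, 0.5),
                    c(0.01, 0.5, 0.01, 0.5))
  shuffled <- r$broc[c(3, 1, 4, 2), ]
  cons <- consensus_select(r$sam, shuffled)
  expect_equal(cons$table$accession, r$sam$accession)
  expect_equal(unname(cons$venn["both"]), 2)
})

test_that("enrichment columns reproduce the count/PH/% arithmetic", {
  universe <- sprintf("U%04d", 1:3000)
  setA <- universe[1:142]
  gs <- gene_sets(list(pathA = setA, pathB = universe[200:299]),
                  universe = universe)
  # 25 of 142 -> 17.6%; 60 of 142 -> 42.3%
  e25 <- enrich(setA[1:25], gs)
  rowA <- e25[e25$term == "pathA", ]
  expect_equal(rowA$count, 25)
  expect_equal(rowA$ph, 142)
  expect_equal(round(rowA$percent, 1), 17.6)
  e60 <- enrich(setA[1:60], gs)
  expect_equal(round(e60$percent[e60$term == "pathA"], 1), 42.3)
})

test_that("Fisher p-value matches direct hypergeometric summation", {
  # 2x2 table (3,7,2,88): 10 DE genes, set of 5 with overlap 3, N = 100
  universe <- sprintf("U%03d", 1:100)
  de <- universe[1:10]
  set <- c(universe[1:3], universe[11:12])
  gs <- gene_sets(list(s = set), universe = universe)
  p_pkg <- enrich(de, gs)$pvalue
  # oracle: sum hypergeometric tail directly
  p_hand <- sum(dhyper(3:5, 10, 90, 5))
  expect_equal(p_pkg, p_hand, tolerance = 1e-12)

  # EASE variant decrements the overlap before testing
  p_ease <- enrich(de, gs, ease = TRUE)$pvalue
  expect_equal(p_ease, sum(dhyper(2:5, 10, 90, 5)), tolerance = 1e-12)
  expect_gt(p_ease, p_pkg)
})

test_that("a set equal to the DE list is the most enriched of its size", {
  universe <- sprintf("U%03d", 1:200)
  de <- universe[1:10]
  gs <- gene_sets(list(exact = de,
                       half = c(universe[1:5], universe[51:55]),
                       none = universe[101:110]),
                  universe = universe)
  e <- enrich(de, gs)
  expect_equal(e$term[1], "exact")  # sorted by p ascending
  expect_true(all(e$pvalue > 0 & e$pvalue <= 1))
  expect_equal(e$percent, 100 * e$count / e$ph)
})

test_that("degenerate enrichment inputs warn and return empty tables", {
  gs <- gene_sets(list(s = c("A", "B")), universe = c("A", "B", "C"))
  expect_warning(e <- enrich(character(0), gs), "empty DE")
  expect_equal(nrow(e), 0)
  expect_error(enrich("A", gene_sets(list(s = "A"))), "universe")
})
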