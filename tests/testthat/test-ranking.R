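mk_cand <- function(gene, expr, chronos, ecd = rep(300L, length(gene))) {
  structure(data.frame(gene = gene, median_expression = expr,
                       ecd_length = ecd, chronos = chronos,
                       stringsAsFactors = FALSE),
            class = c("principal_candidates", "data.frame"))
}

test_that("min-max normalisation hits its endpoints and degenerate rule", {
  norm <- normalize_components(mk_cand(c("G1", "G2"), c(2, 4), c(-1, 0)))
  expect_equal(norm$expression_norm, c(0, 1))
  expect_equal(norm$essentiality_norm, c(1, 0))
  single <- normalize_components(mk_cand("G1", 4, -1))
  expect_equal(single$expression_norm, 0.5)
  expect_equal(single$essentiality_norm, 0.5)
  expect_error(normalize_components(mk_cand(character(), numeric(), numeric())),
               "empty")
})

test_that("vector_score is the Euclidean norm on [0,1]^2", {
  expect_identical(vector_score(0, 0), 0)
  expect_equal(vector_score(1, 1), sqrt(2))
  expect_identical(vector_score(0.6, 0.8), 1)
  expect_equal(vector_score(0.3, 0.7), vector_score(0.7, 0.3))
  expect_error(vector_score(1.2, 0), "\\[0, 1\\]")
  expect_error(vector_score(0.5, -0.1), "\\[0, 1\\]")
})

test_that("rank_targets orders by score with deterministic tie-breaks", {
  r <- rank_targets(mk_cand(c("HI", "LO", "MID"), c(5, 1, 3), c(-2, 0, -1)))
  expect_equal(r$gene, c("HI", "MID", "LO"))
  expect_equal(r$rank, 1:3)
  expect_true(all(diff(r$score) <= 0))
  # exact score tie: symmetric corners (1,0) vs (0,1); more negative chronos wins
  tie <- rank_targets(mk_cand(c("AAA", "BBB"), c(4, 2), c(-0.3, -0.9)))
  expect_equal(tie$score[1], tie$score[2])
  expect_equal(tie$gene[1], "BBB")
  # equal score and chronos: gene symbol breaks the tie
  tie2 <- rank_targets(mk_cand(c("ZZZ", "AAA"), c(3, 3), c(-0.5, -0.5)))
  expect_equal(tie2$gene, c("AAA", "ZZZ"))
})

test_that("Pareto dominance is never violated by the vector score", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 20
    cand <- mk_cand(sprintf("G%02d", 1:n), runif(n, 0, 5), rnorm(n, -0.5, 0.5))
    r <- rank_targets(cand)
    m <- merge(as.data.frame(cand), as.data.frame(r)[, c("gene", "score", "rank")],
               by = "gene")
    for (i in 1:n) for (j in 1:n) {
      dominates <- m$median_expression[i] >= m$median_expression[j] &&
        m$chronos[i] <= m$chronos[j] &&
        (m$median_expression[i] > m$median_expression[j] ||
         m$chronos[i] < m$chronos[j])
      if (dominates) {
        expect_gte(m$score[i], m$score[j])
        expect_lte(m$rank[i], m$rank[j])
      }
    }
  }
})

test_that("ranking is invariant to affine rescaling of raw expression", {
  set.seed(5)
  cand <- mk_cand(sprintf("G%02d", 1:15), runif(15, 0, 5), rnorm(15, -0.5, 0.3))
  r1 <- rank_targets(cand)
  scaled <- cand
  scaled$median_expression <- 0.37 * scaled$median_expression + 1.1
  r2 <- rank_targets(scaled)
  expect_equal(r2$gene, r1$gene)
  expect_equal(r2$score, r1$score)
  # and identical input yields identical output across runs
  expect_identical(rank_targets(cand), r1)
})

test_that("the planted dominant gene ranks first on the default fixture", {
  fx <- get_fixture(3)
  pc <- filter_principal(fx$surf, fx$ess, fx$tiss, filter_config())
  r <- rank_targets(pc)
  expect_equal(r$gene[1], fx$truth$dominant_gene)
})
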