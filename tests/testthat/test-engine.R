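mk_icars <- function(genes, ecd = 300L) {
  structure(data.frame(gene = genes, ecd_length = as.integer(ecd),
                       provenance = "absent_from_surfaceome",
                       stringsAsFactors = FALSE),
            class = c("icar_candidates", "data.frame"))
}

test_that("principal_on_tissues binarises with strict > and flags missing", {
  tm <- toy_tissue_matrix(matrix(c(5, 0, 2, NA), 1, 4, dimnames = list(
    "TFRC", c("liver", "skin", "brain", "lung"))))
  on <- suppressMessages(principal_on_tissues("TFRC", tm, filter_config()))
  expect_setequal(as.character(on), c("liver", "brain"))
  expect_equal(attr(on, "missing_tissues"), "lung")
  zero <- toy_tissue_matrix(matrix(0, 1, 2, dimnames = list("ZZZ", c("a", "b"))))
  expect_length(principal_on_tissues("ZZZ", zero), 0)
  expect_error(principal_on_tissues("ABSENT", tm), "ABSENT")
})

test_that("find_icar_partners scores coverage with safety-first NA handling", {
  vals <- rbind(PRIN = c(3, 2, 0), FULL = c(3, 1, 9), PART = c(3, 0, 1),
                MISS = c(3, NA, 0))
  colnames(vals) <- c("liver", "brain", "skin")
  tm <- toy_tissue_matrix(vals)
  pairs <- find_icar_partners("PRIN", mk_icars(c("FULL", "PART", "MISS", "GONE")), tm)
  expect_equal(attr(pairs, "on_tissues"), c("liver", "brain"))
  by_gene <- split(pairs, pairs$icar)
  expect_true(by_gene$FULL$feasible)
  expect_equal(by_gene$FULL$coverage, 1)
  expect_false(by_gene$PART$feasible)
  expect_equal(by_gene$PART$coverage, 0.5)
  expect_equal(by_gene$PART$uncovered_tissues[[1]], "brain")
  # NA in a required tissue is NOT coverage; absent gene covers nothing
  expect_equal(by_gene$MISS$coverage, 0.5)
  expect_equal(by_gene$GONE$coverage, 0)
  # conservation: covered + uncovered = the ON set, disjointly
  for (i in seq_len(nrow(pairs))) {
    expect_setequal(c(pairs$covered_tissues[[i]], pairs$uncovered_tissues[[i]]),
                    c("liver", "brain"))
    expect_length(intersect(pairs$covered_tissues[[i]],
                            pairs$uncovered_tissues[[i]]), 0)
  }
})

test_that("a fully tumour-specific principal yields vacuous feasibility + warning", {
  vals <- rbind(PRIN = c(0, 0), CAND = c(1, 0))
  colnames(vals) <- c("a", "b")
  tm <- toy_tissue_matrix(vals)
  expect_warning(pairs <- find_icar_partners("PRIN", mk_icars("CAND"), tm),
                 "tumour-specific")
  expect_true(all(pairs$feasible))
  expect_equal(pairs$coverage, 1)
})

test_that("fixture partners: exactly the planted feasible set, oracle agrees", {
  fx <- get_fixture(1)
  ic <- filter_icar(fx$tiss, fx$surf, fx$ecd_cat, filter_config())
  for (p in fx$truth$planted_principals) {
    pairs <- find_icar_partners(p, ic, fx$tiss, filter_config())
    feas <- pairs$icar[pairs$feasible]
    expect_setequal(feas, fx$truth$feasible_partners[[p]])
    expect_setequal(feas, oracle_feasible_partners(p, ic$gene, fx$tiss))
    # partial partners appear with strictly partial coverage
    part <- pairs[pairs$icar %in% fx$truth$partial_partners[[p]], ]
    expect_true(all(part$coverage < 1 & part$n_uncovered >= 1))
  }
})

test_that("min_icar_ecd narrows the partner list like the ECD-size exclusion", {
  fx <- get_fixture(1)
  ic <- filter_icar(fx$tiss, fx$surf, fx$ecd_cat, filter_config())
  p <- fx$truth$planted_principals[1]
  all_p <- find_icar_partners(p, ic, fx$tiss, filter_config())
  cut <- stats::median(all_p$icar_ecd[all_p$feasible])
  narrowed <- find_icar_partners(p, ic, fx$tiss, filter_config(), min_icar_ecd = cut)
  expect_true(all(narrowed$icar_ecd > cut))
  expect_setequal(narrowed$icar[narrowed$feasible],
                  all_p$icar[all_p$feasible & all_p$icar_ecd > cut])
})

test_that("count_combinations is exactly multiplicative, without overflow", {
  expect_equal(count_combinations(716, 1348)$n_theoretical, 965168)
  expect_equal(count_combinations(0, 1348)$n_theoretical, 0)
  expect_equal(count_combinations(31623, 31623)$n_theoretical, 31623^2)
  expect_identical(count_combinations(31623, 31623)$n_theoretical %% 1, 0)
  fx <- get_fixture(1)
  pc <- filter_principal(fx$surf, fx$ess, fx$tiss, filter_config())
  ic <- filter_icar(fx$tiss, fx$surf, fx$ecd_cat, filter_config())
  expect_equal(count_combinations(pc, ic)$n_theoretical, nrow(pc) * nrow(ic))
})

test_that("partner heatmap table: principal first, tumour column zero for iCARs", {
  vals <- rbind(PRIN = c(3, 2, 1), IC1 = c(3, 3, 3), IC2 = c(4, 4, 4),
                NOPE = c(1, 0, 0))
  colnames(vals) <- c("t1", "t2", "t3")
  tm <- toy_tissue_matrix(vals)
  pairs <- find_icar_partners("PRIN", mk_icars(c("IC1", "IC2", "NOPE")), tm)
  heat <- partner_heatmap_table(pairs, tm, c(PRIN = 4.5))
  expect_equal(nrow(heat), 3 * 4)  # 1 principal + 2 feasible, 3 tissues + tumour
  expect_equal(heat$entity[1], "PRIN")
  expect_equal(heat$value[heat$entity == "PRIN" & heat$column == "tumour"], 4.5)
  expect_true(all(heat$value[heat$role == "icar" & heat$column == "tumour"] == 0))
  # mixed principals refuse
  pairs2 <- pairs
  pairs2$principal[1] <- "OTHER"
  expect_error(partner_heatmap_table(pairs2, tm), "single principal")
})

test_that("fixture heatmap: every feasible iCAR row has tumour value 0", {
  fx <- get_fixture(1)
  ic <- filter_icar(fx$tiss, fx$surf, fx$ecd_cat, filter_config())
  p <- fx$truth$planted_principals[1]
  pairs <- find_icar_partners(p, ic, fx$tiss, filter_config())
  heat <- partner_heatmap_table(pairs, fx$tiss,
                                setNames(fx$surf$median_expression, fx$surf$gene))
  expect_true(all(heat$value[heat$role == "icar" & heat$column == "tumour"] == 0))
  expect_equal(unique(heat$entity[heat$role == "principal"]), p)
})

test_that("greedy set cover combines partial partners into full coverage", {
  vals <- rbind(PRIN = c(2, 2, 2, 2), A = c(3, 3, 0, 0), B = c(0, 0, 3, 3),
                C = c(3, 0, 0, 0))
  colnames(vals) <- paste0("t", 1:4)
  tm <- toy_tissue_matrix(vals)
  pairs <- find_icar_partners("PRIN", mk_icars(c("A", "B", "C")), tm)
  cov <- icar_set_cover(pairs)
  expect_true(cov$complete)
  expect_setequal(cov$icars, c("A", "B"))
})
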