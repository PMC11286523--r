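toy_surf <- function(...) {
  rows <- list(...)
  as_surfaceome(do.call(rbind, lapply(rows, as.data.frame)))
}
srow <- function(gene, expr, ecd, membrane = TRUE, has_ecd = ecd > 0) {
  data.frame(gene = gene, median_expression = expr, ecd_length = as.integer(ecd),
             has_defined_ecd = has_ecd, membrane_annotated = membrane)
}

test_that("principal rules accept and reject as specified, with rule traces", {
  surf <- toy_surf(srow("GOODG", 4.0, 760), srow("WEAKE", 4.0, 760),
                   srow("LOWEX", 2.0, 760), srow("SHORT", 4.0, 50),
                   srow("NOMEM", 4.0, 760, membrane = FALSE),
                   srow("TCELX", 4.0, 760), srow("NODEP", 4.0, 760))
  ess <- data.frame(gene = c("GOODG", "WEAKE", "LOWEX", "SHORT", "NOMEM", "TCELX"),
                    chronos = c(-0.9, -0.1, -0.9, -0.9, -0.9, -0.9))
  tm <- toy_tissue_matrix(
    matrix(c(1, 0, 0, 0, 0, 0, 0,
             0, 0, 0, 0, 0, 2, 0), ncol = 2,
           dimnames = list(c("GOODG", "WEAKE", "LOWEX", "SHORT", "NOMEM",
                             "TCELX", "NODEP"), c("liver", "tcells"))),
    t_cell = "tcells")
  # GOODG is expressed in liver (fine) but not in the T-cell tissue
  res <- filter_principal(surf, ess, tm, filter_config(), explain = TRUE)
  expect_equal(res$gene, "GOODG")
  expect_equal(res$chronos, -0.9)
  rej <- attr(res, "rejected")
  fail <- setNames(rej$first_failed_rule, rej$gene)
  expect_equal(fail[["WEAKE"]], "essentiality")   # -0.1 > -0.25
  expect_equal(fail[["LOWEX"]], "expression")
  expect_equal(fail[["SHORT"]], "ecd_size")
  expect_equal(fail[["NOMEM"]], "membrane")
  expect_equal(fail[["TCELX"]], "t_cell_absent")
  expect_equal(fail[["NODEP"]], "dependency_entry")
})

test_that("disabling filters widens the accepted set as documented", {
  fx <- get_fixture(1)
  cfg <- filter_config()
  base <- filter_principal(fx$surf, fx$ess, fx$tiss, cfg)
  no_ess <- filter_principal(fx$surf, fx$ess, fx$tiss,
                             filter_config(max_chronos = Inf))
  expect_true(all(base$gene %in% no_ess$gene))
  no_dep <- filter_principal(fx$surf, fx$ess, fx$tiss,
                             filter_config(max_chronos = Inf,
                                           require_dependency_entry = FALSE))
  expect_true(all(no_ess$gene %in% no_dep$gene))
  expect_identical(nrow(filter_principal(fx$surf[0, ], fx$ess, fx$tiss, cfg)), 0L)
})

test_that("principal filter matches the rule-by-rule brute-force oracle", {
  for (seed in c(1, 9)) {
    fx <- get_fixture(seed)
    for (cfg in list(filter_config(),
                     filter_config(min_expression = 1.0, min_ecd = 50,
                                   max_chronos = 0.1),
                     filter_config(max_chronos = Inf,
                                   require_dependency_entry = FALSE),
                     filter_config(exclude_t_cell_expressed = FALSE))) {
      expect_identical(filter_principal(fx$surf, fx$ess, fx$tiss, cfg)$gene,
                       oracle_principal_filter(fx$surf, fx$ess, fx$tiss, cfg))
    }
  }
})

test_that("iCAR rules: absent-or-zero on tumour, catalogued ECD", {
  tm <- toy_tissue_matrix(matrix(1, 4, 1, dimnames = list(
    c("ONTUM", "ZEROX", "NEWPR", "NOECD"), "liver")))
  surf <- toy_surf(srow("ONTUM", 2.1, 100), srow("ZEROX", 0.0, 150))
  ecd_cat <- c(ONTUM = 100L, ZEROX = 150L, NEWPR = 300L, NOECD = 0L)
  ic <- filter_icar(tm, surf, ecd_cat, filter_config())
  expect_setequal(ic$gene, c("ZEROX", "NEWPR"))
  expect_equal(ic$provenance[ic$gene == "ZEROX"], "zero_surface_expression")
  expect_equal(ic$provenance[ic$gene == "NEWPR"], "absent_from_surfaceome")
  # configurable extra ECD floor
  ic2 <- filter_icar(tm, surf, ecd_cat, filter_config(min_icar_ecd = 200))
  expect_equal(ic2$gene, "NEWPR")
})

test_that("principal and iCAR sets are disjoint on any input bundle", {
  for (seed in c(1, 2, 3)) {
    fx <- get_fixture(seed)
    pc <- filter_principal(fx$surf, fx$ess, fx$tiss, filter_config())
    ic <- filter_icar(fx$tiss, fx$surf, fx$ecd_cat, filter_config())
    expect_length(intersect(pc$gene, ic$gene), 0)
  }
})

test_that("iCAR candidate count on the fixture equals the planted truth", {
  fx <- get_fixture(1)
  ic <- filter_icar(fx$tiss, fx$surf, fx$ecd_cat, filter_config())
  expect_equal(nrow(ic), fx$truth$expected_icar_count)
  expect_setequal(ic$gene, fx$truth$expected_icar_genes)
})

test_that("in-vivo filter is a logged set intersection", {
  cand <- structure(data.frame(gene = c("A", "B"), median_expression = c(4, 4),
                               ecd_length = c(300L, 300L), chronos = c(-1, -1)),
                    class = c("principal_candidates", "data.frame"))
  iv <- data.frame(gene = "A", in_vivo_score = -1.2, significant = TRUE)
  expect_message(out <- apply_in_vivo_filter(cand, iv), "B")
  expect_equal(out$gene, "A")
  expect_warning(empty <- apply_in_vivo_filter(cand, iv[0, ]), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("fixture(seed=2): in-vivo filter recovers the planted intersection", {
  fx <- get_fixture(2)
  pc <- filter_principal(fx$surf, fx$ess, fx$tiss, filter_config())
  iv <- read_invivo(fx$paths[["invivo"]])
  out <- suppressMessages(apply_in_vivo_filter(pc, iv))
  expect_setequal(out$gene, fx$truth$invivo_significant_principals)
})

test_that("filter_config rejects invalid thresholds", {
  expect_error(filter_config(min_expression = 6), "\\[0, 5\\]")
  expect_error(filter_config(min_ecd = -1), "non-negative")
  expect_error(filter_config(tissue_on_threshold = -0.1), ">= 0")
})
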