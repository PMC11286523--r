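# Independent brute-force oracles: deliberately written as per-row /
# per-tissue loops, sharing no code path with the package's vectorised
# implementations.

oracle_on_tissues <- function(gene, tm, thr = 0) {
  out <- character()
  for (t in colnames(tm$values)) {
    v <- tm$values[gene, t]
    if (!is.na(v) && v > thr) out <- c(out, t)
  }
  out
}

# exhaustive per-tissue feasibility scan (rule 7)
oracle_feasible_partners <- function(principal, cand_genes, tm, thr = 0) {
  need <- oracle_on_tissues(principal, tm, thr)
  feas <- character()
  for (g in cand_genes) {
    ok <- TRUE
    for (t in need) {
      v <- if (g %in% rownames(tm$values)) tm$values[g, t] else NA_real_
      if (is.na(v) || v <= thr) { ok <- FALSE; break }
    }
    if (ok) feas <- c(feas, g)
  }
  feas
}

# rule-by-rule conjunction for one surfaceome row (rules 1-4)
oracle_principal_filter <- function(surf, ess, tm, cfg) {
  tc_tissues <- tm$tissue_meta$tissue[tm$tissue_meta$is_t_cell]
  accepted <- character()
  for (i in seq_len(nrow(surf))) {
    g <- surf$gene[i]
    if (!isTRUE(surf$membrane_annotated[i])) next
    if (!isTRUE(surf$has_defined_ecd[i]) || surf$ecd_length[i] <= 0) next
    if (!(surf$median_expression[i] > cfg$min_expression)) next
    if (!(surf$ecd_length[i] > cfg$min_ecd)) next
    ch <- ess$chronos[ess$gene == g]
    if (cfg$require_dependency_entry && length(ch) == 0) next
    if (!(is.infinite(cfg$max_chronos) && cfg$max_chronos > 0)) {
      if (length(ch) == 0 || !(ch <= cfg$max_chronos)) next
    }
    if (cfg$exclude_t_cell_expressed && g %in% rownames(tm$values)) {
      hit <- FALSE
      for (t in tc_tissues) {
        v <- tm$values[g, t]
        if (!is.na(v) && v > cfg$tissue_on_threshold) hit <- TRUE
      }
      if (hit) next
    }
    accepted <- c(accepted, g)
  }
  accepted
}

# small randomised fixture spec within the oracle-equivalence caps
# (<= 200 proteome candidates x <= 30 tissues)
rand_small_spec <- function(seed) {
  set.seed(seed + 10000L)
  k <- sample(1:3, 1)
  n_tissues <- sample(10:30, 1)
  partners <- sample(1:4, 1)
  partials <- sample(0:5, 1)
  n_ess <- sample(0:3, 1)
  n_surface <- sample((k + n_ess + 3):40, 1)
  n_extra <- k * (partners + partials)
  n_proteome <- min(200L, n_surface + n_extra + sample(10:80, 1))
  fixture_spec(seed = seed, n_surface = n_surface, n_proteome = n_proteome,
               n_tissues = n_tissues, n_planted_principals = k,
               planted_partners_per_principal = partners,
               planted_partial_partners = partials,
               n_planted_essentials = n_ess)
}

# one shared default fixture per test session, loaded through the readers
fixture_env <- new.env(parent = emptyenv())
get_fixture <- function(seed = 1L, ...) {
  key <- paste0("fx", seed, paste(c(...), collapse = "_"))
  if (is.null(fixture_env[[key]])) {
    bundle <- generate_fixture(fixture_spec(seed = seed, ...))
    dir <- file.path(tempdir(), paste0("notgate_", key))
    paths <- write_fixture(bundle, dir)
    loaded <- list(
      bundle = bundle, paths = paths, truth = bundle$truth,
      surf = read_surfaceome(paths[["surfaceome"]]),
      tiss = read_tissue_proteome(paths[["tissue_matrix"]], paths[["tissue_meta"]]),
      ecd_cat = read_ecd_catalog(paths[["ecd_catalog"]]))
    loaded$ess <- suppressMessages(
      aggregate_chronos(read_dependency(paths[["dependency"]]), bundle$disease_lines))
    fixture_env[[key]] <- loaded
  }
  fixture_env[[key]]
}

# minimal hand-built tissue matrix for toy tests
toy_tissue_matrix <- function(values, t_cell = character()) {
  tissue_matrix(values, data.frame(
    tissue = colnames(values),
    is_essential_cell_type = FALSE,
    is_t_cell = colnames(values) %in% t_cell))
}
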