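# Deterministic synthetic fixtures with planted, machine-readable ground
# truth. The generator emulates the statistical shape of the real inputs --
# a tumour surfaceome on a 0-5 AU scale, a zero-inflated healthy-tissue
# proteome, a gene x cell-line dependency screen -- at desk scale, and
# plants structure that every pipeline stage must recover exactly:
# principal targets passing all rules, a dominant top-ranked gene, and for
# each principal a known set of feasible and partial iCAR partners.
#
# Exactness is by construction, not by luck:
#   * background surfaceome expression is truncated below 3.5 AU, so only
#     planted principals can pass the expression rule;
#   * planted Chronos draws are clamped below -0.3, background is centred
#     at 0, so planted essentials always pass the essentiality rule;
#   * every non-partner proteome row is zeroed across the union of planted
#     ON-tissue sets, so only planted partners can cover a principal.

#' Specification of a synthetic fixture
#'
#' @param seed Integer RNG seed; fixtures are byte-identical for a fixed seed.
#' @param n_surface Number of tumour surfaceome proteins.
#' @param n_proteome Number of healthy-tissue proteome proteins
#'   (`>= n_surface`; the surfaceome is a subset).
#' @param n_tissues Number of healthy tissues (2 flagged T-cell lineage,
#'   4 flagged essential cell type when room allows).
#' @param n_planted_principals Principals planted to pass all rules.
#' @param planted_partners_per_principal Feasible iCAR partners per principal.
#' @param planted_partial_partners Partners missing >= 1 required tissue.
#' @param noise_sd SD of the positive noise added on top of `on_level`.
#' @param on_level Expression level marking a planted tissue as ON (> 0).
#' @param n_planted_essentials Extra essential genes (low surface
#'   expression, Chronos < -0.25) beyond the principals.
#' @param n_disease_lines,n_other_lines Cell lines in the dependency table;
#'   only disease lines are meant to be aggregated.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_surface = 120L,
                         n_proteome = 400L,
                         n_tissues = 20L,
                         n_planted_principals = 3L,
                         planted_partners_per_principal = 4L,
                         planted_partial_partners = 6L,
                         noise_sd = 0.3,
                         on_level = 2.0,
                         n_planted_essentials = 5L,
                         n_disease_lines = 12L,
                         n_other_lines = 3L) {
  spec <- list(seed = as.integer(seed), n_surface = as.integer(n_surface),
               n_proteome = as.integer(n_proteome), n_tissues = as.integer(n_tissues),
               n_planted_principals = as.integer(n_planted_principals),
               planted_partners_per_principal = as.integer(planted_partners_per_principal),
               planted_partial_partners = as.integer(planted_partial_partners),
               noise_sd = as.numeric(noise_sd), on_level = as.numeric(on_level),
               n_planted_essentials = as.integer(n_planted_essentials),
               n_disease_lines = as.integer(n_disease_lines),
               n_other_lines = as.integer(n_other_lines))
  class(spec) <- "fixture_spec"
  validate_fixture_spec(spec)
}

validate_fixture_spec <- function(spec) {
  k <- spec$n_planted_principals
  n_planted_prot <- k * (spec$planted_partners_per_principal + spec$planted_partial_partners)
  n_surface_planted <- k + spec$n_planted_essentials + 2L  # + 2 zero-expression rows
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$on_level <= 0) stop("on_level must be > 0", call. = FALSE)
  if (spec$n_proteome < spec$n_surface)
    stop("n_proteome must be >= n_surface", call. = FALSE)
  if (spec$n_surface < n_surface_planted)
    stop(sprintf("n_surface=%d too small for %d planted surfaceome genes",
                 spec$n_surface, n_surface_planted), call. = FALSE)
  if (spec$n_proteome - spec$n_surface < n_planted_prot)
    stop(sprintf("n_proteome - n_surface = %d cannot hold %d planted partner genes",
                 spec$n_proteome - spec$n_surface, n_planted_prot), call. = FALSE)
  n_tcell <- if (spec$n_tissues >= 8L) 2L else 1L
  if (k > 0 && (spec$n_tissues - n_tcell) < 2L * k)
    stop("not enough non-T-cell tissues for disjoint planted ON sets", call. = FALSE)
  if (spec$n_disease_lines < 1L) stop("need >= 1 disease line", call. = FALSE)
  spec
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' @param spec A [fixture_spec()].
#' @return List of class `fixture_bundle`: `surfaceome` (table),
#'   `tissue_matrix` (table, first column `gene`), `tissue_meta` (table),
#'   `dependency` (table, first column `gene`), `disease_lines` (character),
#'   `ecd_catalog` (table), `invivo` (table), `truth` (list), `spec`.
#'   All real values are rounded to 6 decimals so written files round-trip
#'   bit-exactly.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  spec <- validate_fixture_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  k <- spec$n_planted_principals
  r6 <- function(x) round(x, 6)

  # --- tissues ----------------------------------------------------------
  n_tcell <- if (spec$n_tissues >= 8L) 2L else 1L
  tcell_tissues <- paste0("TCELL_", sprintf("%02d", seq_len(n_tcell)))
  n_body <- spec$n_tissues - n_tcell
  body_tissues <- paste0("TISSUE_", sprintf("%02d", seq_len(n_body)))
  tissues <- c(body_tissues, tcell_tissues)
  n_ess_t <- min(4L, n_body)
  ess_tissues <- body_tissues[seq_len(n_ess_t)]
  tissue_meta <- data.frame(
    tissue = tissues,
    flags = ifelse(tissues %in% tcell_tissues, "t_cell",
                   ifelse(tissues %in% ess_tissues, "essential", "")),
    stringsAsFactors = FALSE)

  # disjoint planted ON sets over the non-T-cell tissues
  m <- if (k > 0) min(5L, n_body %/% k) else 0L
  on_sets <- if (k > 0)
    split(body_tissues[seq_len(m * k)], rep(seq_len(k), each = m)) else list()

  # --- gene names -------------------------------------------------------
  principals <- if (k > 0) paste0("PRIN", sprintf("%02d", seq_len(k))) else character()
  essentials_extra <- if (spec$n_planted_essentials > 0)
    paste0("ESSG", sprintf("%02d", seq_len(spec$n_planted_essentials))) else character()
  zero_surf <- c("SURFZ01", "SURFZ02")
  n_surf_bg <- spec$n_surface - k - length(essentials_extra) - length(zero_surf)
  surf_bg <- paste0("SURF", sprintf("%03d", seq_len(n_surf_bg)))
  surface_genes <- c(principals, essentials_extra, zero_surf, surf_bg)

  partner_names <- lapply(seq_len(k), function(i)
    paste0("IC", sprintf("%02d", i), "F", sprintf("%02d",
           seq_len(spec$planted_partners_per_principal))))
  partial_names <- lapply(seq_len(k), function(i)
    paste0("IC", sprintf("%02d", i), "P", sprintf("%02d",
           seq_len(spec$planted_partial_partners))))
  all_partners <- unlist(partner_names)
  all_partials <- unlist(partial_names)
  n_prot_bg <- spec$n_proteome - spec$n_surface - length(all_partners) - length(all_partials)
  prot_bg <- if (n_prot_bg > 0) paste0("PROT", sprintf("%03d", seq_len(n_prot_bg))) else character()
  proteome_genes <- c(surface_genes, all_partners, all_partials, prot_bg)

  # --- surfaceome table -------------------------------------------------
  # background expression capped below 3.5 AU so only principals pass rule 3
  expr <- numeric(spec$n_surface)
  names(expr) <- surface_genes
  if (k > 0) {
    expr[principals] <- r6(stats::runif(k, 4.0, 4.6))
    expr[principals[1]] <- 4.8  # dominant: max expression of the whole table
  }
  expr[essentials_extra] <- r6(stats::runif(length(essentials_extra), 0.5, 3.0))
  expr[zero_surf] <- 0
  expr[surf_bg] <- r6(pmin(pmax(stats::rnorm(n_surf_bg, 1.5, 0.8), 0), 3.4))

  ecd <- integer(spec$n_surface)
  names(ecd) <- surface_genes
  if (k > 0) ecd[principals] <- sample(300:900, k, replace = TRUE)
  ecd[essentials_extra] <- sample(50:400, length(essentials_extra), replace = TRUE)
  ecd[zero_surf] <- sample(100:300, 2L, replace = TRUE)
  bg_has_ecd <- stats::runif(n_surf_bg) < 0.6
  ecd[surf_bg] <- ifelse(bg_has_ecd, sample(10:600, n_surf_bg, replace = TRUE), 0L)

  surfaceome <- data.frame(
    gene = surface_genes,
    median_expression = unname(expr),
    ecd_length = unname(ecd),
    has_defined_ecd = unname(ecd) > 0,
    membrane_annotated = c(rep(TRUE, k + length(essentials_extra) + 2L),
                           stats::runif(n_surf_bg) < 0.9),
    stringsAsFactors = FALSE)

  # --- tissue matrix ----------------------------------------------------
  on_union <- unlist(on_sets, use.names = FALSE)
  vals <- matrix(0, nrow = spec$n_proteome, ncol = spec$n_tissues,
                 dimnames = list(proteome_genes, tissues))
  bg_tissues <- setdiff(tissues, on_union)
  # zero-inflated log-normal background, only outside the planted ON union
  bg_rows <- setdiff(proteome_genes, c(principals, all_partners, all_partials))
  for (g in bg_rows) {
    onmask <- stats::runif(length(bg_tissues)) > 0.55
    vals[g, bg_tissues] <- r6(ifelse(onmask, stats::rlnorm(length(bg_tissues), 0, 0.8), 0))
  }
  on_draw <- function(n) r6(spec$on_level + abs(stats::rnorm(n, 0, spec$noise_sd)))
  for (i in seq_len(k)) {
    p <- principals[i]; s <- on_sets[[i]]
    vals[p, ] <- 0
    vals[p, s] <- on_draw(length(s))
    for (g in partner_names[[i]]) {
      vals[g, s] <- on_draw(length(s))
      vals[g, bg_tissues] <- r6(ifelse(stats::runif(length(bg_tissues)) > 0.55,
                                       stats::rlnorm(length(bg_tissues), 0, 0.8), 0))
    }
    for (g in partial_names[[i]]) {
      miss <- sample(s, sample(1:min(2L, length(s) - 1L), 1L))
      cover <- setdiff(s, miss)
      vals[g, cover] <- on_draw(length(cover))
      vals[g, miss] <- 0
      vals[g, bg_tissues] <- r6(ifelse(stats::runif(length(bg_tissues)) > 0.55,
                                       stats::rlnorm(length(bg_tissues), 0, 0.8), 0))
    }
  }
  # sparse missing measurements, background rows / background tissues only
  na_rows <- intersect(bg_rows, prot_bg)
  if (length(na_rows) && length(bg_tissues)) {
    nmiss <- max(1L, round(0.02 * length(na_rows)))
    for (g in sample(na_rows, nmiss))
      vals[g, sample(bg_tissues, 1L)] <- NA_real_
  }
  tissue_tab <- data.frame(gene = proteome_genes, vals, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rownames(tissue_tab) <- NULL

  # --- dependency table -------------------------------------------------
  disease_lines <- paste0("MMLINE", sprintf("%02d", seq_len(spec$n_disease_lines)))
  other_lines <- if (spec$n_other_lines > 0)
    paste0("OTHLINE", sprintf("%02d", seq_len(spec$n_other_lines))) else character()
  lines <- c(disease_lines, other_lines)
  dep_genes <- c(principals, essentials_extra, zero_surf,
                 surf_bg[stats::runif(n_surf_bg) < 0.85])
  dep <- matrix(r6(stats::rnorm(length(dep_genes) * length(lines), 0, 0.15)),
                nrow = length(dep_genes), dimnames = list(dep_genes, lines))
  if (k > 0) {
    dep[principals[1], disease_lines] <-
      r6(pmin(pmax(stats::rnorm(spec$n_disease_lines, -1.5, 0.1), -2), -1.2))
    if (k > 1)
      for (p in principals[-1])
        dep[p, disease_lines] <-
          r6(pmin(pmax(stats::rnorm(spec$n_disease_lines, -0.8, 0.15), -1.1), -0.3))
  }
  for (g in essentials_extra)
    dep[g, disease_lines] <-
      r6(pmin(stats::rnorm(spec$n_disease_lines, -0.8, 0.15), -0.3))
  # sprinkle missing per-line scores in background genes only
  bg_dep <- setdiff(dep_genes, c(principals, essentials_extra))
  if (length(bg_dep) > 4L)
    for (g in sample(bg_dep, 3L)) dep[g, sample(lines, 1L)] <- NA_real_
  dependency <- data.frame(gene = dep_genes, dep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rownames(dependency) <- NULL

  # --- ECD catalog over the whole proteome ------------------------------
  cat_ecd <- integer(spec$n_proteome)
  names(cat_ecd) <- proteome_genes
  cat_ecd[surface_genes] <- ecd[surface_genes]
  cat_ecd[all_partners] <- sample(200:800, length(all_partners), replace = TRUE)
  cat_ecd[all_partials] <- sample(200:800, length(all_partials), replace = TRUE)
  if (length(prot_bg)) {
    bg_cat <- stats::runif(length(prot_bg)) < 0.5
    cat_ecd[prot_bg] <- ifelse(bg_cat, sample(10:1000, length(prot_bg), replace = TRUE), 0L)
  }
  ecd_catalog <- data.frame(gene = proteome_genes, ecd_length = unname(cat_ecd),
                            stringsAsFactors = FALSE)

  # --- in-vivo table ----------------------------------------------------
  iv_sig_principals <- if (k > 0) principals[seq_len(ceiling(k / 2))] else character()
  iv_bg <- if (n_surf_bg >= 10L) sample(surf_bg, 10L) else surf_bg
  iv_genes <- c(principals, iv_bg)
  invivo <- data.frame(
    gene = iv_genes,
    in_vivo_score = r6(stats::rnorm(length(iv_genes), -0.5, 0.5)),
    significant = iv_genes %in% iv_sig_principals | c(rep(FALSE, k),
                   stats::runif(length(iv_bg)) < 0.3),
    stringsAsFactors = FALSE)

  # --- ground truth (independent set arithmetic on the tables above) ----
  surf_pos <- surfaceome$gene[surfaceome$median_expression > 0]
  icar_truth <- proteome_genes[!(proteome_genes %in% surf_pos) & cat_ecd > 0]
  truth <- list(
    seed = spec$seed,
    planted_principals = principals,
    dominant_gene = if (k > 0) principals[1] else NA_character_,
    essential_genes = c(principals, essentials_extra),
    on_tissues = stats::setNames(on_sets, principals),
    feasible_partners = stats::setNames(partner_names, principals),
    partial_partners = stats::setNames(partial_names, principals),
    expected_principal_set = principals,
    expected_icar_count = length(icar_truth),
    expected_icar_genes = icar_truth,
    invivo_significant_principals = iv_sig_principals,
    t_cell_tissues = tcell_tissues,
    n_surface = spec$n_surface, n_proteome = spec$n_proteome,
    n_tissues = spec$n_tissues)

  structure(list(surfaceome = surfaceome, tissue_matrix = tissue_tab,
                 tissue_meta = tissue_meta, dependency = dependency,
                 disease_lines = disease_lines, ecd_catalog = ecd_catalog,
                 invivo = invivo, truth = truth, spec = spec),
            class = "fixture_bundle")
}

#' Write a fixture bundle to disk in the dialects the readers expect
#'
#' @param bundle A `fixture_bundle` from [generate_fixture()].
#' @param directory Output directory (created if needed).
#' @return Named character vector of file paths (`surfaceome`,
#'   `tissue_matrix`, `tissue_meta`, `dependency`, `disease_lines`,
#'   `ecd_catalog`, `invivo`, `truth`).
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    stop(sprintf("cannot create fixture directory '%s'", directory), call. = FALSE)
  p <- function(f) file.path(directory, f)
  paths <- c(surfaceome = p("surfaceome.tsv"), tissue_matrix = p("tissue_matrix.tsv"),
             tissue_meta = p("tissue_meta.tsv"), dependency = p("dependency.tsv"),
             disease_lines = p("disease_lines.tsv"), ecd_catalog = p("ecd_catalog.tsv"),
             invivo = p("invivo.tsv"), truth = p("truth.json"))
  write_tsv(bundle$surfaceome, paths["surfaceome"])
  write_tsv(bundle$tissue_matrix, paths["tissue_matrix"])
  write_tsv(bundle$tissue_meta, paths["tissue_meta"])
  write_tsv(bundle$dependency, paths["dependency"])
  write_tsv(data.frame(line = bundle$disease_lines), paths["disease_lines"])
  write_tsv(bundle$ecd_catalog, paths["ecd_catalog"])
  write_tsv(bundle$invivo, paths["invivo"])
  jsonlite::write_json(bundle$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  paths
}

#' Read a fixture's ground-truth JSON
#' @param path Path to `truth.json`.
#' @return The truth list.
#' @export
read_fixture_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("on_tissues", "feasible_partners", "partial_partners"))
    tr[[f]] <- lapply(tr[[f]], as.character)
  tr
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
}
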