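# The seven eligibility rules.
#
# Principal target:            iCAR partner:
#   1 surface-membrane expressed   5 not expressed on tumour cells
#   2 has an extracellular domain  6 has an extracellular domain
#   3 essential (Chronos)          7 co-expressed with the principal in every
#   4 absent from T cells            healthy tissue where it is on (engine.R)
#
# Rules 1-6 live here; rule 7 is tissue-coverage logic in engine.R.

PRINCIPAL_RULES <- c("membrane", "ecd_defined", "expression", "ecd_size",
                     "dependency_entry", "essentiality", "t_cell_absent")

#' Filter principal CAR target candidates (rules 1-4)
#'
#' Applies, in order: membrane annotation; presence of a defined
#' extracellular domain; median tumour surface expression strictly above
#' `cfg$min_expression`; ECD length strictly above `cfg$min_ecd`; presence in
#' the dependency table (when `cfg$require_dependency_entry`); aggregated
#' Chronos score at or below `cfg$max_chronos` (set `max_chronos = Inf` to
#' run without the essentiality filter); and absence from T-cell-lineage
#' tissues (when `cfg$exclude_t_cell_expressed`), where "absent" means no
#' T-cell tissue value strictly above `cfg$tissue_on_threshold`.
#'
#' A gene missing from the tissue matrix has no evidence of T-cell expression
#' and passes rule 4; a missing (NA) T-cell measurement likewise does not
#' count as expressed. Genes missing from the dependency table pass the
#' essentiality comparison only when it is disabled (`max_chronos = Inf`) or
#' when `require_dependency_entry = FALSE` (their `chronos` is `NA`).
#'
#' @param surfaceome A `surfaceome` object ([read_surfaceome()]).
#' @param essentiality An `essentiality` object ([aggregate_chronos()]).
#' @param tissues A [tissue_matrix()] (used for the T-cell rule); may be
#'   `NULL` when `exclude_t_cell_expressed = FALSE`.
#' @param cfg A [filter_config()].
#' @param explain Keep a table of rejected genes with their first failing
#'   rule (attribute `rejected`)?
#' @return `data.frame` of class `principal_candidates` with columns `gene`,
#'   `median_expression`, `ecd_length`, `chronos`; rows in input order.
#' @export
filter_principal <- function(surfaceome, essentiality, tissues,
                             cfg = filter_config(), explain = FALSE) {
  validate_filter_config(cfg)
  if (nrow(surfaceome) == 0L)
    return(empty_principals())
  chronos <- essentiality$chronos[match(surfaceome$gene, essentiality$gene)]

  t_cell_hit <- rep(FALSE, nrow(surfaceome))
  if (cfg$exclude_t_cell_expressed && !is.null(tissues)) {
    tc <- tissues_of(tissues, "t_cell")
    if (length(tc)) {
      idx <- match(surfaceome$gene, rownames(tissues$values))
      present <- !is.na(idx)
      if (any(present)) {
        sub <- tissues$values[idx[present], tc, drop = FALSE]
        t_cell_hit[present] <- apply(sub > cfg$tissue_on_threshold, 1L, any, na.rm = TRUE)
      }
    }
  }

  pass <- cbind(
    membrane = surfaceome$membrane_annotated,
    ecd_defined = surfaceome$has_defined_ecd & surfaceome$ecd_length > 0,
    expression = surfaceome$median_expression > cfg$min_expression,
    ecd_size = surfaceome$ecd_length > cfg$min_ecd,
    dependency_entry = if (cfg$require_dependency_entry) !is.na(chronos)
                       else rep(TRUE, nrow(surfaceome)),
    essentiality = if (is.infinite(cfg$max_chronos) && cfg$max_chronos > 0)
                     rep(TRUE, nrow(surfaceome))
                   else !is.na(chronos) & chronos <= cfg$max_chronos,
    t_cell_absent = !t_cell_hit
  )
  ok <- rowSums(!pass) == 0L

  out <- data.frame(gene = surfaceome$gene[ok],
                    median_expression = surfaceome$median_expression[ok],
                    ecd_length = surfaceome$ecd_length[ok],
                    chronos = chronos[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("principal_candidates", "data.frame")
  if (explain) {
    first_fail <- apply(pass[!ok, , drop = FALSE], 1L,
                        function(p) PRINCIPAL_RULES[which(!p)[1L]])
    attr(out, "rejected") <- data.frame(gene = surfaceome$gene[!ok],
                                        first_failed_rule = unname(first_fail),
                                        stringsAsFactors = FALSE)
  }
  out
}

empty_principals <- function() {
  structure(data.frame(gene = character(), median_expression = numeric(),
                       ecd_length = integer(), chronos = numeric(),
                       stringsAsFactors = FALSE),
            class = c("principal_candidates", "data.frame"))
}

#' Filter iCAR partner candidates (rules 5-6)
#'
#' An iCAR candidate is any healthy-tissue proteome protein that is not
#' expressed on the tumour cell surface -- absence from the surfaceome table,
#' or a recorded surface expression of exactly 0, both qualify (counted
#' separately in the `provenance` column) -- and that carries a catalogued
#' extracellular domain (`ecd_length > 0`, plus any configured
#' `cfg$min_icar_ecd`).
#'
#' @param proteome A [tissue_matrix()] whose rows define the search space.
#' @param surfaceome A `surfaceome` object (tumour surface expression).
#' @param ecd_catalog Named integer vector gene -> ECD length
#'   ([read_ecd_catalog()]); genes absent from the catalog count as having no
#'   extracellular domain.
#' @param cfg A [filter_config()].
#' @return `data.frame` of class `icar_candidates` with columns `gene`,
#'   `ecd_length`, `provenance` (`"absent_from_surfaceome"` or
#'   `"zero_surface_expression"`).
#' @export
filter_icar <- function(proteome, surfaceome, ecd_catalog, cfg = filter_config()) {
  validate_filter_config(cfg)
  stopifnot(inherits(proteome, "tissue_matrix"))
  if (nrow(proteome$values) == 0L)
    stop("proteome matrix is empty", call. = FALSE)
  genes <- rownames(proteome$values)
  surf_expr <- surfaceome$median_expression[match(genes, surfaceome$gene)]
  in_surf <- !is.na(surf_expr)
  not_on_tumour <- !in_surf | surf_expr == 0           # rule 5
  ecd <- unname(ecd_catalog[genes])
  ecd[is.na(ecd)] <- 0L
  has_ecd <- ecd > 0 & ecd > cfg$min_icar_ecd          # rule 6
  keep <- not_on_tumour & has_ecd
  out <- data.frame(
    gene = genes[keep],
    ecd_length = as.integer(ecd[keep]),
    provenance = ifelse(in_surf[keep], "zero_surface_expression", "absent_from_surfaceome"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("icar_candidates", "data.frame"),
            n_not_on_tumour = sum(not_on_tumour))
}

#' Optional in-vivo CRISPR screen filter for principal candidates
#'
#' Keeps candidates whose gene has an in-vivo record flagged significant.
#' In-vivo surface-protein screens are small, so candidates with no record
#' at all are dropped and reported (attribute `no_record`) rather than
#' silently carried through.
#'
#' @param candidates A `principal_candidates` object.
#' @param invivo `data.frame` from [read_invivo()].
#' @return Filtered `principal_candidates`; warns when `invivo` is empty.
#' @export
apply_in_vivo_filter <- function(candidates, invivo) {
  if (is.null(invivo) || nrow(invivo) == 0L) {
    warning("in-vivo table is empty: every candidate is dropped", call. = FALSE)
    out <- candidates[0L, , drop = FALSE]
    class(out) <- c("principal_candidates", "data.frame")
    return(out)
  }
  rec <- match(candidates$gene, invivo$gene)
  keep <- !is.na(rec) & invivo$significant[rec]
  no_record <- candidates$gene[is.na(rec)]
  if (length(no_record))
    message(sprintf("in-vivo filter: %d candidate(s) with no in-vivo record dropped: %s",
                    length(no_record), paste(no_record, collapse = ", ")))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("principal_candidates", "data.frame")
  attr(out, "no_record") <- no_record
  out
}
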