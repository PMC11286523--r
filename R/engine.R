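# NOT-gate engine: rule 7. An iCAR partner must be co-ordinately expressed
# with the principal everywhere off tumour -- operationalised as set
# coverage: the partner must be ON (value > threshold) in every healthy
# tissue where the principal is ON. Presence/absence per tissue, no
# requirement on quantitative correlation of levels. A missing measurement
# in a required tissue is NOT coverage: an unprotected tissue must never be
# assumed protected.

#' Healthy tissues where a principal target is expressed
#'
#' @param principal Gene symbol; must be a row of `tissues`.
#' @param tissues A [tissue_matrix()].
#' @param cfg A [filter_config()]; `tissue_on_threshold` binarises
#'   expression (strictly greater than).
#' @return Character vector of tissue labels where the principal's value is
#'   above threshold. Tissues with missing values are excluded (unknown is
#'   not ON) and listed in the `missing_tissues` attribute.
#' @export
principal_on_tissues <- function(principal, tissues, cfg = filter_config()) {
  stopifnot(inherits(tissues, "tissue_matrix"))
  principal <- toupper(principal)
  if (!principal %in% rownames(tissues$values))
    stop(sprintf("principal '%s' not found in the tissue matrix", principal),
         call. = FALSE)
  row <- tissues$values[principal, ]
  on <- names(row)[!is.na(row) & row > cfg$tissue_on_threshold]
  miss <- names(row)[is.na(row)]
  if (length(miss))
    message(sprintf("principal_on_tissues('%s'): %d tissue(s) with missing values excluded from the ON set: %s",
                    principal, length(miss), paste(miss, collapse = ", ")))
  structure(on, missing_tissues = miss)
}

#' Find iCAR partners for a principal target (rule 7)
#'
#' Scores every iCAR candidate against the principal's ON-tissue set.
#' `covered` tissues are required tissues where the candidate's value is
#' above `cfg$tissue_on_threshold`; a candidate is `feasible` when it covers
#' all of them (coverage = 1). Candidates missing from the matrix, or with
#' missing values in required tissues, are not covered there. All pairs are
#' returned with their covered/uncovered sets so near-misses stay
#' inspectable; subset on `feasible` for the rule-7 result.
#'
#' If the principal has an empty ON set it is fully tumour-specific and
#' needs no iCAR: every candidate is vacuously feasible and a prominent
#' warning is raised.
#'
#' @param principal Gene symbol of the chosen principal target.
#' @param icar_candidates An `icar_candidates` object ([filter_icar()]).
#' @param tissues A [tissue_matrix()].
#' @param cfg A [filter_config()].
#' @param min_icar_ecd Extra ECD floor (aa, strict `>`) applied here, e.g. to
#'   narrow partners to those with scFv-accessible domains.
#' @return `data.frame` of class `notgate_pairs` with columns `principal`,
#'   `icar`, `icar_ecd`, `n_covered`, `n_uncovered`, `coverage`, `feasible`,
#'   plus list-columns `covered_tissues`, `uncovered_tissues`; sorted
#'   feasible-first, then by coverage, then gene symbol. Attribute
#'   `on_tissues` carries the principal's required set.
#' @export
find_icar_partners <- function(principal, icar_candidates, tissues,
                               cfg = filter_config(), min_icar_ecd = 0) {
  principal <- toupper(principal)
  on_set <- principal_on_tissues(principal, tissues, cfg)
  cand <- icar_candidates[icar_candidates$ecd_length > max(0, min_icar_ecd), ,
                          drop = FALSE]
  n_req <- length(on_set)
  if (n_req == 0L)
    warning(sprintf(paste0("principal '%s' is expressed in no healthy tissue at ",
                           "threshold %.3g: it is fully tumour-specific, needs no ",
                           "iCAR, and every candidate is vacuously feasible"),
                    principal, cfg$tissue_on_threshold), call. = FALSE)

  idx <- match(cand$gene, rownames(tissues$values))
  covered_list <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (is.na(idx[i]) || n_req == 0L) {
      covered_list[[i]] <- character()
    } else {
      v <- tissues$values[idx[i], on_set]
      covered_list[[i]] <- on_set[!is.na(v) & v > cfg$tissue_on_threshold]
    }
  }
  n_cov <- lengths(covered_list)
  coverage <- if (n_req == 0L) rep(1, nrow(cand)) else n_cov / n_req
  out <- data.frame(principal = rep(principal, nrow(cand)),
                    icar = cand$gene,
                    icar_ecd = cand$ecd_length,
                    n_covered = as.integer(n_cov),
                    n_uncovered = as.integer(n_req - n_cov),
                    coverage = coverage,
                    feasible = coverage == 1,
                    stringsAsFactors = FALSE)
  out$covered_tissues <- covered_list
  out$uncovered_tissues <- lapply(covered_list, function(cv) setdiff(on_set, cv))
  ord <- order(-out$feasible, -out$coverage, c_locale_rank(out$icar))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("notgate_pairs", "data.frame"),
            on_tissues = as.character(on_set))
}

#' Count theoretical NOT-gate combinations
#'
#' @param principals A `principal_candidates` object, or an integer count.
#' @param icars An `icar_candidates` object, or an integer count.
#' @param n_feasible_for_query Optional feasible-pair count for a specific
#'   principal query, carried through to the summary.
#' @return List of class `combination_summary`: `n_principals`, `n_icars`,
#'   `n_theoretical` (exact integer arithmetic in doubles, no overflow below
#'   2^53), `n_feasible_for_query`.
#' @export
#' @examples
#' count_combinations(716, 1348)$n_theoretical # 968032
count_combinations <- function(principals, icars, n_feasible_for_query = NA_integer_) {
  np <- if (is.data.frame(principals)) nrow(principals) else as.numeric(principals)
  ni <- if (is.data.frame(icars)) nrow(icars) else as.numeric(icars)
  stopifnot(np >= 0, ni >= 0, np == round(np), ni == round(ni))
  structure(list(n_principals = np, n_icars = ni, n_theoretical = np * ni,
                 n_feasible_for_query = n_feasible_for_query),
            class = "combination_summary")
}

#' @export
print.combination_summary <- function(x, ...) {
  cat(sprintf("NOT-gate combinations: %s principals x %s iCARs = %s theoretical pairs\n",
              format(x$n_principals, big.mark = ","),
              format(x$n_icars, big.mark = ","),
              format(x$n_theoretical, big.mark = ",")))
  if (!is.na(x$n_feasible_for_query))
    cat(sprintf("  feasible for the current query: %s\n",
                format(x$n_feasible_for_query, big.mark = ",")))
  invisible(x)
}

#' Long-format expression table behind the partner heatmap
#'
#' Rebuilds the display behind the co-expression heatmap: the principal
#' target's expression across healthy tissues on the first row-entity,
#' each feasible iCAR partner below it, plus one `tumour` column. Feasible
#' iCARs are by construction not expressed on the tumour, so their tumour
#' value is 0 unless `tumour_expression` records otherwise.
#'
#' @param pairs A `notgate_pairs` object; all rows must share one principal.
#' @param tissues A [tissue_matrix()].
#' @param tumour_expression Named numeric vector gene -> tumour surface AU
#'   (e.g. `setNames(surf$median_expression, surf$gene)`); genes absent from
#'   it get 0.
#' @return Long-format `data.frame` with columns `entity` (gene), `role`
#'   (`principal`/`icar`), `column` (tissue label or `"tumour"`), `value`.
#' @export
partner_heatmap_table <- function(pairs, tissues, tumour_expression = numeric()) {
  if (length(unique(pairs$principal)) > 1L)
    stop("partner_heatmap_table expects pairs for a single principal", call. = FALSE)
  principal <- pairs$principal[1L]
  if (nrow(pairs) == 0L || is.na(principal))
    stop("no pairs supplied", call. = FALSE)
  entities <- c(principal, pairs$icar[pairs$feasible])
  roles <- c("principal", rep("icar", sum(pairs$feasible)))
  tiss <- colnames(tissues$values)
  rows <- lapply(seq_along(entities), function(i) {
    g <- entities[i]
    vals <- if (g %in% rownames(tissues$values)) tissues$values[g, tiss] else
      stats::setNames(rep(NA_real_, length(tiss)), tiss)
    tum <- if (g %in% names(tumour_expression)) unname(tumour_expression[g]) else 0
    data.frame(entity = g, role = roles[i],
               column = c(tiss, "tumour"),
               value = c(unname(vals), tum),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy multi-iCAR set cover (extension)
#'
#' When no single iCAR covers a principal's whole ON-tissue set, a
#' disjunction of iCARs (the T-cell is inhibited if ANY of them binds) may.
#' This greedy report repeatedly picks the candidate covering the most
#' still-uncovered required tissues. It is an extension beyond single-partner
#' NOT-gating and is labelled as such in its output.
#'
#' @param pairs A `notgate_pairs` object for one principal.
#' @param max_icars Maximum number of iCARs to combine.
#' @return List: `icars` (chosen genes in pick order), `covered`,
#'   `uncovered` (tissue labels), `complete` (logical).
#' @export
icar_set_cover <- function(pairs, max_icars = 3L) {
  on_set <- attr(pairs, "on_tissues")
  uncovered <- on_set
  chosen <- character()
  pool <- pairs
  while (length(uncovered) && length(chosen) < max_icars && nrow(pool)) {
    gain <- vapply(pool$covered_tissues,
                   function(cv) length(intersect(cv, uncovered)), integer(1))
    if (max(gain) == 0L) break
    best <- order(-gain, c_locale_rank(pool$icar))[1L]
    chosen <- c(chosen, pool$icar[best])
    uncovered <- setdiff(uncovered, pool$covered_tissues[[best]])
    pool <- pool[-best, , drop = FALSE]
  }
  list(icars = chosen, covered = setdiff(on_set, uncovered),
       uncovered = uncovered, complete = length(uncovered) == 0L)
}
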