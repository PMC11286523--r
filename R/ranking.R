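# Vector score: each principal candidate is a point in the plane
# (surface expression, essentiality); both axes are min-max normalised over
# the candidate set and the score is the Euclidean distance from the origin,
# so "highly expressed AND essential" scores highest and Pareto order is
# preserved. Essentiality enters as -chronos (more negative Chronos = more
# essential = larger coordinate).

#' Min-max normalise the two ranking components
#'
#' Expression is normalised over the candidate set's `median_expression`;
#' essentiality over `-chronos`. A component that is constant across the set
#' carries no ranking information and is set to 0.5 for every candidate.
#'
#' @param candidates A `principal_candidates` object (non-empty, finite
#'   `chronos`).
#' @return `data.frame` with columns `gene`, `expression_norm`,
#'   `essentiality_norm`, all in \[0, 1\].
#' @export
normalize_components <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("cannot normalise an empty candidate set", call. = FALSE)
  if (any(!is.finite(candidates$chronos)))
    stop("all candidates need a finite chronos score for ranking", call. = FALSE)
  data.frame(gene = candidates$gene,
             expression_norm = minmax01(candidates$median_expression),
             essentiality_norm = minmax01(-candidates$chronos),
             stringsAsFactors = FALSE)
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Vector score of a normalised (expression, essentiality) pair
#'
#' The Euclidean norm `sqrt(e^2 + s^2)`; symmetric in its arguments, ranges
#' over \[0, sqrt(2)\].
#'
#' @param expression_norm,essentiality_norm Numeric vectors in \[0, 1\].
#' @return Numeric vector of scores.
#' @export
#' @examples
#' vector_score(0.6, 0.8) # 1, the 3-4-5 triangle
vector_score <- function(expression_norm, essentiality_norm) {
  if (any(!is.finite(expression_norm)) || any(!is.finite(essentiality_norm)) ||
      any(expression_norm < 0 | expression_norm > 1) ||
      any(essentiality_norm < 0 | essentiality_norm > 1))
    stop("vector_score inputs must lie in [0, 1]", call. = FALSE)
  sqrt(expression_norm^2 + essentiality_norm^2)
}

#' Rank principal target candidates by vector score
#'
#' Orders candidates by descending score; exact ties are broken first by more
#' negative chronos, then by gene symbol (C-locale order), so the output is
#' deterministic across runs and platforms.
#'
#' @param candidates A `principal_candidates` object.
#' @return `data.frame` of class `ranked_targets` with columns `gene`,
#'   `median_expression`, `chronos`, `expression_norm`, `essentiality_norm`,
#'   `score`, `rank` (1 = best), ordered by rank.
#' @export
rank_targets <- function(candidates) {
  norm <- normalize_components(candidates)
  score <- vector_score(norm$expression_norm, norm$essentiality_norm)
  ord <- order(-score, candidates$chronos,
               c_locale_rank(candidates$gene))
  out <- data.frame(gene = candidates$gene[ord],
                    median_expression = candidates$median_expression[ord],
                    chronos = candidates$chronos[ord],
                    expression_norm = norm$expression_norm[ord],
                    essentiality_norm = norm$essentiality_norm[ord],
                    score = score[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ranked_targets", "data.frame"))
}

# locale-independent ordering key for gene symbols
c_locale_rank <- function(x) {
  match(x, sort(x, method = "radix"))
}
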