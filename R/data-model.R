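#' Filtering configuration
#'
#' Collects every threshold and toggle of the NOT-gate pipeline in one
#' validated object. The defaults are the published working point: principal
#' targets must have median tumour surface expression strictly above 3.5 AU
#' (on the 0--5 arbitrary-unit surfaceome scale), an extracellular domain
#' strictly longer than 175 amino acids, and an aggregated Chronos dependency
#' score of -0.25 or below (more negative = more essential; the comparison is
#' inclusive, so a gene at exactly -0.25 passes).
#'
#' @param min_expression Minimum median tumour surface expression, AU in
#'   \[0, 5\]. Strict comparison: a candidate needs expression `>` this value.
#' @param min_ecd Minimum extracellular-domain length, amino acids. Strict
#'   comparison (`>`).
#' @param max_chronos Maximum (i.e. least essential) admissible Chronos score;
#'   inclusive (`<=`). Set to `Inf` to disable the essentiality filter, as
#'   recommended when probing dependency-screen false negatives.
#' @param tissue_on_threshold A healthy tissue counts as expressing a protein
#'   when its value is strictly greater than this; the default 0 means any
#'   detection counts. Must be `>= 0`.
#' @param exclude_t_cell_expressed Drop principal candidates detected in any
#'   tissue flagged as T-cell lineage (prevents CAR T-cell fratricide).
#' @param require_dependency_entry Drop principal candidates absent from the
#'   dependency table. Toggleable because dependency screens have false
#'   negatives.
#' @param use_in_vivo Enable the optional in-vivo CRISPR screen filter.
#' @param min_icar_ecd Additional minimum extracellular-domain length for iCAR
#'   candidates, amino acids (inclusive lower bound is `ecd > max(0, min_icar_ecd)`
#'   ... an iCAR always needs `ecd > 0`).
#'
#' @return An object of class `filter_config` (a validated named list).
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$max_chronos
filter_config <- function(min_expression = 3.5,
                          min_ecd = 175,
                          max_chronos = -0.25,
                          tissue_on_threshold = 0,
                          exclude_t_cell_expressed = TRUE,
                          require_dependency_entry = TRUE,
                          use_in_vivo = FALSE,
                          min_icar_ecd = 0) {
  cfg <- list(
    min_expression = as.numeric(min_expression),
    min_ecd = as.numeric(min_ecd),
    max_chronos = as.numeric(max_chronos),
    tissue_on_threshold = as.numeric(tissue_on_threshold),
    exclude_t_cell_expressed = isTRUE(exclude_t_cell_expressed),
    require_dependency_entry = isTRUE(require_dependency_entry),
    use_in_vivo = isTRUE(use_in_vivo),
    min_icar_ecd = as.numeric(min_icar_ecd)
  )
  class(cfg) <- "filter_config"
  validate_filter_config(cfg)
}

validate_filter_config <- function(cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!is.finite(cfg$min_expression) || cfg$min_expression < 0 || cfg$min_expression > 5)
    stop("min_expression must lie in [0, 5] AU", call. = FALSE)
  if (!is.finite(cfg$min_ecd) || cfg$min_ecd < 0)
    stop("min_ecd must be a non-negative number of amino acids", call. = FALSE)
  if (is.na(cfg$max_chronos))
    stop("max_chronos must be a number (or Inf to disable)", call. = FALSE)
  if (!is.finite(cfg$tissue_on_threshold) || cfg$tissue_on_threshold < 0)
    stop("tissue_on_threshold must be >= 0", call. = FALSE)
  if (!is.finite(cfg$min_icar_ecd) || cfg$min_icar_ecd < 0)
    stop("min_icar_ecd must be >= 0", call. = FALSE)
  cfg
}

#' @export
print.filter_config <- function(x, ...) {
  cat("NOT-gate filter configuration\n")
  cat(sprintf("  principal: expression > %.3g AU, ECD > %.4g aa, Chronos <= %.3g\n",
              x$min_expression, x$min_ecd, x$max_chronos))
  cat(sprintf("  tissue 'expressed' means value > %.3g\n", x$tissue_on_threshold))
  cat(sprintf("  exclude T-cell-expressed: %s | require dependency entry: %s | in-vivo filter: %s\n",
              x$exclude_t_cell_expressed, x$require_dependency_entry, x$use_in_vivo))
  if (x$min_icar_ecd > 0)
    cat(sprintf("  iCAR ECD > %.4g aa\n", x$min_icar_ecd))
  invisible(x)
}

# --- tissue expression matrix -------------------------------------------

#' Construct a tissue expression matrix
#'
#' A healthy-tissue proteome: proteins in rows, tissues in columns, values
#' are non-negative expression intensities. Missing measurements stay `NA`;
#' "not expressed" must be an observed 0, never an imputed one, otherwise a
#' tissue could be wrongly cleared during coverage analysis.
#'
#' @param values Numeric matrix, rownames = gene symbols (upper-cased),
#'   colnames = tissue labels. `NA` entries mark missing measurements.
#' @param tissue_meta `data.frame` with columns `tissue`,
#'   `is_essential_cell_type`, `is_t_cell`; one row per tissue column.
#' @return An object of class `tissue_matrix`.
#' @export
tissue_matrix <- function(values, tissue_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("tissue matrix needs row (gene) and column (tissue) names", call. = FALSE)
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein rows in tissue matrix: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("tissue expression values must be non-negative", call. = FALSE)
  meta <- as.data.frame(tissue_meta)
  req <- c("tissue", "is_essential_cell_type", "is_t_cell")
  if (!all(req %in% names(meta)))
    stop("tissue_meta must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  missing_meta <- setdiff(colnames(values), meta$tissue)
  if (length(missing_meta))
    stop("tissue column(s) without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  meta <- meta[match(colnames(values), meta$tissue), req, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, tissue_meta = meta), class = "tissue_matrix")
}

#' @export
print.tissue_matrix <- function(x, ...) {
  cat(sprintf("tissue_matrix: %d proteins x %d tissues (%d T-cell, %d essential-cell-type); %d missing values\n",
              nrow(x$values), ncol(x$values),
              sum(x$tissue_meta$is_t_cell), sum(x$tissue_meta$is_essential_cell_type),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.tissue_matrix <- function(x) dim(x$values)

#' Tissue labels of a tissue matrix
#' @param x A `tissue_matrix`.
#' @param flag Optional metadata flag (`"t_cell"` or `"essential"`); when
#'   given, only tissues carrying that flag are returned.
#' @return Character vector of tissue labels.
#' @export
tissues_of <- function(x, flag = NULL) {
  stopifnot(inherits(x, "tissue_matrix"))
  if (is.null(flag)) return(colnames(x$values))
  col <- switch(match.arg(flag, c("t_cell", "essential")),
                t_cell = "is_t_cell", essential = "is_essential_cell_type")
  colnames(x$values)[x$tissue_meta[[col]]]
}
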