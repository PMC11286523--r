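# Readers for the three (plus one optional) input tables. Gene symbols are
# the join key throughout and are case-normalised to upper case on ingest;
# no alias resolution is attempted.

#' Column-name dialect for the tumour surfaceome table
#'
#' Maps the canonical field names onto the header names actually present in
#' an input file, so published data files can be ingested without code
#' changes.
#'
#' @param gene,median_expression,ecd_length,has_defined_ecd,membrane_annotated
#'   Header names in the file. `has_defined_ecd` and `membrane_annotated` may
#'   be `NA` if the file lacks the column; the flag is then inferred
#'   (`ecd_length > 0`) or assumed `TRUE` respectively.
#' @return Named list of class `surfaceome_dialect`.
#' @export
surfaceome_dialect <- function(gene = "gene",
                               median_expression = "median_expression",
                               ecd_length = "ecd_length",
                               has_defined_ecd = "has_defined_ecd",
                               membrane_annotated = "membrane_annotated") {
  structure(list(gene = gene, median_expression = median_expression,
                 ecd_length = ecd_length, has_defined_ecd = has_defined_ecd,
                 membrane_annotated = membrane_annotated),
            class = "surfaceome_dialect")
}

#' Read a tumour surfaceome table
#'
#' One row per cell-surface protein: gene symbol, median surface expression
#' on the 0--5 AU scale, extracellular-domain (ECD) length in amino acids,
#' and annotation flags. Structural problems (missing columns, duplicate
#' genes, expression outside \[0, 5\]) are errors; rows with missing gene or
#' missing expression are rejected with row-indexed diagnostics, and the
#' reader reports input = accepted + rejected so no row is silently dropped.
#'
#' @param path TSV/CSV file (delimiter auto-detected by [data.table::fread]).
#' @param dialect A [surfaceome_dialect()] mapping canonical fields to the
#'   file's header names.
#' @return A `data.frame` of class `surfaceome` with columns `gene`,
#'   `median_expression`, `ecd_length`, `has_defined_ecd`,
#'   `membrane_annotated`, carrying a `row_report` attribute
#'   (`n_input`, `n_accepted`, `n_rejected`, `rejected` data frame).
#' @export
read_surfaceome <- function(path, dialect = surfaceome_dialect()) {
  raw <- read_table_file(path)
  need <- c("gene", "median_expression", "ecd_length")
  for (f in need)
    if (!dialect[[f]] %in% names(raw))
      stop(sprintf("surfaceome file '%s' lacks required column '%s'", path, dialect[[f]]),
           call. = FALSE)
  df <- data.frame(
    gene = toupper(as.character(raw[[dialect$gene]])),
    median_expression = as.numeric(raw[[dialect$median_expression]]),
    ecd_length = as.integer(round(as.numeric(raw[[dialect$ecd_length]]))),
    stringsAsFactors = FALSE
  )
  df$has_defined_ecd <-
    if (!is.na(dialect$has_defined_ecd) && dialect$has_defined_ecd %in% names(raw))
      as.logical(raw[[dialect$has_defined_ecd]]) else df$ecd_length > 0
  df$membrane_annotated <-
    if (!is.na(dialect$membrane_annotated) && dialect$membrane_annotated %in% names(raw))
      as.logical(raw[[dialect$membrane_annotated]]) else TRUE

  as_surfaceome(df, source = path)
}

#' Validate and classify a surfaceome data frame
#'
#' @param df Data frame with the five canonical surfaceome columns.
#' @param source Label used in diagnostics.
#' @return Validated `surfaceome` object; see [read_surfaceome()].
#' @export
as_surfaceome <- function(df, source = "<in-memory>") {
  n_input <- nrow(df)
  # hard errors: these indicate a malformed table, not a bad row
  bad_expr <- which(!is.na(df$median_expression) &
                    (df$median_expression < 0 | df$median_expression > 5))
  if (length(bad_expr))
    stop(sprintf("surfaceome '%s': expression outside [0, 5] AU at row(s) %s (gene %s)",
                 source, paste(bad_expr, collapse = ", "),
                 paste(df$gene[bad_expr], collapse = ", ")), call. = FALSE)
  dup <- unique(df$gene[duplicated(df$gene) & !is.na(df$gene)])
  if (length(dup))
    stop(sprintf("surfaceome '%s': duplicated gene symbol(s): %s",
                 source, paste(dup, collapse = ", ")), call. = FALSE)

  # soft rejects: row-level incompleteness
  reason <- rep(NA_character_, n_input)
  reason[is.na(df$gene) | df$gene == ""] <- "missing gene symbol"
  reason[is.na(reason) & is.na(df$median_expression)] <- "missing expression"
  reason[is.na(reason) & (is.na(df$ecd_length) | df$ecd_length < 0)] <- "invalid ecd_length"
  rejected <- data.frame(row = which(!is.na(reason)),
                         gene = df$gene[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- df[is.na(reason), , drop = FALSE]
  keep$has_defined_ecd[is.na(keep$has_defined_ecd)] <- keep$ecd_length[is.na(keep$has_defined_ecd)] > 0
  keep$membrane_annotated[is.na(keep$membrane_annotated)] <- FALSE
  # no defined ECD => length treated as 0
  keep$ecd_length[!keep$has_defined_ecd] <- 0L
  rownames(keep) <- NULL
  structure(keep,
            class = c("surfaceome", "data.frame"),
            row_report = list(n_input = n_input, n_accepted = nrow(keep),
                              n_rejected = nrow(rejected), rejected = rejected))
}

#' Read a healthy-tissue proteome matrix with tissue metadata
#'
#' The matrix file has the protein symbol in the first column and one column
#' per tissue; the metadata file has two columns, `tissue` and `flags`, the
#' latter a semicolon-separated list of tokens out of `essential` (essential
#' cell type) and `t_cell` (T-cell lineage). Empty cells in the matrix stay
#' `NA`: a missing measurement is not a zero.
#'
#' @param path Matrix TSV/CSV.
#' @param meta_path Metadata TSV/CSV.
#' @return A [tissue_matrix()] object.
#' @export
read_tissue_proteome <- function(path, meta_path) {
  raw <- read_table_file(path)
  if (ncol(raw) < 2)
    stop(sprintf("tissue matrix '%s' needs a protein column plus >= 1 tissue column", path),
         call. = FALSE)
  genes <- toupper(as.character(raw[[1L]]))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- which(apply(vals < 0, 1L, any, na.rm = TRUE))
    stop(sprintf("tissue matrix '%s': negative expression for %s",
                 path, paste(genes[bad], collapse = ", ")), call. = FALSE)
  }
  meta_raw <- read_table_file(meta_path)
  if (!all(c("tissue", "flags") %in% names(meta_raw)))
    stop(sprintf("tissue metadata '%s' must have columns 'tissue' and 'flags'", meta_path),
         call. = FALSE)
  flags <- strsplit(ifelse(is.na(meta_raw$flags), "", as.character(meta_raw$flags)), ";",
                    fixed = TRUE)
  meta <- data.frame(
    tissue = as.character(meta_raw$tissue),
    is_essential_cell_type = vapply(flags, function(f) "essential" %in% trimws(f), logical(1)),
    is_t_cell = vapply(flags, function(f) "t_cell" %in% trimws(f), logical(1)),
    stringsAsFactors = FALSE
  )
  tissue_matrix(vals, meta)
}

#' Aggregate per-cell-line Chronos scores to one score per gene
#'
#' A dependency screen yields one Chronos score per gene per cell line
#' (more negative = stronger loss of viability on knockout). The pipeline
#' needs one number per gene over the disease cell lines; the default
#' collapse is the median, which is robust to single outlier lines. Missing
#' per-line scores are skipped; a gene with no non-missing score over the
#' disease lines is excluded and reported in the `dropped` attribute.
#'
#' @param per_line_scores Data frame or matrix: one `gene` column (or
#'   rownames) plus one numeric column per cell line.
#' @param disease_lines Character vector of cell-line IDs to aggregate over;
#'   must be a non-empty subset of the score columns.
#' @param method `"median"` (default) or `"mean"`.
#' @return A `data.frame` of class `essentiality` with columns `gene`,
#'   `chronos`, `n_lines`, plus a `dropped` attribute listing genes with no
#'   usable score.
#' @export
aggregate_chronos <- function(per_line_scores, disease_lines, method = c("median", "mean")) {
  method <- match.arg(method)
  if (length(disease_lines) == 0)
    stop("disease_lines must contain at least one cell line", call. = FALSE)
  if (is.matrix(per_line_scores)) {
    genes <- rownames(per_line_scores)
    mat <- per_line_scores
  } else {
    df <- as.data.frame(per_line_scores)
    if (!"gene" %in% names(df))
      stop("per_line_scores needs a 'gene' column (or pass a matrix with rownames)",
           call. = FALSE)
    genes <- toupper(as.character(df$gene))
    mat <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- genes
  }
  missing_lines <- setdiff(disease_lines, colnames(mat))
  if (length(missing_lines))
    stop("disease line(s) absent from score table: ",
         paste(missing_lines, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicated gene symbol(s) in dependency table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  sub <- mat[, disease_lines, drop = FALSE]
  fun <- if (method == "median") stats::median else mean
  chronos <- apply(sub, 1L, fun, na.rm = TRUE)
  n_lines <- rowSums(!is.na(sub))
  usable <- n_lines >= 1L & is.finite(chronos)
  dropped <- genes[!usable]
  if (length(dropped))
    message(sprintf("aggregate_chronos: %d gene(s) with no usable score over %d disease line(s) excluded",
                    length(dropped), length(disease_lines)))
  out <- data.frame(gene = genes[usable], chronos = unname(chronos[usable]),
                    n_lines = as.integer(n_lines[usable]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("essentiality", "data.frame"), dropped = dropped)
}

#' Read a gene-by-cell-line dependency table
#'
#' @param path TSV/CSV: first column `gene`, remaining columns cell lines.
#' @return Numeric matrix, genes in rows (upper-cased), lines in columns.
#' @export
read_dependency <- function(path) {
  raw <- read_table_file(path)
  if (ncol(raw) < 2)
    stop(sprintf("dependency table '%s' needs a gene column plus >= 1 cell line", path),
         call. = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- toupper(as.character(raw[[1L]]))
  mat
}

#' Read an extracellular-domain catalog
#'
#' @param path TSV/CSV with columns `gene` and `ecd_length` (amino acids;
#'   0 = no catalogued extracellular domain).
#' @return Named integer vector, gene symbol -> ECD length.
#' @export
read_ecd_catalog <- function(path) {
  raw <- read_table_file(path)
  if (!all(c("gene", "ecd_length") %in% names(raw)))
    stop(sprintf("ECD catalog '%s' must have columns 'gene' and 'ecd_length'", path),
         call. = FALSE)
  g <- toupper(as.character(raw$gene))
  if (anyDuplicated(g))
    stop("duplicated gene symbol(s) in ECD catalog: ",
         paste(unique(g[duplicated(g)]), collapse = ", "), call. = FALSE)
  stats::setNames(as.integer(round(as.numeric(raw$ecd_length))), g)
}

#' Read an in-vivo CRISPR screen gene list
#'
#' @param path TSV/CSV with columns `gene`, `in_vivo_score`, `significant`.
#' @return `data.frame` with those columns, genes upper-cased and unique.
#' @export
read_invivo <- function(path) {
  raw <- read_table_file(path)
  if (!all(c("gene", "in_vivo_score", "significant") %in% names(raw)))
    stop(sprintf("in-vivo table '%s' must have columns 'gene', 'in_vivo_score', 'significant'",
                 path), call. = FALSE)
  out <- data.frame(gene = toupper(as.character(raw$gene)),
                    in_vivo_score = as.numeric(raw$in_vivo_score),
                    significant = as.logical(raw$significant),
                    stringsAsFactors = FALSE)
  dup <- unique(out$gene[duplicated(out$gene)])
  if (length(dup))
    stop("duplicated gene symbol(s) in in-vivo table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  out
}

# fread wrapper: delimiter auto-detection, blank cells -> NA, never factors
read_table_file <- function(path) {
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  as.data.frame(data.table::fread(path, na.strings = c("", "NA", "NaN"),
                                  data.table = FALSE, showProgress = FALSE))
}
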