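# Pipeline orchestration: simulate -> read -> aggregate -> filter -> rank ->
# partners -> combos, driven by one YAML config, with a run manifest
# (config snapshot, input/output checksums, per-stage row accounting).
# Outputs are plain TSV/JSON with fixed column order; identical config and
# inputs give bit-identical tables.

#' Run the full NOT-gate discovery pipeline
#'
#' Config schema (YAML):
#' \preformatted{
#' fixture:            # optional: generate inputs first
#'   seed: 1
#'   dir: fixtures/
#' io:                 # required unless 'fixture' is given
#'   surfaceome: path.tsv
#'   tissue_matrix: path.tsv
#'   tissue_meta: path.tsv
#'   dependency: path.tsv
#'   disease_lines: path.tsv   # one 'line' column; default: all columns
#'   ecd_catalog: path.tsv
#'   invivo: path.tsv          # optional
#' filter:             # any filter_config() field, e.g. min_expression: 3.5
#' aggregate:
#'   method: median
#' query:              # optional principal for partner search
#'   principal: TFRC
#'   min_icar_ecd: 0
#' output:
#'   dir: out/
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @return The run manifest (list, invisibly written to
#'   `output$dir/manifest.json`): tool version, config snapshot, input
#'   checksums, per-stage row counts, output files with checksums.
#' @export
run_pipeline <- function(config) {
  cfgl <- if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    yaml::read_yaml(config)
  } else config

  if (!is.null(cfgl$fixture)) {
    spec_args <- cfgl$fixture[setdiff(names(cfgl$fixture), "dir")]
    bundle <- generate_fixture(do.call(fixture_spec, spec_args))
    paths <- write_fixture(bundle, cfgl$fixture$dir %||% "fixtures")
    cfgl$io <- utils::modifyList(cfgl$io %||% list(),
                                 as.list(paths[setdiff(names(paths), "truth")]))
  }
  io <- cfgl$io
  req <- c("surfaceome", "tissue_matrix", "tissue_meta", "dependency", "ecd_catalog")
  for (f in req) {
    if (is.null(io[[f]]))
      stop(sprintf("config is missing io.%s", f), call. = FALSE)
    if (!file.exists(io[[f]]))
      stop(sprintf("io.%s: input file not found: '%s'", f, io[[f]]), call. = FALSE)
  }

  fcfg <- do.call(filter_config, cfgl$filter %||% list())
  outdir <- cfgl$output$dir %||% "notgate_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  surf <- stage("read_surfaceome", read_surfaceome(io$surfaceome))
  tiss <- stage("read_tissue_proteome",
                read_tissue_proteome(io$tissue_matrix, io$tissue_meta))
  dep <- stage("read_dependency", read_dependency(io$dependency))
  lines <- if (!is.null(io$disease_lines))
    as.character(read_table_file(io$disease_lines)[[1L]]) else colnames(dep)
  ess <- stage("aggregate_chronos",
               aggregate_chronos(dep, lines,
                                 method = cfgl$aggregate$method %||% "median"))
  ecd_cat <- stage("read_ecd_catalog", read_ecd_catalog(io$ecd_catalog))

  principals <- stage("filter_principal",
                      filter_principal(surf, ess, tiss, fcfg, explain = TRUE))
  if (fcfg$use_in_vivo) {
    if (is.null(io$invivo))
      stop("stage 'in_vivo_filter' failed: use_in_vivo is set but io.invivo is missing",
           call. = FALSE)
    principals <- stage("in_vivo_filter",
                        apply_in_vivo_filter(principals, read_invivo(io$invivo)))
  }
  icars <- stage("filter_icar", filter_icar(tiss, surf, ecd_cat, fcfg))
  ranked <- if (nrow(principals) > 0) stage("rank_targets", rank_targets(principals))
            else NULL

  counts <- list(
    surfaceome = attr(surf, "row_report")[c("n_input", "n_accepted", "n_rejected")],
    principals = list(n_input = nrow(surf), n_accepted = nrow(principals),
                      n_rejected = nrow(surf) - nrow(principals)),
    icars = list(n_input = nrow(tiss$values), n_accepted = nrow(icars),
                 n_rejected = nrow(tiss$values) - nrow(icars)))

  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path)
    outputs[[name]] <<- path
  }
  emit(as.data.frame(principals), "principals.tsv")
  emit(attr(principals, "rejected") %||%
         data.frame(gene = character(), first_failed_rule = character()),
       "rejected.tsv")
  emit(as.data.frame(icars), "icars.tsv")
  if (!is.null(ranked)) emit(round_numeric(as.data.frame(ranked)), "ranked.tsv")

  n_feas <- NA_integer_
  if (!is.null(cfgl$query$principal)) {
    pairs <- stage("find_icar_partners",
                   find_icar_partners(cfgl$query$principal, icars, tiss, fcfg,
                                      min_icar_ecd = cfgl$query$min_icar_ecd %||% 0))
    n_feas <- sum(pairs$feasible)
    emit(round_numeric(flatten_pairs(pairs)), "pairs.tsv")
    heat <- stage("partner_heatmap_table",
                  partner_heatmap_table(pairs, tiss,
                    stats::setNames(surf$median_expression, surf$gene)))
    emit(heat, "heatmap.tsv")
  }
  combos <- count_combinations(principals, icars, n_feasible_for_query = n_feas)
  combos_path <- file.path(outdir, "combos.json")
  jsonlite::write_json(unclass(combos), combos_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  outputs[["combos.json"]] <- combos_path

  manifest <- list(
    tool = "notgate",
    version = as.character(utils::packageVersion("notgate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfgl,
    inputs = lapply(io[!vapply(io, is.null, logical(1))],
                    function(pth) list(path = pth,
                                       md5 = unname(tools::md5sum(pth)))),
    stage_counts = counts,
    combinations = unclass(combos),
    outputs = lapply(names(outputs), function(nm)
      list(file = nm, stage = sub("\\..*$", "", nm), path = unname(outputs[[nm]]),
           md5 = unname(tools::md5sum(outputs[[nm]])))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(manifest)
}

# pairs table without list-columns, for TSV export
flatten_pairs <- function(pairs) {
  out <- as.data.frame(pairs)[, c("principal", "icar", "icar_ecd", "n_covered",
                                  "n_uncovered", "coverage", "feasible")]
  out$uncovered_tissues <- vapply(pairs$uncovered_tissues, paste, character(1),
                                  collapse = ";")
  out
}

# fixed float formatting for bit-stable outputs
round_numeric <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Export a candidate table ordered by name or ECD size
#'
#' @param candidates A `principal_candidates`, `icar_candidates` or any data
#'   frame with `gene` and (for `"ecd"`) an ECD column (`ecd_length` or
#'   `icar_ecd`).
#' @param ordering `"name"` (ascending gene symbol) or `"ecd"` (descending
#'   ECD length, gene symbol breaking ties).
#' @param path Optional TSV output path.
#' @return The reordered data frame (invisibly when `path` is given).
#' @export
export_candidate_table <- function(candidates, ordering = c("name", "ecd"),
                                   path = NULL) {
  ordering <- match.arg(ordering)
  df <- as.data.frame(candidates)
  if (ordering == "name") {
    df <- df[order(c_locale_rank(df$gene)), , drop = FALSE]
  } else {
    ecd_col <- intersect(c("ecd_length", "icar_ecd"), names(df))[1L]
    if (is.na(ecd_col))
      stop("no ECD column found for ordering = 'ecd'", call. = FALSE)
    df <- df[order(-df[[ecd_col]], c_locale_rank(df$gene)), , drop = FALSE]
  }
  rownames(df) <- NULL
  if (!is.null(path)) {
    write_tsv(df, path)
    return(invisible(df))
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
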