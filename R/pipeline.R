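#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Network inputs (`ppi`,
#' `gene_sets`) may be `NULL`, in which case the network stage is skipped
#' and the cohort-side tables are still produced.
#'
#' @param cohort path to the cohort CSV (required).
#' @param ppi path to the interactome edge list, or `NULL`.
#' @param gene_sets path to the GMT file with herb target and symptom gene
#'   sets, or `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param herb_name name of the herb target set inside the GMT.
#' @param disease_label diagnosis string defining the case group.
#' @param top_k how many most frequent symptoms to select (>= 1).
#' @param directed use the one-directional closest distance.
#' @param yates apply the continuity correction to chi-square tests.
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when inputs were generated).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort, ppi = NULL, gene_sets = NULL,
                            out_dir = "results", herb_name = NULL,
                            disease_label = "LUAD", top_k = 5L,
                            directed = FALSE, yates = FALSE, seed = 1L) {
  if (top_k < 1L) stop_input("top_k must be >= 1")
  structure(list(cohort = cohort, ppi = ppi, gene_sets = gene_sets,
                 out_dir = out_dir, herb_name = herb_name,
                 disease_label = disease_label, top_k = as.integer(top_k),
                 directed = isTRUE(directed), yates = isTRUE(yates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (a named
#' list, e.g. parsed command-line flags) take precedence over file values.
#'
#' @param path path to a YAML file.
#' @param overrides named list of values overriding the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  keep <- intersect(names(cfg), names(formals(pipeline_config)))
  do.call(pipeline_config, cfg[keep])
}

#' Run the full herb-symptom analysis
#'
#' Executes, in order: usage-by-diagnosis contingency table with
#' chi-square; per-symptom admission comparison between usage arms
#' (chi-square per symptom); symptom improvement table with ratios;
#' top-k selection of the most frequent relief-tracked admission symptoms
#' in the used group; overlap of the herb target set with the union of the
#' selected symptoms' gene sets; and separation scores of the herb against
#' every symptom gene set. Tables are written to `config$out_dir` via
#' [write_results()] together with a JSON manifest echoing the
#' configuration, package version, warnings and row counts; identical
#' config and inputs yield an identical bundle.
#'
#' When `config$ppi` or `config$gene_sets` is `NULL`, the network stage is
#' marked `"skipped"` and only cohort tables are produced.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the computed tables (`usage`,
#'   `usage_test`, `admission_comparison`, `improvement`, `top_symptoms`,
#'   `overlap`, `separation`), the `manifest`, and the written-file
#'   manifest `files`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  cohort <- read_cohort_csv(config$cohort)
  rep <- attr(cohort, "load_report")
  if (rep$n_repaired > 0L) {
    note(rep$n_repaired, " cohort record(s) repaired (relieved set ",
         "intersected with admission set)")
  }

  ## -- cohort stage ---------------------------------------------------
  usage <- build_usage_table(cohort, config$disease_label)
  usage_test <- chi_square_test(usage, yates = config$yates)
  usage_tab <- data.frame(
    group = rownames(usage),
    used = usage[, "yes"], unused = usage[, "no"],
    used_pct = round(100 * usage[, "yes"] / rowSums(usage)),
    row.names = NULL, stringsAsFactors = FALSE)
  usage_tab$chisq_p <- c(usage_test$p, NA)

  case <- cohort[cohort$diagnosis == config$disease_label, , drop = FALSE]
  all_symptoms <- sort(unique(unlist(case$admission_symptoms)))
  admission_cmp <- NULL
  if (length(all_symptoms)) {
    used_n <- sum(case$used_herb)
    unused_n <- sum(!case$used_herb)
    up <- symptom_presence_counts(case$admission_symptoms[case$used_herb],
                                  all_symptoms)
    np <- symptom_presence_counts(case$admission_symptoms[!case$used_herb],
                                  all_symptoms)
    pvals <- vapply(all_symptoms, function(s) {
      tab <- matrix(c(up[[s]], used_n - up[[s]],
                      np[[s]], unused_n - np[[s]]), nrow = 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        return(NA_real_)
      }
      chi_square_test(tab, yates = config$yates)$p
    }, 0)
    admission_cmp <- data.frame(
      symptom = all_symptoms,
      used_present = unname(up), used_absent = used_n - unname(up),
      unused_present = unname(np), unused_absent = unused_n - unname(np),
      chisq_p = unname(pvals), stringsAsFactors = FALSE)
    admission_cmp <- admission_cmp[order(-admission_cmp$used_present,
                                         admission_cmp$symptom), ]
    rownames(admission_cmp) <- NULL
  }

  improvement <- if (length(all_symptoms)) {
    build_improvement_table(case, all_symptoms)
  } else NULL

  top <- rank_admission_symptoms(case, group = "used", k = config$top_k,
                                 relieved_only = TRUE)

  ## -- network stage --------------------------------------------------
  network_status <- "skipped"
  overlap_tab <- NULL
  sep_tab <- NULL
  if (!is.null(config$ppi) && !is.null(config$gene_sets)) {
    graph <- read_ppi_edgelist(config$ppi)
    sets <- read_gene_sets_gmt(config$gene_sets)
    herb_name <- config$herb_name
    if (is.null(herb_name) || !herb_name %in% names(sets)) {
      stop_input("herb set '", herb_name %||% "<unset>",
                 "' not found in GMT; available: ",
                 paste(names(sets), collapse = ", "))
    }
    herb <- sets[[herb_name]]
    symptom_sets <- sets[setdiff(names(sets), herb_name)]

    selected <- intersect(tolower(names(symptom_sets)), top$symptom)
    selected_sets <- symptom_sets[tolower(names(symptom_sets)) %in% selected]
    ov <- if (length(selected_sets)) {
      overlap_genes(herb, selected_sets)
    } else character(0)
    overlap_tab <- data.frame(gene = ov, stringsAsFactors = FALSE)

    results <- batch_separation(graph, herb, symptom_sets,
                                directed = config$directed)
    sep_tab <- separation_table(results)
    n_undef <- sum(sep_tab$status == "undefined")
    if (n_undef > 0L) {
      note(n_undef, " separation pair(s) undefined (unmapped or ",
           "unreachable gene sets)")
    }
    network_status <- "ok"
  } else {
    note("network stage skipped: interactome and/or gene sets not provided")
  }

  tables <- list(usage = usage_tab)
  if (!is.null(admission_cmp)) tables$admission_comparison <- admission_cmp
  if (!is.null(improvement)) tables$improvement <- improvement
  tables$top_symptoms <- top
  if (!is.null(overlap_tab)) tables$overlap_genes <- overlap_tab
  if (!is.null(sep_tab)) tables$separation <- sep_tab

  files <- write_results(tables, config$out_dir)
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("herbnetsep")),
    network_stage = network_status,
    warnings = warnings_log,
    tables = stats::setNames(as.list(files$n_rows), files$table))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(list(usage = usage, usage_test = usage_test,
                 admission_comparison = admission_cmp,
                 improvement = improvement, top_symptoms = top,
                 overlap = overlap_tab, separation = sep_tab,
                 manifest = manifest, files = files))
}
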