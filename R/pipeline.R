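# High-level workflow functions composing the modules into the standard
# QC and enrichment pipelines, with per-step logging and artifact output.
# These back the command-line wrapper in inst/cli/healthqc.R.

#' Assemble a run configuration
#'
#' @param input path to the input CSV/TSV dataset.
#' @param id_column record-identifier column name.
#' @param out output directory.
#' @param format `"csv"` or `"tsv"`.
#' @param na_token string read as missing on import.
#' @param metadata optional path to a variable-metadata YAML file (per
#'   variable: `type`, `modality`, `ordinal_levels`; plus a global
#'   `missing_encodings` list) or an equivalent list.
#' @param missing_encodings tokens standardised to missing (overrides the
#'   YAML's global list when given).
#' @param rules optional consistency-rule CSV path.
#' @param ontology,mapping,labels optional ontology edge / variable
#'   mapping / label CSV paths for enrichment.
#' @param k node-IC weighting for enrichment.
#' @param normalise min-max normalise constituents before aggregation?
#' @param seed RNG seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(input, id_column, out, format = "csv",
                       na_token = "NA", metadata = NULL,
                       missing_encodings = NULL, rules = NULL,
                       ontology = NULL, mapping = NULL, labels = NULL,
                       k = 0.5, normalise = TRUE, seed = 1) {
  structure(
    list(input = input, id_column = id_column, out = out, format = format,
         na_token = na_token, metadata = metadata,
         missing_encodings = missing_encodings, rules = rules,
         ontology = ontology, mapping = mapping, labels = labels,
         k = k, normalise = normalise, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path with keys matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

load_metadata_config <- function(metadata) {
  if (is.null(metadata)) return(list(overrides = list(),
                                     missing_encodings = NULL))
  cfg <- if (is.character(metadata)) yaml::read_yaml(metadata) else metadata
  enc <- cfg$missing_encodings
  cfg$missing_encodings <- NULL
  overrides <- lapply(cfg, function(e) {
    list(vtype = e$type, modality = e$modality,
         ordinal_levels = e$ordinal_levels)
  })
  list(overrides = overrides, missing_encodings = enc)
}

log_step <- function(log, step, detail) {
  line <- sprintf("%s: %s", step, detail)
  message(line)
  c(log, line)
}

#' Run the quality-control workflow
#'
#' Import, semantic characterisation (inference plus user overrides),
#' missing-value standardisation, completeness assessment, zero-entropy
#' removal, internal-consistency checking, free-text extraction, numeric
#' encoding (ordinal, binary, one-hot, frequency) with a mapping reference
#' table, an all-numeric assertion, and a quality review comparing the
#' dataset before and after. Artifacts written to `config$out`:
#' `cleaned.csv`, `mapping_table.csv`, `completeness.csv`,
#' `inconsistencies.csv`, `quality_report.md`, `run_log.txt`.
#'
#' @param config a [run_config()]; `metadata` supplies type overrides
#'   (notably ordinal level orders and `type: frequency` for
#'   frequency-encoded variables).
#' @return invisibly, a list with the cleaned `table`, the `before`
#'   table, `mapping`, `inconsistencies`, `zero_entropy`, and `log`.
#' @export
run_qc <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)

  tab <- import_dataset(config$input, config$format, config$id_column,
                        config$na_token)
  log <- log_step(log, "import", sprintf("%d records, %d variables",
                                         nrow(tab$data),
                                         length(variables(tab))))

  md <- load_metadata_config(config$metadata)
  enc <- config$missing_encodings
  if (is.null(enc)) enc <- md$missing_encodings
  if (is.null(enc)) enc <- default_missing_encodings()

  std <- standardise_missing(tab, enc)
  tab <- std$table
  log <- log_step(log, "standardise_missing",
                  sprintf("%d cells converted to missing", std$n_altered))
  before <- tab  # post-standardisation baseline for review

  meta <- infer_variable_types(tab)
  freq_vars <- names(md$overrides)[vapply(md$overrides, function(o)
    identical(o$vtype, "frequency"), logical(1))]
  type_overrides <- md$overrides[setdiff(names(md$overrides), freq_vars)]
  meta <- apply_user_review(meta, type_overrides, tab)
  tab <- set_variable_meta(tab, meta)
  log <- log_step(log, "characterise",
                  sprintf("%d variables typed (%d user overrides)",
                          length(variables(tab)), length(type_overrides)))

  comp <- assess_completeness(tab)
  utils::write.csv(
    data.frame(variable = names(comp$variable_completeness),
               completeness = as.numeric(comp$variable_completeness)),
    file.path(config$out, "completeness.csv"), row.names = FALSE)
  log <- log_step(log, "completeness",
                  sprintf("mean variable completeness %.1f%%",
                          100 * mean(comp$variable_completeness)))

  ze <- zero_entropy_variables(tab)
  if (length(ze)) tab <- ht_drop(tab, ze)
  log <- log_step(log, "zero_entropy",
                  sprintf("%d variable(s) removed", length(ze)))

  findings <- NULL
  if (!is.null(config$rules)) {
    rules <- if (is.character(config$rules))
      read_consistency_rules(config$rules) else config$rules
    findings <- identify_inconsistency(tab, rules)
    utils::write.csv(findings,
                     file.path(config$out, "inconsistencies.csv"),
                     row.names = FALSE)
    log <- log_step(log, "consistency",
                    sprintf("%d inconsistent (record, rule) pair(s)",
                            nrow(findings)))
  }

  ft_vars <- variables(tab)[vapply(variables(tab), function(v)
    identical(tab$meta[[v]]$vtype, "free_text"), logical(1))]
  for (v in ft_vars) {
    nv0 <- length(variables(tab))
    tab <- extract_freetext(tab, v)
    tab <- ht_drop(tab, v)
    log <- log_step(log, "free_text",
                    sprintf("'%s' -> %d indicator variable(s)",
                            v, length(variables(tab)) - nv0 + 1))
  }

  mapping <- empty_mapping()
  for (v in variables(tab)) {
    m <- tab$meta[[v]]
    if (v %in% freq_vars) {
      res <- encode_by_frequency(tab, v)
      tab <- res$table
      mapping <- rbind(mapping, res$mapping)
    } else if (identical(m$vtype, "ordinal")) {
      res <- encode_ordinal(tab, v, m$ordinal_levels)
      tab <- res$table
      mapping <- rbind(mapping, res$mapping)
    } else if (identical(m$vtype, "nominal_binary")) {
      col <- tab$data[[v]]
      labs <- sort(unique(col[!is.na(col)]))
      if (all_numeric_values(col)) next
      tab <- encode_binary(tab, v, labs[length(labs)])
      mapping <- rbind(mapping,
                       mapping_rows(v, labs,
                                    seq_along(labs) - 1L))
    } else if (identical(m$vtype, "nominal_multi")) {
      tab <- encode_onehot(tab, v)
    }
  }
  utils::write.csv(mapping, file.path(config$out, "mapping_table.csv"),
                   row.names = FALSE)
  log <- log_step(log, "encode",
                  sprintf("%d variables after encoding; %d mapping rows",
                          length(variables(tab)), nrow(mapping)))

  offenders <- assert_all_numeric(tab)
  if (length(offenders)) {
    stop(sprintf("non-numeric variable(s) after QC: %s",
                 paste(offenders, collapse = ", ")), call. = FALSE)
  }
  log <- log_step(log, "assert_all_numeric", "pass")

  export_dataset(tab, file.path(config$out, "cleaned.csv"), "csv")
  write_quality_report(before, tab,
                       file.path(config$out, "quality_report.md"),
                       inconsistencies = findings, zero_entropy = ze)
  writeLines(log, file.path(config$out, "run_log.txt"))
  invisible(list(table = tab, before = before, mapping = mapping,
                 inconsistencies = findings, zero_entropy = ze,
                 log = log))
}

#' Run the semantic-enrichment workflow
#'
#' Loads the ontology and variable mappings, enriches the (numeric) input
#' table with meta-variables, and writes the enriched table plus the
#' enrichment report and redundancy audit to `config$out`.
#'
#' @param config a [run_config()] with `ontology` and `mapping` set.
#' @return invisibly, a list with the enriched `table` and the `report`.
#' @export
run_enrichment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ontology) || is.null(config$mapping)) {
    stop("enrichment requires `ontology` and `mapping` paths",
         call. = FALSE)
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  tab <- import_dataset(config$input, config$format, config$id_column,
                        config$na_token)
  g <- load_ontology_edges(config$ontology, labels = config$labels)
  g <- attach_variable_mappings(g, config$mapping)
  res <- semantic_enrichment(tab, g, k = config$k,
                             normalise = config$normalise)
  export_dataset(res$table, file.path(config$out, "enriched.csv"), "csv")
  write_enrichment_report(res$report, config$out)
  message(sprintf(
    "enrichment: %d sets, %d candidates - %d zero-entropy = %d appended",
    res$report$n_sets, res$report$n_candidates, res$report$n_dropped,
    res$report$n_appended))
  if (res$report$n_sets == 0) {
    message("no variable sets share a common ancestor; nothing appended")
  }
  invisible(res)
}
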