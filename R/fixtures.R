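# Deterministic generators of synthetic cohorts, toy ontologies and
# planted-defect datasets. Every defect planted (missing-value tokens,
# internal inconsistencies, constant variables) is recorded in a ground
# truth ledger so recovery can be asserted exactly. The generators are pure
# functions of their spec: a fixed seed yields byte-identical output.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Bundled lymph-node staging consistency rules
#'
#' Two semantic dependencies between tumour staging variables:
#' the number of positive lymph nodes cannot exceed the number examined
#' (operator rule), and an N stage of N2 requires at least four positive
#' nodes (boundary rule, inclusive range 4:99).
#'
#' @return list of two [consistency_rule()] objects.
#' @export
lymph_node_rules <- function() {
  list(
    consistency_rule("nodes_positive", "nodes_examined",
                     logical_test = "<="),
    consistency_rule("n_stage", "nodes_positive",
                     variable_a_boundaries = "N2",
                     variable_b_boundaries = "4:99")
  )
}

#' Write consistency rules to the CSV schema
#'
#' @param rules list of [consistency_rule()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_consistency_rules <- function(rules, path) {
  fmt_bound <- function(b) {
    if (is.null(b)) return("")
    if (b$kind == "range") paste0(b$lo, ":", b$hi)
    else paste(b$values, collapse = ";")
  }
  df <- do.call(rbind, lapply(rules, function(r) {
    data.frame(
      variable_a = r$variable_a, variable_b = r$variable_b,
      logical_test = ifelse(is.na(r$logical_test), "", r$logical_test),
      variable_a_boundaries = fmt_bound(r$variable_a_boundaries),
      variable_b_boundaries = fmt_bound(r$variable_b_boundaries),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

default_missing_encodings <- function() {
  c("NA", "N/A", "unknown", "Unknown", "missing", "", "-1", "999")
}

#' Specification of a synthetic multimodal cohort
#'
#' The defaults emulate the structure of a mid-2000s multimodal colorectal
#' cancer cohort: 661 patients and 155 variables across four modalities
#' (clinical pathology including lymph-node staging, epidemiology with one
#' free-text family-history field, a panel of 19 three-level mutation
#' variables, treatment and outcomes), 8 distinct missing-value encodings,
#' modality-aligned block missingness plus uniform noise, 40 planted
#' internal inconsistencies against the bundled lymph-node rules, and 4
#' constant (zero-entropy) variables.
#'
#' @param n_records number of patient records (default 661).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @param modalities named list: per modality, counts per variable kind
#'   (`continuous`, `integer`, `binary`, `nominal`, `mutation`,
#'   `free_text`).
#' @param missing_rate named numeric: per-modality uniform missingness
#'   rate applied to eligible cells (default 0.04 each).
#' @param block_missing_fraction fraction of records covered by each
#'   modality's rectangular missingness block (default 0.12).
#' @param missing_encodings tokens planted to represent missing values
#'   (default 8 encodings).
#' @param n_planted_inconsistencies violations planted against
#'   [lymph_node_rules()] (default 40).
#' @param constant_variable_count number of constant variables appended
#'   (default 4).
#' @param freetext_present_rate fraction of records with free text
#'   (default 0.21).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_records = 661, seed = 1,
                        modalities = NULL,
                        missing_rate = NULL,
                        block_missing_fraction = 0.12,
                        missing_encodings = default_missing_encodings(),
                        n_planted_inconsistencies = 40,
                        constant_variable_count = 4,
                        freetext_present_rate = 0.21) {
  if (is.null(modalities)) {
    modalities <- list(
      clinical_pathology = c(continuous = 12, integer = 8, binary = 24,
                             nominal = 5),
      epidemiology = c(continuous = 6, integer = 4, binary = 20,
                       nominal = 6, free_text = 1),
      mutation = c(mutation = 19),
      treatment_outcomes = c(continuous = 8, integer = 6, binary = 24,
                             nominal = 4)
    )
  }
  if (is.null(missing_rate)) {
    missing_rate <- stats::setNames(rep(0.04, length(modalities)),
                                    names(modalities))
  }
  stopifnot(all(missing_rate >= 0 & missing_rate <= 1),
            block_missing_fraction >= 0, block_missing_fraction <= 1,
            freetext_present_rate >= 0, freetext_present_rate <= 1)
  structure(
    list(n_records = n_records, seed = seed, modalities = modalities,
         missing_rate = missing_rate,
         block_missing_fraction = block_missing_fraction,
         missing_encodings = missing_encodings,
         n_planted_inconsistencies = n_planted_inconsistencies,
         constant_variable_count = constant_variable_count,
         freetext_present_rate = freetext_present_rate),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort with a ground-truth defect ledger
#'
#' Builds a raw (pre-QC, all-string) patient table per the spec: clean
#' consistent values first, then modality-aligned block missingness (true
#' missing markers), uniform missingness planted as encoding tokens,
#' internal inconsistencies against [lymph_node_rules()], and constant
#' variables. The ledger records every planted defect:
#' `missing_tokens` (one row per token cell; equals the cell count
#' [standardise_missing()] will alter), `inconsistencies` (the exact
#' (record, rule) pairs [identify_inconsistency()] must return),
#' `constant_variables`, and `encoding_plan` (ordinal level orders and the
#' frequency-encoded mutation panel, for downstream QC).
#'
#' @param spec a [cohort_spec()].
#' @return list with `table` (a [health_table()]) and `ledger`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_records
  ids <- sprintf("p%04d", seq_len(n))
  df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  meta <- list(patient_id = variable_meta("patient_id", "identifier"))
  modality_vars <- list()
  add_col <- function(name, values, modality) {
    df[[name]] <<- as.character(values)
    meta[[name]] <<- variable_meta(name, modality = modality)
    modality_vars[[modality]] <<- c(modality_vars[[modality]], name)
  }

  # lymph-node staging trio (clinical pathology), internally consistent
  nodes_examined <- sample(8:40, n, replace = TRUE)
  nodes_positive <- stats::rbinom(n, nodes_examined, 0.12)
  n_stage <- ifelse(nodes_positive == 0, "N0",
                    ifelse(nodes_positive <= 3, "N1", "N2"))
  add_col("nodes_examined", nodes_examined, "clinical_pathology")
  add_col("nodes_positive", nodes_positive, "clinical_pathology")
  add_col("n_stage", n_stage, "clinical_pathology")
  add_col("tumour_grade",
          sample(c("low", "moderate", "high"), n, TRUE,
                 prob = c(0.3, 0.5, 0.2)),
          "clinical_pathology")

  subjects <- c("mother", "father", "brother", "sister", "aunt")
  cancers <- c("breast", "lung", "colon", "skin", "stomach")
  for (mod in names(spec$modalities)) {
    counts <- spec$modalities[[mod]]
    for (kind in names(counts)) {
      for (i in seq_len(counts[[kind]])) {
        nm <- sprintf("%s_%s%02d", mod, kind, i)
        vals <- switch(kind,
          continuous = formatC(round(stats::runif(n, 1, 100), 2),
                               format = "fg"),
          integer = sample(0:500, n, replace = TRUE),
          binary = sample(c("yes", "no"), n, replace = TRUE,
                          prob = c(0.35, 0.65)),
          nominal = {
            k <- sample(3:5, 1)
            sample(paste0("lvl", LETTERS[seq_len(k)]), n, replace = TRUE)
          },
          mutation = sample(c("WT", "Het", "Hom"), n, replace = TRUE,
                            prob = c(0.72, 0.2, 0.08)),
          free_text = {
            has <- stats::runif(n) < spec$freetext_present_rate
            txt <- rep(NA_character_, n)
            nclause <- sample(1:2, sum(has), replace = TRUE)
            txt[has] <- vapply(nclause, function(k) {
              paste(paste(sample(subjects, k), sample(cancers, k),
                          "cancer"), collapse = " and ")
            }, character(1))
            txt
          },
          stop(sprintf("unknown variable kind '%s'", kind))
        )
        add_col(nm, vals, mod)
      }
    }
  }

  for (i in seq_len(spec$constant_variable_count)) {
    add_col(sprintf("const%02d", i), rep("0", n), "administrative")
  }

  staging <- c("nodes_examined", "nodes_positive", "n_stage")
  freetext_vars <- names(df)[vapply(names(df), function(v)
    !is.null(meta[[v]]) && grepl("free_text", v), logical(1))]
  constant_vars <- grep("^const", names(df), value = TRUE)

  # modality-aligned block missingness (true missing markers)
  block_cells <- 0L
  for (mod in names(spec$modalities)) {
    vars <- setdiff(modality_vars[[mod]],
                    c(staging, freetext_vars, constant_vars))
    if (length(vars) < 2 || spec$block_missing_fraction == 0) next
    bvars <- sort(sample(vars, max(2, floor(length(vars) / 2))))
    h <- max(1, floor(n * spec$block_missing_fraction))
    r0 <- sample(seq_len(max(1, n - h + 1)), 1)
    rows <- r0:(r0 + h - 1)
    for (v in bvars) df[[v]][rows] <- NA_character_
    block_cells <- block_cells + length(rows) * length(bvars)
  }

  # uniform missingness planted as encoding tokens (strings), logged
  tok_rec <- character(0); tok_var <- character(0); tok_val <- character(0)
  enc <- as.character(spec$missing_encodings)
  for (mod in names(spec$modalities)) {
    rate <- spec$missing_rate[[mod]]
    if (is.null(rate) || rate == 0) next
    vars <- setdiff(modality_vars[[mod]],
                    c(staging, freetext_vars, constant_vars))
    for (v in vars) {
      eligible <- which(!is.na(df[[v]]))
      k <- stats::rbinom(1, length(eligible), rate)
      if (!k) next
      cells <- sample(eligible, k)
      toks <- sample(enc, k, replace = TRUE)
      df[[v]][cells] <- toks
      tok_rec <- c(tok_rec, ids[cells])
      tok_var <- c(tok_var, rep(v, k))
      tok_val <- c(tok_val, toks)
    }
  }

  # planted inconsistencies against the bundled lymph-node rules
  k_inc <- spec$n_planted_inconsistencies
  inc <- data.frame(record_id = character(0), rule = integer(0),
                    stringsAsFactors = FALSE)
  if (k_inc > 0) {
    if (k_inc > n) stop("more planted inconsistencies than records",
                        call. = FALSE)
    recs <- sample(seq_len(n), k_inc)
    rule_of <- rep(c(1L, 2L), length.out = k_inc)
    for (j in seq_len(k_inc)) {
      r <- recs[j]
      if (rule_of[j] == 1L) {
        # positive nodes exceed examined; N stage stays consistent
        df$nodes_examined[r] <- "10"
        df$nodes_positive[r] <- "15"
        df$n_stage[r] <- "N2"
      } else {
        # N2 with too few positive nodes; operator rule stays satisfied
        df$nodes_examined[r] <- "20"
        df$nodes_positive[r] <- as.character(sample(1:3, 1))
        df$n_stage[r] <- "N2"
      }
    }
    inc <- data.frame(record_id = ids[recs], rule = rule_of,
                      stringsAsFactors = FALSE)
    inc <- inc[order(inc$record_id), , drop = FALSE]
    rownames(inc) <- NULL
  }

  table <- health_table(df, "patient_id", meta)
  ledger <- list(
    missing_tokens = data.frame(record_id = tok_rec, variable = tok_var,
                                token = tok_val, stringsAsFactors = FALSE),
    block_missing_cells = block_cells,
    inconsistencies = inc,
    constant_variables = constant_vars,
    rules = lymph_node_rules(),
    encoding_plan = list(
      ordinal = list(
        n_stage = c("N0", "N1", "N2"),
        tumour_grade = c("low", "moderate", "high")
      ),
      frequency = modality_vars[["mutation"]]
    ),
    modalities = modality_vars
  )
  list(table = table, ledger = ledger)
}

#' Generate a toy ontology with mapped variables
#'
#' Builds a deterministic rooted tree over `n_nodes` nodes (heap-shaped:
#' node `i`'s parent is node `floor(i/2)`), optionally augmented with
#' extra child-to-ancestor edges to form a DAG. The five-node tree is the
#' canonical toy used throughout the documentation: R -> A, B and
#' A -> C, D, with variables v1 -> C and v2 -> D. Variables are mapped to
#' leaves (deepest first) or, with `map_to = "any"`, to random non-root
#' nodes.
#'
#' @param shape `"tree"` or `"dag"`.
#' @param n_nodes number of ontology nodes (>= 3).
#' @param n_variables number of mapped variables.
#' @param seed RNG seed (used for DAG augmentation and random mapping).
#' @param map_to `"leaves"` (deterministic) or `"any"` (random).
#' @return list with data.frames `edges` (child, parent), `mappings`
#'   (variable, entity_id) and `labels` (id, label).
#' @export
generate_toy_ontology <- function(shape = c("tree", "dag"), n_nodes = 5,
                                  n_variables = 2, seed = 1,
                                  map_to = c("leaves", "any")) {
  shape <- match.arg(shape)
  map_to <- match.arg(map_to)
  if (n_nodes < 3) stop("n_nodes must be >= 3", call. = FALSE)
  with_seed(seed, {
    # letters only while they cannot collide with the root "R" (LETTERS[18])
    nodes <- if (n_nodes <= 18) c("R", LETTERS[seq_len(n_nodes - 1)])
             else c("R", sprintf("N%03d", seq_len(n_nodes - 1)))
    child <- nodes[2:n_nodes]
    parent <- nodes[floor(seq(2, n_nodes) / 2)]
    edges <- data.frame(child = child, parent = parent,
                        stringsAsFactors = FALSE)
    if (shape == "dag") {
      extra <- max(1, floor(n_nodes / 4))
      for (e in seq_len(extra)) {
        ci <- sample(3:n_nodes, 1)
        pi <- sample(seq_len(ci - 1), 1)
        if (nodes[pi] != parent[ci - 1]) {
          edges <- rbind(edges, data.frame(child = nodes[ci],
                                           parent = nodes[pi],
                                           stringsAsFactors = FALSE))
        }
      }
      edges <- edges[!duplicated(edges), , drop = FALSE]
      rownames(edges) <- NULL
    }
    vars <- paste0("v", seq_len(n_variables))
    if (map_to == "leaves") {
      is_leaf <- !nodes %in% edges$parent
      depth <- floor(log2(seq_len(n_nodes))) + 1
      leaves <- nodes[is_leaf][order(-depth[is_leaf], nodes[is_leaf])]
      targets <- rep(leaves, length.out = n_variables)
    } else {
      targets <- sample(nodes[-1], n_variables, replace = TRUE)
    }
    mappings <- data.frame(variable = vars, entity_id = targets,
                           stringsAsFactors = FALSE)
    labels <- data.frame(id = nodes, label = tolower(nodes),
                         stringsAsFactors = FALSE)
    list(edges = edges, mappings = mappings, labels = labels)
  })
}

#' Nested-MICA heart-disease ontology fixture
#'
#' Five comorbidity variables (`mi`, `ihd`, `af`, `hf`, `vd`) mapped under
#' a "heart disease" branch such that two distinct variable sets arise:
#' all five variables with MICA "heart disease", and the pair
#' `{mi, ihd}` with the deeper, more informative MICA
#' "ischaemic heart disease".
#'
#' @return list with `edges`, `mappings`, `labels` data.frames.
#' @export
ontology_heart_disease <- function() {
  edges <- data.frame(
    child = c("c_heart_disease", "c_ischaemic_heart_disease",
              "c_myocardial_infarction", "c_atrial_fibrillation",
              "c_heart_failure", "c_valve_disorder"),
    parent = c("c_disorder", "c_heart_disease",
               "c_ischaemic_heart_disease", "c_heart_disease",
               "c_heart_disease", "c_heart_disease"),
    stringsAsFactors = FALSE
  )
  mappings <- data.frame(
    variable = c("mi", "ihd", "af", "hf", "vd"),
    entity_id = c("c_myocardial_infarction", "c_ischaemic_heart_disease",
                  "c_atrial_fibrillation", "c_heart_failure",
                  "c_valve_disorder"),
    stringsAsFactors = FALSE
  )
  labels <- data.frame(
    id = c("c_disorder", "c_heart_disease", "c_ischaemic_heart_disease",
           "c_myocardial_infarction", "c_atrial_fibrillation",
           "c_heart_failure", "c_valve_disorder"),
    label = c("disorder", "heart disease", "ischaemic heart disease",
              "myocardial infarction", "atrial fibrillation",
              "heart failure", "valve disorder"),
    stringsAsFactors = FALSE
  )
  list(edges = edges, mappings = mappings, labels = labels)
}

#' Enrichment fixture with a planted zero-entropy candidate budget
#'
#' Constructs a forest ontology of independent two-leaf trees (one
#' variable set per tree root) and a numeric table engineered so that a
#' known number of the five-per-set meta-variable candidates have zero
#' entropy: `n_all_constant` sets hold complementary 0/1 indicators (all
#' five aggregations constant, 5 dropped each) and `n_single_constant`
#' sets hold reciprocal value pairs with constant product (only MULT
#' dropped). The remaining sets drop nothing. With the defaults this
#' yields 36 sets, 180 candidates, 31 dropped and 149 appended. The
#' planted constants rely on raw magnitudes, so enrichment must be run
#' with `normalise = FALSE` on this fixture.
#'
#' @param n_sets total number of variable sets (trees).
#' @param n_all_constant sets whose five candidates are all constant.
#' @param n_single_constant sets with exactly one constant candidate.
#' @param n_records table rows (even, >= 4).
#' @param seed RNG seed for the unconstrained sets' values.
#' @return list with `table`, `edges`, `mappings`, `labels` and
#'   `expected` counts (`n_sets`, `n_candidates`, `n_dropped`,
#'   `n_appended`).
#' @export
enrichment_arithmetic_fixture <- function(n_sets = 36, n_all_constant = 6,
                                          n_single_constant = 1,
                                          n_records = 8, seed = 1) {
  stopifnot(n_all_constant + n_single_constant <= n_sets,
            n_records >= 4, n_records %% 2 == 0)
  with_seed(seed, {
    ids <- sprintf("p%03d", seq_len(n_records))
    df <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    edges <- NULL; mappings <- NULL
    kind <- rep("free", n_sets)
    if (n_all_constant) kind[seq_len(n_all_constant)] <- "all_const"
    if (n_single_constant) {
      kind[n_all_constant + seq_len(n_single_constant)] <- "mult_const"
    }
    half <- n_records / 2
    for (i in seq_len(n_sets)) {
      root <- sprintf("set%02d", i)
      va <- sprintf("u%02da", i); vb <- sprintf("u%02db", i)
      ea <- paste0(root, "_a"); eb <- paste0(root, "_b")
      edges <- rbind(edges, data.frame(child = c(ea, eb),
                                       parent = root,
                                       stringsAsFactors = FALSE))
      mappings <- rbind(mappings,
                        data.frame(variable = c(va, vb),
                                   entity_id = c(ea, eb),
                                   stringsAsFactors = FALSE))
      vals <- switch(kind[i],
        all_const = {
          x <- rep(c(0, 1), half)
          list(x, 1 - x)
        },
        mult_const = {
          x <- rep(c(1, 2, 4), length.out = n_records)
          list(x, 4 / x)
        },
        free = {
          # distinct sums guarantee no aggregation is constant
          x <- sample(1:50, n_records)
          y <- sample(1:50, n_records)
          while (length(unique(x + y)) < 2 || length(unique(x * y)) < 2 ||
                 length(unique(pmin(x, y))) < 2 ||
                 length(unique(pmax(x, y))) < 2) {
            y <- sample(1:50, n_records)
          }
          list(x, y)
        })
      df[[va]] <- as.character(vals[[1]])
      df[[vb]] <- as.character(vals[[2]])
    }
    nodes <- sort(unique(c(edges$child, edges$parent)))
    n_dropped <- 5 * n_all_constant + n_single_constant
    list(
      table = health_table(df, "patient_id"),
      edges = edges,
      mappings = mappings,
      labels = data.frame(id = nodes, label = nodes,
                          stringsAsFactors = FALSE),
      expected = list(n_sets = n_sets, n_candidates = 5 * n_sets,
                      n_dropped = n_dropped,
                      n_appended = 5 * n_sets - n_dropped)
    )
  })
}

#' End-to-end semantic-enrichment worked example
#'
#' A six-record table of the five heart-disease comorbidity indicators of
#' [ontology_heart_disease()], together with the hand-computed
#' meta-variables the enrichment workflow must append: the all-five set
#' yields only SUM and AVG (MIN, MAX and MULT are constant over the
#' observed records, hence zero entropy and dropped), while the
#' `{mi, ihd}` set yields all five aggregations.
#'
#' @return list with `table` (a [health_table()]), `edges`, `mappings`,
#'   `labels`, and `expected` (named list of meta-variable value vectors
#'   plus `counts` of sets/candidates/dropped/appended).
#' @export
worked_example_heart_disease <- function() {
  onto <- ontology_heart_disease()
  df <- data.frame(
    patient_id = paste0("r", 1:6),
    mi  = c("1", "0", "1", NA, "0", "1"),
    ihd = c("1", "1", "0", NA, "0", "0"),
    af  = c("0", "1", "0", NA, NA, "1"),
    hf  = c("0", "0", "1", NA, "0", "0"),
    vd  = c("0", "0", "0", NA, "1", "1"),
    stringsAsFactors = FALSE
  )
  table <- health_table(df, "patient_id")
  expected <- list(
    MV_heart_disease_SUM = c(2, 2, 2, NA, 1, 3),
    MV_heart_disease_AVG = c(0.4, 0.4, 0.4, NA, 0.25, 0.6),
    MV_ischaemic_heart_disease_SUM = c(2, 1, 1, NA, 0, 1),
    MV_ischaemic_heart_disease_MIN = c(1, 0, 0, NA, 0, 0),
    MV_ischaemic_heart_disease_MAX = c(1, 1, 1, NA, 0, 1),
    MV_ischaemic_heart_disease_AVG = c(1, 0.5, 0.5, NA, 0, 0.5),
    MV_ischaemic_heart_disease_MULT = c(1, 0, 0, NA, 0, 0),
    counts = list(n_sets = 2, n_candidates = 10, n_dropped = 3,
                  n_appended = 7)
  )
  c(onto, list(table = table, expected = expected))
}
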