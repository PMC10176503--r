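# Numeric encoding of categorical variables for machine interpretability,
# with a mapping reference table preserving the human-readable labels.

empty_mapping <- function() {
  data.frame(variable = character(0), original_label = character(0),
             numeric_code = integer(0), stringsAsFactors = FALSE)
}

mapping_rows <- function(variable, labels, codes) {
  data.frame(variable = variable, original_label = as.character(labels),
             numeric_code = as.integer(codes), stringsAsFactors = FALSE)
}

#' Encode an ordinal variable as 1-based level positions
#'
#' Each label is replaced by its position in `levels` (1, 2, 3, ...), so
#' e.g. tumour N stages N0, N1, N2 become 1, 2, 3. Missing values are
#' preserved. The label-to-code correspondence is emitted as mapping
#' reference rows.
#'
#' @param table a [health_table()].
#' @param variable variable name.
#' @param levels ordered character vector covering every observed
#'   non-missing label.
#' @return list with `table` (column now integer codes) and `mapping`
#'   (data.frame variable / original_label / numeric_code).
#' @export
encode_ordinal <- function(table, variable, levels) {
  stopifnot(inherits(table, "health_table"))
  col <- as.character(ht_values(table, variable))
  obs <- unique(col[!is.na(col)])
  uncovered <- setdiff(obs, levels)
  if (length(uncovered)) {
    stop(sprintf("levels for '%s' omit observed label(s): %s",
                 variable, paste(sort(uncovered), collapse = ", ")),
         call. = FALSE)
  }
  codes <- match(col, levels)
  table <- ht_set(table, variable, as.integer(codes),
                  meta = variable_meta(variable, "ordinal",
                                       ordinal_levels = levels,
                                       source = "user"))
  list(table = table,
       mapping = mapping_rows(variable, levels, seq_along(levels)))
}

#' Encode a binary variable as 0/1
#'
#' `positive_label` becomes 1, the other observed label 0; missing values
#' are preserved.
#'
#' @param table a [health_table()].
#' @param variable variable name with at most two distinct non-missing
#'   labels.
#' @param positive_label label encoded as 1.
#' @return the table with the column encoded as integer 0/1.
#' @export
encode_binary <- function(table, variable, positive_label) {
  stopifnot(inherits(table, "health_table"))
  col <- as.character(ht_values(table, variable))
  labs <- unique(col[!is.na(col)])
  if (length(labs) > 2) {
    stop(sprintf("'%s' has %d labels; binary encoding requires at most 2",
                 variable, length(labs)), call. = FALSE)
  }
  out <- ifelse(is.na(col), NA_integer_,
                ifelse(col == as.character(positive_label), 1L, 0L))
  ht_set(table, variable, out,
         meta = variable_meta(variable, "nominal_binary", source = "user"))
}

sanitise_label <- function(x) gsub("[[:space:]]+", "_", trimws(x))

#' One-hot encode a multi-level nominal variable
#'
#' Replaces the source variable with one 0/1 indicator per distinct
#' non-missing label, named `<variable>_<label>`; when any value is
#' missing, an additional `<variable>_NA` indicator marks missingness.
#' The generated indicators have no missing values and, per record, sum to
#' exactly 1 (a partition).
#'
#' @param table a [health_table()].
#' @param variable variable name.
#' @return the table with the source removed and indicators appended.
#' @export
encode_onehot <- function(table, variable) {
  stopifnot(inherits(table, "health_table"))
  col <- as.character(ht_values(table, variable))
  labs <- sort(unique(col[!is.na(col)]))
  has_na <- anyNA(col)
  table <- ht_drop(table, variable)
  for (lab in labs) {
    nm <- paste0(variable, "_", sanitise_label(lab))
    ind <- as.integer(!is.na(col) & col == lab)
    table <- ht_set(table, nm, ind,
                    meta = variable_meta(nm, "nominal_binary",
                                         source = "user"))
  }
  if (has_na) {
    nm <- paste0(variable, "_NA")
    table <- ht_set(table, nm, as.integer(is.na(col)),
                    meta = variable_meta(nm, "nominal_binary",
                                         source = "user"))
  }
  table
}

#' Encode a categorical variable by cohort frequency
#'
#' Labels are ranked by descending frequency in the cohort; the most common
#' label is encoded 0, the next 1, and so on (ties broken
#' lexicographically). Used e.g. for single-substitution mutation status
#' where wild type is typically the most common. Missing values are
#' preserved.
#'
#' @param table a [health_table()].
#' @param variable variable name.
#' @return list with `table` and `mapping` reference rows.
#' @export
encode_by_frequency <- function(table, variable) {
  stopifnot(inherits(table, "health_table"))
  col <- as.character(ht_values(table, variable))
  cnt <- table(col[!is.na(col)])
  labs <- names(cnt)[order(-as.numeric(cnt), names(cnt))]
  codes <- seq_along(labs) - 1L
  out <- codes[match(col, labs)]
  table <- ht_set(table, variable, as.integer(out),
                  meta = variable_meta(variable, "ordinal",
                                       ordinal_levels = labs,
                                       source = "user"))
  list(table = table, mapping = mapping_rows(variable, labs, codes))
}

#' Assert that all variables are numeric
#'
#' Final QC check: every non-identifier variable's non-missing values must
#' parse as numbers.
#'
#' @param table a [health_table()].
#' @return character vector of offending variable names; empty means the
#'   assertion passes.
#' @export
assert_all_numeric <- function(table) {
  stopifnot(inherits(table, "health_table"))
  vars <- variables(table)
  vars[!vapply(vars, function(v) all_numeric_values(table$data[[v]]),
               logical(1))]
}
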