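# Quality assessment and control: missing-value standardisation,
# completeness profiling, zero-entropy flagging.

#' Standardise heterogeneous missing-value encodings
#'
#' Health datasets commonly record missingness in several encodings at once
#' (strings such as "unknown" or out-of-range values such as -1). Every cell
#' whose raw value matches one of `encodings` is converted to the canonical
#' missing marker. String matching is exact but case-insensitive; encodings
#' that parse as numbers additionally match cells that are numerically equal
#' (so "-1" matches "-1.0"). Idempotent: a second application alters 0 cells.
#'
#' @param table a [health_table()].
#' @param encodings non-empty character/numeric vector of tokens that
#'   represent missingness.
#' @return list with elements `table` (standardised), `n_altered` (count of
#'   converted cells) and `log` (data.frame of record_id, variable, value
#'   for every converted cell).
#' @export
standardise_missing <- function(table, encodings) {
  stopifnot(inherits(table, "health_table"))
  if (!length(encodings)) {
    stop("`encodings` must be non-empty", call. = FALSE)
  }
  enc <- as.character(encodings)
  enc_lower <- tolower(enc)
  enc_num <- parse_num(enc)
  enc_num <- enc_num[!is.na(enc_num)]
  ids <- record_ids(table)
  log_rec <- character(0); log_var <- character(0); log_val <- character(0)
  for (v in variables(table)) {
    col <- table$data[[v]]
    obs <- !is.na(col)
    if (!any(obs)) next
    chr <- as.character(col)
    hit <- obs & tolower(chr) %in% enc_lower
    if (length(enc_num)) {
      num <- parse_num(chr)
      hit <- hit | (obs & !is.na(num) & num %in% enc_num)
    }
    if (any(hit)) {
      log_rec <- c(log_rec, ids[hit])
      log_var <- c(log_var, rep(v, sum(hit)))
      log_val <- c(log_val, chr[hit])
      col[hit] <- NA
      table$data[[v]] <- col
    }
  }
  list(
    table = table,
    n_altered = length(log_rec),
    log = data.frame(record_id = log_rec, variable = log_var,
                     value = log_val, stringsAsFactors = FALSE)
  )
}

#' Assess dataset completeness
#'
#' Completeness is the fraction of non-missing cells along an axis. Computed
#' per variable (column) and per record (row) over the non-identifier
#' variables.
#'
#' @param table a [health_table()].
#' @return object of class `completeness_report`: list with
#'   `variable_completeness` and `record_completeness` (named numeric
#'   vectors in \[0, 1\]) and `summary` (mean/min/max per axis).
#' @export
assess_completeness <- function(table) {
  stopifnot(inherits(table, "health_table"))
  vars <- variables(table)
  m <- !sapply(table$data[vars], is.na)
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(table$data))
  vc <- colMeans(m)
  names(vc) <- vars
  rc <- rowMeans(m)
  names(rc) <- record_ids(table)
  structure(
    list(
      variable_completeness = vc,
      record_completeness = rc,
      summary = data.frame(
        axis = c("variable", "record"),
        mean = c(mean(vc), mean(rc)),
        min = c(min(vc), min(rc)),
        max = c(max(vc), max(rc))
      )
    ),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("<completeness_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Numeric matrix of the dataset for missingness exploration
#'
#' Produces the inputs of a clustered missingness heatmap: numeric cells
#' pass through; every non-missing cell of a non-numeric variable is
#' replaced by the number of distinct values that variable takes; missing
#' cells are replaced by a highly distant value. Rows and columns are
#' ordered by hierarchical clustering of Euclidean distances with
#' single-linkage agglomeration, so that blocks of co-missing variables
#' (e.g. a whole modality absent for a subset of patients) become adjacent.
#'
#' @param table a [health_table()].
#' @param distant_value value substituted for missing cells; default
#'   `2 * (max(|encoded value|) + 1)`.
#' @return list with `matrix` (records x variables numeric), `row_order`
#'   and `col_order` (names in clustered order), and `mask` (logical
#'   matrix, `TRUE` = present).
#' @export
completeness_matrix <- function(table, distant_value = NULL) {
  stopifnot(inherits(table, "health_table"))
  vars <- variables(table)
  ids <- record_ids(table)
  n <- nrow(table$data)
  m <- matrix(NA_real_, n, length(vars), dimnames = list(ids, vars))
  for (j in seq_along(vars)) {
    col <- table$data[[vars[j]]]
    obs <- !is.na(col)
    if (all_numeric_values(col)) {
      m[obs, j] <- parse_num(col)[obs]
    } else {
      m[obs, j] <- length(unique(col[obs]))
    }
  }
  mask <- !is.na(m)
  if (is.null(distant_value)) {
    mx <- suppressWarnings(max(abs(m), na.rm = TRUE))
    if (!is.finite(mx)) mx <- 0
    distant_value <- 2 * (mx + 1)
  }
  m[!mask] <- distant_value
  row_order <- ids
  col_order <- vars
  if (n > 1) {
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "single")
    row_order <- ids[hc$order]
  }
  if (length(vars) > 1) {
    hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                        method = "single")
    col_order <- vars[hc$order]
  }
  list(matrix = m, row_order = row_order, col_order = col_order,
       mask = mask, distant_value = distant_value)
}

#' Variables with zero entropy
#'
#' A zero-entropy variable takes the same value across all records and so
#' cannot stratify the cohort; such variables are flagged for removal.
#' All-missing variables are included (they carry no information either).
#'
#' @param table a [health_table()].
#' @return character vector of flagged variable names.
#' @export
zero_entropy_variables <- function(table) {
  stopifnot(inherits(table, "health_table"))
  vars <- variables(table)
  flag <- vapply(vars, function(v) {
    col <- table$data[[v]]
    length(unique(col[!is.na(col)])) <= 1
  }, logical(1))
  vars[flag]
}
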