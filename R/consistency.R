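# Internal consistency checking: user-supplied semantic dependencies between
# variable pairs. A rule either compares two numeric variables with a
# logical operator, or restricts the values of variable B given a boundary
# condition on variable A (category sets or inclusive "lo:hi" ranges).

#' Build one internal-consistency rule
#'
#' Exactly one of `logical_test` or the boundary pair must be supplied.
#' Operator rules flag records where `value_a OP value_b` is false (numeric
#' comparison). Boundary rules flag records where the value of `variable_a`
#' falls inside `variable_a_boundaries` while the value of `variable_b`
#' falls outside `variable_b_boundaries`. Boundaries are either a set of
#' category labels (";"-separated in CSV form) or an inclusive numeric
#' range written `"lo:hi"`. Records with a missing value in either variable
#' are never flagged.
#'
#' @param variable_a,variable_b variable names.
#' @param logical_test one of `<`, `<=`, `==`, `!=`, `>=`, `>`, or `NA`.
#' @param variable_a_boundaries,variable_b_boundaries boundary strings, or
#'   `NA`.
#' @return a list of class `consistency_rule`.
#' @export
consistency_rule <- function(variable_a, variable_b, logical_test = NA,
                             variable_a_boundaries = NA,
                             variable_b_boundaries = NA) {
  has_op <- !is.na(logical_test) && nzchar(logical_test)
  has_ba <- !is.na(variable_a_boundaries) && nzchar(variable_a_boundaries)
  has_bb <- !is.na(variable_b_boundaries) && nzchar(variable_b_boundaries)
  if (has_op == (has_ba || has_bb)) {
    stop("exactly one of logical_test or a boundary pair must be supplied",
         call. = FALSE)
  }
  if (has_op && !logical_test %in% c("<", "<=", "==", "!=", ">=", ">")) {
    stop(sprintf("unknown logical_test '%s'", logical_test), call. = FALSE)
  }
  if (!has_op && !(has_ba && has_bb)) {
    stop("boundary rules require boundaries for both variables",
         call. = FALSE)
  }
  rule <- structure(
    list(variable_a = variable_a, variable_b = variable_b,
         logical_test = if (has_op) logical_test else NA_character_,
         variable_a_boundaries =
           if (has_ba) parse_boundary(variable_a_boundaries) else NULL,
         variable_b_boundaries =
           if (has_bb) parse_boundary(variable_b_boundaries) else NULL),
    class = "consistency_rule"
  )
  rule
}

# "lo:hi" -> inclusive numeric range; "a;b;c" -> category set
parse_boundary <- function(spec) {
  spec <- trimws(as.character(spec))
  if (grepl("^[^;]+:[^;]+$", spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    lo <- parse_num(parts[1])
    hi <- parse_num(parts[2])
    if (!is.na(lo) && !is.na(hi)) {
      if (lo > hi) {
        stop(sprintf("malformed range '%s': lo > hi", spec), call. = FALSE)
      }
      return(list(kind = "range", lo = lo, hi = hi))
    }
  }
  list(kind = "set", values = trimws(strsplit(spec, ";", fixed = TRUE)[[1]]))
}

boundary_match <- function(values, boundary) {
  if (boundary$kind == "range") {
    num <- parse_num(values)
    !is.na(num) & num >= boundary$lo & num <= boundary$hi
  } else {
    as.character(values) %in% boundary$values
  }
}

#' Read consistency rules from CSV
#'
#' Expects the columns `variable_a`, `variable_b`, `logical_test`,
#' `variable_a_boundaries`, `variable_b_boundaries` (empty cells for unused
#' fields). Category boundaries are ";"-separated; numeric inclusive ranges
#' are written `"lo:hi"`.
#'
#' @param path CSV file path.
#' @return list of [consistency_rule()] objects.
#' @export
read_consistency_rules <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = character(0))
  need <- c("variable_a", "variable_b", "logical_test",
            "variable_a_boundaries", "variable_b_boundaries")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("rules file lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      consistency_rule(df$variable_a[i], df$variable_b[i],
                       logical_test = df$logical_test[i],
                       variable_a_boundaries = df$variable_a_boundaries[i],
                       variable_b_boundaries = df$variable_b_boundaries[i]),
      error = function(e) {
        stop(sprintf("rules file row %d: %s", i, conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
}

#' Identify internal inconsistencies
#'
#' Applies each rule to every record. Records with a missing value in
#' either rule variable are skipped; findings are unique per (record,
#' rule).
#'
#' @param table a [health_table()].
#' @param rules list of [consistency_rule()].
#' @return data.frame with columns `record_id`, `rule`, `variable_a`,
#'   `variable_b`, `value_a`, `value_b`; zero rows when the data are
#'   consistent.
#' @export
identify_inconsistency <- function(table, rules) {
  stopifnot(inherits(table, "health_table"))
  ids <- record_ids(table)
  out <- list()
  for (r in seq_along(rules)) {
    rule <- rules[[r]]
    if (!inherits(rule, "consistency_rule")) {
      stop("rules must be consistency_rule objects", call. = FALSE)
    }
    for (v in c(rule$variable_a, rule$variable_b)) {
      if (!v %in% names(table$data)) {
        stop(sprintf("rule %d references absent variable '%s'", r, v),
             call. = FALSE)
      }
    }
    a <- table$data[[rule$variable_a]]
    b <- table$data[[rule$variable_b]]
    cc <- !is.na(a) & !is.na(b)
    if (!any(cc)) next
    if (!is.na(rule$logical_test)) {
      an <- parse_num(a)
      bn <- parse_num(b)
      if (any(cc & (is.na(an) | is.na(bn)))) {
        stop(sprintf(
          "rule %d ('%s %s %s') applied to non-numeric data",
          r, rule$variable_a, rule$logical_test, rule$variable_b),
          call. = FALSE)
      }
      ok <- do.call(rule$logical_test, list(an, bn))
      bad <- cc & !ok
    } else {
      in_a <- boundary_match(a, rule$variable_a_boundaries)
      in_b <- boundary_match(b, rule$variable_b_boundaries)
      bad <- cc & in_a & !in_b
    }
    if (any(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        record_id = ids[bad], rule = r,
        variable_a = rule$variable_a, variable_b = rule$variable_b,
        value_a = as.character(a[bad]), value_b = as.character(b[bad]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(record_id = character(0), rule = integer(0),
                      variable_a = character(0), variable_b = character(0),
                      value_a = character(0), value_b = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("record_id", "rule")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
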