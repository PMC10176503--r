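# Variable merging with information-theoretic loss evaluation. A merging
# operation collapses two or more input variables into one; the merged
# variable retains an input's information iff the input's mutual
# information content (MIC) with the merged variable equals the input's
# information content (IC).

#' Specify a merging operation
#'
#' @param inputs character vector of two or more input variable names.
#' @param mapping data.frame whose columns are the input variables plus a
#'   `merged` column; each row maps one combination of input values to a
#'   merged value. The mapping must cover every combination observed in
#'   the data (on records where all inputs are non-missing).
#' @param name name of the merged variable.
#' @param ordered_levels optional ordered levels when the merged variable is
#'   ordinal (e.g. an inserted intermediate category).
#' @return a list of class `merge_spec`.
#' @export
merge_spec <- function(inputs, mapping, name, ordered_levels = NULL) {
  if (length(inputs) < 2) {
    stop("a merge requires at least two input variables", call. = FALSE)
  }
  if (!is.data.frame(mapping) || !"merged" %in% names(mapping)) {
    stop("`mapping` must be a data.frame with a 'merged' column",
         call. = FALSE)
  }
  miss <- setdiff(inputs, names(mapping))
  if (length(miss)) {
    stop(sprintf("mapping lacks column(s) for input(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  key <- do.call(paste, c(lapply(mapping[inputs], as.character),
                          sep = "\x1f"))
  if (anyDuplicated(key)) {
    stop("mapping contains duplicate input-value combinations",
         call. = FALSE)
  }
  structure(
    list(inputs = inputs, mapping = mapping, name = name,
         ordered_levels = ordered_levels),
    class = "merge_spec"
  )
}

#' Merge variables and assess information loss
#'
#' Appends the merged variable defined by `spec` (inputs are retained;
#' removal is a separate explicit step). Records with a missing value in
#' any input get a missing merged value. The accompanying assessment
#' computes, on the records complete across all inputs: each input's
#' discrete information content (IC), its mutual information content (MIC)
#' with the merged variable, a lossless flag (`MIC == IC` within `1e-9`),
#' and the IC of the merged variable. `MIC <= IC` always holds on complete
#' data; equality means the input is recoverable from the merged variable.
#'
#' @param table a [health_table()].
#' @param spec a [merge_spec()].
#' @return list with `table` (merged variable appended) and `assessment`
#'   (class `merge_assessment`).
#' @export
merge_variables <- function(table, spec) {
  stopifnot(inherits(table, "health_table"), inherits(spec, "merge_spec"))
  miss <- setdiff(spec$inputs, names(table$data))
  if (length(miss)) {
    stop(sprintf("input variable(s) not in table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  cols <- lapply(spec$inputs, function(v) table$data[[v]])
  cc <- Reduce(`&`, lapply(cols, function(x) !is.na(x)))
  obs_key <- do.call(paste, c(lapply(cols, as.character), sep = "\x1f"))
  map_key <- do.call(paste, c(lapply(spec$mapping[spec$inputs],
                                     as.character), sep = "\x1f"))
  idx <- match(obs_key, map_key)
  unmapped <- cc & is.na(idx)
  if (any(unmapped)) {
    combos <- unique(do.call(paste, c(lapply(cols, function(x)
      as.character(x)), sep = " / "))[unmapped])
    stop(sprintf("observed combination(s) not covered by the value map: %s",
                 paste(combos, collapse = "; ")), call. = FALSE)
  }
  merged <- rep(NA_character_, nrow(table$data))
  merged[cc] <- as.character(spec$mapping$merged)[idx[cc]]
  vtype <- if (is.null(spec$ordered_levels)) "nominal_multi" else "ordinal"
  table <- ht_set(table, spec$name, merged,
                  meta = variable_meta(spec$name, vtype,
                                       ordinal_levels = spec$ordered_levels,
                                       source = "user"))
  per_input <- lapply(spec$inputs, function(v) {
    x <- table$data[[v]]
    x[!cc] <- NA
    m <- merged
    ic <- information_content_discrete(x)
    mic <- mutual_information_content(x, m)
    data.frame(input = v, ic = ic, mic = mic,
               lossless = abs(mic - ic) <= 1e-9,
               stringsAsFactors = FALSE)
  })
  assessment <- structure(
    list(
      inputs = do.call(rbind, per_input),
      merged_variable = spec$name,
      merged_ic = information_content_discrete(merged),
      n_complete = sum(cc)
    ),
    class = "merge_assessment"
  )
  list(table = table, assessment = assessment)
}

#' @export
print.merge_assessment <- function(x, ...) {
  cat(sprintf("<merge_assessment> merged variable '%s' (IC = %.4g bits, %d complete cases)\n",
              x$merged_variable, x$merged_ic, x$n_complete))
  df <- x$inputs
  df$verdict <- ifelse(df$lossless, "lossless", "information loss")
  print(df, row.names = FALSE)
  invisible(x)
}
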