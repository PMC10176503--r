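# Extraction of structured indicator variables from free-text fields:
# token cleaning, optional skipgram formation, and document-frequency
# thresholding. Free-text clinical notes often hold information (e.g.
# family cancer history) that downstream analyses need in rectangular form.

#' Load a bundled stopword list
#'
#' Returns the stopword snapshot shipped with the package (currently
#' English only), one word per line.
#'
#' @param language language name; `"english"`.
#' @return character vector of stopwords.
#' @export
load_stopwords <- function(language = "english") {
  if (!identical(tolower(language), "english")) {
    stop(sprintf("no bundled stopword list for language '%s'", language),
         call. = FALSE)
  }
  path <- system.file("extdata", "stopwords_en.txt", package = "healthqc")
  readLines(path, encoding = "UTF-8")
}

# lowercase, apply substitutions, strip punctuation, split, drop stopwords
clean_tokens <- function(text, stopwords, substitutions = NULL) {
  s <- tolower(text)
  if (!is.null(substitutions)) {
    for (i in seq_len(nrow(substitutions))) {
      s <- gsub(substitutions$pattern[i], substitutions$replacement[i], s,
                fixed = TRUE)
    }
  }
  s <- gsub("[^a-z0-9]+", " ", s)
  toks <- strsplit(trimws(s), " +")[[1]]
  toks <- toks[nzchar(toks) & !toks %in% stopwords]
  toks
}

# all index tuples of length n with at most `skip` skipped positions
# between consecutive picks; terms joined with "_"
skipgrams <- function(tokens, n, skip) {
  m <- length(tokens)
  if (m < n) return(character(0))
  out <- character(0)
  recurse <- function(idx) {
    if (length(idx) == n) {
      out[[length(out) + 1L]] <<- paste(tokens[idx], collapse = "_")
      return(invisible())
    }
    last <- idx[length(idx)]
    nxt <- seq(last + 1L, min(m, last + 1L + skip))
    for (j in nxt) recurse(c(idx, j))
  }
  for (i in seq_len(m - n + 1L)) recurse(i)
  out
}

#' Extract indicator variables from a free-text variable
#'
#' Each record's text is cleaned (lowercase, punctuation stripped,
#' stopwords removed, optional fixed-string substitutions applied), then
#' tokens — and, when `ngram_length > 1`, skipgrams with 0 to `skip_window`
#' skipped tokens between consecutive picks — are formed. Terms occurring
#' in at least `min_record_frequency` records become new 0/1 presence
#' variables named `<variable>_<term>`. Records with missing text get
#' missing values in every generated variable.
#'
#' @param table a [health_table()].
#' @param variable free-text variable name.
#' @param min_record_frequency minimum document frequency for a term to
#'   become a variable (default 2).
#' @param ngram_length length of skipgram terms in tokens; 1 generates
#'   unigrams only (default 2).
#' @param skip_window maximum tokens skipped between consecutive skipgram
#'   members (default 1).
#' @param stopword_language language of the bundled stopword list.
#' @param substitutions optional data.frame (`pattern`, `replacement`) of
#'   fixed-string substitutions applied before tokenisation (e.g. expanding
#'   abbreviations or correcting known misspellings).
#' @return the table with indicator variables appended (source retained).
#' @export
extract_freetext <- function(table, variable, min_record_frequency = 2,
                             ngram_length = 2, skip_window = 1,
                             stopword_language = "english",
                             substitutions = NULL) {
  stopifnot(inherits(table, "health_table"))
  m <- table$meta[[variable]]
  if (is.null(m) || !identical(m$vtype, "free_text")) {
    stop(sprintf("'%s' is not typed as free_text", variable), call. = FALSE)
  }
  if (min_record_frequency < 2) {
    stop("min_record_frequency must be >= 2", call. = FALSE)
  }
  sw <- load_stopwords(stopword_language)
  col <- as.character(ht_values(table, variable))
  terms_per_record <- lapply(col, function(txt) {
    if (is.na(txt)) return(NULL)
    toks <- clean_tokens(txt, sw, substitutions)
    terms <- unique(toks)
    if (ngram_length > 1) {
      terms <- unique(c(terms, skipgrams(toks, ngram_length, skip_window)))
    }
    terms
  })
  doc_freq <- table(unlist(terms_per_record))
  keep <- sort(names(doc_freq)[doc_freq >= min_record_frequency])
  for (term in keep) {
    nm <- paste0(variable, "_", term)
    ind <- vapply(terms_per_record, function(t) {
      if (is.null(t)) NA_integer_ else as.integer(term %in% t)
    }, integer(1))
    ind[is.na(col)] <- NA_integer_
    table <- ht_set(table, nm, ind,
                    meta = variable_meta(nm, "nominal_binary",
                                         source = "user"))
  }
  table
}
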