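# Crohn's-like lymphoid reaction scoring fixture: input 1 scores {1,2,3},
# input 2 groups the low scores as "1-2". Used for the lossy vs lossless
# merging comparison.
make_clr_table <- function() {
  df <- data.frame(
    input1 = c("1", "2", "3", "1", "2", "3", "1", "2"),
    input2 = c("1-2", "1-2", "3", "1-2", "1-2", "3", "1-2", "1-2"),
    stringsAsFactors = FALSE
  )
  make_ht(df)
}

test_that("collapsing distinct scores into one level loses information", {
  ht <- make_clr_table()
  spec <- merge_spec(
    c("input1", "input2"),
    data.frame(input1 = c("1", "2", "3"),
               input2 = c("1-2", "1-2", "3"),
               merged = c("1-2", "1-2", "3"),
               stringsAsFactors = FALSE),
    name = "clr_merged"
  )
  res <- merge_variables(ht, spec)
  a <- res$assessment$inputs
  expect_false(a$lossless[a$input == "input1"])
  expect_lt(a$mic[a$input == "input1"], a$ic[a$input == "input1"])
  expect_true(a$lossless[a$input == "input2"])
  expect_equal(a$mic[a$input == "input2"], a$ic[a$input == "input2"],
               tolerance = 1e-9)
})

test_that("inserting the grouped score as an intermediate level is lossless", {
  ht <- make_clr_table()
  spec <- merge_spec(
    c("input1", "input2"),
    data.frame(input1 = c("1", "2", "3"),
               input2 = c("1-2", "1-2", "3"),
               merged = c("1", "2", "3"),
               stringsAsFactors = FALSE),
    name = "clr_merged",
    ordered_levels = c("1", "1-2", "2", "3")
  )
  res <- merge_variables(ht, spec)
  a <- res$assessment$inputs
  expect_true(all(a$lossless))
  # the lossless merge retains more information than the lossy one
  lossy <- merge_variables(make_clr_table(), merge_spec(
    c("input1", "input2"),
    data.frame(input1 = c("1", "2", "3"),
               input2 = c("1-2", "1-2", "3"),
               merged = c("1-2", "1-2", "3"),
               stringsAsFactors = FALSE),
    name = "clr_merged"))
  expect_gt(res$assessment$merged_ic, lossy$assessment$merged_ic)
})

test_that("self-merge via identity map is lossless and errors are caught", {
  ht <- make_ht(data.frame(x = c("a", "b", "a"), x2 = c("a", "b", "a"),
                           stringsAsFactors = FALSE))
  spec <- merge_spec(c("x", "x2"),
                     data.frame(x = c("a", "b"), x2 = c("a", "b"),
                                merged = c("a", "b"),
                                stringsAsFactors = FALSE),
                     name = "xm")
  res <- merge_variables(ht, spec)
  expect_true(all(res$assessment$inputs$lossless))
  expect_equal(res$assessment$merged_ic,
               information_content_discrete(c("a", "b", "a")))
  # unmapped observed combination -> error naming it
  bad <- merge_spec(c("x", "x2"),
                    data.frame(x = "a", x2 = "a", merged = "a",
                               stringsAsFactors = FALSE),
                    name = "xm")
  expect_error(merge_variables(ht, bad), "b / b")
  expect_error(merge_spec("x", data.frame(merged = "a"), "m"),
               "at least two")
})

test_that("lossless flag equals brute-force recoverability on random merges", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    x1 <- sample(letters[1:4], n, replace = TRUE)
    x2 <- sample(LETTERS[1:3], n, replace = TRUE)
    combos <- unique(data.frame(a = x1, b = x2, stringsAsFactors = FALSE))
    # random surjective value map onto a smaller alphabet
    m_levels <- paste0("m", seq_len(sample(1:4, 1)))
    combos$merged <- sample(m_levels, nrow(combos), replace = TRUE)
    ht <- make_ht(data.frame(a = x1, b = x2, stringsAsFactors = FALSE))
    res <- merge_variables(ht, merge_spec(c("a", "b"), combos, "m"))
    merged <- ht_values(res$table, "m")
    for (input in c("a", "b")) {
      row <- res$assessment$inputs
      row <- row[row$input == input, ]
      expect_lte(row$mic, row$ic + 1e-9)
      expect_equal(row$lossless,
                   oracle_recoverable(ht_values(res$table, input), merged))
    }
  }
})

test_that("ordinal encoding is positional, reversible, and validated", {
  ht <- make_ht(data.frame(n_stage = c("N1", "N0", "N2", NA),
                           stringsAsFactors = FALSE))
  res <- encode_ordinal(ht, "n_stage", c("N0", "N1", "N2"))
  expect_equal(ht_values(res$table, "n_stage"), c(2L, 1L, 3L, NA))
  expect_equal(res$mapping$numeric_code, 1:3)
  expect_equal(res$mapping$original_label, c("N0", "N1", "N2"))
  # decode via the mapping reference table reproduces the labels
  decoded <- res$mapping$original_label[ht_values(res$table, "n_stage")]
  expect_equal(decoded, c("N1", "N0", "N2", NA))
  expect_error(encode_ordinal(ht, "n_stage", c("N0", "N1")), "N2")
})

test_that("binary encoding maps the positive label to 1", {
  ht <- make_ht(data.frame(resp = c("yes", "no", NA, "yes"),
                           stringsAsFactors = FALSE))
  out <- encode_binary(ht, "resp", "yes")
  expect_equal(ht_values(out, "resp"), c(1L, 0L, NA, 1L))
  one <- make_ht(data.frame(x = c("only", "only"), stringsAsFactors = FALSE))
  expect_equal(ht_values(encode_binary(one, "x", "only"), "x"), c(1L, 1L))
  tri <- make_ht(data.frame(x = c("a", "b", "c"), stringsAsFactors = FALSE))
  expect_error(encode_binary(tri, "x", "a"), "at most 2")
})

test_that("one-hot indicators partition each record, with _NA for missing", {
  ht <- make_ht(data.frame(marital = c("married", "single", NA, "married"),
                           stringsAsFactors = FALSE))
  out <- encode_onehot(ht, "marital")
  expect_false("marital" %in% variables(out))
  expect_setequal(variables(out),
                  c("marital_married", "marital_single", "marital_NA"))
  mat <- sapply(variables(out), function(v) ht_values(out, v))
  expect_false(anyNA(mat))
  expect_true(all(rowSums(mat) == 1))
  expect_equal(ht_values(out, "marital_NA"), c(0L, 0L, 1L, 0L))
  # no missing -> no _NA column; single label -> all-1 indicator
  ht2 <- make_ht(data.frame(x = c("a", "a"), stringsAsFactors = FALSE))
  out2 <- encode_onehot(ht2, "x")
  expect_equal(variables(out2), "x_a")
  expect_equal(ht_values(out2, "x_a"), c(1L, 1L))
})

test_that("frequency encoding ranks by count with lexicographic ties", {
  df <- data.frame(mut = c(rep("WT", 5), rep("Het", 3), "Hom"),
                   stringsAsFactors = FALSE)
  res <- encode_by_frequency(make_ht(df), "mut")
  m <- res$mapping
  expect_equal(m$numeric_code[m$original_label == "WT"], 0L)
  expect_equal(m$numeric_code[m$original_label == "Het"], 1L)
  expect_equal(m$numeric_code[m$original_label == "Hom"], 2L)
  # equal counts: lexicographic
  tie <- encode_by_frequency(
    make_ht(data.frame(x = c("b", "a", "b", "a"),
                       stringsAsFactors = FALSE)), "x")
  expect_equal(tie$mapping$original_label[tie$mapping$numeric_code == 0L],
               "a")
  single <- encode_by_frequency(
    make_ht(data.frame(x = c("z", "z"), stringsAsFactors = FALSE)), "x")
  expect_equal(unique(ht_values(single$table, "x")), 0L)
})

test_that("free-text extraction counts document frequency after cleaning", {
  df <- data.frame(
    notes = c("mother breast cancer", "father lung cancer",
              "mother breast cancer"),
    stringsAsFactors = FALSE
  )
  ht <- make_ht(df)
  ht <- set_variable_meta(ht, apply_user_review(
    infer_variable_types(ht),
    list(notes = list(vtype = "free_text")), ht))
  out <- extract_freetext(ht, "notes", min_record_frequency = 2,
                          ngram_length = 1)
  new_vars <- setdiff(variables(out), "notes")
  expect_setequal(new_vars,
                  c("notes_mother", "notes_breast", "notes_cancer"))
  expect_equal(sum(ht_values(out, "notes_cancer")), 3)
  expect_equal(sum(ht_values(out, "notes_mother")), 2)
  # stopwords are removed before terms are formed
  sw <- make_ht(data.frame(notes = c("a cancer in the colon",
                                     "the cancer of colon"),
                           stringsAsFactors = FALSE))
  sw <- set_variable_meta(sw, apply_user_review(
    infer_variable_types(sw), list(notes = list(vtype = "free_text")), sw))
  out_sw <- extract_freetext(sw, "notes", min_record_frequency = 2,
                             ngram_length = 1)
  expect_setequal(setdiff(variables(out_sw), "notes"),
                  c("notes_cancer", "notes_colon"))
  # threshold above n_records -> nothing generated
  none <- extract_freetext(ht, "notes", min_record_frequency = 4,
                           ngram_length = 1)
  expect_equal(variables(none), "notes")
  expect_error(extract_freetext(make_ht(df), "notes"), "free_text")
})

test_that("skipgrams join nearby tokens within the skip window", {
  df <- data.frame(
    notes = c("mother breast cancer", "mother skin cancer"),
    stringsAsFactors = FALSE
  )
  ht <- make_ht(df)
  ht <- set_variable_meta(ht, apply_user_review(
    infer_variable_types(ht), list(notes = list(vtype = "free_text")), ht))
  out <- extract_freetext(ht, "notes", min_record_frequency = 2,
                          ngram_length = 2, skip_window = 1)
  new_vars <- setdiff(variables(out), "notes")
  # "mother_cancer" needs skip = 1; both records contain it
  expect_true("notes_mother_cancer" %in% new_vars)
  # doc-frequency floor holds for every generated variable
  for (v in new_vars) {
    expect_gte(sum(ht_values(out, v), na.rm = TRUE), 2)
  }
  # records with missing text get missing indicators
  df2 <- data.frame(notes = c("mother breast cancer",
                              "mother breast cancer", NA),
                    stringsAsFactors = FALSE)
  ht2 <- make_ht(df2)
  ht2 <- set_variable_meta(ht2, apply_user_review(
    infer_variable_types(ht2), list(notes = list(vtype = "free_text")),
    ht2))
  out2 <- extract_freetext(ht2, "notes", min_record_frequency = 2)
  expect_true(is.na(ht_values(out2, "notes_mother")[3]))
})

test_that("all-numeric assertion lists exactly the raw string columns", {
  ok <- make_ht(data.frame(x = c("1", "2"), y = c("0.5", NA),
                           stringsAsFactors = FALSE))
  expect_length(assert_all_numeric(ok), 0)
  mixed <- make_ht(data.frame(x = c("1", "2"), y = c("raw", "text"),
                              stringsAsFactors = FALSE))
  expect_equal(assert_all_numeric(mixed), "y")
  empty <- health_table(data.frame(rid = character(0), x = character(0),
                                   stringsAsFactors = FALSE), "rid")
  expect_length(assert_all_numeric(empty), 0)
})
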