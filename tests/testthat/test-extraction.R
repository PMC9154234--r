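test_that("best_long_form recovers known definition pairs", {
  cases <- list(
    list("HIV", "infection with human immunodeficiency virus",
         "human immunodeficiency virus"),
    list("DM2", "patients with diabetes mellitus type 2",
         "diabetes mellitus type 2"),
    list("ACL", "suspected tear of the anterior cruciate ligament",
         "anterior cruciate ligament"),
    list("MRS", "Melkersson-Rosenthal syndrome",
         "Melkersson-Rosenthal syndrome"),
    list("XYZ", "alpha beta gamma", NA_character_)
  )
  for (cs in cases) {
    expect_identical(best_long_form(cs[[1]], cs[[2]]), cs[[3]],
                     label = paste("pair", cs[[1]]))
  }
})

test_that("alignment is case-insensitive and skips short-form hyphens", {
  expect_identical(best_long_form("IL-6", "levels of interleukin 6"),
                   "interleukin 6")
  expect_identical(best_long_form("5-HT", "release of 5-hydroxytryptamine"),
                   "5-hydroxytryptamine")
  # digits must match literally: no digit '2' in the window
  expect_identical(best_long_form("DM2", "diabetes mellitus type two"),
                   NA_character_)
})

test_that("the suffix's first word must start with the short form's first character", {
  # 'R' of Rosenthal sits after a hyphen, not at a whitespace word start
  expect_identical(best_long_form("RS", "Melkersson-Rosenthal syndrome"),
                   NA_character_)
})

test_that("find_candidates applies the validity rules and paren structure", {
  # forward pattern
  cc <- find_candidates("human immunodeficiency virus (HIV)")
  expect_equal(nrow(cc), 1L)
  expect_identical(cc$surface, "HIV")
  expect_true(cc$inside_parens)
  # no parentheses
  expect_equal(nrow(find_candidates("a sentence with no parentheses")), 0L)
  # content too long -> reversed pattern takes the preceding token
  cc <- find_candidates("ACL (anterior cruciate ligament) injury")
  expect_equal(nrow(cc), 1L)
  expect_identical(cc$surface, "ACL")
  expect_false(cc$inside_parens)
  # single character and >10 characters are invalid either side
  expect_equal(nrow(find_candidates("x (q) y")), 0L)
  # >2 words inside parens and a 1-word invalid token before
  expect_equal(nrow(find_candidates("7% (three little words here) rest")), 0L)
})

test_that("nested and unbalanced parentheses are handled", {
  # only the innermost balanced pair is a candidate
  cc <- find_candidates("text (outer (ABC) words here) more")
  expect_equal(nrow(cc), 1L)
  expect_identical(cc$surface, "ABC")
  expect_true(cc$inside_parens)
  # an unbalanced '(' terminates the search from that point
  expect_equal(nrow(find_candidates("text ( broken (ABC) tail")), 0L)
  # but candidates before the unmatched '(' survive
  cc <- find_candidates("alpha beta code (ABC) then ( broken (DEF) tail")
  expect_identical(cc$surface, "ABC")
})

test_that("extract_definitions composes candidates with alignment", {
  d <- acro_document("d1", "Melkersson-Rosenthal syndrome (MRS) was suspected.")
  defs <- extract_definitions(d)
  expect_equal(nrow(defs), 1L)
  expect_identical(defs$short_form, "MRS")
  expect_identical(defs$long_form, "Melkersson-Rosenthal syndrome")
  # spans index the body exactly (0-based half-open)
  expect_identical(substr(d$body, defs$long_start + 1L, defs$long_end),
                   defs$long_form)
  expect_identical(substr(d$body, defs$short_start + 1L, defs$short_end),
                   defs$short_form)
})

test_that("two independent definitions come back in textual order", {
  d <- acro_document("d2", paste0(
    "Heart rate (HR) rose. Later the blood pressure (BP) fell."))
  defs <- extract_definitions(d)
  expect_equal(defs$short_form, c("HR", "BP"))
  expect_equal(defs$long_form, c("Heart rate", "blood pressure"))
  for (i in 1:2) {
    expect_identical(substr(d$body, defs$long_start[i] + 1L,
                            defs$long_end[i]), defs$long_form[i])
  }
})

test_that("failed alignment and self-definitions yield nothing", {
  expect_equal(nrow(extract_definitions(
    acro_document("x", "some unrelated words (HIV) here"))), 0L)
  expect_equal(nrow(extract_definitions(
    acro_document("x", "the use of acronyms (e.g. 'HIV') obscures"))), 0L)
  # short form equal to its long form is dropped
  expect_equal(nrow(extract_definitions(
    acro_document("x", "we saw ABC (abc) again"))), 0L)
  expect_equal(nrow(extract_definitions(
    acro_document("x", "no parentheses at all"))), 0L)
})

test_that("reversed pattern finds the long form inside the parentheses", {
  d <- acro_document("r1", "A torn ACL (anterior cruciate ligament) hurts.")
  defs <- extract_definitions(d)
  expect_equal(nrow(defs), 1L)
  expect_identical(defs$long_form, "anterior cruciate ligament")
  expect_identical(defs$pattern, "reverse")
  expect_identical(substr(d$body, defs$long_start + 1L, defs$long_end),
                   defs$long_form)
  # with patterns = "forward" the reversed candidate is skipped
  expect_equal(nrow(extract_definitions(d, patterns = "forward")), 0L)
  # truncation at the first comma
  d2 <- acro_document("r2", "A torn ACL (anterior cruciate ligament, left) hurts.")
  expect_identical(extract_definitions(d2)$long_form,
                   "anterior cruciate ligament")
})

test_that("alignment matches the brute-force suffix oracle on hand cases", {
  cases <- list(
    c("HIV", "infection with human immunodeficiency virus"),
    c("DM2", "patients with diabetes mellitus type 2"),
    c("ACL", "suspected tear of the anterior cruciate ligament"),
    c("RS", "Melkersson-Rosenthal syndrome"),
    c("AB", "ab a b"),
    c("AA", "a xa a"),
    c("XYZ", "alpha beta gamma"))
  for (cs in cases) {
    expect_identical(best_long_form(cs[1], cs[2]),
                     oracle_best_long_form(cs[1], cs[2]),
                     label = paste(cs[1], "|", cs[2]))
  }
})

test_that("returned long forms always satisfy the alignment invariants", {
  set.seed(901)
  subsequence_ok <- function(sf, lf) {
    sfc <- strsplit(tolower(sf), "")[[1]]
    sfc <- sfc[grepl("[[:alnum:]]", sfc)]
    lfc <- strsplit(tolower(lf), "")[[1]]
    j <- 1L
    for (ch in lfc) if (j <= length(sfc) && ch == sfc[j]) j <- j + 1L
    j > length(sfc)
  }
  for (i in 1:300) {
    sf <- fuzz_short_form()
    window <- fuzz_window(sf)
    lf <- best_long_form(sf, window)
    if (is.na(lf)) next
    expect_true(subsequence_ok(sf, lf), label = paste(sf, "|", window))
    sfc <- strsplit(tolower(sf), "")[[1]]
    sfc <- sfc[grepl("[[:alnum:]]", sfc)]
    expect_identical(tolower(substr(lf, 1L, 1L)), sfc[1])
  }
})
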