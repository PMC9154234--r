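test_that("sentence segmentation splits on terminators and guards abbreviations", {
  s <- split_sentences("MRS was used. MRS detected X.")
  expect_equal(nrow(s), 2L)
  expect_identical(trimws(substring("MRS was used. MRS detected X.",
                                    s$start + 1L, s$end)),
                   c("MRS was used.", "MRS detected X."))
  expect_equal(nrow(split_sentences("Results (e.g. HIV) were shown.")), 1L)
  expect_equal(nrow(split_sentences("See Fig. 2 for details.")), 1L)
  expect_equal(nrow(split_sentences("As shown by Smith J. The end.")), 1L)
  expect_equal(nrow(split_sentences("Seen in patients vs. Controls only.")), 1L)
  expect_equal(nrow(split_sentences("It ended! Then it restarted.")), 2L)
  expect_equal(nrow(split_sentences("")), 0L)
  # intervals tile the body
  body <- "One sentence here. Another one! And a third? Yes."
  s <- split_sentences(body)
  expect_equal(s$start[1], 0L)
  expect_equal(s$end[nrow(s)], nchar(body))
  expect_true(all(s$start[-1] == s$end[-nrow(s)]))
})

two_sense_fixture <- function(n_b = 3L) {
  # HR ambiguous with 2 senses; TB single-sense
  docs <- list(
    acro_document("p1", "Heart rate (HR) rose. The HR fell."),
    acro_document("p3", "Tuberculosis (TB) spread. TB is endemic."))
  for (i in seq_len(n_b)) {
    docs[[length(docs) + 1L]] <-
      acro_document(paste0("q", i), "Hazard ratio (HR) was high.")
  }
  corpus <- acro_corpus(docs)
  defs <- extract_corpus_definitions(corpus)
  inv <- build_inventory(defs)
  dec <- do.call(rbind, lapply(corpus$documents, function(d) {
    a <- unique(normalize_short_form(
      defs$short_form[defs$doc_id == d$doc_id]))
    data.frame(doc_id = d$doc_id, acronym = a, style = "ACRONYM",
               stringsAsFactors = FALSE)
  }))
  ann <- lapply(corpus$documents, function(d)
    globalize(d, defs, inv, dec))
  list(docs = ann, inv = inv)
}

test_that("samples are built only for ambiguous acronyms, with distinct negatives", {
  fx <- two_sense_fixture()
  set.seed(4)
  samples <- generate_samples(fx$docs, fx$inv, k_neg = 1)
  # TB is single-sense: contributes nothing
  expect_false("TB" %in% samples$acronym)
  expect_true(all(samples$acronym == "HR"))
  # each annotated occurrence yields one positive and one negative
  expect_equal(sum(samples$label == 1L), sum(samples$label == 0L))
  # the negative's sense differs from the positive's within each pair
  pos <- samples[samples$label == 1L, ]
  neg <- samples[samples$label == 0L, ]
  expect_true(all(pos$candidate_sense_id != neg$candidate_sense_id))
  # sentences contain the acronym as a standalone token
  expect_true(all(mapply(function(s, a)
    grepl(paste0("(?<![[:alnum:]])", a, "(?![[:alnum:]])"), s, perl = TRUE),
    samples$sentence, samples$acronym)))
  expect_error(generate_samples(fx$docs, fx$inv, k_neg = 0), "k_neg")
})

test_that("negatives never exceed the number of incorrect senses", {
  fx <- two_sense_fixture()
  set.seed(4)
  samples <- generate_samples(fx$docs, fx$inv, k_neg = 5)
  # only 2 senses exist, so min(5, 2 - 1) = 1 negative per positive
  expect_equal(sum(samples$label == 0L), sum(samples$label == 1L))
})

test_that("no annotations yield an empty sample table", {
  d <- acro_document("z", "no definitions here")
  ad <- globalize(d, extract_definitions(d), build_inventory(NULL),
                  data.frame(doc_id = character(0), acronym = character(0),
                             style = character(0)))
  out <- generate_samples(list(ad), build_inventory(NULL))
  expect_equal(nrow(out), 0L)
})

fake_samples <- function(acronym, n) {
  data.frame(doc_id = paste0("d", seq_len(n)),
             sentence = paste(acronym, "in context", seq_len(n)),
             acronym = acronym,
             candidate_long_form = "lf",
             candidate_sense_id = rep(c("S1", "S2"), length.out = n),
             label = rep(c(1L, 0L), length.out = n),
             stringsAsFactors = FALSE)
}

test_that("per-acronym reservation follows the 1000-or-10% rule", {
  set.seed(11)
  samples <- rbind(fake_samples("AA", 20000L), fake_samples("BB", 5000L))
  sp <- reserve_splits(samples)
  counts <- sp$per_acronym_counts
  expect_equal(counts$reserved[counts$acronym == "AA"], 1000L)
  expect_equal(counts$reserved[counts$acronym == "BB"], 500L)
  for (a in c("AA", "BB")) {
    for (part in c("validation", "test")) {
      expect_equal(sum(sp[[part]]$acronym == a),
                   counts$reserved[counts$acronym == a])
    }
  }
  expect_equal(sum(sp$train$acronym == "AA"), 18000L)
  expect_equal(sum(sp$train$acronym == "BB"), 4000L)
})

test_that("splits are disjoint and conserve the samples", {
  set.seed(21)
  samples <- rbind(fake_samples("AA", 137L), fake_samples("BB", 9L),
                   fake_samples("CC", 4000L))
  sp <- reserve_splits(samples)
  key <- function(df) paste(df$doc_id, df$acronym, df$candidate_sense_id,
                            df$label)
  n_parts <- nrow(sp$train) + nrow(sp$validation) + nrow(sp$test)
  expect_equal(n_parts, nrow(samples))
  pooled <- rbind(sp$train, sp$validation, sp$test)
  expect_setequal(key(pooled), key(samples))
  expect_equal(sort(table(key(pooled))), sort(table(key(samples))))
})

test_that("the MFS table picks the majority sense with lexicographic ties", {
  train <- data.frame(
    acronym = "AA",
    candidate_sense_id = c(rep("SA", 7), rep("SB", 3)),
    label = 1L, stringsAsFactors = FALSE)
  expect_identical(unname(mfs_fit(train)["AA"]), "SA")
  tie <- data.frame(acronym = "AA",
                    candidate_sense_id = c(rep("SB", 5), rep("SA", 5)),
                    label = 1L, stringsAsFactors = FALSE)
  expect_identical(unname(mfs_fit(tie)["AA"]), "SA")
  # negatives do not count towards the table
  mixed <- rbind(train,
                 data.frame(acronym = "AA",
                            candidate_sense_id = rep("SB", 20),
                            label = 0L, stringsAsFactors = FALSE))
  expect_identical(unname(mfs_fit(mixed)["AA"]), "SA")
})

test_that("MFS predictions default to negative for unseen acronyms", {
  table <- c(AA = "SA")
  s <- data.frame(acronym = c("AA", "AA", "ZZ"),
                  candidate_sense_id = c("SA", "SB", "SA"),
                  stringsAsFactors = FALSE)
  expect_identical(mfs_predict(s, table), c(TRUE, FALSE, FALSE))
})

test_that("metrics match a hand-counted confusion matrix", {
  # TP=3, FP=1, FN=1, TN=5
  pred <- c(rep(TRUE, 3), TRUE, FALSE, rep(FALSE, 5))
  lab <- c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  m <- evaluate_predictions(pred, lab)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  perfect <- evaluate_predictions(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # all-negative predictions: precision and F1 are both undefined -> 0
  w <- capture_warnings(
    m0 <- evaluate_predictions(c(FALSE, FALSE), c(TRUE, FALSE)))
  expect_true(any(grepl("undefined", w)))
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)
  expect_error(evaluate_predictions(logical(0), logical(0)), "non-empty")
  expect_error(evaluate_predictions(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("dataset splits export as readable TSV", {
  set.seed(33)
  samples <- fake_samples("AA", 60L)
  sp <- reserve_splits(samples)
  prefix <- file.path(withr::local_tempdir(), "wsd")
  write_dataset_tsv(sp, prefix)
  back <- utils::read.delim(paste0(prefix, ".train.tsv"),
                            stringsAsFactors = FALSE)
  expect_identical(names(back),
                   c("sentence", "acronym", "candidate_long_form", "label"))
  expect_equal(nrow(back), nrow(sp$train))
  expect_identical(back$label, sp$train$label)
})

test_that("label balance holds on the study-scale dataset with k_neg = 1", {
  sim <- default_simulation()
  splits <- build_wsd_dataset(sim, k_neg = 1, seed = 42)
  pooled <- rbind(splits$train, splits$validation, splits$test)
  expect_equal(sum(pooled$label == 1L), sum(pooled$label == 0L))
  # all sampled acronyms are ambiguous
  expect_true(all(pooled$acronym %in% ambiguous_acronyms(sim$inventory)))
})
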