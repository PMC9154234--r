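# Synthetic-corpus generator: convention-compliant abstracts with planted,
# ground-truthed acronym definitions ("long form (SF)"), repeated
# subsequent mentions and controlled per-acronym sense frequencies.

#' Default acronym specifications for the synthetic corpus
#'
#' 26 biomedical acronyms with planted senses and document-level sense
#' probabilities: 19 ambiguous (2-3 senses) and 7 single-sense, including
#' digit-bearing (DM2, T2D, HbA1c) and hyphen-bearing (IL-6, 5-HT) short
#' forms. Every (short form, long form) pair is recoverable by the
#' alignment heuristic, which [synth_config()] verifies at construction.
#'
#' @return List of specs; each spec is a list with `short_form` and
#'   `senses` (list of `long_form`, `concept_id`, `prob`).
#' @export
acrosim_default_specs <- function() {
  sn <- function(lf, p, cui = NA_character_) {
    list(long_form = lf, concept_id = cui, prob = p)
  }
  sp <- function(sf, ...) list(short_form = sf, senses = list(...))
  list(
    sp("MRS", sn("magnetic resonance spectroscopy", 0.6),
       sn("melkersson-rosenthal syndrome", 0.4)),
    sp("ACL", sn("anterior cruciate ligament", 0.7),
       sn("anterior chamber lens", 0.3)),
    sp("DM2", sn("diabetes mellitus type 2", 1.0, "C0011860")),
    sp("HIV", sn("human immunodeficiency virus", 1.0)),
    sp("IL-6", sn("interleukin 6", 1.0)),
    sp("PSA", sn("prostate specific antigen", 0.75),
       sn("psoriatic skin assessment", 0.25)),
    sp("CRP", sn("c-reactive protein", 0.8),
       sn("cardiac rehabilitation program", 0.2)),
    sp("MS", sn("multiple sclerosis", 0.5), sn("mitral stenosis", 0.3),
       sn("mass spectrometry", 0.2)),
    sp("RA", sn("rheumatoid arthritis", 0.6), sn("right atrium", 0.4)),
    sp("CF", sn("cystic fibrosis", 0.7), sn("cardiac fibrosis", 0.3)),
    sp("TB", sn("tuberculosis", 1.0)),
    sp("ER", sn("estrogen receptor", 0.5), sn("endoplasmic reticulum", 0.5)),
    sp("PD", sn("parkinson disease", 0.6), sn("peritoneal dialysis", 0.4)),
    sp("GA", sn("gestational age", 0.5), sn("general anesthesia", 0.5)),
    sp("BP", sn("blood pressure", 0.8), sn("bipolar disorder", 0.2)),
    sp("UA", sn("uric acid", 0.5), sn("unstable angina", 0.5)),
    sp("HR", sn("heart rate", 0.7), sn("hazard ratio", 0.3)),
    sp("OA", sn("osteoarthritis", 0.8), sn("occipital artery", 0.2)),
    sp("CS", sn("cesarean section", 0.6), sn("corticosteroid", 0.4)),
    sp("DM", sn("dermatomyositis", 0.6), sn("diastolic murmur", 0.4)),
    sp("LA", sn("left atrium", 0.6), sn("local anesthesia", 0.4)),
    sp("VT", sn("ventricular tachycardia", 0.8), sn("visual threshold", 0.2)),
    sp("SD", sn("standard deviation", 0.7), sn("sleep disorder", 0.3)),
    sp("T2D", sn("type 2 diabetes", 1.0)),
    sp("5-HT", sn("5-hydroxytryptamine", 1.0)),
    sp("HbA1c", sn("hemoglobin a1c", 1.0))
  )
}

#' Default filler vocabulary
#'
#' Neutral words that contain no parentheses, collide with no configured
#' short form and appear in no planted long form, so the generated ground
#' truth stays exact.
#'
#' @return Character vector of words.
#' @export
acrosim_filler_words <- function() {
  c("patients", "study", "results", "cohort", "measured", "observed",
    "significant", "baseline", "reported", "symptoms", "evaluated",
    "findings", "improvement", "methods", "groups", "controls",
    "compared", "increased", "decreased", "during", "within", "without",
    "several", "moreover", "however", "furthermore", "overall", "notably",
    "markedly", "substantially", "routinely", "subsequently",
    "previously", "typically", "frequently", "consistently")
}

#' Configure the synthetic-corpus generator
#'
#' Verifies at construction that per-acronym sense probabilities sum to
#' 1, that every (short form, long form) pair is exactly recoverable by
#' the alignment heuristic ([best_long_form()] applied to the long form
#' must return the long form itself, and the long form must fit the
#' alignment word window), and that filler words contain no parentheses
#' and collide with no short form.
#'
#' @param n_docs Number of documents to generate.
#' @param acronym_specs See [acrosim_default_specs()].
#' @param mentions_per_doc Integer range (length 2) of subsequent
#'   mentions per planted acronym, after the defining mention.
#' @param acronyms_per_doc Integer range (length 2) of distinct acronyms
#'   planted per document.
#' @param filler_vocabulary Character vector of filler words.
#' @param seed Integer seed.
#' @return A list of class `acro_synth_config`.
#' @export
synth_config <- function(n_docs = 2000L,
                         acronym_specs = acrosim_default_specs(),
                         mentions_per_doc = c(2L, 5L),
                         acronyms_per_doc = c(1L, 3L),
                         filler_vocabulary = acrosim_filler_words(),
                         seed = 1L) {
  stopifnot(n_docs >= 0L, length(mentions_per_doc) == 2L,
            length(acronyms_per_doc) == 2L,
            mentions_per_doc[1] >= 0L,
            mentions_per_doc[1] <= mentions_per_doc[2],
            acronyms_per_doc[1] >= 1L,
            acronyms_per_doc[1] <= acronyms_per_doc[2],
            length(filler_vocabulary) >= 5L)
  sfs <- vapply(acronym_specs, `[[`, character(1), "short_form")
  if (anyDuplicated(sfs)) stop("duplicate short forms in acronym_specs",
                               call. = FALSE)
  for (spec in acronym_specs) {
    sf <- spec$short_form
    if (!is_valid_short_form(sf)) {
      stop("short form '", sf, "' fails the validity rules", call. = FALSE)
    }
    probs <- vapply(spec$senses, `[[`, numeric(1), "prob")
    if (abs(sum(probs) - 1) > 1e-8) {
      stop("sense probabilities for '", sf, "' must sum to 1",
           call. = FALSE)
    }
    for (s in spec$senses) {
      lf <- s$long_form
      got <- best_long_form(sf, lf)
      if (is.na(got) || got != lf) {
        stop("pair ('", sf, "', '", lf, "') fails alignment: the long ",
             "form is not exactly recoverable", call. = FALSE)
      }
      if (count_words(lf) > min(nchar(sf) + 5L, 2L * nchar(sf))) {
        stop("pair ('", sf, "', '", lf, "') exceeds the alignment word ",
             "window", call. = FALSE)
      }
    }
  }
  if (any(grepl("[()]", filler_vocabulary))) {
    stop("filler words must not contain parentheses", call. = FALSE)
  }
  clash <- tolower(filler_vocabulary) %in% tolower(sfs)
  if (any(clash)) {
    stop("filler word(s) collide with a short form: ",
         paste(filler_vocabulary[clash], collapse = ", "), call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs),
                 acronym_specs = acronym_specs,
                 mentions_per_doc = as.integer(mentions_per_doc),
                 acronyms_per_doc = as.integer(acronyms_per_doc),
                 filler_vocabulary = filler_vocabulary,
                 seed = as.integer(seed)),
            class = "acro_synth_config")
}

cap_first <- function(w) {
  paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))
}

#' Generate a synthetic corpus with exact ground truth
#'
#' Each document draws 1-3 acronyms (range configurable); per acronym one
#' sense is drawn from its probability table, the first mention is the
#' defining expression `"long form (SF)"`, and the configured number of
#' subsequent mentions alternates randomly between the long and the short
#' form, separated by filler sentences. Same seed, same output.
#'
#' @param config An [synth_config()].
#' @return A list with `corpus` (an [acro_corpus()]) and `ground_truth`
#'   (class `acro_ground_truth`): `definitions` (planted definitions with
#'   0-based spans), `senses` (the true sense per document and acronym),
#'   `counts` (long-form and bare short-form mention counts per document
#'   and acronym) and `mentions` (every planted mention span).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "acro_synth_config"))
  restore <- seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  specs <- config$acronym_specs
  filler <- config$filler_vocabulary
  mrange <- config$mentions_per_doc
  arange <- config$acronyms_per_doc

  docs <- vector("list", config$n_docs)
  defs <- list(); senses <- list(); counts <- list(); mentions <- list()

  for (d in seq_len(config$n_docs)) {
    doc_id <- sprintf("SYN%05d", d)
    k <- min(sample(arange[1]:arange[2], 1L), length(specs))
    chosen <- sample(seq_along(specs), k)
    sents <- character(0)
    cursor <- 0L  # 0-based offset of the next sentence start
    add_sentence <- function(s) {
      sents[[length(sents) + 1L]] <<- s
      start <- cursor
      cursor <<- cursor + nchar(s) + 1L  # +1 for the joining space
      start
    }
    filler_sentence <- function(nw) {
      w <- sample(filler, nw, replace = TRUE)
      w[1L] <- cap_first(w[1L])
      paste0(paste(w, collapse = " "), ".")
    }
    for (ci in chosen) {
      spec <- specs[[ci]]
      sf <- spec$short_form
      probs <- vapply(spec$senses, `[[`, numeric(1), "prob")
      si <- sample.int(length(probs), 1L, prob = probs)
      sense <- spec$senses[[si]]
      lf <- sense$long_form
      n_ment <- if (mrange[1] == mrange[2]) mrange[1] else
        sample(mrange[1]:mrange[2], 1L)

      # defining sentence: "<Filler ...> <long form> (<SF>)."
      pre <- sample(filler, sample(2:4, 1L), replace = TRUE)
      pre[1L] <- cap_first(pre[1L])
      prefix <- paste(pre, collapse = " ")
      sent <- paste0(prefix, " ", lf, " (", sf, ").")
      start <- add_sentence(sent)
      lf_start <- start + nchar(prefix) + 1L
      sf_start <- lf_start + nchar(lf) + 2L
      defs[[length(defs) + 1L]] <- data.frame(
        doc_id = doc_id, short_form = sf, long_form = lf,
        short_start = sf_start, short_end = sf_start + nchar(sf),
        long_start = lf_start, long_end = lf_start + nchar(lf),
        stringsAsFactors = FALSE)
      mentions[[length(mentions) + 1L]] <- data.frame(
        doc_id = doc_id, acronym = sf, surface = lf, start = lf_start,
        end = lf_start + nchar(lf), kind = "definition",
        stringsAsFactors = FALSE)
      n_long <- 1L
      n_short <- 0L

      for (m in seq_len(n_ment)) {
        add_sentence(filler_sentence(sample(3:7, 1L)))
        use_sf <- stats::runif(1L) < 0.5
        surface <- if (use_sf) sf else lf
        pre <- sample(filler, sample(1:3, 1L), replace = TRUE)
        pre[1L] <- cap_first(pre[1L])
        post <- sample(filler, sample(1:3, 1L), replace = TRUE)
        prefix <- paste(pre, collapse = " ")
        sent <- paste0(prefix, " ", surface, " ",
                       paste(post, collapse = " "), ".")
        start <- add_sentence(sent)
        m_start <- start + nchar(prefix) + 1L
        mentions[[length(mentions) + 1L]] <- data.frame(
          doc_id = doc_id, acronym = sf, surface = surface,
          start = m_start, end = m_start + nchar(surface),
          kind = if (use_sf) "short" else "long", stringsAsFactors = FALSE)
        if (use_sf) n_short <- n_short + 1L else n_long <- n_long + 1L
      }
      senses[[length(senses) + 1L]] <- data.frame(
        doc_id = doc_id, acronym = sf, long_form = lf,
        concept_id = sense$concept_id, prob = sense$prob,
        stringsAsFactors = FALSE)
      counts[[length(counts) + 1L]] <- data.frame(
        doc_id = doc_id, acronym = sf, n_long = n_long,
        n_short = n_short, stringsAsFactors = FALSE)
    }
    body <- paste(sents, collapse = " ")
    docs[[d]] <- acro_document(doc_id, body,
                               title = paste("Synthetic abstract", d))
  }

  bind <- function(lst, proto) {
    if (length(lst) == 0L) return(proto)
    out <- do.call(rbind, lst)
    row.names(out) <- NULL
    out
  }
  gt <- structure(list(
    definitions = bind(defs, data.frame(
      doc_id = character(0), short_form = character(0),
      long_form = character(0), short_start = integer(0),
      short_end = integer(0), long_start = integer(0),
      long_end = integer(0), stringsAsFactors = FALSE)),
    senses = bind(senses, data.frame(
      doc_id = character(0), acronym = character(0),
      long_form = character(0), concept_id = character(0),
      prob = numeric(0), stringsAsFactors = FALSE)),
    counts = bind(counts, data.frame(
      doc_id = character(0), acronym = character(0), n_long = integer(0),
      n_short = integer(0), stringsAsFactors = FALSE)),
    mentions = bind(mentions, data.frame(
      doc_id = character(0), acronym = character(0),
      surface = character(0), start = integer(0), end = integer(0),
      kind = character(0), stringsAsFactors = FALSE))),
    class = "acro_ground_truth")

  list(corpus = acro_corpus(docs,
                            source_description = sprintf(
                              "synthetic corpus (n_docs=%d, seed=%d)",
                              config$n_docs, config$seed)),
       ground_truth = gt)
}

#' Compare extraction output against generator ground truth
#'
#' Runs [extract_definitions()] on every document and compares the
#' recognized (short form, long form, spans) tuples to the planted
#' definitions, reporting per-document and pooled exact-match precision
#' and recall.
#'
#' @param corpus Corpus produced by [generate_corpus()].
#' @param ground_truth The matching ground truth.
#' @param patterns Passed to [extract_definitions()].
#' @return A list of class `acro_closed_loop`: `per_document` (data
#'   frame `doc_id`, `n_extracted`, `n_truth`, `n_matched`, `precision`,
#'   `recall`) and pooled `precision` and `recall`.
#' @export
closed_loop_check <- function(corpus, ground_truth,
                              patterns = c("both", "forward")) {
  patterns <- match.arg(patterns)
  gt <- ground_truth$definitions
  gt_key_all <- paste(gt$doc_id, gt$short_form, gt$long_form,
                      gt$short_start, gt$short_end, gt$long_start,
                      gt$long_end, sep = "\r")
  rows <- vector("list", length(corpus$documents))
  for (i in seq_along(corpus$documents)) {
    doc <- corpus$documents[[i]]
    ext <- extract_definitions(doc, patterns)
    ext_key <- paste(doc$doc_id, ext$short_form, ext$long_form,
                     ext$short_start, ext$short_end, ext$long_start,
                     ext$long_end, sep = "\r")
    gkey <- gt_key_all[gt$doc_id == doc$doc_id]
    # multiset intersection
    all_keys <- union(ext_key, gkey)
    matched <- sum(pmin(tabulate(match(ext_key, all_keys),
                                 length(all_keys)),
                        tabulate(match(gkey, all_keys), length(all_keys))))
    rows[[i]] <- data.frame(
      doc_id = doc$doc_id, n_extracted = length(ext_key),
      n_truth = length(gkey), n_matched = matched,
      precision = if (length(ext_key)) matched / length(ext_key) else 1,
      recall = if (length(gkey)) matched / length(gkey) else 1,
      stringsAsFactors = FALSE)
  }
  per_doc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(doc_id = character(0), n_extracted = integer(0),
               n_truth = integer(0), n_matched = integer(0),
               precision = numeric(0), recall = numeric(0),
               stringsAsFactors = FALSE)
  row.names(per_doc) <- NULL
  tot_ext <- sum(per_doc$n_extracted)
  tot_gt <- sum(per_doc$n_truth)
  tot_match <- sum(per_doc$n_matched)
  structure(list(per_document = per_doc,
                 precision = if (tot_ext) tot_match / tot_ext else 1,
                 recall = if (tot_gt) tot_match / tot_gt else 1),
            class = "acro_closed_loop")
}

#' @export
print.acro_closed_loop <- function(x, ...) {
  cat(sprintf("<acro_closed_loop> precision %.4f, recall %.4f over %d document(s)\n",
              x$precision, x$recall, nrow(x$per_document)))
  invisible(x)
}
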