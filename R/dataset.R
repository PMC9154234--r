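# Sentence-level WSD sample construction, per-acronym split reservation,
# and the most-frequent-sense baseline.

#' Rule-based sentence segmentation
#'
#' Splits at '.', '!' or '?' followed by whitespace and an uppercase
#' letter or digit. An abbreviation guard suppresses the split when the
#' period is preceded by a single uppercase letter (initials) or by a
#' token in a small built-in list ("e.g", "i.e", "vs", "Fig", "et al").
#' The returned intervals tile the body: each sentence runs from the end
#' of the previous one, so inter-sentence whitespace belongs to the
#' following interval.
#'
#' @param body Document text.
#' @return Data frame with columns `start`, `end` (0-based half-open
#'   intervals tiling the body). Zero rows for empty input.
#' @export
split_sentences <- function(body) {
  n <- nchar(body)
  if (is.na(body) || n == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- gregexpr("[.!?](?=[[:space:]]+[A-Z0-9])", body, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    for (p in as.integer(m)) {
      if (substr(body, p, p) == ".") {
        before <- substr(body, 1L, p - 1L)
        tok <- sub("^.*[[:space:]]", "", before)
        tok <- gsub("^[^[:alnum:]]+", "", tok)  # strip leading punctuation
        if (grepl("^[A-Z]$", tok)) next  # single-letter initial
        low <- tolower(tok)
        if (low %in% c("e.g", "i.e", "vs", "fig")) next
        if (low == "al" &&
            grepl("(^|[[:space:]])et[[:space:]]+al$", tolower(before))) next
      }
      cuts <- c(cuts, p)  # split right after the punctuation character
    }
  }
  data.frame(start = c(0L, cuts), end = c(cuts, n))
}

#' Generate labelled WSD samples from annotated documents
#'
#' Every annotated acronym occurrence whose acronym is ambiguous (at
#' least two senses in the inventory) yields one positive sample — the
#' enclosing sentence, the acronym, the canonical long form of the
#' annotated sense, label 1 — plus `min(k_neg, n_senses - 1)` negative
#' samples with distinct incorrect senses drawn uniformly without
#' replacement. Non-ambiguous acronyms contribute nothing. Uses the
#' current RNG state; see [build_wsd_dataset()] for the seeded wrapper.
#'
#' @param docs List of `acro_annotated_document` objects.
#' @param inventory The matching [build_inventory()] result.
#' @param k_neg Number of negative samples per positive (>= 1).
#' @return Data frame with columns `doc_id`, `sentence`, `acronym`
#'   (normalized), `candidate_long_form`, `candidate_sense_id`, `label`
#'   (1 positive, 0 negative).
#' @export
generate_samples <- function(docs, inventory, k_neg = 1L) {
  if (!is.numeric(k_neg) || k_neg < 1L) {
    stop("`k_neg` must be a count >= 1", call. = FALSE)
  }
  k_neg <- as.integer(k_neg)
  amb <- ambiguous_acronyms(inventory)
  inv <- unclass(inventory)
  out <- list()
  for (doc in docs) {
    ann <- doc$annotations
    if (is.null(ann) || nrow(ann) == 0L) next
    sent <- split_sentences(doc$body)
    for (i in seq_len(nrow(ann))) {
      acr <- normalize_short_form(ann$acronym[i])
      if (!(acr %in% amb)) next
      senses <- inv[[acr]]
      sids <- vapply(senses, `[[`, character(1), "sense_id")
      canon <- vapply(senses, `[[`, character(1), "canonical_long_form")
      true_sid <- ann$sense_id[i]
      j <- which(sent$start <= ann$start[i] & ann$start[i] < sent$end)[1L]
      stext <- trimws(substr0(doc$body, sent$start[j], sent$end[j]))
      wrong <- setdiff(sids, true_sid)
      neg <- if (length(wrong) <= k_neg) wrong else sample(wrong, k_neg)
      cand_sids <- c(true_sid, neg)
      out[[length(out) + 1L]] <- data.frame(
        doc_id = doc$doc_id,
        sentence = stext,
        acronym = acr,
        candidate_long_form = canon[match(cand_sids, sids)],
        candidate_sense_id = cand_sids,
        label = c(1L, rep(0L, length(neg))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(doc_id = character(0), sentence = character(0),
                      acronym = character(0),
                      candidate_long_form = character(0),
                      candidate_sense_id = character(0), label = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Reserve per-acronym validation and test samples
#'
#' For each acronym with `n` samples, `r = 1000` when `n >= 10000`, else
#' `r = floor(0.10 * n)`, samples are drawn randomly without replacement
#' and reserved for validation, and another `r` for test; the remainder
#' goes to training. Splitting is performed per acronym before pooling.
#' Uses the current RNG state.
#'
#' @param samples Data frame from [generate_samples()].
#' @return A list of class `acro_splits`: `train`, `validation`, `test`
#'   (data frames with the columns of `samples`) and `per_acronym_counts`
#'   (data frame `acronym`, `n`, `reserved`).
#' @export
reserve_splits <- function(samples) {
  cols <- names(samples)
  take <- function(idx) {
    out <- samples[idx, cols, drop = FALSE]
    row.names(out) <- NULL
    out
  }
  acrs <- sort(unique(samples$acronym))
  tr <- va <- te <- integer(0)
  counts <- list()
  for (a in acrs) {
    idx <- which(samples$acronym == a)
    n <- length(idx)
    if (n == 0L) next
    r <- if (n >= 10000L) 1000L else as.integer(floor(0.10 * n))
    perm <- idx[sample.int(n)]
    va <- c(va, perm[seq_len(r)])
    te <- c(te, perm[r + seq_len(r)])
    tr <- c(tr, perm[if (2L * r < n) (2L * r + 1L):n else integer(0)])
    counts[[length(counts) + 1L]] <- data.frame(
      acronym = a, n = n, reserved = r, stringsAsFactors = FALSE)
  }
  counts <- if (length(counts)) do.call(rbind, counts) else
    data.frame(acronym = character(0), n = integer(0),
               reserved = integer(0), stringsAsFactors = FALSE)
  row.names(counts) <- NULL
  structure(list(train = take(sort(tr)), validation = take(sort(va)),
                 test = take(sort(te)), per_acronym_counts = counts),
            class = "acro_splits")
}

#' @export
print.acro_splits <- function(x, ...) {
  cat("<acro_splits> train ", nrow(x$train), ", validation ",
      nrow(x$validation), ", test ", nrow(x$test), " samples over ",
      nrow(x$per_acronym_counts), " acronym(s)\n", sep = "")
  invisible(x)
}

#' Fit the most-frequent-sense baseline
#'
#' For each acronym, picks the sense with the highest positive-sample
#' count in the training split; ties are broken lexicographically by
#' sense id. Acronyms absent from training are absent from the table and
#' default to a negative prediction.
#'
#' @param train Training samples (data frame as from
#'   [generate_samples()]).
#' @return Named character vector: acronym -> most frequent sense id.
#' @export
mfs_fit <- function(train) {
  pos <- train[train$label == 1L, , drop = FALSE]
  if (nrow(pos) == 0L) return(stats::setNames(character(0), character(0)))
  tabs <- tapply(pos$candidate_sense_id, pos$acronym, function(sids) {
    tab <- table(sids)
    sort(names(tab)[tab == max(tab)])[1L]
  })
  out <- as.character(tabs)
  names(out) <- names(tabs)
  out[order(names(out))]
}

#' Predict with the most-frequent-sense baseline
#'
#' A sample is predicted positive iff its candidate sense id equals the
#' table entry for its acronym; acronyms missing from the table are
#' predicted negative.
#'
#' @param samples Data frame of samples.
#' @param table [mfs_fit()] result.
#' @return Logical vector of predictions.
#' @export
mfs_predict <- function(samples, table) {
  pred <- unname(table[samples$acronym]) == samples$candidate_sense_id
  pred[is.na(pred)] <- FALSE
  pred
}

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 with the positive class as target.
#' Ratios with a zero denominator are reported as 0 with a warning.
#'
#' @param predictions Logical (or 0/1) vector of predictions.
#' @param labels Logical (or 0/1) vector of gold labels, same length.
#' @return A list of class `acro_metrics` with `accuracy`, `precision`,
#'   `recall`, `f1` and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_predictions <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels)) {
    stop("predictions and labels must be non-empty and of equal length",
         call. = FALSE)
  }
  p <- as.logical(predictions)
  l <- as.logical(labels)
  if (anyNA(p) || anyNA(l)) stop("NA in predictions or labels", call. = FALSE)
  tp <- sum(p & l); fp <- sum(p & !l); fn <- sum(!p & l); tn <- sum(!p & !l)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as 0",
              call. = FALSE)
      0
    } else num / den
  }
  accuracy <- (tp + tn) / length(p)
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "F1")
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, tp = tp, fp = fp, fn = fn,
                 tn = tn),
            class = "acro_metrics")
}

#' @export
print.acro_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("accuracy %.*f  precision %.*f  recall %.*f  F1 %.*f\n",
              digits, x$accuracy, digits, x$precision, digits, x$recall,
              digits, x$f1))
  invisible(x)
}

#' Build the labelled dataset from a simulation
#'
#' Seeded wrapper around [generate_samples()] and [reserve_splits()].
#'
#' @param sim An [simulate_corpus()] result.
#' @param k_neg Negatives per positive (default 1).
#' @param seed Integer seed for negative-sense draws and split
#'   reservation.
#' @return An `acro_splits` object with attributes `k_neg` and `seed`.
#' @export
build_wsd_dataset <- function(sim, k_neg = 1L, seed = 1L) {
  restore <- seed_guard(seed)
  on.exit(restore(), add = TRUE)
  samples <- generate_samples(sim$documents, sim$inventory, k_neg)
  splits <- reserve_splits(samples)
  attr(splits, "k_neg") <- as.integer(k_neg)
  attr(splits, "seed") <- as.integer(seed)
  splits
}

#' Export dataset splits as tab-separated text
#'
#' Writes one TSV per split (`<prefix>.train.tsv`,
#' `<prefix>.validation.tsv`, `<prefix>.test.tsv`) with columns
#' `sentence`, `acronym`, `candidate_long_form`, `label` — the flat
#' format consumed by external sequence-pair trainers.
#'
#' @param splits An `acro_splits` object.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_dataset_tsv <- function(splits, prefix) {
  stopifnot(inherits(splits, "acro_splits"))
  paths <- character(0)
  for (part in c("train", "validation", "test")) {
    df <- splits[[part]][, c("sentence", "acronym", "candidate_long_form",
                             "label"), drop = FALSE]
    path <- paste0(prefix, ".", part, ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Evaluate the most-frequent-sense baseline on a split
#'
#' Fits [mfs_fit()] on the training split and evaluates on the requested
#' split.
#'
#' @param splits An `acro_splits` object.
#' @param split `"test"` (default), `"validation"` or `"train"`.
#' @return An `acro_metrics` object.
#' @export
eval_mfs_baseline <- function(splits, split = c("test", "validation",
                                                "train")) {
  split <- match.arg(split)
  table <- mfs_fit(splits$train)
  s <- splits[[split]]
  evaluate_predictions(mfs_predict(s, table), s$label)
}
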