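# Global-acronym simulation: rewrite a document so that, per acronym,
# either the acronym or its full form is used consistently throughout,
# recording every removed full form as a sense annotation.

#' Randomly decide the usage style per (document, acronym)
#'
#' One independent fair draw (p = 0.5) per acronym defined in the
#' document: `"ACRONYM"` (the acronym is used globally) or `"FULL_FORM"`
#' (the full form is used globally). Uses the current RNG state; seed via
#' [set.seed()] or the `seed` argument of [simulate_corpus()].
#'
#' @param document An [acro_document()].
#' @param definitions Data frame of definitions for this document
#'   ([extract_definitions()]).
#' @return Data frame with columns `doc_id`, `acronym` (normalized short
#'   form) and `style`.
#' @export
decide_styles <- function(document, definitions) {
  defs <- definitions[definitions$doc_id == document$doc_id, , drop = FALSE]
  acrs <- unique(normalize_short_form(defs$short_form))
  if (length(acrs) == 0L) {
    return(data.frame(doc_id = character(0), acronym = character(0),
                      style = character(0), stringsAsFactors = FALSE))
  }
  data.frame(doc_id = document$doc_id, acronym = acrs,
             style = ifelse(stats::runif(length(acrs)) < 0.5,
                            "ACRONYM", "FULL_FORM"),
             stringsAsFactors = FALSE)
}

empty_annotations <- function() {
  data.frame(start = integer(0), end = integer(0), acronym = character(0),
             sense_id = character(0), removed_surface = character(0),
             stringsAsFactors = FALSE)
}

#' Rewrite a document for consistent acronym or full-form usage
#'
#' For each acronym with an `"ACRONYM"`-style decision, the defining
#' expression `"long form (SF)"` (or its reversed variant) is collapsed to
#' the short form and every other token-boundary, case-insensitive
#' occurrence of any known variant surface of that document's sense is
#' replaced by the short form; every resulting acronym occurrence
#' (including pre-existing bare occurrences) carries a sense annotation
#' whose `removed_surface` is the full form it replaces (empty when the
#' occurrence was already the acronym). For `"FULL_FORM"`-style decisions
#' the defining expression is collapsed to the full form and every bare
#' acronym token is replaced by it; no annotations are emitted. Spans are
#' recomputed after all replacements. Overlapping definition mentions are
#' resolved in favour of the earlier one (the later is dropped with a
#' warning).
#'
#' @param document An [acro_document()].
#' @param definitions Definitions extracted from this document.
#' @param inventory An [build_inventory()] result covering the
#'   definitions.
#' @param decisions Style decisions covering every acronym defined in the
#'   document (error otherwise).
#' @return A list of class `acro_annotated_document`: `doc_id`, `title`,
#'   `body` (transformed), `annotations` (data frame `start`, `end`,
#'   `acronym`, `sense_id`, `removed_surface`; 0-based half-open spans
#'   into the transformed body) and `decisions`.
#' @export
globalize <- function(document, definitions, inventory, decisions) {
  body <- document$body
  defs <- definitions[definitions$doc_id == document$doc_id, , drop = FALSE]
  out_doc <- function(body, ann, dec) {
    structure(list(doc_id = document$doc_id, title = document$title,
                   body = body, annotations = ann, decisions = dec),
              class = "acro_annotated_document")
  }
  dec <- decisions[decisions$doc_id == document$doc_id, , drop = FALSE]
  if (nrow(defs) == 0L) {
    return(out_doc(body, empty_annotations(),
                   dec[, c("doc_id", "acronym", "style"), drop = FALSE]))
  }

  # definition regions cover "long form (SF)" / "SF (long form)"
  defs$region_start <- ifelse(defs$pattern == "reverse",
                              defs$short_start,
                              pmin(defs$long_start, defs$short_start))
  defs$region_end <- defs$paren_close + 1L
  defs <- defs[order(defs$region_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(defs))
  last_end <- -1L
  for (i in seq_len(nrow(defs))) {
    if (defs$region_start[i] < last_end) {
      keep[i] <- FALSE
      warning("overlapping definition mention dropped in document '",
              document$doc_id, "'", call. = FALSE)
    } else {
      last_end <- defs$region_end[i]
    }
  }
  defs <- defs[keep, , drop = FALSE]

  acrs <- unique(normalize_short_form(defs$short_form))
  missing <- setdiff(acrs, dec$acronym)
  if (length(missing)) {
    stop("style decisions missing for acronym(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  def_regions <- defs[, c("region_start", "region_end")]
  overlaps_def <- function(s, e) {
    any(s < def_regions$region_end & def_regions$region_start < e)
  }

  intervals <- list()
  push <- function(start, end, replacement, annotate, removed, acr_surface,
                   sid) {
    intervals[[length(intervals) + 1L]] <<- list(
      start = as.integer(start), end = as.integer(end),
      replacement = replacement, annotate = annotate,
      removed_surface = removed, acronym = acr_surface, sense_id = sid)
  }

  for (a in acrs) {
    adefs <- defs[normalize_short_form(defs$short_form) == a, , drop = FALSE]
    first <- adefs[1L, ]
    sense <- find_sense_for_surface(inventory, a, first$long_form)
    if (is.null(sense)) {
      stop("no sense in inventory for acronym '", a, "' long form '",
           first$long_form, "'", call. = FALSE)
    }
    sf_surface <- first$short_form
    style <- dec$style[dec$acronym == a][1L]

    # 1. collapse defining expressions
    for (i in seq_len(nrow(adefs))) {
      d <- adefs[i, ]
      if (style == "ACRONYM") {
        push(d$region_start, d$region_end, d$short_form, TRUE,
             d$long_form, d$short_form, sense$sense_id)
      } else {
        push(d$region_start, d$region_end, d$long_form, FALSE, "",
             d$short_form, sense$sense_id)
      }
    }

    # 2. replace scattered occurrences of the non-chosen surface and
    #    annotate pre-existing acronym occurrences
    if (style == "ACRONYM") {
      for (v in unique(c(sense$variants, adefs$long_form))) {
        occ <- token_occurrences(body, v)
        for (j in seq_len(nrow(occ))) {
          if (overlaps_def(occ$start[j], occ$end[j])) next
          push(occ$start[j], occ$end[j], sf_surface, TRUE,
               substr0(body, occ$start[j], occ$end[j]),
               sf_surface, sense$sense_id)
        }
      }
      occ <- token_occurrences(body, sf_surface)
      for (j in seq_len(nrow(occ))) {
        if (overlaps_def(occ$start[j], occ$end[j])) next
        push(occ$start[j], occ$end[j],
             substr0(body, occ$start[j], occ$end[j]), TRUE, "",
             substr0(body, occ$start[j], occ$end[j]), sense$sense_id)
      }
    } else {
      occ <- token_occurrences(body, sf_surface)
      for (j in seq_len(nrow(occ))) {
        if (overlaps_def(occ$start[j], occ$end[j])) next
        push(occ$start[j], occ$end[j], first$long_form, FALSE, "",
             sf_surface, sense$sense_id)
      }
    }
  }

  if (length(intervals) == 0L) {
    return(out_doc(body, empty_annotations(),
                   dec[, c("doc_id", "acronym", "style"), drop = FALSE]))
  }
  iv <- do.call(rbind, lapply(intervals, function(x) {
    data.frame(start = x$start, end = x$end, replacement = x$replacement,
               annotate = x$annotate, removed_surface = x$removed_surface,
               acronym = x$acronym, sense_id = x$sense_id,
               stringsAsFactors = FALSE)
  }))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(iv))
  last_end <- -1L
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] < last_end) {
      keep[i] <- FALSE
    } else {
      last_end <- iv$end[i]
    }
  }
  iv <- iv[keep, , drop = FALSE]

  # splice left-to-right, tracking the offset shift for new spans
  pieces <- character(0)
  cursor <- 0L  # 0-based position in original body
  delta <- 0L
  new_start <- integer(nrow(iv))
  new_end <- integer(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    pieces <- c(pieces, substr0(body, cursor, iv$start[i]), iv$replacement[i])
    new_start[i] <- iv$start[i] + delta
    new_end[i] <- new_start[i] + nchar(iv$replacement[i])
    delta <- delta + nchar(iv$replacement[i]) - (iv$end[i] - iv$start[i])
    cursor <- iv$end[i]
  }
  pieces <- c(pieces, substr0(body, cursor, nchar(body)))
  new_body <- paste(pieces, collapse = "")

  ann_rows <- which(iv$annotate)
  ann <- if (length(ann_rows)) {
    data.frame(start = new_start[ann_rows], end = new_end[ann_rows],
               acronym = iv$replacement[ann_rows],
               sense_id = iv$sense_id[ann_rows],
               removed_surface = iv$removed_surface[ann_rows],
               stringsAsFactors = FALSE)
  } else {
    empty_annotations()
  }
  row.names(ann) <- NULL
  out_doc(new_body, ann, dec[, c("doc_id", "acronym", "style"), drop = FALSE])
}

#' @export
print.acro_annotated_document <- function(x, ...) {
  cat("<acro_annotated_document> ", x$doc_id, ": ", nchar(x$body),
      " chars, ", nrow(x$annotations), " annotation(s)\n", sep = "")
  invisible(x)
}

#' Simulate global acronym usage over a whole corpus
#'
#' Runs definition extraction on every document, builds (or reuses) the
#' sense inventory, draws one style decision per (document, acronym) and
#' rewrites every document with [globalize()].
#'
#' @param corpus An [acro_corpus()].
#' @param seed Integer seed driving the style decisions.
#' @param patterns Passed to [extract_definitions()].
#' @param concept_map Optional [concept_map()] used when building the
#'   inventory.
#' @param inventory Optional pre-built inventory; built from the corpus
#'   definitions when `NULL`.
#' @return A list of class `acro_simulation`: `documents` (list of
#'   `acro_annotated_document`), `inventory`, `definitions`, `seed`,
#'   `patterns`.
#' @export
simulate_corpus <- function(corpus, seed = 1L,
                            patterns = c("both", "forward"),
                            concept_map = NULL, inventory = NULL) {
  patterns <- match.arg(patterns)
  definitions <- extract_corpus_definitions(corpus, patterns)
  if (is.null(inventory)) {
    inventory <- build_inventory(definitions, concept_map)
  }
  restore <- seed_guard(seed)
  on.exit(restore(), add = TRUE)
  docs <- lapply(corpus$documents, function(doc) {
    dec <- decide_styles(doc, definitions)
    globalize(doc, definitions, inventory, dec)
  })
  structure(list(documents = docs, inventory = inventory,
                 definitions = definitions, seed = as.integer(seed),
                 patterns = patterns),
            class = "acro_simulation")
}

#' @export
print.acro_simulation <- function(x, ...) {
  n_ann <- sum(vapply(x$documents, function(d) nrow(d$annotations),
                      integer(1)))
  cat("<acro_simulation> ", length(x$documents), " document(s), ",
      nrow(x$definitions), " definition(s), ", n_ann, " annotation(s)\n",
      sep = "")
  invisible(x)
}
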