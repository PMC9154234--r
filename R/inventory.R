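# Sense inventory: normalize long forms, unify variants that denote the
# same concept (via an offline concept map when supplied, else by
# normalized-surface equality), and decide which acronyms are ambiguous.

#' Normalize a long-form surface
#'
#' Lowercases, collapses internal whitespace to single spaces, strips
#' leading/trailing whitespace and sentence-final punctuation. Hyphens are
#' retained, so roman/arabic numeral variants ("type II" vs "type 2") are
#' NOT unified by normalization alone — only a concept map merges those.
#'
#' @param surface Character vector of long-form surfaces.
#' @return Normalized character vector.
#' @export
normalize_long_form <- function(surface) {
  s <- tolower(surface)
  s <- gsub("[[:space:]]+", " ", s)
  s <- trimws(s)
  sub("[.!?;:,]+$", "", s)
}

#' Normalize a short-form surface
#'
#' Uppercases and trims; digits and hyphens pass through ("dm2" -> "DM2").
#'
#' @param surface Character vector of short-form surfaces.
#' @return Normalized character vector.
#' @export
normalize_short_form <- function(surface) {
  toupper(trimws(surface))
}

#' Build a concept map from long forms and concept identifiers
#'
#' The concept map is the offline stand-in for a terminology-service
#' lookup: it sends a normalized long-form surface to at most one concept
#' identifier. Rows whose surfaces normalize to the same form must agree
#' on the identifier.
#'
#' @param long_form Character vector of long-form surfaces.
#' @param concept_id Character vector of concept identifiers (e.g. UMLS
#'   CUIs), same length.
#' @return A named character vector of class `acro_concept_map` keyed by
#'   normalized long form.
#' @export
concept_map <- function(long_form, concept_id) {
  stopifnot(length(long_form) == length(concept_id))
  key <- normalize_long_form(as.character(long_form))
  val <- as.character(concept_id)
  agg <- tapply(val, key, function(v) unique(v), simplify = FALSE)
  bad <- names(agg)[lengths(agg) > 1L]
  if (length(bad)) {
    stop("long form(s) mapped to more than one concept identifier: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- vapply(agg, `[[`, character(1), 1L)
  structure(out, class = "acro_concept_map")
}

#' Read a concept map from a two-column tab-separated file
#'
#' Format: `long_form <TAB> concept_id`, UTF-8, no header.
#'
#' @param path Path to the TSV file.
#' @return An [concept_map()] object.
#' @export
read_concept_map <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("concept map must have 2 tab-separated columns",
                          call. = FALSE)
  concept_map(df[[1L]], df[[2L]])
}

lookup_concept <- function(map, normalized_long_form) {
  if (is.null(map)) return(rep(NA_character_, length(normalized_long_form)))
  out <- unname(unclass(map)[normalized_long_form])
  as.character(out)
}

# small stable string hash (polynomial, mod prime < 2^26) used for sense
# identifiers when no concept identifier is available
stable_hash <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (cp in utf8ToInt(enc2utf8(s))) h <- (h * 31 + cp) %% 67108859
    sprintf("S%08d", h)
  }, character(1), USE.NAMES = FALSE)
}

#' Build a sense inventory from definition mentions
#'
#' Short forms are normalized to uppercase; long forms are grouped into
#' one sense when (a) their normalized surfaces are equal, or (b) a
#' concept map is supplied and both map to the same concept identifier.
#' Long forms without a concept-map hit fall back to rule (a) and are kept
#' as their own sense. The sense id is the concept identifier when
#' present, else a stable hash of the acronym plus the normalized
#' canonical form; the canonical long form is the most frequent variant
#' (ties broken lexicographically).
#'
#' @param mentions Data frame of definition mentions with at least
#'   `short_form` and `long_form` columns (as returned by
#'   [extract_definitions()]).
#' @param concept_map Optional [concept_map()].
#' @return A named list of class `acro_inventory`: one element per
#'   acronym (sorted), each a list of senses; a sense is a list with
#'   `sense_id`, `canonical_long_form`, `concept_id`, `variants` (sorted
#'   character vector of observed surfaces) and `n_mentions`.
#' @export
build_inventory <- function(mentions, concept_map = NULL) {
  out <- structure(list(), class = "acro_inventory")
  if (is.null(mentions) || nrow(mentions) == 0L) return(out)
  acr <- normalize_short_form(mentions$short_form)
  lf_raw <- mentions$long_form
  lf_norm <- normalize_long_form(lf_raw)
  cid <- lookup_concept(concept_map, lf_norm)
  key <- ifelse(is.na(cid), paste0("lf:", lf_norm), paste0("cui:", cid))

  entries <- list()
  for (a in sort(unique(acr))) {
    sel <- which(acr == a)
    senses <- list()
    for (k in unique(key[sel])) {
      rows <- sel[key[sel] == k]
      surfaces <- lf_raw[rows]
      tab <- table(surfaces)
      top <- max(tab)
      canonical <- sort(names(tab)[tab == top])[1L]
      this_cid <- cid[rows][1L]
      sid <- if (!is.na(this_cid)) this_cid else
        stable_hash(paste0(a, "|", normalize_long_form(canonical)))
      senses[[length(senses) + 1L]] <- list(
        sense_id = sid,
        canonical_long_form = canonical,
        concept_id = this_cid,
        variants = sort(unique(surfaces)),
        n_mentions = length(rows))
    }
    sids <- vapply(senses, `[[`, character(1), "sense_id")
    entries[[a]] <- senses[order(sids)]
  }
  structure(entries, class = "acro_inventory")
}

#' @export
print.acro_inventory <- function(x, ...) {
  cat("<acro_inventory> ", length(x), " acronym(s), ",
      sum(lengths(unclass(x))), " sense(s)\n", sep = "")
  invisible(x)
}

#' Acronyms with two or more senses
#'
#' Acronyms mapped to a single unified long form are non-ambiguous and are
#' excluded from dataset construction; this returns exactly the acronyms
#' with at least two senses.
#'
#' @param inventory An [build_inventory()] result.
#' @return Character vector of ambiguous acronyms (sorted).
#' @export
ambiguous_acronyms <- function(inventory) {
  x <- unclass(inventory)
  if (length(x) == 0L) return(character(0))
  sort(names(x)[lengths(x) >= 2L])
}

# sense ids of an acronym, and lookup of the sense that contains a given
# long-form surface (by normalized variant match)
sense_ids <- function(inventory, acronym) {
  senses <- unclass(inventory)[[normalize_short_form(acronym)]]
  vapply(senses, `[[`, character(1), "sense_id")
}

find_sense_for_surface <- function(inventory, acronym, long_form) {
  senses <- unclass(inventory)[[normalize_short_form(acronym)]]
  if (is.null(senses)) return(NULL)
  target <- normalize_long_form(long_form)
  for (s in senses) {
    if (target %in% normalize_long_form(s$variants)) return(s)
  }
  NULL
}
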