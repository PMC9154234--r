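#' Construct a document
#'
#' A document is one scientific abstract: a stable identifier, an optional
#' title and the abstract body. Character offsets into `body` (0-based,
#' half-open, counted in code points) are the coordinate system for every
#' downstream span.
#'
#' @param doc_id Non-empty string identifier, unique within a corpus.
#' @param body Abstract text.
#' @param title Title text; may be empty. Titles are never scanned or
#'   transformed, only the body is.
#' @return A list of class `acro_document` with fields `doc_id`, `title`,
#'   `body`.
#' @export
acro_document <- function(doc_id, body, title = "") {
  if (!is.character(doc_id) || length(doc_id) != 1L || is.na(doc_id) ||
      !nzchar(doc_id)) {
    stop("`doc_id` must be a single non-empty string", call. = FALSE)
  }
  structure(
    list(doc_id = doc_id, title = as.character(title)[1L],
         body = as.character(body)[1L]),
    class = "acro_document"
  )
}

#' Construct a corpus
#'
#' @param documents List of [acro_document()] objects.
#' @param source_description Free text describing provenance (file names,
#'   generator configuration, ...).
#' @return A list of class `acro_corpus` with fields `documents` and
#'   `source_description`.
#' @export
acro_corpus <- function(documents = list(), source_description = "") {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(documents = documents,
         source_description = as.character(source_description)[1L]),
    class = "acro_corpus"
  )
}

#' @export
print.acro_corpus <- function(x, ...) {
  cat("<acro_corpus> ", length(x$documents), " document(s)\n", sep = "")
  if (nzchar(x$source_description)) {
    cat("  source: ", x$source_description, "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.acro_corpus <- function(x) length(x$documents)

#' Read a MEDLINE/PubMed XML citation set
#'
#' Parses a PubMed/MEDLINE XML export (the citation-set dialect with `PMID`,
#' `ArticleTitle` and `AbstractText` elements) into a corpus. One document is
#' produced per citation that has a non-empty abstract; `doc_id` is the PMID.
#' Multi-paragraph abstracts (several `AbstractText` elements) are
#' concatenated with a single space in document order. Citations without a
#' PMID are skipped with a warning.
#'
#' @param path Path to the XML file.
#' @return An [acro_corpus()].
#' @export
read_medline_xml <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  doc <- xml2::read_xml(path)  # malformed XML -> libxml2 error with position
  citations <- xml2::xml_find_all(doc, ".//MedlineCitation")
  if (length(citations) == 0L) {
    # some exports wrap articles without a MedlineCitation element
    citations <- xml2::xml_find_all(doc, ".//PubmedArticle")
  }
  docs <- list()
  for (cit in citations) {
    pmid <- xml2::xml_find_first(cit, ".//PMID")
    if (inherits(pmid, "xml_missing")) {
      warning("citation without PMID skipped", call. = FALSE)
      next
    }
    pmid <- xml2::xml_text(pmid)
    abst <- xml2::xml_find_all(cit, ".//Abstract/AbstractText")
    if (length(abst) == 0L) next
    body <- paste(trimws(xml2::xml_text(abst)), collapse = " ")
    if (!nzchar(trimws(body))) next
    title <- xml2::xml_find_first(cit, ".//ArticleTitle")
    title <- if (inherits(title, "xml_missing")) "" else xml2::xml_text(title)
    docs[[length(docs) + 1L]] <- acro_document(pmid, body, title)
  }
  acro_corpus(docs, source_description = basename(path))
}

#' Read plain-text files as a corpus
#'
#' One document per file; `doc_id` is the file stem (base name without
#' extension), the title is empty. Files whose content is empty after
#' stripping whitespace are retained (they contribute nothing downstream)
#' and flagged with a warning rather than silently dropped.
#'
#' @param paths Character vector of file paths (UTF-8 text).
#' @return An [acro_corpus()].
#' @export
read_plaintext <- function(paths) {
  docs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop("cannot read file: ", p, call. = FALSE)
    body <- paste(readLines(p, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    if (!nzchar(trimws(body))) {
      warning("document '", p, "' is empty after stripping whitespace",
              call. = FALSE)
    }
    docs[[i]] <- acro_document(tools::file_path_sans_ext(basename(p)), body)
  }
  acro_corpus(docs, source_description = paste(basename(paths),
                                               collapse = ", "))
}

#' Read a line-delimited structured-text corpus
#'
#' Each line is a JSON object with fields `doc_id`, `title` and `body`.
#' This is the format the synthetic-corpus generator emits.
#'
#' @param path Path to the JSONL file.
#' @return An [acro_corpus()].
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    acro_document(rec$doc_id, rec$body,
                  if (is.null(rec$title)) "" else rec$title)
  })
  acro_corpus(docs, source_description = basename(path))
}

#' Write a corpus as line-delimited JSON
#'
#' @param corpus An [acro_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "acro_corpus"))
  lines <- vapply(corpus$documents, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, title = d$title, body = d$body),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
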