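# The JSON bundle: documents + sense inventory (+ optional dataset) in a
# single documented layout. Keys are lowercase snake-case; spans are
# half-open [start, end) character offsets, 0-based, into the transformed
# body, counted in code points. Identical inputs produce byte-identical
# files (no timestamps or environment-dependent content).

ann_proto <- function() {
  data.frame(start = integer(0), end = integer(0), acronym = character(0),
             sense_id = character(0), removed_surface = character(0),
             stringsAsFactors = FALSE)
}

dec_proto <- function() {
  data.frame(doc_id = character(0), acronym = character(0),
             style = character(0), stringsAsFactors = FALSE)
}

sample_proto <- function() {
  data.frame(doc_id = character(0), sentence = character(0),
             acronym = character(0), candidate_long_form = character(0),
             candidate_sense_id = character(0), label = integer(0),
             stringsAsFactors = FALSE)
}

counts_proto <- function() {
  data.frame(acronym = character(0), n = integer(0), reserved = integer(0),
             stringsAsFactors = FALSE)
}

# rebuild a data frame from a fromJSON row list, coercing to the
# prototype's column types
df_from_rows <- function(rows, proto) {
  if (length(rows) == 0L) return(proto)
  cols <- names(proto)
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA else v
    })
    v <- unlist(vals, use.names = FALSE)
    if (is.integer(proto[[cn]])) as.integer(v) else as.character(v)
  })
  names(out) <- cols
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}

all_sense_ids <- function(inventory) {
  unlist(lapply(unclass(inventory), function(senses) {
    vapply(senses, `[[`, character(1), "sense_id")
  }), use.names = FALSE)
}

#' Write the annotated corpus, inventory and dataset as one JSON bundle
#'
#' The bundle has top-level sections `documents`, `sense_inventory`, an
#' optional `dataset` and a `meta` section recording the seed, tool
#' version and configuration. Every sense reference in the annotations is
#' validated against the inventory before any bytes are written; spans
#' are checked to lie within their document's body. Reading the file back
#' with [read_bundle()] reproduces the in-memory values, and identical
#' inputs produce byte-identical files.
#'
#' @param documents List of `acro_annotated_document` objects, or an
#'   `acro_simulation` (its inventory is used when `inventory` is
#'   missing).
#' @param inventory An `acro_inventory`.
#' @param path Output file path.
#' @param dataset Optional `acro_splits` object.
#' @param meta Named list of extra metadata (e.g. `seed`,
#'   `configuration`) stored under `meta`.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(documents, inventory = NULL, path, dataset = NULL,
                         meta = list()) {
  if (inherits(documents, "acro_simulation")) {
    sim <- documents
    documents <- sim$documents
    if (is.null(inventory)) inventory <- sim$inventory
    if (is.null(meta$seed)) meta$seed <- sim$seed
    if (is.null(meta$configuration)) {
      meta$configuration <- list(patterns = sim$patterns)
    }
  }
  sids <- all_sense_ids(inventory)
  for (d in documents) {
    ann <- d$annotations
    if (nrow(ann)) {
      dangling <- setdiff(ann$sense_id, sids)
      if (length(dangling)) {
        stop("annotation in document '", d$doc_id,
             "' references unknown sense id(s): ",
             paste(dangling, collapse = ", "), call. = FALSE)
      }
      if (any(ann$start < 0L) || any(ann$end > nchar(d$body))) {
        stop("annotation span outside body in document '", d$doc_id, "'",
             call. = FALSE)
      }
    }
  }

  bundle <- list(
    meta = c(list(tool = "acrosim",
                  version = as.character(utils::packageVersion("acrosim"))),
             meta),
    documents = lapply(documents, function(d) {
      list(doc_id = d$doc_id, title = d$title, body = d$body,
           annotations = d$annotations, decisions = d$decisions)
    }),
    sense_inventory = lapply(unclass(inventory), function(senses) {
      lapply(senses, function(s) {
        list(sense_id = s$sense_id,
             canonical_long_form = s$canonical_long_form,
             concept_id = s$concept_id,
             variants = I(s$variants),
             n_mentions = s$n_mentions)
      })
    })
  )
  if (!is.null(dataset)) {
    bundle$dataset <- list(
      train = dataset$train,
      validation = dataset$validation,
      test = dataset$test,
      per_acronym_counts = dataset$per_acronym_counts)
    if (!is.null(attr(dataset, "k_neg"))) {
      bundle$dataset$k_neg <- attr(dataset, "k_neg")
      bundle$dataset$seed <- attr(dataset, "seed")
    }
  }
  json <- jsonlite::toJSON(bundle, auto_unbox = TRUE, digits = NA,
                           na = "null", null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON bundle back into memory
#'
#' Inverse of [write_bundle()]: rebuilds the annotated documents, the
#' sense inventory and (when present) the dataset splits so that the
#' round trip reproduces values equal to the originals.
#'
#' @param path Path to a bundle written by [write_bundle()].
#' @return A list with `documents`, `inventory`, `dataset` (`NULL` when
#'   absent) and `meta`.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  docs <- lapply(raw$documents, function(d) {
    structure(list(doc_id = d$doc_id, title = d$title, body = d$body,
                   annotations = df_from_rows(d$annotations, ann_proto()),
                   decisions = df_from_rows(d$decisions, dec_proto())),
              class = "acro_annotated_document")
  })
  inv <- lapply(raw$sense_inventory, function(senses) {
    lapply(senses, function(s) {
      list(sense_id = s$sense_id,
           canonical_long_form = s$canonical_long_form,
           concept_id = if (is.null(s$concept_id)) NA_character_ else
             s$concept_id,
           variants = as.character(unlist(s$variants)),
           n_mentions = as.integer(s$n_mentions))
    })
  })
  inv <- structure(inv, class = "acro_inventory")
  dataset <- NULL
  if (!is.null(raw$dataset)) {
    dataset <- structure(
      list(train = df_from_rows(raw$dataset$train, sample_proto()),
           validation = df_from_rows(raw$dataset$validation,
                                     sample_proto()),
           test = df_from_rows(raw$dataset$test, sample_proto()),
           per_acronym_counts = df_from_rows(
             raw$dataset$per_acronym_counts, counts_proto())),
      class = "acro_splits")
    if (!is.null(raw$dataset$k_neg)) {
      attr(dataset, "k_neg") <- as.integer(raw$dataset$k_neg)
      attr(dataset, "seed") <- as.integer(raw$dataset$seed)
    }
  }
  list(documents = docs, inventory = inv, dataset = dataset,
       meta = raw$meta)
}
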