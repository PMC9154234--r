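# Acronym-definition recognition: parenthetical pattern matching plus
# right-to-left heuristic character alignment of the short form against
# the text preceding (or, for the reversed pattern, inside) the parentheses.

# Short-form candidate validity: 2-10 characters, at most 2 whitespace
# words, at least one letter, first character alphanumeric.
is_valid_short_form <- function(surface) {
  if (length(surface) != 1L || is.na(surface)) return(FALSE)
  n <- nchar(surface)
  if (n < 2L || n > 10L) return(FALSE)
  if (!grepl("[[:alpha:]]", surface)) return(FALSE)
  if (!grepl("^[[:alnum:]]", surface)) return(FALSE)
  length(strsplit(trimws(surface), "[[:space:]]+")[[1]]) <= 2L
}

#' Find short-form candidates in a document body
#'
#' Scans for balanced parentheses (innermost pairs only; an unbalanced
#' opening parenthesis terminates the search from that point on) and emits
#' one candidate per parenthesized expression whose content passes the
#' short-form validity rules: 2-10 characters, at most two whitespace-
#' delimited words, at least one letter, first character alphanumeric
#' (pattern `"long form (SF)"`). When the content fails validity but the
#' token immediately preceding the parenthesis passes it, a candidate with
#' `inside_parens = FALSE` is emitted instead (reversed pattern
#' `"SF (long form)"`).
#'
#' @param body Document text.
#' @return A data frame with columns `surface`, `start`, `end` (0-based,
#'   half-open span of the candidate surface), `inside_parens` (logical),
#'   `paren_open`, `paren_close` (0-based positions of the parenthesis
#'   characters). Possibly zero rows; never an error.
#' @export
find_candidates <- function(body) {
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), inside_parens = logical(0),
                      paren_open = integer(0), paren_close = integer(0),
                      stringsAsFactors = FALSE)
  if (is.na(body) || !nzchar(body)) return(empty)
  chars <- strsplit(body, "")[[1]]
  n <- length(chars)

  # innermost balanced pairs via a depth scan
  stack_pos <- integer(0)
  stack_child <- logical(0)
  opens <- integer(0)
  closes <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "(") {
      stack_pos <- c(stack_pos, i)
      stack_child <- c(stack_child, FALSE)
    } else if (ch == ")") {
      k <- length(stack_pos)
      if (k == 0L) next  # stray closing parenthesis: ignored
      open <- stack_pos[k]
      had_child <- stack_child[k]
      stack_pos <- stack_pos[-k]
      stack_child <- stack_child[-k]
      if (length(stack_child)) stack_child[length(stack_child)] <- TRUE
      if (!had_child) {
        opens <- c(opens, open)
        closes <- c(closes, i)
      }
    }
  }
  if (length(stack_pos)) {
    # unbalanced '(': drop candidate pairs at or after it
    cutoff <- min(stack_pos)
    keep <- opens < cutoff
    opens <- opens[keep]
    closes <- closes[keep]
  }
  if (length(opens) == 0L) return(empty)

  rows <- vector("list", length(opens))
  for (j in seq_along(opens)) {
    o <- opens[j]  # 1-based position of '('
    c_ <- closes[j]
    content <- substr(body, o + 1L, c_ - 1L)
    lead <- nchar(content) - nchar(sub("^[[:space:]]+", "", content))
    trimmed <- trimws(content)
    if (is_valid_short_form(trimmed)) {
      start0 <- o + lead  # 0-based start of trimmed content
      rows[[j]] <- data.frame(
        surface = trimmed, start = start0,
        end = start0 + nchar(trimmed), inside_parens = TRUE,
        paren_open = o - 1L, paren_close = c_ - 1L,
        stringsAsFactors = FALSE)
      next
    }
    # reversed pattern: token immediately preceding the parenthesis
    before <- substr(body, 1L, o - 1L)
    before_rt <- sub("[[:space:]]+$", "", before)
    if (!nzchar(before_rt)) next
    tok <- sub("^.*[[:space:]]", "", before_rt)
    if (is_valid_short_form(tok)) {
      start0 <- nchar(before_rt) - nchar(tok)
      rows[[j]] <- data.frame(
        surface = tok, start = start0, end = start0 + nchar(tok),
        inside_parens = FALSE, paren_open = o - 1L, paren_close = c_ - 1L,
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

# Right-to-left greedy alignment of the short form's alphanumeric
# characters against the window. Returns the 1-based start index (within
# the window) of the shortest matching suffix, or NA. The suffix must
# begin at a whitespace-delimited word start whose initial character
# equals the short form's first alphanumeric character (case-insensitive).
# Digits match literally; hyphens and periods in the short form are
# skipped.
align_anchor <- function(short_form, window) {
  sfc <- strsplit(tolower(short_form), "")[[1]]
  sfc <- sfc[grepl("[[:alnum:]]", sfc)]
  if (length(sfc) == 0L) return(NA_integer_)
  wc <- strsplit(tolower(window), "")[[1]]
  if (length(wc) == 0L) return(NA_integer_)
  is_sp <- wc %in% c(" ", "\t", "\n", "\r", "\f", "\v")
  li <- length(wc)
  for (si in rev(seq_along(sfc))) {
    ch <- sfc[si]
    if (si > 1L) {
      while (li >= 1L && wc[li] != ch) li <- li - 1L
    } else {
      while (li >= 1L && !(wc[li] == ch && (li == 1L || is_sp[li - 1L]))) {
        li <- li - 1L
      }
    }
    if (li < 1L) return(NA_integer_)
    li <- li - 1L
  }
  li + 1L
}

#' Align a short form against the text preceding its parenthesis
#'
#' Returns the shortest suffix of `window` such that, scanning the short
#' form right to left, every alphanumeric character of the short form
#' matches a character of the suffix in order, and the first alphanumeric
#' character of the short form matches the initial character of the
#' suffix's first word (words are whitespace-delimited; matching is
#' case-insensitive; digits match literally; hyphens and periods in the
#' short form are skipped).
#'
#' @param short_form The candidate acronym.
#' @param window The word window immediately preceding the parenthesis
#'   (for the forward pattern) or the parenthesized content (reversed
#'   pattern).
#' @return The matched long form, or `NA_character_` when no suffix
#'   satisfies the alignment.
#' @export
#' @examples
#' best_long_form("HIV", "infection with human immunodeficiency virus")
#' best_long_form("DM2", "patients with diabetes mellitus type 2")
#' best_long_form("XYZ", "alpha beta gamma")
best_long_form <- function(short_form, window) {
  anchor <- align_anchor(short_form, window)
  if (is.na(anchor)) return(NA_character_)
  sub("[[:space:]]+$", "", substring(window, anchor))
}

# last `k` whitespace-delimited words of `text`, returned as the 1-based
# start position of the first of them (or 1 when there are fewer words)
last_words_start <- function(text, k) {
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(NA_integer_)
  starts <- as.integer(m)
  if (length(starts) <= k) starts[1] else starts[length(starts) - k + 1L]
}

count_words <- function(text) {
  if (!nzchar(trimws(text))) return(0L)
  length(strsplit(trimws(text), "[[:space:]]+")[[1]])
}

#' Extract acronym definitions from a document
#'
#' Composes [find_candidates()] with [best_long_form()]. For forward
#' candidates (`"long form (SF)"`) the alignment window is the sequence of
#' up to `min(|SF| + 5, 2 * |SF|)` words immediately preceding the
#' parenthesis (`|SF|` = number of characters of the short form). For
#' reversed candidates (`"SF (long form)"`) the long form is sought inside
#' the parentheses, truncated at the first comma or semicolon, and
#' accepted only if it has at most that many words. Candidates that fail
#' alignment are dropped, as is a short form equal (case-insensitively) to
#' its long form. Results are ordered by position in the text.
#'
#' @param document An [acro_document()] (or any list with `doc_id` and
#'   `body`).
#' @param patterns `"both"` (default) to handle forward and reversed
#'   patterns, `"forward"` for the forward pattern only.
#' @return A data frame with one row per recognized definition: `doc_id`,
#'   `short_form`, `long_form`, `short_start`, `short_end`, `long_start`,
#'   `long_end` (0-based, half-open spans into the body), `paren_open`,
#'   `paren_close`, `pattern` (`"forward"` or `"reverse"`).
#' @export
extract_definitions <- function(document, patterns = c("both", "forward")) {
  patterns <- match.arg(patterns)
  body <- document$body
  cands <- find_candidates(body)
  empty <- data.frame(doc_id = character(0), short_form = character(0),
                      long_form = character(0), short_start = integer(0),
                      short_end = integer(0), long_start = integer(0),
                      long_end = integer(0), paren_open = integer(0),
                      paren_close = integer(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(cands) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    sf <- cands$surface[i]
    max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
    if (cands$inside_parens[i]) {
      before <- substr(body, 1L, cands$paren_open[i])  # text before '('
      before <- sub("[[:space:]]+$", "", before)
      if (!nzchar(before)) next
      wstart <- last_words_start(before, max_words)
      if (is.na(wstart)) next
      window <- substr(before, wstart, nchar(before))
      anchor <- align_anchor(sf, window)
      if (is.na(anchor)) next
      lf_start0 <- wstart - 1L + anchor - 1L
      lf <- sub("[[:space:]]+$", "", substring(window, anchor))
      long_start <- lf_start0
      long_end <- lf_start0 + nchar(lf)
      pattern <- "forward"
    } else {
      if (patterns == "forward") next
      content <- substr(body, cands$paren_open[i] + 2L, cands$paren_close[i])
      stopsep <- regexpr("[,;]", content)
      if (stopsep != -1L) content <- substr(content, 1L, stopsep - 1L)
      lead <- nchar(content) - nchar(sub("^[[:space:]]+", "", content))
      window <- trimws(content)
      if (!nzchar(window)) next
      anchor <- align_anchor(sf, window)
      if (is.na(anchor)) next
      lf <- sub("[[:space:]]+$", "", substring(window, anchor))
      if (count_words(lf) > max_words) next
      long_start <- cands$paren_open[i] + 1L + lead + anchor - 1L
      long_end <- long_start + nchar(lf)
      pattern <- "reverse"
    }
    if (!nzchar(lf)) next
    if (tolower(lf) == tolower(sf)) next  # self-definition
    rows[[length(rows) + 1L]] <- data.frame(
      doc_id = document$doc_id, short_form = sf, long_form = lf,
      short_start = cands$start[i], short_end = cands$end[i],
      long_start = long_start, long_end = long_end,
      paren_open = cands$paren_open[i], paren_close = cands$paren_close[i],
      pattern = pattern, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(pmin(out$short_start, out$long_start)), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Extract definitions from every document of a corpus
#'
#' @param corpus An [acro_corpus()].
#' @inheritParams extract_definitions
#' @return Row-bound data frame of [extract_definitions()] results.
#' @export
extract_corpus_definitions <- function(corpus, patterns = c("both", "forward")) {
  patterns <- match.arg(patterns)
  res <- lapply(corpus$documents, extract_definitions, patterns = patterns)
  out <- do.call(rbind, res)
  if (is.null(out)) out <- extract_definitions(acro_document("x", ""), patterns)
  row.names(out) <- NULL
  out
}
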