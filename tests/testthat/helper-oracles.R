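# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation.

# Brute-force long-form alignment: enumerate every whitespace-word-boundary
# suffix of the window, shortest first, and return the first one whose first
# word starts with the short form's first alphanumeric character and that
# contains all alphanumeric characters of the short form as an ordered
# subsequence (case-insensitive).
oracle_best_long_form <- function(short_form, window) {
  sfc <- strsplit(tolower(short_form), "")[[1]]
  sfc <- sfc[grepl("[[:alnum:]]", sfc)]
  if (length(sfc) == 0L) return(NA_character_)
  m <- gregexpr("[^[:space:]]+", window)[[1]]
  if (m[1] == -1L) return(NA_character_)
  starts <- as.integer(m)
  for (s in rev(starts)) {  # last word first = shortest suffix first
    suffix <- substring(window, s)
    if (tolower(substr(suffix, 1L, 1L)) != sfc[1]) next
    chars <- strsplit(tolower(suffix), "")[[1]]
    j <- 1L
    for (ch in chars) {
      if (j <= length(sfc) && ch == sfc[j]) j <- j + 1L
    }
    if (j > length(sfc)) return(sub("[[:space:]]+$", "", suffix))
  }
  NA_character_
}

# Random short forms for fuzzing: 2-10 characters, at least one letter,
# first character alphanumeric, hyphens/digits allowed.
fuzz_short_form <- function() {
  repeat {
    n <- sample(2:10, 1L)
    chars <- sample(c(LETTERS, 0:9, "-"), n, replace = TRUE,
                    prob = c(rep(4, 26), rep(1, 10), 2))
    sf <- paste(chars, collapse = "")
    if (grepl("^[[:alnum:]]", sf) && grepl("[[:alpha:]]", sf)) return(sf)
  }
}

# Random windows of at most 15 words. Half the time the window is seeded
# with words built from the short form's characters so that alignment hits
# are frequent; the rest is unrelated noise.
fuzz_window <- function(short_form) {
  vocab <- c("alpha", "beta", "gamma", "delta", "omega", "study", "cell",
             "acid", "bone", "rate", "x1", "t-2", "of", "the", "with")
  nw <- sample(1:15, 1L)
  words <- sample(vocab, nw, replace = TRUE)
  if (stats::runif(1) < 0.5) {
    # plant a pseudo long form: one word per short-form character
    sfc <- strsplit(tolower(short_form), "")[[1]]
    sfc <- sfc[grepl("[[:alnum:]]", sfc)]
    planted <- vapply(sfc, function(ch) {
      paste0(ch, paste(sample(letters, sample(0:4, 1L), replace = TRUE),
                       collapse = ""))
    }, character(1))
    k <- min(length(planted), nw)
    words[(nw - k + 1L):nw] <- planted[seq_len(k)]
  }
  paste(words, collapse = " ")
}

# Case-insensitive fixed-string occurrence scanner (positions are 0-based
# half-open spans). Used to verify that no replaced long form survives in
# a transformed body.
scan_occurrences <- function(body, surface) {
  b <- tolower(body)
  s <- tolower(surface)
  out <- NULL
  from <- 1L
  repeat {
    rel <- regexpr(s, substring(b, from), fixed = TRUE)
    if (rel == -1L) break
    abs <- from + as.integer(rel) - 1L
    out <- rbind(out, c(abs - 1L, abs - 1L + nchar(s)))
    from <- abs + 1L
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = out[, 1], end = out[, 2])
}

# occurrences of `surface` in `body` that lie outside every [start,end)
# annotation span
residual_count <- function(body, surface, ann) {
  occ <- scan_occurrences(body, surface)
  if (nrow(occ) == 0L) return(0L)
  inside <- vapply(seq_len(nrow(occ)), function(i) {
    any(ann$start <= occ$start[i] & occ$end[i] <= ann$end)
  }, logical(1))
  sum(!inside)
}

# Exact enumeration of the 2x2 outcome space (true sense x sample type)
# for the most-frequent-sense baseline on a two-sense acronym with
# document-level sense probabilities `p` and one negative per positive.
mfs_expected_two_sense <- function(p, mfs_idx) {
  stopifnot(length(p) == 2L, abs(sum(p) - 1) < 1e-12)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:2) {
    # positive sample: candidate = true sense i
    if (i == mfs_idx) tp <- tp + p[i] else fn <- fn + p[i]
    # negative sample: candidate = the other sense
    j <- 3L - i
    if (j == mfs_idx) fp <- fp + p[i] else tn <- tn + p[i]
  }
  list(accuracy = (tp + tn) / 2, precision = tp / (tp + fp),
       recall = tp / (tp + fn))
}
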