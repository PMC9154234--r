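# internal helpers

# Run code after set.seed(seed), restoring the caller's RNG state on exit.
# Returns a restore function to be registered with on.exit().
seed_guard <- function(seed) {
  if (is.null(seed)) return(function() invisible())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(as.integer(seed))
  function() {
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
    invisible()
  }
}

rx_escape <- function(s) {
  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
}

# 0-based half-open spans of standalone-token occurrences of `surface` in
# `body` (case-insensitive; a token boundary is any non-alphanumeric
# context)
token_occurrences <- function(body, surface) {
  pat <- paste0("(?<![[:alnum:]])", rx_escape(surface), "(?![[:alnum:]])")
  m <- gregexpr(pat, body, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# substring by 0-based half-open span
substr0 <- function(x, start, end) substr(x, start + 1L, end)
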