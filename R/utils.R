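#' Round half away from zero
#'
#' Printed percentages in the summary tables use commercial ("half-up")
#' rounding, not the banker's rounding of [base::round()].
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalize typographic apostrophes/quotes so lexicon entries such as
# "didn't help" and "Alzheimer's" match clinical text regardless of the
# apostrophe glyph used.
normalize_text <- function(x) {
  x <- gsub("’|‘|ʼ", "'", x)
  gsub("“|”", "\"", x)
}

# Word tokenizer with character offsets (half-open spans). Tokens are runs
# of letters/digits/apostrophes; everything else is a delimiter.
tokenize <- function(x) {
  m <- gregexpr("[[:alnum:]']+", x)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(
    token = tolower(substring(x, m, m + len - 1L)),
    start = as.integer(m),
    end = as.integer(m + len),   # half-open
    stringsAsFactors = FALSE
  )
}

# Tiny FNV-1a hash (hex string) used to stamp output files with a config
# fingerprint; avoids a dependency for a non-cryptographic need.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n")) %% 256
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

as_date_strict <- function(x, what = "date") {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- !is.na(x) & x != "" & is.na(d)
  if (any(bad)) {
    stop(sprintf("unparseable %s value(s): %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  d[is.na(x) | x == ""] <- NA
  d
}

stop_contract <- function(...) stop(sprintf(...), call. = FALSE)
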