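#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `expr`, and restores the previous state, so simulations are reproducible
#' without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 131L + as.integer(stream) * 7919L) %% 2147483587L
}

#' Reverse complement of DNA strings
#'
#' Case is preserved (lowercase stays lowercase) so donor-provenance marking
#' survives orientation flips. Only `A,C,G,T,N` and their lowercase forms are
#' handled.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", s))))
  }, character(1), USE.NAMES = FALSE)
}

# Count exact base matches between two equal-length strings, case-insensitive;
# positions where either side is N never count as matches.
hamming_matches <- function(a, b) {
  ai <- utf8ToInt(toupper(a)); bi <- utf8ToInt(toupper(b))
  stopifnot(length(ai) == length(bi))
  n_code <- utf8ToInt("N")
  sum(ai == bi & ai != n_code)
}

# Locate runs of a predicate over string characters; returns 0-based half-open
# intervals as a data.frame(start, end).
char_runs <- function(s, chars) {
  v <- strsplit(s, "", fixed = TRUE)[[1]] %in% chars
  if (!any(v)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Do intervals [s1,e1) and [s2,e2) overlap?
iv_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Is point p (0-based) inside any interval of df(start,end), optionally padded?
point_in_intervals <- function(p, df, pad = 0L) {
  if (nrow(df) == 0L) return(rep(FALSE, length(p)))
  vapply(p, function(x) any(x >= df$start - pad & x < df$end + pad), logical(1))
}

# Sample n non-overlapping intervals of given lengths inside [lo, hi),
# avoiding `occupied` (data.frame start,end), with `pad` spacing. Returns a
# data.frame(start, end) or fewer rows if placement keeps failing.
sample_intervals <- function(n, lens, lo, hi, occupied = NULL, pad = 0L,
                             max_tries = 2000L) {
  occ <- if (is.null(occupied)) data.frame(start = integer(0), end = integer(0))
         else occupied[, c("start", "end"), drop = FALSE]
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    len <- lens[((i - 1L) %% length(lens)) + 1L]
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      s <- if (hi - len <= lo) lo else sample(seq.int(lo, hi - len), 1L)
      e <- s + len
      busy <- rbind(occ, out)
      if (nrow(busy) == 0L || !any(iv_overlaps(s - pad, e + pad, busy$start, busy$end))) {
        out <- rbind(out, data.frame(start = s, end = e))
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  out[order(out$start), , drop = FALSE]
}

# Insert lowercase marking: lower a string.
lc <- function(x) tolower(x)

# substring replacement by 0-based half-open interval
splice_str <- function(s, start0, end0, replacement) {
  paste0(substr(s, 1L, start0), replacement, substr(s, end0 + 1L, nchar(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
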