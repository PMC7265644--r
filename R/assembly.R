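#' Assembly container
#'
#' An `assembly` is a named set of DNA sequences plus metadata. The character
#' case of each base is a provenance channel: uppercase bases are native to
#' the assembled individual, lowercase bases were copied in from the donor
#' reference during gap filling, and `N` marks a gap. Only `A,C,G,T,N` and
#' their lowercase forms are permitted; other IUPAC codes are rejected at
#' ingest because the base-comparison logic downstream assumes an unambiguous
#' alphabet.
#'
#' @param seqs named character vector of DNA sequences.
#' @param version version tag recorded in metadata (e.g. `"v0.9"`).
#' @param meta list of additional metadata (source, planted feature tables
#'   from the simulator, ...).
#' @return an object of class `assembly`.
#' @export
assembly <- function(seqs, version = "v0", meta = list()) {
  nms <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), nms)
  if (length(seqs) > 0 && is.null(names(seqs))) {
    stop("assembly sequences must be named")
  }
  bad <- grep("[^ACGTNacgtn]", seqs)
  if (length(bad) > 0) {
    ch <- regmatches(seqs[bad[1]], regexpr("[^ACGTNacgtn]", seqs[bad[1]]))
    stop(sprintf("invalid character '%s' in sequence '%s'", ch, names(seqs)[bad[1]]))
  }
  structure(list(seq = seqs, version = version, meta = meta), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly %s> %d sequence(s), %s bp total\n",
              x$version, length(x$seq),
              format(sum(nchar(x$seq)), big.mark = ",")))
  for (nm in utils::head(names(x$seq), 10)) {
    cat(sprintf("  %-12s %s bp\n", nm, format(nchar(x$seq[[nm]]), big.mark = ",")))
  }
  if (length(x$seq) > 10) cat(sprintf("  ... and %d more\n", length(x$seq) - 10))
  invisible(x)
}

#' Sequence lengths of an assembly
#' @param x an `assembly`.
#' @return named integer vector.
#' @export
seq_lengths <- function(x) {
  stopifnot(inherits(x, "assembly"))
  vapply(x$seq, nchar, integer(1))
}

#' Locate gaps (N runs) in an assembly
#'
#' Every maximal run of `N`/`n` is reported as a gap with 0-based half-open
#' coordinates. Leading and trailing runs are representable (and returned when
#' `include_terminal = TRUE`) but, following the convention used for
#' chromosome gap accounting, they are excluded by default because terminal
#' padding is not an internal gap.
#'
#' @param x an `assembly` or a named character vector.
#' @param include_terminal keep leading/trailing N runs?
#' @return data.frame with columns `seq`, `start`, `end`, `length`.
#' @export
find_gaps <- function(x, include_terminal = FALSE) {
  seqs <- if (inherits(x, "assembly")) x$seq else x
  out <- lapply(names(seqs), function(nm) {
    runs <- char_runs(seqs[[nm]], c("N", "n"))
    if (nrow(runs) == 0L) return(NULL)
    if (!include_terminal) {
      L <- nchar(seqs[[nm]])
      runs <- runs[runs$start > 0L & runs$end < L, , drop = FALSE]
    }
    if (nrow(runs) == 0L) return(NULL)
    data.frame(seq = nm, start = runs$start, end = runs$end,
               length = runs$end - runs$start)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(seq = character(0), start = integer(0),
                               end = integer(0), length = integer(0))
  else out
}

#' Per-sequence length and gap summary
#'
#' Reports, for each sequence, the non-N length, the number of gaps and the
#' total gap length. Leading and trailing N runs are never counted as gaps;
#' only interior N runs are.
#'
#' @param x an `assembly`.
#' @return data.frame with columns `seq`, `length`, `gap_length`, `n_gaps`,
#'   plus a final `TOTAL` row.
#' @export
summarize_assembly <- function(x) {
  stopifnot(inherits(x, "assembly"))
  gaps <- find_gaps(x, include_terminal = FALSE)
  rows <- lapply(names(x$seq), function(nm) {
    s <- x$seq[[nm]]
    n_all <- lengths(regmatches(s, gregexpr("[Nn]", s)))
    g <- gaps[gaps$seq == nm, , drop = FALSE]
    data.frame(seq = nm,
               length = nchar(s) - n_all,
               gap_length = sum(g$length),
               n_gaps = nrow(g))
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(seq = "TOTAL", length = sum(out$length),
                        gap_length = sum(out$gap_length),
                        n_gaps = sum(out$n_gaps)))
}

#' Base-provenance accounting
#'
#' Counts uppercase (native), lowercase (donor-derived) and N bases per
#' sequence and in total, and the lowercase fraction of non-N bases. This is
#' the donor-content report used to state how much of a curated assembly was
#' taken from the donor reference.
#'
#' @param x an `assembly`.
#' @return data.frame with per-sequence rows and a `TOTAL` row; columns
#'   `seq`, `upper_bp`, `lower_bp`, `n_bp`, `lower_frac`.
#' @export
donor_content_report <- function(x) {
  stopifnot(inherits(x, "assembly"))
  rows <- lapply(names(x$seq), function(nm) {
    s <- x$seq[[nm]]
    low <- lengths(regmatches(s, gregexpr("[acgt]", s)))
    nn <- lengths(regmatches(s, gregexpr("[Nn]", s)))
    up <- nchar(s) - low - nn
    data.frame(seq = nm, upper_bp = up, lower_bp = low, n_bp = nn)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(seq = "TOTAL", upper_bp = sum(out$upper_bp),
                               lower_bp = sum(out$lower_bp), n_bp = sum(out$n_bp)))
  out$lower_frac <- ifelse(out$upper_bp + out$lower_bp > 0,
                           out$lower_bp / (out$upper_bp + out$lower_bp), 0)
  out
}
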