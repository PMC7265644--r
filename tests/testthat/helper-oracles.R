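# Independent oracles used to check the package's implementations. These are
# deliberately written from scratch (plain dynamic programming, a hard-coded
# codon table) and share no code with the functions they validate.

# quadratic Needleman-Wunsch with linear gap penalty; returns matches and
# alignment columns from a full traceback
oracle_global_align <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1] <- gap * 0:n
  S[1, ] <- gap * 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (A[i] == B[j]) match else mismatch
      S[i + 1L, j + 1L] <- max(d, S[i, j + 1L] + gap, S[i + 1L, j] + gap)
    }
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      if (A[i] == B[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(matches = matches, columns = cols,
       identity = 100 * matches / cols)
}

# standard genetic code, written out independently of any library constant
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- paste0("FFLLSSSSYY**CC*W",
                "LLLLPPPPHHQQRRRR",
                "IIIMTTTTNNKKSSRR",
                "VVVVAAAADDEEGGGG")
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(strsplit(aas, "")[[1]], codons)
})

oracle_translate <- function(cds) {
  s <- toupper(cds)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(s, 3L * i - 2L, 3L * i)
    out[i] <- if (cod %in% names(oracle_codon_table)) {
      oracle_codon_table[[cod]]
    } else "X"
  }
  paste(out, collapse = "")
}

# classify a CDS change given the source CDS, target CDS and the *known*
# edit(s) applied (type in sub/ins/del, length). Brute-force translate and
# diff, with the disruption precedence the reports use.
oracle_consequence <- function(src_cds, tgt_cds, edit_types, edit_lens) {
  net <- sum(ifelse(edit_types == "ins", edit_lens,
                    ifelse(edit_types == "del", -edit_lens, 0L)))
  indel_lens <- edit_lens[edit_types %in% c("ins", "del")]
  if (length(indel_lens) && any(indel_lens %% 3L != 0L)) return("frameshift")
  ps <- oracle_translate(src_cds); pt <- oracle_translate(tgt_cds)
  has_internal_stop <- function(p) nchar(p) > 1L &&
    grepl("*", substr(p, 1L, nchar(p) - 1L), fixed = TRUE)
  if (has_internal_stop(pt) && !has_internal_stop(ps)) return("stop gained")
  if (substr(ps, nchar(ps), nchar(ps)) == "*" &&
      substr(pt, nchar(pt), nchar(pt)) != "*") return("stop lost")
  if (toupper(substr(src_cds, 1, 3)) == "ATG" &&
      toupper(substr(tgt_cds, 1, 3)) != "ATG") return("start lost")
  if (net > 0L) return("in-frame insertion")
  if (net < 0L) return("in-frame deletion")
  if (ps != pt) return("missense")
  "identical"
}

# exhaustive k-mer set of a string (uppercase)
oracle_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# one-pass character counts of a FASTA file
oracle_fasta_counts <- function(path) {
  lines <- readLines(path)
  seq_lines <- lines[!startsWith(lines, ">")]
  all <- paste(seq_lines, collapse = "")
  ch <- strsplit(all, "", fixed = TRUE)[[1]]
  c(lower = sum(ch %in% c("a", "c", "g", "t")),
    upper = sum(ch %in% c("A", "C", "G", "T")),
    n = sum(ch %in% c("N", "n")))
}

# random DNA helper for tests
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random CDS: ATG + sense codons + TAA (no internal stops)
rand_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- names(oracle_codon_table)
  sense <- setdiff(all_codons, stops)
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}
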