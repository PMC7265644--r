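# Alignment machinery: a minimal deterministic anchor aligner (unique k-mer
# chaining) for locating sequences, plus an affine-gap global aligner for
# base-exact refinement. The anchor aligner reports matches = anchored bases,
# a conservative lower bound on identity; callers needing exact identity
# refine with global_align() on the located slice.

#' Build a unique k-mer index over an assembly
#'
#' Indexes every k-mer that occurs exactly once across all target sequences
#' (k-mers containing N are skipped). Matching is case-insensitive; the index
#' can be reused across many [anchor_align] queries.
#'
#' @param target an [assembly] or named character vector.
#' @param k k-mer size (>= 11).
#' @return an object of class `kmer_index`.
#' @export
kmer_index <- function(target, k = 21L) {
  stopifnot(k >= 11L)
  seqs <- if (inherits(target, "assembly")) target$seq else target
  seqs <- toupper(seqs)
  km <- character(0); sq <- character(0); ps <- integer(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n < k) next
    kk <- substring(s, 1:(n - k + 1L), k:n)
    keep <- !grepl("N", kk, fixed = TRUE)
    km <- c(km, kk[keep]); sq <- c(sq, rep(nm, sum(keep)))
    ps <- c(ps, which(keep) - 1L)
  }
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  lens <- vapply(seqs, nchar, integer(1))
  structure(list(k = k, kmer = km[!dup], seq = sq[!dup], pos = ps[!dup],
                 tlen = lens),
            class = "kmer_index")
}

# Chain anchors (qpos, tpos sorted by qpos) into co-linear runs.
# Vectorized: a chain breaks when query gap/target gap exceeds max_gap, target
# goes backwards, or the diagonal drifts by more than max_diag_drift between
# adjacent anchors.
chain_anchors <- function(qpos, tpos, k, max_gap, max_diag_drift) {
  o <- order(qpos, tpos)
  qpos <- qpos[o]; tpos <- tpos[o]
  n <- length(qpos)
  if (n == 0L) return(list())
  if (n == 1L) {
    return(list(list(qpos = qpos, tpos = tpos)))
  }
  dq <- diff(qpos); dt <- diff(tpos)
  brk <- dq > max_gap | dt <= 0L | dt > max_gap |
    abs(dt - dq) > max_diag_drift
  id <- cumsum(c(TRUE, brk))
  lapply(split(seq_len(n), id), function(ix) list(qpos = qpos[ix], tpos = tpos[ix]))
}

# union length of intervals [p, p+k) for sorted positions p
anchored_bases <- function(pos, k) {
  if (length(pos) == 1L) return(k)
  sum(pmin(diff(pos), k)) + k
}

#' Align queries against a unique k-mer index by anchor chaining
#'
#' Deterministic seed-and-chain alignment: k-mers unique in both the query and
#' the indexed target are matched and chained greedily along the diagonal.
#' Each chain is reported as a PAF-style record with `nmatch` set to the
#' number of anchored query bases (a conservative lower bound on matches) and
#' `alen` the larger of the query and target spans. The reverse strand is
#' handled by aligning the reverse complement; query coordinates are reported
#' on the original strand, per PAF convention.
#'
#' @param query named character vector (or single string) of query sequences.
#' @param index a [kmer_index] (or an [assembly], indexed on the fly).
#' @param min_anchors minimum anchors per reported chain.
#' @param max_gap maximum anchor-to-anchor gap within a chain (bp).
#' @param max_diag_drift maximum diagonal drift between adjacent anchors (bp);
#'   indels larger than this break the chain.
#' @param both_strands also search the reverse complement?
#' @return alignment-record data.frame (see [read_paf]).
#' @export
anchor_align <- function(query, index, min_anchors = 3L, max_gap = 5000L,
                         max_diag_drift = 25L, both_strands = TRUE) {
  if (!inherits(index, "kmer_index")) index <- kmer_index(index)
  k <- index$k
  if (is.null(names(query))) names(query) <- paste0("q", seq_along(query))
  qlens <- vapply(query, nchar, integer(1))

  # collect unique k-mers per (query, strand), then do ONE match() call
  jobs <- list()
  for (nm in names(query)) {
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      s <- toupper(if (st == "+") query[[nm]] else revcomp(query[[nm]]))
      n <- nchar(s)
      if (n < k) next
      kk <- substring(s, 1:(n - k + 1L), k:n)
      keep <- !grepl("N", kk, fixed = TRUE)
      kk <- kk[keep]; qp <- which(keep) - 1L
      dup <- duplicated(kk) | duplicated(kk, fromLast = TRUE)
      jobs[[length(jobs) + 1L]] <- list(q = nm, strand = st,
                                        km = kk[!dup], qp = qp[!dup])
    }
  }
  if (length(jobs) == 0L) return(empty_paf())
  all_km <- unlist(lapply(jobs, `[[`, "km"), use.names = FALSE)
  hit <- match(all_km, index$kmer)
  sizes <- vapply(jobs, function(j) length(j$km), integer(1))
  offs <- cumsum(c(0L, sizes))

  recs <- vector("list", 0L)
  for (ji in seq_along(jobs)) {
    j <- jobs[[ji]]
    h <- hit[(offs[ji] + 1L):(offs[ji] + sizes[ji])]
    ok <- !is.na(h)
    if (!any(ok)) next
    qp <- j$qp[ok]; ti <- h[ok]
    tseq <- index$seq[ti]; tp <- index$pos[ti]
    qlen <- qlens[[j$q]]
    for (ts in unique(tseq)) {
      sel <- tseq == ts
      chains <- chain_anchors(qp[sel], tp[sel], k, max_gap, max_diag_drift)
      for (ch in chains) {
        if (length(ch$qpos) < min_anchors) next
        qs <- ch$qpos[1]; qe <- ch$qpos[length(ch$qpos)] + k
        tss <- ch$tpos[1]; tee <- ch$tpos[length(ch$tpos)] + k
        nm_b <- anchored_bases(ch$qpos, k)
        if (j$strand == "-") {
          qs2 <- qlen - qe; qe2 <- qlen - qs
        } else {
          qs2 <- qs; qe2 <- qe
        }
        recs[[length(recs) + 1L]] <- data.frame(
          qname = j$q, qlen = qlen, qstart = qs2, qend = qe2,
          strand = j$strand, tname = ts, tlen = index$tlen[[ts]],
          tstart = tss, tend = tee, nmatch = nm_b,
          alen = max(qe - qs, tee - tss), mapq = 60L)
      }
    }
  }
  if (length(recs) == 0L) return(empty_paf())
  out <- do.call(rbind, recs)
  out[order(out$qname, out$qstart, out$tname, out$tstart), , drop = FALSE]
}

#' All-vs-all self alignment of a contig set
#'
#' Variant of the anchor aligner for haplotype-duplicate screening: k-mer
#' uniqueness is assessed *excluding the query contig itself*, so a contig
#' that duplicates part of a larger contig still anchors to it. Trivial
#' self-hits (query == target) are excluded.
#'
#' @param contigs an [assembly] or named character vector.
#' @param k k-mer size.
#' @param min_anchors,max_gap,max_diag_drift chaining parameters, see
#'   [anchor_align].
#' @return alignment-record data.frame.
#' @export
self_align_contigs <- function(contigs, k = 21L, min_anchors = 3L,
                               max_gap = 5000L, max_diag_drift = 25L) {
  seqs <- if (inherits(contigs, "assembly")) contigs$seq else contigs
  useqs <- toupper(seqs)
  km <- character(0); sq <- character(0); ps <- integer(0)
  for (nm in names(useqs)) {
    s <- useqs[[nm]]; n <- nchar(s)
    if (n < k) next
    kk <- substring(s, 1:(n - k + 1L), k:n)
    keep <- !grepl("N", kk, fixed = TRUE)
    km <- c(km, kk[keep]); sq <- c(sq, rep(nm, sum(keep)))
    ps <- c(ps, which(keep) - 1L)
  }
  kid <- match(km, unique(km))
  total_cnt <- tabulate(kid)
  lens <- vapply(seqs, nchar, integer(1))
  recs <- list()
  for (qn in names(useqs)) {
    in_q <- sq == qn
    cnt_q <- tabulate(kid[in_q], nbins = length(total_cnt))
    # query k-mers, unique within query, that occur exactly once elsewhere
    qk <- kid[in_q]; qp_all <- ps[in_q]
    uniq_in_q <- cnt_q[qk] == 1L
    outside_once <- (total_cnt[qk] - cnt_q[qk]) == 1L
    sel <- uniq_in_q & outside_once
    if (!any(sel)) next
    qk <- qk[sel]; qp <- qp_all[sel]
    out_idx <- which(!in_q)
    m <- match(qk, kid[out_idx])
    ti <- out_idx[m]
    tseq <- sq[ti]; tp <- ps[ti]
    for (ts in unique(tseq)) {
      selt <- tseq == ts
      chains <- chain_anchors(qp[selt], tp[selt], k, max_gap, max_diag_drift)
      for (ch in chains) {
        if (length(ch$qpos) < min_anchors) next
        qs <- ch$qpos[1]; qe <- ch$qpos[length(ch$qpos)] + k
        tss <- ch$tpos[1]; tee <- ch$tpos[length(ch$tpos)] + k
        # base-exact matches when the chain spans agree (pure diagonal or
        # drift-free substitution-only region); anchored lower bound otherwise
        nm_b <- if (tee - tss == qe - qs) {
          hamming_matches(substr(useqs[[qn]], qs + 1L, qe),
                          substr(useqs[[ts]], tss + 1L, tee))
        } else {
          anchored_bases(ch$qpos, k)
        }
        recs[[length(recs) + 1L]] <- data.frame(
          qname = qn, qlen = lens[[qn]], qstart = qs, qend = qe, strand = "+",
          tname = ts, tlen = lens[[ts]], tstart = tss, tend = tee,
          nmatch = nm_b, alen = max(qe - qs, tee - tss), mapq = 60L)
      }
    }
  }
  if (length(recs) == 0L) return(empty_paf())
  do.call(rbind, recs)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch alignment (via Biostrings) of two sequences, reporting
#' percent coverage of `a`, percent identity, and an edit script. Identity is
#' matches over all alignment columns; `identity_aligned` excludes terminal
#' gap columns (useful when `b` is a truncated version of `a`). Coverage is
#' the fraction of `a`'s bases lying between the first and last column where
#' both sequences are present. Case-insensitive; N never counts as a match.
#'
#' @param a,b DNA strings (non-empty).
#' @return list with elements `coverage`, `identity`, `identity_aligned`
#'   (percentages), `matches`, `columns`, `edits` (data.frame op/a_pos/b_pos/
#'   a_bases/b_bases with 0-based positions), and the gapped strings
#'   `aligned_a`, `aligned_b`.
#' @export
global_align <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b), type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  align_stats(a, ga, gb)
}

# shared stats computation from two gapped strings
align_stats <- function(a, ga, gb) {
  va <- strsplit(ga, "", fixed = TRUE)[[1]]
  vb <- strsplit(gb, "", fixed = TRUE)[[1]]
  ncols <- length(va)
  is_match <- va == vb & va != "-" & va != "N"
  both <- va != "-" & vb != "-"
  first_b <- if (any(both)) min(which(both)) else NA_integer_
  last_b <- if (any(both)) max(which(both)) else NA_integer_
  if (is.na(first_b)) {
    cov <- 0; ident_aln <- 0
  } else {
    inner <- first_b:last_b
    # coverage counts a's bases aligned to a base of b (the length-ratio
    # sense of "at least 50% as long"), so internal deletions reduce it
    cov <- 100 * sum(both) / nchar(a)
    ident_aln <- 100 * sum(is_match[inner]) / length(inner)
  }
  edits <- edit_script(va, vb)
  list(coverage = cov,
       identity = 100 * sum(is_match) / ncols,
       identity_aligned = ident_aln,
       matches = sum(is_match), columns = ncols,
       edits = edits, aligned_a = ga, aligned_b = gb)
}

# Edit script from gapped strings: rows with op in {X (mismatch), I (insertion
# in b relative to a), D (deletion from a)}; a_pos/b_pos are 0-based positions
# on the ungapped sequences at the start of the run.
edit_script <- function(va, vb) {
  op <- ifelse(va == "-", "I", ifelse(vb == "-", "D",
                                      ifelse(toupper(va) == toupper(vb), "M", "X")))
  a_pos_col <- cumsum(va != "-") - (va != "-")
  b_pos_col <- cumsum(vb != "-") - (vb != "-")
  r <- rle(op)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != "M"
  if (!any(keep)) {
    return(data.frame(op = character(0), a_pos = integer(0), b_pos = integer(0),
                      len = integer(0), a_bases = character(0),
                      b_bases = character(0)))
  }
  data.frame(
    op = r$values[keep],
    a_pos = a_pos_col[starts[keep]],
    b_pos = b_pos_col[starts[keep]],
    len = r$lengths[keep],
    a_bases = vapply(which(keep), function(i)
      paste(va[starts[i]:ends[i]][va[starts[i]:ends[i]] != "-"], collapse = ""),
      character(1)),
    b_bases = vapply(which(keep), function(i)
      paste(vb[starts[i]:ends[i]][vb[starts[i]:ends[i]] != "-"], collapse = ""),
      character(1)))
}

# Lift a 0-based position on sequence a through gapped strings to b;
# returns NA if the position falls in a gap column of b.
lift_through_alignment <- function(ga, gb, a_pos0) {
  va <- strsplit(ga, "", fixed = TRUE)[[1]]
  vb <- strsplit(gb, "", fixed = TRUE)[[1]]
  a_idx <- cumsum(va != "-")
  col <- match(a_pos0 + 1L, a_idx)
  if (is.na(col) || vb[col] == "-") return(NA_integer_)
  sum(vb[1:col] != "-") - 1L
}

#' Extract mRNA and CDS sequences for annotated transcripts
#'
#' Concatenates exon (mRNA) and CDS slices per transcript in translation
#' order; minus-strand transcripts are reverse complemented. Transcripts
#' whose CDS length (after the first-CDS phase offset) is not a multiple of
#' three are flagged rather than dropped.
#'
#' @param x an [assembly].
#' @param annot feature table (see [read_gff3]), 1-based inclusive.
#' @return list with named character vectors `mrna` and `cds`, and a
#'   data.frame `flags` (transcript, reason).
#' @export
extract_transcript_sequences <- function(x, annot) {
  stopifnot(inherits(x, "assembly"))
  tx <- annot[annot$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna <- character(0); cds <- character(0)
  flags <- data.frame(transcript = character(0), reason = character(0))
  for (i in seq_len(nrow(tx))) {
    id <- tx$ID[i]; strand <- tx$strand[i]; chrom <- tx$seqid[i]
    if (!chrom %in% names(x$seq)) {
      flags <- rbind(flags, data.frame(transcript = id, reason = "unknown_seq"))
      next
    }
    s <- x$seq[[chrom]]
    pull <- function(type) {
      ft <- annot[annot$type == type & !is.na(annot$Parent) & annot$Parent == id, ,
                  drop = FALSE]
      ft <- ft[order(ft$start), , drop = FALSE]
      if (nrow(ft) == 0L) return(NULL)
      seqc <- paste(substring(s, ft$start, ft$end), collapse = "")
      if (strand == "-") revcomp(seqc) else seqc
    }
    m <- pull("exon"); cd <- pull("CDS")
    if (!is.null(m)) mrna[id] <- m
    if (!is.null(cd)) {
      cds[id] <- cd
      ph <- annot$phase[annot$type == "CDS" & !is.na(annot$Parent) &
                          annot$Parent == id]
      ph0 <- if (length(ph) && !all(is.na(ph))) {
        # phase of the first CDS segment in translation order
        first <- if (strand == "-") which.max(
          annot$start[annot$type == "CDS" & !is.na(annot$Parent) & annot$Parent == id])
        else which.min(
          annot$start[annot$type == "CDS" & !is.na(annot$Parent) & annot$Parent == id])
        p <- ph[first]; if (is.na(p)) 0L else p
      } else 0L
      if ((nchar(cd) - ph0) %% 3L != 0L) {
        flags <- rbind(flags, data.frame(transcript = id,
                                         reason = "cds_length_not_phase_consistent"))
      }
    }
  }
  list(mrna = mrna, cds = cds, flags = flags)
}

# translate a CDS string to protein using the standard code; stops are "*";
# codons with N translate to "X"; trailing partial codon ignored.
translate_cds <- function(cds) {
  s <- toupper(cds)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, 3L * (0:(n - 1L)) + 1L, 3L * (1:n))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}
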