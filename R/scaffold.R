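# Contig-to-chromosome tiling: haplotype-duplicate screening, candidate
# breakpoint detection from alignment ends, coverage-based confirmation,
# contig splitting, and ordered/oriented chromosome construction with
# estimated gaps.

#' Remove haplotype-duplicate contigs
#'
#' A contig is removed iff its alignments to a single larger contig cover at
#' least `containment` of its length and their aggregate identity (summed
#' matches over summed block length) strictly exceeds `identity`. This
#' screens out small contigs that are redundant second-haplotype copies of a
#' region already represented by a larger contig.
#'
#' @param contigs contig [assembly].
#' @param alignments self-alignment records (see [self_align_contigs]);
#'   trivial self-hits must already be absent.
#' @param identity aggregate identity threshold (strict `>`), in (0, 1].
#' @param containment required covered fraction of the smaller contig.
#' @return list with `kept` ([assembly]), `removed` (data.frame contig,
#'   length, covered_by, identity).
#' @export
filter_haplotype_duplicates <- function(contigs, alignments, identity = 0.97,
                                        containment = 0.99) {
  if (identity <= 0 || identity > 1) stop("identity threshold must lie in (0, 1]")
  lens <- seq_lengths(contigs)
  removed <- data.frame(contig = character(0), length = integer(0),
                        covered_by = character(0), identity = numeric(0))
  for (qn in names(lens)) {
    al <- alignments[alignments$qname == qn &
                       lens[alignments$tname] > lens[[qn]], , drop = FALSE]
    if (nrow(al) == 0L) next
    for (tn in unique(al$tname)) {
      a <- al[al$tname == tn, , drop = FALSE]
      iv <- a[order(a$qstart), c("qstart", "qend")]
      cov <- 0L; hi <- -1L
      for (i in seq_len(nrow(iv))) {
        s <- max(iv$qstart[i], hi); e <- iv$qend[i]
        if (e > s) cov <- cov + (e - s)
        hi <- max(hi, e)
      }
      agg_id <- sum(a$nmatch) / sum(a$alen)
      if (cov / lens[[qn]] >= containment && agg_id > identity) {
        removed <- rbind(removed, data.frame(contig = qn, length = lens[[qn]],
                                             covered_by = tn,
                                             identity = agg_id))
        break
      }
    }
  }
  keep <- setdiff(names(contigs$seq), removed$contig)
  list(kept = assembly(contigs$seq[keep], version = contigs$version,
                       meta = contigs$meta),
       removed = removed)
}

#' Assign contigs to donor chromosomes
#'
#' Each contig goes to the chromosome with the greatest summed aligned bases
#' (alignments shorter than `min_len` are ignored); orientation is the strand
#' carrying the majority of aligned bases on that chromosome. Ties break
#' lexicographically by chromosome name for determinism.
#'
#' @param alignments contig-vs-donor alignment records.
#' @param min_len minimum alignment block length considered.
#' @return data.frame contig, chrom, strand, aligned_bp; contigs with no
#'   qualifying alignment are absent (unplaced).
#' @export
assign_contigs <- function(alignments, min_len = 2000L) {
  al <- alignments[alignments$alen >= min_len, , drop = FALSE]
  if (nrow(al) == 0L) {
    return(data.frame(contig = character(0), chrom = character(0),
                      strand = character(0), aligned_bp = integer(0)))
  }
  out <- NULL
  for (qn in sort(unique(al$qname))) {
    a <- al[al$qname == qn, , drop = FALSE]
    by_chr <- tapply(a$qend - a$qstart, a$tname, sum)
    best <- sort(names(by_chr)[by_chr == max(by_chr)])[1]
    ab <- a[a$tname == best, , drop = FALSE]
    by_strand <- tapply(ab$qend - ab$qstart, ab$strand, sum)
    strand <- names(by_strand)[which.max(by_strand)]
    out <- rbind(out, data.frame(contig = qn, chrom = best, strand = strand,
                                 aligned_bp = as.integer(max(by_chr))))
  }
  out
}

#' Detect candidate breakpoints from interior alignment ends
#'
#' Every alignment end lying strictly more than `end_dist` from both contig
#' ends is a candidate mis-assembly breakpoint. Candidates within
#' `merge_radius` of each other are merged (median position kept).
#'
#' @param contig contig name.
#' @param alignments alignment records for that contig (query side).
#' @param end_dist minimum distance from either contig end (strict `>`).
#' @param merge_radius dedup radius for nearby ends.
#' @return data.frame contig, pos, class (`"unconfirmed"`), split_pos (NA).
#' @export
find_candidate_breakpoints <- function(contig, alignments, end_dist = 5000L,
                                       merge_radius = 1000L) {
  al <- alignments[alignments$qname == contig, , drop = FALSE]
  empty <- data.frame(contig = character(0), pos = integer(0),
                      class = character(0), split_pos = integer(0))
  if (nrow(al) == 0L) return(empty)
  L <- al$qlen[1]
  ends <- sort(unique(c(al$qstart, al$qend)))
  ends <- ends[ends > end_dist & ends < L - end_dist]
  if (length(ends) == 0L) return(empty)
  grp <- cumsum(c(TRUE, diff(ends) > merge_radius))
  pos <- as.integer(tapply(ends, grp, function(x) stats::median(x)))
  data.frame(contig = contig, pos = pos, class = "unconfirmed",
             split_pos = NA_integer_)
}

# minimum depth and its closest position to `ref_pos` within [lo, hi) of a
# coverage track restricted to one sequence
min_depth_in_window <- function(cov, seqname, lo, hi, ref_pos) {
  cv <- cov[cov$seq == seqname & cov$end > lo & cov$start < hi, , drop = FALSE]
  if (nrow(cv) == 0L) return(list(min = Inf, max = -Inf, pos = NA_integer_))
  mn <- min(cv$depth); mx <- max(cv$depth)
  # the weak point is the midpoint of the minimum-depth run nearest the
  # reference position; runs are measured on the full per-contig track so a
  # window edge cannot clip them, and every candidate around one junction
  # resolves to the same split position
  full <- cov[cov$seq == seqname, , drop = FALSE]
  full <- full[order(full$start), , drop = FALSE]
  at <- full[full$depth == mn, , drop = FALSE]
  run_id <- cumsum(c(TRUE, at$start[-1] != at$end[-nrow(at)]))
  runs <- data.frame(start = tapply(at$start, run_id, min),
                     end = tapply(at$end, run_id, max))
  # keep runs that intersect the window
  runs <- runs[runs$end > lo & runs$start < hi, , drop = FALSE]
  mid <- as.integer((runs$start + runs$end) %/% 2L)
  dist <- pmax(0L, pmax(runs$start - ref_pos, ref_pos - runs$end + 1L))
  list(min = mn, max = mx, pos = mid[which.min(dist)])
}

#' Confirm candidate breakpoints from read coverage
#'
#' A candidate is confirmed as a mis-assembly iff any position within
#' `window` of it has depth `<= low` or `> high`. Low-coverage confirmations
#' split at the weak point (the minimum-depth position, nearest the
#' candidate among ties); high-coverage confirmations, which indicate a
#' repeat-induced join, split at the alignment breakpoint itself.
#'
#' @param candidates candidate table from [find_candidate_breakpoints].
#' @param coverage coverage track (seq, start, end, depth).
#' @param low,high depth thresholds (`<= low`, `> high`).
#' @param window search half-width around the candidate.
#' @return the candidate table with `class` in
#'   `{"unconfirmed","low-coverage","high-coverage"}` and `split_pos` set for
#'   confirmed rows.
#' @export
classify_breakpoints <- function(candidates, coverage, low = 3, high = 35,
                                 window = 50000L) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    p <- candidates$pos[i]
    st <- min_depth_in_window(coverage, candidates$contig[i],
                              p - window, p + window, p)
    if (st$min <= low) {
      candidates$class[i] <- "low-coverage"
      candidates$split_pos[i] <- st$pos
    } else if (st$max > high) {
      candidates$class[i] <- "high-coverage"
      candidates$split_pos[i] <- p
    }
  }
  candidates
}

#' Split contigs at confirmed breakpoints
#'
#' Confirmed split positions (deduplicated within `merge_radius`) partition
#' each contig; pieces are named `<contig>.1`, `<contig>.2`, ... left to
#' right and their concatenation equals the original contig. Unconfirmed
#' candidates leave contigs intact.
#'
#' @param contigs contig [assembly].
#' @param candidates classified candidate table.
#' @param merge_radius dedup radius for split positions.
#' @return list with `contigs` (new [assembly]), `splits` (data.frame contig,
#'   split_pos, class), `rename` (data.frame old, new, start, end).
#' @export
split_contigs <- function(contigs, candidates, merge_radius = 1000L) {
  conf <- candidates[candidates$class != "unconfirmed" &
                       !is.na(candidates$split_pos), , drop = FALSE]
  seqs <- contigs$seq
  out <- character(0)
  rename <- NULL; splits <- NULL
  for (nm in names(seqs)) {
    cc <- conf[conf$contig == nm, , drop = FALSE]
    L <- nchar(seqs[[nm]])
    pos <- sort(unique(cc$split_pos))
    pos <- pos[pos > 0L & pos < L]
    if (length(pos) > 1L) {
      keep <- c(TRUE, diff(pos) > merge_radius)
      pos <- pos[keep]
    }
    if (length(pos) == 0L) {
      out[nm] <- seqs[[nm]]
      next
    }
    bounds <- c(0L, pos, L)
    for (j in seq_len(length(bounds) - 1L)) {
      nn <- sprintf("%s.%d", nm, j)
      out[nn] <- substr(seqs[[nm]], bounds[j] + 1L, bounds[j + 1L])
      rename <- rbind(rename, data.frame(old = nm, new = nn,
                                         start = bounds[j], end = bounds[j + 1L]))
    }
    splits <- rbind(splits, data.frame(contig = nm, split_pos = pos,
                                       class = cc$class[match(pos, cc$split_pos)]))
  }
  list(contigs = assembly(out, version = contigs$version, meta = contigs$meta),
       splits = splits %||% data.frame(contig = character(0),
                                       split_pos = integer(0),
                                       class = character(0)),
       rename = rename %||% data.frame(old = character(0), new = character(0),
                                       start = integer(0), end = integer(0)))
}

#' Build ordered, oriented chromosome sequences from assigned contigs
#'
#' Contigs assigned to each donor chromosome are projected onto donor
#' coordinates (span of their qualifying alignments), ordered by projected
#' midpoint, reverse-complemented when minus-strand, and joined with N gaps
#' sized from the donor-coordinate distance between neighbours (floor
#' `gap_floor` when the projection implies zero or overlap). Overlapping
#' projections are resolved by trimming the lower-identity contig. Unplaced
#' contigs are returned separately.
#'
#' @param assignments assignment table from [assign_contigs].
#' @param alignments contig-vs-donor alignment records.
#' @param contigs contig [assembly].
#' @param min_len minimum alignment length used for projection.
#' @param gap_floor minimum emitted gap size.
#' @param version version tag for the chromosome assembly.
#' @return list with `chromosomes` ([assembly]), `plan` (tiling-plan
#'   data.frame, see [write_agp]), `unplaced` ([assembly]).
#' @export
build_chromosomes <- function(assignments, alignments, contigs,
                              min_len = 2000L, gap_floor = 100L,
                              version = "v0.9") {
  al <- alignments[alignments$alen >= min_len, , drop = FALSE]
  lens <- seq_lengths(contigs)
  segs <- NULL
  for (i in seq_len(nrow(assignments))) {
    qn <- assignments$contig[i]; ch <- assignments$chrom[i]
    st <- assignments$strand[i]
    a <- al[al$qname == qn & al$tname == ch & al$strand == st, , drop = FALSE]
    if (nrow(a) == 0L) a <- al[al$qname == qn & al$tname == ch, , drop = FALSE]
    if (nrow(a) == 0L) next
    segs <- rbind(segs, data.frame(
      contig = qn, chrom = ch, strand = st,
      tstart = min(a$tstart), tend = max(a$tend),
      identity = sum(a$nmatch) / sum(a$alen),
      clen = lens[[qn]], trim_left = 0L, trim_right = 0L))
  }
  chroms_out <- character(0)
  plan <- NULL
  if (!is.null(segs)) {
    for (ch in sort(unique(segs$chrom))) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      s <- s[order((s$tstart + s$tend) / 2), , drop = FALSE]
      # resolve overlapping donor projections by trimming the weaker contig
      if (nrow(s) > 1L) {
        for (j in seq_len(nrow(s) - 1L)) {
          ov <- s$tend[j] - s$tstart[j + 1L]
          if (ov > 0L) {
            if (s$identity[j] <= s$identity[j + 1L]) {
              s$trim_right[j] <- min(s$trim_right[j] + ov,
                                     s$clen[j] - s$trim_left[j] - 1L)
              s$tend[j] <- s$tend[j] - ov
            } else {
              s$trim_left[j + 1L] <- min(s$trim_left[j + 1L] + ov,
                                         s$clen[j + 1L] - s$trim_right[j + 1L] - 1L)
              s$tstart[j + 1L] <- s$tstart[j + 1L] + ov
            }
          }
        }
      }
      parts <- character(0)
      obj_pos <- 0L
      for (j in seq_len(nrow(s))) {
        if (j > 1L) {
          gap <- s$tstart[j] - s$tend[j - 1L]
          gap <- max(gap, gap_floor)
          parts <- c(parts, strrep("N", gap))
          plan <- rbind(plan, data.frame(object = ch, obj_start = obj_pos,
                                         obj_end = obj_pos + gap, type = "N",
                                         comp = NA_character_,
                                         comp_start = NA_integer_,
                                         comp_end = NA_integer_,
                                         orient = NA_character_,
                                         gap_len = gap))
          obj_pos <- obj_pos + gap
        }
        sq <- contigs$seq[[s$contig[j]]]
        cs <- if (s$strand[j] == "+") s$trim_left[j] else s$trim_right[j]
        ce <- s$clen[j] - (if (s$strand[j] == "+") s$trim_right[j] else s$trim_left[j])
        piece <- substr(sq, cs + 1L, ce)
        if (s$strand[j] == "-") piece <- revcomp(piece)
        parts <- c(parts, piece)
        plan <- rbind(plan, data.frame(object = ch, obj_start = obj_pos,
                                       obj_end = obj_pos + nchar(piece),
                                       type = "W", comp = s$contig[j],
                                       comp_start = cs, comp_end = ce,
                                       orient = s$strand[j],
                                       gap_len = NA_integer_))
        obj_pos <- obj_pos + nchar(piece)
      }
      chroms_out[ch] <- paste(parts, collapse = "")
    }
  }
  placed <- unique(segs$contig)
  unplaced_names <- setdiff(names(contigs$seq), placed)
  list(chromosomes = assembly(chroms_out, version = version),
       plan = plan %||% data.frame(object = character(0), obj_start = integer(0),
                                   obj_end = integer(0), type = character(0),
                                   comp = character(0), comp_start = integer(0),
                                   comp_end = integer(0), orient = character(0),
                                   gap_len = integer(0)),
       unplaced = assembly(contigs$seq[unplaced_names], version = "unplaced"))
}

#' Run the full tiling stage
#'
#' Convenience wrapper: align contigs to the donor, detect and classify
#' breakpoints with the coverage track, split confirmed mis-assemblies,
#' re-align the split contigs, assign, and build chromosomes.
#'
#' @param contigs contig [assembly].
#' @param donor donor [assembly].
#' @param coverage coverage track.
#' @param low,high,window,end_dist,merge_radius see [classify_breakpoints]
#'   and [find_candidate_breakpoints].
#' @param k k-mer size for the anchor aligner.
#' @return list with `chromosomes`, `plan`, `unplaced`, `splits`,
#'   `candidates`, `assignments`.
#' @export
tile_assembly <- function(contigs, donor, coverage, low = 3, high = 35,
                          window = 50000L, end_dist = 5000L,
                          merge_radius = 1000L, k = 21L) {
  idx <- kmer_index(donor, k = k)
  al <- anchor_align(contigs$seq, idx)
  cands <- do.call(rbind, lapply(unique(al$qname), function(nm)
    find_candidate_breakpoints(nm, al, end_dist = end_dist,
                               merge_radius = merge_radius)))
  if (is.null(cands)) cands <- data.frame(contig = character(0), pos = integer(0),
                                          class = character(0),
                                          split_pos = integer(0))
  cands <- classify_breakpoints(cands, coverage, low = low, high = high,
                                window = window)
  sp <- split_contigs(contigs, cands, merge_radius = merge_radius)
  al2 <- anchor_align(sp$contigs$seq, idx)
  asg <- assign_contigs(al2)
  built <- build_chromosomes(asg, al2, sp$contigs)
  c(built, list(splits = sp$splits, candidates = cands, assignments = asg,
                split_contigs = sp$contigs, alignments = al2))
}
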