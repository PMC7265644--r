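# Two-step donor gap filling. Step 1 (spanned fill): a gap is closed with
# contiguous donor sequence when both gap flanks anchor uniquely to the donor
# with sufficient length and identity. Step 2 (fitted contigs): donor contigs
# whose implied donor interval falls inside a remaining gap are inserted,
# each bracketed by 100-N gaps. All inserted bases are lowercased so donor
# content stays distinguishable from native sequence.

# flank of non-N sequence immediately left/right of [gs, ge) on `s`
gap_flank <- function(s, gs, ge, side, width) {
  if (side == "left") {
    lo <- max(0L, gs - width)
    fl <- substr(s, lo + 1L, gs)
    cut <- regexpr("[ACGTacgt]+$", fl)
    if (cut < 0) return(NULL)
    list(seq = substr(fl, cut, nchar(fl)), offset = lo + cut - 1L)
  } else {
    hi <- min(nchar(s), ge + width)
    fl <- substr(s, ge + 1L, hi)
    m <- regexpr("^[ACGTacgt]+", fl)
    if (m < 0) return(NULL)
    list(seq = substr(fl, 1L, attr(m, "match.length")), offset = ge)
  }
}

# map one flank onto the donor; returns NULL unless exactly one locus passes
# the span requirement and the refined identity clears the floor
map_flank <- function(flank_seq, index, donor_seqs, min_flank, identity_floor,
                      unique_required = TRUE) {
  res <- locate_query(flank_seq, index, donor_seqs, min_chain_frac = 0.5,
                      max_diag_drift = 0L)
  if (is.null(res$placement)) return(NULL)
  if (unique_required && res$n_loci != 1L) return(NULL)
  p <- res$placement
  if (p$span < min_flank) return(NULL)
  if (p$identity < 100 * identity_floor) return(NULL)
  p
}

#' Fill assembly gaps spanned by contiguous donor sequence
#'
#' For every interior N run, both flanks (up to `flank_window` bp of non-N
#' sequence) are aligned to the donor. The gap is filled iff each flank has
#' exactly one qualifying placement (uniqueness guards against
#' repeat-mediated mis-fills), both placements exceed `min_flank` aligned
#' bases at `identity_floor` identity, lie on the same donor sequence and
#' strand in spanning order, and the spanned donor slice contains no N. The
#' N run is replaced by the lowercase donor infill.
#'
#' @param x assembly to fill.
#' @param donor donor [assembly].
#' @param min_flank minimum aligned flank length (bp).
#' @param flank_window flank sequence extracted per side (bp).
#' @param identity_floor minimum flank identity, in (0, 1].
#' @param k anchor k-mer size.
#' @param index optional prebuilt donor [kmer_index].
#' @return list with `assembly` (filled, version bumped) and `events`
#'   (data.frame chrom, gap_start, gap_end, mode, donor_chrom, donor_start,
#'   donor_end, strand, bases_inserted, flank_identity_left/right).
#' @export
fill_spanned_gaps <- function(x, donor, min_flank = 2000L,
                              flank_window = 5000L, identity_floor = 0.99,
                              k = 21L, index = NULL) {
  stopifnot(inherits(x, "assembly"), inherits(donor, "assembly"))
  if (is.null(index)) index <- kmer_index(donor, k = k)
  events <- NULL
  seqs <- x$seq
  for (ch in names(seqs)) {
    gaps <- find_gaps(stats::setNames(seqs[ch], ch))
    if (nrow(gaps) == 0L) next
    for (gi in rev(seq_len(nrow(gaps)))) {
      gs <- gaps$start[gi]; ge <- gaps$end[gi]
      lf <- gap_flank(seqs[[ch]], gs, ge, "left", flank_window)
      rf <- gap_flank(seqs[[ch]], gs, ge, "right", flank_window)
      if (is.null(lf) || is.null(rf)) next
      if (nchar(lf$seq) < min_flank || nchar(rf$seq) < min_flank) next
      pl <- map_flank(lf$seq, index, donor$seq, min_flank, identity_floor)
      pr <- map_flank(rf$seq, index, donor$seq, min_flank, identity_floor)
      if (is.null(pl) || is.null(pr)) next
      if (pl$tname != pr$tname || pl$strand != pr$strand) next
      if (pl$strand == "+") {
        b_l <- pl$lift(nchar(lf$seq) - 1L)
        b_r <- pr$lift(0L)
        if (is.na(b_l) || is.na(b_r) || b_r < b_l + 1L) next
        infill <- substr(donor$seq[[pl$tname]], b_l + 2L, b_r)
        ds <- b_l + 1L; de <- b_r
      } else {
        b_l <- pl$lift(nchar(lf$seq) - 1L)
        b_r <- pr$lift(0L)
        if (is.na(b_l) || is.na(b_r) || b_l < b_r + 1L) next
        infill <- revcomp(substr(donor$seq[[pl$tname]], b_r + 2L, b_l))
        ds <- b_r + 1L; de <- b_l
      }
      if (grepl("N", infill, fixed = TRUE)) next  # donor not contiguous here
      seqs[[ch]] <- splice_str(seqs[[ch]], gs, ge, lc(infill))
      events <- rbind(events, data.frame(
        chrom = ch, gap_start = gs, gap_end = ge, mode = "spanned",
        donor_chrom = pl$tname, donor_start = ds, donor_end = de,
        strand = pl$strand, bases_inserted = nchar(infill),
        flank_identity_left = pl$identity, flank_identity_right = pr$identity))
    }
  }
  list(assembly = assembly(seqs, version = "v1.0", meta = x$meta),
       events = events %||% data.frame(
         chrom = character(0), gap_start = integer(0), gap_end = integer(0),
         mode = character(0), donor_chrom = character(0),
         donor_start = integer(0), donor_end = integer(0),
         strand = character(0), bases_inserted = integer(0),
         flank_identity_left = numeric(0), flank_identity_right = numeric(0)))
}

#' Split a donor assembly into its gap-free contigs
#'
#' @param donor donor [assembly].
#' @return data.frame chrom, start, end (0-based half-open) of each maximal
#'   N-free stretch.
#' @export
donor_contig_table <- function(donor) {
  out <- NULL
  for (ch in names(donor$seq)) {
    runs <- char_runs(donor$seq[[ch]], c("A", "C", "G", "T", "a", "c", "g", "t"))
    if (nrow(runs)) out <- rbind(out, data.frame(chrom = ch, start = runs$start,
                                                 end = runs$end))
  }
  out %||% data.frame(chrom = character(0), start = integer(0), end = integer(0))
}

#' Insert donor contigs that fit inside remaining gaps
#'
#' For each remaining gap, the flanks are placed on the donor (best
#' placement, no uniqueness requirement) to get the gap's implied donor
#' interval and size estimate. Every donor contig whose own donor interval
#' lies inside the implied interval, and whose length is at most
#' `tol_factor * estimate + tol_add`, is inserted in donor-coordinate order,
#' lowercase, with a `flank_gap`-N gap on each side — so each insertion
#' raises the gap count by one while shrinking total gap length.
#'
#' @param x assembly after [fill_spanned_gaps].
#' @param donor donor [assembly].
#' @param tol_factor,tol_add fitting tolerance on contig length.
#' @param flank_gap N-gap size placed on both sides of an inserted contig.
#' @param min_flank,flank_window,identity_floor,k,index flank mapping
#'   parameters, as in [fill_spanned_gaps] (identity still enforced; span
#'   requirement is halved because these gaps often have shorter clean
#'   flanks).
#' @return list with `assembly` (version `v1.1`) and `events` (one row per
#'   inserted contig).
#' @export
insert_fitting_contigs <- function(x, donor, tol_factor = 1.1, tol_add = 200L,
                                   flank_gap = 100L, min_flank = 2000L,
                                   flank_window = 5000L, identity_floor = 0.99,
                                   k = 21L, index = NULL) {
  if (is.null(index)) index <- kmer_index(donor, k = k)
  dct <- donor_contig_table(donor)
  events <- NULL
  seqs <- x$seq
  for (ch in names(seqs)) {
    gaps <- find_gaps(stats::setNames(seqs[ch], ch))
    if (nrow(gaps) == 0L) next
    for (gi in rev(seq_len(nrow(gaps)))) {
      gs <- gaps$start[gi]; ge <- gaps$end[gi]
      lf <- gap_flank(seqs[[ch]], gs, ge, "left", flank_window)
      rf <- gap_flank(seqs[[ch]], gs, ge, "right", flank_window)
      if (is.null(lf) || is.null(rf)) next
      pl <- map_flank(lf$seq, index, donor$seq, min_flank %/% 2L,
                      identity_floor, unique_required = FALSE)
      pr <- map_flank(rf$seq, index, donor$seq, min_flank %/% 2L,
                      identity_floor, unique_required = FALSE)
      if (is.null(pl) && is.null(pr)) next
      if (!is.null(pl) && !is.null(pr) &&
          (pl$tname != pr$tname || pl$strand != pr$strand)) next
      gap_len <- ge - gs
      # implied donor interval; with a single mapped flank the N-run length
      # (the tiler's donor-projected size estimate) stands in for the other
      # boundary
      if (!is.null(pl) && pl$strand == "-" || is.null(pl) && pr$strand == "-") {
        d_hi <- if (!is.null(pl)) pl$lift(nchar(lf$seq) - 1L) else NA_integer_
        d_lo <- if (!is.null(pr)) pr$lift(0L) + 1L else NA_integer_
        if (is.na(d_lo)) d_lo <- d_hi - gap_len
        if (is.na(d_hi)) d_hi <- d_lo + gap_len
        strand <- "-"
      } else {
        d_lo <- if (!is.null(pl)) pl$lift(nchar(lf$seq) - 1L) + 1L else NA_integer_
        d_hi <- if (!is.null(pr)) pr$lift(0L) else NA_integer_
        if (is.na(d_lo)) d_lo <- d_hi - gap_len
        if (is.na(d_hi)) d_hi <- d_lo + gap_len
        strand <- "+"
      }
      if (is.null(pl)) pl <- pr
      if (is.null(pr)) pr <- pl
      if (is.na(d_lo) || is.na(d_hi) || d_hi <= d_lo) next
      est <- d_hi - d_lo
      fit <- dct[dct$chrom == pl$tname & dct$start >= d_lo & dct$end <= d_hi, ,
                 drop = FALSE]
      fit <- fit[(fit$end - fit$start) <= tol_factor * est + tol_add, ,
                 drop = FALSE]
      if (nrow(fit) == 0L) next
      fit <- fit[order(fit$start), , drop = FALSE]
      pieces <- vapply(seq_len(nrow(fit)), function(i)
        substr(donor$seq[[pl$tname]], fit$start[i] + 1L, fit$end[i]),
        character(1))
      if (pl$strand == "-") pieces <- rev(revcomp(pieces))
      gap_n <- strrep("N", flank_gap)
      repl <- paste0(gap_n, paste(lc(pieces), collapse = gap_n), gap_n)
      seqs[[ch]] <- splice_str(seqs[[ch]], gs, ge, repl)
      events <- rbind(events, data.frame(
        chrom = ch, gap_start = gs, gap_end = ge, mode = "fitted",
        donor_chrom = pl$tname, donor_start = fit$start, donor_end = fit$end,
        strand = pl$strand, bases_inserted = fit$end - fit$start,
        flank_identity_left = pl$identity, flank_identity_right = pr$identity))
    }
  }
  list(assembly = assembly(seqs, version = "v1.1", meta = x$meta),
       events = events %||% data.frame(
         chrom = character(0), gap_start = integer(0), gap_end = integer(0),
         mode = character(0), donor_chrom = character(0),
         donor_start = integer(0), donor_end = integer(0),
         strand = character(0), bases_inserted = integer(0),
         flank_identity_left = numeric(0), flank_identity_right = numeric(0)))
}
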