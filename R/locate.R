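# Locating a query window on a target assembly: anchor chains give the
# coarse placement; refinement is an exact base-level comparison — a direct
# hamming comparison when the chain sits on a single diagonal (the common
# case on closely related sequences), otherwise a full affine-gap global
# alignment of the implied slice.

# Best match count between two short gap-region strings under a single-indel
# model: the shorter string is split once against the longer, prefix aligned
# left and suffix aligned right; mismatching bases count as mismatches.
# Exact for one indel plus substitutions, which is what a region between two
# adjacent chain blocks contains.
gap_matches <- function(a, b) {
  na_ <- nchar(a); nb_ <- nchar(b)
  if (na_ == 0L || nb_ == 0L) return(list(matches = 0L,
                                          columns = max(na_, nb_)))
  if (na_ > nb_) { tmp <- a; a <- b; b <- tmp; tmp <- na_; na_ <- nb_; nb_ <- tmp }
  av <- utf8ToInt(toupper(a)); bv <- utf8ToInt(toupper(b))
  n_code <- utf8ToInt("N")
  d <- nb_ - na_
  pref <- cumsum(av == bv[seq_len(na_)] & av != n_code)
  sufm <- rev(cumsum(rev(av == bv[seq_len(na_) + d] & av != n_code)))
  best <- max(c(sufm[1], pref[na_],
                if (na_ > 1L) pref[seq_len(na_ - 1L)] + sufm[-1] else integer(0)))
  list(matches = as.integer(best), columns = nb_)
}

# Group chain records for one query into target loci: records on the same
# target sequence whose target intervals lie within `link` of each other
# belong to one locus.
cluster_chains <- function(recs, link) {
  recs <- recs[order(recs$tname, recs$tstart), , drop = FALSE]
  if (nrow(recs) == 0L) return(recs)
  newloc <- c(TRUE, recs$tname[-1] != recs$tname[-nrow(recs)] |
                recs$tstart[-1] - recs$tend[-nrow(recs)] > link)
  recs$locus <- cumsum(newloc)
  recs
}

# Refine the placement of query `q` at the locus described by chain records
# `recs` (all same strand/target). Returns identity/coverage stats, the
# target slice interval, and a lift closure mapping query 0-based positions
# to target 0-based positions (NA in indels).
#
# Three refinement paths, fastest applicable first:
#   diagonal  — the whole chain sits on one diagonal: direct base comparison.
#   blocks    — a few diagonal shifts (isolated indels): per-block base
#               comparison plus a mini global alignment of each shift gap.
#   global    — anything else: full affine-gap alignment of the slice.
refine_placement <- function(q, recs, target_seqs, pad = 100L,
                             max_blocks = 8L, max_block_gap = 400L) {
  strand <- recs$strand[1]
  tname <- recs$tname[1]
  ts <- target_seqs[[tname]]
  qlen <- nchar(q)
  qw <- if (strand == "-") revcomp(q) else q
  # chain coords on the working (possibly reverse-complemented) query
  qs <- if (strand == "-") qlen - recs$qend else recs$qstart
  qe <- if (strand == "-") qlen - recs$qstart else recs$qend
  o <- order(qs)
  qs <- qs[o]; qe <- qe[o]
  tss <- recs$tstart[o]; tee <- recs$tend[o]
  diag0 <- tss - qs
  consistent <- all((tee - tss) == (qe - qs))
  t0 <- tss[1] - qs[1]
  if (consistent && length(unique(diag0)) == 1L &&
      t0 >= 0L && t0 + qlen <= nchar(ts)) {
    slice <- substr(ts, t0 + 1L, t0 + qlen)
    m <- hamming_matches(qw, slice)
    lift <- function(qpos0) {
      wp <- if (strand == "-") qlen - 1L - qpos0 else qpos0
      t0 + wp
    }
    return(list(strand = strand, tname = tname, tstart = t0, tend = t0 + qlen,
                identity = 100 * m / qlen, coverage = 100,
                span = qlen, lift = lift, method = "diagonal",
                target_span = qlen))
  }
  # blockwise path: merge chain segments into runs of constant diagonal
  if (consistent && length(unique(diag0)) <= max_blocks) {
    r <- rle(diag0)
    nb <- length(r$values)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    bq_s <- qs[starts]; bq_e <- qe[ends]
    bd <- r$values
    # adjacent blocks may overlap slightly (anchor jitter at an indel);
    # trim the later block so blocks are disjoint in both coordinates
    if (nb > 1L) {
      for (b in seq_len(nb - 1L)) {
        ov <- max(bq_e[b] - bq_s[b + 1L],
                  (bq_e[b] + bd[b]) - (bq_s[b + 1L] + bd[b + 1L]))
        if (ov > 0L && bq_s[b + 1L] + ov < bq_e[b + 1L]) {
          bq_s[b + 1L] <- bq_s[b + 1L] + ov
        }
      }
    }
    ok_gaps <- nb == 1L ||
      all(bq_s[-1] - bq_e[-nb] <= max_block_gap &
            (bq_s[-1] + bd[-1]) - (bq_e[-nb] + bd[-nb]) <= max_block_gap &
            bq_s[-1] >= bq_e[-nb] &
            (bq_s[-1] + bd[-1]) >= (bq_e[-nb] + bd[-nb]))
    t_lo <- bq_s[1] + bd[1]; t_hi <- bq_e[nb] + bd[nb]
    if (ok_gaps && t_lo >= 0L && t_hi <= nchar(ts)) {
      matches <- 0L; columns <- 0L
      # leading/trailing unanchored query tails: compare on the flanking
      # diagonals where target range allows
      head_n <- bq_s[1]
      t_head <- bd[1]  # target start of head on first diagonal
      if (head_n > 0L) {
        hh <- min(head_n, max(0L, bq_s[1] + bd[1]))
        if (hh > 0L) {
          matches <- matches + hamming_matches(
            substr(qw, bq_s[1] - hh + 1L, bq_s[1]),
            substr(ts, bq_s[1] + bd[1] - hh + 1L, bq_s[1] + bd[1]))
        }
        columns <- columns + head_n
      }
      for (b in seq_len(nb)) {
        matches <- matches + hamming_matches(
          substr(qw, bq_s[b] + 1L, bq_e[b]),
          substr(ts, bq_s[b] + bd[b] + 1L, bq_e[b] + bd[b]))
        columns <- columns + (bq_e[b] - bq_s[b])
        if (b < nb) {
          qg <- substr(qw, bq_e[b] + 1L, bq_s[b + 1L])
          tg <- substr(ts, bq_e[b] + bd[b] + 1L, bq_s[b + 1L] + bd[b + 1L])
          gm <- gap_matches(qg, tg)
          matches <- matches + gm$matches
          columns <- columns + gm$columns
        }
      }
      tail_n <- qlen - bq_e[nb]
      if (tail_n > 0L) {
        tt <- min(tail_n, nchar(ts) - (bq_e[nb] + bd[nb]))
        if (tt > 0L) {
          matches <- matches + hamming_matches(
            substr(qw, bq_e[nb] + 1L, bq_e[nb] + tt),
            substr(ts, bq_e[nb] + bd[nb] + 1L, bq_e[nb] + bd[nb] + tt))
        }
        columns <- columns + tail_n
      }
      lift <- function(qpos0) {
        wp <- if (strand == "-") qlen - 1L - qpos0 else qpos0
        b <- which(wp >= bq_s & wp < bq_e)
        if (length(b) == 1L) return(wp + bd[b])
        if (wp < bq_s[1]) {
          tp <- wp + bd[1]
          return(if (tp >= 0L) tp else NA_integer_)
        }
        if (wp >= bq_e[nb]) {
          tp <- wp + bd[nb]
          return(if (tp < nchar(ts)) tp else NA_integer_)
        }
        NA_integer_  # inside an indel gap between blocks
      }
      tstart <- max(0L, bq_s[1] + bd[1] - head_n)
      tend <- min(nchar(ts), bq_e[nb] + bd[nb] + tail_n)
      # aligned query bases: total minus query bases falling in deletions
      unaligned <- 0L
      if (nb > 1L) {
        qg <- bq_s[-1] - bq_e[-nb]
        tg <- (bq_s[-1] + bd[-1]) - (bq_e[-nb] + bd[-nb])
        unaligned <- sum(pmax(0L, qg - tg))
      }
      return(list(strand = strand, tname = tname, tstart = tstart,
                  tend = tend, identity = 100 * matches / columns,
                  coverage = 100 * (qlen - unaligned) / qlen,
                  span = qlen - unaligned, lift = lift, method = "blocks",
                  target_span = tend - tstart))
    }
  }
  s0 <- max(0L, tss[1] - qs[1] - pad)
  e0 <- min(nchar(ts), tee[length(tee)] + (qlen - qe[length(qe)]) + pad)
  if (e0 - s0 < 10L) return(NULL)
  slice <- substr(ts, s0 + 1L, e0)
  ga <- global_align(qw, slice)
  lift <- function(qpos0) {
    wp <- if (strand == "-") qlen - 1L - qpos0 else qpos0
    tp <- lift_through_alignment(ga$aligned_a, ga$aligned_b, wp)
    if (is.na(tp)) NA_integer_ else s0 + tp
  }
  # span of the query actually aligned (non-terminal-gap columns)
  list(strand = strand, tname = tname, tstart = s0, tend = e0,
       identity = ga$identity_aligned, coverage = ga$coverage,
       span = as.integer(round(ga$coverage / 100 * qlen)), lift = lift,
       method = "global", edits = ga$edits, target_span = {
         va <- strsplit(ga$aligned_a, "", fixed = TRUE)[[1]]
         vb <- strsplit(ga$aligned_b, "", fixed = TRUE)[[1]]
         both <- va != "-" & vb != "-"
         if (any(both)) sum(vb[min(which(both)):max(which(both))] != "-") else 0L
       })
}

# Locate query `q` on the indexed target. Returns list(placement, n_loci):
# placement is NULL when no locus passes `min_chain_frac`, and n_loci counts
# competing loci (for uniqueness decisions).
locate_query <- function(q, index, target_seqs, min_chain_frac = 0.5,
                         pad = 100L, link = NULL, chains = NULL, ...) {
  qlen <- nchar(q)
  if (is.null(link)) link <- qlen + 500L
  recs <- chains
  if (is.null(recs)) recs <- anchor_align(stats::setNames(q, "q"), index, ...)
  if (nrow(recs) == 0L) return(list(placement = NULL, n_loci = 0L))
  recs <- cluster_chains(recs, link)
  spans <- tapply(recs$qend - recs$qstart, recs$locus, sum)
  good <- names(spans)[spans >= min_chain_frac * qlen]
  if (length(good) == 0L) return(list(placement = NULL, n_loci = 0L))
  best <- good[which.max(spans[good])]
  sel <- recs[recs$locus == as.integer(best), , drop = FALSE]
  # mixed strands at one locus: keep the dominant strand
  if (length(unique(sel$strand)) > 1L) {
    bs <- tapply(sel$qend - sel$qstart, sel$strand, sum)
    sel <- sel[sel$strand == names(bs)[which.max(bs)], , drop = FALSE]
  }
  list(placement = refine_placement(q, sel, target_seqs, pad = pad),
       n_loci = length(good))
}
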