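# Haploid-aware small-variant benchmarking. A haploid consensus calls every
# carried variant as homozygous, so discordances with a diploid benchmark
# are partitioned: genotype mismatches at true het sites (FP.gt), calls
# within a proximity window of a true variant (FP.al), calls inside excluded
# repeat-like regions, and the remainder — the modified FP count that feeds
# the Phred-scaled QV and the correction step.

#' Normalize variant representation
#'
#' Trims shared suffix/prefix bases (parsimony) and left-aligns pure indels
#' against the reference sequence, so representation differences do not count
#' as mismatches.
#'
#' @param df variant data.frame (chrom, pos, ref, alt; 1-based).
#' @param genome reference [assembly] for left-shifting.
#' @return the data.frame with normalized pos/ref/alt.
#' @export
normalize_variants <- function(df, genome) {
  for (i in seq_len(nrow(df))) {
    pos <- df$pos[i]; ref <- df$ref[i]; alt <- df$alt[i]
    s <- genome$seq[[df$chrom[i]]]
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      if (nr > 1L && na > 1L &&
          substr(ref, nr, nr) == substr(alt, na, na)) {
        ref <- substr(ref, 1L, nr - 1L); alt <- substr(alt, 1L, na - 1L)
        next
      }
      if ((nr == 0L || na == 0L) && pos > 1L) {
        b <- toupper(substr(s, pos - 1L, pos - 1L))
        ref <- paste0(b, ref); alt <- paste0(b, alt); pos <- pos - 1L
        next
      }
      if (nr > 1L && na > 1L && substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
          nr != na) {
        # keep anchored form for indels; stop trimming prefix
        break
      }
      if (nr > 1L && na > 1L && nr == na &&
          substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nr); alt <- substr(alt, 2L, na); pos <- pos + 1L
        next
      }
      # left-align pure indels: if both end with the same base as the base
      # before pos, shift left
      if (nr != na && nr >= 1L && na >= 1L && pos > 1L &&
          substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        lr <- substr(ref, nchar(ref), nchar(ref))
        la <- substr(alt, nchar(alt), nchar(alt))
        prev <- toupper(substr(s, pos - 1L, pos - 1L))
        if (lr == la && lr == prev) {
          ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
          alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
          pos <- pos - 1L
          ref <- substr(ref, 1L, nchar(ref))
          next
        }
      }
      break
    }
    df$pos[i] <- pos; df$ref[i] <- toupper(ref); df$alt[i] <- toupper(alt)
  }
  df
}

in_regions <- function(chrom, pos, regions) {
  if (nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  vapply(seq_along(pos), function(i)
    any(regions$chrom == chrom[i] & regions$start < pos[i] &
          pos[i] <= regions$end),
    logical(1))
}

gt_is_het <- function(gt) {
  a <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  vapply(a, function(x) length(unique(x[x != "."])) > 1L, logical(1))
}

#' Compare a call set against a diploid benchmark
#'
#' Calls and benchmark records are restricted to the benchmark regions and
#' matched on (chrom, pos, ref, alt) after representation normalization. A
#' call matching a benchmark record's alleles and genotype is a TP; matching
#' alleles with a differing genotype is an FP flagged `gt_mismatch`; matching
#' nothing is a plain FP. Benchmark records with no matching call are FN.
#'
#' @param calls call data.frame (chrom, pos, ref, alt, gt, ...).
#' @param benchmark benchmark data.frame (chrom, pos, ref, alt, gt).
#' @param regions benchmark-region BED data.frame (chrom, start, end).
#' @param genome optional reference [assembly] used to normalize indels.
#' @return list with `tp`, `fp` (with `gt_mismatch` logical), `fn`, and
#'   counts `n_tp`, `n_fp`, `n_fn`.
#' @export
compare_small_variants <- function(calls, benchmark, regions, genome = NULL) {
  if (!is.null(genome)) {
    calls <- normalize_variants(calls, genome)
    benchmark <- normalize_variants(benchmark, genome)
  }
  calls <- calls[in_regions(calls$chrom, calls$pos, regions), , drop = FALSE]
  benchmark <- benchmark[in_regions(benchmark$chrom, benchmark$pos, regions), ,
                         drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, toupper(d$ref), toupper(d$alt))
  bm <- match(key(calls), key(benchmark))
  matched <- !is.na(bm)
  gt_norm <- function(gt) {
    v <- gsub("\\|", "/", gt)
    vapply(strsplit(v, "/"), function(x) paste(sort(x), collapse = "/"),
           character(1))
  }
  call_hom_alt <- gt_norm(calls$gt) %in% c("1", "1/1")
  bench_gt <- ifelse(matched, benchmark$gt[bm], NA)
  gt_match <- matched & gt_norm(ifelse(is.na(bench_gt), "", bench_gt)) ==
    gt_norm(calls$gt) |
    (matched & call_hom_alt & gt_norm(ifelse(is.na(bench_gt), "", bench_gt)) %in%
       c("1", "1/1"))
  tp <- calls[matched & gt_match, , drop = FALSE]
  fp <- calls[!(matched & gt_match), , drop = FALSE]
  fp$gt_mismatch <- matched[!(matched & gt_match)]
  fp$bench_gt <- bench_gt[!(matched & gt_match)]
  fn_idx <- setdiff(seq_len(nrow(benchmark)), bm[matched])
  fn <- benchmark[fn_idx, , drop = FALSE]
  list(tp = tp, fp = fp, fn = fn,
       n_tp = nrow(tp), n_fp = nrow(fp), n_fn = nrow(fn))
}

#' Partition raw false positives into the modified-FP accounting
#'
#' Buckets, with precedence genotype > proximity > region: (a) `fp_gt` —
#' calls whose matched benchmark genotype is heterozygous (the haploid
#' consensus necessarily disagrees there); (b) `fp_al` — calls within
#' `proximity` bp of any benchmark variant; (c) `fp_region` — calls inside
#' the excluded-region BED (self-chain / segmental-duplication analogue);
#' (d) `modified` — the remainder, the error estimate.
#'
#' @param fp FP table from [compare_small_variants].
#' @param benchmark benchmark data.frame.
#' @param proximity distance threshold in bp (`<=` excludes).
#' @param excluded excluded-region BED data.frame.
#' @return list of the four data frames plus a `counts` vector; the four
#'   bucket sizes always sum to `nrow(fp)`.
#' @export
modified_fp_filter <- function(fp, benchmark, proximity = 30L,
                               excluded = NULL) {
  if (is.null(excluded)) excluded <- data.frame(chrom = character(0),
                                                start = integer(0),
                                                end = integer(0))
  if (nrow(fp) == 0L) {
    cnt <- c(fp_gt = 0L, fp_al = 0L, fp_region = 0L, modified = 0L)
    return(list(fp_gt = fp, fp_al = fp, fp_region = fp, modified = fp,
                counts = cnt))
  }
  is_gt <- !is.na(fp$gt_mismatch) & fp$gt_mismatch &
    !is.na(fp$bench_gt) & gt_is_het(fp$bench_gt)
  near <- vapply(seq_len(nrow(fp)), function(i) {
    b <- benchmark[benchmark$chrom == fp$chrom[i], , drop = FALSE]
    nrow(b) > 0L && min(abs(b$pos - fp$pos[i])) <= proximity
  }, logical(1))
  in_excl <- in_regions(fp$chrom, fp$pos, excluded)
  bucket <- ifelse(is_gt, "gt", ifelse(near, "al",
                                       ifelse(in_excl, "region", "modified")))
  out <- list(fp_gt = fp[bucket == "gt", , drop = FALSE],
              fp_al = fp[bucket == "al", , drop = FALSE],
              fp_region = fp[bucket == "region", , drop = FALSE],
              modified = fp[bucket == "modified", , drop = FALSE])
  out$counts <- c(fp_gt = nrow(out$fp_gt), fp_al = nrow(out$fp_al),
                  fp_region = nrow(out$fp_region),
                  modified = nrow(out$modified))
  out
}

#' Phred-scaled consensus quality from the modified FP count
#'
#' `QV = -10 * log10(FP / region_size)`. With zero FPs the estimate is
#' unbounded; a configurable cap is returned with a flag.
#'
#' @param fp modified FP count (>= 0).
#' @param region_size benchmark region size in bp (> 0).
#' @param cap QV returned when `fp == 0`.
#' @return list with `qv` and `capped`.
#' @export
compute_qv <- function(fp, region_size, cap = 90) {
  stopifnot(region_size > 0, fp >= 0)
  if (fp == 0) return(list(qv = cap, capped = TRUE))
  list(qv = -10 * log10(fp / region_size), capped = FALSE)
}

#' Assemble a benchmark-result record
#'
#' @param cmp result of [compare_small_variants].
#' @param part result of [modified_fp_filter].
#' @param region_size benchmark region size (bp).
#' @param cap QV cap for zero FPs.
#' @return data.frame with TP/FN/raw FP, the four FP buckets, region size
#'   and QV.
#' @export
benchmark_result <- function(cmp, part, region_size, cap = 90) {
  qv <- compute_qv(part$counts[["modified"]], region_size, cap = cap)
  data.frame(tp = cmp$n_tp, fn = cmp$n_fn, fp_raw = cmp$n_fp,
             fp_gt = part$counts[["fp_gt"]], fp_al = part$counts[["fp_al"]],
             fp_region = part$counts[["fp_region"]],
             fp_modified = part$counts[["modified"]],
             region_size = region_size, qv = qv$qv, qv_capped = qv$capped)
}

#' Locate donor-anchored calls on an assembly
#'
#' Fills `asm_chrom`/`asm_pos` for calls that lack them by lifting each call
#' position through an anchored window alignment of the surrounding donor
#' sequence (the same machinery the harmonization step uses).
#'
#' @param calls call data.frame (chrom, pos, ref, alt).
#' @param donor donor [assembly].
#' @param x target [assembly].
#' @param window donor window size centered on each call.
#' @param k anchor k-mer size.
#' @param index optional prebuilt index of `x`.
#' @return `calls` with asm_chrom/asm_pos columns (NA where unmappable).
#' @export
locate_calls <- function(calls, donor, x, window = 2000L, k = 21L,
                         index = NULL) {
  if (is.null(index)) index <- kmer_index(x, k = k)
  half <- window %/% 2L
  n <- nrow(calls)
  calls$asm_chrom <- NA_character_
  calls$asm_pos <- NA_integer_
  if (n == 0L) return(calls)
  wins <- character(n); offs <- integer(n)
  for (i in seq_len(n)) {
    ch <- calls$chrom[i]; p0 <- calls$pos[i] - 1L
    s <- donor$seq[[ch]]
    lo <- max(0L, p0 - half); hi <- min(nchar(s), p0 + half)
    wins[i] <- substr(s, lo + 1L, hi)
    offs[i] <- p0 - lo
  }
  names(wins) <- sprintf("call%06d", seq_len(n))
  chains <- anchor_align(wins, index, max_diag_drift = 0L)
  chain_split <- split(seq_len(nrow(chains)), chains$qname)
  for (i in seq_len(n)) {
    ci <- chains[chain_split[[names(wins)[i]]] %||% integer(0), , drop = FALSE]
    res <- locate_query(wins[i], index, x$seq, min_chain_frac = 0.5,
                        chains = ci)
    if (is.null(res$placement) || res$n_loci != 1L) next
    tp <- res$placement$lift(offs[i])
    if (is.na(tp)) next
    calls$asm_chrom[i] <- res$placement$tname
    calls$asm_pos[i] <- tp + 1L
  }
  calls
}

#' Correct assembly errors identified by benchmarking
#'
#' Applies the remaining (modified) FP calls as edits at their assembly
#' coordinates: substitution calls are reverted to the benchmark/donor
#' allele, insertion calls have the spurious bases deleted, and deletion
#' calls have the missing bases restored. Edits are applied right to left
#' per sequence so coordinates stay valid; overlapping edits defer to a
#' warning and a second pass by the caller.
#'
#' @param x [assembly] to correct.
#' @param fp_set modified FP calls with `asm_chrom`, `asm_pos` (1-based
#'   position of the call's anchor base on the assembly), `ref`, `alt`.
#' @return list with `assembly` (version `v1.2`) and `log` (one row per
#'   applied edit: asm_chrom, asm_pos, type, removed, added).
#' @export
apply_corrections <- function(x, fp_set) {
  seqs <- x$seq
  fp <- fp_set[!is.na(fp_set$asm_pos), , drop = FALSE]
  log <- NULL
  skipped <- 0L
  for (ch in unique(fp$asm_chrom)) {
    f <- fp[fp$asm_chrom == ch, , drop = FALSE]
    f <- f[order(f$asm_pos, decreasing = TRUE), , drop = FALSE]
    last_start <- Inf
    for (i in seq_len(nrow(f))) {
      pos0 <- f$asm_pos[i] - 1L
      nr <- nchar(f$ref[i]); na <- nchar(f$alt[i])
      if (nr == 1L && na == 1L) {
        if (pos0 + 1L > last_start) { skipped <- skipped + 1L; next }
        seqs[[ch]] <- splice_str(seqs[[ch]], pos0, pos0 + 1L, f$ref[i])
        log <- rbind(log, data.frame(asm_chrom = ch, asm_pos = f$asm_pos[i],
                                     type = "substitution",
                                     removed = f$alt[i], added = f$ref[i]))
        last_start <- pos0
      } else if (na > nr) {
        # insertion error: assembly has extra bases after the anchor
        extra <- na - nr
        if (pos0 + 1L + extra > last_start) { skipped <- skipped + 1L; next }
        removed <- substr(seqs[[ch]], pos0 + 2L, pos0 + 1L + extra)
        seqs[[ch]] <- splice_str(seqs[[ch]], pos0 + 1L, pos0 + 1L + extra, "")
        log <- rbind(log, data.frame(asm_chrom = ch, asm_pos = f$asm_pos[i],
                                     type = "insertion_error",
                                     removed = removed, added = ""))
        last_start <- pos0 + 1L
      } else {
        # deletion error: assembly is missing benchmark bases after anchor
        miss <- substr(f$ref[i], nr - (nr - na) + 1L, nr)
        if (pos0 + 1L > last_start) { skipped <- skipped + 1L; next }
        seqs[[ch]] <- splice_str(seqs[[ch]], pos0 + 1L, pos0 + 1L, miss)
        log <- rbind(log, data.frame(asm_chrom = ch, asm_pos = f$asm_pos[i],
                                     type = "deletion_error",
                                     removed = "", added = miss))
        last_start <- pos0 + 1L
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " overlapping correction(s) deferred; re-run benchmarking")
  }
  list(assembly = assembly(seqs, version = "v1.2", meta = x$meta),
       log = log %||% data.frame(asm_chrom = character(0),
                                 asm_pos = integer(0), type = character(0),
                                 removed = character(0), added = character(0)))
}

#' Structural-variant presence assay
#'
#' For each SV, the donor-side alternate-allele region (variant applied,
#' plus `flank` bp of donor sequence on each side) is located on the
#' assembly. The SV is `present` iff a single locus covers at least
#' `min_coverage` of the region at `min_identity` identity with the
#' flank-to-flank spacing consistent with the SV length (within
#' `len_tol` bp); `ambiguous` when several loci compete (tandem-repeat
#' situation); `absent` otherwise.
#'
#' @param svs SV table: chrom, pos (1-based anchored, VCF-style), type
#'   (`"ins"`/`"del"`), len, seq (inserted sequence for insertions).
#' @param x assembly to assay.
#' @param donor donor [assembly].
#' @param flank flanking donor sequence on each side (bp).
#' @param min_coverage,min_identity,len_tol presence thresholds.
#' @param k anchor k-mer size.
#' @param index optional prebuilt index of `x`.
#' @return the SV table with `status`, `coverage`, `identity`, `asm_chrom`,
#'   `asm_pos` columns.
#' @export
sv_presence <- function(svs, x, donor, flank = 1000L, min_coverage = 95,
                        min_identity = 99, len_tol = 10L, k = 21L,
                        index = NULL) {
  if (is.null(index)) index <- kmer_index(x, k = k)
  svs$status <- "absent"
  svs$coverage <- NA_real_; svs$identity <- NA_real_
  svs$asm_chrom <- NA_character_; svs$asm_pos <- NA_integer_
  for (i in seq_len(nrow(svs))) {
    ch <- svs$chrom[i]; p0 <- svs$pos[i] - 1L  # anchor base, 0-based
    s <- donor$seq[[ch]]
    if (svs$type[i] == "ins") {
      left <- substr(s, max(1L, p0 + 1L - flank + 1L), p0 + 1L)
      right <- substr(s, p0 + 2L, min(nchar(s), p0 + 1L + flank))
      region <- paste0(left, svs$seq[i], right)
    } else {
      left <- substr(s, max(1L, p0 + 1L - flank + 1L), p0 + 1L)
      right <- substr(s, p0 + 2L + svs$len[i],
                      min(nchar(s), p0 + 1L + svs$len[i] + flank))
      region <- paste0(left, right)
    }
    res <- locate_query(region, index, x$seq, min_chain_frac = 0.5,
                        max_diag_drift = 0L)
    if (res$n_loci > 1L) {
      svs$status[i] <- "ambiguous"
      next
    }
    if (is.null(res$placement)) next
    p <- res$placement
    tspan <- if (!is.null(p$target_span)) p$target_span else (p$tend - p$tstart)
    svs$coverage[i] <- p$coverage
    svs$identity[i] <- p$identity
    svs$asm_chrom[i] <- p$tname
    svs$asm_pos[i] <- p$tstart + 1L
    if (p$coverage >= min_coverage && p$identity >= min_identity &&
        abs(tspan - nchar(region)) <= len_tol) {
      svs$status[i] <- "present"
    }
  }
  svs
}

#' Truth SV table in the assay's input form
#'
#' @param truth truth set from [simulate_sample].
#' @return data.frame chrom, pos, type, len, seq, zygosity, hap1, hap2.
#' @export
truth_sv_table <- function(truth) {
  v <- truth$variants
  sv <- v[v$type %in% c("sv_ins", "sv_del"), , drop = FALSE]
  data.frame(chrom = sv$chrom, pos = sv$pos,
             type = ifelse(sv$type == "sv_ins", "ins", "del"),
             len = sv$len,
             seq = ifelse(sv$type == "sv_ins",
                          substr(sv$alt, 2L, nchar(sv$alt)), ""),
             zygosity = ifelse(sv$hap1 + sv$hap2 == 2L, "hom", "het"),
             hap1 = sv$hap1, hap2 = sv$hap2)
}
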