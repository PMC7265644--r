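# Deterministic synthetic diploid genome generator. Emulates the study
# setting: a finished donor reference, a diploid sample carrying SNVs
# (tagged with population allele frequencies), small indels, structural
# variants >= 50 bp, reciprocal subtelomeric translocations, embedded gene
# loci with isoforms, a fragmented contig set with chimeras and withheld
# (future-gap) intervals, read-coverage tracks with junction dropouts, and a
# population allele-frequency site table. Every output is reproducible byte
# for byte from (seed, config).

#' Simulation configuration
#'
#' All sizes are in bp, rates in `[0, 1]`. The defaults describe the study
#' conditions used throughout the test-suite: a 2 x 500 kb genome with SNVs at
#' 5e-4/bp, small indels at 5e-5/bp, 40 structural variants of 50-500 bp
#' (~46% homozygous), one reciprocal terminal translocation of 5 kb,
#' 40-80 kb contigs with planted chimeras, and ~30x coverage with 2x dropout
#' at chimeric junctions.
#'
#' @param seed master seed; every stage derives its own sub-stream from it.
#' @param n_chrom,chrom_len number and length of chromosomes.
#' @param repeat_count,repeat_len exact repeat pairs planted per chromosome.
#' @param ref_gap_count,ref_gap_len N-run placeholders planted in the donor.
#' @param n_genes,cds_len_range,two_exon_frac,second_isoform_frac toy gene
#'   model: loci per genome, CDS length range (rounded to codons), fraction
#'   with an intron, fraction with a second (internal-start) isoform.
#' @param gene_subtel genes placed inside the future translocated terminal
#'   segment of each translocating chromosome.
#' @param paralog_gene,delete_gene,truncate_gene plant a diverged unannotated
#'   paralog of gene 1, delete gene 1 from the sample (homozygous SV), and
#'   delete >50% of gene 2's CDS (partial mapping), respectively.
#' @param snv_count,indel_count,indel_len_range small-variant load.
#' @param sv_count,sv_len_range,sv_ins_frac,sv_hom_frac structural variants.
#' @param transloc_pairs,transloc_seg_len reciprocal terminal exchanges and
#'   the exchanged segment length (subtelomere = terminal 1% by default).
#' @param subtel_frac fraction of chromosome length considered subtelomeric.
#' @param contig_len_range,chimera_count,orient_minus_frac fragmentation.
#' @param withheld_count,withheld_len_range intervals withheld from the
#'   contig set (future assembly gaps).
#' @param cov_mean,cov_jitter,cov_bin,dropout_depth,dropout_halfwidth
#'   coverage model: uniform depth with +/- jitter, and `dropout_depth` in a
#'   window of `dropout_halfwidth` around each chimeric junction.
#' @param pop_homref_frac,pop_low_count_rows,pop_multibase_rows population
#'   site table: extra high-frequency sites at which the sample is
#'   homozygous-reference, rows reported in < 200 individuals, and multi-base
#'   rows (both exercise the selection filters).
#' @param n_errors,err_sub_frac,err_ins_frac,err_indel_max,err_near_count,
#'   err_excl_count planted consensus errors: total, type mix, max indel
#'   error length, errors deliberately within 30 bp of a true variant, and
#'   errors inside the excluded (repeat) regions.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_len = 500000L,
                       repeat_count = 1L, repeat_len = 3000L,
                       ref_gap_count = 0L, ref_gap_len = 100L,
                       n_genes = 10L, cds_len_range = c(300L, 600L),
                       two_exon_frac = 0.4, second_isoform_frac = 0.5,
                       gene_subtel = 2L,
                       paralog_gene = TRUE, delete_gene = TRUE,
                       truncate_gene = TRUE,
                       snv_count = NULL, indel_count = NULL,
                       indel_len_range = c(1L, 10L),
                       sv_count = 40L, sv_len_range = c(50L, 500L),
                       sv_ins_frac = 0.5, sv_hom_frac = 0.46,
                       transloc_pairs = 1L, transloc_seg_len = 5000L,
                       subtel_frac = 0.01,
                       contig_len_range = c(40000L, 80000L),
                       chimera_count = 4L, orient_minus_frac = 0.3,
                       withheld_count = 3L,
                       withheld_len_range = c(2000L, 6000L),
                       cov_mean = 30, cov_jitter = 4, cov_bin = 500L,
                       dropout_depth = 2, dropout_halfwidth = 2000L,
                       pop_homref_frac = 0.1, pop_low_count_rows = 5L,
                       pop_multibase_rows = 3L,
                       n_errors = 200L, err_sub_frac = 0.6,
                       err_ins_frac = 0.2, err_indel_max = 5L,
                       err_near_count = 10L, err_excl_count = 10L) {
  cfg <- as.list(environment())
  cfg$chrom_len <- rep_len(as.integer(chrom_len), n_chrom)
  genome <- sum(cfg$chrom_len)
  if (is.null(snv_count)) cfg$snv_count <- as.integer(round(5e-4 * genome))
  if (is.null(indel_count)) cfg$indel_count <- as.integer(round(5e-5 * genome))
  fr <- c(two_exon_frac, second_isoform_frac, sv_ins_frac, sv_hom_frac,
          orient_minus_frac, subtel_frac, pop_homref_frac, err_sub_frac,
          err_ins_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(c(cfg$chrom_len, repeat_len, sv_len_range, transloc_seg_len,
            contig_len_range, withheld_len_range) <= 0)) {
    stop("sizes must be positive")
  }
  if (err_sub_frac + err_ins_frac > 1) stop("error type fractions exceed 1")
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the 61 sense codons (standard code)
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Build one gene block on the plus strand. Returns the block sequence and
# feature offsets (0-based half-open, relative to block start).
make_gene <- function(cds_len, two_exon, second_isoform) {
  ncod <- cds_len %/% 3L
  codons <- c("ATG", sample(sense_codons(), ncod - 2L, replace = TRUE), "TAA")
  atg_cod <- NA_integer_
  if (second_isoform) {
    atg_cod <- max(2L, ncod %/% 4L)
    codons[atg_cod + 1L] <- "ATG"
  }
  cds <- paste(codons, collapse = "")
  if (two_exon) {
    sp <- 3L * (ncod %/% 2L) + 1L   # split off codon boundary on purpose
    il <- sample(60:150, 1L)
    block <- paste0(substr(cds, 1L, sp), rand_dna(il),
                    substr(cds, sp + 1L, cds_len))
    exons <- data.frame(start = c(0L, sp + il), end = c(sp, sp + il + cds_len - sp))
  } else {
    il <- 0L; sp <- NA_integer_
    block <- cds
    exons <- data.frame(start = 0L, end = cds_len)
  }
  list(block = block, exons = exons, cds_len = cds_len,
       atg_off = if (is.na(atg_cod)) NA_integer_ else 3L * atg_cod,
       intron_len = il)
}

# Emit GFF-style feature rows (1-based inclusive) for one gene planted at
# 0-based position `at` on `chrom` with the given strand.
gene_features <- function(g, gene_id, chrom, at, strand) {
  B <- nchar(g$block)
  flip <- function(df) {
    # mirror plus-strand block offsets for a reverse-complemented block
    data.frame(start = B - df$end, end = B - df$start)[rev(seq_len(nrow(df))), ,
                                                      drop = FALSE]
  }
  iso_rows <- function(tx_id, exons_off) {
    eo <- if (strand == "-") flip(exons_off) else exons_off
    eo <- eo[order(eo$start), , drop = FALSE]
    n <- nrow(eo)
    # phase per CDS segment in translation order
    ord <- if (strand == "-") rev(seq_len(n)) else seq_len(n)
    lens <- (eo$end - eo$start)[ord]
    phase <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
    ph <- integer(n); ph[ord] <- phase
    rbind(
      data.frame(seqid = chrom, source = "refcurate", type = "mRNA",
                 start = at + min(eo$start) + 1L, end = at + max(eo$end),
                 strand = strand, phase = NA_integer_, ID = tx_id,
                 Parent = gene_id),
      data.frame(seqid = chrom, source = "refcurate", type = "exon",
                 start = at + eo$start + 1L, end = at + eo$end, strand = strand,
                 phase = NA_integer_, ID = paste0(tx_id, ".e", seq_len(n)),
                 Parent = tx_id),
      data.frame(seqid = chrom, source = "refcurate", type = "CDS",
                 start = at + eo$start + 1L, end = at + eo$end, strand = strand,
                 phase = ph, ID = paste0(tx_id, ".c", seq_len(n)),
                 Parent = tx_id))
  }
  rows <- rbind(
    data.frame(seqid = chrom, source = "refcurate", type = "gene",
               start = at + 1L, end = at + B, strand = strand,
               phase = NA_integer_, ID = gene_id, Parent = NA_character_),
    iso_rows(paste0(gene_id, ".t1"), g$exons))
  if (!is.na(g$atg_off)) {
    ex2 <- g$exons
    # second isoform starts at the internal ATG; trim the first exon
    first <- which(ex2$start <= g$atg_off & g$atg_off < ex2$end)[1]
    ex2 <- ex2[ex2$end > g$atg_off, , drop = FALSE]
    ex2$start[1] <- g$atg_off
    rows <- rbind(rows, iso_rows(paste0(gene_id, ".t2"), ex2))
  }
  rows
}

#' Simulate a donor reference genome
#'
#' Generates pseudo-random chromosomes and plants: exact repeat pairs (to
#' exercise uniqueness filters and tie-breaking), optional N-run gap
#' placeholders, clean multi-isoform gene loci (ORFs embedded in the
#' sequence), subtelomeric genes on translocating chromosomes, and optionally
#' a diverged unannotated paralog of gene 1. Planted feature tables are
#' recorded in the assembly metadata.
#'
#' @param config a [sim_config].
#' @return an [assembly] named `chr1..chrN` with metadata elements
#'   `annotation` (GFF-style feature table), `genes`, `repeats`, `ref_gaps`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1L), {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    seqs <- stats::setNames(
      vapply(config$chrom_len, rand_dna, character(1)), chroms)
    occupied <- stats::setNames(
      lapply(chroms, function(x) data.frame(start = integer(0), end = integer(0))),
      chroms)
    note <- function(ch, s, e) {
      occupied[[ch]] <<- rbind(occupied[[ch]], data.frame(start = s, end = e))
    }

    # repeats: two exact copies of a random segment per chromosome
    repeats <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), pair = integer(0))
    pair_id <- 0L
    for (ch in chroms) {
      L <- nchar(seqs[[ch]])
      for (r in seq_len(config$repeat_count)) {
        pair_id <- pair_id + 1L
        iv <- sample_intervals(2L, rep(config$repeat_len, 2L),
                               lo = as.integer(0.05 * L),
                               hi = as.integer(0.92 * L),
                               occupied = occupied[[ch]], pad = 20000L)
        if (nrow(iv) < 2L) next
        unit <- substr(seqs[[ch]], iv$start[1] + 1L, iv$end[1])
        seqs[[ch]] <- splice_str(seqs[[ch]], iv$start[2], iv$end[2], unit)
        for (i in 1:2) {
          note(ch, iv$start[i], iv$end[i])
          repeats <- rbind(repeats, data.frame(chrom = ch, start = iv$start[i],
                                               end = iv$end[i], pair = pair_id))
        }
      }
    }

    # N-run placeholders: planted in pairs bracketing a small donor contig,
    # the situation where a gap in the assembled sample spans a region the
    # donor itself holds only as a separate small contig
    ref_gaps <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), block = integer(0))
    blk <- 0L
    inner <- 1200L
    for (ch in chroms) {
      L <- nchar(seqs[[ch]])
      if (config$ref_gap_count == 0L) next
      gl <- config$ref_gap_len
      span <- 2L * gl + inner
      iv <- sample_intervals(config$ref_gap_count,
                             rep(span, config$ref_gap_count),
                             lo = as.integer(0.1 * L), hi = as.integer(0.9 * L),
                             occupied = occupied[[ch]], pad = 15000L)
      for (i in seq_len(nrow(iv))) {
        blk <- blk + 1L
        s <- iv$start[i]
        runs <- data.frame(start = c(s, s + gl + inner),
                           end = c(s + gl, s + 2L * gl + inner))
        for (r in 1:2) {
          seqs[[ch]] <- splice_str(seqs[[ch]], runs$start[r], runs$end[r],
                                   strrep("N", gl))
        }
        note(ch, s, s + span)
        ref_gaps <- rbind(ref_gaps, data.frame(chrom = ch, start = runs$start,
                                               end = runs$end, block = blk))
      }
    }

    # gene loci
    annotation <- NULL
    genes <- data.frame(gene = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), role = character(0),
                        n_isoforms = integer(0))
    gi <- 0L
    plant_gene <- function(ch, lo, hi, role, force_single_exon = FALSE,
                           force_one_isoform = FALSE) {
      gi <<- gi + 1L
      cds_len <- 3L * (sample(config$cds_len_range[1]:config$cds_len_range[2], 1L) %/% 3L)
      two_exon <- !force_single_exon && stats::runif(1) < config$two_exon_frac
      second <- !force_one_isoform && stats::runif(1) < config$second_isoform_frac
      g <- make_gene(cds_len, two_exon, second)
      B <- nchar(g$block)
      iv <- sample_intervals(1L, B, lo = lo, hi = hi,
                             occupied = occupied[[ch]], pad = 1500L)
      if (nrow(iv) == 0L) { gi <<- gi - 1L; return(invisible(NULL)) }
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      block <- if (strand == "-") revcomp(g$block) else g$block
      seqs[[ch]] <<- splice_str(seqs[[ch]], iv$start, iv$end, block)
      note(ch, iv$start, iv$end)
      id <- sprintf("gene%02d", gi)
      annotation <<- rbind(annotation, gene_features(g, id, ch, iv$start, strand))
      genes <<- rbind(genes, data.frame(
        gene = id, chrom = ch, start = iv$start, end = iv$end, strand = strand,
        role = role, n_isoforms = if (is.na(g$atg_off)) 1L else 2L))
      invisible(g)
    }

    roles <- rep("normal", config$n_genes)
    if (config$delete_gene && config$n_genes >= 1L) roles[1] <- "deleted"
    if (config$truncate_gene && config$n_genes >= 2L) roles[2] <- "truncated"
    for (i in seq_len(config$n_genes)) {
      ch <- chroms[((i - 1L) %% length(chroms)) + 1L]
      L <- nchar(seqs[[ch]])
      plant_gene(ch, as.integer(0.05 * L), as.integer(0.90 * L), roles[i],
                 force_single_exon = roles[i] != "normal",
                 force_one_isoform = roles[i] != "normal")
    }
    # subtelomeric genes inside the future translocated terminal segment
    if (config$transloc_pairs >= 1L && length(chroms) >= 2L) {
      for (ch in chroms[1:2]) {
        L <- nchar(seqs[[ch]])
        for (s in seq_len(config$gene_subtel)) {
          plant_gene(ch, L - config$transloc_seg_len + 200L, L - 600L,
                     "subtel", force_single_exon = TRUE,
                     force_one_isoform = TRUE)
        }
      }
    }

    # unannotated diverged paralog of the to-be-deleted gene
    if (config$paralog_gene && any(genes$role == "deleted")) {
      src <- genes[genes$role == "deleted", ][1, ]
      unit <- substr(seqs[[src$chrom]], src$start + 1L, src$end)
      u <- strsplit(unit, "", fixed = TRUE)[[1]]
      nmut <- max(1L, round(0.01 * length(u)))
      at <- sample(length(u), nmut)
      u[at] <- vapply(u[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1L), character(1))
      unit2 <- paste(u, collapse = "")
      ch2 <- chroms[length(chroms)]
      L2 <- nchar(seqs[[ch2]])
      iv <- sample_intervals(1L, nchar(unit2), lo = as.integer(0.05 * L2),
                             hi = as.integer(0.9 * L2),
                             occupied = occupied[[ch2]], pad = 5000L)
      if (nrow(iv) == 1L) {
        seqs[[ch2]] <- splice_str(seqs[[ch2]], iv$start, iv$end, unit2)
        note(ch2, iv$start, iv$end)
        genes <- rbind(genes, data.frame(gene = "paralog_of_gene01",
                                         chrom = ch2, start = iv$start,
                                         end = iv$end, strand = "+",
                                         role = "paralog_copy",
                                         n_isoforms = 0L))
      }
    }

    assembly(seqs, version = "donor",
             meta = list(annotation = annotation, genes = genes,
                         repeats = repeats, ref_gaps = ref_gaps,
                         config_seed = config$seed))
  })
}

# --- sample simulation ------------------------------------------------------

random_base <- function(exclude) {
  vapply(exclude, function(b) sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1L),
         character(1), USE.NAMES = FALSE)
}

# edit tables use 0-based half-open ref intervals; `alt` replaces the slice.
# Non-overlapping edits are applied in a single pass: unchanged segments and
# replacement strings are collected and pasted once.
apply_edit_table <- function(s, edits) {
  if (nrow(edits) == 0L) return(s)
  edits <- edits[order(edits$start0), , drop = FALSE]
  if (any(edits$start0[-1] < edits$end0[-nrow(edits)])) {
    stop("overlapping edits in edit table")
  }
  n <- nrow(edits)
  keep_start <- c(0L, edits$end0)
  keep_end <- c(edits$start0, nchar(s))
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <-
    substring(s, keep_start + 1L, keep_end)
  pieces[seq(2L, 2L * n, by = 2L)] <- edits$alt
  paste(pieces, collapse = "")
}

#' Simulate a diploid sample from a donor reference
#'
#' Places SNVs (with per-site population allele frequencies drawn from a
#' spectrum with mass on both sides of 0.5), small indels, structural
#' variants >= 50 bp with recorded zygosity, and reciprocal terminal-segment
#' translocations biased to chromosome ends, then builds the two haplotypes.
#' Genotypes are drawn per haplotype from the site frequency, conditioned on
#' the variant being present in the individual. Indels and SVs never straddle
#' exon boundaries; SVs avoid gene bodies and repeats except the designated
#' gene-deleting and gene-truncating events. Truth coordinates are on the
#' donor reference.
#'
#' @param reference donor [assembly] from [simulate_reference].
#' @param config the same [sim_config].
#' @return list with `hap1`, `hap2` (assemblies; `hap1` is the consensus
#'   haplotype) and `truth`, a truth-set list with elements `variants`,
#'   `translocations`, `edits` (per-haplotype edit tables), `ref_lengths`,
#'   `hap_lengths`.
#' @export
simulate_sample <- function(reference, config) {
  stopifnot(inherits(reference, "assembly"), inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 2L), {
    chroms <- names(reference$seq)
    lens <- seq_lengths(reference)
    genes <- reference$meta$genes
    annot <- reference$meta$annotation
    repeats <- reference$meta$repeats
    ref_gaps <- reference$meta$ref_gaps
    excl_term <- config$transloc_seg_len + 1000L

    # region bookkeeping per chromosome for rejection sampling
    busy <- stats::setNames(lapply(chroms, function(ch) {
      b <- data.frame(start = integer(0), end = integer(0))
      b <- rbind(b, data.frame(start = 0L, end = excl_term),
                 data.frame(start = lens[[ch]] - excl_term, end = lens[[ch]]))
      rg <- ref_gaps[ref_gaps$chrom == ch, , drop = FALSE]
      if (nrow(rg)) b <- rbind(b, data.frame(start = rg$start - 20L,
                                             end = rg$end + 20L))
      b
    }), chroms)
    gene_blocks <- stats::setNames(lapply(chroms, function(ch) {
      g <- genes[genes$chrom == ch & genes$role != "paralog_copy", , drop = FALSE]
      data.frame(start = g$start, end = g$end)
    }), chroms)
    cds_iv <- stats::setNames(lapply(chroms, function(ch) {
      cd <- annot[annot$type == "CDS" & annot$seqid == ch, , drop = FALSE]
      data.frame(start = cd$start - 1L, end = cd$end)
    }), chroms)
    rep_iv <- stats::setNames(lapply(chroms, function(ch) {
      r <- repeats[repeats$chrom == ch, , drop = FALSE]
      data.frame(start = r$start, end = r$end)
    }), chroms)

    take <- function(ch, s, e) {
      busy[[ch]] <<- rbind(busy[[ch]], data.frame(start = s, end = e))
    }
    is_free <- function(ch, s, e, pad = 12L) {
      !any(iv_overlaps(s - pad, e + pad, busy[[ch]]$start, busy[[ch]]$end))
    }
    pick_pos <- function(len_needed, ok_fun, tries = 4000L) {
      for (t in seq_len(tries)) {
        ch <- sample(chroms, 1L, prob = lens)
        p <- sample.int(lens[[ch]] - len_needed - 2L, 1L)
        if (ok_fun(ch, p)) return(list(chrom = ch, pos0 = p))
      }
      NULL
    }

    variants <- NULL
    add_variant <- function(chrom, pos0, ref, alt, type, len, af, h1, h2) {
      variants <<- rbind(variants, data.frame(
        chrom = chrom, pos = pos0 + 1L, ref = ref, alt = alt, type = type,
        len = len, af = af, hap1 = h1, hap2 = h2,
        gt = paste0(h1, "|", h2)))
    }
    draw_af <- function() {
      if (stats::runif(1) < 0.5) stats::runif(1, 0.05, 0.5)
      else stats::runif(1, 0.5001, 0.999)
    }
    draw_gt <- function(af) {
      repeat {
        h <- stats::rbinom(2L, 1L, af)
        if (sum(h) > 0L) return(h)
      }
    }

    base_at <- function(ch, pos0) substr(reference$seq[[ch]], pos0 + 1L, pos0 + 1L)
    slice <- function(ch, s0, e0) substr(reference$seq[[ch]], s0 + 1L, e0)

    # designated structural events first, so all later placement avoids them:
    # the gene-deleting SV and the CDS-truncating SV
    sv_special <- list()
    if (config$delete_gene && any(genes$role == "deleted")) {
      g <- genes[genes$role == "deleted", ][1, ]
      sv_special[[length(sv_special) + 1L]] <-
        list(chrom = g$chrom, start0 = g$start - 60L, end0 = g$end + 60L,
             kind = "del", zyg = "hom")
    }
    if (config$truncate_gene && any(genes$role == "truncated")) {
      g <- genes[genes$role == "truncated", ][1, ]
      cd <- annot[annot$type == "CDS" & !is.na(annot$Parent) &
                    annot$Parent == paste0(g$gene, ".t1"), ][1, ]
      cl <- cd$end - cd$start + 1L
      dl <- as.integer(ceiling(0.6 * cl))
      s0 <- cd$start - 1L + (cl - dl) %/% 2L
      sv_special[[length(sv_special) + 1L]] <-
        list(chrom = g$chrom, start0 = s0, end0 = s0 + dl, kind = "del",
             zyg = "hom")
    }
    for (sp in sv_special) {
      p <- sp$start0 - 1L
      take(sp$chrom, p, sp$end0 + 1L)
      add_variant(sp$chrom, p, slice(sp$chrom, p, sp$end0),
                  base_at(sp$chrom, p), "sv_del", sp$end0 - sp$start0,
                  0.5, 1L, 1L)
    }

    # small indels: inside a CDS interior or fully outside gene blocks
    for (i in seq_len(config$indel_count)) {
      len <- sample(config$indel_len_range[1]:config$indel_len_range[2], 1L)
      ins <- stats::runif(1) < 0.5
      span <- if (ins) 1L else len + 1L
      hit <- pick_pos(span + 2L, function(ch, p) {
        if (!is_free(ch, p, p + span)) return(FALSE)
        if (grepl("N", slice(ch, p, p + span), fixed = TRUE)) return(FALSE)
        gb <- gene_blocks[[ch]]
        in_gene <- point_in_intervals(p, gb) | point_in_intervals(p + span, gb)
        if (!any(in_gene)) return(TRUE)
        cd <- cds_iv[[ch]]
        any(p >= cd$start + 6L & (p + span) <= cd$end - 6L)
      })
      if (is.null(hit)) break
      ch <- hit$chrom; p <- hit$pos0
      take(ch, p, p + span)
      af <- draw_af(); h <- draw_gt(af)
      anchor <- base_at(ch, p)
      if (ins) {
        seqi <- rand_dna(len)
        add_variant(ch, p, anchor, paste0(anchor, seqi), "ins", len, af, h[1], h[2])
      } else {
        add_variant(ch, p, slice(ch, p, p + len + 1L), anchor, "del", len, af,
                    h[1], h[2])
      }
    }

    # remaining structural variants: outside genes and repeats, isolated
    n_sv_rand <- max(0L, config$sv_count - length(sv_special))
    for (i in seq_len(n_sv_rand)) {
      len <- sample(config$sv_len_range[1]:config$sv_len_range[2], 1L)
      ins <- stats::runif(1) < config$sv_ins_frac
      span <- if (ins) 1L else len + 1L
      hit <- pick_pos(span + 2L, function(ch, p) {
        if (!is_free(ch, p - 1200L, p + span + 1200L, pad = 0L)) return(FALSE)
        if (grepl("N", slice(ch, max(0L, p - 5L), p + span + 5L), fixed = TRUE))
          return(FALSE)
        gb <- gene_blocks[[ch]]
        if (any(iv_overlaps(p - 100L, p + span + 100L, gb$start, gb$end)))
          return(FALSE)
        rp <- rep_iv[[ch]]
        !any(iv_overlaps(p - 1200L, p + span + 1200L, rp$start, rp$end))
      })
      if (is.null(hit)) break
      ch <- hit$chrom; p <- hit$pos0
      take(ch, p - 1200L, p + span + 1200L)
      hom <- stats::runif(1) < config$sv_hom_frac
      h <- if (hom) c(1L, 1L) else if (stats::runif(1) < 0.5) c(1L, 0L) else c(0L, 1L)
      anchor <- base_at(ch, p)
      if (ins) {
        seqi <- rand_dna(len)
        add_variant(ch, p, anchor, paste0(anchor, seqi), "sv_ins", len, 0.5,
                    h[1], h[2])
      } else {
        add_variant(ch, p, slice(ch, p, p + len + 1L), anchor, "sv_del", len,
                    0.5, h[1], h[2])
      }
    }
    # SNVs, placed in bulk: candidates per chromosome, filtered against all
    # occupied intervals, thinned to a minimum spacing
    want_by_chrom <- table(factor(sample(chroms, config$snv_count,
                                         replace = TRUE, prob = lens),
                                  levels = chroms))
    for (ch in chroms) {
      want <- as.integer(want_by_chrom[[ch]])
      if (want == 0L) next
      cand <- sort(unique(sample.int(lens[[ch]] - 2L, min(3L * want + 50L,
                                                          lens[[ch]] - 2L))))
      occ <- busy[[ch]]
      occ <- occ[order(occ$start), , drop = FALSE]
      # merge occupied intervals (padded) and drop candidates inside them
      st <- occ$start - 12L; en <- occ$end + 12L
      if (length(st) > 1L) {
        grp <- cumsum(c(TRUE, st[-1] > cummax(en[-length(en)])))
        st <- tapply(st, grp, min); en <- tapply(en, grp, max)
      }
      idx <- findInterval(cand, st)
      inside <- idx > 0L & cand < en[pmax(idx, 1L)]
      cand <- cand[!inside]
      bases <- strsplit(reference$seq[[ch]], "", fixed = TRUE)[[1]][cand + 1L]
      cand <- cand[bases %in% c("A", "C", "G", "T")]
      bases <- bases[bases %in% c("A", "C", "G", "T")]
      keep <- c(TRUE, diff(cand) >= 12L)
      cand <- cand[keep]; bases <- bases[keep]
      if (length(cand) > want) {
        sel <- sort(sample.int(length(cand), want))
        cand <- cand[sel]; bases <- bases[sel]
      }
      nn <- length(cand)
      alts <- random_base(bases)
      af <- ifelse(stats::runif(nn) < 0.5, stats::runif(nn, 0.05, 0.5),
                   stats::runif(nn, 0.5001, 0.999))
      # genotype conditioned on carrying at least one alternate allele
      p11 <- af^2; p10 <- af * (1 - af)
      tot <- p11 + 2 * p10
      u <- stats::runif(nn) * tot
      h1 <- as.integer(u < p11 + p10)
      h2 <- as.integer(u < p11 | u >= p11 + p10)
      variants <- rbind(variants, data.frame(
        chrom = ch, pos = cand + 1L, ref = bases, alt = alts, type = "snv",
        len = 1L, af = af, hap1 = h1, hap2 = h2,
        gt = paste0(h1, "|", h2)))
      take(ch, cand, cand + 1L)
    }

    if (is.null(variants)) {
      variants <- data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             type = character(0), len = integer(0),
                             af = numeric(0), hap1 = integer(0),
                             hap2 = integer(0), gt = character(0))
    }
    variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
    rownames(variants) <- NULL

    # per-haplotype edit tables (0-based half-open replacement intervals)
    edit_tables <- lapply(1:2, function(h) {
      pres <- variants[variants[[paste0("hap", h)]] == 1L, , drop = FALSE]
      if (nrow(pres) == 0L) {
        return(data.frame(chrom = character(0), start0 = integer(0),
                          end0 = integer(0), alt = character(0)))
      }
      data.frame(chrom = pres$chrom,
                 start0 = ifelse(pres$type == "snv", pres$pos - 1L, pres$pos),
                 end0 = ifelse(pres$type == "snv", pres$pos,
                               pres$pos + nchar(pres$ref) - 1L),
                 alt = ifelse(pres$type == "snv", pres$alt,
                              substr(pres$alt, 2L, nchar(pres$alt))))
    })

    haps <- lapply(1:2, function(h) {
      et <- edit_tables[[h]]
      s <- reference$seq
      for (ch in chroms) {
        s[[ch]] <- apply_edit_table(s[[ch]], et[et$chrom == ch, , drop = FALSE])
      }
      s
    })

    # reciprocal terminal-segment exchange (applied to both haplotypes);
    # terminal regions are variant-free so hap coordinates equal ref there
    translocations <- data.frame(chrom_a = character(0), chrom_b = character(0),
                                 break_a = integer(0), break_b = integer(0),
                                 seg_len = integer(0))
    if (config$transloc_pairs >= 1L && length(chroms) >= 2L) {
      sl <- config$transloc_seg_len
      a <- chroms[1]; b <- chroms[2]
      for (h in 1:2) {
        sa <- haps[[h]][[a]]; sb <- haps[[h]][[b]]
        tail_a <- substr(sa, nchar(sa) - sl + 1L, nchar(sa))
        tail_b <- substr(sb, nchar(sb) - sl + 1L, nchar(sb))
        haps[[h]][[a]] <- paste0(substr(sa, 1L, nchar(sa) - sl), tail_b)
        haps[[h]][[b]] <- paste0(substr(sb, 1L, nchar(sb) - sl), tail_a)
      }
      translocations <- data.frame(chrom_a = a, chrom_b = b,
                                   break_a = lens[[a]] - sl,
                                   break_b = lens[[b]] - sl, seg_len = sl)
    }

    hap_asm <- lapply(1:2, function(h) {
      assembly(stats::setNames(unlist(haps[[h]]), chroms),
               version = paste0("hap", h))
    })
    truth <- list(variants = variants, translocations = translocations,
                  edits = edit_tables, ref_lengths = lens,
                  hap_lengths = lapply(hap_asm, seq_lengths))
    hap_asm[[1]]$meta$truth <- truth
    hap_asm[[2]]$meta$truth <- truth
    list(hap1 = hap_asm[[1]], hap2 = hap_asm[[2]], truth = truth)
  })
}

#' Lift a donor-reference position onto a sample haplotype
#'
#' Applies the truth edit offsets and the translocation map. Positions inside
#' a non-substitution edit return `NA`.
#'
#' @param truth truth set from [simulate_sample].
#' @param chrom,pos0 reference chromosome and 0-based position (vectorized
#'   over `pos0`).
#' @param hap haplotype (1 or 2).
#' @return data.frame chrom, pos0 on the haplotype (`NA` where undefined).
#' @export
truth_lift <- function(truth, chrom, pos0, hap = 1L) {
  et <- truth$edits[[hap]]
  et <- et[et$chrom == chrom, , drop = FALSE]
  out_chrom <- rep(chrom, length(pos0))
  out_pos <- vapply(pos0, function(p) {
    inside <- et$start0 <= p & p < et$end0
    if (any(inside)) {
      e <- et[inside, ][1, ]
      if (e$end0 - e$start0 == 1L && nchar(e$alt) == 1L) {
        # substitution: position maps through
      } else {
        return(NA_integer_)
      }
    }
    before <- et$end0 <= p
    as.integer(p + sum(nchar(et$alt[before]) -
                         (et$end0[before] - et$start0[before])))
  }, integer(1))
  tr <- truth$translocations
  orig_chrom <- rep(chrom, length(pos0))
  for (i in seq_len(nrow(tr))) {
    sel_a <- orig_chrom == tr$chrom_a[i] & !is.na(out_pos) &
      pos0 >= tr$break_a[i]
    sel_b <- orig_chrom == tr$chrom_b[i] & !is.na(out_pos) &
      pos0 >= tr$break_b[i]
    if (any(sel_a)) {
      dst_len <- truth$hap_lengths[[hap]][[tr$chrom_b[i]]]
      out_pos[sel_a] <- dst_len - tr$seg_len[i] + (pos0[sel_a] - tr$break_a[i])
      out_chrom[sel_a] <- tr$chrom_b[i]
    }
    if (any(sel_b)) {
      dst_len <- truth$hap_lengths[[hap]][[tr$chrom_a[i]]]
      out_pos[sel_b] <- dst_len - tr$seg_len[i] + (pos0[sel_b] - tr$break_b[i])
      out_chrom[sel_b] <- tr$chrom_a[i]
    }
  }
  data.frame(chrom = out_chrom, pos0 = out_pos)
}

#' Fragment a haplotype into a draft contig set
#'
#' Withholds intervals (future assembly gaps: one centered on each donor
#' N-run placeholder, the rest random, all avoiding SVs and repeats), cuts
#' the remaining sequence into contig-sized pieces, builds chimeric contigs
#' by joining pieces from different chromosomes, and reverse-complements a
#' fraction of contigs. The truth tiling, chimera junctions and withheld
#' intervals are returned alongside.
#'
#' @param hap a haplotype [assembly] carrying the truth set in its metadata
#'   (as produced by [simulate_sample]).
#' @param config the [sim_config].
#' @param reference the donor [assembly] (for repeat/gap coordinates).
#' @return list with `contigs` ([assembly]), `tiling`, `chimeras`,
#'   `withheld` data frames.
#' @export
fragment_assembly <- function(hap, config, reference = NULL) {
  stopifnot(inherits(hap, "assembly"))
  truth <- hap$meta$truth
  if (is.null(truth)) stop("haplotype assembly lacks truth metadata")
  with_seed(sub_seed(config$seed, 3L), {
    chroms <- names(hap$seq)
    lens <- seq_lengths(hap)
    avoid <- stats::setNames(lapply(chroms, function(ch) {
      v <- truth$variants
      sv <- v[v$chrom == ch & v$type %in% c("sv_ins", "sv_del"), , drop = FALSE]
      a <- data.frame(start = sv$pos - 3500L, end = sv$pos + sv$len + 3500L)
      if (!is.null(reference)) {
        # keep withheld-gap flanks (up to a 5 kb window) clear of repeats and
        # of the duplicated gene pair, so flank uniqueness is decided by the
        # sequence, not the placement
        rp <- reference$meta$repeats
        rp <- rp[rp$chrom == ch, , drop = FALSE]
        if (nrow(rp)) a <- rbind(a, data.frame(start = rp$start - 6500L,
                                               end = rp$end + 6500L))
        gn <- reference$meta$genes
        gn <- gn[gn$chrom == ch & gn$role %in% c("deleted", "paralog_copy"), ,
                 drop = FALSE]
        if (nrow(gn)) a <- rbind(a, data.frame(start = gn$start - 6500L,
                                               end = gn$end + 6500L))
      }
      a
    }), chroms)

    withheld <- NULL
    for (ch in chroms) {
      L <- lens[[ch]]
      n_here <- sum(seq_len(config$withheld_count) %% length(chroms) ==
                      (match(ch, chroms) %% length(chroms)))
      ivs <- data.frame(start = integer(0), end = integer(0))
      # center one withheld interval over each donor gap block (spanning
      # both N runs and the small contig between them)
      if (!is.null(reference)) {
        rg <- reference$meta$ref_gaps
        rg <- rg[rg$chrom == ch, , drop = FALSE]
        for (b in unique(rg$block)) {
          rb <- rg[rg$block == b, , drop = FALSE]
          blo <- min(rb$start); bhi <- max(rb$end)
          w <- sample(config$withheld_len_range[1]:config$withheld_len_range[2], 1L)
          w <- max(w, (bhi - blo) + 600L)
          mid <- (blo + bhi) %/% 2L
          ivs <- rbind(ivs, data.frame(start = mid - w %/% 2L,
                                       end = mid - w %/% 2L + w))
        }
      }
      extra <- max(0L, n_here - nrow(ivs))
      if (extra > 0L) {
        lens_draw <- sample(config$withheld_len_range[1]:config$withheld_len_range[2],
                            extra, replace = TRUE)
        ivs <- rbind(ivs, sample_intervals(
          extra, lens_draw, lo = 12000L, hi = L - 12000L,
          occupied = rbind(avoid[[ch]], ivs), pad = 10000L))
      }
      ivs <- ivs[order(ivs$start), , drop = FALSE]
      if (nrow(ivs)) {
        withheld <- rbind(withheld, data.frame(chrom = ch, start = ivs$start,
                                               end = ivs$end))
      }
    }
    if (is.null(withheld)) withheld <- data.frame(chrom = character(0),
                                                  start = integer(0),
                                                  end = integer(0))

    # cut kept stretches into pieces
    pieces <- NULL
    for (ch in chroms) {
      L <- lens[[ch]]
      wh <- withheld[withheld$chrom == ch, , drop = FALSE]
      bounds <- c(0L, as.vector(t(as.matrix(wh[, c("start", "end")]))), L)
      keep <- matrix(bounds, ncol = 2L, byrow = TRUE)
      for (r in seq_len(nrow(keep))) {
        s <- keep[r, 1]; e <- keep[r, 2]
        while (e - s > 0L) {
          want <- sample(config$contig_len_range[1]:config$contig_len_range[2], 1L)
          if (e - s - want < 10000L) want <- e - s
          pieces <- rbind(pieces, data.frame(chrom = ch, start = s,
                                             end = s + want))
          s <- s + want
        }
      }
    }
    pieces$id <- seq_len(nrow(pieces))

    # chimeras: join pieces >= 20 kb from different chromosomes
    elig <- pieces$id[pieces$end - pieces$start >= 20000L]
    chim_pairs <- list()
    used <- integer(0)
    for (i in seq_len(config$chimera_count)) {
      cand_a <- setdiff(elig, used)
      if (length(cand_a) == 0L) break
      a <- sample(cand_a, 1L)
      cand_b <- setdiff(elig[pieces$chrom[elig] != pieces$chrom[pieces$id == a]], used)
      cand_b <- setdiff(cand_b, a)
      if (length(cand_b) == 0L) break
      b <- sample(cand_b, 1L)
      used <- c(used, a, b)
      chim_pairs[[length(chim_pairs) + 1L]] <- c(a, b)
    }

    seqs <- character(0)
    tiling <- NULL; chimeras <- NULL
    tig_i <- 0L
    new_name <- function() {
      tig_i <<- tig_i + 1L
      sprintf("tig%05d", tig_i)
    }
    piece_seq <- function(id) {
      p <- pieces[pieces$id == id, ]
      substr(hap$seq[[p$chrom]], p$start + 1L, p$end)
    }
    add_contig <- function(ids) {
      nm <- new_name()
      parts <- lapply(ids, function(id) pieces[pieces$id == id, ])
      s <- paste(vapply(ids, piece_seq, character(1)), collapse = "")
      minus <- stats::runif(1) < config$orient_minus_frac
      L <- nchar(s)
      offs <- cumsum(c(0L, vapply(parts, function(p) p$end - p$start, integer(1))))
      til <- do.call(rbind, lapply(seq_along(parts), function(j) {
        p <- parts[[j]]
        cs <- offs[j]; ce <- offs[j + 1L]
        if (minus) {
          data.frame(contig = nm, contig_start = L - ce, contig_end = L - cs,
                     chrom = p$chrom, hap_start = p$start, hap_end = p$end,
                     orient = "-")
        } else {
          data.frame(contig = nm, contig_start = cs, contig_end = ce,
                     chrom = p$chrom, hap_start = p$start, hap_end = p$end,
                     orient = "+")
        }
      }))
      if (minus) s <- revcomp(s)
      seqs[nm] <<- s
      tiling <<- rbind(tiling, til)
      if (length(ids) == 2L) {
        j <- offs[2L]
        chimeras <<- rbind(chimeras, data.frame(
          contig = nm, junction = if (minus) L - j else j,
          chrom_a = parts[[1]]$chrom, chrom_b = parts[[2]]$chrom))
      }
    }
    for (pr in chim_pairs) add_contig(pr)
    for (id in setdiff(pieces$id, used)) add_contig(id)
    if (is.null(chimeras)) chimeras <- data.frame(contig = character(0),
                                                  junction = integer(0),
                                                  chrom_a = character(0),
                                                  chrom_b = character(0))
    contigs <- assembly(seqs, version = "contigs",
                        meta = list(truth_tiling = tiling, chimeras = chimeras,
                                    withheld = withheld, truth = truth))
    list(contigs = contigs, tiling = tiling, chimeras = chimeras,
         withheld = withheld)
  })
}

#' Plant haplotype-duplicate contigs into a contig set
#'
#' Adds small contigs that are near-identical copies of slices of existing
#' larger contigs (the second-haplotype redundancy a duplicate filter should
#' remove). Each duplicate is mutated at the configured divergence.
#'
#' @param contigs contig [assembly].
#' @param n number of duplicates to plant.
#' @param config the [sim_config] (seed source).
#' @param len duplicate length.
#' @param divergence per-base substitution rate applied to each duplicate.
#' @return list with `contigs` (augmented [assembly]) and `duplicates`
#'   (data.frame dup, source, start, end).
#' @export
plant_duplicate_contigs <- function(contigs, n, config, len = 20000L,
                                    divergence = 0.005) {
  with_seed(sub_seed(config$seed, 7L), {
    lens <- seq_lengths(contigs)
    big <- names(lens)[lens >= len + 1000L]
    dups <- NULL
    seqs <- contigs$seq
    for (i in seq_len(n)) {
      src <- sample(big, 1L)
      s0 <- sample.int(lens[[src]] - len, 1L)
      u <- strsplit(substr(contigs$seq[[src]], s0 + 1L, s0 + len), "",
                    fixed = TRUE)[[1]]
      nmut <- stats::rbinom(1L, len, divergence)
      if (nmut > 0L) {
        at <- sample(len, nmut)
        u[at] <- vapply(u[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1L), character(1))
      }
      nm <- sprintf("dup%03d", i)
      seqs[nm] <- paste(u, collapse = "")
      dups <- rbind(dups, data.frame(dup = nm, source = src, start = s0,
                                     end = s0 + len))
    }
    list(contigs = assembly(seqs, version = contigs$version,
                            meta = contigs$meta),
         duplicates = dups)
  })
}

#' Simulate a read-coverage track over contigs
#'
#' Uniform depth around the configured mean with integer jitter, except in a
#' window around each chimeric junction where the depth drops (or piles up)
#' to `dropout_depth`. Intervals tile each contig exactly.
#'
#' @param contigs contig [assembly].
#' @param chimeras chimera table from [fragment_assembly].
#' @param config the [sim_config].
#' @return coverage data.frame (seq, start, end, depth).
#' @export
simulate_coverage <- function(contigs, chimeras, config) {
  with_seed(sub_seed(config$seed, 4L), {
    out <- NULL
    for (nm in names(contigs$seq)) {
      L <- nchar(contigs$seq[[nm]])
      starts <- seq.int(0L, L - 1L, by = config$cov_bin)
      ends <- pmin(starts + config$cov_bin, L)
      depth <- config$cov_mean +
        sample(seq.int(-config$cov_jitter, config$cov_jitter),
               length(starts), replace = TRUE)
      ch <- chimeras[chimeras$contig == nm, , drop = FALSE]
      for (i in seq_len(nrow(ch))) {
        j <- ch$junction[i]
        hitw <- ends > j - config$dropout_halfwidth &
          starts < j + config$dropout_halfwidth
        depth[hitw] <- config$dropout_depth
      }
      out <- rbind(out, data.frame(seq = nm, start = starts, end = ends,
                                   depth = depth))
    }
    out
  })
}

#' Simulate a population allele-frequency site table
#'
#' Emits one row per sample SNV (REF = donor allele, ALT = the population
#' major-allele candidate) plus extra rows designed to exercise the selection
#' filters: sites where the individual is homozygous reference, rows reported
#' in fewer than 200 individuals, and multi-base rows. For variant-derived
#' rows the ALT allele equals the sample's alternate allele with probability
#' equal to the site allele frequency, so the proportion of sites at which
#' the sample carries the major allele rises with frequency.
#'
#' @param reference donor [assembly].
#' @param truth truth set from [simulate_sample].
#' @param config the [sim_config].
#' @return site data.frame (chrom, pos, ref, alt, af, an).
#' @export
simulate_population_sites <- function(reference, truth, config) {
  with_seed(sub_seed(config$seed, 5L), {
    snv <- truth$variants[truth$variants$type == "snv", , drop = FALSE]
    major <- ifelse(stats::runif(nrow(snv)) < snv$af, snv$alt,
                    mapply(function(r, a)
                      sample(setdiff(c("A", "C", "G", "T"), c(r, a)), 1L),
                      snv$ref, snv$alt))
    rows <- data.frame(chrom = snv$chrom, pos = snv$pos, ref = snv$ref,
                       alt = unname(major), af = snv$af,
                       an = sample(200:1662, nrow(snv), replace = TRUE))

    lens <- seq_lengths(reference)
    occupied <- truth$variants[, c("chrom", "pos")]
    # regions deleted from both haplotypes have no assembly counterpart;
    # population sites are not drawn there
    v <- truth$variants
    homdel <- v[v$type == "sv_del" & v$hap1 == 1L & v$hap2 == 1L, , drop = FALSE]
    fresh_pos <- function(n) {
      out <- NULL
      tries <- 0L
      while (is.null(out) || nrow(out) < n) {
        tries <- tries + 1L
        if (tries > 50L * n) break
        ch <- sample(names(lens), 1L, prob = lens)
        p <- sample.int(lens[[ch]] - 10L, 1L)
        if (any(occupied$chrom == ch & abs(occupied$pos - p) < 15L)) next
        if (nrow(homdel) > 0L &&
            any(homdel$chrom == ch & p > homdel$pos - 1200L &
                  p < homdel$pos + homdel$len + 1200L)) next
        b <- substr(reference$seq[[ch]], p, p)
        if (b == "N") next
        occupied <- rbind(occupied, data.frame(chrom = ch, pos = p))
        out <- rbind(out, data.frame(chrom = ch, pos = p, ref = b))
      }
      out
    }

    n_hom <- round(config$pop_homref_frac * nrow(snv))
    hr <- fresh_pos(n_hom)
    if (!is.null(hr) && nrow(hr)) {
      rows <- rbind(rows, data.frame(
        chrom = hr$chrom, pos = hr$pos, ref = hr$ref,
        alt = random_base(hr$ref), af = stats::runif(nrow(hr), 0.5001, 0.999),
        an = sample(200:1662, nrow(hr), replace = TRUE)))
    }
    lc <- fresh_pos(config$pop_low_count_rows)
    if (!is.null(lc) && nrow(lc)) {
      rows <- rbind(rows, data.frame(
        chrom = lc$chrom, pos = lc$pos, ref = lc$ref,
        alt = random_base(lc$ref), af = stats::runif(nrow(lc), 0.5001, 0.999),
        an = sample(10:199, nrow(lc), replace = TRUE)))
    }
    mb <- fresh_pos(config$pop_multibase_rows)
    if (!is.null(mb) && nrow(mb)) {
      ref2 <- vapply(seq_len(nrow(mb)), function(i)
        substr(reference$seq[[mb$chrom[i]]], mb$pos[i], mb$pos[i] + 1L),
        character(1))
      rows <- rbind(rows, data.frame(
        chrom = mb$chrom, pos = mb$pos, ref = ref2,
        alt = vapply(ref2, function(r) paste(sample(c("A", "C", "G", "T"), 2L,
                                                    replace = TRUE),
                                             collapse = ""), character(1),
                     USE.NAMES = FALSE),
        af = stats::runif(nrow(mb), 0.5001, 0.999),
        an = sample(200:1662, nrow(mb), replace = TRUE)))
    }
    rows <- rows[order(rows$chrom, rows$pos), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  })
}

# classify a CDS change from known overlapping indel lengths plus direct
# translation of the two CDS sequences; shared precedence order
consequence_precedence <- c("unmapped", "truncated", "frameshift",
                            "stop gained", "stop lost", "start lost",
                            "in-frame insertion", "in-frame deletion",
                            "missense", "identical")

label_cds_change <- function(src_cds, tgt_cds, indel_net_lens = integer(0)) {
  if (any(indel_net_lens %% 3L != 0L)) return("frameshift")
  ps <- translate_cds(src_cds); pt <- translate_cds(tgt_cds)
  if (nchar(pt) > 1L && grepl("*", substr(pt, 1L, nchar(pt) - 1L), fixed = TRUE) &&
      !grepl("*", substr(ps, 1L, nchar(ps) - 1L), fixed = TRUE)) {
    return("stop gained")
  }
  if (substr(ps, nchar(ps), nchar(ps)) == "*" &&
      substr(pt, nchar(pt), nchar(pt)) != "*") {
    return("stop lost")
  }
  if (toupper(substr(tgt_cds, 1L, 3L)) != "ATG" &&
      toupper(substr(src_cds, 1L, 3L)) == "ATG") {
    return("start lost")
  }
  if (nchar(tgt_cds) > nchar(src_cds)) return("in-frame insertion")
  if (nchar(tgt_cds) < nchar(src_cds)) return("in-frame deletion")
  if (ps != pt) return("missense")
  "identical"
}

#' Emit the toy annotation, its projection onto the sample, and truth labels
#'
#' Returns the donor-side GFF feature table recorded by
#' [simulate_reference], and, when a truth set is supplied, the annotation
#' projected onto the consensus haplotype (hap1) through the truth edit maps
#' (the synthetic stand-in for an annotation-transfer tool), together with
#' per-transcript truth consequence labels derived from the known variants
#' and direct translation.
#'
#' @param reference donor [assembly] from [simulate_reference].
#' @param truth truth set from [simulate_sample], or `NULL` for the donor
#'   annotation only.
#' @param config the [sim_config].
#' @param hap1 the consensus haplotype [assembly] (required with `truth`).
#' @return list with `source` (donor feature table), and with truth also
#'   `sample` (projected feature table), `consequences` (transcript, gene,
#'   category), `unmapped` (transcript ids).
#' @export
simulate_annotation <- function(reference, truth = NULL, config = NULL,
                                hap1 = NULL) {
  src <- reference$meta$annotation
  if (is.null(truth)) return(list(source = src))
  stopifnot(!is.null(hap1))
  v <- truth$variants
  hom_del <- v[v$type == "sv_del" & v$hap1 == 1L, , drop = FALSE]

  lift_feature <- function(chrom, start1, end1) {
    a <- truth_lift(truth, chrom, start1 - 1L, hap = 1L)
    b <- truth_lift(truth, chrom, end1 - 1L, hap = 1L)
    if (is.na(a$pos0) || is.na(b$pos0) || a$chrom != b$chrom) return(NULL)
    data.frame(seqid = a$chrom, start = a$pos0 + 1L, end = b$pos0 + 1L)
  }

  tx_ids <- src$ID[src$type == "mRNA"]
  sample_rows <- NULL
  unmapped <- character(0)
  for (tid in tx_ids) {
    feats <- src[(!is.na(src$ID) & src$ID == tid) |
                   (!is.na(src$Parent) & src$Parent == tid), , drop = FALSE]
    span <- c(min(feats$start), max(feats$end))
    ch <- feats$seqid[1]
    # dropped entirely if the transcript lies inside a hom deletion
    gone <- any(hom_del$chrom == ch & hom_del$pos < span[1] &
                  hom_del$pos + hom_del$len >= span[2])
    if (gone) {
      unmapped <- c(unmapped, tid)
      next
    }
    ok <- TRUE
    for (i in seq_len(nrow(feats))) {
      lf <- lift_feature(feats$seqid[i], feats$start[i], feats$end[i])
      if (is.null(lf)) { ok <- FALSE; break }
      feats$seqid[i] <- lf$seqid; feats$start[i] <- lf$start
      feats$end[i] <- lf$end
    }
    if (!ok) {
      unmapped <- c(unmapped, tid)
      next
    }
    sample_rows <- rbind(sample_rows, feats)
  }
  # carry over gene rows for genes with any surviving transcript
  gene_rows <- src[src$type == "gene", , drop = FALSE]
  kept_genes <- unique(sample_rows$Parent[sample_rows$type == "mRNA"])
  g_keep <- gene_rows[gene_rows$ID %in% kept_genes, , drop = FALSE]
  for (i in seq_len(nrow(g_keep))) {
    lf <- lift_feature(g_keep$seqid[i], g_keep$start[i], g_keep$end[i])
    if (!is.null(lf)) {
      g_keep$seqid[i] <- lf$seqid; g_keep$start[i] <- lf$start
      g_keep$end[i] <- lf$end
    }
  }
  sample_gff <- rbind(g_keep, sample_rows)

  # truth consequence labels
  src_tx <- extract_transcript_sequences(reference, src)
  smp_tx <- extract_transcript_sequences(hap1, sample_gff)
  tx2gene <- stats::setNames(src$Parent[src$type == "mRNA"],
                             src$ID[src$type == "mRNA"])
  cons <- NULL
  for (tid in tx_ids) {
    if (tid %in% unmapped) {
      cat_ <- "unmapped"
    } else if (nchar(smp_tx$mrna[[tid]]) < 0.5 * nchar(src_tx$mrna[[tid]])) {
      cat_ <- "truncated"
    } else {
      cds_feats <- src[src$type == "CDS" & !is.na(src$Parent) &
                         src$Parent == tid, , drop = FALSE]
      ch <- cds_feats$seqid[1]
      vv <- v[v$chrom == ch & v$hap1 == 1L &
                v$type %in% c("ins", "del", "sv_ins", "sv_del"), , drop = FALSE]
      in_cds <- vapply(seq_len(nrow(vv)), function(i) {
        any(vv$pos[i] >= cds_feats$start & vv$pos[i] + nchar(vv$ref[i]) - 1L <=
              cds_feats$end)
      }, logical(1))
      net <- ifelse(vv$type[in_cds] %in% c("ins", "sv_ins"),
                    vv$len[in_cds], -vv$len[in_cds])
      cat_ <- label_cds_change(src_tx$cds[[tid]], smp_tx$cds[[tid]], net)
    }
    cons <- rbind(cons, data.frame(transcript = tid,
                                   gene = unname(tx2gene[tid]),
                                   category = cat_))
  }
  list(source = src, sample = sample_gff, consequences = cons,
       unmapped = unmapped)
}

#' Plant consensus errors into an assembly
#'
#' Introduces substitution, insertion and deletion errors at
#' donor-reference-anchored positions: most errors land in clean benchmark
#' territory, a configured number within 30 bp of a true variant (to exercise
#' the proximity exclusion), and a configured number inside the excluded
#' (repeat) regions. Error positions avoid true variants by at least 40 bp
#' otherwise.
#'
#' @param x the consensus haplotype [assembly] (chromosome-named like the
#'   donor).
#' @param reference donor [assembly].
#' @param truth truth set from [simulate_sample].
#' @param config the [sim_config].
#' @return list with `assembly` (errors applied) and `planted` (data.frame
#'   chrom, pos0 (donor 0-based anchor), type, len, seq, near, in_excluded).
#' @export
plant_errors <- function(x, reference, truth, config) {
  with_seed(sub_seed(config$seed, 6L), {
    lens <- truth$ref_lengths
    chroms <- names(lens)
    excl <- excluded_regions(reference)
    vpos <- truth$variants[, c("chrom", "pos")]
    vint <- data.frame(chrom = truth$variants$chrom,
                       start = truth$variants$pos,
                       end = truth$variants$pos + nchar(truth$variants$ref))
    margin <- 10000L
    term_block <- config$transloc_seg_len + 2000L

    planted <- NULL
    taken <- data.frame(chrom = character(0), pos = integer(0))
    clear_of_variants <- function(ch, p0, span, dist = 40L) {
      sel <- vint$chrom == ch
      !any(iv_overlaps(p0 - dist, p0 + span + dist,
                       vint$start[sel] - 1L, vint$end[sel]))
    }
    clear_of_errors <- function(ch, p0, span) {
      !any(taken$chrom == ch & abs(taken$pos - p0) < span + 60L)
    }
    draw_type <- function() {
      u <- stats::runif(1)
      if (u < config$err_sub_frac) "sub"
      else if (u < config$err_sub_frac + config$err_ins_frac) "ins"
      else "del"
    }
    add_err <- function(ch, p0, type, near, in_excl) {
      len <- if (type == "sub") 1L else sample.int(config$err_indel_max, 1L)
      sq <- if (type == "sub") {
        random_base(substr(reference$seq[[ch]], p0 + 1L, p0 + 1L))
      } else if (type == "ins") rand_dna(len) else {
        substr(reference$seq[[ch]], p0 + 2L, p0 + 1L + len)
      }
      planted <<- rbind(planted, data.frame(chrom = ch, pos0 = p0, type = type,
                                            len = len, seq = sq, near = near,
                                            in_excluded = in_excl))
      taken <<- rbind(taken, data.frame(chrom = ch, pos = p0))
    }
    in_ok_zone <- function(ch, p0, span) {
      L <- lens[[ch]]
      if (p0 < margin || p0 + span > L - max(margin, term_block)) return(FALSE)
      s <- substr(reference$seq[[ch]], p0 - 2L, p0 + span + 3L)
      !grepl("N", s, fixed = TRUE)
    }

    # deliberate near-variant errors (5-30 bp from a true variant)
    snvs <- truth$variants[truth$variants$type == "snv", , drop = FALSE]
    pick <- snvs[sample.int(nrow(snvs), min(config$err_near_count, nrow(snvs))), ,
                 drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      d <- sample(5:30, 1L)
      p0 <- pick$pos[i] - 1L + d
      if (!in_ok_zone(pick$chrom[i], p0, 1L)) next
      if (!clear_of_errors(pick$chrom[i], p0, 1L)) next
      if (!clear_of_variants(pick$chrom[i], p0, 1L, dist = 3L)) next
      add_err(pick$chrom[i], p0, "sub", near = TRUE, in_excl = FALSE)
    }
    # errors inside excluded regions
    for (i in seq_len(config$err_excl_count)) {
      if (nrow(excl) == 0L) break
      r <- excl[sample.int(nrow(excl), 1L), ]
      p0 <- sample(seq.int(r$start + 100L, r$end - 100L), 1L)
      if (!clear_of_variants(r$chrom, p0, 6L) || !clear_of_errors(r$chrom, p0, 6L))
        next
      if (!in_ok_zone(r$chrom, p0, 6L)) next
      add_err(r$chrom, p0, draw_type(), near = FALSE, in_excl = TRUE)
    }
    # bulk clean errors
    guard <- 0L
    while (is.null(planted) || nrow(planted) < config$n_errors) {
      guard <- guard + 1L
      if (guard > 60L * config$n_errors) break
      ch <- sample(chroms, 1L, prob = unlist(lens))
      p0 <- sample.int(lens[[ch]] - 2L * margin, 1L) + margin
      if (!in_ok_zone(ch, p0, 8L)) next
      if (!clear_of_variants(ch, p0, 8L) || !clear_of_errors(ch, p0, 8L)) next
      in_excl <- nrow(excl) > 0L &&
        any(excl$chrom == ch & excl$start <= p0 & p0 < excl$end)
      if (in_excl) next
      add_err(ch, p0, draw_type(), near = FALSE, in_excl = FALSE)
    }
    planted <- planted[order(planted$chrom, planted$pos0), , drop = FALSE]
    rownames(planted) <- NULL

    # apply errors to the assembly: error coordinates are donor-anchored, so
    # convert through the haplotype lift before splicing
    s <- x$seq
    for (ch in chroms) {
      pp <- planted[planted$chrom == ch, , drop = FALSE]
      if (nrow(pp) == 0L) next
      ap <- truth_lift(truth, ch, pp$pos0, hap = 1L)
      if (anyNA(ap$pos0)) {
        stop("planted error position failed to lift; variant clearance bug")
      }
      ed <- data.frame(chrom = ap$chrom,
                       start0 = ifelse(pp$type == "sub", ap$pos0, ap$pos0 + 1L),
                       end0 = ifelse(pp$type == "sub", ap$pos0 + 1L,
                                     ifelse(pp$type == "del",
                                            ap$pos0 + 1L + pp$len, ap$pos0 + 1L)),
                       alt = ifelse(pp$type == "del", "", pp$seq))
      for (tch in unique(ed$chrom)) {
        s[[tch]] <- apply_edit_table(s[[tch]], ed[ed$chrom == tch, , drop = FALSE])
      }
    }
    out <- assembly(s, version = paste0(x$version, "+err"), meta = x$meta)
    list(assembly = out, planted = planted)
  })
}

#' Consensus variant calls of the sample assembly against the donor
#'
#' Emits the call set an assembly-vs-donor caller would produce for the
#' consensus haplotype: every truth variant carried by that haplotype (as a
#' homozygous call, since a haploid consensus has no second allele) plus one
#' call per planted error. Both donor coordinates and assembly coordinates
#' are reported; assembly coordinates account for all haplotype edits and
#' planted errors together.
#'
#' @param reference donor [assembly].
#' @param truth truth set.
#' @param planted planted-error table from [plant_errors] (or `NULL`).
#' @param hap haplotype represented by the consensus (default 1).
#' @return data.frame chrom, pos, ref, alt, gt, source (`"sample"` or
#'   `"error"`), asm_chrom, asm_pos (1-based).
#' @export
consensus_calls <- function(reference, truth, planted = NULL, hap = 1L) {
  v <- truth$variants
  pres <- v[v[[paste0("hap", hap)]] == 1L, , drop = FALSE]
  calls <- data.frame(chrom = pres$chrom, pos = pres$pos, ref = pres$ref,
                      alt = pres$alt, gt = "1/1", source = "sample")
  if (!is.null(planted) && nrow(planted)) {
    anchor <- vapply(seq_len(nrow(planted)), function(i)
      substr(reference$seq[[planted$chrom[i]]], planted$pos0[i] + 1L,
             planted$pos0[i] + 1L), character(1))
    err_calls <- data.frame(
      chrom = planted$chrom, pos = planted$pos0 + 1L,
      ref = ifelse(planted$type == "del",
                   vapply(seq_len(nrow(planted)), function(i)
                     substr(reference$seq[[planted$chrom[i]]],
                            planted$pos0[i] + 1L,
                            planted$pos0[i] + 1L + planted$len[i]),
                     character(1)),
                   anchor),
      alt = ifelse(planted$type == "sub", planted$seq,
                   ifelse(planted$type == "ins", paste0(anchor, planted$seq),
                          anchor)),
      gt = "1/1", source = "error")
    calls <- rbind(calls, err_calls)
  }
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]

  # assembly coordinates: offsets from haplotype edits plus planted errors
  et <- truth$edits[[hap]]
  if (!is.null(planted) && nrow(planted)) {
    pe <- data.frame(chrom = planted$chrom,
                     start0 = ifelse(planted$type == "sub", planted$pos0,
                                     planted$pos0 + 1L),
                     end0 = ifelse(planted$type == "sub", planted$pos0 + 1L,
                                   ifelse(planted$type == "del",
                                          planted$pos0 + 1L + planted$len,
                                          planted$pos0 + 1L)),
                     alt = ifelse(planted$type == "del", "", planted$seq))
    et <- rbind(et, pe)
  }
  delta <- nchar(et$alt) - (et$end0 - et$start0)
  calls$asm_chrom <- calls$chrom
  calls$asm_pos <- NA_integer_
  for (ch in unique(calls$chrom)) {
    ec <- et[et$chrom == ch, , drop = FALSE]
    o <- order(ec$end0)
    ends <- ec$end0[o]; dl <- cumsum(delta[et$chrom == ch][o])
    sel <- calls$chrom == ch
    p0 <- calls$pos[sel] - 1L
    idx <- findInterval(p0, ends)
    off <- ifelse(idx == 0L, 0L, dl[pmax(idx, 1L)])
    calls$asm_pos[sel] <- p0 + off + 1L
  }
  rownames(calls) <- NULL
  calls
}

#' Benchmark variant table of the truth set
#'
#' The diploid benchmark VCF analogue: every truth variant with its true
#' genotype.
#'
#' @param truth truth set.
#' @return data.frame chrom, pos, ref, alt, gt.
#' @export
benchmark_vcf <- function(truth) {
  v <- truth$variants
  data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gt = v$gt)
}

#' Benchmark (high-confidence) regions of the synthetic genome
#'
#' The interior of each chromosome, trimming a margin off both ends (the
#' synthetic analogue of the confident-call BED).
#'
#' @param reference donor [assembly].
#' @param margin bp trimmed from each chromosome end.
#' @return BED-style data.frame (chrom, start, end), 0-based half-open.
#' @export
benchmark_regions <- function(reference, margin = 10000L) {
  lens <- seq_lengths(reference)
  data.frame(chrom = names(lens), start = margin,
             end = unname(lens) - margin)
}

#' Excluded regions (repeat analogue) of the synthetic genome
#'
#' One >10 kb interval centred on each planted repeat copy, standing in for
#' the self-chain/segmental-duplication exclusion list.
#'
#' @param reference donor [assembly].
#' @param halfwidth half-width of each excluded interval.
#' @return BED-style data.frame (chrom, start, end).
#' @export
excluded_regions <- function(reference, halfwidth = 6000L) {
  rp <- reference$meta$repeats
  if (is.null(rp) || nrow(rp) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  }
  mid <- (rp$start + rp$end) %/% 2L
  data.frame(chrom = rp$chrom, start = pmax(0L, mid - halfwidth),
             end = mid + halfwidth)
}
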