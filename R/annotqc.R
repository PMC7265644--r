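# Annotation-transfer quality control: per-transcript coverage/identity from
# global mRNA alignment, the 50%-coverage mapping rule, cross-chromosome
# (translocation) detection with block grouping, protein-consequence
# classification with a fixed disruption-precedence order, gene-level
# disruption summaries, and a paralog-presence check for unmapped genes.

#' Score transferred transcripts by mRNA coverage and identity
#'
#' For every transcript in the source annotation, the source and target mRNA
#' sequences are aligned globally; coverage is the aligned fraction of the
#' source mRNA and identity is computed over the aligned (non-terminal-gap)
#' columns. A transcript is `mapped` when coverage >= `min_coverage` percent,
#' `partial` below it, and `unmapped` when absent from the target
#' annotation.
#'
#' @param src_genome,src_annot source genome ([assembly]) and feature table.
#' @param tgt_genome,tgt_annot target genome and (transferred) feature table.
#' @param min_coverage mapping threshold in percent.
#' @return data.frame transcript, gene, src_chrom, tgt_chrom, coverage,
#'   identity, status.
#' @export
score_transcript_mappings <- function(src_genome, src_annot, tgt_genome,
                                      tgt_annot, min_coverage = 50) {
  src_tx <- extract_transcript_sequences(src_genome, src_annot)
  tgt_tx <- extract_transcript_sequences(tgt_genome, tgt_annot)
  ids <- names(src_tx$mrna)
  tx_meta <- src_annot[src_annot$type == "mRNA", , drop = FALSE]
  tgt_meta <- tgt_annot[tgt_annot$type == "mRNA", , drop = FALSE]
  out <- NULL
  for (id in ids) {
    gene <- tx_meta$Parent[match(id, tx_meta$ID)]
    src_chrom <- tx_meta$seqid[match(id, tx_meta$ID)]
    if (!id %in% names(tgt_tx$mrna)) {
      out <- rbind(out, data.frame(transcript = id, gene = gene,
                                   src_chrom = src_chrom,
                                   tgt_chrom = NA_character_, coverage = 0,
                                   identity = NA_real_, status = "unmapped"))
      next
    }
    ga <- global_align(src_tx$mrna[[id]], tgt_tx$mrna[[id]])
    status <- if (ga$coverage >= min_coverage) "mapped" else "partial"
    out <- rbind(out, data.frame(transcript = id, gene = gene,
                                 src_chrom = src_chrom,
                                 tgt_chrom = tgt_meta$seqid[match(id, tgt_meta$ID)],
                                 coverage = ga$coverage,
                                 identity = ga$identity_aligned,
                                 status = status))
  }
  out
}

#' Detect genes mapped to a different chromosome
#'
#' Genes whose mapped isoforms land on a different chromosome than their
#' source are reported; adjacent translocated genes (in source order, with no
#' intervening non-translocated gene) sharing the same source/target
#' chromosome pair merge into blocks. Endpoints within the terminal
#' `subtel_frac` of either chromosome are flagged subtelomeric. Genes whose
#' isoforms disagree on the target chromosome get a conflict flag.
#'
#' @param mappings transcript mapping table from
#'   [score_transcript_mappings].
#' @param src_annot source feature table (for gene positions).
#' @param src_lens,tgt_lens named chromosome lengths of the two genomes.
#' @param subtel_frac terminal fraction considered subtelomeric.
#' @return data.frame gene, src_chrom, src_pos, tgt_chrom, block, subtel_src,
#'   subtel_tgt, conflict.
#' @export
detect_translocations <- function(mappings, src_annot, src_lens, tgt_lens,
                                  subtel_frac = 0.01) {
  mp <- mappings[mappings$status != "unmapped" & !is.na(mappings$tgt_chrom), ,
                 drop = FALSE]
  empty <- data.frame(gene = character(0), src_chrom = character(0),
                      src_pos = integer(0), tgt_chrom = character(0),
                      block = integer(0), subtel_src = logical(0),
                      subtel_tgt = logical(0), conflict = logical(0))
  if (nrow(mp) == 0L) return(empty)
  genes <- unique(mp$gene)
  gene_rows <- src_annot[src_annot$type == "gene", , drop = FALSE]
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    m <- mp[mp$gene == g, , drop = FALSE]
    tgt <- unique(m$tgt_chrom)
    main_tgt <- names(sort(table(m$tgt_chrom), decreasing = TRUE))[1]
    data.frame(gene = g, src_chrom = m$src_chrom[1],
               src_pos = gene_rows$start[match(g, gene_rows$ID)],
               tgt_chrom = main_tgt, conflict = length(tgt) > 1L)
  }))
  per_gene <- per_gene[order(per_gene$src_chrom, per_gene$src_pos), , drop = FALSE]
  per_gene$moved <- per_gene$src_chrom != per_gene$tgt_chrom
  tr <- per_gene[per_gene$moved, , drop = FALSE]
  if (nrow(tr) == 0L) return(empty)
  # block grouping: walk genes in source order; a translocated gene starts a
  # new block unless the previous gene (in full source order) was
  # translocated with the same chromosome pair
  per_gene$block <- NA_integer_
  blk <- 0L
  prev_moved <- FALSE; prev_pair <- ""
  for (i in seq_len(nrow(per_gene))) {
    if (!per_gene$moved[i]) { prev_moved <- FALSE; next }
    pair <- paste(per_gene$src_chrom[i], per_gene$tgt_chrom[i])
    if (!prev_moved || pair != prev_pair) blk <- blk + 1L
    per_gene$block[i] <- blk
    prev_moved <- TRUE; prev_pair <- pair
  }
  tr <- per_gene[per_gene$moved, , drop = FALSE]
  near_end <- function(pos, len, frac) {
    !is.na(pos) & !is.na(len) & (pos <= frac * len | pos >= (1 - frac) * len)
  }
  tr$subtel_src <- near_end(tr$src_pos, src_lens[tr$src_chrom], subtel_frac)
  tr$subtel_tgt <- near_end(tr$src_pos, tgt_lens[tr$tgt_chrom], subtel_frac)
  tr[, c("gene", "src_chrom", "src_pos", "tgt_chrom", "block", "subtel_src",
         "subtel_tgt", "conflict")]
}

#' Classify the protein-level consequence of a transferred CDS
#'
#' Translates both CDS sequences and inspects the nucleotide edit script from
#' their global alignment. One category per transcript, chosen by the
#' disruption-precedence order `unmapped > truncated > frameshift >
#' stop gained > stop lost > start lost > in-frame insertion > in-frame
#' deletion > missense > identical` (a transcript carrying both a missense
#' change and a premature stop is counted under the stop gain).
#'
#' @param src_cds,tgt_cds source and target CDS nucleotide sequences
#'   (`tgt_cds` may be `NA` when the transcript did not transfer).
#' @param status mapping status from [score_transcript_mappings].
#' @return a one-row data.frame transcript-agnostic record: category,
#'   n_indels, net_indel.
#' @export
classify_consequence <- function(src_cds, tgt_cds, status = "mapped") {
  rec <- function(cat, ni = 0L, net = 0L)
    data.frame(category = cat, n_indels = ni, net_indel = net)
  if (status == "unmapped" || is.null(tgt_cds) || is.na(tgt_cds) ||
      !nzchar(tgt_cds)) {
    return(rec("unmapped"))
  }
  if (status == "partial") return(rec("truncated"))
  ga <- global_align(src_cds, tgt_cds)
  ed <- ga$edits
  ind <- ed[ed$op %in% c("I", "D"), , drop = FALSE]
  net <- sum(ifelse(ind$op == "I", ind$len, -ind$len))
  if (nrow(ind) > 0L && any(ind$len %% 3L != 0L)) {
    return(rec("frameshift", nrow(ind), net))
  }
  ps <- translate_cds(src_cds); pt <- translate_cds(tgt_cds)
  internal_stop <- function(p) nchar(p) > 1L &&
    grepl("*", substr(p, 1L, nchar(p) - 1L), fixed = TRUE)
  if (internal_stop(pt) && !internal_stop(ps)) {
    return(rec("stop gained", nrow(ind), net))
  }
  if (substr(ps, nchar(ps), nchar(ps)) == "*" &&
      substr(pt, nchar(pt), nchar(pt)) != "*") {
    return(rec("stop lost", nrow(ind), net))
  }
  if (toupper(substr(src_cds, 1L, 3L)) == "ATG" &&
      toupper(substr(tgt_cds, 1L, 3L)) != "ATG") {
    return(rec("start lost", nrow(ind), net))
  }
  if (net > 0L) return(rec("in-frame insertion", nrow(ind), net))
  if (net < 0L) return(rec("in-frame deletion", nrow(ind), net))
  if (ps != pt) return(rec("missense", nrow(ind), net))
  rec("identical", nrow(ind), net)
}

#' Classify consequences for all transcripts of an annotation transfer
#'
#' @param mappings transcript mapping table.
#' @param src_genome,src_annot,tgt_genome,tgt_annot genomes and annotations.
#' @return data.frame transcript, gene, category.
#' @export
classify_all_consequences <- function(mappings, src_genome, src_annot,
                                      tgt_genome, tgt_annot) {
  src_tx <- extract_transcript_sequences(src_genome, src_annot)
  tgt_tx <- extract_transcript_sequences(tgt_genome, tgt_annot)
  out <- NULL
  for (i in seq_len(nrow(mappings))) {
    id <- mappings$transcript[i]
    if (!id %in% names(src_tx$cds)) next
    tgt <- if (id %in% names(tgt_tx$cds)) tgt_tx$cds[[id]] else NA_character_
    cc <- classify_consequence(src_tx$cds[[id]], tgt, mappings$status[i])
    out <- rbind(out, data.frame(transcript = id, gene = mappings$gene[i],
                                 category = cc$category))
  }
  out
}

disrupting_categories <- c("frameshift", "stop gained", "stop lost",
                           "start lost", "truncated", "unmapped")

#' Gene-level disruption summary
#'
#' A gene is `disrupted` iff every isoform carries a disrupting category
#' (frameshift, stop gained/lost, start lost, truncated, unmapped);
#' `affected` when some but not all isoforms do; `intact` otherwise.
#'
#' @param consequences data.frame transcript, gene, category.
#' @return data.frame gene, n_isoforms, n_disrupted, status.
#' @export
gene_disruption_summary <- function(consequences) {
  genes <- unique(consequences$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    cc <- consequences[consequences$gene == g, , drop = FALSE]
    nd <- sum(cc$category %in% disrupting_categories)
    status <- if (nd == nrow(cc)) "disrupted" else if (nd > 0L) "affected"
              else "intact"
    data.frame(gene = g, n_isoforms = nrow(cc), n_disrupted = nd,
               status = status)
  }))
  out
}

#' Check for paralogous copies of unmapped genes
#'
#' Aligns each unmapped gene's source sequence to the target assembly (best
#' locus, refined base-exactly) and reports the best-hit identity and
#' location; a family member is considered present when identity reaches
#' `min_identity` percent.
#'
#' @param gene_seqs named character vector of unmapped gene sequences.
#' @param x target [assembly].
#' @param min_identity presence threshold in percent.
#' @param k anchor k-mer size.
#' @param index optional prebuilt index of `x`.
#' @return data.frame gene, hit_chrom, hit_pos, identity, family_present.
#' @export
paralog_presence <- function(gene_seqs, x, min_identity = 90, k = 21L,
                             index = NULL) {
  if (is.null(index)) index <- kmer_index(x, k = k)
  out <- NULL
  for (g in names(gene_seqs)) {
    res <- locate_query(gene_seqs[[g]], index, x$seq, min_chain_frac = 0.2)
    if (is.null(res$placement)) {
      out <- rbind(out, data.frame(gene = g, hit_chrom = NA_character_,
                                   hit_pos = NA_integer_, identity = NA_real_,
                                   family_present = FALSE))
      next
    }
    p <- res$placement
    out <- rbind(out, data.frame(gene = g, hit_chrom = p$tname,
                                 hit_pos = p$tstart + 1L,
                                 identity = p$identity,
                                 family_present = p$identity >= min_identity))
  }
  out
}
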