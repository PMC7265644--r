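# Population major-allele harmonization. Qualifying SNV sites (reported in
# enough individuals, major-allele frequency strictly above 0.5, single-base,
# major allele differing from the donor base) are lifted onto the assembly
# through 2-kb anchored windows with strict span/identity/uniqueness
# filters. At mapped sites the assembly base is classified against the major
# allele and, where the individual's genotype shows it carries the major
# allele but the assembly recorded the donor allele, the base is replaced —
# personalizing the reference without departing from the underlying
# individual.

#' Select qualifying major-allele sites
#'
#' Keeps single-base substitution rows reported in at least `min_count`
#' individuals whose allele frequency is strictly greater than `min_af` and
#' whose major (alternate) allele differs from the donor reference allele.
#'
#' @param sites site table (chrom, pos, ref, alt, af, an).
#' @param min_count minimum individuals (`>=`).
#' @param min_af frequency threshold (strict `>`).
#' @return the filtered site table with a `major` column.
#' @export
select_sites <- function(sites, min_count = 200L, min_af = 0.5) {
  keep <- !is.na(sites$an) & sites$an >= min_count &
    !is.na(sites$af) & sites$af > min_af &
    nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    toupper(sites$ref) != toupper(sites$alt)
  out <- sites[keep, , drop = FALSE]
  out$major <- toupper(out$alt)
  rownames(out) <- NULL
  out
}

#' Map selected sites onto the assembly via anchored windows
#'
#' A `window`-bp donor region centered on each site is located on the
#' assembly with the unique-anchor chainer and refined base-exactly.
#' Placements must be unique (one competing locus), span at least `min_span`
#' aligned bases and reach `min_identity`; the site position is lifted
#' through the best placement. Sites lifted through a minus-strand placement
#' have their alleles complemented. Sites whose center falls in an indel
#' column are dropped with a flag.
#'
#' @param sites selected site table from [select_sites].
#' @param donor donor [assembly].
#' @param x target [assembly].
#' @param window window size (bp).
#' @param min_span minimum aligned span (bp).
#' @param min_identity minimum identity in percent.
#' @param k anchor k-mer size.
#' @param index optional prebuilt [kmer_index] of `x`.
#' @return list with `mapped` (site table + asm_chrom, asm_pos, asm_allele,
#'   strand), `unmapped` (site table + reason), `n_mapped`, `n_unmapped`.
#' @export
map_sites <- function(sites, donor, x, window = 2000L, min_span = 1980L,
                      min_identity = 99, k = 21L, index = NULL) {
  if (is.null(index)) index <- kmer_index(x, k = k)
  half <- window %/% 2L
  n <- nrow(sites)
  asm_chrom <- rep(NA_character_, n); asm_pos <- rep(NA_integer_, n)
  asm_allele <- rep(NA_character_, n); strand <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  # one anchor_align call over all windows, then per-site refinement
  wins <- character(n)
  offs <- integer(n)
  for (i in seq_len(n)) {
    s <- donor$seq[[sites$chrom[i]]]
    p0 <- sites$pos[i] - 1L
    lo <- max(0L, p0 - half); hi <- min(nchar(s), p0 + half)
    wins[i] <- substr(s, lo + 1L, hi)
    offs[i] <- p0 - lo
  }
  names(wins) <- sprintf("site%06d", seq_len(n))
  # zero diagonal drift: every chain record is a pure diagonal run, so
  # refinement can compare bases directly instead of re-aligning
  chains <- anchor_align(wins, index, max_diag_drift = 0L)
  chain_split <- split(seq_len(nrow(chains)), chains$qname)
  for (i in seq_len(n)) {
    ci <- chains[chain_split[[names(wins)[i]]] %||% integer(0), , drop = FALSE]
    # anchors must cover most of the window (unique-anchor stringency);
    # windows straddling repeats fail here instead of in slow refinement
    res <- locate_query(wins[i], index, x$seq, min_chain_frac = 0.7,
                        chains = ci)
    if (is.null(res$placement)) { reason[i] <- "no_alignment"; next }
    if (res$n_loci != 1L) { reason[i] <- "not_unique"; next }
    p <- res$placement
    if (p$span < min_span) { reason[i] <- "span"; next }
    if (p$identity < min_identity) { reason[i] <- "identity"; next }
    tp <- p$lift(offs[i])
    if (is.na(tp)) { reason[i] <- "indel_at_site"; next }
    asm_chrom[i] <- p$tname
    asm_pos[i] <- tp + 1L
    strand[i] <- p$strand
    b <- toupper(substr(x$seq[[p$tname]], tp + 1L, tp + 1L))
    asm_allele[i] <- if (p$strand == "-") chartr("ACGTN", "TGCAN", b) else b
  }
  sites$asm_chrom <- asm_chrom; sites$asm_pos <- asm_pos
  sites$asm_allele <- asm_allele; sites$strand <- strand
  ok <- !is.na(asm_pos)
  un <- sites[!ok, , drop = FALSE]
  un$reason <- reason[!ok]
  list(mapped = sites[ok, , drop = FALSE], unmapped = un,
       n_mapped = sum(ok), n_unmapped = sum(!ok))
}

#' Classify mapped sites and replace qualifying alleles
#'
#' Per mapped site, with assembly allele `a`, donor reference allele `r`,
#' major allele `M`, and the individual's genotype at the donor site (absent
#' from the genotype set means homozygous reference):
#' `matched` — `a == M` already; `replaced` — `a == r` and the genotype is
#' heterozygous containing `M`, so the base is rewritten to `M` (preserving
#' provenance case); `reference_match` — the assembly keeps `r` because the
#' genotype does not carry `M`; `third_allele` — `a` matches neither.
#' Only replacements toward the major allele, and only where the genotype
#' carries it, are ever made, so the assembly stays faithful to the
#' individual.
#'
#' @param mapped mapped site table from [map_sites].
#' @param x [assembly] to edit.
#' @param genotypes genotype table for the individual (chrom, pos, ref, alt,
#'   gt) on donor coordinates.
#' @return list with `assembly` (version `v1.7`), `sites` (classification
#'   per site), `edits` (replacement log), `accounting` (counts per class).
#' @export
classify_and_replace <- function(mapped, x, genotypes) {
  seqs <- x$seq
  gkey <- paste(genotypes$chrom, genotypes$pos)
  cls <- character(nrow(mapped))
  edits <- NULL
  for (i in seq_len(nrow(mapped))) {
    a <- toupper(mapped$asm_allele[i])
    r <- toupper(mapped$ref[i])
    M <- toupper(mapped$major[i])
    gi <- match(paste(mapped$chrom[i], mapped$pos[i]), gkey)
    alleles <- if (is.na(gi)) r else {
      g <- genotypes[gi, ]
      idx <- strsplit(gsub("\\|", "/", g$gt), "/")[[1]]
      opts <- c(toupper(g$ref), strsplit(toupper(g$alt), ",")[[1]])
      unique(opts[as.integer(idx) + 1L])
    }
    if (a == M) {
      cls[i] <- "matched"
    } else if (a == r && M %in% alleles && length(alleles) > 1L) {
      # heterozygous individual carrying the major allele: replace
      ch <- mapped$asm_chrom[i]; p0 <- mapped$asm_pos[i] - 1L
      old <- substr(seqs[[ch]], p0 + 1L, p0 + 1L)
      newb <- if (mapped$strand[i] == "-") chartr("ACGTN", "TGCAN", M) else M
      if (old == tolower(old)) newb <- tolower(newb)
      seqs[[ch]] <- splice_str(seqs[[ch]], p0, p0 + 1L, newb)
      cls[i] <- "replaced"
      edits <- rbind(edits, data.frame(asm_chrom = ch, asm_pos = p0 + 1L,
                                       from = old, to = newb,
                                       chrom = mapped$chrom[i],
                                       pos = mapped$pos[i]))
    } else if (a == r) {
      cls[i] <- "reference_match"
    } else {
      cls[i] <- "third_allele"
    }
  }
  mapped$class <- cls
  acct <- table(factor(cls, levels = c("matched", "replaced",
                                       "reference_match", "third_allele")))
  list(assembly = assembly(seqs, version = "v1.7", meta = x$meta),
       sites = mapped,
       edits = edits %||% data.frame(asm_chrom = character(0),
                                     asm_pos = integer(0), from = character(0),
                                     to = character(0), chrom = character(0),
                                     pos = integer(0)),
       accounting = as.data.frame(acct, responseName = "count",
                                  stringsAsFactors = FALSE))
}

#' Allele-frequency-binned harmonization report
#'
#' Site counts and the proportion carrying the major allele (matched or
#' replaced), binned over major-allele frequency.
#'
#' @param sites classified site table from [classify_and_replace].
#' @param edges bin edges over allele frequency.
#' @return data.frame bin, n_sites, n_matched, prop_matched.
#' @export
af_binned_report <- function(sites, edges = c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)) {
  bin <- cut(sites$af, breaks = edges, include.lowest = FALSE, right = TRUE)
  ok <- sites$class %in% c("matched", "replaced")
  n <- tapply(rep(1L, nrow(sites)), bin, sum, default = 0L)
  m <- tapply(as.integer(ok), bin, sum, default = 0L)
  data.frame(bin = levels(bin), n_sites = as.integer(n),
             n_matched = as.integer(m),
             prop_matched = ifelse(n > 0, m / n, NA_real_))
}
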