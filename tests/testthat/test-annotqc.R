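test_that("transcript scoring applies the 50% coverage rule", {
  set.seed(81)
  cds <- rand_cds(60L)  # 180 bp
  src_g <- assembly(c(chrS = paste0(rand_seq(500), cds, rand_seq(500))))
  mk_annot <- function(chrom, at, len, id) {
    data.frame(seqid = chrom, source = "t", type = c("mRNA", "exon", "CDS"),
               start = at + 1L, end = at + len, strand = "+",
               phase = c(NA, NA, 0L), ID = c(id, paste0(id, ".e"),
                                             paste0(id, ".c")),
               Parent = c(NA, id, id))
  }
  src_a <- mk_annot("chrS", 500L, 180L, "t1")
  # identical transcript in the target
  tgt_g <- assembly(c(chrT = paste0(rand_seq(300), cds, rand_seq(300))))
  tgt_a <- mk_annot("chrT", 300L, 180L, "t1")
  mp <- score_transcript_mappings(src_g, src_a, tgt_g, tgt_a)
  expect_equal(mp$status, "mapped")
  expect_equal(mp$coverage, 100)
  expect_equal(mp$identity, 100)
  # target mRNA only 40% as long: partial
  short <- substr(cds, 1, 72)
  tgt_g2 <- assembly(c(chrT = paste0(rand_seq(300), short, rand_seq(300))))
  tgt_a2 <- mk_annot("chrT", 300L, 72L, "t1")
  mp2 <- score_transcript_mappings(src_g, src_a, tgt_g2, tgt_a2)
  expect_equal(mp2$status, "partial")
  expect_lt(mp2$coverage, 50)
  # transcript absent from the target annotation: unmapped
  mp3 <- score_transcript_mappings(src_g, src_a, tgt_g, tgt_a[0, ])
  expect_equal(mp3$status, "unmapped")
  expect_equal(mp3$coverage, 0)
})

test_that("consequence classification matches the forced examples", {
  set.seed(82)
  cds <- rand_cds(50L)
  # synonymous change: codon 10 GGG>GGA style — force a synonymous site
  v <- strsplit(cds, "")[[1]]
  stopifnot(substr(cds, 1, 3) == "ATG")
  syn <- cds
  substr(syn, 4, 6) <- "CTA"  # make codon 2 Leu
  syn2 <- syn
  substr(syn2, 4, 6) <- "CTG"  # still Leu
  expect_equal(classify_consequence(syn, syn2)$category, "identical")
  # 3-bp in-frame deletion
  del3 <- paste0(substr(cds, 1, 12), substr(cds, 16, nchar(cds)))
  expect_equal(classify_consequence(cds, del3)$category, "in-frame deletion")
  # 3-bp in-frame insertion
  ins3 <- paste0(substr(cds, 1, 12), "GCT", substr(cds, 13, nchar(cds)))
  expect_equal(classify_consequence(cds, ins3)$category, "in-frame insertion")
  # 1-bp deletion mid-CDS: frameshift
  del1 <- paste0(substr(cds, 1, 12), substr(cds, 14, nchar(cds)))
  expect_equal(classify_consequence(cds, del1)$category, "frameshift")
  # ATG -> ATA at codon 1: start lost
  sl <- cds; substr(sl, 3, 3) <- "A"
  expect_equal(classify_consequence(cds, sl)$category, "start lost")
  # internal codon to TAA: stop gained
  sg <- cds; substr(sg, 31, 33) <- "TAA"
  expect_equal(classify_consequence(cds, sg)$category, "stop gained")
  # terminal stop mutated away: stop lost
  stl <- cds; substr(stl, nchar(cds) - 2, nchar(cds)) <- "TAC"
  expect_equal(classify_consequence(cds, stl)$category, "stop lost")
  # missense
  ms <- cds; substr(ms, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                           substr(cds, 10, 10))[1]
  expect_true(classify_consequence(cds, ms)$category %in%
                c("missense", "identical"))
  # unmapped and truncated come from the mapping status
  expect_equal(classify_consequence(cds, NA, "unmapped")$category, "unmapped")
  expect_equal(classify_consequence(cds, del3, "partial")$category, "truncated")
})

test_that("classification agrees with the translate-and-diff oracle on random pairs", {
  set.seed(83)
  n <- 250L
  mism <- 0L
  for (i in seq_len(n)) {
    cds <- rand_cds(sample(40:120, 1))
    L <- nchar(cds)
    kind <- sample(c("none", "sub", "ins", "del"), 1,
                   prob = c(0.2, 0.4, 0.2, 0.2))
    if (kind == "none") {
      tgt <- cds; types <- character(0); lens <- integer(0)
    } else if (kind == "sub") {
      p <- sample(4:(L - 3), 1)
      b <- setdiff(c("A", "C", "G", "T"), substr(cds, p, p))
      tgt <- cds; substr(tgt, p, p) <- sample(b, 1)
      types <- "sub"; lens <- 1L
    } else if (kind == "ins") {
      p <- sample(4:(L - 3), 1)
      l <- sample(1:6, 1)
      tgt <- paste0(substr(cds, 1, p), rand_seq(l), substr(cds, p + 1, L))
      types <- "ins"; lens <- l
    } else {
      p <- sample(4:(L - 9), 1)
      l <- sample(1:6, 1)
      tgt <- paste0(substr(cds, 1, p), substr(cds, p + l + 1, L))
      types <- "del"; lens <- l
    }
    want <- oracle_consequence(cds, tgt, types, lens)
    got <- classify_consequence(cds, tgt)$category
    if (got != want) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("translocated genes are detected in blocks with subtelomere flags", {
  fx <- fx_annot()
  mp <- score_transcript_mappings(fx$ref, fx$ann$source, fx$smp$hap1,
                                  fx$ann$sample)
  tl <- detect_translocations(mp, fx$ann$source, seq_lengths(fx$ref),
                              seq_lengths(fx$smp$hap1),
                              subtel_frac = fx$cfg$transloc_seg_len /
                                min(seq_lengths(fx$ref)))
  genes <- fx$ref$meta$genes
  subtel_genes <- genes$gene[genes$role == "subtel"]
  expect_setequal(tl$gene, subtel_genes)
  # one block per chromosome side of the reciprocal exchange
  expect_equal(length(unique(tl$block)), 2L)
  expect_true(all(tl$subtel_src))
  # genes on the true chromosome produce no calls
  same <- mp[mp$src_chrom == mp$tgt_chrom, ]
  expect_false(any(same$gene %in% tl$gene))
})

test_that("isoforms landing on two chromosomes raise a conflict flag", {
  mp <- data.frame(transcript = c("g.t1", "g.t2"), gene = "g",
                   src_chrom = "chr1", tgt_chrom = c("chr2", "chr3"),
                   coverage = 100, identity = 100, status = "mapped")
  src_annot <- data.frame(seqid = "chr1", source = "t", type = "gene",
                          start = 100L, end = 500L, strand = "+",
                          phase = NA_integer_, ID = "g", Parent = NA)
  tl <- detect_translocations(mp, src_annot, c(chr1 = 1e6),
                              c(chr2 = 1e6, chr3 = 1e6))
  expect_equal(nrow(tl), 1L)
  expect_true(tl$conflict)
})

test_that("gene disruption summary honours the any-intact-isoform rule", {
  cons <- data.frame(
    transcript = c("a.t1", "a.t2", "b.t1", "b.t2", "c.t1"),
    gene = c("a", "a", "b", "b", "c"),
    category = c("frameshift", "identical", "frameshift", "stop gained",
                 "missense"))
  gd <- gene_disruption_summary(cons)
  expect_equal(gd$status[gd$gene == "a"], "affected")
  expect_equal(gd$status[gd$gene == "b"], "disrupted")
  expect_equal(gd$status[gd$gene == "c"], "intact")
})

test_that("category counts partition the transcript total", {
  fx <- fx_annot()
  mp <- score_transcript_mappings(fx$ref, fx$ann$source, fx$smp$hap1,
                                  fx$ann$sample)
  cons <- classify_all_consequences(mp, fx$ref, fx$ann$source, fx$smp$hap1,
                                    fx$ann$sample)
  expect_equal(nrow(cons), nrow(mp))
  expect_equal(sum(table(cons$category)), nrow(mp))
  # and the categories agree with the generator's truth labels
  mg <- merge(cons, fx$ann$consequences, by = "transcript")
  expect_equal(mean(mg$category.x == mg$category.y), 1.0)
})

test_that("a deleted gene's paralog is found near its planted identity", {
  fx <- fx_annot()
  genes <- fx$ref$meta$genes
  del <- genes[genes$role == "deleted", ][1, ]
  gseq <- substr(fx$ref$seq[[del$chrom]], del$start + 1L, del$end)
  pp <- paralog_presence(stats::setNames(gseq, del$gene), fx$smp$hap1)
  expect_true(pp$family_present)
  expect_gte(pp$identity, 95)
  expect_lte(pp$identity, 100)
  # identity agrees with an independent recomputation at the hit locus
  hit <- substr(fx$smp$hap1$seq[[pp$hit_chrom]], pp$hit_pos,
                pp$hit_pos + nchar(gseq) - 1L)
  oc <- oracle_global_align(gseq, hit)
  expect_equal(pp$identity, oc$identity, tolerance = 0.5)
  # a gene with no homolog in the target reports no family member
  none <- paralog_presence(c(fake = rand_seq(600)), fx$smp$hap1)
  expect_false(none$family_present)
})
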