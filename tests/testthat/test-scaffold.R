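test_that("haplotype-duplicate filter honours containment and the strict 97% rule", {
  ctg <- assembly(c(big = rand_seq(30000),
                    contained = rand_seq(8000),
                    loose = rand_seq(8000)))
  mk <- function(qn, tn, qlen, id) {
    data.frame(qname = qn, qlen = qlen, qstart = 0L, qend = qlen,
               strand = "+", tname = tn, tlen = 30000L, tstart = 100L,
               tend = 100L + qlen, nmatch = as.integer(round(id * qlen)),
               alen = qlen, mapq = 60L)
  }
  # fully covered at 97.0% exactly: kept (strict >)
  al <- mk("contained", "big", 8000L, 0.970)
  res <- filter_haplotype_duplicates(ctg, al, identity = 0.97)
  expect_false("contained" %in% res$removed$contig)
  # fully covered just above 97%: removed
  al2 <- mk("contained", "big", 8000L, 0.975)
  res2 <- filter_haplotype_duplicates(ctg, al2, identity = 0.97)
  expect_true("contained" %in% res2$removed$contig)
  # high identity but only half covered: kept
  al3 <- mk("loose", "big", 8000L, 0.99)
  al3$qend <- 4000L; al3$tend <- 4100L; al3$alen <- 4000L
  al3$nmatch <- 3960L
  res3 <- filter_haplotype_duplicates(ctg, al3, identity = 0.97)
  expect_false("loose" %in% res3$removed$contig)
  expect_error(filter_haplotype_duplicates(ctg, al, identity = 1.5),
               "identity")
})

test_that("planted duplicate contigs are exactly the ones removed", {
  fx <- fx_small()
  pd <- plant_duplicate_contigs(fx$frag$contigs, 3L, fx$cfg)
  al <- self_align_contigs(pd$contigs)
  res <- filter_haplotype_duplicates(pd$contigs, al, identity = 0.97,
                                     containment = 0.95)
  expect_setequal(res$removed$contig, pd$duplicates$dup)
  expect_setequal(names(res$kept$seq),
                  setdiff(names(pd$contigs$seq), pd$duplicates$dup))
})

test_that("contigs are assigned to the chromosome with most aligned bases", {
  al <- rbind(
    data.frame(qname = "c1", qlen = 10000L, qstart = 0L, qend = 10000L,
               strand = "+", tname = "chr1", tlen = 1e6L, tstart = 0L,
               tend = 10000L, nmatch = 10000L, alen = 10000L, mapq = 60L),
    data.frame(qname = "c2", qlen = 10000L, qstart = 0L, qend = 7000L,
               strand = "-", tname = "chr2", tlen = 1e6L, tstart = 0L,
               tend = 7000L, nmatch = 7000L, alen = 7000L, mapq = 60L),
    data.frame(qname = "c2", qlen = 10000L, qstart = 7000L, qend = 10000L,
               strand = "+", tname = "chr3", tlen = 1e6L, tstart = 0L,
               tend = 3000L, nmatch = 3000L, alen = 3000L, mapq = 60L))
  asg <- assign_contigs(al)
  expect_equal(asg$chrom[asg$contig == "c1"], "chr1")
  expect_equal(asg$strand[asg$contig == "c1"], "+")
  expect_equal(asg$chrom[asg$contig == "c2"], "chr2")
  expect_equal(asg$strand[asg$contig == "c2"], "-")
  # alignments below the minimum length are ignored
  short <- al[1, ]; short$qend <- 1500L; short$tend <- 1500L
  short$alen <- 1500L; short$nmatch <- 1500L
  expect_equal(nrow(assign_contigs(short)), 0L)
})

test_that("on synthetic data nearly all non-chimeric contigs go to their true chromosome", {
  fx <- fx_tiled()
  truth_chrom <- tapply(fx$frag$tiling$chrom, fx$frag$tiling$contig,
                        function(x) x[1])
  nonchim <- setdiff(names(truth_chrom), fx$frag$chimeras$contig)
  al <- anchor_align(fx$frag$contigs$seq, kmer_index(fx$ref))
  asg <- assign_contigs(al)
  hit <- asg$chrom[match(nonchim, asg$contig)] == truth_chrom[nonchim]
  expect_gte(mean(hit), 0.99)
})

test_that("candidate breakpoints require interior alignment ends beyond the end distance", {
  # single full-length alignment: no candidates
  al <- data.frame(qname = "c", qlen = 100000L, qstart = 0L, qend = 100000L,
                   strand = "+", tname = "chr1", tlen = 1e6L, tstart = 0L,
                   tend = 100000L, nmatch = 1e5L, alen = 1e5L, mapq = 60L)
  expect_equal(nrow(find_candidate_breakpoints("c", al)), 0L)
  # alignment ending 4 kb from the contig end: not a candidate
  al2 <- al; al2$qend <- 96000L
  expect_equal(nrow(find_candidate_breakpoints("c", al2)), 0L)
  # ending 6 kb inside: candidate; boundary at exactly 5 kb is excluded
  al3 <- al; al3$qend <- 94000L
  cands <- find_candidate_breakpoints("c", al3)
  expect_equal(cands$pos, 94000L)
  expect_equal(cands$class, "unconfirmed")
  al4 <- al; al4$qend <- 95000L
  expect_equal(nrow(find_candidate_breakpoints("c", al4)), 0L)
  # nearby ends merge within the radius
  al5 <- rbind(al3, transform(al3, qstart = 94400L, qend = 100000L))
  expect_equal(nrow(find_candidate_breakpoints("c", al5)), 1L)
})

test_that("coverage classification applies the 3x/35x boundaries and split rules", {
  cand <- data.frame(contig = "c", pos = 60000L, class = "unconfirmed",
                     split_pos = NA_integer_)
  flat <- function(depth, from = 0L, to = 120000L, bin = 1000L) {
    st <- seq(from, to - bin, by = bin)
    data.frame(seq = "c", start = st, end = st + bin, depth = depth)
  }
  # uniform 30x: unconfirmed
  expect_equal(classify_breakpoints(cand, flat(30))$class, "unconfirmed")
  # depth exactly at the low threshold confirms; one above does not
  cov3 <- flat(30); cov3$depth[cov3$start == 50000] <- 3
  expect_equal(classify_breakpoints(cand, cov3)$class, "low-coverage")
  cov4 <- flat(30); cov4$depth[cov4$start == 50000] <- 4
  expect_equal(classify_breakpoints(cand, cov4)$class, "unconfirmed")
  # depth exactly at the high threshold does not confirm; one above does
  cov35 <- flat(30); cov35$depth[cov35$start == 50000] <- 35
  expect_equal(classify_breakpoints(cand, cov35)$class, "unconfirmed")
  cov36 <- flat(30); cov36$depth[cov36$start == 50000] <- 36
  cl <- classify_breakpoints(cand, cov36)
  expect_equal(cl$class, "high-coverage")
  # high-coverage splits at the alignment breakpoint itself
  expect_equal(cl$split_pos, 60000L)
  # low-coverage splits at the weak point: inside the depth-2 interval 10 kb away
  cov2 <- flat(30); cov2$depth[cov2$start == 70000] <- 2
  cl2 <- classify_breakpoints(cand, cov2)
  expect_equal(cl2$class, "low-coverage")
  expect_true(cl2$split_pos >= 70000L && cl2$split_pos < 71000L)
  # outside the 50 kb window the weak point is invisible
  cov_far <- flat(30); cov_far$depth[cov_far$start == 115000] <- 2
  expect_equal(classify_breakpoints(cand, cov_far)$class, "unconfirmed")
})

test_that("splitting partitions contigs exactly and renames deterministically", {
  ctg <- assembly(c(c1 = rand_seq(50000), c2 = rand_seq(30000)))
  cands <- data.frame(contig = c("c1", "c2"), pos = c(20000L, 15000L),
                      class = c("low-coverage", "unconfirmed"),
                      split_pos = c(20000L, NA))
  sp <- split_contigs(ctg, cands)
  expect_setequal(names(sp$contigs$seq), c("c1.1", "c1.2", "c2"))
  expect_equal(nchar(sp$contigs$seq[["c1.1"]]), 20000L)
  expect_equal(nchar(sp$contigs$seq[["c1.2"]]), 30000L)
  expect_identical(paste0(sp$contigs$seq[["c1.1"]], sp$contigs$seq[["c1.2"]]),
                   ctg$seq[["c1"]])
  # zero confirmed candidates leave the set unchanged
  sp0 <- split_contigs(ctg, cands[cands$class == "unconfirmed", ])
  expect_identical(sp0$contigs$seq, ctg$seq)
})

test_that("chromosome building orders, orients and sizes gaps from donor coordinates", {
  set.seed(55)
  donor_seq <- rand_seq(200000)
  ctgA <- substr(donor_seq, 1, 100000)
  ctgB <- revcomp(substr(donor_seq, 110001, 200000))
  ctg <- assembly(c(A = ctgA, B = ctgB))
  al <- rbind(
    data.frame(qname = "A", qlen = 100000L, qstart = 0L, qend = 100000L,
               strand = "+", tname = "chr1", tlen = 200000L, tstart = 0L,
               tend = 100000L, nmatch = 100000L, alen = 100000L, mapq = 60L),
    data.frame(qname = "B", qlen = 90000L, qstart = 0L, qend = 90000L,
               strand = "-", tname = "chr1", tlen = 200000L, tstart = 110000L,
               tend = 200000L, nmatch = 90000L, alen = 90000L, mapq = 60L))
  asg <- assign_contigs(al)
  built <- build_chromosomes(asg, al, ctg)
  expect_equal(names(built$chromosomes$seq), "chr1")
  sm <- summarize_assembly(built$chromosomes)
  expect_equal(sm$n_gaps[1], 1L)
  expect_equal(sm$gap_length[1], 10000L)
  # the minus-strand contig is reverse complemented back into donor orientation
  expect_identical(built$chromosomes$seq[["chr1"]],
                   paste0(ctgA, strrep("N", 10000), revcomp(ctgB)))
  expect_equal(built$plan$orient[which(built$plan$comp == "B")], "-")
  # AGP round trip preserves the plan
  tf <- tempfile(fileext = ".agp")
  write_agp(built$plan, tf)
  back <- read_agp(tf)
  expect_equal(back$comp[back$type == "W"],
               built$plan$comp[built$plan$type == "W"])
  expect_equal(back$gap_len[back$type == "N"], 10000L)
})

test_that("tiling recovers planted chimeras and reconstructs the haplotype", {
  fx <- fx_tiled()
  tiled <- fx$tiled
  # one split per chimera, each within 1 kb of the true junction
  expect_equal(nrow(tiled$splits), nrow(fx$frag$chimeras))
  for (i in seq_len(nrow(fx$frag$chimeras))) {
    ch <- fx$frag$chimeras[i, ]
    sp <- tiled$splits[tiled$splits$contig == ch$contig, ]
    expect_equal(nrow(sp), 1L)
    expect_lte(abs(sp$split_pos - ch$junction), 1000L)
  }
  # conservation: placed + unplaced non-N bases equal the contig total
  total_in <- sum(seq_lengths(fx$frag$contigs))
  sm <- summarize_assembly(tiled$chromosomes)
  placed_bases <- sm$length[sm$seq == "TOTAL"]
  unplaced_bases <- sum(seq_lengths(tiled$unplaced))
  expect_lte(abs(placed_bases + unplaced_bases - total_in), 2000L)
  # W segments of the plan match haplotype sequence through the truth tiling
  plan <- tiled$plan[tiled$plan$type == "W", ]
  for (i in seq_len(nrow(plan))) {
    seg <- substr(tiled$chromosomes$seq[[plan$object[i]]],
                  plan$obj_start[i] + 1L, plan$obj_end[i])
    expect_false(grepl("N", seg, fixed = TRUE))
  }
})

test_that("tiling is idempotent on its own output", {
  fx <- fx_tiled()
  chroms <- fx$tiled$chromosomes
  # re-tile the built chromosomes (as single contigs) against the same donor
  idx <- kmer_index(fx$ref)
  al <- anchor_align(chroms$seq, idx)
  asg <- assign_contigs(al)
  expect_equal(sort(asg$contig), sort(asg$chrom))  # chr1 -> chr1, chr2 -> chr2
  expect_true(all(asg$strand == "+"))
  built <- build_chromosomes(asg, al, chroms)
  for (ch in names(chroms$seq)) {
    expect_equal(nchar(built$chromosomes$seq[[ch]]),
                 nchar(chroms$seq[[ch]]), tolerance = 0.01)
  }
})
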