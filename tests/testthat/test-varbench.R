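test_that("variant normalization trims and left-aligns representations", {
  g <- assembly(c(c1 = "TTTACCCCGTT"))
  # CCG>C del written right-shifted inside the C homopolymer
  a <- normalize_variants(data.frame(chrom = "c1", pos = 6L, ref = "CCG",
                                     alt = "C"), g)
  b <- normalize_variants(data.frame(chrom = "c1", pos = 4L, ref = "ACC",
                                     alt = "A"), g)
  # shared suffix first: CCG>C has no shared suffix; ACC>A is already minimal
  expect_equal(b$pos, 4L); expect_equal(b$ref, "ACC")
  # identical SNV representations stay put
  s <- normalize_variants(data.frame(chrom = "c1", pos = 5L, ref = "C",
                                     alt = "G"), g)
  expect_equal(s$pos, 5L)
})

test_that("calls match the benchmark by position and alleles within regions", {
  bench <- data.frame(chrom = "chr1", pos = c(100L, 300L, 500L),
                      ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                      gt = c("1/1", "0/1", "1/1"))
  regions <- data.frame(chrom = "chr1", start = 0L, end = 400L)
  calls <- data.frame(chrom = "chr1", pos = c(100L, 300L, 500L, 350L),
                      ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                      gt = "1/1")
  cmp <- compare_small_variants(calls, bench, regions)
  # hom call matching hom benchmark is a TP
  expect_equal(cmp$n_tp, 1L)
  # allele match with het benchmark genotype is a genotype-mismatch FP
  expect_true(any(cmp$fp$pos == 300L & cmp$fp$gt_mismatch))
  # plain error is an FP without genotype flag
  expect_true(any(cmp$fp$pos == 350L & !cmp$fp$gt_mismatch))
  # call outside the regions is ignored entirely
  expect_false(500L %in% c(cmp$tp$pos, cmp$fp$pos))
  expect_equal(cmp$n_fp, 2L)
})

test_that("modified FP filter applies the 30 bp, genotype and region rules", {
  bench <- data.frame(chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
                      gt = "0/1")
  excl <- data.frame(chrom = "chr1", start = 5000L, end = 17000L)
  fp <- data.frame(chrom = "chr1",
                   pos = c(1000L, 1029L, 1031L, 1030L, 6000L, 2000L),
                   ref = "C", alt = "T", gt = "1/1",
                   gt_mismatch = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                   bench_gt = c("0/1", NA, NA, NA, NA, NA))
  part <- modified_fp_filter(fp, bench, proximity = 30L, excluded = excl)
  # het-genotype mismatch excluded first
  expect_equal(part$fp_gt$pos, 1000L)
  # 29 bp away: excluded; 30 bp: excluded; 31 bp: retained
  expect_true(1029L %in% part$fp_al$pos)
  expect_true(1030L %in% part$fp_al$pos)
  expect_false(1031L %in% part$fp_al$pos)
  # inside the >10 kb excluded interval: excluded
  expect_true(6000L %in% part$fp_region$pos)
  # the remainder is the error estimate, and the buckets partition raw FP
  expect_setequal(part$modified$pos, c(1031L, 2000L))
  expect_equal(sum(part$counts), nrow(fp))
})

test_that("QV follows the closed form with a capped zero-FP case", {
  expect_equal(compute_qv(1, 1e6)$qv, 60, tolerance = 1e-9)
  expect_equal(compute_qv(10, 1e6)$qv, 50, tolerance = 1e-9)
  z <- compute_qv(0, 1e6)
  expect_equal(z$qv, 90)
  expect_true(z$capped)
  # doubling the region size adds 10*log10(2)
  expect_equal(compute_qv(7, 2e6)$qv - compute_qv(7, 1e6)$qv, 10 * log10(2),
               tolerance = 1e-9)
  expect_error(compute_qv(-1, 1e6))
  expect_error(compute_qv(1, 0))
})

test_that("raw FP partitions exactly on planted errors and QV matches closed form", {
  b <- fx_bench()
  cmp <- compare_small_variants(b$calls, b$bench, b$regions)
  part <- modified_fp_filter(cmp$fp, b$bench, excluded = b$excl)
  expect_equal(sum(part$counts), cmp$n_fp)
  # modified FPs are exactly the planted errors that are clean of variants
  # and outside excluded regions (generator truth)
  clean <- b$pe$planted[!b$pe$planted$near & !b$pe$planted$in_excluded, ]
  expect_equal(part$counts[["modified"]], nrow(clean))
  expect_setequal(part$modified$pos, clean$pos0 + 1L)
  rs <- sum(b$regions$end - b$regions$start)
  res <- benchmark_result(cmp, part, rs)
  expect_equal(res$qv, -10 * log10(nrow(clean) / rs), tolerance = 1e-9)
})

test_that("corrections restore the haplotype and re-benchmarking reaches zero FP", {
  b <- fx_bench()
  cmp <- compare_small_variants(b$calls, b$bench, b$regions)
  part <- modified_fp_filter(cmp$fp, b$bench, excluded = b$excl)
  loc <- locate_calls(part$modified, b$fx$ref, b$pe$assembly)
  expect_true(all(!is.na(loc$asm_pos)))
  corr <- apply_corrections(b$pe$assembly, loc)
  expect_equal(nrow(corr$log), nrow(loc))
  # re-deriving calls without the corrected errors yields zero modified FP
  remaining <- b$pe$planted[b$pe$planted$near | b$pe$planted$in_excluded, ]
  calls2 <- consensus_calls(b$fx$ref, b$fx$smp$truth, remaining)
  cmp2 <- compare_small_variants(calls2, b$bench, b$regions)
  part2 <- modified_fp_filter(cmp2$fp, b$bench, excluded = b$excl)
  expect_equal(part2$counts[["modified"]], 0L)
  # sequence-level check: corrected assembly equals the haplotype rebuilt
  # with only the uncorrectable errors
  hap_expect <- b$fx$smp$hap1$seq
  for (ch in names(hap_expect)) {
    pp <- remaining[remaining$chrom == ch, , drop = FALSE]
    if (nrow(pp) == 0L) next
    ap <- truth_lift(b$fx$smp$truth, ch, pp$pos0, hap = 1L)
    ed <- data.frame(chrom = ap$chrom,
                     start0 = ifelse(pp$type == "sub", ap$pos0, ap$pos0 + 1L),
                     end0 = ifelse(pp$type == "sub", ap$pos0 + 1L,
                                   ifelse(pp$type == "del",
                                          ap$pos0 + 1L + pp$len, ap$pos0 + 1L)),
                     alt = ifelse(pp$type == "del", "", pp$seq))
    for (tch in unique(ed$chrom)) {
      hap_expect[[tch]] <- refcurate:::apply_edit_table(
        hap_expect[[tch]], ed[ed$chrom == tch, , drop = FALSE])
    }
  }
  for (ch in names(hap_expect)) {
    expect_identical(corr$assembly$seq[[ch]], hap_expect[[ch]])
  }
})

test_that("a single substitution correction changes exactly one base", {
  x <- assembly(c(c1 = "AAAAAAAAAA"))
  fp <- data.frame(chrom = "c1", pos = 5L, ref = "C", alt = "A", gt = "1/1",
                   asm_chrom = "c1", asm_pos = 5L)
  corr <- apply_corrections(x, fp)
  expect_identical(corr$assembly$seq[["c1"]], "AAAACAAAAA")
  expect_equal(nrow(corr$log), 1L)
  expect_equal(corr$log$type, "substitution")
})

test_that("SV presence detects planted insertions and deletions by zygosity", {
  fx <- fx_small()
  svt <- truth_sv_table(fx$smp$truth)
  res <- sv_presence(svt, fx$smp$hap1, fx$ref)
  # every SV carried by hap1 is present; every SV only on hap2 is absent
  on1 <- res[res$hap1 == 1L, ]
  off1 <- res[res$hap1 == 0L, ]
  expect_true(all(on1$status == "present"))
  expect_true(all(off1$status == "absent"))
  expect_true(all(res$status[res$zygosity == "hom"] == "present"))
})

test_that("an SV inside a long tandem duplication is flagged ambiguous", {
  set.seed(66)
  unit <- rand_seq(1500)
  donor <- assembly(c(chrD = paste0(rand_seq(3000), unit, unit,
                                    rand_seq(3000))))
  x <- assembly(c(chrD = donor$seq[["chrD"]]))
  sv <- data.frame(chrom = "chrD", pos = 3700L, type = "del", len = 60L,
                   seq = "")
  res <- sv_presence(sv, x, donor, flank = 1000L)
  expect_true(res$status %in% c("ambiguous", "absent"))
})
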