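test_that("site selection applies the count, frequency and single-base rules", {
  sites <- data.frame(chrom = "chr1", pos = 1:7,
                      ref = c("A", "A", "A", "AT", "A", "A", "A"),
                      alt = c("G", "G", "G", "GC", "GT", "A", "G"),
                      af = c(0.6, 0.6, 0.5, 0.8, 0.7, 0.9, NA),
                      an = c(200L, 150L, 300L, 400L, 500L, 600L, 700L))
  sel <- select_sites(sites)
  # row 1 passes; 150 individuals fails the minimum of 200; AF exactly 0.5
  # fails the strict threshold; multi-base rows fail; major==ref fails; NA AF
  # fails
  expect_equal(sel$pos, 1L)
  expect_equal(sel$major, "G")
  # count exactly at 200 is kept (inclusive minimum)
  expect_true(200L %in% sel$an)
})

test_that("sites in unique regions map exactly; repeats stay unmapped", {
  set.seed(71)
  unit <- rand_seq(5000)
  donor <- assembly(c(chrD = paste0(rand_seq(8000), unit, rand_seq(4000),
                                    unit, rand_seq(8000))))
  x <- assembly(c(chrD = donor$seq[["chrD"]]))
  sites <- data.frame(chrom = "chrD",
                      pos = c(4000L, 10500L),  # unique; inside the repeat
                      ref = "A", alt = "G", af = 0.8, an = 500L)
  sites$ref <- substr(donor$seq[["chrD"]], sites$pos, sites$pos)
  sites$alt <- vapply(sites$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  sel <- select_sites(sites)
  mp <- map_sites(sel, donor, x)
  expect_equal(mp$mapped$pos, 4000L)
  expect_equal(mp$mapped$asm_pos, 4000L)
  expect_equal(mp$unmapped$pos, 10500L)
})

test_that("the span and identity filters drop deficient windows", {
  set.seed(72)
  donor <- assembly(c(chrD = rand_seq(20000)))
  # a site near the sequence start truncates the window below 1980 bases
  x <- assembly(c(chrD = donor$seq[["chrD"]]))
  edge <- data.frame(chrom = "chrD", pos = 970L, ref = "A", alt = "G",
                     af = 0.8, an = 500L)
  edge$ref <- substr(donor$seq[["chrD"]], 970, 970)
  edge$alt <- sample(setdiff(c("A", "C", "G", "T"), edge$ref), 1)
  sel <- select_sites(edge)
  mp <- map_sites(sel, donor, x)
  expect_equal(mp$n_mapped, 0L)
  expect_equal(mp$unmapped$reason, "span")
  # relaxing the span threshold to the window size maps the site exactly
  mp2 <- map_sites(sel, donor, x, min_span = 1900L)
  expect_equal(mp2$n_mapped, 1L)
  expect_equal(mp2$mapped$asm_pos, 970L)
  # a 100 bp deletion inside the window drives identity below 99%: dropped
  xd <- assembly(c(chrD = paste0(substr(donor$seq[["chrD"]], 1, 9500),
                                 substr(donor$seq[["chrD"]], 9601, 20000))))
  mid <- data.frame(chrom = "chrD", pos = 10000L, ref = "A", alt = "G",
                    af = 0.8, an = 500L)
  mid$ref <- substr(donor$seq[["chrD"]], 10000, 10000)
  mid$alt <- sample(setdiff(c("A", "C", "G", "T"), mid$ref), 1)
  mpd <- map_sites(select_sites(mid), donor, xd)
  expect_equal(mpd$n_mapped, 0L)
  # with both filters relaxed the site maps, shifted by the deletion
  mpd2 <- map_sites(select_sites(mid), donor, xd, min_span = 1800L,
                    min_identity = 90)
  expect_equal(mpd2$n_mapped, 1L)
  expect_equal(mpd2$mapped$asm_pos, 9900L)
})

test_that("on synthetic data mapped sites land on their truth coordinates", {
  fx <- fx_small()
  sites <- simulate_population_sites(fx$ref, fx$smp$truth, fx$cfg)
  sel <- select_sites(sites)
  mp <- map_sites(sel, fx$ref, fx$smp$hap1)
  expect_gte(mp$n_mapped / nrow(sel), 0.85)
  m <- mp$mapped
  ok <- logical(nrow(m))
  for (ch in unique(m$chrom)) {
    s2 <- m$chrom == ch
    lf <- truth_lift(fx$smp$truth, ch, m$pos[s2] - 1L, hap = 1L)
    ok[s2] <- !is.na(lf$pos0) & lf$pos0 + 1L == m$asm_pos[s2] &
      lf$chrom == m$asm_chrom[s2]
  }
  expect_gte(mean(ok), 0.95)
})

test_that("classification and replacement follow the genotype fidelity rule", {
  x <- assembly(c(c1 = "AAAAAAAAAA"))
  gt <- data.frame(chrom = "chrD", pos = c(2L, 4L, 6L),
                   ref = c("A", "A", "A"), alt = c("G", "G", "G"),
                   gt = c("1/1", "0/1", "0/0"))
  mk_site <- function(pos, asm_allele, major) {
    data.frame(chrom = "chrD", pos = pos, ref = "A", alt = major, af = 0.8,
               an = 500L, major = major, asm_chrom = "c1", asm_pos = pos,
               asm_allele = asm_allele, strand = "+")
  }
  # (a) assembly already carries the major allele
  # (b) assembly has the donor allele, genotype het containing major: edited
  # (c) genotype hom-reference: left unchanged
  # (d) assembly carries a third allele
  mapped <- rbind(mk_site(2L, "G", "G"), mk_site(4L, "A", "G"),
                  mk_site(6L, "A", "G"), mk_site(8L, "T", "G"))
  x2 <- assembly(c(c1 = "AGAAAAATAA"))  # bases at sites: G,A,A,T
  res <- classify_and_replace(mapped, x2, gt)
  expect_equal(res$sites$class, c("matched", "replaced", "reference_match",
                                  "third_allele"))
  expect_equal(nrow(res$edits), 1L)
  expect_equal(res$edits$asm_pos, 4L)
  expect_identical(substr(res$assembly$seq[["c1"]], 4, 4), "G")
  # only replacements toward the major allele at genotype-supported sites
  expect_identical(substr(res$assembly$seq[["c1"]], 6, 6), "A")
  expect_identical(substr(res$assembly$seq[["c1"]], 8, 8), "T")
})

test_that("harmonization is idempotent and bins partition the mapped sites", {
  fx <- fx_small()
  sites <- simulate_population_sites(fx$ref, fx$smp$truth, fx$cfg)
  sel <- select_sites(sites)
  mp <- map_sites(sel, fx$ref, fx$smp$hap1)
  harm <- classify_and_replace(mp$mapped, fx$smp$hap1, benchmark_vcf(fx$smp$truth))
  # all sites where the genotype contains the major allele now carry it
  again <- map_sites(sel, fx$ref, harm$assembly)
  h2 <- classify_and_replace(again$mapped, harm$assembly,
                             benchmark_vcf(fx$smp$truth))
  expect_equal(nrow(h2$edits), 0L)
  expect_equal(sum(h2$sites$class == "replaced"), 0L)
  # accounting buckets partition the mapped sites
  expect_equal(sum(harm$accounting$count), nrow(mp$mapped))
  binned <- af_binned_report(harm$sites)
  expect_equal(sum(binned$n_sites), nrow(harm$sites))
  expect_true(all(binned$prop_matched >= 0 & binned$prop_matched <= 1,
                  na.rm = TRUE))
})
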