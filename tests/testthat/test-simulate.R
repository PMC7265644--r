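test_that("identical seed and config give byte-identical outputs", {
  cfg <- sim_config(seed = 21L, chrom_len = 60000L, snv_count = 50L,
                    sv_count = 6L, n_genes = 4L, chimera_count = 1L,
                    withheld_count = 1L)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$seq, r2$seq)
  s1 <- simulate_sample(r1, cfg)
  s2 <- simulate_sample(r2, cfg)
  expect_identical(s1$hap1$seq, s2$hap1$seq)
  expect_identical(s1$truth$variants, s2$truth$variants)
  f1 <- fragment_assembly(s1$hap1, cfg, reference = r1)
  f2 <- fragment_assembly(s2$hap1, cfg, reference = r2)
  expect_identical(f1$contigs$seq, f2$contigs$seq)
  # and FASTA bytes agree
  t1 <- tempfile(); t2 <- tempfile()
  write_fasta(r1, t1); write_fasta(r2, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("reference has the configured shape and repeat-free option holds", {
  cfg <- sim_config(seed = 22L, n_chrom = 2L, chrom_len = 50000L,
                    repeat_count = 0L, n_genes = 0L, gene_subtel = 0L,
                    transloc_pairs = 0L, paralog_gene = FALSE,
                    delete_gene = FALSE, truncate_gene = FALSE)
  ref <- simulate_reference(cfg)
  expect_equal(length(ref$seq), 2L)
  expect_equal(unname(seq_lengths(ref)), c(50000L, 50000L))
  # with no planted repeats, no 31-mer occurs twice (exhaustive count)
  for (ch in names(ref$seq)) {
    km <- substring(ref$seq[[ch]], 1:(50000 - 30), 31:50000)
    expect_false(any(duplicated(km)))
  }
})

test_that("requested SNV count appears exactly in the truth set", {
  cfg <- sim_config(seed = 23L, chrom_len = 80000L, snv_count = 100L,
                    indel_count = 0L, sv_count = 0L, n_genes = 2L,
                    chimera_count = 0L, delete_gene = FALSE,
                    truncate_gene = FALSE)
  smp <- simulate_sample(simulate_reference(cfg), cfg)
  expect_equal(sum(smp$truth$variants$type == "snv"), 100L)
  # every variant is carried by at least one haplotype
  expect_true(all(smp$truth$variants$hap1 + smp$truth$variants$hap2 >= 1L))
})

test_that("no structural variant is shorter than 50 bp", {
  fx <- fx_small()
  sv <- truth_sv_table(fx$smp$truth)
  expect_true(all(sv$len >= 50L))
  expect_true(all(sv$zygosity %in% c("hom", "het")))
})

test_that("homozygous truth SNVs appear in both haplotypes at lifted positions", {
  fx <- fx_small()
  v <- fx$smp$truth$variants
  hom <- v[v$type == "snv" & v$hap1 == 1L & v$hap2 == 1L, ]
  hom <- hom[seq_len(min(nrow(hom), 40L)), ]
  for (h in 1:2) {
    hap <- if (h == 1) fx$smp$hap1 else fx$smp$hap2
    for (i in seq_len(nrow(hom))) {
      lf <- truth_lift(fx$smp$truth, hom$chrom[i], hom$pos[i] - 1L, hap = h)
      expect_equal(substr(hap$seq[[lf$chrom]], lf$pos0 + 1L, lf$pos0 + 1L),
                   hom$alt[i])
    }
  }
})

test_that("applying the truth edit tables to the donor reproduces each haplotype", {
  fx <- fx_small()
  tr <- fx$smp$truth$translocations
  for (h in 1:2) {
    et <- fx$smp$truth$edits[[h]]
    hap <- if (h == 1) fx$smp$hap1 else fx$smp$hap2
    built <- lapply(names(fx$ref$seq), function(ch) {
      refcurate:::apply_edit_table(fx$ref$seq[[ch]],
                                   et[et$chrom == ch, , drop = FALSE])
    })
    names(built) <- names(fx$ref$seq)
    # re-apply the reciprocal terminal exchange
    for (i in seq_len(nrow(tr))) {
      a <- tr$chrom_a[i]; b <- tr$chrom_b[i]; sl <- tr$seg_len[i]
      ta <- substr(built[[a]], nchar(built[[a]]) - sl + 1L, nchar(built[[a]]))
      tb <- substr(built[[b]], nchar(built[[b]]) - sl + 1L, nchar(built[[b]]))
      built[[a]] <- paste0(substr(built[[a]], 1L, nchar(built[[a]]) - sl), tb)
      built[[b]] <- paste0(substr(built[[b]], 1L, nchar(built[[b]]) - sl), ta)
    }
    for (ch in names(built)) expect_identical(built[[ch]], hap$seq[[ch]])
  }
})

test_that("fragmentation conserves sequence and records truth faithfully", {
  fx <- fx_small()
  frag <- fx$frag
  hap_total <- sum(seq_lengths(fx$smp$hap1))
  withheld_total <- sum(frag$withheld$end - frag$withheld$start)
  expect_equal(sum(seq_lengths(frag$contigs)), hap_total - withheld_total)
  # every tiling segment matches its haplotype slice exactly
  for (i in seq_len(nrow(frag$tiling))) {
    r <- frag$tiling[i, ]
    cs <- substr(frag$contigs$seq[[r$contig]], r$contig_start + 1L, r$contig_end)
    hs <- substr(fx$smp$hap1$seq[[r$chrom]], r$hap_start + 1L, r$hap_end)
    if (r$orient == "-") hs <- revcomp(hs)
    expect_identical(cs, hs)
  }
  # every chimeric junction joins segments from different chromosomes
  for (i in seq_len(nrow(frag$chimeras))) {
    expect_true(frag$chimeras$chrom_a[i] != frag$chimeras$chrom_b[i])
  }
})

test_that("chimera-free fragmentation has an empty chimera list", {
  cfg <- sim_config(seed = 24L, chrom_len = 120000L, chimera_count = 0L,
                    withheld_count = 1L, n_genes = 2L)
  ref <- simulate_reference(cfg)
  smp <- simulate_sample(ref, cfg)
  frag <- fragment_assembly(smp$hap1, cfg, reference = ref)
  expect_equal(nrow(frag$chimeras), 0L)
})

test_that("coverage tracks tile contigs exactly with dropout at junctions", {
  fx <- fx_small()
  cov <- fx$cov
  for (nm in names(fx$frag$contigs$seq)) {
    cc <- cov[cov$seq == nm, ]
    cc <- cc[order(cc$start), ]
    expect_equal(cc$start[1], 0L)
    expect_equal(cc$end[nrow(cc)], nchar(fx$frag$contigs$seq[[nm]]))
    expect_true(all(cc$start[-1] == cc$end[-nrow(cc)]))
  }
  # uniform depth away from junctions, dropout at junctions
  expect_true(all(cov$depth >= fx$cfg$dropout_depth))
  jitter_ok <- cov$depth >= fx$cfg$cov_mean - fx$cfg$cov_jitter
  for (i in seq_len(nrow(fx$frag$chimeras))) {
    ch <- fx$frag$chimeras[i, ]
    cc <- cov[cov$seq == ch$contig, ]
    near <- cc[cc$end > ch$junction - 500 & cc$start < ch$junction + 500, ]
    expect_true(all(near$depth <= fx$cfg$dropout_depth))
  }
  clean <- fx$frag$contigs$seq[!names(fx$frag$contigs$seq) %in%
                                 fx$frag$chimeras$contig]
  cc <- cov[cov$seq %in% names(clean), ]
  expect_true(all(cc$depth >= fx$cfg$cov_mean - fx$cfg$cov_jitter))
})

test_that("population site table exercises all selection filters", {
  fx <- fx_small()
  sites <- simulate_population_sites(fx$ref, fx$smp$truth, fx$cfg)
  expect_true(all(sites$af >= 0 & sites$af <= 1))
  expect_equal(sum(sites$an < 200), fx$cfg$pop_low_count_rows)
  expect_equal(sum(nchar(sites$ref) > 1L), fx$cfg$pop_multibase_rows)
  # variant-derived rows: REF is the donor base at that position
  for (i in sample(nrow(sites), 30)) {
    expect_equal(toupper(substr(fx$ref$seq[[sites$chrom[i]]], sites$pos[i],
                                sites$pos[i] + nchar(sites$ref[i]) - 1L)),
                 toupper(sites$ref[i]))
  }
})

test_that("major allele concordance with the sample follows the site frequency", {
  # pool several seeds: among truth-derived sites, P(major == sample alt) = AF
  tot <- 0L; conc <- 0L; af_sum <- 0
  for (sd in 31:33) {
    cfg <- sim_config(seed = sd, chrom_len = 150000L, snv_count = 400L,
                      n_genes = 2L, chimera_count = 0L)
    ref <- simulate_reference(cfg)
    smp <- simulate_sample(ref, cfg)
    sites <- simulate_population_sites(ref, smp$truth, cfg)
    v <- smp$truth$variants[smp$truth$variants$type == "snv", ]
    key <- paste(v$chrom, v$pos)
    m <- match(paste(sites$chrom, sites$pos), key)
    hit <- !is.na(m)
    tot <- tot + sum(hit)
    conc <- conc + sum(sites$alt[hit] == v$alt[m[hit]])
    af_sum <- af_sum + sum(v$af[m[hit]])
  }
  expect_equal(conc / tot, af_sum / tot, tolerance = 0.06)
})

test_that("annotation truth labels agree with a brute-force codon-walk oracle", {
  fx <- fx_annot()
  ann <- fx$ann
  src_tx <- extract_transcript_sequences(fx$ref, ann$source)
  smp_tx <- extract_transcript_sequences(fx$smp$hap1, ann$sample)
  v <- fx$smp$truth$variants
  for (i in seq_len(nrow(ann$consequences))) {
    tid <- ann$consequences$transcript[i]
    truth_cat <- ann$consequences$category[i]
    if (truth_cat %in% c("unmapped", "truncated")) next
    cds_feats <- ann$source[ann$source$type == "CDS" &
                              !is.na(ann$source$Parent) &
                              ann$source$Parent == tid, ]
    ch <- cds_feats$seqid[1]
    vv <- v[v$chrom == ch & v$hap1 == 1L &
              v$type %in% c("ins", "del", "sv_ins", "sv_del"), ]
    in_cds <- vapply(seq_len(nrow(vv)), function(j)
      any(vv$pos[j] >= cds_feats$start &
            vv$pos[j] + nchar(vv$ref[j]) - 1L <= cds_feats$end), logical(1))
    types <- ifelse(vv$type[in_cds] %in% c("ins", "sv_ins"), "ins", "del")
    oc <- oracle_consequence(src_tx$cds[[tid]], smp_tx$cds[[tid]],
                             types, vv$len[in_cds])
    expect_equal(truth_cat, oc, label = tid)
  }
})

test_that("gene placed in a variant-free region is labelled identical", {
  cfg <- sim_config(seed = 25L, chrom_len = 100000L, snv_count = 0L,
                    indel_count = 0L, sv_count = 0L, n_genes = 3L,
                    delete_gene = FALSE, truncate_gene = FALSE,
                    paralog_gene = FALSE, chimera_count = 0L)
  ref <- simulate_reference(cfg)
  smp <- simulate_sample(ref, cfg)
  ann <- simulate_annotation(ref, smp$truth, cfg, hap1 = smp$hap1)
  expect_true(all(ann$consequences$category == "identical"))
})
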