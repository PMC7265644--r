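# End-to-end orchestration: simulate -> tile (v0.9) -> spanned gap fill
# (v1.0) -> fitted contigs (v1.1) -> benchmark + correct (v1.2) -> major
# allele harmonization (v1.7) -> annotation QC, with an auditable run
# ledger. Stage outputs are immutable version-tagged files; identical
# (config, seed) reruns produce identical bytes.

stage_record <- function(name, version_in, version_out, params, metrics,
                         files = character(0)) {
  list(stage = name, version_in = version_in, version_out = version_out,
       params = params, metrics = metrics,
       files = as.list(stats::setNames(
         vapply(files, function(f) unname(tools::md5sum(f)), character(1)),
         basename(files))))
}

#' Run the full curation pipeline on a simulated genome
#'
#' Generates the donor, sample, contig set, coverage, population sites and
#' truth sets from `config`, then runs every curation stage in order,
#' writing version-tagged FASTA/AGP/VCF/TSV outputs and a JSON run ledger
#' under `out_dir`.
#'
#' @param config a [sim_config].
#' @param out_dir output directory (created if needed).
#' @param k anchor k-mer size used throughout.
#' @return list with `ledger` (stage records), `assembly` (final harmonized
#'   assembly), and the intermediate products (`tiled`, `filled`,
#'   `corrected`, `sim`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("refcurate_run_"),
                         k = 21L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ledger <- list()
  pth <- function(...) file.path(out_dir, paste0(...))

  # --- simulate -------------------------------------------------------------
  donor <- simulate_reference(config)
  smp <- simulate_sample(donor, config)
  pe <- plant_errors(smp$hap1, donor, smp$truth, config)
  frag <- fragment_assembly(pe$assembly, config, reference = donor)
  cov <- simulate_coverage(frag$contigs, frag$chimeras, config)
  sites <- simulate_population_sites(donor, smp$truth, config)
  ann <- simulate_annotation(donor, smp$truth, config, hap1 = smp$hap1)

  write_fasta(donor, pth("donor.fasta"))
  write_fasta(frag$contigs, pth("contigs_v0.5.fasta"))
  write_coverage(cov, pth("coverage.tsv"))
  write_sites(sites, pth("population_sites.tsv"))
  truth_vcf <- benchmark_vcf(smp$truth)
  write_vcf(truth_vcf, pth("truth_variants.vcf"),
            contigs = seq_lengths(donor))
  ledger[[length(ledger) + 1L]] <- stage_record(
    "simulate", NA, "v0.5",
    params = list(seed = config$seed, n_chrom = config$n_chrom,
                  chrom_len = config$chrom_len),
    metrics = list(contigs = length(frag$contigs$seq),
                   chimeras = nrow(frag$chimeras),
                   truth_variants = nrow(smp$truth$variants),
                   planted_errors = nrow(pe$planted)),
    files = c(pth("donor.fasta"), pth("contigs_v0.5.fasta")))

  # --- tile -----------------------------------------------------------------
  tiled <- tile_assembly(frag$contigs, donor, cov, k = k)
  sm <- summarize_assembly(tiled$chromosomes)
  write_fasta(tiled$chromosomes, pth("assembly_v0.9.fasta"))
  write_agp(tiled$plan, pth("assembly_v0.9.agp"))
  if (length(tiled$unplaced$seq)) write_fasta(tiled$unplaced, pth("unplaced.fasta"))
  ledger[[length(ledger) + 1L]] <- stage_record(
    "tile", "v0.5", "v0.9",
    params = list(low = 3, high = 35, window = 50000, end_dist = 5000),
    metrics = list(splits = nrow(tiled$splits),
                   candidates = nrow(tiled$candidates),
                   placed = nrow(tiled$assignments),
                   gap_length = sm$gap_length[sm$seq == "TOTAL"],
                   n_gaps = sm$n_gaps[sm$seq == "TOTAL"]),
    files = pth("assembly_v0.9.fasta"))

  # --- gap fill -------------------------------------------------------------
  didx <- kmer_index(donor, k = k)
  gf1 <- fill_spanned_gaps(tiled$chromosomes, donor, index = didx)
  sm1 <- summarize_assembly(gf1$assembly)
  write_fasta(gf1$assembly, pth("assembly_v1.0.fasta"))
  ledger[[length(ledger) + 1L]] <- stage_record(
    "gapfill_spanned", "v0.9", "v1.0",
    params = list(min_flank = 2000, identity_floor = 0.99),
    metrics = list(gaps_closed = nrow(gf1$events),
                   donor_bp = sum(gf1$events$bases_inserted),
                   gap_length = sm1$gap_length[sm1$seq == "TOTAL"],
                   n_gaps = sm1$n_gaps[sm1$seq == "TOTAL"]),
    files = pth("assembly_v1.0.fasta"))

  gf2 <- insert_fitting_contigs(gf1$assembly, donor, index = didx)
  sm2 <- summarize_assembly(gf2$assembly)
  dcr <- donor_content_report(gf2$assembly)
  write_fasta(gf2$assembly, pth("assembly_v1.1.fasta"))
  ledger[[length(ledger) + 1L]] <- stage_record(
    "gapfill_fitted", "v1.0", "v1.1",
    params = list(flank_gap = 100),
    metrics = list(contigs_inserted = nrow(gf2$events),
                   donor_bp_total = dcr$lower_bp[dcr$seq == "TOTAL"],
                   gap_length = sm2$gap_length[sm2$seq == "TOTAL"],
                   n_gaps = sm2$n_gaps[sm2$seq == "TOTAL"]),
    files = pth("assembly_v1.1.fasta"))

  # --- benchmark + correct --------------------------------------------------
  calls <- consensus_calls(donor, smp$truth, pe$planted)
  regions <- benchmark_regions(donor)
  excl <- excluded_regions(donor)
  cmp <- compare_small_variants(calls, truth_vcf, regions)
  part <- modified_fp_filter(cmp$fp, truth_vcf, excluded = excl)
  region_size <- sum(regions$end - regions$start)
  bres <- benchmark_result(cmp, part, region_size)
  aidx <- kmer_index(gf2$assembly, k = k)
  located <- locate_calls(part$modified, donor, gf2$assembly, index = aidx)
  corr <- apply_corrections(gf2$assembly, located)
  # post-correction benchmark: corrected errors disappear from the call set
  fixed_key <- paste(located$asm_chrom, located$asm_pos)[!is.na(located$asm_pos)]
  remaining <- pe$planted
  if (nrow(corr$log)) {
    done <- paste(located$chrom, located$pos)[!is.na(located$asm_pos)]
    remaining <- remaining[!paste(remaining$chrom, remaining$pos0 + 1L) %in% done, ,
                           drop = FALSE]
  }
  calls2 <- consensus_calls(donor, smp$truth, remaining)
  cmp2 <- compare_small_variants(calls2, truth_vcf, regions)
  part2 <- modified_fp_filter(cmp2$fp, truth_vcf, excluded = excl)
  bres2 <- benchmark_result(cmp2, part2, region_size)
  write_fasta(corr$assembly, pth("assembly_v1.2.fasta"))
  utils::write.table(bres, pth("benchmark_v1.1.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ledger[[length(ledger) + 1L]] <- stage_record(
    "benchmark_correct", "v1.1", "v1.2",
    params = list(proximity = 30, qv_cap = 90),
    metrics = list(fp_raw = bres$fp_raw, fp_modified = bres$fp_modified,
                   qv = bres$qv, corrections = nrow(corr$log),
                   fp_modified_after = bres2$fp_modified,
                   qv_after = bres2$qv),
    files = pth("assembly_v1.2.fasta"))

  # --- SV presence ----------------------------------------------------------
  svt <- truth_sv_table(smp$truth)
  cidx <- kmer_index(corr$assembly, k = k)
  svres <- sv_presence(svt, corr$assembly, donor, index = cidx)
  utils::write.table(svres, pth("sv_presence.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ledger[[length(ledger) + 1L]] <- stage_record(
    "sv_presence", "v1.2", "v1.2",
    params = list(flank = 1000),
    metrics = list(
      hom_present = sum(svres$status == "present" & svres$zygosity == "hom"),
      hom_total = sum(svres$zygosity == "hom"),
      het_present = sum(svres$status == "present" & svres$zygosity == "het"),
      het_total = sum(svres$zygosity == "het")),
    files = pth("sv_presence.tsv"))

  # --- harmonize ------------------------------------------------------------
  sel <- select_sites(sites)
  mp <- map_sites(sel, donor, corr$assembly, index = cidx)
  harm <- classify_and_replace(mp$mapped, corr$assembly, truth_vcf)
  binned <- af_binned_report(harm$sites)
  write_fasta(harm$assembly, pth("assembly_v1.7.fasta"))
  utils::write.table(binned, pth("harmonization_bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ledger[[length(ledger) + 1L]] <- stage_record(
    "harmonize", "v1.2", "v1.7",
    params = list(window = 2000, min_span = 1980, min_identity = 99,
                  min_count = 200, min_af = 0.5),
    metrics = list(selected = nrow(sel), mapped = mp$n_mapped,
                   unmapped = mp$n_unmapped, edits = nrow(harm$edits),
                   matched = sum(harm$sites$class %in% c("matched", "replaced"))),
    files = pth("assembly_v1.7.fasta"))

  # --- annotation QC (donor vs consensus haplotype + projected annotation) --
  mappings <- score_transcript_mappings(donor, ann$source, smp$hap1,
                                        ann$sample)
  cons <- classify_all_consequences(mappings, donor, ann$source, smp$hap1,
                                    ann$sample)
  gds <- gene_disruption_summary(cons)
  tl <- detect_translocations(mappings, ann$source, seq_lengths(donor),
                              seq_lengths(smp$hap1))
  utils::write.table(mappings, pth("transcript_mappings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cons, pth("consequences.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ledger[[length(ledger) + 1L]] <- stage_record(
    "annotqc", "v1.7", "v1.7",
    params = list(min_coverage = 50),
    metrics = list(transcripts = nrow(mappings),
                   mapped = sum(mappings$status == "mapped"),
                   translocated_genes = nrow(tl),
                   disrupted_genes = sum(gds$status == "disrupted")),
    files = pth("transcript_mappings.tsv"))

  jsonlite::write_json(ledger, file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(ledger = ledger, assembly = harm$assembly, tiled = tiled,
       filled = gf2$assembly, corrected = corr$assembly,
       benchmark = list(before = bres, after = bres2),
       sv = svres, harmonized = harm, mappings = mappings,
       consequences = cons, translocations = tl,
       sim = list(donor = donor, sample = smp, fragments = frag,
                  coverage = cov, sites = sites, annotation = ann,
                  planted = pe$planted),
       out_dir = out_dir)
}
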