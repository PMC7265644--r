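# Shared simulated datasets, built once per test run and cached. All
# fixtures are generated in code from a fixed seed; nothing is stored on
# disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# compact genome exercising every feature: repeats, donor gap block, genes
# (including the deleted/truncated/subtelomeric ones), chimeras, withheld
# intervals, planted consensus errors
fx_small <- function() fixture("small", function() {
  cfg <- sim_config(seed = 101L, chrom_len = 150000L, snv_count = 300L,
                    indel_count = 30L, sv_count = 12L, chimera_count = 2L,
                    withheld_count = 2L, ref_gap_count = 1L, n_genes = 8L,
                    n_errors = 60L, err_near_count = 6L, err_excl_count = 6L)
  ref <- simulate_reference(cfg)
  smp <- simulate_sample(ref, cfg)
  frag <- fragment_assembly(smp$hap1, cfg, reference = ref)
  cov <- simulate_coverage(frag$contigs, frag$chimeras, cfg)
  list(cfg = cfg, ref = ref, smp = smp, frag = frag, cov = cov)
})

# the small fixture tiled into chromosomes (reused by gapfill tests)
fx_tiled <- function() fixture("tiled", function() {
  fx <- fx_small()
  tiled <- tile_assembly(fx$frag$contigs, fx$ref, fx$cov)
  c(fx, list(tiled = tiled))
})

# benchmark inputs on the consensus haplotype with planted errors
fx_bench <- function() fixture("bench", function() {
  fx <- fx_small()
  pe <- plant_errors(fx$smp$hap1, fx$ref, fx$smp$truth, fx$cfg)
  calls <- consensus_calls(fx$ref, fx$smp$truth, pe$planted)
  list(fx = fx, pe = pe, calls = calls,
       bench = benchmark_vcf(fx$smp$truth),
       regions = benchmark_regions(fx$ref),
       excl = excluded_regions(fx$ref))
})

# annotation fixture with projected sample annotation and truth labels
fx_annot <- function() fixture("annot", function() {
  fx <- fx_small()
  ann <- simulate_annotation(fx$ref, fx$smp$truth, fx$cfg, hap1 = fx$smp$hap1)
  c(fx, list(ann = ann))
})
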