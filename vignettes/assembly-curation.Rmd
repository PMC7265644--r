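---
title: "Reference-guided curation of draft assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided curation of draft assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refcurate)
```

## The problem

A de novo assembly of a human-scale genome arrives as a bag of contigs:
unordered, unoriented, carrying occasional mis-joins, and missing the
regions the assembler could not resolve. Turning that bag into a usable
*reference* — chromosome-scale sequences, annotated, with known residual
error — is a curation exercise that leans on three external resources: a
finished donor reference genome from the same species, a high-confidence
variant benchmark for the assembled individual, and population allele
frequencies. refcurate implements that curation pipeline as composable,
tested R functions, together with a synthetic diploid genome generator so
that every stage can be validated against known truth without any external
download.

The stages, in the order the pipeline runs them (each producing an
immutable, version-tagged assembly):

1. **Tiling (v0.9).** Contigs are aligned to the donor; redundant
   second-haplotype duplicates are removed; candidate mis-assembly
   breakpoints are read off interior alignment ends and confirmed against
   read coverage; confirmed chimeras are split; contigs are ordered and
   oriented along donor chromosomes with N gaps sized from donor
   coordinates.
2. **Gap filling (v1.0, v1.1).** Gaps spanned by contiguous donor sequence
   with long unique flank anchors are closed outright; donor contigs that
   fit inside remaining gaps are inserted between 100-N spacer gaps. Donor
   bases enter in lowercase so provenance is never lost.
3. **Benchmarking and correction (v1.2).** Variant calls of the assembly
   against the donor are compared to the individual's diploid benchmark.
   Because a consensus assembly is haploid, discordances are partitioned
   before being called errors; the residual errors define a Phred-scaled
   QV and are then corrected in place.
4. **Harmonization (v1.7).** Population sites where the major allele
   differs from the donor base are lifted onto the assembly through
   anchored 2-kb windows; where the individual is heterozygous and carries
   the major allele, the assembly base is set to it.
5. **Annotation QC.** Transferred transcripts are scored by mRNA coverage
   and identity, classified for protein-level consequence, aggregated to
   gene-level disruption calls, and screened for cross-chromosome moves.

## Models and rules, with their parameters

### Mis-assembly detection

Every alignment end that lies strictly more than `end_dist` (default
5,000 bp) from both contig ends is a candidate breakpoint; candidates
within 1 kb merge (alignment ends from adjacent chunks jitter by a few
bases, so some merge radius is required; 1 kb is far below any real
inter-breakpoint distance at these scales). A candidate is confirmed iff
read depth within `window` (50 kb) of it reaches `low` (≤ 3×) or exceeds
`high` (> 35×). Low coverage means the join is physically unsupported and
the contig is split at the *weak point* — we take the midpoint of the
minimum-depth run nearest the candidate, measured on the full per-contig
track so that window clipping cannot shift it; this makes every candidate
around one junction resolve to the same split position. High coverage
indicates a repeat-mediated join and the split lands on the alignment
breakpoint itself. The thresholds are plain configuration values; they do
not auto-scale with mean depth.

Contig-to-chromosome assignment takes the chromosome with the greatest
summed aligned bases per contig (alignments under 2 kb are ignored to
suppress repeat-induced micro-hits), orientation by strand majority, ties
broken lexicographically for determinism. Inter-contig gap sizes come from
the donor-coordinate distance between projected neighbours, floored at
100 N when the projection implies abutment or overlap; overlapping
projections are resolved by trimming the lower-identity contig.

### The built-in anchor aligner

All internal alignment starts from a deliberately minimal seed-and-chain
aligner: k-mers (default k = 21) that are unique in both query and target
are matched and chained along the diagonal (chains break at gaps over 5 kb
or diagonal drift over 25 bp). Its reported matches count only anchored
bases — a conservative lower bound on identity — so every decision that
needs exact identity refines the located slice base-by-base: a direct
comparison when the chain sits on one diagonal, a per-block comparison
with closed-form single-indel gap scoring when it shifts a few times, and
a full affine-gap global alignment (Biostrings) otherwise. Production
users can bypass the built-in aligner entirely by supplying PAF from any
external aligner; uniqueness-based anchoring mirrors the
unique-match-anchor mode of standard whole-genome aligners.

### Gap filling

A gap is spanned-filled iff each flank (up to 5 kb of contiguous non-N
sequence) has **exactly one** qualifying placement on the donor — the
uniqueness requirement is what prevents repeat-mediated mis-fills — with
at least `min_flank` = 2,000 aligned bases at ≥ 99% identity, both flanks
on one donor sequence and strand in spanning order, and no N inside the
spanned donor slice. The 99% flank identity floor is chosen to match the
stringency used for harmonization window mapping. For the fitted-contig
step, a gap's implied donor interval comes from its flank placements
(falling back to the N-run length — which the tiler derived from donor
coordinates — when only one flank maps), and a donor contig is inserted
iff its own interval lies inside the gap's and its length is at most
`1.1 × estimate + 200` bp; "fits" needs *some* bounded slack and this one
allows for estimate error proportional to gap size plus anchor jitter.
Each insertion adds two 100-N spacers, so the gap count rises by one per
event while total gap length falls.

### Haploid-aware benchmarking

A haploid consensus calls every carried variant homozygous, so comparing
it to a diploid benchmark mislabels ordinary heterozygosity as error.
Raw FP therefore partitions, with precedence genotype > proximity >
region: calls matching benchmark alleles at heterozygous benchmark sites
(`FP.gt`); calls within 30 bp of any benchmark variant (`FP.al`,
boundary inclusive: 30 bp away is excluded, 31 retained; distance is
between variant start positions); calls inside the supplied excluded
regions (the self-chain/segmental-duplication analogue); and the
remainder — the *modified FP* count. Indel representations are
left-aligned and made parsimonious before matching so representation
differences are not errors.

`QV = −10·log10(FP / region size)`, log base 10 by Phred convention.
Zero FPs return a configurable cap (default 90) with a flag rather than
infinity. Corrections apply the modified FPs at assembly coordinates
(located by the same anchored-window machinery the harmonization step
uses): substitutions revert to the benchmark base, insertion errors are
excised, deletion errors restored, applied right-to-left; overlapping
edits defer to a second pass with a warning.

### Structural-variant presence

For each SV the donor-side alternate-allele region (variant applied,
± 1,000 bp of flank) is located on the assembly. Present requires a
single locus covering ≥ 95% of the region at ≥ 99% identity with
flank-to-flank spacing within ± 10 bp of expectation; several competing
loci yield `ambiguous` (the tandem-repeat situation where flank-based
placement is unreliable); anything else is `absent`. The three thresholds
are explicit configuration — they concretize an otherwise qualitative
"present" judgement.

### Harmonization

Sites qualify when reported in ≥ 200 individuals, with major-allele
frequency strictly above 0.5, single-base on both alleles, and major
allele differing from the donor base. A 2-kb donor window centered on the
site must place uniquely on the assembly with ≥ 1,980 aligned bases at
≥ 99% identity; the site lifts through the placement (alleles complemented
across minus-strand placements), and sites whose center lands in an indel
column are dropped with a flag rather than guessed. Classification at a
mapped site compares the assembly base to the major allele, and the base
is **only** changed to the major allele when the individual's genotype
(supplied as a genotype VCF — the minimal equivalent of consulting the
raw read data) shows the individual carries it: the step personalizes the
reference without ever departing from the underlying individual, which is
also why re-running it makes zero further edits. The frequency-binned
report uses bin edges 0.5–0.6–0.7–0.8–0.9–1.0; a below-0.5 bin only
appears if selection is run with the frequency filter disabled.

### Annotation QC

Transcript coverage is the fraction of source mRNA bases aligned to a
target base in a global alignment — the length-ratio sense of "at least
50% as long", so internal deletions reduce it — and a transcript is
mapped at ≥ 50%, partial below, unmapped when absent. Consequence
classification translates both CDS sequences and inspects the nucleotide
edit script, assigning exactly one category by the fixed precedence
`unmapped > truncated > frameshift > stop gained > stop lost > start lost
> in-frame insertion > in-frame deletion > missense > identical` (a
transcript with both a missense change and a premature stop counts under
the stop gain; a total order is required for category counts to partition
transcripts, and beyond that one published pairwise hint the rest of the
order is fixed here by decreasing severity). `truncated` is tied to the
partial mapping status, not inferred from alignment ends. Start-lost
checks only for a literal ATG; alternative initiator codons are not
honoured, which is flagged in output. The module never maps genes itself
— mapping is delegated to an upstream transfer tool or, in testing, to
the synthetic projector.

## The synthetic genome generator

The generator emulates the full study setting, and its defaults are the
conditions under which the package's claims are tested: 2 chromosomes ×
500 kb; SNVs at 5 × 10⁻⁴/bp with per-site population frequencies drawn
from a spectrum with mass on both sides of 0.5; small indels (1–10 bp) at
5 × 10⁻⁵/bp; 40 SVs of 50–500 bp, 46% homozygous; one reciprocal
terminal-segment exchange of 5 kb per genome ("subtelomere" means the
terminal 1%); multi-isoform gene loci as embedded clean ORFs (random
sequence is full of stop codons, so ORFs must be planted, not found);
contigs of 40–80 kb with planted cross-chromosome chimeras and withheld
intervals (future gaps, one centered on each donor N-run block); ~30×
coverage with ±4 jitter and 2× dropout around chimeric junctions; and a
population site table whose ALT allele equals the individual's alternate
allele with probability equal to the site frequency — the higher a major
allele's frequency, the likelier a random individual carries it — which
is what produces the monotone frequency-vs-concordance trend the
harmonization report shows. Genotypes at variant sites are drawn per
haplotype from the site frequency, conditioned on the individual carrying
at least one alternate copy. Planted consensus errors avoid true variants
by 40 bp except for a configured number placed deliberately within 30 bp
(to exercise the proximity exclusion) and inside the excluded regions.

Where the harmonization assay is run at scale, the site panel uses a
denser SNV rate (1,600 sites on a 2 × 300 kb genome) than the individual
variation default: population panels aggregate variation across thousands
of individuals and are far denser than any one genome's variant load, and
the binned-trend check needs a few hundred sites per frequency bin for
the expected ordering to dominate sampling noise.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: sequencing-error processes and
read-level artifacts (coverage is drawn directly, not from reads), the
repeat structure of real genomes (a handful of exact planted repeats
stand in for megabases of segmental duplication, so real-world ambiguous
mappings are underrepresented), assembler-specific error modes beyond
random fragmentation and chimeric joins, and population structure beyond
a single allele-frequency spectrum.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at format boundaries (VCF/GFF/AGP are 1-based on disk,
  BED/PAF 0-based).
* IUPAC degenerate codes other than N are rejected at ingest; the
  base-comparison logic assumes an unambiguous alphabet. N never counts
  as a match anywhere.
* Case is provenance and survives every round trip; sequences are held as
  plain character vectors because the usual DNA containers normalize
  case.
* Leading/trailing N runs are representable but never counted as gaps.
* Ties: chromosome assignment breaks lexicographically; best window
  placement is highest identity, then longest span, then lowest target
  coordinate; equal-identity overlap trimming trims the downstream
  segment.
* Empty inputs: an empty FASTA warns and yields an empty assembly; an
  alignment with no chains returns an empty record set, never an error.
* `with_seed()` isolates every simulation from the session RNG, and each
  generator stage draws from its own sub-stream of the master seed, so
  partial pipelines are as reproducible as full ones.

## Scales used by the test-suite

The suite validates parameter recovery at the scales the claims are
stated for: mis-assembly recovery on a 2 × 500 kb genome with 10 planted
chimeras; benchmarking on 200 planted errors at the same scale; the SV
assay on the default 40 SVs; harmonization on five seeds of the 2 ×
300 kb panel genome; and the consequence classifier against a brute-force
translate-and-diff oracle on 1,000 randomized CDS pairs. Unit tests run
the same logic on smaller fixtures built in code.

## Known limitations

* The anchor aligner has no gapped extension; identity from raw chains is
  a lower bound, and every precise decision goes through the refinement
  layer. Heavily diverged or highly repetitive regions should come in as
  external PAF instead.
* Variant calling itself is out of scope: benchmarking consumes a call
  set (the generator supplies the consensus calls a caller would emit).
* Gene mapping across assemblies is out of scope; annotation QC evaluates
  a transfer produced elsewhere, and in the pipeline the annotation QC
  stage runs on the consensus haplotype with the projector's transfer,
  since the tiled assembly carries no annotation coordinates.
* The one-off pseudo-autosomal patching and external polishing steps that
  a full curation campaign would interleave are not modelled; the
  pipeline's version tags jump accordingly.
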