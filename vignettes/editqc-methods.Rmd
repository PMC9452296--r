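---
title: "Models and methods behind editqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind editqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editqc)
```

editqc implements the genome-integrity analyses used to qualify
CRISPR-edited cell products: off-target site enumeration under a
mismatch-plus-bulge budget, edited-vs-control exclusive-indel
cross-referencing, amplicon editing-outcome quantification, and
closed-form knock-in genotype deconvolution. This vignette records the
models, the tunable parameters and their defaults, the numerical
conventions, and the design decisions taken where the underlying assay
descriptions leave room.

## Off-target site model

A candidate site is a genomic interval on either strand whose minimal
alignment penalty against the guide's protospacer is at most a budget,
with an adjacent PAM. The penalty prices a substitution at 1 and every
bulged (unpaired) base at `bulge_cost_per_base` (default 2, i.e. "a bulge
equals two base mismatches"); the budget `max_penalty` defaults to 5 and
the PAM pattern to `NRG` (R = A/G), the relaxed SpCas9 motif. The PAM is
required immediately 3' of the protospacer on the protospacer strand.

Conventions the alignment model fixes explicitly:

* **Bulge geometry.** Both DNA bulges (extra target base) and RNA bulges
  (extra guide base) are allowed. A bulge run is internal — flanked on
  both sides by aligned guide bases — so there are no end gaps on either
  side of the alignment; separate runs must be separated by at least one
  aligned base; a run is at most `max_bulge_len` bases (default 2 — with
  the default cost, longer runs exceed the budget anyway); several runs
  may co-occur subject to the total budget.
* **One representative per locus.** Overlapping alignments on the same
  strand are collapsed to the minimal-penalty representative, breaking
  ties by fewer bulge bases, then leftmost start, then smallest end.
  Opposite-strand sites at the same locus are distinct sites.
* **Ambiguity codes.** Any alignment whose target segment or PAM contains
  a non-ACGT base is ineligible: N-containing windows never match. This is
  the conservative, deterministic reading.
* **Coordinates.** Internal and BED coordinates are 0-based half-open;
  VCF positions are 1-based. A declared on-target locus (1-based position)
  excludes sites within `exclude_on_target_radius` (default 1,000 bp; the
  source assay excludes "sites around the on-target" without a radius)
  from candidate counts — they are still reported, flagged
  `on_target_region`.

Two independent implementations share this model. `scan_offtargets()`
anchors at each PAM occurrence and runs a banded dynamic program over the
protospacer (band width = the bulge-base budget, states tracking the
current bulge run so the run-length cap and run-separation rule hold),
minimising (penalty, bulge bases) lexicographically.
`scan_offtargets_brute()` enumerates every alignment shape — every
placement of bulge runs up to `max_bulge_len` — at every window start and
evaluates the penalty explicitly. The brute scanner is exponentially more
expensive but structurally independent; the test suite asserts exact set
equality of the two on seeded planted genomes, and the synthetic-genome
generator uses the brute scanner to certify planted loci (below).

The worked default (budget 5, bulge cost 2) reproduces the screen used in
practice to nominate candidate sites genome-wide. Reproducing a published
genome-wide candidate count additionally requires the same genome build
and the same (usually unstated) bulge conventions of the original tool,
so such counts should be treated as external targets and explored with
the parameter knobs above; at desk scale the correctness surface is the
oracle equivalence, which is exact.

## WGS exclusive-indel cross-reference

Indel calls (pure indels, < 50 bp, multi-allelic records refused rather
than silently split) are filtered by: supporting reads ≥ `min_support`
(default 4), mapping quality ≥ `min_mq` (default 30), QUAL ≥ `min_qual`
(default 20), no other variant within `near_variant_dist` (default 10 bp —
the source assay removes calls "near other variants" without stating a
distance; the rule is applied only when a variant-position table is
supplied, and against SNVs and indels alike), and no overlap with an
exclusion BED (for example the pseudoautosomal regions; intervals are
always user-supplied, never hard-coded). Each removed call is logged with
the first failing rule.

Edited-exclusive indels are those with no matching control call — exact
matching on (chrom, pos, ref, alt) by default, or windowed matching (same
chromosome, same indel length, positions within `window` bp) for callers
with unstable left-alignment.

Distances to candidate sites use the indel's affected reference interval:
a deletion anchored at 1-based `pos` with `l` deleted bases affects the
0-based interval `[pos, pos + l)`; an insertion is the 0-based boundary
point after its anchor. The distance to a site interval is 0 on overlap,
else the gap between nearest boundaries, and "within ±w bp" means
distance ≤ w, so the two standard windows (15 and 200 bp) nest. The
summary counts distinct sites with at least one hit per window.

## Amplicon editing-outcome quantification

Editing percentages at a locus are computed by explicit read
classification (rather than a trace-deconvolution or platform service, so
the algorithm is fully specified):

1. Reads from FASTQ are 3'-quality-trimmed at Phred `trim_quality`
   (default 20); reads shorter than `min_read_len` (default 50) FAIL.
2. A read is **HDR** when the donor-junction signature k-mer (default
   30-mer, absent from the reference by construction) or its reverse
   complement occurs with ≤ `hdr_max_mismatch` (default 1) mismatches.
   Signature detection is deliberately alignment-free: it is robust for
   short reads spanning the knock-in junction.
3. Otherwise the read is aligned to the amplicon reference (read-global,
   reference ends free; match +1, mismatch −1, gap open −4, gap extend
   −1). A gap is attributed to editing when **any equivalent placement**
   of that gap — slid along flanking sequence repeats without changing
   the alternate sequence — touches the quantification window `cut_site ±
   quant_window` (default ±2 bp). This mirrors standard indel
   normalization practice: aligners place ambiguous gaps arbitrarily
   within a repeat, and the equivalence range is the honest location set.
   The read is **INDEL** when an attributed gap exists with non-zero net
   length, **WT** when no window gap exists and identity
   (matches / read length) ≥ 0.9, **FAIL** below identity 0.6,
   **AMBIGUOUS** otherwise.
4. The cut site defaults to the blunt SpCas9 cut between protospacer
   positions 17 and 18 (3 bp 5' of the PAM) and is configurable per
   amplicon.

Percentages are of passing reads (`FAIL` excluded from denominators) with
Clopper–Pearson 95% intervals. Counts are order-invariant and the class
counts always sum to the passing total.

## Genotype deconvolution

A single semiquantitative PCR with three primers (one cassette-specific
forward, one genomic forward in the left homology arm, one genomic
reverse beyond the right arm) yields a cassette band and a WT/indel band.
With `A`, `B` the WT/indel and cassette band percentages in sorted
(cassette-positive) cells and `C`, `D` the same in unsorted cells, the
cell-genotype fractions follow in closed form:

wt/indel = (B·C − A·D)/B, het = 2·A·D/B, homo = (B − A)·D/B (in %).

The forward model these equations invert assumes unbiased allelic
amplification and within-lane normalization: a mixture with cell
fractions (w, h, m) gives A = h/(2(h+m)), B = (h+2m)/(2(h+m)),
C = (2w+h)/2, D = (h+2m)/2 (×100). `simulate_bands()` implements it with
optional multiplicative Gaussian intensity noise and per-lane
renormalization; `deconvolve_genotypes()` accepts unnormalized inputs as
well since the equations only use within-lane ratios. The three outputs
sum to `C + D` exactly — an algebraic identity used as a machine-precision
test. Equal amplification efficiency of the two amplicons is an assumed
property of the assay design (the amplicons share primers and differ in
insert); no length-bias correction is applied. Noisy lanes can produce a
negative component; these are flagged `consistent = FALSE` and never
clamped, so lane QC can reject them.

A useful bridge between modules: the allelic cassette fraction equals
`D = (het + 2·homo)/2`, which is exactly what the amplicon HDR percentage
estimates on reads drawn from the same cell mixture.

## Synthetic data: what it emulates, and what it does not

All generators are seed-deterministic and emit the standard format their
consumer reads (FASTA/BED/VCF/FASTQ) plus a machine-readable truth table.

* `make_genome()` plants protospacer variants realizing an exact
  mismatch/bulge/PAM description in a uniform-composition background
  (GC configurable; uniform is the simplest null for match statistics).
  Because random flanking bases can accidentally admit a cheaper
  alignment than intended, each planted locus is certified with the
  brute-force scanner — the locus representative must realize the planted
  penalty decomposition exactly, with local resampling until it does —
  so truth tables are guaranteed, not merely probable.
  `sample_plant_sites()` leaves a 300-bp margin at the genome ends so
  downstream simulators can place indels anywhere within the widest
  proximity window of any site.
* `make_vcf_pair()` writes an edited/control VCF pair: shared background
  indels (support ~ Poisson(30), MQ ~ 60 − Exp(mean 5), QUAL ~
  Gamma(4, 10) — chosen to straddle the filter thresholds so both sides
  of every rule are exercised) plus edited-exclusive indels at exact
  requested gap distances from planted sites. Background records reuse
  one quality draw in both samples so shared calls remain shared after
  filtering; the truth table records which planted indels survive the
  filter and the per-window distinct-site counts, counting each indel
  against every site (an indel can fall in a neighbouring site's window).
* `make_reads()` draws reads per class at the true fractions: indel reads
  carry a lesion overlapping the cut (sizes 60% 1-bp deletion, 20% 1-bp
  insertion, 20% 2–10-bp deletion), HDR reads carry the donor signature
  inserted at the cut, and uniform substitution errors are applied.
  `synthetic_amplicon()` generates references with homopolymer runs
  capped at 2 bases, mirroring amplicon design practice and keeping
  planted lesions inside the quantification window under any equivalent
  gap placement. The default testing regime — 60% indels, 20% HDR,
  10,000 reads — matches the operating point reported for clinical
  CAR knock-in products (about 60% indels and 20% integration at
  10,000× coverage).

What the generators do **not** emulate: position- and motif-dependent
sequencing error profiles, PCR chimeras and UMI structure, alignment and
variant-calling artifacts upstream of the VCF, structural variants, or
amplification bias between amplicons. Passing tests therefore demonstrate
algorithmic correctness against the stated models, not robustness to
every artifact of real instruments; the filter thresholds and windows
exist precisely because real data carry those artifacts.

## Numerical and scale choices

Penalties, coordinates and counts are integer throughout the scanner; the
deconvolution is closed-form double arithmetic (grid-inversion error is
at machine epsilon). Test and acceptance problem sizes — 20 genomes of
10 kb with 10 planted sites each for scanner verification, 10,000 records
for filter verification, a 1%-step mixture grid plus 1,000 Monte-Carlo
draws for the deconvolution, 10,000 reads per amplicon run — were chosen
so the full verification completes in minutes on a single core while
keeping every binomial comparison well-powered; all of them are plain
function arguments that scale up directly.

## Known limitations

* The scanner is a straightforward per-chromosome scan without a
  genome-scale index; scanning a full mammalian genome is possible but
  slow, and matching a published genome-wide site count additionally
  depends on the original tool's unstated bulge conventions and build.
* Gap attribution near the cut uses single-gap equivalence ranges; a
  lesion expressible only as a combination of gaps and substitutions may
  be labelled AMBIGUOUS rather than INDEL.
* The deconvolution assumes the sorted lane contains only
  cassette-positive cells; sorting impurity propagates directly into the
  genotype fractions.
* Paired-end merging, UMI handling and chimera detection are out of
  scope; reads are treated as independent single-end observations.
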