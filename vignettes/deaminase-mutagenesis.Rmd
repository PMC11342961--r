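---
title: "Identifying and quantifying deaminase-induced germline mutations"
author: "highevoR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying deaminase-induced germline mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(highevoR)
```

## The experimental system

A transcription factor fused to an activation-induced deaminase (AID) and
expressed in the fly germline converts cytosines near the factor's binding
sites into uracil, read by replication as C→T (plus strand) or G→A (minus
strand) changes. Populations carrying the fusion self-mutagenize: every
generation adds heritable point mutations concentrated around the TF's
regulatory targets. The downstream questions are quantitative: how fast do
mutations accumulate per base per generation, what is their substitution
spectrum, and do they sit closer to TF motif clusters and regulatory
intervals than natural variants do?

The raw observable is a joint multi-sample variant call over mutagenized
individuals, background stocks and chr3-isogenic lines (two flies sequenced
per line as replicates). All analysis in this package starts from that
joint table; read mapping and variant calling are upstream and out of
scope.

## De novo candidates as private variants

The central inference is set logic: a de novo mutation should be **private**
to one designated sample set. `runPrivatePipeline()` implements the chain:

1. **QUAL prefilter.** Records with site QUAL < 10 are dropped (missing QUAL
   is read as 0 and dropped). Applied to the joint call *before*
   privateness, since the prefilter describes the call set as a whole.
2. **Privateness.** A variant is private to the target set iff ≥ 1 target
   sample carries the alternative allele (het or hom-alt) and *no* sample
   outside the target set within the full set carries it — at **any**
   genotype quality. Deciding presence before genotype filtering is
   deliberately strict: a low-quality alt call in a background sample is
   still evidence the variant is standing variation. Missing genotypes do
   not count as carrying. The full set may contain samples in neither
   designated set (balancer stocks); they too veto privateness.
3. **Genotype filter and replicate rescue.** A carrier call passes with
   depth 10–200 (inclusive) and, for heterozygous calls, at least 3 reads
   per allele (AO > 2 and RO > 2). A variant survives if any carrier
   passes, or if it is carried by ≥ 2 samples of one replicate group
   (isogenic-line replicates, occasionally including the sequenced male
   parent) — concordant replicates validate calls in low-coverage regions
   regardless of depth. Failing carriers remain listed, flagged by
   `carrier_pass`.
4. **Cross-set coverage.** A mutagenized-private variant is kept only if
   ≥ 2 background-set samples have non-missing calls at the site, and vice
   versa, so that the two sets are ascertained comparably. All manifest
   samples of the complement set present in the call are counted, including
   samples later excluded by mean depth (the alternative — counting only
   finally-retained samples — is not what the procedure describes).
5. **Introgression removal.** A sample carrying ≥ `min_count` (default 20)
   private variants within any `window_kb` (default 100 kb) window on one
   chromosome carries a foreign haplotype block, not independent de novo
   mutations; it is removed and privateness is **recomputed from scratch**
   without it. Recomputation can only grow the private sets (removing a
   disqualifying carrier may newly qualify a variant); the ledger records
   such additions separately. Defaults are chosen to catch both a ~40 kb
   and a ~630 kb block at realistic variant densities; both are
   configurable. Detection runs once, not iteratively.
6. **Depth exclusion.** For counting, samples below the per-chromosome mean
   depth threshold are dropped as carriers (defaults: 9× for chr2, 5× for
   chr3; unknown chromosomes fall back to 5× with a warning). This stage
   does not trigger privateness recomputation — the samples stay in the
   call; only their counts are suppressed.

All boundary semantics are closed as written: QUAL ≥ 10 kept, DP ∈ [10,
200] kept, AO > 2 strict, mean depth ≥ threshold kept. The
`reversionAudit()` helper counts sites homozygous-alternative across all
background samples and apparent reversions among them, the control for de
novo mutations that happen to match the reference allele.

## Mutation rate

Per isogenic line, `u = N_var / (n_bp × G)`: `N_var` private variants
carried by the line (homozygous and heterozygous calls both counted),
`n_bp` the line's callable bases (positions covered by 10–200 reads),
`G` its generation count. An isogenized chromosome harvests one of the two
chromosome copies of the founding male, so `n_bp` rather than `2 n_bp`
makes `u` a per-base rate of a *diploid* genome. When replicate counts
disagree the higher count is used (`reconcileReplicates()`); `n_bp` is
taken from the replicate attaining that count (ties: first replicate) —
the procedure's description ties the count to a sample but not the
denominator choice, which we fix this way and expose in the output table.
Samples under 9× mean depth are excluded from the rate analysis. The
aggregate is the arithmetic mean across lines; because "±" is ambiguous in
such reports, `aggregateRates()` returns both the SE of the mean and the
SD across lines.

## Spectrum and contingency

`classifyVariant()` partitions records into C→T/G→A SNPs, other SNPs,
insertions, deletions and MNPs (equal-length multi-base substitutions are
carried verbatim as MNPs, without primitive decomposition).
`spectrumFraction()` reports the deaminase-signature fraction among SNPs
and among all variants — both denominators, since both are quoted in
practice. `contingencyTest()` contrasts mutagenized vs background
signature counts with the **cross-product** odds ratio `(a·d)/(b·c)`; the
conditional maximum-likelihood estimator that `fisher.test()` prints is a
different statistic and typically differs in the second decimal. The
two-sided p-value is the exact hypergeometric tail (computed by
`stats::fisher.test`; the test suite checks it against an explicit
enumeration of all tables with fixed margins). Zero cells flag the OR as
0/Inf; the p-value is still defined. Percentages throughout are rounded
half-up to one decimal (`roundHalfUp()`), matching how such tables are
printed; base R's round-half-even would turn 80.85 into 80.8.

## Regulatory enrichment

`pwmScan()` scores every window on both strands with log-odds
`Σ log(p_j(base) / bg(base))`; windows containing N are skipped. When a
matrix cell is 0 a 0.01 pseudocount is added to the affected columns
before log-odds. The default hit threshold is 60% of the maximal
achievable score — the conventional default of cluster-scanning tools,
exposed as a parameter since the choice is not principled.
`clusterHits()` chains hits whose inter-hit gap (next start minus previous
end, half-open coordinates) is ≤ `max_gap` (default 35 bp) and keeps
chains with ≥ `min_hits` (default 2); both are free parameters.

`nearestFeatureDistance()` returns 0 for a position inside an interval and
otherwise the number of bases strictly between the position and the
nearest interval on the same chromosome (∞ if the chromosome has no
intervals). Two conventions were on the table — counting intervening bases
(an adjacent position has distance 0... 1 base away has distance 1) versus
edge-difference arithmetic that assigns an adjacent position distance 1.
We fixed the intervening-bases convention, which matches GenomicRanges'
`distanceToNearest` and keeps containment→0 continuous; "within 100 bp"
means distance ≤ 100.

`proximityEnrichment()` draws `n_sample` (default 10,000) background
positions per replicate (without replacement when the pool allows,
otherwise with replacement, announced), forms the 2×2 table of within- vs
beyond-window counts for focal and background variants, computes the
cross-product OR and exact p, and BH-adjusts p-values **across tracks
within each replicate** (the adjustment's family is the set of feature
tracks tested together). Replicates (default 500) share the focal set and
differ only in the background draw, so the replicate distribution
quantifies resampling noise around one observed focal configuration — not
sampling noise of the focal set itself. Distances to each track are
computed once per input and reused across replicates, which is what makes
500 × 10,000 resampling cheap. Background pools are matched per
chromosome by construction of the inputs; genome-wide pools can be passed
just as well. `extractWindows()` exports `width`-bp (default 200)
mutation-centred FASTA windows, the variant at position `⌈width/2⌉`,
N-padded and flagged at chromosome ends — the input de novo motif
discovery consumes; motif discovery itself is out of scope.
`sharedVariantPolicy()` keeps variants found in both of two analyses in
both exported lists and reports the overlap fraction (shared / union).

## The forward simulator

`simulateStudy()` generates data with the statistical structure the
analysis assumes, so every stage is testable without sequencing data:

* **Genome** (`buildGenome()`): i.i.d. sequence at a given GC (default
  0.42, fly euchromatin), `n_motif_sites` non-overlapping PWM consensus
  matches planted uniformly on random strands, and peak intervals each
  containing a motif site. The default motif is a synthetic 8-bp
  homeodomain-like PWM (`examplePwm()`), not a database matrix.
* **Standing variation** (`simulateBackgroundStocks()`): per stock,
  private fixed differences (default 5 × 10⁻⁴/bp), fixed differences
  shared by all stocks relative to the reference (2 × 10⁻⁴/bp, feeding
  the reversion audit), and pockets of residual heterozygosity (two
  pockets of 10 kb at 2 × 10⁻³ het sites/bp) shared by all individuals
  of the stock — the lab-stock heterogeneity that makes naive private
  calls wrong and introgression detection necessary.
* **Mutagenesis** (`simulateMutagenesis()`): per lineage and generation,
  Poisson counts at `base_rate` outside and `base_rate ×
  target_rate_multiplier` inside windows of `target_window` bp (default
  100) around motif sites. With probability `deamination_fraction`
  (default 0.85) the mutation is a deamination at a C or G (position
  re-drawn within the same region class until it lands on C/G); otherwise
  a uniform substitution *excluding* the deamination change, so the
  parameter equals the observable C→T/G→A fraction exactly. Mutations are
  heterozygous with probability `het_fraction` (default 0.883) and
  accumulate monotonically across generations. `MutagenesisModel`
  defaults anchor to the endogenous fly rate (8.4 × 10⁻⁹ per base per
  generation, diploid); because a desk-scale genome is 10²–10³ times
  smaller than a fly genome, desk-scale runs pass proportionally larger
  `base_rate` so expected counts per line stay in the realistic 5–40
  range. The genome-wide elevation implied by the default multiplier 50
  depends on window coverage; the multiplier is a free knob, not a
  measured quantity.
* **Isogenization** (`simulateIsogenization()`): one chromosome copy is
  sampled — heterozygous de novo mutations transmit with probability 1/2
  and become homozygous, homozygous ones always transmit; heterozygosity
  pockets transmit as haplotype blocks with probability 1/2. Replicates
  share the identical isogenized-chromosome variant set. Non-isogenized
  chromosomes of the replicates carry stock standing variation only (the
  isogenizing crosses replace them), which is also why isogenic
  replicates belong to the mutagenized set of the isogenized chromosome
  only.
* **Sequencing** (`emitJointTable()`): depth is negative-binomial per
  100-bp bin (dispersion 0.2 by default; binning reflects the local
  autocorrelation of short-read coverage and keeps tracks run-length
  encodable — dispersion 0 gives constant depth, the noise-free limit),
  allele observations are binomial in allele dosage with per-read error
  `error_rate`, genotypes are called at allele-fraction thresholds
  (< 0.25 hom-ref, > 0.75 hom-alt, else het) and emitted missing below
  `missing_below` reads. True sites get QUAL in [50, 2000]; injected
  artifact records (a configurable fraction, one low-AO carrier each) get
  QUAL < 10 so the prefilter is exercised. Mean depth defaults to 19.2×,
  the coverage scale of the motivating design.

**What the simulator does not model**, and hence what green tests do not
establish about real data: overlapping generations (G is a discrete
integer count), selection and lethality of induced mutations, indel/MNP
generation (induced mutations are SNPs; indel and MNP classification is
exercised by constructed fixtures), shared ancestry between mutagenized
individuals (each lineage is independent, so population-level singleton
fractions are not comparable to a real cohort's), residual heterozygosity
in isogenized chromosomes (transmitted variants are exactly homozygous),
mapping artifacts and repeat regions, and read-level effects (no FASTQ).
Balancer-chromosome genetics is abstracted into "samples present in the
full set but in neither designated set".

## Numerical and interface conventions

* Coordinates: VCF positions are 1-based; BED intervals 0-based half-open.
  `bedToGRanges()` / `grangesToBed()` are the only places ±1 arithmetic
  occurs; everything internal is 1-based `GRanges`.
* Multi-allelic records are decomposed on read: one record per ALT, a
  genotype's dosage of that ALT mapped to het/hom-alt, other-alt copies
  counting as reference for zygosity; AO is per-allele, RO shared.
  Missing QUAL becomes 0 (fails the prefilter, conservatively).
* The VCF writer emits the narrow `GT:DP:RO:AO` dialect as plain text so
  that fixed-seed simulations are byte-identical across runs; the reader
  (vcfR-backed) round-trips it field for field.
* Degenerate inputs are flagged, not silently zeroed: empty variant sets
  give `defined = FALSE` spectra with NA fractions; empty feature tracks
  give ∞ distances and degenerate-flagged enrichment results; zero
  contingency cells flag the OR.
* Every stochastic function takes an explicit integer seed and is
  deterministic given it; pipeline commands write a JSON run manifest with
  package version, config hash and seed, and reject configs with unknown
  keys or out-of-bounds values.

## Problem sizes used in the tests

The test suite runs entirely on simulated data at desk scale, chosen to
keep the whole suite in a few minutes on one CPU while leaving enough
events for the statistical checks: randomized pipeline-vs-brute-force
instances use up to 500 variants × 20 samples (100 instances); rate
recovery uses 20 isogenic lines on a 10-Mb chromosome at an effective
diploid rate of 5 × 10⁻⁸ with G = 10 and noise-free sequencing, repeated
over 10 seeds with a 3-SE acceptance band; enrichment power uses 30
mutagenized individuals on 500 kb with multiplier 50 against a 25,000-
position uniform background pool (10,000 × 500 resampling); null
calibration uses 500 independently drawn null focal sets. The published
real-data quantities that need the original sequencing archive (per-
chromosome mutation counts, the 4.7 ± 0.5 × 10⁻⁸ and 8.1 ± 1.3 × 10⁻⁸
rates, motif-discovery p-values) are not desk-reproducible and are covered
by these property checks instead; the exact published count tables
(contingency cells, privateness totals) are reproduced directly from their
printed values by `scripts/acceptance.R`.

## Known limitations

* Privateness recomputation after introgression removal is the
  conservative reading of "samples were removed"; the original procedure
  may have subtracted samples without recomputing, which can only shrink
  the private sets relative to ours.
* The pipeline treats pooled sampling generations as one mutagenized set;
  per-line G is the line's own sampled generation.
* MNP length normalization of the upstream caller is not replicated;
  MNP records are carried verbatim.
* `n_bp` ties callable sites to one replicate while rescue can count
  variants in regions that replicate's depth track calls uncallable; at
  realistic coverage this inflates `u` by at most a few percent and
  vanishes in the noise-free limit.
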