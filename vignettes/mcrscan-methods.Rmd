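---
title: "Multi-copy regions and their impact on short-read variant calling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-copy regions and their impact on short-read variant calling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrscan)
```

## The problem

A multi-copy sequence (MCS) is an exact nucleotide sequence of at least a
window length $w$ (default 300 bp) that occurs at two or more genomic loci;
each locus it occupies is a multi-copy region (MCR). Because $w$ exceeds the
read length of common short-read sequencing, a read drawn from the interior
of one copy is equally consistent with every other copy. Pipelines that keep
only uniquely mapped reads therefore starve MCR interiors of usable
coverage, and variants planted there are systematically missed or
mis-assigned. `mcrscan` implements the full desk-scale experiment that
quantifies this: exact-repeat discovery, a synthetic genome generator with
known planted duplications, a paired-end read simulator, a strict
unique-mapping mapper with a pileup SNV caller, stratified evaluation
statistics, and a matched-random-region enrichment test.

## Finding MCRs by tiling-seed merging

Seed windows of length $w$ are tiled at 1-bp steps over every chromosome.
For each N-free window all exact occurrences genome-wide are enumerated, by
default on both strands, because the mapping step the procedure abstracts is
strand-blind; `strand_mode = "forward"` is available for debugging.
Implementation: every window receives a polynomial rolling hash on both
strands; windows sharing a canonical (strand-min) hash are bucketed and then
*verified by direct base comparison*, so hash collisions cannot create
spurious occurrences. There is no cap on occurrences per seed — the
contract is *all* occurrences, which is exactly where a capped multi-hit
aligner approximates.

Windows with two or more occurrences are merged into MCSs: a run of
consecutive window positions is extended while the occurrence sets shift in
lockstep (+1 per step for same-strand occurrences, −1 for opposite-strand
ones). A run of $r$ windows yields an MCS of length $r + w - 1$. Any change
in the occurrence set interrupts continuity. This makes groups well defined
when a sub-segment of a repeat has extra copies elsewhere: blocks split so
that every reported group shares one MCS across a constant locus set.
Groups rediscovered from each of their loci have identical locus extents and
are fused; the canonical representation sorts loci by position and flips
strands so the first locus is `+`. Consequences worth knowing:

* the minimum reported MCS length is exactly $w$; a duplicate of length
  $w - 1$ produces nothing;
* every reported group is maximal — extending all loci by one base in
  either direction breaks sequence identity or leaves the genome;
* overlapping MCRs from different groups are permitted; coverage statistics
  use their union;
* exact tandem arrays of $k \ge 3$ copies additionally produce the
  junction-straddling repeats that genuinely exist in such arrays (a
  $2L - w$ long sequence straddling the first junction equals the one
  straddling the second), so "finder output = planted truth" holds exactly
  for dispersed copies and 2-copy tandems, which is what the recovery tests
  use.

`brute_force_repeat_oracle()` re-derives the same decomposition
independently: all windows are materialised as strings, occurrence sets come
from direct string identity (forward and against whole-chromosome reverse
complements), and runs are grouped by a shift-normalised occurrence-set key
($q - p$ for `+` occurrences, $q + p$ for `-`) rather than the incremental
lockstep walk. The two implementations share no code in the hot path and are
required to agree set-identically on randomized planted genomes up to the
oracle's 200 kb size guard.

## The synthetic genome generator

`generate_background()` draws i.i.d. bases at a configurable GC content
(default 0.41, the human genome-wide value). An i.i.d. background contains
no repeat structure of its own: the probability that two random 300-mers
coincide anywhere in a megabase-scale genome is below $10^{-80}$, so planted
duplications are the only exact repeats at or above $w$ and oracle equality
against planted truth is sharp. What this deliberately does *not* emulate:
real repeat families (Alu/LINE), GC heterogeneity, assembly gaps beyond
optional N runs, and divergence with indels. Passing tests on these genomes
demonstrate the mechanism, not performance on hg19-like repeat landscapes.

`plant_duplications()` copies a background segment into `copies − 1`
destination loci (reverse-complemented for `-` strand copies), keeping every
planted segment at least `margin` (default 1 kb) away from chromosome ends
and other planted segments. The margin guarantees unambiguous seed-merge
boundaries and keeps the flank strata used later from colliding with other
repeats. Two details matter for exactness:

* **Junction distinctness.** After copying, the bases immediately flanking
  the copies are adjusted so no two copies of a group share the same
  "extension letter" on either side (for a `-` copy the letter is read
  complemented from the opposite end). Without this, two copies share a
  flanking base with probability 1/4 per side and the maximal exact repeat
  is longer than the planted segment — the finder would be right and the
  truth annotation wrong. With a 4-letter alphabet the adjustment is
  guaranteed for up to 4 copies per group; interior junctions of tandem
  arrays are fixed sequence and cannot be adjusted, which is another reason
  the exact-recovery guarantee is stated for 2-copy tandems.
* **Divergence.** Copies may receive Binomial(length, divergence)
  substitutions. Divergent copies exist to test exactness: the finder must
  *not* report them as one full-length group, only exact sub-blocks of
  length $\ge w$ may appear.

## Read simulation

`simulate_read_pairs()` follows the standard whole-genome shotgun model:
the number of pairs is $\mathrm{round}(d \cdot L / (2\ell))$ for depth $d$,
genome length $L$ and read length $\ell$; fragments start uniformly;
fragment length is Normal(`insert_mean`, `insert_sd`) truncated to at least
$2\ell$; each fragment comes from one of two haplotypes chosen uniformly;
mate 2 is the reverse complement of the far fragment end; each base flips to
a uniformly chosen different base with probability `error_rate`. Defaults:
insert 400 ± 50 bp (midpoint of the 300–500 bp range typical of paired-end
libraries), error rate 0.01, constant Phred 35 qualities in FASTQ output
(the error model is positional, not quality-driven, so qualities are
bookkeeping). Truth origins are recorded per pair. The diploid genome comes
from `plant_snvs()` (each stratum base mutated independently with
probability `rate`, default 0.001 = one SNV per kb; heterozygous with
probability `het_fraction`, default 0.5) and `build_haplotypes()`
(homozygous variants on both haplotypes, heterozygous on one, recorded).

MCR and flank strata come from `define_strata()`: every MCR contributes
flanking sequence of the same total length, half upstream and half
downstream, clipped at chromosome ends (with the shortfall reallocated to
the other side when space allows) and trimmed so flanks never overlap the
MCR union or each other.

## Mapping and calling

`build_index()` stores the full position list of every N-free k-mer
(default $k = 31$, odd, 15–63) of the forward strand; reads are queried in
both orientations. `map_read_pairs()` gathers candidate placements from
three anchors per mate per orientation (offsets 0, middle, end), verifies
them by mismatch counting with a per-read tolerance of
$\lceil 0.04\,\ell \rceil$ (tolerates the default error rate with margin),
keeps concordant combinations (forward/reverse orientation, fragment length
within mean ± 4 sd) and scores them by total mismatches. **Uniqueness is a
strict co-optimality test**: a pair is retained iff exactly one placement
attains the minimal score. There are no mapping-quality heuristics — this
is the hard "only uniquely mapped reads" filter, and it is the entire
mechanism of the study: a pair wholly inside a 2-copy exact repeat has two
co-optimal placements by symmetry and is always discarded, while a pair
with one mate anchored in unique flank is kept.

`pileup_and_call()` counts bases from retained reads per site. The
alternate allele is the most frequent non-reference base (ties broken
lexicographically for determinism); a call requires depth ≥ 4, alternate
count ≥ 2 and alternate fraction ≥ 0.2, and is homozygous at fraction
≥ 0.8. These thresholds are deliberately explicit and fixed — the
likelihood machinery of a production caller is out of scope, and the
consequences are visible in the results (below).

Since simulated qualities are constant, no low-quality read filter is
applied before mapping; the mismatch tolerance plays that role.

## Evaluation statistics

A called variant is a true positive iff a truth variant matches on
(chromosome, position, alternate allele); genotype concordance is reported
separately rather than folded into TP matching, since mixing the two
changes the meaning of "accuracy" silently. The rates are
$\mathrm{accuracy} = TP/(TP+FP)$, $\mathrm{fp} = FP/(TP+FP)$,
$\mathrm{fn} = FN/(TP+FN)$; with an empty called set the first two are
reported missing, never zero. Records are stratified by the stratum
containing their position; calls outside both strata land in an `other`
stratum (they arise from sequencing errors on uniquely mapped reads and
must not be silently dropped). Strategy comparisons use the pooled-variance
two-sample t-test on per-replicate metrics, all unordered pairs.

`sample_matched_regions()` draws a null region set with the same number and
length multiset as a template: chromosome proportional to length, start
uniform given the chromosome, non-overlapping by rejection (longest placed
first; bounded retries then an explicit error). `enrichment_test()` counts
query intervals overlapping at least one feature, repeats the count over
`n_sims` (default 1000) matched shuffles, computes a per-shuffle 2×2
Pearson chi-squared (no continuity correction) of
(overlap, non-overlap) × (real, shuffled), and reports as the headline the
empirical two-sided permutation p-value
$2\min(r_{\ge}, r_{\le})$ with $r_{\ge} = (1 + \#\{sims \ge obs\})/(n+1)$
(and symmetrically $r_{\le}$), capped at 1. The tie-aware form matters: when
features saturate the genome every shuffle ties with the observed count and
the p-value is 1, not 0. Both per-sim chi-squared p-values and a pooled
chi-squared are also returned because aggregating 1000 per-sim tests into
one number admits more than one convention; the permutation p is the
distribution-free headline.

## The experiment grid

`run_experiment_grid()` crosses read lengths {75, 150} with depths
{10, 30, 50, 100}× at 20 replicates by default (160 datasets). Per cell:
plant SNVs → build haplotypes → simulate → map → call → evaluate. The
per-cell seed is a deterministic polynomial mix of the base seed and the
cell coordinates, so cells are independent, any cell can be recomputed alone,
and full reruns are bit-identical; with an output directory each cell's rows
are written to a TSV, checksummed in the manifest, and reused on resume.
The simulate→map→pileup stage of a cell runs through a fused native driver
that shares its core routines (same RNG stream, same mapping and pileup
code) with the exported `simulate_read_pairs()` / `map_read_pairs()` /
`pileup_and_call()` functions; the two paths are bit-identical for the same
seed, which the pipeline tests assert.

## Problem sizes, numerical choices and what the results show

The package's own evaluation (the acceptance suite) uses:

* **Oracle equivalence**: 50 randomized builds of 2 × 20 kb with 2 planted
  groups each (lengths 250–1200 bp, 2–6 copies, both strands, tandem and
  dispersed), finder vs brute-force oracle, exact set equality.
* **Threshold**: a 200 kb build with planted pair lengths
  250…350 bp; reported lengths are exactly {300, 310, 325, 350} and the
  minimum is the window length.
* **Headline mechanism**: a 2 × 500 kb build with ten 2-copy exact MCRs of
  2–5 kb, the full 8-strategy × 20-replicate grid (~38 M read pairs
  total). Mean false-negative rate in the MCR stratum exceeds the flank
  stratum in every replicate of every strategy — the unique-mapping filter
  starves exact-repeat interiors (typical values ~0.74–0.88 in MCRs vs
  ~0.00–0.07 in flanks). Mean accuracy is lower in MCRs than flanks at
  every strategy. At 10× the margin is narrow for an instructive reason:
  with a 1% base error rate and no quality model, two concordant errors at
  a ~10× site pass the fixed caller thresholds, so error-driven false
  positives dilute *flank* accuracy, while MCR interiors are too starved of
  retained coverage to accumulate them. At ≥30× those false positives
  need six concordant errors and vanish.
* **Trends**: per-dataset pooled accuracy is non-decreasing in depth at
  both read lengths. The read-length comparison improves or ties at
  10–50× but *saturates* at 100×, where PE150 sits about one accuracy
  point below PE75 (≈2.5 standard errors): the mismatch tolerance scales
  with read length, so longer reads retain noisier alignments whose errors
  concentrate in the low-coverage ramp at MCR edges. The trend check
  therefore allows 3 standard errors of the difference — with 11
  simultaneous ordered comparisons, a 2-SE band would flag chance
  violations about a quarter of the time even under perfect monotonicity —
  and this saturation is a documented property of the strict-uniqueness
  stand-in, not of the underlying biology.
* **Enrichment calibration**: with features drawn from the same shuffling
  law as the null, the fraction of per-sim chi-squared p-values below 0.001
  stays within a 3-sd binomial band of 0.001 over 2000 shuffles, and the
  hand-computed 2×2 statistic (90/10 vs 50/50 → 38.0952) matches to four
  decimals.

Degenerate inputs are handled explicitly rather than silently: empty
strata warn and return empty variant sets; chromosomes shorter than the
maximum fragment are excluded from simulation with a warning; an MCR
occupying a whole chromosome yields no flank with a warning; unplaceable
duplications or matched regions raise placement errors after bounded
retries; VCF records on chromosomes outside the namespace are skipped and
counted.

## Known limitations

* Exact repeats only; diverged repeat families, indels and CNV dosage are
  out of scope by design.
* The mapper is ungapped and anchor-based: a read whose three anchors all
  contain errors can go unmapped (~rare at the default error rate); with
  error rate 0 mapping is exhaustive for the planted designs.
* The caller has no base-quality or likelihood model, which produces the
  documented error-FP behaviour at 10×.
* Genome-wide hg19 results (tens of thousands of MCS groups, ~2% genome
  coverage) are supported in principle by the same code paths but are not
  part of the test suite; desk-scale synthetic genomes are.
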