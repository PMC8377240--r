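# mcrscan

Exact multi-copy region discovery and a simulation framework for measuring
how such regions degrade short-read variant calling.

## The problem

A **multi-copy sequence (MCS)** is an exact sequence of at least a window
length *w* (default 300 bp) occurring at two or more genomic loci; each
locus is a **multi-copy region (MCR)**. Because *w* exceeds common
short-read lengths, reads from an MCR interior are consistent with every
copy, and pipelines that keep only uniquely mapped reads starve those
interiors of coverage. Variants there are missed (false negatives) or
mis-assigned (false positives). `mcrscan` is for anyone who wants to
detect exact repeats in a genome, quantify this failure mode with a
controlled simulation, or filter variant files against repeat annotations.

The core algorithm tiles seed windows of length *w* at 1-bp steps, maps
each window to **all** of its exact occurrences genome-wide (both strands),
and merges maximal runs of consecutive windows whose occurrence sets shift
in lockstep into MCS groups of length `run + w − 1`. Every group shares one
MCS across a constant locus set; a change in the occurrence set splits
groups, and groups are maximal (one more base breaks identity). A
brute-force all-window string-identity oracle re-derives the same
decomposition independently and is required to agree exactly in the tests.

Around the finder, the package provides:

* a synthetic genome generator with planted exact (or divergent)
  duplications and truth annotation (`generate_background`,
  `plant_duplications`);
* SNV planting at one per kb in MCRs and matched flanks, diploid haplotype
  construction, and a wgsim-style paired-end simulator (`define_strata`,
  `plant_snvs`, `build_haplotypes`, `simulate_read_pairs`);
* a seed-and-verify read mapper whose uniqueness flag is a strict
  co-optimality test, plus an explicit-threshold pileup SNV caller
  (`build_index`, `map_read_pairs`, `pileup_and_call`);
* stratified accuracy / false-positive / false-negative evaluation
  (accuracy = TP/(TP+FP), fn = FN/(TP+FN)), all-to-all t-tests across
  sequencing strategies, and a matched-random-region chi-squared
  enrichment test (`evaluate_calls`, `compare_strategies_ttest`,
  `enrichment_test`);
* a factorial experiment driver crossing read lengths {75, 150} with
  depths {10, 30, 50, 100}× over replicates (`run_experiment_grid`), and a
  VCF-by-region extraction utility (`extract_variants_in_regions`).

## Worked example

```r
library(mcrscan)

bg <- generate_background(c(chr1 = 200000, chr2 = 200000), gc = 0.41, seed = 1)
tb <- plant_duplications(bg, list(
  duplication_spec(2000, 2, "inter"),
  duplication_spec(3000, 2, "intra"),
  duplication_spec(400, 2, "tandem")), seed = 2)

mcrs <- find_mcrs(tb$genome)   # 300 bp windows, 1 bp step, both strands
mcrs$groups
#>   group_id length n_loci
#> 1        1    400      2
#> 2        2   2000      2
#> 3        3   3000      2
summarize_mcrs(mcrs, tb$genome)
#> <mcr_summary> 3 group(s), 6 loci
#>   genome coverage: 2.7000%
#>   intra/inter-chromosome groups: 2/1
```

All three planted duplications are recovered at exactly their planted
lengths and loci (10,800 bp of MCRs = 2.7% of the 400 kb genome). Now the
simulation experiment on a small grid:

```r
cfg <- experiment_config(tb, read_lengths = c(75, 150), depths = c(10, 30),
                         replicates = 3, base_seed = 42)
res <- run_experiment_grid(cfg)
aggregate(cbind(accuracy, fn_rate) ~ strategy + stratum,
          res$report[res$report$stratum != "other", ], mean)
#>    strategy stratum accuracy fn_rate
#> 1 PE150_10x   flank     0.67   0.033
#> 5 PE150_10x     MCR     0.67   0.542
#> 2 PE150_30x   flank     1.00   0.000
#> 6 PE150_30x     MCR     0.87   0.631
#> 3  PE75_10x   flank     0.63   0.048
#> 7  PE75_10x     MCR     0.50   0.798
#> 4  PE75_30x   flank     1.00   0.000
#> 8  PE75_30x     MCR     0.78   0.689
```

The mechanism is visible directly: more than half of the variants planted
inside MCRs are never called (`fn_rate` 0.54–0.80, versus ≤ 0.05 in the
matched flanks) because read pairs wholly inside an exact repeat have two
co-optimal placements and are discarded by the unique-mapping filter.
Accuracy inside MCRs trails the flanks at every strategy.

A thin command-line dispatcher over the same functions ships in
`inst/cli/mcrscan.R` (subcommands `simulate-genome`, `find-mcrs`,
`mcr-variants`, `plant-variants`, `simulate-reads`, `map-call`, `evaluate`,
`enrich`), e.g.

```sh
Rscript inst/cli/mcrscan.R find-mcrs --fasta genome.fa --out-bed mcr.bed \
    --out-groups groups.tsv --summary summary.tsv
Rscript inst/cli/mcrscan.R mcr-variants --vcf calls.vcf --bed mcr.bed --out in_mcr.vcf
```

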