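# mixasm — multi-k de Bruijn transcriptome assembly at desk scale

Transcriptome shotgun sequencing covers each transcript in proportion to
its expression level, and expression levels follow a power law: coverage
depths in one experiment routinely span three to four orders of
magnitude. In de Bruijn (Euler-path) assembly the k-mer size k is the
minimum overlap that joins two reads, so a single k cannot serve the
whole transcriptome — weakly expressed transcripts need small k to be
joined at all, strongly expressed ones assemble better at large k where
sequencing errors cause less tangling. `mixasm` implements the multi-k
answer end to end, self-contained in one R package:

1. **Simulate** paired-end reads (36 bp, FR orientation, inserts uniform
   on [175, 225]) from synthetic transcripts with power-law expression
   and a position-ramped substitution error profile: the rate at 0-based
   read position *i* is `start + i * 0.005%`, with the 0.3%-average
   profile starting at 0.2%.
2. **Assemble** the reads at every k of a schedule (default 19, 21, ...,
   35) with a built-in canonical-k-mer de Bruijn assembler (multiplicity
   cutoff, tip clipping, bubble popping).
3. **Merge** the per-k contig sets: exact duplicate/containment removal,
   near-duplicate collapsing, then either exact suffix–prefix overlap
   merging (≥ 40 bp, unambiguous junctions only) or a second single-end
   de Bruijn pass at k = 39.
4. **Remap** the reads to the merged contigs for per-contig expression
   counts.
5. **Evaluate** any assembly against the reference transcripts:
   *overlap* precision/recall/F (union of all alignment areas, 100 bp /
   95% identity filters), stricter *consistent* measures (greedy
   bit-score selection with a 5% pairwise-overlap rule, one transcript
   per contig, no rearrangements), N50 and friends, and
   transcripts-detected (overlap recall ≥ 80%).

The Lander–Waterman model ties it together: treating each transcript of
length *G* as a genome sequenced at coverage *c* with reads of length
*L*, the expected number of contigs when overlaps of at least *k* are
detectable is

```
E[#contigs] = (c·G/L) · exp(−(1 − k/L)·c)
```

A k is *model-optimum* for a transcript when this expectation is ≤ 1,
and *empirically optimum* when the assembly at that k recovers the
transcript with consistent recall > 95%. `optimum_k_experiment()`
computes both classifications over a coverage × k grid and reproduces
the two qualitative phenomena that motivate multi-k assembly: optimum
k's sit on smaller values at low coverage, and sequencing errors push
the smallest usable k upward at high coverage.

## Worked example

```r
library(mixasm)

tx      <- generate_transcripts(20, c(500, 2000), seed = 42)
tx      <- sample_power_law_expression(tx, exponent = 2, seed = 43,
                                       max_count = 100)
profile <- allocate_reads(tx, 20000)
profile
#> Expression profile: 20 transcripts, 20000 read pairs
#>   coverage: min 34.61x, median 34.67x, max 207.92x

reads <- simulate_dataset(profile, profile_for_average(0.003), seed = 44)
run   <- run_pipeline(reads, mixasm_config(), references = tx)
run
#> Multi-k assembly run: k in {19, 21, 23, 25, 27, 29, 31, 33, 35}
#>   per-k contigs: 20, 20, 25, 26, 35, 41, 66, 60, 10
#>   merged contigs: 20
#>   merged consistent F: 99.88%

run$eval
#> Assembly evaluation
#>   overlap:     P 100.00%  R 99.76%  F 99.88%
#>   consistent:  P 100.00%  R 99.76%  F 99.88%
#>   contigs >= filter: 20  mean 1264.9 bp  largest 1826  N50 1596
#>   transcripts detected: 20

run$expression
#> Expression table: 20 contigs, 39909 of 40000 reads mapped (99.8%)
```

Twenty transcripts at 35–208x coverage with 0.3% average error assemble
into exactly twenty merged contigs recovering 99.76% of the reference
bases; the per-k columns show how higher k fragments the assembly
(66 contigs at k = 31, only 10 at k = 35) while the merged set keeps the
best of each. 99.8% of the reads remap to the merged contigs.

A command-line front end over the same functions ships in
`inst/cli/mixasm` (subcommands `simulate`, `assemble`, `merge`, `remap`,
`evaluate`, `lw-grid`, `pipeline`, `optimum-k-experiment`).

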