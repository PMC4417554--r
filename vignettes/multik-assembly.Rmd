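---
title: "Multi-k de Bruijn transcriptome assembly: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-k de Bruijn transcriptome assembly: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixasm)
```

## The problem

De novo transcriptome assembly from short shotgun reads differs from
genome assembly in one decisive respect: coverage depth is not roughly
uniform but proportional to expression level, and expression levels are
power-law distributed. A de Bruijn (Euler-path) assembler joins reads
through shared k-mers, so the parameter k acts as the minimum detectable
overlap between reads. Weakly expressed transcripts leave few overlapping
reads and need a small k to be joined at all; strongly expressed
transcripts provide deep coverage where a larger k is preferable because
it is less tangled by sequencing errors and repeats. No single k serves
both ends of the expression range.

`mixasm` implements the whole multi-k workflow at desk scale: simulate a
transcriptome shotgun experiment, assemble the reads at every k of a
schedule, merge the per-k contig sets into one assembly, remap the reads
for expression counts, and score the result against the reference
transcripts.

## The Lander–Waterman view of the optimum k

Treating each transcript of length $G$ as the "genome" of a small
sequencing project with read length $L$ and coverage depth $c$, the
expected number of contigs when an overlap of at least $k$ bases is
required to join two reads is

$$ E[\#\text{contigs}] = \frac{cG}{L} \, e^{-(1 - k/L)\,c}. $$

`lw_expected_contigs()` evaluates this, `lw_optimum_k()` classifies a k
as *optimum* for a transcript when the expectation is at most one (the
transcript is expected to assemble into a single contig), and
`lw_grid()` tabulates, over coverage bins and k values, the fraction of
transcripts for which each k is optimum. Because the expectation is
nondecreasing in k at fixed $c > 0$, optimum-k sets are always
downward-closed prefixes of the candidate list; the model predicts that
transcripts of low coverage have their optimum k's concentrated on small
values. The empirical counterpart (`empirical_optimum_k()`, threshold:
consistent recall strictly above 95%) lets the two views be compared
cell by cell.

Coverage bins default to powers of two (2, 4, ..., 16384), matching the
usual coverage ladder of such experiments; the bin edges are a free
choice and configurable.

## The read simulator

`simulate_dataset()` emulates a paired-end transcriptome shotgun
experiment:

* **Expression.** `sample_power_law_expression()` draws per-transcript
  EST counts from a discrete power law $P(X = x) \propto x^{-a}$ on
  $1..\texttt{max\_count}$. The exponent defaults to $a = 2$: the data
  being emulated are only described as power-law with coverage spanning
  roughly four orders of magnitude (about 1 to 4,266), and a Zipf
  exponent of 2 with the default support reproduces that spread. Both
  knobs are configurable.
* **Read allocation.** Read pair counts are proportional to
  `est_count * length` with largest-remainder rounding
  (`allocate_reads()`), so the total is conserved exactly and the
  allocation is invariant to rescaling the weights. Coverage per
  transcript is `reads * 2 * read_length / length`.
* **Fragments.** Insert sizes (total fragment length) are uniform
  integers on [175, 225] by default and fragment starts are uniform over
  the transcript; mate 1 is the 5' prefix of the fragment and mate 2 the
  reverse complement of its 3' suffix (FR orientation, 36 bp each by
  default). "Insert size" is interpreted as the full fragment length,
  the common usage consistent with 175–225 bp fragments sequenced as
  36 bp mates.
* **Errors.** Substitutions only, with a linearly ramped per-position
  probability: position $i$ (0-based) is substituted with probability
  $\texttt{start} + i \cdot \texttt{increment}$, to a uniformly chosen
  different base. The default increment is 0.005 percentage points per
  position. For the standard series of average rates (0.3%, 0.6%, ...,
  2.4% at 36 bp) the starting rate is the average minus 0.1 percentage
  points — 0.3% average starts at 0.2%, 2.4% at 2.3% — following the
  convention of the experimental series being emulated; note this is not
  exactly the analytic mean of the ramp (a 0.2% start with 0.005%/nt
  increment averages 0.2875% over 36 positions), and
  `profile_for_average()` therefore uses the series mapping only for
  those listed rates and the analytic mapping
  $\texttt{start} = \texttt{avg} - \texttt{inc}\,(L-1)/2$ for any other
  average. Indels, homopolymer artefacts and trained quality models are
  out of scope.
* **Truth and output.** Every pair records its source transcript,
  fragment start, insert size and substituted positions; FASTQ qualities
  encode the expected per-position error rate (Phred+33), so the quality
  string is a deterministic function of the profile.

What passing tests on these data do *not* show: real transcriptomes have
repeats, shared isoform structure and alternative splicing, which the
i.i.d.-uniform synthetic sequences lack entirely. On such data small k
additionally collapses repeats — a failure mode this generator cannot
exhibit — so results here isolate the coverage/error mechanism only.

## The built-in assembler

`dbg_assemble()` is a deliberately simple Euler-path assembler standing
in for the external tools a production pipeline would call, so that the
multi-k procedure is runnable and testable self-contained:

* canonical k-mers (a k-mer and its reverse complement are one node);
  k must be odd so no k-mer is its own reverse complement;
* a multiplicity cutoff drops noise k-mers: 2 when the mean k-mer
  multiplicity exceeds 10, otherwise 1 (chosen to mirror common
  Euler-path practice of removing singleton error k-mers only when
  coverage can afford it);
* *tips* (short dead ends, the typical product of an error near a read
  end) are clipped when shorter than `2k` bp and below the coverage of
  the strongest competing branch, iterated to a fixed point;
* *bubbles* (two short parallel paths, the typical product of an
  internal error) are popped keeping the higher-coverage arm; equal
  coverage resolves lexicographically so assembly stays deterministic;
  only simple two-arm bubbles with arm length difference up to 2 nodes
  are handled — nested or tangled bubbles are left in place and
  fragment the assembly, which is precisely the small-k failure mode at
  high coverage with errors;
* maximal non-branching paths become contigs, emitted in canonical
  orientation, ordered by length then lexicographically, filtered at
  100 bp by default.

Scaffolding, mate-pair resolution and quality-aware error correction are
deliberately absent. Stage 1 of the pipeline also accepts pre-computed
per-k contig FASTA files, so contigs from an external assembler can be
merged and evaluated identically.

## Merging per-k assemblies

Results from different k are redundant: the same transcript region
assembles at several k, with extents that differ and, occasionally, with
single-base differences where error bubbles were resolved differently.
`pool_contigs()` removes exact duplicates and exact substring
containments (either orientation, keeping the longer contig).
`merge_contigs()` then offers two strategies:

* `"overlap"` (default): join contigs across exact suffix–prefix
  overlaps of at least 40 bp, merging only unambiguous junctions (each
  contig end pairs with at most one partner). 40 bp is the conventional
  default overlap size of lightweight second-stage assemblers.
* `"dbg"`: re-assemble the pooled contigs as single-end reads with the
  built-in assembler at k = 39, mirroring a second-stage single-end
  de Bruijn pass.

Before either strategy, near-duplicate contigs are collapsed: a contig
is dropped when at least 95% of its bases align to one longer surviving
contig at ≥95% identity (the same identity convention the evaluation
uses). This step was a genuinely open design point: exact-only
containment provably leaves behind variant contigs that differ by a
single resolved error base, and a consensus-forming second-stage
assembler would absorb them; without this filter the merged assembly
carries redundant contigs whose alignments the consistent measures then
reject, charging the merged assembly for redundancy the merger was
supposed to remove. Inexact *junction* detection (merging across
non-identical overlaps with consensus) remains out of scope; at the
error rates simulated here, exact junctions plus the redundancy filter
suffice.

Merging never invents sequence — every merged contig is a chain of
pooled contigs with exact junction overlaps — and never increases the
contig count.

## Remapping and expression

`map_reads()` assigns each read to at most one contig: exact seeds
(17-mers at both read ends, both strands) index into the contigs, and
candidate placements are verified over the full read allowing at most
2 substitutions — matching the simulator's substitution-only error
model at 36 bp. Best placement (fewest mismatches) wins; ties go to the
longer contig, then the lexicographically smaller id, so mapping is
deterministic. Counts are conserved: mapped plus unmapped equals the
number of reads. No indel-aware alignment, no pair constraints, no
fractional multi-mapping — the remap stage's contract is expression
counts, not alignments.

## Evaluation

Contigs of at least 100 bp are aligned to the references (built-in
seed-and-extend ungapped aligner, or imported BLAST 12-column tabular
alignments) and alignments below 95% identity are discarded; both
thresholds are inclusive boundaries.

**Overlap measures** count the union of all alignment areas, once per
base: recall is the union on the reference side over the total length of
*all* references (aligned or not); precision is the union on the contig
side over the total length of the contigs passing the 100 bp filter;
F is the harmonic mean, defined as 0 when both are 0. Overlapping
alignments are never excluded, so overlap measures are an upper bound.

**Consistent measures** restrict the same formulas to a greedily
selected collection: walking alignments from highest to lowest bit
score, an alignment is accepted iff (a) on both the reference and the
contig side its overlap with every accepted alignment is at most 5% of
the shorter of the two spans on that side, and (b) all acceptances of
one contig share reference and strand (one contig stands for one
transcript) and are colinear in orientation-adjusted order (no
rearrangements). Three conventions had to be fixed where the procedure
is under-specified, and are implemented as follows: the 5% rule
normalises by the *shorter* of the two spans, checked independently per
side; consistency binds alignments of the same contig only, so two
different contigs may legitimately cover the same reference
(cross-contig redundancy is handled by the 5% rule); bit-score ties
break by longer alignment, then reference id, reference start and contig
id, making the collection invariant to input order. The precision
denominator uses filtered contigs only, since sub-100 bp contigs can
never contribute true-positive bases under the filtering rules.

Contig statistics (count, mean size, largest, N50 — shortest contig in
the smallest set of longest contigs reaching half the total length) and
transcripts-detected (references with overlap recall ≥ 80%) complete
the report. All interval arithmetic is 0-based half-open internally and
1-based inclusive at the BLAST-tabular boundary; the test suite checks
the union computations against a brute-force per-base boolean-array
oracle on randomized fixtures.

## Problem sizes and numerical choices

The package's standard benchmark ("mini" preset: `mini_transcripts()`,
`mini_expression()`) uses 200 transcripts of 500–3000 bp with power-law
expression capped so coverage spans roughly 2–500x once the read budget
anchors the least-expressed transcript at 2x, 36 bp pairs at 0.3%
average error, and k from 19 to 35 in steps of two — a desk-scale
analogue of a real mouse transcriptome shotgun experiment (tens of
thousands of transcripts, 80 million reads) chosen so a full multi-k run
takes tens of seconds. The optimum-k experiment
(`optimum_k_experiment()`) defaults to 4 transcripts of 1000 bp at
coverages 2x–2048x (powers of two) and error rates 0% and 0.3%; the
ladder must reach four-digit coverage because the error-driven upward
shift of the smallest usable k only materialises once error k-mers recur
often enough to survive the multiplicity cutoff and tangle the small-k
graph — at a few hundred x the cleanup still rescues k = 19, around
1000–2000x it no longer can. The k schedule's lower bound of 19 is
the conventional smallest useful k for 36 bp reads; the upper bound is
the largest odd value not exceeding the read length (35).

Degenerate inputs are defined, not special-cased: zero reads give empty
FASTQ files and empty assemblies; an empty alignment set scores
P = R = F = 0; empty coverage bins are reported as missing (`NaN`);
allocation with all-zero weights, infeasible error profiles and even k
are errors. All randomness flows through explicit integer seeds, and
every stage is deterministic given its inputs.

## Known limitations

* Random uniform transcripts carry no repeat or isoform structure; the
  repeat-collapse disadvantage of small k is invisible here, so multi-k
  gains measured on the synthetic benchmark are conservative relative to
  real data.
* The built-in aligner is ungapped; indel-containing assemblies would be
  under-scored (the simulator produces none).
* Exact-junction merging cannot join fragments across a divergent base;
  such fragments survive as separate contigs and the consistent measures
  charge for them.
* Mate-pair information is simulated and recorded but not used by the
  assembler (single-end graph only), matching the scope of the procedure
  being modelled.
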