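---
title: "Screening exon arrays and RACE-seq reads for novel RNA variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exon arrays and RACE-seq reads for novel RNA variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racescreen)
library(dplyr)
```

racescreen implements a two-stage strategy for finding novel RNA variants
in tumor cohorts: an exon-level expression screen that nominates genes
whose 3′ end is overexpressed in individual samples (the signature of a 3′
fusion partner under a foreign promoter), followed by analysis of targeted
5′ RACE sequencing (RACE-seq) reads that identifies the upstream partner
and quantifies junction support. This vignette documents the models, the
tunable parameters, the numerical choices, and what the accompanying
synthetic-data module does and does not emulate.

## The expression break score

### Model

The input is a probe-set × sample matrix of log2 intensities, with probe
sets annotated by gene, genomic interval, strand and transcriptional order
(`order_index`, 1..k from the 5′ end; for minus-strand genes this runs
against genomic coordinates, and `read_expression_matrix()` derives it
from strand when the annotation omits it). Each probe set is first placed
on a common scale:

$$s_{ij} = \frac{p_{ij} - \mu_j}{\sigma_j}$$

where $\mu_j$ is the cohort **median** and $\sigma_j$ the cohort standard
deviation of probe set $j$. The median makes the centering robust to the
very outliers the screen is looking for. For the scale we use the ordinary
n−1 standard deviation about the mean: it is the standard definition, and
because a single deviating sample among ~100 inflates it by only a few
percent, the choice between mean- and median-based scale estimators has
little effect at cohort size. Both choices are fixed in
`normalize_probesets()`; probe sets whose SD does not exceed `sigma_floor`
(default `1e-8`, i.e. effectively constant columns) carry no usable signal
and are excluded rather than producing infinities. Missing values are
rejected outright — summarized exon arrays are complete, and silently
imputing would bias the medians.

For a gene with $k \ge 2$ retained probe sets, the expression break score
of sample $i$ is the largest absolute difference between the mean
normalized expression of the 3′ and 5′ sides over all $k-1$ intragenic
breakpoints:

$$\mathrm{EBS}_{ig} = \max_{j=1,\dots,k-1}
  \left| \mathrm{mean}(s_{i,j+1},\dots,s_{i,k}) -
         \mathrm{mean}(s_{i,1},\dots,s_{i,j}) \right|$$

`ebs_profile()` is the scalar reference implementation; `ebs_all()`
evaluates the same contrasts vectorized over samples, and the test suite
checks the two against each other and against exhaustive enumeration.

Two numerical details are worth stating. Ties in $|d_j|$ are broken toward
the smallest $j$, so results are deterministic; and accumulated rounding
in the running sums is snapped to an exact zero (threshold
$10^{-10}\max(1, \max|s|)$) so a constant profile reports direction
`none` rather than an arbitrary sign. A single breakpoint — the argmax —
is reported per gene and sample; profiles with several breaks are outside
the model.

### Nomination and its thresholds

`nominate_candidates()` turns per-sample scores into a ranked gene list.
For each gene the *deviating sample* is the tumor or cell-line sample with
the highest EBS among profiles whose 3′ side is up (`d > 0`); 5′-up
profiles are never nominated because fusion expression is expected to be
driven from the 5′ partner's promoter. Three filters follow:

* **No elevated normals** (`normal_ebs_max`). A gene whose break score is
  elevated in any normal sample is not cancer-specific. The default
  threshold is 4. This is a deliberate calibration against the null
  distribution of the statistic: the edge contrasts (one probe set against
  the mean of the remaining $k-1$) have standard deviation
  $\sqrt{1 + 1/(k-1)} \approx 1.07$ at $k = 8$, so for a cohort of ~100
  samples a no-break profile exceeds an EBS of 2 roughly 10% of the time,
  and a cutoff of 2 would flag most genes through normal-sample noise
  alone — with ten normals, around three quarters of all genes. A cutoff
  of 4 sits above the practical null range while still firing on normals
  with genuine expression steps.
* **Flanking probe support** (`min_probes_5`, `min_probes_3`, default 2).
  A breakpoint inferred from a single flanking probe set is fragile; the
  filter requires more than one probe set on each side, with
  `probe_count_overrides` admitting named exceptions for very high-scoring
  genes targeted by a single 5′ probe set.
* **Exclusion list** (`excluded_genes`). Paralog cross-hybridization and
  already-annotated alternative transcripts are matters of curation, not
  computation; the package accepts a user-supplied list rather than
  attempting automated paralog detection.

Survivors are ranked by EBS and truncated to `top_n`; each emitted
candidate carries a `filter_log` recording the decisions, and the dropped
genes with their first failing filter are attached as an attribute.

### What effect sizes are detectable

The null analysis above also bounds what the screen can recover. With
noise SD 1 and $k = 8$, a planted 3′ step of $\delta$ log2 units yields a
break score near $\delta$ with spread ~0.5, while the per-gene maximum of
the null over 100 tumor samples concentrates around 2.2–2.6. Steps of
$\delta = 6$ are therefore recovered essentially always (the recovery test
in the suite asserts this), while $\delta = 3$ sits *on* the noise
ceiling: the planted sample is the gene's top scorer only about half the
time, and ranked lists at that effect size mix true and false positives.
This is a property of the statistic, not of the implementation — published
screens of this design report candidate lists whose minimum scores sit
just above the same ceiling and lean on manual curation — and the
acceptance report states the measured recovery at $\delta = 3$ rather than
an aspirational one.

## RACE assay planning

`plan_assays()` is bookkeeping: one nested RACE assay per candidate and
per positive-control gene, run separately in every sample, so first-round
reactions number (candidates + controls) × samples. `place_primer_windows()`
places design windows in transcript coordinates — the nested gene-specific
primer (NGSP) window immediately 3′ of the suspected breakpoint, the
first-round primer (GSP) window beyond it, and a forward internal control
primer (ICP) window 5′ of the break — and projects them through the exon
model onto the genome, splitting across exons and running right-to-left on
the minus strand. The default window length is 300 bp, clipped at
transcript ends; a `margin` parameter moves the NGSP window further
downstream for assays that must leave room for sequencing reads on both
sides of a suspected breakpoint. `check_primer()` verifies the length
(23–28 nt) and GC content (50–70%) constraints of touchdown-PCR RACE
primers; melting temperature belongs to the primer-design software and is
reported as unchecked rather than re-implemented from thermodynamic
tables.

## RACE-seq read analysis

All read-level matching is exact or bounded-mismatch string matching
against desk-scale references. That is a deliberate scope decision: the
package's simulations are error-free or low-error and its references are
toy transcriptomes with globally unique 20-mers, so indel-aware alignment
would add machinery without changing any answer. On real data these steps
would sit downstream of a spliced aligner.

* `trim_adapter()` removes, from each mate independently, the longest read
  prefix matching a suffix (or the whole) of the 5′ template-switch
  adapter with at least `min_overlap = 5` aligned bases and mismatch rate
  at most `max_mismatch_rate = 0.1`. Trimming never lengthens a read and
  is idempotent at mismatch rate 0.
* `find_primer_reads()` emulates a grep-based rescue: it returns reads
  containing any exact substring of the NGSP of length at least
  `min_match_len = 15`, in either orientation, reporting position, length
  and orientation of the best match. Fifteen bases makes a random hit in
  a toy read set vanishingly unlikely (~$10^{-7}$ per read) while
  tolerating reads that clip into the primer.
* `split_map()` finds all maximal exact matches of length at least
  `seed_len = 20` between a read (both orientations) and the transcripts,
  then greedily covers the read with non-overlapping segments, always
  taking the candidate that extends furthest from the leftmost uncovered
  base. A read is chimeric when its cover uses two or more genes. Twenty
  bases matches the uniqueness guarantee of the simulated references.
* `build_scaffold()` concatenates the upstream partner's transcript up to
  its breakpoint with the downstream partner's from its breakpoint.
  Breakpoints must coincide with annotated exon boundaries — fusions formed
  through intact splice sites — and the flank default of 150 bp per side
  accommodates full containment of 150 nt reads.
* `count_junction_reads()` realigns mates to the scaffold (full
  containment, at most `max_mismatches = 0` substitutions, both
  orientations). A **split read** crosses the junction with at least
  `min_overhang = 10` bases on each side; a read ending exactly at the
  junction has overhang zero and never counts. A **spanning pair** has one
  mate entirely on each side with neither touching the junction. Both
  counts are of distinct read ids: duplicate sequences under different ids
  count separately, and one crossing mate suffices for the pair to count
  once. This single counting rule is used everywhere; published
  split-read counts from different tools can disagree with each other
  precisely because such rules differ.
* `scaffold_kmer_search()` counts reads containing the exact $2h$-mer
  centered on the junction for half-lengths $h \in \{8, 10, 15, 20, 24\}$
  (either orientation). Longer spanning k-mers nest inside shorter ones,
  so counts are non-increasing in $h$ — a useful internal consistency
  check when validating a junction by grep in external read sets.
* `exon_coverage()` attributes each read once per overlapped exon through
  its leftmost segment, reports reads per kilobase of exon sequence (RPK),
  and normalizes per-gene counts across samples with median-of-ratios
  size factors (`size_factors()`; genes with a zero count in any sample
  are excluded from the median, and the test suite cross-checks the
  factors against DESeq2's implementation).

## Junction filtering and validation

Junctions are identified by chromosome, the 1-based coordinate of the last
base of the upstream exon (`pos1`), the first base of the downstream exon
(`pos2`), and strand; `junction_span()` is `pos2 − pos1`. BED12 junction
records (two blocks flanking one junction, support in the score column)
are converted at the boundary — BED is 0-based half-open, so
`pos1 = chromStart + blockSize1` and `pos2 = chromStart + blockStart2 + 1`
— and a plain five-column TSV is accepted interchangeably. Strand `*`
(unknown, from unstranded dialects) matches either strand in all set
operations.

The discovery cascade (`filter_cascade()`) keeps junctions supported by at
least `min_reads = 100` split reads in at least one sample, removes those
present in the annotation key set, and removes anything detected — any
support at all, count ≥ 1 — in a normal or body-map sample. "At least one
sample" and "≥ 100" are the chosen readings of thresholds that could also
be read strictly; both are parameters, so either reading is expressible.
The three filters only ever remove junction keys and never alter the
per-sample counts of survivors, which makes them commute — a property the
test suite asserts.

`validate_junction()` probes one junction across named cohorts with
per-dataset thresholds written the way methods sections state them
(`">10"`, `">=2"`, `">=1"`): a sample is positive when its split-read
count satisfies the comparison, and the summary reports positives, totals
and fractions per dataset.

## The synthetic-data module

Every stage has a seeded generator whose outputs carry truth labels, so
end-to-end behavior is testable without downloads. All generators are pure
functions of their configuration and seed (the suite asserts byte-identical
reruns), and their defaults are the study conditions the package's tests
use.

* `simulate_expression_cohort()`: probe-set baselines ~ N(8, 1), Gaussian
  log2 noise (SD 1), 100 tumors + 10 normals over 200 genes of 8 probe
  sets; planted breaks add δ to the probe sets 3′ of a breakpoint in one
  named sample (negative δ plants a 5′-up profile). Noise is Gaussian on
  the log2 scale, as for summarized arrays; heavier-tailed intensity
  models are out of scope.
* `simulate_reference()`: 10 genes × 6 exons × 120 bp on a toy chromosome,
  alternating strand, rejection-sampled so no 20-mer repeats across
  transcripts in either orientation. `plant_fusion()` joins exons through
  intact boundaries and records the genomic breakpoints that
  `build_scaffold()` must be given.
* `simulate_race_reads()`: each source transcript yields an amplicon of
  5′ adapter + transcript prefix ending at the NGSP site; fragments are
  drawn uniformly along the amplicon with Normal(300, 60) lengths
  (tagmentation idealized as uniform — no insertion-bias model), paired
  2 × 150 nt reads are cut from the fragment ends with the second mate
  reverse-complemented, and substitutions are applied at `error_rate`.
  The shipped 30-mer adapter is a documented stand-in, since real
  template-switch oligo sequences are proprietary kit components. Truth
  labels record per-mate junction crossing and overhang, adapter content
  and primer-site overlap. No PCR duplication, GC bias, indels or
  quality-score error model — so passing tests demonstrate the logic of
  the read analysis, not robustness to real instrument artifacts.
* `simulate_junction_cohorts()`: 19 tumors + 3 cell lines versus 1 matched
  normal + 16 body-map tissues, with three planted junction classes —
  annotated (broadly present, listed in the known set), normal-shared
  (present in at least one normal), and novel-cancer (tumor/cell-line
  only, with one carrier guaranteed ≥ 100 + Poisson(50) reads at
  prevalence 0.4). By construction the filter cascade must return exactly
  the novel-cancer class, which is what the end-to-end test asserts.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated data at
the sizes above: a 110 × 1600 expression matrix, ~400 read pairs per
read-analysis scenario, 155 junctions across 39 samples, and 1000 random
profiles for the enumeration check. These sizes give stable statistics
while keeping a full run to a few minutes on one core. Every source of
randomness flows through an explicit seed argument; the acceptance script
derives all of its seeds from its single `--seed` flag.

## Known limitations

* The break-score model assumes one breakpoint per gene and sample;
  multi-break profiles report only the argmax.
* Detection power at effect sizes near the null ceiling (δ ≈ 3 at noise
  SD 1) is intrinsically partial; see the calibration discussion above.
* Read analysis is exact-match based and desk-scale; it is a stand-in for
  spliced alignment, not a replacement on real data.
* The junction identity ignores transcript context; two junctions with
  identical coordinates on opposite strands are distinct unless either
  strand is unknown.
* Coverage normalization uses plain median-of-ratios; no length-bias or
  GC correction is attempted for amplicon data.
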