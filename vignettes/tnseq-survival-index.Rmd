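---
title: "Survival-index analysis of Tn-seq selection screens: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-index analysis of Tn-seq selection screens: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

A Tn-seq selection screen starts from a pooled library of transposon
insertion mutants — here modelled on a saturated mini-Tn10 library in
*E. coli*, with about one insert per 20 bp and therefore roughly 25 distinct
mutants per gene or intergenic region. The pool is split, one aliquot grows
under control conditions and the others are exposed to a bactericidal
treatment; survivors are plated, pooled, and the transposon-genome junctions
are sequenced. The read count of each insertion site measures the abundance
of one mutant lineage before and after selection.

`tnseqsi` computes the per-feature statistic this design calls for. For a
feature (gene or intergenic region) of length $\ell$ on a genome of length
$L$, in a sample with $N$ total reads of which $n$ map into the feature:

$$
\mathrm{predicted} = N\,\frac{\ell}{L}, \qquad
\mathrm{Dval} = \frac{n}{\mathrm{predicted}}, \qquad
\mathrm{SI} = \frac{\mathrm{Dval}_{\mathrm{treated}}}{\mathrm{Dval}_{\mathrm{control}}}.
$$

Dval is a length- and depth-normalised abundance: Dval = 1 means the feature
holds exactly its genomic share of the library. The survival index SI is the
fold-change of that abundance under treatment. SI = 1 is neutral; SI > 1
means insertions in the feature *improve* survival (the intact gene product
contributes to killing); SI < 1 means they sensitise. SI is computed per
biological replicate and averaged (arithmetic mean, with the SEM reported);
because SI is a ratio a geometric-mean mode is provided as an option, but
the arithmetic mean across replicates is the default and the headline
number.

Two robustness rules surround the statistic:

* **Minimum-site filter.** A feature is only reported when it contains at
  least `min_sites = 3` distinct insertion sites — fold-changes supported by
  one or two mutant lineages are dominated by lineage-specific noise. The
  filter counts sites in the *control* sample of each replicate: the control
  pool is the library's pre-selection representation, and treatment removes
  sites rather than adding them. Counting sites in the union of both
  samples is available via `site_filter = "union"`.
* **Undefined, not zero.** When the control Dval is 0 the SI is undefined
  and propagates as `NA`, never as a silent zero or an infinity. No
  pseudocount is applied by default; `pseudocount = n` adds `n` reads to
  every feature in both samples before Dval for users who want shrunken
  ratios, and is off unless requested.

## The generative simulator

Every stage of the pipeline is testable against ground truth because the
package carries a generative model of the whole experiment
(`make_genome()`, `make_annotation()`, `make_library()`,
`selection_scenario()`, `simulate_selection()`, `emit_reads()`).

The simulated experiment proceeds exactly as the screen it emulates:

1. **Library.** `round(density × L)` insertion events are placed uniformly
   over positions × orientations and collapsed to unique sites. The default
   density of 1/20 bp reproduces the saturation of the real library; a
   pooled library is taken to have a known number of picked mutants, so the
   event count is fixed rather than Poisson-distributed. Sites are keyed by
   (position, orientation): the transposon is oriented, and the two
   orientations at one base are distinct mutants.
2. **Growth and killing are deterministic.** Control abundances are
   multiplied by `control_growth` (default 40, the ~40-fold CFU increase of
   the 3-h control culture). In a treated sample each site's abundance is
   multiplied by `baseline_survival × s(feature)`, where
   `baseline_survival` is the survival of a *neutral* mutant at that dose
   (defaults 0.5 and 0.01, i.e. ~50% and >99% kill) and `s` is the
   per-feature survival factor — the simulator's planted ground truth,
   1 everywhere by default. Selection acts identically on every site within
   a feature; within-gene position effects are deliberately out of scope
   because SI is a per-feature quantity. A site under overlapping features
   with explicit factors receives their product.
3. **Stochasticity enters at the two sampling steps that dominate real
   screens.** Plating draws a multinomial of the per-sample colony count
   (defaults 100,000 / 50,000 / 1,000) over abundances; sequencing draws a
   multinomial of the read depth over the plated colonies. Modelling growth
   as a deterministic scalar and putting all noise into these two
   bottlenecks captures the dominant variance source (the 1,000-colony
   bottleneck) at a small fraction of the cost of per-cell branching
   simulations.
4. **Reads.** `emit_reads()` renders site counts as junction-PCR reads:
   junction + genomic sequence extending from the insertion point in the
   site's orientation + poly(C) tail, truncated to the read length
   (default 50). Fragment lengths are uniform on 200–600 bp (the sonication
   range); poly(C) tail lengths are uniform on 5–20 nt — only the tail's
   presence is observable after trimming, so its length distribution is a
   free choice. The junction sequence itself is a configurable placeholder
   (`tn_junction()`): real libraries define it through their PCR primers,
   and the simulator and trimmer simply use the same constant.

One RNG stream per scenario, seeded explicitly, with a fixed sample order
(control first, then treated samples in declared order) makes every
simulator output bit-identical across runs at a fixed seed; the end-to-end
pipeline writes byte-identical output directories.

### What the simulator does not emulate

No PCR duplicates, no sequencing errors or quality-score model, no chimeric
reads, no insertion hot/cold spots, no growth-rate differences among
neutral mutants, and a single replicon. Passing tests therefore demonstrate
that the *statistics and bookkeeping* are correct under the stated noise
model — not that the pipeline is robust to artefacts real sequencing data
can contain. Real data should arrive through an external aligner
(`ingest_alignments()` accepts SAM or BED6) where those artefacts are
handled by dedicated tools upstream.

## Coordinates and file boundaries

Internally everything is 0-based, half-open. Conversions happen only at
file boundaries: GenBank and SAM are 1-based inclusive, BED is already
0-based half-open. The insertion coordinate of a reverse-strand alignment
is the *rightmost* aligned base (SAM `POS − 1 + reference span − 1`),
because the junction-adjacent genomic base is the one nearest the
transposon regardless of strand. Ambiguously-placed fragments are excluded
from counting — never randomly assigned — and their count is logged, as is
the count of unmapped and rejected reads; the manifest asserts
`reads in = placed + unmapped + ambiguous + rejected`.

Intergenic features are derived as the maximal intervals not covered by any
gene, so promoters and other regulatory DNA are counted implicitly. On a
circular genome the two gaps flanking the origin are joined into a single
wrap-around feature, stored with `end > L` and interpreted modulo the
genome length. Gene + intergenic features tile the genome exactly when
genes do not overlap; where genes overlap, a site in the overlap counts
fully toward every overlapping feature (per-feature completeness matters
more for SI than global read additivity, which is then relaxed and the
unassigned/duplicated accounting reported).

## Numerical and degenerate-input choices

* Feature length is `end − start`, with no correction for overlap with
  neighbouring features.
* `dval()` returns `NA` when predicted reads are ≤ 0 (only possible at zero
  total reads); `survival_index()` returns `NA` when the control Dval is 0.
* Replicate means use only replicates with defined SI;
  `n_replicates_defined` is reported alongside. Features undefined in all
  replicates are kept in the table with `NA` mean.
* Ranking breaks ties lexicographically on `feature_id` and sorts
  undefined-SI features last, so reports are stable across runs.
* Junction matching tolerates `max_junction_mismatch = 1` substitution;
  the poly(C) trimmer only strips a terminal C-run of at least
  `min_polyc_run = 5` (shorter runs are indistinguishable from genomic
  C's), and fragments shorter than `min_fragment_len = 20` after trimming
  are rejected rather than risk spurious placements.
* `locate_fragments()` is an exact-match placement engine for desk-scale
  verification; it reports multi-hit fragments as ambiguous. Genome-scale
  real data belongs in an external aligner.
* An optional one-sample t-test on ln(SI) across replicates
  (`si_replicate_test()`) is provided for triage; the core report is means
  and SEMs only, and no multiple-testing machinery is included by design.

## Problem sizes

The bundled examples, tests and the acceptance script run the simulator at
desk scale: 200-kb genomes with ~150 genes (~10,000 insertion sites),
plating counts of 50,000–100,000 and sequencing depths of 10^6 reads per
sample, three replicates. These sizes keep every property of interest
(neutral calibration, bottleneck noise, planted-effect recovery within
±30% at s = 10) measurable in seconds. For full-genome work the same code
paths accept a 4.6-Mb annotation and aligner output unchanged; only the
exact-match placement stage is deliberately desk-scale.

## Known limitations

Single-replicon genomes only (matching the target organism); no RNA-feature
classes; whether real pipelines collapse the two orientations at one base
into one site is not standardised — collapsing would change site counts by
at most 2× but no read sums, and this package keeps them distinct. The full
published screen can only be reproduced from the deposited sequencing runs
plus an external aligner; the package documents that path (`README`,
*Reproducing the results*) but bundles no real data.
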