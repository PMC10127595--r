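---
title: "Delineating active prophages from induced-phage read coverage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating active prophages from induced-phage read coverage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysoscan)
```

## The problem and the measurement model

A lysogen spontaneously releases a small number of phage particles as it
grows. If the phage fraction of a culture is concentrated, DNase-treated and
sequenced, and the reads are mapped back to the host genome, the coverage
track separates into three regimes:

* **Background** — host DNA that survived the phage prep covers the whole
  genome thinly and evenly (tens of fold).
* **Prophage core** — the packaged phage genome covers its integration locus
  three to four orders of magnitude above background (in real data, tens of
  thousands of fold against ~35-fold background).
* **Flank** — when packaging runs past the prophage end (headful packaging,
  specialized/lateral transduction), host DNA on one side of the prophage is
  over-packaged at an intermediate level, one to two orders of magnitude
  above background.

Two artifacts complicate the picture. Multi-copy identical insertion
sequences (IS) make reads from an IS inside the prophage multi-map: under a
random-best assignment each chromosomal copy receives an equal share of
those reads, creating spurious peaks far from the prophage — and a
corresponding coverage *dip* inside the prophage over the internal copy.
And a fraction of reads (sequencing-kit contaminants) maps nowhere.

`lysoscan` implements this whole measurement chain as testable code: a
synthetic lysogen simulator with ground truth, a small seeded read mapper, a
fold-enrichment segmentation caller, interval comparison against external
prophage predictions, IS mobilome profiling, and culture/virion statistics.
Coordinates are 0-based half-open everywhere internally and 1-based
inclusive in reports (BED-compatible arithmetic internally, conventional
genome coordinates at the reporting boundary).

## The caller

`call_prophages()` runs five stages.

1. **Background estimation** (`estimate_background`): the global median of
   the track, zeros included. Enriched features occupy far less than half of
   a bacterial genome, so the median is insensitive to them; a masked-interval
   option exists for unusual inputs. All-zero or majority-zero tracks are an
   error, never a silent zero.
2. **Smoothing** (`smooth_track`): a running median (default window 201 bp,
   Tukey endpoint rule at the edges). A median, unlike a mean, does not smear
   a 1,000-fold step into intermediate values, and it removes single-position
   spikes entirely.
3. **Segmentation** (`segment_coverage`): each position's fold over
   background is classified as background (< `flank_fold`), elevated
   (≥ `flank_fold`) or enriched (≥ `core_fold`); maximal constant-level runs
   become segments; same-level segments separated by at most `merge_gap` bp
   of strictly lower level are merged, and the bridged gaps are kept as
   `dips`; segments shorter than `min_peak_len` are dropped. The merge step
   is what rides over the IS-caused internal dip without fusing distinct
   prophages.
4. **Boundary refinement** (`refine_boundaries`): the plateau is the median
   of the segment interior; boundaries move to the outermost positions
   holding at least `max(core_fold × background, plateau / 2)`, never
   extending beyond one smoothing window. The half-plateau rule pins the
   edge of the ~read-length coverage ramp a sharp feature produces, so the
   recovered edges sit within roughly half a read length of the truth. A
   segment whose plateau does not exceed background is returned unchanged
   and flagged.
5. **Classification** (`classify_segments`): enriched segments at least
   `min_core_len` long are cores; elevated segments within `merge_gap` of a
   core are that core's flank (reported separately — a flank never extends
   the core's coordinates, because the over-packaged host DNA is not part of
   the phage genome); remaining segments overlapping an IS annotation and at
   most twice its length are repeat artifacts; anything left is an artifact
   marked `unexplained`.

### Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `core_fold` | 500 | fold over background | sits between observed flank folds (~15–60) and core folds (~1,700–4,300) with wide margins on both sides |
| `flank_fold` | 10 | fold | below the flank regime, well above Poisson noise on a ≥30-fold background after smoothing |
| `min_core_len` | 5,000 | bp | a tailed-phage genome is tens of kb; excludes IS-scale peaks from core status |
| `min_peak_len` | 200 | bp | drops sub-read-scale blips |
| `merge_gap` | 2,000 | bp | bridges an IS-length internal dip; distinct prophages are typically much farther apart |
| `smooth_window` | 201 | bp (odd) | two read lengths; removes spikes without displacing a step by more than half a window |

The decision rule is deliberately magnitude-based, not model-based: the
phenomenon is a three-to-four-order-of-magnitude contrast, and calls are
invariant under any positive rescaling of the track (a property the tests
assert). A Poisson/FDR enrichment model would add nothing at these effect
sizes and is out of scope.

## The simulator and what it does (not) emulate

`simulate_genome()` plants prophages (with one-sided flat or geometrically
decaying flanks) and IS families (identical sequence per family, which is
exactly what creates multi-mapping) in a uniformly random circular replicon
of chosen GC. `simulate_phage_reads()` draws read starts as a Poisson
process with per-base rate `expected_profile / L`, applies substitution
errors, both strands, circular wrap, and appends contaminant reads drawn
from a fixed unrelated 50-kb sequence; every read carries a truth label.
`simulate_host_reads()` is the uniform-depth negative control.
`expected_coverage_profile()` is the analytic expectation used as the
simulator's and the caller's oracle.

For coverage-level experiments at real-data depths (70,000-fold cores imply
tens of millions of reads), `simulate_poisson_coverage()` draws the same
per-position start counts and convolves them with the read length without
materialising sequences. This preserves the sampling structure that matters
to the caller — Poisson noise and ~read-length ramps at sharp edges — at
desk scale. Because start rates follow the profile, simulated "reads" can
run past a feature's right edge (as headful packaging does past a pac
site); both core edges are still recovered to within ±200 bp.

Deliberate simplifications: substitution errors only (coverage analysis is
insensitive to indel realism); no mechanistic packaging model (flank
over-packaging is phenomenological — a rate, a side, an extent, a decay
shape); no long-read simulation; replicons are simulated circular but
tracks are treated as linear by the caller, which only matters for features
near the origin (the test genomes never put them there). Passing tests on
this generator show the caller recovers planted structure under realistic
fold ratios and Poisson sampling; they cannot show robustness to mapper
biases, GC-coverage coupling, or strain heterogeneity, which real data add.

Default study conditions follow the real experiment where it states them:
~35-fold background, flanks around 500–2,000-fold, cores around
60,000–150,000-fold, 2×101-bp-style reads at length 100, sampling at 0, 6,
12, 24, 36, 48 h, duplicate cultures, a 7.1-h doubling time for the
fast-growing strain. The flank's physical extent is not stated anywhere, so
it is a free parameter (default 10 kb at paper scale, 3 kb in the desk-scale
demo). Unit tests run a scaled profile (background 5, flank 100, core 5,000
on ≤ 300-kb replicons): fold ratios, not absolute depths, drive every
decision in the caller, and the scale-invariance test makes that explicit.

## The mapper

`build_index()`/`map_reads()` implement seed-and-verify placement: exact
k-mer anchors (k = 21 by default) at `max_mismatches + 1` evenly spaced
offsets — the pigeonhole guarantee that a read with at most
`max_mismatches` substitutions has at least one clean anchor — then
full-read Hamming verification, collecting *all* equally best loci.
`max_mismatches` defaults to 2 because a 100-bp read at ≤1% error carries
fewer than one expected substitution. Multi-map policies: `random_best`
(seeded; the default, and the semantics under which an n-copy repeat splits
its reads 1/n per copy — the mechanism behind the artifact peaks),
`unique` (discard multi-mappers) and `all_weighted` (every best locus at
weight 1/n, under which coverage totals conserve placed bases exactly).
Pairs are mapped as independent singletons: nothing downstream uses
pairing. The mapper exists so the pipeline is self-contained and testable
end to end against a brute-force substring-search oracle; externally
produced BedGraph coverage is an equally valid entry point
(`read_bedgraph`).

## Prediction comparison, mobilome, growth statistics

`compare_intervals()` matches each external prediction to the called core
with the greatest base overlap (ties: smaller summed boundary offset, then
leftmost; many-to-one by design, since external predictors fragment), and
reports Jaccard, base-level precision/recall, and signed boundary offsets.
The tie-break rule is a determinism requirement, not a scientific claim.

`is_totals_and_density()` reports counts and per-Mb densities with the
rounding convention recorded in the output, because published density
tables do not always follow from published lengths under any single
convention and the convention must therefore be explicit.
`windowed_density()` assigns an element to the window holding its midpoint
— the one rule that makes windows a partition, so counts always sum to the
total. `consecutive_duplicates()` counts adjacent same-family pairs within
`max_gap` (default 500 bp — adjacency is not defined quantitatively in the
literature this emulates, so the threshold is exposed and reported); a run
of n elements counts n − 1 pairs. `plasmid_feature_screen()` matches
gene-name-shaped tokens only (`repA/B/C`, `tra*`, `par*`), so free text
like "transposase, partial" cannot fire it.

`doubling_time()` computes `t / (3.3 · log10(b/B))`. The classical printed
form of this formula sometimes omits the logarithm; without it the
expression is dimensionally wrong and sends the doubling time to zero for
large growth, while with it 3.3 ≈ 1/log10(2) makes one doubling over `t`
hours return `g ≈ t`. The log form is implemented and the choice is
recorded here and in the function documentation. `capsid_volume()` is the
sphere volume, reported to two significant figures; published volume tables
match the sphere formula only for some rows, so the formula is stated
rather than fitted. `genome_size_from_capsid()` multiplies the volume by a
dsDNA packing density of 0.40–0.53 bp/nm³, calibrated once so a 60-nm
capsid implies 45–60 kb.

The growth simulator integrates `dP/dt = y·B(t) − δ·P` in closed form for
exponential `B(t)` (validated in the tests against independent numerical
integration), with an optional carrying-capacity cap handled on a fine
grid using the exact per-step update of the linear equation. Default yield
0.35 PLP·cell⁻¹·h⁻¹ and decay 0.01 h⁻¹ give a PLP:cell trajectory that
rises toward a low-single-digit maximum over 48 h, the regime the real
counts show; lognormal counting noise (σ = 0.1) emulates
microscopy-counting error.

## Numerical choices and degenerate inputs

* Problem sizes: recovery experiments run 50 Poisson-sampled tracks of
  200–300 kb (seconds each); the read-level artifact experiment maps ~350k
  reads on a 40-kb genome. These sizes make every stochastic claim in the
  tests cheap to re-verify while preserving the fold ratios that drive the
  method.
* Seeds fix every stochastic step (genome, reads, random-best tie-breaks,
  noise); identical seeds give byte-identical FASTA/FASTQ and identical
  placements.
* Zero-coverage tracks, zero-median backgrounds, empty read sets,
  even-length smoothing windows, overlapping BedGraph intervals, negative
  coverage, end ≤ start intervals, b ≤ B growth, non-positive diameters:
  all are explicit errors with messages naming the offence, never silent
  corrections. Degenerate segments (plateau ≤ background) are flagged and
  passed through unchanged.
* The BED score column caps fold at 1000 (format convention); the JSON
  report carries the uncapped values.

## Known limitations

* The caller treats tracks as linear; a prophage spanning the replicon
  origin would be split into two calls.
* Flank classification requires proximity (gap ≤ `merge_gap`) to a core: a
  genuine flank beside a prophage that fell below `core_fold` is reported
  as an artifact, and an IS peak inside a flank merges into it.
* A uniformly elevated genome with IS peaks but no core — the
  gene-transfer-agent-like pattern — is reported as "0 cores + elevated
  artifacts", not as a distinct verdict.
* `all_weighted` coverage reduces variance but blurs the artifact-peak
  phenomenon `random_best` exposes; the choice is a flag, and the default
  follows the semantics that reproduces the observed artifact peaks.
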