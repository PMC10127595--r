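# lysoscan

Delineation of spontaneously produced prophages from induced-phage read
coverage, for microbial genomicists studying lysogeny and the mobilome.

Bioinformatic prophage predictors disagree with each other and routinely
truncate or fragment prophage regions. A direct measurement is available
instead: sequence the spontaneously produced phage fraction of a culture,
map the reads to the host genome, and read the prophage off the coverage
track. The packaged phage genome covers its integration locus thousands of
fold above the thin host-DNA background, over-packaged host DNA flanking
the prophage (lateral/specialized transduction) sits at an intermediate
level, and multi-copy insertion sequences (IS) create predictable spurious
peaks. `lysoscan` turns that measurement into a tested pipeline.

## Method

For a per-base coverage track `c(x)` with background estimate
`b = median(c)`, positions are classified by fold enrichment
`f(x) = c(x)/b` after running-median smoothing:

```
f(x) >= core_fold   (default 500)  -> enriched  (prophage-core level)
f(x) >= flank_fold  (default 10)   -> elevated  (flank level)
otherwise                          -> background
```

Maximal constant-level runs become segments; same-level segments separated
by ≤ `merge_gap` (2 kb) of lower-level coverage merge, bridging the
internal dip an IS inside the prophage causes under multi-mapped read
assignment. Core boundaries are refined to the outermost positions holding
`max(core_fold·b, plateau/2)`, where the plateau is the segment's interior
median. Segments are then classified: enriched ≥ 5 kb → **core**; elevated
adjacent to a core → **flank** (reported separately, never extending the
core); the rest → **artifact**, annotated with any overlapping IS. All
calls are invariant under positive rescaling of the track — the logic is
ratio-based throughout.

The package also provides: a synthetic lysogen simulator with full ground
truth (planted prophages, flank profiles, identical-sequence IS families,
contaminant reads, culture count series); a seeded k-mer read mapper
(seed-and-verify, all-best-loci, `random_best`/`unique`/`all_weighted`
multi-map policies) with BedGraph input/output so external coverage can
feed the caller directly; interval comparison against external prophage
predictions (Jaccard, base-level precision/recall, boundary offsets);
IS mobilome profiling (densities per Mb, windowed density, family classes
DDE/DEDD/HUH, consecutive duplicates, plasmid backbone screen); and
culture/virion statistics (doubling time `t/(3.3·log10(b/B))`,
PLP:bacterium ratios, sphere capsid volume, capsid-based genome size).

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 01
builds a 40-kb synthetic lysogen carrying an 8-kb prophage (1,000-fold
enriched, right-hand flank) and seven identical IS66 copies — one inside
the prophage, six elsewhere; steps 02–03 map the simulated phage fraction
(8% contaminant reads) and call regions:

```
phage_fraction: 324432/352914 mapped (91.9%), 36378 multi-mapped

<delineation_report> chr (40,000 bp): background 6.00x
  1 core, 1 flank, 6 artifact region(s)
  artifact chr:1,009-1,993    (985 bp,   88x fold)
  artifact chr:4,509-5,491    (983 bp,   90x fold)
  artifact chr:8,009-8,991    (983 bp,   87x fold)
  artifact chr:11,512-12,491  (980 bp,   88x fold)
  core     chr:15,076-23,024  (7,949 bp, 601x fold)
  flank    chr:23,025-26,047  (3,023 bp,  25x fold)
  artifact chr:29,008-29,989  (982 bp,   88x fold)
  artifact chr:33,513-34,489  (977 bp,   86x fold)
```

Reading this: the planted core `[15000,23000)` is recovered with +75/+24 bp
boundary offsets at 601-fold enrichment; the over-packaged flank is called
separately at 25-fold; and the six chromosomal IS copies appear as ~1-kb
artifact peaks at ~88-fold — each one the 1/7 share of the prophage-internal
IS copy's reads that `random_best` assignment hands to every identical
copy. The host-control track calls 0 cores. Steps 04–06 compare the call
against (synthetic) external predictions — no prediction matches the mapped
core exactly; best Jaccard 0.74 — and compute mobilome and growth/virion
tables under `results/`.

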