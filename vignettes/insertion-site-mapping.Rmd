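---
title: "Mapping integrated DNA payloads: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping integrated DNA payloads: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertmap)
library(dplyr)
```

## The problem

Gene-therapy vectors, transposons and knock-in donors integrate DNA payloads
into host genomes, sometimes where they should and often where they should
not. Junction-capture sequencing reads out integration sites directly: each
read spans the boundary between payload sequence and flanking host DNA, so a
correctly processed read pins one insertion to one genomic coordinate. Two
things make this harder than generic read mapping. First, amplification-based
library preparation over-represents some molecules, so raw read counts do not
measure clonal abundance; unique molecular identifiers (UMIs) ligated before
amplification are needed to count molecules rather than reads. Second, a
large fraction of mammalian genomes is repetitive, and a junction whose
genomic flank lies entirely inside a repeat cannot be uniquely placed at all
— these reads need their own, family-level treatment rather than silent
disposal.

`insertmap` implements the full workflow: structured-read parsing and UMI
deduplication, mapping, a coverage-shape filter for anchored insertion
calls, putative family-level calling for unanchored reads, annotation and
feature association — together with seedable simulators that make every
stage testable against known ground truth without touching real data.

## The structured read and its preparation

A junction read is modelled as

```
adapter – sample barcode – UMI – payload end – genomic flank
```

observed in either orientation. Preparation runs in fixed order:

1. **QC**: keep reads with mean per-base Phred quality strictly above 10 and
   length strictly above 200 bp. Both cutoffs are strict inequalities and
   configurable (`pipeline_config()`). The mean here is the arithmetic mean
   of Phred scores; tools that average error probabilities instead give a
   slightly different mean on heterogeneous quality strings, but the
   package's quality model (constant Q with optional jitter) makes the two
   coincide, and only the threshold crossing matters.
2. **Structure enforcement**: each element is located allowing up to
   `floor(0.1 * element length)` edits (configurable). The adapter is
   searched in both orientations; the barcode is assigned to the closest
   library barcode within 1 edit, with equidistant matches rejected as
   ambiguous rather than guessed; the UMI is the fixed-length window after
   the barcode; the payload end must be present downstream, and everything
   payload-ward of the junction is trimmed. The emitted fragment is
   *payload-first*: the genomic junction is fragment position 0, which
   makes the junction coordinate of an alignment a pure convention
   (start on `+`, end on `-`) rather than a heuristic.
3. **UMI clustering**: greedy centroid clustering in descending
   mean-quality order (ties by read id, so the traversal is deterministic).
   A read joins a cluster when its UMI is within 1 edit of the centroid UMI
   *and* its fragment has identity ≥ 0.9 to the centroid fragment. Identity
   is matched columns over the alignment length excluding terminal gaps,
   with the extra requirement that the overlap span at least 90% of the
   shorter sequence. The ends-free definition is deliberate: two reads from
   the same molecule differ only in how far the flank extends, so one is
   essentially a prefix of the other and must score identity 1; a plain
   ends-free ratio without the overlap floor, however, lets unrelated reads
   score perfectly over a few-base corner overlap, which we exclude.
4. **Consensus**: per-column plurality over members aligned to the longest
   member, ties broken by summed member quality and then alphabetically;
   single-member clusters pass through verbatim. Plurality consensus is
   deterministic and dependency-free; external polishing tools can replace
   it behind the same contract without changing anything downstream.

The greedy order means clustering is not exactly connected components: a
chain u1–u2–u3 of single-edit UMIs collapses or splits depending on which
read founds the cluster. With 12-nt random UMIs the probability that two
distinct molecules land within one edit is ~2×10⁻⁶ per pair, so chains are
vanishingly rare at realistic depths; the test suite checks equivalence with
a connected-components oracle on chain-free configurations, which is the
regime the method is designed for.

## Mapping and the anchored/unanchored partition

Fragments are mapped by a deterministic built-in seed-and-extend matcher:
exact 31-mers (15 for the short-read preset) from the fragment start, middle
and end, in both orientations, are matched in batch against every contig;
each candidate placement is scored by edit distance; the placement count at
the optimal score defines uniqueness. The mapping-quality surrogate is 60
for a unique optimum and 0 otherwise — deliberately coarse, because the
pipeline only ever asks "strictly above 30?". A fragment that spans from a
repeat copy into unique flank has multi-locus seeds but a unique optimal
placement, and is therefore anchored; a fragment wholly inside a
zero-divergence multi-copy repeat ties across copies and is not. A real
long-read mapper can stand behind the same interface (`mapped`, `mapq`,
`n_secondary` per fragment) for production data.

A read is **anchored** iff it maps with no secondary placements and
mapq > 30 (strict); everything else — unmapped, multi-mapping, low quality —
is **unanchored**. The two sets partition the input, which the run report
asserts on every run.

## Anchored peak calling and the beta shape filter

Anchored alignments are grouped into candidate peaks by connected interval
union (gap 0 by default): the spec of a peak is simply the maximal set of
reads whose reference intervals touch. For each candidate the per-base
coverage profile across the union span is tested for *shape*: genuine
junction pile-ups rise at the junction and decay once, whereas chimeric or
noisy pile-ups look multi-modal or ragged.

The statistic maps positions to bin midpoints $x_i = (i - 0.5)/L$ and
normalises coverage to a discrete density $d_i = c_i \cdot L / \sum_j c_j$
(so scaling coverage by any constant leaves the profile unchanged), then
fits a beta density by least squares:

$$\mathrm{RSS}(\alpha, \beta) = \frac{1}{L} \sum_{i=1}^{L}
  \left(d_i - f(x_i; \alpha, \beta)\right)^2 .$$

A candidate passes when RSS is strictly below 1. The beta family is a good
shape dictionary here: it covers uniform, one-sided ramps and single interior
humps — everything a true junction pile-up can look like — while two-mode
profiles cannot be approximated and fail with RSS well above 1. The fit is
by direct RSS minimisation (not moments or likelihood) because the filter
statistic *is* the RSS of the fit: a bounded grid over
$\alpha, \beta \in [0.1, 50]$ (step 1 by default) followed by multistart
L-BFGS-B refinement, both stages deterministic. `beta_shape_rss()` exposes
`grid_step` and `refine` so the grid backbone can be checked against
brute-force enumeration; the tests do exactly that at step 0.1. The
normalisation makes the printed threshold dimensionless, but because the
original statistic's normalisation is not recoverable in closed form from a
bare "RSS < 1", the threshold remains configurable, and
`evaluate_shape_threshold()` reproduces the labelled-profile calibration
design that motivates the default.

Calls take their coordinate from the modal member junction site (ties to the
smaller coordinate), their strand from the modal member strand (ties to
`+`), and their abundance `dedup_count` from the number of distinct UMI
clusters among members. Degenerate candidates spanning fewer than 3 bp skip
the fit and are rejected outright.

## Unanchored (repeat) calling

Unanchored reads are processed in four steps, each a separate function with
its own tests:

1. `discard_called()`: reads explained by an already-called insertion
   (identity ≥ 0.9 over at least half the read against the ±2 kb call
   flank) are removed. An exact 15-mer seed screen precedes the local
   alignment, which changes nothing for decisions but avoids aligning every
   read against every flank.
2. `assign_repeat()`: remaining reads are classified to a repeat family,
   either from an external hit table (e.g. a profile-HMM search) or by the
   built-in local-alignment classifier against family consensuses; below
   `min_assign_score` (default 30, comfortably above random-alignment
   scores for desk-scale reads) a read stays unassigned. Ties go to the
   lexicographically first family.
3. `cluster_by_identity()`: within a family, greedy clustering at identity
   ≥ 0.9 (longest read first) decides whether the family's reads represent
   one putative insertion or several.
4. `call_unanchored()`: a cluster is called when its deduplicated coverage
   reaches at least 50% of the mean deduplicated coverage of the anchored
   calls (inclusive ≥, since the rule's strictness is a convention; the
   comparison is deliberately between deduplicated counts on both sides —
   comparing raw reads to deduplicated peaks would be incoherent), and its
   pileup on the family-consensus coordinates passes the same beta shape
   filter. With no anchored calls at all, a configured floor
   (`unanchored_coverage_floor`, default 2 molecules) stands in for the
   undefined mean. All unanchored peaks are flagged putative: they name a
   family, not a coordinate, because placing them at a specific repeat copy
   is impossible by construction.

## Annotation and feature association

Repeat context uses a ±10 bp probe around the call site (a 21-bp closed
window mapped to half-open coordinates); the overlapping family with the
largest overlap wins, ties lexicographic. Genomic features are labelled with
fixed priority exon > promoter > intron > intergenic, promoters being a
2 kb strand-aware window upstream of the transcription start.

Association of insertion sites with an interval track (open chromatin,
histone marks, …) is scored per position as the number of track intervals
within ±100 kb (configurable; the window is read as ±window, i.e. a 200 kb
span) and summarised as the rank-based Mann–Whitney AUC against random
genomic positions, ties counting one half. Negatives are drawn uniformly
with contigs weighted by length, excluding positions within one window of a
contig edge so every negative has full window support. AUC above 0.5 means
insertions co-occur with the feature more than chance.

## The simulators: what they emulate, and what they do not

`build_synthetic_genome()` draws i.i.d. uniform A/C/G/T background — the
most mappable background possible, which maximises the contrast with the
planted repeat families (copies of a random consensus at configurable count
and per-base divergence up to 0.3). `plant_insertions()` adds truth sites,
optionally inside repeats; planted sites keep a minimum mutual distance
(default 1 kb) so independently planted peaks cannot merge, and an optional
margin from repeat edges controls whether in-repeat junction reads can
escape into unique flank. `simulate_junction_reads()` emits the full
structured read with Normal-distributed flank lengths (resampled to stay
positive, truncated — not discarded — at contig edges, mirroring real
fragmentation), a substitution/insertion/deletion error model applied
per base, constant-Q qualities with optional jitter, and uniformly drawn
sequencing orientation. One simulated read is one molecule;
`pcr_amplify()` layers exact PCR duplicates (uniform 1–50 per molecule) on
top, so UMI correction has something real to correct.

The read-length study (`run_length_study()`) samples random positions
uniformly over the genome — all positions are drawn *before* any read
lengths, so every length setting is simulated at identical locations, which
is what makes per-replicate detection differences attributable to length
alone. Default study conditions are 100 sites × 10 replicates per length
with sd 10 at 250 bp and 25 at 1000 bp. Peak calling is deliberately not
applied; detection means an anchored junction within ±20 bp of the truth
position. The ±20 bp default tolerance is a package decision on the scale
of the ±10 bp repeat-annotation window; it is exposed in the interface.

The dilution study (`run_lod_study()`) mixes two single-insertion read
pools at ratios 1:1 … 1:10⁴ with a binomial draw of the minor molecule
count at fixed total depth (1500 molecules by default), runs the full
pipeline per mixture, and reports whether the minor site is called with at
least `min_dedup` (default 4) deduplicated molecules. With these defaults
the expected minor yield is ~15 molecules at 1:100 and ~1.5 at 1:1000, so
the expected detection limit sits at the 1% dilution; the draw is seeded,
and the observable contract is that the pipeline's detection equals the
binomial sampling prediction exactly at the same seed.

What the simulators do **not** emulate: nanopore-specific error structure
(homopolymer compression, quality–error correlation), chimeric reads,
payload-internal rearrangements, biased integration-site selection, and
genome composition (GC structure, nested/fragmented repeats, satellite
arrays). Passing tests therefore demonstrate the pipeline's logic —
filters, accounting, deduplication, uniqueness handling, thresholds — under
a clean error model, not calibrated performance on real nanopore data.

## Numerical and degenerate-input conventions

* All interval arithmetic is 0-based half-open; BED files match natively.
* `beta_shape_rss()` rejects all-zero and shorter-than-3 profiles
  explicitly; peak spans below 3 bp are logged as degenerate, not fitted.
* Grid + multistart refinement makes the fit deterministic; no randomness
  anywhere in the pipeline proper — every stochastic step (simulation,
  negative-position draws, dilution sampling) takes an explicit seed, and
  fixed seeds give byte-identical outputs.
* Ties are always broken by a stated rule (smaller coordinate, `+` strand,
  lexicographic family/barcode), never by hash or insertion order.
* Problem sizes used in the shipped tests and acceptance script: a 2 Mb
  two-contig genome with a 30-copy 2-kb family for parameter recovery
  (50 planted insertions, 10 reads each), 100 sites × 10 replicates for the
  length study, ~10,500 amplified reads for the UMI study, and 5 × 1500
  molecules for the dilution series.

## Known limitations

* The built-in matcher is exact-seeded: reads with errors in all three
  seed positions go unmapped rather than being rescued; production use
  should supply an external mapper behind the alignment contract.
* The RSS threshold of 1 is calibrated to the package's own normalisation;
  porting the filter to a different normalisation requires re-running the
  labelled-profile calibration.
* UMI clustering is quality-greedy, not graph-optimal; see above for why
  this is immaterial at realistic UMI lengths.
* Unanchored calls are family-level and putative by design; the package
  never attempts to resolve which repeat copy received the insertion.
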