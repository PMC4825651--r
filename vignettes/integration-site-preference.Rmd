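---
title: "Methods: integration-site preference analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integration-site preference analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intsitepref)
```

This vignette documents the statistical model, the tunable parameters, the
synthetic-data generator, and the numerical and design choices behind
`intsitepref`. It is the package's reference for *why* each stage works the
way it does; the function help pages document *how* to call them.

## The analysis problem

An integration-site catalogue is a list of genomic positions where a
transposon or retrovirus inserted, each with a strand, a vector class, a
detection method (TAIL-PCR, inverse PCR, or linker-mediated-PCR NGS) and,
for NGS detections, a fragment count — the number of distinct sequenced
fragments supporting the site. The scientific questions are distributional:
does the vector prefer genes, promoters, particular chromatin features?
Does it favour sequences with a motif, or with elevated local
deformability? Every such question is a comparison against a null model of
where sites *would* land absent preference, and the detection protocol
itself distorts that null — restriction-digest libraries can only recover
sites at mappable distances from a recognition site. The package therefore
couples every statistic to an explicit matched-control generator.

## Fragment-count filtering

Selected (single-insert) NGS sets keep sites with fragment count
strictly greater than 50; TAIL-PCR and inverse-PCR detections carry their
own validation and pass unconditionally. Unselected (pooled, diluted) sets
use an inclusive cut-off of 7, except that sites whose insertion-point
neighbourhood (±20 bp by default) contains a recognition motif of one of
the library's enzymes — MseI `TTAA`, BfaI `CTAG`, Csp6I `GTAC`, all
palindromic — require at least 50 fragments, because artefactual junctions
concentrate at exactly those motifs as count-1 singletons. Both boundaries
and the window are exposed as arguments: the inclusive/exclusive reading
of "a cut-off of 7" and the motif window size are conventions, and the
filter report (`n_kept`, `fraction_RE`) lets the analyst verify that no
more than a tolerable fraction of kept sites are motif-adjacent.
Near-duplicate detections across methods are collapsed by single-linkage
clustering of insertion points within a 5-bp tolerance (deduplication
radius is not a biological quantity; 5 bp absorbs end-trimming jitter
between pipelines while never bridging independent sites at realistic
densities), keeping the maximum fragment count and the union of methods.

## Matched controls

**Uniform mode** emulates random insertion under mappability constraints:
a pool of 10⁶ random 50-bp locations (the 50-bp width mirrors typical read
length; use width 1 when the experimental sites are represented as points,
so that overlap geometry is like-for-like) restricted to an optional
mappability track, sampled without replacement into N replicate sets of
the experimental size. **Restriction-matched mode** reproduces
digestion-protocol bias: each experimental site is keyed by
(nearest enzyme, absolute distance), ties broken by the fixed enzyme order
then lower coordinate, and each replicate control is placed at exactly the
keyed distance from a uniformly drawn genome-wide occurrence of the keyed
enzyme, side chosen uniformly, off-chromosome placements redrawn. Matching
is *constructive*: the control provably lies at the keyed distance from
its recorded occurrence (this is asserted in the test suite by recomputing
distances), but its own nearest occurrence may be closer — an exact and
fast realisation of "same distance, same enzyme". The distance is absolute
rather than signed because site tables do not record the sequencing-primer
orientation that would justify a directional match.

N = 1000 replicates is the default; calibration and recovery studies in
the test suite scale N down (100–200) to keep runtimes in seconds.

## The bootstrap enrichment statistic

For feature track F: x = experimental overlap count (≥1 bp shared, each
site counted once, strand ignored), xᵢ = overlap count of control set i.

* ratio = mean over sets with xᵢ > 0 of x / xᵢ; zero-count sets are
  excluded from the mean (not pseudocounted — the printed formula is kept
  pure) and their number is always reported. If *every* set has xᵢ = 0 the
  ratio is undefined (`NA` with a warning) while the P-values are still
  returned.
* p_enrich = #{xᵢ ≥ x}/N and p_deplete = #{xᵢ ≤ x}/N. Ties count on both
  sides, which is the conservative resolution of "sets in which the
  feature was enriched or depleted"; consequently p_enrich + p_deplete ≥ 1
  and the minimum reportable P is 0, printed as "< 1/N".
* No multiplicity adjustment by default, matching the convention of
  reporting per-feature empirical P-values; `enrichment_panel(bh = TRUE)`
  adds Benjamini–Hochberg columns.

Because the empirical P is tie-inclusive and not add-one corrected, the
test is mildly conservative: with everything null, the flag rate at
P ≤ 0.05 sits slightly *below* 0.05 (continuous exchangeability would give
⌊0.05·N⌋+1 / (N+1); ties pull it further down). The package ships this
calibration study as `null_calibration_fraction()`, which
`scripts/acceptance.R` runs: 500 experimental sites drawn from the
controls' own uniform generator on a 2-Mb genome, 200 control sets, 200
random ~10%-coverage feature tracks. Typical values are 0.03–0.05.

## Gene context

Two assignment rules coexist because they serve different questions.
Region and metagene analyses use the window [TSS − 5 kb, TTS] along the
gene's own strand; expression association uses ±5 kb of TSS *and* TTS
(`downstream_bp = 5000`). A site is assigned to every gene whose window it
overlaps, and every subregion it touches is counted — an 8-bp target-site
duplication across an exon/intron boundary scores both. Exonic sequence is
split at the CDS bounds into 5′ UTR / coding exon / 3′ UTR; introns are
span minus exons; genes without an annotated CDS yield `noncoding_exon`.
The metagene position is 100 · (distance from TSS along orientation) /
(span length), over the unspliced span — "gene area", not mature
transcript. Interval sites use their midpoint for metagene and anchor
offsets while overlap rules keep the full interval.

Expression classes split FPKM at the zygotic-genome-activation boundary:
maternal = detected (FPKM ≥ 1, the conventional detection floor) at any
pre-ZGA timepoint, zygotic = at any post-ZGA timepoint, giving
maternal_only / zygotic_only / maternal_zygotic / silent. The ZGA column
index and the floor are arguments; genes missing from the expression table
are counted as silent and tallied.

## Sequence windows, motif matrices, flexibility

Windows are 48 nt, oriented 5′→3′ on the site's strand (minus-strand
windows reverse-complemented). Transposon (`tsd`) layout: 20 bases either
side of the 8-bp duplication, so the TSD occupies positions 21–28.
Point (`point`) layout: 20 before, 28 after, so position 21 is the first
integrated base. Windows running off the chromosome or containing `N` are
excluded (not masked — per-position averaging assumes complete windows)
and tallied.

The position matrix is the per-position base-frequency table with
information content 2 + Σ p·log₂p bits against a uniform background, no
small-sample correction by default (the matrix stays a pure function of
the frequencies; the e(n) correction is available for logo-tool parity).

The flexibility proxy is the set of six rigid-body base-pair step
parameters averaged over protein-bound DNA crystal structures, vendored as
a 16-step table whose reverse-complement symmetry (Twist/Roll/Rise/Slide
equal, Tilt/Shift negated) is asserted in tests, and whose orientation
convention is pinned by four anchor values asserted at every call:
Twist(GC) = 36.1°, Slide(GC) = 0.41 Å, Twist(GG) = 32.9°,
Slide(GG) = −0.22 Å. Each window contributes its 47 overlapping steps; per
position, values are averaged over windows, and the same reduction applied
to each replicate control window set yields the null envelope
(`ctrl_mean`, `ctrl_sd`). `profile_divergence()` reports
z = (exp − ctrl_mean)/ctrl_sd per position (flagged `NA` where the
envelope sd is 0) plus the empirical fraction of control replicates
deviating at least as far; it requires ≥30 replicates so the envelope sd
is meaningful.

A quantitative caution established while validating the planted-bias
generator: a bias applied to the *window-mean* parameter produces a
per-position shift of only β · sd(window mean). Overlapping dinucleotide
steps are strongly anti-correlated (adjacent-step Twist correlation
≈ −0.45), so sd(window mean) is about three times smaller than independent
steps would suggest — for Twist, ≈ 0.12° rather than 2.4°/√47 ≈ 0.35°.
Against a control envelope sd of σ_step/√n, a β = 0.5 tilt on n = 2000
sites yields expected per-position z ≈ 1, and the *maximum* central |z|
crosses 3 only with moderate probability. Detecting window-level
flexibility preferences of this size reliably needs ~10⁴ sites or β ≳ 1;
the package reports the per-position z-scores and leaves the power
arithmetic to the analyst.

## The synthetic-data generator

`make_genome` draws i.i.d. bases at a configurable GC fraction.
`make_gene_models` places non-overlapping genes (uniform random gaps,
uniform strand) with short exons (~100–300 bp) and long introns — keeping
the genomic exon fraction realistic (~5% at default densities), which
matters because a planted fold f on a track covering fraction q is
recovered by the enrichment ratio as f/(1 + (f−1)q) under the generator's
mixture reweighting. Derived tracks (exons, introns, coding exons, UTRs,
5-kb promoter windows, spans, intergenic) are exactly consistent with the
models by construction and verified by conservation tests.

`simulate_sites` draws candidate points uniformly (a 30-bp margin keeps
every site's 48-bp window on-chromosome; negligible at megabase scales)
and accepts by rejection sampling with a weight multiplying per-track fold
factors, a TSS-window factor, and exp(β·z) where z is the candidate
window's mean step parameter standardised against 10⁴ random windows
(clipped to ±4 so the acceptance bound is finite; the clipping costs a
small fraction of the nominal tilt). Fragment counts are log-normal
(median 150 by default, matching the heavy-tailed counts of real selected
libraries); a configurable fraction of count-1 noise singletons is planted
within ±10 bp of restriction motifs, exercising exactly the stringent
filter path. `make_expression_table` assigns classes and draws FPKM
patterns that the classifier recovers perfectly at zero noise — a
round-trip identity, not a statistical test.

What the generator deliberately does **not** emulate: repeat families and
mappability holes, chromatin tracks correlated with sequence, PCR
chimerism, local hopping from donor sites. Passing recovery tests
therefore demonstrates correctness of the *statistics*, not robustness to
every artefact of real libraries; on real data the matched-control modes
(mappability track, restriction matching) are the guard against the two
biases the generator also omits.

## Determinism and problem sizes

Every stochastic function takes an integer `seed` and restores the RNG
state afterwards (`withr::with_seed`); `run_pipeline` derives per-stage
seeds from the master seed by stable label hashing, so stages can be rerun
in isolation. Reruns with identical inputs and config are byte-identical.

The test-suite study sizes — 2-Mb genomes, 500–2000 sites, 100–200 control
replicates, 200 simulated features — were chosen so each recovery or
calibration study completes in seconds while keeping Monte-Carlo error
well inside the asserted tolerances; defaults in the API (N = 1000 sets,
10⁶-location pool) remain at the scales used for real genome-wide
analyses.

## Known limitations

* Enrichment ratios are undefined when all control counts are zero; very
  sparse features at small set sizes should use larger N.
* The constructive restriction match reproduces distance-to-enzyme
  exactly but not the joint distribution of *multiple* nearby enzymes.
* Gene assignment is transcript-model-blind (one span per gene); isoform
  TSS diversity is not represented.
* The step-parameter table is a fixed crystallographic average; it proxies
  deformability, it does not model sequence-dependent elasticity tensors.
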