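---
title: "Detecting horizontal transfer of transposable elements and modelling TE-load evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transfer of transposable elements and modelling TE-load evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tehorizon)
```

## What the package does

`tehorizon` implements a comparative transposable-element (TE) analysis
for a clade of related genomes, of the kind applied to noctuid moths:

1. **Copy-divergence dating.** Each annotated TE copy carries a
   divergence from its subfamily consensus; Kimura 2-parameter (K2P)
   distances are converted to insertion ages through a neutral clock,
   and per-subfamily *landscapes* (bases or copies per divergence bin)
   describe when each subfamily was active.
2. **Horizontal-transfer (HTT) detection.** A TE pair shared by two
   species that is far *less* diverged than the hosts themselves is a
   horizontal-transfer candidate. The host divergence null is the
   distribution of synonymous rates (dS) over single-copy orthologs;
   a TE pair whose dS falls below the lower 2.5% quantile of that
   distribution is called a hit.
3. **Minimal-event clustering.** One ancient transfer followed by
   speciation produces many pairwise hits; hits are clustered into a
   minimal set of independent transfer events.
4. **TE loads as a continuous trait.** Per-species TE content is
   analysed on the timetree: phylogenetic signal (Pagel's lambda,
   Blomberg's K), comparative model selection (BM, OU, Early-Burst,
   white noise) by AICc, ancestral reconstruction with per-branch
   expansion/reduction calls, and TE-load/genome-size correlations.
5. **A synthetic-data generator** that produces complete datasets with
   known truth, so every stage is testable without genome downloads.

## The molecular clock

Divergence is converted to time with `T = K / (2 r)`, where `K` is the
K2P distance between a copy and its consensus (the factor 2 accounts for
divergence accumulating on both the copy and the consensus lineage) and
`r` is the neutral substitution rate per year. The default clock is
`r = 2.9e-9` substitutions/site/generation with one generation per year,
the standard lepidopteran estimate; under it a 10% divergence dates to
17.24 My:

```{r}
divergence_to_age(0.10)
```

Both parameters are explicit in `clock_parameters()` because every
downstream age (landscape axes, the vertical-inheritance ceiling in hit
clustering) scales linearly in `1/r`.

## dS estimation

dS is computed with the Nei–Gojobori (1986) counting method:
per-codon synonymous-site fractions averaged over both sequences,
multi-hit codons resolved by averaging over all minimal mutational
pathways, and the Jukes–Cantor correction
`dS = -(3/4) log(1 - (4/3) pS)`. Two conventions are fixed and
documented rather than configurable: single mutations that would create
a stop codon count as nonsynonymous, and pathways passing through stop
codons are retained (with those steps nonsynonymous). `pS >= 3/4` is
reported as saturated rather than extrapolated. The estimator choice
matters little here because hits are called on *quantiles* of the same
estimator applied to both TE pairs and orthologs; the interface is kept
pluggable so a likelihood-based dS could be substituted.

Length filters mirror standard practice: TE pairs must exceed 300
aligned nucleotides and ortholog pairs 300 aligned amino acids (both
strict, both configurable), and copies entering the protein/dS stage
must be at least 80% of their consensus length. Ortholog pairing uses
reciprocal best hits sharing a single-copy marker identifier, with
bitscore ties broken lexicographically for determinism.

## Hit calling and its calibration

For every species pair the threshold is the empirical `q = 0.025`
quantile (type-7, linear interpolation at index `(n-1)q`) of the pair's
finite ortholog dS values; a TE pair is a hit when its dS is *strictly*
below the threshold. SINEs are excluded (no protein, no dS). Species
pairs with fewer than 40 ortholog values fall back to a pooled
threshold with a warning; pairs with none are skipped.

Because the threshold is a quantile, roughly a fraction `q` of fully
vertical TE pairs will be called whenever TE divergence mimics host
divergence — the method is intentionally a candidate screen, not a
proof. The calibration test in this package draws 2000 TE pairs and a
genome-scale (8000-gene) ortholog null from the *same* distribution and
checks that the hit fraction falls in the binomial 95% band around `q`.
The large null matters: with only a few hundred genes the threshold
itself is noisy and the realised hit fraction can leave the band for
reasons unrelated to the calling rule.

One practical caveat surfaced by the synthetic data: on deeply diverged,
fully neutral TE pairs the NG86+JC estimate sits a few percent below the
true synonymous distance (pathway averaging under multiple hits), while
orthologs — evolving with low dN/dS — are estimated nearly unbiasedly.
Deep vertical TE pairs are therefore slightly *over*-called, which is
the conservative direction for a screen but worth remembering when
interpreting borderline hits between the most distant species.

## Lineage collapsing and minimal events

Cross-species hits are only meaningful between lineages that are
distant enough for vertical inheritance to be excluded. Working
bottom-up over the guide-tree nodes, a clade is collapsed into one
lineage when (i) for every species pair inside it more than 0.3% of
ortholog dS values lie below the highest nucleotide divergence of the
TEs under scrutiny, or (ii) its crown age is under 40 My. Maximal
qualifying clades form the partition.

Two open choices were fixed as follows:

* **Which TE divergence is "the highest".** The ceiling is taken as the
  90th percentile of the called hits' pairwise K2P divergences, not the
  raw maximum: since ~`q` of deep vertical pairs are expected borderline
  calls, a raw maximum lets a single such call exceed the deepest
  ortholog dS and collapse the entire tree into one lineage, silently
  ending the analysis. The value is exposed as `max_te_divergence` for
  users who prefer a different rule.
* **Per-pair vs pooled thresholds.** Thresholds are per species pair by
  default (host divergence differs per pair); a pooled variant is
  available via a flag.

Hits are clustered into minimal events on a graph: two hits connect
when they join the same unordered lineage pair, share a subfamily, and
on each side the involved copies are mutually compatible with vertical
inheritance inside that lineage — identical copies always, distinct
copies when their K2P divergence is below `2 r` times the lineage's
**stem** age. The stem age (when the lineage split from its sister) is
the correct bound: two vertically inherited descendants of one
transferred element coalesce no later than the lineage's origin, and a
crown-age bound would both exclude legitimately vertical copies older
than the crown and give singleton lineages a zero ceiling. Missing
divergences block the edge, which errs toward more, smaller groups.
Connected components are the reported events.

## Phylogenetic signal, model selection, ancestral states

All Gaussian fits profile the root state and rate analytically (GLS via
Cholesky); only the shape parameter is optimised numerically over a
fixed bracket split into five segments (tolerance 1e-8), so every fit is
deterministic. Lambda is bounded above by tree height divided by the
tallest internal node height, which on trees with short deep branches
allows estimates slightly above 1 — matching the behaviour of the
reference implementations (`tehorizon`'s lambda and K agree with
`phytools::phylosig` to numerical precision in the test suite, and
ancestral states match `phytools::fastAnc` exactly). Blomberg's K uses
the phylogenetically corrected mean and a seeded tip-permutation test
(default 1000 permutations). The Early-Burst model rescales each branch
segment `(t1, t2)` to `(e^{a t2} - e^{a t1})/a` with
`a` in `[-10/height, -1e-8]`; `expm1` keeps the transform exact as
`a -> 0`, where EB reproduces BM. AICc is
`-2 logL + 2k + 2k(k+1)/(n-k-1)` with `k` = 2 (BM, WN) or 3 (OU, EB).
Branch direction labels (expansion/reduction) use a relative tie band of
1e-8, so a constant trait reconstructs as "no change" everywhere.

Printed reference values that require the study's unpublished timetree
branch lengths (the signal statistics of the real TE loads) are *not*
asserted anywhere; signal and model recovery are validated on synthetic
traits instead — BM simulations on a 64-tip, 60-My tree recover mean
lambda ≈ 1 and mean K ≈ 1, and EB simulations (`a = -0.05`/My) give EB
the lowest mean AICc among the four models.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with these design choices:

* **Coding sequences** are built from the six fourfold-degenerate codon
  families with no synonymous first-position alternative (Val, Ser-TCN,
  Pro, Thr, Ala, Gly). Third positions are then synonymous by
  construction and carry the neutral clock exactly; Leu (CTN) and Arg
  (CGN) are excluded because their synonymous first-position swaps would
  add synonymous *sites* where the generator never places substitutions,
  diluting realised dS below the clock expectation by about 5%.
* **Orthologs** evolve along the tree with third positions at rate `r`
  (equal exchange rates, so the Jukes–Cantor-corrected estimator is
  exactly calibrated) and first/second positions at `omega * r` with
  stop-creating and synonymous outcomes reverted — dN/dS is controlled
  without touching the synonymous truth. Expected pair dS is
  `2 r T_split`, which the test suite verifies within 3 standard errors.
* **TE copies** diverge from their species' subfamily master by
  `2 r * insertion age`, with ages drawn around the subfamily's burst
  centres (default spread 3 My); masters themselves evolve along the
  tree, so cross-species vertical TE pairs are at least as diverged as
  the hosts. TE nucleotide evolution uses a transition/transversion
  rate ratio of 2, the typical genomic bias, which the K2P estimator
  models explicitly.
* **Horizontal transfers** sample the donor lineage's master *at the
  event date* (edges are split at event points during simulation), so a
  transferred copy and the donor's present-day element have diverged
  only since the event — the signature the detector looks for. A
  recipient clade receives independently evolving descendants in each
  species.
* **Genome tables** add a constant non-TE baseline (250 Mb) to weighted
  TE bases (each simulated copy standing for 1000 genomic copies), with
  a per-species multiplier ramp (0.6–1.8) that makes TE load vary and
  correlates it with genome size by construction.
* The default timetree is a nine-species noctuid-like topology of
  height 60 My (basal split 60, a 45-My stem lineage, shallow
  radiations at 5–15 My) with clock-consistent ages.

Everything is driven by one integer seed; the same scenario and seed
reproduce byte-identical files. What the generator does **not** emulate:
indels and alignment error, nested/fragmented insertions, assembly
artifacts, rate variation among sites or lineages, and selection on TE
copies after insertion. Passing tests therefore demonstrate the
correctness and calibration of the procedure under its own model
assumptions, not robustness to annotation noise in real genomes.

## Problem sizes and numerical choices

The bundled tests run the pipeline at deliberately modest scale — tens
of genes and copies per species, 2000-pair calibration sets, 100–200
trait replicates on 64 tips — sizes chosen so the full suite completes
in well under a minute while keeping every statistical check inside its
stated tolerance. Degenerate inputs are handled explicitly: saturated
K2P or dS values are flagged or error with a dedicated condition class,
star trees return a degenerate-flagged lambda, zero-length branches are
floored at a relative epsilon in the ancestral solver, and empty hit
sets propagate as empty (not missing) tables.

## Limitations

* The dS screen inherits NG86's small-sample and saturation behaviour;
  between the most distant species pairs thresholds sit near saturation
  and calls there deserve scrutiny.
* Lineage collapsing is a hard partition; transfers *within* a collapsed
  clade are invisible by design.
* The minimal-event count is a lower bound under the clustering
  heuristic; independent transfers of near-identical elements between
  the same lineage pair are merged.
* Real annotation pipelines (defragmentation, protein extraction,
  alignment) are out of scope: the package consumes their outputs, and
  the length filter stands in for defragmentation.
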