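---
title: "Methods: activity-guided screening of mint essential oils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-guided screening of mint essential oils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mintscreen)
```

## The screening model

`mintscreen` formalizes a comparative, activity-guided fractionation of
essential oils. The premise: closely related species produce chemically
distinct oils, and when their bioassay activities also differ, the
covariation of composition and activity across the panel filters out the
compound responsible. The statistic at the core is the per-compound
bioactivity score

$$B = \frac{1}{n} \sum_{i=1}^{n} a(i)\, g(i),$$

with $n$ accessions, $a(i)$ the compound's relative GC peak area (percent
of total ion signal) in accession $i$'s oil, and $g(i)$ the germination
inhibition (percent vs. control) of that oil. Both factors live on 0–100,
so $B$ is bounded by 10,000 — attained only by a hypothetical pure,
fully inhibitory oil. $B$ is deliberately descriptive: it attaches no
p-value, and the package attaches none either. Its identities (linearity
in $g$, the $n/(n+1)$ rescaling when an inert accession joins the panel)
are tested exactly.

Key modelling commitments, each a point where the underlying screen design
is silent and a choice had to be made:

* **Raw areas, never renormalized.** $a(i)$ are relative peak areas as
  reported; renormalizing to identified peaks only would change $B$.
  A flag for renormalization was considered and rejected as a default —
  unidentified peaks are real signal mass.
* **Isomer pooling upstream.** Menthone/isomenthone interconvert by
  enolization and α-/β-citral are isomeric; each group is pooled by exact
  area addition *before* scoring, so the score sees one compound. Pooling
  preserves total area to machine precision, is idempotent, and commutes
  with matrix assembly (all property-tested).
* **Negative inhibitions clamp to zero inside the score.** Sampling noise
  around an inactive oil can push $g(i)$ slightly negative; the score
  presumes inhibition, and a negative term would reward absence.

## Authentication

Distances default to the **p-distance** under pairwise deletion (sites
with a gap or `N` in either sequence are excluded pair-by-pair); the
Kimura two-parameter model is available by flag. The tree-building
software used in typical barcode studies leaves its distance model
implicit, so the package defaults to the simplest metric and treats
printed support values of any particular study as non-targets.

**Neighbor joining** follows Saitou–Nei with two deterministic
conventions: ties in the $Q$ criterion break toward the lexicographically
smallest pair of cluster labels, and a negative estimated branch length is
clamped to zero with the excess moved to its sister branch, preserving the
joined pair's distance. (Some programs print negative branch lengths; we
do not, because non-negativity is what makes tree-metric invariants
testable.) On any additive matrix the implementation reproduces the
generating tree's bipartitions exactly — verified against a brute-force
least-squares topology search for up to six taxa.

**Bootstrap support** resamples alignment columns with replacement,
rebuilds the tree per replicate, and scores each bipartition of the
full-data tree by its replicate frequency; the tree is then rooted on the
outgroup. Supports are invariant to the row order of the input alignment.

**Mislabel flagging** walks each accession rootward to the nearest clade
with support at or above the threshold (default **65%**, the weakest
support still conventionally interpreted in small barcode panels) that
contains at least two other leaves, and compares the accession's declared
species to the strict majority of declared species among those leaves.
One neighbour is never treated as a reference majority — a planted label
swap would otherwise drag its innocent clade-mate down with it. Species
that a marker cannot separate produce supported but mixed clades with no
strict majority; their members are reported `"unresolved"`, not flagged
(plastid markers genuinely cannot separate some hybrid-derived mints).
An accession whose declared species has no second representative is
`"untestable"`. This majority rule is one defensible formalization of
"clusters with the wrong species"; it is exercised against planted truth.

Read merging (consensus over the best ungapped overlap, disagreements
becoming `N` since no quality scores exist at this stage) and primer
trimming (leftmost forward / rightmost reverse approximate match, insert
strictly between) are provided for assembling barcodes from paired reads;
an overlap must match at ≥ 75% of its positions to count as an alignment
at all, which is what makes genuinely disjoint reads fail rather than
"merge" on a spurious zero-match overlap.

## Germination and dose–response

Inhibition is a ratio of replicate means, $g = 100(1 - \bar t/\bar c)$,
with a delta-method standard error. It is invariant to a common scaling
of all counts. Solvent controls are the reference for their compounds
(ethanol for menthol, which is applied dissolved; n-hexane otherwise);
a water control is used only when no solvent is declared.

The "sigmoidal model" of germination dose–response work is pinned down
here as the **4-parameter log-logistic**
$f(d) = lower + (upper-lower)/(1 + (EC_{50}/d)^{slope})$ — the standard
family in germination and toxicology software, equivalent to a logistic
in log-dose up to reparameterization. Fitting is Levenberg–Marquardt
least squares with a multi-start grid (EC50 spanning the observed dose
range geometrically at 7 points; slopes 0.5/1/2/4), keeping the best
residual sum of squares. With fewer than 4 points or fewer than 3
distinct doses the 2-parameter version ($lower=0$, $upper=100$) is used;
it is also the natural model for mortality percentages. The slope is
constrained positive (responses must be oriented as inhibition or
mortality, not viability), so fitted curves are monotone; $d = EC_{50}$
maps to the exact midpoint by construction. Zero doses are rejected:
a control belongs in the response definition, not on the log-dose axis.
Failures return `converged = FALSE` rather than raising, so a screening
loop never dies on one refractory curve. EC50 fold changes propagate
uncertainty on the log scale, which makes the fold symmetric:
$fold(a,b) = 1/fold(b,a)$ to machine precision.

Doses are **nominal labels** throughout (ppm for germination, % v/v for
cytotoxicity). The µl-to-ppm conversion used in box assays depends on an
unstated headspace basis, so the package never converts between units —
only within-axis ratios (EC50 folds) are meaningful.

## Cytotoxicity readouts

Evans Blue dye exclusion gives per-replicate mortality
$100 \cdot stained/scored$; condition estimates are replicate means with
standard errors. Time-course and dose–response analyses are kept
separate — no pooling across time points.

The AO/EB double stain grades membrane permeabilization by nucleus color.
The cited staining protocols do not publish a numeric rule, so the
package's classification is an explicit, configurable formalization: the
red fraction $r = red/(red+green)$ is thresholded at $t_{low} = 1/3$ and
$t_{high} = 2/3$ (green / orange / red, half-open intervals so a boundary
ratio falls upward deterministically). Nuclei with both intensities zero
are tallied as unclassifiable and excluded from frequencies, which then
sum to one per condition.

## The synthetic-data generator

The generator exists so that every estimator above has a
parameter-recovery test against known truth. The shipped scenario
(`paper_scenario()`) encodes a ten-accession mint panel and the narrated
study conditions as its defaults: 100 cress seeds × 3 replicate boxes per
germination condition, 600 cells × 3 replicates per mortality condition,
two series of 275 nuclei (the middle of the narrated 250–300) per AO/EB
condition, and truth values taken from the narrated results —
menthone/isomenthone inhibiting 70/80/99% at 0.01/0.1/1 ppm with
limonene at 20% even at 1 ppm; wild-type mortality above 90% within
15 min for menthone/isomenthone at 0.2% v/v, menthol at 25% (15 min)
rising past 60% (30 min) and amplified to ~90% in the tubulin marker
line; and a 4-fold lower menthone/isomenthone EC50 in the tubulin marker
line (1.5-fold for the actin line). Control germination probability is
not something a results section reports; the default is 0.95,
configurable. Inhibition acts multiplicatively on it, which makes
"inhibition of the control = 0" exact rather than approximate.

Design of the stochastic pieces:

* **Sequences** evolve from a random root along the scenario tree under
  Jukes–Cantor site substitution; branch lengths are expected
  substitutions per site. Aligned output is guaranteed because sites are
  never inserted or deleted (alignment itself is consumed, not computed).
  Two curated **reference sequences per species** accompany the panel —
  barcode authentication is only as good as its references, and without
  them most species would be single-accession and untestable.
* **Oil compositions** are scaled-Dirichlet draws around per-accession
  chemotype means (concentration 250), with an implicit "unidentified"
  simplex component equal to the mean row's shortfall below 100 — real GC
  tables rarely assign all peaks, and this keeps realized rows at or
  below 100 without renormalization. The means are a synthetic
  reconstruction of the narrated chemotypes (pooled menthone/isomenthone
  near 30% in *M. longifolia* and *A. rugosa*, carvone in spice-type
  spearmints, citral isomers in the *Nepeta*/*Melissa* branch), chosen
  once so that the planted active compound is genuinely the top-scoring
  one — that is the scenario's declared ground truth, mirroring the
  screen it emulates.
* **Counts** are binomial at the encoded truth probabilities; **nucleus
  ratios** are beta-distributed (precision 25) around a mean that rises
  log-logistically with dose from 0.06 to 0.97, so the red class
  frequency is stochastically increasing in dose by construction.
* **Mislabels** are declared-label swaps between accessions of different
  true species. (Real mis-assignments need not be pairwise swaps; the
  swap model is the simplest mechanism that leaves the panel's species
  census intact.)
* Each table draws from its **own RNG stream** (seed + table tag), so
  adding one assay to a study never perturbs the draws of another, and
  identical (scenario, seed) pairs are byte-identical.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: GC co-elution and quantitation error
(compound areas are noisy but never misassigned), sequencing error and
alignment ambiguity (no indels, no `N`s unless merged in), overdispersion
between replicate boxes beyond binomial sampling, plate/batch effects,
and solvent–compound interactions. Passing recovery tests show the
estimators are correct under the stated noise model, not that the noise
model exhausts reality.

## Problem sizes and numerical choices

Recovery checks run at the study's own scale (3 × 100 seeds, 3 × 600
cells) averaged over 10 simulated studies, and 20 studies for the EC50
fold; barcode alignments are 600 sites with 100–200 bootstrap replicates
in tests (1,000 remains the user-facing default, matching barcode
practice). Brute-force topology oracles stop at six taxa, where the 105
unrooted topologies are still enumerable. Distance ties in neighbor
joining are resolved at a relative tolerance of 1e-12; peak-table sums
accept a 1e-6 overshoot above 100 for rounded inputs.

## Known limitations

* The flagging rule assumes declared labels are majority-correct within
  a clade; a panel where most members of a species are mislabelled the
  same way will pass unflagged.
* The log-logistic family cannot represent non-monotone (hormetic)
  dose responses; such data end with `converged = FALSE` or a poor RSS
  rather than a warning about model family.
* EC50 fold uncertainty uses the per-fit asymptotic standard errors;
  with 6-dose designs these are approximate, and the package reports
  them as such rather than bootstrapping the fold.
* The score $B$ inherits the compositional coupling of relative areas:
  a compound can score high partly because another compound is absent.
  The screen treats $B$ as a filter for follow-up, not as an effect
  estimate — as does the package.
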