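---
title: "Comparative regulon reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative regulon reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`regrec` reconstructs the regulon of a bacterial transcription factor (TF)
by combining a position-weight-matrix (PWM) model of its operator with the
comparative signal in a clade of related genomes, and provides the
quantification tools (4PL titration fits, growth AUC, affinity–expression
correlation) used to characterize the factor downstream. This vignette is
the package's own account of the underlying models, the parameters that
matter, and the choices made where the design was genuinely open.

## The PWM model and its score scale

Given an alignment of N operator sites of length L, the weight of base b at
column k is

    w(b, k) = ln(N(b,k) + p) − (1/4) Σ_b' ln(N(b',k) + p),      p = 0.5

This is the log-count convention of the classical bacterial
regulon-reconstruction tools rather than the log-odds-over-background
convention of most eukaryotic motif software. The distinction is normative,
not cosmetic: published operator score thresholds (such as the 4.3 used for
NagR scans) are meaningful only on this scale, so the scale itself is part
of the method. Columns sum to zero by construction; a sequence's score is
the sum of its positional weights, and any `N` scores −∞ (never a hit).

Operators bound by symmetric dimers are near-palindromic. With
`palindromic = TRUE`, every site's reverse complement is added to the
counts before the weights are computed, which makes the matrix exactly
self-reverse-complementary and scores strand-symmetric. This is opt-in:
it is the right model for dimeric repressors like NagR, wrong for
asymmetric motifs such as σ70 promoter hexamers.

Information content per column is `2 + Σ f log2 f` bits on the raw count
frequencies. No pseudocount or small-sample correction is applied here:
the IC track is descriptive (logo data), not part of scoring, and
simplicity wins over display parity with any particular logo tool.

## Threshold calibration and the divergence allowance

Three calibration rules are provided: `fixed` (a published cutoff taken
verbatim), `min_training_site` (the weakest training site defines the
floor), and `percentile` of the training-site score distribution. All
accept an `allowance` subtracted from the calibrated value.

The allowance exists because training sites and scanned sites are not
drawn from the same distribution: in a diverging clade, each leaf's
operators carry substitutions accumulated since the ancestor whose sites
trained the matrix. For the default synthetic benchmark the in-site
substitution probability is 0.02/site, so a 21-bp operator carries at
least one substitution with probability ≈ 0.35 and two with ≈ 0.05; the
average cost of one substitution under the default generating matrix is
≈ 2.7 score units. The benchmark workflow therefore uses
`min_training_site` with `allowance = 6` — two average substitution
penalties — which tolerates the two-substitution case while remaining
roughly ten units above the maximum background score expected across all
scanned windows (≈ 2.7 × 10^5 windows at the default clade size). A larger
allowance buys sensitivity at the price of correlated background false
positives, which the consistency filter cannot remove (conserved sequence
looks conserved whether or not it is an operator).

## Scanning conventions

Scans cover a fixed gene-relative window, by default −500..+50 with +1 the
first base of the start codon and no position 0. Internally all coordinates
are 0-based half-open; the biologist convention appears only at the
interface. Three conventions are deliberate:

* A hit must lie entirely inside the window; its reported position is that
  of its 5′-most base on the coding strand.
* Overlap with an upstream neighboring CDS does **not** truncate the
  window — bacterial operators frequently sit inside or beyond neighboring
  genes, and the fixed window matches how such scans are actually run.
  Truncation happens only at replicon edges (flagged `clipped`).
  Replicons are treated as linear; a window spanning a circular origin is
  clipped rather than wrapped.
* For palindromically symmetrized matrices every forward hit has an exact
  mirror on the opposite strand. Opposite-strand hits whose starts differ
  by ≤ 2 bp collapse to the higher-scoring one (ties prefer the coding
  strand). Same-strand tandem hits never collapse — tandem operators are
  real biology.

A physical site in the shared intergenic region of a divergent gene pair
falls inside both genes' windows and is reported once per gene; distinct
absolute intervals are what genome-level operator tallies count.

## Orthology and the consistency filter

Orthologs are bidirectional best hits (BBH) under global protein alignment
(match +1, mismatch −1, gap open −5, extend −1), kept at ≥ 40% identity
and ≥ 70% mutual length coverage. Two shortcuts make this fast without
changing results in the regime the filter operates in: pairs whose length
ratio already violates the coverage bound are never aligned, and pairs
sharing fewer than 5% of their 4-mers (≈ below 47% identity) are skipped.
BBH at 40–47% identity is therefore unreachable with the default
prescreen; set `prescreen = 0` to align everything.

The consistency filter is the heart of the comparative step. A candidate
site upstream of gene x in genome g survives iff in at least `min_support`
(default 2) other genomes an ortholog of x — or of any gene in x's operon —
also carries an above-threshold site in its window. Support is counted at
the transcription-unit level because gene fission/fusion across genomes
otherwise breaks support chains, and all sites upstream of one
transcription unit share one fate. Operons are maximal same-strand runs
with intergenic gaps ≤ 150 bp; no terminator model is used.

The filter's power comes from an asymmetry in the data-generating process:
real operators are under purifying selection (conserved across orthologous
promoters), while false positives at a matched score are not. The
simulator makes this the *hardest* possible test by drawing decoys from
the same generating matrix — decoys are statistically indistinguishable
from operators by score and can be removed only by cross-genome support.

## Promoter architecture

σ70 −35/−10 elements are called with two 6-mer PWMs and a spacer
constraint of 15–19 bp, the −10 element starting at or upstream of +1.
The package ships a small **synthetic** training set built around the
canonical TTGACA/TATAAT consensus families (files
`sigma70_*_synthetic.txt`); it is a stand-in for an experimentally mapped
promoter collection, which users should substitute when available
(`train_promoter_pwms()` accepts any paired hexamer lists). The combined
score cutoff defaults to the minimum combined score of the paired training
promoters. In pipeline mode only the best promoter call per region is used
for overlap classification, since one promoter per gene is the typical
annotation granularity. Any positive overlap between the operator and
either hexamer is classified repression-consistent — a bound factor there
occludes RNA polymerase — which is how operator–promoter geometry is read
as evidence for a repressor.

## Quantification

EMSA titrations are fit with the four-parameter logistic
`y = c + (d−c)/(1+(x/e)^b)` with the lower limit fixed at 0 and the upper
at 1, following the convention of dose-response fitting in R (the `drc`
parameterization). `e` is the EC50; the sign of `b` encodes orientation,
negative for protein titrations (fraction shifted rises with
concentration) and positive for effector-disruption curves. The
least-squares solve runs over `(b, log e)` — the log keeps `e` positive
and makes the fit exactly scale-equivariant — initialized at the
concentration whose response is nearest 0.5 with |b| = 1, with a restart
grid of slopes on non-convergence. The 95% CI on `e` comes from the
linearized covariance of `log e`; profile likelihood would be more
accurate far from the asymptotic regime, but point estimates are what the
downstream correlation consumes.

Growth-curve AUC is the plain trapezoidal integral of OD over time, no
baseline subtraction, no model fit — an *empirical* AUC deliberately free
of growth-model assumptions. The affinity–expression association is a
Pearson correlation between probe EC50s and expression fold changes,
untransformed by default (flags expose log10 EC50 and log2 FC, since
published analyses are often ambiguous about the scale).

## The simulator: what it emulates and what it does not

`simulate_clade()` generates the setting the reconstruction assumes: one
ancestral genome (default 50 genes, lengths uniform 300–1500 bp, gaps
uniform 50–400 bp, genes on alternating strands, GC 0.60 as in high-GC
actinobacteria), operators sampled from a 21-bp palindromic generating
matrix (consensus probability 0.9, free central column) planted at uniform
−120..−30 positions upstream of a 20-gene regulon, leaves derived by
i.i.d. substitutions at 0.05/site (0.02 inside operators, modelling
purifying selection), and 10 decoys, each drawn from the same matrix and
planted in exactly one genome. Substitutions are uniform over the three
alternative bases; there are no indels, rearrangements, gene gain/loss or
codon-aware protein evolution. Everything is reproducible from one seed.

Two derived conventions matter for interpreting benchmark results:

* **The truth regulon is the governed gene set.** With 550-bp windows and
  50–400-bp intergenic gaps, a planted operator in a shared intergenic
  region unavoidably lies in more than one gene's window (divergent
  partners; occasionally a short downstream neighbor). The truth is
  therefore derived by independent interval arithmetic as *all
  transcription units in which some gene's window fully contains a planted
  site* — the set a correct reconstruction can and should recover — rather
  than the 20 anchor genes alone.
* **Decoy placement is constrained to be falsifiable.** Decoy genes are
  drawn outside the governed set, at positions falling in no governed
  gene's window; otherwise a decoy would inherit the retained fate of a
  genuinely regulated transcription unit and "decoy removal" would be
  unmeasurable.

Passing these benchmarks shows the machinery is correct under the model's
assumptions. Real genomes add everything the simulator omits — indels and
rearrangements that break ungapped footprints, horizontal transfer that
violates the clade model, operon read-through, condition-dependent
promoters — so synthetic recovery rates are upper bounds, not forecasts.

## Numerical and degenerate-input choices

* Tie-breaks in dedup prefer the coding strand, then the smaller start.
* `N` bases never score; windows shorter than the motif scan empty with a
  message rather than an error.
* A clade with fewer than two retained sites falls back to the global
  matrix during per-clade refinement.
* A single-genome run cannot be consistency-filtered; the pipeline warns
  and flags the regulon `"unsupported"` instead of failing.
* Footprint alignments are ungapped and operator-anchored (no MSA): the
  quantity of interest is conservation relative to the operator frame, and
  an alignment dependency would buy little for 550-bp windows at ≤ 10%
  divergence.
* Pipeline reports contain no timestamps, so identical inputs give
  byte-identical output bundles.

## Problem sizes used in the tests

The shipped suite exercises the scanner-versus-enumeration equivalence on
single-genome clades of 12–15 genes, the full recovery benchmark on the
default 5 × 50-gene clade, EC50 recovery on 100 simulated titrations, and
strand symmetry on 10^4 random 21-mers — sizes chosen so the whole suite
runs in a few minutes on one core while every code path is exercised at
the defaults stated above.
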