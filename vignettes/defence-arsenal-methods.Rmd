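---
title: "Methods: models, estimators and design choices in defarsenal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in defarsenal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`defarsenal` analyses the anti-phage defence arsenal of a bacterial
cohort from detector output: per-gene hit tables for defence systems and
biosynthetic gene clusters (BGCs), replicon metadata, prophage intervals
and per-genus trees. This vignette is the package's own account of the
statistics it implements, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices behind the code.

## Coordinates and data model

All coordinates are 0-based half-open (BED convention), chosen so that
interval lengths are `end - start` and overlap arithmetic carries no ±1
corrections. Readers for 1-based inclusive dialects must convert at the
boundary; the bundled schema (`inst/extdata/schema.md`) documents this
assumption explicitly, since detector exports rarely state their
convention. Hit tables are long format — one gene per row, grouped by
`hit_id` — and a hit must keep genome, replicon and system type constant
across its rows; readers validate these invariants plus coordinate sanity
and (when metadata is supplied) replicon bounds, so downstream statistics
assume clean input. Strand is carried but never used by any statistic.

## Arsenal profiling

*Frequency* of a type in a group is the fraction of genomes with at least
one copy; *abundance* is the mean copy number per genome. Abundance
dominates frequency (copies ≥ indicator) and per-type abundances of a
group sum to its mean arsenal size, which the tests assert as a
conservation property. The *defence genome fraction* divides the bp
covered by defence genes by the genome's total replicon length; genes are
merged per replicon first so overlapping annotations are not counted
twice (the sources are silent on this corner; merging is the conservative
reading).

**Defence islands.** Two systems on a replicon chain when strictly fewer
than `max_intervening` (default 20) protein-coding genes lie between
them, counted on CDS ordinals — between the largest gene ordinal of the
upstream system and the smallest of the downstream one, exclusive.
"Fewer than 20" is read as a strict `< 20`; counting on gene ordinals
rather than bp distance matches how island descriptions are phrased in
the field. Islands are maximal chains computed with a running-maximum
sweep over systems sorted by first ordinal, which equals the transitive
closure of the pairwise criterion (including nested systems); the test
suite checks this against an explicit graph-components oracle on random
layouts. Singletons are not islands.

## Differential abundance

For each system type with focal/background abundances $A_{in}$,
$A_{out}$ and pooled abundance
$A_{all} = (n_{in}A_{in} + n_{out}A_{out})/(n_{in}+n_{out})$, the
estimator is $E = (A_{in} - A_{out})/A_{all}$. Normalizing by the pooled
abundance puts heterogeneous systems (frequencies spanning orders of
magnitude) on one scale; $E$ is antisymmetric under group swap and
reaches $\pm(n_{in}+n_{out})/n_{\cdot}$ when a system is absent from one
group. A type absent from the whole cohort has no estimator and is
excluded.

Significance comes from a fixed-effects one-way ANOVA on raw per-genome
copy counts (not presence/absence): F on $(1, n-2)$ df, which for two
groups equals the square of the pooled-variance t statistic — a
property-tested identity. Copy counts are integers, so the Gaussian
assumptions are approximations; with group sizes in the tens and the
Bonferroni correction on top, the screen is conservative, which the null
calibration test quantifies. Two degenerate corners are resolved
explicitly rather than left to `NaN`: zero within-group variance with
equal means gives $F = 0, p = 1$; with unequal means, $p = 0$ plus a
`degenerate` flag.

Bonferroni uses family size `m` = number of types tested in the run by
default, configurable upward (e.g. to the full size of a detector's model
catalogue) for fidelity with screens corrected across a fixed model set.
Classification at level `alpha` (default 0.05, on the adjusted p):
*absent* (zero focal copies but background copies — no test is run, the
category takes precedence), *enriched* ($p_{adj} \le \alpha$, $E > 0$),
*depleted* ($p_{adj} \le \alpha$, $E < 0$), otherwise *not significant*;
a zero estimator with significant p (possible only through degenerate
rounding) is deliberately *not significant*. Abundance is computed per
genome, not per replicon: a genome with three plasmids still counts once
in the denominator.

## MGE attribution and GC score

Attribution is a tri-partition with precedence prophage > plasmid >
chromosome (a prophage integrated on a plasmid is "prophage"); exactly
one location per hit. The defence rule — prophage-encoded as soon as one
gene overlaps a prophage interval by ≥ 1 bp under half-open arithmetic —
is deliberately permissive because prophage boundary predictions are
imprecise. The BGC rule is stricter: the hit's span (first gene start to
last gene end) must be covered ≥ 50 % by the merged prophage union, with
the tie at exactly one half counting as prophage ("at least 50 %").
Overlap is computed against merged, disjoint prophage unions with ~15
lines of interval arithmetic that the tests pin to a per-base brute-force
oracle on random layouts. Report percentages round half-up to one
decimal, matching the convention of printed percentage tables.

The GC score of a gene is its GC fraction divided by the replicon's GC
fraction; a system's score is the arithmetic mean over its genes (the
alternative — computing on concatenated sequence — weights genes by
length; with no sequence in hand, the per-gene mean is the natural
choice, and the aggregation is not specified by the sources). Scores well
below one mark AT-enriched candidates for horizontal transfer; the
`low_gc` flag defaults to a 0.8 threshold and is configurable.
`frequency_vs_mge()` joins genus-level frequency, MGE fraction and mean
GC score per type without forcing a statistic: the expected negative
association (rare systems are the mobile, AT-shifted ones) is asserted
only on synthetic cohorts with planted structure.

## Spatial distribution on linear replicons

A hit's normalized position is its smallest gene start divided by the
replicon length, in $[0, 1)$; using the first gene's start (rather than
an annotated system start, which detector exports do not reliably carry)
makes multi-gene systems unambiguous. Positions are only computed on
linear replicons; circular-annotated replicons raise an error and are
dropped by the profile stage, mirroring the practice of excluding
circular-annotated chromosomes instead of re-linearizing them. Extremity
membership is half-open — $x < t$ or $x \ge 1 - t$ — so the boundary
$1 - t$ counts as extremity; ties there are measure-zero on real
coordinates. The two default thresholds, 10 % (chromosomal arms) and 1 %
(chromosome ends), are the conventional compartment widths for linear
*Streptomyces* chromosomes; arms are defined purely by these fixed
thresholds, with no attempt to estimate arm lengths from gene
conservation. The occurrence floor (default 45) is strict: a type needs
*more than* 45 occurrences to be profiled.

`uniformity_test()` compares the extremity count to the uniform baseline
$p_0 = 2t$ with an exact binomial two-sided p computed as twice the
smaller tail, capped at one. The doubled-tail form (rather than the
minimum-likelihood two-sided p of `binom.test`) is used because it has a
closed form the tests verify by enumeration, e.g. $p = 2(1-p_0)^n$ when
no position falls in the extremities.

## Pagel's λ

Under Brownian motion on a tree, a trait is multivariate normal with
covariance $\sigma^2 C$, where $C_{ij}$ is the shared root-to-MRCA path
length of leaves $i, j$ and $C_{ii}$ the leaf depth. Pagel's λ scales the
off-diagonal of $C$: λ = 0 erases phylogenetic structure (independent
leaves), λ = 1 is plain Brownian motion. The log-likelihood

$$\ell(\lambda) = -\tfrac12\left[n\log(2\pi\hat\sigma^2) + \log|C(\lambda)| + n\right]$$

profiles the root state analytically as the GLS mean
$\hat z_0 = (\mathbf 1^\top C^{-1}\mathbf 1)^{-1}\mathbf 1^\top C^{-1}y$
and the rate as the mean residual quadratic form
$\hat\sigma^2 = (y-\hat z_0\mathbf 1)^\top C^{-1}(y-\hat z_0\mathbf 1)/n$
(ML, not REML, matching the default of the standard tool for this
statistic). Each evaluation is one Cholesky factorization; infeasible λ
(Cholesky failure) evaluates to $-\infty$ so the bounded search skirts
the positive-definiteness boundary. λ is maximized on $[0, 1]$ by
`optimize()` at tolerance 1e-8, with both bounds evaluated as explicit
candidates since a 1-D search can miss boundary optima; when the
likelihood is flat in λ (a star tree), the tie-break returns the smallest
candidate, λ = 0. The search interval is restricted to $[0, 1]$ by
default for interpretability (configurable, subject to positive
definiteness).

The p-value is the upper χ²₁ tail of $2(\ell(\hat\lambda) - \ell(0))$.
Because λ = 0 lies on the boundary of the parameter space, the χ²₁
reference is conservative relative to the ½δ₀+½χ²₁ boundary mixture; the
plain tail is used deliberately and the null-calibration test confirms
the realized level stays at or below nominal. Presence/absence traits are
treated as continuous 0/1 values under the Gaussian model — the standard
(if imperfect) practice when a continuous-trait signal measure is applied
to binary data. The caveat matters: thresholding attenuates correlation,
so λ̂ on binarized traits is biased toward zero relative to the latent
continuous trait, and the screen's p-values should be read as evidence
against independence, not as calibrated estimates of a binary-trait
evolutionary model. The screen requires at least two presences and two
absences (and ≥ 4 leaves); other types are reported as skipped with a
reason, and an optional frequency filter restricts the screen to rare
systems. The unusual "no signal at p > 0.95" style of cutoff some
analyses use is *not* hard-coded: raw p-values are reported and the
patchiness cutoff is a parameter (default 0.05). An independent
implementation (`phytools::phylosig`) serves as a cross-check in the test
suite, never as the computation.

## The synthetic cohort generator

The generator emulates the *statistical structure* of detector output,
not biology: genomes with one chromosome (6–9 Mb uniform, GC 0.45–0.75
uniform) and an optional circular plasmid (50–300 kb, probability
`plasmid_prob`); prophage counts per genome Poisson(`prophage_rate`) with
lengths uniform on 10–60 kb placed uniformly and merged — only the
overlap topology matters downstream, so no attempt is made at realistic
phage biology. Per-genome copy numbers are Poisson (or Bernoulli) at the
group mean; each copy is MGE-designated with probability `mge_prob` and
placed inside a prophage interval or on the plasmid (falling back to the
chromosome when the genome carries neither); gene GC is replicon GC ×
`gc_shift` clamped to [0.05, 0.95]. Chromosomal placement families are
minimal Beta shapes reproducing the two archetypal spatial patterns:
`core_biased` Beta(5, 5), `arm_biased` an equal mixture of Beta(1, 9)
and Beta(9, 1), `end_biased` the same mixture with Beta(0.2, 20) —
centre-peaked versus extremity-peaked. Genes are 900 bp CDS on a nominal
1-per-kb backbone, which also supplies the CDS ordinals that island
detection needs. One RNG stream per cohort is seeded once from the spec,
with draws in a fixed order, so cohorts are byte-identical given the
spec — the determinism contract the pipeline tests assert. The planted
location of every copy is carried in a `planted_location` column so
recovery tests can score attribution exactly.

Trees are pure-birth (Yule) rescaled to unit depth; traits are single
multivariate-normal draws with covariance $\sigma^2 C(\lambda)$,
optionally thresholded at an empirical quantile into presence/absence.

What passing tests on this generator do **not** show about real data:
real cohorts have phylogenetically autocorrelated abundances (the
generator draws genomes i.i.d. within groups), detector false
positives/negatives, imprecise prophage boundaries beyond the ≥ 1 bp
rule's tolerance, gene-length and intergenic-distance variation, and
compositional GC structure along replicons. The generator validates the
estimators' algebra, calibration and power under their own assumptions —
it cannot validate the detectors or the biological interpretation.

## Problem sizes and numerical tolerances

The test suite exercises: interval and island logic against brute-force
oracles (hundreds to a thousand random layouts on ≤ 10 kb toy replicons);
ANOVA against the $F = t^2$ identity on 1 000 random two-group data sets;
null calibration of the Bonferroni screen on 200 cohorts of 30 + 30
genomes with 8 types; planted 10× enrichment/depletion recovery on 50
cohorts of 200 + 200 genomes; the uniform spatial baseline at ~10 000
positions (3σ binomial band); λ grid-oracle dominance on 4- and 16-leaf
trees against a 1 001-point grid (argmax within 1e-3), the λ = 0 closed
form to 1e-9, recovery at λ = 1 on 128-leaf trees (200 replicates) and
null calibration at λ = 0 (300 replicates on 64 leaves). These sizes were
chosen to make Monte-Carlo bands decisive (3σ separation or better) while
keeping a full run in the low minutes on a single core. Algebraic
identities are asserted at 1e-9–1e-12; Monte-Carlo quantities at their
binomial/CLT bands; nothing is asserted that the tests do not themselves
compute.

## Known limitations

- The Gaussian ANOVA on counts and the Gaussian treatment of 0/1 traits
  are pragmatic approximations inherited from the analysis style the
  package reproduces; GLM-based alternatives would be natural extensions.
- Attribution relies entirely on the supplied prophage intervals and
  replicon annotations; misannotated plasmids or missed prophages
  propagate directly.
- Spatial statistics assume the linear annotation is correct and define
  arms by fixed thresholds, not by synteny or terminal inverted repeats.
- The λ screen tests one trait at a time; no multiplicity correction is
  applied across types by default (the p-values are reported raw, and the
  patchiness cutoff is a parameter).
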