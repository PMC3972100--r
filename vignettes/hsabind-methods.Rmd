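---
title: "HSAbind: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HSAbind: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HSAbind)
```

## The problem and the model

Serum albumin buffers the free plasma concentration of most lipophilic
drugs. Two pockets dominate specific small-molecule binding — site I (the
warfarin site, large, mainly hydrophobic) and site II (the
indole/benzodiazepine site, smaller, hydrophobic plus hydrogen bonding and
electrostatics) — while substantial non-specific binding tracks overall
lipophilicity. HSAbind operationalizes that two-channel picture:

1. **Specific channel.** Dock each compound against site I and site II in
   every member of an HSA crystal-structure ensemble and keep the most
   favorable score per site and overall. Ensemble docking stands in for
   receptor flexibility: with ten structures and two sites there are 20
   predictions per compound; the reduced model keeps site I of 2BXP and
   site II of 1N5U, retaining the 1N5U site II myristic acid because fatty
   acids modulate site II more strongly than site I.
2. **Non-specific channel.** An octanol/water logP estimate.
3. **Combination.** A single affine score on the %HSA scale,
   `25.41 − 1.95·XP + 7.68·logP`, with the published coefficients as the
   default and `fitCombined()` to re-estimate them from any
   (score, logP, %HSA) table with seeded case-resampling bootstrap
   intervals (percentile method, resampling rows with replacement; the
   method of interval construction is a package choice, since only the
   replicate count of 1000 is prescribed).

The model assumes that one dominant site drives the bound fraction at
therapeutic concentrations (no multi-site occupancy or dose dependence),
that the docking score convention is kcal/mol with more negative = more
favorable, and that %HSA is the response on its natural scale (no logit or
affinity transform; the linear fit against %HSA is the documented,
deliberately simple choice).

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| binder cutoff | 80 | %HSA | above: strong binder (positive class) |
| weak cutoff | 25 | %HSA | below: weak/non-binder (negative class) |
| `[HSA]` | 0.6 | mM | albumin concentration in the binding isotherm |
| site threshold | 2.0 | kcal/mol | gap in Δ = best(II) − best(I) separating site II from site I calls |
| intercept, α, β | 25.41, −1.95, 7.68 | %HSA scale | combined-model coefficients |
| bootstrap replicates | 1000 | — | percentile intervals in `fitCombined()` |

Classification inequalities are strict on both cutoffs; compounds exactly
on a boundary are classified intermediate and flagged with a message, so
boundary handling is auditable rather than silent. The site threshold has
no published value — the continuous Δ statistic is therefore always
reported alongside the categorical call, and both ROC orientations of Δ
can be evaluated. Binding constants follow the single-site isotherm
`f_b = K_A[HSA]/(1 + K_A[HSA])` with `K_i = 1/K_A`; the isotherm form is a
documented design choice consistent with affinity-chromatography-derived
association constants at fixed albumin concentration. All its round trips
are exact identities on `[0, 1)`, and `f_b = 1` is rejected rather than
mapped to an infinite constant.

## logP: atomic contributions, and what is deliberately not modeled

QikProp-style descriptors are commercial, so the package computes the
published Wildman–Crippen atomic-contribution logP itself: atoms are typed
from the molecular graph (ChemmineR does the SDF parsing; formal charges
are recovered from `M CHG` blocks, which the in-memory path discards) and
the published per-type contributions are summed, including implicit
hydrogens derived from standard valences adjusted for formal charge.
Aromaticity is perceived in-package with a Hückel-style rule (5- and
6-membered rings, 4n+2 π electrons on the kekulized graph, fused-ring
double bonds counted into both rings) because the ring-flag shipped by the
parser marks any ring containing a double bond as aromatic, which is wrong
for cyclohexene-like rings. The implementation is checked atom-type by
atom-type against an independent implementation of the same published
table on a 32-molecule panel spanning alkanes, heteroaromatics, fused
systems, charge-separated nitro and carboxylate groups, sulfonamides, and
several named HSA ligands (warfarin, diazepam, penicillin V); agreement is
to 1e-4 on every panel member.

Deliberate simplifications: compounds are processed in their neutral input
form (no pKa enumeration — ionization-state engines differ too much to
make a reproducible default; the upstream protocol used a pH 7.0 ± 2.0
enumeration), tautomers are not enumerated, and conformer quality is out
of scope because the descriptor is 2D. Selenium can optionally be mapped
to sulfur (`seToS`), mirroring the receptor-preparation convention; it is
off by default. Both members of an enantiomer pair are kept as separate
records — racemic %HSA reporting cannot be attributed to one enantiomer,
so neither record is dropped.

## Docking backends

Scores enter through a backend contract: `scoreTableBackend()` replays
injected tables (the first-class path — published scores, or any external
engine's output), and `commandBackend()` adapts an external engine as a
subprocess with a fixed seed so reruns agree. A ligand absent from a table
or an engine failure yields status `failed`, never an exception; failed
results are excluded from aggregation (the conservative convention —
imputing a worst-case score would silently penalize missing data) and
reported. Aggregation is a minimum, hence permutation-invariant and
monotone: adding a result can never worsen a compound's best score. Site
grids are 10 Å inner / 30 Å outer boxes centered on the site I and site II
centroids in the 1N5U-aligned frame; structural superposition onto 1N5U is
upstream preprocessing, and per-structure centroid overrides are the
escape hatch when a user supplies unaligned receptors.

## The synthetic generator

`generateSynthetic()` makes the whole chain testable without any external
engine or corpus. It emulates three statistical features of the curated
literature data: a bimodal %HSA distribution (strong binders high, weak
binders low, 112:22 by default, matching the strict evaluation set), a
weak pooled correlation between logP and docking score (target R² = 0.10),
and an exactly linear latent relationship between (score, logP) and %HSA
with the published coefficients as the generating truth. Class-conditional
(logP, score) Gaussians put binders at logP ≈ 3.6, scores ≈ −18 kcal/mol
and weak binders at logP ≈ −0.8, scores ≈ −2.5 — the geometry the combined
model itself implies for compounds above 80 and below 25 %HSA. Because the
class separation alone already induces pooled correlation, the
within-class correlation is first solved in closed form from the mixture
moments and then calibrated against the truncated distribution on a
deterministic internal pilot sample; specs whose targets are unreachable
(for example, zero pooled correlation with balanced, widely separated
classes) raise an "infeasible spec" error rather than silently missing the
target. Draws whose noise-free %HSA would leave [0, 100] are rejected and
redrawn — truncating the latent propensity rather than clipping it keeps
the noise-free table exactly linear, so coefficient recovery is exact at
zero noise; the *noisy* %HSA is then clipped to the physical range. The
default residual noise of 7.5 %HSA reflects a realistic between-laboratory
spread for equilibrium binding measurements. Site labels are assigned in
the strict-set site proportions, and site II compounds receive
systematically more favorable site II scores (Δ ≈ −4 kcal/mol versus ≈ 0),
so the site-preference machinery is exercisable end to end.

What the generator does **not** emulate — and what green tests therefore do
not show about real data: chemical structure (rows are abstract
descriptor tuples), assay heterogeneity and concentration dependence,
enantiomer effects, the heavy intermediate population of real corpora, and
crucially the *hardness* of real discrimination. Real docking scores carry
large structured errors, so published ensemble AUCs sit near 0.8 and a
combined model near 0.94, whereas the generator's well-specified linear
world yields AUCs near 1. Synthetic results validate the machinery
(arithmetic, aggregation, ranking, interval construction), not the
attainable accuracy on real compounds.

## Curation rules

Multi-source %HSA values are averaged per compound unless any two sources
differ by more than 30 %HSA, in which case the compound is excluded and
the offending pair reported. The discrepancy test is the maximum pairwise
difference (equivalently the range), applied before averaging, and a gap of
exactly 30 is kept. Standard deviations are reported only with at least
two sources. Curation is idempotent — curating the curated means changes
nothing — and always conserves counts (kept + excluded = input). The
strict evaluation set takes > 80 as positive and < 25 as negative,
excluding intermediates and boundary compounds.

## Numerical conventions

* ROC curves sweep thresholds in descending score order with tie groups
  collapsed to a single step (one diagonal segment). The AUC is computed
  by the trapezoid rule **and** by Mann–Whitney pair counting with half
  credit for ties; every call cross-checks the two to 1e-12 and fails
  loudly on disagreement.
* Early enrichment (TPR at FPR = 0) reads the last curve vertex with zero
  false-positive rate; a positive tied with a negative is counted
  pessimistically (the tie group already raises FPR).
* Rank correlation is Spearman with average ranks for ties; constant
  vectors are an error, not an NA.
* The bootstrap and the generator save and restore the global RNG state,
  so library calls never perturb a caller's random stream.
* Pipeline artifacts are stamped with a config hash and seed and contain
  no timestamps outside the log, so identical configurations reproduce
  prediction tables byte for byte.

## Problem sizes in the test suite

The suite and acceptance script size their simulations to run in seconds
while leaving no property undersampled: dual-route AUC agreement on 40–50
random instances up to n = 200; coefficient recovery at n = 134 (exact,
noise-free) and bias decay checked at n ∈ {50, 500}; bootstrap coverage at
n = 200 with 1000 replicates (25 replications in the acceptance script);
generator R² at n = 2000; end-to-end AUC comparisons at the strict-set
size n = 134.

## Known limitations

Receptor preparation (protonation, His242 double protonation, Arg218
repositioning, crystallographic refinement) and structural alignment are
documented prerequisites, not package features. No open docking engine is
bundled; the command backend is a contract, and its correctness beyond the
failure path depends on the adapter configuration. The curation module
reproduces rules, not the original literature corpus, which exists only as
a document-format supplement. Multi-site simultaneous binding,
concentration-dependent binding, and stereo-specific affinities are out of
scope.
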