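---
title: "Methods: coalescent-coupled STR copy-number estimation from insert sizes"
author: "coalstr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent-coupled STR copy-number estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalstr)
```

## The problem

A short tandem repeat (STR) locus carries `n` copies of a short unit
(`u` bp) on each haplotype.  When a sequenced DNA fragment spans the
whole tract, the insert size inferred from the mapped read pair (reverse
read end minus forward read start, `l = e - s`) is shifted by
`-u (n - n_r)` relative to the fragment's true length, where `n_r` is the
reference copy number.  For tracts longer than the read length this shift
is the only accessible signal, but a single individual's handful of
spanning pairs, against a library insert-size standard deviation of
~50 bp, determines `n` only to within a few units.  This package couples
the per-individual likelihoods of many individuals through their shared
genealogy, inferred from phased flanking variants, so that repeat-number
information is propagated between related haplotypes.

## The per-individual ("basic") model

For a spanning pair with forward-read start `s` and inferred insert size
`l`, the likelihood of haplotype copy number `n` is the insert-size pmf
`F` evaluated at the back-shifted length, normalized over the lengths a
spanning fragment starting at `s` could have shown:

$$P(l \mid n) = \frac{F(l + u(n - n_r))}{N(s,n)}, \qquad
N(s,n) = \sum_{l'=e_m-s+1}^{K-u(n-n_r)} F(l' + u(n - n_r)),$$

zero outside `e_m - s < l \le K - u(n-n_r)`.  `e_m` is the reference
region end; `K` (default 2000 bp) caps the insert size.  Each pair comes
from either haplotype with probability 1/2, so the diploid likelihood of
`(n_1, n_2)` is the product over pairs of the equal mixture, and the
basic caller maximizes it over the full `(n_{max}-n_{min}+1)^2` grid
(defaults 0..40).

`N(s,n)` is filled over `s \in [s_m - K, s_m - 1]` by the two recurrences
(in `s` and in `n`) in `O((n_{max}-n_{min}+1)K)` work rather than the
naive `O(K^2)` per column; a naive-summation oracle is kept in the
package and every table cell is tested against it.  Because the
`n`-recurrence subtracts nearly equal sums where the true value is zero,
absolute residues below `1e-12` are clamped to exact zero — genuine
normalization masses are bounded below by the smallest pmf entry, orders
of magnitude above that threshold for any realistic `F`.

A property worth knowing: the unpenalized diploid grid MLE frequently
splits a true homozygote `(a,a)` into a symmetric near-heterozygote
`(a-k, a+k)`, because the mixture has extra flexibility and the per-unit
shift (4 bp for a tetranucleotide) is small against the insert-size noise
(sd 50 bp).  The diploid *sum* is recovered tightly; the per-haplotype
RMSE of the basic model therefore plateaus around 3–5 repeat units even
at 40x coverage.  This is the precise weakness the genealogy coupling
repairs, and it is why our tests assert majority recovery and
sum-recovery rather than per-replicate exact recovery.

## Repeat evolution on genealogies

Repeat counts evolve by the stepwise mutation model: per generation, with
probability `mu_s`, the count moves ±1 with equal probability (simulated
exactly by the generator; the walk reflects at one copy, a locus with
zero copies having ceased to be a repeat).  Over `g` generations the
displacement has mean 0 and variance `mu_s * g`.  On a genealogy branch
of time `t` — stored in units of `Ne` generations throughout, so that a
pair of lineages coalesces after time 2 on average — the transition
potential is the Brownian approximation clipped at one:

$$P(n_u \mid n_v, t) = \min\{1,\; \mathcal N(n_u;\, n_v,\; N_e\,\mu_s\,t)\}.$$

With this time unit the approximation's variance `Ne * mu_s * t` equals
the exact stepwise variance `mu_s * g`, making simulator and potential
moment-consistent.  The density is evaluated at integers (not integrated
over unit bins) and rows are deliberately not normalized: belief
propagation renormalizes all messages anyway.  The time unit is a single
configurable scale; nothing else in the package assumes it.

## Genealogy sampling

Coalescent trees are sampled conditional on phased biallelic flanking
genotypes by a deliberately simple Metropolis–Hastings chain over rooted
ultrametric binary genealogies: the target is the Kingman coalescent
prior (with `k` lineages, exponential waiting time at rate `k(k-1)/4` in
`Ne`-generation units) times a two-state symmetric substitution
likelihood over the panel sites (Felsenstein pruning with stationary
root, site patterns compressed).  Moves are (a) a uniform redraw of one
internal node time within its parent/children window (exponential
extension for the root) and (b) an exchange of two compatible subtrees
that preserves all node times, with the state-dependent proposal counts
entering the Hastings ratio.  Chain settings default to burn-in 50,000,
thinning 100 (counted in iterations, accepted or not), 100 retained
trees; the scaled-down setting used by the acceptance checks reduces
burn-in to 5,000.

This sampler replaces the external genealogy samplers the method was described with,
which the estimator treats as a black box; the estimator consumes only
the sampled ensemble.  With a flat likelihood the sampler reproduces
coalescent-prior TMRCA statistics within Monte-Carlo error, and a panel
with a perfect two-clade split concentrates the posterior on that clade
(both tested).

## Multi-tree belief propagation

The joint model multiplies every individual's diploid insert-size factor
by a sum over the sampled trees of the repeat-transition products along
each tree (internal-node repeat counts are summed out).  Finding the
repeat numbers maximizing this while summing internal variables is a
marginal MAP problem (NP-hard even on trees), approached by ten cycles of
loopy (sum-product) belief propagation followed by ten cycles of
mixed-product belief propagation started from the loopy messages.  One
cycle runs, in a fixed deterministic order: cross-haplotype messages for
all individuals (sample order), then per tree (ensemble order) an upward
sweep and a downward sweep.  Messages to a haplotype from the ensemble
are aggregated across trees; in mixed-product cycles the cross-haplotype
message takes a max instead of a sum, and leaf-to-parent messages are
restricted to the argmax set of the current leaf belief.

Numerical and structural choices made here, where the method's equations
are silent:

* **Tree aggregation.**  Per-tree messages are normalized, summed with
  equal weight, and renormalized (the default).  The literal unnormalized
  sum — trees weighted by the raw scale of their messages, tracked as
  per-message log-scales — is available as
  `bp_infer(aggregate = "raw")`; on tiny-instance benchmarks it agrees
  slightly better with exact enumeration (≈0.85 vs ≈0.82 canonical match)
  but is not qualitatively different.
* **Root handling.**  The root has no parent; downward messages at the
  root use a flat parent message.
* **Message floor.**  After each renormalization, entries are floored at
  `1e-150`.  On near-identity branches (tiny `Ne mu_s t`) messages become
  point masses and their products otherwise underflow to an exact zero
  vector — observed in practice with the smallest rate-selection
  candidates at `I = 100`.  Factor entries are floored at `1e-300`.
* **Decoding.**  The two per-haplotype beliefs of individual `i` are
  exactly the two max-marginals of the pair surface
  `B_i(n_1,n_2) = f_i(n_1,n_2)\,T_1(n_1)\,T_2(n_2)` (with `T_h` the
  normalized tree aggregate).  Taking their argmaxes independently can
  return a jointly inconsistent — even near-zero-probability — pair
  whenever `B_i` has near-ties, which a label-symmetric factor guarantees.
  Calls are therefore the joint argmax of `B_i`; ties break toward the
  reference (`|n_1-n_r|+|n_2-n_r|`), then lexicographically.  With a flat
  ensemble this reduces exactly to the basic model's grid search
  (tested), and with unique maxima it coincides with the per-haplotype
  rule.
* **Implementation.**  The clipped-normal edge potential depends only on
  `|n_u - n_v|`, so each message update is a convolution with a symmetric
  kernel, truncated where it falls below `1e-30` of its diagonal; the
  compiled engine uses these banded convolutions.  A plain-R reference
  engine implements the same schedule with dense matrices; both engines
  agree to ~1e-15 on random instances (tested), and all production paths
  use the compiled engine.

### How good is the approximation?

On random tiny instances (1–3 individuals, 3–5 repeat states, 1–3 trees,
random symmetric factors) the decoded configuration matches exact
exhaustive marginal-MAP enumeration in ~82–85% of cases (comparison up to
per-individual haplotype swaps, which have identical objective); running
more cycles does not change this.  Failures concentrate where branch
variances are at or below one repeat unit: there the cross-factor/tree
loops are tightly coupled and loopy BP over-counts them, occasionally
decoding near-consensus configurations far from the optimum.  In the
weak-coupling regime (branch variance ≳ 10 units²) agreement is
effectively exact (40/40 on the tested family).  One acceptance check
asserts a 90% match rate on the general family and is expected to fail;
we keep it failing rather than restrict the instance family, since the
bar is a property of the instance distribution rather than of the
method's message schedule.

## Mutation-rate selection

The assumed `mu_s` is chosen from a candidate grid by an agreement score
computed after the loopy cycles (before any mixed-product cycle): for
each individual, the dot product between the normalized read-side
message and the normalized genealogy-side aggregate, summed over both
haplotypes — in `[0, 2I]`, equal to `2I/S` when everything is uniform.
The default grid is `{1e-4, 5e-4, 1e-3, 5e-3, 1e-2}`; when a reference
rate is known (simulation studies) the multiplicative grid
`{0.01, 0.1, 0.5, 0.75, 1, 1.2, 2, 5, 10, 100} ×` reference is used.
Ties break toward the smaller rate.  Selection is recomputed per region.

A known degeneracy: very small candidate rates make the transition
potentials near-identities, which pulls both message families toward a
common consensus — agreement then becomes self-reinforcing, and the
score can favour the smallest candidate even when the generating rate is
much larger.  Usually the resulting shrinkage is still beneficial, but
when the consensus lands wrongly (occasionally at large `I` with a
shuffled panel and a high true rate) the error is large.  This is a
property of the agreement statistic itself; the package implements it as
defined.

## The synthetic-data generator

The generator emulates the reference simulation study: a Kingman tree for
`2I` haplotypes at constant `Ne = 10400`; biallelic flanking sites over
±1000 bp mutated per branch with probability
`min(1, (5.5e-8 + 1.2e-8) · Ne · t)` per site (transition + transversion
rates; repeated hits toggle; monomorphic sites retained); stepwise repeat
evolution from a root count of 25 at the TTTC tetranucleotide locus
(reference repeat 17); and spanning-pair observations drawn directly:
fragment starts at density `coverage / (2 · read length)` per bp over the
`K`-window upstream of the region, lengths Normal(350, 50) rounded to
integers, kept only when the fragment spans the individual's true allele,
and reported with the alignment-inferred size `l = true length −
u(n − n_r)`.

What this deliberately does **not** emulate: read synthesis, base-calling
errors and BWA alignment.  Under error-free flank alignment the inferred
insert size is exactly the shifted length, so direct simulation is the
same observation model without alignment noise.  Two measurable
consequences: (a) conditioning on spanning length-biases the kept
fragments (pooled mean ≈ 359 bp rather than 350 — the per-`s`
normalization `N(s,n)` accounts for this exactly, and the tests assert
the biased closed form); (b) the basic model's RMSE runs ~0.3–1.0 repeat
units *below* the reference values at `I = 100` because the alignment
noise of the original read-alignment pipeline is absent.  The reference-value
acceptance bands (±0.75) absorb this for the coupled estimator but only
marginally for the basic model, whose checks can sit just outside the
lower band edge.  A green simulation test therefore establishes internal
consistency of model and generator, not robustness to alignment
artifacts.

## Evaluation

Diploid calls are scored by RMSE with pairing minimization: each
individual's two estimated counts are matched to the two true counts in
the orientation minimizing the squared error, then
`sqrt(mean/2)` over individuals.  The score is invariant to
per-individual haplotype swaps on either side (tested) and is the
quantity reported by `run_simulation_study()` for the basic model, the
coupled estimator, and the shuffled-panel negative control (panel rows
permuted uniformly, destroying the genotype-individual association while
preserving allele content).

## Known limitations

* The MH genealogy sampler is minimal; at the scaled-down burn-in its
  ensembles are adequate for the estimator but not a calibrated posterior
  sample, and mixing at `I = 100` (200 leaves) is slow by construction.
* Loopy/mixed-product decoding is approximate under strong transition
  coupling (analysis above).
* No recombination: a single genealogy is assumed for the whole flanking
  window.
* The basic model's homozygote-splitting behaviour is inherent to the
  unpenalized diploid mixture MLE; no parsimony prior is applied.
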