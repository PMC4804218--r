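---
title: "Fold classification under structure-space continuity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold classification under structure-space continuity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldcep)
```

## The problem

Hierarchical classifications of protein domain structures (CATH, SCOP)
place every domain into exactly one fold — the CATH topology (T) level or
the SCOP fold level. This implicitly treats folds as isolated islands in
structure space. A large body of evidence instead supports a *continuous*
fold space: domains from different folds can share substantial structural
similarity, especially substructure similarity. `foldcep` implements a
likelihood-style classification of a query domain into existing folds that
accounts for this continuity, together with everything needed to study it
end to end: TM-score computation for fixed residue correspondences, fold
profiling, repeated hold-out experiments, evaluation summaries, and a
synthetic fold-universe generator with known truth.

## Structure similarity: the TM-score

For two structures with a residue correspondence of `L_ali` aligned CA
pairs, the TM-score is

    TM = max over superpositions of (1/L_norm) * sum_i 1 / (1 + (d_i/d0(L_norm))^2)

where `d_i` is the distance between the i-th aligned pair after rigid
superposition and `d0(L) = max(1.24 (L - 15)^(1/3) - 1.8, 0.5)` Angstrom
makes random-pair scores length-independent. Two normalizations are
supported:

* **local** — `L_norm` is the length of the shorter domain. Emphasizes
  substructure similarity; a domain nested inside a larger one can reach
  a local score of 1.
* **global** — `L_norm` is the mean length (rounded half-up, since `d0`
  is defined on integer lengths). Penalizes length mismatch.

The "max over superpositions" is made deterministic and reproducible by a
fixed seed-and-refine schedule: every contiguous alignment fragment of
length `L_ali`, `L_ali/2`, `L_ali/4` (at least 4 pairs, all offsets) seeds
a Kabsch superposition, which is refined for up to 20 rounds by
re-superposing on pairs closer than a cutoff that starts at `d0` and grows
by 0.5 Angstrom whenever fewer than 3 pairs qualify; the best score over
all seeds is reported. On structures whose shared part superposes well
(distances below the `d0` scale) this search provably has nothing left to
find: a dense random-start oracle in the test suite converges to the same
optimum to 1e-6. On genuinely dissimilar structures (TM below roughly 0.3)
the score landscape is rugged and *any* finite search — ours, or a dense
independent one — can land in near-tied basins differing in the third
decimal; scores in that range should not be over-interpreted, which is
also true of the alignment tools the field uses.

Alignment *search* (finding the correspondence) is out of scope: residue
correspondences come from input files or from the synthetic generator.
Precomputed score tables from external alignment programs can be imported
with `read_score_table()`; when both orientations of a pair are present
with unequal scores the larger is kept, matching how TM_max statistics
consume scores.

A caution on the empirical rule "local >= global for unequal lengths": it
is not a theorem. The ratio of normalizations behaves like
`L / (L - 15)^(2/3)`, which *decreases* below L = 45, so for very short,
very noisy pairs the inequality can reverse. It holds in the regime the
package targets (domains of 40+ residues whose shared substructure
superposes), and the tests draw their randomized pairs from that regime.

## Fold profiles and CEP

For each fold, the profile is the vector `x` of **within-fold TM_max
scores**: for every member, the highest TM-score to any other member. Its
mean measures structure homogeneity (near 1 for tight folds, down to
0.6-0.7 for heterogeneous ones) and its sample SD (N-1 denominator, fixed
for reproducibility) measures heterogeneity; empirically the two are
strongly anti-correlated — folds with a low mean owe it to a long lower
tail, not to uniformly low scores. Only folds with at least 25 members are
profiled by default: smaller folds give too noisy an empirical
distribution (the threshold is a `min_fold_size` argument everywhere).

A query's fit to a fold is summarized by the **query-fold TM_max score**
`s` (its best score to any member — the argmax member is the "partner
domain"; ties break to the lexicographically smallest id). The
**cumulative empirical probability** is

    CEP(s, fold) = #{ x_i <= s } / N          (inclusive comparison)

— the fraction of the fold's own within-fold TM_max scores at or below the
query's. A heterogeneous fold accommodates a query more readily than a
tight one at the same raw similarity, which is exactly the continuity
effect: classification by `argmax CEP` can move a query to a fold with a
*lower* TM_max. Ties break by higher TM_max, then lexicographic fold id
(the tie-break is our documented choice; nothing in the method fixes it).
If fold space were perfectly discrete, CEP and TM_max classification would
always agree — a property the test suite checks on generated discrete
universes.

## C3P: smoothing CEP with a Bayesian mixture

With modest fold sizes the empirical CEP is coarse (a query scoring just
below every observed `x_i` gets CEP = 0 although the true value must be
positive). C3P replaces the empirical distribution with the posterior
predictive distribution of a Gaussian mixture with an unknown number of
components fitted to `x` — multimodality is expected because folds contain
multiple superfamilies.

The model, for a fold with scores `x_1..x_N`:

* `x_i | z_i ~ Normal(mu_{z_i}, sigma^2_{z_i})`, allocations
  `z_i ~ Categorical(pi)`;
* `pi ~ Dirichlet(gamma, ..., gamma)` with `gamma = 1`;
* `mu_j ~ Normal(xi, 1/kappa)` with `xi = median(x)`, `kappa = 1/R^2`,
  `R = max(x) - min(x)`;
* `1/sigma^2_j ~ Gamma(alpha = 2, beta)` with the hierarchical rate
  `beta ~ Gamma(g = 0.2, h = 10/R^2)` (component variances are similar);
* `k ~ Poisson(lambda = 1)`, truncated to `1..k_max` (`k_max = 30`; k = 0
  is meaningless and a proper reversible-jump implementation needs a
  ceiling).

These are the weakly informative settings of Richardson and Green's
univariate mixture analysis, which the data are meant to dominate.

`fit_rjmcmc()` is a full reversible-jump MCMC sampler written for this
package. One sweep is: Gibbs updates of `pi` (Dirichlet full conditional),
of each `(mu_j, sigma^2_j)` (Normal / Gamma full conditionals), of the
allocations, and of `beta`; then a split/combine move (moment-matching
proposals with `u1, u2 ~ Beta(2,2)`, `u3 ~ Beta(1,1)`; only components
adjacent in mean order may combine, and a split whose two means straddle
another component's mean is rejected, making split and combine exact
inverses); then a birth/death move for empty components (birth weight
`~ Beta(1, k)`, parameters from the prior). Acceptance ratios are the
Richardson-Green expressions on the unordered state space, including the
order-statistics factor. Defaults follow the standard analysis recipe:
30,000 sweeps, 5,000 burn-in, thinning 5. No relabeling is applied —
C3P is a predictive quantity and therefore invariant to label switching
(asserted in the tests).

Numerical notes: component variances are clamped to `[1e-10, 1e10]` so
exactly tied scores (possible in principle with rounded inputs) cannot
collapse a component variance to zero; the chain is initialized from a
single component at the data moments with `beta` at its prior mean, and is
byte-reproducible from `settings$seed`.

The posterior predictive is sampled by Monte Carlo: for each retained
posterior sample, draw a component from `pi` and then a Normal variate
(`draws_per_sample` is configurable, default 1; the Gaussians are *not*
truncated to (0, 1] — draws outside simply count as below or above the
query score). Then

    C3P(s, fold) = #{ predictive draws <= s } / #draws,

the same inclusive rule as CEP. `c3p_analytic()` is the Rao-Blackwellized
version (posterior-averaged mixture CDF), used as a variance-reduced
cross-check: the Monte-Carlo estimator must agree with it within binomial
error, and the analytic form must agree with numerical quadrature of the
mixture CDF to 1e-8. Classification by C3P (`classify_c3p()`) follows the
CEP protocol with C3P as the per-fold score; per-fold fits are computed
once per profile set and cached, because the posterior depends on the
profile, never the query.

When a fold has fewer than 5 scores the sampler refuses and directs the
caller to the empirical CEP — too little data for a mixture of unknown
order.

## The hold-out experiment

`holdout_experiment()` implements the standard protocol for comparing an
automated classification against a reference hierarchy: per repeat, sample
`floor(fraction * N_f)` members from each profiled fold (minimum one) as
queries; rebuild every profile without them (a query must never contribute
to the profile it is scored against — also enforced by an error if
violated); classify each query by each requested method; record the
disagreement fraction against the original assignment. Defaults are a 10%
fraction and 30 repeats. The per-fold floor (rather than a global 10%
sample) reproduces the usual bookkeeping in which the total query count
falls slightly short of a strict 10% of all domains. Queries are
classified independently — no joint reassignment.

## The synthetic fold universe

The generator (`generate_universe()`) produces classification tables and
local/global score matrices with known truth. Scores are generated
*directly as matrix entries* rather than derived from embedded geometry:
the classifiers consume only scores, and direct generation gives exact
control over within- and between-fold supports. (Toy helical structures,
`generate_toy_structures()`, exist separately to exercise the geometry
code.) All scores are clipped to (0.01, 1]; generating Normals are kept
inside the clip window (within-support upper bound 0.99 by default)
because an atom of probability at exactly 1.0 — a clipping artifact real
TM-score distributions do not show — degenerates CEP into ties at 1.

Two canned configurations define the regimes of interest:

* **discrete** (`discrete_universe_config()`): 8 folds of 30 members,
  within-fold scores in [0.8, 0.99], cross-fold scores in [0.05, 0.4].
  Every classifier must agree with the truth on every hold-out query.
* **continuum** (`continuum_universe_config()`): 12 folds of 30 members; a
  gradient of mostly tight folds plus two markedly heterogeneous folds,
  and 10 "bridge" domains (sourced from the two tightest folds, 5 + 5)
  with elevated scores (level 0.9) into those two heterogeneous folds.

Three design points in the continuum configuration deserve explanation:

* *Fold count.* Rank statistics across folds are the analysis output
  (heterogeneity-vs-attraction correlations with label-permutation
  p-values). With very few folds such a permutation test cannot reach
  conventional significance no matter how clean the pattern — with 8 folds
  and two attracting folds the two-sided floor is 2/28, about 0.07 — so
  the default is 12 folds, enough resolution for the test to have power
  while staying desk-sized.
* *Concentrated heterogeneity.* The within-fold TM_max statistic is a
  maximum over ~30 correlated pairwise scores, which compresses generating
  SDs severely; a shallow linear SD ramp does not survive into the
  realized TM_max spread. Real fold sets likewise show a small number of
  strongly heterogeneous folds rather than a smooth ramp, so the two
  attractor folds get generating SDs of 0.16/0.18 against a 0.02-0.06
  ramp.
* *Peripheral bridges.* A domain that bridges two folds is structurally
  intermediate, so its within-home scores are drawn 1.5 SD below the home
  fold's mean — these are exactly the boundary members that continuity
  arguments concern — and its cross scores to the target (level 0.9,
  comparable to its home fold's own within scores) fall in the upper range
  of the target's TM_max distribution. A "bridge" whose cross-fold score
  sits below the target's typical within-fold TM_max would not be a bridge
  at all.

Russian-doll pairs (one fold's domains resembling substructures of
another's) are modeled as `local = base + boost`, `global = base -
penalty` with nested lengths, reproducing the signature by which length
mismatch depresses global but not local similarity.

What the generator does *not* emulate: triangle-inequality-like
constraints among scores (entries are drawn independently given the block
structure), sequence-level redundancy, alignment errors, or any particular
real fold's score distribution. Passing tests on synthetic universes
therefore demonstrate correctness of the statistical machinery under
controlled conditions, not calibration against CATH or SCOP — the
reference-scale analyses require full database downloads and all-vs-all
structure alignment far beyond a desk run.

## Evaluation

`reclassification_rate()` counts queries whose assignment differs from the
original classification and tallies which folds attract them.
`heterogeneity_attraction_correlation()` is a Spearman-type rank
correlation (Pearson correlation of mid-ranks) between a fold property
(`sd_x`, `mean_x`, or size) and attraction counts, with a two-sided
p-value from at least 10,000 seeded label permutations — exact in spirit
at synthetic fold counts, with no asymptotic approximation. Folds
attracting nothing enter as zeros; excluding them would change the
estimate, so the choice is fixed and documented. `method_overlap()`
produces the five-cell consistency partition between two methods and the
original, plus the "same-way" fractions (among A's reclassifications, the
share B reclassified identically). `relative_length_difference()` is
`|L_q - L_p| / min(L_q, L_p)` for a query and its partner domain, the
diagnostic for Russian-doll-driven reclassification. Group-location
comparisons are delegated to `stats::wilcox.test()` via
`compare_groups()` — a convenience wrapper, not a re-implementation.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run the sampler at its default
length (30,000 sweeps) for the dedicated parameter-recovery checks
(N = 300 and N = 400 observations), and at 2,000 sweeps / 500 burn-in for
the per-fold fits inside hold-out experiments, where each fold has ~27
scores and the posterior is effectively unimodal — chain length there
buys nothing beyond the recovery runs already demonstrating convergence
behavior. Universes are 8 x 30 (discrete) and 12 x 30 (continuum); these
sizes were chosen so every experiment reads clearly while a full run of
suite plus script stays comfortable on a laptop.

## Known limitations

* No alignment search: the package scores given correspondences and
  imports externally computed scores, it does not align structures.
* Every query is forced into an existing fold (closed-set protocol, as in
  the hold-out experiment); there is no new-fold detection.
* The mixture kernel is Normal and untruncated; scores are bounded in
  (0, 1], so for folds pressed against the upper bound the predictive
  places mass above 1 (harmless for C3P, which only compares draws to a
  threshold, but the fitted density is not a density on (0, 1]).
* The RJMCMC sampler targets the univariate Richardson-Green model only;
  no marginal likelihoods, no model averaging beyond the predictive.
* `read_cath_domain_list()` / `read_scop_cla()` implement the common
  public release dialects (whitespace CathDomainList with the length in
  the last column; tab-separated dir.cla with the sccs in field 4);
  unusual historical variants may need pre-processing.

## A worked micro-example

```{r example, eval = FALSE}
library(foldcep)

u <- generate_universe(continuum_universe_config(), seed = 7)
profiles <- build_profiles(u$local, u$classification, min_fold_size = 25)
heterogeneity_table(profiles)

## classify the known bridge domains, each held out of its own fold
res <- classify_members(u$truth$bridge_domains, u$classification, u$local,
                        methods = "cep", min_fold_size = 2)
summary_cep <- reclassification_rate(u$classification, res, method = "cep")
summary_cep
heterogeneity_attraction_correlation(profiles, summary_cep,
                                     property = "sd_x", seed = 1)
```
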