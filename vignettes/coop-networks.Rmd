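---
title: "Co-occurring opinion networks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurring opinion networks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopnet)
```

## The model

`coopnet` analyzes multiple-response free-association data: each of *n*
respondents produces five associations to one cue, attaches two emotion
labels (from a fixed inventory of twenty) to each association, and may
additionally complete Likert attitude scales — perceived outgroup threat
(POT, 1–5), group malleability (GM, 1–6) and social dominance orientation
(SDO, 1–7).

The statistical object is the **co-occurring opinions (CoOp) network**:
nodes are the associations retained after a rarity filter, and every pair
of nodes carries a signed weight measuring whether the two associations
appear in the *same respondents* more or less often than chance.

### The signed LLR edge weight

All counting is at respondent level: a respondent contributes at most once
to an association's frequency and at most once to a pair's joint count,
however many slots repeat a lemma. For a pair with margins $i_n, j_n$,
joint count $k$ and total $n$, the weight is the binomial log-likelihood
ratio comparing a single rate for $j$ (independence) against separate
rates for $j$ given $i$ present/absent, signed positive when $k$ exceeds
the independence expectation $i_n j_n / n$ and negative below it. The
binomial coefficients cancel in the ratio, so only the kernels
$k\ln p + (m-k)\ln(1-p)$ are evaluated, with $0\ln 0 \equiv 0$. At exact
equality of observed and expected the two branches coincide at
$\ln 1 = 0$, and the implementation pins the value to zero.

Natural logarithms are used throughout: the package reproduces the
reference worked values ($-7.27$ and $-8.4$ for the repulsion between two
associations with margins 93/97 and 99/146 out of 505, joint counts 6 and
13) only in nats. Twice the absolute weight is the G statistic of the
respondent-level 2×2 table — this χ²(1) correspondence is verified against
a brute-force oracle in the test suite and exposed as `llr_chisq_p()`, but
never used to prune edges: the network is kept **complete** over retained
nodes, because both module detection and the binned affect correlation
consume the full weight distribution, including near-zero weights.

The printed integer for the expected co-occurrence truncates toward zero
(93·97/505 = 17.86 is reported as 17); the continuous value always
accompanies it in the `exact` attribute, since truncation versus rounding
is an interpretive choice the caller may want to revisit.

### The rarity filter

`build_vocabulary()` retains lemmas mentioned by at least `min_occurrence`
respondents (default 3). Rare associations are idiosyncratic — they belong
to the periphery rather than the stable core of the social representation —
and removing them stabilizes the network. The filter is monotone: raising
the threshold never adds nodes. The threshold-sweep analysis
(`threshold_sweep()`) exercises 3→13 and reports how cross-sample
similarity changes as the analysis narrows to core associations.

### Signed modularity and consensus

Modules maximize the signed generalization of weighted Newman–Girvan
modularity, with the positive and negative layers carrying separate
configuration-model expectations built from positive/negative strengths.
Note a subtlety the implementation must respect: the objective is *not* a
function of net weights — aggregating a positive and a negative edge into
their sum changes $v^+$, $v^-$ and the strengths — so the Louvain
aggregation phase keeps the two layers separate.

The expectation term uses the signed configuration model
$e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm$; a resolution multiplier on the
expectations is available but defaults to 1 and is not part of the standard
analysis.

The Louvain optimizer here is multi-start greedy: local moves (including
extraction of a node into a fresh singleton, which matters when repulsive
weight dominates a community), aggregation, and iterated refinement passes
that restart from the flat partition, with one additional random-initial
climb per run. On 4–6-node networks the test suite checks it against
exhaustive partition enumeration. Visit order is seeded per run; the
consensus procedure spawns per-run seeds deterministically from one master
seed, so a 5,000-run consensus is exactly reproducible.

Consensus partitioning follows the standard co-classification scheme: the
n_runs Louvain partitions define a co-classification frequency matrix;
that non-negative matrix is re-partitioned n_check times (same optimizer,
empty negative layer — co-classification frequencies have no repulsive
part, and no threshold is applied to the matrix before re-partitioning);
if all n_check partitions agree they are the consensus, otherwise their
own co-classification matrix replaces the previous one. The loop is capped
at `max_rounds` (default 50) with a convergence error after, since the
agreement loop needs a termination guarantee. Both the mean modularity of
the initial runs and the consensus partition's own Q are reported — the
two need not coincide, and which one a study should quote is a reporting
decision left visible to the user.

Modules are labeled by their two most frequent lemmas (ties broken
lexicographically so labels are deterministic), and modules with fewer
than two distinct lemmas are flagged and excluded from attitude
comparisons, while remaining in the network.

### Affective similarity and the binned correlation

Each retained association accumulates a 20-bin emotion-label count vector;
each mentioning respondent contributes the two labels of their first slot
holding that lemma, so column sums are at least twice the rarity
threshold. Similarity is $2 - \mathrm{L1}$ between normalized columns: 2
for identical label distributions, 0 for disjoint support. If raw data
ever contained a duplicated label choice within a pair it would be counted
twice — the formula consumes raw counts.

The association between LLR and affective similarity is tested on **bin
means**: the LLR range is split into 100 equal-width intervals (right-most
closed, empty bins dropped), both variables are averaged within bins, and
Spearman's correlation is computed across bins. Binning moderates the mass
of near-zero LLR pairs, which would otherwise dominate the correlation
with very heterogeneous affect values. Reported degrees of freedom are
(non-empty bins − 2). Significance is QAP: node labels of the affect
matrix are permuted jointly over rows and columns and the *entire*
binning-and-averaging pipeline is re-run per permutation, so the observed
and null statistics are computed identically; the permutation order
(permute-then-rebin) is recorded in the result's metadata because the
alternative (permuting after binning) is not equivalent.

### Reproducibility machinery

Two survey waves are compared only on their shared node set. Edge-level
similarity is Spearman's correlation over shared off-diagonal pairs with a
QAP permutation test (joint row/column permutation of one matrix preserves
the within-node dependence of edges that makes naive correlation tests
anti-conservative). Modular similarity is normalized mutual information,
$\mathrm{nMI} = 2(H(M_1)+H(M_2)-H(M_1,M_2))/(H(M_1)+H(M_2))$, with the
continuity conventions nMI = 1 when both partitions are trivial and 0 when
exactly one is.

The null reference for modular similarity is the edge-, weight- and
strength-preserving randomization of each wave's network: positive and
negative degree sequences are preserved exactly by signed double-edge
swaps — in dense signed networks the only available move is the
checkerboard swap, where two same-sign edges exchange endpoints and the
two opposite-sign edges occupying the target slots relocate to the vacated
ones — and the original weight multiset of each sign layer is then
re-assigned by iterative rank-matching of edges (by the product of their
endpoints' residual strengths) to same-rank weights. The batch fraction of
the re-assignment (default 0.1, i.e. strengths are re-evaluated after
every 10% of edges) trades strength fidelity against cost; at the default,
node strengths correlate with the originals above 0.9 on networks of the
size this package targets, and the exact invariants (degrees, multisets)
hold by construction and are asserted in the tests.

Because a full cross-product of 5,000 × 5,000 run-level partition
comparisons is infeasible, the run-pair average nMI is estimated from a
seeded random sample of cross pairs, and the consensus-vs-consensus nMI is
reported alongside. Null-model comparisons use a single seeded Louvain run
per null network; re-running a full consensus per null network is
supported in principle but costs three orders of magnitude more for a
quantity whose null distribution it barely moves. All permutation p-values
use the add-one (include-the-observed) convention, so the smallest
attainable p is 1/(n_perm + 1) and p = 0 never occurs.

### Attitude comparisons

Respondents are assigned to the module holding a **strict** majority of
their retained associations, weighted by that count; ties and respondents
with no retained association are discarded and reported. Weighted means
and variances are
$\mathrm{WAM} = \sum w_i x_i / \sum w_i$ and
$\mathrm{WAV} = \sum w_i (x_i - \mathrm{WAM})^2 / \sum w_i$.
The pairwise test is a pooled two-sample t on the weighted moments with
degrees of freedom from **respondent counts** (n_a + n_b − 2), not summed
weights — reference analyses of this design print df of respondent-count
magnitude — which also makes the statistic invariant to rescaling all
weights; a Welch variant is available (`var = "welch"`). Cohen's d uses
the same pooled SD as the t. Power annotations use the exact noncentral-t
power at the two group sizes; the conventional planning figure — 64 per
group for power .8 at d = 0.5, α = .05 — is reproduced by
`required_n_per_group()`. No multiplicity correction is applied; the
number of comparisons is reported so the caller can apply one.

## The synthetic-data generator

`generate_population()` emulates the survey design end to end so every
analysis is testable without the (undeposited) field data: respondents are
drawn from latent opinion groups (default three equal groups, about five
hundred respondents); each group has a 40-word vocabulary with
Zipf-weighted occurrence probabilities (association frequencies in real
free-association data are heavy-tailed, and the tests assert the generated
rank-frequency curve is), disjoint between groups by default with a
configurable shared fraction; emotion labels concentrate 80% of their mass
on four group-typical labels; attitude scores are truncated normals
(truncation by resampling, keeping scores in range) with a planted
between-group gradient across each scale's range and SD 1.
`generate_paired_samples()` draws two waves from the same population, with
a `drift` parameter that multiplies word log-probabilities by Gaussian
noise in the second wave to emulate discourse change between waves.

What the generator does **not** emulate: real lexical content (tokens are
abstract), respondent-level heterogeneity in response style, correlation
between emotion choice and attitude score within group, and missing or
malformed entries (incomplete records are exercised by separate fixtures).
Passing tests therefore show the machinery recovers planted structure
under the stated design, not that any particular field dataset has such
structure.

## Numerical choices and degenerate inputs

* $0\ln 0 \equiv 0$ in likelihood kernels; exact observed-equals-expected
  ties give LLR = 0.
* Expected co-occurrence integers truncate toward zero; continuous values
  are always attached.
* Equal-width LLR bins over the observed range, right-most bin closed;
  empty bins dropped; fewer than 3 non-empty bins is a degenerate-input
  error, as is a constant affect vector (Spearman undefined).
* Louvain move acceptance requires a gain above 1e-12; consensus
  agreement means bitwise-identical canonical memberships.
* Networks with fewer than 2 retained lemmas, comparisons with fewer than
  3 shared nodes, modules with fewer than 2 scored respondents, and
  zero pooled variance all raise explicit degenerate-input errors rather
  than returning NaN.
* Lemma merge maps must be idempotent (a value may not map onward to a
  different form); case folding and Unicode NFC normalization are applied
  before any matching, because survey exports are noisy about both.

## Problem sizes used in the shipped tests

The package defaults follow the reference analysis (5,000 consensus runs,
5,000 permutations, 5,000 null models). The shipped test-suite and
validation runs use smaller Monte Carlo sizes chosen to keep the full
suite fast while leaving every conclusion comfortably determined:
consensus with 25–200 runs (the planted structures are unambiguous —
agreement is reached in one round), 120–500 permutations (smallest
attainable p of 1/501 ≈ 0.002 against tested thresholds of 0.05), 19–39
null models, and populations of 120–500 respondents. The threshold sweep
runs 3→13 with 30 runs per threshold on paired 400-respondent samples.

## Known limitations

* The Louvain optimizer is a stochastic heuristic; global optimality is
  verified only where enumeration is feasible (≤ 6 nodes). On large
  networks the consensus procedure is the hedge against local optima.
* Strength preservation in the null model is approximate by construction;
  only degrees and weight multisets are exact.
* The weighted t test's df convention (respondent counts) is one of two
  defensible readings of a weighted design; the Welch option and the
  reported moments let users recompute under other conventions.
* QAP calibration is verified under exchangeable null matrices; heavy
  dependence structures beyond node exchangeability are outside its
  guarantee.
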