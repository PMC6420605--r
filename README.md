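# coopnet

Networks of co-occurring opinions from free-association surveys.

`coopnet` is for survey researchers who collect **multiple-response free
associations** — each respondent writes five words that come to mind for a
cue, labels each word with two emotions from a fixed 20-label inventory,
and (optionally) fills in attitude scales — and who want to recover the
*structure of opinions* in the population from those responses. The package
turns a respondent table into a signed co-occurrence network, finds opinion
modules in it, and validates the modules three independent ways.

## The method

**1. Signed LLR co-occurrence network.** For associations *i* and *j*
mentioned by *i<sub>n</sub>* and *j<sub>n</sub>* of *n* respondents, with
*k* respondents mentioning both, the edge weight is the Dunning
log-likelihood-ratio statistic of the 2×2 respondent table, signed by
attraction versus repulsion:

    λ(i,j) = L(k, i_n, j_n/n) · L(j_n−k, n−i_n, j_n/n)
             ───────────────────────────────────────────────
             L(k, i_n, k/i_n) · L(j_n−k, n−i_n, (j_n−k)/(n−i_n))

    LLR(i,j) = −ln λ   if k/n ≥ (i_n/n)(j_n/n)     (attraction, positive)
             =  ln λ   otherwise                    (repulsion, negative)

with L(s, m, p) the binomial likelihood of *s* successes in *m* trials.
`2·|LLR|` is the G statistic and is asymptotically χ²(1). Associations
mentioned by fewer than 3 respondents are dropped (rare responses are
idiosyncratic, not part of the shared representation).

**2. Opinion modules.** The complete signed network is partitioned by
maximizing the signed generalization of Newman–Girvan modularity,

    Q = 1/(v⁺+v⁻) · Σ_ij [ (w⁺_ij − s⁺_i s⁺_j / v⁺) − (w⁻_ij − s⁻_i s⁻_j / v⁻) ] δ(M_i, M_j),

via a Louvain optimizer run thousands of times; the runs' co-classification
frequencies form a consensus matrix that is re-partitioned until 100
consecutive partitions agree.

**3. Validation.**
* *Affective similarity* — `2 − L1` distance between two associations'
  normalized 20-bin emotion-label distributions; its binned Spearman
  correlation with LLR (QAP permutation test) checks that co-occurring
  associations carry similar feelings.
* *Reproducibility* — edge-level QAP correlation and modular nMI between
  two survey waves, compared against edge-, weight- and
  strength-preserving signed null networks; plus a sweep of the rarity
  threshold (3→13) showing stability rises as the analysis narrows to core
  associations.
* *Attitudes* — respondents are assigned to the module holding the strict
  majority of their associations and compared across modules by weighted
  *t* tests (weights = association counts), with Cohen's *d* and a power
  annotation (64 per group reaches power .8 at *d* = 0.5).

## Worked example

A single LLR evaluation — two associations mentioned by 93 and 97 of 505
respondents that co-occur in only 6 (independence would predict 17):

```r
compute_llr(93, 97, 6, 505)
#> [1] -7.270041        # strong repulsion, in nats
expected_cooccurrence(93, 97, 505)
#> [1] 17  (exact 17.86)
```

Full pipeline on a synthetic population with three planted opinion groups
(the generator mirrors the survey design: 5 associations, 2 emotion labels
each, POT/GM/SDO scores):

```r
library(coopnet)
cfg <- population_config(n_respondents = 505)
pop <- generate_population(cfg, seed = 1)
voc <- build_vocabulary(pop$records, min_occurrence = 3)
net <- build_coop_network(pop$records, voc)
net
#> CoOp network: 120 associations, 505 respondents (min occurrence 3)
#>   signed LLR edges: 1362 positive, 5778 negative, 0 zero
#>   weight range [-46.656, 64.271]

cons <- consensus_partition(net$weights, n_runs = 200, n_check = 50, seed = 2)
cons
#> Consensus partition: 3 modules after 1 agreement round(s)
#>   mean Q over 200 runs: 0.4433; consensus partition Q: 0.4433

aff <- affective_matrix(pop$records, voc)
binned_llr_affect_correlation(net, aff, n_perm = 500, seed = 3)
#> Binned LLR-affect correlation: rs(55) = 0.820, p_QAP = 0.001996 (500 permutations)

rep_ <- attitude_report(pop$records, cons$partition, voc, scales = "pot")
rep_$moments
#>   module           label scale  wam   wav   n total_weight
#> 1      1 G3_w01 & G3_w02   pot 3.67 0.671 182          910
#> 2      2 G2_w01 & G2_w02   pot 3.01 0.737 164          820
#> 3      3 G1_w01 & G1_w02   pot 2.40 0.695 159          795
```

The three modules recover the three planted groups exactly (nMI = 1 against
the ground truth), module POT means reproduce the planted gradient, and all
pairwise weighted *t* tests are significant with adequate power.

A command-line wrapper with `build` / `compare` / `attitudes` / `simulate`
subcommands is installed at `inst/cli/coopnet.R`:

```sh
Rscript inst/cli/coopnet.R build --input responses.csv --out results/ --seed 1
```

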