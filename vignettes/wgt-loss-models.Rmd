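---
title: "Modeling biased gene loss after a whole-genome triplication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling biased gene loss after a whole-genome triplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgtloss)
```

## The problem

An ancient hexaploidy (whole-genome triplication, WGT) gives every
ancestral locus three homoeologous copies, one per parental subgenome.
Over time most loci lose one or two copies, and in allopolyploids the
losses are *biased*: one parental subgenome (the least fractionated,
LF) keeps more genes than the other two (MF1 and MF2).  Given several
descendant genomes, two questions arise:

1. For each locus ("pillar") and each genome, *which* syntenic track
   descends from which parental subgenome?
2. Do the subgenomes differ statistically in their loss rates, and did
   the hexaploidy form in one step or in two successive
   hybridizations?

`wgtloss` answers both with a single likelihood: a hidden Markov chain
along ordered pillars whose hidden states are, per genome, one of the
$3! = 6$ assignments of track slots to subgenomes (so $6^G$ combined
states for $G$ genomes; $1296$ for four), and whose emissions are
phylogenetic likelihoods of the observed presence/absence patterns
under a seven-state gene-loss chain running down the species tree.

## The loss chain

The copy-number state of a pillar is a nonempty subset of the three
subgenomes: the triplicated state `T`, three duplicated states `D12`,
`D13`, `D23`, and three absorbing single-copy states `S1`--`S3` (a
locus is never lost entirely — pillars are defined by having at least
one surviving gene per genome).  From a state with all three copies,
the copy from subgenome $g$ is lost at relative rate $f^T_g$; from a
duplicated state at rate $\sigma f^D_g$.  Subgenome 3 (MF2) is the
baseline, $f^T_3 = f^D_3 = 1$, and the overall loss rate $\alpha$ is
absorbed into the branch lengths $\nu = \alpha t$, so a branch length
is the expected number of loss events per surviving baseline copy at
the triplicated level.

The nested variants are:

| variant      | free loss parameters                  | count |
|--------------|---------------------------------------|-------|
| `null`       | $\sigma$                              | 1     |
| `1dom`       | $\sigma, f^T_1, f^D_1$                | 3     |
| `g3`         | $\sigma, f^T_{1,2}, f^D_{1,2}$        | 5     |
| `g3rootspec` | the `g3` set, twice (root vs rest)    | 10    |
| `g3root`     | the `g3` set $+\ \tau, \beta_{12}, \beta_{13}$ | 8 |

Fractionation factors act at *both* the triplicated and duplicated
levels.  This is the unique parameterization under which the
likelihood-ratio tests between adjacent variants have the degrees of
freedom 2 (`null` vs `1dom`), 2 (`1dom` vs `g3`), 5 (`g3` vs
`g3rootspec`) and 3 (`g3` vs `g3root`).

### The two-step (`g3root`) model

Under the two-step hypothesis the first hybridization merges MF1 and
MF2; the LF genome arrives later, along the root branch.  Each pillar
therefore starts the root branch in the duplicated state of the two
first subgenomes and the arrival is modeled as a transition to `T` (at
rate $\tau$, no losses before the arrival) or directly to `D12` /
`D13` (at rates $\beta_{12}$, $\beta_{13}$: a loss from MF2 or MF1
folded into the arrival).  Pillars still in the pre-arrival state at
the end of the root branch never received an LF copy.

Two modeling decisions deserve comment, because the natural
seven-state picture is ambiguous about them:

* **Arrival is a one-off event.**  Internally the root branch runs on
  an expanded eight-state chain (`g3root_expanded_generator()`): the
  pre-arrival duplicated state is distinct from the post-arrival `D23`
  that can be re-entered by losing the LF copy again.  Without the
  distinction, a pillar that lost its newly arrived LF copy could
  "re-arrive", and the model would *not* reduce to the one-step `g3`
  model as $\tau \to \infty$ — a reduction we consider definitional
  for a nested arrival model, and which `fit_pillars(fixed =
  list(tau = 1e4, beta12 = 0, beta13 = 0))` verifies to within
  optimizer tolerance.
* **Pre-arrival losses travel through $\beta$.**  The pre-arrival
  state has no other exits: the $\beta$ rates *are* the pre-arrival
  loss process, and every pre-arrival loss of MF1 (say) is a
  $\beta_{13}$ transition.  This keeps the pre-arrival loss accounting
  exact (each root-branch loss of a first subgenome is unambiguously
  dated by its transition type) and matches the interpretation of
  pillars that remain duplicated as "never received the third
  subgenome".  `prearrival_loss_fractions()` reports, per first
  subgenome, the expected fraction of its root-branch losses that
  predate the arrival, using expected transition counts conditional on
  the posterior root-branch endpoint (the block matrix-exponential
  identity for conditioned Markov jump counts).

### Subgenome label conventions

`g3` and `g3rootspec` are invariant under exchanging subgenomes 1 and
2 (swap $f^T_1 \leftrightarrow f^T_2$, $f^D_1 \leftrightarrow f^D_2$
and relabel states).  Fits are therefore canonicalized so that
subgenome 1 is the *least* fractionated (smallest $f^T + f^D$ sum),
matching the LF/MF1/MF2 naming.  The `1dom` and `g3root` variants are
not label-symmetric (`1dom` distinguishes only subgenome 1; in
`g3root` subgenome `last_subgenome` is the late arriver).

## The pillar HMM

Between adjacent pillars each genome's hidden permutation persists
with probability $1 - \theta_g$ and is redrawn uniformly over all six
permutations otherwise; at an annotated synteny break the redraw is
forced.  $\theta_g$ is the per-genome synteny turnover probability per
pillar step (default 0.05, the order of magnitude implied by a few
hundred rearrangement breakpoints among ~10,000 pillars).  The initial
distribution is uniform: nothing is known before the first pillar.
Emissions are computed by Felsenstein pruning of the loss chain over
the species tree, with the tip likelihood the indicator of the state
obtained by mapping the presence pattern through the genome's
permutation; the root prior is a point mass on `T` (or on the
pre-arrival duplicated state for `g3root`).

Because emissions depend on a pillar only through its per-genome
presence masks, they are computed once per distinct mask combination
(at most $7^G$, typically a few hundred); the forward, backward and
branch-endpoint passes are C++ (`Rcpp`), with the transition kernel
applied as $G$ axis contractions of the $6^G$ tensor.

`fit_pillars()` maximizes the likelihood jointly over the loss
parameters, all branch lengths and $\theta$ with box-constrained
L-BFGS-B: rates ($\sigma$, $\tau$, $\beta$, $\nu$) on the log scale,
fractionation factors and $\theta$ raw inside $[0,1]$.  We use the box
rather than a logit transform so boundary optima ($\hat f = 1$) are
reached exactly, which keeps likelihood-ratio statistics clean.
Multi-start is supported (`n_starts`, seeded and recorded); nested
pairs should be fitted with `fit_nested_pair()`, which warm-starts the
general variant at the nested optimum so the ratio statistic cannot go
negative, and for `g3root` adds starts over a grid of arrival time
scales because the instantaneous-arrival plateau is flat in $\tau$.

## Loss bookkeeping

`expected_losses_per_branch()` gives posterior expected surviving-copy
counts at both ends of every branch and expected loss events on it,
per subgenome.  Because a copy, once lost, never returns, expected
event counts equal expected endpoint-indicator counts, and the
conservation identity `survivors_top - losses + gains =
survivors_bottom` holds exactly by construction (`gains` is nonzero
only for the arriving subgenome on the root branch of `g3root`).
Endpoint-pair posteriors are computed by an inside--outside pass over
the tree for every hidden orthology state, aggregated per unique
pattern combination.

## What the generator simulates — and what it does not

`simulate_pillars()` draws the hidden permutation chains, runs the
loss chain down the tree by exact stochastic simulation (competing
exponentials; the expanded chain on the root branch under `g3root`),
and writes tip states through the true permutations into track slots.
Every sampled transition is recorded, so tests can compare posterior
expectations against planted event counts.  Break flags are emitted
exactly where a redraw occurred, as a synteny-based pillar builder
would flag them.

Default study conditions (used by the acceptance tests and
`scripts/acceptance.R`): the four-genome tree of `default_study_tree()`
(the two *Brassica* genomes sisters, *Crambe* joining them, *Sinapis*
diverging at the end of a long root branch; root $\nu = 0.45$ so that
roughly half of all losses accrue before the first divergence, tips
$\nu \approx 0.12$--$0.28$), `g3` truth $\sigma = 0.8$,
$f^T = (0.6, 0.8, 1)$, $f^D = (0.5, 0.7, 1)$, $\theta = 0.05$, 5,000
pillars; the two-step block uses a three-genome tree, 3,000 pillars
and $\tau = 1$, $\beta = 0.3$.  Problem sizes were chosen once, as the
smallest at which the parameter-recovery targets are comfortably
inside their tolerances; the 0.12 tolerance on recovered pre-arrival
fractions is ~2.7 sampling standard deviations of that estimator at
this size (measured over independent replicates).

What the generator does **not** emulate: assembly and annotation
error, missing pillars (every simulated pillar has all genomes),
tandem arrays inside tracks, gene conversion between homoeologs, and
rate variation across loci.  Passing recovery tests therefore show
correctness of the inference machinery under the model's own
assumptions, not robustness to real-data violations of them.

Network and expression generators are deliberately simple:
`simulate_labeled_network()` joins same-class pairs
`enrichment`-fold more often within a fixed expected mean degree
(`enrichment = 1` is an exchangeable null); `simulate_expression()`
plants log-normal coexpression blocks sharing a latent condition
profile, with independent missingness.

## Numerical choices

* Matrix exponentials by eigendecomposition with a condition-number
  guard (reciprocal condition $> 10^{-7}$) and a scaling-and-squaring
  fallback — the loss chain is defective at parameter values where the
  triplicated and duplicated exit rates coincide (e.g. `null` with
  $\sigma = 1.5$).  Round-off negatives are clamped and rows
  renormalized; entries outside each state's reachable set are forced
  to exact zeros.
* Forward/backward passes are scaled per pillar; posteriors are
  normalized per pillar.  Zero-likelihood evaluations inside the
  optimizer return a large finite penalty instead of `-Inf`.
* L-BFGS-B convergence: `factr = 1e7` (about $10^{-2}$ lnL units at
  study scale), `maxit = 400`; parameter values are clamped inside
  their boxes before evaluation so finite-difference gradients can
  probe just outside a bound.
* Annealing defaults: $T_0 = 1$, geometric cooling 0.995 per sweep,
  stop after 200 sweeps without improvement; best-seen layout
  returned, so the result never scores below the input.  The adjacency
  window is $w = 1$ (strict order neighbours) — synteny here is an
  order property, not a base-pair one.
* Maximum-weight matching is exact per connected component
  (branch-and-bound with a suffix-weight bound).  Components of
  gene-adjacency endpoint graphs are short chains with local
  conflicts, where the search is effectively linear; adversarial dense
  components could be exponential.

## A caveat on the fractionation likelihood-ratio tests

The tests between nested variants use the $\chi^2$ reference with the
parameter-count degrees of freedom.  On data with real fractionation
bias the statistics are enormous and the reference is immaterial.  At
the *exchangeable null* (all $f = 1$), however, the reference is
strongly conservative, for a structural reason worth recording: the
orthology permutations are latent and uniform, so a first-order
perturbation of a single subgenome's loss rate is indistinguishable,
to first order, from a symmetric rescaling of all triplicated-level
rates — a direction the null model's own $\sigma$ and branch lengths
already span.  The score in the fractionation directions therefore
vanishes identically at the null optimum, the Fisher information is
singular there, and the null distribution of $2\Delta\ln L$ collapses
toward zero (empirically $\sim 10^{-5}$) rather than following
$\chi^2_2$.  A nominal 5% test at the exchangeable null rejects
essentially never.  The practical consequence is only that these tests
are conservative when there is nothing to find; the package documents
the measured null rejection rate in its acceptance suite instead of
pretending the $\chi^2$ calibration holds there.

## Known limitations

* The boundary caveat above; also $\hat f = 1$ estimates sit on the
  box boundary and their standard errors are not returned.
* The HMM assumes at least one surviving gene per genome per pillar;
  loci absent from a genome must be filtered out upstream.
* Orientation of homology sets in the ancestral-order module is
  inferred from traversal order because gene-order input carries no
  strand; segments inverted in a subset of genomes split their
  adjacency support accordingly.
* `enumerate_topologies()` is exhaustive ($(2n-3)!!$); it is meant for
  the handful of genomes a pillar analysis uses, not for large trees.

## A worked micro-example

```{r example, eval = FALSE}
tree <- default_study_tree()
truth <- loss_model("g3", sigma = 0.8, fT = c(0.6, 0.8, 1),
                    fD = c(0.5, 0.7, 1))
sim <- simulate_pillars(tree, truth, hmm_spec(0.05),
                        n_pillars = 500, seed = 1)
fit <- fit_pillars(sim$pillars, tree, loss_model("g3"),
                   hmm_spec(0.1), n_starts = 1, seed = 1)
fit
lrt(fit_pillars(sim$pillars, fit$tree, loss_model("null"),
                hmm_spec(fit$theta), n_starts = 1, seed = 2), fit)
head(expected_losses_per_branch(fit))
```

At 500 pillars this runs in well under a minute; the acceptance script
(`scripts/acceptance.R`) runs the full study-scale analysis.
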