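---
title: "Models and methods behind haloasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haloasr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloasr)
```

`haloasr` implements the computational chain of an ancestral protein
resurrection study of halophilic enzymes — species tree, DTL gene
histories, marginal ancestral reconstruction, halophily metrics — with a
synthetic-data generator supplying ground truth at every stage. This
vignette documents the models, the defaults and why they were chosen, the
numerical conventions, and what the package's validation does and does not
establish.

## Substitution model and likelihood

The model is a standard reversible amino-acid process: symmetric
exchangeabilities $S$, stationary frequencies $\pi$, generator
$q_{ij} = S_{ij}\pi_j$ with the diagonal set so rows sum to zero, rescaled
so the expected rate at stationarity is 1 — branch lengths are therefore
expected replacements per site. Rate heterogeneity among sites is the
discrete-gamma model: $K$ equal-probability categories of a
$\Gamma(\alpha,\alpha)$ distribution, each category carrying the **mean of
its quantile bin** (the mean/median choice is rarely stated in
applications; the mean-of-bin convention is fixed here for
reproducibility). Defaults are $\alpha = 1$, $K = 4$.

The state order is the PAML dat-file convention
(A, R, N, D, …, V), used by every matrix, profile and tie-break in the
package. The default empirical model is LG, shipped as a plain PAML-format
file and parsed by `read_paml_dat()`; a Poisson (uniform) model is built in
so that tests do not depend on any particular published matrix.

Likelihoods use Felsenstein pruning with per-node, per-column rescaling, so
deep trees do not underflow. Gaps (`-`) and unknown residues (`X`, `?`) are
treated as missing data — an all-ones partial vector — which is standard
practice; an impossible column (conflicting states across a zero-length
path) yields the explicit sentinel `-Inf`, never an exception. Transition
probabilities come from a symmetric eigendecomposition of the generator,
cached per model; entries are clipped at zero and rows renormalized to
absorb round-off.

Pairwise ML distances (`ml_pairwise_distance()`) maximize the two-sequence
likelihood over $t \in [10^{-6}, 10]$ by Brent search; pair counts are
canonicalized (unordered pairs) so the estimate is *exactly* symmetric in
its arguments. Tree inference is deliberately modest: NJ on ML distances
with negative branch estimates clamped to zero, then midpoint rooting.
Branch lengths are **not** re-optimized on the full tree; this stand-in
keeps inference desk-scale and is a documented limitation, not a claim of
parity with Bayesian tree inference.

## Column filters

Two filters mirror common practice in concatenation pipelines:

* `filter_gappy_columns()` drops columns with **strictly more than** 20 %
  gaps (the threshold is a parameter; the strict inequality is the
  documented convention).
* `remove_fast_sites()` removes exactly $\lfloor fL \rfloor$ columns of
  highest posterior mean rate, ties resolved toward the lower column index.
  Rates are estimated **once** from the full alignment and removal is
  cumulative across 10 % steps; whether the original tools re-estimated
  rates between steps is ambiguous, so one convention is fixed and
  re-estimation is available by recomputing `site_posterior_rates()` on the
  filtered alignment.

## Synthetic data: what it emulates, and what it does not

The generator reproduces the *structure* of a halobacterial unicopy protein
family study: a dated (ultrametric) species tree, a gene history with
duplications, transfers and losses, an alignment with rate heterogeneity,
indels and an acidic compositional bias, and folded-fraction-versus-salt
transition curves.

* **Species trees** come from forward birth–death simulation observed at
  the first passage to $n$ extant lineages (the observation instant is
  drawn uniformly within the following inter-event wait, so the final
  sojourn is not degenerate); extinct side branches are pruned. This is the
  simple-sampling variant; it is adequate for generating study conditions
  but is not a sampler of the fully conditioned birth–death posterior.
* **Gene histories**: one lineage enters at the species root; D/T/L fire
  as independent Poisson processes per unit time; a transfer copies the
  lineage into a uniformly chosen *contemporaneous* other branch; with
  `replace = TRUE` the recipient's resident copies are deleted
  (replacement-transfer semantics). DTL rates for Halobacteria are not
  quantified anywhere usable, so the demo defaults (0.05 each per unit
  time on trees of height ~1) are illustrative, chosen to yield a handful
  of events per family, and are not estimates.
* **Sequences**: the root is drawn from $\pi$ (or the halophilic
  frequencies); each site draws its gamma category once at the root and
  inherits it ("sites have rates", matching the inference model); child
  states are sampled directly from rows of $e^{Qrt}$ — exact, no
  uniformization needed at this scale. Indels fire per branch at a rate
  per site per unit length with geometric lengths (mean 3 by default);
  column bookkeeping maintains the true alignment exactly, and an
  insertion never re-occupies a previously deleted homologous column.
  Downstream stages therefore consume *true* alignments: alignment error
  is deliberately outside the simulated error budget, isolating
  reconstruction behavior from aligner behavior.
* **Halophilic bias** is an alternative stationary composition: D+E total
  0.22 and K+R total 0.06 (each split proportionally to the base model,
  remaining mass renormalized), used both for the root draw and for a
  matched rate matrix. The 0.22/0.06 totals encode the strong acidic
  enrichment (DE/KR ≈ 3.7 in expectation) typical of halophilic MalDH
  surfaces; the bias is compositional only — no structure, no solvent.
* **Stability curves** are increasing logistics
  $f(c) = 1/(1+e^{-(c-m)/w})$ (halophilic proteins unfold at *low* salt)
  with Gaussian noise clamped to $[0,1]$.

Every generator is a pure function of (parameters, seed): the same call is
byte-identical, and the simulation truth object records tree, ancestors,
per-site categories and parameters.

Passing tests on these data show that the algorithms are correct and that
recovery is achievable under the stated conditions; they do not show
robustness to alignment error, model misspecification beyond
Poisson-vs-LG contrasts, site-heterogeneous (CAT-like) processes, or
compositional drift over time, none of which the generator emulates.

## DTL reconciliation

Reconciliation is a minimum-cost dynamic program over (gene node × species
branch × time slice), where slices are bounded by consecutive internal-node
ages of the dated species tree (ages must be distinct; ties raise an error
asking for a jitter). Events and costs: speciation 0, duplication
$\delta = 2$, transfer $\tau = 3$, loss $\lambda = 1$ by default, with the
compound speciation-loss and transfer-loss steps; transfers are allowed
only between distinct branches of the same slice. The gene lineage enters
on a virtual branch above the species root, matching the simulator's entry
convention — a family that "originates" lower in the tree is charged the
losses implied by that convention. Parsimony deliberately replaces ML
amalgamation and rate estimation: it is exact, enumerable, and testable
against brute force on small instances. One optimal scenario is returned,
with deterministic tie-breaking (speciation < duplication < transfer, then
ascending species-branch index). Transfers "from the dead" (extinct,
unsampled donors) are not modeled; a transfer whose true donor went extinct
will be attributed to a sampled contemporaneous branch.

Conditional clade probabilities (`compute_ccp()`) are computed from
gene-tree samples as frequency ratios and serve as a support diagnostic
only; no amalgamated tree search is performed.

## Marginal ASR and ancestral gaps

`marginal_profiles()` performs the empirical-Bayes marginal reconstruction:
model parameters are taken as given, and for each internal node and column
the posterior over states given all tip data is computed by an
inside–outside pass, marginalized over gamma categories weighted by the
per-column category likelihoods (the per-site category is *not* fixed —
standard marginal ASR). The MAP state is reported with its posterior
probability; exact ties are broken by the fixed state order and counted in
the output. Joint reconstruction and Bayesian sampling of ancestors are out
of scope.

Ancestral gaps are inferred from the binary presence character of each
column: two-pass Fitch parsimony with ambiguous assignments resolved as
"present" (a liberal convention that favors reconstructing a residue
whenever parsimony allows it), or optionally Dollo parsimony (single
origin at the MRCA of present leaves, losses below). `compose_ancestors()`
then substitutes gaps into the MAP sequences, so a node's sequence has a
gap exactly where its inferred presence state is absent.

Two conventions deserve explicit flags because published descriptions
leave them open: the "well identified" statistic uses a **strict**
threshold (PP > 0.9), and replacement counts between gapped sequences
**exclude** any column where either sequence has a gap. Replacement counts
against a fixed root are monotone along root-to-leaf paths only at low
divergence; at higher divergence reversals can decrease the count, which
is why the ground-truth monotonicity check runs on short branches.

## Stability-midpoint fitting

`fit_mf_half()` replaces a graphical reading of transition curves with an
explicit estimator: least squares on the two-parameter logistic, initialized
at the concentration whose fraction is nearest 0.5 and a width of one tenth
of the concentration span. Very sharp transitions can defeat that start, so
a small deterministic grid of alternative widths is tried and the best
residual kept; if the optimizer fails entirely, the 0.5 crossing is linearly
interpolated and the result flagged (`method = "interpolation"`), which
reproduces the graphical procedure. Bell-shaped curves (MgCl2-type
stabilization then chaotropic unfolding) are handled by restricting the fit
window to the low-concentration limb via `window=`; no two-transition model
is fitted.

## Pipeline, seeds and determinism

`run_pipeline()` executes the stages in the canonical order and scores
recovery against the simulation truth. One master seed generates stage
seeds by a fixed counter scheme (`seed + stage index`), each recorded in
the report so any stage can be replayed in isolation. ASR runs on the true
gene tree by default (`asr_tree = "inferred"` switches), separating
reconstruction error from tree error — the same logic as fixing a single
"joint tree" topology for ASR. Internal nodes are matched to truth by
identical descendant leaf sets; unmatched nodes are listed, never silently
dropped. Two runs with the same configuration leave byte-identical
artifact trees; for that reason wall-clock timings live only in the
returned report object, not in the on-disk JSON.

The default demo conditions (8 taxa, 200 columns, gamma $\alpha=1$,
$K=4$, tree height 0.4 replacements/site) and the validation problem sizes
(32-taxon, 300-column reconstruction-confidence simulations; 16-taxon
short-branch recovery replicates; 100-curve midpoint recovery) were chosen
as representative of a single protein-family study — a few hundred
alignment columns, tens of taxa — while remaining comfortable on a single
CPU.

## Known limitations

* No CAT/CAT+GTR mixtures, MCMC, model selection, or time-heterogeneous
  (COaLA-type) models; the NJ stand-in explores no topology space.
* Parsimony reconciliation has no transfer-rate estimation and no
  transfers from extinct lineages.
* DE/KR is computed on whole sequences, not solvent-accessible surfaces —
  the structure-based calculation requires crystal structures and is out
  of scope; whole-sequence ratios are what a sequence-only pipeline can
  supply.
* The generator's DTL rates are illustrative defaults, not organism
  estimates, and the birth–death sampler is the simple-sampling variant.
* No DNA/codon layer, hence no Dn/Ds; no structural, solvent or enzymatic
  simulation.
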