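# haloasr

Ancestral protein resurrection studies of halophilic enzymes — such as the
malate dehydrogenases (MalDH) of Halobacteria — rest on a chain of
phylogenetic computations: a dated species tree, gene trees reconciled
against it with duplication/transfer/loss (DTL) events, marginal ancestral
sequence reconstruction (ASR) with ancestral-gap handling, and sequence-level
proxies of halophily. `haloasr` re-implements that chain as a desk-scale,
fully testable R package. Every stage can be exercised on synthetic data with
known ground truth, so reconstruction quality is measurable rather than
assumed.

It is aimed at molecular evolution researchers who want to prototype or
sanity-check resurrection pipelines, and at methods teaching: each component
is small, seeded, and validated against brute-force oracles.

## What it computes

**Likelihood core.** For a reversible amino-acid model with exchangeabilities
*S* and stationary frequencies *π*, the normalized generator is
*q<sub>ij</sub> = S<sub>ij</sub>π<sub>j</sub>* (rescaled so
−Σ<sub>i</sub> π<sub>i</sub>q<sub>ii</sub> = 1), with discrete-gamma rate
heterogeneity (shape *α*, *K* mean-of-bin categories). Felsenstein pruning
gives per-column log-likelihoods; site-specific posterior mean rates
*Σ<sub>k</sub> w<sub>k</sub>r<sub>k</sub>* drive stepwise fast-site removal,
and a strict >20 % rule filters gappy columns. The LG model ships as a
PAML-format file; any dat-style matrix can be loaded.

**Synthetic data.** Birth-death dated species trees; DTL gene histories
(Poisson events in time, transfers restricted to contemporaneous branches,
optional replacement transfers); protein alignments with inherited per-site
rate categories, geometric indels with exact column bookkeeping, and an
acidic-biased ("halophilic") stationary composition; logistic folded-fraction
vs. salt transition curves. All generators are pure functions of
(parameters, seed).

**Reconciliation.** A minimum-cost DTL dynamic program over (gene node ×
species branch × time slice), with conditional clade probabilities (CCPs)
computed from gene-tree samples as a support diagnostic.

**ASR.** Marginal (empirical-Bayes) posteriors for every internal node and
column via an inside–outside computation; maximum-posterior (MAP) states;
Fitch (or Dollo) presence/absence parsimony for ancestral gaps, substituted
into the final ancestral sequences.

**Halophily metrics.** The DE/KR ratio (acidic over basic residue counts;
values > 2 mark halophilic surfaces), the stability midpoint M<sup>f</sup>½
from a two-parameter logistic fit of folded-fraction curves, and
metric-vs-replacement trajectory tables.

## Worked example

```r
library(haloasr)

cfg <- pipeline_config(n_taxa = 8L, root_length = 200L, seed = 1L)
report <- run_pipeline(cfg, "demo_out")
report
#> Recovery report:
#>   matched internal nodes: 8
#>   mean ancestral identity: 0.963519
#>   mean well-identified fraction: 0.849375
#>   gene-tree RF distance: 2
#>   DTL event precision/recall: 1 / 1
```

The pipeline simulated an 8-species dated tree, evolved a 200-column
halophilic-biased MalDH-like family along a DTL gene history, filtered,
re-inferred the gene tree (ML distances + NJ + midpoint rooting), reconciled
it, and reconstructed ancestors on the true tree. Here 96.4 % of ancestral
residues match the simulated truth, 85 % of ancestral sites are
"well identified" (MAP posterior > 0.9), the re-inferred tree differs from
truth by one bipartition (RF 2), and the parsimony reconciliation recovered
the simulated DTL events exactly.

```r
fit_mf_half(simulate_stability_curve(0.30, 0.05, seq(0, 2, 0.1)))
#> M^f1/2 = 0.3 M (width 0.05 M; logistic fit; rss 6.47782e-32 )

anc <- read_fasta("demo_out/ancestors_inferred.fasta")
de_kr_ratio(anc[1, ])   # root ancestor under the acidic-biased generator
#> [1] 6
```

A noiseless transition curve generated at a 0.30 M midpoint is recovered
exactly, and the reconstructed root ancestor shows the strongly acidic
composition (DE/KR ≫ 2) the generator encodes.

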