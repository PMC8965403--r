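# lingstab

Stability analysis of binary structural traits on phylogenies: which
features of a language (or any presence/absence character) persist along
lines of descent, and which change too fast to carry genealogical signal?

`lingstab` measures stability as the combination of

* **phylogenetic signal** — the D statistic for binary traits,
  `D = (d_obs − d̄_Brownian) / (d̄_random − d̄_Brownian)`, where `d` is the
  sum of sister-clade differences of nodal values computed bottom-up as
  daughter means. D is calibrated at 1 under random shuffling and 0 under
  a thresholded Brownian process; D < 0 is overclumped, D > 1
  overdispersed;
* **evolutionary rate** — maximum-likelihood gain (`q01`) and loss (`q10`)
  rates under a hidden-rates model: each observed state splits into a slow
  and a fast class, giving a 4-state CTMC (`0S, 0F, 1S, 1F`) with eight
  free rates, fitted by Felsenstein pruning with the conditional-likelihood
  (FitzJohn/Maddison) root treatment;
* **reconstructability** — marginal ancestral state probabilities at each
  family's root node (the proto-language), with band summaries, per-category
  normalized proportions and pairwise family overlaps.

Because trees estimated from the traits themselves would make the signal
circular, trees come from a *data-free pseudo-posterior*: a classification
taxonomy with monophyly constraints is expanded into resolved ultrametric
trees in which every constraint holds with frequency 1 and every polytomy
is resolved uniformly over labeled histories (a trichotomy pairing appears
with probability 1/3). Root height is normalized to 1, which fixes the
unit rates are expressed in.

A synthetic-data generator (5 families of 12/2/14/11/21 taxa, binary
features under known CTMC / clumped / shuffled / Brownian-threshold
regimes, configurable missingness) provides ground truth for every stage.

## Worked example

The analysis workflow lives in `analysis/01_simulate.R` …
`analysis/06_summaries.R`; each script is a thin driver over the package
functions and writes its tables under `results/`. A scaled run (40
features, 10 trees, 100 null simulations, 3 optimizer starts; about ten
minutes on one core):

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

prints, among other things:

```
matrix: 60 x 40, 14.4% missing; regimes: brownian_threshold=8, clumped=8, ctmc=16, shuffled=8
  family Family1 (12 tips): clade frequency 1.00
  unresolved pair {F5_t06, F5_t18}: frequency 0.50 (low = agnostic)
median D by generating regime:
  brownian_threshold   n= 8  median D =   0.13
  clumped              n= 8  median D =  -1.49
  ctmc                 n=16  median D =   0.51
  shuffled             n= 8  median D =   0.96
Kendall tau, median D vs median log10 rate:
      gain               all 40 0.5477872 6.513676e-07
      loss               all 40 0.6307692 9.907257e-09
```

Reading this: the constrained families are monophyletic in every sampled
tree while an unresolved pairing inside a family floats at low frequency;
the D statistic lands where each generating regime says it should
(single-origin clumped traits strongly negative, shuffled traits at ~1,
Brownian-threshold traits at ~0); and features that change faster show
weaker signal (positive τ between median D and median log10 rate, p ≈ 0).
Full per-feature tables (`stability.csv`, `rate_fits.csv`,
`asr_root_probs.csv`, …) and a manifest with the configuration hash are
written under `results/run/`.

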