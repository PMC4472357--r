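---
title: "Modelling multilocus hybrid seed lethality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multilocus hybrid seed lethality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdmseed)
```

## The genetic model

Crosses between the selfing species *Capsella rubella* and its outcrossing
relative *C. grandiflora* fail non-reciprocally: with the selfer as seed
parent every hybrid seed aborts (an endosperm-cellularization failure),
while the reciprocal direction yields viable F1 plants. `bdmseed`
implements the multilocus Bateson–Dobzhansky–Muller (BDM) model of that
barrier and everything needed to confront it with crossing data.

The model has one class of *maternal-incompatibility* loci (default one
locus, allele written `R`, carried by the selfer) and one class of
*paternal-incompatibility* loci (default three, alleles `A`, `B`, `C`,
carried by the outcrosser), all unlinked. A seed dies if and only if

* its **maternally inherited** gamete carries `R` at every maternal locus,
  and
* its **paternally inherited** gamete carries `A`, `B` *and* `C` — the full
  paternal complement.

Everything else survives. The conjunction acts on the gamete pair, not on
the parental sporophytes, which is what makes the barrier
parent-of-origin dependent: the pure selfer (`RR|aabbcc`) pollinated by
the pure outcrosser (`rr|AABBCC`) loses every seed (all eggs carry `R`,
all pollen carries `ABC`), while the reciprocal cross loses none (no egg
carries `R`). The endosperm's 2m:1p genome dosage is not modelled
separately; because both central-cell nuclei derive from the same
megaspore, a rule stated on the fertilizing gamete pair is equivalent for
the designs modelled here.

Two assumptions are worth making explicit. First, loci segregate freely
(no linkage parameter); the model is about locus *counts*, not map
positions. Second, there is no gametophytic selection: all pollen classes
are transmitted at Mendelian rates, consistent with the normal pollen
viability observed among F2 plants in this system. For a heterozygous
`Rr` mother the maternal requirement is implemented gametophytically (the
egg's own allele decides); the distinction is invisible in the standard
designs, where every seed-parent tester is homozygous `RR`.

## Exact arithmetic

All model predictions are small rationals — the selfed F1 aborts 1/16 of
its seeds, one F2 plant in 120 recreates the full lethal complement — and
the package's tests pin them exactly. Probability bookkeeping therefore
runs on reduced numerator/denominator pairs (`rat()`) rather than
floating point. Numerators and denominators live in doubles, exact for
integers up to 2^53; any operation that would leave that range raises an
error rather than silently rounding. In practice the exact
single-seed-descent propagator stays far below the bound even at ten
selfing generations (largest denominator about 1.6e13).

## What the package computes

**Cross outcomes.** `cross()` enumerates the product of the two parental
gamete distributions, removes lethal pairs, and returns the exact
abortion rate plus the survivor genotype distribution, kept over
*ordered* genotypes (maternal vs paternal allele tracked) because
offspring fates are again parent-of-origin dependent; an unordered
"marker view" is derived on demand.

**The F2 panel prediction.** An F2 plant used as pollen donor on the
selfer tester triggers seed abortion at the fraction of its pollen that
carries the full `ABC` complement: 0, 1/8, 1/4, 1/2 or 1 under the
three-paternal-locus model. `f2_class_distribution()` works out the exact
frequency of each class among F2 plants. By default the F2 distribution
is conditioned on seed survival — the plants one can grow and backcross
are survivors of the F2 abortion episode — which matters: the
100%-abortion class has frequency 1/120 among survivors versus 1/64
unconditioned. Both variants are exposed; conditioned is the default
because it is the distribution a real panel realizes.

**RIL purging.** `ril_panel_distribution()` propagates a
recombinant-inbred panel from the F1 by single-seed descent with
viability selection applied at every selfing generation, exactly. The
published RIL panel's construction depth is not part of the model, so the
generation count is a parameter; six generations is a typical depth and
is the package default in the simulator. Selection purges the
incompatible combination: the fraction of lines that would trigger any
abortion on the selfer tester falls from 23/60 after one generation to
about 7% after six — below the 1/8 that neutral single-seed descent would
fix — which reproduces the qualitative observation that most RILs trigger
no seed abortion.

## Statistical confrontation

Observed data arrive as per-plant seed counts (`plant_id`, `n_seeds`,
`n_aborted`). The analysis pipeline is:

1. **Class assignment** (`assign_class()`): each plant is assigned the
   class rate maximizing the binomial likelihood of its counts. A
   mis-scoring rate ε (default 0.01, below the 2% binarization threshold
   so noise cannot flip binary calls) moves each class rate `c` to
   `c(1−ε) + (1−c)ε`, keeping the boundary classes 0 and 1 available for
   imperfectly scored plants. Ties break toward the smaller class. The
   binning rule used for the original figure is not on record; maximum
   likelihood is a principled choice that reduces to nearest-rate
   rounding as seed numbers grow.

2. **Goodness of fit** (`chisq_gof()`): Pearson chi-square of the class
   counts, pooling adjacent classes (ascending) until every expected
   count reaches 5, with the pooling map reported. One design point is
   easy to get wrong: with ~30 seeds per plant, likelihood assignment
   misreads adjacent classes at a material rate (about 17% of true-1/8
   plants are read as 1/4), so testing assigned counts against the *raw*
   theoretical frequencies rejects a true model far too often (measured
   rejection rate 0.25 at the nominal 0.05). The correct multinomial null
   is the theoretical distribution pushed through the known binomial
   read-out channel given each plant's seed count
   (`expected_assigned_counts()`); `compare_models()` uses it, and the
   type-I error is then calibrated (0.05 measured over 1000 simulated
   panels). The uncorrected expectation remains available as
   `expected_counts()` and as `chisq_gof()`'s default when no seed
   numbers are supplied.

3. **Model selection** (`compare_models()`): candidates (by default two
   vs three paternal loci) are ranked by p-value; candidates with
   p ≤ 0.05 are flagged rejected, mirroring the original non-rejection
   criterion. Selection is deliberately not information-criterion based:
   the candidates have no free parameters, so the GOF p-value is the
   natural ranking.

4. **Binarization** (`binarize_abortion()`): the strict >2% rule that
   converts rates to the binary trait consumed by QTL software, with the
   log-rate histogram attached for threshold auditing. QTL mapping itself
   is out of scope here — it needs the external marker data of the RIL
   population.

`binomial_ci()` provides Wilson score intervals for abortion proportions;
Wald intervals collapse at the 0-of-n boundary that dominates these
panels.

## The synthetic-data generator

`sim_config()` fixes a complete experiment description: the model, panel
size (default 250 plants, the size of the original F2 panel),
seeds-per-plant distribution, scoring noise ε, survivor-conditioning flag
and one integer seed that governs every draw. Defaults were chosen once,
as study conditions: seeds per plant are truncated-Poisson with mean 25
(a plausible per-plant scoring effort for a crucifer silique assay; the
original per-silique counts are not printed), ε = 0.01, conditioning on.
The generator emulates:

* `simulate_f2_cohort()` — F2 genotypes drawn from the exact
  (survivor-conditioned) distribution by a single categorical draw;
* `simulate_backcross_panel()` — per-plant seed counts, aborted counts
  binomial at the genotype's predicted rate pushed through the ε channel;
  an optional beta-binomial switch (`overdispersion`, default off) models
  intra-plant correlation of seed fates, whose true magnitude is unknown;
* `simulate_f1_selfing()` — the small F1 selfing series (default 7
  mothers, 207 seeds total);
* `simulate_ril_panel()` — stochastic single-seed descent with selection.

What the generator does *not* emulate — maternal-background QTL effects,
silique-level heterogeneity beyond the optional beta-binomial, partial
penetrance, linkage — bounds what passing tests show: they validate the
inference machinery under the model's own assumptions, not the biology of
any particular data set.

## Numerical and design choices

* Exact rationals end-to-end in the cross engine; floats only at
  presentation and in the statistical layer.
* Class assignment ties break to the smaller class (deterministic).
* Chi-square pooling is ascending and greedy with a trailing merge; fewer
  than two pooled classes is an explicit error, not a silent p = 1.
* Simulation problem sizes used in the test suite (e.g. 100 panels of 250
  plants for model recovery, 1000 panels for calibration, 2×10^4-line
  cohorts for convergence checks) were chosen to keep Monte-Carlo error
  an order of magnitude below the margins being asserted while the whole
  suite runs in a few minutes.
* Degenerate inputs fail loudly with classed conditions
  (`bdmseed_config_error`, `bdmseed_data_error`, `bdmseed_stat_error`),
  which the command-line wrapper maps to exit codes 2/3/4.

## Known limitations

The model is qualitative by construction: abortion classes are exact
pollen fractions, with no dosage-graded severity. The observed ~50%
abortion when the *outcrosser* is the seed parent in some accessions is a
different, endosperm-dosage phenomenon that this genetic model predicts
as 0% and does not attempt to capture. Linkage between incompatibility
loci, gametophytic selection, polyploidy and imprinting mechanisms are
all outside the model's scope.

## A worked example

```{r example, eval = FALSE}
model <- bdm_model(n_maternal = 1, n_paternal = 3)
f2_class_distribution(model)
cfg <- sim_config(model = model, n_plants = 250, seeds_per_plant = 30,
                  seed = 1)
sim <- simulate_f2_experiment(cfg)
compare_models(sim$records, list(bdm_model(1, 2), model))
```
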