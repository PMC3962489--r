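---
title: "Inferring chromosome pairing in new allotetraploids from marker segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring chromosome pairing in new allotetraploids from marker segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyseg)
```

## The biological question

When two diploid genomes are combined in a synthetic allotetraploid, the
behaviour of chromosomes at meiosis determines whether the new lineage
can generate heritable variation. If each chromosome pairs strictly with
its homologue, every gamete receives one allele from each subgenome and
all progeny are heterozygous at every marker that differs between the
progenitors ("fixed heterozygosity"). If homeologous chromosomes pair,
single-locus segregation produces `AA`, `Aa` and `aa` gamete classes,
progeny that are quadruple homozygotes for one subgenome's allele, and —
at the phenotypic level — segregational variance in selfed or
intercrossed progeny. `polyseg` implements the marker-based inference of
where a new allotetraploid sits on this spectrum, and the simulator and
variance analyses needed to interpret such data.

## Pairing models and their exact expectations

`pairing_model()` encodes the five classical single-locus models for a
duplex (`AAaa`) tetraploid as exact integer ratios (`0:1:0`, `1:2:1`,
`1:4:1`, `3:8:3`, `2:5:2`). Progeny genotype distributions are dose
convolutions of two gamete distributions
(`progeny_genotype_frequencies()`), with the backcross design fixing the
tester side at `aa`. *Apparent* heterozygosity — the quantity a dominant
band assay sees — counts every individual with at least one allele from
each parent, so its expectation is one minus the quadruple-homozygote
mass (`expected_apparent_heterozygosity()`).

Two of the ratios are rederived rather than merely asserted:
`enumerate_random_chromosome()` enumerates the three bivalent partitions
of the four chromosomes and `enumerate_random_chromatid()` the 28
unordered pairs of the eight chromatids. These enumerations serve as
independent oracles in the test suite; restricting them (homologous
partition only, sister pairs excluded) reproduces the other classical
ratios, which is a strong internal consistency check. The maximal
equational ratio `2:5:2` rests on a nine-configuration quadrivalent
argument whose full enumeration requires material we do not reproduce;
it is taken as authoritative and no oracle is provided for it.

## The preferential pairing factor

The continuous alternative to the discrete models is the preferential
pairing factor $p \in [0, 2/3]$: one third of random bivalent pairings
are homologous, and strict homologous pairing corresponds to the upper
bound $2/3$. With double reduction rate $\alpha$, the balanced-gamete
frequency of a duplex parent is

$$f_{GN}(p,\alpha) = \tfrac{2}{9} + \tfrac{p}{3} + \tfrac{5p^2}{4}
  + \tfrac{2}{3}\left(\tfrac{2}{3} - \tfrac{3p^2}{2}
  - \alpha\left(\tfrac{2}{3} - \tfrac{3p^2}{2}\right)\right),$$

and the total double-reduction gamete frequency is
$\alpha\,(2/3 - 3p^2/2)$. One term of the published form of this model
is typographically corrupted in our source material; the reading
implemented here (the $3p^2/2$ bracket shared by both equations) is the
one under which the $\alpha = 0$ case collapses to
$f_{GN} = 2/3 + p/3 + p^2/4$ and reproduces all published point
estimates, so we adopt it as the package's definition.

In a backcross to the `NNNN` tester only `NN` gametes from the F1 are
visible (as band-loss progeny); `GG` gametes hide inside the
heterozygous class. `estimate_preferential_pairing()` therefore assumes
equal `GG` and `NN` gamete numbers, infers
$f_{GN} = (n - 2\,\mathrm{loss})/n$, and solves the quadratic directly:

* **bivalent-only** (default): $\alpha = 0$, positive root
  $p = (-4 + \sqrt{144 f_{GN} - 80})/6$;
* **quadrivalent**: 3/8 of all `GG`/`NN` gametes attributed to double
  reduction (the share expected when all nine quadrivalent
  arrangement/separation combinations are equally likely), giving
  $p = (-4 + \sqrt{108 f_{GN} - 44})/6$, slightly larger than the
  bivalent solution for the same data.

The estimate is clamped to $[0, 2/3]$; when $f_{GN} < 2/3$ the root
leaves the parameter space and `NA` is returned with an explanatory
attribute rather than an extrapolated value. The direct solution (not
EM over unobserved genotype classes) is exact under the two stated
assumptions and is what makes per-marker estimation possible from
collapsed heterozygous/loss counts.

A likelihood ratio test against an interior null value is provided
(`lrt_preferential_pairing()`), but the natural null of strict pairing
($p = 2/3$) assigns probability zero to *any* observed loss, so the test
is degenerate there; the function flags this rather than reporting a
finite p-value, and the package deliberately does not attach
significance codes to per-marker estimates.

## Panel-level statistics

* **Detection power.** `prob_fail_to_detect()` reports $(1-q)^n$, the
  chance of observing no quadruple homozygote in $n$ progeny, with $q$
  the model- and design-specific quadruple-homozygote frequency (selfed
  random chromosome: $q = 2/36$; backcross: $q = 1/6$). Each scored
  individual is treated as one meiosis from a fully heterozygous parent;
  cumulative multi-generation homozygosity is available through the
  simulator instead.
* **Exact intervals.** `clopper_pearson_ci()` uses the beta-quantile
  form; at $k = n$ the lower bound has the closed form
  $(\alpha/2)^{1/n}$, a useful hand check.
* **Goodness of fit.** `gtest_goodness_of_fit()` computes
  $G = 2\sum o \ln(o/e)$ with the Williams divisor
  $1 + (a^2-1)/(6n(a-1))$; `heterogeneity_gtest()` computes the
  replicated-test heterogeneity $G_H$ against pooled proportions — an
  identity makes this equal $\sum G_i - G_{pooled}$ for any common
  extrinsic ratio, which the tests verify. Following standard practice
  the Williams correction is applied to the pooled test but not to
  $G_H$.

`marker_screen()` binds these into one classed object (print, summary,
`coef`); `reproduce_marker_screen()` runs it on the bundled panel. The
bundled panel retains a known outlier individual (six of the ten loss
calls) by default, matching how the original data were reported;
`exclude_outlier = TRUE` switches to the companion counts.

## What the simulator emulates

`simulate_gametes()` draws gamete classes at the *frequency level* of
the model above — `GN` at $f_{GN}(p,\alpha)$, `GG`/`NN` at equal shares
of the remainder, with the double-reduction share realised as
sister-allele pairs. A mechanistic bivalent-configuration mode was
considered and rejected: the marginal `GN` frequency of the obvious
configuration model ($2/3 + p/2$) disagrees with $f_{GN}$ between the
endpoints, and the estimator's model is the ground truth the simulator
must match for recovery studies to be meaningful. Consequences:

* loci are simulated independently (the marker designs use one marker
  per linkage group, so linkage is irrelevant to the target analyses);
* meiosis of *non-duplex* genotypes (3+1 or 4+0 subgenome compositions,
  which arise in selfed lineages once homeologous segregation has
  occurred) falls outside the duplex model; the package uses random
  chromosome assortment (uniform distinct chromosome pairs) there. At
  $p = 2/3$ lineages never leave the duplex state, so the fixed-
  heterozygosity invariant is exact.

`simulate_lineages()` reproduces the crossing design of the motivating
experiment: 48 independent family lines per cross direction, advanced by
single-seed descent (the original line-maintenance method is unstated;
single-seed descent is the configurable default), split into two
maternal lines at the penultimate generation with three measured
individuals each in the final one. `simulate_phenotypes()` adds
`mu + additive * dose + dominance * het + family + maternal + residual`
with normal deviates: the real traits motivating this design are
non-normal, but the downstream analyses are variance-based and normality
is the simplest structure satisfying their assumptions — passing
recovery tests therefore validates the estimators' arithmetic, not their
robustness to non-normal real data.

## Variance analyses

* `variance_ratio_test()` orients F2 over F1 ($F = s^2_{F2}/s^2_{F1}$)
  with a two-sided p-value $2\min(\text{tail}, 1-\text{tail})$.
* `levene_test()` centers on the group **median** by default
  (Brown–Forsythe), the appropriate choice for asymmetric floral-trait
  distributions; mean-centering is a flag.
* `cv_with_ci()` applies the standard small-sample correction
  $(1 + 1/(4n))$ and a normal-approximation interval with
  $SE = CV^*\sqrt{1/(2(n-1))}$. The textbook formula the motivating
  analysis cited could not be verified directly; this standard form is a
  documented package choice.
* `broad_sense_heritability()` defaults to the weighted environmental
  variance $V_E = (V_{P1} + V_{P2} + 2V_{F1})/4$ (configurable to the
  unweighted three-way mean, since only "from parental and F1 variance"
  is specified by convention). Negative $H^2$ is returned unmodified —
  it is the honest signal of absent segregational variance.
* `nested_variance_components()` uses expected-mean-square
  (method-of-moments) estimators with unbalanced-design coefficients,
  not REML: estimates are closed-form, negative components are reported
  as such (matching how such tables are conventionally printed), and on
  balanced data with interior estimates the EMS solution coincides with
  REML, which the test suite verifies against `lme4`. Percent-of-total
  floors negative components at zero so the column sums to 100.
  Standard errors are large-sample approximations from
  $\mathrm{Var}(MS) = 2MS^2/df$.

## Numerical choices and problem sizes

Distribution invariants are enforced at $10^{-12}$; the estimator's
forward/backward consistency at $10^{-9}$. Simulation-based checks in
the test suite use: estimator recovery at $n = 5000$ gametes and 200
replicates per true value (observed bias well under the $\pm 0.02$
tolerance); Clopper–Pearson coverage over 1000 draws at three true
proportions; nested-component recovery over 200 replicates of a balanced
40 x 2 x 3 design; heritability recovery as the mean of 20 studies of
300 individuals per class. These sizes give comfortable margins for the
stated tolerances while keeping the full suite under a minute.

## Limitations

* Per-marker significance of $\hat p$ against the strict-pairing null is
  undefined (degenerate likelihood), and the package does not guess an
  alternative null construction.
* The estimator assumes the collapsed het/loss dichotomy (`GGNN` and
  `GNNN` indistinguishable) and equal `GG`/`NN` gamete numbers; with
  fully dosage-informative markers a joint $(p, \alpha)$ likelihood
  would be identifiable, which is out of scope here.
* The simulator's non-duplex meiosis rule and normal phenotype deviates
  are pragmatic choices, documented above; conclusions about real,
  non-normal traits should lean on the median-centered Levene test.
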