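# polyseg

Inference of chromosome-pairing behaviour in newly formed (synthetic)
allotetraploids from single-locus marker segregation data, with a
tetraploid meiosis/phenotype simulator and the variance-based
quantitative-genetic analyses that go with such experiments.

## The problem

A new allotetraploid carries two complete diploid genomes (subgenomes *G*
and *N*). At meiosis its chromosomes may pair strictly with their
homologues — in which case every gamete carries one allele from each
subgenome and progeny show **fixed heterozygosity** — or they may pair
with homeologues, producing segregating `AA`/`Aa`/`aa` gamete classes and,
in the progeny, **quadruple homozygotes** (`GGGG`/`NNNN`) that have lost
one parental marker band. Five classical models fix the expected gametic
ratio `AA:Aa:aa` of a duplex (`AAaa`) parent:

| model | gametic ratio | expected apparent heterozygosity (F2 / BC1) |
|---|---|---|
| homolog–homolog (disomic) | 0:1:0 | 1.00 / 1.00 |
| homolog–homeolog (disomic) | 1:2:1 | 0.88 / 0.75 |
| random chromosome | 1:4:1 | 0.94 / 0.83 |
| random chromatid | 3:8:3 | 0.91 / 0.79 |
| maximal equational | 2:5:2 | 0.90 / 0.78 |

The degree of preferential pairing is quantified by the **preferential
pairing factor** *p* ∈ [0, 2/3] (*p* = 0: fully random pairing; *p* = 2/3:
strict homologous bivalents). For a duplex parent the balanced-gamete
frequency is, with double reduction rate α,

    f_GN(p, α) = 2/9 + p/3 + 5p²/4 + (2/3)(2/3 − 3p²/2 − α(2/3 − 3p²/2)),

which at α = 0 simplifies to `f_GN = 2/3 + p/3 + p²/4`. In a backcross of
the duplex F1 to the `NNNN` tester, band-loss progeny count the F1's `NN`
gametes; assuming equal numbers of (unobservable) `GG` gametes,
`f_GN = (n − 2·loss)/n` and the quadratic is solved directly for *p*.

Panel-level inference uses exact (Clopper–Pearson) binomial confidence
intervals for apparent heterozygosity, the probability `(1−q)^n` of
failing to observe any quadruple homozygote under a null pairing model
(with `q` that model's quadruple-homozygote frequency), a
Williams-corrected *G*-test of the pooled heterozygous/loss counts, and a
heterogeneity *G*-test across markers. Downstream phenotype analyses
cover variance-ratio and Brown–Forsythe Levene tests, coefficients of
variation with small-sample correction, broad-sense heritability
`H² = (Var(F2) − V_E)/Var(F2)`, and two-level nested (family /
maternal-within-family) variance components by expected mean squares.

## Worked example

The package bundles the marker panel of the original screen (two pooled
selfed classes and seven backcross markers of 48 progeny each):

```r
library(polyseg)
fit <- marker_screen()   # bundled panel, random-chromosome null model
fit
```

```
Marker screen for non-homologous segregation
  null model: random-chromosome; 95% exact binomial CIs; estimator assumption: bivalent

        marker class     het loss app_het          ci   p_fail p_hat
 S2G_pooled_13   S2G 309/309    0   1.000 0.988-1.000 2.14e-08      
 S2N_pooled_13   S2N 308/308    0   1.000 0.988-1.000 2.26e-08      
      MgSTS_98  BC1N   46/48    2   0.958 0.857-0.995 1.58e-04  0.54
     MgSTS_787  BC1N   47/48    1   0.979 0.889-0.999 1.58e-04  0.60
     MgSTS_724  BC1N   45/48    3   0.938 0.828-0.987 1.58e-04  0.46
     MgSTS_376  BC1N   48/48    0   1.000 0.926-1.000 1.58e-04  0.67
     MgSTS_358  BC1N   47/48    1   0.979 0.889-0.999 1.58e-04  0.60
     MgSTS_780  BC1N   47/48    1   0.979 0.889-0.999 1.58e-04  0.60
     MgSTS_847  BC1N   46/48    2   0.958 0.857-0.995 1.58e-04  0.54

Pooled classes:
 class markers     het app_het          ci   p_fail      G_p
   S2G       1 309/309    1.00 0.988-1.000 2.14e-08 2.87e-09
   S2N       1 308/308    1.00 0.988-1.000 2.26e-08 3.05e-09
  BC1N       7 326/336    0.97 0.946-0.986 2.48e-27 9.07e-16

Heterogeneity G (BC1N, markers with loss): G_H = 1.99, df = 5, p = 0.85
```

Reading the report: `p_fail` is the chance the panel would have missed
homeologous segregation entirely under the null model — vanishingly small
for the pooled classes, so the observed near-absence of band loss (10 of
336 backcross calls, against 56 expected under random chromosome pairing;
`G_p = 9.07e-16`) is strong evidence against regular homeologous pairing.
The per-marker pairing factors `p_hat` (0.46–0.67, boundary 0.67 = strict
pairing) show pairing is strongly, but not perfectly, preferential, and
the heterogeneity test (`p = 0.85`) shows the loss rate is homogeneous
across markers. `coef(fit)` extracts the `p_hat` vector;
`marker_screen(exclude_outlier = TRUE)` recomputes without the single
individual responsible for six of the ten losses.

Simulation-based checking of the whole chain:

```r
run_simulation_study(p_true = 0.54, n_progeny = 5000, n_reps = 200, seed = 1)
#   p_true mean_p_hat   sd_p_hat          bias n_reps n_progeny
# 1   0.54  0.5398467 0.00978872 -0.0001533274    200      5000
```

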