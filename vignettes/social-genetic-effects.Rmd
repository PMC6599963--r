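---
title: "Social genetic effects on growth and sow longevity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social genetic effects on growth and sow longevity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In group-housed pigs, an animal's genes affect not only its own growth but
also the growth of its pen mates — through competition, aggression, or
calmness at the feeder. These *social (indirect) genetic effects* mean that
the heritable variation exploitable by selection is not the classical
additive variance but the variance of *total breeding values*,

$$\mathrm{TBV}_i = a_{D,i} + (\bar n - 1)\, a_{S,i},$$

the sum of the direct effect of animal $i$ on itself and its social effect
on each of its $\bar n - 1$ pen mates. Sow longevity enters because fast
growth is genetically associated with early culling: selection on growth
alone can erode stayability. `sgepig` fits a multi-trait model in which
growth carries both direct and social genetic effects while two sow traits
— stayability to second parity (binary, modelled on an underlying liability
scale) and litter size at first parity — carry direct effects only, so
that the correlations of direct, social and total growth effects with the
sow traits can be estimated jointly.

## The model

For average daily gain (ADG, g/d, recorded on pen-tested pigs):

$$y = Xb + Z_D a_D + Z_S a_S + Vg + Ul + Qk + e$$

and for stayability (STAY, coded 1 = culled before second farrowing,
2 = stayed) and litter size (NBA1):

$$y = Xb + Z_D a_D + Ul + e,$$

where $b$ are fixed effects (growth: birth year-month, sex, group-size
class, with age and age squared at target weight as covariates; sow traits:
farrowing year-month), $g$ is an iid pen effect, $l$ the birth-litter
effect and $k$ the *social early-life* effect — the influence of a pen
mate's birth litter on the record. The four genetic effects
$(a_D^{ADG}, a_S^{ADG}, a_D^{STAY}, a_D^{NBA1})$ are jointly
$\mathrm{MVN}(0, C \otimes A)$ with $A$ the pedigree relationship matrix;
the four litter effects are $\mathrm{MVN}(0, K \otimes I)$. Residuals are
trait-wise independent, with the stayability liability residual fixed at 1.

**Dilution.** Pens range from 4 to 14 pigs. Social contributions are
weighted by $d_g = (\bar n - 1)/(n_g - 1)$, so every record carries a total
social load of exactly $\bar n - 1$ regardless of its pen size; $\bar n$ is
a configured constant (default 8.2, the reference herd's average) used
consistently in the incidences and in all TBV formulas. It is deliberately
*not* recomputed per dataset, so that parameters remain comparable across
runs.

**Derived parameters.** With $m = \bar n - 1$:
$\sigma^2_{TBV} = \sigma^2_{a_D} + 2m\,\sigma_{a_Da_S} + m^2 \sigma^2_{a_S}$;
$\sigma^2_P = \sigma^2_{a_D} + m\sigma^2_{a_S} + \sigma^2_g + \sigma^2_l +
m\sigma^2_k + \sigma^2_e$; total heritability $T^2 = \sigma^2_{TBV}/\sigma^2_P$;
classical $h^2 = \sigma^2_{a_D}/\sigma^2_P$ for growth and
$\sigma^2_{a_D}/(\sigma^2_{a_D}+\sigma^2_l+\sigma^2_e)$ for the sow traits;
and $\mathrm{Cov}(\mathrm{TBV}_{ADG}, \mathrm{DBV}_{rep}) =
\sigma_{a_D a_D} + m\,\sigma_{a_D(rep)a_S(ADG)}$. All ratios and
correlations are computed **per posterior sample** and then summarised —
the posterior mean of a ratio is not the ratio of posterior means, and for
skewed posteriors the difference is material (a property test constructs a
chain where it exceeds 5%). A plug-in mode on point estimates exists for
consistency checks against published tables.

## Estimation

A single-chain Gibbs sampler alternates:

1. **Liabilities.** Each stayability record's liability is redrawn from a
   unit-variance normal centred at its current linear predictor, truncated
   to $(-\infty, 0)$ for culled sows and $[0, \infty)$ for stayers
   (threshold fixed at 0).
2. **Location effects.** One single-site sweep over all unknowns in block
   order (fixed, genetic, pen, litter), each drawn from its full
   conditional normal; the genetic conditionals use the sparse
   $A^{-1} \otimes C^{-1}$ structure, the litter conditionals
   $I \otimes K^{-1}$. The sweep is a compiled kernel that keeps the
   residual vector consistent in place and uses R's RNG stream, so chains
   are bit-reproducible from the seed.
3. **Variances.** $C$ from an inverse-Wishart with scale
   $U^\top A^{-1} U + S_0$ and df $N + \nu_0$; $K$ likewise with
   $L^\top L + S_0$; the pen and free residual variances from
   scaled-inverse-$\chi^2$ conditionals. The stayability residual stays at
   1 for identifiability.

**Priors.** The default is weakly informative: $\nu_0 = \mathrm{dim} + 2$
and $S_0 = (\nu_0 - \mathrm{dim} - 1)\,\mathrm{diag}(\text{start})$, which
makes the prior mean equal the starting values (the inverse-Wishart mean is
$S_0/(\nu_0 - p - 1)$); scalar variances get 4 prior df centred the same
way. A flat option ($\nu_0 = -(p+1)$, $S_0 = 0$) is provided. Starting
values default to the reference herd magnitudes.

**Fixed-effect identifiability.** Categorical blocks are full one-hot with
no explicit constraint. The flat-prior directions that are not identified
(relative shifts between factor blocks) random-walk harmlessly; every
reported quantity — variance components, correlations, fitted values — is
invariant to them, which matches common practice in animal-breeding Gibbs
samplers.

**Residual covariances** between the three traits are fixed at zero:
growth is measured between 30 and 90 kg liveweight, the sow traits around
first farrowing, and the model's missing-trait handling (each record's
likelihood restricted to its observed traits) is exact under a diagonal
residual covariance, so no phenotype augmentation is needed.

**Terms not carried.** The growth model is sometimes written with
additional group-litter (`c`) and permanent-environment (`pe`) terms; they
are undefined in the source analysis, carry no reported variance, and are
excluded here. Sow birth litters and growth birth litters are merged into
one level set, which is what a single 4x4 litter covariance implies. An
animal's pen mates born in its own litter do count in its social
early-life row (they are genuine social partners); a flag excludes them
for sensitivity analysis.

## Pedigree machinery

`tabular_A()` is the dense recursive oracle ($A_{ii} = 1 + F_i$,
$A_{ji} = \tfrac12 (A_{js} + A_{jd})$), intended for pedigrees up to a few
thousand animals. The sampler uses `build_A_inverse()`: Henderson's sparse
rules with per-animal coefficients
$\alpha_i = 1/(1 - 0.25\sum_p (1 + F_p))$, with inbreeding coefficients
from the Meuwissen–Luo algorithm. Inbreeding adjustment is on by default —
closed nucleus herds are inbred after a few generations — and a flag
recovers the classical 2, 4/3, 1 coefficients. Unknown parents are treated
as founders (no genetic groups). The two constructions are tested against
each other: $\|A^{-1}A - I\|_\infty < 10^{-8}$ on simulated pedigrees of
hundreds to ~2,000 animals.

## The synthetic herd generator

`simulate_herd()` generates data *from the fitted model itself* with known
parameters, which is what makes parameter recovery a meaningful test:

* discrete-generation pedigree (founder sires and dams, one sire x dam
  mating per litter, truncated-Poisson litter sizes, both parents known
  for all non-founders);
* breeding values by the recursive Mendelian-sampling scheme (founders
  $\mathrm{MVN}(0, C)$, offspring = parent average +
  $\mathrm{MVN}(0, C(0.5 - 0.25(F_s + F_d)))$), giving exactly
  $C \otimes A$;
* same-sex pens with sizes drawn around mean 8.2 (SD 2, range 4–14),
  iid pen effects, litter effects $\mathrm{MVN}(0,K)$;
* growth assembled term by term from the model equation, including the
  dilution-weighted social sums;
* stayability on the liability scale with the fixed-effect level solved
  from the target survival rate (0.85 -> mean code 1.85), coded 1/2;
* litter size as a rounded Gaussian floored at zero (the model treats it
  linearly; the target phenotypic variance 7.87 = 2.84^2 is matched by
  construction, and rounding adds only 1/12);
* days-to-target-weight decreasing in TBV (slope -0.03 d per g/d,
  SD 6 d), so the age covariate is genuinely confounded with the genetic
  effects as it is in performance-test data;
* sow traits for 70% of females and growth records for 85% of pigs,
  reproducing the partial trait overlap of real recording schemes.

Default magnitudes are the reference herd's estimates (growth
802 +/- 93 g/d; ADG variances 2437/18/298/249/32/3816; stayability
0.10/0.19/1.00; litter size 0.80/0.17/6.90; covariances from the reported
correlations). What the generator does **not** emulate: selection across
generations, non-random pen assignment by litter or weight, seasonal
patterns in the year-month effects, and culling decisions that depend on
the recorded traits. Passing recovery tests therefore demonstrates that
the estimator is correct *under the model*, not that the model is correct
for any particular herd.

## Problem sizes and numerical choices

The package's standard study sizes, chosen so every stage runs comfortably
on a laptop: `tiny` (~60 animals) for smoke tests, `desk` (~2,250 pedigree
animals, ~1,850 growth records in ~230 pens, ~740 sows) for recovery
studies, `full` (~28,000) for scale checks. The desk chain protocol is
20,000 rounds, 10,000 burn-in, thinning 10 (1,000 stored samples, about
two minutes); it is a proportional shrinkage of the reference protocol
(1.2M rounds, 600k burn-in, thinning 100, 6,000 samples), which the
configuration accepts unchanged for full-scale runs.

Numerical details worth knowing:

* HPD intervals are the shortest contiguous window containing
  $\lceil 0.95\,m \rceil$ sorted draws; ties resolve to the lowest start.
  Tested against a brute-force scan of all windows.
* Monte Carlo errors use batch means with 20 batches (an
  effective-sample-size variant is provided); "significant" means the 95%
  HPD excludes zero.
* Liability draws use inverse-CDF truncated-normal sampling with clamping,
  accurate for the moderate predictors that arise here.
* Starting liabilities are +/-0.5 by category; solutions start at zero.
* Cholesky factorisations guard positive definiteness; a non-PD
  inverse-Wishart scale (a symptom of upstream NaN) is a fatal error, as
  is any non-finite stored sample.
* Single-site sweeps trade mixing speed for simplicity and exactness of
  the conditionals; at desk scale the chain mixes adequately (Monte Carlo
  errors an order of magnitude below posterior SDs for the variance
  components).

## What the desk-scale study shows

On the committed desk scenario, 9 of the 11 free variance components cover
their generating values with their 95% HPD intervals, and all four
covariances with generating correlation magnitude >= 0.3 recover their
signs. The two misses are instructive about scale, not about the code: the
social genetic variance (truth 18) and the sow litter-size genetic
variance (truth 0.80) are weakly identified from ~230 pens and ~740 sows
— the reference analysis needed tens of thousands of records, and its
reported SDs (5 and 0.12) shrink roughly with the square root of the data
size. The derived-parameter plug-ins on the reference posterior means
reproduce the published summary values exactly after table-style rounding
(T2 0.48, h2 0.34/0.07/0.10, social share 27%, TBV–stayability correlation
-0.23, TBV–litter-size correlation 0.11). One known wrinkle: the plug-in
stayability heritability is 0.10/1.29 = 0.078 -> 0.08 while the reported
per-sample mean is 0.07 — exactly the Jensen-gap behaviour described above,
so the two are not forced to agree.

## Limitations

* Single chains only; no cross-chain convergence diagnostics.
* No genomic relationships, single-step matrices, or unknown-parent
  groups.
* Residual covariances among traits are not estimated (an option for the
  jointly-recorded sow pair exists but is off by default).
* The threshold model fixes one threshold at zero with unit residual —
  appropriate for a binary trait, not ordinal ones.
* Dense `tabular_A()` is quadratic in memory; use it only as an oracle.
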