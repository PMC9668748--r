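# cortexARI

Attenuation of transcriptomic regional identity (ARI) in multi-region brain
expression cohorts.

In the neurotypical cortex, pairs of regions are distinguished by thousands of
gene-expression differences, many following an anterior-to-posterior gradient.
In conditions such as autism spectrum disorder these between-region differences
shrink: cortical regions become more molecularly homogeneous. cortexARI is for
analysts with multi-region, multi-subject (bulk) expression data and diagnosis
labels who want to quantify that attenuation, test it, and extract the genes
driving it.

## The statistics

For a region pair *(a, b)* and a diagnosis group, the primitive is the DE
count

> n_de = #{ genes g : BH-q( signed-rank p of { x_g(b, s) − x_g(a, s) } over
> subjects s with both regions ) < 0.05 },

computed on a *regressed* matrix retaining only subject, diagnosis and region
effects plus residual. Attenuation at a pair is a deficit of
n_de(case) relative to n_de(control), assessed two ways:

* **Permutation test** — diagnosis labels are reassigned at the subject level
  (group sizes preserved) B times; two-tailed p is the add-one fraction of
  permuted |n_de(case) − n_de(control)| at least as large as observed. A pair
  with p < 0.05 and fewer case DE genes is *attenuated*; with more, it is
  *over-patterned*.
* **Bootstrap test** — each group is subset to the k = 10 subjects closest in
  age to the pair's median age (making counts comparable across pairs), the
  count is bootstrapped by resampling subjects with replacement, and the two
  count distributions are compared by a Mann–Whitney test, BH-adjusted across
  the 55 pairs.

Genes driving an attenuated pair pass the **occurrence filter**: a control-DE
gene is retained only if it was pseudo-control-DE in < 95% of that pair's own
permutations. Retained genes are assigned to the region with higher control
expression and unioned into two groups by the sign of the Spearman correlation
between their control median regional profile and anterior→posterior rank
(posterior-high = `ari_down`, anterior-high = `ari_up`).

Regional vs whole-cortex effect sizes are compared by **total least squares
(orthogonal) regression** — the slope S is the leading-eigenvector direction of
the 2×2 covariance of the (regional log2FC, cortex-wide log2FC) cloud,
invariant to the axis choice — with a gene-resampling bootstrap CI and test of
S against unity.

A synthetic cohort generator (`generate_dataset()`, `emit_counts()`) draws
log-scale expression with subject random intercepts, Gaussian
anterior-posterior gradient slopes, a diagnosis-dependent multiplicative
attenuation factor λ, optional nuisance covariate effects and
negative-binomial counts — so the whole pipeline runs with no external data
and known ground truth.

## Worked example

```r
library(cortexARI)

cfg <- simulation_config(n_control = 15, n_case = 15, n_genes = 200,
                         gradient_fraction = 0.3, gradient_effect_sd = 0.3,
                         noise_sd = 0.3, missing_rate = 0, attenuation = 0.3,
                         seed = 5L)
ds <- generate_dataset(cfg)

pk <- pair_key("BA9", "BA17")          # the maximal anterior-posterior span
count_de(ds$expr, ds$meta, pk, "control")
#> de_result BA9|BA17 [control]: 57/200 genes DE at q < 0.05 (n = 15 subjects)
count_de(ds$expr, ds$meta, pk, "case")
#> de_result BA9|BA17 [case]: 47/200 genes DE at q < 0.05 (n = 15 subjects)

ari_test(ds$expr, ds$meta, pk, B = 1000, seed = 7L)
#> ari_perm BA9|BA17: n_de control = 57, case = 47, true diff = -10, p = 0.01099 (attenuated, B = 1000)
```

The control group shows 57 genes distinguishing BA9 from BA17; in cases, where
the simulated gradients run at 30% strength, 47 remain. Only 10 of the 1,000
subject relabellings produced a count difference as extreme as −10, so the
pair is classified attenuated (add-one p = 11/1001 ≈ 0.011).

The numbered scripts in `analysis/` run the same machinery as a full
workflow — simulate counts, QC and covariate regression, all 55 pairwise DE
counts, permutation and bootstrap attenuation scans, ARI-gene extraction, and
per-region TLS slopes — writing tables under `results/`.

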