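# heterofit

Does it matter, for a seedling's survival and growth, how genetically
different its two parents are? In tropical tree stands whose adults fall
into distinct but interfertile genetic clusters (a *syngameon*), matings
across clusters produce offspring that combine divergent genomes, and a
fitness advantage for those offspring is one mechanism that can maintain
the coexistence of closely related lineages. `heterofit` is an R package
for testing this hypothesis from codominant (microsatellite) genotypes and
nursery fitness records. It provides the full analysis chain:

1. **IO** — GenePop and wide-CSV genotype tables, allele-frequency
   estimation with pseudo-count smoothing (`read_genepop`, `read_wide_csv`,
   `allele_frequencies`).
2. **Admixture clustering** — a Gibbs sampler for the Bayesian admixture
   model with correlated allele frequencies (the F-model): ancestry matrix
   Q, per-cluster drift F_k, replicate runs, Evanno ΔK model choice, and
   label alignment across runs (`fit_admixture`, `run_admixture_set`,
   `evanno_delta_k`, `align_runs`).
3. **Paternity** — categorical allocation by LOD score with a
   simulation-calibrated Δ confidence threshold and a Mendelian exclusion
   override, yielding the four classic categories selfing / immigrant /
   ambiguous / single donor (`calibrate_delta`, `assign_paternity`).
4. **Relatedness** — maximum-likelihood pairwise relatedness
   r = k1/2 + k2 from the standard no-inbreeding pair likelihood
   (`ml_relatedness`).
5. **Biparental statistics** — `qdis`, Rogers' distance between the
   parents' ancestry vectors, `qdis(Q_i, Q_j) = sqrt(Σ_k (Q_ik − Q_jk)² / 2)`;
   and `fdis`, the signed-Fst-weighted joint membership,
   `fdis = Σ_k (Q_ik + Q_jk)·fst_k / 2`.
6. **Fitness models** — Cox proportional-hazards models of seedling
   mortality over any subset of {w, r, qdis, fdis} with AIC/BIC model
   tables and grouped Kaplan–Meier curves (`fit_cox`, `cox_model_set`,
   `km_by_group`), and a per-period Bayesian normal mixed model of relative
   growth rate with split-chain Rhat diagnostics (`compute_rgr`,
   `fit_growth_model`, `rhat`).
7. **Simulation** — a forward generator of admixed adults, matings
   (selfing / immigrant / outcross) and discrete-time survival plus growth,
   with full truth records, so every estimator is testable against known
   parameters (`simulate_study`).
8. **Pipeline** — `run_pipeline()` chains all stages from one config and
   seed into a directory of CSV artifacts plus a JSON manifest; runs are
   byte-identical given the same seed.

## A worked example

Simulate a study at its default design (182 adults in 3 clusters with
drift (0.10, 0.01, 0.10), 10 loci × 8 alleles, 6 mothers × 98 seeds, 9%
selfing, 10% immigrant pollen, hazard coefficient −3.4 on qdis), then ask
whether qdis predicts mortality:

```r
library(heterofit)
sim <- simulate_study(sim_config(rng_seed = 1))
records <- code_survival(sim$fitness$survival)
truth <- sim$fitness$covariates_true
fit <- fit_cox(records, truth, c("w", "qdis"))
print(fit)
#> cox_fit: w + qdis  n = 588  events = 114
#>         coef     se      p
#> w     0.3522 0.3238 0.2767
#> qdis -3.1825 0.3622 0.0000
#> AIC 1338.08  BIC 1343.55  deviance 1334.08
```

The fitted qdis coefficient −3.18 (SE 0.36) recovers the generating value
−3.4 well within two standard errors: seedlings whose parents share a
cluster (low qdis) die at a substantially higher rate, while seed weight
carries no signal here because the generator gave it none. The same
machinery runs on estimated covariates instead of truth — cluster the
adults, assign fathers, compute r/qdis/fdis per parent pair — in one call:

```r
run_pipeline(list(rng_seed = 1), "results/run1")
```

which writes the Q matrix, ΔK table, parentage records and per-mother
category bookkeeping, the parent-pair covariate table, the eleven-model
Cox comparison, grouped Kaplan–Meier curves, per-period growth posteriors,
and a manifest of seeds and counts.

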