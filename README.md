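# famhet

Simulation, estimation and closed-form theory for what family-based and
population-based GWAS designs actually estimate when allelic effects are
**heterogeneous** — when the effect of an allele depends on the family
environment (gene-by-environment interaction) or on which haplotype it tags
(population differences in linkage disequilibrium).

Family-based (trio and sibling) association studies are often described as
randomized experiments that deliver the average causal effect of an allele
or polygenic score. Mendelian segregation, however, only randomizes alleles
in the children of *heterozygous* parents. If heterozygous parents are
distributed non-randomly across environments, the trio design estimates a
*local* average effect — the average in the complier families — which can
differ systematically from the sample-wide average and from the
population-based estimate. `famhet` makes every step of that argument
executable: it simulates family cohorts with exactly the assumed
statistical structure, runs the standard OLS estimators, computes
noise-free closed-form predictions for each design, and verifies the two
against each other.

The package is aimed at statistical and population geneticists who want to
study, teach or extend these results: every analytical claim ships with a
simulation that checks it.

## The model

Phenotype of child *i* in family *f*, single bi-allelic locus with focal
allele counted as *g* ∈ {0, 1, 2}:

    Y = Y* + (α + α_f + α_i) g + ε_f + ε_i

with mean effect α and mean-zero family/individual effect deviations α_f,
α_i (G×E) and environmental deviations ε_f, ε_i. Writing the child genotype
as midparent plus segregation deviation, g = (g_m + g_f)/2 + ς, the three
designs estimate, in expectation:

* **population**: `Cov(Y, g)/Var(g)` — a mixture of between-family and
  within-family terms; the within-family term is
  `(1 − F)/(2(1 + F))` times the trio slope, with F the (pooled) inbreeding
  coefficient at the locus;
* **trio / sibling difference**: `α + E[α_f | parent heterozygous]` — a
  local average effect for the children of heterozygous parents;
* **allele flips** (counterfactual manipulations): the flip effect
  polarized by the flipped allele always averages back to α.

For a polygenic score `PGS = Σ_l β̂_l g_l` over loci Λ, the within-family
regression slope is

    δ̂_fam = Σ_l H_l β̂_l (α_l + E[α_lf | h_l]) / Σ_l H_l β̂_l²

(H_l = heterozygosity; h_l = a parent heterozygous at *l*), the population
slope mixes this with a between-family covariance term, and the PGS
variance decomposes as `V_PGS = Var(midparent PGS) + V_ς` with the
segregation part V_ς ≈ V_PGS/2 under random mating and linkage
equilibrium. The internally valid share of phenotypic variance attributable
to the PGS is `δ̂_fam² V_ς / V_P`, not the extrapolated
`δ̂_fam² V_PGS / V_P`.

## Worked example

Two populations in distinct environments: per-allele effect 1.1 in red,
0.9 in blue (α = 1, offsets ±0.1). The focal allele is common in red
(p = 0.5) and rare in blue (p = 0.05), so most heterozygous parents are in
the red environment:

```r
library(famhet)
set.seed(2024)
cohort <- simulate_cohort(
  list(population_spec("red",  allele_freq = 0.5,  env_effect_dev = +0.1, n_families = 25000),
       population_spec("blue", allele_freq = 0.05, env_effect_dev = -0.1, n_families = 25000)),
  locus_effect_model(alpha = 1, sd_env_family = 0.5, sd_env_indiv = 0.5))

population_gwas(cohort)
#> famhet estimate [population] locus 1: slope = 1.08832 (HC1 SE 0.00449), n = 50000
family_gwas(cohort)
#> famhet estimate [trio_family] locus 1: slope = 1.07614 (HC1 SE 0.00835), n = 50000

j <- discrete_joint(weight = c(0.5, 0.5), p = c(0.5, 0.05),
                    alpha_f = c(+0.1, -0.1))
predicted_family_estimate(j, alpha = 1)
#> [1] 1.068067
predicted_population_estimate(j, alpha = 1)$slope
#> [1] 1.09
```

Both designs are biased away from the sample-average effect of 1, each in
its own way, and each matches its closed-form prediction within sampling
error: the population slope (1.088 ± 0.004) reflects where the allele is
common (theory 1.090), the trio slope (1.076 ± 0.008) reflects where the
heterozygous parents live (theory 1.068).

`run_drift_experiment()` wraps the full drift experiment (independent Wright–Fisher
drift in the two populations, then both association studies per
replicate), `verify_all()` runs the whole prediction-vs-simulation matrix,
and `write_ped()`/`read_ped()` move cohorts through PED/FAM-style text
files. See the vignette in `vignettes/` for the methods account.

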