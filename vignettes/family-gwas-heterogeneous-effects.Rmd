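---
title: "Family and population GWAS under heterogeneous allelic effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family and population GWAS under heterogeneous allelic effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famhet)
```

## The problem

Trio and sibling GWAS designs exploit the randomness of Mendelian
segregation: conditional on the parents, which alleles a child inherits is
a coin flip, so regressing the child's phenotype on their genotype while
controlling for parental genotypes removes environmental and dynastic
confounding. The analogy to a randomized trial, however, has a precise
limit: segregation only randomizes alleles transmitted by *heterozygous*
parents. Children of homozygotes contribute no within-family genotype
variation, so their allelic effects are invisible to the design. When
effects vary across families — through gene-by-environment (G×E)
interaction, epistasis, or family-level differences in linkage
disequilibrium (LD) between a genotyped marker and the causal variant —
the family-based estimate is an average over the *complier* families only,
and need not equal the sample-average effect, the population-based
estimate, or the effect of any well-defined counterfactual manipulation.

`famhet` implements this theory as three interlocking components: a
simulator that generates cohorts with exactly the assumed structure, OLS
estimators for each study design, and closed-form (or exact-enumeration)
predictions for what each estimator converges to. The verification matrix
(`verify_all()`) confronts every prediction with its simulated estimate.

## Generative model

A cohort is a set of families drawn from one or more populations, each
population inhabiting a distinct environment. At a single bi-allelic locus
the phenotype of child $i$ in family $f$ is

$$Y = Y^* + (\alpha + \alpha_f + \alpha_i)\,g + \epsilon_f + \epsilon_i,$$

where $g \in \{0,1,2\}$ counts the focal allele, $\alpha$ is the mean
per-allele effect, and $\alpha_f$, $\alpha_i$ are mean-zero family- and
individual-level effect deviations. $\alpha_f$ is composed of a
population-level offset (`env_effect_dev`, shared by all families of a
population) plus optional Gaussian noise; the generator *rejects*
configurations whose population offsets do not average to zero under the
family-count weights, because the theory's normalization
$E[\alpha_f] = 0$ is part of the model, not an approximation. The
multi-locus version sums $(\alpha_l + \alpha_{lf} + \alpha_{il}) g_l$ over
causal loci $L$, with a polygenic score
$\mathrm{PGS} = \sum_{l \in \Lambda} \hat\beta_l g_l$ computed over a
subset $\Lambda \subseteq L$.

Parents are formed by monogamous random mating within population, children
by per-locus Mendelian segregation. The identity
$g = (g_m + g_f)/2 + \varsigma$ holds exactly for every simulated child;
the segregation deviation $\varsigma$ has conditional variance
$(h_m + h_f)/4$, with $h$ the parental heterozygosity indicator.

### What the generator emulates, and what it does not

It emulates: structured allele frequencies (fixed, or produced by
independent Wright–Fisher drift from a shared ancestor), environment-linked
effect heterogeneity, inbreeding, two-locus haplotype transmission with
recombination, and multi-locus PGS cohorts with unlinked loci in linkage
equilibrium within population. Sibling designs share the family-level
draws ($\alpha_f$, $\epsilon_f$) between the two children, as the theory
assumes.

It does **not** emulate assortative mating, selection or participation
bias, indirect (parental or sibling) genetic effects, sex chromosomes, LD
*between* causal loci, or missing genotypes. Passing tests therefore show
that the estimators and predictions agree under the stated model; they say
nothing about robustness to those excluded processes, several of which
(assortative mating in particular) would change the
$V_\varsigma = V_{PGS}/2$ benchmark.

### Inbreeding

An inbreeding coefficient $F$ enters the theory through the parental
genotype frequencies $p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq$ *and* through
the assumption that offspring show the same $F$. Drawing the two parents
independently from deformed genotype frequencies would return the children
to Hardy–Weinberg proportions, contradicting that assumption. The
generator therefore realizes $F$ as a two-deme Wahlund mixture: each
family belongs, with equal probability, to a deme with allele frequency
$p \pm \sqrt{Fpq}$, and mating is random within deme. This reproduces the
deformed genotype frequencies exactly in the parents and yields the same
$F$ among offspring. Feasibility requires
$F \le \min(p,q)/\max(p,q)$; infeasible configurations are rejected. Note
that a *pooled* locus additionally acquires a between-population Wahlund
component, so the $F$ entering the population-slope decomposition is the
pooled coefficient reported by `discrete_joint()`, not the
within-population parameter.

## Estimators

All estimators are OLS with HC1 heteroskedasticity-robust standard errors
(`sandwich`), because G×E makes the residual variance depend on genotype
by construction.

* `population_gwas()`: $Y$ on $g$, children only.
* `family_gwas()`: $Y$ on $g$ controlling for parental genotypes. The two
  parents can be controlled separately (default) or as their sum; the two
  parameterizations are asymptotically equivalent, and separate controls
  additionally absorb parent-of-origin frequency differences. Whether the
  controls enter separately or summed was left open in the theory; the
  package exposes both and the tests check their agreement empirically.
* `sib_difference()`: within-pair phenotype difference on genotype
  difference, through the origin. Equivalent to the trio design in
  expectation (both regress phenotypes on segregation deviations).
* `family_pgs()` / `population_pgs()`: the PGS analogues; the population
  slope is decomposed exactly (in-sample) into a between-family term and a
  within-family term, because $\mathrm{PGS} = \text{midparent} +
  \varsigma$ holds identically.
* `seg_regression()`: $Y$ on $\varsigma$, with $\varsigma$ either
  structural (child minus midparent, the estimand-defining form, also the
  form available for real trio data) or the finite-sample OLS residual of
  the child score on the parental sum. In residual mode the slope equals
  the corresponding family regression's child coefficient *exactly*
  (Frisch–Waugh–Lovell), and the tests assert this at $10^{-10}$.

Degenerate inputs fail loudly with named causes: monomorphic loci, cohorts
without heterozygous parents (no compliers), genotypically identical
sibling pairs, zero PGS variance, zero phenotypic variance. Monomorphic
loci are never silently dropped.

## Closed-form predictions and enumeration

`flip_effects()` gives the expected phenotypic consequence of flipping the
allele in a randomly chosen gamete (either direction), and the
allele-polarized average, which equals $\alpha$ identically — asserted at
machine precision over 1,000 random configurations.

`predicted_population_estimate()` computes the population slope by exact
enumeration of every (population, deme, parental genotype, segregation
outcome) cell with rational weights (1/4, 1/2), never by sampling: the
oracle must be noise-free. The enumeration's within-family term equals
$\frac{1-F}{2(1+F)}$ times the predicted trio slope, an identity the tests
check at $10^{-12}$ together with the between/within split.

For a genotyped marker tagging an ungenotyped causal locus,
`predicted_marker_family_estimate()` uses haplotype proportions among
heterozygous parents of the *parental* generation, computed from the
parental haplotype joint (random union of gametes); a flag reproduces the
small-$r$ approximation based on offspring-generation frequencies. One
modeling point surfaced by simulation: the model's haplotype frequencies
describe the parental pool, and one round of recombination multiplies the
LD coefficient by $1-r$ in the gametes — offspring haplotype frequencies
are $f' = (1-r)f + r\,(\text{marginal product})$.
Population-level marker predictions are therefore evaluated at the
offspring-generation frequencies (`offspring_hap_freqs()`); in a
structured sample the population slope additionally picks up a
between-population term from allele-frequency covariance, which
`predicted_marker_population_estimate()` includes.

For PGS cohorts, the heterozygote-conditional deviations
$E[\alpha_{lf} \mid h_l]$ can be computed analytically from the
configuration (`het_conditional_devs()`) or estimated from simulation
truth (`empirical_het_devs()`); both paths are tested against each other.
Under multiplicative heterogeneity ($\alpha_{lf} = C_f \alpha_l$,
$\hat\beta_l = B\alpha_l$) each family has a slope $(1 + C_f)/B$, and the
within-family regression recovers the average weighted by each family's
PGS segregation variance — `verify_all()` includes a designed
configuration where the weighted and unweighted averages are separated by
far more than the Monte Carlo error, and checks that simulation recovers
the weighted one.

## Segregation averaging

`segregation_averaging()` replaces each child's phenotype by its
conditional mean over segregation at the PGS loci (computable exactly from
simulation truth) and reports the resulting variance reduction next to the
prediction $\hat\delta_{fam}^2 V_\varsigma$. The two are asserted equal
only in the homogeneous regime ($\hat\beta_l = \alpha_l$, no G×E, no
individual deviations). Under heterogeneous slopes the exact reduction is
$E_f[\delta_f^2 V_{\varsigma,f}]$, which can exceed
$\hat\delta_{fam}^2 V_\varsigma$ by a Jensen gap; the function therefore
reports both quantities rather than asserting equality in general.

## Tunable parameters and defaults

| parameter | default | rationale |
|---|---|---|
| drift: diploid population size | 1000 | with 200 generations gives realized $F_{ST}$ spread of roughly 0–0.4, covering the regimes of interest |
| drift: generations | 200 | as above; $E[F_{ST}] \approx t/2N = 0.1$ |
| shared initial frequency $p_0$ | 0.5 | maximizes segregating outcomes after drift |
| two-environment per-allele effects | 1.1 / 0.9 | mean effect 1 with offsets $\pm 0.1$: heterogeneity large enough to separate designs, small relative to the mean |
| environmental noise SDs ($\epsilon_f$, $\epsilon_i$) | 0.5 | phenotypic noise comparable to the genetic signal at a common locus |
| drift experiment cohort | 50,000 families | slope SEs ≈ 0.005–0.01, so 3-SE comparisons are decisive per replicate |
| verification matrix cohorts | 50,000 (30,000 in the test suite) | same criterion; the suite size keeps a full test run around half a minute |
| PGS verification | 200 loci × 20,000 families | enough loci for the PGS-level CLT and a tight $V_\varsigma/V_{PGS}$ ratio |

## Numerical and reproducibility choices

Randomness flows from a single seed per entry point; draws occur in a
fixed order, so equal seed and configuration give byte-identical outputs
(the file writer is covered by a byte-identity test). Exact identities are
asserted at $10^{-10}$–$10^{-12}$; stochastic comparisons at 3 Monte Carlo
SEs, with batch-means SEs (25 batches over families) for variance ratios,
where no analytic SE is available. Goodness-of-fit checks on discrete
segregation distributions use $\chi^2$ tests at $\alpha = 0.01$ on at
least $10^4$ draws. In the drift experiment, sign-concordance summaries
condition on replicates whose deviation from the mean effect is at least
2 SEs — where the expected deviation is near zero the sign is sampling
noise, and including such replicates would make the summary meaningless
rather than conservative.

## File formats

`write_ped()`/`read_ped()` use a minimal PED/FAM-style dialect (documented
in the function help): a six-column FAM file, a genotype file with two
1/2-coded allele columns per locus (0 = missing), and an optional truth
sidecar carrying population labels and realized effect deviations —
simulation truth for oracle use only. Trios are assembled by parent-ID
linkage; children lacking a genotyped parent are excluded with a count,
and a missing genotype drops the trio at that locus only. Flipping the
declared effect allele negates every slope exactly and leaves variance
components unchanged, which the tests assert. The configuration reader is
strict: unknown JSON keys are an error, never silently ignored.

## Known limitations

* The estimators support no covariates beyond parental genotypes/PGS; no
  kinship/LMM correction, no imputation, no GWAS-scale multiple-testing
  machinery (loci are pre-specified).
* The PGS theory assumes $\Lambda \subseteq L$, linkage equilibrium and
  unlinked loci; weights are taken as given (no estimation noise model
  beyond the multiplicative-bias analysis).
* The two-locus model handles one marker tagging one causal locus;
  multiple tagged loci and LD among causal loci are out of scope.
* Conclusions about real data inherit every idealization listed above;
  the package's claims are about the model, verified by simulation.
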