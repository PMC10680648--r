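test_that("parental genotype draws follow Hardy-Weinberg proportions", {
  expect_identical(draw_parent_genotypes(0, 5, seed = 1),
                   rep(0L, 5))
  expect_identical(draw_parent_genotypes(1, 3, seed = 1),
                   rep(2L, 3))
  expect_error(draw_parent_genotypes(1.2, 5), "allele frequency")

  g <- draw_parent_genotypes(0.5, 1e5, seed = 42)
  het_frac <- mean(g == 1L)
  se <- sqrt(0.5 * 0.5 / 1e5)
  expect_lt(abs(het_frac - 0.5), 3 * se)
})

test_that("segregation transmits parental alleles fairly", {
  expect_identical(segregate(rep(0L, 50), rep(0L, 50), seed = 1),
                   rep(0L, 50))
  expect_identical(segregate(rep(2L, 50), rep(2L, 50), seed = 1),
                   rep(2L, 50))
  expect_error(segregate(3, 0), "allele counts")

  # both parents heterozygous: child genotype is {0: 1/4, 1: 1/2, 2: 1/4}
  set.seed(7)
  n <- 4e4
  kid <- segregate(rep(1L, n), rep(1L, n))
  tab <- tabulate(kid + 1L, nbins = 3L)
  gof <- chisq.test(tab, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.01)
})

test_that("children satisfy the midparent + segregation-deviation identity", {
  co <- simulate_cohort(two_env_specs(0.6, 0.3, 1500), two_env_model(),
                        seed = 11)
  s <- seg_deviation(co$geno_child[, 1], co$geno_mother[, 1],
                     co$geno_father[, 1])
  expect_true(all(co$geno_child[, 1] == (co$geno_mother[, 1] +
                                           co$geno_father[, 1]) / 2 + s))
  expect_true(all(s %in% c(-1, -0.5, 0, 0.5, 1)))
  both_hom <- co$geno_mother[, 1] != 1L & co$geno_father[, 1] != 1L
  expect_true(all(s[both_hom] == 0))
  expect_true(all(abs(co$geno_child[, 1] -
                        (co$geno_mother[, 1] + co$geno_father[, 1]) / 2)
                  <= 1))
})

test_that("conditional segregation variance is (h_m + h_f)/4", {
  set.seed(13)
  n <- 4000
  for (gm in 0:2) for (gf in 0:2) {
    kid <- segregate(rep(gm, n), rep(gf, n))
    s <- kid - (gm + gf) / 2
    theo <- ((gm == 1) + (gf == 1)) / 4
    if (theo == 0) {
      expect_true(all(s == 0))
    } else {
      # SE of the mean of s^2 (zero when exactly one parent is
      # heterozygous, where s^2 is constant at 1/4)
      se <- sd(s^2) / sqrt(n)
      expect_lte(abs(mean(s^2) - theo), 3 * se)
    }
  }
})

test_that("a panmictic cohort's children are in HWE", {
  p <- 0.3
  co <- simulate_cohort(list(population_spec("pop", p, 0, 2e4)),
                        locus_effect_model(alpha = 1), seed = 5)
  g <- co$geno_child[, 1]
  exp_freq <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  for (k in 0:2) {
    se <- sqrt(exp_freq[k + 1] * (1 - exp_freq[k + 1]) / length(g))
    expect_lt(abs(mean(g == k) - exp_freq[k + 1]), 3 * se)
  }
})

test_that("phenotypes follow the single-locus effect model", {
  # no noise: Y = Y* + (alpha + alpha_f) g exactly
  m <- locus_effect_model(intercept = 0, alpha = 1)
  expect_equal(assign_phenotype(2, m, env_effect_dev = 0.1)$phenotype, 2.2)
  m5 <- locus_effect_model(intercept = 5, alpha = 1)
  expect_equal(assign_phenotype(1, m5)$phenotype, 6)
  # g = 0: genotype contributes nothing, Y = Y* + noise
  mn <- locus_effect_model(intercept = 3, alpha = 7, sd_env_family = 1,
                           sd_env_indiv = 1)
  r <- assign_phenotype(0, mn, seed = 2)
  expect_equal(r$phenotype, 3 + r$eps_f + r$eps_i)

  # cohort-level: noise-free two-environment cohort has Y = (1 +/- 0.1) g
  co <- simulate_cohort(two_env_specs(0.5, 0.5, 400),
                        locus_effect_model(alpha = 1), seed = 3)
  eff <- ifelse(co$children$population == "red", 1.1, 0.9)
  expect_equal(co$children$phenotype, eff * co$geno_child[, 1])
})

test_that("population deviations must be mean-zero under family weights", {
  expect_error(
    simulate_cohort(list(population_spec("a", 0.5, +0.1, 100),
                         population_spec("b", 0.5, +0.1, 100)),
                    locus_effect_model()),
    "average to zero")
})

test_that("Wright-Fisher drift behaves at its limits", {
  expect_equal(unname(simulate_drift(0.5, 100, 0, seed = 1)), c(0.5, 0.5))
  # one generation in a huge population barely moves the frequency
  fr <- simulate_drift(0.5, 1e6, 1, seed = 2)
  se <- sqrt(0.5 * 0.5 / 2e6)
  expect_true(all(abs(fr - 0.5) < 3 * se))
  # long drift in a tiny population fixes the allele
  fr2 <- simulate_drift(0.5, 50, 1e4, seed = 3)
  expect_true(all(fr2 %in% c(0, 1)))
  expect_error(simulate_drift(0, 50, 10), "p0")
})

test_that("F_ST matches hand-computed Nei G_ST", {
  expect_equal(compute_fst(0.4, 0.4), 0)
  expect_equal(compute_fst(0, 1), 1)
  expect_equal(compute_fst(0.3, 0.7), 1 - 0.42 / 0.5)
  expect_equal(compute_fst(0, 0), 0)   # H_T = 0 convention
})

test_that("two-locus gamete distribution matches recombination enumeration", {
  # population containing only MA and ma haplotypes: any marker-and-causal
  # double heterozygote parent must be MA/ma
  tl <- two_locus_model(list(pop = c(0.5, 0, 0, 0.5)),
                        recomb_fraction = 0.2, causal_alpha = 1)
  co <- simulate_two_locus_cohort(
    tl, list(population_spec("pop", 0.5, 0, 2e4)), seed = 21)
  h <- co$truth$haplotypes
  is_ma_het <- (co$geno_mother[, "marker"] == 1L) &
    (co$geno_mother[, "causal"] == 1L)
  gam <- h$gam_m[is_ma_het]
  expect_gt(length(gam), 5e3)
  tab <- tabulate(gam, nbins = 4L)
  gof <- chisq.test(tab, p = c(0.4, 0.1, 0.1, 0.4))
  expect_gt(gof$p.value, 0.01)

  # r = 0: every gamete is one of the parent's own haplotypes
  tl0 <- two_locus_model(list(pop = rep(0.25, 4)), recomb_fraction = 0,
                         causal_alpha = 1)
  co0 <- simulate_two_locus_cohort(
    tl0, list(population_spec("pop", 0.5, 0, 3000)), seed = 22)
  h0 <- co0$truth$haplotypes
  expect_true(all(h0$gam_m == h0$hm1 | h0$gam_m == h0$hm2))
  expect_true(all(h0$gam_f == h0$hf1 | h0$gam_f == h0$hf2))

  # r = 0.5: marker and causal transmission independent given an MA/ma
  # parent, so all four gametes are equally likely
  tl5 <- two_locus_model(list(pop = c(0.5, 0, 0, 0.5)),
                         recomb_fraction = 0.5, causal_alpha = 1)
  co5 <- simulate_two_locus_cohort(
    tl5, list(population_spec("pop", 0.5, 0, 2e4)), seed = 23)
  h5 <- co5$truth$haplotypes
  het5 <- (co5$geno_mother[, "marker"] == 1L) &
    (co5$geno_mother[, "causal"] == 1L)
  gof5 <- chisq.test(tabulate(h5$gam_m[het5], nbins = 4L),
                     p = rep(0.25, 4))
  expect_gt(gof5$p.value, 0.01)

  expect_error(
    simulate_two_locus_cohort(
      two_locus_model(list(pop = c(0, 0, 0.3, 0.7)), 0.1, 1),
      list(population_spec("pop", 0.5, 0, 10))),
    "monomorphic")
})

test_that("PGS cohorts aggregate per-locus segregation correctly", {
  # single locus with weight 1: the PGS is the genotype itself
  p1 <- pgs_model(alpha = 0.5, beta_hat = 1, freq = 0.4)
  c1 <- simulate_pgs_cohort(p1, list(population_spec("pop", 0.4, 0, 2000)),
                            seed = 31)
  expect_equal(c1$children$pgs, as.numeric(c1$geno_child[, 1]))
  expect_equal(c1$children$seg_pgs,
               seg_deviation(c1$geno_child[, 1], c1$geno_mother[, 1],
                             c1$geno_father[, 1]))

  # all parents homozygous at the PGS loci: segregation deviation is zero
  pfix <- pgs_model(alpha = c(0.5, 0.5), beta_hat = c(1, 1),
                    freq = c(0, 1))
  cfix <- simulate_pgs_cohort(pfix,
                              list(population_spec("pop", 0.5, 0, 500)),
                              seed = 32)
  expect_true(all(cfix$children$seg_pgs == 0))

  # many loci, random mating: cohort-mean segregation deviation is zero
  al <- rep(0.1, 200)
  pm <- pgs_model(alpha = al, beta_hat = al, freq = 0.5)
  cm <- simulate_pgs_cohort(pm, list(population_spec("pop", 0.5, 0, 4000)),
                            seed = 33)
  se <- sd(cm$children$seg_pgs) / sqrt(nrow(cm$children))
  expect_lt(abs(mean(cm$children$seg_pgs)), 3 * se)

  # PGS loci must be a subset of the causal loci
  expect_error(pgs_model(alpha = c(1, 1), beta_hat = 1, pgs_loci = 3),
               "subset")
})
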