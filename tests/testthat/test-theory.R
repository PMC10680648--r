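# independent brute-force oracle for the allele-flip effects: enumerate the
# (population, parental genotype) cells and weight by the probability that a
# random gamete carrying the relevant allele derives from each cell
flip_oracle <- function(weight, p, alpha_f, alpha) {
  q <- 1 - p
  cells <- expand.grid(k = seq_along(weight), g = 0:2)
  gf <- cbind(q^2, 2 * p * q, p^2)
  cells$prob <- weight[cells$k] * gf[cbind(cells$k, cells$g + 1)]
  cells$a <- alpha_f[cells$k]
  # P(a random gamete from this cell carries A1) = (2 - g)/2
  w1 <- cells$prob * (2 - cells$g) / 2
  w2 <- cells$prob * cells$g / 2
  list(flip_1to2 = alpha + sum(w1 * cells$a) / sum(w1),
       flip_2to1 = -alpha - sum(w2 * cells$a) / sum(w2))
}

test_that("allele-flip effects match brute-force enumeration", {
  # no heterogeneity: both flips equal +/- alpha
  j0 <- discrete_joint(c(0.5, 0.5), c(0.3, 0.6), c(0, 0))
  f0 <- flip_effects(j0, alpha = 2)
  expect_equal(f0$flip_1to2, 2)
  expect_equal(f0$flip_2to1, -2)
  expect_equal(f0$averaged, 2)

  # two-environment configuration, allele absent in blue
  fe <- flip_effects(discrete_joint(c(0.5, 0.5), c(0.5, 0),
                                    c(+0.1, -0.1)), alpha = 1)
  or <- flip_oracle(c(0.5, 0.5), c(0.5, 0), c(+0.1, -0.1), alpha = 1)
  expect_equal(fe$flip_1to2, or$flip_1to2)
  expect_equal(fe$flip_2to1, or$flip_2to1)

  set.seed(61)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    w <- runif(k); w <- w / sum(w)
    p <- runif(k, 0.05, 0.95)
    a <- runif(k, -0.5, 0.5); a <- a - sum(w * a)
    fe <- flip_effects(discrete_joint(w, p, a), alpha = 1.3)
    or <- flip_oracle(w, p, a, alpha = 1.3)
    expect_equal(fe$flip_1to2, or$flip_1to2, tolerance = 1e-12)
    expect_equal(fe$flip_2to1, or$flip_2to1, tolerance = 1e-12)
  }

  expect_error(flip_effects(discrete_joint(1, 1, 0), 1), "absent or fixed")
})

test_that("allele-polarized average flip equals the mean effect exactly", {
  set.seed(62)
  for (i in 1:1000) {
    alpha <- runif(1, -2, 2)
    fe <- flip_effects(random_joint(), alpha)
    expect_equal(fe$averaged, alpha, tolerance = 1e-12)
  }
})

test_that("the predicted trio estimate conditions on heterozygous parents", {
  j <- discrete_joint(c(0.5, 0.5), c(0.4, 0.6), c(0, 0))
  expect_equal(predicted_family_estimate(j, 1), 1)
  # heterozygous parents only in red (+0.1) / only in blue (-0.1)
  expect_equal(predicted_family_estimate(
    discrete_joint(c(0.5, 0.5), c(0.5, 0), c(+0.1, -0.1)), 1), 1.1)
  expect_equal(predicted_family_estimate(
    discrete_joint(c(0.5, 0.5), c(1, 0.5), c(+0.1, -0.1)), 1), 0.9)
  expect_error(predicted_family_estimate(
    discrete_joint(c(0.5, 0.5), c(0, 1), c(0.1, -0.1)), 1),
    "no heterozygous")
})

test_that("population-slope enumeration satisfies the within/between split", {
  # homogeneous: slope is alpha
  j0 <- discrete_joint(c(0.6, 0.4), c(0.3, 0.3), c(0, 0))
  expect_equal(predicted_population_estimate(j0, 1.7)$slope, 1.7)
  # equal frequencies in both environments: slope is the mean effect
  jf <- discrete_joint(c(0.5, 0.5), c(0.5, 0.5), c(+0.1, -0.1))
  expect_equal(predicted_population_estimate(jf, 1)$slope, 1)

  set.seed(63)
  for (i in 1:50) {
    j <- random_joint(max_f = 0.5)
    pe <- predicted_population_estimate(j, 1)
    expect_equal(pe$slope, pe$between_term + pe$within_term,
                 tolerance = 1e-12)
    expect_equal(pe$within_term,
                 (1 - pe$f) / (2 * (1 + pe$f)) * pe$family_estimate,
                 tolerance = 1e-12)
  }
  expect_error(predicted_population_estimate(
    discrete_joint(c(0.5, 0.5), c(0, 0), c(0.1, -0.1)), 1), "variance")
})

test_that("haplotype-flip effect follows the conditional-frequency formula", {
  perfect <- two_locus_model(list(pop = c(0.5, 0, 0, 0.5)), 0, 1)
  expect_equal(hap_flip_effect(perfect), 1)
  le <- two_locus_model(list(pop = c(0.25, 0.25, 0.25, 0.25)), 0, 1)
  expect_equal(hap_flip_effect(le), 0)
  # p_{A|M} = 0.8, p_{A|m} = 0.3 with p_M = 0.5
  m <- two_locus_model(list(pop = c(0.4, 0.1, 0.15, 0.35)), 0, 1)
  expect_equal(hap_flip_effect(m), 0.5)
  expect_error(hap_flip_effect(
    two_locus_model(list(pop = c(0, 0, 0.3, 0.7)), 0, 1)), "undefined")
})

test_that("marker-locus trio prediction handles recombination and LD bias", {
  # free recombination: marker transmission carries no causal information
  free <- two_locus_model(list(pop = c(0.4, 0.1, 0.15, 0.35)), 0.5, 1)
  expect_equal(predicted_marker_family_estimate(free)$value, 0)
  # single population, r = 0: equals the haplotype-flip effect exactly
  one <- two_locus_model(list(pop = c(0.4, 0.1, 0.15, 0.35)), 0, 1)
  pm <- predicted_marker_family_estimate(one)
  expect_equal(pm$value, hap_flip_effect(one), tolerance = 1e-12)
  expect_equal(pm$ld_bias, 0, tolerance = 1e-12)

  # decomposition identity at r = 0 for random two-population configurations
  set.seed(64)
  for (i in 1:100) {
    f1 <- runif(4); f1 <- f1 / sum(f1)
    f2 <- runif(4); f2 <- f2 / sum(f2)
    m2 <- two_locus_model(list(a = f1, b = f2), 0, 1)
    pr <- predicted_marker_family_estimate(m2)
    expect_equal(pr$value, pr$hap_flip + pr$ld_bias, tolerance = 1e-12)
  }
  expect_error(predicted_marker_family_estimate(
    two_locus_model(list(pop = c(0.5, 0.5, 0, 0)), 0, 1)), "heterozygous")
})

test_that("PGS randomization effect is the heterozygosity-weighted ratio", {
  al <- c(0.2, -0.1, 0.4)
  expect_equal(pgs_randomization_effect(
    pgs_model(alpha = al, beta_hat = al, freq = 0.3)), 1)
  expect_equal(pgs_randomization_effect(
    pgs_model(alpha = 0.6, beta_hat = 2, freq = 0.4)), 0.3)
  # two loci at p = 0.5 with weights (1, 2) and effects (1, 1)
  expect_equal(pgs_randomization_effect(
    pgs_model(alpha = c(1, 1), beta_hat = c(1, 2), freq = 0.5)), 0.6)
  expect_error(pgs_randomization_effect(
    pgs_model(alpha = 1, beta_hat = 1, freq = 0)), "monomorphic")
})

test_that("predicted family PGS slope generalizes the randomization effect", {
  al <- c(0.2, -0.1, 0.4)
  pm <- pgs_model(alpha = al, beta_hat = al, freq = c(0.3, 0.5, 0.7))
  expect_equal(predicted_pgs_family_estimate(pm),
               pgs_randomization_effect(pm))

  # single locus: consistent with the single-locus trio prediction
  off <- rbind(red = 0.1, blue = -0.1)
  p1 <- pgs_model(alpha = 1, beta_hat = 2, freq = 0.5,
                  family_dev = list(type = "offsets", offsets = off))
  sp <- list(population_spec("red", 0.5, 0, 100),
             population_spec("blue", 0.2, 0, 100))
  j <- discrete_joint(c(0.5, 0.5), c(0.5, 0.2), c(+0.1, -0.1))
  expect_equal(predicted_pgs_family_estimate(p1, specs = sp),
               predicted_family_estimate(j, 1) / 2, tolerance = 1e-12)

  # analytic and empirical heterozygote-conditional deviations agree
  al2 <- rnorm(10, 0, 0.2)
  off2 <- rbind(red = rep(0.05, 10), blue = rep(-0.05, 10))
  p2 <- pgs_model(alpha = al2, beta_hat = al2, freq = runif(10, 0.2, 0.8),
                  family_dev = list(type = "offsets", offsets = off2))
  sp2 <- list(population_spec("red", pmin(p2$freq + 0.1, 0.95), 0, 15000),
              population_spec("blue", pmax(p2$freq - 0.1, 0.05), 0, 15000))
  co <- simulate_pgs_cohort(p2, sp2, seed = 65)
  expect_lt(max(abs(het_conditional_devs(p2, sp2) -
                      empirical_het_devs(co))), 0.01)
})

test_that("multiplicative heterogeneity weights families by segregation variance", {
  # two families, C = (+0.5, -0.5), B = 1, parents of family 1 heterozygous
  # at three times as many equal-heterozygosity loci
  ms <- multiplicative_family_slopes(C = c(0.5, -0.5), B = 1,
                                     seg_var = c(3, 1))
  expect_equal(ms$delta_f, c(1.5, 0.5))
  expect_equal(ms$weighted_mean, 1.25)
  expect_equal(ms$unweighted_mean, 1)
  # no heterogeneity, unbiased weights: every family slope is 1
  m0 <- multiplicative_family_slopes(C = c(0, 0), B = 1, seg_var = c(1, 2))
  expect_equal(m0$delta_f, c(1, 1))
  expect_equal(m0$weighted_mean, 1)
  expect_error(multiplicative_family_slopes(0.5, 0, 1), "nonzero")
  expect_error(multiplicative_family_slopes(c(0.5, -0.5), 1, c(0, 0)),
               "zero")
})
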