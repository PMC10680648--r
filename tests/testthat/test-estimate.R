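test_that("population regression recovers the OLS slope exactly on a toy", {
  co <- toy_cohort(g = c(0, 1, 1, 2), y = c(0, 1, 1, 2))
  expect_equal(population_gwas(co)$slope, 1)
  co2 <- toy_cohort(g = c(0, 1, 1, 2), y = c(0, 2, 2, 4))
  expect_equal(population_gwas(co2)$slope, 2)
  expect_error(population_gwas(toy_cohort(g = rep(1, 4), y = 1:4)),
               "monomorphic")
})

test_that("all designs agree on a homogeneous-effect cohort", {
  m <- locus_effect_model(alpha = 1, sd_env_family = 0.5,
                          sd_env_indiv = 0.5)
  specs <- list(population_spec("pop", 0.4, 0, 15000))
  co <- simulate_cohort(specs, m, seed = 41)
  ep <- population_gwas(co)
  ef <- family_gwas(co)
  es <- seg_regression(co)
  expect_lt(abs(ep$slope - 1), 3 * ep$stderr)
  expect_lt(abs(ef$slope - 1), 3 * ef$stderr)
  expect_lt(abs(es$slope - 1), 3 * es$stderr)
  co2 <- simulate_cohort(specs, m, children_per_family = 2L, seed = 42)
  eb <- sib_difference(co2)
  expect_lt(abs(eb$slope - 1), 3 * eb$stderr)
})

test_that("trio regression estimates the complier (heterozygous-parent) effect", {
  # focal allele absent in the blue environment: every heterozygous parent
  # is in the red environment, where the per-allele effect is 1.1
  co <- simulate_cohort(two_env_specs(0.5, 0, 12500), two_env_model(),
                        seed = 43)
  ef <- family_gwas(co)
  expect_lt(abs(ef$slope - 1.1), 3 * ef$stderr)
  # separate and summed parental controls agree
  ef2 <- family_gwas(co, parental = "sum")
  expect_lt(abs(ef$slope - ef2$slope), 3 * ef2$stderr)

  # sibling differences estimate the same quantity
  co2 <- simulate_cohort(two_env_specs(0.5, 0, 12500), two_env_model(),
                         children_per_family = 2L, seed = 44)
  es <- sib_difference(co2)
  expect_lt(abs(es$slope - 1.1), 3 * sqrt(es$stderr^2 + ef$stderr^2))
})

test_that("degenerate within-family variance raises informative errors", {
  co <- toy_cohort(g = c(0, 2, 0, 2), y = 1:4,
                   gm = c(0, 2, 0, 2), gf = c(0, 2, 0, 2))
  expect_error(family_gwas(co), "heterozygous parents")
  expect_error(seg_regression(co), "all zero")
  twins <- toy_cohort(g = rep(1L, 8), y = rnorm(8),
                      children_per_family = 2L)
  expect_error(sib_difference(twins), "identical")
})

test_that("partialling out the parental PGS reproduces the family slope exactly", {
  al <- rnorm(25, 0, 0.2)
  pm <- pgs_model(alpha = al, beta_hat = al, freq = runif(25, 0.2, 0.8),
                  sd_env_family = 0.5, sd_env_indiv = 0.5)
  co <- simulate_pgs_cohort(pm, list(population_spec("pop", 0.5, 0, 4000)),
                            seed = 45)
  fam <- family_pgs(co)
  fwl <- seg_regression(co, "pgs", mode = "residual")
  expect_lt(abs(fam$slope - fwl$slope), 1e-10)
  # structural segregation deviation gives the same answer up to sampling
  str <- seg_regression(co, "pgs", mode = "structural")
  expect_lt(abs(str$slope - fam$slope),
            3 * sqrt(str$stderr^2 + fam$stderr^2))

  # same identity at a single locus with summed parental control
  c1 <- simulate_cohort(list(population_spec("pop", 0.4, 0, 3000)),
                        locus_effect_model(alpha = 1, sd_env_indiv = 0.5),
                        seed = 46)
  expect_lt(abs(family_gwas(c1, parental = "sum")$slope -
                  seg_regression(c1, mode = "residual")$slope), 1e-10)
})

test_that("a PGS built from the true effects has unit family slope", {
  al <- rnorm(25, 0, 0.2)
  pm <- pgs_model(alpha = al, beta_hat = al, freq = runif(25, 0.2, 0.8),
                  sd_env_family = 0.5, sd_env_indiv = 0.5)
  co <- simulate_pgs_cohort(pm, list(population_spec("pop", 0.5, 0, 8000)),
                            seed = 47)
  fam <- family_pgs(co)
  expect_lt(abs(fam$slope - 1), 3 * fam$stderr)
  pop <- population_pgs(co)
  expect_lt(abs(pop$slope - fam$slope),
            3 * sqrt(pop$stderr^2 + fam$stderr^2))
})

test_that("a single-locus PGS rescales the trio regression", {
  c1 <- simulate_cohort(list(population_spec("pop", 0.4, 0, 3000)),
                        locus_effect_model(alpha = 1, sd_env_indiv = 0.5),
                        seed = 48)
  p1 <- pgs_model(alpha = 1, beta_hat = 2, freq = 0.4)
  fam_locus <- family_gwas(c1, parental = "sum")
  fam_pgs <- family_pgs(c1, p1)
  expect_lt(abs(fam_pgs$slope - fam_locus$slope / 2), 1e-10)
})

test_that("population PGS slope decomposes exactly into between + within", {
  al <- rnorm(20, 0, 0.2)
  pm <- pgs_model(alpha = al, beta_hat = al, freq = 0.5,
                  sd_env_indiv = 0.5)
  co <- simulate_pgs_cohort(pm, list(population_spec("pop", 0.5, 0, 3000)),
                            seed = 49)
  pop <- population_pgs(co)
  expect_lt(abs(pop$slope - (pop$decomposition$between_term +
                               pop$decomposition$within_term)), 1e-10)
  # Y constant: slope is zero
  co$children$phenotype <- rep(1, nrow(co$children))
  expect_equal(population_pgs(co)$slope, 0, tolerance = 1e-12)
})

test_that("PGS variance decomposes into midparent and segregation parts", {
  al <- rnorm(30, 0, 0.2)
  pm <- pgs_model(alpha = al, beta_hat = al, freq = runif(30, 0.2, 0.8))
  co <- simulate_pgs_cohort(pm, list(population_spec("pop", 0.5, 0, 8000)),
                            seed = 50)
  vd <- pgs_variance_decomposition(co)
  # V_PGS = V_between + V_seg up to twice the (mean-zero) covariance term
  sc <- compute_pgs(co)
  mid <- (sc$pgs_mother + sc$pgs_father) / 2
  cv <- cov(mid, sc$seg_pgs)
  se_cv <- sqrt(var(mid) * var(sc$seg_pgs) / nrow(sc))
  expect_lt(abs(cv), 3 * se_cv)
  expect_equal(vd$v_pgs, vd$v_between + vd$v_seg + 2 * cv,
               tolerance = 1e-10)
  # no noise, weights = effects: whole phenotype is the genetic value, so
  # the within-family share of phenotypic variance is V_seg / V_P
  expect_lt(abs(vd$family_slope - 1), 0.05)
  expect_lt(abs(vd$seg_explained - vd$v_seg / vd$v_pheno), 0.05)
  # degenerate: all parents homozygous
  pfix <- pgs_model(alpha = c(1, 1), beta_hat = c(1, 1), freq = c(0, 1),
                    sd_env_indiv = 1)
  cfix <- simulate_pgs_cohort(pfix,
                              list(population_spec("pop", 0.5, 0, 200)),
                              seed = 51)
  vdf <- pgs_variance_decomposition(cfix, family_slope = 0)
  expect_equal(vdf$v_seg, 0)
  expect_equal(vdf$seg_explained, 0)
  expect_error(family_pgs(cfix), "rank-deficient")
})
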