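# shared fixtures: the two-environment effect model with per-allele effects
# 1.1 (red) and 0.9 (blue), i.e. mean effect 1 with offsets +/- 0.1

two_env_model <- function(noise = 0.5) {
  locus_effect_model(alpha = 1, sd_env_family = noise, sd_env_indiv = noise)
}

two_env_specs <- function(p_red, p_blue, n_per_pop) {
  list(population_spec("red", p_red, +0.1, n_per_pop),
       population_spec("blue", p_blue, -0.1, n_per_pop))
}

# batch-means Monte Carlo SE for var(a)/var(b)
ratio_se <- function(a, b, batches = 25L) {
  grp <- rep(seq_len(batches), length.out = length(a))
  r <- vapply(seq_len(batches), function(g) {
    var(a[grp == g]) / var(b[grp == g])
  }, 0)
  sd(r) / sqrt(batches)
}

# hand-built minimal cohort for exact-value estimator tests
toy_cohort <- function(g, y, gm = NULL, gf = NULL, children_per_family = 1L) {
  n <- length(g)
  if (is.null(gm)) gm <- rep(1L, n)
  if (is.null(gf)) gf <- rep(1L, n)
  nfam <- n / children_per_family
  famhet:::new_cohort(
    children = data.frame(
      family_id = rep(seq_len(nfam), each = children_per_family),
      child_no = rep(seq_len(children_per_family), nfam),
      population = "pop", phenotype = y, stringsAsFactors = FALSE),
    geno_child = matrix(as.integer(g), ncol = 1,
                        dimnames = list(NULL, "L1")),
    geno_mother = matrix(as.integer(gm), ncol = 1,
                         dimnames = list(NULL, "L1")),
    geno_father = matrix(as.integer(gf), ncol = 1,
                         dimnames = list(NULL, "L1")),
    loci = data.frame(locus_id = "L1", effect_allele = "2",
                      stringsAsFactors = FALSE),
    meta = list(children_per_family = children_per_family))
}

# random mean-zero discrete joints for property-style theory tests
random_joint <- function(max_f = 0) {
  k <- sample(2:4, 1)
  w <- runif(k, 0.2, 1); w <- w / sum(w)
  p <- runif(k, 0.05, 0.95)
  a <- runif(k, -0.5, 0.5)
  a <- a - sum(w * a)                      # center under the weights
  # F is bounded by the feasibility of the two-deme representation,
  # p +/- sqrt(F p q) in [0, 1], i.e. F <= min(p, q) / max(p, q)
  f_feas <- min(pmin(p, 1 - p) / pmax(p, 1 - p))
  f <- if (max_f > 0) runif(1, 0, min(max_f, 0.95 * f_feas)) else 0
  discrete_joint(w, p, a, f = f)
}
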