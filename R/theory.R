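#' Discrete joint distribution of parental genotypes and environments
#'
#' The exact joint distribution underlying the closed-form predictions: a
#' mixture of populations, each with a weight, a focal-allele frequency, an
#' inbreeding coefficient and a family effect deviation \eqn{\alpha_f}
#' shared by all its families. Within a population, parental genotype
#' frequencies are \eqn{p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq} (realized as a
#' two-deme mixture at \eqn{p \pm \sqrt{Fpq}}, with random mating within
#' deme, so offspring carry the same F).
#'
#' @param weight population weights (proportions of families; normalized).
#' @param p per-population focal-allele frequencies.
#' @param alpha_f per-population effect deviations; must average to zero
#'   under `weight`.
#' @param f per-population inbreeding coefficients.
#' @return An object of class `famhet_joint` with pooled frequency `p`,
#'   pooled genotype frequencies `p11`, `p12`, `p22`, pooled inbreeding
#'   coefficient `F`, and conditional means `e_dev` of \eqn{\alpha_f} given
#'   parental genotype.
#' @export
discrete_joint <- function(weight, p, alpha_f, f = 0) {
  k <- length(weight)
  stopifnot(length(p) == k, length(alpha_f) == k)
  if (length(f) == 1L) f <- rep(f, k)
  stopifnot(length(f) == k)
  if (any(weight < 0) || sum(weight) <= 0) {
    stop("weights must be nonnegative with positive sum", call. = FALSE)
  }
  weight <- weight / sum(weight)
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0,1]",
                               call. = FALSE)
  if (any(f < 0 | f >= 1)) stop("inbreeding coefficients must lie in [0,1)",
                                call. = FALSE)
  if (abs(sum(weight * alpha_f)) > 1e-8) {
    stop("alpha_f values must average to zero under the population weights",
         call. = FALSE)
  }
  d <- sqrt(f * p * (1 - p))
  if (any(p - d < -1e-12 | p + d > 1 + 1e-12)) {
    stop("inbreeding coefficient too large for this allele frequency: ",
         "deme frequencies p +/- sqrt(F p q) fall outside [0, 1]",
         call. = FALSE)
  }
  q <- 1 - p
  p11_k <- q^2 + f * p * q
  p12_k <- 2 * p * q * (1 - f)
  p22_k <- p^2 + f * p * q
  pool <- function(x) sum(weight * x)
  p_bar <- pool(p)
  p11 <- pool(p11_k); p12 <- pool(p12_k); p22 <- pool(p22_k)
  f_bar <- if (p_bar %in% c(0, 1)) 0 else 1 - p12 / (2 * p_bar * (1 - p_bar))
  cond <- function(pk) {
    tot <- pool(pk)
    if (tot == 0) NA_real_ else sum(weight * pk * alpha_f) / tot
  }
  structure(
    list(weight = weight, p_k = p, f_k = f, alpha_f = alpha_f,
         p11_k = p11_k, p12_k = p12_k, p22_k = p22_k,
         p = p_bar, p11 = p11, p12 = p12, p22 = p22, f = f_bar,
         e_dev = c(A1A1 = cond(p11_k), A1A2 = cond(p12_k),
                   A2A2 = cond(p22_k))),
    class = "famhet_joint"
  )
}

#' Allele-flip (counterfactual manipulation) effects at a locus
#'
#' The expected phenotypic consequence of flipping the allele carried by a
#' randomly chosen parental gamete: `flip_1to2` for flipping A1 to A2 (the
#' gamete comes from an A1A1 parent with probability \eqn{p_{11}/(1-p)} and
#' from a heterozygote with probability \eqn{p_{12}/(2(1-p))}),
#' `flip_2to1` for the reverse, and `averaged` — the flip effect polarized by
#' the flipped allele, \eqn{(1-p)\,\alpha^{flip}_{1\to2} +
#' p\,(-\alpha^{flip}_{2\to1})} — which always equals the mean effect
#' \eqn{\alpha}.
#'
#' @param joint a [discrete_joint()].
#' @param alpha mean per-allele effect.
#' @return list with `flip_1to2`, `flip_2to1`, `averaged`.
#' @export
flip_effects <- function(joint, alpha) {
  stopifnot(inherits(joint, "famhet_joint"))
  p <- joint$p
  if (p <= 0 || p >= 1) {
    stop("allele-flip effects are undefined when the focal allele is ",
         "absent or fixed in the pooled sample", call. = FALSE)
  }
  e <- joint$e_dev
  e[is.na(e)] <- 0
  flip12 <- alpha + joint$p11 / (1 - p) * e[["A1A1"]] +
    joint$p12 / (2 * (1 - p)) * e[["A1A2"]]
  flip21 <- -alpha - joint$p22 / p * e[["A2A2"]] -
    joint$p12 / (2 * p) * e[["A1A2"]]
  list(flip_1to2 = flip12, flip_2to1 = flip21,
       averaged = (1 - p) * flip12 + p * (-flip21))
}

#' Predicted family-based (trio) estimate at a locus
#'
#' The average per-allele effect among children of heterozygous parents:
#' \eqn{\alpha + E[\alpha_f \mid \mathrm{parent\ heterozygous}]}. This is
#' what the trio and sibling-difference regressions estimate in expectation
#' (a local average treatment effect for the "complier" families).
#'
#' @param joint a [discrete_joint()].
#' @param alpha mean per-allele effect.
#' @return predicted slope (scalar).
#' @export
predicted_family_estimate <- function(joint, alpha) {
  stopifnot(inherits(joint, "famhet_joint"))
  if (joint$p12 == 0) {
    stop("no heterozygous parents under this joint: the family-based ",
         "estimand is undefined", call. = FALSE)
  }
  alpha + joint$e_dev[["A1A2"]]
}

## Exact cell table over (population, deme, parental genotypes, gamete
## outcomes) with rational segregation weights. One row per elementary
## outcome; used as the noise-free enumeration oracle.
joint_cells <- function(joint) {
  rows <- list()
  for (k in seq_along(joint$weight)) {
    pk <- joint$p_k[k]
    fk <- joint$f_k[k]
    demes <- if (fk > 0) {
      d <- sqrt(fk * pk * (1 - pk))
      data.frame(w = c(0.5, 0.5), p = c(pk - d, pk + d))
    } else data.frame(w = 1, p = pk)
    for (j in seq_len(nrow(demes))) {
      pd <- demes$p[j]
      gw <- c((1 - pd)^2, 2 * pd * (1 - pd), pd^2)  # HWE within deme
      grid <- expand.grid(gm = 0:2, gf = 0:2, tm = 0:1, tf = 0:1)
      ## transmission probability from a parent with genotype g: P(t=1)=g/2
      pt <- function(g, t) ifelse(t == 1, g / 2, 1 - g / 2)
      prob <- joint$weight[k] * demes$w[j] *
        gw[grid$gm + 1] * gw[grid$gf + 1] *
        pt(grid$gm, grid$tm) * pt(grid$gf, grid$tf)
      keep <- prob > 0
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        pop = k, prob = prob[keep], gm = grid$gm[keep], gf = grid$gf[keep],
        g = grid$tm[keep] + grid$tf[keep],
        alpha_f = joint$alpha_f[k])
    }
  }
  do.call(rbind, rows)
}

#' Predicted population-based estimate at a locus (exact enumeration)
#'
#' Computes \eqn{Cov(Y, g)/Var(g)} exactly by enumerating every
#' (population, deme, parental-genotype, segregation) outcome with rational
#' weights — the noise-free oracle for the population regression. Also
#' returns the two-term split of the slope: the between-family term
#' \eqn{Cov(Y, (g_m+g_f)/2)/Var(g)} and the within-family term, which equals
#' \eqn{\frac{1-F}{2(1+F)}} times the predicted family estimate.
#'
#' @param joint a [discrete_joint()].
#' @param alpha mean per-allele effect.
#' @param intercept trait intercept (does not affect the slope).
#' @return list with `slope`, `between_term`, `within_term`,
#'   `family_estimate`, `f` (pooled inbreeding coefficient).
#' @export
predicted_population_estimate <- function(joint, alpha, intercept = 0) {
  stopifnot(inherits(joint, "famhet_joint"))
  cells <- joint_cells(joint)
  w <- cells$prob
  g <- cells$g
  mid <- (cells$gm + cells$gf) / 2
  y <- intercept + (alpha + cells$alpha_f) * g
  m <- function(x) sum(w * x)
  var_g <- m(g^2) - m(g)^2
  if (var_g <= 0) {
    stop("genotypic variance is zero under this joint", call. = FALSE)
  }
  cv <- function(a, b) m(a * b) - m(a) * m(b)
  s <- cells$g - mid
  list(
    slope = cv(y, g) / var_g,
    between_term = cv(y, mid) / var_g,
    within_term = cv(y, s) / var_g,
    family_estimate = predicted_family_estimate(joint, alpha),
    f = joint$f
  )
}

## haplotype frequencies among gametes after one round of recombination:
## D decays by (1 - r), allele frequencies are unchanged
gamete_hap_freqs <- function(f, r) {
  pM <- f[1] + f[2]
  pA <- f[1] + f[3]
  out <- c((1 - r) * f[1] + r * pM * pA,
           (1 - r) * f[2] + r * pM * (1 - pA),
           (1 - r) * f[3] + r * (1 - pM) * pA,
           (1 - r) * f[4] + r * (1 - pM) * (1 - pA))
  names(out) <- names(f)
  out
}

#' Offspring-generation haplotype frequencies
#'
#' The model's `hap_freqs` describe the parental haplotype pool; children
#' are formed from gametes, whose LD coefficient is decayed by a factor
#' `1 - r`. Population-level predictions about the offspring sample use
#' these frequencies.
#'
#' @param model a [two_locus_model()].
#' @return named list of per-population length-4 frequency vectors.
#' @export
offspring_hap_freqs <- function(model) {
  stopifnot(inherits(model, "famhet_two_locus"))
  lapply(model$hap_freqs, gamete_hap_freqs, r = model$recomb_fraction)
}

pool_hap_freqs <- function(model, weights = NULL) {
  f <- do.call(rbind, model$hap_freqs)
  if (is.null(weights)) weights <- rep(1, nrow(f))
  weights <- weights / sum(weights)
  as.numeric(weights %*% f)
}

#' Haplotype-flip effect at a marker locus
#'
#' Expected phenotypic effect of swapping, in a random m-bearing gamete, the
#' haplotype around the marker for a random M-bearing haplotype (long enough
#' to span the causal locus):
#' \eqn{(p_{A|M} - p_{A|m})\,\alpha}. This also equals the expectation of an
#' unconfounded population-based association study at the marker.
#'
#' @param model a [two_locus_model()].
#' @param weights population weights used to pool haplotype frequencies
#'   (default equal).
#' @param hap_freqs optionally, a length-4 vector of pooled haplotype
#'   frequencies (order MA, Ma, mA, ma) overriding the model's.
#' @return scalar flip effect.
#' @export
hap_flip_effect <- function(model, weights = NULL, hap_freqs = NULL) {
  f <- if (is.null(hap_freqs)) pool_hap_freqs(model, weights) else hap_freqs
  p_m <- f[1] + f[2]
  if (p_m <= 0 || p_m >= 1) {
    stop("marker allele M absent or fixed in the pooled sample: ",
         "haplotype flip undefined", call. = FALSE)
  }
  p_a_M <- f[1] / p_m
  p_a_m <- f[3] / (1 - p_m)
  (p_a_M - p_a_m) * model$causal_alpha
}

#' Predicted family-based estimate at a marker locus
#'
#' Expectation of the trio regression at a genotyped marker tagging an
#' ungenotyped causal locus:
#' \eqn{(1-2r)\,(p'_{A|M,Mm} - p'_{A|m,Mm})\,\alpha}, where the primed
#' conditionals are haplotype proportions within *heterozygous (Mm) parents*
#' of the parental generation (parents are random unions of haplotypes drawn
#' from their population's frequencies). Also returns the decomposition into
#' the haplotype-flip effect plus an LD-difference bias term,
#' \eqn{[(p'_{A|M,Mm} - p_{A|M}) - (p'_{A|m,Mm} - p_{A|m})]\,\alpha},
#' which is exact when r = 0.
#'
#' @param model a [two_locus_model()].
#' @param weights population weights (proportions of families).
#' @param approx if `TRUE`, use the r-is-small approximation with
#'   offspring-generation (gamete) haplotype frequencies instead of the
#'   parental conditionals.
#' @return list with `value`, `hap_flip`, `ld_bias`, `r` and the het
#'   conditionals `p_A_M_het`, `p_A_m_het`.
#' @export
predicted_marker_family_estimate <- function(model, weights = NULL,
                                             approx = FALSE) {
  stopifnot(inherits(model, "famhet_two_locus"))
  fmat <- do.call(rbind, model$hap_freqs)
  if (is.null(weights)) weights <- rep(1, nrow(fmat))
  weights <- weights / sum(weights)
  r <- model$recomb_fraction
  if (approx) {
    ## offspring-generation (gamete) haplotype frequencies
    fmat <- t(apply(fmat, 1, gamete_hap_freqs, r = r))
  }
  fM <- fmat[, 1] + fmat[, 2]   # per-population P(M haplotype)
  fm <- 1 - fM
  denom <- sum(weights * fM * fm)   # prop. to P(parent is Mm)
  if (denom <= 0) {
    stop("no heterozygous (Mm) parents under these haplotype frequencies",
         call. = FALSE)
  }
  p_A_M_het <- sum(weights * fmat[, 1] * fm) / denom
  p_A_m_het <- sum(weights * fmat[, 3] * fM) / denom
  alpha <- model$causal_alpha
  value <- if (approx) (p_A_M_het - p_A_m_het) * alpha
    else (1 - 2 * r) * (p_A_M_het - p_A_m_het) * alpha
  pooled <- as.numeric(weights %*% do.call(rbind, model$hap_freqs))
  flip <- hap_flip_effect(model, hap_freqs = pooled)
  p_m_pool <- pooled[1] + pooled[2]
  p_a_M <- pooled[1] / p_m_pool
  p_a_m <- pooled[3] / (1 - p_m_pool)
  ld_bias <- ((p_A_M_het - p_a_M) - (p_A_m_het - p_a_m)) * alpha
  list(value = value, hap_flip = flip, ld_bias = ld_bias, r = r,
       p_A_M_het = p_A_M_het, p_A_m_het = p_A_m_het)
}

#' Predicted population-based estimate at a marker locus
#'
#' Exact expectation of the population regression of trait on marker
#' genotype in a (possibly structured) sample:
#' \eqn{\alpha\,Cov(g_A, g_M)/Var(g_M)}, with within-population covariance
#' \eqn{2D_k} (D the LD coefficient) and a between-population term from
#' allele-frequency differences. Computed at the offspring generation (the
#' parental LD coefficient decays by `1 - r` in the gametes forming the
#' children). In a single random-mating population this equals the
#' haplotype-flip effect \eqn{(p_{A|M} - p_{A|m})\alpha} evaluated at the
#' offspring haplotype frequencies; in a structured sample it instead
#' reflects haplotype-frequency differences across populations.
#'
#' @param model a [two_locus_model()].
#' @param weights population weights (default equal).
#' @return scalar predicted slope.
#' @export
predicted_marker_population_estimate <- function(model, weights = NULL) {
  stopifnot(inherits(model, "famhet_two_locus"))
  fmat <- do.call(rbind, offspring_hap_freqs(model))
  if (is.null(weights)) weights <- rep(1, nrow(fmat))
  w <- weights / sum(weights)
  pM <- fmat[, 1] + fmat[, 2]
  pA <- fmat[, 1] + fmat[, 3]
  d <- fmat[, 1] - pM * pA
  wm <- function(x) sum(w * x)
  cov_gAgM <- wm(2 * d) +
    (wm(4 * pA * pM) - wm(2 * pA) * wm(2 * pM))
  var_gM <- wm(2 * pM * (1 - pM)) + (wm(4 * pM^2) - wm(2 * pM)^2)
  if (var_gM <= 0) {
    stop("marker monomorphic in the pooled sample", call. = FALSE)
  }
  model$causal_alpha * cov_gAgM / var_gM
}

## pooled parental heterozygote frequency per causal locus
pooled_het <- function(pgs, specs = NULL) {
  if (is.null(specs)) return(heterozygosity(pgs$freq))
  specs <- if (inherits(specs, "famhet_population")) list(specs) else specs
  w <- vapply(specs, `[[`, 1L, "n_families")
  w <- w / sum(w)
  h <- 0
  for (k in seq_along(specs)) {
    p <- specs[[k]]$allele_freq
    if (length(p) != length(pgs$alpha)) p <- pgs$freq
    h <- h + w[k] * heterozygosity(p)
  }
  h
}

#' Randomization effect of a polygenic score
#'
#' The expected slope of trait on PGS if genotypes at the PGS loci were
#' randomly assigned, independent of environments:
#' \eqn{\delta_{rand} = \sum_l H_l \hat\beta_l \alpha_l \,/\,
#' \sum_l H_l \hat\beta_l^2}, with \eqn{H_l} the heterozygosity of locus l.
#' This is the natural definition of the average causal effect of the PGS.
#'
#' @param pgs a [pgs_model()].
#' @param specs optional population specs; when given, \eqn{H_l} is pooled
#'   over populations with family-count weights.
#' @return scalar \eqn{\delta_{rand}}.
#' @export
pgs_randomization_effect <- function(pgs, specs = NULL) {
  stopifnot(inherits(pgs, "famhet_pgs_model"))
  lam <- pgs$pgs_loci
  h <- pooled_het(pgs, specs)[lam]
  denom <- sum(h * pgs$beta_hat^2)
  if (denom <= 0) {
    stop("zero genic variance: all PGS loci monomorphic or weightless",
         call. = FALSE)
  }
  sum(h * pgs$beta_hat * pgs$alpha[lam]) / denom
}

#' Heterozygote-conditional effect deviations of PGS loci
#'
#' For each PGS locus, \eqn{E[\alpha_{lf} \mid h_l]}: the mean family effect
#' deviation conditional on a parent being heterozygous at the locus,
#' computed analytically from the populations' frequencies and deviations.
#'
#' @param pgs a [pgs_model()].
#' @param specs list of [population_spec()] objects.
#' @return numeric vector, one value per PGS locus.
#' @export
het_conditional_devs <- function(pgs, specs) {
  stopifnot(inherits(pgs, "famhet_pgs_model"))
  specs <- if (inherits(specs, "famhet_population")) list(specs) else specs
  w <- vapply(specs, `[[`, 1L, "n_families")
  w <- w / sum(w)
  n_causal <- length(pgs$alpha)
  num <- den <- numeric(n_causal)
  for (k in seq_along(specs)) {
    p <- specs[[k]]$allele_freq
    if (length(p) != n_causal) p <- pgs$freq
    h <- heterozygosity(p)
    dev <- pgs_dev_row(pgs, specs[[k]]$label)
    num <- num + w[k] * h * dev
    den <- den + w[k] * h
  }
  out <- ifelse(den > 0, num / den, 0)
  out[pgs$pgs_loci]
}

#' Empirical heterozygote-conditional deviations from simulation truth
#'
#' Same quantity as [het_conditional_devs()], estimated from a simulated
#' cohort: the mean realized \eqn{\alpha_{lf}} over parents, weighted by each
#' parent's heterozygosity indicator at the locus.
#'
#' @param cohort a `famhet_cohort` from [simulate_pgs_cohort()].
#' @param pgs optional [pgs_model()] (defaults to the cohort's).
#' @return numeric vector, one value per PGS locus.
#' @export
empirical_het_devs <- function(cohort, pgs = NULL) {
  if (is.null(pgs)) pgs <- cohort$truth$model
  stopifnot(inherits(pgs, "famhet_pgs_model"))
  first <- cohort$children$child_no == 1L
  pop <- cohort$children$population[first]
  gm <- cohort$geno_mother[first, , drop = FALSE]
  gf <- cohort$geno_father[first, , drop = FALSE]
  labs <- unique(pop)
  dev_tab <- matrix(vapply(labs, function(l) pgs_dev_row(pgs, l),
                           numeric(length(pgs$alpha))),
                    nrow = length(pgs$alpha))
  devs <- dev_tab[, match(pop, labs), drop = FALSE]   # loci x families
  hets <- t(gm == 1L) + t(gf == 1L)   # loci x families
  num <- rowSums(hets * devs)
  den <- rowSums(hets)
  out <- ifelse(den > 0, num / den, 0)
  out[pgs$pgs_loci]
}

#' Predicted family-based PGS slope
#'
#' Expectation of the within-family PGS regression coefficient:
#' \deqn{\hat\delta_{fam} = \frac{\sum_l H_l \hat\beta_l (\alpha_l +
#' E[\alpha_{lf} \mid h_l])}{\sum_l H_l \hat\beta_l^2}.}
#' Reduces to [pgs_randomization_effect()] when no locus's heterozygous
#' parents are concentrated in particular environments.
#'
#' @param pgs a [pgs_model()].
#' @param het_dev per-PGS-locus values of \eqn{E[\alpha_{lf} \mid h_l]};
#'   computed via [het_conditional_devs()] from `specs` when omitted.
#' @param specs optional population specs (for pooled heterozygosities and
#'   the default `het_dev`).
#' @return scalar predicted \eqn{\hat\delta_{fam}}.
#' @export
predicted_pgs_family_estimate <- function(pgs, het_dev = NULL,
                                          specs = NULL) {
  stopifnot(inherits(pgs, "famhet_pgs_model"))
  lam <- pgs$pgs_loci
  if (is.null(het_dev)) {
    het_dev <- if (is.null(specs) || is.null(pgs$family_dev)) {
      numeric(length(lam))
    } else het_conditional_devs(pgs, specs)
  }
  stopifnot(length(het_dev) == length(lam))
  h <- pooled_het(pgs, specs)[lam]
  denom <- sum(h * pgs$beta_hat^2)
  if (denom <= 0) {
    stop("zero genic variance: all PGS loci monomorphic or weightless",
         call. = FALSE)
  }
  sum(h * pgs$beta_hat * (pgs$alpha[lam] + het_dev)) / denom
}

#' Family-specific PGS slopes under multiplicative heterogeneity
#'
#' When each family's effect deviations are a fixed multiple of the mean
#' effects (\eqn{\alpha_{lf} = C_f \alpha_l}) and the PGS weights are a fixed
#' multiple of the mean effects (\eqn{\hat\beta_l = B \alpha_l}), every
#' family has a well-defined PGS slope \eqn{\delta_f = (1 + C_f)/B}. The
#' within-family regression recovers not the plain average of these slopes
#' but the average weighted by each family's PGS segregation variance
#' (families whose parents are heterozygous at more PGS loci contribute more
#' within-family PGS variation and are upweighted).
#'
#' @param C per-family (or per-group) multipliers \eqn{C_f}.
#' @param B multiplicative bias of the PGS weights.
#' @param seg_var per-family PGS segregation variances (same length as `C`),
#'   e.g. from [pgs_family_seg_var()]; used (normalized) as weights.
#' @return list with `delta_f`, `weights`, `weighted_mean` (the predicted
#'   \eqn{\hat\delta_{fam}}), `unweighted_mean`, `B`.
#' @export
multiplicative_family_slopes <- function(C, B, seg_var) {
  if (B == 0) stop("B must be nonzero", call. = FALSE)
  stopifnot(length(C) == length(seg_var), all(seg_var >= 0))
  if (sum(seg_var) <= 0) {
    stop("total segregation variance is zero", call. = FALSE)
  }
  delta_f <- (1 + C) / B
  w <- seg_var / sum(seg_var)
  list(delta_f = delta_f, weights = w,
       weighted_mean = sum(w * delta_f),
       unweighted_mean = mean(delta_f), B = B)
}

#' Per-family PGS segregation variance
#'
#' \eqn{\sum_{l \in \Lambda} \hat\beta_l^2 (h_{m,l} + h_{f,l})/4} computed
#' from the parental genotypes of each family (h = heterozygosity
#' indicator): the conditional variance of the child's PGS segregation
#' deviation given the parents.
#'
#' @param cohort a `famhet_cohort`.
#' @param pgs optional [pgs_model()].
#' @return numeric vector, one value per family (in family order).
#' @export
pgs_family_seg_var <- function(cohort, pgs = NULL) {
  if (is.null(pgs)) pgs <- cohort$truth$model
  stopifnot(inherits(pgs, "famhet_pgs_model"))
  first <- cohort$children$child_no == 1L
  lam <- pgs$pgs_loci
  hm <- cohort$geno_mother[first, lam, drop = FALSE] == 1L
  hf <- cohort$geno_father[first, lam, drop = FALSE] == 1L
  as.numeric((hm + hf) %*% (pgs$beta_hat^2)) / 4
}
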