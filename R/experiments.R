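## batch-means Monte Carlo SE for the ratio var(a)/var(b) over families
batch_ratio_se <- function(a, b, batches = 25L) {
  n <- length(a)
  grp <- rep(seq_len(batches), length.out = n)
  r <- vapply(seq_len(batches), function(g) {
    stats::var(a[grp == g]) / stats::var(b[grp == g])
  }, 0)
  stats::sd(r) / sqrt(batches)
}

#' Drift, sampling and association-study experiment (two environments)
#'
#' For each replicate: allele frequencies drift independently in a red and a
#' blue population from a shared starting frequency; a large cohort is drawn
#' equally from the two populations (which inhabit distinct environments, so
#' the focal allele has per-allele effect `effect_red` in red families and
#' `effect_blue` in blue families); and both a population-based and a
#' family-based (trio) association study are run. Replicates in which the
#' locus is fixed in both populations are skipped.
#'
#' @param replicates number of drift replicates.
#' @param n_families total families per replicate (split equally).
#' @param pop_size,generations,p0 Wright-Fisher drift parameters
#'   (see [simulate_drift()]).
#' @param effect_red,effect_blue per-allele effects in the two environments;
#'   their mean is the population-average effect.
#' @param noise_sd SD of the family- and individual-level environmental
#'   deviations.
#' @param seed optional integer seed.
#' @return data frame with one row per retained replicate: `replicate`,
#'   `fst`, `p_red`, `p_blue`, `est_pop`, `se_pop`, `est_fam`, `se_fam`,
#'   `higher_freq_pop`, `higher_het_pop`. The number of skipped replicates is
#'   in `attr(, "skipped")`.
#' @export
run_drift_experiment <- function(replicates = 200L, n_families = 50000L,
                        pop_size = 1000L, generations = 200L, p0 = 0.5,
                        effect_red = 1.1, effect_blue = 0.9,
                        noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alpha <- (effect_red + effect_blue) / 2
  dev <- (effect_red - effect_blue) / 2
  model <- locus_effect_model(alpha = alpha, sd_env_family = noise_sd,
                              sd_env_indiv = noise_sd)
  nf <- as.integer(round(n_families / 2))
  rows <- vector("list", replicates)
  skipped <- 0L
  for (rep_i in seq_len(replicates)) {
    freqs <- simulate_drift(p0, pop_size, generations)
    p_r <- freqs[["p_red"]]; p_b <- freqs[["p_blue"]]
    if (p_r %in% c(0, 1) && p_b %in% c(0, 1)) {
      skipped <- skipped + 1L
      next
    }
    cohort <- simulate_cohort(
      list(population_spec("red", p_r, +dev, nf),
           population_spec("blue", p_b, -dev, nf)),
      model)
    pooled_poly <- stats::var(cohort$geno_child[, 1]) > 0
    ep <- if (pooled_poly) population_gwas(cohort) else NULL
    ef <- if (any(cohort$geno_mother[, 1] == 1L |
                  cohort$geno_father[, 1] == 1L)) family_gwas(cohort)
      else NULL
    het_r <- heterozygosity(p_r); het_b <- heterozygosity(p_b)
    rows[[rep_i]] <- data.frame(
      replicate = rep_i, fst = compute_fst(p_r, p_b),
      p_red = p_r, p_blue = p_b,
      est_pop = if (is.null(ep)) NA_real_ else ep$slope,
      se_pop = if (is.null(ep)) NA_real_ else ep$stderr,
      est_fam = if (is.null(ef)) NA_real_ else ef$slope,
      se_fam = if (is.null(ef)) NA_real_ else ef$stderr,
      higher_freq_pop = if (p_r > p_b) "red" else if (p_b > p_r) "blue"
        else "tie",
      higher_het_pop = if (het_r > het_b) "red" else if (het_b > het_r)
        "blue" else "tie",
      stringsAsFactors = FALSE)
  }
  kept <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(kept)) do.call(rbind, kept) else
    data.frame(replicate = integer(0), fst = numeric(0),
               p_red = numeric(0), p_blue = numeric(0),
               est_pop = numeric(0), se_pop = numeric(0),
               est_fam = numeric(0), se_fam = numeric(0),
               higher_freq_pop = character(0),
               higher_het_pop = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Summary statistics of a drift experiment table
#'
#' @param rows output of [run_drift_experiment()].
#' @param fst_low replicates with `fst` below this count as undifferentiated.
#' @param fst_high replicates with `fst` above this count as differentiated.
#' @return list with `mean_est_pop_low_fst` (and its SE and count),
#'   `concord_pop` (fraction of differentiated replicates where the sign of
#'   `est_pop - 1` matches the sign of `p_red - p_blue`), `concord_fam`
#'   (fraction where the sign of `est_fam - 1` matches the
#'   higher-heterozygosity population), and `fam_vs_pop_z` (paired
#'   difference of the two estimates over differentiated replicates,
#'   oriented by the sign of `p_red - p_blue`, in SE-of-the-mean units:
#'   the population estimate is systematically pulled further toward the
#'   higher-frequency population's effect than the trio estimate is, so
#'   this oriented difference is negative under G by E).
#' @export
drift_experiment_summary <- function(rows, fst_low = 0.01, fst_high = 0.05) {
  low <- rows[!is.na(rows$est_pop) & rows$fst < fst_low, ]
  high <- rows[rows$fst > fst_high, ]
  ## concordance is only meaningful where the deviation from 1 is
  ## statistically detectable; otherwise its sign is sampling noise
  hp <- high[!is.na(high$est_pop) & high$higher_freq_pop != "tie" &
               abs(high$est_pop - 1) > 2 * high$se_pop, ]
  hf <- high[!is.na(high$est_fam) & high$higher_het_pop != "tie" &
               abs(high$est_fam - 1) > 2 * high$se_fam, ]
  both <- high[!is.na(high$est_pop) & !is.na(high$est_fam) &
                 high$higher_freq_pop != "tie", ]
  d <- (both$est_fam - both$est_pop) * sign(both$p_red - both$p_blue)
  list(
    mean_est_pop_low_fst = mean(low$est_pop),
    se_mean_est_pop_low_fst = stats::sd(low$est_pop) /
      sqrt(max(nrow(low), 1L)),
    n_low_fst = nrow(low),
    concord_pop = mean(sign(hp$est_pop - 1) ==
                         ifelse(hp$higher_freq_pop == "red", 1, -1)),
    n_concord_pop = nrow(hp),
    concord_fam = mean(sign(hf$est_fam - 1) ==
                         ifelse(hf$higher_het_pop == "red", 1, -1)),
    n_concord_fam = nrow(hf),
    fam_vs_pop_z = if (nrow(both) > 1) {
      mean(d) / (stats::sd(d) / sqrt(nrow(both)))
    } else NA_real_,
    n_fam_vs_pop = nrow(both)
  )
}

verify_row <- function(check, theory, estimate, se, tol) {
  z <- if (se > 0) abs(estimate - theory) / se else
    ifelse(abs(estimate - theory) < 1e-10, 0, Inf)
  data.frame(check = check, theory = theory, estimate = estimate,
             se = se, z = z, pass = z < tol, stringsAsFactors = FALSE)
}

#' Verification matrix: closed-form predictions vs simulation
#'
#' Runs a bank of generative configurations spanning the package's models —
#' no gene-by-environment interaction, two-environment G by E, inbreeding,
#' two-locus LD heterogeneity, and homogeneous / heterogeneous /
#' multiplicative polygenic-score settings — and checks every estimator
#' against its closed-form or exact-enumeration prediction within
#' `tolerance_sigma` Monte Carlo standard errors. The rows named
#' `*_excludes_*` are separation checks: they pass when the estimate is
#' *more* than `tolerance_sigma` SEs away from a deliberately wrong theory
#' value (e.g. the unweighted average of family slopes).
#'
#' @param n_families families per simulated cohort.
#' @param tolerance_sigma tolerance in Monte Carlo SE units.
#' @param seed optional integer seed.
#' @return data frame (check, theory, estimate, se, z, pass) with attribute
#'   `"n_failures"`.
#' @export
verify_all <- function(n_families = 50000L, tolerance_sigma = 3,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tol <- tolerance_sigma
  nf <- as.integer(n_families)
  half <- nf %/% 2L
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- verify_row(..., tol = tol)

  ## 1. no G by E: every design recovers alpha
  m0 <- locus_effect_model(alpha = 1, sd_env_family = 0.5,
                           sd_env_indiv = 0.5)
  s0 <- list(population_spec("pop", 0.4, 0, nf))
  co <- simulate_cohort(s0, m0)
  add("no_gxe_population", 1, population_gwas(co)$slope,
      population_gwas(co)$stderr)
  add("no_gxe_family", 1, family_gwas(co)$slope, family_gwas(co)$stderr)
  co2 <- simulate_cohort(s0, m0, children_per_family = 2L)
  add("no_gxe_sib", 1, sib_difference(co2)$slope, sib_difference(co2)$stderr)

  ## 2. two environments, G by E (drifted frequencies)
  mg <- locus_effect_model(alpha = 1, sd_env_family = 0.5,
                           sd_env_indiv = 0.5)
  sg <- list(population_spec("red", 0.7, +0.1, half),
             population_spec("blue", 0.2, -0.1, half))
  jg <- discrete_joint(c(0.5, 0.5), c(0.7, 0.2), c(+0.1, -0.1))
  cg <- simulate_cohort(sg, mg)
  add("gxe_family_vs_theory", predicted_family_estimate(jg, 1),
      family_gwas(cg)$slope, family_gwas(cg)$stderr)
  add("gxe_population_vs_enumeration",
      predicted_population_estimate(jg, 1)$slope,
      population_gwas(cg)$slope, population_gwas(cg)$stderr)
  cg2 <- simulate_cohort(sg, mg, children_per_family = 2L)
  ef <- family_gwas(cg)
  es <- sib_difference(cg2)
  add("gxe_trio_vs_sib", ef$slope, es$slope,
      sqrt(ef$stderr^2 + es$stderr^2))

  ## 3. inbreeding F = 0.2
  si <- list(population_spec("red", 0.5, +0.1, half, inbreeding_f = 0.2),
             population_spec("blue", 0.3, -0.1, half, inbreeding_f = 0.2))
  ji <- discrete_joint(c(0.5, 0.5), c(0.5, 0.3), c(+0.1, -0.1), f = 0.2)
  ci <- simulate_cohort(si, mg)
  add("inbred_family_vs_theory", predicted_family_estimate(ji, 1),
      family_gwas(ci)$slope, family_gwas(ci)$stderr)
  add("inbred_population_vs_enumeration",
      predicted_population_estimate(ji, 1)$slope,
      population_gwas(ci)$slope, population_gwas(ci)$stderr)

  ## 4. two-locus LD heterogeneity (different LD and marker frequency)
  tl <- two_locus_model(
    hap_freqs = list(red = c(MA = 0.30, Ma = 0.10, mA = 0.10, ma = 0.50),
                     blue = c(MA = 0.10, Ma = 0.60, mA = 0.20, ma = 0.10)),
    recomb_fraction = 0.1, causal_alpha = 1)
  st <- list(population_spec("red", 0.5, 0, half),
             population_spec("blue", 0.5, 0, half))
  ct <- simulate_two_locus_cohort(tl, st)
  add("marker_family_vs_theory",
      predicted_marker_family_estimate(tl)$value,
      family_gwas(ct, "marker")$slope, family_gwas(ct, "marker")$stderr)
  add("marker_population_vs_enumeration",
      predicted_marker_population_estimate(tl),
      population_gwas(ct, "marker")$slope,
      population_gwas(ct, "marker")$stderr)
  ## in a single random-mating population the population-level marker slope
  ## equals the haplotype-flip effect
  tl1 <- two_locus_model(
    hap_freqs = list(pop = c(MA = 0.30, Ma = 0.10, mA = 0.10, ma = 0.50)),
    recomb_fraction = 0.1, causal_alpha = 1)
  ct1 <- simulate_two_locus_cohort(tl1, list(population_spec("pop", 0.5, 0,
                                                             nf)))
  add("marker_population_vs_hap_flip_single_pop",
      hap_flip_effect(tl1, hap_freqs = offspring_hap_freqs(tl1)$pop),
      population_gwas(ct1, "marker")$slope,
      population_gwas(ct1, "marker")$stderr)

  ## 5. homogeneous PGS (weights equal true effects)
  n_loci <- 30L
  al <- stats::rnorm(n_loci, 0, 0.15)
  ph <- pgs_model(alpha = al, beta_hat = al,
                  freq = stats::runif(n_loci, 0.2, 0.8),
                  sd_env_family = 0.5, sd_env_indiv = 0.5)
  sp <- list(population_spec("pop", 0.5, 0, nf))
  cp <- simulate_pgs_cohort(ph, sp)
  add("pgs_homogeneous_family", 1, family_pgs(cp)$slope,
      family_pgs(cp)$stderr)
  add("pgs_homogeneous_population", 1, population_pgs(cp)$slope,
      population_pgs(cp)$stderr)
  add("pgs_seg_variance_half", 0.5,
      stats::var(cp$children$seg_pgs) / stats::var(cp$children$pgs),
      batch_ratio_se(cp$children$seg_pgs, cp$children$pgs))

  ## 6. heterogeneous PGS (population offsets, drifted frequencies)
  off <- rbind(red = al * 0 + 0.05, blue = al * 0 - 0.05)
  phet <- pgs_model(alpha = al, beta_hat = al,
                    freq = stats::runif(n_loci, 0.2, 0.8),
                    family_dev = list(type = "offsets", offsets = off),
                    sd_env_family = 0.5, sd_env_indiv = 0.5)
  fr <- pmin(pmax(phet$freq + stats::runif(n_loci, -0.15, 0.15), 0.02), 0.98)
  fb <- pmin(pmax(phet$freq - stats::runif(n_loci, -0.15, 0.15), 0.02), 0.98)
  sh <- list(population_spec("red", fr, 0, half),
             population_spec("blue", fb, 0, half))
  chh <- simulate_pgs_cohort(phet, sh)
  add("pgs_heterogeneous_family_vs_theory",
      predicted_pgs_family_estimate(phet, specs = sh),
      family_pgs(chh)$slope, family_pgs(chh)$stderr)
  pp <- population_pgs(chh)
  add("pgs_population_decomposition",
      pp$decomposition$between_term +
        pp$decomposition$v_seg / pp$decomposition$v_pgs *
          family_pgs(chh)$slope,
      pp$slope, pp$stderr)

  ## 7. multiplicative C_f: segregation-variance weighting
  am <- stats::rnorm(20L, 0, 0.2)
  pm <- pgs_model(alpha = am, beta_hat = am,
                  family_dev = list(
                    type = "multiplicative", C = c(red = 0.5, blue = -0.5)),
                  freq = rep(0.5, 20L),
                  sd_env_family = 0.3, sd_env_indiv = 0.3)
  sm <- list(population_spec("red", rep(0.5, 20L), 0, half),
             population_spec("blue", rep(0.067, 20L), 0, half))
  cm <- simulate_pgs_cohort(pm, sm)
  fs <- pgs_family_seg_var(cm, pm)
  cf <- ifelse(cm$children$population[cm$children$child_no == 1L] == "red",
               0.5, -0.5)
  ms <- multiplicative_family_slopes(cf, B = 1, seg_var = fs)
  fam_m <- family_pgs(cm)
  add("pgs_multiplicative_weighted", ms$weighted_mean, fam_m$slope,
      fam_m$stderr)
  unw <- verify_row("pgs_multiplicative_excludes_unweighted",
                    ms$unweighted_mean, fam_m$slope, fam_m$stderr, tol)
  unw$pass <- unw$z > tol
  rows[[length(rows) + 1L]] <- unw

  ## 8. segregation averaging in the homogeneous regime
  sa <- segregation_averaging(cp)
  add("segregation_averaging_reduction", sa$predicted_reduction,
      sa$reduction, sa$mc_se)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_failures") <- sum(!out$pass)
  out
}

#' Segregation-averaging manipulation
#'
#' Replaces each child's phenotype by its conditional mean over Mendelian
#' segregation at the PGS loci, given the parents, the environment and all
#' non-PGS contributions (computable exactly because simulation truth
#' records each child's realized segregation contribution). The resulting
#' drop in phenotypic variance is the contribution of within-family
#' segregation at the PGS loci; in the homogeneous regime (weights equal to
#' true effects, no G by E, no individual effect deviations) it equals
#' \eqn{\hat\delta_{fam}^2 V_\varsigma} in expectation. Under heterogeneous
#' effects the realized reduction can exceed that prediction (family slopes
#' enter through their squares), so both numbers are reported rather than
#' asserted equal.
#'
#' @param cohort a `famhet_cohort` from [simulate_pgs_cohort()] (must carry
#'   simulation truth).
#' @param pgs optional [pgs_model()].
#' @return list with `v_p`, `v_p_after`, `reduction`,
#'   `predicted_reduction` (\eqn{\hat\delta_{fam}^2 V_\varsigma}),
#'   `family_slope`, `v_seg` and a batch-means `mc_se` for the reduction.
#' @export
segregation_averaging <- function(cohort, pgs = NULL) {
  if (is.null(cohort$truth) || is.null(cohort$truth$seg_contrib)) {
    stop("cohort carries no simulation truth (seg_contrib): ",
         "segregation averaging requires a simulated PGS cohort",
         call. = FALSE)
  }
  y <- cohort$children$phenotype
  y_after <- y - cohort$truth$seg_contrib
  v_p <- stats::var(y)
  v_p_after <- stats::var(y_after)
  seg <- cohort$children$seg_pgs
  v_seg <- stats::var(seg)
  if (v_seg < 1e-12) {
    fam_slope <- NA_real_
    predicted <- 0
  } else {
    fam_slope <- family_pgs(cohort, pgs)$slope
    predicted <- fam_slope^2 * v_seg
  }
  ## batch-means SE of the variance reduction
  nb <- 25L
  grp <- rep(seq_len(nb), length.out = length(y))
  red_b <- vapply(seq_len(nb), function(g) {
    stats::var(y[grp == g]) - stats::var(y_after[grp == g])
  }, 0)
  list(v_p = v_p, v_p_after = v_p_after, reduction = v_p - v_p_after,
       predicted_reduction = predicted, family_slope = fam_slope,
       v_seg = v_seg, mc_se = stats::sd(red_b) / sqrt(nb))
}
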