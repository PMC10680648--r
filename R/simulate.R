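#' Draw parental genotypes under Hardy-Weinberg equilibrium
#'
#' @param p focal-allele frequency.
#' @param n number of genotypes to draw.
#' @param seed optional integer seed.
#' @return integer vector of focal-allele counts in \{0, 1, 2\}, i.i.d. with
#'   probabilities \eqn{(1-p)^2, 2p(1-p), p^2}.
#' @export
draw_parent_genotypes <- function(p, n, seed = NULL) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("allele frequency p must lie in [0, 1]", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(as.integer(n), 2L, p)
}

## One gamete per parent: a heterozygous parent transmits each allele with
## probability 1/2; homozygotes transmit their only allele.
transmit_gamete <- function(g) {
  out <- integer(length(g))
  out[g == 2L] <- 1L
  het <- g == 1L
  if (any(het)) out[het] <- stats::rbinom(sum(het), 1L, 0.5)
  out
}

#' Mendelian segregation from parental genotypes
#'
#' Child genotype = maternal gamete + paternal gamete. The segregation
#' deviation is `child - (g_mother + g_father)/2`; it is zero whenever both
#' parents are homozygous and has conditional variance
#' \eqn{(h_m + h_f)/4} where \eqn{h} indicates a heterozygous parent.
#'
#' @param g_mother,g_father integer vectors of genotypes in \{0, 1, 2\}
#'   (recycled against each other).
#' @param seed optional integer seed.
#' @return integer vector of child genotypes.
#' @export
segregate <- function(g_mother, g_father, seed = NULL) {
  if (any(!g_mother %in% 0:2) || any(!g_father %in% 0:2)) {
    stop("genotypes must be allele counts in {0, 1, 2}", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- max(length(g_mother), length(g_father))
  g_mother <- rep_len(as.integer(g_mother), n)
  g_father <- rep_len(as.integer(g_father), n)
  transmit_gamete(g_mother) + transmit_gamete(g_father)
}

#' Segregation deviation
#'
#' @param g_child,g_mother,g_father genotype vectors.
#' @return `g_child - (g_mother + g_father)/2`, in
#'   \{-1, -1/2, 0, 1/2, 1\}.
#' @export
seg_deviation <- function(g_child, g_mother, g_father) {
  g_child - (g_mother + g_father) / 2
}

## Population spec list -> validated list; enforces the mean-zero constraint
## on population-level effect deviations under family-count weights.
validate_specs <- function(specs) {
  if (inherits(specs, "famhet_population")) specs <- list(specs)
  if (!length(specs) || !all(vapply(specs, inherits, TRUE,
                                    "famhet_population"))) {
    stop("specs must be a list of population_spec objects", call. = FALSE)
  }
  labels <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("population labels must be unique",
                                  call. = FALSE)
  w <- vapply(specs, `[[`, 1L, "n_families")
  dev <- vapply(specs, `[[`, 0, "env_effect_dev")
  if (abs(sum(w * dev) / sum(w)) > 1e-8) {
    stop("population env_effect_dev values must average to zero under the ",
         "family-count weights (E[alpha_f] = 0 by construction)",
         call. = FALSE)
  }
  specs
}

## Per-family deme allele frequencies implementing inbreeding F as a
## two-deme Wahlund mixture (see population_spec); each family is assigned
## to one deme, both parents drawn from it.
family_freqs <- function(spec) {
  n <- spec$n_families
  p <- spec$allele_freq
  if (spec$inbreeding_f <= 0) return(rep(p, n))
  d <- sqrt(spec$inbreeding_f * p * (1 - p))
  deme <- stats::rbinom(n, 1L, 0.5)
  ifelse(deme == 1L, p + d, p - d)
}

new_cohort <- function(children, geno_child, geno_mother, geno_father,
                       loci, truth = NULL, meta = list()) {
  structure(
    list(children = children, geno_child = geno_child,
         geno_mother = geno_mother, geno_father = geno_father,
         loci = loci, truth = truth, meta = meta),
    class = "famhet_cohort"
  )
}

#' @export
print.famhet_cohort <- function(x, ...) {
  cat("famhet cohort:", nrow(x$children), "children,",
      length(unique(x$children$family_id)), "families,",
      ncol(x$geno_child), "locus/loci\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$children$population)),
                    table(x$children$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of children in a cohort
#' @param cohort a `famhet_cohort`.
#' @return integer count of child records.
#' @export
n_children <- function(cohort) nrow(cohort$children)

#' Simulate a single-locus trio or sibling cohort
#'
#' Families are formed by monogamous random mating within population: both
#' parents are drawn under Hardy-Weinberg equilibrium at the population's
#' allele frequency (deformed by the inbreeding coefficient if set), and
#' each child's genotype is produced by Mendelian segregation. Each family's
#' per-allele effect deviation is its population's `env_effect_dev` plus
#' optional Gaussian noise; phenotypes follow the single-locus model (see
#' [locus_effect_model()]). Family-level draws (effect deviation,
#' environmental deviation) are shared between siblings.
#'
#' @param specs list of [population_spec()] objects.
#' @param model a [locus_effect_model()].
#' @param children_per_family 1 for trio designs, 2 for sibling designs.
#' @param seed optional integer seed.
#' @return A `famhet_cohort`: child-level data frame plus genotype matrices
#'   for child, mother, father, and a `truth` list holding realized effect
#'   deviations (simulation truth, for oracle use only).
#' @export
simulate_cohort <- function(specs, model, children_per_family = 1L,
                            seed = NULL) {
  specs <- validate_specs(specs)
  stopifnot(inherits(model, "famhet_effect_model"))
  children_per_family <- as.integer(children_per_family)
  stopifnot(children_per_family >= 1L)
  if (!is.null(seed)) set.seed(seed)

  per_pop <- lapply(specs, function(spec) {
    nf <- spec$n_families
    pf <- family_freqs(spec)
    gm <- stats::rbinom(nf, 2L, pf)
    gf <- stats::rbinom(nf, 2L, pf)
    alpha_f <- spec$env_effect_dev +
      if (model$sd_family_dev > 0) stats::rnorm(nf, 0, model$sd_family_dev)
      else 0
    eps_f <- if (model$sd_env_family > 0)
      stats::rnorm(nf, 0, model$sd_env_family) else numeric(nf)
    alpha_f <- rep_len(alpha_f, nf)
    idx <- rep(seq_len(nf), each = children_per_family)
    nc <- length(idx)
    gc <- segregate(gm[idx], gf[idx])
    alpha_i <- if (model$sd_indiv_dev > 0)
      stats::rnorm(nc, 0, model$sd_indiv_dev) else numeric(nc)
    eps_i <- if (model$sd_env_indiv > 0)
      stats::rnorm(nc, 0, model$sd_env_indiv) else numeric(nc)
    y <- model$intercept +
      (model$alpha + alpha_f[idx] + alpha_i) * gc + eps_f[idx] + eps_i
    list(
      children = data.frame(
        family_id = idx, child_no = ((seq_len(nc) - 1L) %%
                                       children_per_family) + 1L,
        population = spec$label, phenotype = y,
        alpha_f = alpha_f[idx], alpha_i = alpha_i,
        stringsAsFactors = FALSE),
      gc = gc, gm = gm[idx], gf = gf[idx]
    )
  })

  children <- do.call(rbind, lapply(per_pop, `[[`, "children"))
  ## family ids made globally unique across populations
  offs <- cumsum(c(0L, vapply(specs, `[[`, 1L, "n_families")))
  for (k in seq_along(per_pop)) {
    sel <- children$population == specs[[k]]$label
    children$family_id[sel] <- children$family_id[sel] + offs[k]
  }
  rownames(children) <- NULL
  as_mat <- function(field) {
    matrix(unlist(lapply(per_pop, `[[`, field)), ncol = 1,
           dimnames = list(NULL, "L1"))
  }
  new_cohort(
    children,
    geno_child = as_mat("gc"), geno_mother = as_mat("gm"),
    geno_father = as_mat("gf"),
    loci = data.frame(locus_id = "L1", effect_allele = "2",
                      stringsAsFactors = FALSE),
    truth = list(model = model, specs = specs),
    meta = list(children_per_family = children_per_family)
  )
}

#' Assign a phenotype to one trio record
#'
#' Convenience scalar form of the phenotype model
#' \eqn{Y = Y^* + (\alpha + \alpha_f + \alpha_i) g + \epsilon_f + \epsilon_i},
#' drawing any deviations whose SDs are positive.
#'
#' @param g child genotype (0, 1 or 2).
#' @param model a [locus_effect_model()].
#' @param env_effect_dev population-level component of \eqn{\alpha_f}.
#' @param seed optional integer seed.
#' @return list with `phenotype` and the realized `alpha_f`, `alpha_i`,
#'   `eps_f`, `eps_i`.
#' @export
assign_phenotype <- function(g, model, env_effect_dev = 0, seed = NULL) {
  stopifnot(inherits(model, "famhet_effect_model"), g %in% 0:2)
  if (!is.null(seed)) set.seed(seed)
  alpha_f <- env_effect_dev +
    if (model$sd_family_dev > 0) stats::rnorm(1, 0, model$sd_family_dev)
    else 0
  alpha_i <- if (model$sd_indiv_dev > 0)
    stats::rnorm(1, 0, model$sd_indiv_dev) else 0
  eps_f <- if (model$sd_env_family > 0)
    stats::rnorm(1, 0, model$sd_env_family) else 0
  eps_i <- if (model$sd_env_indiv > 0)
    stats::rnorm(1, 0, model$sd_env_indiv) else 0
  list(phenotype = model$intercept +
         (model$alpha + alpha_f + alpha_i) * g + eps_f + eps_i,
       alpha_f = alpha_f, alpha_i = alpha_i, eps_f = eps_f, eps_i = eps_i)
}

#' Wright-Fisher drift in two isolated populations
#'
#' From a shared initial frequency, two populations of `pop_size` diploids
#' drift independently by binomial resampling of 2N gametes per generation.
#'
#' @param p0 initial focal-allele frequency, in (0, 1).
#' @param pop_size diploid population size N.
#' @param generations number of generations of drift.
#' @param seed optional integer seed.
#' @return named numeric vector `c(p_red = ..., p_blue = ...)` of terminal
#'   frequencies.
#' @export
simulate_drift <- function(p0, pop_size, generations, seed = NULL) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_gam <- 2L * as.integer(pop_size)
  drift_one <- function() {
    p <- p0
    for (g in seq_len(generations)) {
      p <- stats::rbinom(1L, n_gam, p) / n_gam
      if (p == 0 || p == 1) break
    }
    p
  }
  c(p_red = drift_one(), p_blue = drift_one())
}

#' F_ST between two populations (Nei's G_ST, equal weights)
#'
#' \eqn{F_{ST} = 1 - H_S / H_T} with \eqn{H_S} the mean within-population
#' heterozygosity and \eqn{H_T} the heterozygosity at the mean frequency.
#' Returns 0 when \eqn{H_T = 0} (both populations fixed for the same allele).
#'
#' @param p_red,p_blue allele frequencies in the two populations.
#' @return F_ST in \[0, 1\].
#' @export
compute_fst <- function(p_red, p_blue) {
  stopifnot(p_red >= 0, p_red <= 1, p_blue >= 0, p_blue <= 1)
  p_bar <- (p_red + p_blue) / 2
  h_t <- 2 * p_bar * (1 - p_bar)
  if (h_t == 0) return(0)
  h_s <- (2 * p_red * (1 - p_red) + 2 * p_blue * (1 - p_blue)) / 2
  1 - h_s / h_t
}

## haplotype codes 1..4 = MA, Ma, mA, ma
HAP_NAMES <- c("MA", "Ma", "mA", "ma")
hap_has_M <- c(TRUE, TRUE, FALSE, FALSE)
hap_has_A <- c(TRUE, FALSE, TRUE, FALSE)

## recombinant of (marker from h1, causal from h2)
recombine_haps <- function(h1, h2) {
  m <- hap_has_M[h1]
  a <- hap_has_A[h2]
  ifelse(m, ifelse(a, 1L, 2L), ifelse(a, 3L, 4L))
}

## one gamete from a diplotype (h1, h2) with recombination fraction r:
## pick the chromosome contributing the marker allele at random; the causal
## allele comes from the same chromosome w.p. 1-r, else from the other.
gamete_from_diplotype <- function(h1, h2, r) {
  n <- length(h1)
  first <- stats::rbinom(n, 1L, 0.5) == 1L
  hm <- ifelse(first, h1, h2)      # chromosome providing the marker allele
  ho <- ifelse(first, h2, h1)
  rec <- stats::rbinom(n, 1L, r) == 1L
  out <- hm
  out[rec] <- recombine_haps(hm[rec], ho[rec])
  out
}

#' Simulate a two-locus (marker + causal) trio cohort
#'
#' Parents are random unions of haplotypes drawn from their population's
#' haplotype frequencies; each transmits one gamete, recombinant with
#' probability r. Phenotype = `causal_alpha` times the causal-allele count
#' (plus optional environmental noise); there is no gene-by-environment
#' interaction. Phase is known in the output.
#'
#' @param model a [two_locus_model()]; its `hap_freqs` names must match the
#'   population labels of `specs`.
#' @param specs list of [population_spec()] objects (their `allele_freq` is
#'   ignored; haplotype frequencies come from `model`).
#' @param seed optional integer seed.
#' @return A `famhet_cohort` with loci `"marker"` and `"causal"` and a
#'   `truth` list carrying the child/parent haplotype codes.
#' @export
simulate_two_locus_cohort <- function(model, specs, seed = NULL) {
  stopifnot(inherits(model, "famhet_two_locus"))
  if (inherits(specs, "famhet_population")) specs <- list(specs)
  labels <- vapply(specs, `[[`, "", "label")
  if (!all(labels %in% names(model$hap_freqs))) {
    stop("every population needs haplotype frequencies in the model",
         call. = FALSE)
  }
  p_marker <- vapply(labels, function(l) {
    sum(model$hap_freqs[[l]][hap_has_M])
  }, 0)
  if (all(p_marker %in% c(0, 1))) {
    stop("marker locus monomorphic in all populations (degenerate ",
         "haplotype frequencies)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- model$recomb_fraction

  per_pop <- lapply(specs, function(spec) {
    nf <- spec$n_families
    f <- model$hap_freqs[[spec$label]]
    draw <- function(n) sample.int(4L, n, replace = TRUE, prob = f)
    hm1 <- draw(nf); hm2 <- draw(nf)   # mother's two haplotypes
    hf1 <- draw(nf); hf2 <- draw(nf)   # father's
    gam_m <- gamete_from_diplotype(hm1, hm2, r)
    gam_f <- gamete_from_diplotype(hf1, hf2, r)
    count_M <- function(a, b) as.integer(hap_has_M[a]) +
      as.integer(hap_has_M[b])
    count_A <- function(a, b) as.integer(hap_has_A[a]) +
      as.integer(hap_has_A[b])
    g_causal <- count_A(gam_m, gam_f)
    eps <- if (model$sd_env > 0) stats::rnorm(nf, 0, model$sd_env)
      else numeric(nf)
    list(
      children = data.frame(
        family_id = seq_len(nf), child_no = 1L, population = spec$label,
        phenotype = model$causal_alpha * g_causal + eps,
        stringsAsFactors = FALSE),
      gc = cbind(count_M(gam_m, gam_f), g_causal),
      gm = cbind(count_M(hm1, hm2), count_A(hm1, hm2)),
      gf = cbind(count_M(hf1, hf2), count_A(hf1, hf2)),
      haps = data.frame(hm1 = hm1, hm2 = hm2, hf1 = hf1, hf2 = hf2,
                        gam_m = gam_m, gam_f = gam_f)
    )
  })

  children <- do.call(rbind, lapply(per_pop, `[[`, "children"))
  offs <- cumsum(c(0L, vapply(specs, `[[`, 1L, "n_families")))
  for (k in seq_along(per_pop)) {
    sel <- children$population == specs[[k]]$label
    children$family_id[sel] <- children$family_id[sel] + offs[k]
  }
  rownames(children) <- NULL
  stack <- function(field) {
    m <- do.call(rbind, lapply(per_pop, `[[`, field))
    dimnames(m) <- list(NULL, c("marker", "causal"))
    m
  }
  new_cohort(
    children,
    geno_child = stack("gc"), geno_mother = stack("gm"),
    geno_father = stack("gf"),
    loci = data.frame(locus_id = c("marker", "causal"),
                      effect_allele = c("2", "2"), stringsAsFactors = FALSE),
    truth = list(model = model, specs = specs,
                 haplotypes = do.call(rbind, lapply(per_pop, `[[`, "haps"))),
    meta = list(children_per_family = 1L)
  )
}

#' Simulate a multi-locus polygenic-score cohort
#'
#' All loci are unlinked and in linkage equilibrium within population;
#' parents are drawn under HWE at per-population, per-locus frequencies and
#' children produced by independent Mendelian segregation at every locus.
#' Phenotypes follow the multi-locus model
#' \eqn{Y = Y^* + \sum_{l \in L} (\alpha_l + \alpha_{lf} + \alpha_{il}) g_l
#' + \epsilon_f + \epsilon_i}; the PGS is
#' \eqn{\sum_{l \in \Lambda} \hat\beta_l g_l}.
#'
#' @param model a [pgs_model()].
#' @param specs list of [population_spec()] objects; a spec's `allele_freq`
#'   may be a vector (one per causal locus) overriding `model$freq`.
#' @param children_per_family 1 (trios) or 2 (sibling designs).
#' @param seed optional integer seed.
#' @return A `famhet_cohort`; `children` additionally carries `pgs`,
#'   `pgs_mother`, `pgs_father` and the PGS-level segregation deviation
#'   `seg_pgs`; `truth$seg_contrib` holds each child's realized segregation
#'   contribution to the phenotype at the PGS loci (for the
#'   segregation-averaging experiment).
#' @export
simulate_pgs_cohort <- function(model, specs, children_per_family = 1L,
                                seed = NULL) {
  stopifnot(inherits(model, "famhet_pgs_model"))
  specs <- if (inherits(specs, "famhet_population")) list(specs) else specs
  labels <- vapply(specs, `[[`, "", "label")
  n_causal <- length(model$alpha)
  children_per_family <- as.integer(children_per_family)
  if (!is.null(seed)) set.seed(seed)

  fd <- model$family_dev
  dev_row <- function(label) pgs_dev_row(model, label)
  ## mean-zero G-by-E check under family-count weights
  if (!is.null(fd)) {
    w <- vapply(specs, `[[`, 1L, "n_families")
    devs <- vapply(labels, dev_row, numeric(n_causal))
    if (is.null(dim(devs))) devs <- matrix(devs, nrow = n_causal)
    wm <- as.numeric(devs %*% w) / sum(w)
    if (max(abs(wm)) > 1e-8) {
      stop("per-locus family effect deviations must average to zero over ",
           "populations (weighted by n_families)", call. = FALSE)
    }
  }

  per_pop <- lapply(specs, function(spec) {
    nf <- spec$n_families
    ## a spec-level frequency vector (one per causal locus) overrides the
    ## model default; otherwise model$freq applies
    p <- spec$allele_freq
    if (length(p) != n_causal) p <- model$freq
    gm <- matrix(stats::rbinom(nf * n_causal, 2L,
                               rep(p, each = nf)), nrow = nf)
    gf <- matrix(stats::rbinom(nf * n_causal, 2L,
                               rep(p, each = nf)), nrow = nf)
    eps_f <- if (model$sd_env_family > 0)
      stats::rnorm(nf, 0, model$sd_env_family) else numeric(nf)
    alpha_lf <- dev_row(spec$label)

    idx <- rep(seq_len(nf), each = children_per_family)
    nc <- length(idx)
    gmx <- gm[idx, , drop = FALSE]
    gfx <- gf[idx, , drop = FALSE]
    gc <- matrix(0L, nrow = nc, ncol = n_causal)
    for (l in seq_len(n_causal)) {
      gc[, l] <- segregate(gmx[, l], gfx[, l])
    }
    alpha_il <- if (model$indiv_dev_sd > 0) {
      matrix(stats::rnorm(nc * n_causal, 0, model$indiv_dev_sd), nrow = nc)
    } else NULL
    eff <- matrix(rep(model$alpha + alpha_lf, each = nc), nrow = nc)
    if (!is.null(alpha_il)) eff <- eff + alpha_il
    eps_i <- if (model$sd_env_indiv > 0)
      stats::rnorm(nc, 0, model$sd_env_indiv) else numeric(nc)
    y <- model$intercept + rowSums(eff * gc) + eps_f[idx] + eps_i

    bh <- model$beta_hat
    lam <- model$pgs_loci
    pgs_c <- as.numeric(gc[, lam, drop = FALSE] %*% bh)
    pgs_m <- as.numeric(gmx[, lam, drop = FALSE] %*% bh)
    pgs_f <- as.numeric(gfx[, lam, drop = FALSE] %*% bh)
    sig <- gc - (gmx + gfx) / 2
    seg_pgs <- as.numeric(sig[, lam, drop = FALSE] %*% bh)
    seg_contrib <- rowSums(eff[, lam, drop = FALSE] *
                             sig[, lam, drop = FALSE])
    list(
      children = data.frame(
        family_id = idx, child_no = ((seq_len(nc) - 1L) %%
                                       children_per_family) + 1L,
        population = spec$label, phenotype = y,
        pgs = pgs_c, pgs_mother = pgs_m, pgs_father = pgs_f,
        seg_pgs = seg_pgs, stringsAsFactors = FALSE),
      gc = gc, gm = gmx, gf = gfx, seg_contrib = seg_contrib
    )
  })

  children <- do.call(rbind, lapply(per_pop, `[[`, "children"))
  offs <- cumsum(c(0L, vapply(specs, `[[`, 1L, "n_families")))
  for (k in seq_along(per_pop)) {
    sel <- children$population == specs[[k]]$label
    children$family_id[sel] <- children$family_id[sel] + offs[k]
  }
  rownames(children) <- NULL
  locus_ids <- sprintf("L%d", seq_len(n_causal))
  stack <- function(field) {
    m <- do.call(rbind, lapply(per_pop, `[[`, field))
    dimnames(m) <- list(NULL, locus_ids)
    m
  }
  new_cohort(
    children,
    geno_child = stack("gc"), geno_mother = stack("gm"),
    geno_father = stack("gf"),
    loci = data.frame(locus_id = locus_ids,
                      effect_allele = "2", stringsAsFactors = FALSE),
    truth = list(model = model, specs = specs,
                 seg_contrib = unlist(lapply(per_pop, `[[`, "seg_contrib"),
                                      use.names = FALSE)),
    meta = list(children_per_family = children_per_family)
  )
}
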