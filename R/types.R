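#' Population specification
#'
#' Describes one population contributing families to a simulated cohort. Each
#' population inhabits a distinct environment, represented by a constant
#' deviation `env_effect_dev` added to the per-allele effect of every family
#' it contains (the population-level component of the family deviation
#' \eqn{\alpha_f}).
#'
#' @param label character scalar naming the population (e.g. `"red"`).
#' @param allele_freq frequency of the focal allele A2 in the population.
#'   A scalar for single-locus cohorts, or a vector (one entry per locus) for
#'   multi-locus / polygenic-score cohorts.
#' @param env_effect_dev per-allele effect deviation \eqn{\alpha_f} shared by
#'   all families in this population. Across populations these must average to
#'   zero under the family-count weights (checked at simulation time).
#' @param n_families number of families to simulate from this population.
#' @param inbreeding_f inbreeding coefficient F at the locus
#'   (heterozygote deficit). Realized as a two-deme Wahlund mixture at
#'   frequencies \eqn{p \pm \sqrt{F p q}}, which produces the genotype
#'   frequencies \eqn{p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq} in parents and the
#'   same F among offspring. Only supported for single-locus cohorts.
#'
#' @return An object of class `famhet_population`.
#' @export
population_spec <- function(label, allele_freq, env_effect_dev = 0,
                            n_families = 1L, inbreeding_f = 0) {
  stopifnot(is.character(label), length(label) == 1L)
  if (any(allele_freq < 0 | allele_freq > 1)) {
    stop("allele_freq must lie in [0, 1]", call. = FALSE)
  }
  if (length(env_effect_dev) != 1L || !is.finite(env_effect_dev)) {
    stop("env_effect_dev must be a finite scalar", call. = FALSE)
  }
  n_families <- as.integer(n_families)
  if (n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  if (inbreeding_f < 0 || inbreeding_f >= 1) {
    stop("inbreeding_f must lie in [0, 1)", call. = FALSE)
  }
  if (inbreeding_f > 0) {
    if (length(allele_freq) != 1L) {
      stop("inbreeding_f > 0 is only supported for single-locus cohorts",
           call. = FALSE)
    }
    d <- sqrt(inbreeding_f * allele_freq * (1 - allele_freq))
    if (allele_freq - d < 0 || allele_freq + d > 1) {
      stop("inbreeding_f too large for this allele frequency: ",
           "deme frequencies p +/- sqrt(F p q) fall outside [0, 1]",
           call. = FALSE)
    }
  }
  structure(
    list(label = label, allele_freq = allele_freq,
         env_effect_dev = env_effect_dev, n_families = n_families,
         inbreeding_f = inbreeding_f),
    class = "famhet_population"
  )
}

#' Single-locus effect model
#'
#' The generating model for a phenotype influenced by one bi-allelic locus,
#' \deqn{Y = Y^* + (\alpha + \alpha_f + \alpha_i)\,g + \epsilon_f + \epsilon_i,}
#' where g counts copies of the focal allele, \eqn{\alpha} is the mean
#' per-allele effect, \eqn{\alpha_f} and \eqn{\alpha_i} are mean-zero family-
#' and individual-specific effect deviations (gene-by-environment interaction),
#' and \eqn{\epsilon_f}, \eqn{\epsilon_i} are mean-zero family- and
#' individual-level environmental deviations of the trait itself.
#'
#' The realized \eqn{\alpha_f} of a family is the population's
#' `env_effect_dev` plus Gaussian noise with SD `sd_family_dev`.
#'
#' @param intercept trait intercept \eqn{Y^*}.
#' @param alpha mean per-allele effect of the focal allele.
#' @param sd_family_dev SD of extra mean-zero family-specific effect noise.
#' @param sd_indiv_dev SD of the individual-specific effect deviation.
#' @param sd_env_family SD of the family-level environmental deviation.
#' @param sd_env_indiv SD of the individual-level environmental deviation.
#'
#' @return An object of class `famhet_effect_model`.
#' @export
locus_effect_model <- function(intercept = 0, alpha = 1,
                               sd_family_dev = 0, sd_indiv_dev = 0,
                               sd_env_family = 0, sd_env_indiv = 0) {
  sds <- c(sd_family_dev, sd_indiv_dev, sd_env_family, sd_env_indiv)
  if (any(sds < 0)) stop("standard deviations must be nonnegative",
                         call. = FALSE)
  structure(
    list(intercept = intercept, alpha = alpha,
         sd_family_dev = sd_family_dev, sd_indiv_dev = sd_indiv_dev,
         sd_env_family = sd_env_family, sd_env_indiv = sd_env_indiv),
    class = "famhet_effect_model"
  )
}

#' Two-locus marker/causal haplotype model
#'
#' A genotyped marker locus (alleles M/m) that does not itself affect the
#' trait, in linkage disequilibrium with an ungenotyped causal locus
#' (alleles A/a) whose A allele adds `causal_alpha` to the trait per copy with
#' no gene-by-environment interaction. Haplotypes are ordered (MA, Ma, mA, ma)
#' and may have population-specific frequencies, so that both LD and marker
#' allele frequency can differ between populations.
#'
#' @param hap_freqs named list: one numeric vector of four haplotype
#'   frequencies (order MA, Ma, mA, ma; summing to 1) per population label.
#' @param recomb_fraction recombination fraction r between the loci, in
#'   \[0, 0.5\].
#' @param causal_alpha per-allele effect of causal allele A.
#' @param sd_env SD of an individual environmental deviation added to the
#'   phenotype (no G by E; default 0).
#'
#' @return An object of class `famhet_two_locus`.
#' @export
two_locus_model <- function(hap_freqs, recomb_fraction = 0,
                            causal_alpha = 1, sd_env = 0) {
  if (!is.list(hap_freqs) || is.null(names(hap_freqs)) ||
      any(names(hap_freqs) == "")) {
    stop("hap_freqs must be a named list (one vector per population)",
         call. = FALSE)
  }
  for (nm in names(hap_freqs)) {
    f <- hap_freqs[[nm]]
    if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stop("haplotype frequencies for population '", nm,
           "' must be 4 nonnegative values summing to 1", call. = FALSE)
    }
  }
  if (recomb_fraction < 0 || recomb_fraction > 0.5) {
    stop("recomb_fraction must lie in [0, 0.5]", call. = FALSE)
  }
  if (sd_env < 0) stop("sd_env must be nonnegative", call. = FALSE)
  hap_freqs <- lapply(hap_freqs, function(f) {
    names(f) <- c("MA", "Ma", "mA", "ma")
    f
  })
  structure(
    list(hap_freqs = hap_freqs, recomb_fraction = recomb_fraction,
         causal_alpha = causal_alpha, sd_env = sd_env),
    class = "famhet_two_locus"
  )
}

#' Polygenic score model
#'
#' Defines a set of causal loci L underlying a trait and a subset
#' \eqn{\Lambda \subseteq L} of genotyped loci carrying PGS weights
#' \eqn{\hat\beta_l}, so that an individual's score is
#' \eqn{PGS = \sum_{l \in \Lambda} \hat\beta_l g_l}. Loci are mutually
#' unlinked and in linkage equilibrium in the generator. Per-locus family
#' effect deviations \eqn{\alpha_{lf}} come either from population-level
#' offsets (one value per population and locus) or from a multiplicative
#' family factor, \eqn{\alpha_{lf} = C_f \alpha_l}, with \eqn{C_f} constant
#' within a population.
#'
#' @param alpha numeric vector of causal per-allele effects \eqn{\alpha_l},
#'   one per causal locus (defines L and its size).
#' @param beta_hat numeric vector of PGS weights \eqn{\hat\beta_l} for the
#'   loci in `pgs_loci`.
#' @param pgs_loci integer indices into the causal loci giving \eqn{\Lambda}
#'   (default: all causal loci).
#' @param freq default focal-allele frequencies, length 1 (recycled) or one
#'   per causal locus; a `population_spec` may override with its own vector.
#' @param family_dev one of:
#'   `NULL` (no G by E);
#'   `list(type = "offsets", offsets = M)` where `M` is a matrix with one row
#'   per population (rownames = population labels) and one column per causal
#'   locus, giving \eqn{\alpha_{lf}} for every family of that population;
#'   `list(type = "multiplicative", C = c(pop = value, ...))` giving the
#'   per-population multiplier \eqn{C_f}.
#' @param indiv_dev_sd SD of the individual-specific per-locus effect
#'   deviation \eqn{\alpha_{il}} (0 disables it).
#' @param intercept trait intercept \eqn{Y^*}.
#' @param sd_env_family,sd_env_indiv SDs of family-/individual-level
#'   environmental deviations of the trait.
#'
#' @return An object of class `famhet_pgs_model`.
#' @export
pgs_model <- function(alpha, beta_hat, pgs_loci = seq_along(alpha),
                      freq = 0.5, family_dev = NULL, indiv_dev_sd = 0,
                      intercept = 0, sd_env_family = 0, sd_env_indiv = 0) {
  n_causal <- length(alpha)
  pgs_loci <- as.integer(pgs_loci)
  if (any(pgs_loci < 1L) || any(pgs_loci > n_causal) ||
      anyDuplicated(pgs_loci)) {
    stop("pgs_loci must be distinct indices into the causal loci ",
         "(the PGS locus set must be a subset of the causal set)",
         call. = FALSE)
  }
  if (length(beta_hat) != length(pgs_loci)) {
    stop("beta_hat must have one weight per PGS locus", call. = FALSE)
  }
  if (length(freq) == 1L) freq <- rep(freq, n_causal)
  if (length(freq) != n_causal || any(freq < 0 | freq > 1)) {
    stop("freq must give one frequency in [0,1] per causal locus",
         call. = FALSE)
  }
  if (!is.null(family_dev)) {
    if (!is.list(family_dev) ||
        !family_dev$type %in% c("offsets", "multiplicative")) {
      stop("family_dev must be NULL or a list with type 'offsets' or ",
           "'multiplicative'", call. = FALSE)
    }
    if (family_dev$type == "offsets") {
      m <- family_dev$offsets
      if (!is.matrix(m) || ncol(m) != n_causal || is.null(rownames(m))) {
        stop("family_dev$offsets must be a matrix with rownames = population",
             " labels and one column per causal locus", call. = FALSE)
      }
    } else {
      if (is.null(names(family_dev$C))) {
        stop("family_dev$C must be named by population label", call. = FALSE)
      }
    }
  }
  if (indiv_dev_sd < 0 || sd_env_family < 0 || sd_env_indiv < 0) {
    stop("standard deviations must be nonnegative", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta_hat = beta_hat, pgs_loci = pgs_loci,
         freq = freq, family_dev = family_dev, indiv_dev_sd = indiv_dev_sd,
         intercept = intercept, sd_env_family = sd_env_family,
         sd_env_indiv = sd_env_indiv),
    class = "famhet_pgs_model"
  )
}

## Realized per-locus family effect deviations alpha_lf for every family of
## a given population, under the model's family_dev specification.
pgs_dev_row <- function(model, label) {
  fd <- model$family_dev
  n <- length(model$alpha)
  if (is.null(fd)) return(numeric(n))
  if (fd$type == "offsets") {
    if (!label %in% rownames(fd$offsets)) {
      stop("no family_dev offsets for population '", label, "'",
           call. = FALSE)
    }
    as.numeric(fd$offsets[label, ])
  } else {
    if (!label %in% names(fd$C)) {
      stop("no multiplier C for population '", label, "'", call. = FALSE)
    }
    fd$C[[label]] * model$alpha
  }
}

#' Heterozygosity at a locus
#'
#' @param p allele frequency.
#' @return `2 p (1 - p)`, the Hardy-Weinberg heterozygote frequency.
#' @export
heterozygosity <- function(p) 2 * p * (1 - p)
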