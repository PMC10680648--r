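## HC1 heteroskedasticity-robust standard error for one coefficient.
## G-by-E makes the regression error variance depend on genotype, so the
## classical OLS standard errors are not valid; HC1 is the usual fix.
hc1_se <- function(fit, term) {
  v <- sandwich::vcovHC(fit, type = "HC1")
  sqrt(v[term, term])
}

new_estimate <- function(estimator, slope, intercept = NA_real_,
                         parental_coef = NA_real_, stderr, n_used,
                         locus = NA) {
  structure(
    list(estimator = estimator, slope = slope, intercept = intercept,
         parental_coef = parental_coef, stderr = stderr,
         n_used = as.integer(n_used), locus = locus),
    class = "famhet_estimate"
  )
}

#' @export
print.famhet_estimate <- function(x, ...) {
  cat(sprintf("famhet estimate [%s]%s: slope = %.5f (HC1 SE %.5f), n = %d\n",
              x$estimator,
              if (is.na(x$locus)) "" else paste0(" locus ", x$locus),
              x$slope, x$stderr, x$n_used))
  if (!is.na(x$parental_coef)) {
    cat(sprintf("  parental coefficient gamma = %.5f\n", x$parental_coef))
  }
  invisible(x)
}

get_locus <- function(cohort, locus) {
  if (is.character(locus)) {
    locus <- match(locus, colnames(cohort$geno_child))
    if (is.na(locus)) stop("unknown locus id", call. = FALSE)
  }
  locus
}

#' Population-based association study at one locus
#'
#' OLS regression of child phenotype on child genotype (no parental
#' controls). Its slope mixes between-family and within-family genotype
#' variance and therefore reflects allelic effects in whichever environments
#' the allele happens to be found.
#'
#' @param cohort a `famhet_cohort`.
#' @param locus locus index or id (default first).
#' @return A `famhet_estimate` with HC1 robust standard error.
#' @export
population_gwas <- function(cohort, locus = 1L) {
  locus <- get_locus(cohort, locus)
  g <- cohort$geno_child[, locus]
  y <- cohort$children$phenotype
  keep <- !is.na(g)
  g <- g[keep]; y <- y[keep]
  if (length(g) < 2L || stats::var(g) == 0) {
    stop("locus is monomorphic in the cohort: population regression is ",
         "undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ g)
  new_estimate("population", slope = unname(stats::coef(fit)["g"]),
               intercept = unname(stats::coef(fit)[1]),
               stderr = hc1_se(fit, "g"), n_used = length(y), locus = locus)
}

#' Family-based (trio) association study at one locus
#'
#' OLS regression of child phenotype on child genotype controlling for the
#' parental genotypes. Only children of heterozygous parents carry
#' within-family genotype variation, so the slope estimates the average
#' allelic effect among those "complier" families (a local average treatment
#' effect), not the sample-wide average.
#'
#' @param cohort a `famhet_cohort`.
#' @param locus locus index or id.
#' @param parental `"separate"` controls mother and father genotypes as two
#'   regressors; `"sum"` controls their sum (the two are asymptotically
#'   equivalent here; separate controls additionally absorb parent-of-origin
#'   frequency differences).
#' @return A `famhet_estimate`; `parental_coef` is the coefficient on the
#'   parental sum when `parental = "sum"`.
#' @export
family_gwas <- function(cohort, locus = 1L,
                        parental = c("separate", "sum")) {
  parental <- match.arg(parental)
  locus <- get_locus(cohort, locus)
  g <- cohort$geno_child[, locus]
  gm <- cohort$geno_mother[, locus]
  gf <- cohort$geno_father[, locus]
  y <- cohort$children$phenotype
  keep <- !is.na(g) & !is.na(gm) & !is.na(gf)
  g <- g[keep]; gm <- gm[keep]; gf <- gf[keep]; y <- y[keep]
  if (!any(gm == 1L | gf == 1L)) {
    stop("no heterozygous parents at this locus: there is no within-family ",
         "genotype variance and the trio regression is rank-deficient",
         call. = FALSE)
  }
  if (parental == "separate") {
    fit <- stats::lm(y ~ g + gm + gf)
    gamma <- NA_real_
  } else {
    gpar <- gm + gf
    fit <- stats::lm(y ~ g + gpar)
    gamma <- unname(stats::coef(fit)["gpar"])
  }
  new_estimate("trio_family", slope = unname(stats::coef(fit)["g"]),
               intercept = unname(stats::coef(fit)[1]),
               parental_coef = gamma,
               stderr = hc1_se(fit, "g"), n_used = length(y), locus = locus)
}

#' Sibling-difference association study at one locus
#'
#' OLS regression (through the origin) of the within-pair phenotype
#' difference on the within-pair genotype difference, for cohorts with two
#' children per family. In expectation this equals the trio estimate: both
#' designs regress phenotypes on segregation deviations.
#'
#' @param cohort a `famhet_cohort` simulated with `children_per_family = 2`.
#' @param locus locus index or id.
#' @return A `famhet_estimate` (`n_used` = number of sib pairs).
#' @export
sib_difference <- function(cohort, locus = 1L) {
  if (is.null(cohort$meta$children_per_family) ||
      cohort$meta$children_per_family != 2L) {
    stop("sib_difference requires a cohort with two children per family",
         call. = FALSE)
  }
  locus <- get_locus(cohort, locus)
  ch <- cohort$children
  i1 <- which(ch$child_no == 1L)
  i2 <- which(ch$child_no == 2L)
  stopifnot(all(ch$family_id[i1] == ch$family_id[i2]))
  dg <- cohort$geno_child[i1, locus] - cohort$geno_child[i2, locus]
  dy <- ch$phenotype[i1] - ch$phenotype[i2]
  keep <- !is.na(dg)
  dg <- dg[keep]; dy <- dy[keep]
  if (all(dg == 0)) {
    stop("all sibling pairs are genotypically identical at this locus: ",
         "the sibling-difference regression is degenerate", call. = FALSE)
  }
  fit <- stats::lm(dy ~ dg + 0)
  new_estimate("sib_difference", slope = unname(stats::coef(fit)["dg"]),
               stderr = hc1_se(fit, "dg"), n_used = length(dy),
               locus = locus)
}

#' Compute child and parental polygenic scores for a cohort
#'
#' @param cohort a `famhet_cohort`.
#' @param pgs a [pgs_model()] whose locus indices refer to the cohort's
#'   genotype columns; defaults to the model the cohort was simulated from.
#' @return data frame with `pgs`, `pgs_mother`, `pgs_father` and the
#'   structural PGS segregation deviation `seg_pgs`.
#' @export
compute_pgs <- function(cohort, pgs = NULL) {
  if (is.null(pgs)) {
    if (!is.null(cohort$children$pgs)) {
      return(cohort$children[, c("pgs", "pgs_mother", "pgs_father",
                                 "seg_pgs")])
    }
    pgs <- cohort$truth$model
  }
  stopifnot(inherits(pgs, "famhet_pgs_model"))
  lam <- pgs$pgs_loci
  bh <- pgs$beta_hat
  sc <- function(m) as.numeric(m[, lam, drop = FALSE] %*% bh)
  p_c <- sc(cohort$geno_child)
  p_m <- sc(cohort$geno_mother)
  p_f <- sc(cohort$geno_father)
  data.frame(pgs = p_c, pgs_mother = p_m, pgs_father = p_f,
             seg_pgs = p_c - (p_m + p_f) / 2)
}

#' Regression of phenotype on the segregation deviation
#'
#' Regresses child phenotype on the segregation deviation of a locus or of
#' the PGS. With the structural deviation (child minus midparent) this is the
#' quantity the family designs estimate in expectation; with
#' `mode = "residual"` the deviation is instead the finite-sample OLS
#' residual of the child PGS (or genotype) on the parental sum, in which case
#' the slope equals the corresponding family regression's child coefficient
#' exactly, by the Frisch-Waugh-Lovell theorem.
#'
#' @param cohort a `famhet_cohort`.
#' @param locus locus index/id, or `"pgs"` to use the polygenic score.
#' @param pgs a [pgs_model()] when `locus = "pgs"` (optional if the cohort
#'   was simulated with one).
#' @param mode `"structural"` or `"residual"`.
#' @return A `famhet_estimate`.
#' @export
seg_regression <- function(cohort, locus = 1L, pgs = NULL,
                           mode = c("structural", "residual")) {
  mode <- match.arg(mode)
  y <- cohort$children$phenotype
  if (identical(locus, "pgs")) {
    sc <- compute_pgs(cohort, pgs)
    child <- sc$pgs
    parsum <- sc$pgs_mother + sc$pgs_father
    s <- sc$seg_pgs
    locus_lab <- "pgs"
  } else {
    locus <- get_locus(cohort, locus)
    child <- cohort$geno_child[, locus]
    parsum <- cohort$geno_mother[, locus] + cohort$geno_father[, locus]
    s <- child - parsum / 2
    locus_lab <- locus
  }
  keep <- !is.na(child) & !is.na(parsum)
  child <- child[keep]; parsum <- parsum[keep]
  s <- s[keep]; y <- y[keep]
  if (mode == "residual") {
    s <- stats::resid(stats::lm(child ~ parsum))
  }
  if (all(abs(s) < 1e-12)) {
    stop("segregation deviations are all zero: regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ s)
  new_estimate("seg_regression", slope = unname(stats::coef(fit)["s"]),
               intercept = unname(stats::coef(fit)[1]),
               stderr = hc1_se(fit, "s"), n_used = length(y),
               locus = locus_lab)
}

#' Family-based PGS regression
#'
#' OLS of child phenotype on the child PGS controlling for the parental PGS
#' sum (the standard within-family PGS design), or for the two parental PGSs
#' separately.
#'
#' @param cohort a `famhet_cohort`.
#' @param pgs optional [pgs_model()] (defaults to the cohort's own).
#' @param parental `"sum"` (default) or `"separate"`.
#' @return A `famhet_estimate`: `slope` is the child-PGS coefficient
#'   \eqn{\hat\delta_{fam}}, `parental_coef` the coefficient \eqn{\gamma} on
#'   the parental sum.
#' @export
family_pgs <- function(cohort, pgs = NULL, parental = c("sum", "separate")) {
  parental <- match.arg(parental)
  sc <- compute_pgs(cohort, pgs)
  y <- cohort$children$phenotype
  if (all(abs(sc$seg_pgs) < 1e-12)) {
    stop("child PGS is collinear with the midparent PGS (no within-family ",
         "PGS variance): family PGS regression is rank-deficient",
         call. = FALSE)
  }
  p <- sc$pgs
  if (parental == "sum") {
    parsum <- sc$pgs_mother + sc$pgs_father
    fit <- stats::lm(y ~ p + parsum)
    gamma <- unname(stats::coef(fit)["parsum"])
  } else {
    pm <- sc$pgs_mother
    pf <- sc$pgs_father
    fit <- stats::lm(y ~ p + pm + pf)
    gamma <- NA_real_
  }
  new_estimate("family_pgs", slope = unname(stats::coef(fit)["p"]),
               intercept = unname(stats::coef(fit)[1]),
               parental_coef = gamma,
               stderr = hc1_se(fit, "p"), n_used = length(y), locus = "pgs")
}

#' Population-based PGS regression with within/between decomposition
#'
#' OLS of child phenotype on child PGS alone. Because
#' `PGS = midparent + seg deviation` exactly, the slope decomposes exactly
#' (in the sample) into a between-family term,
#' `cov(Y, midparent)/var(PGS)`, and a within-family term,
#' `cov(Y, seg)/var(PGS)` — the latter equal to `(V_seg/V_PGS)` times the
#' structural segregation-regression slope.
#'
#' @param cohort a `famhet_cohort`.
#' @param pgs optional [pgs_model()].
#' @return A `famhet_estimate` with an extra `decomposition` element:
#'   `between_term`, `within_term`, `v_seg`, `v_pgs`, `seg_slope`.
#' @export
population_pgs <- function(cohort, pgs = NULL) {
  sc <- compute_pgs(cohort, pgs)
  y <- cohort$children$phenotype
  if (stats::var(sc$pgs) == 0) {
    stop("PGS has zero variance in the cohort", call. = FALSE)
  }
  p <- sc$pgs
  fit <- stats::lm(y ~ p)
  mid <- (sc$pgs_mother + sc$pgs_father) / 2
  v_pgs <- stats::var(p)
  v_seg <- stats::var(sc$seg_pgs)
  between <- stats::cov(y, mid) / v_pgs
  within <- stats::cov(y, sc$seg_pgs) / v_pgs
  est <- new_estimate("population_pgs",
                      slope = unname(stats::coef(fit)["p"]),
                      intercept = unname(stats::coef(fit)[1]),
                      stderr = hc1_se(fit, "p"), n_used = length(y),
                      locus = "pgs")
  est$decomposition <- list(
    between_term = between, within_term = within,
    v_seg = v_seg, v_pgs = v_pgs,
    seg_slope = stats::cov(y, sc$seg_pgs) / v_seg)
  est
}

#' Variance decomposition of the PGS and its phenotypic contribution
#'
#' Sample-moment decomposition of the PGS variance into between-family
#' (midparent) and within-family (segregation) components, and the fractions
#' of phenotypic variance attributed to the PGS: `seg_explained`
#' (\eqn{\hat\delta_{fam}^2 V_\varsigma / V_P}, the internally valid
#' within-family contribution from Mendelian segregation) and
#' `full_extrapolated` (\eqn{\hat\delta_{fam}^2 V_{PGS} / V_P}, which
#' extrapolates the within-family slope to the between-family variance).
#'
#' @param cohort a `famhet_cohort`.
#' @param pgs optional [pgs_model()].
#' @param family_slope \eqn{\hat\delta_{fam}}, normally from [family_pgs()];
#'   computed from the cohort when missing.
#' @return An object of class `famhet_vardecomp` with fields `v_pgs`,
#'   `v_between`, `v_seg`, `v_pheno`, `seg_explained`, `full_extrapolated`,
#'   `family_slope`.
#' @export
pgs_variance_decomposition <- function(cohort, pgs = NULL,
                                       family_slope = NULL) {
  sc <- compute_pgs(cohort, pgs)
  y <- cohort$children$phenotype
  v_p <- stats::var(y)
  if (v_p == 0) stop("phenotypic variance is zero", call. = FALSE)
  if (is.null(family_slope)) family_slope <- family_pgs(cohort, pgs)$slope
  mid <- (sc$pgs_mother + sc$pgs_father) / 2
  out <- list(
    v_pgs = stats::var(sc$pgs),
    v_between = stats::var(mid),
    v_seg = stats::var(sc$seg_pgs),
    v_pheno = v_p,
    seg_explained = family_slope^2 * stats::var(sc$seg_pgs) / v_p,
    full_extrapolated = family_slope^2 * stats::var(sc$pgs) / v_p,
    family_slope = family_slope
  )
  structure(out, class = "famhet_vardecomp")
}

#' @export
print.famhet_vardecomp <- function(x, ...) {
  cat("PGS variance decomposition:\n")
  cat(sprintf("  V_PGS = %.5f = V_between (%.5f) + V_seg (%.5f) [+ cov]\n",
              x$v_pgs, x$v_between, x$v_seg))
  cat(sprintf("  V_seg / V_PGS = %.4f\n", x$v_seg / x$v_pgs))
  cat(sprintf("  phenotypic variance explained: within-family %.4f, ",
              x$seg_explained))
  cat(sprintf("extrapolated %.4f\n", x$full_extrapolated))
  invisible(x)
}
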