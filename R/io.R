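## number formatting that survives a text round-trip exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a cohort as PED/FAM-style whitespace-delimited files
#'
#' Writes a minimal trio-oriented dialect: `<prefix>.fam` with columns
#' (family_id, individual_id, father_id, mother_id, sex = 0, phenotype;
#' parental phenotypes are recorded as -9 = missing), and `<prefix>.geno`
#' with (family_id, individual_id) followed by two allele columns per locus,
#' alleles coded 1/2 with 2 the focal (effect) allele and 0 reserved for
#' missing. When the cohort carries simulation truth, a sidecar
#' `<prefix>.truth.tsv` records each child's population label and realized
#' family effect deviation — simulation truth for oracle use only, never an
#' input to the estimators. Output is deterministic: equal cohorts produce
#' byte-identical files.
#'
#' @param cohort a `famhet_cohort`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_ped <- function(cohort, prefix) {
  ch <- cohort$children
  ord <- order(ch$family_id, ch$child_no)
  ch <- ch[ord, , drop = FALSE]
  gc <- cohort$geno_child[ord, , drop = FALSE]
  gm <- cohort$geno_mother[ord, , drop = FALSE]
  gf <- cohort$geno_father[ord, , drop = FALSE]
  fam_first <- !duplicated(ch$family_id)

  fam_id <- ch$family_id
  mid <- sprintf("F%d_M", fam_id)
  fid <- sprintf("F%d_F", fam_id)
  cid <- sprintf("F%d_C%d", fam_id, ch$child_no)

  fam_lines <- c(
    sprintf("%d %s 0 0 0 -9", fam_id[fam_first], mid[fam_first]),
    sprintf("%d %s 0 0 0 -9", fam_id[fam_first], fid[fam_first]),
    sprintf("%d %s %s %s 0 %s", fam_id, cid, fid, mid,
            fmt_num(ch$phenotype)))
  ## order: per family, mother then father then children
  key <- c(fam_id[fam_first] * 100 + 1, fam_id[fam_first] * 100 + 2,
           fam_id * 100 + 2 + ch$child_no)
  fam_lines <- fam_lines[order(key)]

  geno_str <- function(gmat) {
    apply(gmat, 1, function(g) {
      paste(unlist(lapply(g, function(x) {
        if (is.na(x)) c("0", "0") else c(rep("1", 2 - x), rep("2", x))
      })), collapse = " ")
    })
  }
  geno_lines <- c(
    sprintf("%d %s %s", fam_id[fam_first], mid[fam_first],
            geno_str(gm[fam_first, , drop = FALSE])),
    sprintf("%d %s %s", fam_id[fam_first], fid[fam_first],
            geno_str(gf[fam_first, , drop = FALSE])),
    sprintf("%d %s %s", fam_id, cid, geno_str(gc)))
  geno_lines <- geno_lines[order(key)]

  fam_path <- paste0(prefix, ".fam")
  geno_path <- paste0(prefix, ".geno")
  writeLines(fam_lines, fam_path)
  writeLines(geno_lines, geno_path)
  paths <- c(fam_path, geno_path)

  if (!is.null(ch$alpha_f)) {
    truth_path <- paste0(prefix, ".truth.tsv")
    tl <- c("family_id\tindividual_id\tpopulation\talpha_f",
            sprintf("%d\t%s\t%s\t%s", fam_id, cid, ch$population,
                    fmt_num(ch$alpha_f)))
    writeLines(tl, truth_path)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

split_ws <- function(lines, path) {
  toks <- strsplit(trimws(lines), "[ \t]+")
  toks <- toks[lengths(toks) > 0]
  n <- lengths(toks)
  if (any(n != n[1])) {
    bad <- which(n != n[1])[1]
    stop("malformed line ", bad, " in ", path, ": expected ",
         n[1], " fields, found ", n[bad], call. = FALSE)
  }
  toks
}

#' Read a trio cohort from PED/FAM-style files
#'
#' Reassembles trios by parent-ID linkage from the dialect written by
#' [write_ped()]. Children lacking a genotyped mother or father are excluded
#' (with a warning giving the count). Genotypes are converted to counts of
#' the declared effect allele per locus; a missing genotype (allele code 0)
#' in any member of a trio marks that trio's genotype as missing at that
#' locus, and the estimators drop such trios locus-wise.
#'
#' @param fam_path path to the `.fam` file.
#' @param geno_path path to the genotype file.
#' @param truth_path optional path to the truth sidecar (population labels
#'   and realized effect deviations).
#' @param effect_allele the allele counted as the focal allele, `"2"` by
#'   default; a vector (one per locus) flips the coding locus-wise.
#' @return a `famhet_cohort`.
#' @export
read_ped <- function(fam_path, geno_path, truth_path = NULL,
                     effect_allele = "2") {
  fam <- split_ws(readLines(fam_path), fam_path)
  if (any(lengths(fam) != 6L)) {
    stop("malformed line ", which(lengths(fam) != 6L)[1], " in ", fam_path,
         ": expected 6 fields", call. = FALSE)
  }
  fam <- data.frame(
    family_id = vapply(fam, `[`, "", 1), id = vapply(fam, `[`, "", 2),
    father = vapply(fam, `[`, "", 3), mother = vapply(fam, `[`, "", 4),
    phenotype = as.numeric(vapply(fam, `[`, "", 6)),
    stringsAsFactors = FALSE)

  geno <- split_ws(readLines(geno_path), geno_path)
  n_fields <- lengths(geno)
  if (any((n_fields - 2L) %% 2L != 0L)) {
    stop("malformed genotype file ", geno_path,
         ": odd number of allele columns", call. = FALSE)
  }
  n_loci <- (n_fields[1] - 2L) %/% 2L
  ids <- vapply(geno, `[`, "", 2)
  if (length(effect_allele) == 1L) {
    effect_allele <- rep(effect_allele, n_loci)
  }
  stopifnot(length(effect_allele) == n_loci)
  gmat <- matrix(NA_integer_, nrow = length(geno), ncol = n_loci)
  for (l in seq_len(n_loci)) {
    a1 <- vapply(geno, `[`, "", 2L + 2L * l - 1L)
    a2 <- vapply(geno, `[`, "", 2L + 2L * l)
    miss <- a1 == "0" | a2 == "0"
    g <- (a1 == effect_allele[l]) + (a2 == effect_allele[l])
    g[miss] <- NA_integer_
    gmat[, l] <- g
  }
  rownames(gmat) <- ids

  is_child <- fam$father != "0" & fam$mother != "0"
  kids <- fam[is_child, , drop = FALSE]
  ok <- kids$father %in% ids & kids$mother %in% ids & kids$id %in% ids
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    warning(n_excluded, " child(ren) excluded: parent or own genotype ",
            "record missing", call. = FALSE)
  }
  kids <- kids[ok, , drop = FALSE]
  if (nrow(kids) == 0L) stop("no complete trios found", call. = FALSE)

  fam_int <- suppressWarnings(as.integer(kids$family_id))
  if (any(is.na(fam_int))) fam_int <- as.integer(factor(kids$family_id))
  ord <- order(fam_int, kids$id)
  kids <- kids[ord, , drop = FALSE]
  fam_int <- fam_int[ord]
  child_no <- stats::ave(fam_int, fam_int, FUN = seq_along)

  children <- data.frame(
    family_id = fam_int, child_no = as.integer(child_no),
    population = "unknown", phenotype = kids$phenotype,
    stringsAsFactors = FALSE)
  truth <- NULL
  if (!is.null(truth_path)) {
    tr <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
    m <- match(kids$id, tr$individual_id)
    children$population <- tr$population[m]
    children$alpha_f <- tr$alpha_f[m]
    truth <- list(sidecar = tr)
  }
  locus_ids <- sprintf("L%d", seq_len(n_loci))
  take <- function(id_vec) {
    m <- gmat[id_vec, , drop = FALSE]
    dimnames(m) <- list(NULL, locus_ids)
    m
  }
  new_cohort(
    children,
    geno_child = take(kids$id), geno_mother = take(kids$mother),
    geno_father = take(kids$father),
    loci = data.frame(locus_id = locus_ids, effect_allele = effect_allele,
                      stringsAsFactors = FALSE),
    truth = truth,
    meta = list(children_per_family = max(child_no),
                n_excluded = n_excluded)
  )
}

config_fields <- list(
  top = c("seed", "populations", "effect_model", "parental_control",
          "out_prefix", "verbosity"),
  population = c("label", "allele_freq", "env_effect_dev", "n_families",
                 "inbreeding_f"),
  effect_model = c("intercept", "alpha", "sd_family_dev", "sd_indiv_dev",
                   "sd_env_family", "sd_env_indiv")
)

#' Run configuration
#'
#' Bundles everything a simulation-plus-estimation run depends on, so that a
#' run is fully reproducible from its config and seed.
#'
#' @param seed integer seed for all randomness.
#' @param populations list of [population_spec()] objects.
#' @param effect_model a [locus_effect_model()].
#' @param parental_control `"separate"` or `"sum"` (see [family_gwas()]).
#' @param out_prefix output path prefix for [write_ped()].
#' @param verbosity 0 (quiet) or 1.
#' @return an object of class `famhet_config`.
#' @export
run_config <- function(seed, populations, effect_model,
                       parental_control = "separate", out_prefix = "famhet",
                       verbosity = 0L) {
  populations <- validate_specs(populations)
  stopifnot(inherits(effect_model, "famhet_effect_model"),
            parental_control %in% c("separate", "sum"))
  structure(
    list(seed = as.integer(seed), populations = populations,
         effect_model = effect_model,
         parental_control = parental_control,
         out_prefix = out_prefix, verbosity = as.integer(verbosity)),
    class = "famhet_config"
  )
}

#' Write a run configuration to JSON
#' @param config a [run_config()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "famhet_config"))
  obj <- list(
    seed = config$seed,
    populations = lapply(config$populations, function(s) {
      list(label = s$label, allele_freq = s$allele_freq,
           env_effect_dev = s$env_effect_dev, n_families = s$n_families,
           inbreeding_f = s$inbreeding_f)
    }),
    effect_model = unclass(config$effect_model),
    parental_control = config$parental_control,
    out_prefix = config$out_prefix,
    verbosity = config$verbosity
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' Strict: unknown keys anywhere in the file are rejected, so typos cannot
#' silently fall back to defaults. Round-trips losslessly with
#' [write_run_config()].
#'
#' @param path JSON path.
#' @return a `famhet_config`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(obj, config_fields$top, "config")
  pops <- lapply(obj$populations, function(p) {
    check_keys(p, config_fields$population, "population spec")
    population_spec(p$label, unlist(p$allele_freq),
                    p$env_effect_dev %||% 0,
                    p$n_families %||% 1L, p$inbreeding_f %||% 0)
  })
  em <- obj$effect_model %||% list()
  check_keys(em, config_fields$effect_model, "effect model")
  model <- do.call(locus_effect_model, em)
  run_config(obj$seed %||% 1L, pops, model,
             obj$parental_control %||% "separate",
             obj$out_prefix %||% "famhet",
             obj$verbosity %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
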