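#' Simulation configuration for a synthetic genotype-phenotype cohort
#'
#' Collects every generative parameter of the synthetic cohort: genotype
#' dimensions and allele-frequency range, missingness, ancestry strata,
#' genotyping platforms and an optional platform batch artefact, the
#' scoring-file writing quirks (allele swaps, strand complements), and the
#' logistic outcome model (per-SD log-odds for each component score plus
#' covariate effects).  All randomness derives from `seed` via named,
#' deterministic child seeds.
#'
#' @param n_individuals,n_variants cohort dimensions (both >= 1).
#' @param n_traits number of component scores; defaults to the nine-trait
#'   set returned by [meta_traits()]`("all")`.
#' @param trait_names labels for the component traits.
#' @param maf_range minor-allele-frequency range, both ends in (0, 0.5].
#' @param missing_rate per-entry probability of a missing dosage.
#' @param dosage_noise_sd SD of Gaussian noise added to integer allele
#'   counts (imputation-like uncertainty); result clipped to `[0, 2]`.
#' @param ambiguous_fraction fraction of variants written with a
#'   strand-ambiguous (A/T or C/G) allele pair.
#' @param n_ancestries,ancestry_fst number of ancestry strata and the
#'   Balding-Nichols divergence of per-stratum allele frequencies
#'   (`ancestry_fst = 0` collapses to a single panmictic population).
#' @param n_platforms number of genotyping platforms (samples split
#'   uniformly at random).
#' @param batch_variant_fraction fraction of variants given a platform
#'   batch artefact by [inject_platform_batch_effect()].
#' @param batch_freq_shift allele-frequency shift applied to batch-affected
#'   variants on the last platform.
#' @param score_variant_fraction fraction of panel variants carrying a
#'   weight in each scoring file.
#' @param swap_fraction fraction of scoring records written in the
#'   opposite allele orientation (effect/other exchanged, weight negated
#'   so the underlying score is unchanged up to a constant).
#' @param flip_fraction fraction of non-ambiguous scoring records written
#'   on the opposite strand (both alleles complemented).
#' @param trait_effects named or unnamed vector of per-1-SD log-odds for
#'   each component score in the outcome model.
#' @param covariate_effects named log-odds per unit for
#'   `age, age2, sex, bmi, sbp, smoking, statin, art` (continuous
#'   covariates are centered before entering the linear predictor).
#' @param intercept baseline log-odds of the outcome.
#' @param seed master seed.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_variants = 50, seed = 1)
sim_config <- function(n_individuals,
                       n_variants,
                       n_traits = 9L,
                       trait_names = NULL,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       dosage_noise_sd = 0.05,
                       ambiguous_fraction = 0.1,
                       n_ancestries = 2L,
                       ancestry_fst = 0.05,
                       n_platforms = 2L,
                       batch_variant_fraction = 0,
                       batch_freq_shift = 0.2,
                       score_variant_fraction = 0.5,
                       swap_fraction = 0.1,
                       flip_fraction = 0.1,
                       trait_effects = NULL,
                       covariate_effects = NULL,
                       intercept = qlogis(0.2),
                       seed = 1L) {
  if (n_variants < 1) stop("invalid config: n_variants must be >= 1")
  if (n_individuals < 1) stop("invalid config: n_individuals must be >= 1")
  if (n_traits < 1) stop("invalid config: n_traits must be >= 1")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("invalid config: maf_range must lie in (0, 0.5]")
  for (p in c(missing_rate, ambiguous_fraction, batch_variant_fraction,
              score_variant_fraction, swap_fraction, flip_fraction))
    if (p < 0 || p > 1) stop("invalid config: proportions must be in [0, 1]")
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 9L) meta_traits("all")
                   else paste0("trait", seq_len(n_traits))
  }
  stopifnot(length(trait_names) == n_traits)
  if (is.null(trait_effects)) trait_effects <- rep(0, n_traits)
  stopifnot(length(trait_effects) == n_traits)
  trait_effects <- setNames(as.numeric(trait_effects), trait_names)
  cov_default <- c(age = 0, age2 = 0, sex = 0, bmi = 0, sbp = 0,
                   smoking = 0, statin = 0, art = 0)
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), names(cov_default))
    if (length(bad)) stop("unknown covariate effect(s): ", paste(bad, collapse = ", "))
    cov_default[names(covariate_effects)] <- covariate_effects
  }
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_traits = as.integer(n_traits),
    trait_names = trait_names,
    maf_range = maf_range,
    missing_rate = missing_rate,
    dosage_noise_sd = dosage_noise_sd,
    ambiguous_fraction = ambiguous_fraction,
    n_ancestries = as.integer(n_ancestries),
    ancestry_fst = ancestry_fst,
    n_platforms = as.integer(n_platforms),
    batch_variant_fraction = batch_variant_fraction,
    batch_freq_shift = batch_freq_shift,
    score_variant_fraction = score_variant_fraction,
    swap_fraction = swap_fraction,
    flip_fraction = flip_fraction,
    trait_effects = trait_effects,
    covariate_effects = cov_default,
    intercept = intercept,
    seed = as.integer(seed))
  cfg$stage_seeds <- derive_seeds(seed,
    c("genotypes", "scoring", "covariates", "phenotype", "platform", "batch"))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_individuals, "individuals x", x$n_variants,
      "variants,", x$n_traits, "traits, seed", x$seed, "\n")
  invisible(x)
}

new_dosage_matrix <- function(dosages, variants, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("S%05d", seq_len(nrow(dosages)))
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "individuals x", ncol(x$dosages),
      "variants;", sum(is.na(x$dosages)), "missing entries\n")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

## subset a dosage_matrix by sample and/or variant index
subset_dosages <- function(dm, samples = NULL, variants = NULL) {
  i <- samples %||% seq_len(nrow(dm$dosages))
  j <- variants %||% seq_len(ncol(dm$dosages))
  new_dosage_matrix(dm$dosages[i, j, drop = FALSE],
                    dm$variants[j, , drop = FALSE],
                    dm$samples[i])
}

## alt-allele frequency per variant from non-missing dosages
alt_freq <- function(dm) colMeans(dm$dosages, na.rm = TRUE) / 2

.non_ambiguous_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))

#' Simulate imputed genotype dosages
#'
#' Draws per-variant alt-allele frequencies uniformly from
#' `config$maf_range`, then per-individual dosages as binomial(2, p)
#' allele counts plus clipped Gaussian noise emulating imputation
#' uncertainty.  With more than one ancestry stratum, stratum-specific
#' frequencies follow a Balding-Nichols model around the shared ancestral
#' frequency.  Variants are independent (no linkage disequilibrium).
#' Missing entries (`NA`) are flagged at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a `dosage_matrix`: list with the numeric `dosages` matrix
#'   (individuals x variants, `NA` = missing), a `variants` metadata
#'   data frame (id, chrom, pos, ref, alt) and `samples`.  The ancestry
#'   stratum of each sample is stored in `attr(, "ancestry")`, the
#'   per-stratum allele frequencies in `attr(, "true_freq")`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$stage_seeds[["genotypes"]])
  n <- config$n_individuals; m <- config$n_variants
  p_anc <- runif(m, config$maf_range[1], config$maf_range[2])

  ancestry <- sample.int(config$n_ancestries, n, replace = TRUE)
  fst <- config$ancestry_fst
  ## per-stratum frequencies: Balding-Nichols Beta(p(1-F)/F, (1-p)(1-F)/F)
  p_strat <- matrix(p_anc, nrow = config$n_ancestries, ncol = m, byrow = TRUE)
  if (config$n_ancestries > 1 && fst > 0) {
    for (s in seq_len(config$n_ancestries)) {
      p_strat[s, ] <- rbeta(m, p_anc * (1 - fst) / fst,
                               (1 - p_anc) * (1 - fst) / fst)
      p_strat[s, ] <- pmin(pmax(p_strat[s, ], 1e-4), 1 - 1e-4)
    }
  }
  D <- matrix(rbinom(n * m, 2L, p_strat[ancestry, ]), nrow = n, ncol = m)
  D <- D + 0
  if (config$dosage_noise_sd > 0)
    D <- pmin(pmax(D + rnorm(n * m, 0, config$dosage_noise_sd), 0), 2)
  if (config$missing_rate > 0)
    D[runif(n * m) < config$missing_rate] <- NA_real_

  n_amb <- round(config$ambiguous_fraction * m)
  amb <- rep(FALSE, m)
  if (n_amb > 0) amb[sample.int(m, n_amb)] <- TRUE
  ref <- alt <- character(m)
  amb_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  k_amb <- sample.int(4, m, replace = TRUE)
  k_non <- sample.int(nrow(.non_ambiguous_pairs), m, replace = TRUE)
  ref <- ifelse(amb, amb_pairs[k_amb, 1], .non_ambiguous_pairs[k_non, 1])
  alt <- ifelse(amb, amb_pairs[k_amb, 2], .non_ambiguous_pairs[k_non, 2])
  variants <- data.frame(
    id = sprintf("var%06d", seq_len(m)),
    chrom = as.character(rep_len(1:22, m)),
    pos = seq_len(m) * 1000L,
    ref = ref, alt = alt,
    stringsAsFactors = FALSE)
  dm <- new_dosage_matrix(D, variants)
  attr(dm, "ancestry") <- ancestry
  attr(dm, "true_freq") <- p_strat
  dm
}

#' Simulate scoring files for the component traits
#'
#' Each trait receives a sparse weight vector over a random subset of the
#' panel variants, with weights drawn from a zero-mean normal.  To
#' exercise allele harmonization, a configurable fraction of records is
#' written in the opposite allele orientation (effect/other exchanged and
#' the weight negated, which preserves the underlying score up to an
#' additive constant) and a configurable fraction of non-ambiguous
#' records is written on the opposite strand (alleles complemented,
#' weight unchanged).
#'
#' @param config a [sim_config()].
#' @param dosages the panel `dosage_matrix` the files are written against.
#' @return list of `scoring_file` objects, one per trait; each carries
#'   attributes `truth` (data frame: panel variant index, alt-allele
#'   weight, swapped/flipped flags) used by [simulate_phenotype()].
#' @export
simulate_scoring_files <- function(config, dosages) {
  stopifnot(inherits(config, "sim_config"), inherits(dosages, "dosage_matrix"))
  set.seed(config$stage_seeds[["scoring"]])
  v <- dosages$variants
  m <- nrow(v)
  ambig <- is_ambiguous_pair(v$ref, v$alt)
  lapply(seq_len(config$n_traits), function(k) {
    nk <- max(1L, round(config$score_variant_fraction * m))
    idx <- sort(sample.int(m, nk))
    w_alt <- rnorm(nk, 0, 1)
    swapped <- runif(nk) < config$swap_fraction
    flipped <- runif(nk) < config$flip_fraction & !ambig[idx]
    eff <- ifelse(swapped, v$ref[idx], v$alt[idx])
    oth <- ifelse(swapped, v$alt[idx], v$ref[idx])
    eff <- ifelse(flipped, comp_allele(eff), eff)
    oth <- ifelse(flipped, comp_allele(oth), oth)
    w_file <- ifelse(swapped, -w_alt, w_alt)
    rec <- data.frame(
      rsID = v$id[idx], chr_name = v$chrom[idx], chr_position = v$pos[idx],
      effect_allele = eff, other_allele = oth, effect_weight = w_file,
      stringsAsFactors = FALSE)
    sf <- new_scoring_file(config$trait_names[k], rec)
    attr(sf, "truth") <- data.frame(variant = idx, w_alt = w_alt,
                                    swapped = swapped, flipped = flipped)
    sf
  })
}

## true (generative) component scores on the alt-dosage scale,
## standardized in-sample; missing dosages mean-imputed by 2*p-hat
true_component_scores <- function(dosages, scoring_files) {
  D <- dosages$dosages
  p <- alt_freq(dosages)
  for (j in seq_len(ncol(D))) {
    miss <- is.na(D[, j])
    if (any(miss)) D[miss, j] <- 2 * p[j]
  }
  Z <- sapply(scoring_files, function(sf) {
    tr <- attr(sf, "truth")
    as.numeric(D[, tr$variant, drop = FALSE] %*% tr$w_alt)
  })
  colnames(Z) <- vapply(scoring_files, function(sf) sf$trait_name, "")
  scale(Z)[, , drop = FALSE]
}

#' Simulate baseline covariates and platform labels
#'
#' Covariate distributions are chosen to resemble a mixed HIV/seronegative
#' adult cohort: age ~ N(50, 10) years, BMI ~ N(28, 5) kg/m^2,
#' SBP ~ N(127, 15) mmHg, 60% male, 25% current smokers, 45% statin use,
#' 90% ART exposure.  Samples are assigned uniformly at random to
#' `n_platforms` genotyping platforms.
#'
#' @param config a [sim_config()].
#' @return data frame with columns sample, age, sex, bmi, sbp, smoking,
#'   statin, art, platform.
#' @export
simulate_covariates <- function(config) {
  set.seed(config$stage_seeds[["covariates"]])
  n <- config$n_individuals
  out <- data.frame(
    sample = sprintf("S%05d", seq_len(n)),
    age = rnorm(n, 50, 10),
    sex = rbinom(n, 1L, 0.6),
    bmi = rnorm(n, 28, 5),
    sbp = rnorm(n, 127, 15),
    smoking = rbinom(n, 1L, 0.25),
    statin = rbinom(n, 1L, 0.45),
    art = rbinom(n, 1L, 0.90),
    stringsAsFactors = FALSE)
  set.seed(config$stage_seeds[["platform"]])
  out$platform <- paste0("P", sample.int(config$n_platforms, n, replace = TRUE))
  out
}

#' Simulate the binary outcome from a logistic model
#'
#' The linear predictor is
#' `alpha + sum_k gamma_k * Z_k + covariate terms`, where `Z_k` are the
#' true component scores standardized in-sample (so `gamma_k` is a
#' per-1-SD log-odds) and continuous covariates are centered (age at 50,
#' BMI at 28, SBP at 127; the `age2` effect applies to centered age
#' squared).  The outcome is Bernoulli with the stage seed.
#'
#' @param Z matrix of standardized true component scores
#'   (from [true_component_scores()] internals; columns named by trait).
#' @param covariates data frame from [simulate_covariates()].
#' @param config a [sim_config()].
#' @return integer 0/1 vector of length `n_individuals`.
#' @export
simulate_phenotype <- function(Z, covariates, config) {
  stopifnot(nrow(Z) == config$n_individuals,
            nrow(covariates) == config$n_individuals)
  g <- config$trait_effects
  ce <- config$covariate_effects
  age_c <- covariates$age - 50
  lp <- config$intercept +
    as.numeric(Z[, names(g), drop = FALSE] %*% g) +
    ce[["age"]] * age_c + ce[["age2"]] * age_c^2 +
    ce[["sex"]] * covariates$sex +
    ce[["bmi"]] * (covariates$bmi - 28) +
    ce[["sbp"]] * (covariates$sbp - 127) +
    ce[["smoking"]] * covariates$smoking +
    ce[["statin"]] * covariates$statin +
    ce[["art"]] * covariates$art
  if (any(!is.finite(lp))) stop("non-finite linear predictor in outcome model")
  set.seed(config$stage_seeds[["phenotype"]])
  rbinom(length(lp), 1L, plogis(lp))
}

#' Inject a platform batch artefact into dosages
#'
#' For a `batch_variant_fraction` of variants (chosen at the batch stage
#' seed), the allele frequency on the *last* platform is shifted by
#' `batch_freq_shift`: dosages of affected samples are redrawn as
#' binomial(2, p + shift) counts (frequency clipped to `[0.01, 0.99]`).
#' This creates the platform-frequency artefact that
#' [platform_harmonize()] is designed to remove.
#'
#' @param dosages a `dosage_matrix`.
#' @param platform character/factor vector of platform labels per sample.
#' @param config a [sim_config()].
#' @return the modified `dosage_matrix`; indices of affected variants in
#'   `attr(, "batch_variants")`.
#' @export
inject_platform_batch_effect <- function(dosages, platform, config) {
  stopifnot(inherits(dosages, "dosage_matrix"),
            length(platform) == nrow(dosages$dosages))
  m <- ncol(dosages$dosages)
  n_aff <- round(config$batch_variant_fraction * m)
  if (n_aff == 0) {
    attr(dosages, "batch_variants") <- integer(0)
    return(dosages)
  }
  set.seed(config$stage_seeds[["batch"]])
  aff <- sort(sample.int(m, n_aff))
  last <- sort(unique(as.character(platform)))
  target <- platform == last[length(last)]
  p <- alt_freq(dosages)
  for (j in aff) {
    pj <- min(max(p[j] + config$batch_freq_shift, 0.01), 0.99)
    keep_na <- is.na(dosages$dosages[target, j])
    newd <- rbinom(sum(target), 2L, pj) + 0
    newd[keep_na] <- NA_real_
    dosages$dosages[target, j] <- newd
  }
  attr(dosages, "batch_variants") <- aff
  dosages
}

#' Generate a complete synthetic cohort
#'
#' Runs genotype, scoring-file, covariate and outcome simulation in a
#' fixed stage order and finally injects the platform batch artefact
#' (after the outcome is drawn, so the artefact is purely technical).
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_cohort`: `dosages`,
#'   `scoring_files`, `covariates` (incl. platform and outcome columns),
#'   `outcome`, `platform`, and `truth` (the config plus the true
#'   standardized scores and batch-affected variant indices).
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(300, 80, seed = 7))
#' table(coh$outcome)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dosages <- simulate_genotypes(config)
  scoring_files <- simulate_scoring_files(config, dosages)
  covariates <- simulate_covariates(config)
  Z_true <- true_component_scores(dosages, scoring_files)
  outcome <- simulate_phenotype(Z_true, covariates, config)
  dosages <- inject_platform_batch_effect(dosages, covariates$platform, config)
  covariates$ancestry <- paste0("A", attr(dosages, "ancestry"))
  covariates$outcome <- outcome
  structure(list(
    dosages = dosages,
    scoring_files = scoring_files,
    covariates = covariates,
    outcome = outcome,
    platform = covariates$platform,
    truth = list(config = config, Z_true = Z_true,
                 batch_variants = attr(dosages, "batch_variants"))),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$outcome), "individuals,",
      ncol(x$dosages$dosages), "variants,", length(x$scoring_files),
      "scoring files; prevalence", round(mean(x$outcome), 3), "\n")
  invisible(x)
}
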