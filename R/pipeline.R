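#' 70/30 cohort split
#'
#' Simple random (optionally outcome-stratified) split of sample indices
#' into training and validation sets; the training size is
#' `round(fraction * n)`.
#'
#' @param n number of samples, or a vector of ids.
#' @param fraction training fraction in (0, 1); default 0.70.
#' @param seed split seed.
#' @param stratify optional binary vector; if given, the split is drawn
#'   within each outcome class.
#' @return list with `training` and `validation` (indices or ids).
#' @export
#' @examples
#' split_cohort(10, 0.7, seed = 1)
split_cohort <- function(n, fraction = 0.70, seed = 1L, stratify = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ids <- if (length(n) == 1 && is.numeric(n)) seq_len(n) else n
  set.seed(seed)
  if (is.null(stratify)) {
    tr <- sort(sample(seq_along(ids), round(fraction * length(ids))))
  } else {
    stopifnot(length(stratify) == length(ids))
    tr <- sort(unlist(lapply(unique(stratify), function(cl) {
      idx <- which(stratify == cl)
      sample(idx, round(fraction * length(idx)))
    })))
  }
  list(training = ids[tr], validation = ids[-tr])
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the synthetic cohort (the
#'   pipeline can alternatively start from files via `paths`).
#' @param paths optional named list (`dosages`, `covariates`,
#'   `scoring_dir`) to load a cohort from disk instead of simulating.
#' @param qc_preset QC preset name for [qc_thresholds()].
#' @param enet an [enet_config()].
#' @param split_fraction training fraction (default 0.70).
#' @param split_seed,eval_seed seeds for the cohort split and the NRI
#'   bootstrap.
#' @param n_boot NRI bootstrap replicates.
#' @param n_pcs number of principal components.
#' @param out_dir output directory for artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            qc_preset = "cnics",
                            enet = enet_config(),
                            split_fraction = 0.70,
                            split_seed = 1L, eval_seed = 1L,
                            n_boot = 1000L, n_pcs = 10L,
                            out_dir = tempfile("metaprs_run_")) {
  if (is.null(sim) && is.null(paths))
    stop("either a simulation config or input paths are required")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  structure(list(sim = sim, paths = paths, qc_preset = qc_preset,
                 enet = enet, split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 eval_seed = as.integer(eval_seed),
                 n_boot = as.integer(n_boot), n_pcs = as.integer(n_pcs),
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path, digits = 10) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Run the end-to-end metaPRS pipeline on a synthetic cohort
#'
#' Orchestrates the full study design: simulate (or load) the cohort,
#' variant and sample QC, principal components, cross-platform
#' harmonization, component-score computation, a seeded 70/30 split,
#' elastic-net fitting of the meta-inflammation and meta-lipids weights
#' on the training set, application of the frozen models to the
#' validation set (component scores re-standardized in-cohort),
#' per-quintile and per-SD association models, the five-model battery
#' and the discrimination report.  Training rows never enter any
#' evaluation table.  Every artifact directory is stamped with the
#' serialized configuration, its md5 hash, and all seeds.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: the run directory, QC
#'   reports, fitted models, association tables (`table2`), the
#'   discrimination report (`table3`), split ids, and the log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  t0 <- Sys.time()
  stage <- function(msg) {
    line <- sprintf("[%7.2fs] %s", as.numeric(Sys.time() - t0, units = "secs"), msg)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(name, expr) {
    stage(paste("start", name))
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage(paste("done ", name))
    out
  }

  ## ---- inputs ----
  cohort <- run_stage("input", {
    if (!is.null(config$sim)) simulate_cohort(config$sim)
    else {
      dm <- if (grepl("\\.vcf$", config$paths$dosages))
        read_vcf_dosage(config$paths$dosages)
      else read_dosage_tsv(config$paths$dosages)
      cov <- data.table::fread(config$paths$covariates, data.table = FALSE)
      sfs <- lapply(list.files(config$paths$scoring_dir,
                               pattern = "^scoring_.*\\.txt$",
                               full.names = TRUE), parse_scoring_file)
      structure(list(dosages = dm, scoring_files = sfs, covariates = cov,
                     outcome = cov$outcome, platform = cov$platform,
                     truth = NULL), class = "synthetic_cohort")
    }
  })

  th <- qc_thresholds(config$qc_preset, n_pcs = config$n_pcs)

  ## ---- QC ----
  vqc <- run_stage("variant_qc", variant_qc(cohort$dosages, th))
  sqc <- run_stage("sample_qc", sample_qc(vqc$dosages, th))
  keep_samples <- match(sqc$dosages$samples, cohort$covariates$sample)
  covariates <- cohort$covariates[keep_samples, , drop = FALSE]
  outcome <- cohort$outcome[keep_samples]
  pcs <- run_stage("pcs", compute_pcs(sqc$dosages, config$n_pcs))
  harm <- run_stage("platform_harmonize",
    platform_harmonize(sqc$dosages, covariates$platform, pcs,
                       th$platform_p_remove))
  panel <- harm$dosages
  write_tsv(vqc$report, file.path(config$out_dir, "qc_variants.tsv"))
  write_tsv(sqc$report, file.path(config$out_dir, "qc_samples.tsv"))
  write_tsv(harm$report, file.path(config$out_dir, "qc_platform.tsv"))

  ## ---- component scores ----
  raw <- run_stage("score", compute_component_scores(panel, cohort$scoring_files))

  ## ---- split ----
  split <- run_stage("split",
    split_cohort(nrow(raw), config$split_fraction, config$split_seed))
  tr <- split$training; va <- split$validation

  ## ---- train metaPRS (frozen thereafter) ----
  covdf <- data.frame(age = covariates$age - mean(covariates$age),
                      sex = covariates$sex)
  covdf$age2 <- covdf$age^2
  Xadj <- cbind(as.matrix(covdf[c("age", "age2", "sex")]), pcs)
  Z_tr <- standardize_scores(raw[tr, , drop = FALSE])
  models <- run_stage("train_meta", {
    lapply(c(inflammation = "inflammation", lipids = "lipids"), function(pr) {
      fit_component_weights(Z_tr[, meta_traits(pr), drop = FALSE],
                            outcome[tr], Xadj[tr, , drop = FALSE],
                            config$enet)
    })
  })
  write_metaprs_model(models$inflammation,
                      file.path(config$out_dir, "model_inflammation.json"))
  write_metaprs_model(models$lipids,
                      file.path(config$out_dir, "model_lipids.json"))

  ## ---- apply frozen models to validation cohort ----
  Z_va <- standardize_scores(raw[va, , drop = FALSE])
  scores_va <- list(
    "T2D-PRS" = as.numeric(Z_va[, "T2D"]),
    "meta-inflammation" = apply_metaprs(Z_va, models$inflammation),
    "meta-lipids" = apply_metaprs(Z_va, models$lipids))

  ## ---- association models (Table-2 style) ----
  adj_va <- data.frame(age = covariates$age[va] - mean(covariates$age[va]),
                       sex = covariates$sex[va])
  adj_va$age2 <- adj_va$age^2
  adj_va <- cbind(adj_va, as.data.frame(pcs[va, , drop = FALSE]))
  adj_va$platform <- factor(covariates$platform[va])
  if (nlevels(adj_va$platform) < 2) adj_va$platform <- NULL
  table2 <- run_stage("associate", {
    do.call(rbind, lapply(names(scores_va), function(nm) {
      qr_ <- fit_or_model(outcome[va], scores_va[[nm]], adj_va, "quintile")
      sd_ <- fit_or_model(outcome[va], scores_va[[nm]], adj_va, "per_sd")
      out <- rbind(as.data.frame(qr_), as.data.frame(sd_))
      cbind(score = nm, out)
    }))
  })
  write_tsv(table2, file.path(config$out_dir, "table2_validation.tsv"))

  ## ---- model battery + discrimination (Table-3 style) ----
  batt_df <- data.frame(outcome = outcome[va],
                        age = covariates$age[va],
                        sex = covariates$sex[va],
                        bmi = covariates$bmi[va],
                        sbp = covariates$sbp[va],
                        smoking = covariates$smoking[va],
                        statin = covariates$statin[va],
                        art = covariates$art[va],
                        platform = factor(covariates$platform[va]))
  batt_df <- cbind(batt_df, as.data.frame(pcs[va, , drop = FALSE]))
  variant <- if (nlevels(batt_df$platform) < 2) "regards" else "cnics"
  battery <- run_stage("battery",
    run_model_battery(batt_df, scores_va,
                      model_specs(config$n_pcs, variant)))
  report <- run_stage("evaluate",
    build_report(battery, n_boot = config$n_boot, seed = config$eval_seed))
  write_tsv(report$table, file.path(config$out_dir, "table3_validation.tsv"))
  jsonlite::write_json(
    list(table = report$table, delong_p = report$delong_p, n = report$n),
    file.path(config$out_dir, "table3_validation.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## ---- provenance ----
  cfg_out <- list(
    qc_preset = config$qc_preset, split_fraction = config$split_fraction,
    split_seed = config$split_seed, eval_seed = config$eval_seed,
    n_boot = config$n_boot, n_pcs = config$n_pcs,
    enet = unclass(config$enet),
    sim = if (!is.null(config$sim)) {
      s <- unclass(config$sim)
      s$stage_seeds <- as.list(s$stage_seeds)
      s$trait_effects <- as.list(s$trait_effects)
      s$covariate_effects <- as.list(s$covariate_effects)
      s
    })
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(cfg_out, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stage(paste("config md5", cfg_hash))
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))

  structure(list(out_dir = config$out_dir,
                 qc = list(variants = vqc$report, samples = sqc$report,
                           platform = harm$report),
                 models = models,
                 scores_validation = scores_va,
                 table2 = table2, report = report,
                 split = split, config_hash = cfg_hash,
                 log = log_lines),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result in", x$out_dir, "\n")
  cat("  training n =", length(x$split$training),
      "; validation n =", length(x$split$validation), "\n")
  print(x$report)
  invisible(x)
}
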