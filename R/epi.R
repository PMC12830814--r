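#' Quintile bins of a score
#'
#' Cut points are the in-cohort 20/40/60/80 percentiles (type-7,
#' linear-interpolation quantiles); values exactly equal to a cut point
#' fall in the lower bin, so an all-tied block straddling a cut point is
#' assigned as a whole to the lower bin.
#'
#' @param x numeric score vector (at least 5 distinct values).
#' @return integer bins 1..5; cut points in `attr(, "cuts")`.
#' @export
#' @examples
#' quintile_bin(1:10)
quintile_bin <- function(x) {
  if (length(unique(x[!is.na(x)])) < 5)
    stop("quintile_bin requires at least 5 distinct values")
  cuts <- quantile(x, c(0.2, 0.4, 0.6, 0.8), na.rm = TRUE, names = FALSE)
  bins <- rowSums(outer(x, cuts, ">")) + 1L
  bins[is.na(x)] <- NA_integer_
  structure(as.integer(bins), cuts = cuts)
}

## extract OR table from a fitted glm for selected terms
or_table <- function(fit, terms, n) {
  sm <- summary(fit)$coefficients
  keep <- intersect(terms, rownames(sm))
  data.frame(term = keep,
             or = exp(sm[keep, 1]),
             ci_low = exp(sm[keep, 1] - 1.96 * sm[keep, 2]),
             ci_high = exp(sm[keep, 1] + 1.96 * sm[keep, 2]),
             p = sm[keep, 4],
             n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

check_fit <- function(fit, label = "model") {
  if (!fit$converged) stop(label, ": logistic fit did not converge")
  sm <- summary(fit)$coefficients
  bad <- rownames(sm)[!is.finite(sm[, 2]) | sm[, 2] > 100 | abs(sm[, 1]) > 15]
  if (length(bad))
    stop(label, ": separation or unstable estimate for term(s) ",
         paste(bad, collapse = ", "))
  if (any(is.na(coef(fit))))
    stop(label, ": rank-deficient design (aliased term(s) ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "), ")")
  invisible(fit)
}

#' Logistic odds-ratio model for a score
#'
#' Maximum-likelihood logistic regression of the outcome on the score
#' (coded per-SD, or as quintile indicators with the middle quintile Q3
#' as reference) plus covariates.  Returns Wald odds ratios with 95%
#' confidence intervals `exp(coef +/- 1.96 SE)`.
#'
#' @param outcome binary 0/1 vector.
#' @param score numeric score vector.
#' @param covariates optional data frame / matrix of adjustment columns.
#' @param coding `"per_sd"` (score standardized to unit SD in-cohort
#'   unless `standardize = FALSE`) or `"quintile"`.
#' @param standardize for per-SD coding, standardize the score in-cohort
#'   first (default TRUE).
#' @return data frame of effect estimates (class `effect_estimates`):
#'   term, or, ci_low, ci_high, p, n.  For quintile coding the reference
#'   row Q3 is included with OR 1.  The fitted glm is in `attr(, "fit")`.
#' @export
fit_or_model <- function(outcome, score, covariates = NULL,
                         coding = c("per_sd", "quintile"),
                         standardize = TRUE) {
  coding <- match.arg(coding)
  df <- data.frame(.y = as.integer(outcome))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  if (length(unique(df$.y)) < 2) stop("both outcome classes required")
  if (coding == "per_sd") {
    df$.score <- if (standardize) as.numeric(scale(score)) else score
    fit <- glm(.y ~ ., data = df, family = binomial())
    check_fit(fit, "per-SD model")
    out <- or_table(fit, ".score", nrow(df))
    out$term <- "per_sd"
  } else {
    q <- quintile_bin(score)
    df$.q <- factor(paste0("Q", q), levels = paste0("Q", c(3, 1, 2, 4, 5)))
    fit <- glm(.y ~ ., data = df, family = binomial())
    check_fit(fit, "quintile model")
    out <- or_table(fit, paste0(".qQ", c(1, 2, 4, 5)), nrow(df))
    out$term <- sub("^\\.q", "", out$term)
    ref <- data.frame(term = "Q3", or = 1, ci_low = NA, ci_high = NA,
                      p = NA, n = nrow(df))
    out <- rbind(out[out$term %in% c("Q1", "Q2"), ], ref,
                 out[out$term %in% c("Q4", "Q5"), ])
    rownames(out) <- NULL
  }
  class(out) <- c("effect_estimates", class(out))
  attr(out, "fit") <- fit
  out
}

#' Specifications of the five nested prediction models
#'
#' Model 1 (base): age, age squared, sex, principal components, and
#' genotyping platform.  Model 2 (clinical): Model 1 plus ART use,
#' statin use, BMI, SBP and current smoking.  Models 3-5: Model 2 plus,
#' respectively, the single-trait T2D score, the meta-inflammation score,
#' and the meta-lipids score (each per SD).  The `"regards"` variant
#' drops the genotyping-platform, ART and statin terms.
#'
#' @param n_pcs number of principal-component covariates.
#' @param variant `"cnics"` (full covariate set) or `"regards"`.
#' @return list of five `model_spec` lists (id, label, covariates, score).
#' @export
model_specs <- function(n_pcs = 10L, variant = c("cnics", "regards")) {
  variant <- match.arg(variant)
  pcs <- paste0("PC", seq_len(n_pcs))
  base <- c("age", "age2", "sex", pcs)
  clin <- c("bmi", "sbp", "smoking")
  if (variant == "cnics") {
    base <- c(base, "platform")
    clin <- c("art", "statin", clin)
  }
  scores <- c(NA, NA, "T2D-PRS", "meta-inflammation", "meta-lipids")
  labels <- c("Model 1", "Model 2", "Model 3", "Model 4", "Model 5")
  lapply(1:5, function(i) {
    covs <- if (i == 1) base else c(base, clin)
    structure(list(id = i, label = labels[i], covariates = covs,
                   score = scores[i]), class = "model_spec")
  })
}

#' Fit the nested model battery
#'
#' Fits all model specifications by maximum likelihood on the identical
#' complete-case rows, and returns the fits together with per-model
#' linear predictors and fitted risks for downstream discrimination
#' statistics.
#'
#' @param data data frame containing the outcome column `outcome` and
#'   every covariate named in the specs (age is centered and `age2`
#'   derived internally if absent).
#' @param scores named list/data frame of score vectors keyed by the
#'   spec score labels (e.g. `"T2D-PRS"`, `"meta-inflammation"`,
#'   `"meta-lipids"`), each standardized per SD in-cohort.
#' @param specs list from [model_specs()].
#' @return object of class `model_battery`: per model the fitted glm,
#'   linear predictor, fitted risk, log-likelihood, plus the shared
#'   outcome vector and row index used.
#' @export
run_model_battery <- function(data, scores, specs = model_specs()) {
  data <- as.data.frame(data)
  if (!"outcome" %in% names(data)) stop("data must contain an 'outcome' column")
  if (!"age2" %in% names(data) && "age" %in% names(data)) {
    age_c <- data$age - mean(data$age, na.rm = TRUE)
    data$age <- age_c
    data$age2 <- age_c^2
  }
  score_names <- unique(stats::na.omit(vapply(specs, `[[`, "", "score")))
  for (sn in score_names) {
    if (is.null(scores[[sn]])) stop("missing score vector: ", sn)
    data[[paste0("score_", make.names(sn))]] <- as.numeric(scale(scores[[sn]]))
  }
  needed <- unique(c("outcome", unlist(lapply(specs, `[[`, "covariates")),
                     paste0("score_", make.names(score_names))))
  miss_cols <- setdiff(needed, names(data))
  if (length(miss_cols)) stop("missing covariate column(s): ",
                              paste(miss_cols, collapse = ", "))
  cc <- complete.cases(data[, needed, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  fits <- lapply(specs, function(sp) {
    vars <- sp$covariates
    if (!is.na(sp$score)) vars <- c(vars, paste0("score_", make.names(sp$score)))
    fml <- stats::reformulate(vars, response = "outcome")
    fit <- tryCatch(glm(fml, data = data, family = binomial()),
                    error = function(e)
                      stop(sp$label, " failed: ", conditionMessage(e)))
    check_fit(fit, sp$label)
    fit
  })
  structure(list(
    specs = specs,
    fits = fits,
    lp = lapply(fits, function(f) unname(f$linear.predictors)),
    risk = lapply(fits, function(f) unname(f$fitted.values)),
    loglik = vapply(fits, function(f) as.numeric(logLik(f)), numeric(1)),
    outcome = data$outcome,
    rows = which(cc)),
    class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat("model_battery:", length(x$fits), "models on", length(x$outcome),
      "complete cases\n")
  invisible(x)
}
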