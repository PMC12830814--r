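#' Elastic-net configuration for metaPRS weight fitting
#'
#' @param alpha_grid elastic-net mixing parameters to search (each in
#'   `[0, 1]`; default `{0.1, 0.25, 0.5, 0.75, 1}`; 0 = pure ridge is
#'   accepted for diagnostic fits).
#' @param nlambda length of the penalty path per mixing value.
#' @param n_folds cross-validation folds (default 10).
#' @param fold_seed seed for the (outcome-stratified) fold assignment,
#'   drawn once per fit.
#' @return object of class `enet_config`.
#' @export
enet_config <- function(alpha_grid = c(0.1, 0.25, 0.5, 0.75, 1),
                        nlambda = 100L, n_folds = 10L, fold_seed = 1L) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0 & alpha_grid <= 1),
            n_folds >= 2)
  structure(list(alpha_grid = alpha_grid, nlambda = as.integer(nlambda),
                 n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed)),
            class = "enet_config")
}

## outcome-stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit component-score weights by penalized logistic regression
#'
#' Fits elastic-net logistic regression of the binary outcome on the
#' standardized component scores, with covariates (e.g. age, age squared,
#' sex, principal components) included *unpenalized* as confounder
#' adjustments.  The (mixing, penalty) grid point with the highest mean
#' cross-validated AUC is selected; folds are drawn once from
#' `config$fold_seed`, stratified by outcome.  All trait coefficients are
#' reported, including exact zeros.
#'
#' @param Z standardized score matrix (individuals x traits, columns
#'   named by trait), e.g. from [standardize_scores()].
#' @param outcome binary 0/1 vector.
#' @param covariates optional numeric matrix/data frame of unpenalized
#'   adjustment columns.
#' @param config an [enet_config()].
#' @return object of class `metaprs_model`: `traits`, `beta` (named
#'   per-trait log-odds weights), `alpha`, `lambda`, `cv_auc`,
#'   `standardization` (provenance of Z), `covariate_names`.
#' @export
fit_component_weights <- function(Z, outcome, covariates = NULL,
                                  config = enet_config()) {
  Z <- as.matrix(Z)
  if (anyNA(Z) || anyNA(outcome)) stop("missing values not allowed in fit")
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) stop("degenerate outcome: single class")
  traits <- colnames(Z)
  if (is.null(traits)) stop("Z must have trait column names")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X <- if (is.null(C)) Z else cbind(Z, C)
  pf <- c(rep(1, ncol(Z)), rep(0, if (is.null(C)) 0 else ncol(C)))
  foldid <- stratified_folds(y, config$n_folds, config$fold_seed)
  if (any(tabulate(foldid[y == 1], config$n_folds) == 0) ||
      any(tabulate(foldid[y == 0], config$n_folds) == 0))
    stop("both outcome classes must be present in every fold")
  best <- NULL
  for (a in config$alpha_grid) {
    cvf <- glmnet::cv.glmnet(X, y, family = "binomial",
                             type.measure = "auc", alpha = a,
                             nlambda = config$nlambda, foldid = foldid,
                             penalty.factor = pf, standardize = FALSE)
    i <- which.max(cvf$cvm)
    if (is.null(best) || cvf$cvm[i] > best$cv_auc) {
      cf <- as.numeric(coef(cvf$glmnet.fit, s = cvf$lambda[i]))
      if (any(!is.finite(cf)))
        stop("non-converged elastic-net fit at selected grid point (alpha=",
             a, ", lambda=", signif(cvf$lambda[i], 4), ")")
      best <- list(alpha = a, lambda = cvf$lambda[i], cv_auc = cvf$cvm[i],
                   coefs = setNames(cf, c("(Intercept)", colnames(X))))
    }
  }
  structure(list(
    traits = traits,
    beta = best$coefs[traits],
    alpha = best$alpha,
    lambda = best$lambda,
    cv_auc = best$cv_auc,
    intercept = unname(best$coefs[1]),
    covariate_names = if (is.null(C)) character(0) else colnames(C),
    covariate_beta = if (is.null(C)) numeric(0) else best$coefs[colnames(C)],
    standardization = attr(Z, "provenance") %||% "unknown",
    n = length(y), n_folds = config$n_folds,
    fold_seed = config$fold_seed),
    class = "metaprs_model")
}

#' @export
print.metaprs_model <- function(x, ...) {
  cat("metaprs_model (", length(x$traits), " traits; alpha=", x$alpha,
      ", lambda=", signif(x$lambda, 3), ", CV-AUC=", round(x$cv_auc, 4),
      ")\n", sep = "")
  print(round(x$beta, 4))
  invisible(x)
}

## shared by build/apply: weighted average of standardized columns
meta_weighted_average <- function(Z, model) {
  Z <- as.matrix(Z)
  if (!all(model$traits %in% colnames(Z)))
    stop("missing trait column(s): ",
         paste(setdiff(model$traits, colnames(Z)), collapse = ", "))
  b <- model$beta[model$traits]
  if (all(b == 0)) stop("all component weights are zero")
  s <- sum(b)
  if (s == 0) stop("weighted average undefined: component weights sum to zero")
  if (s < 0) stop("component weights sum to a negative value; ",
                  "refusing to build a sign-flipped meta-score")
  as.numeric(Z[, model$traits, drop = FALSE] %*% b) / s
}

#' Build the meta-score on the fitting cohort
#'
#' The meta-score is the weighted average of the standardized component
#' scores, the weights being the fitted per-trait log-odds:
#' `PRS_meta_i = sum_k beta_k Z_ik / sum_k beta_k`.
#'
#' @param Z standardized score matrix containing the model's traits.
#' @param model a `metaprs_model`.
#' @return numeric meta-score vector.
#' @export
build_metaprs <- function(Z, model) {
  stopifnot(inherits(model, "metaprs_model"))
  meta_weighted_average(Z, model)
}

#' Apply a frozen meta-score model to a new cohort
#'
#' Identical formula to [build_metaprs()] with the weights held fixed
#' (no refitting); trait columns are matched by label, so column order is
#' irrelevant.
#'
#' @param Z standardized score matrix for the new cohort.
#' @param model a frozen `metaprs_model`.
#' @return numeric meta-score vector; standardization provenance of the
#'   input is recorded in `attr(, "standardization")`.
#' @export
apply_metaprs <- function(Z, model) {
  stopifnot(inherits(model, "metaprs_model"))
  out <- meta_weighted_average(Z, model)
  attr(out, "standardization") <- attr(Z, "provenance") %||% "unknown"
  out
}

#' Serialize / restore a metaPRS model as JSON
#'
#' @param model a `metaprs_model`.
#' @param path output path.
#' @return `read_metaprs_model` returns the restored `metaprs_model`.
#' @export
write_metaprs_model <- function(model, path) {
  stopifnot(inherits(model, "metaprs_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metaprs_model
#' @export
read_metaprs_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$traits <- as.character(x$traits)
  x$beta <- setNames(as.numeric(x$beta), x$traits)
  if (length(x$covariate_beta))
    x$covariate_beta <- setNames(as.numeric(x$covariate_beta),
                                 x$covariate_names)
  class(x) <- "metaprs_model"
  x
}
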