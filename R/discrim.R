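## Placement values (structural components) for the Mann-Whitney AUC.
## V10[i]: for case i, the proportion of controls it outranks (ties 1/2);
## V01[j]: for control j, the proportion of cases outranking it.
placement_values <- function(pred, outcome) {
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) stop("both outcome classes required")
  cases <- pred[y == 1]; ctrls <- pred[y == 0]
  m <- length(cases); n <- length(ctrls)
  ## midranks give O((m+n) log(m+n)) placement values
  r_all <- rank(c(cases, ctrls), ties.method = "average")
  r_cases <- rank(cases, ties.method = "average")
  r_ctrls <- rank(ctrls, ties.method = "average")
  V10 <- (r_all[seq_len(m)] - r_cases) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - r_ctrls) / m
  list(V10 = V10, V01 = V01, m = m, n = n)
}

#' AUC with DeLong standard error
#'
#' Area under the ROC curve by Mann-Whitney placement (ties count 1/2)
#' with variance from DeLong's structural-components method:
#' `var(V10)/m + var(V01)/n`.  The Wald 95% interval is on the AUC scale,
#' clipped to `[0, 1]`.
#'
#' @param pred numeric predictions (any monotone risk scale).
#' @param outcome binary 0/1 vector.
#' @return list of class `roc_result`: auc, se, ci (length 2), n_events,
#'   n_nonevents.
#' @export
#' @examples
#' auc_delong(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc
auc_delong <- function(pred, outcome) {
  pv <- placement_values(pred, outcome)
  a <- mean(pv$V10)
  se <- sqrt(var(pv$V10) / pv$m + var(pv$V01) / pv$n)
  if (is.na(se)) se <- 0   # single case or control
  ci <- pmin(pmax(a + c(-1.96, 1.96) * se, 0), 1)
  structure(list(auc = a, se = se, ci = ci,
                 n_events = pv$m, n_nonevents = pv$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f-%.4f), %d events / %d nonevents\n",
              x$auc, x$ci[1], x$ci[2], x$n_events, x$n_nonevents))
  invisible(x)
}

#' DeLong test for two correlated ROC curves
#'
#' Paired comparison of the AUCs of two prediction vectors on the same
#' individuals: `z = (AUC_A - AUC_B)/SE_diff`, where `SE_diff` uses the
#' DeLong covariance of the placement-value vectors,
#' `var(V10A - V10B)/m + var(V01A - V01B)/n`; two-sided normal p-value.
#' If `SE_diff = 0` with equal AUCs (e.g. identical predictions) the
#' degenerate result `p = 1` is returned.
#'
#' @param pred_a,pred_b prediction vectors on identical rows.
#' @param outcome binary 0/1 vector.
#' @return list: auc_a, auc_b, diff, se, z, p.
#' @export
delong_test <- function(pred_a, pred_b, outcome) {
  stopifnot(length(pred_a) == length(pred_b))
  pa <- placement_values(pred_a, outcome)
  pb <- placement_values(pred_b, outcome)
  auc_a <- mean(pa$V10); auc_b <- mean(pb$V10)
  se <- sqrt(var(pa$V10 - pb$V10) / pa$m + var(pa$V01 - pb$V01) / pa$n)
  d <- auc_a - auc_b
  if (!is.finite(se) || se == 0) {
    if (isTRUE(all.equal(auc_a, auc_b)))
      return(list(auc_a = auc_a, auc_b = auc_b, diff = 0, se = 0,
                  z = 0, p = 1))
    stop("zero DeLong variance with unequal AUCs")
  }
  z <- d / se
  list(auc_a = auc_a, auc_b = auc_b, diff = d, se = se, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2, `1 - exp((2/n)(L0 - L1))`, rescaled by its maximum
#' `1 - exp((2/n) L0)` so that a saturated binary model reaches 1.
#'
#' @param loglik_null,loglik_full log-likelihoods of the null
#'   (intercept-only) and fitted model.
#' @param n number of observations.
#' @return R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  if (n < 1) stop("n must be >= 1")
  if (loglik_full < loglik_null - 1e-8)
    stop("loglik_full must be >= loglik_null")
  cs <- 1 - exp((2 / n) * (loglik_null - loglik_full))
  maxcs <- 1 - exp((2 / n) * loglik_null)
  if (maxcs <= 0) return(0)
  min(max(cs / maxcs, 0), 1)
}

## population (no-CI) continuous NRI from per-subject movement signs
nri_point <- function(risk_old, risk_new, outcome) {
  s <- sign(risk_new - risk_old)
  ev <- outcome == 1
  event_comp <- mean(s[ev])          # P(up|ev) - P(down|ev)
  nonevent_comp <- -mean(s[!ev])     # P(down|ne) - P(up|ne)
  c(event = event_comp, nonevent = nonevent_comp)
}

#' Continuous (category-free) net reclassification improvement
#'
#' `NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#' P(up|nonevent)]`, where up/down are strict increases/decreases of the
#' predicted risk from the old to the new model; exact ties contribute to
#' neither direction.  The confidence interval is a seeded percentile
#' bootstrap over individuals.
#'
#' @param risk_old,risk_new predicted risks in `[0, 1]` on the same rows.
#' @param outcome binary 0/1 vector.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return list of class `nri_result`: nri, event_component,
#'   nonevent_component, ci, n_boot, seed.
#' @export
continuous_nri <- function(risk_old, risk_new, outcome, n_boot = 1000L,
                           seed = 1L) {
  stopifnot(length(risk_old) == length(risk_new),
            length(risk_old) == length(outcome))
  if (any(risk_old < 0 | risk_old > 1 | risk_new < 0 | risk_new > 1))
    stop("risks must be in [0, 1]")
  y <- as.integer(outcome)
  if (!any(y == 1) || !any(y == 0)) stop("both outcome classes required")
  comp <- nri_point(risk_old, risk_new, y)
  est <- sum(comp)
  s <- sign(risk_new - risk_old)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(y), replace = TRUE)
    yb <- y[idx]; sb <- s[idx]
    if (!any(yb == 1) || !any(yb == 0)) return(NA_real_)
    mean(sb[yb == 1]) - mean(sb[yb == 0])
  }, numeric(1))
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(nri = est, event_component = unname(comp["event"]),
                 nonevent_component = unname(comp["nonevent"]),
                 ci = ci, n_boot = n_boot, seed = seed),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("continuous NRI %.4f (95%% CI %.4f-%.4f; events %.4f, nonevents %.4f)\n",
              x$nri, x$ci[1], x$ci[2], x$event_component, x$nonevent_component))
  invisible(x)
}

#' Assemble the discrimination report for a model battery
#'
#' For each fitted model: AUC with DeLong CI, full-model Nagelkerke R2,
#' the PRS-specific R2 (full R2 minus the clinical Model 2 R2, for the
#' score models 3-5), and the continuous NRI with bootstrap CI (Model 2
#' is compared to Model 1; Models 3-5 to Model 2, with the comparison
#' against Model 1 also emitted).  All pairwise DeLong p-values are
#' included.
#'
#' @param battery a `model_battery` from [run_model_battery()].
#' @param n_boot,seed bootstrap settings for the NRI intervals.
#' @return object of class `discrimination_report`: `table` (one row per
#'   model: auc, auc_lo, auc_hi, r2_full, r2_prs, nri, nri_lo, nri_hi,
#'   nri_vs_m1), `delong_p` (pairwise matrix), `n`.
#' @export
build_report <- function(battery, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(battery, "model_battery"))
  y <- battery$outcome
  k <- length(battery$fits)
  n <- length(y)
  ll0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  rocs <- lapply(battery$lp, auc_delong, outcome = y)
  r2 <- vapply(battery$loglik, nagelkerke_r2, numeric(1),
               loglik_null = ll0, n = n)
  r2_prs <- rep(NA_real_, k)
  if (k >= 3) r2_prs[3:k] <- r2[3:k] - r2[2]
  nri <- nri_lo <- nri_hi <- nri_m1 <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    ref <- if (i == 2) 1L else if (i >= 3) 2L else NA_integer_
    if (!is.na(ref)) {
      r <- continuous_nri(battery$risk[[ref]], battery$risk[[i]], y,
                          n_boot = n_boot, seed = seed + i)
      nri[i] <- r$nri; nri_lo[i] <- r$ci[1]; nri_hi[i] <- r$ci[2]
    }
    if (i >= 3)
      nri_m1[i] <- sum(nri_point(battery$risk[[1]], battery$risk[[i]], y))
    if (i == 2) nri_m1[i] <- nri[i]
  }
  dl <- matrix(NA_real_, k, k,
               dimnames = list(paste0("M", 1:k), paste0("M", 1:k)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    dl[i, j] <- dl[j, i] <- delong_test(battery$lp[[i]], battery$lp[[j]], y)$p
  tab <- data.frame(
    model = vapply(battery$specs, `[[`, "", "label"),
    score = vapply(battery$specs, function(s) s$score %||% NA_character_, ""),
    auc = vapply(rocs, `[[`, numeric(1), "auc"),
    auc_lo = vapply(rocs, function(r) r$ci[1], numeric(1)),
    auc_hi = vapply(rocs, function(r) r$ci[2], numeric(1)),
    r2_full = r2, r2_prs = r2_prs,
    nri = nri, nri_lo = nri_lo, nri_hi = nri_hi, nri_vs_m1 = nri_m1,
    stringsAsFactors = FALSE)
  structure(list(table = tab, delong_p = dl, n = n,
                 n_boot = n_boot, seed = seed),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) round(v, 4))
  print(tab)
  invisible(x)
}
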