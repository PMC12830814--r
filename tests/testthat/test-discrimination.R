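test_that("AUC handles the degenerate and hand-checkable cases", {
  expect_equal(auc_delong(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc_delong(rep(0.5, 20), rep(0:1, 10))$auc, 0.5)
  expect_error(auc_delong(rnorm(5), rep(1, 5)), "both outcome classes")
  r <- auc_delong(c(0.9, 0.7, 0.7, 0.2), c(1, 0, 1, 0))
  expect_equal(r$auc, auc_pairs_oracle(c(0.9, 0.7, 0.7, 0.2), c(1, 0, 1, 0)))
  expect_equal(r$n_events, 2); expect_equal(r$n_nonevents, 2)
  expect_true(all(r$ci >= 0 & r$ci <= 1))
})

test_that("placement AUC equals pair counting and trapezoid integration", {
  set.seed(91)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pred <- sample(seq(0, 1, 0.05), n, TRUE)   # coarse grid forces ties
    a <- auc_delong(pred, y)$auc
    expect_equal(a, auc_pairs_oracle(pred, y), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid_oracle(pred, y), tolerance = 1e-10)
  }
})

test_that("delong_test matches the structural-component oracle at n = 12", {
  set.seed(92)
  y <- rep(c(1, 0), each = 6)
  pa <- c(2.1, 1.7, 3.0, 0.9, 1.2, 2.6, 0.4, 1.1, 0.8, 1.9, 0.2, 1.0)
  pb <- pa + rnorm(12, 0, 0.8)
  got <- delong_test(pa, pb, y)
  orc <- delong_oracle(pa, pb, y)
  expect_equal(got$auc_a, orc$auc_a, tolerance = 1e-12)
  expect_equal(got$auc_b, orc$auc_b, tolerance = 1e-12)
  expect_equal(got$se, orc$se, tolerance = 1e-12)
  ## placement vectors themselves agree with brute force
  pv <- metaprs:::placement_values(pa, y)
  expect_equal(pv$V10, orc$V10a, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pv$V01, orc$V01a, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("delong_test degenerate and symmetry behavior", {
  set.seed(93)
  y <- rbinom(40, 1, 0.5)
  p1 <- rnorm(40); p2 <- rnorm(40)
  expect_equal(delong_test(p1, p1, y)$p, 1)
  ab <- delong_test(p1, p2, y); ba <- delong_test(p2, p1, y)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$z, -ba$z)
})

test_that("DeLong SE shrinks as n grows", {
  se_at <- function(n) {
    set.seed(94)
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + s))
    auc_delong(s, y)$se
  }
  ses <- vapply(c(200, 2000, 20000), se_at, numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[3], 0.02)
})

test_that("Nagelkerke R2 endpoints and likelihood oracle", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  expect_equal(nagelkerke_r2(-13.86, 0, 20), 1.0)   # perfect prediction
  expect_error(nagelkerke_r2(-10, -20, 30), "loglik_full")
  expect_error(nagelkerke_r2(-10, -5, 0), "n must be")

  ## n = 20, one binary predictor: likelihoods evaluated directly
  set.seed(95)
  x <- rep(0:1, each = 10)
  y <- c(rbinom(10, 1, 0.3), rbinom(10, 1, 0.7))
  fit <- glm(y ~ x, family = binomial())
  ll1 <- sum(dbinom(y, 1, fitted(fit), log = TRUE))
  ll0 <- sum(dbinom(y, 1, mean(y), log = TRUE))
  r2_oracle <- (1 - exp(2 / 20 * (ll0 - ll1))) / (1 - exp(2 / 20 * ll0))
  expect_equal(nagelkerke_r2(as.numeric(logLik(glm(y ~ 1, family = binomial()))),
                             as.numeric(logLik(fit)), 20),
               r2_oracle, tolerance = 1e-10)
})

test_that("continuous NRI: hand cases, bounds, and identity", {
  ## 2 events moving (up, down); 2 nonevents moving (down, tie)
  old <- c(0.2, 0.4, 0.3, 0.5)
  new <- c(0.3, 0.3, 0.2, 0.5)
  y <- c(1, 1, 0, 0)
  r <- continuous_nri(old, new, y, n_boot = 50, seed = 1)
  expect_equal(r$nri, 0.5)
  expect_equal(r$event_component, 0)
  expect_equal(r$nonevent_component, 0.5)
  expect_equal(r$nri, r$event_component + r$nonevent_component)

  ## identity: NRI 0 with CI containing 0
  set.seed(96)
  risk <- runif(200)
  y2 <- rbinom(200, 1, risk)
  r0 <- continuous_nri(risk, risk, y2, n_boot = 200, seed = 2)
  expect_equal(r0$nri, 0)
  expect_true(r0$ci[1] <= 0 && r0$ci[2] >= 0)

  ## bound attained: every event up, every nonevent down
  up <- pmin(risk + 0.1, 1); down <- pmax(risk - 0.1, 0)
  r2 <- continuous_nri(risk, ifelse(y2 == 1, up, down), y2,
                       n_boot = 50, seed = 3)
  expect_equal(r2$nri, 2)

  expect_error(continuous_nri(risk, risk + 5, y2), "risks must be")
  expect_error(continuous_nri(risk, risk, rep(1, 200)), "both outcome")
})

test_that("NRI bootstrap is seeded and deterministic", {
  set.seed(97)
  old <- runif(300); new <- pmin(pmax(old + rnorm(300, 0, 0.05), 0), 1)
  y <- rbinom(300, 1, old)
  a <- continuous_nri(old, new, y, n_boot = 300, seed = 5)
  b <- continuous_nri(old, new, y, n_boot = 300, seed = 5)
  expect_identical(a$ci, b$ci)
})

test_that("bootstrap NRI CI approximately covers the large-sample truth", {
  ## scaled-down coverage study: 150 replicates at n = 1500 with 400
  ## bootstrap draws (the full-size study is documented in the vignette);
  ## generative model: old risk from x1, new risk adds an informative x2
  truth <- local({
    set.seed(981)
    n <- 5e5
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + x1 + 0.5 * x2))
    old <- plogis(-1 + x1); new <- plogis(-1 + x1 + 0.5 * x2)
    s <- sign(new - old)
    mean(s[y == 1]) - mean(s[y == 0])
  })
  hits <- 0L
  n_rep <- 150L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n <- 1500
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + x1 + 0.5 * x2))
    if (length(unique(y)) < 2) next
    res <- continuous_nri(plogis(-1 + x1), plogis(-1 + x1 + 0.5 * x2), y,
                          n_boot = 400, seed = r)
    if (res$ci[1] <= truth && truth <= res$ci[2]) hits <- hits + 1L
  }
  coverage <- hits / n_rep
  expect_gt(coverage, 0.90)
  expect_lte(coverage, 1.0)
})

test_that("build_report assembles consistent per-model statistics", {
  fx_seed <- 99
  set.seed(fx_seed)
  n <- 2500
  df <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                   bmi = rnorm(n, 28, 5), sbp = rnorm(n, 127, 15),
                   smoking = rbinom(n, 1, 0.25), statin = rbinom(n, 1, 0.45),
                   art = rbinom(n, 1, 0.9),
                   platform = factor(sample(c("P1", "P2"), n, TRUE)))
  for (k in 1:10) df[[paste0("PC", k)]] <- rnorm(n)
  t2d <- rnorm(n)
  df$outcome <- rbinom(n, 1, plogis(-1.3 + 0.05 * (df$bmi - 28) + 0.6 * t2d))
  scores <- list("T2D-PRS" = t2d, "meta-inflammation" = rnorm(n),
                 "meta-lipids" = rnorm(n))
  batt <- run_model_battery(df, scores, model_specs(10, "cnics"))
  rep1 <- build_report(batt, n_boot = 200, seed = 7)
  tab <- rep1$table
  ## PRS R2 definition: full R2 minus Model 2 R2, to numerical precision
  expect_equal(tab$r2_prs[3:5], tab$r2_full[3:5] - tab$r2_full[2],
               tolerance = 1e-10)
  ## strong score signal: Model 3 beats Model 2 on AUC
  expect_gte(tab$auc[3], tab$auc[2])
  ## DeLong matrix symmetric with unit-free p in [0,1]
  expect_equal(rep1$delong_p, t(rep1$delong_p))
  expect_true(all(rep1$delong_p[upper.tri(rep1$delong_p)] >= 0 &
                  rep1$delong_p[upper.tri(rep1$delong_p)] <= 1))
  ## deterministic given seed
  rep2 <- build_report(batt, n_boot = 200, seed = 7)
  expect_identical(rep1$table, rep2$table)
})
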