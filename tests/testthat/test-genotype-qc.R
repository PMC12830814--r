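test_that("hwe_exact_p matches hand cases and the enumeration oracle", {
  expect_equal(hwe_exact_p(0, 0, 50), 1.0)
  ## modal table: full enumeration confirms every table is included
  expect_equal(hwe_exact_p(25, 50, 25), 1.0)
  expect_equal(hwe_exact_p(3, 1, 5), hwe_oracle_p(3, 1, 5), tolerance = 1e-12)
  expect_error(hwe_exact_p(-1, 2, 3), "non-negative")
})

test_that("hwe_exact_p equals the oracle across all tables up to n = 60", {
  for (n in c(1:15, 30, 45, 60)) {
    for (nA in 0:n) {
      hs <- seq(nA %% 2, nA, by = 2)
      for (h in hs) {
        a <- (nA - h) / 2; b <- n - a - h
        expect_equal(hwe_exact_p(a, h, b), hwe_oracle_p(a, h, b),
                     tolerance = 1e-12,
                     info = sprintf("table (%d,%d,%d)", a, h, b))
      }
    }
  }
})

test_that("variant_qc flags each failure with its first-failing reason", {
  set.seed(1)
  n <- 400
  D <- cbind(
    miss = ifelse(runif(n) < 0.10, NA, rbinom(n, 2, 0.3)),   # call rate 0.90
    rare = rbinom(n, 2, 0.005),                              # MAF ~ 0.005
    mono = rep(0, n),                                        # monomorphic
    hwe  = c(rep(0, 200), rep(2, 200)),                      # no hets
    ok   = rbinom(n, 2, 0.3),
    amb  = rbinom(n, 2, 0.3))
  dm <- make_dm(D, ref = c("A", "A", "A", "A", "A", "A"),
                   alt = c("G", "G", "G", "G", "G", "T"))
  res <- variant_qc(dm, qc_thresholds("cnics"))
  rep_ <- res$report
  expect_equal(rep_$reason[rep_$id == "v001"], "call_rate")
  expect_equal(rep_$reason[rep_$id == "v002"], "maf")
  ## monomorphic: HWE p = 1 so the MAF rule removes it
  expect_equal(rep_$reason[rep_$id == "v003"], "maf")
  expect_equal(hwe_exact_p(0, 0, n), 1.0)
  expect_equal(rep_$reason[rep_$id == "v004"], "hwe")
  expect_true(rep_$pass[rep_$id == "v005"])
  expect_equal(rep_$reason[rep_$id == "v006"], "ambiguous")
  expect_equal(ncol(res$dosages$dosages), sum(rep_$pass))
})

test_that("variant_qc is idempotent", {
  coh <- simulate_cohort(sim_config(300, 80, missing_rate = 0.03, seed = 21))
  r1 <- variant_qc(coh$dosages)
  r2 <- variant_qc(r1$dosages)
  expect_true(all(r2$report$pass))
  expect_identical(r1$dosages$dosages, r2$dosages$dosages)
})

test_that("pi-hat: duplicates are 1, unrelated samples near 0", {
  cfg <- sim_config(60, 500, missing_rate = 0, dosage_noise_sd = 0,
                    n_ancestries = 1, seed = 33)
  G <- simulate_genotypes(cfg)$dosages
  PI <- pihat_matrix(G)
  off <- PI[upper.tri(PI)]
  ## estimates scatter around 0 with MC SD ~ 0.035 at 500 variants, so
  ## the per-pair |pi-hat| < 0.1 (~3 SE) check is applied to the bulk:
  ## the extreme of ~1800 clipped estimates necessarily exceeds 3 SE
  expect_lt(mean(off), 0.05)
  expect_lt(median(off), 0.05)
  expect_gt(mean(abs(off) < 0.1), 0.95)

  ## append an exact duplicate of sample 1
  G2 <- rbind(G, G[1, ])
  PI2 <- pihat_matrix(G2)
  expect_equal(PI2[1, 61], 1.0)
})

test_that("sample_qc removes duplicates and respects thresholds", {
  cfg <- sim_config(40, 300, missing_rate = 0, dosage_noise_sd = 0,
                    n_ancestries = 1, seed = 12)
  dm <- simulate_genotypes(cfg)
  ## duplicate sample 2 into sample 40, then knock out some of sample 40's
  ## calls so it has the lower call rate of the pair
  dm$dosages[40, ] <- dm$dosages[2, ]
  dm$dosages[40, 1:30] <- NA
  res <- sample_qc(dm, qc_thresholds("cnics"))
  expect_equal(res$report$reason[40], "pihat")
  expect_true(res$report$pass[2])
  expect_gt(res$report$max_pihat[2], 0.9)

  ## permissive threshold: nothing removed
  res2 <- sample_qc(dm, qc_thresholds("cnics", pihat_max = 1.1,
                                      sample_call_rate_min = 0.5))
  expect_true(all(res2$report$pass))
})

test_that("compute_pcs separates two divergent subpopulations", {
  set.seed(7)
  n <- 120; m <- 300
  grp <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.5); p2 <- pmin(p1 + runif(m, 0.1, 0.3), 0.95)
  D <- t(vapply(grp, function(g)
    rbinom(m, 2, if (g == 0) p1 else p2), numeric(m)))
  dm <- make_dm(D)
  pcs <- compute_pcs(dm, 4)
  pc1 <- pcs[, 1]
  m0 <- mean(pc1[grp == 0]); m1 <- mean(pc1[grp == 1])
  expect_lt(m0 * m1, 0)
  within_sd <- sqrt(mean(c(var(pc1[grp == 0]), var(pc1[grp == 1]))))
  expect_gt(abs(m0 - m1), 4 * within_sd)
  ## decomposition properties
  expect_lt(max(abs(crossprod(pcs) - diag(4))), 1e-8)
  expect_true(all(diff(attr(pcs, "d")) <= 1e-8))
})

test_that("compute_pcs input validation and zero-variance handling", {
  D <- cbind(rbinom(30, 2, 0.4), rep(2, 30), rbinom(30, 2, 0.4))
  dm <- make_dm(D)
  expect_warning(pcs <- compute_pcs(dm, 2), "zero-variance")
  expect_equal(ncol(pcs), 2)
  expect_error(compute_pcs(dm, 10), "n_pcs")
})

test_that("platform_harmonize removes a strongly shifted variant", {
  set.seed(5)
  n <- 800
  platform <- rep(c("P1", "P2"), each = n / 2)
  D <- cbind(
    shifted = c(rbinom(n / 2, 2, 0.1), rbinom(n / 2, 2, 0.5)),
    null1 = rbinom(n, 2, 0.3),
    null2 = rbinom(n, 2, 0.2))
  dm <- make_dm(D)
  res <- platform_harmonize(dm, platform, pcs = NULL, p_remove = 5e-8)
  expect_equal(res$report$reason[1], "platform_assoc")
  expect_true(all(res$report$pass[2:3]))

  ## constant platform vector: no-op with warning
  expect_warning(res2 <- platform_harmonize(dm, rep("P1", n)), "single platform")
  expect_identical(res2$dosages$dosages, dm$dosages)
})

test_that("three-platform harmonization merges sequentially", {
  set.seed(6)
  n <- 900
  platform <- rep(c("P1", "P2", "P3"), each = n / 3)
  ## variant shifted only on P3: survives the P1-P2 round, removed at merge 3
  D <- cbind(p3shift = c(rbinom(600, 2, 0.15), rbinom(300, 2, 0.6)),
             null = rbinom(n, 2, 0.35))
  dm <- make_dm(D)
  res <- platform_harmonize(dm, platform, p_remove = 5e-8)
  expect_false(res$report$pass[1])
  expect_true(res$report$pass[2])
})

test_that("qc_thresholds presets match their stated values", {
  th <- qc_thresholds("cnics")
  expect_equal(th$variant_call_rate_min, 0.95)
  expect_equal(th$maf_min, 0.01)
  expect_equal(th$hwe_p_min, 1e-5)
  expect_equal(th$sample_call_rate_min, 0.90)
  expect_equal(th$pihat_max, 0.9)
  expect_equal(th$platform_p_remove, 5e-8)
  th1 <- qc_thresholds("regards1")
  expect_equal(th1$variant_call_rate_min, 0.90)
  expect_equal(th1$hwe_p_min, 1e-12)
  ## explicit override wins
  expect_equal(qc_thresholds("cnics", maf_min = 0.05)$maf_min, 0.05)
})
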