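test_that("scoring files round-trip through the PGS-style format", {
  sf <- make_scoring("CRP", chrom = c(1, 1, 2), pos = c(100, 200, 300),
                     eff = c("A", "G", "C"), oth = c("G", "A", "T"),
                     w = c(0.2, -0.5, 1e-3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_scoring_file(sf, path)
  back <- parse_scoring_file(path)
  expect_s3_class(back, "scoring_file")
  expect_equal(back$trait_name, "CRP")
  expect_equal(nrow(back$records), 3)
  expect_equal(back$records$effect_weight, c(0.2, -0.5, 0.001))
})

test_that("parser errors are specific", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#comment",
               "rsID\tchr_name\tchr_position\teffect_allele\tother_allele",
               "rs1\t1\t100\tA\tG"), path)
  expect_error(parse_scoring_file(path), "effect_weight")

  writeLines(c("rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
               "rs1\t1\t100\tA\tG\tabc"), path)
  expect_error(parse_scoring_file(path), "non-numeric")

  writeLines(c("rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
               "rs1\t1\t100\tA\tG\t0.1",
               "rs2\t1\t100\tG\tA\t0.2"), path)
  expect_error(parse_scoring_file(path), "duplicate")

  expect_error(parse_scoring_file(file.path(tempdir(), "nope.txt")),
               "not found")
})

test_that("scoring-file construction enforces its invariants", {
  expect_error(make_scoring("t", c(1, 1), c(100, 100),
                            eff = c("A", "G"), oth = c("G", "A"),
                            w = c(0.1, 0.2)),
               "duplicate")
  expect_error(make_scoring("t", 1, 100, eff = "N", oth = "G", w = 1),
               "alleles")
  expect_error(make_scoring("t", 1, 100, eff = "A", oth = "G", w = Inf),
               "finite")
})

test_that("harmonize_scoring actions match the defined matching rules", {
  dm <- make_dm(matrix(1, 2, 5), ref = c("G", "G", "G", "C", "G"),
                alt = c("A", "A", "A", "G", "A"),
                pos = c(100, 200, 300, 400, 500))
  sf <- make_scoring("t", chrom = rep(1, 5),
                     pos = c(100, 200, 300, 400, 999),
                     eff = c("A", "G", "T", "C", "A"),
                     oth = c("G", "A", "C", "G", "G"),
                     w = rep(1, 5))
  map <- harmonize_scoring(sf, dm)
  expect_equal(map$action,
               c("direct",              # (A,G) vs alt=A/ref=G
                 "allele_swap",         # (G,A): effect is the ref
                 "strand_complement",   # (T,C) complements to (A,G)
                 "dropped",             # C/G is strand-ambiguous
                 "dropped"))            # unmatched position
  expect_equal(map$reason[4:5], c("ambiguous", "unmatched"))
  expect_true(all(is.na(map$variant[map$action == "dropped"])))

  ## complement_then_swap: effect complements to the ref
  sf2 <- make_scoring("t", 1, 100, eff = "C", oth = "T", w = 1)
  expect_equal(harmonize_scoring(sf2, dm)$action, "complement_then_swap")
})

test_that("compute_prs reproduces hand-computed sums", {
  D <- rbind(c(1, 2, 0), c(0, 1, 2), c(2, 0, 1))
  dm <- make_dm(D, ref = rep("G", 3), alt = rep("A", 3),
                pos = c(100, 200, 300))
  sf <- make_scoring("t", rep(1, 3), c(100, 200, 300),
                     eff = rep("A", 3), oth = rep("G", 3),
                     w = c(0.2, -0.5, 0.1))
  s <- compute_prs(dm, sf)
  expect_equal(as.numeric(s), c(0.2 - 1.0 + 0, -0.5 + 0.2, 0.4 + 0.1))
  expect_equal(attr(s, "n_variants_used"), 3L)

  ## zero weights, identity variant
  sf0 <- make_scoring("t", rep(1, 3), c(100, 200, 300),
                      eff = rep("A", 3), oth = rep("G", 3), w = rep(0, 3))
  expect_equal(as.numeric(compute_prs(dm, sf0)), c(0, 0, 0))
  sf1 <- make_scoring("t", 1, 100, eff = "A", oth = "G", w = 1)
  expect_equal(as.numeric(compute_prs(dm, sf1)), D[, 1])

  ## all records dropped -> error
  sf_un <- make_scoring("t", 1, 9999, eff = "A", oth = "G", w = 1)
  expect_error(compute_prs(dm, sf_un), "no contributing variants")
})

test_that("missing dosages are mean-imputed by 2 p-hat", {
  D <- matrix(c(0, 1, 2, NA), ncol = 1)
  dm <- make_dm(D, ref = "G", alt = "A")
  sf <- make_scoring("t", 1, 100, eff = "A", oth = "G", w = 2)
  s <- compute_prs(dm, sf)
  expect_equal(as.numeric(s), c(0, 2, 4, 2 * 2 * mean(c(0, 1, 2)) / 2))
  ## omit policy: renormalized by observed weight (single variant -> NA)
  s2 <- compute_prs(dm, sf, missing = "omit")
  expect_true(is.na(s2[4]))
})

test_that("score linearity: disjoint split of records sums to the whole", {
  coh <- simulate_cohort(sim_config(120, 60, missing_rate = 0.02, seed = 14))
  sf <- coh$scoring_files[[1]]
  full <- compute_prs(coh$dosages, sf)
  k <- nrow(sf$records)
  idx <- seq_len(k) <= k / 2
  sfa <- metaprs:::new_scoring_file("a", sf$records[idx, ])
  sfb <- metaprs:::new_scoring_file("b", sf$records[!idx, ])
  sa <- compute_prs(coh$dosages, sfa)
  sb <- compute_prs(coh$dosages, sfb)
  expect_equal(as.numeric(sa) + as.numeric(sb), as.numeric(full),
               tolerance = 1e-10)
})

test_that("allele swap shifts the score by 2*sum(w); strand flip is a no-op", {
  D <- matrix(rbinom(200 * 4, 2, 0.4), 200, 4)
  dm <- make_dm(D, ref = rep("G", 4), alt = rep("A", 4),
                pos = c(100, 200, 300, 400))
  w <- c(0.3, -0.2, 0.5, 0.1)
  direct <- make_scoring("t", rep(1, 4), c(100, 200, 300, 400),
                         eff = rep("A", 4), oth = rep("G", 4), w = w)
  swapped <- make_scoring("t", rep(1, 4), c(100, 200, 300, 400),
                          eff = rep("G", 4), oth = rep("A", 4), w = w)
  flipped <- make_scoring("t", rep(1, 4), c(100, 200, 300, 400),
                          eff = rep("T", 4), oth = rep("C", 4), w = w)
  s_dir <- as.numeric(compute_prs(dm, direct))
  s_swp <- as.numeric(compute_prs(dm, swapped))
  s_flp <- as.numeric(compute_prs(dm, flipped))
  expect_equal(s_swp, 2 * sum(w) - s_dir, tolerance = 1e-12)
  expect_equal(s_flp, s_dir, tolerance = 1e-12)
})

test_that("standardization follows the stated conventions", {
  z <- standardize_scores(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "provenance"), "in-sample")
  expect_error(standardize_scores(rep(2, 5)), "zero or non-finite SD")
  zr <- standardize_scores(matrix(4, 1, 1, dimnames = list(NULL, "s")),
                           reference = list(center = c(s = 0), scale = c(s = 2)))
  expect_equal(as.numeric(zr), 2)
  ## in-sample invariant: |mean| < 1e-10, SD within 1e-10 of 1
  X <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("t", 1:5)))
  Z <- standardize_scores(X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
})
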