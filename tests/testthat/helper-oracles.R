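## Fixture builders and independent oracles shared across test files.
## Oracles deliberately use different formulas / code paths than the
## package implementation they check.

## hand-built dosage_matrix with explicit alleles
make_dm <- function(D, ref = NULL, alt = NULL, chrom = NULL, pos = NULL) {
  m <- ncol(D)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  variants <- data.frame(id = sprintf("v%03d", seq_len(m)),
                         chrom = as.character(chrom), pos = as.integer(pos),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  metaprs:::new_dosage_matrix(D, variants)
}

make_scoring <- function(trait, chrom, pos, eff, oth, w) {
  metaprs:::new_scoring_file(trait, data.frame(
    rsID = paste0("rs", seq_along(pos)), chr_name = as.character(chrom),
    chr_position = as.integer(pos), effect_allele = eff, other_allele = oth,
    effect_weight = w, stringsAsFactors = FALSE))
}

## HWE enumeration oracle: conditional probability of each heterozygote
## count computed from binomial coefficients via choose() ratios
## (a different route than the package's lfactorial form).
hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nA <- min(nA, 2 * n - nA)
  hs <- seq(nA %% 2, nA, by = 2)
  ## unnormalized weight of each table: multinomial count of genotype
  ## assignments times 2^h phase factor, normalized by the explicit sum
  ## over all admissible heterozygote counts
  wt <- vapply(hs, function(h) {
    a <- (nA - h) / 2
    choose(n, a) * choose(n - a, h) * 2^h
  }, numeric(1))
  pr <- wt / sum(wt)
  obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

## brute-force pair-counting AUC (O(mn))
auc_pairs_oracle <- function(pred, y) {
  cases <- pred[y == 1]; ctrls <- pred[y == 0]
  s <- 0
  for (ca in cases) s <- s + sum(ca > ctrls) + 0.5 * sum(ca == ctrls)
  s / (length(cases) * length(ctrls))
}

## brute-force DeLong structural components and paired variance
delong_oracle <- function(pa, pb, y) {
  comp <- function(pred) {
    cases <- pred[y == 1]; ctrls <- pred[y == 0]
    V10 <- vapply(cases, function(v)
      mean((v > ctrls) + 0.5 * (v == ctrls)), numeric(1))
    V01 <- vapply(ctrls, function(v)
      mean((cases > v) + 0.5 * (cases == v)), numeric(1))
    list(V10 = V10, V01 = V01)
  }
  A <- comp(pa); B <- comp(pb)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(A$V10, B$V10))
  s01 <- stats::cov(cbind(A$V01, B$V01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  list(auc_a = mean(A$V10), auc_b = mean(B$V10),
       se = sqrt(var_diff), V10a = A$V10, V01a = A$V01)
}

## dosage_matrix restricted to the variants not in `drop`
subset_clean <- function(dm, drop) {
  metaprs:::subset_dosages(dm, variants = setdiff(seq_len(ncol(dm$dosages)),
                                                  drop))
}

## trapezoidal ROC-integration AUC
auc_trapezoid_oracle <- function(pred, y) {
  th <- c(Inf, sort(unique(pred), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(pred[y == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(pred[y == 0] >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## Mann-Whitney AUC via the rank-sum identity (independent of placement
## values): used as the oracle for simulated-outcome discrimination
auc_ranksum_oracle <- function(pred, y) {
  r <- rank(pred)
  m <- as.numeric(sum(y == 1)); n <- as.numeric(sum(y == 0))
  (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
}
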