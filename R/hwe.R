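## Conditional distribution of the heterozygote count given the total
## sample size and minor-allele count: the classical Levene/Haldane
## distribution underlying the exact Hardy-Weinberg test.
## P(h | n, nA) = n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)!
## Returns the support (possible h, matching the parity of nA) and the
## normalized probabilities, computed on the log scale for stability.
hwe_het_dist <- function(n, nA) {
  na <- 2L * n - nA
  if (nA > na) stop("internal: nA must be the minor allele count")
  hs <- seq.int(nA %% 2L, nA, by = 2L)
  aa <- (nA - hs) %/% 2L
  bb <- (na - hs) %/% 2L
  logp <- lfactorial(n) - lfactorial(aa) - lfactorial(hs) - lfactorial(bb) +
    hs * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  list(h = hs, p = p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Plain (not mid-p) exact conditional test on hard genotype counts: the
#' p-value is the total probability, under the conditional distribution
#' of the heterozygote count given the allele counts, of all tables whose
#' probability does not exceed that of the observed table.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorized; recycled).
#' @return p-value(s) in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(25, 50, 25)   # modal table -> 1
#' hwe_exact_p(20, 10, 20)   # heterozygote deficit -> small p
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0, na.rm = TRUE))
    stop("genotype counts must be non-negative")
  vapply(seq_len(k), function(i) {
    a <- round(n_AA[i]); h <- round(n_Aa[i]); b <- round(n_aa[i])
    if (anyNA(c(a, h, b))) return(NA_real_)
    n <- a + h + b
    if (n < 1) stop("at least one genotype required")
    nA <- 2L * a + h
    if (nA > n) { nA <- 2L * n - nA }   # fold to minor allele
    d <- hwe_het_dist(n, nA)
    p_obs <- d$p[match(h, d$h)]
    sum(d$p[d$p <= p_obs * (1 + 1e-9)])
  }, numeric(1))
}
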