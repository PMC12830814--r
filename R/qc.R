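#' Quality-control thresholds
#'
#' Bundles all variant- and sample-level QC thresholds.  Presets:
#' \describe{
#'   \item{`"cnics"`}{variant call rate >= 0.95, MAF >= 0.01,
#'     HWE p >= 1e-5, sample call rate >= 0.90, pi-hat <= 0.9,
#'     platform-association removal at p < 5e-8.}
#'   \item{`"regards1"`}{first genotyping batch: variant call rate
#'     >= 0.90 (missing rate <= 10%), HWE p >= 1e-12.}
#'   \item{`"regards2"`}{second batch: variant call rate >= 0.95
#'     (missing rate <= 5%), HWE p >= 1e-5, sample call rate >= 0.98.}
#' }
#'
#' @param preset one of `"cnics"`, `"regards1"`, `"regards2"`, or
#'   `"custom"` (defaults equal the cnics preset); explicit arguments
#'   override the preset values.
#' @param variant_call_rate_min,maf_min,hwe_p_min,sample_call_rate_min,pihat_max,platform_p_remove,n_pcs
#'   individual thresholds.
#' @return object of class `qc_thresholds`.
#' @export
#' @examples
#' qc_thresholds("cnics")
qc_thresholds <- function(preset = c("cnics", "regards1", "regards2", "custom"),
                          variant_call_rate_min = NULL, maf_min = NULL,
                          hwe_p_min = NULL, sample_call_rate_min = NULL,
                          pihat_max = NULL, platform_p_remove = NULL,
                          n_pcs = NULL) {
  preset <- match.arg(preset)
  th <- switch(preset,
    cnics    = list(variant_call_rate_min = 0.95, maf_min = 0.01,
                    hwe_p_min = 1e-5, sample_call_rate_min = 0.90,
                    pihat_max = 0.9, platform_p_remove = 5e-8, n_pcs = 10L),
    regards1 = list(variant_call_rate_min = 0.90, maf_min = 0.01,
                    hwe_p_min = 1e-12, sample_call_rate_min = 0.90,
                    pihat_max = 0.9, platform_p_remove = 5e-8, n_pcs = 10L),
    regards2 = list(variant_call_rate_min = 0.95, maf_min = 0.01,
                    hwe_p_min = 1e-5, sample_call_rate_min = 0.98,
                    pihat_max = 0.9, platform_p_remove = 5e-8, n_pcs = 10L),
    custom   = list(variant_call_rate_min = 0.95, maf_min = 0.01,
                    hwe_p_min = 1e-5, sample_call_rate_min = 0.90,
                    pihat_max = 0.9, platform_p_remove = 5e-8, n_pcs = 10L))
  ovr <- list(variant_call_rate_min = variant_call_rate_min, maf_min = maf_min,
              hwe_p_min = hwe_p_min, sample_call_rate_min = sample_call_rate_min,
              pihat_max = pihat_max, platform_p_remove = platform_p_remove,
              n_pcs = n_pcs)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) th[[nm]] <- ovr[[nm]]
  stopifnot(th$variant_call_rate_min > 0, th$variant_call_rate_min <= 1,
            th$maf_min >= 0, th$maf_min <= 0.5,
            th$hwe_p_min > 0, th$hwe_p_min < 1,
            th$platform_p_remove > 0, th$platform_p_remove < 1)
  th$preset <- preset
  class(th) <- "qc_thresholds"
  th
}

## hard-call dosages for count-based tests (HWE, pi-hat): round to the
## nearest genotype; entries farther than 0.1 from an integer are treated
## as missing for these tests only
hard_calls <- function(D, tol = 0.1) {
  G <- round(D)
  G[abs(D - G) > tol] <- NA_real_
  G
}

#' Variant-level quality control
#'
#' Removes variants failing, in fixed order (so that each removed variant
#' has a deterministic first-failing reason): call rate, folded minor
#' allele frequency (mean non-missing dosage / 2, folded to <= 0.5),
#' Hardy-Weinberg exact test on hard-called genotypes, strand-ambiguous
#' (A/T, C/G) allele pair, multi-allelic record.
#'
#' @param dosages a `dosage_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return list with the filtered `dosages` and `report`, a per-variant
#'   data frame (id, call_rate, maf, hwe_p, pass, reason).
#' @export
variant_qc <- function(dosages, thresholds = qc_thresholds()) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  D <- dosages$dosages
  if (ncol(D) == 0) stop("empty variant panel")
  call_rate <- colMeans(!is.na(D))
  p <- colMeans(D, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  G <- hard_calls(D)
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_p(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  ambiguous <- is_ambiguous_pair(dosages$variants$ref, dosages$variants$alt)
  multi <- grepl(",", dosages$variants$alt, fixed = TRUE) |
           nchar(dosages$variants$alt) > 1 | nchar(dosages$variants$ref) > 1

  reason <- rep(NA_character_, ncol(D))
  reason[is.na(reason) & call_rate < thresholds$variant_call_rate_min] <- "call_rate"
  reason[is.na(reason) & maf < thresholds$maf_min] <- "maf"
  reason[is.na(reason) & !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min] <- "hwe"
  reason[is.na(reason) & ambiguous] <- "ambiguous"
  reason[is.na(reason) & multi] <- "multiallelic"
  pass <- is.na(reason)
  report <- data.frame(id = dosages$variants$id, call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, pass = pass,
                       reason = reason, stringsAsFactors = FALSE)
  if (!any(pass)) stop("variant QC removed all variants (empty panel)")
  list(dosages = subset_dosages(dosages, variants = which(pass)),
       report = report)
}

#' Method-of-moments pi-hat matrix
#'
#' PLINK-style IBD estimation from identity-by-state counts on hard-called
#' genotypes: per pair, the observed counts of IBS 0/1/2 sites are
#' compared to their expectations under IBD states Z0/Z1/Z2 given sample
#' allele frequencies, solved sequentially for (Z0, Z1, Z2), and
#' pi-hat = Z1/2 + Z2, clipped to `[0, 1]`.  Identical genotype vectors
#' give pi-hat exactly 1.
#'
#' @param G hard-called genotype matrix (individuals x variants, values
#'   0/1/2 or NA).
#' @return symmetric matrix of pi-hat estimates (diagonal 1).
#' @export
pihat_matrix <- function(G) {
  n <- nrow(G)
  ## per-variant allele counts; expectations use falling-factorial
  ## (unbiased) moments of the allele frequency, as in the PLINK
  ## method-of-moments estimator, so small panels are not biased by
  ## plugging in p-hat directly
  X <- colSums(G, na.rm = TRUE)             # alt alleles observed
  Nc <- 2 * colSums(!is.na(G))              # chromosomes observed
  Y <- Nc - X
  ff <- function(x, k) {                    # falling factorial x(x-1)...(x-k+1)
    out <- rep(1, length(x))
    for (i in 0:(k - 1)) out <- out * (x - i)
    out
  }
  d3 <- ff(Nc, 3); d4 <- ff(Nc, 4)
  e0_ibs0 <- 2 * ff(X, 2) * ff(Y, 2) / d4
  e0_ibs1 <- 4 * (ff(X, 3) * Y + X * ff(Y, 3)) / d4
  e0_ibs2 <- (ff(X, 4) + ff(Y, 4) + 4 * ff(X, 2) * ff(Y, 2)) / d4
  e1_ibs1 <- 2 * (ff(X, 2) * Y + X * ff(Y, 2)) / d3
  e1_ibs2 <- (ff(X, 3) + ff(Y, 3) + ff(X, 2) * Y + X * ff(Y, 2)) / d3
  p <- X / Nc
  PI <- diag(1, n)
  if (n < 2) return(PI)
  for (i in seq_len(n - 1)) {
    gi <- G[i, ]
    for (j in (i + 1):n) {
      gj <- G[j, ]
      ok <- !is.na(gi) & !is.na(gj) & p > 0 & p < 1 & Nc >= 4
      if (!any(ok)) { PI[i, j] <- PI[j, i] <- NA_real_; next }
      d <- abs(gi[ok] - gj[ok])
      N0 <- sum(d == 2); N1 <- sum(d == 1)
      E0_0 <- sum(e0_ibs0[ok]); E0_1 <- sum(e0_ibs1[ok]); E1_1 <- sum(e1_ibs1[ok])
      E0_2 <- sum(e0_ibs2[ok]); E1_2 <- sum(e1_ibs2[ok]); m <- sum(ok)
      z0 <- if (E0_0 > 0) N0 / E0_0 else 0
      z1 <- if (E1_1 > 0) (N1 - z0 * E0_1) / E1_1 else 0
      z2 <- (m - N0 - N1 - z0 * E0_2 - z1 * E1_2) / m
      ph <- min(max(z1 / 2 + z2, 0), 1)
      PI[i, j] <- PI[j, i] <- ph
    }
  }
  dimnames(PI) <- list(rownames(G), rownames(G))
  PI
}

#' Sample-level quality control
#'
#' Removes samples below the call-rate threshold, then estimates pairwise
#' pi-hat ([pihat_matrix()]) on the remaining samples and, for each pair
#' exceeding `pihat_max`, removes the member with the lower call rate
#' (ties broken by removing the later sample index).
#'
#' @param dosages a `dosage_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return list with filtered `dosages` and per-sample `report`
#'   (sample, call_rate, max_pihat, pass, reason).
#' @export
sample_qc <- function(dosages, thresholds = qc_thresholds()) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  D <- dosages$dosages
  call_rate <- rowMeans(!is.na(D))
  reason <- rep(NA_character_, nrow(D))
  reason[call_rate < thresholds$sample_call_rate_min] <- "call_rate"
  keep <- which(is.na(reason))
  max_pihat <- rep(NA_real_, nrow(D))
  if (length(keep) < 2) {
    warning("fewer than 2 samples after call-rate filter; pi-hat step skipped")
  } else {
    G <- hard_calls(D[keep, , drop = FALSE])
    PI <- pihat_matrix(G)
    diag(PI) <- 0
    max_pihat[keep] <- apply(PI, 1, max, na.rm = TRUE)
    repeat {
      over <- which(PI > thresholds$pihat_max, arr.ind = TRUE)
      over <- over[over[, 1] < over[, 2], , drop = FALSE]
      if (!nrow(over)) break
      i <- over[1, 1]; j <- over[1, 2]
      cri <- call_rate[keep[i]]; crj <- call_rate[keep[j]]
      drop_local <- if (cri < crj) i else if (crj < cri) j else max(i, j)
      reason[keep[drop_local]] <- "pihat"
      PI <- PI[-drop_local, -drop_local, drop = FALSE]
      keep <- keep[-drop_local]
    }
  }
  pass <- is.na(reason)
  report <- data.frame(sample = dosages$samples, call_rate = call_rate,
                       max_pihat = max_pihat, pass = pass, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(pass)) stop("sample QC removed all samples")
  list(dosages = subset_dosages(dosages, samples = which(pass)),
       report = report)
}

#' Principal components of the dosage matrix
#'
#' EIGENSTRAT-style normalization: each variant is centered by twice its
#' alt-allele frequency estimate and scaled by `sqrt(2 p (1 - p))`;
#' missing entries become 0 after centering (mean imputation).  The top
#' `n_pcs` left singular vectors of the normalized matrix are returned
#' (unit-norm columns, ordered by singular value).
#'
#' @param dosages a post-QC `dosage_matrix`.
#' @param n_pcs number of components (< min(dimensions)).
#' @return matrix (individuals x n_pcs) with columns `PC1..`; singular
#'   values in `attr(, "d")`.
#' @export
compute_pcs <- function(dosages, n_pcs = 10L) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  D <- dosages$dosages
  if (n_pcs >= min(dim(D))) stop("n_pcs must be < min(n_individuals, n_variants)")
  p <- colMeans(D, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance variant(s) excluded from PCA")
    D <- D[, keep, drop = FALSE]; p <- p[keep]
  }
  X <- sweep(D, 2, 2 * p, "-")
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = n_pcs, nv = 0)
  pcs <- sv$u
  colnames(pcs) <- paste0("PC", seq_len(n_pcs))
  rownames(pcs) <- dosages$samples
  attr(pcs, "d") <- sv$d[seq_len(n_pcs)]
  pcs
}

## Wald p-value for the dosage term in logistic regression of a binary
## platform indicator on dosage plus covariates.  Returns list(p, status).
wald_platform_p <- function(y, x, covars) {
  ok <- !is.na(x)
  if (sum(ok) < length(y)) { y <- y[ok]; x <- x[ok]
                             covars <- covars[ok, , drop = FALSE] }
  if (length(unique(y)) < 2 || sd(x) == 0)
    return(list(p = NA_real_, status = "untestable"))
  X <- cbind(`(Intercept)` = 1, dosage = x, covars)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  V <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(V) || !fit$converged)
    return(list(p = 0, status = "separation"))
  se <- sqrt(diag(V))[order(piv)]
  b <- fit$coefficients
  if (any(!is.finite(b)) || abs(b[2]) > 15 || se[2] > 100)
    return(list(p = 0, status = "separation"))
  z <- b[2] / se[2]
  list(p = 2 * pnorm(-abs(z)), status = "ok")
}

#' Cross-platform harmonization filter
#'
#' Tests every variant for association with genotyping platform: a
#' logistic regression of the platform indicator on the variant dosage
#' plus the principal components; variants whose dosage coefficient has
#' Wald p below `p_remove` are removed.  With more than two platforms the
#' first two are compared, then the merged set against the next platform,
#' and so on.  Fits with complete separation are treated as removals with
#' reason `"separation"`.
#'
#' @param dosages a `dosage_matrix`.
#' @param platform platform label per sample.
#' @param pcs principal-component matrix (same rows), or `NULL` for an
#'   unadjusted test.
#' @param p_remove removal threshold (default genome-wide 5e-8).
#' @return list with filtered `dosages` and per-variant `report`
#'   (id, p, pass, reason).
#' @export
platform_harmonize <- function(dosages, platform, pcs = NULL,
                               p_remove = 5e-8) {
  stopifnot(inherits(dosages, "dosage_matrix"),
            length(platform) == nrow(dosages$dosages))
  plats <- sort(unique(as.character(platform)))
  m <- ncol(dosages$dosages)
  report <- data.frame(id = dosages$variants$id, p = NA_real_,
                       pass = TRUE, reason = NA_character_,
                       stringsAsFactors = FALSE)
  if (length(plats) < 2) {
    warning("single platform: harmonization is a no-op")
    return(list(dosages = dosages, report = report))
  }
  if (is.null(pcs)) pcs <- matrix(numeric(0), nrow(dosages$dosages), 0)
  for (k in 2:length(plats)) {
    rows <- which(platform %in% plats[1:k])
    y <- as.integer(platform[rows] == plats[k])
    C <- pcs[rows, , drop = FALSE]
    for (j in seq_len(m)) {
      if (!report$pass[j]) next
      w <- wald_platform_p(y, dosages$dosages[rows, j], C)
      if (w$status == "separation") {
        report$pass[j] <- FALSE; report$reason[j] <- "separation"
        report$p[j] <- w$p
      } else if (w$status == "ok") {
        report$p[j] <- if (is.na(report$p[j])) w$p else min(report$p[j], w$p)
        if (w$p < p_remove) {
          report$pass[j] <- FALSE; report$reason[j] <- "platform_assoc"
        }
      }
    }
  }
  if (!any(report$pass)) stop("platform harmonization removed all variants")
  list(dosages = subset_dosages(dosages, variants = which(report$pass)),
       report = report)
}
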