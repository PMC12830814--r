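new_scoring_file <- function(trait_name, records) {
  need <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  stopifnot(all(need %in% names(records)))
  records$chr_name <- as.character(records$chr_name)
  records$chr_position <- as.integer(records$chr_position)
  if (!all(records$effect_allele %in% names(.complement)) ||
      !all(records$other_allele %in% names(.complement)))
    stop("scoring-file alleles must be A, C, G or T")
  if (any(!is.finite(records$effect_weight)))
    stop("scoring-file weights must be finite")
  key <- paste(records$chr_name, records$chr_position)
  if (anyDuplicated(key))
    stop("duplicate variant key(s) in scoring file: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(trait_name = trait_name,
                 records = records[, need]),
            class = "scoring_file")
}

#' @export
print.scoring_file <- function(x, ...) {
  cat("scoring_file:", x$trait_name, "-", nrow(x$records), "variant weights\n")
  invisible(x)
}

#' Parse a PGS-Catalog-style scoring file
#'
#' Reads a tab-separated scoring file: `#`-prefixed header lines are
#' skipped; the first non-comment line is the column-name row (column
#' order is free).  Mandatory columns: `effect_allele`, `effect_weight`,
#' and `chr_name` + `chr_position` (an `rsID` column is carried through
#' if present, otherwise synthesized from position).
#'
#' @param path file path.
#' @param trait_name trait label; defaults to a `#trait_name=` header
#'   field if present, else the file name.
#' @return a `scoring_file`.
#' @export
parse_scoring_file <- function(path, trait_name = NULL) {
  if (!file.exists(path)) stop("scoring file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  if (is.null(trait_name)) {
    tn <- sub("^#trait_name=", "", grep("^#trait_name=", meta, value = TRUE))
    trait_name <- if (length(tn)) tn[1] else
      sub("\\.[^.]*$", "", basename(path))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("scoring file has no records: ", path)
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("effect_allele", "effect_weight", "chr_name", "chr_position"))
    if (!col %in% names(df))
      stop("scoring file missing mandatory column: ", col)
  if (!"other_allele" %in% names(df))
    stop("scoring file missing mandatory column: other_allele")
  if (!"rsID" %in% names(df))
    df$rsID <- paste0(df$chr_name, ":", df$chr_position)
  w <- suppressWarnings(as.numeric(df$effect_weight))
  if (anyNA(w))
    stop("non-numeric effect_weight at record line(s): ",
         paste(which(is.na(w)), collapse = ", "))
  df$effect_weight <- w
  new_scoring_file(trait_name, df)
}

#' Write a scoring file in PGS-Catalog-like format
#'
#' @param scoring a `scoring_file`.
#' @param path output path.
#' @export
write_scoring_file <- function(scoring, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("### metaprs scoring file",
               paste0("#trait_name=", scoring$trait_name)), con)
  write.table(scoring$records, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Harmonize scoring records against a genotype panel
#'
#' Matches each scoring record to the panel by chromosome + position and
#' classifies the allele orientation.  Panel dosages count the `alt`
#' allele, so:
#' \describe{
#'   \item{direct}{effect/other equal panel alt/ref; weight applies to
#'     the dosage.}
#'   \item{allele_swap}{effect/other equal panel ref/alt; weight applies
#'     to `2 - dosage`.}
#'   \item{strand_complement}{alleles match after complementing both;
#'     dosage unchanged.}
#'   \item{complement_then_swap}{complemented and exchanged; weight
#'     applies to `2 - dosage`.}
#'   \item{dropped}{strand-ambiguous (A/T, C/G) record, unmatched
#'     position, or irreconcilable alleles; the drop reason is recorded.}
#' }
#'
#' @param scoring a `scoring_file`.
#' @param variants panel variant metadata (data frame with
#'   chrom, pos, ref, alt) or a `dosage_matrix`.
#' @return data frame of class `harmonization_map`: one row per scoring
#'   record with `variant` (panel index or NA), `action`, `reason`.
#' @export
harmonize_scoring <- function(scoring, variants) {
  if (inherits(variants, "dosage_matrix")) variants <- variants$variants
  rec <- scoring$records
  idx <- match(paste(rec$chr_name, rec$chr_position),
               paste(variants$chrom, variants$pos))
  action <- rep("dropped", nrow(rec))
  reason <- rep(NA_character_, nrow(rec))
  amb <- is_ambiguous_pair(rec$effect_allele, rec$other_allele)
  reason[amb] <- "ambiguous"
  reason[!amb & is.na(idx)] <- "unmatched"
  ok <- !amb & !is.na(idx)
  if (any(ok)) {
    eff <- rec$effect_allele[ok]; oth <- rec$other_allele[ok]
    ref <- variants$ref[idx[ok]]; alt <- variants$alt[idx[ok]]
    a <- rep("dropped", sum(ok))
    a[eff == alt & oth == ref] <- "direct"
    a[eff == ref & oth == alt & a == "dropped"] <- "allele_swap"
    ceff <- comp_allele(eff); coth <- comp_allele(oth)
    a[a == "dropped" & ceff == alt & coth == ref] <- "strand_complement"
    a[a == "dropped" & ceff == ref & coth == alt] <- "complement_then_swap"
    action[ok] <- a
    reason[ok][a == "dropped"] <- "allele_mismatch"
  }
  out <- data.frame(rsID = rec$rsID, variant = ifelse(action == "dropped",
                                                      NA_integer_, idx),
                    action = action, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonization_map", class(out))
  out
}

#' Compute a raw polygenic risk score
#'
#' `score_i = sum_j w_j d*_ij` over non-dropped scoring records, where
#' `d*` is the dosage for direct / strand_complement records and
#' `2 - dosage` for swap actions.  Missing dosages are mean-imputed by
#' twice the panel alt-allele frequency before orientation (configurable
#' to omit the variant for that individual with per-individual
#' renormalization of the score by the fraction of weight observed).
#'
#' @param dosages a `dosage_matrix`.
#' @param scoring a `scoring_file`.
#' @param map harmonization map from [harmonize_scoring()]; computed on
#'   the fly if `NULL`.
#' @param missing one of `"mean_impute"` (default) or `"omit"`.
#' @return numeric score vector (one per individual) with attributes
#'   `n_variants_used` and `trait_name`.
#' @export
compute_prs <- function(dosages, scoring, map = NULL,
                        missing = c("mean_impute", "omit")) {
  missing <- match.arg(missing)
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(scoring, "scoring_file"))
  if (is.null(map)) map <- harmonize_scoring(scoring, dosages)
  use <- which(map$action != "dropped")
  if (!length(use)) stop("no contributing variants for trait ", scoring$trait_name)
  idx <- map$variant[use]
  w <- scoring$records$effect_weight[use]
  swap <- map$action[use] %in% c("allele_swap", "complement_then_swap")
  D <- dosages$dosages[, idx, drop = FALSE]
  if (missing == "mean_impute") {
    p <- colMeans(D, na.rm = TRUE) / 2
    p[is.nan(p)] <- 0
    for (j in seq_along(idx)) {
      mis <- is.na(D[, j])
      if (any(mis)) D[mis, j] <- 2 * p[j]
    }
    if (any(swap)) D[, swap] <- 2 - D[, swap]
    score <- as.numeric(D %*% w)
  } else {
    if (any(swap)) D[, swap] <- 2 - D[, swap]
    obs <- !is.na(D)
    D[!obs] <- 0
    score <- as.numeric(D %*% w)
    wt_total <- sum(abs(w))
    wt_obs <- as.numeric(obs %*% abs(w))
    score <- ifelse(wt_obs > 0, score * wt_total / wt_obs, NA_real_)
  }
  structure(score, n_variants_used = length(use),
            trait_name = scoring$trait_name)
}

#' Standardize score columns to zero mean and unit SD
#'
#' `Z = (score - mean) / SD`; the SD uses the n-1 (sample) convention.
#' Moments come from a reference (e.g. the training cohort) if supplied,
#' otherwise they are computed in-sample; the provenance is recorded.
#'
#' @param scores numeric vector or matrix (individuals x traits).
#' @param reference optional list with `center` and `scale` vectors
#'   (named by trait) to standardize against.
#' @return matrix of class `score_matrix` with attributes `center`,
#'   `scale`, `provenance`.
#' @export
standardize_scores <- function(scores, reference = NULL) {
  X <- as.matrix(scores)
  if (is.null(colnames(X)))
    colnames(X) <- if (!is.null(attr(scores, "trait_name")))
      attr(scores, "trait_name") else paste0("score", seq_len(ncol(X)))
  if (is.null(reference)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    prov <- "in-sample"
  } else {
    ctr <- reference$center[colnames(X)]
    scl <- reference$scale[colnames(X)]
    if (anyNA(ctr) || anyNA(scl)) stop("reference moments missing for some traits")
    prov <- reference$provenance %||% "reference"
  }
  if (any(scl <= 0 | !is.finite(scl)))
    stop("zero or non-finite SD for trait(s): ",
         paste(colnames(X)[scl <= 0 | !is.finite(scl)], collapse = ", "))
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  structure(Z, center = setNames(ctr, colnames(X)),
            scale = setNames(scl, colnames(X)), provenance = prov,
            class = c("score_matrix", "matrix", "array"))
}

#' Compute all component scores for a panel
#'
#' Convenience wrapper: harmonizes and scores every scoring file against
#' the panel and returns the raw score matrix.
#'
#' @param dosages a `dosage_matrix`.
#' @param scoring_files list of `scoring_file` objects.
#' @param missing missing-dosage policy, see [compute_prs()].
#' @return matrix (individuals x traits) of raw scores; harmonization
#'   maps in `attr(, "maps")`, contributing-variant counts in
#'   `attr(, "n_variants_used")`.
#' @export
compute_component_scores <- function(dosages, scoring_files,
                                     missing = "mean_impute") {
  maps <- lapply(scoring_files, harmonize_scoring, variants = dosages)
  raw <- mapply(function(sf, mp) compute_prs(dosages, sf, mp, missing),
                scoring_files, maps)
  colnames(raw) <- vapply(scoring_files, function(sf) sf$trait_name, "")
  rownames(raw) <- dosages$samples
  structure(raw,
            maps = setNames(maps, colnames(raw)),
            n_variants_used = vapply(maps, function(m)
              sum(m$action != "dropped"), integer(1)))
}
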