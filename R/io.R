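#' Write dosages as a tab-separated matrix
#'
#' Layout: one header row (`id chrom pos ref alt` then sample names), one
#' row per variant; missing dosages written as `NA`.
#'
#' @param dosages a `dosage_matrix`.
#' @param path output path.
#' @export
write_dosage_tsv <- function(dosages, path) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  out <- cbind(dosages$variants,
               as.data.frame(t(signif(dosages$dosages, 8))))
  names(out) <- c(names(dosages$variants), dosages$samples)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a tab-separated dosage matrix
#'
#' @param path file written by [write_dosage_tsv()].
#' @return a `dosage_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(meta_cols %in% names(dt)))
    stop("dosage TSV must contain columns ", paste(meta_cols, collapse = ", "))
  variants <- dt[, meta_cols]
  variants$chrom <- as.character(variants$chrom)
  D <- t(as.matrix(dt[, setdiff(names(dt), meta_cols), drop = FALSE]))
  new_dosage_matrix(D, variants, samples = rownames(D))
}

#' Write dosages as a minimal VCF with a DS FORMAT field
#'
#' Emits a VCFv4.2 text file whose per-sample genotype field carries the
#' dosage (`GT:DS`, GT from the rounded dosage, missing as `./.:.`).
#'
#' @param dosages a `dosage_matrix`.
#' @param path output path (plain text, uncompressed).
#' @export
write_vcf_dosage <- function(dosages, path) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  v <- dosages$variants
  D <- dosages$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed allelic dosage of the ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dosages$samples), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- D[, j]
    g <- pmin(pmax(round(d), 0), 2)
    cell <- ifelse(is.na(d), "./.:.",
                   paste0(gt_codes[g + 1], ":", signif(d, 6)))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT:DS", cell), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read per-sample dosages from a VCF
#'
#' Parses an uncompressed VCF text file and extracts the `DS` FORMAT
#' field (falling back to the alt-allele count of `GT` when `DS` is
#' absent for a record).
#'
#' @param path VCF path.
#' @return a `dosage_matrix`.
#' @export
read_vcf_dosage <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: no #CHROM header in ", path)
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- fields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("VCF has no variant records")
  mat <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  variants <- data.frame(id = mat[, 3], chrom = mat[, 1],
                         pos = as.integer(mat[, 2]),
                         ref = mat[, 4], alt = mat[, 5],
                         stringsAsFactors = FALSE)
  fmt <- strsplit(mat[, 9], ":", fixed = TRUE)
  D <- matrix(NA_real_, nrow = length(samples), ncol = nrow(mat))
  for (j in seq_len(nrow(mat))) {
    ds_i <- match("DS", fmt[[j]])
    gt_i <- match("GT", fmt[[j]])
    cells <- strsplit(mat[j, -(1:9)], ":", fixed = TRUE)
    D[, j] <- vapply(cells, function(cc) {
      if (!is.na(ds_i) && length(cc) >= ds_i && cc[ds_i] != ".")
        return(as.numeric(cc[ds_i]))
      if (!is.na(gt_i)) {
        gt <- cc[gt_i]
        if (grepl("\\.", gt)) return(NA_real_)
        return(sum(as.numeric(strsplit(gt, "[/|]")[[1]])))
      }
      NA_real_
    }, numeric(1))
  }
  new_dosage_matrix(D, variants, samples = samples)
}

#' Write a synthetic cohort to disk
#'
#' Emits the dosage panel (TSV and/or VCF), one PGS-Catalog-style scoring
#' file per trait, the covariate/phenotype table, and a JSON ground-truth
#' file (generative parameters, stage seeds, batch-affected variants).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param format `"tsv"`, `"vcf"`, or both.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "vcf")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("tsv" %in% format)
    write_dosage_tsv(cohort$dosages, file.path(dir, "dosages.tsv"))
  if ("vcf" %in% format)
    write_vcf_dosage(cohort$dosages, file.path(dir, "cohort.vcf"))
  for (sf in cohort$scoring_files)
    write_scoring_file(sf, file.path(dir, paste0(
      "scoring_", gsub("[^A-Za-z0-9]", "", sf$trait_name), ".txt")))
  data.table::fwrite(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE)
  cfg <- cohort$truth$config
  truth <- list(config = unclass(cfg)[setdiff(names(cfg), "stage_seeds")],
                stage_seeds = as.list(cfg$stage_seeds),
                batch_variants = cohort$truth$batch_variants)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
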