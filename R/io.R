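# serialize double columns at 17 significant digits so numeric fields
# round-trip bit-exactly through the TSV
fmt_doubles <- function(df) {
  for (j in names(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  df
}

#' Write a cohort to plain-text files
#'
#' Emits `panel.tsv` (one row per SNP), `dosages.tsv` (rows = SNPs, columns =
#' individuals, missing = `NA`), `phenotypes.tsv`, and optionally
#' `cohort.vcf`, a minimal VCF 4.2 with a per-genotype `DS` dosage FORMAT
#' field (ALT = effect allele, missing dosage = `.`). All files round-trip
#' losslessly through the corresponding readers.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param panel SNP panel `data.frame`.
#' @param phenotypes Phenotype `data.frame`.
#' @param out_dir Output directory (created if absent).
#' @param vcf Also write `cohort.vcf`? Default `FALSE`.
#' @return Invisibly, the named vector of paths written.
#' @export
write_cohort <- function(genotypes, panel, phenotypes, out_dir, vcf = FALSE) {
  stopifnot(identical(rownames(genotypes), phenotypes$individual_id),
            all(colnames(genotypes) %in% panel$snp_id))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta_gp", "se_gp", "pval_gp", "imputation_r2")
  paths <- c(panel = file.path(out_dir, "panel.tsv"),
             dosages = file.path(out_dir, "dosages.tsv"),
             phenotypes = file.path(out_dir, "phenotypes.tsv"))
  data.table::fwrite(fmt_doubles(panel[, panel_cols]), paths["panel"], sep = "\t")
  dos <- data.table::data.table(snp_id = colnames(genotypes))
  dos <- cbind(dos, fmt_doubles(data.table::as.data.table(t(genotypes))))
  data.table::fwrite(dos, paths["dosages"], sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(fmt_doubles(phenotypes), paths["phenotypes"], sep = "\t",
                     na = "NA")
  if (vcf) {
    paths <- c(paths, vcf = file.path(out_dir, "cohort.vcf"))
    write_dosage_vcf(genotypes, panel, paths["vcf"])
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @param dir Directory previously written by [write_cohort()].
#' @return `read_cohort()`: list with `panel`, `genotypes`, `phenotypes`.
#' @export
read_cohort <- function(dir) {
  list(panel = read_panel(file.path(dir, "panel.tsv")),
       genotypes = read_dosages(file.path(dir, "dosages.tsv")),
       phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")))
}

#' Read a SNP instrument panel TSV
#' @param path Tab-separated file with header columns `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta_gp`, `se_gp`,
#'   `pval_gp`, `imputation_r2`.
#' @return `data.frame` of SNP records.
#' @export
read_panel <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = "chrom")))
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta_gp", "se_gp", "pval_gp", "imputation_r2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("panel file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$eaf <= 0 | df$eaf >= 1)) stop("eaf must lie strictly in (0,1)", call. = FALSE)
  if (any(df$se_gp <= 0)) stop("se_gp must be positive", call. = FALSE)
  df
}

#' Read a dosage TSV (rows = SNPs, columns = individuals)
#' @param path Tab-separated dosage file with `snp_id` first column.
#' @return Individuals x SNPs numeric matrix with `NA` for missing.
#' @export
read_dosages <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA")
  snp_ids <- dt[[1L]]
  m <- t(as.matrix(dt[, -1L]))
  colnames(m) <- snp_ids
  ok <- !is.na(m)
  if (any(m[ok] < 0 | m[ok] > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  m
}

#' Read a phenotype TSV
#' @param path Tab-separated file with columns `individual_id`, `age`, `sex`,
#'   `country`, `study`, `height_cm`, `smoking`, `drinking`, `case_status`.
#' @return `data.frame`, one row per individual.
#' @export
read_phenotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  need <- c("individual_id", "age", "sex", "country", "study", "height_cm",
            "smoking", "drinking", "case_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual ids in phenotype file", call. = FALSE)
  if (any(!is.na(df$height_cm) & df$height_cm <= 0))
    stop("height_cm must be positive when present", call. = FALSE)
  df
}

# Minimal VCF 4.2 writer with dosage (DS) FORMAT field; positions sorted.
write_dosage_vcf <- function(genotypes, panel, path) {
  pan <- panel[match(colnames(genotypes), panel$snp_id), , drop = FALSE]
  ord <- order(suppressWarnings(as.integer(pan$chrom)), pan$pos)
  pan <- pan[ord, , drop = FALSE]
  geno <- genotypes[, pan$snp_id, drop = FALSE]
  ds <- t(geno)
  ds_chr <- matrix(ifelse(is.na(ds), ".", format(ds, trim = TRUE, digits = 10)),
                   nrow = nrow(ds))
  body <- paste(pan$chrom, pan$pos, pan$snp_id, pan$other_allele,
                pan$effect_allele, ".", "PASS", ".", "DS",
                apply(ds_chr, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=heightMR",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of the ALT (effect) allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#' @param path VCF file as written by [write_cohort()] (`vcf = TRUE`).
#' @return Individuals x SNPs dosage matrix (`NA` for `.`).
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (length(hdr) != 1L) stop("not a valid VCF: missing #CHROM header", call. = FALSE)
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1L]]
  ids <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  snp_ids <- vapply(fields, `[[`, character(1), 3L)
  fmt <- vapply(fields, `[[`, character(1), 9L)
  if (!all(fmt == "DS")) stop("expected a pure DS FORMAT field", call. = FALSE)
  m <- vapply(fields, function(f) {
    v <- f[-(1:9)]
    suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  }, numeric(length(ids)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(ids))
  rownames(m) <- ids
  colnames(m) <- snp_ids
  m
}
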