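qc_report <- function(filter, n_variants_in, n_variants_out,
                      n_individuals_in, n_individuals_out,
                      removed_variants, removed_individuals, thresholds,
                      empty_result = FALSE) {
  structure(list(
    filter = filter,
    n_variants_in = n_variants_in, n_variants_out = n_variants_out,
    n_individuals_in = n_individuals_in, n_individuals_out = n_individuals_out,
    removed_variants = removed_variants,
    removed_individuals = removed_individuals,
    thresholds = thresholds, empty_result = empty_result
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %s> variants %d -> %d, individuals %d -> %d\n",
              x$filter, x$n_variants_in, x$n_variants_out,
              x$n_individuals_in, x$n_individuals_out))
  invisible(x)
}

#' Filter variants and individuals by genotype call rate
#'
#' Variants with a non-missing fraction strictly below `threshold` are removed
#' first; individuals are then filtered on their call rate over the remaining
#' variants. The boundary is read strictly ("less than"), so a call rate
#' exactly at the threshold is retained.
#'
#' @param genotypes Individuals x SNPs dosage matrix with `NA` for missing.
#' @param threshold Minimum call rate in `(0, 1]` (default 0.95).
#' @return List with the filtered `genotypes` and a `report` (`qc_report`);
#'   an empty result sets `report$empty_result` rather than erroring.
#' @export
filter_call_rate <- function(genotypes, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  n_var <- ncol(genotypes); n_ind <- nrow(genotypes)
  var_cr <- colMeans(!is.na(genotypes))
  drop_var <- which(var_cr < threshold)
  g <- genotypes[, setdiff(seq_len(n_var), drop_var), drop = FALSE]
  ind_cr <- if (ncol(g)) rowMeans(!is.na(g)) else rep(0, n_ind)
  drop_ind <- which(ind_cr < threshold)
  g <- g[setdiff(seq_len(n_ind), drop_ind), , drop = FALSE]
  rv <- data.frame(id = colnames(genotypes)[drop_var],
                   reason = sprintf("call_rate=%.4f", var_cr[drop_var]),
                   stringsAsFactors = FALSE)
  ri <- data.frame(id = rownames(genotypes)[drop_ind],
                   reason = sprintf("call_rate=%.4f", ind_cr[drop_ind]),
                   stringsAsFactors = FALSE)
  list(genotypes = g,
       report = qc_report("call_rate", n_var, ncol(g), n_ind, nrow(g),
                          rv, ri, list(call_rate = threshold),
                          empty_result = ncol(g) == 0L || nrow(g) == 0L))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: given the observed allele
#' counts, the two-sided p-value sums the probabilities of all heterozygote
#' counts (of the same parity) whose conditional probability does not exceed
#' that of the observed count. Probabilities are computed by the standard
#' recurrence over heterozygote counts (Wigginton, Cutler & Abecasis 2005),
#' without a mid-p correction. A relative guard of 1e-7 is applied to the
#' inclusion comparison so floating-point ties are handled symmetrically.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Two-sided exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  if (n == 0L) stop("undefined input: all genotype counts are zero", call. = FALSE)
  rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het  # minor allele count
  if (rare == 0L) return(1)                        # monomorphic
  h_max <- if (rare %% 2L == 0L) min(rare, 2L * n - rare) else min(rare, 2L * n - rare)
  h_vals <- seq(rare %% 2L, h_max, by = 2L)
  probs <- numeric(length(h_vals))
  # start near the conditional mode and fill by recurrence
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, rare %% 2L), h_max)
  i_mid <- match(mid, h_vals)
  probs[i_mid] <- 1
  if (i_mid > 1L) {
    for (i in seq(i_mid, 2L)) {
      h <- h_vals[i]
      hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (i_mid < length(h_vals)) {
    for (i in seq(i_mid, length(h_vals) - 1L)) {
      h <- h_vals[i]
      hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Harden dosages to genotype classes for the exact test:
# > 1.5 -> 2, < 0.5 -> 0, else 1; NA dropped.
harden_dosages <- function(d) {
  d <- d[!is.na(d)]
  g <- integer(length(d))
  g[d > 1.5] <- 2L
  g[d >= 0.5 & d <= 1.5] <- 1L
  g
}

#' Filter SNPs by Hardy-Weinberg equilibrium in controls
#'
#' Dosages of control individuals are hardened to genotype classes and tested
#' with [hwe_exact_test()]; SNPs with p strictly below `threshold` are
#' removed. Cases are ignored, so a SNP out of equilibrium only among cases
#' is retained.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param phenotypes Phenotype table with `case_status` identifying controls.
#' @param threshold Removal p-value threshold (default 1e-7).
#' @return List with filtered `genotypes`, a `report`, and the per-SNP
#'   control-only `p_values`.
#' @export
filter_hwe <- function(genotypes, phenotypes, threshold = 1e-7) {
  ph <- phenotypes[match(rownames(genotypes), phenotypes$individual_id), ]
  ctrl <- which(!is.na(ph$case_status) & ph$case_status == "control")
  if (length(ctrl) == 0L)
    stop("no controls present: HWE filtering is defined among controls",
         call. = FALSE)
  p_vals <- apply(genotypes[ctrl, , drop = FALSE], 2L, function(d) {
    g <- harden_dosages(d)
    if (length(g) == 0L) return(1)  # no information: retain
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  drop <- which(p_vals < threshold)
  g <- genotypes[, setdiff(seq_len(ncol(genotypes)), drop), drop = FALSE]
  rv <- data.frame(id = colnames(genotypes)[drop],
                   reason = sprintf("hwe_p=%.3g", p_vals[drop]),
                   stringsAsFactors = FALSE)
  list(genotypes = g,
       report = qc_report("hwe_controls", ncol(genotypes), ncol(g),
                          nrow(genotypes), nrow(g), rv,
                          data.frame(id = character(), reason = character()),
                          list(hwe_p = threshold)),
       p_values = p_vals)
}

#' Squared Pearson correlation between two dosage vectors
#'
#' Computed over pairwise-complete observations. If either vector has zero
#' variance (or fewer than two complete pairs), the LD is undefined and is
#' reported as 1 so that uninformative variants prune together.
#'
#' @param dosage_a,dosage_b Equal-length dosage vectors.
#' @return Squared correlation in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) return(1)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (var(a) == 0 || var(b) == 0) return(1)
  min(1, cor(a, b)^2)
}

#' Greedy LD pruning of an instrument panel
#'
#' SNPs are visited in ascending GWAS p-value order (ties broken by
#' chromosome then position), and a SNP is kept iff its squared correlation
#' with every already-kept SNP is strictly below `r2_threshold`. Missing
#' dosages are mean-imputed for the pairwise correlations; zero-variance
#' (monomorphic) SNPs are never kept.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param panel Panel providing `pval_gp`, `chrom`, `pos` for prioritisation.
#' @param r2_threshold Pairwise R-squared threshold (default 0.01).
#' @return Character vector of kept SNP ids, in visiting (priority) order.
#' @export
ld_prune <- function(genotypes, panel, r2_threshold = 0.01) {
  ids <- colnames(genotypes)
  pan <- panel[match(ids, panel$snp_id), , drop = FALSE]
  ord <- order(pan$pval_gp, suppressWarnings(as.integer(pan$chrom)), pan$pos)
  g <- genotypes
  mono <- logical(ncol(g))
  for (j in seq_len(ncol(g))) {
    na <- is.na(g[, j])
    mu <- mean(g[, j], na.rm = TRUE)
    if (any(na)) g[na, j] <- mu
    mono[j] <- var(g[, j]) == 0 || all(na)
  }
  r2 <- suppressWarnings(cor(g))^2
  r2[!is.finite(r2)] <- 1
  kept <- integer(0)
  for (j in ord) {
    if (mono[j]) next
    if (length(kept) == 0L || all(r2[j, kept] < r2_threshold))
      kept <- c(kept, j)
  }
  ids[kept]
}

#' Filter a panel by imputation quality
#'
#' SNPs with `imputation_r2` strictly greater than `threshold` are retained;
#' a SNP at exactly the threshold is removed. SNPs with a missing quality
#' value are removed with a per-SNP error entry in the report.
#'
#' @param panel SNP panel `data.frame`.
#' @param threshold Imputation R-squared threshold (default 0.7; the
#'   sensitivity analysis uses 0.9).
#' @return List with the retained `panel` subset and a `report`.
#' @export
filter_imputation <- function(panel, threshold = 0.7) {
  r2 <- panel$imputation_r2
  bad_na <- which(is.na(r2))
  drop <- union(bad_na, which(!is.na(r2) & r2 <= threshold))
  keep <- setdiff(seq_len(nrow(panel)), drop)
  reason <- ifelse(seq_len(nrow(panel)) %in% bad_na, "missing_quality",
                   sprintf("imputation_r2=%.4f", r2))
  rv <- data.frame(id = panel$snp_id[drop], reason = reason[drop],
                   stringsAsFactors = FALSE)
  list(panel = panel[keep, , drop = FALSE],
       report = qc_report("imputation", nrow(panel), length(keep),
                          NA_integer_, NA_integer_, rv,
                          data.frame(id = character(), reason = character()),
                          list(impute_r2 = threshold)))
}

#' Genotype principal components for population stratification
#'
#' Each SNP column is mean-imputed, centered at its mean and scaled by
#' `sqrt(2 p (1-p))` with `p` the sample allele frequency; the top-`k` left
#' singular vectors of the standardized matrix (equivalently eigenvectors of
#' the individual-by-individual covariance) are returned as scores, with the
#' fraction of variance each explains. Monomorphic SNPs are excluded. If `k`
#' exceeds the matrix rank the result is truncated with a warning flag.
#'
#' @param genotypes Individuals x SNPs dosage matrix (post-QC).
#' @param k Number of components (default 15, the number used in the
#'   adjusted regression models).
#' @return A `pca_result`: list with `scores` (individuals x k),
#'   `explained_variance` (nonincreasing), `variant_ids_used`, `truncated`.
#' @export
compute_pcs <- function(genotypes, k = 15L) {
  stopifnot(k >= 1L)
  n <- nrow(genotypes)
  x <- genotypes
  use <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    mu <- mean(x[, j], na.rm = TRUE)
    if (any(na)) x[na, j] <- mu
    p_hat <- mu / 2
    s <- sqrt(2 * p_hat * (1 - p_hat))
    if (is.finite(s) && s > 0) {
      x[, j] <- (x[, j] - mu) / s
      use[j] <- TRUE
    }
  }
  x <- x[, use, drop = FALSE]
  ev <- eigen(crossprod(x), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  rank <- sum(lambda > max(lambda) * 1e-12)
  truncated <- FALSE
  k_eff <- as.integer(min(k, rank, n, ncol(x)))
  if (k_eff < k) {
    warning("k exceeds rank; returning ", k_eff, " components")
    truncated <- TRUE
  }
  scores <- x %*% ev$vectors[, seq_len(k_eff), drop = FALSE]
  rownames(scores) <- rownames(genotypes)
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  structure(list(scores = scores,
                 explained_variance = lambda[seq_len(k_eff)] / sum(lambda),
                 variant_ids_used = colnames(genotypes)[use],
                 truncated = truncated),
            class = "pca_result")
}

#' Run the full genotype QC chain
#'
#' Applies, in order: call-rate filtering (variants then individuals), the
#' Hardy-Weinberg exact test in controls, the imputation-quality filter on
#' the panel, LD pruning, and principal components on the surviving set.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param panel SNP panel.
#' @param phenotypes Phenotype table (controls identify the HWE stratum).
#' @param call_rate,hwe_p,impute_r2,r2_prune QC thresholds.
#' @param k_pcs Number of principal components (default 15).
#' @return List with post-QC `genotypes`, `panel`, `phenotypes`, `pcs`, and
#'   `reports` (one `qc_report` per filter, counts reconciling exactly).
#' @export
run_qc <- function(genotypes, panel, phenotypes, call_rate = 0.95,
                   hwe_p = 1e-7, impute_r2 = 0.7, r2_prune = 0.01,
                   k_pcs = 15L) {
  reports <- list()
  cr <- filter_call_rate(genotypes, call_rate)
  reports$call_rate <- cr$report
  g <- cr$genotypes
  ph <- phenotypes[phenotypes$individual_id %in% rownames(g), , drop = FALSE]
  hw <- filter_hwe(g, ph, hwe_p)
  reports$hwe <- hw$report
  g <- hw$genotypes
  pan <- panel[panel$snp_id %in% colnames(g), , drop = FALSE]
  im <- filter_imputation(pan, impute_r2)
  reports$imputation <- im$report
  pan <- im$panel
  g <- g[, pan$snp_id, drop = FALSE]
  kept <- ld_prune(g, pan, r2_prune)
  reports$ld_prune <- qc_report("ld_prune", ncol(g), length(kept),
                                nrow(g), nrow(g),
                                data.frame(id = setdiff(colnames(g), kept),
                                           reason = "ld_r2",
                                           stringsAsFactors = FALSE),
                                data.frame(id = character(), reason = character()),
                                list(ld_r2 = r2_prune))
  g <- g[, kept, drop = FALSE]
  pan <- pan[match(kept, pan$snp_id), , drop = FALSE]
  pcs <- compute_pcs(g, k_pcs)
  list(genotypes = g, panel = pan, phenotypes = ph, pcs = pcs,
       reports = reports)
}

# Serialize a list of qc_reports to JSON (per-filter sections)
qc_reports_to_json <- function(reports, path) {
  out <- lapply(reports, function(r) {
    list(filter = r$filter,
         n_variants_in = r$n_variants_in, n_variants_out = r$n_variants_out,
         n_individuals_in = r$n_individuals_in,
         n_individuals_out = r$n_individuals_out,
         removed_variants = r$removed_variants,
         removed_individuals = r$removed_individuals,
         thresholds = r$thresholds, empty_result = r$empty_result)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
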