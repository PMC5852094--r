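mr_estimate <- function(method, beta, se, p, stratum = "overall",
                        n_snps = NA_integer_, n_individuals = NA_integer_,
                        egger_intercept = NULL, egger_intercept_se = NULL,
                        egger_intercept_p = NULL, df = NULL) {
  q <- if (!is.null(df) && is.finite(df)) stats::qt(0.975, df) else qnorm(0.975)
  out <- list(method = method, beta = beta, se = se,
              ci_low = exp(beta - q * se), ci_high = exp(beta + q * se),
              p = p, stratum = stratum, n_snps = n_snps,
              n_individuals = n_individuals)
  if (method == "Egger") {
    out$egger_intercept <- egger_intercept
    out$egger_intercept_se <- egger_intercept_se
    out$egger_intercept_p <- egger_intercept_p
  }
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate %s [%s]> OR = %.3f (%.3f-%.3f), p = %.3g\n",
              x$method, x$stratum, exp(x$beta), x$ci_low, x$ci_high, x$p))
  if (x$method == "Egger")
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  invisible(x)
}

#' Weighted genetic risk score
#'
#' `GRS = sum_i beta_gp_i * dosage_i` over the panel SNPs present in the
#' genotype matrix, with dosages oriented to the panel's effect allele.
#' Missing dosages are imputed at their Hardy-Weinberg mean `2 * eaf`, which
#' preserves the expected score.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param panel Panel with `beta_gp` weights (SD-of-height units per allele).
#' @return Named numeric vector of scores (one per individual) with the SNP
#'   ids used attached as attribute `"snp_ids"`.
#' @export
compute_grs <- function(genotypes, panel) {
  missing_snps <- setdiff(colnames(genotypes), panel$snp_id)
  if (length(missing_snps))
    stop("mapping error: SNPs absent from panel: ",
         paste(head(missing_snps, 5), collapse = ", "), call. = FALSE)
  pan <- panel[match(colnames(genotypes), panel$snp_id), , drop = FALSE]
  d <- genotypes
  for (j in seq_len(ncol(d))) {
    na <- is.na(d[, j])
    if (any(na)) d[na, j] <- 2 * pan$eaf[j]
  }
  grs <- drop(d %*% pan$beta_gp)
  names(grs) <- rownames(genotypes)
  attr(grs, "snp_ids") <- pan$snp_id
  grs
}

# align a GRS vector with a phenotype table
align_grs <- function(grs, phenotypes) {
  g <- unname(grs[match(phenotypes$individual_id, names(grs))])
  if (anyNA(g)) stop("GRS missing for some individuals", call. = FALSE)
  g
}

#' Instrument strength: height regressed on the GRS
#'
#' Linear model `height_cm ~ GRS + age + sex [+ PCs]`; the GRS coefficient is
#' the cm of height per unit of the weighted score, with a 95% Wald CI.
#'
#' @param grs Named score vector from [compute_grs()].
#' @param phenotypes Phenotype table.
#' @param pcs Optional `pca_result`.
#' @return An `assoc_result`; attributes `cm_per_unit`, `ci_low`, `ci_high`.
#' @export
grs_instrument_strength <- function(grs, phenotypes, pcs = NULL) {
  x <- cbind(build_covariate_design(phenotypes, terms = c("age", "sex"), pcs = pcs),
             grs = align_grs(grs, phenotypes))
  fit <- fit_linear(phenotypes$height_cm, x)
  b <- unname(fit$beta["grs"]); se <- unname(fit$se["grs"])
  attr(fit, "cm_per_unit") <- b
  attr(fit, "ci_low") <- b - qnorm(0.975) * se
  attr(fit, "ci_high") <- b + qnorm(0.975) * se
  fit
}

#' GRS confounder screen
#'
#' Regresses each measured potential confounder on the GRS (adjusted for age,
#' sex and PCs, omitting the screened covariate itself): linear models for
#' quantitative covariates, logistic for binary ones, and one
#' indicator-versus-rest logistic model per country level.
#'
#' @param grs Named score vector.
#' @param phenotypes Phenotype table.
#' @param pcs Optional `pca_result`.
#' @return data.frame with one row per covariate (or country level):
#'   `covariate`, `level`, `model_kind`, `estimate` (per GRS unit), `se`,
#'   `or`, `ci_low`, `ci_high`, `p`.
#' @export
grs_confounder_screen <- function(grs, phenotypes, pcs = NULL) {
  g <- align_grs(grs, phenotypes)
  base <- function(terms) build_covariate_design(phenotypes, terms = terms, pcs = pcs)
  rows <- list()
  add_row <- function(covariate, level, kind, fit) {
    b <- unname(fit$beta["grs"]); se <- unname(fit$se["grs"])
    is_log <- kind == "logistic"
    rows[[length(rows) + 1L]] <<- data.frame(
      covariate = covariate, level = level, model_kind = kind,
      estimate = b, se = se,
      or = if (is_log) exp(b) else NA_real_,
      ci_low = if (is_log) exp(b - qnorm(0.975) * se) else b - qnorm(0.975) * se,
      ci_high = if (is_log) exp(b + qnorm(0.975) * se) else b + qnorm(0.975) * se,
      p = unname(fit$p["grs"]), stringsAsFactors = FALSE)
  }
  add_row("age", NA, "linear",
          fit_linear(phenotypes$age, cbind(base(c("sex")), grs = g)))
  add_row("sex", "male", "logistic",
          fit_logistic(code_binary(phenotypes$sex, "male"),
                       cbind(base(c("age")), grs = g)))
  for (lvl in sort(unique(phenotypes$country)))
    add_row("country", lvl, "logistic",
            fit_logistic(as.numeric(phenotypes$country == lvl),
                         cbind(base(c("age", "sex")), grs = g)))
  add_row("smoking", "ever", "logistic",
          fit_logistic(code_binary(phenotypes$smoking, "ever"),
                       cbind(base(c("age", "sex")), grs = g)))
  add_row("drinking", "ever", "logistic",
          fit_logistic(code_binary(phenotypes$drinking, "ever"),
                       cbind(base(c("age", "sex")), grs = g)))
  do.call(rbind, rows)
}

#' GRS instrumental-variable estimate of the height-HNC effect
#'
#' Logistic model `case ~ GRS + age + sex + country + smoking + drinking
#' [+ PCs]`. Because the GRS weights are per-allele height effects in SD
#' units, one GRS unit is one SD of genetically predicted height, and the
#' per-unit coefficient is reported as the log-OR per SD. An alternative
#' rescaling through the measured-height regression (`sd_height_cm /
#' cm_per_grs_unit`) is available but not the default.
#'
#' @param grs Named score vector.
#' @param phenotypes Phenotype table with `case_status`.
#' @param pcs Optional `pca_result`.
#' @param adjust Covariates to adjust for (drop a stratifier here when
#'   running within a stratum).
#' @param cm_per_grs_unit,sd_height_cm Optional rescaling pair: when both are
#'   given the estimate is rescaled by `sd_height_cm / cm_per_grs_unit`.
#' @return An `mr_estimate` with `method = "GRS"`.
#' @export
grs_outcome_estimate <- function(grs, phenotypes, pcs = NULL,
                                 adjust = c("age", "sex", "country",
                                            "smoking", "drinking"),
                                 cm_per_grs_unit = NULL, sd_height_cm = NULL) {
  x <- cbind(build_covariate_design(phenotypes, terms = adjust, pcs = pcs),
             grs = align_grs(grs, phenotypes))
  fit <- fit_logistic(case_indicator(phenotypes), x)
  b <- unname(fit$beta["grs"]); se <- unname(fit$se["grs"])
  if (!is.null(cm_per_grs_unit) && !is.null(sd_height_cm)) {
    k <- sd_height_cm / cm_per_grs_unit
    b <- b * k; se <- se * k
  }
  mr_estimate("GRS", b, se, wald_p(b, se), n_individuals = fit$n_used)
}

#' Per-SNP Wald ratio
#'
#' `ratio = beta_gd / beta_gp` with first-order standard error
#' `se_gd / |beta_gp|`. Vectorized over the rows of `pair`.
#'
#' @param pair data.frame or list with `beta_gp`, `beta_gd`, `se_gd`.
#' @return List with `ratio` and `se`.
#' @export
wald_ratio <- function(pair) {
  if (any(pair$beta_gp == 0))
    stop("undefined ratio: beta_gp is zero", call. = FALSE)
  list(ratio = pair$beta_gd / pair$beta_gp,
       se = pair$se_gd / abs(pair$beta_gp))
}

#' Inverse-variance weighted (fixed-effect) MR estimate
#'
#' Fixed-effect meta-analysis of per-SNP Wald ratios with weights
#' `w_i = beta_gp_i^2 / se_gd_i^2`: `beta = sum(w * ratio) / sum(w)`,
#' `se = 1 / sqrt(sum(w))`. This equals the weighted regression of `beta_gd`
#' on `beta_gp` through the origin with weights `1 / se_gd^2`; both routes
#' are computed and must agree to 1e-8 (numerical cross-check).
#'
#' @param pairs Summary-pair data.frame (`beta_gp != 0` throughout).
#' @return An `mr_estimate` with `method = "IVW"`.
#' @export
ivw_estimate <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("empty input: at least one summary pair required", call. = FALSE)
  wr <- wald_ratio(pairs)
  w <- pairs$beta_gp^2 / pairs$se_gd^2
  beta <- sum(w * wr$ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  # regression route: beta_gd ~ 0 + beta_gp, weights 1/se_gd^2
  wreg <- 1 / pairs$se_gd^2
  beta_reg <- sum(wreg * pairs$beta_gp * pairs$beta_gd) /
    sum(wreg * pairs$beta_gp^2)
  if (abs(beta - beta_reg) > 1e-8 * max(1, abs(beta)))
    stop("internal inconsistency: IVW meta-analysis and origin-constrained ",
         "regression disagree", call. = FALSE)
  mr_estimate("IVW", beta, se, wald_p(beta, se), n_snps = nrow(pairs))
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_gd` on `beta_gp` with a free intercept and
#' weights `1 / se_gd^2`, after orienting instruments so every `beta_gp` is
#' positive (flipping the signs of both coordinates where needed). The slope
#' is the pleiotropy-adjusted causal log-OR per SD; the intercept estimates
#' average directional pleiotropy. Standard errors are scaled by the
#' multiplicative overdispersion estimate floored at 1, and tests use a t
#' reference with `n_snps - 2` degrees of freedom.
#'
#' @param pairs Summary-pair data.frame with at least 3 rows.
#' @param constrain_intercept Fit through the origin instead (this reproduces
#'   the IVW estimate exactly; exposed for the equivalence check).
#' @return An `mr_estimate` with `method = "Egger"` and intercept fields.
#' @export
mr_egger <- function(pairs, constrain_intercept = FALSE) {
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("insufficient instruments: MR-Egger needs at least 3 pairs",
         call. = FALSE)
  if (any(pairs$beta_gp == 0))
    stop("beta_gp must be nonzero for orientation", call. = FALSE)
  flip <- sign(pairs$beta_gp)
  bx <- pairs$beta_gp * flip
  by <- pairs$beta_gd * flip
  w <- 1 / pairs$se_gd^2
  k <- nrow(pairs)
  if (constrain_intercept) {
    beta <- sum(w * bx * by) / sum(w * bx^2)
    se <- 1 / sqrt(sum(w * bx^2))
    return(mr_estimate("IVW", beta, se, wald_p(beta, se), n_snps = k))
  }
  if (var(bx) == 0)
    stop("unidentifiable intercept: all oriented beta_gp are equal",
         call. = FALSE)
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X * sqrt(w))
  xtwy <- crossprod(X, w * by)
  coefs <- drop(solve(xtwx, xtwy))
  resid <- by - drop(X %*% coefs)
  phi <- sum(w * resid^2) / (k - 2)          # multiplicative overdispersion
  scale2 <- max(1, phi)
  covb <- scale2 * solve(xtwx)
  se_slope <- sqrt(covb[2, 2]); se_int <- sqrt(covb[1, 1])
  df <- k - 2
  p_slope <- 2 * stats::pt(-abs(coefs[2] / se_slope), df)
  p_int <- 2 * stats::pt(-abs(coefs[1] / se_int), df)
  mr_estimate("Egger", unname(coefs[2]), se_slope, p_slope, n_snps = k,
              egger_intercept = unname(coefs[1]),
              egger_intercept_se = se_int, egger_intercept_p = p_int,
              df = df)
}

#' Stratified MR analyses
#'
#' Re-runs the GRS, IVW and MR-Egger estimates overall and within each level
#' of the requested strata (sex, study), dropping the stratifying covariate
#' from the adjustment set. Strata with a single outcome class (or too few
#' instruments) are skipped with a logged reason.
#'
#' @param cohort List with `genotypes`, `panel`, `phenotypes`, and optionally
#'   `pcs` (a `pca_result` computed on the full sample).
#' @param strata Character subset of `c("sex", "study")`.
#' @param engine Per-SNP engine, see [per_snp_outcome_assoc()].
#' @return List with `estimates` (list of `mr_estimate`) and `skipped`
#'   (data.frame of stratum + reason).
#' @export
run_stratified <- function(cohort, strata = c("sex", "study"),
                           engine = c("cpp", "glm")) {
  engine <- match.arg(engine)
  pcs <- cohort$pcs
  grs <- compute_grs(cohort$genotypes, cohort$panel)
  estimates <- list()
  skipped <- data.frame(stratum = character(), reason = character(),
                        stringsAsFactors = FALSE)
  run_one <- function(label, idx, drop_term) {
    ph <- cohort$phenotypes[idx, , drop = FALSE]
    if (nrow(ph) == 0L) {
      skipped <<- rbind(skipped, data.frame(stratum = label, reason = "empty"))
      return(invisible())
    }
    if (length(unique(ph$case_status)) < 2L) {
      skipped <<- rbind(skipped, data.frame(stratum = label,
                                            reason = "single_outcome_class"))
      return(invisible())
    }
    sub_pcs <- if (is.null(pcs)) NULL else {
      p2 <- pcs
      p2$scores <- pcs$scores[rownames(pcs$scores) %in% ph$individual_id, ,
                              drop = FALSE]
      p2
    }
    adjust <- setdiff(c("age", "sex", "country", "smoking", "drinking"), drop_term)
    est_grs <- grs_outcome_estimate(grs, ph, sub_pcs, adjust = adjust)
    est_grs$stratum <- label
    g_sub <- cohort$genotypes[rownames(cohort$genotypes) %in% ph$individual_id, ,
                              drop = FALSE]
    scan <- per_snp_outcome_assoc(g_sub, ph, sub_pcs, cohort$panel,
                                  engine = engine, adjust = adjust)
    est_ivw <- ivw_estimate(scan$pairs); est_ivw$stratum <- label
    est_egg <- mr_egger(scan$pairs); est_egg$stratum <- label
    estimates[[length(estimates) + 1L]] <<- est_grs
    estimates[[length(estimates) + 1L]] <<- est_ivw
    estimates[[length(estimates) + 1L]] <<- est_egg
  }
  run_one("overall", seq_len(nrow(cohort$phenotypes)), character())
  if ("sex" %in% strata)
    for (s in c("male", "female"))
      run_one(s, which(cohort$phenotypes$sex == s), "sex")
  if ("study" %in% strata)
    for (s in c("CE", "ARCAGE"))
      run_one(s, which(cohort$phenotypes$study == s), character())
  list(estimates = estimates, skipped = skipped)
}

# flatten a list of mr_estimates into a data.frame
estimates_to_df <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method, stratum = e$stratum,
               beta = e$beta, se = e$se, or = exp(e$beta),
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               n_snps = e$n_snps, n_individuals = e$n_individuals,
               egger_intercept = e$egger_intercept %||% NA_real_,
               egger_intercept_se = e$egger_intercept_se %||% NA_real_,
               egger_intercept_p = e$egger_intercept_p %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}
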