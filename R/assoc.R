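assoc_result <- function(term_names, beta, se, p, n_used, model_kind,
                         converged = TRUE) {
  structure(list(term_names = term_names,
                 beta = setNames(beta, term_names),
                 se = setNames(se, term_names),
                 p = setNames(p, term_names),
                 n_used = n_used, model_kind = model_kind,
                 converged = converged),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result: %s, n = %d%s>\n", x$model_kind, x$n_used,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(data.frame(beta = x$beta, se = x$se, p = x$p, row.names = x$term_names))
  invisible(x)
}

# two-sided Wald p against the normal reference; handles se = 0 edge cases
wald_p <- function(beta, se) {
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  p[se == 0 & beta != 0] <- 0
  p[se == 0 & beta == 0] <- 1
  p
}

#' Least-squares linear model with Wald inference
#'
#' Ordinary least squares on the supplied design matrix (no intercept is
#' added; include one as a column if wanted). Rows with any missing value are
#' dropped (complete-case). Standard errors use the unbiased residual-variance
#' estimator; p-values are two-sided Wald against the normal reference.
#'
#' @param response Numeric response vector.
#' @param design Numeric matrix with named columns.
#' @return An `assoc_result`.
#' @export
fit_linear <- function(response, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  ok <- complete.cases(response, design)
  y <- response[ok]; x <- design[ok, , drop = FALSE]
  n <- length(y); p <- ncol(x)
  fit <- lm.fit(x, y)
  if (fit$rank < p) {
    aliased <- colnames(x)[is.na(fit$coefficients)]
    stop("collinearity error: design is rank deficient in terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- if (n > p) rss / (n - p) else 0
  r_inv <- backsolve(qr.R(fit$qr), diag(p))
  xtx_inv <- tcrossprod(r_inv)
  se <- sqrt(pmax(0, sigma2 * diag(xtx_inv)))
  beta <- fit$coefficients[colnames(x)]
  assoc_result(colnames(x), unname(beta), se, wald_p(unname(beta), se),
               n, "linear")
}

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm.fit`, convergence tolerance 1e-8, at most 50 iterations) on
#' the supplied design matrix; complete-case rows only. Wald standard errors
#' come from the inverse observed information. Perfect separation raises an
#' error; non-convergence is flagged on the result, never silent.
#'
#' @param response Binary (0/1 or logical) response vector.
#' @param design Numeric matrix with named columns (include the intercept).
#' @return An `assoc_result` with `model_kind = "logistic"`.
#' @export
fit_logistic <- function(response, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  ok <- complete.cases(response, design)
  y <- as.numeric(response[ok]); x <- design[ok, , drop = FALSE]
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  fit <- suppressWarnings(
    glm.fit(x, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 50L))
  )
  if (fit$rank < ncol(x)) {
    aliased <- colnames(x)[is.na(fit$coefficients)]
    stop("collinearity error: design is rank deficient in terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  mu <- fit$fitted.values
  beta <- fit$coefficients[colnames(x)]
  boundary <- any(mu < 1e-10 | mu > 1 - 1e-10)
  if (boundary && max(abs(beta)) > 12)
    stop("separation error: fitted probabilities at the boundary with ",
         "diverging coefficients", call. = FALSE)
  w <- mu * (1 - mu)
  info <- crossprod(x * sqrt(w))
  se <- sqrt(diag(chol2inv(chol(info))))
  assoc_result(colnames(x), unname(beta), se, wald_p(unname(beta), se),
               length(y), "logistic", converged = fit$converged)
}

# -- design-matrix construction -----------------------------------------------

# binary recodings: "missing" and NA propagate as NA (complete-case later)
code_binary <- function(x, one) {
  out <- rep(NA_real_, length(x))
  out[!is.na(x) & x == one] <- 1
  out[!is.na(x) & x != one & x != "missing"] <- 0
  out[!is.na(x) & x == "missing"] <- NA
  out
}

# reference-level indicator coding, reference = lexicographically first level
code_factor <- function(x, prefix) {
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) < 2L) return(NULL)
  m <- vapply(lev[-1L], function(l) as.numeric(x == l), numeric(length(x)))
  colnames(m) <- paste0(prefix, lev[-1L])
  m
}

# Standard covariate design from a phenotype table. `terms` picks covariates;
# pcs appends principal-component scores aligned on individual_id.
build_covariate_design <- function(phenotypes, terms = c("age", "sex", "country",
                                                         "smoking", "drinking"),
                                   pcs = NULL, intercept = TRUE) {
  n <- nrow(phenotypes)
  parts <- list()
  if (intercept) parts$intercept <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  if ("age" %in% terms) parts$age <- matrix(phenotypes$age, ncol = 1,
                                            dimnames = list(NULL, "age"))
  if ("sex" %in% terms) parts$sex <- matrix(code_binary(phenotypes$sex, "male"),
                                            ncol = 1, dimnames = list(NULL, "sex_male"))
  if ("country" %in% terms) parts$country <- code_factor(phenotypes$country, "country_")
  if ("study" %in% terms) parts$study <- code_factor(phenotypes$study, "study_")
  if ("smoking" %in% terms)
    parts$smoking <- matrix(code_binary(phenotypes$smoking, "ever"), ncol = 1,
                            dimnames = list(NULL, "smoking_ever"))
  if ("drinking" %in% terms)
    parts$drinking <- matrix(code_binary(phenotypes$drinking, "ever"), ncol = 1,
                             dimnames = list(NULL, "drinking_ever"))
  if (!is.null(pcs)) {
    sc <- pcs$scores[match(phenotypes$individual_id, rownames(pcs$scores)), ,
                     drop = FALSE]
    parts$pcs <- sc
  }
  do.call(cbind, Filter(Negate(is.null), parts))
}

case_indicator <- function(phenotypes) code_binary(phenotypes$case_status, "case")

#' Observed phenotypic height-HNC model
#'
#' Logistic regression of case status on measured height standardized to 1
#' SD, adjusted for age, sex, country, smoking and drinking. By default
#' height is standardized by the control-sample SD (controls approximate the
#' source population); alternatives are the overall sample SD or an external
#' SD in cm.
#'
#' @param phenotypes Phenotype table with `case_status` filled.
#' @param sd_scope One of `"control"`, `"overall"`, `"external"`.
#' @param external_sd_cm SD in cm used when `sd_scope = "external"`.
#' @return An `assoc_result` whose `"height_sd"` term is the log-OR per SD of
#'   measured height, with `or`, `ci_low`, `ci_high` attached as attributes.
#' @export
phenotypic_height_model <- function(phenotypes,
                                    sd_scope = c("control", "overall", "external"),
                                    external_sd_cm = 6.9) {
  sd_scope <- match.arg(sd_scope)
  h <- phenotypes$height_cm
  s <- switch(sd_scope,
              control = sd(h[phenotypes$case_status == "control"], na.rm = TRUE),
              overall = sd(h, na.rm = TRUE),
              external = external_sd_cm)
  x <- cbind(build_covariate_design(phenotypes),
             height_sd = (h - mean(h, na.rm = TRUE)) / s)
  fit <- fit_logistic(case_indicator(phenotypes), x)
  b <- fit$beta["height_sd"]; se <- fit$se["height_sd"]
  attr(fit, "or") <- exp(unname(b))
  attr(fit, "ci_low") <- exp(unname(b - qnorm(0.975) * se))
  attr(fit, "ci_high") <- exp(unname(b + qnorm(0.975) * se))
  fit
}

#' Per-SNP outcome associations and summary pairs
#'
#' Fits one adjusted logistic model per SNP dosage
#' (`case ~ dosage + age + sex + country + smoking + drinking [+ PCs]`) and
#' merges the resulting log-ORs with the panel's height effects into
#' summary-statistics pairs for IVW / MR-Egger. Missing dosages are
#' mean-imputed per SNP; SNPs whose fit fails (zero variance, separation,
#' non-convergence) are dropped with a reason, never aborting the scan.
#'
#' @param genotypes Post-QC individuals x SNPs dosage matrix.
#' @param phenotypes Phenotype table with `case_status`.
#' @param pcs Optional `pca_result` whose scores enter the design.
#' @param panel Panel supplying `beta_gp` / `se_gp`.
#' @param engine `"cpp"` (batch IRLS, default) or `"glm"` (stats::glm.fit via
#'   [fit_logistic()]), numerically equivalent.
#' @param adjust Covariates to adjust for; drop a stratifier here when
#'   scanning within a stratum.
#' @return List with `pairs` (data.frame: `snp_id`, `beta_gp`, `se_gp`,
#'   `beta_gd`, `se_gd`, `pval_gd`) and `dropped` (id + reason).
#' @export
per_snp_outcome_assoc <- function(genotypes, phenotypes, pcs = NULL, panel,
                                  engine = c("cpp", "glm"),
                                  adjust = c("age", "sex", "country",
                                             "smoking", "drinking")) {
  engine <- match.arg(engine)
  if (!all(colnames(genotypes) %in% panel$snp_id))
    stop("mapping error: genotype SNPs absent from panel", call. = FALSE)
  x <- build_covariate_design(phenotypes, terms = adjust, pcs = pcs)
  y <- case_indicator(phenotypes)
  ok <- complete.cases(y, x)
  x <- x[ok, , drop = FALSE]; y <- y[ok]
  # guard against covariates degenerate within the analysed rows
  keep_col <- colnames(x) == "intercept" |
    apply(x, 2L, function(v) var(v) > 0)
  x <- x[, keep_col, drop = FALSE]
  g <- genotypes[phenotypes$individual_id[ok], , drop = FALSE]
  ids <- colnames(g)
  dropped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  mono <- logical(ncol(g))
  for (j in seq_len(ncol(g))) {
    na <- is.na(g[, j])
    mu <- mean(g[, j], na.rm = TRUE)
    if (any(na)) g[na, j] <- mu
    mono[j] <- !is.finite(mu) || var(g[, j]) == 0
  }
  if (any(mono)) {
    dropped <- rbind(dropped, data.frame(id = ids[mono], reason = "zero_variance",
                                         stringsAsFactors = FALSE))
    g <- g[, !mono, drop = FALSE]
    ids <- ids[!mono]
  }
  if (engine == "cpp") {
    res <- batch_logistic(x, y, g, 1e-8, 50L)
    beta_gd <- res[, 1L]; se_gd <- res[, 2L]; conv <- res[, 3L] > 0.5
  } else {
    beta_gd <- se_gd <- rep(NA_real_, ncol(g)); conv <- logical(ncol(g))
    for (j in seq_len(ncol(g))) {
      f <- tryCatch(fit_logistic(y, cbind(x, dosage = g[, j])),
                    error = function(e) NULL)
      if (!is.null(f)) {
        beta_gd[j] <- f$beta["dosage"]; se_gd[j] <- f$se["dosage"]
        conv[j] <- f$converged
      }
    }
  }
  bad <- !conv | !is.finite(beta_gd) | !is.finite(se_gd) | se_gd <= 0
  if (any(bad)) {
    dropped <- rbind(dropped, data.frame(id = ids[bad], reason = "fit_failure",
                                         stringsAsFactors = FALSE))
  }
  keep <- which(!bad)
  pan <- panel[match(ids[keep], panel$snp_id), , drop = FALSE]
  pairs <- data.frame(snp_id = ids[keep],
                      beta_gp = pan$beta_gp, se_gp = pan$se_gp,
                      beta_gd = beta_gd[keep], se_gd = se_gd[keep],
                      pval_gd = wald_p(beta_gd[keep], se_gd[keep]),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, dropped = dropped, n_used = length(y))
}

#' Write / read summary-statistics pairs
#'
#' The exchange TSV consumed by the summary-level MR estimators:
#' `snp_id`, `beta_gp`, `se_gp`, `beta_gd`, `se_gd`.
#'
#' @param pairs Summary-pair data.frame.
#' @param path TSV path.
#' @export
write_summary_pairs <- function(pairs, path) {
  data.table::fwrite(pairs[, c("snp_id", "beta_gp", "se_gp", "beta_gd", "se_gd")],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_summary_pairs
#' @export
read_summary_pairs <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("snp_id", "beta_gp", "se_gp", "beta_gd", "se_gd")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("summary-pair file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$se_gp <= 0) || any(df$se_gd <= 0))
    stop("standard errors must be positive", call. = FALSE)
  df
}
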