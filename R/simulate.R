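#' Simulation configuration for a synthetic height-MR case-control cohort
#'
#' Builds the configuration object consumed by the cohort simulator. Defaults
#' emulate the study conditions of the analysed cohort: 2,082 head-and-neck
#' cancer cases and 3,477 controls, 599 independent height instruments jointly
#' explaining 16% of height variance (1 SD of height = 6.9 cm), sex-specific
#' mean heights of 161.8 cm (women) and 173.7 cm (men), a causal odds ratio of
#' 1.24 per SD of height, and a negative association between the genetic
#' height score and ever-smoking (log-OR -0.09 per SD of the score, i.e.
#' roughly OR 0.80 per unit of the weighted GRS).
#'
#' @param n_snps Number of clean instrument SNPs (default 599).
#' @param n_cases,n_controls Case-control sample sizes retained (2082 / 3477).
#' @param h2_snp Fraction of height variance explained by the instruments, in
#'   `[0, 1)` (default 0.16). `0` gives a null panel with all effects zero.
#' @param sd_height_cm SD of height in cm used to convert SD units (6.9).
#' @param mean_height_female_cm,mean_height_male_cm Sex-specific mean heights.
#' @param or_height_per_sd Causal odds ratio of case status per SD of height.
#' @param or_smoking,or_drinking Odds ratios of case status for ever- versus
#'   never-smokers / drinkers.
#' @param p_smoke_by_stratum,p_drink_by_stratum 2 x 2 numeric matrices of
#'   ever-use probabilities with rownames `c("female","male")` and colnames
#'   `c("CE","ARCAGE")`.
#' @param grs_smoking_log_or Genetic-confounding channel: log-OR of
#'   ever-smoking per SD of the true genetic height score (negative default
#'   mimics the inverse height-smoking association).
#' @param pleiotropy_frac,pleiotropy_mean Fraction of clean SNPs with direct
#'   outcome effects and the mean of their direct log-ORs (defaults 0, 0).
#' @param missing_rate Per-genotype missingness probability.
#' @param n_hwe_violating Count of extra SNPs appended with heterozygote
#'   deficiency (genotyping-error signature) to exercise the HWE filter.
#' @param n_ld_duplicates Count of extra SNPs appended as noisy copies of
#'   clean SNPs to exercise LD pruning.
#' @param seed Integer RNG seed; fixed seed gives byte-identical cohorts.
#' @param n_population Size of the simulated source population from which the
#'   case-control sample is drawn (default `2.2 * (n_cases + n_controls)`).
#' @param case_oversample Factor by which the expected population case count
#'   exceeds `n_cases`, so the exact case draw is feasible (default 1.3).
#' @param p_male Population male fraction (default 0.75, a hospital-based
#'   control series, not a population census).
#' @param age_mean,age_sd Age distribution in years.
#' @param p_arcage Probability an individual belongs to the ARCAGE study.
#' @param countries,country_probs Country labels and sampling probabilities.
#' @param covariate_missing_rate Probability smoking/drinking is missing.
#' @param het_deficit Fraction of heterozygotes converted to homozygotes in
#'   HWE-violating SNPs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_snps = 599L,
                       n_cases = 2082L,
                       n_controls = 3477L,
                       h2_snp = 0.16,
                       sd_height_cm = 6.9,
                       mean_height_female_cm = 161.8,
                       mean_height_male_cm = 173.7,
                       or_height_per_sd = 1.24,
                       or_smoking = 3.0,
                       or_drinking = 1.5,
                       p_smoke_by_stratum = matrix(c(0.35, 0.72, 0.42, 0.78), 2, 2,
                         dimnames = list(c("female", "male"), c("CE", "ARCAGE"))),
                       p_drink_by_stratum = matrix(c(0.76, 0.95, 0.76, 0.95), 2, 2,
                         dimnames = list(c("female", "male"), c("CE", "ARCAGE"))),
                       grs_smoking_log_or = -0.09,
                       pleiotropy_frac = 0,
                       pleiotropy_mean = 0,
                       missing_rate = 0.01,
                       n_hwe_violating = 0L,
                       n_ld_duplicates = 0L,
                       seed = 1L,
                       n_population = NULL,
                       case_oversample = 1.3,
                       p_male = 0.75,
                       age_mean = 59.5,
                       age_sd = 10.8,
                       p_arcage = 0.45,
                       countries = c("czechia", "poland", "romania", "italy", "germany"),
                       country_probs = c(0.25, 0.2, 0.2, 0.2, 0.15),
                       covariate_missing_rate = 5e-4,
                       het_deficit = 0.7) {
  cfg <- list(
    n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls), h2_snp = h2_snp,
    sd_height_cm = sd_height_cm,
    mean_height_female_cm = mean_height_female_cm,
    mean_height_male_cm = mean_height_male_cm,
    or_height_per_sd = or_height_per_sd, or_smoking = or_smoking,
    or_drinking = or_drinking, p_smoke_by_stratum = p_smoke_by_stratum,
    p_drink_by_stratum = p_drink_by_stratum,
    grs_smoking_log_or = grs_smoking_log_or,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_mean = pleiotropy_mean,
    missing_rate = missing_rate, n_hwe_violating = as.integer(n_hwe_violating),
    n_ld_duplicates = as.integer(n_ld_duplicates), seed = as.integer(seed),
    n_population = if (is.null(n_population))
      as.integer(round(2.2 * (n_cases + n_controls))) else as.integer(n_population),
    case_oversample = case_oversample, p_male = p_male,
    age_mean = age_mean, age_sd = age_sd, p_arcage = p_arcage,
    countries = countries, country_probs = country_probs,
    covariate_missing_rate = covariate_missing_rate, het_deficit = het_deficit
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_snps > 0L, cfg$n_cases > 0L, cfg$n_controls > 0L)
  if (!is.numeric(cfg$h2_snp) || cfg$h2_snp < 0 || cfg$h2_snp >= 1)
    stop("invalid config: h2_snp must lie in [0, 1)", call. = FALSE)
  for (f in c("missing_rate", "pleiotropy_frac", "covariate_missing_rate",
              "p_male", "p_arcage", "het_deficit"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config: ", f, " must lie in [0, 1]", call. = FALSE)
  if (any(cfg$p_smoke_by_stratum < 0 | cfg$p_smoke_by_stratum > 1) ||
      any(cfg$p_drink_by_stratum < 0 | cfg$p_drink_by_stratum > 1))
    stop("invalid config: stratum probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(cfg$or_height_per_sd > 0, cfg$or_smoking > 0, cfg$or_drinking > 0,
            cfg$sd_height_cm > 0, cfg$case_oversample >= 1)
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields mirror [sim_config()] argument names; the stratum probability
#' matrices may be given as nested maps `female: {CE: ..., ARCAGE: ...}`.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("p_smoke_by_stratum", "p_drink_by_stratum")) {
    if (!is.null(raw[[f]]) && is.list(raw[[f]])) {
      m <- matrix(c(raw[[f]]$female$CE, raw[[f]]$male$CE,
                    raw[[f]]$female$ARCAGE, raw[[f]]$male$ARCAGE), 2, 2,
                  dimnames = list(c("female", "male"), c("CE", "ARCAGE")))
      raw[[f]] <- m
    }
  }
  do.call(sim_config, raw)
}

# Stage-specific deterministic seeds (kept below 2^31)
stage_seed <- function(cfg, offset) (abs(cfg$seed) %% 2000000000L) + offset

#' Simulate a SNP instrument panel for height
#'
#' Draws effect-allele frequencies uniform on (0.05, 0.95) and per-allele
#' height effects (SD units) from a zero-mean normal, then rescales the clean
#' SNPs so that the theoretical variance explained under Hardy-Weinberg
#' independence, `sum(2 p (1-p) beta^2)`, equals `h2_snp` exactly. Imputation
#' quality scores are uniform on (0.4, 1.0) so that both the 0.7 and 0.9
#' filters bite. When `n_hwe_violating` or `n_ld_duplicates` are positive,
#' extra defective SNPs are appended beyond `n_snps` (marked in the `defect`
#' column); duplicates reuse a source SNP's effect with an inflated GWAS
#' p-value so LD pruning keeps the source.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta_gp`, `se_gp`, `pval_gp`,
#'   `imputation_r2`, plus generator metadata `defect` and `ld_source`.
#' @export
simulate_snp_panel <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config, 1L))
  n_base <- config$n_snps + config$n_hwe_violating
  n_tot <- n_base + config$n_ld_duplicates

  chrom <- sort(sample(1:22, n_base, replace = TRUE))
  pos <- integer(n_base)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(2.4e8, length(idx)))
  }
  eaf <- runif(n_base, 0.05, 0.95)
  beta_raw <- rnorm(n_base)
  defect <- rep("none", n_base)
  if (config$n_hwe_violating > 0L) {
    bad <- sample.int(n_base, config$n_hwe_violating)
    defect[bad] <- "hwe"
    # moderate frequencies so the heterozygote deficit fires the exact test
    # predictably at realistic control counts
    eaf[bad] <- runif(length(bad), 0.25, 0.75)
  }
  clean <- defect == "none"
  # exact rescale of the clean panel to h2_snp
  if (config$h2_snp == 0) {
    beta <- rep(0, n_base)
  } else {
    beta <- beta_raw
    s2 <- sum(2 * eaf[clean] * (1 - eaf[clean]) * beta_raw[clean]^2)
    beta[clean] <- beta_raw[clean] * sqrt(config$h2_snp / s2)
    s2_bad <- sum(2 * eaf[!clean] * (1 - eaf[!clean]) * beta_raw[!clean]^2)
    if (s2_bad > 0) # defective SNPs get comparably sized effects
      beta[!clean] <- beta_raw[!clean] *
        sqrt(config$h2_snp * (sum(!clean) / max(1, sum(clean))) / s2_bad)
  }
  z <- runif(n_base, 6, 15)
  se <- ifelse(beta != 0, abs(beta) / z, 0.003)
  pval <- 2 * pnorm(-z)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n_base, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
  panel <- data.frame(
    snp_id = sprintf("rs%07d", sample.int(9999999L, n_base)),
    chrom = as.character(chrom), pos = pos,
    effect_allele = ea, other_allele = unname(oa),
    eaf = eaf, beta_gp = beta, se_gp = se, pval_gp = pval,
    imputation_r2 = runif(n_base, 0.4, 1.0),
    defect = defect, ld_source = NA_character_,
    stringsAsFactors = FALSE
  )
  if (config$n_ld_duplicates > 0L) {
    src <- sample(which(clean), config$n_ld_duplicates,
                  replace = config$n_ld_duplicates > sum(clean))
    dup <- panel[src, , drop = FALSE]
    dup$snp_id <- paste0(dup$snp_id, "_dup")
    dup$pos <- dup$pos + 1L
    dup$pval_gp <- pmin(1, dup$pval_gp * 10)
    dup$defect <- "ld_dup"
    dup$ld_source <- panel$snp_id[src]
    panel <- rbind(panel, dup)
  }
  ord <- order(as.integer(panel$chrom), panel$pos, panel$snp_id)
  panel <- panel[ord, , drop = FALSE]
  rownames(panel) <- NULL
  stopifnot(nrow(panel) == n_tot)
  panel
}

#' Simulate hard genotype dosages for a panel
#'
#' Clean SNPs are drawn binomially (2 trials, probability `eaf`), i.e. in
#' Hardy-Weinberg proportions. SNPs marked `defect == "hwe"` have a fraction
#' `het_deficit` of their heterozygotes converted to homozygotes (the classic
#' genotyping-error signature), SNPs marked `defect == "ld_dup"` copy their
#' source SNP's dosages with a small resampling perturbation, and missingness
#' is injected completely at random at `missing_rate`.
#'
#' @param panel Panel from [simulate_snp_panel()].
#' @param n_individuals Number of individuals to draw.
#' @param config A [sim_config()] object.
#' @return Numeric matrix, individuals x SNPs, entries in `[0, 2]` or `NA`;
#'   `rownames` are individual ids, `colnames` SNP ids.
#' @export
simulate_genotypes <- function(panel, n_individuals, config) {
  stopifnot(nrow(panel) > 0L, n_individuals > 0L)
  validate_sim_config(config)
  set.seed(stage_seed(config, 2L))
  n <- as.integer(n_individuals)
  p <- nrow(panel)
  geno <- matrix(rbinom(n * p, 2L, rep(panel$eaf, each = n)), nrow = n, ncol = p)
  dimnames(geno) <- list(sprintf("ind%06d", seq_len(n)), panel$snp_id)

  for (j in which(panel$defect == "ld_dup")) {
    src <- match(panel$ld_source[j], panel$snp_id)
    g <- geno[, src]
    flip <- runif(n) < 0.05
    g[flip] <- rbinom(sum(flip), 2L, panel$eaf[src])
    geno[, j] <- g
  }
  for (j in which(panel$defect == "hwe")) {
    het <- which(geno[, j] == 1L)
    conv <- het[runif(length(het)) < config$het_deficit]
    geno[conv, j] <- ifelse(runif(length(conv)) < panel$eaf[j], 2L, 0L)
  }
  if (config$missing_rate > 0) {
    miss <- runif(n * p) < config$missing_rate
    geno[miss] <- NA_real_
  }
  storage.mode(geno) <- "double"
  geno
}

# True standardized genetic score over clean SNPs, missing dosages imputed at
# their Hardy-Weinberg mean 2*eaf. Var(G*) = h2_snp exactly by panel rescaling.
true_genetic_score <- function(genotypes, panel) {
  clean <- if ("defect" %in% names(panel)) panel$defect == "none"
           else rep(TRUE, nrow(panel))
  sub <- panel[clean, , drop = FALSE]
  d <- genotypes[, sub$snp_id, drop = FALSE]
  for (j in seq_len(ncol(d))) {
    na <- is.na(d[, j])
    if (any(na)) d[na, j] <- 2 * sub$eaf[j]
  }
  drop(sweep(d, 2L, 2 * sub$eaf) %*% sub$beta_gp)
}

#' Simulate phenotypes for a genotyped population
#'
#' Height in SD units is the true genetic score plus environmental noise of
#' variance `1 - h2_snp`; height in cm adds the sex-specific mean and scales
#' by `sd_height_cm`. Age, country and study are drawn independently of
#' genotype. Ever-smoking propensity is logistic in the sex-by-study base rate
#' plus `grs_smoking_log_or` times the standardized genetic score (the
#' genetic-confounding channel); drinking uses its base rates with no genetic
#' channel. `case_status` is left `NA` for [simulate_case_status()].
#'
#' @param genotypes Matrix from [simulate_genotypes()].
#' @param panel Matching panel.
#' @param config A [sim_config()] object.
#' @return `data.frame` with columns `individual_id`, `age`, `sex`, `country`,
#'   `study`, `height_cm`, `smoking`, `drinking`, `case_status`.
#' @export
simulate_phenotypes <- function(genotypes, panel, config) {
  validate_sim_config(config)
  if (!all(colnames(genotypes) %in% panel$snp_id))
    stop("consistency error: genotype SNPs not all present in panel", call. = FALSE)
  set.seed(stage_seed(config, 3L))
  n <- nrow(genotypes)
  g_star <- true_genetic_score(genotypes, panel)
  height_sd <- g_star + rnorm(n, 0, sqrt(1 - config$h2_snp))
  sex <- ifelse(runif(n) < config$p_male, "male", "female")
  height_cm <- ifelse(sex == "male", config$mean_height_male_cm,
                      config$mean_height_female_cm) +
    config$sd_height_cm * height_sd
  age <- pmin(94, pmax(18, round(rnorm(n, config$age_mean, config$age_sd))))
  country <- sample(config$countries, n, replace = TRUE, prob = config$country_probs)
  study <- ifelse(runif(n) < config$p_arcage, "ARCAGE", "CE")
  g_std <- if (config$h2_snp > 0) g_star / sqrt(config$h2_snp) else rep(0, n)

  base_smoke <- config$p_smoke_by_stratum[cbind(sex, study)]
  p_smoke <- plogis(qlogis(base_smoke) + config$grs_smoking_log_or * g_std)
  smoking <- ifelse(runif(n) < p_smoke, "ever", "never")
  base_drink <- config$p_drink_by_stratum[cbind(sex, study)]
  drinking <- ifelse(runif(n) < base_drink, "ever", "never")
  if (config$covariate_missing_rate > 0) {
    smoking[runif(n) < config$covariate_missing_rate] <- "missing"
    drinking[runif(n) < config$covariate_missing_rate] <- "missing"
  }
  data.frame(
    individual_id = rownames(genotypes), age = age, sex = sex,
    country = country, study = study, height_cm = height_cm,
    smoking = smoking, drinking = drinking, case_status = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Assign case status and draw the case-control sample
#'
#' Disease liability follows an additive logistic model:
#' `logit P(case) = a + log(or_height_per_sd) * height_SD +
#' log(or_smoking) * smoke + log(or_drinking) * drink + direct SNP effects`,
#' where direct effects exist for a `pleiotropy_frac` share of clean SNPs with
#' log-ORs drawn around `pleiotropy_mean`. The intercept `a` is tuned by
#' bisection so the expected population case count is
#' `case_oversample * n_cases` (the oversampling margin makes the exact draw
#' feasible); exactly `n_cases` cases and `n_controls` controls are then
#' sampled from the realized population.
#'
#' @param phenotypes Population phenotypes from [simulate_phenotypes()].
#' @param genotypes Matching genotype matrix.
#' @param panel Matching panel.
#' @param config A [sim_config()] object.
#' @return The retained cohort's phenotype table (`n_cases + n_controls`
#'   rows) with `case_status` filled.
#' @export
simulate_case_status <- function(phenotypes, genotypes, panel, config) {
  validate_sim_config(config)
  stopifnot(identical(phenotypes$individual_id, rownames(genotypes)))
  set.seed(stage_seed(config, 4L))
  n <- nrow(phenotypes)
  height_sd <- (phenotypes$height_cm -
                  ifelse(phenotypes$sex == "male", config$mean_height_male_cm,
                         config$mean_height_female_cm)) / config$sd_height_cm
  lp <- log(config$or_height_per_sd) * height_sd +
    log(config$or_smoking) * (phenotypes$smoking == "ever") +
    log(config$or_drinking) * (phenotypes$drinking == "ever")
  if (config$pleiotropy_frac > 0) {
    clean <- which((panel$defect %||% rep("none", nrow(panel))) == "none")
    m <- max(1L, round(config$pleiotropy_frac * length(clean)))
    sel <- sample(clean, m)
    delta <- rnorm(m, config$pleiotropy_mean, abs(config$pleiotropy_mean) / 2)
    d <- genotypes[, panel$snp_id[sel], drop = FALSE]
    for (j in seq_len(ncol(d))) {
      na <- is.na(d[, j])
      if (any(na)) d[na, j] <- 2 * panel$eaf[sel][j]
    }
    # direct effects act on the height-increasing allele, so a nonzero mean
    # is directional in the frame MR-Egger orients to
    orient <- sign(panel$beta_gp[sel])
    orient[orient == 0] <- 1
    lp <- lp + drop(d %*% (delta * orient))
  }
  target <- config$case_oversample * config$n_cases
  if (target >= n - config$n_controls)
    stop("sampling error: population too small for requested case-control counts",
         call. = FALSE)
  lo <- -30; hi <- 30
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (sum(plogis(mid + lp)) < target) lo <- mid else hi <- mid
  }
  intercept <- (lo + hi) / 2
  case <- runif(n) < plogis(intercept + lp)
  if (sum(case) < config$n_cases || sum(!case) < config$n_controls)
    stop("sampling error: realized population cannot supply requested counts",
         call. = FALSE)
  keep_case <- sample(which(case), config$n_cases)
  keep_ctrl <- sample(which(!case), config$n_controls)
  out <- phenotypes[sort(c(keep_case, keep_ctrl)), , drop = FALSE]
  out$case_status <- ifelse(out$individual_id %in%
                              phenotypes$individual_id[keep_case],
                            "case", "control")
  rownames(out) <- NULL
  out
}

#' Simulate a complete seeded case-control cohort
#'
#' Runs panel, genotype, phenotype and case-status simulation and subsets the
#' genotype matrix to the retained case-control sample.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `panel`, `genotypes` (cohort rows only) and
#'   `phenotypes` (cohort rows, `case_status` filled).
#' @export
simulate_cohort <- function(config) {
  panel <- simulate_snp_panel(config)
  geno <- simulate_genotypes(panel, config$n_population, config)
  phen <- simulate_phenotypes(geno, panel, config)
  cohort <- simulate_case_status(phen, geno, panel, config)
  list(panel = panel,
       genotypes = geno[cohort$individual_id, , drop = FALSE],
       phenotypes = cohort)
}
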