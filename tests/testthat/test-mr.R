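test_that("GRS construction is exact, linear, and mean-imputes missingness", {
  pan <- toy_panel(eaf = c(0.3, 0.4), beta = c(0.02, 0.03))
  g <- matrix(c(1, 2), nrow = 1, dimnames = list("i1", pan$snp_id))
  expect_equal(as.vector(compute_grs(g, pan)), 0.08)
  # all-zero weights
  pan0 <- toy_panel(eaf = c(0.3, 0.4), beta = c(0, 0))
  expect_equal(as.vector(compute_grs(g, pan0)), 0)
  # linearity over a panel split
  co <- small_cohort()
  half <- seq_len(ncol(co$genotypes) %/% 2)
  g1 <- compute_grs(co$genotypes[, half, drop = FALSE], co$panel)
  g2 <- compute_grs(co$genotypes[, -half, drop = FALSE], co$panel)
  expect_equal(as.vector(g1 + g2), as.vector(compute_grs(co$genotypes, co$panel)),
               tolerance = 1e-12)
  # missing dosage imputed at 2 * eaf
  gm <- matrix(c(NA, 2), nrow = 1, dimnames = list("i1", pan$snp_id))
  expect_equal(as.vector(compute_grs(gm, pan)), 0.02 * 0.6 + 0.03 * 2)
  # SNPs absent from the panel are a mapping error
  colnames(gm) <- c("unknown", pan$snp_id[2])
  expect_error(compute_grs(gm, pan), "mapping error")
})

test_that("instrument strength: strong on real scores, null on permuted ones", {
  co <- default_cohort()
  grs <- compute_grs(co$genotypes, co$panel)
  st <- grs_instrument_strength(grs, co$phenotypes)
  expect_lt(unname(st$p["grs"]), 1e-10)
  expect_gt(attr(st, "cm_per_unit"), 0)
  # the generator's weights are the true ones, so a unit of GRS is a unit of
  # genetic height: the slope should sit near sd_height_cm
  expect_lt(abs(attr(st, "cm_per_unit") - 6.9), 3 * unname(st$se["grs"]))
  set.seed(123)
  perm <- grs; names(perm) <- sample(names(grs))
  stp <- grs_instrument_strength(perm, co$phenotypes)
  expect_lt(abs(stp$beta["grs"]), 3 * stp$se["grs"])
  # noiseless toy: height exactly 5 x GRS
  ph <- co$phenotypes
  ph$height_cm <- 5 * unname(grs[ph$individual_id])
  st5 <- grs_instrument_strength(grs, ph)
  expect_equal(unname(st5$beta["grs"]), 5, tolerance = 1e-8)
})

test_that("wald ratios follow the first-order definition", {
  wr <- wald_ratio(list(beta_gp = 0.05, beta_gd = 0.02, se_gd = 0.01))
  expect_equal(wr$ratio, 0.4)
  expect_equal(wr$se, 0.2)
  expect_equal(wald_ratio(list(beta_gp = 0.05, beta_gd = 0, se_gd = 0.01))$ratio, 0)
  # flipping the coded allele leaves the ratio unchanged
  wrf <- wald_ratio(list(beta_gp = -0.05, beta_gd = -0.02, se_gd = 0.01))
  expect_equal(wrf$ratio, wr$ratio)
  expect_equal(wrf$se, wr$se)
  expect_error(wald_ratio(list(beta_gp = 0, beta_gd = 1, se_gd = 1)),
               "undefined ratio")
})

test_that("IVW equals its two routes and the hand-computed oracle", {
  # degenerate meta-analysis: a single pair is its own Wald ratio
  p1 <- data.frame(snp_id = "a", beta_gp = 0.05, se_gp = 0.005,
                   beta_gd = 0.02, se_gd = 0.01)
  e1 <- ivw_estimate(p1)
  expect_equal(e1$beta, 0.4); expect_equal(e1$se, 0.2)
  # two-pair hand arithmetic: ratios (0.2, 0.1), weights (25, 4)
  p2 <- data.frame(snp_id = c("a", "b"), beta_gp = c(0.05, 0.02),
                   se_gp = c(0.005, 0.004), beta_gd = c(0.01, 0.002),
                   se_gd = c(0.01, 0.01))
  e2 <- ivw_estimate(p2)
  expect_equal(e2$beta, 5.4 / 29, tolerance = 1e-10)
  expect_equal(e2$se, 1 / sqrt(29), tolerance = 1e-10)
  # exact proportionality recovers the constant whatever the weights
  set.seed(5)
  bp <- runif(20, 0.01, 0.1)
  p3 <- data.frame(snp_id = paste0("s", 1:20), beta_gp = bp, se_gp = 0.005,
                   beta_gd = 0.37 * bp, se_gd = runif(20, 0.005, 0.05))
  expect_equal(ivw_estimate(p3)$beta, 0.37, tolerance = 1e-12)
  expect_error(ivw_estimate(p3[0, ]), "empty input")
})

test_that("MR-Egger recovers exact lines and reduces to IVW when constrained", {
  set.seed(6)
  bp <- runif(10, 0.02, 0.1)
  # line through the origin
  p0 <- data.frame(snp_id = paste0("s", 1:10), beta_gp = bp, se_gp = 0.005,
                   beta_gd = 0.25 * bp, se_gd = runif(10, 0.01, 0.03))
  e0 <- mr_egger(p0)
  expect_equal(e0$beta, 0.25, tolerance = 1e-10)
  expect_equal(e0$egger_intercept, 0, tolerance = 1e-10)
  # affine line: intercept and slope recovered exactly
  pa <- transform(p0, beta_gd = 0.013 + 0.25 * beta_gp)
  ea <- mr_egger(pa)
  expect_equal(ea$beta, 0.25, tolerance = 1e-10)
  expect_equal(ea$egger_intercept, 0.013, tolerance = 1e-10)
  # constraining the intercept reproduces IVW exactly
  pr <- transform(p0, beta_gd = 0.25 * beta_gp + rnorm(10, sd = 0.02))
  expect_equal(mr_egger(pr, constrain_intercept = TRUE)$beta,
               ivw_estimate(pr)$beta, tolerance = 1e-14)
  expect_error(mr_egger(p0[1:2, ]), "insufficient instruments")
  pe <- transform(p0, beta_gp = 0.05)
  expect_error(mr_egger(pe), "unidentifiable intercept")
})

test_that("allele reorientation leaves GRS, IVW and Egger estimates unchanged", {
  co <- small_cohort()
  qc <- run_qc(co$genotypes, co$panel, co$phenotypes, k_pcs = 5)
  scan <- per_snp_outcome_assoc(qc$genotypes, qc$phenotypes, qc$pcs, qc$panel)
  set.seed(9)
  flip <- sample(nrow(scan$pairs), nrow(scan$pairs) %/% 2)
  pf <- scan$pairs
  pf$beta_gp[flip] <- -pf$beta_gp[flip]
  pf$beta_gd[flip] <- -pf$beta_gd[flip]
  expect_equal(ivw_estimate(pf)$beta, ivw_estimate(scan$pairs)$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(pf)$beta, mr_egger(scan$pairs)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pf)$egger_intercept,
               mr_egger(scan$pairs)$egger_intercept, tolerance = 1e-12)
  # individual-level route: flip dosages and weights together
  ids <- qc$panel$snp_id[flip]
  g2 <- qc$genotypes; g2[, ids] <- 2 - g2[, ids]
  pan2 <- qc$panel
  pan2$beta_gp[flip] <- -pan2$beta_gp[flip]
  pan2$eaf[flip] <- 1 - pan2$eaf[flip]
  grs1 <- grs_outcome_estimate(compute_grs(qc$genotypes, qc$panel),
                               qc$phenotypes, qc$pcs)
  grs2 <- grs_outcome_estimate(compute_grs(g2, pan2), qc$phenotypes, qc$pcs)
  expect_equal(grs2$beta, grs1$beta, tolerance = 1e-6)
})

test_that("the confounder screen recovers the planted smoking channel", {
  co <- default_cohort()   # grs_smoking_log_or = -0.09 by default
  grs <- compute_grs(co$genotypes, co$panel)
  scr <- grs_confounder_screen(grs, co$phenotypes)
  smoke <- scr[scr$covariate == "smoking", ]
  expect_lt(smoke$or, 1)
  expect_lt(smoke$p, 0.05)
  # age is simulated independent of genotype
  expect_gt(scr$p[scr$covariate == "age"], 0.001)
})

test_that("null-confounding screens reject at the nominal 5% rate", {
  # 200 seeded replicates of the GRS-smoking association with the channel off
  rej <- vapply(1:200, function(s) {
    cfg <- sim_config(n_snps = 50, seed = 30000 + s, grs_smoking_log_or = 0,
                      missing_rate = 0, covariate_missing_rate = 0)
    pan <- simulate_snp_panel(cfg)
    g <- simulate_genotypes(pan, 500, cfg)
    ph <- simulate_phenotypes(g, pan, cfg)
    grs <- compute_grs(g, pan)
    fit <- fit_logistic(as.numeric(ph$smoking == "ever"),
                        cbind(intercept = 1, age = ph$age,
                              sex = as.numeric(ph$sex == "male"), grs = grs))
    unname(fit$p["grs"]) < 0.05
  }, logical(1))
  band <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(sum(rej), band[1])
  expect_lte(sum(rej), band[2])
})

test_that("negative genetic confounding masks the unadjusted GRS estimate", {
  # strong planted channel; paired adjusted/unadjusted fits per replicate
  diffs <- vapply(1:6, function(s) {
    cfg <- sim_config(n_snps = 150, n_cases = 1000, n_controls = 1600,
                      seed = 40000 + s, grs_smoking_log_or = -0.3,
                      missing_rate = 0, covariate_missing_rate = 0)
    co <- simulate_cohort(cfg)
    grs <- compute_grs(co$genotypes, co$panel)
    adj <- grs_outcome_estimate(grs, co$phenotypes)
    una <- grs_outcome_estimate(grs, co$phenotypes,
                                adjust = c("age", "sex", "country", "drinking"))
    una$beta - adj$beta
  }, numeric(1))
  expect_lt(mean(diffs), 0)     # unadjusted systematically below adjusted
  expect_gt(mean(diffs < 0), 0.5)
})

test_that("Egger detects planted directional pleiotropy", {
  ps <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 50000 + s, pleiotropy_frac = 0.3,
                      pleiotropy_mean = 0.03, missing_rate = 0)
    co <- simulate_cohort(cfg)
    scan <- per_snp_outcome_assoc(co$genotypes, co$phenotypes, NULL, co$panel)
    mr_egger(scan$pairs)$egger_intercept_p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.5)
})

test_that("power calculation is sized, monotone, and formula-consistent", {
  # a null effect has power exactly alpha under both formulations
  for (f in c("linear_probability", "log_odds"))
    expect_equal(mr_power_binary(1000, 1000, or_per_sd = 1, alpha = 0.05,
                                 formula = f), 0.05, tolerance = 1e-12)
  # monotone in sample size, R2 and |log OR|
  p_base <- mr_power_binary(2082, 3477)
  expect_gt(mr_power_binary(4164, 6954), p_base)
  expect_gt(mr_power_binary(2082, 3477, r2_instrument = 0.3), p_base)
  expect_gt(mr_power_binary(2082, 3477, or_per_sd = 1.5), p_base)
  # protective effects mirror harmful ones approximately, not degenerately
  expect_gt(mr_power_binary(2082, 3477, or_per_sd = 0.8), 0.5)
  expect_error(mr_power_binary(100, 100, alpha = 1.5), "alpha")
  expect_error(mr_power_binary(100, 100, r2_instrument = 0), "r2_instrument")
})

test_that("stratified runs honour the stratum contracts", {
  co <- small_cohort()
  qc <- run_qc(co$genotypes, co$panel, co$phenotypes, k_pcs = 5)
  bundle <- list(genotypes = qc$genotypes, panel = qc$panel,
                 phenotypes = qc$phenotypes, pcs = qc$pcs)
  out <- run_stratified(bundle, strata = c("sex", "study"))
  df <- heightMR:::estimates_to_df(out$estimates)
  expect_setequal(unique(df$stratum), c("overall", "male", "female", "CE", "ARCAGE"))
  expect_setequal(unique(df$method), c("GRS", "IVW", "Egger"))
  # homogeneous simulation: sex-stratum IVW intervals overlap
  ivw <- df[df$method == "IVW", ]
  m <- ivw[ivw$stratum == "male", ]; f <- ivw[ivw$stratum == "female", ]
  expect_true(log(m$ci_low) <= log(f$ci_high) &&
                log(f$ci_low) <= log(m$ci_high))
  # a stratum with a single outcome class is skipped with a reason
  ph2 <- qc$phenotypes
  ph2$case_status[ph2$sex == "female"] <- "control"
  out2 <- run_stratified(list(genotypes = qc$genotypes, panel = qc$panel,
                              phenotypes = ph2, pcs = qc$pcs),
                         strata = "sex")
  expect_true("female" %in% out2$skipped$stratum)
  expect_false("female" %in%
                 heightMR:::estimates_to_df(out2$estimates)$stratum)
})
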