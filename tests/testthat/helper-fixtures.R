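# Shared fixtures and independent oracles for the test suite.

# Independent Hardy-Weinberg exact-test oracle: direct enumeration of the
# conditional distribution of the heterozygote count at fixed allele counts,
# via log-factorials (a different route than the package's recurrence).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2L * n_hom_ref + n_het          # allele-A count
  n_b <- 2L * n - n_a
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  h_vals <- seq(rare %% 2L, min(n_a, n_b), by = 2L)
  logp <- vapply(h_vals, function(h) {
    na2 <- (n_a - h) / 2; nb2 <- (n_b - h) / 2
    lfactorial(n) - lfactorial(na2) - lfactorial(h) - lfactorial(nb2) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2L * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_vals)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# small simulated cohort reused across files (built once per session)
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- sim_config(n_snps = 80, n_cases = 250, n_controls = 400,
                      seed = 42, n_hwe_violating = 3, n_ld_duplicates = 4,
                      missing_rate = 0.01)
    .fixture_env$small <- c(simulate_cohort(cfg), list(config = cfg))
  }
  .fixture_env$small
}

# full-scale default cohort (the study conditions), clean channels
default_cohort <- function() {
  if (is.null(.fixture_env$default)) {
    cfg <- sim_config(seed = 2024, missing_rate = 0)
    .fixture_env$default <- c(simulate_cohort(cfg), list(config = cfg))
  }
  .fixture_env$default
}

# a hand-built panel data.frame for direct genotype/GRS arithmetic tests
toy_panel <- function(eaf, beta, snp_id = sprintf("snp%02d", seq_along(eaf))) {
  data.frame(snp_id = snp_id, chrom = "1", pos = seq_along(eaf) * 1000L,
             effect_allele = "A", other_allele = "G", eaf = eaf,
             beta_gp = beta, se_gp = pmax(abs(beta) / 10, 1e-3),
             pval_gp = rep(1e-9, length(eaf)),
             imputation_r2 = rep(0.99, length(eaf)),
             defect = "none", ld_source = NA_character_,
             stringsAsFactors = FALSE)
}

# phenotype table reproducing the printed female/male smoking and drinking
# counts of the studied sample (ages/heights filled with constants)
table1_phenotypes <- function() {
  build <- function(sex, status, smoke_never, smoke_ever, smoke_missing,
                    drink_never, drink_ever, drink_missing) {
    n <- smoke_never + smoke_ever + smoke_missing
    stopifnot(n == drink_never + drink_ever + drink_missing)
    data.frame(
      sex = sex, case_status = status,
      smoking = rep(c("never", "ever", "missing"),
                    c(smoke_never, smoke_ever, smoke_missing)),
      drinking = rep(c("never", "ever", "missing"),
                     c(drink_never, drink_ever, drink_missing)),
      stringsAsFactors = FALSE)
  }
  df <- rbind(
    build("female", "control", 567, 350, 0, 222, 694, 1),
    build("female", "case", 124, 234, 0, 78, 279, 1),
    build("male", "control", 641, 1916, 3, 119, 2441, 0),
    build("male", "case", 81, 1643, 0, 38, 1685, 1))
  df$individual_id <- sprintf("ind%05d", seq_len(nrow(df)))
  df$age <- 60
  df$country <- "czechia"
  df$study <- "CE"
  df$height_cm <- ifelse(df$sex == "male", 173.7, 161.8)
  df
}
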