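#' Pipeline run configuration
#'
#' Bundles the simulation configuration, QC thresholds, model options and
#' strata for [run_pipeline()].
#'
#' @param simulation A [sim_config()] object (ignored when a cohort directory
#'   is supplied to the pipeline).
#' @param call_rate,hwe_p,impute_r2,ld_r2 QC thresholds.
#' @param k_pcs Number of genetic principal components.
#' @param qc_enabled Run the QC stage? (`FALSE` analyses the raw cohort.)
#' @param strata Strata for the stratified analyses.
#' @param engine Per-SNP regression engine (`"cpp"` or `"glm"`).
#' @param power_formula Non-centrality formulation for [mr_power_binary()].
#' @param use_pcs Adjust models for the genetic PCs (default `TRUE`).
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = sim_config(), call_rate = 0.95,
                       hwe_p = 1e-7, impute_r2 = 0.7, ld_r2 = 0.01,
                       k_pcs = 15L, qc_enabled = TRUE,
                       strata = c("sex", "study"),
                       engine = c("cpp", "glm"),
                       power_formula = c("linear_probability", "log_odds"),
                       use_pcs = TRUE) {
  stopifnot(inherits(simulation, "sim_config"),
            call_rate > 0, call_rate <= 1, hwe_p >= 0, hwe_p <= 1,
            impute_r2 >= 0, impute_r2 <= 1, ld_r2 > 0, ld_r2 <= 1, k_pcs >= 1)
  structure(list(simulation = simulation, call_rate = call_rate,
                 hwe_p = hwe_p, impute_r2 = impute_r2, ld_r2 = ld_r2,
                 k_pcs = as.integer(k_pcs), qc_enabled = qc_enabled,
                 strata = strata, engine = match.arg(engine),
                 power_formula = match.arg(power_formula),
                 use_pcs = use_pcs),
            class = "run_config")
}

# config echo with matrices flattened, for the JSON manifest
config_echo <- function(cfg) {
  lapply(unclass(cfg), function(x) {
    if (inherits(x, "sim_config")) config_echo(x)
    else if (is.matrix(x)) as.list(as.data.frame(x))
    else x
  })
}

#' Run the full simulate - QC - MR pipeline
#'
#' Executes, in order: cohort simulation (or loading of user-supplied cohort
#' files), genotype QC with principal components, GRS construction and its
#' three regression specifications, the confounder screen, per-SNP outcome
#' associations, IVW and MR-Egger estimation, the power calculation, the
#' stratified analyses, and report rendering. All outputs are plain text;
#' identical configuration and seed give byte-identical result files. Any
#' stage error aborts with the stage name after persisting the manifest.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory.
#' @param cohort_dir Optional directory of cohort files (as written by
#'   [write_cohort()]) replacing the simulation stage.
#' @return Invisibly, a list with the cohort, QC output, estimates and the
#'   manifest. Files written: `manifest.json`, `qc_report.json`,
#'   `table1.tsv`, `estimates.tsv`, `summary_pairs.tsv`,
#'   `confounder_screen.tsv`, `power.txt`, `log.txt`, and `cohort/`.
#' @export
run_pipeline <- function(config, out_dir, cohort_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("heightMR")),
                   seed = config$simulation$seed,
                   config = config_echo(config), stages = list())
  log_lines <- character()
  log_stage <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s (%.2fs elapsed)", stage, msg,
                                       as.numeric(proc.time()[3L])))
  }
  persist_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      persist_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_stage(name, "done")
    res
  }

  cohort <- stage("simulate", {
    if (is.null(cohort_dir)) {
      co <- simulate_cohort(config$simulation)
      write_cohort(co$genotypes, co$panel, co$phenotypes,
                   file.path(out_dir, "cohort"))
      co
    } else read_cohort(cohort_dir)
  })
  manifest$stages$simulate <- list(
    n_snps = ncol(cohort$genotypes), n_individuals = nrow(cohort$genotypes),
    n_cases = sum(cohort$phenotypes$case_status == "case"),
    n_controls = sum(cohort$phenotypes$case_status == "control"))

  qc <- stage("qc", {
    if (config$qc_enabled) {
      run_qc(cohort$genotypes, cohort$panel, cohort$phenotypes,
             call_rate = config$call_rate, hwe_p = config$hwe_p,
             impute_r2 = config$impute_r2, r2_prune = config$ld_r2,
             k_pcs = config$k_pcs)
    } else {
      list(genotypes = cohort$genotypes, panel = cohort$panel,
           phenotypes = cohort$phenotypes,
           pcs = compute_pcs(cohort$genotypes, config$k_pcs),
           reports = list())
    }
  })
  if (length(qc$reports))
    qc_reports_to_json(qc$reports, file.path(out_dir, "qc_report.json"))
  acct <- list(n_input = ncol(cohort$genotypes),
               n_post_qc = ncol(qc$genotypes))
  for (nm in names(qc$reports))
    acct[[paste0("removed_", nm)]] <- nrow(qc$reports[[nm]]$removed_variants)
  manifest$stages$qc <- acct
  pcs <- if (config$use_pcs) qc$pcs else NULL

  grs <- stage("grs", compute_grs(qc$genotypes, qc$panel))
  strength <- stage("instrument_strength",
                    grs_instrument_strength(grs, qc$phenotypes, pcs))
  screen <- stage("confounder_screen",
                  grs_confounder_screen(grs, qc$phenotypes, pcs))
  phen <- stage("phenotypic_model", phenotypic_height_model(qc$phenotypes))
  scan <- stage("per_snp", per_snp_outcome_assoc(qc$genotypes, qc$phenotypes,
                                                 pcs, qc$panel,
                                                 engine = config$engine))
  manifest$stages$per_snp <- list(n_pairs = nrow(scan$pairs),
                                  n_dropped = nrow(scan$dropped))
  write_summary_pairs(scan$pairs, file.path(out_dir, "summary_pairs.tsv"))

  strat <- stage("mr_estimates",
                 run_stratified(list(genotypes = qc$genotypes, panel = qc$panel,
                                     phenotypes = qc$phenotypes, pcs = pcs),
                                strata = config$strata, engine = config$engine))
  power <- stage("power", {
    n_ca <- sum(qc$phenotypes$case_status == "case")
    n_co <- sum(qc$phenotypes$case_status == "control")
    mr_power_binary(n_ca, n_co,
                    r2_instrument = config$simulation$h2_snp,
                    or_per_sd = config$simulation$or_height_per_sd,
                    formula = config$power_formula)
  })
  manifest$stages$power <- list(power = power)

  stage("report", {
    tab1 <- format(descriptive_table(qc$phenotypes))
    data.table::fwrite(tab1, file.path(out_dir, "table1.tsv"), sep = "\t")
    est_fmt <- estimate_table(strat$estimates, phenotypic = phen)
    data.table::fwrite(est_fmt, file.path(out_dir, "estimates.tsv"), sep = "\t")
    data.table::fwrite(estimates_to_df(strat$estimates),
                       file.path(out_dir, "estimates_numeric.tsv"), sep = "\t")
    data.table::fwrite(screen, file.path(out_dir, "confounder_screen.tsv"),
                       sep = "\t")
    writeLines(sprintf("power_fraction\t%.6f", power),
               file.path(out_dir, "power.txt"))
    TRUE
  })
  manifest$stages$mr_estimates <- list(
    n_estimates = length(strat$estimates),
    skipped = if (nrow(strat$skipped)) strat$skipped else NULL,
    cm_per_grs_unit = attr(strength, "cm_per_unit"))
  persist_manifest()
  invisible(list(cohort = cohort, qc = qc, grs = grs, strength = strength,
                 screen = screen, phenotypic = phen, pairs = scan$pairs,
                 estimates = strat$estimates, power = power,
                 manifest = manifest, out_dir = out_dir))
}
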