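test_that("call-rate filtering applies the strict boundary, variants first", {
  g <- matrix(1, nrow = 100, ncol = 3,
              dimnames = list(sprintf("i%03d", 1:100), c("s1", "s2", "s3")))
  g[1:6, 1] <- NA   # call rate 0.94 -> removed
  g[1:5, 2] <- NA   # call rate 0.95 -> retained (strictly less than)
  out <- filter_call_rate(g, 0.95)
  expect_equal(colnames(out$genotypes), c("s2", "s3"))
  expect_equal(out$report$n_variants_in - nrow(out$report$removed_variants),
               out$report$n_variants_out)
  # no missingness: identity
  g2 <- matrix(0:1, 10, 4, dimnames = list(sprintf("i%d", 1:10), sprintf("s%d", 1:4)))
  out2 <- filter_call_rate(g2)
  expect_identical(out2$genotypes, g2)
  # individuals filtered on the remaining variants
  g3 <- g
  g3[7, 2:3] <- NA  # individual call rate 1/3 over all, 0/2 over remaining
  out3 <- filter_call_rate(g3, 0.95)
  expect_false("i007" %in% rownames(out3$genotypes))
  # an empty result is flagged, not a crash
  g4 <- matrix(NA_real_, 5, 2, dimnames = list(paste0("i", 1:5), c("a", "b")))
  expect_true(filter_call_rate(g4)$report$empty_result)
})

test_that("the HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(30, 0, 0), 1)  # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  p_def <- hwe_exact_test(50, 0, 50)   # complete heterozygote deficit
  expect_equal(p_def, hwe_oracle(50, 0, 50), tolerance = 1e-12)
  expect_lt(p_def, 1e-7)
  expect_error(hwe_exact_test(0, 0, 0), "undefined input")
  # random triple suite against the independent oracle
  set.seed(99)
  for (i in 1:80) {
    n <- sample(3:200, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1); c <- n - a - b
    expect_equal(hwe_exact_test(a, b, c), hwe_oracle(a, b, c),
                 tolerance = 1e-12)
  }
})

test_that("HWE filtering is controls-only and removes injected violators", {
  co <- small_cohort()
  bad <- co$panel$snp_id[co$panel$defect == "hwe"]
  out <- filter_hwe(co$genotypes, co$phenotypes)
  expect_true(all(!bad %in% colnames(out$genotypes)))
  expect_gte(length(bad), 3)
  # threshold zero removes nothing (strict inequality)
  out0 <- filter_hwe(co$genotypes, co$phenotypes, threshold = 0)
  expect_equal(ncol(out0$genotypes), ncol(co$genotypes))
  # a SNP violating HWE only among cases is retained
  set.seed(7)
  n <- 400
  ids <- sprintf("i%04d", 1:n)
  status <- rep(c("control", "case"), each = n / 2)
  g <- cbind(ok = rbinom(n, 2, 0.4), case_only = rbinom(n, 2, 0.4))
  g[status == "case", "case_only"] <- rep(c(0, 2), n / 4)  # het-free in cases
  rownames(g) <- ids
  ph <- data.frame(individual_id = ids, case_status = status,
                   stringsAsFactors = FALSE)
  out2 <- filter_hwe(g, ph)
  expect_true("case_only" %in% colnames(out2$genotypes))
  expect_error(filter_hwe(g, transform(ph, case_status = "case")),
               "no controls")
})

test_that("pairwise LD follows the squared-correlation definition", {
  set.seed(11)
  x <- rbinom(500, 2, 0.3)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)  # reflection symmetry
  expect_equal(ld_r2(x, rep(1, 500)), 1)  # zero variance: prune together
  # independent SNPs at n = 5000 stay below the pruning threshold
  r2 <- replicate(100, ld_r2(rbinom(5000, 2, 0.5), rbinom(5000, 2, 0.5)))
  expect_true(all(r2 < 0.01))
})

test_that("greedy LD pruning keeps the strongest instrument of each cluster", {
  set.seed(13)
  n <- 800
  # genotype chain with ~30% per-step resampling: r2(A,B) and r2(B,C) ~ 0.49,
  # r2(A,C) ~ 0.24
  a <- rbinom(n, 2, 0.5)
  resample <- function(x) {
    i <- runif(n) < 0.3
    x[i] <- rbinom(sum(i), 2, 0.5)
    x
  }
  b <- resample(a); c <- resample(b)
  g <- cbind(A = a, B = b, C = c)
  rownames(g) <- sprintf("i%03d", 1:n)
  pan <- toy_panel(eaf = rep(0.5, 3), beta = rep(0.02, 3),
                   snp_id = c("A", "B", "C"))
  pan$pval_gp <- c(1e-10, 1e-9, 1e-8)  # visiting order A, B, C
  r2ab <- ld_r2(g[, "A"], g[, "B"]); r2bc <- ld_r2(g[, "B"], g[, "C"])
  r2ac <- ld_r2(g[, "A"], g[, "C"])
  thr <- (r2ac + min(r2ab, r2bc)) / 2
  expect_true(r2ac < thr && r2ab > thr && r2bc > thr)
  expect_equal(ld_prune(g, pan, r2_threshold = thr), c("A", "C"))
  # duplicated pair: the smaller-p member is kept
  g2 <- g[, c("A", "A")]; colnames(g2) <- c("dup1", "dup2")
  pan2 <- toy_panel(rep(0.5, 2), rep(0.02, 2), snp_id = c("dup1", "dup2"))
  pan2$pval_gp <- c(1e-6, 1e-12)
  expect_equal(ld_prune(g2, pan2), "dup2")
  # mutually independent SNPs are all kept, and the output is clean
  co <- small_cohort()
  kept <- ld_prune(co$genotypes, co$panel)
  sub <- co$genotypes[, kept]
  r2max <- 0
  for (i in seq_len(ncol(sub) - 1))
    for (j in (i + 1):ncol(sub))
      r2max <- max(r2max, ld_r2(sub[, i], sub[, j]))
  expect_lt(r2max, 0.01)
  # a duplicate and its source are never both kept
  dup <- co$panel[co$panel$defect == "ld_dup", ]
  expect_false(any(dup$snp_id %in% kept & dup$ld_source %in% kept))
})

test_that("imputation-quality filtering is strict and monotone", {
  pan <- toy_panel(rep(0.5, 3), rep(0.02, 3))
  pan$imputation_r2 <- c(0.5, 0.75, 0.95)
  expect_equal(nrow(filter_imputation(pan, 0.7)$panel), 2)
  pan$imputation_r2[1] <- 0.70
  out <- filter_imputation(pan, 0.7)
  expect_false(pan$snp_id[1] %in% out$panel$snp_id)  # boundary removed
  strict <- filter_imputation(pan, 0.9)$panel$snp_id
  expect_true(all(strict %in% out$panel$snp_id))     # 0.9 set nested in 0.7 set
  pan$imputation_r2[2] <- NA
  out2 <- filter_imputation(pan, 0.7)
  expect_true("missing_quality" %in% out2$report$removed_variants$reason)
})

test_that("genotype PCA separates structured subpopulations and is orthonormal", {
  set.seed(31)
  n <- 1000; p <- 200
  f1 <- runif(p, 0.1, 0.9)
  shift <- ifelse(runif(p) < 0.5, 0.25, -0.25)
  f2 <- pmin(pmax(f1 + shift, 0.05), 0.95)
  pop <- rep(0:1, each = n / 2)
  g <- rbind(matrix(rbinom(n / 2 * p, 2, rep(f1, each = n / 2)), n / 2, p),
             matrix(rbinom(n / 2 * p, 2, rep(f2, each = n / 2)), n / 2, p))
  dimnames(g) <- list(sprintf("i%04d", 1:n), sprintf("s%03d", 1:p))
  pcs <- compute_pcs(g, k = 10)
  expect_gt(abs(cor(pcs$scores[, 1], pop)), 0.9)
  ip <- crossprod(pcs$scores)
  expect_lt(max(abs(ip[upper.tri(ip)])) / max(diag(ip)), 1e-8)
  expect_true(all(diff(pcs$explained_variance) <= 1e-12))
  # k above rank truncates with a warning
  g_small <- g[1:5, 1:50]
  expect_warning(res <- compute_pcs(g_small, k = 20), "rank")
  expect_true(res$truncated)
  expect_lte(ncol(res$scores), 5)
})

test_that("the composed QC chain reconciles its accounting exactly", {
  co <- small_cohort()
  qc <- run_qc(co$genotypes, co$panel, co$phenotypes, k_pcs = 5)
  n <- ncol(co$genotypes)
  for (nm in c("call_rate", "hwe")) {
    r <- qc$reports[[nm]]
    expect_equal(r$n_variants_in, n)
    expect_equal(r$n_variants_out, n - nrow(r$removed_variants))
    n <- r$n_variants_out
  }
  r <- qc$reports$imputation
  expect_equal(r$n_variants_in, n)
  n <- r$n_variants_out
  r <- qc$reports$ld_prune
  expect_equal(r$n_variants_in, n)
  expect_equal(r$n_variants_out, ncol(qc$genotypes))
  # every removed id carries exactly one primary reason
  removed <- do.call(rbind, lapply(qc$reports, function(x) x$removed_variants))
  expect_false(anyDuplicated(removed$id) > 0)
  # JSON serialization round-trips structurally
  f <- tempfile(fileext = ".json")
  qc_reports_to_json <- heightMR:::qc_reports_to_json
  qc_reports_to_json(qc$reports, f)
  parsed <- jsonlite::read_json(f)
  expect_named(parsed, c("call_rate", "hwe", "imputation", "ld_prune"))
  unlink(f)
})
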