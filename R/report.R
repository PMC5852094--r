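#' Descriptive cohort table stratified by sex and case status
#'
#' Reproduces the structure of a population-characteristics table: per
#' (sex x case-status) column the sample size, mean (SD) of age and height,
#' and counts with percentages for smoking and drinking levels including
#' missing. Percentages are computed over the column total including missing
#' rows, so within each column the level percentages sum to 100.
#'
#' @param phenotypes Phenotype table with `case_status` filled.
#' @return A `descriptive_table`: list with `cells` (long-format data.frame:
#'   `sex`, `status`, `characteristic`, `level`, `n`, `pct`, `mean`, `sd`)
#'   and `sex_by_status` (percent male/female among cases and controls).
#' @export
descriptive_table <- function(phenotypes) {
  stopifnot(nrow(phenotypes) > 0L)
  sexes <- c("female", "male")
  statuses <- c("control", "case")
  cells <- list()
  add <- function(sex, status, characteristic, level = NA, n = NA,
                  pct = NA, mean = NA, sd = NA) {
    cells[[length(cells) + 1L]] <<- data.frame(
      sex = sex, status = status, characteristic = characteristic,
      level = level, n = n, pct = pct, mean = mean, sd = sd,
      stringsAsFactors = FALSE)
  }
  for (sex in sexes) {
    n_sex <- sum(phenotypes$sex == sex)
    for (status in statuses) {
      sub <- phenotypes[phenotypes$sex == sex &
                          phenotypes$case_status == status, , drop = FALSE]
      n_col <- nrow(sub)
      add(sex, status, "total", n = n_col,
          pct = if (n_sex > 0) 100 * n_col / n_sex else NA)
      add(sex, status, "age", mean = mean(sub$age, na.rm = TRUE),
          sd = sd(sub$age, na.rm = TRUE))
      add(sex, status, "height_cm", mean = mean(sub$height_cm, na.rm = TRUE),
          sd = sd(sub$height_cm, na.rm = TRUE))
      for (ch in c("smoking", "drinking")) {
        v <- sub[[ch]]
        v[is.na(v)] <- "missing"
        for (lvl in c("never", "ever", "missing")) {
          n_lvl <- sum(v == lvl)
          add(sex, status, ch, level = lvl, n = n_lvl,
              pct = if (n_col > 0) 100 * n_lvl / n_col else NA)
        }
      }
    }
  }
  n_by_status <- table(factor(phenotypes$case_status, levels = statuses))
  sbs <- do.call(rbind, lapply(statuses, function(status) {
    n_col <- n_by_status[[status]]
    data.frame(status = status, sex = sexes,
               n = vapply(sexes, function(s)
                 sum(phenotypes$sex == s &
                       phenotypes$case_status == status), integer(1)),
               pct = if (n_col > 0)
                 vapply(sexes, function(s)
                   100 * sum(phenotypes$sex == s &
                               phenotypes$case_status == status) / n_col,
                   numeric(1)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(sbs) <- NULL
  structure(list(cells = do.call(rbind, cells), sex_by_status = sbs),
            class = "descriptive_table")
}

# one-decimal percentage, two-decimal OR: the table's presentation rounding
fmt_pct <- function(x) ifelse(is.na(x), "", sprintf("%.1f%%", x))
fmt_or <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

#' Render a descriptive table to a wide TSV-ready data.frame
#' @param x A `descriptive_table`.
#' @param ... Unused.
#' @return data.frame with one row per characteristic/level and one column
#'   per sex x status stratum, percentages to one decimal.
#' @export
format.descriptive_table <- function(x, ...) {
  cells <- x$cells
  cols <- unique(cells[, c("sex", "status")])
  row_key <- unique(cells[, c("characteristic", "level")])
  out <- data.frame(characteristic = row_key$characteristic,
                    level = row_key$level, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cols))) {
    nm <- paste(cols$sex[i], cols$status[i], sep = "_")
    col <- character(nrow(row_key))
    for (r in seq_len(nrow(row_key))) {
      cell <- cells[cells$sex == cols$sex[i] & cells$status == cols$status[i] &
                      cells$characteristic == row_key$characteristic[r] &
                      (is.na(row_key$level[r]) |
                         (!is.na(cells$level) & cells$level == row_key$level[r])), ,
                    drop = FALSE]
      cell <- cell[1L, ]
      col[r] <- if (!is.na(cell$n))
        sprintf("%d (%s)", cell$n, fmt_pct(cell$pct))
      else sprintf("%.1f (%.1f)", cell$mean, cell$sd)
    }
    out[[nm]] <- col
  }
  out
}

#' Formatted method-by-stratum estimate table
#'
#' Rows are method x stratum; columns are the odds ratio (2 decimals), its
#' 95% CI as `"(a-b)"`, and the p-value; Egger rows carry intercept columns,
#' blank for the other methods. An observed phenotypic estimate can be
#' prepended.
#'
#' @param results List of `mr_estimate` objects.
#' @param phenotypic Optional `assoc_result` from [phenotypic_height_model()].
#' @return data.frame of formatted strings (also suitable for TSV output).
#' @export
estimate_table <- function(results, phenotypic = NULL) {
  stopifnot(length(results) > 0L || !is.null(phenotypic))
  rows <- list()
  fmt_row <- function(method, stratum, or, lo, hi, p, int = NA, int_se = NA,
                      int_p = NA) {
    data.frame(method = method, stratum = stratum,
               or = fmt_or(or),
               ci_95 = sprintf("(%.2f–%.2f)", lo, hi),
               p = sprintf("%.3g", p),
               egger_intercept = ifelse(is.na(int), "", sprintf("%.4f", int)),
               egger_intercept_se = ifelse(is.na(int_se), "", sprintf("%.4f", int_se)),
               egger_intercept_p = ifelse(is.na(int_p), "", sprintf("%.3g", int_p)),
               stringsAsFactors = FALSE)
  }
  if (!is.null(phenotypic))
    rows[[1L]] <- fmt_row("Phenotypic", "overall", attr(phenotypic, "or"),
                          attr(phenotypic, "ci_low"), attr(phenotypic, "ci_high"),
                          unname(phenotypic$p["height_sd"]))
  for (e in results)
    rows[[length(rows) + 1L]] <-
      fmt_row(e$method, e$stratum, exp(e$beta), e$ci_low, e$ci_high, e$p,
              e$egger_intercept %||% NA, e$egger_intercept_se %||% NA,
              e$egger_intercept_p %||% NA)
  do.call(rbind, rows)
}
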