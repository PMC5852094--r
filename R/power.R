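#' Analytic power of a Mendelian randomization test with a binary outcome
#'
#' Closed-form asymptotic power of a two-sided Wald test, at level `alpha`,
#' of the instrumental-variable log-odds-ratio, given total sample size, the
#' case fraction, the variance in the exposure explained by the instruments,
#' and the hypothesized odds ratio per SD of the exposure.
#'
#' Two published non-centrality formulations are implemented:
#' \describe{
#'   \item{`"linear_probability"`}{(default) the binary-outcome formula of
#'   the mRnd MR power calculator (Brion, Shakhbazov & Visscher 2013, Int J
#'   Epidemiol 42:1497-1501): the effect on the probability scale is
#'   `b = K * (OR / (1 + K (OR - 1)) - 1)` with `K` the case fraction, its
#'   variance `(K (1 - K) - b^2) / (N R^2)`, and the non-centrality `b^2`
#'   over that variance, referred to a chi-square(1) test.}
#'   \item{`"log_odds"`}{the log-odds-scale approximation (Burgess 2014, Int
#'   J Epidemiol 43:922-929): non-centrality
#'   `log(OR)^2 * N * R^2 * K * (1 - K)`.}
#' }
#' Both are exactly of size `alpha` at `OR = 1` and strictly increasing in
#' `N`, `R^2` and `|log OR|`.
#'
#' @param n_cases,n_controls Case and control counts.
#' @param r2_instrument Fraction of exposure variance explained by the
#'   instruments, in `(0, 1)` (default 0.16).
#' @param or_per_sd Hypothesized odds ratio per SD of the exposure (1.24).
#' @param alpha Two-sided significance level (0.05).
#' @param formula Non-centrality formulation, see Details.
#' @return Power as a fraction in `[alpha, 1)`.
#' @export
mr_power_binary <- function(n_cases, n_controls, r2_instrument = 0.16,
                            or_per_sd = 1.24, alpha = 0.05,
                            formula = c("linear_probability", "log_odds")) {
  formula <- match.arg(formula)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  if (r2_instrument <= 0 || r2_instrument >= 1)
    stop("r2_instrument must lie strictly in (0, 1)", call. = FALSE)
  if (or_per_sd <= 0) stop("or_per_sd must be positive", call. = FALSE)
  stopifnot(n_cases > 0, n_controls > 0)
  n <- n_cases + n_controls
  k <- n_cases / n
  if (formula == "linear_probability") {
    b <- k * (or_per_sd / (1 + k * (or_per_sd - 1)) - 1)
    v <- (k * (1 - k) - b^2) / (n * r2_instrument)
    ncp <- b^2 / v
    1 - pchisq(qchisq(1 - alpha, 1), df = 1, ncp = ncp)
  } else {
    z <- sqrt(n * r2_instrument * k * (1 - k)) * abs(log(or_per_sd))
    crit <- qnorm(1 - alpha / 2)
    pnorm(z - crit) + pnorm(-z - crit)
  }
}
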