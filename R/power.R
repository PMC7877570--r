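#' Design parameters for a one-stage case-control power calculation
#'
#' @param n_cases,n_controls numbers of cases and unaffected controls.
#' @param prevalence population disease prevalence, in (0,1).
#' @param risk_allele_freq population frequency of the risk allele, in (0,1).
#' @param grr multiplicative per-allele genotype relative risk (> 0).
#' @param alpha two-sided significance level, in (0,1).
#' @return object of class `power_params` (a list).
#' @export
power_params <- function(n_cases, n_controls, prevalence, risk_allele_freq,
                         grr, alpha = 0.05) {
  stopifnot(
    n_cases >= 1, n_controls >= 1,
    prevalence > 0, prevalence < 1,
    risk_allele_freq > 0, risk_allele_freq < 1,
    grr > 0, alpha > 0, alpha < 1
  )
  structure(
    list(
      n_cases = n_cases, n_controls = n_controls, prevalence = prevalence,
      risk_allele_freq = risk_allele_freq, grr = grr, alpha = alpha
    ),
    class = "power_params"
  )
}

# expected risk-allele frequency in cases and in unaffected controls under
# Hardy-Weinberg genotypes and multiplicative per-allele risk scaled so the
# population prevalence matches
case_control_freqs <- function(p) {
  q <- p$risk_allele_freq
  r <- p$grr
  g <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f0 <- p$prevalence / sum(g * c(1, r, r^2))
  f <- f0 * c(1, r, r^2)
  if (any(f > 1) || any(f < 0)) {
    stop("parameters imply genotype penetrance outside [0,1]", call. = FALSE)
  }
  p_case <- sum(g * f * c(0, 0.5, 1)) / p$prevalence
  p_ctrl <- sum(g * (1 - f) * c(0, 0.5, 1)) / (1 - p$prevalence)
  list(p_case = p_case, p_ctrl = p_ctrl, penetrance = f)
}

#' Analytic one-stage case-control power (allelic test)
#'
#' Computes the power of a two-sided two-proportion test on allele counts
#' (2 per individual) comparing cases with unaffected controls, in the
#' one-stage form used by genetic-association power calculators: expected
#' case and control risk-allele frequencies are derived from Hardy-Weinberg
#' genotype frequencies and a multiplicative per-allele risk scaled to the
#' population prevalence, and the rejection probability comes from the
#' normal approximation with the variance evaluated under the alternative.
#' At `grr = 1` the power equals `alpha`; power is non-decreasing in sample
#' sizes and in `|log(grr)|`.
#'
#' @param p a [power_params()] object.
#' @return power in `[0,1]`.
#' @export
gas_power <- function(p) {
  stopifnot(inherits(p, "power_params"))
  fr <- case_control_freqs(p)
  n1 <- 2 * p$n_cases
  n0 <- 2 * p$n_controls
  delta <- fr$p_case - fr$p_ctrl
  se_alt <- sqrt(fr$p_case * (1 - fr$p_case) / n1 +
                   fr$p_ctrl * (1 - fr$p_ctrl) / n0)
  z <- stats::qnorm(1 - p$alpha / 2)
  stats::pnorm(delta / se_alt - z) + stats::pnorm(-delta / se_alt - z)
}
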