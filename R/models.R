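#' Disease model
#'
#' Scalar description of one binary disorder: population prevalence,
#' liability-scale heritability, and GWAS case/control counts. These are the
#' inputs of the case-case reconstruction and of the liability-threshold
#' simulator.
#'
#' @param label trait name.
#' @param prevalence population prevalence K in (0, 1).
#' @param h2_liability liability-scale heritability in [0, 1).
#' @param n_case,n_control GWAS sample counts.
#' @return a `disease_model` list with derived fields `threshold`
#'   (= qnorm(1 - K)) and `n_eff` (= 4 / (1/n_case + 1/n_control)).
#' @export
disease_model <- function(label, prevalence, h2_liability, n_case, n_control) {
  stopifnot(prevalence > 0, prevalence < 1,
            h2_liability >= 0, h2_liability < 1,
            n_case > 0, n_control > 0)
  structure(list(label = label, prevalence = prevalence,
                 h2_liability = h2_liability,
                 n_case = n_case, n_control = n_control,
                 threshold = stats::qnorm(1 - prevalence),
                 n_eff = 4 / (1 / n_case + 1 / n_control)),
            class = "disease_model")
}

#' Cross-trait model
#'
#' Parameters coupling the two disorders: the genetic correlation of causal
#' liability effects, the sampling covariance of effect estimates (the
#' bivariate LD score regression intercept, driven by sample overlap), and
#' the number of effectively independent causal variants.
#'
#' @param rg genetic correlation in [-1, 1].
#' @param error_covariance cross-trait sampling covariance of z-scores.
#' @param m_causal count of effectively independent causal variants (>= 1).
#' @return a `cross_trait_model` list.
#' @export
cross_trait_model <- function(rg, error_covariance = 0, m_causal = 1000) {
  if (abs(rg) > 1) stop("rg must lie in [-1, 1]")
  stopifnot(m_causal >= 1)
  structure(list(rg = rg, error_covariance = error_covariance,
                 m_causal = m_causal),
            class = "cross_trait_model")
}

## liability -> case/population delta-scale heritability multiplier:
## a standardized liability effect b shifts the standardized case-group
## genotype mean by b * phi(tau) / K.
delta_scale_factor <- function(d) {
  stats::dnorm(d$threshold) / d$prevalence
}

## liability -> observed (0/1 at 50/50 ascertainment, the n_eff convention)
## scale factor for per-variant effects: Lee et al. conversion at sample
## prevalence P = 1/2.
obs_scale_factor <- function(d) {
  K <- d$prevalence
  stats::dnorm(d$threshold) / (K * (1 - K)) * sqrt(0.25)
}

#' Convert observed-scale to liability-scale heritability
#'
#' Standard threshold-model conversion (Lee et al.) for a case-control study
#' analysed at effective sample size, i.e. sample prevalence 1/2:
#' `h2_liab = h2_obs * K^2 (1 - K)^2 / (phi(tau)^2 * P(1 - P))`.
#'
#' @param h2_obs observed-scale estimate.
#' @param prevalence population prevalence K.
#' @param sample_prev sample prevalence P (default 0.5, the n_eff convention).
#' @return liability-scale heritability.
#' @export
h2_observed_to_liability <- function(h2_obs, prevalence, sample_prev = 0.5) {
  tau <- stats::qnorm(1 - prevalence)
  h2_obs * prevalence^2 * (1 - prevalence)^2 /
    (stats::dnorm(tau)^2 * sample_prev * (1 - sample_prev))
}
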