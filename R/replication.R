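#' Assemble a replication input table
#'
#' Aligns discovery and replication statistics on shared variants and the
#' same effect allele (both inputs are assumed pre-harmonised with
#' [harmonize_pair()]). Variants absent from replication are counted as
#' untestable, never imputed.
#'
#' @param discovery,replication sumstats tables.
#' @return a `replication_input` data.frame with `variant_id`,
#'   `beta_disc`, `se_disc`, `beta_repl`, `se_repl`, `z_repl`, plus
#'   attribute `n_untestable`.
#' @export
replication_input <- function(discovery, replication) {
  idx <- match(discovery$variant_id, replication$variant_id)
  testable <- !is.na(idx)
  out <- data.frame(variant_id = discovery$variant_id[testable],
                    beta_disc = discovery$beta[testable],
                    se_disc = discovery$se[testable],
                    beta_repl = replication$beta[idx[testable]],
                    se_repl = replication$se[idx[testable]],
                    z_repl = replication$z[idx[testable]],
                    stringsAsFactors = FALSE)
  mism <- discovery$effect_allele[testable] !=
    replication$effect_allele[idx[testable]]
  if (any(mism)) stop("effect alleles not aligned; harmonise first")
  attr(out, "n_untestable") <- sum(!testable)
  class(out) <- c("replication_input", "data.frame")
  out
}

## exact upper-tail binomial probability P(X >= k | n, p)
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Sign-concordance replication test
#'
#' Counts variants whose replication effect has the same sign as the
#' discovery effect and computes the exact upper-tail binomial probability
#' `P(X >= k | n, 0.5)`. Variants with a zero effect in either dataset are
#' excluded from both `k` and `n`.
#'
#' @param r a `replication_input`.
#' @return list `k`, `n`, `p`.
#' @export
sign_concordance_test <- function(r) {
  nz <- r$beta_disc != 0 & r$beta_repl != 0
  if (sum(!nz) > 0) {
    message("sign_concordance_test: excluded ", sum(!nz),
            " variant(s) with zero effect")
  }
  k <- sum(sign(r$beta_disc[nz]) == sign(r$beta_repl[nz]))
  n <- sum(nz)
  list(k = k, n = n, p = binom_upper_tail(k, n, 0.5))
}

#' Nominal-replication binomial test
#'
#' One-sided replication p-values are computed from the replication z-score
#' oriented by the discovery sign, `p_one = 1 - pnorm(z_repl *
#' sign(beta_disc))`; `k` counts variants with `p_one < alpha` and the test
#' reports the exact `P(X >= k | n, null_rate)`.
#'
#' @param r a `replication_input`.
#' @param alpha one-sided nominal threshold (default 0.05).
#' @param null_rate chance replication rate under the null (default 0.05).
#' @return list `k`, `n`, `p`, `p_one_sided` (per-variant).
#' @export
nominal_replication_test <- function(r, alpha = 0.05, null_rate = 0.05) {
  p_one <- 1 - stats::pnorm(r$z_repl * sign(r$beta_disc))
  k <- sum(p_one < alpha)
  n <- nrow(r)
  list(k = k, n = n, p = binom_upper_tail(k, n, null_rate),
       p_one_sided = p_one)
}

#' Allele-frequency enrichment against a reference panel
#'
#' One-sided Fisher's exact test on the 2x2 allele-count table (cases vs
#' reference) under the additive coding (two alleles per individual).
#' `direction = 1` tests for enrichment of the effect allele in cases,
#' `-1` for depletion.
#'
#' @param case_counts length-2 vector `c(effect, other)` allele counts in
#'   cases.
#' @param reference_counts length-2 vector for the reference panel.
#' @param direction expected sign of the enrichment (+1 or -1).
#' @return list `odds_ratio`, `p`, `zero_margin` flag.
#' @export
af_enrichment_test <- function(case_counts, reference_counts, direction = 1) {
  stopifnot(length(case_counts) == 2, length(reference_counts) == 2,
            all(case_counts >= 0), all(reference_counts >= 0))
  tab <- rbind(cases = case_counts, reference = reference_counts)
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  alternative <- if (direction >= 0) "greater" else "less"
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- (case_counts[1] * reference_counts[2]) /
    (case_counts[2] * reference_counts[1])
  list(odds_ratio = unname(or), p = unname(ft$p.value),
       conditional_or = unname(ft$estimate), zero_margin = zero_margin)
}

#' Discovery-replication effect-size agreement
#'
#' Pearson correlation (two-sided p) and regression slope of replication
#' betas on discovery betas, with the z-score analogue as a sensitivity
#' output.
#'
#' @param r a `replication_input` with at least 3 testable variants.
#' @return list `r`, `p`, `slope`, `slope_se`, `r_z` (z-score variant).
#' @export
effect_agreement <- function(r) {
  if (nrow(r) < 3) stop("need at least 3 testable variants")
  if (stats::sd(r$beta_disc) == 0 || stats::sd(r$beta_repl) == 0) {
    stop("constant effect vector: correlation undefined")
  }
  ct <- stats::cor.test(r$beta_disc, r$beta_repl)
  fit <- summary(stats::lm(beta_repl ~ beta_disc, data = r))$coefficients
  z_disc <- r$beta_disc / r$se_disc
  r_z <- stats::cor(z_disc, r$z_repl)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = fit["beta_disc", "Estimate"],
       slope_se = fit["beta_disc", "Std. Error"],
       r_z = r_z)
}
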