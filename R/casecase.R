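#' Convert case-control effects to the standardized frequency-difference scale
#'
#' Maps each log-odds effect to the standardized difference in effect-allele
#' dosage between cases and the population ("delta" scale), using the
#' small-effect approximation `delta = beta * sqrt(2 p (1 - p)) * (1 - K)`:
#' `beta * sqrt(2p(1-p))` estimates the standardized case-control dosage
#' difference (dosage variance `2p(1-p)`), and the `(1 - K)` factor rescales
#' case-versus-control to case-versus-population, so that a standardized
#' liability effect `b` maps to `b * phi(tau) / K` on this scale.
#' `var_delta = se^2 * 2 p (1 - p) * (1 - K)^2` under the same approximation.
#' The conversion constants are recorded in the `conversion` attribute.
#'
#' @param t binary-trait sumstats table (beta on the log-odds scale).
#' @param d the trait's [disease_model()].
#' @return data.frame with `variant_id`, `delta`, `var_delta`; variants with
#'   `eaf` at 0 or 1 are skipped with a log entry.
#' @export
to_delta_scale <- function(t, d) {
  ok <- t$eaf > 0 & t$eaf < 1
  if (any(!ok)) {
    message("to_delta_scale: skipped ", sum(!ok), " variant(s) with eaf at 0 or 1")
  }
  t <- t[ok, , drop = FALSE]
  K <- d$prevalence
  pq2 <- 2 * t$eaf * (1 - t$eaf)
  out <- data.frame(variant_id = t$variant_id,
                    delta = t$beta * sqrt(pq2) * (1 - K),
                    var_delta = t$se^2 * pq2 * (1 - K)^2,
                    stringsAsFactors = FALSE)
  attr(out, "conversion") <- c(dosage_var_factor = 2, one_minus_K = 1 - K)
  out
}

#' Expected per-variant genetic distance between the two case groups
#'
#' F_ST,causal: the expected squared standardized difference in effect-allele
#' frequency between cases of disease a and cases of disease b at a causal
#' variant. Computed from the delta-scale heritabilities
#' `h2_delta = h2_liability * (phi(tau) / K)^2` (the liability heritability
#' transformed through the threshold model at each prevalence) as
#' `(h2d_a + h2d_b - 2 rg sqrt(h2d_a h2d_b)) / m_causal`.
#'
#' @param a,b [disease_model()] objects.
#' @param x [cross_trait_model()] carrying `rg` and `m_causal`.
#' @return scalar expected squared standardized case-group frequency
#'   difference per causal variant.
#' @export
fst_causal <- function(a, b, x) {
  if (abs(x$rg) > 1) stop("rg must lie in [-1, 1]")
  h2d_a <- a$h2_liability * delta_scale_factor(a)^2
  h2d_b <- b$h2_liability * delta_scale_factor(b)^2
  (h2d_a + h2d_b - 2 * x$rg * sqrt(h2d_a * h2d_b)) / x$m_causal
}

#' Reconstruct case-case association statistics from two case-control GWAS
#'
#' The ordinary (OLS) statistic contrasts the delta-scale effects directly:
#' `delta_ols = delta_a - delta_b` with variance
#' `var_a + var_b - 2 c sqrt(var_a var_b)` where `c` is the cross-trait
#' sampling covariance of z-scores (the bivariate LD score intercept). It
#' tests for any difference in standardized case-group allele frequencies,
#' and is therefore biased away from zero at variants whose causal liability
#' effects are equal in the two disorders but whose prevalences or
#' heritabilities differ.
#'
#' The exact statistic rescales each disorder's delta by the inverse of its
#' liability-to-delta factor, `w_t = K_t / phi(tau_t)`, before differencing,
#' so that a variant with equal causal liability effects in both disorders
#' has expectation exactly zero (the zero-expectation contract; its
#' calibration is enforced by stress-test simulation).
#'
#' @param a,b harmonised sumstats tables (same variants, same order).
#' @param da,db [disease_model()] objects for the two disorders.
#' @param x [cross_trait_model()]; `error_covariance` feeds the overlap term.
#'   When NULL, the exact path is still produced but overlap is taken as 0
#'   with a warning.
#' @param attenuation sample-size attenuation scalar applied to both n_eff
#'   (default 1, recorded in the output metadata).
#' @param gw_threshold genome-wide significance threshold (default 5e-8).
#' @return a `casecase_result` data.frame with per-variant `delta_ols`,
#'   `se_ols`, `z_ols`, `p_ols`, `delta_exact`, `se_exact`, `z_exact`,
#'   `p_exact`, `sig_ols`, `sig_exact` and `flag_stress` (ordinary
#'   significant, exact not). A `parameters` attribute records every scalar
#'   input.
#' @export
casecase_stats <- function(a, b, da, db, x = NULL, attenuation = 1,
                           gw_threshold = 5e-8) {
  stopifnot(nrow(a) == nrow(b))
  if (!all(a$variant_id == b$variant_id)) {
    stop("tables must be harmonised (shared variant order) first")
  }
  if (is.null(x)) {
    warning("no cross-trait model supplied; overlap covariance taken as 0")
    x <- cross_trait_model(rg = 0, error_covariance = 0, m_causal = 1000)
  }
  c_ov <- x$error_covariance
  if (abs(c_ov) > 0.95) {
    warning("overlap covariance ", signif(c_ov, 3),
            " outside (-0.95, 0.95); clamped (noisy intercept estimate?)")
    c_ov <- sign(c_ov) * 0.95
  }

  dta <- to_delta_scale(a, da)
  dtb <- to_delta_scale(b, db)
  keep <- intersect(dta$variant_id, dtb$variant_id)
  dta <- dta[match(keep, dta$variant_id), ]
  dtb <- dtb[match(keep, dtb$variant_id), ]
  meta <- a[match(keep, a$variant_id),
            c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf")]

  ## attenuation scales effective sample sizes, i.e. variances by 1/atten
  va <- dta$var_delta / attenuation
  vb <- dtb$var_delta / attenuation

  d_ols <- dta$delta - dtb$delta
  v_ols <- va + vb - 2 * c_ov * sqrt(va * vb)
  se_ols <- sqrt(v_ols)
  z_ols <- d_ols / se_ols
  p_ols <- 2 * stats::pnorm(-abs(z_ols))

  w_a <- 1 / delta_scale_factor(da)
  w_b <- 1 / delta_scale_factor(db)
  d_ex <- w_a * dta$delta - w_b * dtb$delta
  v_ex <- w_a^2 * va + w_b^2 * vb - 2 * c_ov * w_a * w_b * sqrt(va * vb)
  se_ex <- sqrt(v_ex)
  z_ex <- d_ex / se_ex
  p_ex <- 2 * stats::pnorm(-abs(z_ex))

  out <- data.frame(meta,
                    delta_ols = d_ols, se_ols = se_ols, z_ols = z_ols,
                    p_ols = p_ols,
                    delta_exact = d_ex, se_exact = se_ex, z_exact = z_ex,
                    p_exact = p_ex,
                    stringsAsFactors = FALSE)
  out$sig_ols <- out$p_ols < gw_threshold
  out$sig_exact <- out$p_exact < gw_threshold
  out$flag_stress <- out$sig_ols & !out$sig_exact
  rownames(out) <- NULL
  attr(out, "parameters") <- list(
    prevalence_a = da$prevalence, prevalence_b = db$prevalence,
    h2_a = da$h2_liability, h2_b = db$h2_liability,
    rg = x$rg, error_covariance = c_ov, m_causal = x$m_causal,
    fst_causal = fst_causal(da, db, x),
    attenuation = attenuation, gw_threshold = gw_threshold,
    exact_weights = c(w_a = w_a, w_b = w_b))
  class(out) <- c("casecase_result", "data.frame")
  out
}

#' Express a case-case result as a summary-statistics table
#'
#' Re-expresses either path's statistics in the canonical sumstats dialect
#' (delta-scale effects as `beta`) so downstream stages (loci, MTAG, PGS)
#' consume case-case results like any other GWAS. `n_eff` is the harmonic
#' combination of the two case counts, the case-case analogue of the
#' effective sample size.
#'
#' @param cc a `casecase_result`.
#' @param da,db the input [disease_model()]s.
#' @param path which statistic to export ("exact", the default consumed by
#'   locus definition, or "ols").
#' @return a `sumstats` object labelled `casecase`.
#' @export
casecase_to_sumstats <- function(cc, da, db, path = c("exact", "ols")) {
  path <- match.arg(path)
  cols <- if (path == "exact") {
    list(beta = cc$delta_exact, se = cc$se_exact, z = cc$z_exact)
  } else {
    list(beta = cc$delta_ols, se = cc$se_ols, z = cc$z_ols)
  }
  n_cc <- 4 / (1 / da$n_case + 1 / db$n_case)
  as_sumstats(data.frame(variant_id = cc$variant_id, chrom = cc$chrom,
                         pos = cc$pos, effect_allele = cc$effect_allele,
                         other_allele = cc$other_allele, eaf = cc$eaf,
                         beta = cols$beta, se = cols$se, z = cols$z,
                         n = n_cc, stringsAsFactors = FALSE),
              trait_label = "casecase")
}
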