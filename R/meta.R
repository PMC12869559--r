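#' Remove variants with outlying precision differences
#'
#' A variant much better powered in one study dominates an inverse-variance
#' meta-analysis. Per variant the log-ratio of standard errors is computed;
#' variants whose log-ratio deviates from the median by more than `k` robust
#' SDs (median absolute deviation, scaled to the normal) are removed. When
#' all ratios are identical (MAD 0) nothing is removed.
#'
#' @param a,b harmonised sumstats tables.
#' @param k robust-SD multiplier (default 3).
#' @return list with `a`, `b` (filtered, same order), `keep` (logical),
#'   `n_removed`.
#' @export
precision_filter <- function(a, b, k = 3) {
  stopifnot(nrow(a) == nrow(b))
  lr <- log(a$se / b$se)
  med <- stats::median(lr)
  s <- stats::mad(lr)
  keep <- if (s == 0) rep(TRUE, length(lr)) else abs(lr - med) <= k * s
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message("precision_filter removed ", n_removed, " variant(s)")
  }
  list(a = restore_sumstats(a[keep, , drop = FALSE], a),
       b = restore_sumstats(b[keep, , drop = FALSE], b),
       keep = keep, n_removed = n_removed)
}

#' Fixed-effects inverse-variance meta-analysis of two studies
#'
#' `beta_fe = (beta_a / se_a^2 + beta_b / se_b^2) / (1/se_a^2 + 1/se_b^2)`,
#' `se_fe = (1/se_a^2 + 1/se_b^2)^(-1/2)`, two-sided normal p. Variants with
#' exactly opposite effects and equal precision cancel to `beta_fe = 0`.
#'
#' @param a,b harmonised, precision-filtered sumstats tables.
#' @return a `meta_result` data.frame with `beta_fe`, `se_fe`, `p_fe` and
#'   placeholder random-effects fields (`stage_flag = "fe_only"`).
#' @export
fixed_effects_meta <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  if (any(a$se <= 0 | b$se <= 0)) stop("nonpositive standard error")
  wa <- 1 / a$se^2
  wb <- 1 / b$se^2
  beta_fe <- (a$beta * wa + b$beta * wb) / (wa + wb)
  se_fe <- 1 / sqrt(wa + wb)
  z_fe <- beta_fe / se_fe
  out <- data.frame(variant_id = a$variant_id, chrom = a$chrom, pos = a$pos,
                    effect_allele = a$effect_allele,
                    other_allele = a$other_allele, eaf = a$eaf,
                    beta_fe = beta_fe, se_fe = se_fe,
                    p_fe = 2 * stats::pnorm(-abs(z_fe)),
                    q_stat = NA_real_, tau2 = NA_real_,
                    beta_re = NA_real_, se_re = NA_real_, p_re = NA_real_,
                    stage_flag = "fe_only", stringsAsFactors = FALSE)
  out$p_final <- out$p_fe
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Conservative random-effects substitution (second stage)
#'
#' For variants passing the first-stage trigger (`p_fe < trigger_p`), a
#' two-study DerSimonian-Laird random-effects estimate is computed:
#' `Q = sum w (beta - beta_fe)^2`, `tau2 = max(0, (Q - 1) / (sum w - sum
#' w^2 / sum w))`, RE weights `1 / (se^2 + tau2)`. The final p-value is the
#' more conservative of the two, `p_final = max(p_fe, p_re)`, and
#' `stage_flag` is set to `"re_substituted"`; untriggered variants keep the
#' fixed-effects p. With no heterogeneity (tau2 = 0) the RE and FE estimates
#' coincide.
#'
#' @param fe a `meta_result` from [fixed_effects_meta()].
#' @param a,b the input sumstats tables (same order as `fe`).
#' @param trigger_p first-stage trigger threshold (default 1e-4).
#' @return completed `meta_result`.
#' @export
random_effects_update <- function(fe, a, b, trigger_p = 1e-4) {
  stopifnot(nrow(fe) == nrow(a), nrow(fe) == nrow(b))
  trig <- which(fe$p_fe < trigger_p)
  if (length(trig) > 0) {
    wa <- 1 / a$se[trig]^2
    wb <- 1 / b$se[trig]^2
    sw <- wa + wb
    q <- wa * (a$beta[trig] - fe$beta_fe[trig])^2 +
      wb * (b$beta[trig] - fe$beta_fe[trig])^2
    tau2 <- pmax(0, (q - 1) / (sw - (wa^2 + wb^2) / sw))
    wa_re <- 1 / (a$se[trig]^2 + tau2)
    wb_re <- 1 / (b$se[trig]^2 + tau2)
    beta_re <- (a$beta[trig] * wa_re + b$beta[trig] * wb_re) / (wa_re + wb_re)
    se_re <- 1 / sqrt(wa_re + wb_re)
    p_re <- 2 * stats::pnorm(-abs(beta_re / se_re))
    fe$q_stat[trig] <- q
    fe$tau2[trig] <- tau2
    fe$beta_re[trig] <- beta_re
    fe$se_re[trig] <- se_re
    fe$p_re[trig] <- p_re
    fe$p_final[trig] <- pmax(fe$p_fe[trig], p_re)
    fe$stage_flag[trig] <- "re_substituted"
  }
  attr(fe, "trigger_p") <- trigger_p
  fe
}

#' Two-stage shared-effect meta-analysis
#'
#' Convenience wrapper: precision filter, fixed-effects combination, then
#' the conservative random-effects substitution.
#'
#' @param a,b harmonised sumstats tables.
#' @param k precision-filter robust-SD multiplier.
#' @param trigger_p second-stage trigger (default 1e-4).
#' @param gw_threshold genome-wide significance (default 5e-8, recorded).
#' @return a completed `meta_result` with attribute `n_removed_precision`.
#' @export
shared_effect_meta <- function(a, b, k = 3, trigger_p = 1e-4,
                               gw_threshold = 5e-8) {
  flt <- precision_filter(a, b, k = k)
  fe <- fixed_effects_meta(flt$a, flt$b)
  out <- random_effects_update(fe, flt$a, flt$b, trigger_p = trigger_p)
  attr(out, "n_removed_precision") <- flt$n_removed
  attr(out, "gw_threshold") <- gw_threshold
  out
}
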