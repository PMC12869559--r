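#' Build a simple clumping-and-thresholding polygenic score
#'
#' Greedy distance-based clumping: variants are visited best p-value first;
#' each retained variant suppresses all unvisited variants within
#' `merge_distance` on the same chromosome. Retained variants below
#' `p_threshold` contribute their `beta` as weight. A stand-in for
#' genome-wide Bayesian weight fitting, intended for synthetic end-to-end
#' evaluation.
#'
#' @param sumstats harmonised sumstats table.
#' @param p_threshold inclusion p-value threshold (default 5e-8).
#' @param merge_distance clumping distance in bp (default 1e6).
#' @return data.frame `variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `weight`, `p`. Empty after thresholding raises a warning.
#' @export
build_simple_pgs <- function(sumstats, p_threshold = 5e-8,
                             merge_distance = 1e6) {
  t <- sumstats[sumstats$p < p_threshold, , drop = FALSE]
  if (nrow(t) == 0) {
    warning("no variants pass the p-value threshold; empty score")
    return(data.frame(variant_id = character(0), chrom = character(0),
                      pos = numeric(0), effect_allele = character(0),
                      weight = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  t <- t[order(t$p, t$chrom, t$pos), , drop = FALSE]
  kept <- logical(nrow(t))
  suppressed <- logical(nrow(t))
  for (i in seq_len(nrow(t))) {
    if (suppressed[i]) next
    kept[i] <- TRUE
    near <- t$chrom == t$chrom[i] & abs(t$pos - t$pos[i]) <= merge_distance
    suppressed[near] <- TRUE
  }
  out <- t[kept, , drop = FALSE]
  out <- out[order(chrom_rank(out$chrom), out$pos), ]
  data.frame(variant_id = out$variant_id, chrom = out$chrom, pos = out$pos,
             effect_allele = out$effect_allele, weight = out$beta,
             p = out$p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Score individuals with a weight table
#'
#' @param dosage individuals x variants dosage matrix with variant-id
#'   column names.
#' @param weights output of [build_simple_pgs()].
#' @return numeric raw score per individual.
#' @export
score_individuals <- function(dosage, weights) {
  idx <- match(weights$variant_id, colnames(dosage))
  if (anyNA(idx)) stop("weights reference variants absent from the cohort")
  as.numeric(dosage[, idx, drop = FALSE] %*% weights$weight)
}

#' Ancestry-robust polygenic score standardization
#'
#' Residualises raw scores on the principal components, models the variance
#' of the residuals log-linearly on the same PCs (which guarantees a
#' positive predicted SD), divides each residual by its predicted SD, and
#' finally centres/scales to mean 0 and unit variance over the
#' standardization sample.
#'
#' @param raw numeric raw scores.
#' @param pcs matrix of principal-component covariates (full column rank).
#' @return numeric adjusted scores (mean 0, variance 1).
#' @export
standardize_pgs <- function(raw, pcs) {
  pcs <- as.matrix(pcs)
  if (stats::sd(raw) == 0) stop("constant score vector cannot be standardized")
  qr_p <- qr(cbind(1, pcs))
  if (qr_p$rank < ncol(pcs) + 1) {
    drop_cols <- colnames(pcs)[qr_p$pivot[seq(qr_p$rank + 1,
                                              ncol(pcs) + 1)] - 1]
    stop("rank-deficient PC matrix; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  res <- stats::lm.fit(cbind(1, pcs), raw)$residuals
  lv <- stats::lm.fit(cbind(1, pcs), log(res^2 + 1e-300))$fitted.values
  adj <- res / exp(lv / 2)
  as.numeric(scale(adj))
}

auc_rank <- function(score, y) {
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## average precision (area under the precision-recall step curve)
auprc_ap <- function(score, y) {
  ord <- order(-score, seq_along(score))
  y <- y[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Convert observed-scale R2 to the liability scale
#'
#' Lee et al. transformation with ascertainment correction:
#' `C = K^2 (1-K)^2 / (z^2 P (1-P))`, `theta = m (P-K)/(1-K) *
#' (m (P-K)/(1-K) - tau)` with `m = phi(tau)/K`;
#' `R2_liab = R2_obs C / (1 + R2_obs theta C)`.
#'
#' @param r2_obs observed (0/1) scale R2.
#' @param prevalence population prevalence K.
#' @param sample_prev sample case fraction P.
#' @return liability-scale R2.
#' @export
r2_liability <- function(r2_obs, prevalence, sample_prev) {
  K <- prevalence; P <- sample_prev
  tau <- stats::qnorm(1 - K)
  z <- stats::dnorm(tau)
  m <- z / K
  C <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  theta <- m * (P - K) / (1 - K) * (m * (P - K) / (1 - K) - tau)
  r2_obs * C / (1 + r2_obs * theta * C)
}

#' Evaluate polygenic-score discrimination for one contrast
#'
#' Logistic regression of the contrast on the adjusted score plus
#' covariates gives the OR per SD with Wald CI and two-sided p; AUC and
#' AUPRC are computed from the univariate score (bootstrap percentile CIs,
#' seeded by the caller's RNG state); Nagelkerke pseudo-R2 gain is the
#' full-model minus covariate-only value; liability-scale R2 gain applies
#' [r2_liability()] at the configured population prevalence.
#'
#' @param score adjusted scores (see [standardize_pgs()]).
#' @param y 0/1 contrast labels.
#' @param covariates optional covariate matrix/data.frame (PCs, age, sex).
#' @param prevalence population prevalence of the positive class for the
#'   liability conversion (default: sample prevalence).
#' @param n_boot bootstrap resamples for AUC/AUPRC CIs (default 2000;
#'   0 disables).
#' @return a `pgs_eval_result` list: `or_per_sd`, `or_lo`, `or_hi`, `p`,
#'   `auc`, `auc_lo`, `auc_hi`, `auprc`, `auprc_lo`, `auprc_hi`,
#'   `nagelkerke_r2_gain`, `liability_r2_gain`, `perfect_separation`.
#' @export
evaluate_discrimination <- function(score, y, covariates = NULL,
                                    prevalence = NULL, n_boot = 2000) {
  y <- as.integer(y)
  if (length(unique(y)) != 2) stop("both contrast classes must be non-empty")
  dat <- data.frame(y = y, score = score)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  full <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  sep <- !full$converged || any(abs(stats::coef(full)) > 15)
  co <- summary(full)$coefficients["score", ]
  or <- exp(co["Estimate"])
  if (sep) {
    or_lo <- 0; or_hi <- Inf
  } else {
    or_lo <- exp(co["Estimate"] - 1.96 * co["Std. Error"])
    or_hi <- exp(co["Estimate"] + 1.96 * co["Std. Error"])
  }
  p <- co["Pr(>|z|)"]

  auc <- auc_rank(score, y)
  auprc <- auprc_ap(score, y)
  auc_ci <- auprc_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- length(y)
    bs <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[j])) < 2) return(c(NA_real_, NA_real_))
      c(auc_rank(score[j], y[j]), auprc_ap(score[j], y[j]))
    }, numeric(2))
    auc_ci <- stats::quantile(bs[1, ], c(0.025, 0.975), na.rm = TRUE)
    auprc_ci <- stats::quantile(bs[2, ], c(0.025, 0.975), na.rm = TRUE)
  }

  nagelkerke <- function(fit, null_dev, n) {
    (1 - exp((fit$deviance - null_dev) / n)) / (1 - exp(-null_dev / n))
  }
  n <- length(y)
  if (!is.null(covariates)) {
    cov_only <- suppressWarnings(
      stats::glm(y ~ ., data = dat[, -2, drop = FALSE],
                 family = stats::binomial()))
    null_dev <- full$null.deviance
    r2_full <- nagelkerke(full, null_dev, n)
    r2_cov <- nagelkerke(cov_only, null_dev, n)
  } else {
    null_dev <- full$null.deviance
    r2_full <- nagelkerke(full, null_dev, n)
    r2_cov <- 0
  }
  nag_gain <- r2_full - r2_cov

  ## observed-scale R2 of the score (linear), transformed to liability
  samp_prev <- mean(y)
  K <- prevalence %||% samp_prev
  r2_obs_full <- summary(stats::lm(y ~ ., data = dat))$r.squared
  r2_obs_cov <- if (!is.null(covariates)) {
    summary(stats::lm(y ~ ., data = dat[, -2, drop = FALSE]))$r.squared
  } else 0
  liab_gain <- r2_liability(r2_obs_full, K, samp_prev) -
    r2_liability(r2_obs_cov, K, samp_prev)

  structure(list(or_per_sd = unname(or), or_lo = unname(or_lo),
                 or_hi = unname(or_hi), p = unname(p),
                 auc = auc, auc_lo = unname(auc_ci[1]),
                 auc_hi = unname(auc_ci[2]),
                 auprc = auprc, auprc_lo = unname(auprc_ci[1]),
                 auprc_hi = unname(auprc_ci[2]),
                 nagelkerke_r2_gain = nag_gain,
                 liability_r2_gain = liab_gain,
                 perfect_separation = sep),
            class = "pgs_eval_result")
}
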