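#' LD reference for block-structured genomes
#'
#' Holds the block membership and per-variant LD scores `l_j` (each variant's
#' summed squared correlation with its neighbours, self included, so
#' `l_j >= 1`). For the compound-symmetric blocks produced by the simulator,
#' `l = 1 + (block_size - 1) * rho^2` in closed form; `rho` is carried so
#' that the regional method-of-moments estimator can whiten exactly.
#'
#' @param block integer block id per variant.
#' @param l numeric LD score per variant (>= 1).
#' @param rho within-block genotype correlation, per variant or scalar, if
#'   known (NA otherwise).
#' @return an `ld_reference` list with fields `block`, `l`, `rho`, `M`.
#' @export
ld_reference <- function(block, l, rho = NA_real_) {
  stopifnot(length(block) == length(l))
  if (any(l < 1)) stop("LD scores must be >= 1 (self-correlation included)")
  rho <- rep_len(rho, length(l))
  structure(list(block = block, l = l, rho = rho, M = length(l)),
            class = "ld_reference")
}

#' Read/write LD scores as two-column tab-separated files
#' @param x sumstats or character variant ids matched to `l`.
#' @param l LD scores.
#' @param path file path.
#' @export
write_ld_scores <- function(x, l, path) {
  ids <- if (inherits(x, "sumstats")) x$variant_id else as.character(x)
  utils::write.table(data.frame(variant_id = ids, l = l), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_scores
#' @export
read_ld_scores <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

sumstats_n <- function(t) {
  if (!is.null(t$n_eff) && !all(is.na(t$n_eff))) return(t$n_eff)
  if (!is.null(t$n) && !all(is.na(t$n))) return(t$n)
  stop("no per-variant sample size (n_eff or n) in table '",
       trait_label(t), "'")
}

wls_fit <- function(y, x, w) {
  if (stats::sd(x) < 1e-10 * max(abs(x), 1)) {
    stop("LD-score predictor is constant; the regression slope is ",
         "unidentifiable (use a reference with varying LD scores)")
  }
  sw <- sqrt(w)
  X <- cbind(1, x) * sw
  coef <- solve(crossprod(X), crossprod(X, y * sw))
  c(intercept = coef[1], slope = coef[2])
}

## group LD blocks into at most n_jack contiguous jackknife groups
jack_groups <- function(block, n_jack = 200) {
  ub <- unique(block)
  g <- ceiling(seq_along(ub) / max(1, ceiling(length(ub) / n_jack)))
  g[match(block, ub)]
}

jack_se <- function(est_all, est_del) {
  g <- length(est_del)
  sqrt((g - 1) / g * sum((est_del - mean(est_del))^2))
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics on `N * l_j / M`; the slope is
#' the (observed-scale) heritability and the intercept captures confounding
#' and miscalibration. Standard errors come from a delete-one block jackknife
#' over LD blocks. Regression weights follow the usual LDSC
#' heteroskedasticity form `1 / (l_j * (1 + N h2 l_j / M)^2)` (two-step) and
#' can be switched off for oracle checks.
#'
#' @param t sumstats table aligned to `ld`'s variant universe.
#' @param ld an [ld_reference()].
#' @param weights "ldsc" or "none".
#' @param min_variants refuse estimation below this count.
#' @param pop_prev population prevalence; when given, a liability-scale
#'   estimate is added via [h2_observed_to_liability()].
#' @param n_jack maximum number of jackknife groups.
#' @return an `h2_estimate` list: `h2`, `se`, `intercept`, `intercept_se`,
#'   `lambda_gc`, optional `h2_liab`/`h2_liab_se`, `n_variants`.
#' @export
estimate_h2 <- function(t, ld, weights = c("ldsc", "none"),
                        min_variants = 200, pop_prev = NULL, n_jack = 200) {
  weights <- match.arg(weights)
  if (nrow(t) < min_variants) {
    stop("too few variants for LD score regression (", nrow(t), " < ",
         min_variants, ")")
  }
  stopifnot(nrow(t) == ld$M)
  n <- sumstats_n(t)
  chi2 <- t$z^2
  x <- n * ld$l / ld$M

  w <- rep(1, ld$M)
  if (weights == "ldsc") {
    for (step in 1:2) {
      fit0 <- wls_fit(chi2, x, w)
      slope0 <- max(fit0["slope"], 0)
      int0 <- max(fit0["intercept"], 0.1)
      w <- 1 / (ld$l * (int0 + slope0 * x)^2)
    }
  }
  fit <- wls_fit(chi2, x, w)

  grp <- jack_groups(ld$block, n_jack)
  dels <- vapply(unique(grp), function(g) {
    i <- grp != g
    wls_fit(chi2[i], x[i], w[i])
  }, numeric(2))
  se <- jack_se(fit["slope"], dels["slope", ])
  int_se <- jack_se(fit["intercept"], dels["intercept", ])

  out <- list(h2 = unname(fit["slope"]), se = se,
              intercept = unname(fit["intercept"]), intercept_se = int_se,
              lambda_gc = stats::median(chi2) / stats::qchisq(0.5, 1),
              n_variants = ld$M)
  if (!is.null(pop_prev)) {
    out$h2_liab <- h2_observed_to_liability(out$h2, pop_prev)
    out$h2_liab_se <- h2_observed_to_liability(se, pop_prev)
  }
  structure(out, class = "h2_estimate")
}

#' Estimate cross-trait genetic correlation by bivariate LD score regression
#'
#' Regresses the per-variant z-score product on `sqrt(N_a N_b) l_j / M`; the
#' slope is the genetic covariance and the intercept the cross-trait sampling
#' covariance induced by sample overlap. `rg = gencov / sqrt(h2_a h2_b)` with
#' the univariate slopes estimated on the same variant universe. SE and
#' two-sided p come from a delete-one block jackknife of the full ratio.
#'
#' @param a,b harmonised sumstats tables on `ld`'s variant universe.
#' @param ld an [ld_reference()].
#' @param weights "ldsc" or "none".
#' @param n_jack maximum number of jackknife groups.
#' @param require_h2 when TRUE (default) a nonpositive heritability estimate
#'   aborts with an explicit error (rg is then undefined); when FALSE the
#'   covariance components are still returned with `rg = NA` (used by the
#'   multi-trait moment estimator, which needs only `gencov` and the
#'   intercept).
#' @return an `rg_estimate` list: `rg`, `se`, `p`, `gencov`, `gencov_se`,
#'   `bivariate_intercept`, `intercept_se`, `h2_a`, `h2_b`. `rg` outside
#'   [-1, 1] is tolerated up to 1.25 (flagged), beyond which estimation
#'   aborts.
#' @export
estimate_rg <- function(a, b, ld, weights = c("ldsc", "none"), n_jack = 200,
                        require_h2 = TRUE) {
  weights <- match.arg(weights)
  stopifnot(nrow(a) == ld$M, nrow(b) == ld$M)
  na <- sumstats_n(a); nb <- sumstats_n(b)
  xa <- na * ld$l / ld$M
  xb <- nb * ld$l / ld$M
  xab <- sqrt(na * nb) * ld$l / ld$M
  chi_a <- a$z^2; chi_b <- b$z^2; zz <- a$z * b$z

  wa <- wb <- wab <- rep(1, ld$M)
  if (weights == "ldsc") {
    ha <- max(wls_fit(chi_a, xa, wa)["slope"], 0)
    hb <- max(wls_fit(chi_b, xb, wb)["slope"], 0)
    wa <- 1 / (ld$l * (1 + ha * xa)^2)
    wb <- 1 / (ld$l * (1 + hb * xb)^2)
    wab <- 1 / (ld$l * (1 + ha * xa) * (1 + hb * xb))
  }

  fit_all <- function(i) {
    h2a <- wls_fit(chi_a[i], xa[i], wa[i])["slope"]
    h2b <- wls_fit(chi_b[i], xb[i], wb[i])["slope"]
    co <- wls_fit(zz[i], xab[i], wab[i])
    c(h2a = unname(h2a), h2b = unname(h2b),
      gencov = unname(co["slope"]), icpt = unname(co["intercept"]))
  }
  full <- fit_all(rep(TRUE, ld$M))
  h2_ok <- full["h2a"] > 0 && full["h2b"] > 0
  if (!h2_ok && require_h2) {
    stop("rg undefined: nonpositive heritability estimate (h2_a = ",
         signif(full["h2a"], 3), ", h2_b = ", signif(full["h2b"], 3), ")")
  }
  rg <- if (h2_ok) {
    unname(full["gencov"] / sqrt(full["h2a"] * full["h2b"]))
  } else NA_real_
  if (isTRUE(abs(rg) > 1.25)) {
    stop("rg estimate far outside [-1, 1]: ", signif(rg, 3))
  }

  grp <- jack_groups(ld$block, n_jack)
  dels <- vapply(unique(grp), function(g) {
    est <- fit_all(grp != g)
    c(rg = unname(est["gencov"] / sqrt(pmax(est["h2a"], 1e-12) *
                                         pmax(est["h2b"], 1e-12))),
      icpt = unname(est["icpt"]), gencov = unname(est["gencov"]))
  }, numeric(3))
  se <- jack_se(rg, dels["rg", ])
  icpt_se <- jack_se(full["icpt"], dels["icpt", ])
  gencov_se <- jack_se(full["gencov"], dels["gencov", ])
  p <- 2 * stats::pnorm(-abs(rg / se))

  structure(list(rg = rg, se = se, p = p,
                 gencov = unname(full["gencov"]), gencov_se = gencov_se,
                 bivariate_intercept = unname(full["icpt"]),
                 intercept_se = icpt_se,
                 h2_a = unname(full["h2a"]), h2_b = unname(full["h2b"]),
                 out_of_range = abs(rg) > 1),
            class = "rg_estimate")
}

## exact whitening for compound-symmetric blocks: R^(-1/2) z;
## rho per variant (constant within block)
cs_whiten <- function(z, block, rho) {
  if (all(rho == 0)) return(z)
  cnt <- as.numeric(table(block))
  names(cnt) <- names(table(block))
  sizes <- cnt[as.character(block)]
  zbar <- (rowsum(z, block)[, 1] / cnt)[as.character(block)]
  unname((z - zbar) / sqrt(1 - rho) + zbar / sqrt(1 + (sizes - 1) * rho))
}

#' Simplified two-stage regional genetic-correlation scan
#'
#' A method-of-moments stand-in for full regional bivariate decomposition,
#' exact for the compound-symmetric LD the simulator emits (requires
#' `ld$rho`). Stage 1 whitens each region's z-scores with the known block
#' correlation and tests the summed chi-square of both traits against its
#' null chi-square distribution; regions where both traits pass the
#' Bonferroni threshold `alpha / length(regions)` are retained. Stage 2
#' estimates regional heritabilities `(sum(u^2) - M_r) / N`, the regional
#' genetic covariance `(sum(u_a u_b) - c M_r) / sqrt(N_a N_b)` (with `c` the
#' supplied overlap intercept) and their correlation, and tests the
#' cross-product sum with a plug-in normal approximation at the Bonferroni
#' threshold `alpha / n_retained`.
#'
#' @param a,b harmonised sumstats tables on `ld`'s variant universe.
#' @param ld an [ld_reference()] with known `rho`.
#' @param regions list of integer variant-index vectors partitioning the
#'   universe.
#' @param overlap_intercept cross-trait sampling covariance of z-scores
#'   (e.g. `estimate_rg(...)$bivariate_intercept`); default 0.
#' @param alpha family-wise error target at each stage (default 0.05).
#' @return data.frame with one row per region (`region`, `n_variants`,
#'   `h2_a`, `h2_b`, `p_h2_a`, `p_h2_b`, `stage1_pass`, `rg`, `p_rg`,
#'   `significant`), with attributes `stage1_threshold` and
#'   `stage2_threshold`.
#' @export
regional_rg <- function(a, b, ld, regions, overlap_intercept = 0,
                        alpha = 0.05) {
  if (anyNA(ld$rho)) {
    stop("regional_rg needs the within-block correlation (ld$rho)")
  }
  na <- sumstats_n(a); nb <- sumstats_n(b)
  n_regions <- length(regions)
  thr1 <- alpha / n_regions

  rows <- lapply(seq_along(regions), function(r) {
    idx <- regions[[r]]
    if (length(idx) == 0) {
      message("regional_rg: region ", r, " has no variants; skipped")
      return(NULL)
    }
    u_a <- cs_whiten(a$z[idx], ld$block[idx], ld$rho[idx])
    u_b <- cs_whiten(b$z[idx], ld$block[idx], ld$rho[idx])
    m_r <- length(idx)
    t_a <- sum(u_a^2); t_b <- sum(u_b^2)
    p_a <- stats::pchisq(t_a, df = m_r, lower.tail = FALSE)
    p_b <- stats::pchisq(t_b, df = m_r, lower.tail = FALSE)
    na_r <- mean(na[idx]); nb_r <- mean(nb[idx])
    h2a <- (t_a - m_r) / na_r
    h2b <- (t_b - m_r) / nb_r
    s_ab <- sum(u_a * u_b)
    gencov <- (s_ab - overlap_intercept * m_r) / sqrt(na_r * nb_r)
    rg <- if (h2a > 0 && h2b > 0) gencov / sqrt(h2a * h2b) else NA_real_
    zstat <- (s_ab - overlap_intercept * m_r) / sqrt(sum(u_a^2 * u_b^2))
    p_rg <- 2 * stats::pnorm(-abs(zstat))
    data.frame(region = r, n_variants = m_r, h2_a = h2a, h2_b = h2b,
               p_h2_a = p_a, p_h2_b = p_b,
               stage1_pass = p_a < thr1 & p_b < thr1,
               rg = rg, p_rg = p_rg)
  })
  out <- do.call(rbind, rows)
  n_retained <- sum(out$stage1_pass)
  thr2 <- if (n_retained > 0) alpha / n_retained else NA_real_
  out$p_rg[!out$stage1_pass] <- NA_real_
  out$significant <- out$stage1_pass & !is.na(out$p_rg) & out$p_rg < thr2
  attr(out, "stage1_threshold") <- thr1
  attr(out, "stage2_threshold") <- thr2
  out
}
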