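#' Select genetically correlated secondary traits
#'
#' Estimates the genetic correlation of each candidate with the target by
#' bivariate LD score regression and returns the candidates whose `|rg|`
#' meets the threshold (default 0.65, the usual inclusion rule for
#' multi-trait combination), ordered by `|rg|` descending.
#'
#' @param candidates named list of sumstats tables harmonised to the
#'   target's variant universe.
#' @param target sumstats table.
#' @param ld an [ld_reference()].
#' @param threshold minimum `|rg|` (default 0.65).
#' @return list with `selected` (subset of candidates, ordered) and
#'   `rg` (data.frame of all estimates with `selected` flag).
#' @export
select_secondary_traits <- function(candidates, target, ld, threshold = 0.65) {
  ests <- lapply(candidates, function(cand) estimate_rg(cand, target, ld))
  tab <- data.frame(trait = names(candidates),
                    rg = vapply(ests, `[[`, numeric(1), "rg"),
                    se = vapply(ests, `[[`, numeric(1), "se"),
                    p = vapply(ests, `[[`, numeric(1), "p"),
                    bivariate_intercept = vapply(ests, `[[`, numeric(1),
                                                 "bivariate_intercept"),
                    stringsAsFactors = FALSE)
  tab$selected <- abs(tab$rg) >= threshold
  ord <- order(-abs(tab$rg))
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(selected = candidates[tab$trait[tab$selected]], rg = tab)
}

#' Estimate the multi-trait genetic and sampling covariance matrices
#'
#' `sigma` (sampling covariance of z-scores) is assembled from the pairwise
#' bivariate LD score intercepts with a unit diagonal. `omega` (per-variant
#' genetic covariance, in standardized-effect units `z / sqrt(N)`) comes from
#' the pairwise genetic-covariance slopes divided by the variant count. When
#' the moment estimate of omega is indefinite it is projected to the nearest
#' positive semi-definite matrix by eigenvalue clipping, and the Frobenius
#' distance moved is recorded.
#'
#' @param traits named list of >= 2 harmonised sumstats tables.
#' @param ld an [ld_reference()].
#' @return a `multitrait_model` list: `omega`, `sigma`, `trait_labels`, `n`
#'   (per-trait scalar sample sizes), `projection_distance`.
#' @export
estimate_omega_sigma <- function(traits, ld) {
  k <- length(traits)
  stopifnot(k >= 2)
  labels <- names(traits) %||% paste0("trait", seq_len(k))
  n <- vapply(traits, function(t) mean(sumstats_n(t)), numeric(1))

  omega <- diag(k); sigma <- diag(k)
  omega_se <- matrix(0, k, k); sigma_se <- matrix(0, k, k)
  for (i in seq_len(k)) {
    hi <- estimate_h2(traits[[i]], ld)
    omega[i, i] <- hi$h2 / ld$M
    omega_se[i, i] <- hi$se / ld$M
    sigma[i, i] <- 1
    if (i < k) for (j in seq((i + 1), k)) {
      est <- estimate_rg(traits[[i]], traits[[j]], ld, require_h2 = FALSE)
      omega[i, j] <- omega[j, i] <- est$gencov / ld$M
      omega_se[i, j] <- omega_se[j, i] <- est$gencov_se / ld$M
      sigma[i, j] <- sigma[j, i] <- est$bivariate_intercept
      sigma_se[i, j] <- sigma_se[j, i] <- est$intercept_se
    }
  }
  if (any(!is.finite(sigma)) || abs(det(sigma)) < 1e-12) {
    stop("sampling covariance matrix not invertible; check trait pairs")
  }

  ev <- eigen(omega, symmetric = TRUE)
  proj_dist <- 0
  if (any(ev$values < 0)) {
    clipped <- pmax(ev$values, 0)
    omega_psd <- ev$vectors %*% diag(clipped, k) %*% t(ev$vectors)
    proj_dist <- sqrt(sum((omega - omega_psd)^2))
    message("omega projected to PSD; Frobenius distance ",
            signif(proj_dist, 3))
    omega <- omega_psd
  }
  dimnames(omega) <- dimnames(sigma) <- list(labels, labels)
  dimnames(omega_se) <- dimnames(sigma_se) <- list(labels, labels)
  structure(list(omega = omega, sigma = sigma,
                 omega_se = omega_se, sigma_se = sigma_se,
                 trait_labels = labels,
                 n = n, M = ld$M, projection_distance = proj_dist),
            class = "multitrait_model")
}

#' Multi-trait generalised least squares update of a target trait
#'
#' Per variant, the target's standardized effect is re-estimated as the GLS
#' combination of all traits' standardized effects, assuming each trait's
#' true effect is proportional to the target's through the genetic
#' covariance matrix:
#' `beta_hat = (w' V^-1 beta) / (w' V^-1 w)` with `w = Omega_j[,t]/Omega_j[t,t]`,
#' `V_j = Omega_j - w Omega_j[t,] + S` where `Omega_j = omega * l_j * M / mean(l)`
#' scales the average per-variant genetic covariance by local LD and
#' `S_kl = sigma_kl / sqrt(N_k N_l)`. A single input trait, or diagonal
#' omega and sigma, return the input unchanged. The effective-sample-size
#' gain is summarised as the mean chi-square ratio mapped through the
#' standard N-scaling (an approximation).
#'
#' @param traits named list of harmonised sumstats tables (same variants,
#'   same order).
#' @param model a `multitrait_model` from [estimate_omega_sigma()].
#' @param target_index index of the target trait in `traits`.
#' @param ld an [ld_reference()] (for the per-variant LD scaling).
#' @return a `sumstats` table for the updated target with attributes
#'   `mean_chisq_in`, `mean_chisq_out`, `n_eff_gain`.
#' @export
mtag_combine <- function(traits, model, target_index = 1, ld = NULL) {
  k <- length(traits)
  t_idx <- target_index
  target <- traits[[t_idx]]
  if (k == 1) return(target)
  stopifnot(nrow(model$omega) == k)
  m <- nrow(target)
  for (t in traits) stopifnot(nrow(t) == m)

  n <- model$n
  Z <- vapply(traits, function(t) t$z, numeric(m))
  B <- sweep(Z, 2, sqrt(n), "/")
  S <- model$sigma / tcrossprod(sqrt(n))

  lscale <- if (is.null(ld)) rep(1, m) else ld$l / mean(ld$l)
  om <- model$omega

  w <- om[, t_idx] / om[t_idx, t_idx]
  beta_out <- numeric(m); var_out <- numeric(m)
  for (ls in unique(round(lscale, 10))) {
    i <- which(round(lscale, 10) == ls)
    om_j <- om * ls
    V <- om_j - tcrossprod(om_j[, t_idx]) / om_j[t_idx, t_idx] + S
    Vi <- solve(V)
    wv <- as.numeric(Vi %*% w)
    den <- sum(w * wv)
    beta_out[i] <- as.numeric(B[i, , drop = FALSE] %*% wv) / den
    var_out[i] <- 1 / den
  }
  z_out <- beta_out / sqrt(var_out)
  out <- target
  ## report on the target's original effect scale via z and the input se
  out$z <- z_out
  out$se <- target$se
  out$beta <- z_out * out$se
  out$p <- 2 * stats::pnorm(-abs(z_out))
  attr(out, "trait_label") <- paste0(trait_label(target), "_mtag")
  attr(out, "mean_chisq_in") <- mean(target$z^2)
  attr(out, "mean_chisq_out") <- mean(z_out^2)
  attr(out, "n_eff_gain") <-
    (mean(z_out^2) - 1) / max(mean(target$z^2) - 1, 1e-12)
  out
}
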