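dm_a <- disease_model("A", 0.004, 0.142, 9365, 1199156)
dm_b <- disease_model("B", 0.002, 0.18, 5900, 68359)

test_that("delta conversion is zero at beta zero and odd under allele flips", {
  t <- toy_sumstats(6, seed = 12)
  t$beta[2] <- 0; t$z[2] <- 0
  d <- to_delta_scale(t, dm_a)
  expect_equal(d$delta[2], 0)

  tf <- t
  tf$beta <- -tf$beta; tf$z <- -tf$z; tf$eaf <- 1 - tf$eaf
  df <- to_delta_scale(tf, dm_a)
  expect_equal(df$delta, -d$delta, tolerance = 1e-12)
  expect_equal(df$var_delta, d$var_delta, tolerance = 1e-12)

  t$eaf[5] <- 1
  expect_message(d2 <- to_delta_scale(t, dm_a), "skipped 1")
  expect_equal(nrow(d2), 5)
})

test_that("delta estimates match directly computed case frequency shifts", {
  # individual-level oracle: the same truth drives a cohort, whose realized
  # standardized case-versus-population dosage differences the summary-level
  # delta must reproduce
  K <- 0.1
  d <- disease_model("d", K, 0.35, 5000, 45000)
  cfg <- simulation_config(m_variants = 600, m_causal = 120,
                           ld_block_size = 10, within_block_corr = 0,
                           disease_a = d, disease_b = d, rg = 0, seed = 61)
  sim <- simulate_paired_sumstats(cfg)
  delta_hat <- to_delta_scale(sim$a, d)$delta

  coh <- simulate_cohort(cfg, n_individuals = 20000)
  sd_dos <- sqrt(2 * coh$eaf * (1 - coh$eaf))
  delta_direct <- (colMeans(coh$dosage[coh$y_a == 1, , drop = FALSE]) -
                     colMeans(coh$dosage)) / sd_dos

  ci <- sim$truth$causal_index
  fit <- summary(lm(delta_direct[ci] ~ delta_hat[ci]))$coefficients
  expect_lt(abs(fit[2, 1] - 1), 2.5 * fit[2, 2])
  # and both are centred on the same thing
  expect_lt(abs(mean(delta_direct[ci] - delta_hat[ci])),
            3 * sd(delta_direct[ci] - delta_hat[ci]) / sqrt(length(ci)))
})

test_that("fst_causal follows its closed form and its limits", {
  x1 <- cross_trait_model(rg = 1, m_causal = 500)
  expect_equal(fst_causal(dm_a, dm_a, x1), 0, tolerance = 1e-15)

  # dilution: monotone decreasing in the causal count
  vals <- vapply(c(100, 1000, 10000), function(m) {
    fst_causal(dm_a, dm_b, cross_trait_model(rg = -0.56, m_causal = m))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  # study parameterization against a forward simulation that draws causal
  # liability effects and computes realized case-group frequency differences
  x <- cross_trait_model(rg = -0.56, error_covariance = 0.012,
                         m_causal = 1223)
  closed <- fst_causal(dm_a, dm_b, x)
  set.seed(62)
  nrep <- 2e5
  z1 <- rnorm(nrep); z2 <- rnorm(nrep)
  b_a <- sqrt(0.142 / 1223) * z1
  b_b <- sqrt(0.18 / 1223) * (-0.56 * z1 + sqrt(1 - 0.56^2) * z2)
  s_a <- dnorm(qnorm(1 - 0.004)) / 0.004
  s_b <- dnorm(qnorm(1 - 0.002)) / 0.002
  draws <- (b_a * s_a - b_b * s_b)^2
  mc_se <- sd(draws) / sqrt(nrep)
  expect_lt(abs(closed - mean(draws)), 2 * mc_se)

  expect_error(cross_trait_model(rg = 1.5), "\\[-1, 1\\]")
})

test_that("case-case closed forms: null difference and the sqrt(2) boost", {
  # same disease model on both sides so the exact weights coincide
  mk <- function(beta) {
    as_sumstats(data.frame(chrom = "1", pos = (1:3) * 1e5,
                           effect_allele = "A", other_allele = "G",
                           eaf = 0.5, beta = beta, se = 0.02,
                           n_case = dm_a$n_case, n_control = dm_a$n_control))
  }
  x0 <- cross_trait_model(rg = 0, error_covariance = 0, m_causal = 100)
  same <- suppressWarnings(
    casecase_stats(mk(c(0.1, -0.05, 0)), mk(c(0.1, -0.05, 0)),
                   dm_a, dm_a, x0))
  expect_equal(same$z_ols, rep(0, 3), tolerance = 1e-12)
  expect_equal(same$z_exact, rep(0, 3), tolerance = 1e-12)

  opp <- casecase_stats(mk(c(0.1, -0.05, 0.02)), mk(-c(0.1, -0.05, 0.02)),
                        dm_a, dm_a, x0)
  z_single <- c(0.1, -0.05, 0.02) / 0.02
  expect_equal(opp$z_ols, sqrt(2) * z_single, tolerance = 1e-10)
  expect_equal(opp$z_exact, sqrt(2) * z_single, tolerance = 1e-10)
})

test_that("swapping the diseases negates deltas and preserves p-values", {
  ps <- paired_sim()
  x <- cross_trait_model(rg = -0.58, error_covariance = 0.1, m_causal = 800)
  ab <- casecase_stats(ps$sim$a, ps$sim$b, ps$cfg$disease_a,
                       ps$cfg$disease_b, x)
  ba <- casecase_stats(ps$sim$b, ps$sim$a, ps$cfg$disease_b,
                       ps$cfg$disease_a, x)
  expect_equal(ba$delta_ols, -ab$delta_ols, tolerance = 1e-12)
  expect_equal(ba$delta_exact, -ab$delta_exact, tolerance = 1e-12)
  expect_equal(ba$p_ols, ab$p_ols, tolerance = 1e-12)
  expect_equal(ba$p_exact, ab$p_exact, tolerance = 1e-12)
})

test_that("a missing cross-trait model warns and zeroes the overlap term", {
  t <- toy_sumstats(4, seed = 13)
  expect_warning(res <- casecase_stats(t, t, dm_a, dm_b), "overlap")
  expect_true(all(res$se_ols > 0))
})

test_that("case-case boosts power on opposing-effect variants", {
  d <- disease_model("d", 0.01, 0.2, 20000, 100000)
  cfg <- simulation_config(m_variants = 10000, m_causal = 500,
                           ld_block_size = 25, within_block_corr = 0.5,
                           disease_a = d, disease_b = d, rg = -0.6,
                           seed = 77)
  sim <- simulate_paired_sumstats(cfg)
  x <- cross_trait_model(rg = -0.6, error_covariance = 0, m_causal = 500)
  cc <- casecase_stats(sim$a, sim$b, d, d, x)
  ci <- sim$truth$causal_index
  eff <- sim$truth$effects_liability
  opp <- ci[sign(eff[ci, "a"]) != sign(eff[ci, "b"])]
  single_best <- pmax(abs(sim$a$z[opp]), abs(sim$b$z[opp]))
  expect_gt(median(abs(cc$z_exact[opp])), median(single_best))
  # the discovery-yield mirror: more genome-wide significant case-case
  # variants than in either input GWAS
  expect_gt(sum(cc$p_exact < 5e-8), sum(sim$a$p < 5e-8))
  expect_gt(sum(cc$p_exact < 5e-8), sum(sim$b$p < 5e-8))
})
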