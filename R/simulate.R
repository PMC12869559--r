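#' Simulation configuration
#'
#' Parameters for the paired liability-threshold generator. The defaults
#' mirror the cardiomyopathy study conditions: prevalences 0.4% and 0.2%,
#' liability heritabilities 14.2% and 18%, cross-disorder genetic correlation
#' -0.58, 1223 effectively independent causal variants, and the published
#' case/control counts. LD is block-diagonal compound-symmetric so that LD
#' scores are known in closed form (`l = 1 + (block_size - 1) * rho^2`).
#'
#' @param m_variants total number of variants.
#' @param m_causal number of causal variants (<= m_variants).
#' @param ld_block_size variants per LD block.
#' @param within_block_corr maximum pairwise genotype correlation rho within
#'   a block, in [0, 1). Blocks receive correlations spread evenly over
#'   `[0, within_block_corr]` so that LD scores vary across the genome (the
#'   leverage LD score regression needs) while remaining known in closed
#'   form per block.
#' @param disease_a,disease_b [disease_model()] objects.
#' @param rg cross-disorder genetic correlation of causal liability effects.
#' @param shared_controls number of control individuals shared between the
#'   two GWAS; induces a cross-trait sampling covariance
#'   `shared_controls / sqrt(n_control_a * n_control_b)`.
#' @param endophenotypes list of `list(label=, h2=, rg_axis=)` entries
#'   describing quantitative traits correlated with the case-case causal
#'   axis; see [default_endophenotypes()].
#' @param n_endo GWAS sample size for each endophenotype.
#' @param seed integer seed; all randomness derives from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(m_variants = 50000,
                              m_causal = 1223,
                              ld_block_size = 50,
                              within_block_corr = 0.5,
                              disease_a = disease_model("disease_a", 0.004, 0.142,
                                                        9365, 1199156),
                              disease_b = disease_model("disease_b", 0.002, 0.18,
                                                        5900, 68359),
                              rg = -0.58,
                              shared_controls = 0,
                              endophenotypes = NULL,
                              n_endo = 36083,
                              seed = 1L) {
  stopifnot(m_causal <= m_variants, m_causal >= 1,
            within_block_corr >= 0, within_block_corr < 1)
  if (abs(rg) > 1) stop("rg must lie in [-1, 1]")
  for (d in list(disease_a, disease_b)) {
    if (sqrt(d$h2_liability / m_causal) > 0.5) {
      stop("h2 too large for m_causal: per-variant liability effects diverge")
    }
  }
  structure(list(m_variants = m_variants, m_causal = m_causal,
                 ld_block_size = ld_block_size,
                 within_block_corr = within_block_corr,
                 disease_a = disease_a, disease_b = disease_b, rg = rg,
                 shared_controls = shared_controls,
                 endophenotypes = endophenotypes, n_endo = n_endo,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' The study's endophenotype panel
#'
#' Three quantitative cardiac-MRI-like traits with case-case-axis genetic
#' correlations 0.793, 0.711 and -0.668 (contractility, volume and
#' concentricity analogues). Heritability 0.3 each, a typical value for
#' imaging-derived traits.
#'
#' @param h2 liability (here: trait) heritability used for each entry.
#' @return list of endophenotype descriptors for [simulation_config()].
#' @export
default_endophenotypes <- function(h2 = 0.3) {
  list(list(label = "strain", h2 = h2, rg_axis = 0.793),
       list(label = "volume", h2 = h2, rg_axis = 0.711),
       list(label = "concentricity", h2 = h2, rg_axis = -0.668))
}

## Variant frame shared by all generator outputs: blocks never span
## chromosome boundaries; positions are 5 kb apart within a chromosome.
variant_frame <- function(cfg) {
  m <- cfg$m_variants
  bs <- cfg$ld_block_size
  n_block <- ceiling(m / bs)
  block <- rep(seq_len(n_block), each = bs)[seq_len(m)]
  blocks_per_chrom <- ceiling(n_block / 22)
  chrom_of_block <- ((seq_len(n_block) - 1) %/% blocks_per_chrom) + 1
  chrom <- as.character(chrom_of_block[block])
  pos <- integer(m)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    pos[i] <- seq_along(i) * 5000L
  }
  ## per-block correlations spread over [0, rho_max]; per-variant vector
  rho_block <- if (n_block > 1) {
    cfg$within_block_corr * (seq_len(n_block) - 1) / (n_block - 1)
  } else cfg$within_block_corr
  rho <- rho_block[block]
  sizes <- tabulate(block)[block]
  list(block = block, chrom = chrom, pos = pos, n_block = n_block,
       rho = rho, block_size = sizes)
}

## Ground truth: variant frame, frequencies, causal set and liability
## effects. Deterministic given cfg$seed; shared by the summary-statistics
## and the individual-level generators.
sim_truth <- function(cfg) {
  set.seed(cfg$seed)
  vf <- variant_frame(cfg)
  m <- cfg$m_variants
  eaf <- stats::runif(m, 0.05, 0.95)
  causal <- sort(sample.int(m, cfg$m_causal))

  da <- cfg$disease_a; db <- cfg$disease_b
  sd_a <- sqrt(da$h2_liability / cfg$m_causal)
  sd_b <- sqrt(db$h2_liability / cfg$m_causal)
  z1 <- stats::rnorm(cfg$m_causal)
  z2 <- stats::rnorm(cfg$m_causal)
  b_a <- numeric(m); b_b <- numeric(m)
  b_a[causal] <- sd_a * z1
  b_b[causal] <- sd_b * (cfg$rg * z1 + sqrt(max(0, 1 - cfg$rg^2)) * z2)

  realized_rg <- if (cfg$m_causal > 2 && sd_a > 0 && sd_b > 0) {
    stats::cor(b_a[causal], b_b[causal])
  } else NA_real_

  list(frame = vf, eaf = eaf, causal_index = causal,
       effects_liability = cbind(a = b_a, b = b_b),
       realized_rg = realized_rg, seed = cfg$seed)
}

## y <- R x blockwise for compound-symmetric R = (1-rho) I + rho J;
## rho is a per-variant vector (constant within block)
cs_mult <- function(x, block, rho) {
  if (all(rho == 0)) return(x)
  bsum <- rowsum(x, block)[as.character(block), 1]
  unname((1 - rho) * x + rho * bsum)
}

## correlated N(0, R) noise per block, with cross-trait correlation c
cs_noise_pair <- function(m, block, rho, c_overlap) {
  u1 <- stats::rnorm(m)
  u2 <- c_overlap * u1 + sqrt(max(0, 1 - c_overlap^2)) * stats::rnorm(m)
  list(a = cs_color(u1, block, rho), b = cs_color(u2, block, rho))
}

## color iid noise to N(0, R): R^(1/2) in closed form for compound symmetry
cs_color <- function(u, block, rho) {
  if (all(rho == 0)) return(u)
  cnt <- as.numeric(table(block))
  names(cnt) <- names(table(block))
  sizes <- cnt[as.character(block)]
  ubar <- (rowsum(u, block)[, 1] / cnt)[as.character(block)]
  s1 <- sqrt(1 - rho)
  s2 <- sqrt(1 + (sizes - 1) * rho)
  unname((u - ubar) * s1 + ubar * s2)
}

sumstats_from_z <- function(z, vf, eaf, d, label) {
  se <- 2 / sqrt(d$n_eff * 2 * eaf * (1 - eaf))
  as_sumstats(data.frame(chrom = vf$chrom, pos = vf$pos,
                         effect_allele = "A", other_allele = "G",
                         eaf = eaf, beta = z * se, se = se, z = z,
                         n_case = d$n_case, n_control = d$n_control,
                         stringsAsFactors = FALSE),
              trait_label = label)
}

#' Simulate paired case-control summary statistics
#'
#' Draws causal liability effects for the two disorders from a bivariate
#' normal (per-trait variance `h2 / m_causal`, correlation `rg`), converts
#' them to the observed scale under the liability-threshold model at each
#' prevalence, applies block LD, and adds sampling noise with cross-trait
#' correlation `shared_controls / sqrt(n_control_a * n_control_b)`. Effect
#' sizes are reported on the log-odds scale with
#' `se = 2 / sqrt(n_eff * 2 p (1-p))`. Endophenotype statistics, when
#' configured, are generated with causal effects correlated to the case-case
#' liability axis at the configured `rg_axis`.
#'
#' Outputs are byte-identical across runs for a fixed seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `a`, `b` (sumstats), `endo` (named list of
#'   sumstats, possibly empty), `truth` (causal index, liability effects,
#'   realised rg, overlap correlation, seed) and `ld` (an [ld_reference()]).
#' @export
simulate_paired_sumstats <- function(cfg) {
  truth <- sim_truth(cfg)
  set.seed(cfg$seed + 1L)
  vf <- truth$frame
  m <- cfg$m_variants
  rho <- vf$rho
  da <- cfg$disease_a; db <- cfg$disease_b

  c_overlap <- cfg$shared_controls / sqrt(da$n_control * db$n_control)
  c_overlap <- min(c_overlap, 1)

  a_obs <- cs_mult(truth$effects_liability[, "a"] * obs_scale_factor(da),
                   vf$block, rho)
  b_obs <- cs_mult(truth$effects_liability[, "b"] * obs_scale_factor(db),
                   vf$block, rho)
  eps <- cs_noise_pair(m, vf$block, rho, c_overlap)
  z_a <- sqrt(da$n_eff) * a_obs + eps$a
  z_b <- sqrt(db$n_eff) * b_obs + eps$b

  out <- list(a = sumstats_from_z(z_a, vf, truth$eaf, da, da$label),
              b = sumstats_from_z(z_b, vf, truth$eaf, db, db$label),
              endo = list())

  if (length(cfg$endophenotypes) > 0) {
    ## standardized case-case axis: per-causal-variant difference of
    ## delta-scale effects, scaled to unit per-variant variance
    sa <- delta_scale_factor(da); sb <- delta_scale_factor(db)
    d_axis <- sa * truth$effects_liability[, "a"] -
      sb * truth$effects_liability[, "b"]
    h2d_a <- da$h2_liability * sa^2
    h2d_b <- db$h2_liability * sb^2
    fst1 <- (h2d_a + h2d_b - 2 * cfg$rg * sqrt(h2d_a * h2d_b)) / cfg$m_causal
    d_std <- d_axis / sqrt(fst1)
    for (e in cfg$endophenotypes) {
      w <- numeric(m)
      w[truth$causal_index] <- stats::rnorm(cfg$m_causal)
      eff <- sqrt(e$h2 / cfg$m_causal) *
        (e$rg_axis * d_std + sqrt(max(0, 1 - e$rg_axis^2)) * w)
      z_e <- sqrt(cfg$n_endo) * cs_mult(eff, vf$block, rho) +
        cs_color(stats::rnorm(m), vf$block, rho)
      se_e <- 1 / sqrt(cfg$n_endo * 2 * truth$eaf * (1 - truth$eaf))
      tab <- as_sumstats(data.frame(chrom = vf$chrom, pos = vf$pos,
                                    effect_allele = "A", other_allele = "G",
                                    eaf = truth$eaf, beta = z_e * se_e,
                                    se = se_e, z = z_e, n = cfg$n_endo,
                                    stringsAsFactors = FALSE),
                         trait_label = e$label)
      out$endo[[e$label]] <- tab
    }
  }

  truth$overlap_corr <- c_overlap
  out$truth <- truth
  out$ld <- ld_reference(block = vf$block,
                         l = 1 + (vf$block_size - 1) * rho^2,
                         rho = rho)
  out
}

#' Simulate an individual-level cohort under the same genetic truth
#'
#' Genotypes are drawn as binomial dosages at the configured frequencies
#' (independently across variants; LD is a summary-statistics-level device
#' here). Liabilities combine the causal effects from [simulation_config()]'s
#' truth with independent environmental noise; disease labels threshold each
#' liability at its prevalence. An optional ancestry gradient loads allele
#' frequencies (logit scale) on a latent ancestry axis carried by the leading
#' principal component.
#'
#' When `ascertain` is given, individuals are over-sampled by rejection until
#' the requested numbers of disease-a cases, disease-b cases and controls are
#' reached, which keeps rare-disease polygenic-score evaluations desk-scale.
#'
#' @param cfg a [simulation_config()] with `m_variants <= 5000`.
#' @param n_individuals cohort size (ignored when `ascertain` is given).
#' @param n_pcs number of principal-component covariates returned (<= 20).
#' @param ancestry_sd standard deviation of per-variant logit-frequency
#'   loadings on the ancestry axis (0 = no structure).
#' @param ascertain optional `c(case_a =, case_b =, control =)` quotas.
#' @return list with `dosage` (individuals x variants), `y_a`, `y_b` (0/1
#'   labels), `pcs`, `ancestry`, `variant_id`, `eaf`, and `truth`.
#' @export
simulate_cohort <- function(cfg, n_individuals = 1000, n_pcs = 4,
                            ancestry_sd = 0, ascertain = NULL) {
  if (cfg$m_variants > 5000) {
    stop("individual-level simulation supports at most 5000 variants")
  }
  if (n_pcs > 20 || n_pcs < 1) stop("n_pcs must lie in 1..20")
  truth <- sim_truth(cfg)
  set.seed(cfg$seed + 2L)
  da <- cfg$disease_a; db <- cfg$disease_b
  m <- cfg$m_variants
  eaf <- truth$eaf
  causal <- truth$causal_index
  b_a <- truth$effects_liability[causal, "a"]
  b_b <- truth$effects_liability[causal, "b"]
  load <- if (ancestry_sd > 0) stats::rnorm(m, 0, ancestry_sd) else numeric(m)

  draw_batch <- function(n, cols = seq_len(m)) {
    anc <- stats::rnorm(n)
    p0 <- eaf[cols]
    if (ancestry_sd > 0) {
      lg <- outer(anc, load[cols]) + rep(stats::qlogis(p0), each = n)
      pr <- stats::plogis(lg)
      x <- matrix(stats::rbinom(n * length(cols), 2, pr), nrow = n)
    } else {
      x <- matrix(stats::rbinom(n * length(cols), 2, rep(p0, each = n)),
                  nrow = n)
    }
    list(x = x, anc = anc)
  }
  liab_labels <- function(xc, n) {
    xs <- sweep(sweep(xc, 2, 2 * eaf[causal]), 2,
                sqrt(2 * eaf[causal] * (1 - eaf[causal])), "/")
    g_a <- as.numeric(xs %*% b_a)
    g_b <- as.numeric(xs %*% b_b)
    l_a <- g_a + stats::rnorm(n, 0, sqrt(max(0, 1 - da$h2_liability)))
    l_b <- g_b + stats::rnorm(n, 0, sqrt(max(0, 1 - db$h2_liability)))
    list(y_a = as.integer(l_a > da$threshold),
         y_b = as.integer(l_b > db$threshold))
  }

  if (is.null(ascertain)) {
    batch <- draw_batch(n_individuals)
    lab <- liab_labels(batch$x[, causal, drop = FALSE], n_individuals)
    dosage <- batch$x
    anc <- batch$anc
    y_a <- lab$y_a; y_b <- lab$y_b
  } else {
    stopifnot(all(c("case_a", "case_b", "control") %in% names(ascertain)))
    got <- c(case_a = 0, case_b = 0, control = 0)
    keep_x <- list(); keep_anc <- list(); keep_ya <- list(); keep_yb <- list()
    guard <- 0
    while (any(got < ascertain) && guard < 1000) {
      guard <- guard + 1
      nb <- 5000L
      batch <- draw_batch(nb, cols = causal)
      lab <- liab_labels(batch$x, nb)
      grp <- ifelse(lab$y_a == 1, "case_a",
                    ifelse(lab$y_b == 1, "case_b", "control"))
      take <- logical(nb)
      for (g in names(got)) {
        need <- ascertain[[g]] - got[[g]]
        if (need > 0) {
          i <- which(grp == g)
          i <- utils::head(i, need)
          take[i] <- TRUE
          got[[g]] <- got[[g]] + length(i)
        }
      }
      if (any(take)) {
        keep_x[[length(keep_x) + 1L]] <- batch$x[take, , drop = FALSE]
        keep_anc[[length(keep_anc) + 1L]] <- batch$anc[take]
        keep_ya[[length(keep_ya) + 1L]] <- lab$y_a[take]
        keep_yb[[length(keep_yb) + 1L]] <- lab$y_b[take]
      }
    }
    if (any(got < ascertain)) stop("ascertainment quotas not reached")
    xc <- do.call(rbind, keep_x)
    anc <- unlist(keep_anc)
    y_a <- unlist(keep_ya); y_b <- unlist(keep_yb)
    n_tot <- length(anc)
    ## fill in the non-causal genotypes for retained individuals only
    dosage <- matrix(0L, n_tot, m)
    dosage[, causal] <- xc
    noncausal <- setdiff(seq_len(m), causal)
    if (length(noncausal) > 0) {
      if (ancestry_sd > 0) {
        lg <- outer(anc, load[noncausal]) +
          rep(stats::qlogis(eaf[noncausal]), each = n_tot)
        dosage[, noncausal] <- stats::rbinom(n_tot * length(noncausal), 2,
                                             stats::plogis(lg))
      } else {
        dosage[, noncausal] <- stats::rbinom(n_tot * length(noncausal), 2,
                                             rep(eaf[noncausal], each = n_tot))
      }
    }
  }

  n_tot <- length(anc)
  pcs <- matrix(stats::rnorm(n_tot * n_pcs, 0, 1), n_tot, n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(n_pcs))))
  if (ancestry_sd > 0) {
    pcs[, 1] <- as.numeric(scale(anc + stats::rnorm(n_tot, 0, 0.1)))
  }
  vf <- truth$frame
  vid <- variant_key(vf$chrom, vf$pos, rep("A", m), rep("G", m))
  colnames(dosage) <- vid
  list(dosage = dosage, y_a = y_a, y_b = y_b, pcs = pcs, ancestry = anc,
       variant_id = vid, eaf = eaf, truth = truth)
}
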