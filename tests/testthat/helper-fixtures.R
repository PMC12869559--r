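# Shared fixtures built in code. Heavier simulations are cached across test
# files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small handmade summary-statistics table.
toy_sumstats <- function(n = 5, chrom = "1", seed = 1, label = "toy") {
  set.seed(seed)
  beta <- rnorm(n, 0, 0.1)
  se <- runif(n, 0.02, 0.05)
  as_sumstats(data.frame(
    chrom = chrom, pos = seq_len(n) * 1e5,
    effect_allele = "A", other_allele = "G",
    eaf = runif(n, 0.1, 0.9), beta = beta, se = se,
    n_case = 1000, n_control = 2000,
    stringsAsFactors = FALSE), trait_label = label)
}

# Study-condition paired simulation at reduced size; used by several files.
paired_sim <- function() {
  cached("paired_sim", function() {
    cfg <- simulation_config(m_variants = 20000, m_causal = 800,
                             ld_block_size = 50, within_block_corr = 0.5,
                             shared_controls = 30000, seed = 101)
    list(cfg = cfg, sim = simulate_paired_sumstats(cfg))
  })
}

# Paired simulation with the endophenotype panel (third trait uncorrelated
# enough to fail the selection threshold).
endo_sim <- function() {
  cached("endo_sim", function() {
    endos <- list(list(label = "strain", h2 = 0.3, rg_axis = 0.79),
                  list(label = "volume", h2 = 0.3, rg_axis = 0.71),
                  list(label = "weak", h2 = 0.3, rg_axis = 0.30))
    cfg <- simulation_config(m_variants = 20000, m_causal = 1500,
                             ld_block_size = 20, within_block_corr = 0.5,
                             endophenotypes = endos, seed = 202)
    sim <- simulate_paired_sumstats(cfg)
    x <- cross_trait_model(rg = cfg$rg, error_covariance = 0,
                           m_causal = cfg$m_causal)
    cc <- casecase_stats(sim$a, sim$b, cfg$disease_a, cfg$disease_b, x)
    ccss <- casecase_to_sumstats(cc, cfg$disease_a, cfg$disease_b)
    list(cfg = cfg, sim = sim, ccss = ccss)
  })
}
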