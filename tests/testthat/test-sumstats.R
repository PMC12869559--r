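test_that("reading reconstructs missing statistics and rejects bad rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.tsv")

  df <- data.frame(chrom = "1", pos = c(100, 200, 300),
                   effect_allele = "A", other_allele = "G",
                   eaf = c(0.2, 0.5, 0.8),
                   beta = c(0.1, -0.2, 0.05), se = c(0.02, 0.04, 0.01))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  t1 <- read_sumstats(path)
  expect_equal(nrow(t1), 3)
  expect_equal(t1$z, t1$beta / t1$se)

  # a zero standard error invalidates exactly that row
  df2 <- df; df2$se[2] <- 0
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(t2 <- read_sumstats(path), "dropped 1")
  expect_equal(nrow(t2), 2)

  # p-only input: z = sign(beta) * qnorm(1 - p/2), against a numeric
  # inversion oracle
  df3 <- df[, c("chrom", "pos", "effect_allele", "other_allele", "eaf", "beta")]
  df3$p <- c(0.01, 0.3, 1e-6)
  write.table(df3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  t3 <- read_sumstats(path)
  z_oracle <- vapply(seq_len(3), function(i) {
    f <- function(z) 2 * pnorm(-abs(z)) - df3$p[i]
    sign(df3$beta[i]) * uniroot(f, c(1e-8, 40), tol = 1e-12)$root
  }, numeric(1))
  expect_equal(t3$z, z_oracle, tolerance = 1e-6)

  # a foreign dialect maps through the column config; missing mapped
  # columns are configuration errors naming the column
  df4 <- df
  names(df4)[names(df4) == "chrom"] <- "CHR"
  write.table(df4, path, sep = "\t", quote = FALSE, row.names = FALSE)
  t4 <- read_sumstats(path, dialect = c(chrom = "CHR"))
  expect_equal(t4$chrom, rep("1", 3))
  expect_error(read_sumstats(path, dialect = c(chrom = "NOPE")), "NOPE")
  expect_error(read_sumstats(path, dialect = c(chrom = "pos")),
               "mandatory")

  # a non-numeric effect entry drops only that row
  df5 <- df; df5$beta <- as.character(df5$beta); df5$beta[1] <- "bad"
  write.table(df5, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(t5 <- read_sumstats(path), "dropped 1")
  expect_equal(nrow(t5), 2)
})

test_that("z wins over an inconsistent p-value", {
  df <- data.frame(chrom = "1", pos = 1:2, effect_allele = "A",
                   other_allele = "G", eaf = 0.4,
                   beta = c(0.1, 0.1), se = c(0.02, 0.02),
                   p = c(2 * pnorm(-5), 0.5))
  expect_message(t <- as_sumstats(df), "inconsistent")
  expect_equal(t$p, rep(2 * pnorm(-5), 2))
})

test_that("harmonisation flips alleles, drops ambiguity, intersects", {
  a <- toy_sumstats(7, seed = 2)
  b <- a
  # swapped effect/other alleles at variant 3: beta negates, eaf complements
  b$effect_allele[3] <- "G"; b$other_allele[3] <- "A"
  b$beta[3] <- -b$beta[3]; b$z[3] <- -b$z[3]; b$eaf[3] <- 1 - b$eaf[3]
  # drop two variants from b: intersection shrinks to 5 in both outputs
  b <- b[1:5, ]
  h <- harmonize_pair(a, b)
  expect_equal(nrow(h$a), 5)
  expect_equal(h$a$variant_id, h$b$variant_id)
  # after the flip, b carries the same effect allele and original beta
  expect_equal(h$b$effect_allele, h$a$effect_allele)
  expect_equal(h$b$beta, a$beta[1:5])
  expect_equal(h$b$eaf, a$eaf[1:5])

  # strand-ambiguous variants go when flagged
  a2 <- a
  a2$effect_allele[2] <- "A"; a2$other_allele[2] <- "T"
  h2 <- harmonize_pair(a2, a2, remove_ambiguous = TRUE)
  expect_equal(nrow(h2$a), 6)
  expect_false("1:200000:A:T" %in% h2$a$variant_id)

  # symmetry up to order: (a,b) and (b,a) give the same variant set
  hab <- harmonize_pair(a, b)
  hba <- harmonize_pair(b, a)
  expect_setequal(hab$a$variant_id, hba$a$variant_id)

  # empty intersection is an explicit error
  c_tab <- toy_sumstats(3, chrom = "9", seed = 3)
  expect_error(harmonize_pair(a, c_tab), "empty")
})

test_that("QC filters by region, sample-size fraction and frequency", {
  # the excluded-region rule at the published coordinates
  t <- as_sumstats(data.frame(
    chrom = c("11", "11", "12"), pos = c(47e6, 90e6, 47e6),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = 0.1, se = 0.05, n_case = 100, n_control = 100))
  cfg <- qc_config(excluded_regions = data.frame(
    chrom = "11", start = 29978453, end = 80288956))
  out <- suppressMessages(apply_qc(t, cfg))
  expect_equal(out$pos, c(90e6, 47e6))

  # fractional sample-size boundary: 0.69 x max fails at threshold 0.70
  t2 <- as_sumstats(data.frame(
    chrom = "1", pos = c(1, 2) * 1e5, effect_allele = "A",
    other_allele = "G", eaf = 0.3, beta = 0.1, se = 0.05,
    n_case = c(1000, 690), n_control = c(1000, 690)))
  out2 <- suppressMessages(apply_qc(t2, qc_config(min_fraction_n = 0.70)))
  expect_equal(nrow(out2), 1)
  expect_equal(out2$pos, 1e5)
  expect_error(qc_config(min_fraction_n = 1.2), "0, 1")

  # 10 variants, 3 violating exactly one filter each; exhaustive row-wise
  # oracle agrees
  set.seed(9)
  t3 <- as_sumstats(data.frame(
    chrom = "2", pos = (1:10) * 1e5, effect_allele = "A", other_allele = "G",
    eaf = c(0.005, rep(0.3, 9)),
    beta = 0.05, se = 0.02,
    n_case = c(1000, 1000, 500, rep(1000, 7)),
    n_control = c(1000, 1000, 500, rep(1000, 7))))
  cfg3 <- qc_config(min_fraction_n = 0.7, min_eaf = 0.01,
                    excluded_regions = data.frame(chrom = "2", start = 5.5e5,
                                                  end = 6.5e5))
  out3 <- suppressMessages(apply_qc(t3, cfg3))
  oracle <- vapply(seq_len(nrow(t3)), function(i) {
    t3$n_eff[i] >= 0.7 * max(t3$n_eff) &&
      t3$eaf[i] >= 0.01 && t3$eaf[i] <= 0.99 &&
      !(t3$chrom[i] == "2" && t3$pos[i] >= 5.5e5 && t3$pos[i] <= 6.5e5)
  }, logical(1))
  expect_equal(out3$variant_id, t3$variant_id[oracle])
  expect_equal(nrow(out3), 7)

  # idempotence
  out3b <- suppressMessages(apply_qc(out3, cfg3))
  expect_equal(out3b, out3, ignore_attr = TRUE)
})

test_that("write/read round-trip preserves all numeric fields", {
  t <- toy_sumstats(6, seed = 4)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rt.tsv.gz")
  write_sumstats(t, path)
  t2 <- read_sumstats(path, trait_label = trait_label(t))
  for (col in c("pos", "eaf", "beta", "se", "z", "p")) {
    expect_equal(t2[[col]], t[[col]], tolerance = 1e-12)
  }
})
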