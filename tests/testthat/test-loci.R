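test_that("credible-set pips equal a direct ABF normalization", {
  t <- toy_sumstats(10, seed = 17)
  t$z <- c(1, 2, 8.5, 7.9, 1.5, 0.3, 6, 2.2, 0.8, 3)
  t$beta <- t$z * t$se
  t$p <- 2 * pnorm(-abs(t$z))
  cs <- abf_credible_sets(t, prior_sd = 0.2, coverage = 0.95)
  expect_length(cs, 1)

  W <- 0.04
  abf <- sqrt(t$se^2 / (t$se^2 + W)) *
    exp(t$z^2 / 2 * W / (t$se^2 + W))
  pip_oracle <- abf / sum(abf)
  expect_equal(unname(cs[[1]]$pip_all[t$variant_id]), pip_oracle,
               tolerance = 1e-12)
  # smallest set reaching 95% coverage, by ranked pips
  ord <- order(-pip_oracle)
  n_in <- which(cumsum(pip_oracle[ord]) >= 0.95)[1]
  expect_equal(nrow(cs[[1]]$members), n_in)
  expect_equal(sum(cs[[1]]$pip_all), 1, tolerance = 1e-12)
})

test_that("credible sets honour significance gates and symmetry", {
  # a lone strong variant: single-member set with pip ~ 1
  t <- toy_sumstats(5, seed = 18)
  t$z <- c(0.5, 8, 0.2, -0.7, 1.1)
  t$p <- 2 * pnorm(-abs(t$z))
  cs <- abf_credible_sets(t)
  expect_equal(nrow(cs[[1]]$members), 1)
  expect_gt(cs[[1]]$members$pip[1], 0.99)
  expect_equal(cs[[1]]$top_variant, t$variant_id[2])

  # two variants with identical statistics split the posterior evenly
  t2 <- t[c(2, 2), ]
  t2$pos[2] <- t2$pos[2] + 1000
  t2$variant_id[2] <- "dup"
  cs2 <- abf_credible_sets(t2)
  expect_equal(cs2[[1]]$members$pip, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(nrow(cs2[[1]]$members), 2)

  # nothing genome-wide significant: no set
  t3 <- toy_sumstats(5, seed = 19)
  expect_length(abf_credible_sets(t3), 0)
})

test_that("locus merging is transitive and matches brute force", {
  # 1.0, 1.9, 2.8 Mb chain on one chromosome: a single locus
  chain <- data.frame(chrom = "1", pos = c(1.0e6, 1.9e6, 2.8e6),
                      study = "s", p = 1e-9)
  expect_equal(nrow(define_loci(chain)), 1)
  # different chromosomes never merge
  twochr <- data.frame(chrom = c("1", "2"), pos = c(1e6, 1e6),
                       study = "s", p = 1e-9)
  expect_equal(nrow(define_loci(twochr)), 2)

  # randomized fixture versus brute-force single linkage (connected
  # components of the within-1Mb graph)
  set.seed(20)
  iv <- data.frame(chrom = as.character(sample(1:3, 60, replace = TRUE)),
                   pos = sample(1e6:5e7, 60),
                   study = sample(c("s1", "s2"), 60, replace = TRUE),
                   p = runif(60, 1e-12, 1e-8))
  cat_pkg <- define_loci(iv)

  adj <- outer(seq_len(60), seq_len(60), function(i, j) {
    iv$chrom[i] == iv$chrom[j] & abs(iv$pos[i] - iv$pos[j]) <= 1e6
  })
  comp <- rep(0L, 60)
  cid <- 0L
  for (i in seq_len(60)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      frontier <- i
      while (length(frontier) > 0) {
        comp[frontier] <- cid
        frontier <- which(apply(adj[, frontier, drop = FALSE], 1, any) &
                            comp == 0L)
      }
    }
  }
  expect_equal(nrow(cat_pkg), length(unique(comp)))
  brute_bounds <- t(vapply(split(seq_len(60), comp), function(ii) {
    c(min(iv$pos[ii]), max(iv$pos[ii]))
  }, numeric(2)))
  expect_setequal(paste(cat_pkg$start, cat_pkg$end),
                  paste(brute_bounds[, 1], brute_bounds[, 2]))

  # permutation invariance and empty input
  cat_perm <- define_loci(iv[sample(60), ])
  expect_equal(cat_perm, cat_pkg)
  expect_equal(nrow(define_loci(data.frame())), 0)
})

test_that("consolidation unions sources and flags novelty", {
  c1 <- define_loci(data.frame(chrom = "1", pos = c(1e6, 9e6),
                               study = "gwas_a", p = 1e-9))
  c2 <- define_loci(data.frame(chrom = "1", pos = c(1.2e6, 30e6),
                               study = "casecase", p = 1e-10))
  merged <- consolidate_loci(list(gwas_a = c1, casecase = c2),
                             reference_studies = "gwas_a")
  expect_equal(nrow(merged), 3)
  joint <- merged[grepl("gwas_a", merged$source_studies) &
                    grepl("casecase", merged$source_studies), ]
  expect_equal(nrow(joint), 1)
  expect_false(joint$novel_flag)
  only_cc <- merged[merged$source_studies == "casecase", ]
  expect_true(only_cc$novel_flag)

  # same index variant in three studies: one locus, three sources
  cats <- lapply(c("s1", "s2", "s3"), function(s) {
    define_loci(data.frame(chrom = "2", pos = 5e6, study = s, p = 1e-9))
  })
  names(cats) <- c("s1", "s2", "s3")
  m3 <- consolidate_loci(cats, reference_studies = c("s1", "s2"))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$source_studies, "s1,s2,s3")

  # randomized fixture: novelty flags match a brute-force membership scan
  set.seed(21)
  mk <- function(study, n) {
    define_loci(data.frame(chrom = as.character(sample(1:4, n, TRUE)),
                           pos = sample(1e6:8e7, n), study = study,
                           p = 1e-9))
  }
  cats2 <- list(ref1 = mk("ref1", 20), ref2 = mk("ref2", 15),
                new1 = mk("new1", 15))
  m <- consolidate_loci(cats2, reference_studies = c("ref1", "ref2"))
  brute_novel <- !grepl("ref1|ref2", m$source_studies)
  expect_equal(m$novel_flag, brute_novel)
  # merging an already-consolidated catalogue changes nothing
  m_again <- consolidate_loci(list(all = m), reference_studies = "none")
  expect_equal(m_again[, c("chrom", "start", "end")],
               m[, c("chrom", "start", "end")])
})

test_that("gene scoring reproduces the two-study worked example", {
  noms <- data.frame(
    locus_id = "locus12",
    study = c("study1", "study1", "study2", "study2"),
    method = c("network", "ml", "network", "ml"),
    gene = c("GENE_X", "GENE_X", "GENE_Y", "GENE_X"))
  sg <- score_genes(noms)
  expect_equal(sg$scores$score[sg$scores$gene == "GENE_X"], 1.5)
  expect_equal(sg$scores$score[sg$scores$gene == "GENE_Y"], 0.5)
  expect_equal(sg$leads$lead_genes, "GENE_X")

  # conservation: total score is 0.5 x number of nominations
  expect_equal(sum(sg$scores$score), 0.5 * nrow(noms))

  # exact ties are joint leads
  noms2 <- data.frame(locus_id = "l", study = c("s1", "s1", "s2", "s2"),
                      method = c("m1", "m2", "m1", "m2"),
                      gene = c("A", "A", "B", "B"))
  sg2 <- score_genes(noms2)
  expect_equal(sg2$leads$lead_genes, "A,B")

  # a sub-margin gap keeps the runner-up as joint candidate
  noms3 <- data.frame(locus_id = "l", study = c("s1", "s1", "s2"),
                      method = c("m1", "m2", "m1"),
                      gene = c("A", "B", "A"))
  sg3 <- score_genes(noms3)  # A = 1.0, B = 0.5, gap 0.5 < 1.0
  expect_equal(sg3$leads$lead_genes, "A,B")

  # a single nomination is the sole lead at 0.5
  sg4 <- score_genes(data.frame(locus_id = "l", study = "s", method = "m",
                                gene = "Z"))
  expect_equal(sg4$scores$score, 0.5)
  expect_equal(sg4$leads$lead_genes, "Z")

  # unknown locus ids are named in the error
  expect_error(score_genes(noms, known_loci = "other"), "locus12")
  # duplicate (locus, study, method) rejected
  expect_error(score_genes(noms[c(1, 1), ]), "duplicate")
})
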