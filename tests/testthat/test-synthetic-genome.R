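test_that("genome-wide ancestry fraction matches the spec within 3 SE", {
  spec <- admixture_spec(n_snps = 2000, n_chroms = 10)
  tr <- gen_ancestry_tracts(spec, n_samples = 48, seed = 51)
  f <- ancestry_frequency(tr$calls)$f
  # band: 3 x per-SNP binomial SE scaled by ~50 effective independent
  # tract blocks (tract LD makes the 2000 SNPs far from independent)
  expect_lt(abs(mean(f) - 0.55), 3 * sqrt(0.55 * 0.45 / 96) / sqrt(50))
  expect_identical(gen_ancestry_tracts(spec, 10, seed = 5)$calls$calls,
                   gen_ancestry_tracts(spec, 10, seed = 5)$calls$calls)
})

test_that("vanishing FST gives near-identical panels", {
  spec <- admixture_spec(n_snps = 500, n_chroms = 5, fst = 0.001)
  bun <- gen_admixed_genotypes(spec, n_samples = 10, seed = 61)
  expect_lt(mean(abs(bun$genotypes$snps$p_amr - bun$genotypes$snps$p_eur)),
            0.05)
})

test_that("posterior table is a valid simplex and collapses to the truth", {
  spec <- admixture_spec(n_snps = 60, n_chroms = 3,
                         posterior_confidence = 0.9)
  bun <- gen_admixed_genotypes(spec, n_samples = 5, seed = 71,
                               posteriors = TRUE)
  calls <- collapse_posteriors(bun$posteriors)
  m_true <- bun$calls$calls
  m_obs <- calls$calls[rownames(m_true), colnames(m_true)]
  assigned <- m_obs != "UNK"
  expect_gt(mean(assigned), 0.75)     # confidence 0.9 minus sampling noise
  expect_true(all(m_obs[assigned] == m_true[assigned]))
})

test_that("relatedness generator plants PiHat and inbreeding structure", {
  cohort <- tiny_cohort(n_per_group = 8)
  rel0 <- gen_relatedness(cohort, n_related_pairs = 0, seed = 81)
  expect_true(all(rel0$kinship$pihat < 0.05))
  rel <- gen_relatedness(cohort, n_related_pairs = 3, n_inbred = 4,
                         seed = 82)
  expect_equal(sum(rel$kinship$pihat > 0.25), 3)
  expect_equal(sum(rel$cohort$inbreeding_f > 0.04), 4)
  expect_identical(gen_relatedness(cohort, 2, 2, seed = 9),
                   gen_relatedness(cohort, 2, 2, seed = 9))
})

test_that("gwas catalog p-values follow the two-sided normal Wald formula", {
  spec <- admixture_spec(n_snps = 60, n_chroms = 2,
                         enriched_region = list(chrom = "chr1",
                                                start_idx = 10,
                                                end_idx = 20, excess = 0.2))
  bun <- gen_admixed_genotypes(spec, n_samples = 8, seed = 91)
  causal <- bun$genotypes$snps$snp[15]
  cat <- gen_gwas_catalog(bun, causal_snp = causal, effect = 0.29,
                          jitter = FALSE, seed = 92)
  expect_equal(cat$p, 2 * pnorm(-abs(cat$effect_a1 / cat$se)),
               tolerance = 1e-12)
  row <- cat[cat$snp == causal, ]
  expect_equal(abs(row$effect_a1), 0.29, tolerance = 1e-12)
  expect_error(gen_gwas_catalog(bun, causal_snp = "rs0000001", seed = 1),
               "truth region")
})

test_that("null catalog rows pass p < 0.01 at roughly the nominal rate", {
  spec <- admixture_spec(n_snps = 400, n_chroms = 1,
                         enriched_region = list(chrom = "chr1",
                                                start_idx = 1,
                                                end_idx = 400, excess = 0))
  bun <- gen_admixed_genotypes(spec, n_samples = 4, seed = 93)
  cat <- gen_gwas_catalog(bun, causal_snp = bun$genotypes$snps$snp[1],
                          effect = 0, jitter = TRUE, seed = 94)
  rate <- mean(cat$p < 0.01)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 400) + 1e-3)
})
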