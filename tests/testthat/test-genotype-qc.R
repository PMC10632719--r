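test_that("missingness filter removes samples first, SNPs second, strict >", {
  d <- matrix(0, nrow = 4, ncol = 4)
  d[1, 1] <- NA; d[2, 1] <- NA        # sample 1: 50% missing
  d[3, 2] <- NA                        # snp 3: 1/3 missing after removal
  g <- tiny_genotypes(d)
  res <- filter_missingness(g, mind = 0.3, geno = 0.05)
  expect_equal(colnames(res$genotypes$dosage), c("S02", "S03", "S04"))
  expect_equal(res$genotypes$snps$snp, c("rs001", "rs002", "rs004"))
  # boundary: exactly 5% missing is retained (20-sample row, 1 NA)
  d2 <- matrix(0, nrow = 2, ncol = 20)
  d2[1, 1] <- NA
  res2 <- filter_missingness(tiny_genotypes(d2), mind = 0.5, geno = 0.05)
  expect_equal(nrow(res2$genotypes$snps), 2)
  # no missing data: identity; idempotent
  g3 <- tiny_genotypes(matrix(rep(0:2, 4), nrow = 3))
  once <- filter_missingness(g3)
  twice <- filter_missingness(once$genotypes)
  expect_identical(once$genotypes$dosage, twice$genotypes$dosage)
  # report counts are conserved
  expect_equal(res$report$samples_removed[1] + res$report$samples_left[1], 4)
})

test_that("exact HWE test matches hand-derived values and conventions", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_test(10, 0, 0), 1)   # monomorphic convention
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  p <- hwe_exact_test(3, 4, 13)
  expect_true(p > 0 && p <= 1)
})

test_that("exact HWE test equals the enumeration oracle for all 2n <= 20", {
  for (n in 1:10) {
    for (n_aa in 0:n) {
      for (n_ab in 0:(n - n_aa)) {
        n_bb <- n - n_aa - n_ab
        expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                     hwe_enumeration_oracle(n_aa, n_ab, n_bb),
                     tolerance = 1e-10,
                     label = sprintf("table (%d,%d,%d)", n_aa, n_ab, n_bb))
      }
    }
  }
})

test_that("ambiguous A/T and C/G SNPs are removed", {
  d <- matrix(0, nrow = 6, ncol = 2)
  g <- tiny_genotypes(d, a1 = c("A", "A", "C", "G", "T", "C"),
                      a2 = c("T", "G", "G", "A", "C", "T"))
  res <- remove_ambiguous(g)          # rs001 A/T and rs003 C/G drop
  expect_equal(res$genotypes$snps$snp,
               c("rs002", "rs004", "rs005", "rs006"))
  expect_equal(nrow(res$genotypes$snps), 4)
})

test_that("PiHat recovers duplicates, unrelateds and parent-offspring", {
  set.seed(77)
  n_snp <- 3000
  p <- runif(n_snp, 0.1, 0.9)
  draw_hap <- function() rbinom(n_snp, 1, p)
  # samples: A, duplicate of A, unrelated B, child sharing one haplotype of A
  a1 <- draw_hap(); a2 <- draw_hap()
  b1 <- draw_hap(); b2 <- draw_hap()
  kid <- a1 + draw_hap()
  d <- cbind(A = a1 + a2, Adup = a1 + a2, B = b1 + b2, kid = kid)
  g <- tiny_genotypes(d)
  kin <- ibd_pihat(g, allele_freqs = p)
  get <- function(x, y) kin$pihat[(kin$id1 == x & kin$id2 == y) |
                                    (kin$id1 == y & kin$id2 == x)]
  expect_gt(get("A", "Adup"), 0.95)
  expect_lt(abs(get("A", "B")), 0.05)
  expect_lt(abs(get("A", "kid") - 0.5), 0.05)
})

test_that("relatedness pruning removes one member per offending pair", {
  kin <- data.frame(id1 = c("S01", "S01", "S02"),
                    id2 = c("S02", "S03", "S03"),
                    pihat = c(0.5, 0.45, 0.4))
  g <- tiny_genotypes(matrix(0, nrow = 2, ncol = 3))
  res <- filter_related(g, kin)
  expect_equal(length(res$removed), 2)   # triangle: greedy removes two
  expect_equal(ncol(res$genotypes$dosage), 1)
  # one planted pair: exactly one removed, tie broken lexicographically
  kin1 <- data.frame(id1 = "S01", id2 = "S02", pihat = 0.3)
  res1 <- filter_related(g, kin1)
  expect_identical(res1$removed, "S02")
  # nothing above threshold: identity
  res0 <- filter_related(g, data.frame(id1 = "S01", id2 = "S02",
                                       pihat = 0.2))
  expect_equal(ncol(res0$genotypes$dosage), 3)
})

test_that("LD pruning drops duplicated columns and satisfies its own bound", {
  set.seed(5)
  base <- matrix(rbinom(30 * 48, 2, 0.4), nrow = 30)
  base[2, ] <- base[1, ]                 # identical pair in one window
  g <- tiny_genotypes(base)
  kept <- ld_prune(g, window = 10, step = 5, r2_max = 0.2)
  expect_false("rs002" %in% kept)
  expect_true("rs001" %in% kept)
  # post-hoc property: no surviving within-window pair exceeds r2_max
  idx <- match(kept, g$snps$snp)
  for (st in seq(1, length(idx) - 9, by = 5)) {
    win <- idx[st:min(st + 9, length(idx))]
    cm <- suppressWarnings(cor(t(g$dosage[win, , drop = FALSE])))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    expect_lt(max(cm^2), 0.2 + 1e-12)
  }
})

test_that("independent SNPs are mostly retained at r2_max = 0.2", {
  # small-sample r^2 inflation at n = 48: P(|r| > sqrt(0.2)) ~ 0.002 per
  # null pair and ~8.5k within-window pairs over 200 SNPs, so the expected
  # retention is ~0.94; assert the analytically derived floor
  set.seed(6)
  d <- matrix(rbinom(200 * 48, 2, 0.5), nrow = 200)
  g <- tiny_genotypes(d)
  kept <- ld_prune(g)
  expect_gte(length(kept) / 200, 0.90)
})

test_that("the full QC chain conserves counts and is idempotent", {
  spec <- admixture_spec(n_snps = 600, n_chroms = 3)
  bun <- gen_admixed_genotypes(spec, n_samples = 12, seed = 15)
  freqs <- bun$genotypes$snps$freq_a1
  names(freqs) <- bun$genotypes$snps$snp
  res <- run_genotype_qc(bun$genotypes, allele_freqs = freqs)
  rep <- res$report
  expect_true(all(rep$samples_removed + rep$samples_left == 12))
  res2 <- run_genotype_qc(res$genotypes,
                          allele_freqs = freqs[res$genotypes$snps$snp])
  expect_equal(nrow(res2$genotypes$snps), nrow(res$genotypes$snps))
  expect_equal(ncol(res2$genotypes$dosage), ncol(res$genotypes$dosage))
  # single filters are idempotent too
  amb <- remove_ambiguous(bun$genotypes)
  expect_equal(nrow(remove_ambiguous(amb$genotypes)$genotypes$snps),
               nrow(amb$genotypes$snps))
  hw <- hwe_filter(bun$genotypes)
  expect_equal(nrow(hwe_filter(hw$genotypes)$genotypes$snps),
               nrow(hw$genotypes$snps))
})
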