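mock_catalog <- function(pos, p, chrom = "chr1", a1 = "A", a2 = "G",
                         effect = 0.1, enriched = a1) {
  n <- length(pos)
  data.frame(snp = sprintf("rs%04d", seq_len(n)), chrom = chrom, pos = pos,
             a1 = rep_len(a1, n), a2 = rep_len(a2, n), freq_a1 = 0.5,
             effect_a1 = rep_len(effect, n), se = 0.03, p = p, n = 35000,
             enriched_allele = rep_len(enriched, n),
             stringsAsFactors = FALSE)
}

test_that("discovery is an inclusive-bound pure filter", {
  regions <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                        direction = "over")
  cat <- mock_catalog(pos = c(999, 1000, 1500, 2000, 2001),
                      p = c(0.001, 0.001, 0.02, 0.005, 0.001))
  hits <- discover(regions, cat)
  expect_identical(hits$pos, c(1000, 2000))   # boundaries in, p=0.02 out
  expect_true(all(hits$snp %in% cat$snp))
  expect_identical(discover(regions, hits)$snp, hits$snp)  # idempotent
  expect_error(discover(data.frame(chrom = "chr9", start = 1, end = 2,
                                   direction = "over"), cat),
               "chromosome")
})

test_that("allele orientation counts the enriched allele and flips effects", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), nrow = 2, byrow = TRUE)
  g <- tiny_genotypes(d, a1 = "A", a2 = "G")
  cand <- mock_catalog(pos = c(1000, 2000), p = 0.001, effect = 0.3)
  cand$snp <- c("rs001", "rs002")
  cand$enriched_allele <- c("A", "G")
  al <- align_alleles(cand, g)
  expect_equal(unname(al$dosage[1, ]), c(0, 1, 2))       # a1 enriched
  expect_equal(unname(al$dosage[2, ]), c(0, 1, 2))       # a2: 2 - d
  expect_equal(unname(al$effect_enriched), c(0.3, -0.3))
  # orienting twice restores the original dosage
  cand2 <- cand[2, ]
  cand2$enriched_allele <- "A"
  al2 <- align_alleles(cand2, g)
  expect_equal(unname(al2$dosage[1, ]), 2 - unname(al$dosage[2, ]))
  # allele-set mismatch is dropped with a warning
  bad <- cand
  bad$a2 <- "C"
  expect_warning(al3 <- align_alleles(bad, g), "unmatched")
  expect_equal(nrow(al3$candidates), 0)
})

test_that("replication recovers an exact dosage relationship", {
  set.seed(40)
  d <- matrix(rbinom(3 * 24, 2, 0.5), nrow = 3)
  colnames(d) <- sprintf("P%02d", 1:24)
  g <- tiny_genotypes(d)
  est <- setNames(0.5 * d[1, ], colnames(d))
  cand <- mock_catalog(pos = 1000, p = 0.001, effect = 0.3)
  cand$snp <- "rs001"
  res <- suppressWarnings(replicate_candidates(g, est, cand))  # exact fit
  expect_equal(res$beta, 0.5, tolerance = 1e-10)
  expect_true(res$replicated)
  expect_true(res$direction_consistent)
  # monomorphic SNP is skipped with a note
  d2 <- d
  d2[1, ] <- 1
  g2 <- tiny_genotypes(d2)
  res2 <- replicate_candidates(g2, setNames(rnorm(24), colnames(d)), cand)
  expect_false(res2$replicated)
  expect_match(res2$note, "monomorphic")
})

test_that("planted per-allele effects replicate with consistent direction", {
  set.seed(41)
  hits <- replicate(100, {
    d <- rbinom(24, 2, 0.5)
    y <- 0.29 * d + rnorm(24, sd = 0.5)
    dm <- matrix(d, nrow = 1, dimnames = list("rs001",
                                              sprintf("P%02d", 1:24)))
    g <- tiny_genotypes(dm)
    cand <- mock_catalog(pos = 1000, p = 0.001, effect = 0.29)
    cand$snp <- "rs001"
    res <- replicate_candidates(g, setNames(y, colnames(dm)), cand)
    isTRUE(res$direction_consistent)
  })
  expect_gte(sum(hits), 90)
})

test_that("LD grouping joins near-duplicate SNPs only", {
  set.seed(42)
  a <- rbinom(40, 2, 0.5)
  b <- a
  flip <- sample(40, 2)
  b[flip] <- 2 - b[flip]
  c_ <- rbinom(40, 2, 0.5)
  g <- tiny_genotypes(rbind(a, b, c_))
  grp <- ld_groups(g, c("rs001", "rs002", "rs003"))
  expect_equal(grp[["rs001"]], grp[["rs002"]])
  expect_false(grp[["rs001"]] == grp[["rs003"]])
})
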