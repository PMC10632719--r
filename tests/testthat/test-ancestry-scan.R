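make_posterior_row <- function(snp, hap, anc, post, pos = 1000) {
  data.frame(chrom = "chr1", pos = pos, snp = snp, haplotype = hap,
             ancestry = c(anc, setdiff(c("AMR", "EUR"), anc)),
             posterior = c(post, 1 - post), stringsAsFactors = FALSE)
}

test_that("posterior collapse applies the strict 0.9 threshold", {
  post <- rbind(make_posterior_row("rs1", "h1", "AMR", 0.95),
                make_posterior_row("rs1", "h2", "EUR", 0.9),
                make_posterior_row("rs1", "h3", "AMR", 0.55),
                make_posterior_row("rs1", "h4", "AMR", 0.905))
  calls <- collapse_posteriors(post)
  expect_identical(unname(calls$calls["rs1", c("h1", "h2", "h3", "h4")]),
                   c("AMR", "UNK", "UNK", "AMR"))
  bad <- post
  bad$posterior[1] <- 0.7             # breaks the simplex for (rs1, h1)
  expect_error(collapse_posteriors(bad), "sum to 1")
})

test_that("ancestry frequency counts informative haplotypes only", {
  snps <- data.frame(chrom = "chr1", pos = c(100, 200), snp = c("a", "b"))
  m <- rbind(c("AMR", "AMR", "EUR", "UNK"),
             c("AMR", "AMR", "AMR", "AMR"))
  rownames(m) <- snps$snp
  colnames(m) <- paste0("h", 1:4)
  calls <- ancestry_calls(snps, m)
  f <- ancestry_frequency(calls)
  expect_equal(f$f, c(2 / 3, 1))
  expect_equal(f$n_informative, c(3, 4))
  f_unk <- ancestry_frequency(calls, count_unk = TRUE)
  expect_equal(f_unk$f[1], 2 / 4)
})

test_that("zscan matches hand arithmetic and the printed Z-to-p anchor", {
  freq <- data.frame(chrom = "chr1", pos = 1:4 * 100,
                     snp = paste0("s", 1:4), n_informative = 10,
                     f = c(0.5, 0.5, 0.5, 0.9))
  sc <- zscan(freq)
  expect_equal(attr(sc, "mu"), 0.6)
  expect_equal(attr(sc, "sigma"), 0.2)
  expect_equal(sc$z, c(-0.5, -0.5, -0.5, 1.5))
  expect_equal(sc$p[1], 2 * (1 - pnorm(0.5)))
  # standardisation invariant
  spec <- admixture_spec(n_snps = 400, n_chroms = 4)
  tr <- gen_ancestry_tracts(spec, 24, seed = 31)
  sc2 <- zscan(ancestry_frequency(tr$calls))
  expect_lt(abs(mean(sc2$z)), 1e-10)
  expect_lt(abs(sd(sc2$z) - 1), 1e-10)
  expect_error(zscan(data.frame(f = c(0.5, 0.5))), "variance")
})

test_that("region caller follows the same-sign consecutive-run rule", {
  scan <- data.frame(chrom = "chr1", pos = 1:5 * 1000,
                     snp = paste0("s", 1:5),
                     z = c(1, 3.5, 3.6, 2, -3.2))
  scan$p <- 2 * pnorm(-abs(scan$z))
  reg <- call_regions(scan)
  expect_equal(nrow(reg), 1)           # the lone -3.2 run is too short
  expect_equal(reg$start, 2000)
  expect_equal(reg$end, 3000)
  expect_equal(reg$z_max, 3.6)
  expect_identical(reg$direction, "over")
  # a sign change splits runs even when |z| stays above threshold
  scan$z <- c(3.5, 3.6, -3.5, -3.6, 1)
  scan$p <- 2 * pnorm(-abs(scan$z))
  reg2 <- call_regions(scan)
  expect_equal(nrow(reg2), 2)
  expect_identical(sort(reg2$direction), c("over", "under"))
  # empty when nothing exceeds the threshold
  scan$z <- rep(1, 5)
  expect_equal(nrow(call_regions(scan)), 0)
})

test_that("region calling is invariant to chromosome processing order", {
  spec <- admixture_spec(n_snps = 600, n_chroms = 6,
                         enriched_region = list(chrom = "chr2",
                                                start_idx = 20,
                                                end_idx = 40,
                                                excess = 0.3))
  tr <- gen_ancestry_tracts(spec, 48, seed = 32)
  sc <- zscan(ancestry_frequency(tr$calls))
  r1 <- call_regions(sc)
  shuffled <- sc[order(rev(seq_len(nrow(sc)))), ]
  r2 <- call_regions(shuffled)
  ord <- function(r) r[order(r$chrom, r$start), ]
  expect_equal(ord(r1), ord(r2), ignore_attr = TRUE)
})

test_that("global ancestry correlation gates method and finds planted links", {
  set.seed(33)
  n <- 30
  amr <- runif(n, 0.3, 0.8)
  est <- data.frame(sample_id = sprintf("s%02d", 1:n),
                    linked = 10 * amr + rnorm(n, sd = 1e-4),
                    noise = rnorm(n))
  class(est) <- c("estimator_table", class(est))
  res <- global_ancestry_correlation(data.frame(AMR = amr), est)
  linked <- res[res$estimator == "linked", ]
  expect_gt(abs(linked$r), 0.99)
  expect_lt(linked$p, 1e-10)
  skewed <- exp(rnorm(n) * 2)
  res2 <- global_ancestry_correlation(data.frame(AMR = skewed), est)
  expect_true(all(res2$method == "kendall"))
})
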