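# Shared small fixtures, built in code at test time.

tiny_cohort <- function(seed = 101, n_per_group = 8) {
  gen_cohort(cohort_spec(n_per_group = n_per_group,
                         sex_balance = rep(n_per_group / 2, 2),
                         rural_counts = c(n_per_group - 1, 0)),
             seed = seed)
}

tiny_genotypes <- function(dosage, chrom = "chr1", a1 = "A", a2 = "G") {
  n_snp <- nrow(dosage)
  snps <- data.frame(snp = sprintf("rs%03d", seq_len(n_snp)),
                     chrom = chrom, pos = seq_len(n_snp) * 1000,
                     a1 = rep_len(a1, n_snp), a2 = rep_len(a2, n_snp),
                     stringsAsFactors = FALSE)
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  }
  genotype_matrix(snps, dosage)
}

# independent exact HWE oracle: enumerate every genotype table with the
# observed allele counts via explicit multinomial conditional probabilities
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (n_a == 0 || n_a == 2 * n) return(1)
  tables <- list()
  for (h in 0:min(n_a, 2 * n - n_a)) {
    aa <- (n_a - h) / 2
    if (aa != floor(aa) || aa < 0) next
    bb <- n - aa - h
    if (bb < 0) next
    tables[[length(tables) + 1]] <- c(aa = aa, ab = h, bb = bb)
  }
  pr <- vapply(tables, function(tb) {
    exp(lfactorial(n) - lfactorial(tb[1]) - lfactorial(tb[2]) -
          lfactorial(tb[3]) + tb[2] * log(2) +
          lfactorial(n_a) + lfactorial(2 * n - n_a) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- which(vapply(tables, function(tb) tb[2] == n_ab, logical(1)))
  sum(pr[pr <= pr[obs] + 1e-12])
}

# brute-force LMG oracle: average sequential R^2 gain over all p! orderings
lmg_ordering_oracle <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    fit <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- do.call(rbind, combinat_perms(seq_len(p)))
  shares <- numeric(p)
  for (i in seq_len(nrow(perms))) {
    ordv <- perms[i, ]
    for (j in seq_len(p)) {
      prev <- if (j == 1) integer(0) else ordv[seq_len(j - 1)]
      shares[ordv[j]] <- shares[ordv[j]] + r2(c(prev, ordv[j])) - r2(prev)
    }
  }
  shares / nrow(perms)
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
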