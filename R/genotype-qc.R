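# Genotype quality control --------------------------------------------------
#
# Re-implements the stated QC filters: per-sample and per-SNP missingness
# (PLINK-like order: samples first), exact Hardy-Weinberg test, removal of
# strand-ambiguous SNPs, method-of-moments IBD PiHat, relatedness pruning at
# PiHat > 0.25, and sliding-window LD pruning (50 SNPs, step 5, r^2 > 0.2).

qc_report_row <- function(step, samples_removed, snps_removed,
                          samples_left, snps_left, params = "") {
  data.frame(step = step, samples_removed = samples_removed,
             snps_removed = snps_removed, samples_left = samples_left,
             snps_left = snps_left, params = params,
             stringsAsFactors = FALSE)
}

subset_genotypes <- function(g, snp_keep = NULL, sample_keep = NULL) {
  snps <- g$snps
  dosage <- g$dosage
  if (!is.null(snp_keep)) {
    snps <- snps[snp_keep, , drop = FALSE]
    dosage <- dosage[snp_keep, , drop = FALSE]
  }
  if (!is.null(sample_keep)) dosage <- dosage[, sample_keep, drop = FALSE]
  structure(list(snps = snps, dosage = dosage), class = "genotype_matrix")
}

#' Missingness filters (samples then SNPs)
#'
#' Samples whose missing-genotype fraction strictly exceeds `mind` are
#' removed first; then SNPs whose missing fraction (over the surviving
#' samples) strictly exceeds `geno`.
#'
#' @param g A [genotype_matrix()].
#' @param mind Maximum tolerated per-sample missing fraction.
#' @param geno Maximum tolerated per-SNP missing fraction.
#' @return List with `genotypes` and a `report` data frame.
#' @export
filter_missingness <- function(g, mind = 0.05, geno = 0.05) {
  stopifnot(mind >= 0, mind <= 1, geno >= 0, geno <= 1)
  sample_miss <- colMeans(is.na(g$dosage))
  keep_samples <- sample_miss <= mind
  g1 <- subset_genotypes(g, sample_keep = keep_samples)
  snp_miss <- rowMeans(is.na(g1$dosage))
  keep_snps <- snp_miss <= geno
  g2 <- subset_genotypes(g1, snp_keep = keep_snps)
  report <- rbind(
    qc_report_row("mind", sum(!keep_samples), 0, sum(keep_samples),
                  nrow(g$snps), sprintf("mind=%g", mind)),
    qc_report_row("geno", 0, sum(!keep_snps), sum(keep_samples),
                  sum(keep_snps), sprintf("geno=%g", geno)))
  if (ncol(g2$dosage) == 0 || nrow(g2$snps) == 0) {
    warning("missingness filtering left an empty genotype matrix")
  }
  list(genotypes = g2, report = report)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: conditional on the allele counts, the p-value is
#' the sum of probabilities of heterozygote counts whose conditional
#' probability does not exceed that of the observed table.  Monomorphic
#' SNPs return 1 by convention.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (homozygote a1, heterozygote,
#'   homozygote a2).
#' @return Exact p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(1, 0, 1)   # 1/3: het counts 0 and 2 are feasible
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop_acl("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop_acl("all genotype counts are zero")
  n_a <- 2 * n_aa + n_ab
  n_r <- min(n_a, 2 * n - n_a)             # rarer allele count
  if (n_r == 0) return(1)                   # monomorphic
  hets <- seq(n_r %% 2, n_r, by = 2)
  log_w <- hets * log(2) - lfactorial((n_r - hets) / 2) -
    lfactorial(hets) - lfactorial(n - (n_r + hets) / 2)
  w <- exp(log_w - max(log_w))
  prob <- w / sum(w)
  obs <- match(n_ab, hets)
  sum(prob[prob <= prob[obs] * (1 + 1e-10)])
}

#' Filter SNPs deviating from Hardy-Weinberg equilibrium
#'
#' @param g A [genotype_matrix()].
#' @param p_min SNPs with exact HWE p strictly below this are removed
#'   (default the printed Bonferroni-style threshold 7e-08).
#' @return List with `genotypes`, `p` (per-SNP HWE p for the input) and
#'   `report`.
#' @export
hwe_filter <- function(g, p_min = 7e-08) {
  d <- g$dosage
  p <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, ]
    hwe_exact_test(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                   sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  keep <- p >= p_min
  list(genotypes = subset_genotypes(g, snp_keep = keep),
       p = stats::setNames(p, g$snps$snp),
       report = qc_report_row("hwe", 0, sum(!keep), ncol(d), sum(keep),
                              sprintf("p_min=%g", p_min)))
}

#' Remove strand-ambiguous SNPs
#'
#' Drops SNPs whose allele pair is `{A, T}` or `{C, G}`; for such SNPs the
#' strand cannot be resolved when merging datasets.
#'
#' @param g A [genotype_matrix()].
#' @return List with `genotypes` and `report`.
#' @export
remove_ambiguous <- function(g) {
  pair <- paste(pmin(g$snps$a1, g$snps$a2), pmax(g$snps$a1, g$snps$a2))
  keep <- !(pair %in% c("A T", "C G"))
  list(genotypes = subset_genotypes(g, snp_keep = keep),
       report = qc_report_row("ambiguous", 0, sum(!keep), ncol(g$dosage),
                              sum(keep)))
}

#' Method-of-moments IBD sharing (PiHat)
#'
#' For each sample pair, estimates P(IBD = 0/1/2) from the observed
#' identity-by-state counts and the expected IBS distribution given the
#' allele frequencies, clips the estimate to the probability simplex, and
#' reports `PiHat = P(IBD=2) + P(IBD=1)/2`.  SNPs with frequency 0 or 1
#' (or missing in a pair) are excluded from that pair's estimator.
#'
#' @param g A [genotype_matrix()].
#' @param allele_freqs Per-SNP a1 frequency; defaults to the sample
#'   frequency computed from the dosages.
#' @return Data frame `id1`, `id2`, `ibs0`, `ibs1`, `ibs2`, `p_ibd0`,
#'   `p_ibd1`, `p_ibd2`, `pihat`.
#' @export
ibd_pihat <- function(g, allele_freqs = NULL) {
  d <- g$dosage
  if (ncol(d) < 2) stop_acl("PiHat needs at least two samples")
  p <- allele_freqs %||% (rowMeans(d, na.rm = TRUE) / 2)
  informative <- is.finite(p) & p > 0 & p < 1
  q <- 1 - p
  # expected IBS class probabilities given IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2
  ids <- colnames(d)
  pairs <- utils::combn(seq_along(ids), 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    use <- informative & !is.na(d[, i]) & !is.na(d[, j])
    ibs <- 2 - abs(d[use, i] - d[use, j])
    n0 <- sum(ibs == 0); n1 <- sum(ibs == 1); n2 <- sum(ibs == 2)
    p0 <- n0 / sum(e0_ibd0[use])
    p1 <- (n1 - p0 * sum(e1_ibd0[use])) / sum(e1_ibd1[use])
    p2 <- (n2 - p0 * sum(e2_ibd0[use]) - p1 * sum(e2_ibd1[use])) / sum(use)
    pr <- pmax(c(p0, p1, p2), 0)
    pr <- pr / sum(pr)
    out[[k]] <- data.frame(id1 = ids[i], id2 = ids[j], ibs0 = n0, ibs1 = n1,
                           ibs2 = n2, p_ibd0 = pr[1], p_ibd1 = pr[2],
                           p_ibd2 = pr[3], pihat = pr[3] + pr[2] / 2,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Remove one member of each related pair
#'
#' Greedy pruning: while any remaining pair exceeds the PiHat threshold,
#' the pair with the highest PiHat is resolved by removing the member with
#' the higher genotype missingness (ties broken towards the
#' lexicographically later id).
#'
#' @param g A [genotype_matrix()].
#' @param kin Kinship data frame (`id1`, `id2`, `pihat`).
#' @param threshold PiHat threshold (default 0.25, strictly greater).
#' @return List with `genotypes`, `removed` (character vector of sample
#'   ids) and `report`.
#' @export
filter_related <- function(g, kin, threshold = 0.25) {
  miss <- colMeans(is.na(g$dosage))
  removed <- character(0)
  active <- kin[kin$id1 %in% names(miss) & kin$id2 %in% names(miss), ,
                drop = FALSE]
  repeat {
    live <- active[!(active$id1 %in% removed) & !(active$id2 %in% removed) &
                     active$pihat > threshold, , drop = FALSE]
    if (nrow(live) == 0) break
    top <- live[which.max(live$pihat), ]
    m1 <- miss[[top$id1]]; m2 <- miss[[top$id2]]
    victim <- if (m1 > m2) top$id1
    else if (m2 > m1) top$id2
    else max(top$id1, top$id2)
    removed <- c(removed, victim)
  }
  keep <- !(colnames(g$dosage) %in% removed)
  list(genotypes = subset_genotypes(g, sample_keep = keep),
       removed = removed,
       report = qc_report_row("related", length(removed), 0, sum(keep),
                              nrow(g$snps),
                              sprintf("pihat>%g", threshold)))
}

#' Sliding-window LD pruning
#'
#' Within each window of `window` SNPs (advanced by `step`, per
#' chromosome), any pair of retained SNPs with squared dosage correlation
#' above `r2_max` is resolved by dropping the later-positioned SNP.
#'
#' @param g A [genotype_matrix()].
#' @param window Window size in SNPs.
#' @param step Window advance in SNPs.
#' @param r2_max Maximum tolerated pairwise r-squared (composite LD on
#'   dosages).
#' @return Character vector of retained SNP ids, in position order.
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_max = 0.2) {
  if (window < 2) stop_acl("window must span at least 2 SNPs")
  keep <- rep(TRUE, nrow(g$snps))
  names(keep) <- g$snps$snp
  for (ch in unique(g$snps$chrom)) {
    rows <- which(g$snps$chrom == ch)
    rows <- rows[order(g$snps$pos[rows])]
    n <- length(rows)
    starts <- if (n <= window) 1 else seq(1, n - window + 1, by = step)
    for (st in starts) {
      win <- rows[st:min(st + window - 1, n)]
      live <- win[keep[win]]
      if (length(live) < 2) next
      cm <- suppressWarnings(
        stats::cor(g$dosage[live, , drop = FALSE] |> t(),
                   use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      for (a in seq_len(length(live) - 1)) {
        if (!keep[live[a]]) next
        for (b in seq(a + 1, length(live))) {
          if (!keep[live[b]]) next
          if (cm[a, b]^2 > r2_max) keep[live[b]] <- FALSE
        }
      }
    }
  }
  g$snps$snp[keep]
}

#' Run the full genotype QC chain
#'
#' Missingness (samples then SNPs), exact HWE, relatedness (PiHat), then
#' strand-ambiguous removal; LD pruning is reported as a kept-SNP list
#' rather than applied, mirroring its use for ancestry analyses only.
#'
#' @param g A [genotype_matrix()].
#' @param mind,geno Missingness thresholds.
#' @param hwe_p HWE exact-test threshold.
#' @param pihat_max Relatedness threshold.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @param allele_freqs Optional per-SNP a1 frequencies for the PiHat
#'   estimator.
#' @return List with `genotypes` (analysis-ready), `kinship`, `removed`,
#'   `ld_keep`, and the concatenated `report` (a `qc_report`).
#' @export
run_genotype_qc <- function(g, mind = 0.05, geno = 0.05, hwe_p = 7e-08,
                            pihat_max = 0.25, ld_window = 50, ld_step = 5,
                            ld_r2 = 0.2, allele_freqs = NULL) {
  s1 <- filter_missingness(g, mind, geno)
  s2 <- hwe_filter(s1$genotypes, hwe_p)
  kin <- ibd_pihat(s2$genotypes, allele_freqs)
  s3 <- filter_related(s2$genotypes, kin, pihat_max)
  s4 <- remove_ambiguous(s3$genotypes)
  ld_keep <- ld_prune(s4$genotypes, ld_window, ld_step, ld_r2)
  report <- rbind(s1$report, s2$report, s3$report, s4$report)
  class(report) <- unique(c("qc_report", class(report)))
  list(genotypes = s4$genotypes, kinship = kin, removed = s3$removed,
       ld_keep = ld_keep, report = report)
}
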