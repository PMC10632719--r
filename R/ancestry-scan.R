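# Local-ancestry deviation scan ---------------------------------------------
#
# Posterior collapse (argmax > 0.9, else UNK), per-SNP ancestry frequency
# over informative haplotypes, the standardised deviation
# Z = (f - mu) / sigma with mu and sigma taken genome-wide (sample SD,
# n - 1), two-sided normal p-values, and region calling over runs of
# consecutive same-sign |Z| > 3 SNPs.

#' Collapse ancestry posteriors to hard calls
#'
#' Assigns the argmax ancestry when its posterior strictly exceeds the
#' threshold, `UNK` otherwise.
#'
#' @param post Long posterior table with columns `chrom`, `pos`, `snp`,
#'   `haplotype`, `ancestry`, `posterior`; posteriors for one (haplotype,
#'   SNP) cell must sum to one.
#' @param threshold Assignment threshold (strict `>`; default 0.9).
#' @return An [ancestry_calls()] object.
#' @export
collapse_posteriors <- function(post, threshold = 0.9) {
  require_columns(post, c("chrom", "pos", "snp", "haplotype", "ancestry",
                          "posterior"), "posterior table")
  cell <- interaction(post$snp, post$haplotype, drop = TRUE)
  sums <- tapply(post$posterior, cell, sum)
  bad <- which(abs(sums - 1) > 1e-6)
  if (length(bad)) {
    stop_acl(sprintf("posteriors do not sum to 1 for %s (sum %.6f)",
                     names(sums)[bad[1]], sums[bad[1]]))
  }
  ord <- order(post$haplotype, post$snp, -post$posterior)
  top <- post[ord, ][!duplicated(cell[ord]), ]
  top$label <- ifelse(top$posterior > threshold, top$ancestry, "UNK")
  snps <- unique(post[, c("chrom", "pos", "snp")])
  snps <- snps[order(snps$chrom, snps$pos), ]
  haps <- sort(unique(post$haplotype))
  m <- matrix("UNK", nrow = nrow(snps), ncol = length(haps),
              dimnames = list(snps$snp, haps))
  m[cbind(match(top$snp, snps$snp), match(top$haplotype, haps))] <- top$label
  ancestry_calls(snps, m)
}

#' Per-SNP ancestry frequency over informative haplotypes
#'
#' `f = (haplotypes called `anc`) / (haplotypes not UNK)` at each SNP; SNPs
#' with no informative haplotype are masked (NA) and excluded downstream.
#'
#' @param calls An [ancestry_calls()] object.
#' @param anc Ancestry label to count (default `"AMR"`).
#' @param count_unk Count UNK haplotypes in the denominator instead of
#'   excluding them (config switch; default FALSE).
#' @return Data frame `chrom`, `pos`, `snp`, `n_informative`, `f`.
#' @export
ancestry_frequency <- function(calls, anc = "AMR", count_unk = FALSE) {
  m <- calls$calls
  n_anc <- rowSums(m == anc)
  n_inf <- if (count_unk) ncol(m) else rowSums(m != "UNK")
  f <- ifelse(n_inf > 0, n_anc / n_inf, NA_real_)
  if (any(n_inf == 0)) {
    warning(sprintf("%d SNP(s) masked: no informative haplotypes",
                    sum(n_inf == 0)))
  }
  data.frame(calls$snps, n_informative = n_inf, f = f,
             stringsAsFactors = FALSE)
}

#' Standardised ancestry deviation scan
#'
#' `Z = (f - mu) / sigma` per SNP, with `mu` and `sigma` the genome-wide
#' mean and sample standard deviation (n - 1) of `f` over unmasked SNPs;
#' two-sided p from the normal reference, `p = 2 * (1 - Phi(|Z|))`.
#'
#' @param freq Output of [ancestry_frequency()] (or any data frame with a
#'   numeric `f` column; NAs are masked).
#' @return The input with `z` and `p` columns plus attributes `mu` and
#'   `sigma`.
#' @export
zscan <- function(freq) {
  f <- freq$f
  use <- !is.na(f)
  if (sum(use) < 2) stop_acl("zscan needs at least two unmasked SNPs")
  mu <- mean(f[use])
  sigma <- stats::sd(f[use])
  if (sigma == 0) stop_acl("no ancestry variance across SNPs")
  freq$z <- (f - mu) / sigma
  freq$p <- 2 * stats::pnorm(-abs(freq$z))
  attr(freq, "mu") <- mu
  attr(freq, "sigma") <- sigma
  class(freq) <- unique(c("ancestry_scan", class(freq)))
  freq
}

#' Call ancestry-deviant regions
#'
#' Maximal runs of consecutive (position-sorted, per chromosome) SNPs with
#' `|Z|` above the threshold and the same sign, of length at least
#' `min_snps`.  Region bounds are the first and last member SNP positions
#' (1-based inclusive); `z_max` is the member Z of largest magnitude,
#' signed.
#'
#' @param scan Output of [zscan()] (needs `chrom`, `pos`, `z`, `p`).
#' @param z_threshold Threshold on `|Z|` (default 3).
#' @param min_snps Minimum run length (default 2).
#' @return Data frame `chrom`, `start`, `end`, `n_snps`, `z_max`, `p_min`,
#'   `direction` (`over`/`under`).
#' @export
call_regions <- function(scan, z_threshold = 3, min_snps = 2) {
  out <- list()
  for (ch in unique(scan$chrom)) {
    s <- scan[scan$chrom == ch & !is.na(scan$z), , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    if (nrow(s) == 0) next
    state <- ifelse(abs(s$z) > z_threshold, sign(s$z), 0)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0 || r$lengths[k] < min_snps) next
      idx <- starts[k]:ends[k]
      zi <- s$z[idx]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = s$pos[idx[1]], end = s$pos[idx[length(idx)]],
        n_snps = length(idx), z_max = zi[which.max(abs(zi))],
        p_min = min(s$p[idx]),
        direction = if (r$values[k] > 0) "over" else "under",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      z_max = numeric(0), p_min = numeric(0),
                      direction = character(0)))
  }
  do.call(rbind, out)
}

#' Full ancestry deviation scan from calls
#'
#' Convenience wrapper: frequency, Z-scan, region calling.
#'
#' @inheritParams ancestry_frequency
#' @inheritParams call_regions
#' @return List with `scan` (per-SNP table) and `regions`.
#' @export
ancestry_zscan <- function(calls, anc = "AMR", z_threshold = 3,
                           min_snps = 2, count_unk = FALSE) {
  freq <- ancestry_frequency(calls, anc, count_unk)
  scan <- zscan(freq)
  list(scan = scan,
       regions = call_regions(scan, z_threshold, min_snps))
}

#' Correlate global ancestry proportions with estimators
#'
#' Pearson when both variables pass the Shapiro-Wilk gate, Kendall
#' otherwise; constant columns are skipped with a note.
#'
#' @param props Data frame/matrix of per-sample ancestry proportions
#'   (samples in rows, components in columns), row-matched to `est`.
#' @param est An `estimator_table`.
#' @param shapiro_alpha Normality-gate level.
#' @param fdr_q Optional BH flag level applied per ancestry component.
#' @return Data frame: `component`, `estimator`, `method`, `r`, `p`,
#'   `bh_q`.
#' @export
global_ancestry_correlation <- function(props, est, shapiro_alpha = 0.05,
                                        fdr_q = 0.1) {
  props <- as.data.frame(props)
  cols <- estimator_columns(est)
  if (nrow(props) != nrow(est)) stop_acl("props/est row mismatch")
  out <- list()
  for (comp in names(props)) {
    a <- props[[comp]]
    for (cn in cols) {
      e <- est[[cn]]
      ok <- is.finite(a) & is.finite(e)
      if (sum(ok) < 4) next
      if (stats::var(a[ok]) == 0 || stats::var(e[ok]) == 0) {
        out[[length(out) + 1]] <- data.frame(
          component = comp, estimator = cn, method = "skipped (constant)",
          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      method <- if (normality_gate(a[ok], e[ok], shapiro_alpha) == "normal") {
        "pearson"
      } else {
        "kendall"
      }
      ct <- suppressWarnings(stats::cor.test(a[ok], e[ok], method = method))
      out[[length(out) + 1]] <- data.frame(
        component = comp, estimator = cn, method = method,
        r = unname(ct$estimate), p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$bh_q <- NA_real_
  for (comp in unique(res$component)) {
    idx <- which(res$component == comp & !is.na(res$p))
    if (length(idx)) res$bh_q[idx] <- bh_adjust(res$p[idx], fdr_q)$qvals
  }
  res
}
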