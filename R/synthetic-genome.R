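# Synthetic admixed genome --------------------------------------------------
#
# Two-way admixture is emulated with Balding-Nichols ancestral allele
# frequency panels and per-haplotype ancestry tracts from a two-state Markov
# chain parameterised per morgan on a uniform 1 cM/Mb map.  One region can
# be planted with excess ancestry of the first (AMR-role) population; tract
# state is re-equilibrated at the region boundary so the within-region
# marginal equals the boosted stationary frequency exactly.

#' Admixed-genome specification
#'
#' @param n_snps Total SNP count across all chromosomes.
#' @param n_chroms Chromosome count (SNPs are split evenly).
#' @param fst Balding-Nichols divergence between the two ancestral panels.
#' @param global_amr_fraction Stationary AMR ancestry fraction (default
#'   0.55, an even Native-American/European mixture).
#' @param tract_rate Expected ancestry switches per morgan; `Inf` gives
#'   independent per-SNP ancestry draws (a tract-free null genome).
#' @param snp_spacing_bp Physical spacing between adjacent SNPs (1 cM/Mb
#'   map, so 1e6 bp = 1 cM).
#' @param enriched_region `NULL`, or `list(chrom, start_idx, end_idx,
#'   excess)` giving the planted region by within-chromosome SNP indices and
#'   the increment added to the AMR assignment probability inside it.
#' @param posterior_confidence Probability that a generated posterior
#'   exceeds the 0.9 collapse threshold (controls the UNK rate).
#' @param ambiguous_fraction Fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) allele pairs.
#' @return An object of class `admixture_spec`.
#' @export
admixture_spec <- function(n_snps = 5000, n_chroms = 20, fst = 0.15,
                           global_amr_fraction = 0.55, tract_rate = 12,
                           snp_spacing_bp = 1e6, enriched_region = NULL,
                           posterior_confidence = 0.95,
                           ambiguous_fraction = 0.05) {
  if (fst <= 0 || fst >= 1) stop_acl("fst must be in (0, 1)")
  if (global_amr_fraction <= 0 || global_amr_fraction >= 1) {
    stop_acl("global_amr_fraction must be in (0, 1)")
  }
  if (!is.null(enriched_region)) {
    er <- enriched_region
    if (!all(c("chrom", "start_idx", "end_idx", "excess") %in% names(er))) {
      stop_acl("enriched_region needs chrom, start_idx, end_idx, excess")
    }
    if (global_amr_fraction + er$excess > 1) {
      stop_acl("excess pushes the AMR assignment probability above 1")
    }
    per_chrom <- ceiling(n_snps / n_chroms)
    if (er$start_idx < 1 || er$end_idx > per_chrom ||
        er$start_idx > er$end_idx) {
      stop_acl("enriched_region indices outside the chromosome")
    }
  }
  structure(list(n_snps = n_snps, n_chroms = n_chroms, fst = fst,
                 global_amr_fraction = global_amr_fraction,
                 tract_rate = tract_rate, snp_spacing_bp = snp_spacing_bp,
                 enriched_region = enriched_region,
                 posterior_confidence = posterior_confidence,
                 ambiguous_fraction = ambiguous_fraction),
            class = "admixture_spec")
}

snp_layout <- function(spec) {
  base <- spec$n_snps %/% spec$n_chroms
  counts <- rep(base, spec$n_chroms)
  extra <- spec$n_snps - base * spec$n_chroms
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  chrom <- rep(sprintf("chr%d", seq_len(spec$n_chroms)), counts)
  idx <- unlist(lapply(counts, seq_len))
  data.frame(chrom = chrom,
             pos = idx * spec$snp_spacing_bp,
             snp = sprintf("rs%07d", seq_len(spec$n_snps)),
             chrom_idx = idx,
             stringsAsFactors = FALSE)
}

#' Generate per-haplotype ancestry tracts
#'
#' Simulates the two-state (AMR/EUR) Markov switch process for
#' `2 * n_samples` haplotypes and records the planted truth region.
#'
#' @param spec An [admixture_spec()].
#' @param n_samples Number of diploid samples (haplotypes are
#'   `<sample>_1`, `<sample>_2`).
#' @param seed Integer RNG seed.
#' @return List with `calls` (an [ancestry_calls()] object), `truth` (data
#'   frame of planted regions, possibly empty) and `snps`.
#' @export
gen_ancestry_tracts <- function(spec = admixture_spec(), n_samples, seed) {
  stopifnot(inherits(spec, "admixture_spec"))
  snps <- snp_layout(spec)
  n_hap <- 2L * n_samples
  hap_ids <- paste0(rep(sprintf("S%03d", seq_len(n_samples)), each = 2),
                    c("_1", "_2"))
  pi_amr <- rep(spec$global_amr_fraction, nrow(snps))
  er <- spec$enriched_region
  if (!is.null(er)) {
    in_region <- snps$chrom == er$chrom &
      snps$chrom_idx >= er$start_idx & snps$chrom_idx <= er$end_idx
    pi_amr[in_region] <- pi_amr[in_region] + er$excess
  }
  d_morgan <- spec$snp_spacing_bp * 1e-8          # 1 cM/Mb
  rho <- if (is.finite(spec$tract_rate)) exp(-spec$tract_rate * d_morgan) else 0
  with_seed(seed, {
    states <- matrix(0L, nrow = nrow(snps), ncol = n_hap)
    for (ch in unique(snps$chrom)) {
      rows <- which(snps$chrom == ch)
      s <- matrix(0L, nrow = length(rows), ncol = n_hap)
      s[1, ] <- stats::rbinom(n_hap, 1L, pi_amr[rows[1]])
      if (length(rows) > 1) {
        for (i in 2:length(rows)) {
          # re-equilibrate where the stationary changes (region boundary)
          r <- if (pi_amr[rows[i]] != pi_amr[rows[i - 1]]) 0 else rho
          stay <- stats::runif(n_hap) < r
          fresh <- stats::rbinom(n_hap, 1L, pi_amr[rows[i]])
          s[i, ] <- ifelse(stay, s[i - 1, ], fresh)
        }
      }
      states[rows, ] <- s
    }
    labels <- matrix(c("EUR", "AMR")[states + 1L], nrow = nrow(snps),
                     dimnames = list(snps$snp, hap_ids))
    truth <- if (is.null(er)) {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 ancestry = character(0), excess = numeric(0))
    } else {
      data.frame(chrom = er$chrom,
                 start = er$start_idx * spec$snp_spacing_bp,
                 end = er$end_idx * spec$snp_spacing_bp,
                 ancestry = "AMR", excess = er$excess,
                 stringsAsFactors = FALSE)
    }
    list(calls = ancestry_calls(snps[, c("chrom", "pos", "snp")], labels),
         truth = truth, snps = snps, states = states)
  })
}

assign_alleles <- function(n, ambiguous_fraction) {
  pairs_ok <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
  pairs_amb <- list(c("A", "T"), c("C", "G"))
  amb <- stats::runif(n) < ambiguous_fraction
  pick <- function(pool, k) {
    idx <- sample.int(length(pool), k, replace = TRUE)
    do.call(rbind, pool[idx])
  }
  out <- matrix("", n, 2)
  if (any(!amb)) out[!amb, ] <- pick(pairs_ok, sum(!amb))
  if (any(amb)) out[amb, ] <- pick(pairs_amb, sum(amb))
  out
}

#' Generate an admixed genotype dataset
#'
#' Builds on [gen_ancestry_tracts()]: draws two ancestral allele-frequency
#' panels under the Balding-Nichols model at the spec's FST, then draws each
#' haplotype's allele from its local ancestry's panel frequency.  Optionally
#' emits an RFMix-style long posterior table consistent with the true
#' tracts (max-ancestry posterior above the 0.9 collapse threshold with
#' probability `posterior_confidence`).
#'
#' @inheritParams gen_ancestry_tracts
#' @param posteriors Emit the per-(haplotype, SNP) posterior table? (Large:
#'   `2 * n_samples * n_snps` rows.)
#' @return List with `genotypes` (a [genotype_matrix()] whose snp table
#'   carries the panel frequencies `p_amr`, `p_eur`), `calls`, `truth`, and
#'   `posteriors` (or `NULL`).
#' @export
gen_admixed_genotypes <- function(spec = admixture_spec(), n_samples, seed,
                                  posteriors = FALSE) {
  tracts <- gen_ancestry_tracts(spec, n_samples, seed)
  snps <- tracts$snps
  n_snp <- nrow(snps)
  n_hap <- 2L * n_samples
  with_seed(derive_seed(seed, 1), {
    p0 <- stats::runif(n_snp, 0.1, 0.9)
    shp <- (1 - spec$fst) / spec$fst
    p_amr <- stats::rbeta(n_snp, p0 * shp, (1 - p0) * shp)
    p_eur <- stats::rbeta(n_snp, p0 * shp, (1 - p0) * shp)
    p_amr <- pmin(pmax(p_amr, 1e-4), 1 - 1e-4)
    p_eur <- pmin(pmax(p_eur, 1e-4), 1 - 1e-4)
    freq <- p_amr * spec$global_amr_fraction +
      p_eur * (1 - spec$global_amr_fraction)
    pm <- matrix(p_eur, n_snp, n_hap)
    pm[tracts$states == 1L] <- matrix(p_amr, n_snp, n_hap)[tracts$states == 1L]
    hap_alleles <- matrix(stats::rbinom(n_snp * n_hap, 1L, pm), n_snp, n_hap)
    odd <- seq(1, n_hap, by = 2)
    dosage <- hap_alleles[, odd, drop = FALSE] +
      hap_alleles[, odd + 1L, drop = FALSE]
    colnames(dosage) <- sub("_1$", "", colnames(tracts$calls$calls)[odd])
    al <- assign_alleles(n_snp, spec$ambiguous_fraction)
    snp_table <- data.frame(snp = snps$snp, chrom = snps$chrom,
                            pos = snps$pos, a1 = al[, 1], a2 = al[, 2],
                            p_amr = p_amr, p_eur = p_eur, freq_a1 = freq,
                            stringsAsFactors = FALSE)
    g <- genotype_matrix(snp_table, dosage)
    post <- NULL
    if (posteriors) {
      conf <- stats::runif(n_snp * n_hap) < spec$posterior_confidence
      pmax_val <- ifelse(conf, stats::runif(n_snp * n_hap, 0.905, 0.999),
                         stats::runif(n_snp * n_hap, 0.5, 0.9))
      true_lab <- as.vector(tracts$calls$calls)
      post <- data.frame(
        chrom = rep(snps$chrom, times = n_hap),
        pos = rep(snps$pos, times = n_hap),
        snp = rep(snps$snp, times = n_hap),
        haplotype = rep(colnames(tracts$calls$calls), each = n_snp),
        ancestry = true_lab,
        posterior = pmax_val,
        stringsAsFactors = FALSE)
      other <- post
      other$ancestry <- ifelse(true_lab == "AMR", "EUR", "AMR")
      other$posterior <- 1 - pmax_val
      post <- rbind(post, other)
      post <- post[order(post$haplotype, post$chrom, post$pos,
                         post$ancestry), ]
      rownames(post) <- NULL
    }
    list(genotypes = g, calls = tracts$calls, truth = tracts$truth,
         posteriors = post)
  })
}

#' Plant relatedness and inbreeding structure on a cohort
#'
#' Planted related pairs receive PiHat drawn from `[0.3, 0.6]`, all other
#' pairs from `[0, 0.05]`; `n_inbred` samples receive inbreeding
#' coefficients from `[0.05, 0.15]`, the rest near zero.
#'
#' @param cohort A `sample_table`.
#' @param n_related_pairs Number of planted related pairs.
#' @param n_inbred Number of planted inbred individuals.
#' @param seed Integer RNG seed.
#' @return List with `kinship` (data frame `id1`, `id2`, `pihat` over all
#'   unordered pairs) and `cohort` (input with an `inbreeding_f` column).
#' @export
gen_relatedness <- function(cohort, n_related_pairs = 0, n_inbred = 0, seed) {
  validate_sample_table(cohort)
  n <- nrow(cohort)
  n_pairs <- n * (n - 1) / 2
  if (n_related_pairs > n_pairs) stop_acl("more planted pairs than pairs exist")
  with_seed(seed, {
    pairs <- t(utils::combn(cohort$sample_id, 2))
    pihat <- stats::runif(n_pairs, 0, 0.05)
    if (n_related_pairs > 0) {
      planted <- sample.int(n_pairs, n_related_pairs)
      pihat[planted] <- stats::runif(n_related_pairs, 0.3, 0.6)
    }
    f <- stats::runif(n, 0, 0.01)
    if (n_inbred > 0) {
      f[sample.int(n, n_inbred)] <- stats::runif(n_inbred, 0.05, 0.15)
    }
    cohort$inbreeding_f <- f
    list(kinship = data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                              pihat = pihat, stringsAsFactors = FALSE),
         cohort = cohort)
  })
}

#' Generate a mock GWAS catalog over the planted regions
#'
#' Emits one catalog row per SNP inside a truth region.  The causal SNP's
#' enriched (AMR) allele carries `effect` estimator units per allele;
#' neighbouring SNPs decay exponentially with distance; all other true
#' effects are zero.  Reported effects optionally add Normal(0, se)
#' estimation noise, and p-values follow the two-sided normal Wald formula
#' `2 * pnorm(-|effect / se|)`, so a zero-effect catalog passes `p < 0.01`
#' only at the nominal 1% rate.
#'
#' @param bundle Output of [gen_admixed_genotypes()] (uses `$genotypes` and
#'   `$truth`).
#' @param causal_snp SNP id; must lie inside a truth region.
#' @param effect Effect of the enriched allele at the causal SNP, estimator
#'   units per allele.
#' @param se Reported standard error for every row.
#' @param decay_bp Exponential decay length of the neighbour effects, bp.
#' @param n_gwas Reported meta-analysis sample size.
#' @param jitter Add Normal(0, se) noise to the reported effects?
#' @param seed Integer RNG seed.
#' @return A GWAS-catalog data frame (schema `gwas_catalog`) with an extra
#'   `enriched_allele` column.
#' @export
gen_gwas_catalog <- function(bundle, causal_snp, effect = 0.29, se = 0.03,
                             decay_bp = 1.5e6, n_gwas = 35000,
                             jitter = TRUE, seed) {
  snps <- bundle$genotypes$snps
  truth <- bundle$truth
  if (nrow(truth) == 0) stop_acl("no truth regions to build a catalog over")
  in_region <- rep(FALSE, nrow(snps))
  for (i in seq_len(nrow(truth))) {
    in_region <- in_region | (snps$chrom == truth$chrom[i] &
                                snps$pos >= truth$start[i] &
                                snps$pos <= truth$end[i])
  }
  cat_snps <- snps[in_region, , drop = FALSE]
  ci <- match(causal_snp, cat_snps$snp)
  if (is.na(ci)) stop_acl("causal_snp must lie inside a truth region")
  with_seed(seed, {
    # enriched allele: the one commoner in the AMR panel
    enriched <- ifelse(cat_snps$p_amr >= cat_snps$p_eur,
                       cat_snps$a1, cat_snps$a2)
    dist <- ifelse(cat_snps$chrom == cat_snps$chrom[ci],
                   abs(cat_snps$pos - cat_snps$pos[ci]), Inf)
    true_eff_enriched <- effect * exp(-dist / decay_bp)
    true_eff_a1 <- ifelse(enriched == cat_snps$a1,
                          true_eff_enriched, -true_eff_enriched)
    est <- true_eff_a1 + if (jitter) stats::rnorm(nrow(cat_snps), 0, se) else 0
    p <- 2 * stats::pnorm(-abs(est / se))
    p[p == 0] <- .Machine$double.xmin
    out <- data.frame(snp = cat_snps$snp, chrom = cat_snps$chrom,
                      pos = cat_snps$pos, a1 = cat_snps$a1, a2 = cat_snps$a2,
                      freq_a1 = pmin(pmax(cat_snps$freq_a1, 0.01), 0.99),
                      effect_a1 = est, se = se, p = p,
                      n = round(stats::rnorm(nrow(cat_snps), n_gwas, 1000)),
                      enriched_allele = enriched,
                      stringsAsFactors = FALSE)
    validate_gwas_catalog(out)
    out
  })
}
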