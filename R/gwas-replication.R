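# GWAS discovery / replication ----------------------------------------------
#
# Discovery intersects an external catalog with the ancestry-deviant
# regions (1-based inclusive bounds) at the catalog's nominal p < 0.01;
# replication re-tests each candidate in-cohort by OLS of the estimator on
# the dosage oriented to the ancestry-enriched allele.

#' Discover candidate SNPs inside ancestry-deviant regions
#'
#' A pure filter: catalog rows whose position falls within any region
#' (inclusive bounds) and whose catalog p-value is below `p_max`, annotated
#' with the region index and direction.
#'
#' @param regions Region table from [call_regions()].
#' @param catalog GWAS catalog data frame (schema `gwas_catalog`).
#' @param p_max Catalog p-value threshold (default 0.01, strict `<`).
#' @return Subset of the catalog with `region_id` and `region_direction`
#'   columns.
#' @export
discover <- function(regions, catalog, p_max = 0.01) {
  validate_gwas_catalog(catalog)
  if (nrow(regions) > 0) {
    unmatched <- setdiff(catalog$chrom, regions$chrom)
    shared <- intersect(catalog$chrom, regions$chrom)
    if (length(shared) == 0 && nrow(catalog) > 0) {
      stop_acl(sprintf(
        "no catalog chromosome matches any region (catalog: %s; regions: %s)",
        paste(unique(catalog$chrom), collapse = ", "),
        paste(unique(regions$chrom), collapse = ", ")))
    }
  }
  region_id <- rep(NA_integer_, nrow(catalog))
  for (i in seq_len(nrow(regions))) {
    hit <- catalog$chrom == regions$chrom[i] &
      catalog$pos >= regions$start[i] & catalog$pos <= regions$end[i]
    region_id[hit & is.na(region_id)] <- i
  }
  keep <- !is.na(region_id) & catalog$p < p_max
  out <- catalog[keep, , drop = FALSE]
  out$region_id <- region_id[keep]
  out$region_direction <- regions$direction[out$region_id]
  rownames(out) <- NULL
  out
}

#' Orient dosages and effects to the enriched allele
#'
#' Re-orients each candidate's dosage column to count the
#' ancestry-enriched allele and flips the catalog effect sign when the
#' catalog effect allele differs from the enriched allele.  SNPs whose
#' allele set does not match the genotype data are dropped with a warning
#' (no strand flipping is attempted; ambiguous SNPs are removed upstream).
#'
#' @param candidates Catalog subset with columns `snp`, `a1`, `a2`,
#'   `effect_a1` and `enriched_allele`.
#' @param genotypes A [genotype_matrix()] containing the candidate SNPs.
#' @return List with `dosage` (SNP x sample matrix counting the enriched
#'   allele), `effect_enriched` (aligned catalog effects) and `candidates`
#'   (surviving rows).
#' @export
align_alleles <- function(candidates, genotypes) {
  require_columns(candidates, c("snp", "a1", "a2", "effect_a1",
                                "enriched_allele"), "candidates")
  gi <- match(candidates$snp, genotypes$snps$snp)
  dropped <- character(0)
  rows <- list()
  eff <- numeric(0)
  keep_idx <- integer(0)
  for (k in seq_len(nrow(candidates))) {
    i <- gi[k]
    if (is.na(i)) { dropped <- c(dropped, candidates$snp[k]); next }
    cat_set <- sort(c(candidates$a1[k], candidates$a2[k]))
    gen_set <- sort(c(genotypes$snps$a1[i], genotypes$snps$a2[i]))
    if (!identical(cat_set, gen_set)) {
      dropped <- c(dropped, candidates$snp[k]); next
    }
    enr <- candidates$enriched_allele[k]
    if (!enr %in% gen_set) { dropped <- c(dropped, candidates$snp[k]); next }
    d <- genotypes$dosage[i, ]
    if (enr != genotypes$snps$a1[i]) d <- 2 - d
    e <- if (enr == candidates$a1[k]) candidates$effect_a1[k]
    else -candidates$effect_a1[k]
    rows[[length(rows) + 1]] <- d
    eff <- c(eff, e)
    keep_idx <- c(keep_idx, k)
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d candidate(s) with unmatched alleles: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  surv <- candidates[keep_idx, , drop = FALSE]
  dosage <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, ncol(genotypes$dosage))
  rownames(dosage) <- surv$snp
  list(dosage = dosage, effect_enriched = stats::setNames(eff, surv$snp),
       candidates = surv)
}

#' Replicate candidate associations in-cohort
#'
#' Per-SNP OLS of the estimator on the enriched-allele dosage (plus
#' optional covariates); two-sided p from the t distribution.  A SNP
#' replicates when p < `alpha`; direction consistency compares the sign of
#' the in-cohort slope with the aligned catalog effect.
#'
#' @param genotypes A [genotype_matrix()].
#' @param est_values Named numeric vector of estimator values (names =
#'   sample ids matching the genotype columns).
#' @param candidates Catalog subset (see [align_alleles()]).
#' @param alpha Replication significance level (default 0.01).
#' @param covariates Optional data frame of covariates, row-matched to
#'   `est_values`.
#' @return Data frame: `snp`, `enriched_allele`, `catalog_effect`,
#'   `beta`, `se`, `nominal_p`, `replicated`, `direction_consistent`.
#' @export
replicate_candidates <- function(genotypes, est_values, candidates,
                                 alpha = 0.01, covariates = NULL) {
  aligned <- align_alleles(candidates, genotypes)
  samples <- intersect(colnames(genotypes$dosage), names(est_values))
  if (length(samples) < 10) stop_acl("replication needs n >= 10 samples")
  y <- est_values[samples]
  out <- list()
  for (k in seq_len(nrow(aligned$candidates))) {
    snp <- aligned$candidates$snp[k]
    d <- aligned$dosage[k, samples]
    ok <- is.finite(d) & is.finite(y)
    if (stats::var(d[ok]) == 0) {
      out[[length(out) + 1]] <- data.frame(
        snp = snp, enriched_allele = aligned$candidates$enriched_allele[k],
        catalog_effect = unname(aligned$effect_enriched[k]),
        beta = NA_real_, se = NA_real_, nominal_p = NA_real_,
        replicated = FALSE, direction_consistent = NA,
        note = "monomorphic in cohort", stringsAsFactors = FALSE)
      next
    }
    df <- data.frame(y = y[ok], dosage = d[ok])
    if (!is.null(covariates)) {
      df <- cbind(df, as.data.frame(covariates)[samples, , drop = FALSE][ok, ,
                                                                drop = FALSE])
    }
    fit <- stats::lm(y ~ ., data = df)
    co <- summary(fit)$coefficients["dosage", ]
    out[[length(out) + 1]] <- data.frame(
      snp = snp, enriched_allele = aligned$candidates$enriched_allele[k],
      catalog_effect = unname(aligned$effect_enriched[k]),
      beta = unname(co[1]), se = unname(co[2]), nominal_p = unname(co[4]),
      replicated = unname(co[4]) < alpha,
      direction_consistent = sign(co[1]) ==
        sign(aligned$effect_enriched[k]),
      note = "", stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(snp = character(0), enriched_allele = character(0),
                      catalog_effect = numeric(0), beta = numeric(0),
                      se = numeric(0), nominal_p = numeric(0),
                      replicated = logical(0),
                      direction_consistent = logical(0),
                      note = character(0)))
  }
  do.call(rbind, out)
}

#' Cluster replicated SNPs by linkage disequilibrium
#'
#' Pairwise dosage r-squared clustering at the given threshold; connected
#' components are reported as shared-LD groups.
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_ids SNPs to cluster.
#' @param r2_min LD threshold (default 0.8).
#' @return Named integer vector: LD-group membership per SNP.
#' @export
ld_groups <- function(genotypes, snp_ids, r2_min = 0.8) {
  idx <- match(snp_ids, genotypes$snps$snp)
  if (anyNA(idx)) stop_acl("unknown SNP id(s) for LD grouping")
  if (length(idx) < 2) {
    return(stats::setNames(rep(1L, length(idx)), snp_ids))
  }
  cm <- suppressWarnings(stats::cor(t(genotypes$dosage[idx, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  adj <- cm^2 >= r2_min
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  stats::setNames(igraph::components(gr)$membership, snp_ids)
}
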