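# Pipeline orchestration ----------------------------------------------------
#
# Binds the stages together over a synthetic dataset (or user-supplied
# files), writes per-stage TSV/JSON reports and a log with stage timings
# and record counts.  All randomness derives from the config seed, so a
# run is reproducible byte-for-byte (timings live only in the log).

#' Pipeline configuration
#'
#' Thresholds default to the printed analysis constants: FDR q < 0.1,
#' Shapiro-Wilk alpha 0.05, |Z| > 3, posterior > 0.9, replication p < 0.01,
#' HWE p < 7e-08, PiHat > 0.25.
#'
#' @param seed Non-negative integer seed driving every stage.
#' @param out_dir Output directory for reports (created if absent).
#' @param stages Named logical vector toggling report emission per stage.
#' @param fdr_q,shapiro_alpha,z_threshold,posterior_min,replication_alpha
#'   Analysis thresholds (fractions in (0, 1) except `z_threshold` > 0).
#' @param hwe_p,pihat_max,mind,geno QC thresholds.
#' @param n_snps,n_chroms Synthetic genome size used by the pipeline run.
#' @param noise_sd Beta-matrix noise SD.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("admixclock_"),
                            stages = c(simulate = TRUE, qc = TRUE,
                                       clocks = TRUE, compare = TRUE,
                                       scan = TRUE, replicate = TRUE,
                                       kinship = TRUE, importance = TRUE),
                            fdr_q = 0.1, shapiro_alpha = 0.05,
                            z_threshold = 3, posterior_min = 0.9,
                            replication_alpha = 0.01, hwe_p = 7e-08,
                            pihat_max = 0.25, mind = 0.05, geno = 0.05,
                            n_snps = 2000, n_chroms = 10, noise_sd = 0.01) {
  fracs <- c(fdr_q = fdr_q, shapiro_alpha = shapiro_alpha,
             posterior_min = posterior_min,
             replication_alpha = replication_alpha, mind = mind, geno = geno)
  if (any(fracs <= 0 | fracs >= 1)) {
    stop_acl("fractional thresholds must lie in (0, 1)")
  }
  if (z_threshold <= 0) stop_acl("z_threshold must be positive")
  if (seed < 0) stop_acl("seed must be non-negative")
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 fdr_q = fdr_q, shapiro_alpha = shapiro_alpha,
                 z_threshold = z_threshold, posterior_min = posterior_min,
                 replication_alpha = replication_alpha, hwe_p = hwe_p,
                 pihat_max = pihat_max, mind = mind, geno = geno,
                 n_snps = n_snps, n_chroms = n_chroms, noise_sd = noise_sd),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the default study-design cohort and genome, then runs genotype QC,
#' the clock engine, inter-population comparison, the ancestry Z-scan,
#' catalog discovery/replication, kinship/inbreeding association and the
#' LMG importance models.  Stage toggles suppress the corresponding
#' reports (and their entries in the bundle) without changing the others.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle: a named list of stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  timer <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stop_acl(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    log_lines <<- c(log_lines, sprintf("%s\t%.2fs", stage,
                                       proc.time()[["elapsed"]] - t0))
    res
  }
  on_stage <- function(s) isTRUE(config$stages[[s]])
  out <- function(f) file.path(config$out_dir, f)
  bundle <- list()

  # --- simulate (inputs for everything downstream) ------------------------
  sim <- timer("simulate", {
    spec <- cohort_spec()
    cohort <- gen_cohort(spec, seed = derive_seed(config$seed, 1))
    clocks <- gen_default_clocks(seed = derive_seed(config$seed, 2))
    betas <- gen_betas(cohort, clocks, spec, noise_sd = config$noise_sd,
                       seed = derive_seed(config$seed, 3))
    rel <- gen_relatedness(cohort, n_related_pairs = 2, n_inbred = 4,
                           seed = derive_seed(config$seed, 4))
    cohort <- rel$cohort
    n_admixed <- sum(cohort$population == spec$group_names[2])
    region <- list(chrom = "chr3", start_idx = 40, end_idx = 55,
                   excess = 0.25)
    gspec <- admixture_spec(n_snps = config$n_snps,
                            n_chroms = config$n_chroms,
                            enriched_region = region)
    genome <- gen_admixed_genotypes(gspec, n_samples = n_admixed,
                                    seed = derive_seed(config$seed, 5))
    admixed_ids <- cohort$sample_id[cohort$population == spec$group_names[2]]
    colnames(genome$genotypes$dosage) <- admixed_ids
    colnames(genome$calls$calls) <-
      paste0(rep(admixed_ids, each = 2), c("_1", "_2"))
    catalog <- gen_gwas_catalog(
      genome, causal_snp = genome$genotypes$snps$snp[
        genome$genotypes$snps$chrom == region$chrom &
          genome$genotypes$snps$pos ==
          ((region$start_idx + region$end_idx) %/% 2) * gspec$snp_spacing_bp],
      seed = derive_seed(config$seed, 6))
    # global ancestry proportions from the true local-ancestry calls
    amr_prop <- vapply(admixed_ids, function(s) {
      cols <- paste0(s, c("_1", "_2"))
      mean(genome$calls$calls[, cols] == "AMR")
    }, numeric(1))
    cohort$anc_AMR <- ifelse(cohort$population == spec$group_names[1], 1,
                             amr_prop[cohort$sample_id])
    cohort$anc_EUR <- 1 - cohort$anc_AMR
    validate_sample_table(cohort)
    list(spec = spec, cohort = cohort, clocks = clocks, betas = betas,
         kinship = rel$kinship, genome = genome, catalog = catalog,
         admixed_ids = admixed_ids)
  })
  if (on_stage("simulate")) {
    write_sample_table(sim$cohort, out("cohort.tsv"))
    write_beta_matrix(sim$betas, out("betas.tsv"))
    write_kinship(sim$kinship, out("kinship.tsv"))
    write_gwas_catalog(sim$catalog, out("catalog.tsv"))
    write_ancestry_calls(sim$genome$calls, out("ancestry_calls.tsv"))
    write_genotypes(sim$genome$genotypes, out("genotypes.tsv"))
    bundle$simulate <- sim["spec"]
  }

  # --- qc ------------------------------------------------------------------
  qc <- timer("qc", {
    run_genotype_qc(sim$genome$genotypes, mind = config$mind,
                    geno = config$geno, hwe_p = config$hwe_p,
                    pihat_max = config$pihat_max)
  })
  if (on_stage("qc")) {
    write_tsv_raw(qc$report, out("qc_report.tsv"), c(schema = "qc_report"))
    writeLines(qc$ld_keep, out("ld_keep.txt"))
    bundle$qc <- qc["report"]
  }

  # --- clocks --------------------------------------------------------------
  est <- timer("clocks", {
    compute_all(sim$betas, sim$clocks, sim$cohort)
  })
  if (on_stage("clocks")) {
    write_tsv_raw(est, out("estimators.tsv"), c(schema = "estimators"))
    bundle$clocks <- list(estimators = est)
  }

  # --- compare -------------------------------------------------------------
  cmp <- timer("compare", {
    groups <- sim$cohort$population[match(est$sample_id,
                                          sim$cohort$sample_id)]
    list(table = compare_all(est, groups, fdr_q = config$fdr_q,
                             shapiro_alpha = config$shapiro_alpha),
         clusters = independence_groups(est),
         medians = median_discrepancy(est, groups))
  })
  if (on_stage("compare")) {
    write_tsv_raw(cmp$table, out("comparisons.tsv"),
                  c(schema = "comparisons"))
    med <- data.frame(group = rownames(cmp$medians), cmp$medians,
                      check.names = FALSE)
    write_tsv_raw(med, out("medians.tsv"), c(schema = "medians"))
    jsonlite::write_json(cmp$clusters["clusters"], out("clusters.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    bundle$compare <- cmp
  }

  # --- scan ----------------------------------------------------------------
  scan <- timer("scan", {
    ancestry_zscan(sim$genome$calls, anc = "AMR",
                   z_threshold = config$z_threshold)
  })
  if (on_stage("scan")) {
    write_tsv_raw(scan$scan, out("scan.tsv"), c(schema = "scan"))
    write_tsv_raw(scan$regions, out("regions.tsv"), c(schema = "regions"))
    if (nrow(scan$regions)) {
      write_regions_bed(scan$regions, out("regions.bed"))
    }
    bundle$scan <- scan
  }

  # --- replicate -----------------------------------------------------------
  repl <- timer("replicate", {
    cand <- discover(scan$regions, sim$catalog,
                     p_max = config$replication_alpha)
    hv <- stats::setNames(est$AgeAccelHannum, est$sample_id)[sim$admixed_ids]
    if (nrow(cand)) {
      replicate_candidates(sim$genome$genotypes, hv, cand,
                           alpha = config$replication_alpha)
    } else {
      replicate_candidates(sim$genome$genotypes, hv, sim$catalog[0, ],
                           alpha = config$replication_alpha)
    }
  })
  if (on_stage("replicate")) {
    write_tsv_raw(repl, out("replication.tsv"), c(schema = "replication"))
    bundle$replicate <- list(replication = repl)
  }

  # --- kinship -------------------------------------------------------------
  kin <- timer("kinship", {
    grp1 <- sim$cohort$sample_id[sim$cohort$population ==
                                   sim$spec$group_names[1]]
    est1 <- est[est$sample_id %in% grp1, , drop = FALSE]
    list(delta = kinship_delta_association(
           est1, sim$kinship, n_perm = 199,
           seed = derive_seed(config$seed, 7)),
         inbreeding = inbreeding_association(
           sim$cohort[sim$cohort$population == sim$spec$group_names[1], ],
           est1))
  })
  if (on_stage("kinship")) {
    write_tsv_raw(kin$delta, out("kinship_delta.tsv"),
                  c(schema = "kinship_delta"))
    write_tsv_raw(kin$inbreeding, out("inbreeding.tsv"),
                  c(schema = "inbreeding"))
    bundle$kinship <- kin
  }

  # --- importance ----------------------------------------------------------
  imp <- timer("importance", {
    frames <- build_model_frames(sim$cohort,
                                 groups = sim$spec$group_names)
    importance_report(frames, est)
  })
  if (on_stage("importance")) {
    write_tsv_raw(imp, out("importance.tsv"), c(schema = "importance"))
    bundle$importance <- list(report = imp)
  }

  summary <- list(seed = config$seed,
                  n_samples = nrow(sim$cohort),
                  n_snps = nrow(sim$genome$genotypes$snps),
                  n_estimators = length(estimator_columns(est)),
                  n_regions = nrow(scan$regions),
                  n_candidates = nrow(repl),
                  stages = names(config$stages)[unlist(config$stages)])
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(log_lines, out("log.txt"))
  invisible(bundle)
}
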