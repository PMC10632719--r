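# Clock engine -------------------------------------------------------------
#
# All supported epigenetic estimators are linear in CpG beta values:
# score = intercept + sum(coef * beta), optionally followed by the piecewise
# log-linear age anti-transform used by calculator-style age clocks.  The
# engine is clock-agnostic: published coefficient files or generated clocks
# both load as `clock_definition` objects.

#' Construct a clock definition
#'
#' @param name Clock name (used as the estimator column label).
#' @param kind `"age"` for DNAm-age clocks (output in years after the
#'   anti-transform), `"surrogate"` for protein/exposure surrogates (output
#'   in clock units).
#' @param intercept Intercept on the linear-predictor scale.
#' @param coefficients Named numeric vector, CpG id -> weight.
#' @param transform `"identity"` or `"horvath"` (piecewise log-linear in
#'   age, continuous at `adult_age`).
#' @param adult_age Breakpoint of the horvath transform, in years.
#' @return An object of class `clock_definition`.
#' @export
clock_definition <- function(name, kind = c("age", "surrogate"),
                             intercept = 0, coefficients,
                             transform = c("identity", "horvath"),
                             adult_age = 20) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  if (length(coefficients) < 1L || is.null(names(coefficients))) {
    stop_acl("clock needs at least one named coefficient")
  }
  if (transform == "horvath" && adult_age <= 0) {
    stop_acl("adult_age must be positive for the horvath transform")
  }
  structure(list(name = name, kind = kind, intercept = intercept,
                 coefficients = coefficients, transform = transform,
                 adult_age = adult_age),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("clock_definition '%s': %d CpGs, kind=%s, transform=%s\n",
              x$name, length(x$coefficients), x$kind, x$transform))
  invisible(x)
}

#' Linear predictor of a clock over a beta matrix
#'
#' Computes `intercept + sum(coef * beta)` per sample.  Clock CpGs that are
#' absent from the matrix or NA in a sample are handled by `missing_policy`;
#' the default imputes the cohort mean beta of that CpG, falling back to 0.5
#' for CpGs missing in every sample.
#'
#' @param beta Beta matrix (CpGs x samples, values in `[0, 1]` or NA).
#' @param clock A [clock_definition()].
#' @param missing_policy `"mean"` (cohort-mean imputation, the default) or
#'   `"error"` (any missing clock CpG is an error).
#' @param min_coverage Minimum fraction of clock CpGs that must be observed
#'   (non-NA) per sample; below this the sample errors out with the list of
#'   missing CpGs.
#' @param fallback Beta value used for clock CpGs absent from the matrix
#'   entirely.
#' @return Named numeric vector of per-sample scores.
#' @export
linear_predictor <- function(beta, clock, missing_policy = c("mean", "error"),
                             min_coverage = 0.5, fallback = 0.5) {
  missing_policy <- match.arg(missing_policy)
  validate_beta_matrix(beta)
  cpgs <- names(clock$coefficients)
  present <- intersect(cpgs, rownames(beta))
  absent <- setdiff(cpgs, present)
  sub <- matrix(fallback, nrow = length(cpgs), ncol = ncol(beta),
                dimnames = list(cpgs, colnames(beta)))
  if (length(present)) sub[present, ] <- beta[present, , drop = FALSE]
  observed <- !is.na(sub)
  observed[absent, ] <- FALSE
  coverage <- colMeans(observed)
  if (any(coverage < min_coverage)) {
    worst <- colnames(beta)[which.min(coverage)]
    miss <- cpgs[!observed[, which.min(coverage)]]
    stop_acl(sprintf(
      "clock '%s': sample %s covers %.0f%% of clock CpGs (< %.0f%%); missing: %s",
      clock$name, worst, 100 * min(coverage), 100 * min_coverage,
      paste(utils::head(miss, 10), collapse = ", ")))
  }
  if (missing_policy == "error" && (length(absent) || anyNA(sub))) {
    stop_acl(sprintf("clock '%s': missing CpGs under missing_policy='error'",
                     clock$name))
  }
  # cohort-mean imputation per CpG
  if (anyNA(sub)) {
    cpg_mean <- rowMeans(sub, na.rm = TRUE)
    cpg_mean[is.nan(cpg_mean)] <- fallback
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    sub[na_idx] <- cpg_mean[na_idx[, 1]]
  }
  drop(clock$intercept + crossprod(sub, clock$coefficients))[colnames(beta)]
}

#' Piecewise age transform and its inverse
#'
#' The forward transform maps age to the linear-predictor scale:
#' `log((age + 1) / (adult_age + 1))` below `adult_age`, linear above.  The
#' inverse maps a score back to years: `(1 + adult_age) * exp(x) - 1` for
#' `x <= 0`, else `(1 + adult_age) * x + adult_age`.  Both are continuous
#' and strictly monotone, and mutual inverses on ages > -1.
#'
#' @param age Age in years.
#' @param x Score on the transformed scale.
#' @param adult_age Breakpoint in years (default 20).
#' @return Transformed value(s).
#' @export
forward_age_transform <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname forward_age_transform
#' @export
inverse_age_transform <- function(x, adult_age = 20) {
  ifelse(x <= 0,
         (1 + adult_age) * exp(x) - 1,
         (1 + adult_age) * x + adult_age)
}

#' DNAm age (or surrogate level) for one clock
#'
#' @inheritParams linear_predictor
#' @param ... Passed to [linear_predictor()].
#' @return Named per-sample estimates: years for `kind = "age"` clocks with
#'   the horvath transform, raw score units otherwise.
#' @export
dnam_estimate <- function(beta, clock, ...) {
  score <- linear_predictor(beta, clock, ...)
  if (clock$transform == "horvath") {
    inverse_age_transform(score, clock$adult_age)
  } else {
    score
  }
}

#' Age-adjust an estimator by OLS residualisation
#'
#' Residuals of the ordinary least-squares regression of the estimate on
#' chronological age.  Positive residuals mean "epigenetically older than
#' expected for that age".  Residuals have mean zero and are orthogonal to
#' age by construction.
#'
#' @param estimates Per-sample estimates (years or clock units).
#' @param ages Chronological ages in years.
#' @return Residuals, same length and names as `estimates`.
#' @export
age_adjust <- function(estimates, ages) {
  if (length(estimates) != length(ages)) stop_acl("length mismatch")
  if (length(ages) < 3) stop_acl("age adjustment needs at least 3 samples")
  if (stats::var(ages) == 0) stop_acl("constant ages: cannot age-adjust")
  stats::setNames(stats::residuals(stats::lm(estimates ~ ages)),
                  names(estimates))
}

#' Intrinsic age acceleration (cell-composition-purged residual)
#'
#' Residual of the multiple OLS of the DNAm-age estimate on chronological
#' age plus cell-fraction columns.  Because the fractions lie on a simplex,
#' one column is dropped to avoid exact collinearity with the intercept.
#'
#' @param estimates DNAm-age estimates in years.
#' @param ages Chronological ages.
#' @param cell_fractions Numeric matrix/data frame, samples x cell types,
#'   rows summing to one.
#' @return Residuals in years.
#' @export
ieaa <- function(estimates, ages, cell_fractions) {
  cf <- as.matrix(cell_fractions)
  if (nrow(cf) != length(estimates)) stop_acl("cell fractions: row mismatch")
  if (anyNA(cf)) stop_acl("cell fractions must be complete for IEAA")
  keep <- cf[, -ncol(cf), drop = FALSE]   # drop last type: simplex redundancy
  keep <- keep[, apply(keep, 2, stats::var) > 0, drop = FALSE]
  X <- cbind(age = ages, keep)
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X) + 1)] - 1]
    stop_acl(sprintf("IEAA design is rank deficient; collinear column(s): %s",
                     paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(cbind(1, X), estimates)
  stats::setNames(fit$residuals, names(estimates))
}

#' Extrinsic age acceleration (cell-composition-enriched)
#'
#' Standardised weighted average of a first-generation DNAm-age estimate
#' and three age-associated blood-cell measures, rescaled back to the
#' clock's units and then age-adjusted.  Components are z-scored before
#' weighting; zero-variance components are excluded with a warning.
#'
#' @param estimates DNAm-age estimates (Hannum-type clock), years.
#' @param ages Chronological ages.
#' @param aging_cells Matrix/data frame with three columns of age-associated
#'   cell measures (naive cytotoxic T, exhausted cytotoxic T, plasmablast).
#' @param weights Weights for `c(estimate, cells...)`; default equal.
#' @return Age-adjusted residuals in clock units.
#' @export
eeaa <- function(estimates, ages, aging_cells,
                 weights = rep(1, 1 + ncol(as.matrix(aging_cells)))) {
  ac <- as.matrix(aging_cells)
  if (ncol(ac) != 3) stop_acl("EEAA expects exactly three cell measures")
  comp <- cbind(est = estimates, ac)
  if (length(weights) != ncol(comp)) stop_acl("one weight per component needed")
  ok <- apply(comp, 2, stats::var) > 0
  if (!all(ok)) {
    warning(sprintf("EEAA: zero-variance component(s) excluded: %s",
                    paste(colnames(comp)[!ok], collapse = ", ")))
    comp <- comp[, ok, drop = FALSE]
    weights <- weights[ok]
  }
  if (all(weights == 0)) stop_acl("EEAA: all weights zero")
  z <- scale(comp)
  wavg <- drop(z %*% weights) / sum(abs(weights))
  rescaled <- wavg * stats::sd(estimates) + mean(estimates)
  age_adjust(stats::setNames(rescaled, names(estimates)), ages)
}

#' Compute the full estimator table
#'
#' One column per clock: age-kind clocks yield age-acceleration residuals in
#' years; surrogate-kind clocks yield age-residualised levels in clock
#' units.  Column order follows the clock list.  A failing clock is
#' reported but does not abort the remaining columns.
#'
#' @param beta Beta matrix (CpGs x samples).
#' @param clocks List of [clock_definition()] objects.
#' @param metadata Sample table with `sample_id` and `age`; rows are matched
#'   to beta columns by `sample_id`.
#' @return Data frame of class `estimator_table`: `sample_id` plus one
#'   numeric column per clock.
#' @export
compute_all <- function(beta, clocks, metadata) {
  validate_sample_table(metadata)
  samples <- colnames(beta)
  idx <- match(samples, metadata$sample_id)
  if (anyNA(idx)) {
    stop_acl(sprintf("samples absent from metadata: %s",
                     paste(samples[is.na(idx)], collapse = ", ")))
  }
  ages <- metadata$age[idx]
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  errors <- character(0)
  for (clock in clocks) {
    col <- tryCatch({
      est <- dnam_estimate(beta, clock)
      unname(age_adjust(est, ages))
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", clock$name, conditionMessage(e)))
      rep(NA_real_, length(samples))
    })
    out[[clock$name]] <- col
  }
  if (length(errors)) {
    warning(sprintf("clock(s) failed: %s", paste(errors, collapse = "; ")))
  }
  class(out) <- unique(c("estimator_table", class(out)))
  out
}

estimator_columns <- function(est) {
  setdiff(names(est), "sample_id")
}
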