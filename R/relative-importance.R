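# LMG variance decomposition ------------------------------------------------
#
# The Lindeman-Merenda-Gold statistic decomposes a linear model's R^2
# across predictors as each predictor's sequential R^2 gain averaged over
# all orderings of entry -- the Shapley value of R^2.  Computed here by
# exact subset enumeration with the closed-form subset weights
# w(s) = s! (p - s - 1)! / p!, which is equivalent to (and far cheaper
# than) enumerating the p! orderings.

subset_r2 <- function(y, X) {
  # R^2 for every subset of predictor columns, indexed by bitmask + 1
  p <- ncol(X)
  tss <- sum((y - mean(y))^2)
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0)
    fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    r2[mask + 1] <- 1 - sum(fit$residuals^2) / tss
  }
  r2
}

#' LMG decomposition of linear-model R-squared
#'
#' For each predictor k,
#' `LMG_k = sum over subsets S of the other predictors of
#'  w(|S|) * (R2(S + k) - R2(S))` with `w(s) = s!(p-s-1)!/p!`.  The raw
#' shares sum to the full-model R^2; normalised shares sum to one.
#'
#' @param y Outcome vector.
#' @param X Predictor matrix or data frame (p <= 15; no constant columns).
#' @return An object of class `lmg_result`: list with `r2_full`,
#'   `lmg_raw`, `lmg_norm`, `top_predictor` and `pct_total_variance`
#'   (the raw LMG share of the top predictor, i.e. normalised share times
#'   full R^2).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- X %*% c(1, 0.5, 0) + rnorm(20)
#' lmg(y, X)
lmg <- function(y, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (p > 15) {
    stop_acl("p > 15: exact subset enumeration is infeasible; no sampling mode")
  }
  if (nrow(X) <= p + 1) stop_acl("need n > p + 1 observations")
  vars <- apply(X, 2, stats::var)
  if (any(vars == 0)) {
    stop_acl(sprintf("constant predictor(s): %s",
                     paste(colnames(X)[vars == 0], collapse = ", ")))
  }
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, p + 1)] - 1]
    stop_acl(sprintf("collinear design; near-dependent column(s): %s",
                     paste(bad, collapse = ", ")))
  }
  r2 <- subset_r2(y, X)
  w <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - 0:(p - 1)) -
             lfactorial(p))
  shares <- numeric(p)
  bits <- bitwShiftL(1L, 0:(p - 1))
  for (k in seq_len(p)) {
    others <- setdiff(seq_len(p), k)
    n_other <- p - 1
    for (mask_o in 0:(2^n_other - 1)) {
      cols <- others[which(bitwAnd(mask_o, bitwShiftL(1L, 0:(n_other - 1)))
                           != 0)]
      s <- length(cols)
      mask <- sum(bits[cols])
      shares[k] <- shares[k] +
        w[s + 1] * (r2[mask + bits[k] + 1] - r2[mask + 1])
    }
  }
  if (any(shares < -1e-12)) {
    stop_acl("numerically negative LMG share beyond tolerance")
  }
  shares <- pmax(shares, 0)
  names(shares) <- colnames(X)
  r2_full <- r2[2^p]
  norm <- if (sum(shares) > 0) shares / sum(shares) else shares
  top <- names(shares)[which.max(shares)]
  structure(list(r2_full = r2_full, lmg_raw = shares, lmg_norm = norm,
                 top_predictor = top,
                 pct_total_variance = unname(norm[top] * r2_full)),
            class = "lmg_result")
}

#' @export
print.lmg_result <- function(x, ...) {
  cat(sprintf("lmg_result: R2 = %.4f, top = %s (%.1f%% of total variance)\n",
              x$r2_full, x$top_predictor, 100 * x$pct_total_variance))
  print(round(rbind(raw = x$lmg_raw, normalised = x$lmg_norm), 4))
  invisible(x)
}

#' Build the three relative-importance model frames
#'
#' The three linear-model configurations: joint (both populations;
#' predictors `Pop`, `Female`, `T.cruzi`), indigenous-role group only
#' (`Inbreed`, `Paraje`, `Female`, `T.cruzi`) and admixed-role group only
#' (`EUR`, `AMR`, `Female`, `T.cruzi`).  Encodings: `Pop` = 1 for the
#' indigenous-role group, `Female` = 1 for females, `T.cruzi` = 1 for
#' infected, `Paraje` = 1 for urban.
#'
#' @param metadata Sample table; the group-specific frames additionally
#'   need `inbreeding_f` (indigenous role) and `anc_EUR`/`anc_AMR`
#'   (admixed role).
#' @param groups Two group labels, indigenous role first; defaults to the
#'   sorted population labels.
#' @return Named list of three frames, each `list(rows, X)` with `rows`
#'   the metadata row indices and `X` the predictor matrix.
#' @export
build_model_frames <- function(metadata,
                               groups = sort(unique(metadata$population))) {
  validate_sample_table(metadata)
  if (length(groups) != 2) stop_acl("exactly two groups expected")
  base <- function(rows) {
    cbind(Female = as.numeric(metadata$sex[rows] == "F"),
          T.cruzi = as.numeric(metadata$infected[rows]))
  }
  all_rows <- seq_len(nrow(metadata))
  joint <- cbind(Pop = as.numeric(metadata$population == groups[1]),
                 base(all_rows))
  rows_a <- which(metadata$population == groups[1])
  if (!"inbreeding_f" %in% names(metadata) ||
      anyNA(metadata$inbreeding_f[rows_a])) {
    stop_acl("indigenous-role model needs a complete inbreeding_f column")
  }
  frame_a <- cbind(Inbreed = metadata$inbreeding_f[rows_a],
                   Paraje = as.numeric(metadata$paraje[rows_a] == "urban"),
                   base(rows_a))
  rows_b <- which(metadata$population == groups[2])
  for (col in c("anc_EUR", "anc_AMR")) {
    if (!col %in% names(metadata) || anyNA(metadata[[col]][rows_b])) {
      stop_acl(sprintf("admixed-role model needs a complete %s column", col))
    }
  }
  frame_b <- cbind(EUR = metadata$anc_EUR[rows_b],
                   AMR = metadata$anc_AMR[rows_b],
                   base(rows_b))
  # EUR + AMR can approach the simplex: report conditioning
  kappa_b <- kappa(cbind(1, frame_b), exact = TRUE)
  list(joint = list(rows = all_rows, X = joint),
       group1 = list(rows = rows_a, X = frame_a),
       group2 = list(rows = rows_b, X = frame_b, condition_number = kappa_b))
}

#' Relative-importance report over models and estimators
#'
#' Runs [lmg()] for every (model, estimator) cell; a failing fit is
#' reported as NA with its reason rather than aborting the grid.
#'
#' @param frames Output of [build_model_frames()].
#' @param est An `estimator_table`, row-matched to the metadata used for
#'   the frames.
#' @return Data frame with one row per (model, estimator): `r2_full`,
#'   `top_predictor`, `pct_total_variance`, one `lmg_<predictor>`
#'   normalised share column per predictor, and `note`.
#' @export
importance_report <- function(frames, est) {
  cols <- estimator_columns(est)
  out <- list()
  for (mn in names(frames)) {
    fr <- frames[[mn]]
    for (cn in cols) {
      y <- est[[cn]][fr$rows]
      res <- tryCatch(lmg(y, fr$X), error = function(e) e)
      row <- data.frame(model = mn, estimator = cn, stringsAsFactors = FALSE)
      if (inherits(res, "error")) {
        row$r2_full <- NA_real_
        row$top_predictor <- NA_character_
        row$pct_total_variance <- NA_real_
        row$note <- conditionMessage(res)
      } else {
        row$r2_full <- res$r2_full
        row$top_predictor <- res$top_predictor
        row$pct_total_variance <- res$pct_total_variance
        for (pn in names(res$lmg_norm)) {
          row[[paste0("lmg_", pn)]] <- unname(res$lmg_norm[pn])
        }
        row$note <- ""
      }
      out[[length(out) + 1]] <- row
    }
  }
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
  do.call(rbind, out)
}
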