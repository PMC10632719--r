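# Kinship / inbreeding association ------------------------------------------
#
# The pairwise "delta" statistic: the absolute difference between two
# individuals' estimator values.  If kinship structures the epigenetic
# signal, more related pairs should show smaller deltas.  Because pairs
# sharing an individual are not independent, a label-permutation p-value
# (permuting individuals and recomputing deltas) is reported alongside the
# naive pair-level correlation as the recommended inference.

#' All pairwise estimator deltas
#'
#' @param est An `estimator_table` (n >= 2 rows).
#' @return Data frame with `id1`, `id2` (unordered pairs) and one
#'   `delta_<estimator>` column per estimator, all non-negative.
#' @export
pairwise_delta <- function(est) {
  if (nrow(est) < 2) stop_acl("pairwise deltas need n >= 2")
  cols <- estimator_columns(est)
  pairs <- t(utils::combn(seq_len(nrow(est)), 2))
  out <- data.frame(id1 = est$sample_id[pairs[, 1]],
                    id2 = est$sample_id[pairs[, 2]],
                    stringsAsFactors = FALSE)
  for (cn in cols) {
    out[[paste0("delta_", cn)]] <-
      abs(est[[cn]][pairs[, 1]] - est[[cn]][pairs[, 2]])
  }
  out
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Associate kinship with pairwise estimator deltas
#'
#' Per estimator: correlation of PiHat with delta over the overlapping
#' pairs, Pearson or Kendall per the normality gate, plus a
#' label-permutation p-value (permuting individuals, recomputing deltas;
#' `n_perm` permutations) that respects the non-independence of pairs.
#'
#' @param est An `estimator_table`.
#' @param kin Kinship table (`id1`, `id2`, `pihat`).
#' @param shapiro_alpha Normality-gate level.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer RNG seed for the permutations.
#' @return Data frame: `estimator`, `method`, `r`, `p`, `p_perm`, `n_pairs`.
#' @export
kinship_delta_association <- function(est, kin, shapiro_alpha = 0.05,
                                      n_perm = 999, seed = 1) {
  deltas <- pairwise_delta(est)
  key_d <- pair_key(deltas$id1, deltas$id2)
  key_k <- pair_key(kin$id1, kin$id2)
  idx <- match(key_d, key_k)
  ok <- !is.na(idx)
  if (sum(ok) < 4) stop_acl("fewer than 4 overlapping pairs")
  pihat <- kin$pihat[idx[ok]]
  cols <- estimator_columns(est)
  with_seed(seed, {
    perms <- replicate(n_perm, sample.int(nrow(est)))
    out <- lapply(cols, function(cn) {
      d <- deltas[[paste0("delta_", cn)]][ok]
      method <- if (normality_gate(pihat, d, shapiro_alpha) == "normal") {
        "pearson"
      } else {
        "kendall"
      }
      ct <- suppressWarnings(stats::cor.test(pihat, d, method = method))
      r_obs <- unname(ct$estimate)
      v <- est[[cn]]
      pairs <- t(utils::combn(seq_len(nrow(est)), 2))
      r_perm <- vapply(seq_len(n_perm), function(b) {
        vp <- v[perms[, b]]
        dp <- abs(vp[pairs[, 1]] - vp[pairs[, 2]])[ok]
        suppressWarnings(stats::cor(pihat, dp, method = method))
      }, numeric(1))
      p_perm <- (1 + sum(abs(r_perm) >= abs(r_obs), na.rm = TRUE)) /
        (n_perm + 1)
      data.frame(estimator = cn, method = method, r = r_obs, p = ct$p.value,
                 p_perm = p_perm, n_pairs = sum(ok),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Associate individual inbreeding coefficients with estimators
#'
#' Both Pearson and Kendall correlation tests per estimator, with BH
#' q-values per method and significance flags at the printed FDR level
#' 0.01.
#'
#' @param f Named numeric vector of inbreeding coefficients (names =
#'   sample ids) or a `sample_table` with an `inbreeding_f` column.
#' @param est An `estimator_table`.
#' @param fdr_q FDR flag level (default 0.01).
#' @return Data frame: `estimator`, `r_pearson`, `p_pearson`, `r_kendall`,
#'   `p_kendall`, `q_pearson`, `q_kendall`, `significant`.
#' @export
inbreeding_association <- function(f, est, fdr_q = 0.01) {
  if (is.data.frame(f)) {
    if (!"inbreeding_f" %in% names(f)) stop_acl("no inbreeding_f column")
    f <- stats::setNames(f$inbreeding_f, f$sample_id)
  }
  fv <- f[est$sample_id]
  if (length(fv) < 4 || anyNA(fv)) {
    stop_acl("inbreeding coefficients must cover all samples (n >= 4)")
  }
  if (stats::var(fv) == 0) stop_acl("constant inbreeding coefficients")
  cols <- estimator_columns(est)
  rows <- lapply(cols, function(cn) {
    e <- est[[cn]]
    pe <- suppressWarnings(stats::cor.test(fv, e, method = "pearson"))
    ke <- suppressWarnings(stats::cor.test(fv, e, method = "kendall"))
    data.frame(estimator = cn,
               r_pearson = unname(pe$estimate), p_pearson = pe$p.value,
               r_kendall = unname(ke$estimate), p_kendall = ke$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # exact linear relationships yield p = 0; floor for the BH step-up
  out$q_pearson <- bh_adjust(pmax(out$p_pearson, .Machine$double.xmin),
                             fdr_q)$qvals
  out$q_kendall <- bh_adjust(pmax(out$p_kendall, .Machine$double.xmin),
                             fdr_q)$qvals
  out$significant <- out$q_pearson <= fdr_q | out$q_kendall <= fdr_q
  out
}
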