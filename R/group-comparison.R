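# Inter-population comparison ----------------------------------------------
#
# Each estimator is tested between the two populations with a
# normality-gated choice: Welch t-test when a Shapiro-Wilk test accepts
# normality in BOTH groups, a two-sided Wilcoxon rank-sum test otherwise.
# Both tests are always computed and reported; the gated one supplies the
# headline p-value.  FDR control is Benjamini-Hochberg at q < 0.1.

#' Normality gate for the two-sample test choice
#'
#' @param x,y Numeric vectors (one per group); `y` may be omitted to gate a
#'   single vector.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return `"normal"` when every supplied vector passes Shapiro-Wilk at
#'   `alpha`, else `"non-normal"`.  Degenerate (constant or n < 3) vectors
#'   gate as non-normal.
#' @export
normality_gate <- function(x, y = NULL, alpha = 0.05) {
  passes <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || length(v) > 5000) return(FALSE)
    if (stats::var(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha
  }
  ok <- passes(x) && (is.null(y) || passes(y))
  if (ok) "normal" else "non-normal"
}

#' Compare one estimator between two groups
#'
#' Computes both the Welch t-test and the two-sided Wilcoxon rank-sum test
#' (exact enumeration when both groups have n <= 10 and no ties, normal
#' approximation with continuity and tie correction otherwise); the
#' normality gate selects which p-value is the headline `nominal_p`.
#'
#' @param values Numeric vector of estimator values.
#' @param groups Factor/character vector of group labels (exactly two
#'   levels, each with n >= 3).
#' @param shapiro_alpha Gate significance level.
#' @return One-row data frame: `test_used`, `statistic`, `nominal_p`,
#'   `p_t`, `p_wilcoxon`, and the two group medians.
#' @export
compare_groups <- function(values, groups, shapiro_alpha = 0.05) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop_acl("exactly two groups required")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (length(x) < 3 || length(y) < 3) stop_acl("each group needs n >= 3")
  gate <- normality_gate(x, y, shapiro_alpha)
  tt <- stats::t.test(x, y)
  exact <- length(x) <= 10 && length(y) <= 10
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  use_t <- gate == "normal"
  data.frame(group1 = lev[1], group2 = lev[2],
             test_used = if (use_t) "t" else "wilcoxon",
             statistic = unname(if (use_t) tt$statistic else wt$statistic),
             nominal_p = if (use_t) tt$p.value else wt$p.value,
             p_t = tt$p.value, p_wilcoxon = wt$p.value,
             median1 = stats::median(x), median2 = stats::median(y),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up q-values with monotone enforcement.
#'
#' @param pvals Nominal p-values in `(0, 1]`.
#' @param q FDR level for the flags (default 0.1).
#' @return List with `qvals` and logical `flags` (`q <=` level).
#' @export
bh_adjust <- function(pvals, q = 0.1) {
  if (length(pvals) == 0) return(list(qvals = numeric(0), flags = logical(0)))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    stop_acl("p-values must be in (0, 1]")
  }
  qv <- stats::p.adjust(pvals, method = "BH")
  list(qvals = qv, flags = qv <= q)
}

#' Compare every estimator between the two populations
#'
#' @param est An `estimator_table` (see [compute_all()]).
#' @param groups Group label per row of `est`.
#' @param fdr_q FDR level for the significance flags.
#' @param shapiro_alpha Normality-gate level.
#' @return Data frame with one row per estimator: gated test, both
#'   p-values, BH q-value and significance flag, group medians.
#' @export
compare_all <- function(est, groups, fdr_q = 0.1, shapiro_alpha = 0.05) {
  cols <- estimator_columns(est)
  rows <- lapply(cols, function(cn) {
    r <- compare_groups(est[[cn]], groups, shapiro_alpha)
    cbind(estimator = cn, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bh_adjust(out$nominal_p, fdr_q)
  out$bh_q <- adj$qvals
  out$significant <- adj$flags
  out
}

#' Group estimators into independent clusters
#'
#' Builds a graph with an edge between two estimators when their Spearman
#' correlation is significant at `alpha`; connected components are the
#' clusters, and the number of components counts the independent signals.
#'
#' @param est An `estimator_table`.
#' @param alpha Significance level for the Spearman test (default 0.01).
#' @return List with `clusters` (list of estimator-name vectors) and
#'   `membership` (named integer vector).
#' @export
independence_groups <- function(est, alpha = 0.01) {
  cols <- estimator_columns(est)
  if (length(cols) < 2) stop_acl("need at least two estimators")
  m <- as.matrix(est[, cols, drop = FALSE])
  edges <- character(0)
  for (i in seq_len(length(cols) - 1)) {
    for (j in seq(i + 1, length(cols))) {
      p <- suppressWarnings(
        stats::cor.test(m[, i], m[, j], method = "spearman",
                        exact = FALSE)$p.value)
      if (!is.na(p) && p < alpha) edges <- c(edges, cols[i], cols[j])
    }
  }
  gr <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(cols)
  if (length(edges)) gr <- gr + igraph::edges(edges)
  comp <- igraph::components(gr)
  membership <- comp$membership[cols]
  clusters <- split(cols, membership)
  names(clusters) <- NULL
  list(clusters = clusters, membership = membership,
       n_independent = comp$no)
}

#' Per-group medians of acceleration columns
#'
#' The headline summary of epigenetic-age discrepancy: the median of each
#' acceleration column within each population.
#'
#' @param est An `estimator_table`.
#' @param groups Group label per row.
#' @param clock_subset Estimator names to summarise (default all).
#' @return Matrix, groups x estimators, of medians.
#' @export
median_discrepancy <- function(est, groups,
                               clock_subset = estimator_columns(est)) {
  missing <- setdiff(clock_subset, names(est))
  if (length(missing)) {
    stop_acl(sprintf("estimators not present: %s",
                     paste(missing, collapse = ", ")))
  }
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  out <- sapply(clock_subset, function(cn) {
    tapply(est[[cn]], factor(groups, levels = lev), stats::median)
  })
  matrix(out, nrow = length(lev),
         dimnames = list(lev, clock_subset))
}
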