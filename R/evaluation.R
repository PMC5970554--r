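#' Pearson correlation coefficient
#'
#' @param a,b Numeric series of equal length >= 3.
#' @return Correlation in \[-1, 1\]; `NaN` with a warning if either series
#'   is constant.
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  if (length(a) < 3) stop("need at least 3 points")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant input; correlation undefined")
    return(NaN)
  }
  cor(a, b)
}

#' Mean absolute error
#'
#' @param pred,target Numeric series of equal length >= 1.
#' @return Mean of `|pred - target|`, in index units.
#' @export
mae <- function(pred, target) {
  if (length(pred) != length(target)) stop("series must have equal length")
  if (length(pred) < 1) stop("need at least 1 point")
  mean(abs(pred - target))
}

#' AUC of the index against the awake/anaesthesia boundary
#'
#' Labels rows awake (positive) when the reference is at or above
#' `threshold` (default 65, the conventional BIS boundary) and computes the
#' area under the ROC curve of the index as the normalised Mann-Whitney U
#' statistic, with ties counted half. An index oriented like BIS (higher =
#' more awake) scores near 1.
#'
#' @param index Numeric index values (the classifier score).
#' @param ref Reference index values, same length.
#' @param threshold Awake boundary on the reference (default 65).
#' @return AUC in \[0, 1\].
#' @export
auc_vs_reference <- function(index, ref, threshold = 65) {
  if (length(index) != length(ref)) stop("series must have equal length")
  pos <- ref >= threshold
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present (reference on both sides of threshold)")
  r <- rank(index)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assign anaesthesia phases from the reference index
#'
#' Phase 1 \[0, 40): deep anaesthesia; Phase 2 \[40, 65): general
#' anaesthesia; Phase 3 \[65, 85): light anaesthesia; Phase 4 \[85, 100\]:
#' awake. Boundary values belong to the upper phase.
#'
#' @param ref Numeric values in \[0, 100\].
#' @return Integer vector of phases 1-4.
#' @export
assign_phases <- function(ref) {
  if (any(ref < 0 | ref > 100)) stop("reference values must lie in [0, 100]")
  findInterval(ref, c(40, 65, 85)) + 1L
}

#' Phase distribution table
#'
#' Cross-tabulates reference phases (rows) against predicted-output bins
#' using the same phase bounds, reporting counts and row percentages. Rows
#' sum to the number of windows in each reference phase.
#'
#' @param pred Predicted index values in \[0, 100\].
#' @param ref Reference index values in \[0, 100\], same length.
#' @return List with matrices `counts` and `percent` (4 x 4) and vector
#'   `n` of per-phase totals.
#' @export
phase_distribution_table <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("series must have equal length")
  pr <- factor(assign_phases(ref), levels = 1:4)
  pp <- factor(assign_phases(pred), levels = 1:4)
  counts <- unclass(table(pr, pp))
  dimnames(counts) <- list(ref_phase = paste0("P", 1:4),
                           pred_bin = paste0("P", 1:4))
  ntot <- rowSums(counts)
  percent <- counts / ifelse(ntot == 0, 1, ntot) * 100
  list(counts = counts, percent = percent, n = ntot)
}

#' One-way ANOVA on ranks with Student-Newman-Keuls pairwise tests
#'
#' Kruskal-Wallis H (with tie correction) across the groups, followed by
#' SNK stepwise pairwise comparisons on the group mean ranks: groups are
#' ordered by mean rank and ranges are tested largest-span-first against
#' studentized-range critical values (infinite degrees of freedom); when a
#' range is not significant, all pairs inside it are declared not
#' significant without further testing. Pairwise testing is only performed
#' when the overall test is significant at `alpha`.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @param alpha Significance level (default 0.05).
#' @return List with `H`, `p`, and data.frame `pairwise` (`group1`,
#'   `group2`, `q`, `span`, `significant`).
#' @export
anova_on_ranks <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 values")
  kw <- kruskal.test(groups)
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  N <- sum(ns)
  rk <- rank(unlist(groups))
  gid <- rep(seq_len(k), ns)
  rbar <- tapply(rk, gid, mean)
  ord <- order(rbar)

  sig <- matrix(NA, k, k) # in mean-rank order
  qmat <- matrix(NA_real_, k, k)
  overall_sig <- kw$p.value < alpha

  test_range <- function(i, j) {
    if (!is.na(sig[i, j])) return()
    span <- j - i + 1
    a <- ord[i]; b <- ord[j]
    se <- sqrt(N * (N + 1) / 12 * (1 / ns[a] + 1 / ns[b]))
    q <- sqrt(2) * abs(rbar[a] - rbar[b]) / se
    qmat[i, j] <<- q
    if (overall_sig && q >= qtukey(1 - alpha, span, Inf)) {
      sig[i, j] <<- TRUE
      if (j - i >= 2) {
        test_range(i, j - 1)
        test_range(i + 1, j)
      }
    } else {
      for (ii in i:(j - 1)) for (jj in (ii + 1):j) {
        if (is.na(sig[ii, jj])) sig[ii, jj] <<- FALSE
      }
    }
  }
  test_range(1, k)
  # fill q statistics for reporting where blocking skipped the computation
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (is.na(qmat[i, j])) {
      a <- ord[i]; b <- ord[j]
      se <- sqrt(N * (N + 1) / 12 * (1 / ns[a] + 1 / ns[b]))
      qmat[i, j] <- sqrt(2) * abs(rbar[a] - rbar[b]) / se
    }
  }
  nm <- names(groups) %||% paste0("group", seq_len(k))
  pw <- do.call(rbind, lapply(seq_len(k - 1), function(i) {
    do.call(rbind, lapply((i + 1):k, function(j) {
      data.frame(group1 = nm[ord[i]], group2 = nm[ord[j]],
                 q = qmat[i, j], span = j - i + 1,
                 significant = sig[i, j])
    }))
  }))
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}

#' Evaluate an index trace against the reference
#'
#' Bundles the full evaluation battery: Pearson correlation, mean absolute
#' error, AUC at the awake boundary, the phase distribution table, and
#' ANOVA on ranks (with SNK pairwise decisions) of the predicted index
#' grouped by reference phase. Phases with fewer than 2 windows are omitted
#' from the ANOVA; it is skipped (NA) when fewer than 2 phases remain.
#'
#' @param pred Predicted index values in \[0, 100\].
#' @param ref Reference index values in \[0, 100\], aligned with `pred`.
#' @param threshold Awake boundary for the AUC (default 65).
#' @param alpha Significance level for the ANOVA (default 0.05).
#' @return An object of class `evaluation_report`: list with `cc`, `mae`,
#'   `auc`, `phase_table`, `anova`, `n`.
#' @export
evaluate_session <- function(pred, ref, threshold = 65, alpha = 0.05) {
  if (length(pred) != length(ref)) stop("series must have equal length")
  cc <- pearson_cc(pred, ref)
  err <- mae(pred, ref)
  auc <- auc_vs_reference(pred, ref, threshold)
  pt <- phase_distribution_table(pred, ref)
  ph <- assign_phases(ref)
  groups <- split(pred, ph)
  groups <- groups[vapply(groups, length, 0L) >= 2]
  an <- if (length(groups) >= 2) anova_on_ranks(groups, alpha) else
    list(H = NA_real_, p = NA_real_, pairwise = NULL)
  structure(list(cc = cc, mae = err, auc = auc, phase_table = pt,
                 anova = an, n = length(pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d  CC=%.3f  MAE=%.2f  AUC=%.3f\n",
              x$n, x$cc, x$mae, x$auc))
  cat(sprintf("  ANOVA on ranks: H=%.2f, p=%.3g\n", x$anova$H, x$anova$p))
  cat("  phase counts (reference):",
      paste(x$phase_table$n, collapse = " / "), "\n")
  invisible(x)
}
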