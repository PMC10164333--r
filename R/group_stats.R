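#' @title Nonparametric repeated-measures statistics
#' @description
#' The study's statistical pipeline over condition-level metrics: a
#' Shapiro-Wilk normality screen per condition, the Friedman test for
#' differences between conditions (complete cases), pairwise Wilcoxon
#' signed-rank tests with Pratt's treatment of zero differences, and
#' Holm-Bonferroni control of the family-wise error rate.  The unit of
#' analysis is a per-participant summary (e.g. median TTI+Pre-TTI) per
#' condition; rows are participants, columns conditions, and missing cells
#' (withdrawals, lost sessions) are allowed.
#' @name group-stats
NULL

#' Shapiro-Wilk normality screen per condition
#'
#' @param table numeric matrix or data frame, participants x conditions.
#' @return Named numeric vector of p-values; `NA` (with a message) for
#'   conditions with fewer than 3 non-missing values or zero variance.
#' @export
normality_screen <- function(table) {
  m <- as.matrix(table)
  out <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j][!is.na(m[, j])]
    if (length(x) < 3L) {
      message("condition ", colnames(m)[j] %||% j,
              ": fewer than 3 values, normality screen skipped")
      return(NA_real_)
    }
    if (stats::sd(x) == 0) {
      message("condition ", colnames(m)[j] %||% j,
              ": constant values, normality screen skipped")
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  names(out) <- colnames(m)
  out
}

#' Friedman test over a repeated-measures table
#'
#' Rank-based Friedman chi-square (average ranks for ties), p-value from
#' the chi-square distribution with k-1 degrees of freedom.  Participants
#' with any missing condition are excluded listwise.
#'
#' @param table numeric matrix or data frame, participants x conditions.
#' @return List with `statistic`, `df`, `p_value`, `n_complete`.
#' @export
friedman_rm <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 2L) stop("need at least 2 conditions")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 complete cases")
  if (all(apply(m, 1L, function(x) length(unique(x)) == 1L))) {
    # every participant fully tied: no rank information at all
    return(list(statistic = 0, df = ncol(m) - 1L, p_value = 1,
                n_complete = nrow(m)))
  }
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value, n_complete = nrow(m))
}

#' Wilcoxon signed-rank test with Pratt's zero method
#'
#' Paired two-sided signed-rank test in which zero differences are kept
#' when ranking the absolute differences and dropped from the signed rank
#' sums afterwards (Pratt's method; the classical Wilcoxon procedure drops
#' zeros before ranking).  The p-value is exact (enumeration of all sign
#' assignments of the non-zero ranks, conditional on the observed ties and
#' zeros) when at most `exact_max` non-zero differences are present, and
#' uses a normal approximation with continuity correction otherwise; the
#' use of the actual mid-ranks makes the variance tie-corrected.
#'
#' @param x,y paired numeric vectors; `y` may be omitted to test
#'   differences `x` against zero.
#' @param exact_max largest number of non-zero differences for which the
#'   exact enumeration is used (default 12).
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n`, `n_nonzero`, `method`.
#' @export
wilcoxon_pratt <- function(x, y = NULL, exact_max = 12L) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  if (length(d) < 3L) stop("need at least 3 paired differences")
  r <- rank(abs(d))              # zeros included in the ranking (Pratt)
  nz <- d != 0
  if (!any(nz)) {
    message("all differences are zero; no evidence against the null")
    return(list(statistic = 0, p_value = 1, n = length(d),
                n_nonzero = 0L, method = "degenerate"))
  }
  rnz <- r[nz]
  v <- sum(rnz[d[nz] > 0])
  s <- sum(rnz)
  m <- sum(nz)
  if (m <= exact_max) {
    # exhaustive sign-flip enumeration conditional on observed ranks
    w <- 0
    for (bits in 0:(2^m - 1)) {
      signs <- bitwAnd(bits, 2^(seq_len(m) - 1L)) > 0
      wv <- sum(rnz[signs])
      if (abs(wv - s / 2) >= abs(v - s / 2) - 1e-9) w <- w + 1
    }
    p <- w / 2^m
    method <- "exact"
  } else {
    sigma <- sqrt(sum(rnz^2) / 4)
    z <- (v - s / 2)
    z <- sign(z) * max(0, abs(z) - 0.5) / sigma   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = min(1, p), n = length(d),
       n_nonzero = m, method = method)
}

#' Holm-Bonferroni step-down correction
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return List with `adjusted` (monotone Holm-adjusted p-values, same
#'   order as input) and `rejected` (logical flags at level `alpha`).
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "holm")
  list(adjusted = adj, rejected = !is.na(adj) & adj < alpha)
}

#' Full statistical pipeline over a repeated-measures table
#'
#' Shapiro-Wilk screen per condition, Friedman omnibus over complete
#' cases, then all pairwise Wilcoxon-Pratt comparisons (pairwise deletion)
#' Holm-corrected within this family of comparisons.
#'
#' @param table numeric matrix or data frame, participants x conditions
#'   (named columns).
#' @param alpha family-wise error rate.
#' @param gate_on_friedman if `TRUE` (default) pairwise tests are only
#'   reported as rejections when the Friedman omnibus is itself
#'   significant at `alpha`.
#' @return An object of class `stats_report`: list with `normality`,
#'   `friedman`, `pairwise` (data frame: comparison, statistic, raw and
#'   Holm-adjusted p, rejection flag) and `alpha`.
#' @export
stats_pipeline <- function(table, alpha = 0.05, gate_on_friedman = TRUE) {
  m <- as.matrix(table)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("cond", seq_len(ncol(m)))
  norm_p <- normality_screen(m)
  fr <- friedman_rm(m)
  pairs <- utils::combn(colnames(m), 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ok <- stats::complete.cases(m[, c(a, b)])
    wt <- wilcoxon_pratt(m[ok, a], m[ok, b])
    data.frame(comparison = paste(a, "vs", b), statistic = wt$statistic,
               p_raw = wt$p_value, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  hb <- holm_bonferroni(pw$p_raw, alpha)
  pw$p_holm <- hb$adjusted
  pw$rejected <- hb$rejected
  if (gate_on_friedman && fr$p_value >= alpha) pw$rejected <- FALSE
  structure(list(normality = norm_p, friedman = fr, pairwise = pw,
                 alpha = alpha,
                 family = "pairwise condition comparisons (one metric)"),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report>\n")
  cat("  Shapiro-Wilk p per condition:",
      paste(sprintf("%s=%.3g", names(x$normality), x$normality),
            collapse = ", "), "\n")
  cat(sprintf("  Friedman: chi^2 = %.3f, df = %d, p = %.4g (n = %d complete)\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value,
              x$friedman$n_complete))
  cat("  Pairwise Wilcoxon-Pratt (Holm-corrected):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
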