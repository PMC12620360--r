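#' Paired Wilcoxon signed-rank test with effect size
#'
#' Two-sided within-subject signed-rank test on stress-minus-relax
#' differences. Zero differences are dropped (the classical Wilcoxon
#' convention). For `n <= 25` nonzero differences without ties in `|d|`
#' the exact null distribution is used (via `psignrank`); otherwise the
#' normal approximation with tie correction and continuity correction.
#' The effect size is Rosenthal's r, `|z| / sqrt(n)`, with `n` the
#' original pair count; `z` is the signed standardized statistic (reported
#' from the normal approximation in both regimes).
#'
#' @param stress,relax paired numeric vectors (same subjects, same order).
#' @return list with `p` (two-sided), `z`, `r`, `n` (original pair count),
#'   `nEffective` (pairs after zero removal), `W` (positive-rank sum),
#'   `exact` (logical).
#' @export
wilcoxonSignedRank <- function(stress, relax) {
  stopifnot(length(stress) == length(relax))
  d <- stress - relax
  d <- d[is.finite(d)]
  n0 <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stopTyped("earstress_degenerate_data", "all paired differences are zero")
  if (n < 5L)
    stopTyped("earstress_degenerate_data",
              "fewer than 5 nonzero paired differences (%d)", n)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L

  mu <- n * (n + 1) / 4
  tieTab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tieTab^3 - tieTab) / 48
  cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
  z <- (W - mu - cc) / sqrt(sigma2)

  exact <- n <= 25L && !ties
  p <- if (exact) {
    min(1, 2 * min(stats::psignrank(W, n),
                   1 - stats::psignrank(W - 1, n)))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  list(p = p, z = z, r = abs(z) / sqrt(n0), n = n0, nEffective = n,
       W = W, exact = exact)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted q-values `q(i) = min over j >= i (sorted) of m p(j) / j`
#' (capped at 1, mapped back to input order) via `p.adjust(method = "BH")`,
#' plus the step-up rejection set: the largest `k` with
#' `p(k) <= (k / m) Q` and flags for all sorted `p(i)`, `i <= k`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param Q target false discovery rate.
#' @return list with `q` (adjusted p-values, input order), `significant`
#'   (logical, input order), `k` (step-up index; 0 if nothing rejected).
#' @export
bhFdrAdjust <- function(pvals, Q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stopTyped("earstress_bad_pvalue", "p-values must lie in [0, 1]")
  m <- length(pvals)
  q <- stats::p.adjust(pvals, method = "BH")
  ord <- order(pvals)
  ps <- pvals[ord]
  below <- which(ps <= seq_len(m) / m * Q)
  k <- if (length(below)) max(below) else 0L
  significant <- rep(FALSE, m)
  if (k > 0L) significant[ord[seq_len(k)]] <- TRUE
  list(q = q, significant = significant, k = k)
}

#' Paradigm validation: paired marker tests with FDR control
#'
#' Runs the within-subject Wilcoxon signed-rank test (stress vs relax) for
#' each of the seven markers and applies Benjamini-Hochberg FDR control
#' jointly across the seven tests.
#'
#' @param markers data.frame from [computeMarkers()]; every subject must
#'   have both conditions.
#' @param Q target false discovery rate.
#' @return data.frame with one row per marker: feature, p, q, z, r, n,
#'   significant. q-values are unrounded; use [writeValidationReport()]
#'   for the 4-decimal report.
#' @export
validateParadigm <- function(markers, Q = 0.05) {
  byCond <- split(markers, markers$condition)
  if (!all(c("stress", "relax") %in% names(byCond)))
    stopTyped("earstress_unpaired", "markers must contain both conditions")
  s <- byCond$stress[order(byCond$stress$subjectId), ]
  r <- byCond$relax[order(byCond$relax$subjectId), ]
  if (!identical(s$subjectId, r$subjectId))
    stopTyped("earstress_unpaired",
              "every subject needs exactly one stress and one relax row")
  tests <- lapply(MARKER_NAMES, function(f)
    wilcoxonSignedRank(s[[f]], r[[f]]))
  p <- vapply(tests, `[[`, numeric(1), "p")
  adj <- bhFdrAdjust(p, Q = Q)
  data.frame(
    feature = MARKER_NAMES,
    p = p,
    q = adj$q,
    z = vapply(tests, `[[`, numeric(1), "z"),
    r = vapply(tests, `[[`, numeric(1), "r"),
    n = vapply(tests, `[[`, numeric(1), "n"),
    significant = adj$significant,
    stringsAsFactors = FALSE)
}

#' Write a validation report as TSV (p, q rounded to 4 decimals)
#'
#' @param results data.frame from [validateParadigm()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeValidationReport <- function(results, path) {
  out <- results
  out$p <- round(out$p, 4)
  out$q <- round(out$q, 4)
  out$z <- round(out$z, 3)
  out$r <- round(out$r, 3)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
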