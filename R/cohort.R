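#' Sample skewness (moment estimator)
#'
#' The uncorrected moment estimator
#' \deqn{g_1 = m_3 / m_2^{3/2}, \quad m_k = \frac{1}{n}\sum (v_i - \bar v)^k.}
#' Set `bias_corrected = TRUE` for the adjusted Fisher-Pearson variant
#' `G1 = g1 * sqrt(n (n-1)) / (n-2)`.
#'
#' @param values Numeric vector, at least 3 finite values with nonzero
#'   variance.
#' @param bias_corrected Use the bias-corrected estimator (default `FALSE`,
#'   matching the moment convention used by the skewness test).
#' @return The sample skewness (dimensionless).
#' @export
sample_skewness <- function(values, bias_corrected = FALSE) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) {
    stop_dsskit("skewness needs at least 3 finite values",
                "dsskit_error_insufficient_data")
  }
  d <- values - mean(values)
  m2 <- mean(d^2)
  if (m2 == 0) {
    stop_dsskit("skewness undefined for zero-variance values",
                "dsskit_error_zero_variance")
  }
  g1 <- mean(d^3) / m2^1.5
  if (bias_corrected) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' D'Agostino test of skewness
#'
#' Tests departure from normality through the sample skewness, using
#' D'Agostino's (1970) normalizing transformation of the moment estimator
#' `g1` to an approximately standard normal `z`. The default one-sided
#' alternative `"greater"` asks whether the distribution is more
#' right-skewed than a normal one, the reading used to flag drugs with a
#' small highly-responsive sub-group in the right tail of their response
#' distribution.
#'
#' @param values Numeric vector with at least 8 finite values (the
#'   transformation is not valid below that) and nonzero variance.
#' @param alternative `"greater"` (positive skewness, default),
#'   `"less"`, or `"two.sided"`.
#' @return Object of class `agostino_test` with elements `gamma` (the sample
#'   skewness), `z`, `p.value`, `alternative`, `n`. `tidy()` returns it as a
#'   one-row tibble.
#' @export
agostino_test <- function(values, alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) {
    stop_dsskit("sample too small for D'Agostino transformation (need n >= 8)",
                "dsskit_error_insufficient_data")
  }
  g1 <- sample_skewness(values)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * asinh(y / alpha)
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  structure(list(gamma = g1, z = z, p.value = p,
                 alternative = alternative, n = n),
            class = "agostino_test")
}

#' @export
print.agostino_test <- function(x, ...) {
  cat(sprintf("D'Agostino skewness test: gamma = %.4f, z = %.4f, p = %.4g (%s), n = %d\n",
              x$gamma, x$z, x$p.value, x$alternative, x$n))
  invisible(x)
}

#' @export
tidy.agostino_test <- function(x, ...) {
  tibble(gamma = x$gamma, z = x$z, p.value = x$p.value,
         alternative = x$alternative, n = x$n)
}

#' Detect a right-tail responder sub-group in per-sample scores
#'
#' If the one-sided D'Agostino skewness test over all samples is significant
#' at `alpha`, the responder set is the minimal right tail whose removal makes
#' the test non-significant: the maximum value is peeled off and the remaining
#' values re-tested, repeatedly, until `p >= alpha` (or too few values remain
#' for the test). The responders are therefore always the top-k samples by
#' score for some k >= 1; with a non-significant initial test the set is
#' empty.
#'
#' @param values Per-sample scores for one drug (>= 8 finite values).
#' @param ids Optional sample ids aligned with `values` (defaults to names of
#'   `values`, or indices). Ties in the score are peeled in `ids` order.
#' @param alpha Significance level for the one-sided test (default 0.05).
#' @return List with `responder_ids`, `k` (number of responders), and `test`
#'   (the initial [agostino_test()] result).
#' @export
detect_responders <- function(values, ids = NULL, alpha = 0.05) {
  ids <- ids %||% names(values) %||% as.character(seq_along(values))
  keep <- is.finite(values)
  values <- values[keep]
  ids <- ids[keep]
  test0 <- agostino_test(values, alternative = "greater")
  ord <- order(values, decreasing = TRUE)
  k <- 0L
  while (TRUE) {
    remaining <- if (k == 0) values[ord] else values[ord][-seq_len(k)]
    if (length(remaining) == 0) break
    p <- tryCatch(agostino_test(remaining, alternative = "greater")$p.value,
                  dsskit_error = function(e) NA_real_)
    if (is.na(p) || p >= alpha) break
    k <- k + 1L
    if (length(remaining) - 1L < 8L) break
  }
  list(responder_ids = if (k > 0) ids[ord][seq_len(k)] else character(0),
       k = k, test = test0)
}

#' Per-drug responder sub-group screen over a score matrix
#'
#' Applies [detect_responders()] to every drug column of a score matrix and
#' reports the skewness statistics, Benjamini-Hochberg FDR across drugs
#' (raw p-values are primary; FDR is reported alongside), the responder ids,
#' and the Wilcoxon rank-sum p-value of responders versus the remaining
#' samples (NA when no responders).
#'
#' @param x A `dss_score_matrix` (typically dDSS).
#' @param alpha Significance level for the one-sided skewness test.
#' @return Tibble with one row per drug: `drug_id`, `n`, `gamma`, `z`,
#'   `p.value`, `fdr`, `n_responders`, `responders` (list column),
#'   `ranksum_p`.
#' @export
detect_responder_subgroups <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, score_matrix_class))
  vals <- score_matrix_values(x)
  rows <- purrr::map(colnames(vals), function(drug) {
    v <- vals[, drug]
    det <- tryCatch(detect_responders(v, ids = rownames(vals), alpha = alpha),
                    dsskit_error = function(e) NULL)
    if (is.null(det)) {
      return(tibble(drug_id = drug, n = sum(is.finite(v)), gamma = NA_real_,
                    z = NA_real_, p.value = NA_real_,
                    n_responders = NA_integer_, responders = list(character(0)),
                    ranksum_p = NA_real_))
    }
    rs_p <- NA_real_
    if (det$k > 0 && det$k < sum(is.finite(v))) {
      in_grp <- rownames(vals) %in% det$responder_ids
      rs_p <- rank_sum_test(v[in_grp], v[!in_grp & is.finite(v)])$p.value
    }
    tibble(drug_id = drug, n = det$test$n, gamma = det$test$gamma,
           z = det$test$z, p.value = det$test$p.value,
           n_responders = det$k, responders = list(det$responder_ids),
           ranksum_p = rs_p)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- p.adjust(out$p.value, method = "BH")
  out[, c("drug_id", "n", "gamma", "z", "p.value", "fdr",
          "n_responders", "responders", "ranksum_p")]
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Wilcoxon-Mann-Whitney rank-sum test via [stats::wilcox.test()]: the exact
#' null distribution is used when both groups have at most 20 observations
#' and there are no ties; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (the Mann-Whitney W for `group_a`),
#'   `p.value` (two-sided), and `exact` (whether the exact branch was used).
#' @export
rank_sum_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_dsskit("both groups must be non-empty", "dsskit_error_insufficient_data")
  }
  no_ties <- !anyDuplicated(c(group_a, group_b))
  exact <- no_ties && length(group_a) <= 20 && length(group_b) <= 20
  ht <- stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value, exact = exact)
}

#' Area under the ROC curve of a response metric
#'
#' AUROC as the probability that a randomly chosen active curve outscores a
#' randomly chosen inactive one (ties counted half), computed by the midrank
#' formula. For metrics where smaller means more active (IC50), pass
#' `orientation = "lower_is_active"`, which negates the scores first.
#'
#' @param scores Numeric scores, one per curve.
#' @param labels Logical (or 0/1) activity labels aligned with `scores`;
#'   both classes must be present.
#' @param orientation `"higher_is_active"` (default) or `"lower_is_active"`.
#' @return Object of class `roc_result` with `auroc`, `n_pos`, `n_neg`,
#'   `orientation`; `tidy()` gives a one-row tibble.
#' @export
auroc <- function(scores, labels,
                  orientation = c("higher_is_active", "lower_is_active")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_dsskit("both label classes must be present", "dsskit_error_single_class")
  }
  if (orientation == "lower_is_active") scores <- -scores
  r <- rank(scores)
  a <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(auroc = a, n_pos = n_pos, n_neg = n_neg,
                 orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC = %.4f (%d active, %d inactive, %s)\n",
              x$auroc, x$n_pos, x$n_neg, x$orientation))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg,
         orientation = x$orientation)
}

# placement values of DeLong (1988): for each positive, the fraction of
# negatives it beats (ties half), and vice versa
delong_placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), theta = mean(cmp))
}

#' DeLong paired test for two correlated AUROCs
#'
#' Compares the AUROCs of two response metrics evaluated on the same labelled
#' curves, using DeLong's (1988) nonparametric covariance estimate from
#' placement values (structural components). When the variance of the
#' difference is degenerate (e.g. identical score vectors), the difference is
#' reported as 0 with `p = 1` and `degenerate = TRUE`.
#'
#' @param scores_1,scores_2 Paired score vectors over the same curves.
#' @param labels Logical (or 0/1) activity labels; both classes required.
#' @return Object of class `delong_test` with `auroc_1`, `auroc_2`, `diff`,
#'   `var_diff`, `z`, `p.value`, `degenerate`; `tidy()` gives a one-row
#'   tibble.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  labels <- as.logical(labels)
  keep <- is.finite(scores_1) & is.finite(scores_2) & !is.na(labels)
  scores_1 <- scores_1[keep]
  scores_2 <- scores_2[keep]
  labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    stop_dsskit("both label classes must be present", "dsskit_error_single_class")
  }
  p1 <- delong_placements(scores_1, labels)
  p2 <- delong_placements(scores_2, labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  d <- p1$theta - p2$theta
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  if (degenerate) {
    z <- 0
    p <- 1
    d <- if (abs(d) < 1e-12) 0 else d
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  structure(list(auroc_1 = p1$theta, auroc_2 = p2$theta, diff = d,
                 var_diff = var_diff, z = z, p.value = p,
                 degenerate = degenerate),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("DeLong test: AUROC %.4f vs %.4f, diff = %.4f, z = %.3f, p = %.4g%s\n",
              x$auroc_1, x$auroc_2, x$diff, x$z, x$p.value,
              if (x$degenerate) " (degenerate variance)" else ""))
  invisible(x)
}

#' @export
tidy.delong_test <- function(x, ...) {
  tibble(auroc_1 = x$auroc_1, auroc_2 = x$auroc_2, diff = x$diff,
         z = x$z, p.value = x$p.value, degenerate = x$degenerate)
}

#' Evaluate several response metrics against activity labels
#'
#' Computes the AUROC of each metric column and the pairwise DeLong tests
#' between metrics, over the same labelled curves.
#'
#' @param scores Tibble with one row per curve and one numeric column per
#'   metric (any identifier columns are ignored via `metrics`).
#' @param labels Logical (or 0/1) activity labels aligned with rows.
#' @param metrics Character vector naming the metric columns (default: all
#'   numeric columns).
#' @param orientation Named character vector of per-metric orientations;
#'   unnamed metrics default to `"higher_is_active"`.
#' @return List with `auroc` (tibble metric/auroc/n_pos/n_neg) and `delong`
#'   (tibble metric_1/metric_2/diff/p.value).
#' @export
evaluate_metrics <- function(scores, labels, metrics = NULL, orientation = NULL) {
  metrics <- metrics %||% names(scores)[vapply(scores, is.numeric, logical(1))]
  get_orient <- function(mtr) {
    o <- orientation[mtr]
    if (is.null(orientation) || is.na(o)) "higher_is_active" else unname(o)
  }
  oriented <- lapply(metrics, function(mtr) {
    v <- scores[[mtr]]
    if (get_orient(mtr) == "lower_is_active") -v else v
  })
  names(oriented) <- metrics
  auc_tbl <- dplyr::bind_rows(lapply(metrics, function(mtr) {
    r <- auroc(oriented[[mtr]], labels)
    tibble(metric = mtr, auroc = r$auroc, n_pos = r$n_pos, n_neg = r$n_neg)
  }))
  pairs <- utils::combn(metrics, 2, simplify = FALSE)
  delong_tbl <- dplyr::bind_rows(lapply(pairs, function(pr) {
    dt <- delong_test(oriented[[pr[1]]], oriented[[pr[2]]], labels)
    tibble(metric_1 = pr[1], metric_2 = pr[2], auroc_1 = dt$auroc_1,
           auroc_2 = dt$auroc_2, diff = dt$diff, p.value = dt$p.value)
  }))
  list(auroc = auc_tbl, delong = delong_tbl)
}
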