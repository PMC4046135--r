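# Closed-form integral of the fitted response above the activity threshold.
# Antiderivative of (R(x) - a_min):
#   F(x) = (r_min - a_min) x + (r_max - r_min)/(s ln 10) * ln(1 + 10^{s(x - m)})
# evaluated stably via log1p10(). Vectorized over parameter vectors.
integral_core <- function(r_min, r_max, m, s, a_min, x_lo, x_hi) {
  n <- max(length(r_min), length(r_max), length(m), length(s),
           length(a_min), length(x_lo), length(x_hi))
  r_min <- rep_len(r_min, n); r_max <- rep_len(r_max, n)
  m <- rep_len(m, n); s <- rep_len(s, n); a_min <- rep_len(a_min, n)
  x_lo <- rep_len(x_lo, n); x_hi <- rep_len(x_hi, n)
  antideriv <- function(x) {
    (r_min - a_min) * x + (r_max - r_min) / (s * log(10)) * log1p10(s * (x - m))
  }
  never <- r_max <= a_min
  always <- r_min >= a_min
  crossing <- rep(NA_real_, n)
  mid <- which(!never & !always)
  if (length(mid) > 0) {
    crossing[mid] <- m[mid] - (1 / s[mid]) *
      log10((r_max[mid] - a_min[mid]) / (a_min[mid] - r_min[mid]))
  }
  x1 <- ifelse(never, x_hi,
               ifelse(always, x_lo, clip(crossing, x_lo, x_hi)))
  x2 <- x_hi
  i <- ifelse(never, 0, antideriv(x2) - antideriv(x1))
  i <- pmax(i, 0)
  list(i = i, x1 = x1, x2 = x2)
}

#' Integral response above the minimum activity level
#'
#' Computes the closed-form integral
#' \deqn{I = \int_{x_1}^{x_2} (R(x) - A_{min})\, dx}
#' of a fitted logistic response above the activity threshold `a_min`, over
#' the part of the tested log10-concentration window `[x_lo, x_hi]` where the
#' fitted curve exceeds the threshold. `x2` is always the upper window bound;
#' `x1` is the fitted curve's crossing of `a_min` (clipped into the window)
#' when the threshold lies between the asymptotes, the lower bound when the
#' curve is always above the threshold, and the result is `I = 0` with an
#' empty active window when the top asymptote never reaches the threshold.
#'
#' @param fit A `dss_fit` (or anything with `r_min`, `r_max`, `m`, `s`,
#'   `x_lo`, `x_hi` elements).
#' @param a_min Minimum activity level, percent inhibition (default 10):
#'   responses below it are treated as baseline noise.
#' @param x_lo,x_hi Log10 nM integration window; default the fit's tested
#'   window.
#' @return Tibble with one row: `i_value` (percent x log10-units), `x1`, `x2`.
#' @export
integral_above <- function(fit, a_min = 10, x_lo = NULL, x_hi = NULL) {
  x_lo <- x_lo %||% fit$x_lo
  x_hi <- x_hi %||% fit$x_hi
  stopifnot(x_lo < x_hi, a_min >= 0, a_min < 100)
  res <- integral_core(fit$r_min, fit$r_max, fit$m, fit$s, a_min, x_lo, x_hi)
  tibble(i_value = res$i, x1 = res$x1, x2 = res$x2)
}

# vectorized scores from raw parameters; returns numeric vector
dss_from_params <- function(r_min, r_max, m, s, x_lo, x_hi, a_min = 10,
                            metric = "DSS2") {
  metric <- match.arg(metric, c("DSS1", "DSS2", "DSS3"))
  res <- integral_core(r_min, r_max, m, s, rep(a_min, length(r_min)), x_lo, x_hi)
  dss1 <- 100 * res$i / ((100 - a_min) * (x_hi - x_lo))
  if (metric == "DSS1") return(dss1)
  dss2 <- dss1 * log10(pmax(r_max, 1)) / 2
  if (metric == "DSS2") return(dss2)
  dss2 * (res$x2 - res$x1) / (x_hi - x_lo)
}

#' Drug sensitivity score of a fitted curve
#'
#' The DSS normalizes the integral response `I` (see [integral_above()]) to a
#' 0-100 scale:
#' * `DSS1 = 100 I / ((100 - A_min) (x_hi - x_lo))` — the area above the
#'   activity threshold relative to the maximal attainable area (a compound at
#'   100% inhibition over the full window scores exactly 100);
#' * `DSS2 = DSS1 * log10(max(R_max, 1)) / 2` — additionally penalizes low top
#'   asymptotes (compounds effective only partially even at high dose);
#' * `DSS3 = DSS2 * (x2 - x1) / (x_hi - x_lo)` — additionally penalizes narrow
#'   active dose windows (activity at the highest doses only), favouring
#'   potency over a wide therapeutic window.
#'
#' All three are 0 exactly when `I = 0`, and `DSS3 <= DSS2 <= DSS1`.
#'
#' @inheritParams integral_above
#' @param metric `"DSS1"`, `"DSS2"` or `"DSS3"`.
#' @return A single score in \[0, 100\].
#' @export
dss <- function(fit, metric = "DSS2", a_min = 10, x_lo = NULL, x_hi = NULL) {
  x_lo <- x_lo %||% fit$x_lo
  x_hi <- x_hi %||% fit$x_hi
  stopifnot(x_lo < x_hi, a_min >= 0, a_min < 100)
  dss_from_params(fit$r_min, fit$r_max, fit$m, fit$s, x_lo, x_hi,
                  a_min = a_min, metric = metric)
}

#' Activity Area of observed responses
#'
#' Discrete rectangle approximation of the area under the observed responses:
#' the sum over dose levels of the measured inhibition (negative responses
#' clipped to zero) divided by 100. Ranges from 0 (no activity at any dose)
#' to the number of doses (100% inhibition at every dose), e.g. 8 for full
#' inhibition across an 8-point dilution series.
#'
#' @param responses Numeric vector of percent inhibition values, one per dose.
#' @return The activity area, in \[0, n_doses\].
#' @export
activity_area <- function(responses) {
  if (length(responses) == 0) {
    stop_dsskit("activity_area needs at least one response",
                "dsskit_error_bad_input")
  }
  sum(pmax(0, responses)) / 100
}

#' Relative IC50 of a fitted curve
#'
#' The concentration (nM) at which the fitted curve reaches the midpoint of
#' its own asymptotes, i.e. `10^m`. Curves whose top asymptote does not exceed
#' the activity threshold are flagged inactive and return `NA`.
#'
#' @inheritParams integral_above
#' @return IC50 in nM, or `NA` for inactive curves.
#' @export
relative_ic50 <- function(fit, a_min = 10) {
  if (is.na(fit$r_max) || fit$r_max <= a_min) return(NA_real_)
  10^fit$m
}

#' Score every fitted curve into a score matrix
#'
#' Computes the requested response metric for each row of a [fit_curves()]
#' table and assembles a samples x drugs [as_score_matrix()] matrix. For the
#' DSS metrics the integration window defaults to each curve's own tested
#' window; pass `window` (in nM) to impose a fixed cohort-wide window so
#' scores are comparable across drugs tested at different concentration
#' ranges. The `AA` metric needs the observed responses, so pass the long
#' dose-response `data` as well; `IC50` uses the fitted relative IC50 with
#' inactive curves missing.
#'
#' @param fits Output of [fit_curves()].
#' @param metric One of `"DSS1"`, `"DSS2"`, `"DSS3"`, `"AA"`, `"IC50"`.
#' @param a_min Minimum activity level (percent inhibition), default 10.
#' @param window Optional `c(lo, hi)` concentration window in nM.
#' @param data Long dose-response table (required for `metric = "AA"`).
#' @return A `dss_score_matrix`.
#' @export
score_curves <- function(fits, metric = c("DSS2", "DSS1", "DSS3", "AA", "IC50"),
                         a_min = 10, window = NULL, data = NULL) {
  metric <- match.arg(metric)
  x_lo <- fits$x_lo
  x_hi <- fits$x_hi
  if (!is.null(window)) {
    stopifnot(length(window) == 2, all(window > 0), window[1] < window[2])
    x_lo <- rep(log10(window[1]), nrow(fits))
    x_hi <- rep(log10(window[2]), nrow(fits))
  }
  if (metric %in% c("DSS1", "DSS2", "DSS3")) {
    score <- dss_from_params(fits$r_min, fits$r_max, fits$log10_ic50,
                             fits$slope, x_lo, x_hi, a_min = a_min,
                             metric = metric)
  } else if (metric == "IC50") {
    score <- ifelse(!is.na(fits$r_max) & fits$r_max > a_min,
                    10^fits$log10_ic50, NA_real_)
  } else {
    if (is.null(data)) {
      stop_dsskit("metric 'AA' needs the long dose-response data",
                  "dsskit_error_bad_input")
    }
    aa <- collapse_replicates(data) |>
      dplyr::group_by(.data$sample_id, .data$drug_id) |>
      dplyr::summarise(score = activity_area(.data$response), .groups = "drop")
    keys <- dplyr::left_join(fits[, c("sample_id", "drug_id")], aa,
                             by = c("sample_id", "drug_id"))
    score <- keys$score
  }
  settings <- list(a_min = a_min,
                   window_nM = if (is.null(window)) "per-curve" else window)
  as_score_matrix(
    tibble(sample_id = fits$sample_id, drug_id = fits$drug_id, score = score),
    metric = metric, settings = settings
  )
}

#' Differential scores against control samples
#'
#' For every sample (patients and controls alike) and drug, the differential
#' score is the sample's score minus the mean score of the control samples for
#' that drug (missing control values excluded). Control samples keep their own
#' (nonzero) differential scores, reflecting variability among controls; per
#' drug the control dDSS values sum to zero.
#'
#' @param x A `dss_score_matrix` with metric `DSS1`, `DSS2` or `DSS3`.
#' @param control_ids Character vector of control sample ids; at least one
#'   must be present in the matrix.
#' @return A `dss_score_matrix` with metric `"dDSS"`. Drugs whose control
#'   values are all missing get `NA` everywhere.
#' @export
differential_scores <- function(x, control_ids) {
  stopifnot(inherits(x, score_matrix_class))
  if (!score_metric(x) %in% c("DSS1", "DSS2", "DSS3")) {
    stop_dsskit("differential scoring needs a DSS1/DSS2/DSS3 matrix",
                "dsskit_error_bad_input")
  }
  present <- intersect(control_ids, x$sample_id)
  if (length(present) == 0) {
    stop_dsskit("no control sample ids found in the score matrix",
                "dsskit_error_no_controls")
  }
  vals <- score_matrix_values(x)
  ctrl_mean <- colMeans(vals[present, , drop = FALSE], na.rm = TRUE)
  ctrl_mean[is.nan(ctrl_mean)] <- NA_real_
  dvals <- sweep(vals, 2, ctrl_mean, "-")
  wide <- dplyr::bind_cols(tibble(sample_id = x$sample_id),
                           as_tibble(dvals))
  new_score_matrix(wide, "dDSS",
                   c(score_settings(x),
                     list(base_metric = score_metric(x),
                          control_ids = present)))
}
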