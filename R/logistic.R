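#' Four-parameter logistic response curve
#'
#' The response model is an increasing-inhibition logistic in log10
#' concentration:
#' \deqn{R(x) = R_{min} + \frac{R_{max} - R_{min}}{1 + 10^{s (m - x)}}}
#' with bottom asymptote `r_min`, top asymptote `r_max` (percent inhibition),
#' `m` the log10 IC50 (half-maximal point between the asymptotes) and `s > 0`
#' the slope at the IC50, so inhibition is monotone non-decreasing in dose.
#'
#' @param x Log10 concentration(s), log10(nM).
#' @param r_min,r_max Bottom and top asymptotes, percent inhibition.
#' @param m Log10 IC50, log10(nM).
#' @param s Slope at the IC50 (> 0).
#' @return `logistic_response()`: percent inhibition at `x`.
#' @examples
#' logistic_response(3, r_min = 0, r_max = 100, m = 2, s = 1)  # 90.909...
#' @export
logistic_response <- function(x, r_min, r_max, m, s) {
  r_min + (r_max - r_min) / (1 + 10^(s * (m - x)))
}

#' @rdname logistic_response
#' @param level Percent inhibition level to invert; must lie strictly between
#'   `r_min` and `r_max`, otherwise an `dsskit_error_unattained_level` error is
#'   signalled (the caller decides whether the curve is never- or
#'   always-active).
#' @return `logistic_inverse()`: the unique log10 concentration at which the
#'   curve attains `level`.
#' @export
logistic_inverse <- function(level, r_min, r_max, m, s) {
  if (any(level <= r_min | level >= r_max)) {
    stop_dsskit(
      "response level is not attained strictly inside (r_min, r_max)",
      "dsskit_error_unattained_level"
    )
  }
  m - (1 / s) * log10((r_max - level) / (level - r_min))
}

#' Fit a four-parameter logistic model to one dose-response curve
#'
#' Bounded nonlinear least squares in log10-concentration space via
#' [minpack.lm::nls.lm()], with a deterministic multi-start: `r_min` starts at
#' the minimum observed response, `r_max` at the maximum, `m` at the dose whose
#' response is nearest the midpoint of the two, and the slope starts at 0.5, 1
#' and 2. A deterministic coarse grid over `(m, s)` — with the asymptotes
#' solved per cell by linear least squares — seeds further polish runs, and a
#' flat-curve candidate is always in the pool (so decreasing dose trends,
#' which the increasing-slope model cannot represent, settle on a flat line).
#' The best residual sum of squares wins; ties prefer the smallest slope,
#' then the smallest `m`. Box constraints: `r_min`, `r_max` in \[0, 100\]
#' with `r_min <= r_max`, `m` within the tested log10 window widened by 2
#' (IC50 extrapolation limited to 100x beyond the tested range), `s` in
#' \[0.1, 10\]. If every least-squares run fails, the best grid cell is
#' returned with the fit flagged non-converged.
#'
#' Degenerate plateaus (response variance essentially zero, e.g. an entirely
#' inactive or entirely lethal compound) skip optimization: both asymptotes are
#' set to the common response level, `m` to the midpoint of the tested window
#' and `s` to 1, since `m` and `s` are unidentifiable and downstream scores
#' depend only on the asymptotes.
#'
#' @param data Data frame for a single curve with columns `concentration_nM`
#'   and `response` (percent inhibition); duplicate concentrations are
#'   collapsed to their median first. At least 3 distinct concentrations are
#'   required, otherwise a `dsskit_error_insufficient_data` error is signalled.
#' @param plateau_tol Response standard deviation below which the curve is
#'   treated as a degenerate plateau.
#' @return An object of class `dss_fit`: a list with elements `r_min`,
#'   `r_max`, `m` (log10 IC50), `s` (slope), `converged`, `rss`, `n_points`,
#'   `x_lo`/`x_hi` (log10 of the smallest/largest tested concentration) and
#'   the collapsed `data`.
#' @examples
#' curve <- simulate_curve(r_min = 0, r_max = 100, m = 2, s = 1)
#' fit <- fit_logistic(curve)
#' tidy(fit)

# vectorized (m, s) grid evaluation: for every cell solve the 2x2 normal
# equations for the asymptotes (clipped into [0, 100] and ordered) and
# return the resulting rss
grid_candidates <- function(x, y, m_seq, s_seq) {
  cells <- expand.grid(m = m_seq, s = s_seq)
  w <- 1 / (1 + 10^(outer(cells$s * cells$m, rep(1, length(x))) -
                      outer(cells$s, x)))      # cells x n
  u <- 1 - w
  s11 <- rowSums(u * u); s12 <- rowSums(u * w); s22 <- rowSums(w * w)
  t1 <- as.vector(u %*% y); t2 <- as.vector(w %*% y)
  det <- s11 * s22 - s12^2
  det[abs(det) < 1e-300] <- NA
  a <- (s22 * t1 - s12 * t2) / det
  b <- (s11 * t2 - s12 * t1) / det
  a <- clip(a, 0, 100); b <- clip(b, 0, 100)
  swap <- !is.na(a) & a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  yy <- sum(y * y)
  rss <- yy - 2 * (a * t1 + b * t2) + a^2 * s11 + 2 * a * b * s12 + b^2 * s22
  keep <- !is.na(rss)
  data.frame(m = cells$m[keep], s = cells$s[keep], a = a[keep], b = b[keep],
             rss = pmax(rss[keep], 0))
}

#' @export
fit_logistic <- function(data, plateau_tol = 1e-6) {
  check_columns(data, c("concentration_nM", "response"), "curve data")
  if (any(data$concentration_nM <= 0)) {
    stop_dsskit("concentrations must be positive", "dsskit_error_bad_concentration")
  }
  pts <- data |>
    dplyr::group_by(.data$concentration_nM) |>
    dplyr::summarise(response = median(.data$response), .groups = "drop") |>
    dplyr::arrange(.data$concentration_nM)
  x <- log10(pts$concentration_nM)
  y <- pts$response
  n <- length(x)
  if (n < 3) {
    stop_dsskit("insufficient data: need >= 3 distinct concentrations",
                "dsskit_error_insufficient_data")
  }
  x_lo <- min(x)
  x_hi <- max(x)

  if (sd(y) < plateau_tol) {
    level <- clip(mean(y), 0, 100)
    return(new_dss_fit(level, level, (x_lo + x_hi) / 2, 1, TRUE,
                       sum((y - level)^2), n, x_lo, x_hi, pts))
  }

  lower <- c(0, 0, x_lo - 2, 0.1)
  upper <- c(100, 100, x_hi + 2, 10)
  rmin0 <- clip(min(y), 0, 100)
  rmax0 <- clip(max(y), 0, 100)
  m0 <- x[which.min(abs(y - (rmin0 + rmax0) / 2))]
  m0 <- clip(m0, lower[3], upper[3])

  # ordering r_min <= r_max is restored by clamping after each solve; a
  # candidate distorted by the clamp loses on its recomputed rss
  resid_fn <- function(p) {
    y - logistic_response(x, p[1], p[2], p[3], p[4])
  }

  rss_of <- function(p) sum((y - logistic_response(x, p[1], p[2], p[3], p[4]))^2)
  refine <- function(p0, ftol = 1e-15) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, ftol = ftol, ptol = ftol, gtol = 0)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    p <- fit$par
    if (p[1] > p[2]) p[1] <- p[2]  # restore asymptote ordering
    rss <- rss_of(p)
    # info 1-3: ftol/ptol conditions; 4: gradient orthogonality, which is
    # how an exact (zero-residual) solution reports
    list(p = p, rss = rss, converged = fit$info %in% 1:4 || rss < 1e-12)
  }

  candidates <- list()
  for (s0 in c(0.5, 1, 2)) {
    cand <- refine(c(rmin0, rmax0, m0, s0))
    if (!is.null(cand)) candidates[[length(candidates) + 1L]] <- cand
  }
  # the flat curve is always a candidate, so data with no dose trend (or a
  # decreasing one, which the s > 0 model cannot represent) settle there
  flat <- clip(mean(y), 0, 100)
  candidates[[length(candidates) + 1L]] <-
    list(p = c(flat, flat, (x_lo + x_hi) / 2, 1),
         rss = rss_of(c(flat, flat, 0, 1)), converged = TRUE)
  incumbent <- if (length(candidates) > 0) {
    min(vapply(candidates, function(cand) cand$rss, numeric(1)))
  } else Inf

  # deterministic coarse grid over (m, s); asymptotes per cell come from the
  # closed-form 2x2 linear solve (the model is linear in the asymptotes at
  # fixed m and s), vectorized over all cells
  grid <- grid_candidates(x, y, seq(lower[3], upper[3], length.out = 41),
                          c(0.3, 0.5, 1, 2, 3, 5, 8))
  # polish the best cell per slope when it beats the incumbent (top 2), and
  # always the overall best cell
  by_s <- split(seq_len(nrow(grid)), grid$s)
  best_per_s <- vapply(by_s, function(idx) idx[which.min(grid$rss[idx])], 0L)
  beating <- best_per_s[grid$rss[best_per_s] < incumbent]
  seeds <- unique(c(best_per_s[which.min(grid$rss[best_per_s])],
                    beating[order(grid$rss[beating])][seq_len(min(2, length(beating)))]))
  for (k in seeds) {
    g <- list(p = c(grid$a[k], grid$b[k], grid$m[k], grid$s[k]),
              rss = grid$rss[k], converged = FALSE)
    polished <- refine(g$p)
    candidates[[length(candidates) + 1L]] <-
      if (!is.null(polished)) polished else g
  }

  # an essentially perfect fit that is not at machine precision signals a
  # shallow decoy valley on (near-)noiseless data; a fine (m, s) scan seeds
  # a handful of extra polishes
  near_noiseless <- incumbent < 1e-4 * max(1, sum(y^2) / length(y))
  if (near_noiseless && incumbent > 1e-18) {
    fine <- grid_candidates(x, y, seq(lower[3], upper[3], by = 0.1),
                            c(0.3, 0.5, 0.8, 1, 1.5, 2, 3, 4, 5, 6, 8, 10))
    for (k in order(fine$rss)[seq_len(min(5, nrow(fine)))]) {
      polished <- refine(c(fine$a[k], fine$b[k], fine$m[k], fine$s[k]))
      if (!is.null(polished)) {
        candidates[[length(candidates) + 1L]] <- polished
      }
    }
  }
  if (length(candidates) == 0) {
    stop_dsskit("logistic fit failed for this curve", "dsskit_error_fit_failure")
  }

  # one restart from the incumbent helps the trust region settle fully
  rsss0 <- vapply(candidates, function(cand) cand$rss, numeric(1))
  again <- refine(candidates[[which.min(rsss0)]]$p)
  if (!is.null(again)) candidates[[length(candidates) + 1L]] <- again

  rsss <- vapply(candidates, function(cand) cand$rss, numeric(1))
  tol <- max(1e-14, 1e-9 * min(rsss))
  near <- which(rsss <= min(rsss) + tol)
  slopes <- vapply(candidates[near], function(cand) cand$p[4], numeric(1))
  ms <- vapply(candidates[near], function(cand) cand$p[3], numeric(1))
  pick <- near[order(slopes, ms)[1]]
  cand <- candidates[[pick]]
  new_dss_fit(cand$p[1], cand$p[2], cand$p[3], cand$p[4], cand$converged,
              cand$rss, n, x_lo, x_hi, pts)
}

new_dss_fit <- function(r_min, r_max, m, s, converged, rss, n_points,
                        x_lo, x_hi, data = NULL) {
  structure(
    list(r_min = unname(r_min), r_max = unname(r_max), m = unname(m),
         s = unname(s), converged = converged, rss = rss,
         n_points = n_points, x_lo = x_lo, x_hi = x_hi, data = data),
    class = "dss_fit"
  )
}

#' @export
print.dss_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<dss_fit> r_min = %.2f, r_max = %.2f, IC50 = %.3g nM ",
           "(m = %.3f), slope = %.3f\n  n = %d, rss = %.4g, converged: %s\n"),
    x$r_min, x$r_max, 10^x$m, x$m, x$s, x$n_points, x$rss, x$converged))
  invisible(x)
}

#' @export
predict.dss_fit <- function(object, x, ...) {
  logistic_response(x, object$r_min, object$r_max, object$m, object$s)
}

#' @export
tidy.dss_fit <- function(x, ...) {
  tibble(term = c("r_min", "r_max", "log10_ic50", "slope"),
         estimate = c(x$r_min, x$r_max, x$m, x$s))
}

#' @export
glance.dss_fit <- function(x, ...) {
  tibble(r_min = x$r_min, r_max = x$r_max, log10_ic50 = x$m,
         ic50_nM = 10^x$m, slope = x$s, rss = x$rss,
         n_points = x$n_points, converged = x$converged)
}

#' @export
autoplot.dss_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble(
    x = seq(object$x_lo - 0.5, object$x_hi + 0.5, length.out = n_grid)
  )
  grid$response <- predict(object, grid$x)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$response)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(
      data = tibble(x = log10(object$data$concentration_nM),
                    response = object$data$response),
      size = 2
    ) +
    ggplot2::labs(x = "log10 concentration (nM)", y = "inhibition (%)") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Fit logistic models to every curve of a long dose-response table
#'
#' Groups `data` by (sample, drug), fits each curve with [fit_logistic()] and
#' returns one row per curve. Curves with fewer than 3 distinct concentrations
#' get `NA` parameters (their scores propagate as missing downstream).
#'
#' @inheritParams collapse_replicates
#' @param ... Passed on to [fit_logistic()].
#' @return Tibble with columns `sample_id`, `drug_id`, `n_points`, `r_min`,
#'   `r_max`, `log10_ic50`, `slope`, `ic50_nM`, `converged`, `rss`, `x_lo`,
#'   `x_hi` (log10 nM bounds of the tested window for that curve).
#' @export
fit_curves <- function(data, ...) {
  data <- collapse_replicates(data)
  keys <- dplyr::distinct(data, .data$sample_id, .data$drug_id)
  fits <- purrr::pmap(keys, function(sample_id, drug_id) {
    curve <- data[data$sample_id == sample_id & data$drug_id == drug_id, ]
    fit <- tryCatch(fit_logistic(curve, ...),
                    dsskit_error_insufficient_data = function(e) NULL)
    if (is.null(fit)) {
      tibble(sample_id = sample_id, drug_id = drug_id,
             n_points = nrow(curve), r_min = NA_real_, r_max = NA_real_,
             log10_ic50 = NA_real_, slope = NA_real_, ic50_nM = NA_real_,
             converged = FALSE, rss = NA_real_,
             x_lo = log10(min(curve$concentration_nM)),
             x_hi = log10(max(curve$concentration_nM)))
    } else {
      tibble(sample_id = sample_id, drug_id = drug_id,
             n_points = fit$n_points, r_min = fit$r_min, r_max = fit$r_max,
             log10_ic50 = fit$m, slope = fit$s, ic50_nM = 10^fit$m,
             converged = fit$converged, rss = fit$rss,
             x_lo = fit$x_lo, x_hi = fit$x_hi)
    }
  })
  dplyr::bind_rows(fits)
}
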