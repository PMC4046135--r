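#' Standard dose grids
#'
#' `default_dose_grid()` is the 5-point 10-fold dilution series spanning a
#' 10,000-fold concentration range (1 to 10,000 nM by default), the layout
#' used for ex vivo patient-cell screens; `ccle_dose_grid()` is the 8-point
#' series 2.5, 8, 25, 80, 250, 800, 2,530, 8,000 nM used for the CCLE cell
#' line screens.
#'
#' @param n_points Number of dilution points (default 5).
#' @param fold Dilution factor between consecutive points (default 10).
#' @param top Highest concentration in nM (default 10000).
#' @return Numeric vector of concentrations in nM, ascending.
#' @export
default_dose_grid <- function(n_points = 5, fold = 10, top = 10000) {
  sort(top / fold^(seq_len(n_points) - 1))
}

#' @rdname default_dose_grid
#' @export
ccle_dose_grid <- function() {
  c(2.5, 8, 25, 80, 250, 800, 2530, 8000)
}

#' Simulate one dose-response curve
#'
#' Responses are the logistic model evaluated at the doses plus additive
#' Gaussian noise on the inhibition-% scale, clipped to \[0, 100\] (the
#' simplest noise model consistent with control-normalized plate readouts).
#' Deterministic given the seed.
#'
#' @inheritParams logistic_response
#' @param doses Concentrations in nM (default [default_dose_grid()]).
#' @param noise_sd Gaussian noise standard deviation in percent inhibition.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Tibble with columns `concentration_nM`, `response`.
#' @export
simulate_curve <- function(r_min = 0, r_max = 100, m = 2, s = 1,
                           doses = default_dose_grid(), noise_sd = 0,
                           seed = NULL) {
  stopifnot(all(doses > 0), noise_sd >= 0)
  mu <- logistic_response(log10(doses), r_min, r_max, m, s)
  if (noise_sd > 0) {
    if (is.null(seed)) {
      stop_dsskit("a seed is required when simulating with noise",
                  "dsskit_error_missing_seed")
    }
    mu <- withr::with_seed(seed, mu + rnorm(length(doses), sd = noise_sd))
  }
  tibble(concentration_nM = doses, response = clip(mu, 0, 100))
}

# true DSS1 for given parameters over a dose window, used to calibrate
# planted effects
true_dss1 <- function(r_min, r_max, m, s, doses, a_min = 10) {
  dss_from_params(r_min, r_max, m, s, log10(min(doses)), log10(max(doses)),
                  a_min = a_min, metric = "DSS1")
}

# draw per-drug background characteristics: weakly-to-modestly active
# compounds (low base scores, IC50 towards the top of the tested window), so
# low responses dominate as in real screens. The base activity is drawn on
# the score scale; each curve's top asymptote is later solved to match, so
# between-sample score variation stays symmetric and the responder detector
# is calibrated on unplanted cohorts.
draw_background_params <- function(n, x_hi) {
  tibble(r_min = 0,
         base_dss1 = runif(n, 7, 15),
         m = runif(n, x_hi - 2, x_hi - 1),
         s = runif(n, 1, 2))
}

# solve for planted parameters reaching a target true DSS1; r_max is tuned
# at mid-window IC50, falling back to shifting m down when r_max saturates
solve_planted_params <- function(target_dss1, doses, a_min = 10) {
  x_lo <- log10(min(doses)); x_hi <- log10(max(doses))
  m_mid <- (x_lo + x_hi) / 2
  f_rmax <- function(r) true_dss1(0, r, m_mid, 1, doses, a_min) - target_dss1
  if (f_rmax(100) >= 0) {
    r <- uniroot(f_rmax, c(a_min + 1e-6, 100), tol = 1e-9)$root
    return(list(r_min = 0, r_max = r, m = m_mid, s = 1))
  }
  f_m <- function(mm) true_dss1(0, 100, mm, 1, doses, a_min) - target_dss1
  if (f_m(x_lo - 2) < 0) return(list(r_min = 0, r_max = 100, m = x_lo - 2, s = 1))
  mm <- uniroot(f_m, c(x_lo - 2, m_mid), tol = 1e-9)$root
  list(r_min = 0, r_max = 100, m = mm, s = 1)
}

#' Simulate a screening cohort with known ground truth
#'
#' Generates a long dose-response table for `n_patients` patient and
#' `n_controls` control samples over `n_drugs` drugs. Background curves are
#' mostly inactive (low top asymptotes, IC50 near the upper window edge), as
#' in real screens. Planted responder sub-groups elevate the true DSS1 of the
#' named patient samples on the named drug by `effect` score units above the
#' background mean (parameters solved so the planted truth is exact before
#' noise). Drugs sharing a planted mechanism-of-action class receive
#' correlated response profiles through a shared per-sample latent factor.
#' Everything is a pure function of the arguments and `seed`.
#'
#' @param n_patients,n_controls,n_drugs Cohort dimensions.
#' @param doses Dose grid in nM (default the 5-point 10-fold series).
#' @param noise_sd Response noise, percent inhibition (default 5).
#' @param planted_subgroups List of `list(drug =, responders =, effect =)`
#'   entries; responder ids must be patient sample ids.
#' @param planted_moa Optional named character vector `drug_id -> class`
#'   inducing correlated profiles within a class.
#' @param seed Integer seed (required).
#' @return List with `data` (long tibble: `sample_id`, `drug_id`,
#'   `concentration_nM`, `response`), `truth` (per-curve parameter tibble
#'   with true DSS1), `sample_info` (tibble `sample_id`, `group`), and the
#'   generator settings.
#' @export
simulate_cohort <- function(n_patients = 20, n_controls = 4, n_drugs = 8,
                            doses = default_dose_grid(), noise_sd = 5,
                            planted_subgroups = list(), planted_moa = NULL,
                            seed) {
  stopifnot(n_patients >= 1, n_controls >= 1, n_drugs >= 1, noise_sd >= 0)
  patients <- sprintf("patient_%02d", seq_len(n_patients))
  controls <- sprintf("control_%02d", seq_len(n_controls))
  samples <- c(patients, controls)
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  for (pg in planted_subgroups) {
    stopifnot(pg$drug %in% drugs, all(pg$responders %in% patients))
  }
  x_hi <- log10(max(doses))

  withr::with_seed(seed, {
    drug_params <- dplyr::bind_cols(tibble(drug_id = drugs),
                                    draw_background_params(n_drugs, x_hi))
    grid <- tidyr::expand_grid(sample_id = samples, drug_id = drugs)
    truth <- dplyr::left_join(grid, drug_params, by = "drug_id")
    # between-sample variation is symmetric on the score scale: a shared
    # per-sample sensitivity effect (overall sample quality / cellular
    # composition) plus independent bounded per-curve biological noise (the
    # bounded support keeps the truth free of floor/ceiling truncation that
    # would distort its symmetry); each curve's top asymptote is solved so
    # its true DSS1 hits the target exactly
    sample_effect <- setNames(runif(length(samples), -3, 3), samples)
    target <- pmax(truth$base_dss1 + sample_effect[truth$sample_id] +
                     runif(nrow(truth), -6, 6), 0.2)
    truth$r_max <- vapply(seq_len(nrow(truth)), function(i) {
      f <- function(r) true_dss1(0, r, truth$m[i], truth$s[i], doses) - target[i]
      if (f(100) <= 0) return(100)
      uniroot(f, c(10 + 1e-9, 100), tol = 1e-8)$root
    }, numeric(1))

    # shared latent factor per (planted MoA class, sample) -> correlated
    # top asymptotes for drugs of the same class
    if (!is.null(planted_moa)) {
      classes <- unique(planted_moa)
      latent <- matrix(rnorm(length(classes) * length(samples), sd = 18),
                       nrow = length(samples),
                       dimnames = list(samples, classes))
      in_class <- truth$drug_id %in% names(planted_moa)
      cls <- planted_moa[truth$drug_id[in_class]]
      z <- latent[cbind(truth$sample_id[in_class], cls)]
      truth$r_max[in_class] <- clip(truth$r_max[in_class] + 30 + z, 0, 100)
      # the shared factor also moves potency, so class-mates co-vary in
      # both efficacy and IC50
      truth$m[in_class] <- truth$m[in_class] - 2 - z / 60
    }

    # planted responder sub-groups: exact parameter solve per planted curve
    for (pg in planted_subgroups) {
      bg_rows <- truth$drug_id == pg$drug &
        !(truth$sample_id %in% pg$responders)
      bg_mean <- mean(true_dss1(truth$r_min[bg_rows], truth$r_max[bg_rows],
                                truth$m[bg_rows], truth$s[bg_rows], doses))
      pp <- solve_planted_params(bg_mean + pg$effect, doses)
      hit <- truth$drug_id == pg$drug & truth$sample_id %in% pg$responders
      truth$r_min[hit] <- pp$r_min
      truth$r_max[hit] <- pp$r_max
      truth$m[hit] <- pp$m
      truth$s[hit] <- pp$s
    }

    truth$true_dss1 <- true_dss1(truth$r_min, truth$r_max, truth$m, truth$s,
                                 doses)
    x <- log10(doses)
    data <- truth |>
      dplyr::rowwise() |>
      dplyr::reframe(
        sample_id = .data$sample_id, drug_id = .data$drug_id,
        concentration_nM = doses,
        response = clip(
          logistic_response(x, .data$r_min, .data$r_max, .data$m, .data$s) +
            if (noise_sd > 0) rnorm(length(doses), sd = noise_sd) else 0,
          0, 100)
      )
    list(
      data = data,
      truth = truth,
      sample_info = tibble(sample_id = samples,
                           group = rep(c("patient", "control"),
                                       c(n_patients, n_controls))),
      planted_subgroups = planted_subgroups,
      planted_moa = planted_moa,
      doses = doses,
      noise_sd = noise_sd,
      seed = seed
    )
  })
}

#' Simulate a binary drug-target matrix with optional planted addiction
#'
#' Entries are independent Bernoulli(`density`); a planted kinase column can
#' be forced to match a stated drug subset exactly (those drugs target it,
#' no others do). Deterministic given the seed.
#'
#' @param n_drugs,n_kinases Matrix dimensions.
#' @param density Target density in (0, 1), exclusive.
#' @param planted_addiction Optional `list(kinase =, drugs =)`; `kinase`
#'   must be one of the generated kinase ids, `drugs` a subset of drug ids.
#' @param seed Integer seed (required).
#' @return List with `targets` (binary drugs x kinases matrix with dimnames)
#'   and `truth` (the planted addiction, or `NULL`).
#' @export
simulate_target_matrix <- function(n_drugs, n_kinases, density,
                                   planted_addiction = NULL, seed) {
  if (!(density > 0 && density < 1)) {
    stop_dsskit("density must be strictly inside (0, 1)",
                "dsskit_error_bad_input")
  }
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  kinases <- sprintf("KIN%02d", seq_len(n_kinases))
  withr::with_seed(seed, {
    m <- matrix(stats::rbinom(n_drugs * n_kinases, 1, density),
                nrow = n_drugs, dimnames = list(drugs, kinases))
    if (!is.null(planted_addiction)) {
      stopifnot(planted_addiction$kinase %in% kinases,
                all(planted_addiction$drugs %in% drugs))
      m[, planted_addiction$kinase] <- 0
      m[planted_addiction$drugs, planted_addiction$kinase] <- 1
    }
    list(targets = m, truth = planted_addiction)
  })
}
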