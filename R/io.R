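#' Read a long-format dose-response table
#'
#' Reads a CSV with columns `sample_id`, `drug_id`, `concentration_nM`,
#' `response` (and optionally `replicate`), validates it, collapses technical
#' replicates to per-dose medians and sorts points by ascending concentration
#' within each (sample, drug) curve.
#'
#' @param path Path to a CSV file (UTF-8, comma separated, header required,
#'   concentrations in nM). Lines starting with `#` are ignored.
#' @return Tibble with one row per (sample, drug, concentration).
#' @export
read_drt <- function(path) {
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(data) == 0) {
    stop_dsskit(sprintf("dose-response file '%s' is empty", path),
                "dsskit_error_empty_file")
  }
  check_columns(data, c("sample_id", "drug_id", "concentration_nM", "response"),
                sprintf("dose-response file '%s'", path))
  bad <- which(!is.finite(data$concentration_nM) | data$concentration_nM <= 0)
  if (length(bad) > 0) {
    stop_dsskit(
      sprintf("non-positive concentration in '%s' at data row(s) %s",
              path, paste(head(bad, 5), collapse = ", ")),
      "dsskit_error_bad_concentration"
    )
  }
  collapse_replicates(data)
}

score_matrix_class <- "dss_score_matrix"

#' Construct a score matrix from long per-curve scores
#'
#' A score matrix is a wide tibble (one row per sample, one column per drug)
#' carrying the scoring metric and its settings as attributes. Missing cells
#' (curves that could not be fitted or scored) are `NA`.
#'
#' @param scores Long tibble with columns `sample_id`, `drug_id`, `score`.
#' @param metric One of `"DSS1"`, `"DSS2"`, `"DSS3"`, `"dDSS"`, `"AA"`, `"IC50"`.
#' @param settings Named list of scoring settings (e.g. `a_min`, `x_lo`, `x_hi`).
#' @return A `dss_score_matrix` tibble.
#' @export
as_score_matrix <- function(scores, metric, settings = list()) {
  check_columns(scores, c("sample_id", "drug_id", "score"), "score table")
  metric <- match.arg(metric, c("DSS1", "DSS2", "DSS3", "dDSS", "AA", "IC50"))
  wide <- tidyr::pivot_wider(scores[, c("sample_id", "drug_id", "score")],
                             names_from = "drug_id", values_from = "score")
  new_score_matrix(wide, metric, settings)
}

new_score_matrix <- function(wide, metric, settings) {
  structure(wide,
            metric = metric,
            settings = settings,
            class = c(score_matrix_class, class(tibble())))
}

#' @export
print.dss_score_matrix <- function(x, ...) {
  cat(sprintf("<dss_score_matrix> metric: %s, %d samples x %d drugs\n",
              attr(x, "metric"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Metric and settings of a score matrix
#' @param x A `dss_score_matrix`.
#' @return `score_metric()` the metric string; `score_settings()` the settings list.
#' @export
score_metric <- function(x) attr(x, "metric")

#' @rdname score_metric
#' @export
score_settings <- function(x) attr(x, "settings")

#' Pivot a score matrix to long form
#' @param x A `dss_score_matrix`.
#' @return Tibble with columns `sample_id`, `drug_id`, `score`.
#' @export
score_matrix_long <- function(x) {
  tidyr::pivot_longer(as_tibble(x), -"sample_id",
                      names_to = "drug_id", values_to = "score")
}

# samples x drugs numeric matrix view (rownames = sample ids)
score_matrix_values <- function(x) {
  m <- as.matrix(as_tibble(x)[, -1, drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' Write / read a score matrix CSV
#'
#' The file starts with `#`-prefixed comment lines recording the metric and a
#' JSON rendering of the settings, followed by a plain CSV (samples in rows,
#' drugs in columns, missing cells empty). `read_score_matrix()` restores the
#' matrix, its metric and settings, so write-then-read round-trips exactly.
#'
#' @param x A `dss_score_matrix`.
#' @param path Output (input) file path.
#' @return `write_score_matrix()` returns `path` invisibly;
#'   `read_score_matrix()` returns a `dss_score_matrix`.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, score_matrix_class))
  header <- c(
    "# dsskit score matrix v1",
    sprintf("# metric: %s", attr(x, "metric")),
    sprintf("# settings: %s",
            jsonlite::toJSON(attr(x, "settings"), auto_unbox = TRUE, digits = NA))
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_dsskit(sprintf("cannot write score matrix to '%s'", path),
                "dsskit_error_io")
  })
  writeLines(header, con)
  close(con)
  readr::write_csv(as_tibble(x), path, na = "", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, n = 10L)
  comments <- grep("^#", lines, value = TRUE)
  metric <- sub("^# metric: ", "", grep("^# metric: ", comments, value = TRUE)[1])
  settings_json <- sub("^# settings: ", "",
                       grep("^# settings: ", comments, value = TRUE)[1])
  settings <- if (is.na(settings_json)) list() else
    jsonlite::fromJSON(settings_json, simplifyVector = TRUE)
  wide <- readr::read_csv(path, comment = "#", na = "", show_col_types = FALSE,
                          progress = FALSE)
  new_score_matrix(wide, metric, as.list(settings))
}
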