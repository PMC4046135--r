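#' Read or write a pipeline configuration
#'
#' Configurations are flat key-value YAML files with a schema version. A
#' config round-trips through its file form: `read_run_config(write_run_config(cfg))`
#' returns an equivalent list. Unknown keys are an error so typos fail early.
#'
#' @param config Named list of settings (see [run_pipeline()]).
#' @param path File path.
#' @return `read_run_config()`: the config list; `write_run_config()`:
#'   `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

config_keys <- c(
  "schema_version", "input", "controls", "metric", "a_min", "window_nM",
  "alpha", "n_perm", "seed", "out_dir", "moa", "targets", "expressed",
  "kiss_threshold", "corr_threshold", "simulate", "stages"
)

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown) > 0) {
    stop_dsskit(sprintf("unknown config key '%s'", unknown[1]),
                "dsskit_error_bad_config")
  }
  defaults <- list(schema_version = 1L, metric = "DSS2", a_min = 10,
                   alpha = 0.05, n_perm = 10000, kiss_threshold = 5,
                   corr_threshold = 0.5,
                   stages = c("input", "fit", "score", "differential",
                              "subgroups", "cluster", "kiss"))
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$seed)) {
    stop_dsskit("config must set an explicit seed", "dsskit_error_bad_config")
  }
  cfg
}

run_stage <- function(manifest, name, enabled, fun, on_fail = NULL) {
  if (!enabled) return(manifest)
  res <- tryCatch(fun(), error = function(e) e)
  if (inherits(res, "error")) {
    manifest$stages[[name]] <- "FAILED"
    manifest$error <- conditionMessage(res)
    if (!is.null(on_fail)) on_fail(manifest)
    stop_dsskit(sprintf("pipeline stage '%s' failed: %s",
                        name, conditionMessage(res)),
                "dsskit_error_stage_failure",
                manifest = manifest)
  }
  manifest$stages[[name]] <- "completed"
  manifest
}

#' Run the scoring pipeline end to end
#'
#' Executes the enabled stages in order: read (or simulate) the dose-response
#' table, fit logistic models, score, differential scoring against controls,
#' responder sub-group detection, drug-profile clustering (against
#' mechanism-of-action classes when provided), and KISS target-addiction
#' scoring (when a target matrix is provided). Every intermediate table is
#' written as CSV under `out_dir`, and a `manifest.json` records the package
#' version, a hash of the config, the seed and the stage outcomes. Re-running
#' with the same config reproduces the numeric outputs exactly.
#'
#' Config keys: `input` (dose-response CSV path) or `simulate` (list of
#' [simulate_cohort()] arguments), `controls` (character vector of control
#' sample ids; required for the differential/subgroups/kiss stages),
#' `metric`, `a_min`, `window_nM`, `alpha`, `n_perm`, `seed` (required),
#' `out_dir`, `moa` (annotation CSV with drug_id, moa_class), `targets`
#' (drug x kinase CSV with a drug_id column), `expressed` (file of kinase
#' ids, one per line), `kiss_threshold`, `corr_threshold`, `stages`.
#'
#' @param config A config list or the path to a YAML config file.
#' @return Invisibly, a list with the computed artifacts (`fits`, `scores`,
#'   `ddss`, `subgroups`, `clustering`, `kiss`) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enabled <- function(stage) stage %in% cfg$stages
  manifest <- list(
    package = "dsskit",
    version = as.character(packageVersion("dsskit")),
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    stages = list()
  )
  art <- list()
  finish <- function(m = manifest) {
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  need_ddss <- any(c("differential", "subgroups", "kiss") %in% cfg$stages)
  if (need_ddss && is.null(cfg$controls)) {
    manifest$stages[["differential"]] <- "FAILED"
    finish()
    stop_dsskit(
      "config field 'controls' is missing but differential scoring is enabled",
      "dsskit_error_bad_config"
    )
  }

  manifest <- run_stage(manifest, "input", TRUE, function() {
    if (!is.null(cfg$simulate)) {
      sim <- do.call(simulate_cohort,
                     modifyList(cfg$simulate, list(seed = cfg$seed)))
      art$data <<- sim$data
      art$sim_truth <<- sim$truth
      readr::write_csv(sim$data, file.path(out_dir, "dose_response.csv"),
                       progress = FALSE)
    } else {
      if (is.null(cfg$input)) stop("neither 'input' nor 'simulate' given")
      art$data <<- read_drt(cfg$input)
    }
    invisible(NULL)
  }, on_fail = finish)

  manifest <- run_stage(manifest, "fit", enabled("fit"), function() {
    art$fits <<- fit_curves(art$data)
    readr::write_csv(art$fits, file.path(out_dir, "fits.csv"),
                     progress = FALSE)
  }, on_fail = finish)

  manifest <- run_stage(manifest, "score", enabled("score"), function() {
    art$scores <<- score_curves(art$fits, metric = cfg$metric,
                                a_min = cfg$a_min, window = cfg$window_nM,
                                data = art$data)
    write_score_matrix(art$scores, file.path(out_dir, "scores.csv"))
  }, on_fail = finish)

  manifest <- run_stage(manifest, "differential", enabled("differential"),
                        function() {
    art$ddss <<- differential_scores(art$scores, cfg$controls)
    write_score_matrix(art$ddss, file.path(out_dir, "ddss.csv"))
  }, on_fail = finish)

  manifest <- run_stage(manifest, "subgroups", enabled("subgroups"), function() {
    art$subgroups <<- detect_responder_subgroups(art$ddss, alpha = cfg$alpha)
    flat <- art$subgroups
    flat$responders <- vapply(flat$responders, paste, character(1),
                              collapse = ";")
    readr::write_csv(flat, file.path(out_dir, "subgroups.csv"),
                     progress = FALSE)
  }, on_fail = finish)

  manifest <- run_stage(manifest, "cluster", enabled("cluster"), function() {
    moa <- if (!is.null(cfg$moa)) {
      readr::read_csv(cfg$moa, show_col_types = FALSE, progress = FALSE)
    } else NULL
    prof <- if (!is.null(art$ddss)) art$ddss else art$scores
    art$clustering <<- cluster_drug_profiles(prof, moa = moa)
    readr::write_csv(art$clustering$partition,
                     file.path(out_dir, "clusters.csv"), progress = FALSE)
    export_newick(art$clustering$tree, file.path(out_dir, "dendrogram.nwk"))
    if (!is.null(art$clustering$indices)) {
      readr::write_csv(art$clustering$indices,
                       file.path(out_dir, "cluster_indices.csv"),
                       progress = FALSE)
    }
  }, on_fail = finish)

  manifest <- run_stage(manifest, "kiss",
                        enabled("kiss") && !is.null(cfg$targets), function() {
    targets <- as.data.frame(readr::read_csv(cfg$targets,
                                             show_col_types = FALSE,
                                             progress = FALSE))
    tm <- as.matrix(targets[, -1, drop = FALSE])
    rownames(tm) <- targets[[1]]
    expressed <- if (!is.null(cfg$expressed)) readLines(cfg$expressed) else NULL
    art$kiss <<- kiss_profiles(art$ddss, binarize_targets(tm),
                               alpha = cfg$alpha)
    readr::write_csv(art$kiss, file.path(out_dir, "kiss.csv"),
                     progress = FALSE)
    for (sid in unique(art$kiss$sample_id)) {
      prof <- art$kiss[art$kiss$sample_id == sid, ]
      net <- addiction_network(prof, binarize_targets(tm),
                               kiss_threshold = cfg$kiss_threshold,
                               corr_threshold = cfg$corr_threshold,
                               expressed = expressed)
      export_network(net, file.path(out_dir, paste0("network_", sid, ".sif")),
                     "SIF")
      export_network(net,
                     file.path(out_dir, paste0("network_", sid, ".graphml")),
                     "GraphML")
    }
  }, on_fail = finish)

  finish()
  invisible(c(art, list(manifest = manifest)))
}
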