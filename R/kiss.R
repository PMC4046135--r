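#' Binarize a drug-target affinity matrix
#'
#' Affinity matrices (e.g. dissociation constants in nM) are thresholded so
#' that affinity below `threshold` counts as "targets". Binary 0/1 matrices
#' pass through unchanged.
#'
#' @param targets Drugs x kinases numeric matrix with dimnames.
#' @param threshold Affinity threshold in nM (default 1000).
#' @return Binary 0/1 matrix of the same shape.
#' @export
binarize_targets <- function(targets, threshold = 1000) {
  stopifnot(is.matrix(targets), !is.null(rownames(targets)),
            !is.null(colnames(targets)))
  if (all(targets %in% c(0, 1))) return(targets)
  1 * (targets < threshold)
}

#' Kinase inhibition sensitivity score (KISS) profile for one sample
#'
#' Aggregates a sample's differential drug sensitivity scores over the
#' selective inhibitors of each kinase target: for kinase `k`,
#' \deqn{KISS_k = \frac{1}{n_k} \sum_{i} dDSS_i}
#' over the `n_k` eligible inhibitors `i` that target `k`. An inhibitor is
#' eligible when its response distribution across the cohort shows
#' significant positive skewness (one-sided D'Agostino `p < alpha`), i.e.
#' when it is selective for a sample sub-group rather than broadly toxic.
#' Kinases with no eligible targeting inhibitor are absent from the profile
#' (not zero). The `1/n_k` averaging keeps kinases with different inhibitor
#' coverage comparable; set `aggregate = "sum"` for the raw sum.
#'
#' @param ddss Named numeric vector of dDSS values for one sample (names are
#'   drug ids), or a two-column tibble `drug_id`, `ddss`.
#' @param targets Binary drugs x kinases matrix (see [binarize_targets()]).
#' @param skew_p Named numeric vector of per-drug one-sided skewness
#'   p-values.
#' @param alpha Eligibility threshold on `skew_p` (default 0.05).
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return Tibble with columns `kinase_id`, `kiss`, `n_contributing`. Empty
#'   (with a warning) when no inhibitor is eligible.
#' @export
kiss_profile <- function(ddss, targets, skew_p, alpha = 0.05,
                         aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(ddss)) {
    check_columns(ddss, c("drug_id", "ddss"), "ddss table")
    ddss <- setNames(ddss$ddss, ddss$drug_id)
  }
  drugs <- intersect(names(ddss), rownames(targets))
  drugs <- intersect(drugs, names(skew_p))
  eligible <- drugs[!is.na(skew_p[drugs]) & skew_p[drugs] < alpha &
                      !is.na(ddss[drugs])]
  if (length(eligible) == 0) {
    warn("no eligible (significantly selective) inhibitors: empty KISS profile")
    return(tibble(kinase_id = character(0), kiss = numeric(0),
                  n_contributing = integer(0)))
  }
  sub <- targets[eligible, , drop = FALSE]
  n_k <- colSums(sub)
  hit <- n_k > 0
  total <- as.numeric(ddss[eligible] %*% sub[, hit, drop = FALSE])
  kiss <- if (aggregate == "mean") total / n_k[hit] else total
  tibble(kinase_id = colnames(sub)[hit], kiss = unname(kiss),
         n_contributing = as.integer(n_k[hit]))
}

#' KISS profiles for every sample of a dDSS matrix
#'
#' Computes the per-drug eligibility (one-sided D'Agostino skewness test on
#' each drug's dDSS distribution across all samples) once, then a
#' [kiss_profile()] per sample.
#'
#' @param x A `dss_score_matrix` with metric dDSS.
#' @param targets Binary drugs x kinases matrix.
#' @param alpha Eligibility threshold (default 0.05).
#' @param aggregate Passed to [kiss_profile()].
#' @return Tibble with columns `sample_id`, `kinase_id`, `kiss`,
#'   `n_contributing`.
#' @export
kiss_profiles <- function(x, targets, alpha = 0.05,
                          aggregate = c("mean", "sum")) {
  stopifnot(inherits(x, score_matrix_class))
  aggregate <- match.arg(aggregate)
  vals <- score_matrix_values(x)
  skew_p <- vapply(colnames(vals), function(drug) {
    tryCatch(agostino_test(vals[, drug], "greater")$p.value,
             dsskit_error = function(e) NA_real_)
  }, numeric(1))
  purrr::map_dfr(rownames(vals), function(sid) {
    prof <- suppressWarnings(
      kiss_profile(vals[sid, ], targets, skew_p, alpha = alpha,
                   aggregate = aggregate)
    )
    if (nrow(prof) == 0) return(prof)
    dplyr::bind_cols(tibble(sample_id = sid), prof)
  })
}

#' Kinase addiction network for one KISS profile
#'
#' Nodes are the kinases whose KISS exceeds `kiss_threshold` (intersected
#' with the `expressed` kinase list when given, since a sample cannot be
#' addicted to a kinase it does not express), annotated with their KISS.
#' Edges connect kinases whose drug-selectivity columns in the target matrix
#' have Spearman rank correlation above `corr_threshold`, i.e. kinases hit by
#' similar sets of inhibitors. The network is undirected without self-edges;
#' an empty network is allowed.
#'
#' @param profile A [kiss_profile()] tibble (`kinase_id`, `kiss`, ...).
#' @param targets Binary drugs x kinases matrix.
#' @param kiss_threshold Minimum KISS for a node (default 5).
#' @param corr_threshold Minimum selectivity-profile correlation for an edge
#'   (default 0.5).
#' @param expressed Optional character vector of expressed kinases.
#' @return An [igraph::make_graph()] undirected graph with node attribute
#'   `kiss` and edge attribute `rho`.
#' @export
addiction_network <- function(profile, targets, kiss_threshold = 5,
                              corr_threshold = 0.5, expressed = NULL) {
  nodes <- profile$kinase_id[profile$kiss > kiss_threshold]
  if (!is.null(expressed)) nodes <- intersect(nodes, expressed)
  nodes <- intersect(nodes, colnames(targets))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (length(nodes) > 0) {
    g <- igraph::add_vertices(g, length(nodes), name = nodes,
                              kiss = profile$kiss[match(nodes, profile$kinase_id)])
    if (length(nodes) > 1) {
      rho <- suppressWarnings(
        cor(targets[, nodes, drop = FALSE], method = "spearman")
      )
      edges <- which(upper.tri(rho) & rho > corr_threshold, arr.ind = TRUE)
      if (nrow(edges) > 0) {
        g <- igraph::add_edges(
          g, as.vector(t(cbind(edges[, 1], edges[, 2]))),
          rho = rho[edges]
        )
      }
    }
  }
  g
}

#' Export an addiction network to SIF or GraphML
#'
#' SIF writes one `kinase_a pp kinase_b` line per edge plus bare lines for
#' isolated nodes (loadable by standard network viewers); GraphML keeps the
#' KISS node attribute and the correlation edge attribute.
#'
#' @param network An igraph graph (see [addiction_network()]).
#' @param path Output file path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("SIF", "GraphML")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) {
                       stop_dsskit("unknown network export format",
                                   "dsskit_error_bad_format")
                     })
  if (format == "GraphML") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    names <- igraph::V(network)$name
    el <- igraph::as_edgelist(network)
    lines <- character(0)
    if (nrow(el) > 0) {
      lines <- sprintf("%s pp %s", el[, 1], el[, 2])
    }
    isolated <- setdiff(names, unique(as.vector(el)))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}
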