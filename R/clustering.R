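#' Spearman rank-correlation distance between drug response profiles
#'
#' Distance `d(i, j) = 1 - rho_spearman(profile_i, profile_j)` in \[0, 2\],
#' computed over pairwise-complete samples. Pairs overlapping in fewer than
#' `min_overlap` samples are set to the maximum finite distance in the matrix
#' (conservative separation). A drug whose observed values are constant has no
#' rank variance and raises an error naming the drug.
#'
#' @param profiles Numeric matrix, drugs in rows, samples in columns (row
#'   names are drug ids), or a `dss_score_matrix` (then transposed
#'   internally).
#' @param min_overlap Minimum number of mutually observed samples per pair.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
spearman_distance <- function(profiles, min_overlap = 3) {
  if (inherits(profiles, score_matrix_class)) {
    profiles <- t(score_matrix_values(profiles))
  }
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2, ncol(profiles) >= 3)
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("item_", seq_len(nrow(profiles)))
  }
  const <- apply(profiles, 1, function(v) {
    v <- v[is.finite(v)]
    length(v) > 0 && sd(v) == 0
  })
  if (any(const)) {
    stop_dsskit(
      sprintf("constant response profile for drug '%s': rank correlation undefined",
              rownames(profiles)[which(const)[1]]),
      "dsskit_error_constant_profile"
    )
  }
  rho <- suppressWarnings(
    cor(t(profiles), method = "spearman", use = "pairwise.complete.obs")
  )
  d <- 1 - rho
  obs <- !is.na(profiles)
  overlap <- obs %*% t(obs)
  d[overlap < min_overlap] <- NA
  if (anyNA(d)) {
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative Ward linkage applied directly to the supplied dissimilarities
#' (the classic un-squared dialect, `hclust(method = "ward.D")`); the
#' rank-based Spearman distance has no Euclidean embedding, so the
#' squared-Euclidean Ward variant is not meaningful here. The result is
#' deterministic given the input.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return An [stats::hclust] dendrogram.
#' @export
ward_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8)) {
      stop_dsskit("distance matrix must be symmetric", "dsskit_error_bad_input")
    }
    d <- as.dist(d)
  }
  hclust(d, method = "ward.D")
}

#' Adaptive branch cut of a dendrogram
#'
#' A simplified dynamic branch-cutting rule: a static cut at
#' `cut_fraction * max(merge height)` defines candidate branches; branches of
#' at least `min_cluster_size` items become core clusters, remaining items
#' are joined to the nearest core by average distance, and if no core exists
#' (no branch separates below the cut, e.g. all items mutually equidistant)
#' everything forms a single cluster.
#'
#' @param hc An [stats::hclust] tree.
#' @param d The distance matrix the tree was built from (used to attach
#'   leftover items).
#' @param min_cluster_size Minimum cluster size (default 3, mirroring the
#'   exclusion of mechanism-of-action classes with fewer than three drugs).
#' @param cut_fraction Fraction of the maximum merge height at which the
#'   static cut is made (default 0.99).
#' @return Partition tibble with columns `item_id`, `cluster`.
#' @export
cut_dynamic <- function(hc, d, min_cluster_size = 3, cut_fraction = 0.99) {
  labels <- hc$labels %||% as.character(seq_along(hc$order))
  n <- length(labels)
  if (is.matrix(d)) dmat <- d else dmat <- as.matrix(d)
  single <- function() tibble(item_id = labels, cluster = "C1")
  if (n < min_cluster_size) return(single())
  assign0 <- cutree(hc, h = cut_fraction * max(hc$height))
  sizes <- table(assign0)
  cores <- names(sizes)[sizes >= min_cluster_size]
  if (length(cores) == 0) return(single())
  cluster <- rep(NA_character_, n)
  for (i in seq_along(cores)) {
    cluster[assign0 == as.integer(cores[i])] <- paste0("C", i)
  }
  leftover <- which(is.na(cluster))
  for (i in leftover) {
    avg <- vapply(seq_along(cores), function(k) {
      mean(dmat[i, which(cluster == paste0("C", k))])
    }, numeric(1))
    cluster[i] <- paste0("C", which.min(avg))
  }
  tibble(item_id = labels, cluster = cluster)
}

#' External cluster-evaluation indices of two partitions
#'
#' Pair-counting comparison over all item pairs (together in both, in the
#' first only, in the second only, in neither): Rand, Hubert-Arabie adjusted
#' Rand, Jaccard and Fowlkes-Mallows indices. Identical partitions score 1 on
#' all four; the adjusted Rand is approximately 0 for random partitions and
#' may be negative for worse-than-chance agreement.
#'
#' @param p1,p2 Partitions over the same item set, each a tibble
#'   (`item_id`, `cluster`) or a named vector of cluster labels.
#' @return One-row tibble with `rand`, `adjusted_rand`, `jaccard`,
#'   `fowlkes_mallows`.
#' @export
partition_indices <- function(p1, p2) {
  a <- as_partition_vector(p1, "p1")
  b <- as_partition_vector(p2, "p2")
  if (!setequal(names(a), names(b))) {
    stop_dsskit("partitions must cover the same item set",
                "dsskit_error_item_mismatch")
  }
  idx <- partition_index_core(a, b[names(a)])
  tibble(rand = idx[["rand"]], adjusted_rand = idx[["adjusted_rand"]],
         jaccard = idx[["jaccard"]], fowlkes_mallows = idx[["fowlkes_mallows"]])
}

# fast path: aligned label vectors in, named numeric out
partition_index_core <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  s11 <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  s10 <- sum_a - s11
  s01 <- sum_b - s11
  s00 <- total - s11 - s10 - s01
  rand <- (s11 + s00) / total
  jaccard <- if (s11 + s10 + s01 == 0) 1 else s11 / (s11 + s10 + s01)
  fm <- if (sum_a == 0 || sum_b == 0) {
    if (sum_a == sum_b) 1 else 0
  } else {
    s11 / sqrt(sum_a * sum_b)
  }
  expected <- sum_a * sum_b / total
  denom <- 0.5 * (sum_a + sum_b) - expected
  ari <- if (denom == 0) {
    if (abs(s11 - expected) < 1e-12) 1 else 0
  } else {
    (s11 - expected) / denom
  }
  c(rand = rand, adjusted_rand = ari, jaccard = jaccard,
    fowlkes_mallows = fm)
}

#' Permutation test for a difference in cluster-evaluation indices
#'
#' Tests whether partition `partition_a` matches the reference classes better
#' than `partition_b` does. The observed difference is
#' `index(a, reference) - index(b, reference)` for each index. The null is
#' built by shuffling item labels within each observed partition
#' independently (cluster counts and sizes preserved), recomputing the
#' difference between the shuffled solutions, and the empirical p-value is
#' the fraction of the `n_perm` null differences at least as large as the
#' observed one. Reference classes with fewer than `min_class_size` items are
#' removed (with their items) before comparison.
#'
#' @param partition_a,partition_b Partitions (tibble or named vector) over a
#'   common item set.
#' @param reference Reference partition (e.g. mechanism-of-action classes).
#' @param n_perm Number of permutations (default 10000; fewer than 100 logs a
#'   warning).
#' @param seed Integer seed (required: every stochastic operation is seeded).
#' @param min_class_size Minimum reference class size (default 3).
#' @return Tibble with one row per index: `index`, `observed_a`,
#'   `observed_b`, `difference`, `p.value`.
#' @export
index_permutation_test <- function(partition_a, partition_b, reference,
                                   n_perm = 10000, seed, min_class_size = 3) {
  if (n_perm < 100) warn("n_perm < 100: permutation p-values will be coarse")
  a <- as_partition_vector(partition_a, "partition_a")
  b <- as_partition_vector(partition_b, "partition_b")
  ref <- as_partition_vector(reference, "reference")
  keep_classes <- names(table(ref))[table(ref) >= min_class_size]
  ref <- ref[ref %in% keep_classes]
  if (length(unique(ref)) < 2) {
    stop_dsskit("reference must keep at least 2 classes of sufficient size",
                "dsskit_error_bad_reference")
  }
  items <- intersect(names(ref), intersect(names(a), names(b)))
  a <- a[items]; b <- b[items]; ref <- ref[items]
  idx_names <- c("rand", "adjusted_rand", "jaccard", "fowlkes_mallows")
  obs_a <- partition_index_core(a, ref)[idx_names]
  obs_b <- partition_index_core(b, ref)[idx_names]
  obs_diff <- obs_a - obs_b
  au <- unname(a)
  bu <- unname(b)
  null_diff <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- partition_index_core(sample(au), ref)[idx_names]
      ib <- partition_index_core(sample(bu), ref)[idx_names]
      ia - ib
    }, numeric(length(idx_names)))
  })
  p <- vapply(seq_along(idx_names), function(j) {
    sum(null_diff[j, ] >= obs_diff[j]) / n_perm
  }, numeric(1))
  tibble(index = idx_names, observed_a = unname(obs_a),
         observed_b = unname(obs_b), difference = unname(obs_diff),
         p.value = p)
}

#' Cluster drugs by their differential response profiles
#'
#' Convenience wrapper: Spearman distance over drug profiles, Ward linkage,
#' adaptive branch cut, and (when mechanism-of-action annotations are given)
#' the external index comparison against the annotation classes.
#'
#' @param x A `dss_score_matrix` (typically dDSS), samples x drugs.
#' @param moa Optional drug annotation tibble with columns `drug_id`,
#'   `moa_class`; classes with fewer than `min_class_size` drugs are dropped
#'   for the index evaluation.
#' @param min_cluster_size Minimum cluster size for the branch cut.
#' @param min_class_size Minimum annotation class size.
#' @return List with `distance` (matrix), `tree` (hclust), `partition`
#'   (tibble `item_id`, `cluster`), and when `moa` is given, `indices`
#'   (tibble of the four external indices against the annotation).
#' @export
cluster_drug_profiles <- function(x, moa = NULL, min_cluster_size = 3,
                                  min_class_size = 3) {
  d <- spearman_distance(x)
  hc <- ward_linkage(d)
  part <- cut_dynamic(hc, d, min_cluster_size = min_cluster_size)
  out <- list(distance = d, tree = hc, partition = part)
  if (!is.null(moa)) {
    check_columns(moa, c("drug_id", "moa_class"), "MoA annotation")
    ref <- setNames(as.character(moa$moa_class), as.character(moa$drug_id))
    keep <- names(table(ref))[table(ref) >= min_class_size]
    ref <- ref[ref %in% keep]
    common <- intersect(part$item_id, names(ref))
    pa <- setNames(part$cluster, part$item_id)[common]
    out$indices <- partition_indices(pa, ref[common])
  }
  out
}

#' Export a dendrogram in Newick format
#'
#' @param hc An [stats::hclust] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
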