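# two well-separated blocks of drug profiles with within-block correlation
make_blob_profiles <- function(n_per = 5, n_samples = 12, seed = 5) {
  withr::with_seed(seed, {
    base1 <- rnorm(n_samples)
    base2 <- -base1 + rnorm(n_samples, sd = 0.1)
    m <- rbind(
      t(replicate(n_per, base1 + rnorm(n_samples, sd = 0.15))),
      t(replicate(n_per, base2 + rnorm(n_samples, sd = 0.15)))
    )
    rownames(m) <- c(sprintf("a%d", 1:n_per), sprintf("b%d", 1:n_per))
    m
  })
}

test_that("Spearman distance hits its rank-formula anchors", {
  m <- rbind(x = c(1, 2, 3, 4, 5), y = c(1, 2, 3, 5, 4), z = c(5, 4, 3, 2, 1))
  d <- spearman_distance(m)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  # one adjacent inversion: rho = 1 - 6*2/(5*24) = 0.9
  expect_equal(d["x", "y"], 0.1)
  expect_equal(d["x", "z"], 2)           # exactly reversed ranks
  expect_equal(d["x", "x"], 0)
  expect_true(all(d >= 0 & d <= 2))
  const <- rbind(x = c(1, 2, 3, 4), flatdrug = c(7, 7, 7, 7))
  expect_error(spearman_distance(const), regexp = "flatdrug",
               class = "dsskit_error_constant_profile")
})

test_that("pairs below the overlap floor get the maximum distance", {
  m <- make_blob_profiles()
  m[1, 3:12] <- NA                       # drug a1 overlaps others in 2 samples
  d <- spearman_distance(m, min_overlap = 3)
  others <- setdiff(rownames(m), "a1")
  expect_true(all(d["a1", others] == max(d)))
  expect_equal(d["a1", "a1"], 0)
})

test_that("Ward linkage merges the nearest pair first and recovers blobs", {
  d3 <- matrix(c(0, 0.1, 1, 0.1, 0, 1.1, 1, 1.1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  hc <- ward_linkage(d3)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))   # {a, b} merged first
  m <- make_blob_profiles()
  hc2 <- ward_linkage(spearman_distance(m))
  top2 <- cutree(hc2, k = 2)
  expect_equal(length(unique(top2[sprintf("a%d", 1:5)])), 1)
  expect_equal(length(unique(top2[sprintf("b%d", 1:5)])), 1)
  bad <- d3; bad[1, 2] <- 9
  expect_error(ward_linkage(bad), class = "dsskit_error_bad_input")
})

test_that("Ward linkage is invariant to item order up to relabeling", {
  # tie-free distances so the merge sequence is unique
  pts <- withr::with_seed(9, matrix(rnorm(8 * 3), nrow = 8,
                                    dimnames = list(letters[1:8], NULL)))
  d <- as.matrix(dist(pts))
  perm <- withr::with_seed(2, sample(rownames(d)))
  hc1 <- ward_linkage(d)
  hc2 <- ward_linkage(d[perm, perm])
  c1 <- as.matrix(cophenetic(hc1))
  c2 <- as.matrix(cophenetic(hc2))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("adaptive cut finds planted blobs and collapses unstructured data", {
  m <- make_blob_profiles(n_per = 10)
  d <- spearman_distance(m)
  hc <- ward_linkage(d)
  part <- cut_dynamic(hc, d)
  expect_equal(length(unique(part$cluster)), 2)
  blocks <- split(part$item_id, part$cluster)
  expect_true(setequal(blocks[[1]], sprintf("a%d", 1:10)) ||
              setequal(blocks[[1]], sprintf("b%d", 1:10)))
  # all items mutually equidistant: one cluster
  n <- 6
  eq <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(eq) <- 0
  part_eq <- cut_dynamic(ward_linkage(eq), eq)
  expect_equal(length(unique(part_eq$cluster)), 1)
  # min_cluster_size larger than n: single cluster
  part_small <- cut_dynamic(ward_linkage(eq), eq, min_cluster_size = 10)
  expect_equal(length(unique(part_small$cluster)), 1)
})

test_that("partition indices match brute-force enumeration and known anchors", {
  p1 <- c(a = 1, b = 1, c = 2)
  p2 <- c(a = 1, b = 2, c = 2)
  idx <- partition_indices(p1, p2)
  expect_equal(idx$rand, 1 / 3)          # only the (a, c) pair agrees
  same <- partition_indices(p1, p1)
  expect_equal(unlist(same), c(rand = 1, adjusted_rand = 1, jaccard = 1,
                               fowlkes_mallows = 1))
  # exhaustive check against pair enumeration for all partitions of 5 items
  parts <- all_partitions(5)
  ids <- letters[1:5]
  withr::with_seed(41, picks <- sample(length(parts), 12))
  for (i in picks) for (j in picks) {
    a <- setNames(as.character(parts[[i]]), ids)
    b <- setNames(as.character(parts[[j]]), ids)
    got <- partition_indices(a, b)
    ref <- enum_partition_indices(a, b)
    expect_equal(got$rand, ref$rand)
    expect_equal(got$jaccard, ref$jaccard)
    expect_equal(got$fowlkes_mallows, ref$fowlkes_mallows)
    expect_equal(got$adjusted_rand, ref$adjusted_rand)
  }
  expect_error(partition_indices(p1, c(x = 1, y = 2, z = 2)),
               class = "dsskit_error_item_mismatch")
})

test_that("indices agree with an independent adjusted-Rand implementation", {
  withr::with_seed(6, {
    for (i in 1:10) {
      a <- setNames(sample(1:3, 20, replace = TRUE), paste0("i", 1:20))
      b <- setNames(sample(1:4, 20, replace = TRUE), paste0("i", 1:20))
      expect_equal(partition_indices(a, b)$adjusted_rand,
                   mclust::adjustedRandIndex(a, b[names(a)]),
                   tolerance = 1e-12)
    }
  })
})

test_that("adjusted Rand of random partitions is centred on zero", {
  aris <- withr::with_seed(44, {
    vapply(seq_len(1000), function(i) {
      a <- setNames(sample(rep(1:3, each = 6)), paste0("i", 1:18))
      b <- setNames(sample(rep(1:3, each = 6)), paste0("i", 1:18))
      partition_indices(a, b)$adjusted_rand
    }, numeric(1))
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("index permutation test behaves at the null and on planted truth", {
  ids <- paste0("d", 1:18)
  ref <- setNames(rep(c("moa1", "moa2", "moa3"), each = 6), ids)
  pa <- setNames(rep(c("x", "y", "z"), each = 6), ids)   # = ref relabelled
  pb <- setNames(withr::with_seed(3, sample(rep(c("x", "y", "z"), 6))), ids)
  res <- index_permutation_test(pa, pb, ref, n_perm = 2000, seed = 10)
  expect_true(all(res$p.value[res$index == "adjusted_rand"] < 0.01))
  expect_equal(res$observed_a[res$index == "adjusted_rand"], 1)
  # identical partitions: difference 0, p near 1/2
  res0 <- index_permutation_test(pb, pb, ref, n_perm = 2000, seed = 11)
  expect_equal(res0$difference, rep(0, 4))
  expect_true(all(res0$p.value > 0.2 & res0$p.value < 0.8))
  # determinism under the seed
  res0b <- index_permutation_test(pb, pb, ref, n_perm = 2000, seed = 11)
  expect_identical(res0$p.value, res0b$p.value)
  # small classes are excluded from the reference
  ref_small <- c(ref, d19 = "tiny")
  pa19 <- c(pa, d19 = "x"); pb19 <- c(pb, d19 = "y")
  res2 <- index_permutation_test(pa19, pb19, ref_small, n_perm = 200, seed = 4)
  expect_equal(nrow(res2), 4)
  expect_error(
    index_permutation_test(pa, pb, setNames(rep("one", 18), ids),
                           n_perm = 200, seed = 4),
    class = "dsskit_error_bad_reference"
  )
})

test_that("permutation p-values are near-uniform under a true null", {
  # panel-sized item set: with few items the index difference is too
  # discrete for near-uniform p-values
  n <- 60
  ids <- paste0("d", seq_len(n))
  ref <- setNames(rep(paste0("m", 1:4), each = n / 4), ids)
  ps <- withr::with_seed(50, {
    vapply(seq_len(300), function(i) {
      pa <- setNames(sample(rep(paste0("c", 1:4), n / 4)), ids)
      pb <- setNames(sample(rep(paste0("c", 1:4), n / 4)), ids)
      index_permutation_test(pa, pb, ref, n_perm = 200,
                             seed = i)$p.value[1]
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("cluster_drug_profiles wires distance, tree, cut and indices", {
  m <- make_blob_profiles(n_per = 5, n_samples = 10, seed = 13)
  scores <- tibble::tibble(
    sample_id = rep(sprintf("s%02d", 1:10), times = 10),
    drug_id = rep(rownames(m), each = 10),
    score = as.vector(t(m))
  )
  mat <- as_score_matrix(scores, "DSS3", list())
  moa <- tibble::tibble(drug_id = rownames(m),
                        moa_class = rep(c("A", "B"), each = 5))
  out <- cluster_drug_profiles(mat, moa = moa)
  expect_s3_class(out$tree, "hclust")
  expect_equal(nrow(out$partition), 10)
  expect_equal(out$indices$adjusted_rand, 1)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  export_newick(out$tree, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(m))
})
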