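# Independent brute-force oracles kept deliberately separate from the
# package's implementations.

# numerical quadrature of the response area above a threshold; summed over
# panels so the kink where the curve crosses the threshold is resolved
quad_integral <- function(r_min, r_max, m, s, a_min, x_lo, x_hi,
                          n_panels = 32) {
  f <- function(x) pmax(0, logistic_response(x, r_min, r_max, m, s) - a_min)
  edges <- seq(x_lo, x_hi, length.out = n_panels + 1)
  sum(vapply(seq_len(n_panels), function(i) {
    stats::integrate(f, edges[i], edges[i + 1], rel.tol = 1e-12,
                     abs.tol = 1e-13, subdivisions = 200L)$value
  }, numeric(1)))
}

# O(n^2) pair-counting AUROC
pair_count_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of rank assignments
enum_wilcox_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
  mu <- n_a * length(b) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# brute-force pair enumeration of partition agreement indices
enum_partition_indices <- function(a, b) {
  b <- b[names(a)]
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa) s10 <- s10 + 1
      else if (sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  total <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / total
  denom <- 0.5 * ((s11 + s10) + (s11 + s01)) - expected
  list(rand = (s11 + s00) / total,
       jaccard = if (s11 + s10 + s01 == 0) 1 else s11 / (s11 + s10 + s01),
       fowlkes_mallows = if ((s11 + s10) == 0 || (s11 + s01) == 0) {
         if ((s11 + s10) == (s11 + s01)) 1 else 0
       } else {
         s11 / sqrt((s11 + s10) * (s11 + s01))
       },
       adjusted_rand = if (denom == 0) 1 else (s11 - expected) / denom)
}

# all partitions of n labelled items (restricted growth strings)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (lab in seq_len(maxlab + 1L)) {
      out <- c(out, rec(c(prefix, lab), max(maxlab, lab)))
    }
    out
  }
  rec(1L, 1L)
}

# DeLong variance of the AUROC difference written out directly from the
# placement-value definition
direct_delong <- function(s1, s2, labels) {
  labels <- as.logical(labels)
  pos <- which(labels)
  neg <- which(!labels)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  comp <- function(s) {
    v10 <- sapply(pos, function(i) mean(psi(s[i], s[neg])))
    v01 <- sapply(neg, function(j) mean(psi(s[pos], s[j])))
    list(v10 = v10, v01 = v01, theta = mean(v10))
  }
  c1 <- comp(s1)
  c2 <- comp(s2)
  var_diff <- (var(c1$v10) + var(c2$v10) - 2 * cov(c1$v10, c2$v10)) / length(pos) +
    (var(c1$v01) + var(c2$v01) - 2 * cov(c1$v01, c2$v01)) / length(neg)
  list(theta1 = c1$theta, theta2 = c2$theta, var_diff = var_diff)
}

# small labelled curve-score fixture used across cohort tests
make_labelled_scores <- function(seed, n_pos = 25, n_neg = 40) {
  withr::with_seed(seed, {
    tibble::tibble(
      label = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
      good = c(rnorm(n_pos, 2), rnorm(n_neg, 0)),
      noisy = c(rnorm(n_pos, 0.5), rnorm(n_neg, 0))
    )
  })
}
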