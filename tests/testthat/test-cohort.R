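test_that("sample skewness matches the moment definition", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  # direct moment computation: m2 = 1522, m3 = 88920
  expect_equal(sample_skewness(c(1, 2, 3, 4, 100)), 88920 / 1522^1.5)
  v <- c(2, 5, 1, 9, 4, 4, 7)
  expect_equal(sample_skewness(-v), -sample_skewness(v))
  expect_error(sample_skewness(c(1, 2)), class = "dsskit_error_insufficient_data")
  expect_error(sample_skewness(rep(3, 10)), class = "dsskit_error_zero_variance")
})

test_that("skewness test reproduces reference values and null behaviour", {
  # frozen from an independent implementation of the same transformation
  x1 <- c(1.2, 2.3, 2.9, 3.1, 3.4, 3.7, 4.0, 4.4, 4.9, 5.3, 6.1, 14.0)
  t1 <- agostino_test(x1, "greater")
  expect_equal(t1$gamma, 2.136910144783, tolerance = 1e-10)
  expect_equal(t1$z, 3.395648288526, tolerance = 1e-10)
  expect_equal(t1$p.value, 0.000342331377, tolerance = 1e-8)
  expect_equal(agostino_test(x1, "two.sided")$p.value, 0.000684662754,
               tolerance = 1e-8)
  x2 <- c(10, 9.5, 9.1, 8.8, 8.6, 8.5, 8.3, 8.2, 8.0, 7.9, 7.7, 7.4, 7.0,
          6.0, 1.0)
  t2 <- agostino_test(x2, "greater")
  expect_equal(t2$z, -3.658061796962, tolerance = 1e-10)
  expect_equal(t2$p.value, 0.999872935110, tolerance = 1e-8)
  expect_equal(sign(t2$z), sign(t2$gamma))
  # symmetric sample: gamma ~ 0, one-sided p ~ 0.5
  sym <- rep(c(-2, -1, 0, 1, 2), 6)
  ts <- agostino_test(sym, "greater")
  expect_equal(ts$gamma, 0, tolerance = 1e-12)
  expect_equal(ts$p.value, 0.5, tolerance = 1e-9)
  expect_error(agostino_test(1:7), class = "dsskit_error_insufficient_data")
})

test_that("skewness test holds its type-I error near the nominal level", {
  n_rep <- 2000   # the 10,000-replicate calibration runs in acceptance
  rejections <- withr::with_seed(505, {
    vapply(seq_len(n_rep), function(i) {
      agostino_test(rnorm(30), "greater")$p.value < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.015)
})

test_that("an extreme right outlier drives the one-sided p below 0.05", {
  withr::with_seed(99, {
    x <- c(rnorm(29), 8)
    expect_lt(agostino_test(x, "greater")$p.value, 0.05)
  })
})

test_that("responder detection returns the minimal top tail", {
  withr::with_seed(21, {
    background <- rnorm(20, mean = 5, sd = 2)
    planted <- rnorm(4, mean = 30, sd = 1)
    values <- c(background, planted)
    ids <- c(sprintf("bg_%02d", 1:20), sprintf("hit_%d", 1:4))
    det <- detect_responders(values, ids)
    expect_setequal(det$responder_ids, sprintf("hit_%d", 1:4))
    expect_equal(det$k, 4)
    # responders are a prefix of the descending sort
    expect_equal(det$responder_ids,
                 ids[order(values, decreasing = TRUE)][seq_len(det$k)])
  })
  # symmetric data: empty set
  sym <- rep(c(-2, -1, 0, 1, 2), 5)
  expect_equal(detect_responders(sym)$k, 0)
  expect_error(detect_responders(rep(1, 10)),
               class = "dsskit_error_zero_variance")
})

test_that("per-drug sub-group screen reports FDR and rank-sum confirmation", {
  withr::with_seed(32, {
    scores <- tidyr::expand_grid(sample_id = sprintf("s%02d", 1:24),
                                 drug_id = c("hit_drug", "null_drug"))
    scores$score <- rnorm(nrow(scores), 5, 2)
    boost <- scores$drug_id == "hit_drug" & scores$sample_id %in% sprintf("s%02d", 1:4)
    scores$score[boost] <- scores$score[boost] + 25
  })
  mat <- as_score_matrix(scores, "DSS3", list())
  tbl <- detect_responder_subgroups(mat)
  hit <- tbl[tbl$drug_id == "hit_drug", ]
  expect_equal(hit$n_responders, 4L)
  expect_setequal(hit$responders[[1]], sprintf("s%02d", 1:4))
  expect_lt(hit$ranksum_p, 0.01)
  expect_true(all(tbl$fdr >= tbl$p.value - 1e-12))
})

test_that("rank-sum test uses the exact branch and matches enumeration", {
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  expect_equal(same$statistic, 4.5)        # null mean of W for 3 vs 3
  sep <- rank_sum_test(c(1, 2, 3), c(10, 20, 30))
  expect_true(sep$exact)
  expect_equal(sep$p.value, 0.1)           # 2/20 fully separated assignments
  expect_equal(rank_sum_test(c(10, 20, 30), c(1, 2, 3))$p.value, sep$p.value)
  # exact branch agrees with full enumeration for all group sizes <= 5
  withr::with_seed(77, {
    for (na in 2:5) for (nb in 2:5) {
      a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
      expect_equal(rank_sum_test(a, b)$p.value, enum_wilcox_p(a, b),
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  })
  expect_error(rank_sum_test(numeric(0), 1:3),
               class = "dsskit_error_insufficient_data")
})

test_that("AUROC matches pair counting, handles ties and orientation", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auroc, 1)
  s <- c(1, 2, 3, 4, 3)                     # one tie across classes
  l <- c(0, 0, 1, 1, 0)
  expect_equal(auroc(s, l)$auroc, pair_count_auroc(s, l))
  withr::with_seed(8, {
    for (i in 1:20) {
      sc <- rnorm(30)
      lb <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
      if (sum(lb) == 0 || sum(!lb) == 0) next
      expect_equal(auroc(sc, lb)$auroc, pair_count_auroc(sc, lb))
      # invariance under strictly monotone transforms
      expect_equal(auroc(exp(sc), lb)$auroc, auroc(sc, lb)$auroc)
    }
  })
  # lower_is_active flips the orientation (IC50-style metrics)
  expect_equal(auroc(c(5, 4, 1, 2), c(1, 1, 0, 0),
                     orientation = "lower_is_active")$auroc, 0)
  expect_error(auroc(1:5, rep(1, 5)), class = "dsskit_error_single_class")
  # large random scores: AUROC near 1/2
  withr::with_seed(12, {
    r <- auroc(rnorm(4000), rep(c(TRUE, FALSE), 2000))
    expect_lt(abs(r$auroc - 0.5), 0.03)
  })
})

test_that("DeLong test matches the placement-value formulas and pROC", {
  df <- make_labelled_scores(14, n_pos = 6, n_neg = 6)
  dt <- delong_test(df$good, df$noisy, df$label)
  ref <- direct_delong(df$good, df$noisy, df$label)
  expect_equal(dt$auroc_1, ref$theta1)
  expect_equal(dt$auroc_2, ref$theta2)
  expect_equal(dt$var_diff, ref$var_diff)
  # independent cross-check against pROC's DeLong implementation
  df2 <- make_labelled_scores(15)
  dt2 <- delong_test(df2$good, df2$noisy, df2$label)
  pr <- pROC::roc.test(
    pROC::roc(df2$label, df2$good, quiet = TRUE, direction = "<"),
    pROC::roc(df2$label, df2$noisy, quiet = TRUE, direction = "<"),
    method = "delong"
  )
  expect_equal(dt2$p.value, pr$p.value, tolerance = 1e-9)
  # degenerate cases
  ident <- delong_test(df2$good, df2$good, df2$label)
  expect_true(ident$degenerate)
  expect_equal(ident$p.value, 1)
  expect_equal(ident$diff, 0)
  mono <- delong_test(df2$good, exp(df2$good), df2$label)
  expect_equal(mono$diff, 0)
})

test_that("DeLong p-values are near-uniform under a permutation null", {
  df <- make_labelled_scores(16, n_pos = 20, n_neg = 20)
  ps <- withr::with_seed(17, {
    vapply(seq_len(400), function(i) {
      lb <- sample(df$label)
      delong_test(df$good, df$noisy, lb)$p.value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("evaluate_metrics ranks a clean metric above a noisy one", {
  df <- make_labelled_scores(18, n_pos = 40, n_neg = 60)
  df$ic50_like <- -df$good + rnorm(100, sd = 0.1)
  ev <- evaluate_metrics(df, df$label,
                         metrics = c("good", "noisy", "ic50_like"),
                         orientation = c(ic50_like = "lower_is_active"))
  aucs <- setNames(ev$auroc$auroc, ev$auroc$metric)
  expect_gt(aucs["good"], aucs["noisy"])
  expect_gt(aucs["ic50_like"], 0.9)        # orientation handled
  expect_equal(nrow(ev$delong), 3)
})
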