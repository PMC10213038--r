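test_that("active-sham deltas match hand subtraction and drop unpaired arms", {
  beh <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 2),
    task = "Flanker", metric = "accuracy",
    stimulation = rep(c("active", "sham"), 3),
    concurrency = "concurrent",
    value = c(0.9, 0.8, 0.7, 0.7, 0.6, 0.75))
  d <- compute_deltas(beh)
  expect_equal(d$delta[match(c("a", "b", "c"), d$subject_id)],
               c(0.1, 0, -0.15))
  # missing sham arm excludes that subject from the endpoint
  d2 <- compute_deltas(beh[-2, ])
  expect_false("a" %in% d2$subject_id)
  expect_equal(attr(d2, "excluded"), 1L)
})

test_that("outlier masking implements the +/- c SD rule", {
  expect_true(all(outlier_mask(rep(5, 10))))
  x <- c(rep(0, 9), 100)
  expect_identical(outlier_mask(x), c(rep(TRUE, 9), FALSE))
  expect_true(all(outlier_mask(x, c = Inf)))
})

test_that("partial Spearman reduces to Spearman and is monotone invariant", {
  set.seed(5)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(partial_spearman(exp(x), y)$rho, ps$rho, tolerance = 1e-12)
  expect_equal(partial_spearman(x, y^3 + 10)$rho, ps$rho, tolerance = 1e-12)
  expect_equal(partial_spearman(x, exp(x))$rho, 1, tolerance = 1e-12)
  expect_true(is.na(partial_spearman(rep(1, 10), rnorm(10))$rho))
})

test_that("partial Spearman with a covariate matches the rank-residual oracle", {
  set.seed(6)
  x <- rnorm(8); z <- rnorm(8); y <- x + z + rnorm(8)
  got <- partial_spearman(x, y, Z = cbind(z))
  # independent matrix-algebra route: explicit projection of ranks
  rx <- rank(x); ry <- rank(y)
  M <- cbind(1, z)
  P <- diag(8) - M %*% solve(t(M) %*% M) %*% t(M)
  ex <- P %*% rx; ey <- P %*% ry
  rho <- as.numeric(t(ex) %*% ey / sqrt(sum(ex^2) * sum(ey^2)))
  expect_equal(got$rho, rho, tolerance = 1e-12)
  df <- 8 - 2 - 1
  tv <- rho * sqrt(df / (1 - rho^2))
  expect_equal(got$p, 2 * pt(-abs(tv), df), tolerance = 1e-12)
  expect_error(partial_spearman(x[1:3], y[1:3], Z = cbind(z[1:3])), "at least")
})

test_that("BH adjustment reproduces the step-up procedure", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$p_adj, rep(0.04, 4))
  expect_true(all(r$significant))
  expect_equal(bh_fdr(0.2)$p_adj, 0.2)
  expect_equal(bh_fdr(rep(1, 5))$p_adj, rep(1, 5))
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  # all small families against the enumeration oracle, plus order invariance
  set.seed(7)
  for (m in 1:5) {
    for (rep_i in 1:20) {
      p <- round(runif(m), 3)
      expect_equal(bh_fdr(p)$p_adj, bh_stepup_oracle(p), tolerance = 1e-12)
      perm <- sample(m)
      expect_equal(bh_fdr(p[perm])$p_adj, bh_stepup_oracle(p)[perm],
                   tolerance = 1e-12)
    }
  }
  p10 <- runif(10)
  expect_true(all(bh_fdr(p10)$p_adj >= p10))
})

test_that("rank-sum p-values match exhaustive enumeration for small samples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)                       # 2 * 1/20
  expect_equal(r$p, ranksum_exact_oracle(c(1, 2, 3), c(4, 5, 6)))
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(rank_sum_test(x, y)$p, ranksum_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum type-I error sits at the nominal level", {
  set.seed(13)
  rej <- mean(replicate(1000, rank_sum_test(rnorm(20), rnorm(20))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("verdict drafting follows the accuracy/RT sign rules", {
  cr <- data.frame(metric = c("accuracy", "rt", "accuracy", "rt", "accuracy"),
                   rho = c(0.4, 0.4, -0.4, -0.4, 0.4),
                   significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  v <- label_clusters(cr)$verdict
  expect_equal(v, c("positive", "negative", "negative", "positive", "non"))
})

test_that("confirmation demotes unconfirmed verdicts", {
  cr <- data.frame(cluster = c(1, 2), group = "B",
                   concurrency = "non-concurrent", task = "N-Back",
                   metric = "accuracy", verdict = c("positive", "positive"))
  wt <- data.frame(cluster = c(1, 2), group = "B",
                   concurrency = "non-concurrent", task = "N-Back",
                   metric = "accuracy", p_adj = c(0.01, 0.4),
                   significant = c(TRUE, FALSE))
  out <- confirm_responders(cr, wt)
  expect_equal(out$verdict, c("positive", "non"))
  expect_equal(out$wilcoxon_p_adj, c(0.01, 0.4))
  out2 <- confirm_responders(cr, NULL)
  expect_equal(out2$verdict, c("non", "non"))
})

test_that("members-vs-rest comparison uses the endpoint deltas", {
  d <- c(1, 2, 3, 10, 11, 12)
  cl <- c(1, 1, 1, 2, 2, 2)
  r <- wilcoxon_members_vs_rest(d, cl, 2)
  expect_equal(r$p, 0.1)
  expect_equal(r$n_members, 3)
  expect_error(wilcoxon_members_vs_rest(d, cl, 3), "empty")
})

test_that("planted responder phenotypes are labeled correctly end to end", {
  hits <- vapply(1:8, function(s) planted_labels_recovered(run_labeling(s)),
                 logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("null cohorts stay essentially label free", {
  null_cfg <- cohort_config(responder_classes = rep("non", 4), effect_size = 0)
  false_rates <- vapply(1:8, function(s) {
    run <- run_labeling(500 + s, null_cfg)
    lab <- run$result$labels
    fam <- interaction(lab$group, lab$concurrency)
    mean(tapply(lab$verdict != "non", fam, any))
  }, numeric(1))
  expect_lte(mean(false_rates), 0.05)
})
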