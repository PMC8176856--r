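test_that("the Shapiro-Wilk gate picks Pearson for normal, Spearman otherwise", {
  set.seed(7)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  z <- exp(rnorm(200))
  # oracle: the gate must agree with Shapiro-Wilk on the realized samples
  expect_true(shapiro.test(x)$p.value > 0.05 && shapiro.test(y)$p.value > 0.05)
  expect_lt(shapiro.test(z)$p.value, 0.05)
  expect_equal(choose_correlation_type(x, y), "pearson")
  expect_equal(choose_correlation_type(x, z), "spearman")
  expect_error(choose_correlation_type(rep(1, 10), rnorm(10)), "constant")
  expect_error(choose_correlation_type(rnorm(3), rnorm(3)), "n >= 4")
})

test_that("correlate reports r, r squared and two-sided p", {
  x <- c(1, 2.2, 3.1, 4.7, 6.0, 8.5)
  cr <- correlate(2 * x + 1, x)
  expect_equal(cr$r, 1.0, tolerance = 1e-12)
  expect_equal(cr$r_squared, 1.0, tolerance = 1e-12)

  cr2 <- correlate(rev(x), x, type = "spearman")
  expect_equal(cr2$r, -1.0)

  # r^2 always equals r * r
  set.seed(5)
  a <- rnorm(30); b <- a + rnorm(30)
  cr3 <- correlate(a, b)
  expect_equal(cr3$r_squared, cr3$r^2)
  expect_error(correlate(rep(1, 10), rnorm(10)), "variance")
})

test_that("coefficient of variation uses the sample SD over the mean", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50.0)
  expect_equal(coefficient_of_variation(rep(4.2, 5)), 0)
  expect_error(coefficient_of_variation(c(-3, 1)), "mean")
  expect_error(coefficient_of_variation(5), "n >= 2")
})

test_that("Bland-Altman mean difference and limits of agreement", {
  x <- c(1, 4, 2.5, 7, 3)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, c(0, 0))

  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$mean_diff, 2)
  expect_equal(ba2$loa, c(2, 2))

  set.seed(77)
  a <- runif(50, 0, 20); b <- runif(50, 0, 20)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa, c(mean(d) - 1.96 * sd(d), mean(d) + 1.96 * sd(d)))

  # antisymmetry
  expect_equal(bland_altman(b, a)$mean_diff, -ba$mean_diff)
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("Kruskal-Wallis H matches a hand rank computation", {
  expect_equal(kruskal_wallis(list(rep(1, 3), rep(1, 3), rep(1, 3)))$H, 0)

  g <- list(c(1, 2, 3), c(101, 102, 103))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, oracle_kruskal_h(g), tolerance = 1e-12)
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)

  set.seed(13)
  g3 <- list(rnorm(8), rnorm(12), c(rnorm(6), rnorm(2)))
  expect_equal(kruskal_wallis(g3)$H, oracle_kruskal_h(g3), tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("the Kruskal-Wallis null keeps its nominal type-I error", {
  set.seed(2024)
  pool <- rnorm(30)
  reject <- logical(2000)
  for (i in seq_len(2000)) {
    lab <- sample(rep(1:3, each = 10))
    reject[i] <- kruskal_wallis(split(pool, lab))$p_value < 0.05
  }
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("CoV is scale invariant", {
  set.seed(3)
  x <- runif(20, 1, 9)
  for (c in c(0.1, 2, 37)) {
    expect_equal(coefficient_of_variation(c * x), coefficient_of_variation(x),
                 tolerance = 1e-12)
  }
})

test_that("sweep produces one row per case, family and level", {
  coh <- default_cohort()
  one <- sweep_delineations(coh$cases[1], list(
    fixed = method_grid("fixed", c(2.5, 3, 3.5, 4, 4.5, 5, 7.5, 10, 15))))
  expect_equal(nrow(one), 9)
  expect_true(all(one$method == "fixed"))

  sw <- default_sweep()
  expect_equal(nrow(sw$results), 50 * (9 + 16 + 6 + 6 + 6))
  expect_equal(nrow(sw$agreement), 43)
  expect_true(all(abs(sw$agreement$r_squared - sw$agreement$r^2) < 5e-4))
  expect_true(all(sw$results$volume_ml ==
                    sw$results$n_voxels * 0.008))
})

test_that("rank_methods picks the argmax r with ties toward lower levels", {
  s <- data.frame(method = c("fixed", "fixed", "fixed"),
                  level = c(2.5, 4, 10),
                  r = c(0.3, 0.9, 0.5))
  rk <- rank_methods(s)
  expect_equal(rk$overall$level, 4)
  expect_equal(rk$overall$r, 0.9)

  s_tie <- data.frame(method = "fixed", level = c(3, 4), r = c(0.8, 0.8))
  expect_equal(rank_methods(s_tie)$overall$level, 3)

  s1 <- data.frame(method = "isocontour", level = 55, r = 0.62)
  expect_equal(rank_methods(s1)$overall$r, 0.62)
  expect_error(rank_methods(s1[0, ]), "no summaries")
})

test_that("backwards summary aggregates thresholds and reapplies the mean", {
  coh <- default_cohort()
  cases <- coh$cases[1:6]
  gt <- coh$ground_truth[1:6, ]
  bw <- do.call(rbind, lapply(cases, function(cs)
    backwards_threshold(cs$pet, cs$voi,
                        gt$ct_reference_volume_ml[gt$case_id == cs$case_id],
                        cs$case_id)))
  # achieved volumes sit within one voxel of the attainable-volume target
  expect_true(all(abs(bw$achieved_volume_ml - bw$target_volume_ml) <= 0.008))

  summ <- backwards_summary(cases, bw, gt)
  expect_equal(summ$mean_threshold, mean(bw$threshold_suv))
  expect_equal(summ$cov_percent,
               100 * sd(bw$threshold_suv) / mean(bw$threshold_suv))
  expect_false(is.null(summ$reapplied_agreement$r))

  # hand check of the threshold statistics
  toy <- bw[1:2, ]; toy$threshold_suv <- c(4, 6)
  s2 <- backwards_summary(cases[1:2], toy, gt[1:2, ])
  expect_equal(s2$mean_threshold, 5)
  expect_equal(s2$sd_threshold, sqrt(2))
  expect_equal(s2$cov_percent, 100 * sqrt(2) / 5)
  # n = 2 reapplied volumes: correlation undefined -> flagged error
  expect_true(!is.null(s2$reapplied_agreement$error))
})

test_that("the reapplied mean backwards threshold is never better than the
           best fixed-grid threshold on the same cohort", {
  coh <- default_cohort()
  sw <- default_sweep()
  fixed <- sw$agreement[sw$agreement$method == "fixed", ]
  bw <- do.call(rbind, lapply(coh$cases, function(cs)
    backwards_threshold(cs$pet, cs$voi,
                        coh$ground_truth$ct_reference_volume_ml[
                          coh$ground_truth$case_id == cs$case_id],
                        cs$case_id)))
  summ <- backwards_summary(coh$cases, bw, coh$ground_truth)
  m <- summ$mean_threshold
  expect_gte(m, min(fixed$level))
  expect_lte(m, max(fixed$level))
  expect_lte(summ$reapplied_agreement$r, max(fixed$r))
})
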