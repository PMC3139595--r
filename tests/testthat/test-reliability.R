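# ICC machinery, grading, AUC, edgewise and metric-level reliability,
# strength-reliability fits, and the paired-comparison wrappers.

test_that("ICC matches an explicit sums-of-squares oracle", {
  pm <- cbind(c(1, 3, 5, 7), c(2, 3, 4, 8))
  res <- icc(pm)
  expect_equal(res$icc, bf_icc(pm), tolerance = 1e-12)
  # hand-enumerated ANOVA for the same table
  grand <- mean(pm)
  ms_b <- 2 * sum((rowMeans(pm) - grand)^2) / 3
  ms_w <- sum((pm - rowMeans(pm))^2) / 4
  expect_equal(res$ms_between, ms_b, tolerance = 1e-12)
  expect_equal(res$ms_within, ms_w, tolerance = 1e-12)
  expect_equal(res$icc, (ms_b - ms_w) / (ms_b + ms_w), tolerance = 1e-12)
  expect_equal(res$f_value, ms_b / ms_w, tolerance = 1e-12)
})

test_that("identical columns give ICC 1; identical everything is flagged", {
  x <- c(1, 4, 9, 2)
  res <- icc(cbind(x, x))
  expect_equal(res$icc, 1)
  expect_equal(res$grade, "excellent")
  flat <- icc(matrix(5, 4, 2))
  expect_true(is.na(flat$icc))
  expect_error(icc(cbind(1:2, 3:4)), "3 subjects")
})

test_that("the F-relation reproduces the ANOVA ICC on random tables", {
  set.seed(30)
  for (i in 1:200) {
    pm <- matrix(rnorm(25 * 2), 25, 2)
    res <- icc(pm)
    expect_equal(icc_from_f(res$f_value, 2), res$icc, tolerance = 1e-10)
  }
  # k = 3 too
  pm3 <- matrix(rnorm(10 * 3), 10, 3)
  res3 <- icc(pm3)
  expect_equal(icc_from_f(res3$f_value, 3), res3$icc, tolerance = 1e-10)
  expect_equal(icc_from_f(1, 2), 0)
  expect_equal(icc_from_f(3, 2), 0.5)
  expect_gt(icc_from_f(1e12, 2), 1 - 1e-11)
})

test_that("ICC is invariant to affine transforms and column order", {
  set.seed(31)
  pm <- matrix(rnorm(20), 10, 2)
  base <- icc(pm)$icc
  expect_equal(icc(pm + 7)$icc, base, tolerance = 1e-10)
  expect_equal(icc(pm * 3.5)$icc, base, tolerance = 1e-10)
  expect_equal(icc(pm[, 2:1])$icc, base, tolerance = 1e-10)
  # negative ICC is reported as computed, graded poor
  neg <- cbind(c(1, 2, 3), c(3, 2, 1))
  expect_lt(icc(neg)$icc, 0)
  expect_equal(icc(neg)$grade, "poor")
})

test_that("grade bands are lower-inclusive with the documented cut points", {
  expect_equal(grade_icc(c(-0.1, 0, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6, 0.7,
                           0.75, 0.9, 1)),
               c("poor", "poor", "poor", "low", "low", "fair", "fair",
                 "good", "good", "excellent", "excellent", "excellent"))
  expect_error(grade_icc(1.2), "exceed 1")
})

test_that("AUC is the trapezoidal integral with NA pruning", {
  g <- seq(0.1, 0.5, 0.1)
  expect_equal(auc(g, rep(2, 5)), 2 * 0.4, tolerance = 1e-12)
  # exact for linear curves
  expect_equal(auc(g, 3 * g + 1), 3 * (0.5^2 - 0.1^2) / 2 + 1 * 0.4,
               tolerance = 1e-12)
  # fine-grained Riemann oracle on a random curve
  set.seed(32)
  v <- rnorm(5)
  riemann <- 0
  for (i in 1:4) {
    xs <- seq(g[i], g[i + 1], length.out = 10001)
    ys <- approx(g, v, xs)$y
    riemann <- riemann + sum((ys[-1] + ys[-10001]) / 2) * diff(xs)[1]
  }
  expect_equal(auc(g, v), riemann, tolerance = 1e-9)
  # NA values pruned with their grid points
  expect_equal(auc(g, c(1, NA, 1, 1, 1)),
               auc(g[-2], rep(1, 4)), tolerance = 1e-12)
  expect_error(auc(g, c(1, NA, NA, NA, NA)), "2 usable")
})

test_that("edgewise reliability: identity, counts, and ground-truth pull", {
  cfg <- cohort_config(10, 2, 6, sigma_b = 0.3, sigma_w = 0.2, seed = 40)
  co <- generate_cohort(cfg)
  a <- cohort_scans(co, 1)
  ew_same <- edgewise_reliability(a, a)
  expect_equal(ew_same$mean_icc, 1)
  expect_equal(ew_same$n_edges, 15)
  expect_equal(sum(ew_same$grade_counts), 15)
  expect_equal(unname(ew_same$grade_counts["excellent"]), 15L)
  # sigma_b = 0: grade counts concentrate in poor/low
  cfg0 <- cohort_config(25, 2, 8, sigma_b = 0, sigma_w = 0.3, seed = 41)
  co0 <- generate_cohort(cfg0)
  ew0 <- edgewise_reliability(cohort_scans(co0, 1), cohort_scans(co0, 2))
  expect_gt(sum(ew0$grade_counts[c("poor", "low")]) / sum(ew0$grade_counts),
            0.8)
  mismatched <- a
  names(mismatched) <- rev(names(a))
  expect_error(edgewise_reliability(a, mismatched), "do not match")
  expect_error(edgewise_reliability(a[1:2], a[1:2]), "3 subjects")
})

test_that("a 90-ROI cohort evaluates all 4005 connections", {
  cfg <- cohort_config(5, 2, 90, sigma_b = 0.2, sigma_w = 0.2, seed = 42)
  co <- generate_cohort(cfg)
  ew <- edgewise_reliability(cohort_scans(co, 1), cohort_scans(co, 2))
  expect_equal(ew$n_edges, 90 * 89 / 2)
})

test_that("metric reliability handles identity, AUC pruning and grids", {
  set.seed(43)
  tabs <- lapply(1:5, function(s) {
    m <- random_corr_like(8)
    metrics_over_grid(m, c(0.2, 0.3, 0.4), "absolute_both", "binarized",
                      global_names = c("Cp", "Eglob"),
                      nodal_names = "degree", n_random = 0,
                      subject_id = paste0("s", s), scan_id = "t")
  })
  tab <- do.call(rbind, tabs)
  res <- metric_reliability(tab, tab, mode = "auc")
  expect_true(all(res$icc[!is.na(res$icc)] == 1))
  res_thr <- metric_reliability(tab, tab, mode = "per_threshold")
  expect_true(all(res_thr$sparsity %in% c("0.2", "0.3", "0.4")))
  # a flagged value at one threshold still yields an AUC from the rest
  tab_b <- tab
  tab_b$value <- tab_b$value + rnorm(nrow(tab_b), 0, 0.01)
  tab_b$value[tab_b$metric == "Cp" & tab_b$sparsity == 0.3 &
                tab_b$subject == "s1"] <- NA
  res_pruned <- metric_reliability(tab, tab_b, mode = "auc")
  expect_false(any(is.na(res_pruned$icc[res_pruned$metric == "Cp"])))
  # mismatched grids error
  tab_c <- tab[tab$sparsity != 0.2, ]
  expect_error(metric_reliability(tab, tab_c), "grids")
})

test_that("gamma/lambda are excluded cleanly when n_random = 0", {
  # metric subsets avoid the surrogate ensemble entirely
  m <- random_corr_like(8)
  tab <- metrics_over_grid(m, c(0.3, 0.4), "absolute_both", "binarized",
                           global_names = c("Cp", "Lp"), nodal_names = NULL)
  expect_setequal(unique(tab$metric), c("Cp", "Lp"))
})

test_that("strength-reliability fits recover planted relations", {
  set.seed(44)
  strength <- runif(200, 0.05, 0.9)
  icc_exact <- strength
  fit <- strength_vs_reliability(strength, icc_exact, "positive")
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # planted linear relation with noise
  icc_noisy <- 0.2 + 0.5 * strength + rnorm(200, 0, 0.05)
  fit2 <- strength_vs_reliability(strength, icc_noisy, "positive")
  expect_equal(fit2$slope, 0.5, tolerance = 0.1)
  expect_gt(fit2$r, 0.8)
  # degenerate: constant ICC flags r as NA
  fit3 <- strength_vs_reliability(strength, rep(0.5, 200), "positive")
  expect_true(is.na(fit3$r))
  expect_error(strength_vs_reliability(strength, icc_exact, "negative"),
               "fewer than 3")
})

test_that("paired t and Pearson wrappers flag degenerate inputs", {
  set.seed(45)
  a <- rnorm(20)
  b <- a + rnorm(20, 0.3, 0.5)
  tt <- paired_t(a, b)
  d <- a - b
  expect_equal(tt$t, mean(d) / (sd(d) / sqrt(20)), tolerance = 1e-10)
  expect_equal(tt$df, 19)
  expect_equal(paired_t(a, a + 2)$t, NA_real_)  # zero-variance differences
  expect_equal(paired_t(a, a)$t, NA_real_)
  pr <- pearson_r(a, b)
  expect_equal(pr$r, cor(a, b), tolerance = 1e-12)
  expect_true(is.na(pearson_r(a, rep(1, 20))$r))
})
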