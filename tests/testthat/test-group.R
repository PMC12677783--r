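# Group statistics and classifier benchmark.

test_that("Kruskal-Wallis hand example and degenerate input", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                       rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))

  kw0 <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_identical(kw0$H, 0)
  expect_identical(kw0$p, 1)

  # invariance under monotone transforms
  set.seed(70)
  x <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(exp(x), g)$H)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("BH step-up matches hand computation and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- p.adjust(p, "BH")
  expect_true(all(q <= 0.05)) # largest k with p(k) <= k*alpha/m is 4
  expect_true(all(p.adjust(c(0.2, 0.8), "BH") > 0.05))
  set.seed(71)
  ps <- sort(runif(12))
  expect_true(!is.unsorted(p.adjust(ps, "BH")))
})

test_that("posthoc_fdr produces Dunn z tests with BH-adjusted q >= p", {
  set.seed(72)
  x <- c(rnorm(15), rnorm(15, 3), rnorm(15))
  g <- rep(c("a", "b", "c"), each = 15)
  res <- posthoc_fdr(x, g)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$q >= res$p - 1e-15))
  ab <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_true(ab$significant)
  ac <- res[res$group1 == "a" & res$group2 == "c", ]
  expect_false(ac$significant)
})

test_that("omnibus type-I rate is calibrated on identical groups", {
  set.seed(73)
  n_rep <- 500
  rej <- 0
  for (r in seq_len(n_rep)) {
    x <- rnorm(5 * 12)
    g <- rep(paste0("g", 1:5), each = 12)
    if (kruskal_wallis(x, g)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})

test_that("group_stats and significance_matrix wire together", {
  set.seed(74)
  tab <- expand.grid(subject_id = paste0("s", 1:30), band = c("alpha"),
                     site = c("Fz", "Cz"), metric = "cohesion_strength",
                     stringsAsFactors = FALSE)
  tab$group <- rep(c("control", "patient"), 15)[match(tab$subject_id,
                                                      paste0("s", 1:30))]
  tab$value <- rnorm(nrow(tab)) +
    ifelse(tab$group == "patient" & tab$site == "Fz", -3, 0)
  gs <- group_stats(tab)
  expect_true(all(c("H", "p") %in% names(gs$omnibus)))
  m <- significance_matrix(gs, "cohesion_strength", "control", "patient",
                           sites = c("Fz", "Cz"), bands = "alpha")
  expect_identical(m["Fz", "alpha"], 1L)
  expect_identical(m["Cz", "alpha"], 0L)
})

test_that("classifier benchmark: separable features, report shape,
           chance level under shuffling", {
  set.seed(75)
  x <- rbind(matrix(rnorm(30 * 8, 2), 30), matrix(rnorm(30 * 8, -2), 30))
  y <- rep(c("pat", "ctl"), each = 30)
  rep1 <- benchmark_classifiers(x, y, "pat", n_repetitions = 25, seed = 1)
  expect_s3_class(rep1, "classification_report")
  expect_identical(nrow(rep1$scores), 6L * 4L)
  expect_true(all(c("mean", "sd") %in% names(rep1$scores)))
  expect_true(all(rep1$scores$mean >= 0 & rep1$scores$mean <= 1))
  acc <- rep1$scores[rep1$scores$statistic == "accuracy", ]
  expect_true(all(acc$mean[acc$classifier %in% c("svm", "rf", "knn")] >=
                    0.95))

  ys <- sample(y)
  rep2 <- benchmark_classifiers(x, ys, "pat", n_repetitions = 100, seed = 2)
  acc2 <- rep2$scores[rep2$scores$statistic == "accuracy", ]
  expect_true(all(abs(acc2$mean - 0.5) <= 0.15))

  expect_error(benchmark_classifiers(x[1:6, ], y[c(1:3, 31:33)], "pat"),
               "too small")
})

test_that("standardization uses training statistics only (no leakage)", {
  set.seed(76)
  xtr <- matrix(rnorm(20 * 4, 5, 2), 20)
  xte <- matrix(rnorm(10 * 4, -5, 7), 10)
  sc <- netreconfig:::standardize_fit(xtr)
  expect_equal(sc$mu, colMeans(xtr))
  expect_equal(sc$sd, apply(xtr, 2, sd))
  # applying train statistics to test data must not re-center the test set
  zte <- netreconfig:::standardize_apply(xte, sc)
  expect_gt(abs(mean(zte)), 1) # would be ~0 had test stats leaked in
  ztr <- netreconfig:::standardize_apply(xtr, sc)
  expect_lt(max(abs(colMeans(ztr))), 1e-10)
})

test_that("reproducibility: same seed gives the same report", {
  set.seed(77)
  x <- matrix(rnorm(40 * 5), 40)
  y <- rep(c("a", "b"), 20)
  r1 <- benchmark_classifiers(x, y, "a", n_repetitions = 10, seed = 9,
                              classifiers = c("svm", "knn", "nb"))
  r2 <- benchmark_classifiers(x, y, "a", n_repetitions = 10, seed = 9,
                              classifiers = c("svm", "knn", "nb"))
  expect_identical(r1$scores, r2$scores)
})
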