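# two-class toy table with known statistics
two_class_table <- function(x1, x2, extra = NULL) {
  vals <- cbind(f1 = c(x1, x2))
  if (!is.null(extra)) vals <- cbind(vals, extra)
  toyFeatures(vals, rep(c(1, 2), c(length(x1), length(x2))))
}

test_that("Fisher score matches its closed form and degenerate cases", {
  # means 0 and 2, unit variances -> F = 4/2 = 2
  set.seed(1)
  x1 <- scale(rnorm(200))[, 1]          # exactly mean 0, sd 1
  x2 <- scale(rnorm(200))[, 1] + 2
  tab <- two_class_table(x1, x2)
  expect_equal(fisherScore(tab, "f1", 1, 2), 2, tolerance = 1e-9)
  # identical distributions -> 0
  tab0 <- two_class_table(x1, x1)
  expect_equal(fisherScore(tab0, "f1", 1, 2), 0)
})

test_that("Welch t score matches the hand formula and t.test", {
  set.seed(2)
  x1 <- scale(rnorm(25))[, 1]           # mean 0, sd 1, n = 25
  x2 <- scale(rnorm(25))[, 1] + 1       # mean 1, sd 1, m = 25
  tab <- two_class_table(x1, x2)
  expect_equal(ttest2Score(tab, "f1", 1, 2), 1 / sqrt(2 / 25),
               tolerance = 1e-9)
  # independent oracle: the Welch statistic from stats::t.test
  expect_equal(ttest2Score(tab, "f1", 1, 2),
               abs(unname(t.test(x1, x2)$statistic)), tolerance = 1e-9)
  # symmetry in the class labels
  expect_equal(ttest2Score(tab, "f1", 2, 1), ttest2Score(tab, "f1", 1, 2))
})

test_that("Pearson class-similarity score has its analytic extremes", {
  set.seed(3)
  x1 <- rnorm(30)
  tab <- two_class_table(x1, 3 * x1 + 2)   # affine increasing copy -> |R| = 1
  expect_equal(pearsonScore(tab, "f1", 1, 2), 1, tolerance = 1e-12)
  # hand evaluation on two pairs
  tab2 <- two_class_table(c(0, 2), c(1, 5))
  # (1/2)*[(0-1)(1-3)+(2-1)(5-3)] / (1*2) = 2/2/... pop sds are 1 and 2
  expect_equal(pearsonScore(tab2, "f1", 1, 2), 1, tolerance = 1e-12)
  # independence -> near zero
  xa <- rnorm(4000); xb <- rnorm(4000)
  tab3 <- two_class_table(xa, xb)
  expect_lt(pearsonScore(tab3, "f1", 1, 2), 0.05)
  # unequal class sizes are rejected
  tab4 <- toyFeatures(cbind(f1 = rnorm(5)), c(1, 1, 1, 2, 2))
  expect_error(pearsonScore(tab4, "f1", 1, 2), "equal class sizes")
})

test_that("ANOVA score is the classical one-way F statistic", {
  set.seed(4)
  y <- rep(1:6, each = 10)
  x <- rnorm(60)
  tab <- toyFeatures(cbind(f1 = x), y)
  # independent oracle: aov
  f_aov <- summary(stats::aov(x ~ factor(y)))[[1]][["F value"]][1]
  expect_equal(anovaScore(tab, "f1"), f_aov, tolerance = 1e-9)
  # null Monte-Carlo: E[F] = dfw/(dfw-2) ~ 1 under the null
  fs <- replicate(300, {
    xx <- rnorm(60)
    anovaScore(toyFeatures(cbind(f1 = xx), y), "f1")
  })
  expect_equal(mean(fs), 54 / 52, tolerance = 0.15)
  # a far-shifted class gives a large F
  xs <- x; xs[y == 3] <- xs[y == 3] + 50
  expect_gt(anovaScore(toyFeatures(cbind(f1 = xs), y), "f1"), 1000)
})

test_that("two-class pooled ANOVA equals the squared pooled t", {
  set.seed(5)
  x1 <- rnorm(20); x2 <- rnorm(20) + 1
  tab <- toyFeatures(cbind(f1 = c(x1, x2)), rep(1:2, each = 20))
  t_pooled <- unname(t.test(x1, x2, var.equal = TRUE)$statistic)
  expect_equal(anovaScore(tab, "f1"), t_pooled^2, tolerance = 1e-9)
})

test_that("ReliefF rewards separating features and ignores noise", {
  set.seed(6)
  n <- 100
  y <- rep(1:2, each = n / 2)
  sep <- ifelse(y == 1, 0, 1) + rnorm(n, sd = 0.05)  # near-perfect separator
  noise <- rnorm(n)
  tab <- toyFeatures(cbind(sep = sep, noise = noise, sep2 = sep), y)
  w <- relieffScore(tab, k = 5)
  expect_gt(w[["sep"]], w[["noise"]])
  expect_gt(w[["sep"]], 0.5)
  expect_lt(abs(w[["noise"]]), 0.1)
  # duplicated feature column receives the same weight
  expect_equal(w[["sep"]], w[["sep2"]], tolerance = 1e-12)
})

test_that("a pure-noise feature has near-zero ReliefF weight at n = 200", {
  set.seed(7)
  y <- rep(1:2, each = 100)
  tab <- toyFeatures(cbind(f1 = rnorm(200)), y)
  w <- relieffScore(tab, k = 10)
  expect_lt(abs(w[["f1"]]), 0.05)
})

test_that("k is reduced with a warning when a class is too small", {
  y <- rep(1:2, c(4, 30))
  tab <- toyFeatures(cbind(f1 = rnorm(34)), y)
  expect_warning(relieffScore(tab, k = 10), "reducing k")
})

test_that("filter scores are invariant to affine feature transforms", {
  ft <- smallDirect()
  v <- featureValues(ft)
  f <- "AccYm"
  for (tr in list(c(3, 5), c(-2, 100))) {
    v2 <- v
    v2[, f] <- tr[1] * v2[, f] + tr[2]
    ft2 <- toyFeatures(v2, situations(ft))
    expect_equal(fisherScore(ft2, f, 1, 2), fisherScore(ft, f, 1, 2),
                 tolerance = 1e-9)
    expect_equal(ttest2Score(ft2, f, 2, 5), ttest2Score(ft, f, 2, 5),
                 tolerance = 1e-9)
    expect_equal(anovaScore(ft2, f), anovaScore(ft, f), tolerance = 1e-9)
    expect_equal(abs(pearsonScore(ft2, f, 3, 4)), pearsonScore(ft, f, 3, 4),
                 tolerance = 1e-9)
  }
})

test_that("aggregate filter normalizes to [0, 1] and ranks sensibly", {
  set.seed(8)
  y <- rep(1:6, each = 8)
  strong <- as.numeric(y) + rnorm(48, sd = 0.1)   # dominates every test
  tab <- toyFeatures(cbind(strong = strong,
                           weak1 = rnorm(48), weak2 = rnorm(48),
                           constant = rep(1, 48)), y)
  fs <- suppressWarnings(aggregateFilter(tab, relieffK = 5))
  expect_true(all(fs@normalized >= 0 & fs@normalized <= 1))
  expect_true(all(fs@aggregate >= 0 & fs@aggregate <= 1))
  expect_identical(fs@ranking$aggregate[1], "strong")
  expect_identical(fs@ranking$ttest2[1], "strong")
  # a constant feature scores 0 on every test statistic; after min-max
  # normalization it is 0 wherever 0 is the column minimum (ReliefF admits
  # negative weights, so there the constant need not be the minimum)
  expect_equal(unname(fs@raw["constant", 1:4]), rep(0, 4))
  expect_equal(unname(fs@normalized["constant", 1:4]), rep(0, 4))
  expect_equal(fs@raw["constant", "relieff"], 0, tolerance = 1e-12)
})

test_that("top-20 truncation returns exactly 20 names from the direct bank", {
  fs <- suppressWarnings(aggregateFilter(smallDirect(), relieffK = 5))
  top <- topFeatures(fs, "ttest2", 20)
  expect_length(top, 20)
  expect_false(anyDuplicated(top) > 0)
  expect_true(all(top %in% directFeatureNames()))
})

test_that("filter scores are invariant to trial permutation", {
  ft <- smallDirect()
  v <- featureValues(ft)
  set.seed(9)
  perm <- sample(nrow(v))
  ft2 <- toyFeatures(v[perm, ], situations(ft)[perm])
  fs1 <- suppressWarnings(aggregateFilter(ft, relieffK = 5))
  fs2 <- suppressWarnings(aggregateFilter(ft2, relieffK = 5))
  expect_equal(fs2@raw[, c("fisher", "ttest2", "anova", "relieff")],
               fs1@raw[, c("fisher", "ttest2", "anova", "relieff")],
               tolerance = 1e-9)
  expect_equal(fs2@aggregate[c("fisher", "ttest2")],
               fs1@aggregate[c("fisher", "ttest2")], tolerance = 1e-6)
})

test_that("SFS step 1 equals the brute-force single-feature argmax", {
  set.seed(10)
  y <- rep(1:3, each = 12)
  vals <- cbind(a = rnorm(36), b = as.numeric(y) + rnorm(36, sd = 0.6),
                c = rnorm(36), d = as.numeric(y) + rnorm(36, sd = 2),
                e = rnorm(36))
  tab <- toyFeatures(vals, y)
  evalfun <- function(fset)
    meanRate(evaluateCv(tab, fset, repetitions = 1, folds = 3, seed = 4,
                        maxit = 60))
  res <- sfsWrapper(tab, colnames(vals), evaluator = evalfun)
  brute <- vapply(colnames(vals), function(f) evalfun(f), numeric(1))
  best <- names(brute)[which.max(brute)]
  expect_identical(rankedFeatures(res)[1], best)
  expect_equal(accuracyTrace(res)[1], max(brute))
})

test_that("SFS ordering is a permutation and the prefix rule holds", {
  set.seed(11)
  y <- rep(1:2, each = 10)
  vals <- cbind(a = ifelse(y == 1, 0, 4) + rnorm(20, sd = 0.2),
                b = rnorm(20), c = rnorm(20))
  tab <- toyFeatures(vals, y)
  res <- sfsWrapper(tab, colnames(vals), folds = 2, seed = 3, maxit = 60)
  expect_setequal(rankedFeatures(res), colnames(vals))
  # a perfectly separating feature wins step 1 and suffices
  expect_identical(rankedFeatures(res)[1], "a")
  expect_identical(selectedFeatures(res), "a")
  expect_equal(accuracyTrace(res)[1], max(accuracyTrace(res)))
})

test_that("hybrid selection is contained in the filter top-20 and deterministic", {
  ft <- smallDirect()
  res1 <- suppressWarnings(
    hybridSelect(ft, variant = "ttest2", folds = 3, seed = 2, nKeep = 6,
                 relieffK = 5, maxit = 60))
  res2 <- suppressWarnings(
    hybridSelect(ft, variant = "ttest2", folds = 3, seed = 2, nKeep = 6,
                 relieffK = 5, maxit = 60))
  fs <- suppressWarnings(aggregateFilter(ft, relieffK = 5))
  expect_true(all(selectedFeatures(res1) %in% topFeatures(fs, "ttest2", 6)))
  expect_identical(rankedFeatures(res1), rankedFeatures(res2))
  expect_equal(accuracyTrace(res1), accuracyTrace(res2))
})

test_that("selection results export as a rank/accuracy CSV", {
  res <- new("SelectionResult", rankedFeatures = c("a", "b"),
             accuracyTrace = c(0.9, 0.95), selected = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSelection(res, path)
  df <- read.csv(path)
  expect_identical(df$feature, c("a", "b"))
  expect_equal(df$cv_accuracy_after_adding, c(0.9, 0.95))
})
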