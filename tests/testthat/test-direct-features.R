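test_that("acceleration statistics behave on constant and known signals", {
  acc <- cbind(rep(2.5, 50), rep(-1, 50), rep(9.8, 50))
  f <- suppressWarnings(accFeatures(acc))
  expect_length(f, 18)
  expect_equal(f[["AccXm"]], 2.5)
  expect_equal(f[["AccXmax"]], 2.5)
  expect_equal(f[["AccXvar"]], 0)
  expect_equal(f[["AccXstd"]], 0)
  expect_equal(f[["AccXrms"]], 2.5)
  expect_equal(f[["AccYrms"]], 1)      # rms of -1 is |−1|
  expect_error(accFeatures(acc[1:3, ]), "4 samples")
})

test_that("kurtosis follows the Pearson convention (normal -> 3)", {
  set.seed(42)
  acc <- cbind(rnorm(2e4), rnorm(2e4), rnorm(2e4))
  f <- accFeatures(acc)
  expect_equal(f[["AccYkurt"]], 3, tolerance = 0.2 / 3)
  # uniform kurtosis is 1.8
  accu <- cbind(runif(2e4), runif(2e4), runif(2e4))
  expect_equal(accFeatures(accu)[["AccXkurt"]], 1.8, tolerance = 0.05)
})

test_that("statokinesigram features match hand geometry on a unit square path", {
  cop <- copTrajectory(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), fs = 1)
  f <- statokinesigramFeatures(cop)
  expect_equal(f[["lg_tot"]], 3)
  expect_equal(f[["dist_prdr"]], 1)
  expect_equal(f[["Am_X"]], 1)
  expect_equal(f[["Am_Y"]], 1)
  expect_equal(f[["m_lg_seg"]], 1)
  expect_equal(f[["std_lg_seg"]], 0)
})

test_that("a repeated single point is fully degenerate", {
  cop <- copTrajectory(matrix(5, 10, 2), fs = 10)
  f <- suppressWarnings(statokinesigramFeatures(cop))
  expect_equal(unname(f[c("lg_tot", "Am_X", "Am_Y", "surf_ellip", "lfs")]),
               rep(0, 5))
  expect_warning(statokinesigramFeatures(cop), "degenerate")
})

test_that("the 90% ellipse has the Gaussian closed-form area and coverage", {
  set.seed(9)
  xy <- matrix(rnorm(2e4), ncol = 2)     # isotropic, sigma = 1
  f <- statokinesigramFeatures(copTrajectory(xy, fs = 100))
  chi2 <- qchisq(0.90, 2)                # 4.605: area = pi * chi2 * sigma^2
  expect_equal(f[["surf_ellip"]], pi * chi2, tolerance = 0.03)
  # empirical coverage of the ellipse
  S <- cov(xy)
  d2 <- mahalanobis(xy, colMeans(xy), S)
  expect_equal(mean(d2 <= chi2), 0.90, tolerance = 0.02 / 0.90)
})

test_that("stabilogram features satisfy their algebraic identities", {
  tr <- smallCorpus()[[8]]
  cop <- computeCop(tr, defaultLayout())
  f <- stabilogramFeatures(cop)
  expect_length(f, 30)
  expect_equal(f[["Xstd"]]^2, f[["Xvar"]], tolerance = 1e-9)
  expect_equal(f[["VYstd"]]^2, f[["VYvar"]], tolerance = 1e-9)
})

test_that("a constant-speed circle has Vm = r*omega and tiny Vstd", {
  fs <- 200; r <- 5; omega <- 2 * pi * 0.5      # rad/s
  t <- seq(0, 10, by = 1 / fs)
  cop <- copTrajectory(cbind(r * cos(omega * t), r * sin(omega * t)), fs = fs)
  f <- stabilogramFeatures(cop)
  expect_equal(f[["Vm"]], r * omega, tolerance = 1e-3)
  expect_lt(f[["Vstd"]], 0.05 * r * omega)
})

test_that("frequency features locate a pure tone and a flat spectrum", {
  fs <- 64; n <- 1024
  t <- (0:(n - 1)) / fs
  cop <- copTrajectory(cbind(sin(2 * pi * 1.5 * t), cos(2 * pi * 4 * t)), fs)
  f <- frequencyFeatures(cop)
  bin <- fs / n
  expect_equal(f[["mnfreqX"]], 1.5, tolerance = 2 * bin / 1.5)
  expect_equal(f[["mdfreqX"]], 1.5, tolerance = 2 * bin / 1.5)
  expect_equal(f[["mdfreqY"]], 4, tolerance = 2 * bin / 4)
  # white noise: mean frequency ~ fs/4 (first moment of a flat spectrum)
  set.seed(5)
  fw <- frequencyFeatures(copTrajectory(matrix(rnorm(2 * 2e4), ncol = 2), fs))
  expect_equal(fw[["mnfreqX"]], fs / 4, tolerance = 0.05)
  # constant signal -> all-zero features after mean removal
  fz <- frequencyFeatures(copTrajectory(matrix(3, 32, 2), fs))
  expect_equal(unname(fz), rep(0, 4))
})

test_that("the direct bank has exactly 60 stable, complete columns", {
  reg <- directFeatureNames()
  expect_length(reg, 60)
  expect_false(anyDuplicated(reg) > 0)
  ft <- smallDirect()
  expect_identical(colnames(featureValues(ft)), reg)
  expect_false(anyNA(featureValues(ft)))
  expect_equal(nrow(featureValues(ft)), length(smallCorpus()))
  # determinism: identical trials give identical rows
  two <- extractDirect(smallCorpus()[c(1, 1)], defaultLayout())
  v <- featureValues(two)
  expect_equal(v[1, ], v[2, ])
})

test_that("total path length dominates start-end distance on every trial", {
  ft <- featureValues(smallDirect())
  expect_true(all(ft[, "lg_tot"] >= ft[, "dist_prdr"] - 1e-12))
})

test_that("features are translation-invariant except the positional means", {
  set.seed(19)
  path <- 10 + apply(matrix(rnorm(2 * 300, sd = 0.5), ncol = 2), 2, cumsum)
  cop <- copTrajectory(path, fs = 100)
  shift <- c(3, -7)
  cop2 <- copTrajectory(sweep(copSamples(cop), 2, shift, `+`),
                        fs = samplingRate(cop))
  f1 <- c(stabilogramFeatures(cop), statokinesigramFeatures(cop))
  f2 <- c(stabilogramFeatures(cop2), statokinesigramFeatures(cop2))
  moved <- c("Xm", "Ym", "Xmax", "Ymax", "Xrms", "Yrms")
  same <- setdiff(names(f1), moved)
  expect_equal(f1[same], f2[same], tolerance = 1e-9)
  expect_equal(f2[["Xm"]], f1[["Xm"]] + 3, tolerance = 1e-9)
  expect_equal(f2[["Ym"]], f1[["Ym"]] - 7, tolerance = 1e-9)
})

test_that("adequate static trials sway less than inadequate ones", {
  ft <- featureValues(smallDirect())
  sit <- situations(smallDirect())
  for (col in c("Am_X", "Am_Y", "surf_ellip")) {
    expect_lt(mean(ft[sit == 5, col]), mean(ft[sit == 6, col]))
    expect_lt(mean(ft[sit == 1, col]), mean(ft[sit == 2, col]))
  }
})
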