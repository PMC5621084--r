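test_that("default situation specs encode the protocol contrasts", {
  specs <- defaultSituationSpecs()
  expect_length(specs, 6)
  expect_identical(vapply(specs, function(s) s@situation, integer(1)), 1:6)
  kinds <- vapply(specs, function(s) s@kind, character(1))
  expect_identical(kinds, c("static", "static", "dynamic", "dynamic",
                            "static", "static"))
  durations <- vapply(specs, function(s) s@duration, numeric(1))
  expect_identical(durations, c(20, 20, 15, 15, 20, 20))
  # adequate static sway < inadequate static sway
  disp <- vapply(specs, function(s) s@copDispersion, numeric(1))
  expect_lt(disp[1], disp[2])
  expect_lt(disp[5], disp[6])
  # dynamic excursions dwarf static dispersion
  sweep4 <- max(specs[[4]]@sweepAmplitude)
  expect_gt(sweep4, 5 * max(disp[c(1, 5)]))
  # head-acceleration means: X ~ (2, 2, 1, 2), Y ~ (0, 2, 0, 0) for the
  # static situations, Z dominated by gravity everywhere
  accX <- vapply(specs, function(s) s@accMeans[1], numeric(1))
  accY <- vapply(specs, function(s) s@accMeans[2], numeric(1))
  accZ <- vapply(specs, function(s) s@accMeans[3], numeric(1))
  expect_equal(accX[c(1, 2, 5, 6)], c(2, 2, 1, 2))
  expect_equal(accY[c(1, 2, 5, 6)], c(0, 2, 0, 0))
  expect_true(all(accZ > 9 & accZ < 10.5))
  expect_true(all(accZ > accX & accZ > accY))
  # COP centers inside the insole bounds
  for (s in specs) {
    expect_true(all(s@copCenter > 0))
    expect_true(s@copCenter[1] < 43 && s@copCenter[2] < 134)
  }
})

test_that("computeCop recovers the generator's target path", {
  # the generated pressures are a bilinear allocation of the simulated path:
  # the barycenter must invert it to well below 0.1 mm RMS
  lay <- defaultLayout()
  for (sit in c(1, 4)) {
    tr <- generateTrial(defaultSituationSpecs()[[sit]], lay, fs = 50,
                        seed = 99 + sit)
    cop <- copSamples(computeCop(tr, lay))
    xy <- sensorCoords(lay)
    expect_true(all(cop[, 1] >= min(xy[, 1]) & cop[, 1] <= max(xy[, 1])))
    expect_true(all(cop[, 2] >= min(xy[, 2]) & cop[, 2] <= max(xy[, 2])))
  }
  # explicit inverse check on a known path via the internal allocator
  set.seed(14)
  path <- cbind(runif(200, 5, 38), runif(200, 5, 129))
  P <- PostureSense:::.allocate_pressures(path, sensorCoords(lay), 700)
  tr <- postureTrial(P, matrix(9.8, 200, 3), 1, "alloc")
  rec <- copSamples(computeCop(tr, lay))
  rmse <- sqrt(mean((rec - path)^2))
  expect_lt(rmse, 0.1)
})

test_that("non-rectangular layouts allocate by non-negative least squares", {
  lay <- sensorLayout(rbind(c(2, 2), c(41, 2), c(21, 131), c(5, 80)))
  set.seed(15)
  path <- cbind(runif(50, 15, 25), runif(50, 20, 70))
  P <- PostureSense:::.allocate_pressures(path, sensorCoords(lay), 700)
  expect_true(all(P >= 0))
  tr <- postureTrial(P, matrix(9.8, 50, 3), 1, "nonrect")
  rec <- copSamples(computeCop(tr, lay))
  expect_lt(sqrt(mean((rec - path)^2)), 0.1)
})

test_that("trials are bit-reproducible from the seed", {
  spec <- defaultSituationSpecs()[[2]]
  t1 <- generateTrial(spec, seed = 5, fs = 50)
  t2 <- generateTrial(spec, seed = 5, fs = 50)
  expect_identical(pressures(t1), pressures(t2))
  expect_identical(headAcc(t1), headAcc(t2))
  t3 <- generateTrial(spec, seed = 6, fs = 50)
  expect_false(identical(pressures(t1), pressures(t3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(generateTrial(defaultSituationSpecs()[[1]],
                                        seed = 123, fs = 50))
  expect_identical(rnorm(1), before)
})

test_that("static COP dispersion approaches the AR(1) stationary scale", {
  # 10^4-sample simulated path: empirical s.d. within 15% of the stationary
  # dispersion implied by the AR(1) closed form
  spec <- defaultSituationSpecs()[[5]]
  set.seed(301)
  path <- PostureSense:::.simulate_cop_path(spec, 1e4, 50,
                                            c(2.5, 2.5), c(40.5, 131.5))
  dev <- sqrt(mean(c((path[, 1] - mean(path[, 1]))^2,
                     (path[, 2] - mean(path[, 2]))^2)))
  expect_equal(dev, spec@copDispersion, tolerance = 0.15)
  # end-to-end: generated trials carry lognormal trial effects on top, so
  # the geometric mean over several trials is a looser match
  lay <- defaultLayout()
  devs <- sapply(1:8, function(i) {
    tr <- generateTrial(spec, lay, fs = 50, seed = 300 + i)
    cop <- copSamples(computeCop(tr, lay))
    sqrt(mean(c((cop[, 1] - mean(cop[, 1]))^2, (cop[, 2] - mean(cop[, 2]))^2)))
  })
  expect_equal(exp(mean(log(devs))), spec@copDispersion, tolerance = 0.30)
})

test_that("the default corpus has the protocol shape", {
  corpus <- smallCorpus()
  expect_length(corpus, 36)
  expect_equal(as.integer(table(vapply(corpus, situation, integer(1)))),
               rep(6L, 6))
  durations <- vapply(corpus, function(tr) nrow(pressures(tr)) / tr@fsInsole,
                      numeric(1))
  sits <- vapply(corpus, situation, integer(1))
  expect_true(all(durations[sits %in% c(1, 2, 5, 6)] == 20))
  expect_true(all(durations[sits %in% c(3, 4)] == 15))
  # head-acceleration means approximate the situation table
  ft <- featureValues(smallDirect())
  for (sit in c(1, 2, 5, 6)) {
    spec <- defaultSituationSpecs()[[sit]]
    expect_equal(mean(ft[sits == sit, "AccXm"]), spec@accMeans[1],
                 tolerance = 0.3 / max(spec@accMeans[1], 1))
    expect_equal(mean(ft[sits == sit, "AccZm"]), 9.81, tolerance = 0.05)
  }
  # corpus-level determinism
  c1 <- generateCorpus(2, seed = 3, fs = 50)
  c2 <- generateCorpus(2, seed = 3, fs = 50)
  expect_identical(lapply(c1, pressures), lapply(c2, pressures))
  c3 <- generateCorpus(2, seed = 4, fs = 50)
  expect_false(identical(lapply(c1, pressures), lapply(c3, pressures)))
})

test_that("a misconfigured center outside the hull is rejected", {
  spec <- defaultSituationSpecs()[[1]]
  spec@copCenter <- c(60, 200)
  expect_error(generateTrial(spec, seed = 1), "outside the sensor hull")
})
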