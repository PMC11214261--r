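# Brute-force p-value oracle: the counting definition over the pooled
# multiset, written independently of the package's ranking code.
bruteForceP <- function(calib, a) {
  pool <- c(calib, a)
  sum(pool >= a) / length(pool)
}

test_that("standard p-values match the worked examples and the brute-force oracle", {
  expect_equal(pValueStandard(c(1, 2, 3, 4, 5), 3.5), 0.5)
  expect_equal(pValueStandard(c(1, 2, 3, 4, 5), 0), 1)
  expect_equal(pValueStandard(c(1, 2, 3, 4, 5), 10), 1 / 6)

  for (trial in 1:50) {
    calib <- withSeed(trial, round(stats::rnorm(sample(1:50, 1)), 1))
    tests <- withSeed(trial + 100, round(stats::rnorm(20), 1))
    expect_equal(pValueStandard(calib, tests),
                 vapply(tests, bruteForceP, 0, calib = calib))
  }
  expect_error(pValueStandard(numeric(0), 1), "empty calibration")
})

test_that("smoothed p-values split ties and reduce to standard at tau = 1", {
  expect_equal(pValueSmoothed(c(1, 2, 3), 2, 0.5), 0.5)
  expect_equal(pValueSmoothed(c(1, 2, 3), 2.5, 0.5), 0.375)
  calib <- c(0.3, 0.3, 1, 2, 2, 5)
  tests <- c(-1, 0.3, 1.5, 2, 9)
  expect_equal(pValueSmoothed(calib, tests, 1), pValueStandard(calib, tests))
  expect_error(pValueSmoothed(1:3, 1, 1.5), "tau")
})

test_that("interpolated p-values pass through knots, clamp at ends, stay within one step", {
  calib <- c(1, 2, 3, 4, 5)
  expect_equal(pValueInterpolated(calib, 2.5), 0.75)
  expect_equal(pValueInterpolated(calib, 0.2), 1)
  expect_equal(pValueInterpolated(calib, calib), pValueStandard(calib, calib))
  expect_equal(pValueInterpolated(calib, 100), 1 / 6)

  for (trial in 1:25) {
    # distinct calibration values: with k-fold ties the standard p-value
    # jumps by k/(n+1) at the knot and the one-step bound cannot hold
    calib <- withSeed(trial, stats::rnorm(sample(2:40, 1)))
    tests <- withSeed(trial + 50, stats::rnorm(30))
    pi <- pValueInterpolated(calib, tests)
    ps <- pValueStandard(calib, tests)
    n <- length(calib)
    expect_true(all(abs(pi - ps) <= 1 / (n + 1) + 1e-12))
    # monotone non-increasing in the test nonconformity
    ord <- order(tests)
    expect_true(all(diff(pi[ord]) <= 1e-12))
  }
})

test_that("mondrian calibration stores hold per-class nonconformities", {
  data <- genNumericClassification(200, imbalance = 0.25, seed = 21)
  m <- fitConformalClassifier(data, scorerConfig("svc"),
         strategy = samplingStrategy("random-stratified", 0.2, seed = 2))
  ns <- vapply(m@splits[[1]]$calibration, length, 0L)
  expect_equal(unname(ns), c(30, 10))  # 150:50 classes at ratio 0.2
  expect_true(all(vapply(m@splits[[1]]$calibration,
                         function(s) !is.unsorted(s), TRUE)))
})

test_that("every p-value respects the 1/(n+1) lower bound and set rule", {
  data <- toyClassification()
  m <- fitConformalClassifier(data, scorerConfig("svc"),
         strategy = samplingStrategy("random", 0.25, seed = 3))
  pv <- predictPValues(m, data@x[1:40, ])
  nByClass <- vapply(m@splits[[1]]$calibration, length, 0L)
  for (k in seq_along(nByClass))
    expect_true(all(pv[, k] >= 1 / (nByClass[k] + 1) - 1e-12))

  sets <- predictionSet(c(A = 0.4, B = 0.05), 0.1)
  expect_equal(sets[[1]], "A")
  expect_equal(predictionSet(c(A = 0.4, B = 0.05), 0.02)[[1]], c("A", "B"))
  expect_length(predictionSet(c(A = 0.4, B = 0.05), 0.5)[[1]], 0)
  # membership uses p >= epsilon, so a p-value exactly at the level is kept
  expect_equal(predictionSet(c(A = 0.1, B = 0.05), 0.1)[[1]], "A")
  expect_error(predictionSet(c(A = 0.4), 1.2), "epsilon")
})

test_that("a duplicated calibration object ties into its class p-value", {
  data <- toyClassification()
  m <- fitConformalClassifier(data, scorerConfig("svc"),
         strategy = samplingStrategy("random", 0.25, seed = 3))
  calIdx <- splitSampling(samplingStrategy("random", 0.25, seed = 3),
                          nrow(data@x), data@y)[[1]]$calibration
  pick <- calIdx[5]
  cls <- as.character(data@y[pick])
  nY <- length(m@splits[[1]]$calibration[[cls]])
  pv <- predictPValues(m, data@x[pick, , drop = FALSE])
  expect_gte(pv[1, cls], 2 / (nY + 1) - 1e-12)
})

test_that("ACP with one split equals ICP and aggregation averages p-values", {
  data <- toyClassification()
  icp <- fitConformalClassifier(data, scorerConfig("svc"),
           strategy = samplingStrategy("random", 0.2, nSplits = 1, seed = 5))
  acp1 <- fitConformalClassifier(data, scorerConfig("svc"),
           strategy = samplingStrategy("random", 0.2, nSplits = 1, seed = 5))
  expect_identical(predictPValues(icp, data@x[1:20, ]),
                   predictPValues(acp1, data@x[1:20, ]))

  acp3 <- fitConformalClassifier(data, scorerConfig("svc"),
           strategy = samplingStrategy("random", 0.2, nSplits = 3, seed = 5))
  perSplit <- lapply(acp3@splits, function(sp) {
    one <- acp3
    one@splits <- list(sp)
    predictPValues(one, data@x[1:10, ])
  })
  expect_equal(predictPValues(acp3, data@x[1:10, ]),
               Reduce(`+`, perSplit) / 3)
})

test_that("classes missing from a calibration part are a hard error", {
  x <- matrix(rnorm(24), 12)
  y <- rep(c("a", "b"), c(10, 2))
  data <- sparseFeatureSet(x, y, "classification")
  st <- samplingStrategy("predefined",
    partitions = list(list(properTrain = c(1:8, 11, 12), calibration = c(9, 10))))
  expect_error(fitConformalClassifier(data, scorerConfig("svc"), strategy = st),
               "absent from calibration.*split 1")
})

test_that("TCP ranks against same-label training instances plus the test object", {
  data <- separableData(16, seed = 8)
  pv <- tcpPredict(data, scorerConfig("svc", cost = 10), classificationNCM(),
                   data@x[3, , drop = FALSE])
  nUp <- sum(data@y == "up"); nDown <- sum(data@y == "down")
  # denominator structure: p is a multiple of 1/(n_y+1)
  expect_true(abs(pv[1, "up"] * (nUp + 1) - round(pv[1, "up"] * (nUp + 1))) < 1e-9)
  expect_true(abs(pv[1, "down"] * (nDown + 1) -
                    round(pv[1, "down"] * (nDown + 1))) < 1e-9)
  # a training duplicate ties with itself: p >= 2/(n_y+1) for its own class
  cls <- as.character(data@y[3])
  nY <- sum(data@y == cls)
  expect_gte(pv[1, cls], 2 / (nY + 1) - 1e-12)
  # deterministic
  expect_identical(pv, tcpPredict(data, scorerConfig("svc", cost = 10),
                                  classificationNCM(), data@x[3, , drop = FALSE]))
})

test_that("regression calibration stores and interval arithmetic are exact", {
  mult <- conformalsig:::.intervalMultiplier
  store <- c(1, 2, 3, 4, 5)
  expect_equal(mult(store, 0.5, FALSE), 3)    # k = ceil(0.5*6) = 3
  expect_equal(mult(store, 0.3, FALSE), 5)    # k = ceil(0.7*6) = 5
  expect_equal(mult(store, 0.15, FALSE), Inf) # k = 6 > n
  expect_equal(mult(store, 1 / 6 + 1e-9, FALSE), 5)
  # interpolated mode: q = (1-eps)(n+1), linear between order statistics
  expect_equal(mult(store, 0.25, TRUE), 4.5)  # q = 4.5
  expect_equal(mult(store, 0.15, TRUE), Inf)
  # scaled half-width arithmetic: sigma 2.0 with beta 0.01, multiplier 3
  expect_equal(3 * (2.0 + 0.01), 6.03)
})

test_that("abs-diff calibration equals the absolute residuals", {
  x <- matrix(seq(-3, 3, length.out = 40))
  data <- sparseFeatureSet(x, 2 * x[, 1], "regression")
  # calibration rows get labels shifted by known residuals 1..5
  yShift <- c(1, -2, 3, -4, 5)
  data@y[36:40] <- data@y[36:40] + yShift
  st <- samplingStrategy("predefined",
    partitions = list(list(properTrain = 1:35, calibration = 36:40)))
  m <- fitConformalRegressor(data, scorerConfig("svr", cost = 100,
                                                epsilon = 0.001),
                             regressionNCM("abs-diff"), st)
  expect_equal(m@splits[[1]]$calibration, 1:5, tolerance = 0.05)
})

test_that("normalized and log-normalized nonconformities follow their definitions", {
  data <- genNumericRegression(200, c(2, -1), noise = 0.6,
                               heteroscedastic = TRUE, seed = 31)
  st <- samplingStrategy("random", 0.2, seed = 4)
  calIdx <- splitSampling(st, nrow(data@x))[[1]]$calibration
  for (kind in c("normalized", "log-normalized")) {
    ncm <- regressionNCM(kind, beta = 0.01)
    m <- fitConformalRegressor(data, scorerConfig("svr"), ncm, st)
    sp <- m@splits[[1]]
    calX <- data@x[calIdx, , drop = FALSE]
    resid <- abs(data@y[calIdx] - decisionScores(sp$scorer, calX))
    eHat <- decisionScores(sp$errorModel, calX)
    sigma <- if (kind == "normalized") pmax(eHat, 0) + 0.01
             else exp(eHat) + 0.01
    expect_equal(sp$calibration, sort(resid / sigma), info = kind)
    expect_true(all(sigma > 0))
  }
})

test_that("intervals widen as significance decreases, both modes", {
  data <- toyRegression()
  grid <- seq(0.05, 0.5, by = 0.05)
  for (mode in c("standard", "linear-interpolated")) {
    m <- fitConformalRegressor(data, scorerConfig("svr"),
           regressionNCM("abs-diff"),
           samplingStrategy("random", 0.25, seed = 6),
           pconfig = pValueConfig(mode))
    iv <- predictInterval(m, data@x[1:5, ], grid)
    for (r in 1:5) {
      w <- iv$upper[iv$row == r] - iv$lower[iv$row == r]
      expect_true(all(diff(w) <= 1e-9))
      expect_true(all(iv$lower[iv$row == r] <= iv$midpoint[iv$row == r] &
                        iv$midpoint[iv$row == r] <= iv$upper[iv$row == r]))
    }
  }
})

test_that("normalized NCM beats abs-diff on heteroscedastic data", {
  train <- genNumericRegression(1200, c(2, -1), noise = 0.8,
                                heteroscedastic = TRUE, seed = 41)
  test <- genNumericRegression(800, c(2, -1), noise = 0.8,
                               heteroscedastic = TRUE, seed = 42)
  st <- samplingStrategy("random", 0.25, seed = 7)
  # an RBF error model is needed: the residual scale 1 + |x1| is not a
  # linear function of the features
  cfg <- scorerConfig("svr", kernel = "rbf")
  mAbs <- fitConformalRegressor(train, cfg, regressionNCM("abs-diff"), st)
  mNorm <- fitConformalRegressor(train, cfg, regressionNCM("normalized"), st)
  ivA <- predictInterval(mAbs, test@x, 0.2)
  ivN <- predictInterval(mNorm, test@x, 0.2)
  mA <- regressionMetrics(ivA, test@y)
  mN <- regressionMetrics(ivN, test@y)
  # difficulty scaling narrows the typical (median) interval at equal
  # coverage; under 1 + |x1| Gaussian heteroscedasticity the MEAN width
  # does not improve even with a perfect error model (the scaling trades
  # tail width for center width), so the median is the honest comparison
  expect_lt(mN$medianWidth, mA$medianWidth)
  expect_lt(abs(mN$errorRate - mA$errorRate), 0.06)
})

test_that("smoothed p-values of the true class are uniform on exchangeable data", {
  train <- genNumericClassification(2000, seed = 51)
  test <- genNumericClassification(5000, seed = 52)
  m <- fitConformalClassifier(train, scorerConfig("svc"),
         strategy = samplingStrategy("random-stratified", 0.5, seed = 8),
         pconfig = pValueConfig("smoothed", tau = "random", seed = 9))
  pv <- predictPValues(m, test@x)
  pTrue <- pv[cbind(seq_len(nrow(pv)), as.integer(test@y))]
  ks <- suppressWarnings(stats::ks.test(pTrue, "punif"))
  # Conditional on one calibration draw of nCal values per class, the test
  # p-values are iid from a CDF that itself fluctuates around uniform at
  # scale 1/sqrt(nCal) (a two-sample comparison): the 1% critical value is
  # taken at the effective sample size 1/(1/m + 1/nCal).
  nCal <- length(m@splits[[1]]$calibration[[1]])
  nEff <- 1 / (1 / 5000 + 1 / nCal)
  expect_lt(unname(ks$statistic), 1.63 / sqrt(nEff))
})
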