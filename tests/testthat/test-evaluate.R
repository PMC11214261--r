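test_that("classification metrics match hand counting", {
  pv <- rbind(c(A = 0.5, B = 0.2), c(A = 0.6, B = 0.4))
  m <- classificationMetrics(pv, c("A", "A"), grid = 0.3)
  expect_equal(m$observedFuzziness, 0.3)  # mean of false-label p: (0.2+0.4)/2

  # sets {A},{A,B},{} with truths A,A,B
  pv2 <- rbind(c(A = 0.5, B = 0.1), c(A = 0.5, B = 0.4), c(A = 0.05, B = 0.1))
  m2 <- classificationMetrics(pv2, c("A", "A", "B"), grid = 0.2)
  expect_equal(m2$perEpsilon$averageC, 1.0)
  expect_equal(m2$perEpsilon$singleRatio, 1 / 3)
  expect_equal(m2$perEpsilon$errorRate, 1 / 3)
  expect_equal(m2$perEpsilon$emptyRatio, 1 / 3)
  conf <- m2$confusion
  expect_equal(conf$correctSingle[conf$class == "A"], 1L)
  expect_equal(conf$multi[conf$class == "A"], 1L)
  expect_equal(conf$empty[conf$class == "B"], 1L)
  # per-true-class counts sum to that class's test count
  expect_equal(conf$correctSingle + conf$wrongSingle + conf$multi + conf$empty,
               c(2L, 1L))

  pv3 <- rbind(c(A = 0.9, B = 0), c(A = 0.7, B = 0))
  expect_equal(classificationMetrics(pv3, c("A", "A"),
                                     grid = 0.1)$observedFuzziness, 0)
  expect_error(classificationMetrics(pv3, c("A", "C"), grid = 0.1),
               "label domain")
})

test_that("regression metrics handle finite and infinite intervals", {
  iv <- data.frame(row = c(1, 2), epsilon = 0.2,
                   lower = c(0, 1), upper = c(2, 3))
  m <- regressionMetrics(iv, c(1, 5))
  expect_equal(m$errorRate, 0.5)
  expect_equal(m$meanWidth, 2)

  ivInf <- data.frame(row = 1:2, epsilon = 0.1,
                      lower = -Inf, upper = Inf)
  mInf <- regressionMetrics(ivInf, c(10, -10))
  expect_equal(mInf$errorRate, 0)
  expect_equal(mInf$nInfinite, 2L)

  ivW <- data.frame(row = 1:3, epsilon = 0.2, lower = 0,
                    upper = c(2, 4, 100))
  expect_equal(regressionMetrics(ivW, c(1, 1, 1))$medianWidth, 4)
})

test_that("calibration statistics match the capped-RMSE definition", {
  s <- calibrationStats(c(0.05, 0.25), c(0.1, 0.2))
  expect_equal(s$cappedRMSE, sqrt((0^2 + 0.05^2) / 2))
  expect_equal(s$cappedRMSE, 0.03535534, tolerance = 1e-6)
  expect_equal(s$maxSignedDeviation, 0.05)

  grid <- seq(0.05, 0.3, 0.05)
  perfect <- calibrationStats(grid, grid)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$cappedRMSE, 0)
  expect_equal(perfect$maxSignedDeviation, 0)

  conservative <- calibrationStats(grid - 0.02, grid)
  expect_equal(conservative$cappedRMSE, 0)
  expect_gt(conservative$rmse, 0)
  expect_error(calibrationStats(c(0.1), c(0.1, 0.2)), "length mismatch")
})

test_that("capped RMSE never exceeds RMSE on random curves", {
  for (trial in 1:20) {
    grid <- significanceGrid("classification")
    err <- withSeed(trial, pmin(pmax(grid + stats::rnorm(30, 0, 0.05), 0), 1))
    s <- calibrationStats(err, grid)
    expect_lte(s$cappedRMSE, s$rmse + 1e-15)
  }
})

test_that("validation schemes run, aggregate and reproduce", {
  data <- genNumericClassification(120, seed = 71)
  spec <- list(scorer = scorerConfig("svc"),
               ncm = classificationNCM(),
               strategy = samplingStrategy("random", 0.3, seed = 1))
  v1 <- runValidation(data, spec, scheme = list(kind = "kfold", k = 4),
                      seed = 5, grid = c(0.1, 0.2))
  expect_length(v1$perFold, 4)
  expect_true(all(c("mean", "sd") %in% names(v1$summary)))
  v2 <- runValidation(data, spec, scheme = list(kind = "kfold", k = 4),
                      seed = 5, grid = c(0.1, 0.2))
  expect_identical(v1$summary, v2$summary)

  # stratified folds keep the class ratio within one record
  folds <- conformalsig:::.validationFolds(list(kind = "kfold", k = 5),
    100, factor(rep(c("a", "b"), c(90, 10))), TRUE, 3, 1)
  for (f in folds)
    expect_equal(sum(f > 90), 2)  # 10 minority records over 5 folds

  expect_error(runValidation(data, spec, scheme = list(kind = "kfold", k = 999)),
               "k > n")
  expect_error(runValidation(data, spec,
                             scheme = list(kind = "split", fraction = 2)),
               "fraction")
})

test_that("leave-one-out performs one evaluation per record", {
  data <- genNumericClassification(25, seed = 72)
  spec <- list(scorer = scorerConfig("svc"),
               ncm = classificationNCM(),
               strategy = samplingStrategy("random", 0.3, seed = 1))
  v <- runValidation(data, spec, scheme = list(kind = "loo"), grid = 0.2)
  expect_length(v$perFold, 25)
  expect_true(v$pooled)
})

test_that("the default RBF grid enumerates 60 combinations", {
  g <- defaultRBFGrid()
  expect_length(g$cost, 10)
  expect_length(g$gamma, 6)
  expect_equal(g$cost[1], 2^-6)
  expect_equal(g$cost[10], 2^12)
  expect_equal(g$gamma, 2^seq(-14, -4, 2))
  expect_equal(nrow(expand.grid(g)), 60)
})

test_that("grid search finds the separating configuration and breaks ties in order", {
  # XOR layout: solvable by an RBF scorer only at an adequate kernel width
  x <- withSeed(9, {
    centers <- matrix(c(1, 1, -1, -1, 1, -1, -1, 1), 4, 2, byrow = TRUE)
    centers[rep(1:4, each = 15), ] + 0.2 * matrix(stats::rnorm(120), 60, 2)
  })
  y <- rep(c("a", "a", "b", "b"), each = 15)
  data <- sparseFeatureSet(x, y, "classification")
  res <- gridSearch(data, scorerConfig("svc", kernel = "rbf", cost = 10),
                    list(gamma = c(1e-7, 1)), mode = "scorer-only",
                    scheme = list(kind = "kfold", k = 4), seed = 2)
  expect_equal(res$best$gamma, 1)  # near-constant kernel cannot solve XOR
  expect_gt(max(res$results$objective), 0.95)
  expect_equal(res$objectiveName, "macroF1")

  # equal objectives: first grid point in enumeration order wins
  resTie <- gridSearch(data, scorerConfig("svc", kernel = "rbf", cost = 10),
                       list(gamma = c(1, 1.000001)), mode = "scorer-only",
                       scheme = list(kind = "kfold", k = 4), seed = 2)
  if (abs(diff(resTie$results$objective)) < 1e-12)
    expect_equal(resTie$best$gamma, 1)

  expect_error(gridSearch(data, scorerConfig("svc"), list(nonsense = 1)),
               "unknown tuning parameter")
})

test_that("scorer-only tuning never trains a calibration store", {
  data <- genNumericClassification(100, seed = 73)
  before <- conformalsig:::.calibrationFitCount()
  gridSearch(data, scorerConfig("svc"), list(cost = c(0.5, 2)),
             mode = "scorer-only", scheme = list(kind = "kfold", k = 3),
             seed = 4)
  expect_equal(conformalsig:::.calibrationFitCount(), before)

  gridSearch(data, scorerConfig("svc"), list(cost = c(0.5, 2)),
             mode = "full-predictor", objective = "observedFuzziness",
             scheme = list(kind = "kfold", k = 3),
             spec = list(strategy = samplingStrategy("random", 0.3, seed = 1)),
             seed = 4)
  expect_gt(conformalsig:::.calibrationFitCount(), before)
})

test_that("metric files are tidy and machine-readable", {
  pv <- rbind(c(A = 0.5, B = 0.1), c(A = 0.3, B = 0.2))
  m <- classificationMetrics(pv, c("A", "B"), grid = c(0.1, 0.2))
  prefix <- tempfile()
  writeMetrics(m, prefix)
  csv <- utils::read.csv(paste0(prefix, ".csv"))
  expect_true(all(c("epsilon", "metric", "value") %in% names(csv)))
  expect_true("observedFuzziness" %in% csv$metric)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_true("perEpsilon" %in% names(js))
})
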