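# Scaling, SVM training, cross-validation, prediction, persistence

test_that("min-max scaling maps the training range onto [0,1] with clipping", {
  x <- matrix(c(-1.17, 0.15, 1.36), ncol = 1)
  sc <- fitScaler(x)
  expect_equal(sc$min, -1.17, ignore_attr = TRUE)
  expect_equal(sc$max, 1.36, ignore_attr = TRUE)
  y <- applyScaler(sc, x)
  expect_equal(as.numeric(y), c(0, (0.15 + 1.17) / 2.53, 1))
  expect_equal(as.numeric(y)[2], 0.5217, tolerance = 1e-4)
  # unseen values are clipped into [0,1]
  expect_equal(as.numeric(applyScaler(sc, matrix(c(2.0, -5)))), c(1, 0))
  # constant columns map to 0
  xc <- matrix(7, nrow = 3, ncol = 1)
  expect_true(all(applyScaler(fitScaler(xc), xc) == 0))
  expect_error(applyScaler(sc, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("training separates a separable toy problem and validates input", {
  x <- matrix(c(rep(1, 20), rep(0, 20)), ncol = 1)
  x <- cbind(x, 0.5)  # constant second feature
  fm <- methods::new("CleavageFeatures", x = x,
                     labels = c(rep(1L, 20), rep(-1L, 20)),
                     indexMap = S4Vectors::DataFrame(
                       feature = c("P1_VHSE1", "P1'_VHSE1"),
                       position = c("P1", "P1'"),
                       component = c(1L, 1L)),
                     scaled = TRUE)
  m <- trainSvm(fm, kernel = "linear", C = 10)
  pred <- predictCleavage(m, fm)
  expect_identical(pred$label, fm@labels)
  # margin property: support-vector decision values reach the margin
  expect_true(all(abs(decisionValues(m, m@supportVectors)) >= 1 - 1e-2))
  # input validation
  expect_error(trainSvm(fm, kernel = "poly"), "kernel")
  expect_error(trainSvm(fm, C = -1), "positive")
  expect_error(trainSvm(fm, kernel = "rbf"), "gamma")
  one <- methods::new("CleavageFeatures", x = x[1:20, , drop = FALSE],
                      labels = rep(1L, 20), indexMap = fm@indexMap,
                      scaled = TRUE)
  expect_error(trainSvm(one), "both")
})

test_that("linear decision values equal the explicit w, b on random inputs", {
  fx <- fixtureLinearModel()
  m <- fx$model
  set.seed(3)
  x <- matrix(runif(20 * length(m@w)), ncol = length(m@w))
  expect_equal(decisionValues(m, x), as.numeric(x %*% m@w + m@b),
               tolerance = 1e-8)
  # decision(x) - decision(0) recovers w . x
  d0 <- decisionValues(m, matrix(0, 1, length(m@w)))
  expect_equal(decisionValues(m, x) - d0, as.numeric(x %*% m@w),
               tolerance = 1e-8)
})

test_that("pipeline is invariant to affine transforms of raw feature columns", {
  fx <- fixtureLinearModel()
  raw <- fx$raw
  shifted <- raw
  shifted@x <- sweep(sweep(raw@x, 2, runif(ncol(raw@x), 0.5, 2), "*"),
                     2, rnorm(ncol(raw@x)), "+")
  s1 <- applyScaler(fitScaler(raw), raw)
  s2 <- applyScaler(fitScaler(shifted), shifted)
  expect_equal(s1@x, s2@x, tolerance = 1e-12)
})

test_that("stratified CV has balanced folds and is seed-deterministic", {
  n <- 100L
  set.seed(5)
  x <- matrix(rnorm(n * 4), ncol = 4)
  y <- c(rep(1L, 60), rep(-1L, 40))
  x[y == 1L, 1] <- x[y == 1L, 1] + 1.5
  x <- (x - min(x)) / (max(x) - min(x))
  fm <- methods::new("CleavageFeatures", x = x, labels = y,
                     indexMap = S4Vectors::DataFrame(
                       feature = c("P2_VHSE1", "P1_VHSE1",
                                   "P1'_VHSE1", "P2'_VHSE1"),
                       position = c("P2", "P1", "P1'", "P2'"),
                       component = rep(1L, 4)),
                     scaled = TRUE)
  cv <- crossValidate(fm, Cgrid = c(0.5, 2), folds = 10L, seed = 99L)
  folds <- cv$folds
  expect_identical(as.integer(table(folds)), rep(10L, 10L))
  # class ratio 6:4 within every fold (+/- 1)
  for (f in 1:10) {
    expect_lte(abs(sum(y[folds == f] == 1L) - 6L), 1L)
    expect_lte(abs(sum(y[folds == f] == -1L) - 4L), 1L)
  }
  cv2 <- crossValidate(fm, Cgrid = c(0.5, 2), folds = 10L, seed = 99L)
  expect_identical(cv$table, cv2$table)
  expect_identical(cv$best$C, cv2$best$C)
  cv3 <- crossValidate(fm, Cgrid = c(0.5, 2), folds = 10L, seed = 7L)
  expect_identical(colnames(cv3$table), colnames(cv$table))
  expect_error(crossValidate(fm, folds = 45L), "per class")
})

test_that("prediction flags unscorable windows instead of dropping them", {
  fx <- fixtureLinearModel()
  m <- fx$model
  wins <- sampleWindows(fx$sampleSet)[1:3]
  p <- predictCleavage(m, c(wins[1], "SHORT", wins[2],
                            paste0("X", substr(wins[3], 2, 20))))
  expect_identical(p$status,
                   c("ok", "wrong_length", "ok", "non_canonical_residue"))
  expect_true(all(is.na(p$decision[p$status != "ok"])))
  expect_false(anyNA(p$decision[p$status == "ok"]))
  # identical input twice gives identical output
  p2 <- predictCleavage(m, c(wins[1], wins[1]))
  expect_identical(p2$decision[1], p2$decision[2])
  expect_error(predictCleavage(m, matrix(0, 2, 7)), "dimension mismatch")
})

test_that("JSON persistence round-trips linear and RBF models", {
  fx <- fixtureLinearModel()
  raw <- fx$raw
  scaled <- applyScaler(fx$scaler, raw)
  x <- scaled@x[1:7, , drop = FALSE]
  for (spec in list(list(kernel = "linear", gamma = NULL),
                    list(kernel = "rbf", gamma = 0.05))) {
    m <- trainSvm(scaled, kernel = spec$kernel, C = 1,
                  gamma = spec$gamma, scaler = fx$scaler)
    f <- withr::local_tempfile(fileext = ".json")
    saveModel(m, f, provenance = "test")
    m2 <- loadModel(f)
    expect_identical(m2@kernel, m@kernel)
    expect_equal(decisionValues(m2, x), decisionValues(m, x),
                 tolerance = 1e-10)
    expect_identical(m2@halfWidth, m@halfWidth)
    expect_identical(m2@selection, m@selection)
  }
  expect_error(loadModel(withr::local_tempfile(lines = "{}",
                                               fileext = ".json")),
               "not a procleave model")
})

test_that("feature CSV export/import preserves matrix, labels and index map", {
  fx <- fixtureLinearModel()
  raw <- fx$raw
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCsv(raw, f)
  back <- readFeatureCsv(f)
  expect_equal(back@x, raw@x, ignore_attr = TRUE)
  expect_identical(back@labels, raw@labels)
  expect_identical(as.character(back@indexMap$position),
                   as.character(raw@indexMap$position))
  expect_identical(back@indexMap$component, raw@indexMap$component)
})
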