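test_that("PLS recovers an exact linear relation perfectly", {
  set.seed(1)
  # single informative column, one component: exact recovery
  X1 <- cbind(a = rnorm(12))
  y1 <- 2 + 3 * X1[, "a"]
  m1 <- fitPls(X1, y1, 1)
  expect_equal(m1@r2, 1, tolerance = 1e-9)
  expect_equal(m1@see, 0, tolerance = 1e-6)
  expect_equal(predictPls(m1, X1), y1, tolerance = 1e-8, ignore_attr = TRUE)
  # noise-free signal inside a wider matrix: exact at full rank
  X <- cbind(X1, b = rnorm(12), c = rnorm(12))
  m3 <- fitPls(X, y1, 3)
  expect_equal(m3@r2, 1, tolerance = 1e-9)
})

test_that("full-rank PLS equals ordinary least squares", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(30), 10, 3)
    y <- drop(X %*% rnorm(3)) + rnorm(10, 0, 0.3)
    m <- fitPls(X, y, 3)
    ols <- stats::lm.fit(cbind(1, X), y)
    expect_equal(m@fitted, drop(cbind(1, X) %*% ols$coefficients),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("PLS predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  X <- matrix(rnorm(25 * 12), 25, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  y <- drop(X[, 1:3] %*% c(1, -0.5, 0.25)) + rnorm(25, 0, 0.2)
  m <- fitPls(X, y, 4)
  ref <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  refFit <- drop(stats::predict(ref, X)$predict[, 1, 4])
  expect_equal(m@fitted, refFit, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("row duplication leaves coefficients unchanged", {
  set.seed(3)
  X <- matrix(rnorm(24), 8, 3)
  y <- drop(X %*% c(1, 2, -1)) + rnorm(8, 0, 0.1)
  m1 <- fitPls(X, y, 2)
  m2 <- fitPls(rbind(X, X), c(y, y), 2)
  expect_equal(coef(m1), coef(m2), tolerance = 1e-8)
})

test_that("guard rails on degenerate fits", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fitPls(X, rep(2, 4), 1), "zero-variance")
  expect_error(fitPls(X, rnorm(4), 4), "ncomp")
  expect_error(fitPls(X[1:2, ], rnorm(2), 1), "at least 3")
})

test_that("LOO q2 equals an explicit n-refit loop", {
  s <- cachedSeries()
  keep <- 1:14
  X <- s$M[keep, ]; y <- s$act$pic50[keep]
  got <- looQ2(X, y, 3)
  # independent brute-force loop over held-out samples
  pred <- vapply(seq_along(y), function(i) {
    m <- fitPls(X[-i, ], y[-i], 3)
    predictPls(m, X[i, , drop = FALSE])
  }, 1)
  press <- sum((y - pred)^2)
  expect_equal(got$press, press, tolerance = 1e-10)
  expect_equal(got$q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(got$sep, sqrt(press / (length(y) - 3 - 1)), tolerance = 1e-10)
})

test_that("q2 is near 1 for noise-free signal and low for permuted response", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- drop(X %*% c(2, -1, 0.5, 0, 0, 0))
  expect_gt(looQ2(X, y, 6)$q2, 0.999)
  # permutation control: 50 seeded repeats
  q2perm <- vapply(1:50, function(s) {
    yp <- scrambleLabels(y, 1, seed = s)
    looQ2(X, yp, 3)$q2
  }, 1)
  expect_true(mean(q2perm <= 0.2) >= 0.95)
  expect_lt(stats::median(q2perm), 0)
})

test_that("component selection finds planted low-rank structure", {
  set.seed(8)
  n <- 30
  scoresTrue <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(rnorm(2 * 40), 2, 40)
  X <- scoresTrue %*% load + matrix(rnorm(n * 40, 0, 0.05), n, 40)
  y <- drop(scoresTrue %*% c(2, -1)) + rnorm(n, 0, 0.1)
  sel <- selectOnc(X, y, 8)
  expect_equal(sel$onc, 2L)
  expect_gt(max(sel$q2ByComponent), 0.9)
  # pure-noise response: onc collapses to 1 with useless q2
  yNoise <- withr::with_seed(42, rnorm(n))
  selN <- selectOnc(X, yNoise, 8)
  expect_equal(selN$onc, 1L)
  expect_lt(max(selN$q2ByComponent), 0.2)
  expect_equal(selectOnc(X, y, 1)$onc, 1L)
})

test_that("field contributions reflect |coef| * sd mass per kind", {
  s <- cachedSeries()
  m <- fitPls(s$block, s$act$pic50, 3)
  contrib <- fieldContributions(m, s$block)
  expect_equal(sum(contrib), 100, tolerance = 0.1)
  expect_true(all(contrib >= 0))
  expect_setequal(names(contrib), c("S", "E"))
  # constructed 3:1 ratio across two kinds
  X <- cbind(a = c(-3, -1, 1, 3, 0, 0), b = c(0, 0, -1.5, 1.5, -1.5, 1.5))
  blk <- new("DescriptorBlock", matrix = X * 4,
             columnMeta = data.frame(point = 1:2, kind = c("S", "E")),
             keptMask = c(TRUE, TRUE), imputed = matrix(FALSE, 6, 2),
             scheme = "comfa", grid = GridSpec(c(0, 0, 0), 2, c(2, 1, 1)))
  y <- drop(X %*% c(1, 1))
  mm <- fitPls(blk, y, 2)
  w <- abs(coef(mm)) * mm@colSD
  expect_equal(unname(100 * w / sum(w)),
               unname(fieldContributions(mm, blk)[c("S", "E")]),
               tolerance = 1e-9)
  # single-kind block is 100%
  blk1 <- new("DescriptorBlock", matrix = X,
              columnMeta = data.frame(point = 1:2, kind = "S"),
              keptMask = c(TRUE, TRUE), imputed = matrix(FALSE, 6, 2),
              scheme = "comfa", grid = GridSpec(c(0, 0, 0), 2, c(2, 1, 1)))
  m1 <- fitPls(blk1, y, 2)
  expect_equal(unname(fieldContributions(m1, blk1)), 100)
})

test_that("StDev*Coeff field maps kept columns back to grid points", {
  s <- cachedSeries()
  m <- fitPls(s$block, s$act$pic50, 3)
  cf <- stdevCoeffField(m, s$block)
  expect_equal(nrow(cf@values), nGridPoints(s$grid))
  # sign of the field value matches the coefficient sign, exhaustively
  sc <- coef(m) * m@colSD
  meta <- columnMeta(s$block)
  expect_equal(vapply(seq_along(sc), function(j)
    cf@values[meta$point[j], meta$kind[j]], 1), unname(sc),
    tolerance = 1e-12)
  # filtered-out columns stay zero
  dropped <- columnMeta(s$block, filtered = FALSE)[!s$block@keptMask, ]
  onlyDropped <- !dropped$point %in% meta$point
  if (any(onlyDropped))
    expect_true(all(cf@values[dropped$point[onlyDropped], ] == 0))
})

test_that("prediction is linear and honours the centering identity", {
  s <- cachedSeries()
  m <- fitPls(s$block, s$act$pic50, 3)
  X <- s$M
  expect_equal(predictPls(m, X), m@fitted, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(predictPls(m, matrix(m@xMean, 1)), m@yMean, tolerance = 1e-9)
  a <- 0.3
  mix <- a * X[1, ] + (1 - a) * X[2, ]
  expect_equal(predictPls(m, matrix(mix, 1)),
               a * predictPls(m, X[1, , drop = FALSE]) +
                 (1 - a) * predictPls(m, X[2, , drop = FALSE]),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(predictPls(m, X[, 1:5]), "columns")
})

test_that("model JSON serialization round-trips predictions", {
  s <- cachedSeries()
  m <- fitPlsCv(s$block, s$act$pic50, ncomp = 3)
  f <- tempfile(fileext = ".json")
  writePlsModelJson(m, f)
  back <- readPlsModelJson(f)
  expect_equal(predictPls(back, s$M), predictPls(m, s$M), tolerance = 1e-10)
  expect_equal(back@q2, m@q2, tolerance = 1e-12)
})
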