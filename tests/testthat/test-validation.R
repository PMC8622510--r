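test_that("fitness metrics match hand-evaluated closed forms", {
  y <- c(1, 2); yhat <- c(1.1, 1.9)
  fm <- fitnessMetrics(y, yhat)
  expect_equal(fm$rmse, sqrt(0.02 / 1), tolerance = 1e-9)   # n - 1 = 1
  expect_equal(fm$rmse, 0.14142, tolerance = 1e-5)
  expect_equal(fm$chi2, 0.01 / 1 + 0.01 / 4, tolerance = 1e-12)
  expect_equal(fm$mae, 0.1, tolerance = 1e-12)
  expect_equal(fm$rss, 0.02, tolerance = 1e-12)
  # alternate denominator convention
  fmY <- fitnessMetrics(y, yhat, chiDenominator = "y")
  expect_equal(fmY$chi2, 0.01 / 1 + 0.01 / 2, tolerance = 1e-12)
  # perfect prediction zeroes everything
  fm0 <- fitnessMetrics(y, y)
  expect_true(all(unlist(fm0) == 0))
  expect_error(fitnessMetrics(c(0, 1), c(0, 1)), "0")
})

test_that("perfect external prediction saturates every metric", {
  y <- c(5, 6, 7, 5.5, 6.5)
  rep <- externalMetrics(y, y, yTrain = c(4, 5, 6, 7, 8))
  m <- metrics(rep)
  # rm2 involves sqrt(|r2 - r0^2|), which amplifies ~1e-15 rounding to ~1e-7
  expect_equal(unname(m[c("k", "k_prime", "r0_2", "r2", "rm2", "qf3_2",
                          "ccc")]),
               rep(1, 7), tolerance = 1e-6)
  expect_true(all(passFlags(rep)))
})

test_that("external metrics equal an independent closed-form recomputation", {
  # spreadsheet-style oracle coded from the definitions
  oracle <- function(y, f, ytr) {
    r2 <- cor(y, f)^2
    k <- sum(y * f) / sum(f^2); kp <- sum(y * f) / sum(y^2)
    r02 <- 1 - sum((y - k * f)^2) / sum((y - mean(y))^2)
    r02p <- 1 - sum((f - kp * y)^2) / sum((f - mean(f))^2)
    rm2 <- r2 * (1 - sqrt(abs(r2 - r02)))
    rm2p <- r2 * (1 - sqrt(abs(r2 - r02p)))
    n <- length(y)
    sxy <- mean((y - mean(y)) * (f - mean(f)))
    ccc <- 2 * sxy / (mean((y - mean(y))^2) + mean((f - mean(f))^2) +
                        (mean(y) - mean(f))^2)
    c(k = k, k_prime = kp, r0_2 = r02, r0_2_prime = r02p, rm2 = rm2,
      rm2_bar = (rm2 + rm2p) / 2, delta_rm2 = abs(rm2 - rm2p),
      qf3_2 = 1 - (sum((y - f)^2) / n) / (sum((ytr - mean(ytr))^2) /
                                            length(ytr)),
      ccc = ccc)
  }
  for (s in 1:100) {
    set.seed(s)
    y <- rnorm(8, 6, 1)
    f <- y + rnorm(8, 0, 0.4)
    ytr <- rnorm(25, 6, 1.1)
    got <- metrics(externalMetrics(y, f, ytr))
    want <- oracle(y, f, ytr)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("concordance penalises location shifts that Pearson ignores", {
  y <- c(5, 6, 7)
  f <- y + 1
  expect_equal(cor(y, f)^2, 1)
  expect_lt(concordanceCC(y, f), 1)
  # |ccc| <= |r| on random inputs; equality only for identity-like fits
  for (s in 1:25) {
    set.seed(s)
    a <- rnorm(10); b <- 0.6 * a + rnorm(10, 0.2, 0.3)
    expect_lte(abs(concordanceCC(a, b)), abs(cor(a, b)) + 1e-12)
  }
})

test_that("QF3^2 is exactly 1 for perfect prediction, any test composition", {
  for (s in 1:10) {
    set.seed(s)
    y <- rnorm(3 + s %% 4, 5 + s, 2)
    ytr <- rnorm(20, 6, runif(1, 0.5, 2))
    expect_equal(metrics(externalMetrics(y, y, ytr))[["qf3_2"]], 1)
  }
  expect_error(externalMetrics(c(5, 5, 5), c(5, 5.1, 4.9), rnorm(10)),
               "degenerate")
})

test_that("internal validation bundles training statistics with fitness", {
  s <- cachedSeries()
  m <- fitPlsCv(s$block, s$act$pic50, ncomp = 3)
  rep <- internalValidation(m, s$act$pic50)
  v <- metrics(rep)
  expect_equal(v[["q2"]], m@q2)
  expect_equal(v[["r2"]], m@r2)
  expect_equal(v[["rmse"]],
               sqrt(sum((s$act$pic50 - m@fitted)^2) /
                      (length(s$act$pic50) - 1)), tolerance = 1e-12)
  expect_true(passFlags(rep)[["q2"]])
})

test_that("leverage analysis follows the hat-value formulas", {
  expect_equal(warningLeverage(30, 6), 0.70)
  set.seed(4)
  S <- matrix(rnorm(40), 20, 2)
  r <- rnorm(20, 0, 0.25)
  ad <- applicabilityDomain(S, r, testScores = rbind(colMeans(S)),
                            residualsTest = 0)
  tab <- ad@table
  # training leverages: hat values of the score regression with intercept
  H <- hatvalues(lm(rnorm(20) ~ S))
  expect_equal(tab$leverage[tab$set_label == "train"], unname(H),
               tolerance = 1e-9)
  expect_true(all(tab$leverage[tab$set_label == "train"] <= 1 + 1e-12))
  # centroid compound has leverage exactly 1/n
  expect_equal(tab$leverage[tab$set_label == "test"], 1 / 20,
               tolerance = 1e-12)
  # huge standardized residual flags an outlier regardless of leverage
  r2 <- r; r2[1] <- 10 * sd(r)
  ad2 <- applicabilityDomain(S, r2)
  expect_true(ad2@table$outlier_flag[1])
  expect_gt(abs(ad2@table$std_residual[1]), 3)
})

test_that("model scores feed the applicability domain end to end", {
  s <- cachedSeries()
  tr <- 1:30; te <- 31:40
  m <- fitPls(s$M[tr, ], s$act$pic50[tr], 3)
  ad <- applicabilityDomain(plsScores(m),
                            s$act$pic50[tr] - m@fitted,
                            testScores = plsScores(m, s$M[te, ]),
                            residualsTest = s$act$pic50[te] -
                              predictPls(m, s$M[te, ]))
  expect_equal(nrow(ad@table), 40)
  expect_equal(ad@warningLeverage, 3 * (3 + 1) / 30)
  expect_true(all(is.finite(ad@table$leverage)))
})
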