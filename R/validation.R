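## Internal fitness and external predictivity battery.

#' Internal fitness metrics (chi-squared, RMSE, MAE, RSS)
#'
#' `chi2 = sum((y - yhat)^2 / y^2)` by default (each squared residual
#' normalised by the squared observation; set `chiDenominator = "y"` for the
#' per-observation variant), `RMSE = sqrt(sum((y - yhat)^2) / (n - 1))`,
#' plus the mean absolute error and residual sum of squares.
#'
#' @param y observed activities
#' @param yhat predicted activities
#' @param chiDenominator "y2" (default) or "y"
#' @return named list (chi2, rmse, mae, rss)
#' @export
fitnessMetrics <- function(y, yhat, chiDenominator = c("y2", "y")) {
  chiDenominator <- match.arg(chiDenominator)
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least 2 observations")
  if (any(y == 0))
    stop("chi2 undefined: observed activity of 0 in the denominator")
  res2 <- (y - yhat)^2
  denom <- if (chiDenominator == "y2") y^2 else y
  list(chi2 = sum(res2 / denom),
       rmse = sqrt(sum(res2) / (length(y) - 1)),
       mae = mean(abs(y - yhat)),
       rss = sum(res2))
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with the biased
#' (1/n) variance/covariance convention of Lin (1989). Penalises both
#' location and scale shifts, so ccc < |r| unless slope 1 and intercept 0.
#'
#' @param y observed values
#' @param yhat predicted values
#' @return concordance correlation in [-1, 1]
#' @export
concordanceCC <- function(y, yhat) {
  n <- length(y)
  mx <- mean(y); my <- mean(yhat)
  sxy <- sum((y - mx) * (yhat - my)) / n
  sx2 <- sum((y - mx)^2) / n
  sy2 <- sum((yhat - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' External predictivity metrics for a test set
#'
#' Computes the through-origin (Golbraikh-Tropsha) battery, the rm2 metric
#' family, QF3^2 and Lin's concordance correlation:
#' \itemize{
#'   \item `k = sum(y yhat) / sum(yhat^2)` and
#'     `k' = sum(y yhat) / sum(y^2)`, the regression-through-origin slopes;
#'   \item `r0^2 = 1 - sum((y - k yhat)^2) / sum((y - mean(y))^2)` and
#'     `r'0^2` with roles swapped;
#'   \item `rm2 = r2 (1 - sqrt(|r2 - r0^2|))`, its primed counterpart,
#'     their mean `rm2_bar` and absolute difference `delta_rm2`;
#'   \item `QF3^2 = 1 - (sum_test((y - yhat)^2)/n_test) /
#'     (sum_train((y - mean(y_train))^2)/n_train)`;
#'   \item `ccc`, Lin's concordance correlation.
#' }
#' `r2` is the squared Pearson correlation of observed vs predicted test
#' activities. Pass flags follow the conventional thresholds
#' (0.85 <= k, k' <= 1.15; |r0^2 - r'0^2| < 0.3; (r2 - r0^2)/r2 < 0.1;
#' rm2 and rm2_bar > 0.5; QF3^2 > 0.6).
#'
#' @param yTest observed test activities (length >= 3, non-constant)
#' @param yhatTest predicted test activities
#' @param yTrain observed training activities (for the QF3^2 denominator)
#' @return a [ValidationReport-class]
#' @export
externalMetrics <- function(yTest, yhatTest, yTrain) {
  if (length(yTest) != length(yhatTest))
    stop("yTest and yhatTest must have equal length")
  if (length(yTest) < 3) stop("need at least 3 test compounds")
  if (stats::sd(yTest) < 1e-12) stop("degenerate (constant) test activities")
  y <- yTest; f <- yhatTest
  r2 <- stats::cor(y, f)^2
  k <- sum(y * f) / sum(f^2)
  kPrime <- sum(y * f) / sum(y^2)
  r02 <- 1 - sum((y - k * f)^2) / sum((y - mean(y))^2)
  r02Prime <- 1 - sum((f - kPrime * y)^2) / sum((f - mean(f))^2)
  rm2 <- r2 * (1 - sqrt(abs(r2 - r02)))
  rm2Prime <- r2 * (1 - sqrt(abs(r2 - r02Prime)))
  rm2Bar <- (rm2 + rm2Prime) / 2
  deltaRm2 <- abs(rm2 - rm2Prime)
  qf32 <- 1 - (sum((y - f)^2) / length(y)) /
    (sum((yTrain - mean(yTrain))^2) / length(yTrain))
  ccc <- concordanceCC(y, f)
  m <- c(r2 = r2, k = k, k_prime = kPrime, r0_2 = r02,
         r0_2_prime = r02Prime, abs_diff_r0 = abs(r02 - r02Prime),
         rel_gap = (r2 - r02) / r2, rm2 = rm2, rm2_prime = rm2Prime,
         rm2_bar = rm2Bar, delta_rm2 = deltaRm2, qf3_2 = qf32, ccc = ccc)
  flags <- c(r2 = r2 > 0.6,
             k = k >= 0.85 && k <= 1.15,
             k_prime = kPrime >= 0.85 && kPrime <= 1.15,
             abs_diff_r0 = abs(r02 - r02Prime) < 0.3,
             rel_gap = (r2 - r02) / r2 < 0.1,
             rm2 = rm2 > 0.5,
             rm2_bar = rm2Bar > 0.5,
             qf3_2 = qf32 > 0.6)
  new("ValidationReport", metrics = m, passFlags = flags)
}

#' Internal validation report for a fitted model
#'
#' Bundles the training statistics of a cross-validated PLS model with the
#' fitness metrics into a [ValidationReport-class] (q2 > 0.5, r2 > 0.6,
#' chi2 < 0.5, RMSE < 0.3 pass thresholds).
#'
#' @param model a [PlsModel-class] fitted with [fitPlsCv()]
#' @param y training activities
#' @param chiDenominator passed to [fitnessMetrics()]
#' @param fitted fitted training activities (default: the model's stored
#'   fitted values; supply explicitly for a deserialized model)
#' @return a [ValidationReport-class]
#' @export
internalValidation <- function(model, y, chiDenominator = "y2",
                               fitted = model@fitted) {
  fm <- fitnessMetrics(y, fitted, chiDenominator)
  m <- c(q2 = model@q2, onc = as.numeric(model@onc), sep = model@sep,
         r2 = model@r2, see = model@see, f_value = model@fvalue,
         chi2 = fm$chi2, rmse = fm$rmse, mae = fm$mae, rss = fm$rss)
  flags <- c(q2 = isTRUE(model@q2 > 0.5), r2 = model@r2 > 0.6,
             chi2 = fm$chi2 < 0.5, rmse = fm$rmse < 0.3)
  new("ValidationReport", metrics = m, passFlags = flags)
}
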