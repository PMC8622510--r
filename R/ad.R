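## Leverage-based applicability domain (Williams plot).

#' Applicability-domain analysis in latent-component space
#'
#' Leverages are hat values in the model's latent-component (score) space:
#' `h_i = 1/n + t_i' (T'T)^{-1} t_i` with `T` the centered training score
#' matrix (PLS scores are centered by construction; the `1/n` term is the
#' intercept column of the hat matrix, so a compound at the training
#' centroid has leverage exactly `1/n`). Test-compound leverages use the
#' same `(T'T)^{-1}` with projected scores. The warning leverage is
#' `h* = 3 (p + 1) / n` with `p` the number of components and `n` the
#' training size. Standardized residuals are residuals divided by the SD of
#' the training residuals; a compound is flagged as an outlier when its
#' leverage exceeds `h*` or its standardized residual exceeds 3 in absolute
#' value.
#'
#' @param trainScores training score matrix (n x p), e.g. from
#'   [plsScores()]
#' @param residualsTrain training residuals (observed - fitted)
#' @param testScores optional test score matrix
#' @param residualsTest optional test residuals
#' @param ids optional compound identifiers (train then test)
#' @return an [AdReport-class]
#' @export
applicabilityDomain <- function(trainScores, residualsTrain,
                                testScores = NULL, residualsTest = NULL,
                                ids = NULL) {
  Tm <- as.matrix(trainScores)
  n <- nrow(Tm); p <- ncol(Tm)
  Tc <- sweep(Tm, 2, colMeans(Tm))
  G <- crossprod(Tc)
  if (abs(det(G)) < 1e-300) stop("singular score cross-product T'T")
  Ginv <- solve(G)
  lev <- function(S) 1 / n + rowSums((S %*% Ginv) * S)
  hTrain <- lev(Tc)
  sdRes <- stats::sd(residualsTrain)
  if (sdRes < 1e-12) sdRes <- 1e-12
  tab <- data.frame(id = character(0), leverage = numeric(0),
                    std_residual = numeric(0), set_label = character(0))
  tab <- data.frame(
    id = if (is.null(ids)) sprintf("train_%d", seq_len(n)) else ids[seq_len(n)],
    leverage = hTrain, std_residual = residualsTrain / sdRes,
    set_label = "train", stringsAsFactors = FALSE)
  if (!is.null(testScores)) {
    St <- sweep(as.matrix(testScores), 2, colMeans(Tm))
    m <- nrow(St)
    idsTest <- if (is.null(ids)) sprintf("test_%d", seq_len(m))
               else ids[n + seq_len(m)]
    tab <- rbind(tab, data.frame(
      id = idsTest, leverage = lev(St),
      std_residual = if (is.null(residualsTest)) rep(NA_real_, m)
                     else residualsTest / sdRes,
      set_label = "test", stringsAsFactors = FALSE))
  }
  hStar <- warningLeverage(n, p)
  tab$outlier_flag <- tab$leverage > hStar |
    (!is.na(tab$std_residual) & abs(tab$std_residual) > 3)
  rownames(tab) <- NULL
  new("AdReport", table = tab, warningLeverage = hStar)
}

#' Warning leverage h* = 3 (p + 1) / n
#'
#' @param n training-set size
#' @param p number of model parameters (latent components)
#' @return the warning leverage threshold
#' @export
warningLeverage <- function(n, p) 3 * (p + 1) / n
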