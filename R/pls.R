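## PLS1 regression (NIPALS) on mean-centered descriptors, no autoscaling.
## For a single response the NIPALS weight vector is available in closed
## form per component (w = X'y / ||X'y||), so the algorithm is deterministic
## and needs no iterative refinement; deflation proceeds component by
## component and the coefficient vector for every cumulative component
## count is retained.

.plsEngine <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  X0 <- sweep(X, 2, xm); y0 <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp)
  Xd <- X0; yd <- y0
  a <- 0L
  while (a < ncomp) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    a <- a + 1L
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; qv[a] <- qa
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t
  }
  used <- max(a, 1L)
  B <- matrix(0, p, ncomp)
  for (k in seq_len(used)) {
    B[, k] <- W[, 1:k, drop = FALSE] %*%
      solve(crossprod(P[, 1:k, drop = FALSE], W[, 1:k, drop = FALSE]),
            qv[1:k])
  }
  if (used < ncomp)  # signal exhausted: later counts reuse the last fit
    for (k in (used + 1L):ncomp) B[, k] <- B[, used]
  list(xMean = xm, yMean = ym, W = W[, seq_len(used), drop = FALSE],
       P = P[, seq_len(used), drop = FALSE],
       Tm = Tm[, seq_len(used), drop = FALSE], q = qv[seq_len(used)],
       B = B, used = used)
}

.asMatrixX <- function(X) {
  if (is(X, "DescriptorBlock")) descriptorMatrix(X) else as.matrix(X)
}

#' Fit a PLS1 regression model
#'
#' NIPALS PLS1 on the mean-centered descriptor matrix and response (no
#' autoscaling). Stores the fitted r2, `SEE = sqrt(RSS/(n - c - 1))` and
#' `F = (r2/c) / ((1 - r2)/(n - c - 1))` at the requested component count,
#' along with coefficient vectors for every cumulative count.
#'
#' @param X descriptor matrix (rows = compounds) or a column-filtered
#'   [DescriptorBlock-class]
#' @param y response vector (pIC50)
#' @param ncomp number of latent components
#' @return a [PlsModel-class]
#' @export
fitPls <- function(X, y, ncomp) {
  meta <- if (is(X, "DescriptorBlock")) columnMeta(X) else
    data.frame(point = seq_len(ncol(as.matrix(X))), kind = "S")
  X <- .asMatrixX(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 training compounds")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (stats::sd(y) < 1e-12) stop("zero-variance response")
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must lie in [1, min(n - 1, ncol(X))] = [1, ",
         min(n - 1, p), "]")
  eng <- .plsEngine(X, y, ncomp)
  fitted <- drop(eng$yMean + sweep(X, 2, eng$xMean) %*% eng$B[, ncomp])
  rss <- sum((y - fitted)^2)
  ss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / ss
  dfree <- n - ncomp - 1
  see <- if (dfree > 0) sqrt(rss / dfree) else NA_real_
  fval <- if (dfree > 0 && r2 < 1) (r2 / ncomp) / ((1 - r2) / dfree)
          else Inf
  new("PlsModel", xMean = eng$xMean, yMean = eng$yMean, weights = eng$W,
      loadings = eng$P, yLoadings = eng$q, scores = eng$Tm,
      coefMatrix = eng$B, ncomp = as.integer(ncomp), fitted = fitted,
      r2 = r2, see = see, fvalue = fval, q2 = NA_real_, sep = NA_real_,
      onc = NA_integer_, colSD = apply(X, 2, stats::sd), columnMeta = meta)
}

#' Predict activities with a fitted PLS model
#'
#' `yhat = y_mean + (X_new - x_mean) %*% coefficients`. Columns of `X_new`
#' must match the model's descriptor columns.
#'
#' @param model a [PlsModel-class]
#' @param Xnew matrix of new descriptor rows, or a column-filtered
#'   [DescriptorBlock-class]
#' @param ncomp component count (default: the model's)
#' @return numeric vector of predicted activities
#' @export
predictPls <- function(model, Xnew, ncomp = NULL) {
  Xnew <- .asMatrixX(Xnew)
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  if (ncol(Xnew) != length(model@xMean))
    stop("Xnew has ", ncol(Xnew), " columns; model expects ",
         length(model@xMean))
  if (is.null(ncomp)) ncomp <- model@ncomp
  drop(model@yMean + sweep(Xnew, 2, model@xMean) %*% model@coefMatrix[, ncomp])
}

#' Latent-component scores for training or new compounds
#'
#' Projects centered descriptor rows onto the model's score space using
#' `R = W (P'W)^{-1}`; with `Xnew = NULL` the training scores are returned.
#'
#' @param model a [PlsModel-class]
#' @param Xnew optional matrix of new descriptor rows
#' @param ncomp number of score columns (default: the model's)
#' @return numeric matrix (rows x ncomp)
#' @export
plsScores <- function(model, Xnew = NULL, ncomp = NULL) {
  if (is.null(ncomp)) ncomp <- model@ncomp
  ncomp <- min(ncomp, ncol(model@scores))
  if (is.null(Xnew)) return(model@scores[, seq_len(ncomp), drop = FALSE])
  Xnew <- .asMatrixX(Xnew)
  R <- model@weights %*% solve(crossprod(model@loadings, model@weights))
  (sweep(Xnew, 2, model@xMean) %*% R)[, seq_len(ncomp), drop = FALSE]
}

#' Leave-one-out cross-validation profile
#'
#' For each left-out compound the model is refitted on the remaining n - 1
#' and the held-out activity predicted at every component count up to
#' `maxComp` (PLS solutions are nested, so one refit per left-out sample
#' yields the full profile).
#'
#' @param X descriptor matrix or column-filtered [DescriptorBlock-class]
#' @param y response vector
#' @param maxComp maximum component count
#' @return list with `press` (PRESS per component), `q2` (per component),
#'   `predictions` (n x maxComp matrix of held-out predictions)
#' @export
looProfile <- function(X, y, maxComp) {
  X <- .asMatrixX(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 compounds for LOO cross-validation")
  if (maxComp < 1 || maxComp > min(n - 2, ncol(X)))
    stop("maxComp must lie in [1, min(n - 2, ncol(X))]")
  pred <- matrix(NA_real_, n, maxComp)
  for (i in seq_len(n)) {
    eng <- .plsEngine(X[-i, , drop = FALSE], y[-i], maxComp)
    x0 <- X[i, ] - eng$xMean
    pred[i, ] <- eng$yMean + drop(x0 %*% eng$B)
  }
  press <- colSums((y - pred)^2)
  ss <- sum((y - mean(y))^2)
  list(press = press, q2 = 1 - press / ss, predictions = pred)
}

#' Leave-one-out q2 at a fixed component count
#'
#' `q2 = 1 - PRESS / sum((y - mean(y))^2)` with
#' `PRESS = sum((y_i - yhat_(-i))^2)`, and
#' `SEP = sqrt(PRESS / (n - c - 1))`.
#'
#' @param X descriptor matrix or column-filtered [DescriptorBlock-class]
#' @param y response vector
#' @param ncomp component count
#' @return list with `q2`, `sep`, `press`
#' @export
looQ2 <- function(X, y, ncomp) {
  prof <- looProfile(X, y, ncomp)
  n <- length(y)
  dfree <- n - ncomp - 1
  list(q2 = prof$q2[ncomp],
       sep = if (dfree > 0) sqrt(prof$press[ncomp] / dfree) else NA_real_,
       press = prof$press[ncomp])
}

#' Select the optimal number of components by LOO q2
#'
#' Returns the component count maximising the leave-one-out q2, with ties
#' broken toward fewer components: the smallest count whose q2 lies within
#' `tol` (default 0.005) of the maximum.
#'
#' @param X descriptor matrix or column-filtered [DescriptorBlock-class]
#' @param y response vector
#' @param maxComp maximum candidate count (default 10, truncated to the
#'   data's limit)
#' @param tol parsimony tolerance on q2 (default 0.005)
#' @return list with `onc` and `q2ByComponent`
#' @export
selectOnc <- function(X, y, maxComp = 10, tol = 0.005) {
  X <- .asMatrixX(X)
  if (maxComp < 1) stop("maxComp must be >= 1")
  maxComp <- min(maxComp, nrow(X) - 2, ncol(X))
  prof <- looProfile(X, y, maxComp)
  onc <- which(prof$q2 >= max(prof$q2) - tol)[1]
  list(onc = as.integer(onc), q2ByComponent = prof$q2)
}

#' Fit a PLS model with cross-validated statistics filled in
#'
#' Convenience wrapper: selects the optimal component count by LOO q2 (or
#' uses `ncomp` when given), fits the final model, and fills the `q2`,
#' `sep` and `onc` slots.
#'
#' @param X descriptor matrix or column-filtered [DescriptorBlock-class]
#' @param y response vector
#' @param ncomp fixed component count, or NULL to select by LOO
#' @param maxComp maximum candidate count when selecting
#' @return a [PlsModel-class] with LOO statistics set
#' @export
fitPlsCv <- function(X, y, ncomp = NULL, maxComp = 10) {
  if (is.null(ncomp)) {
    sel <- selectOnc(X, y, maxComp)
    ncomp <- sel$onc
  }
  model <- fitPls(X, y, ncomp)
  cv <- looQ2(X, y, ncomp)
  model@q2 <- cv$q2
  model@sep <- cv$sep
  model@onc <- as.integer(ncomp)
  model
}

#' Relative field contributions of a fitted model
#'
#' Contribution of field kind k is `sum_j |coef_j| * sd_j` over that kind's
#' kept columns, normalised to 100 percent.
#'
#' @param model a [PlsModel-class]
#' @param block the column-filtered [DescriptorBlock-class] the model was
#'   fitted on (default: use the metadata stored in the model)
#' @return named numeric percentages summing to 100
#' @export
fieldContributions <- function(model, block = NULL) {
  meta <- if (is.null(block)) model@columnMeta else columnMeta(block)
  w <- abs(coef(model)) * model@colSD
  contrib <- c(tapply(w, meta$kind, sum))
  out <- 100 * contrib / sum(contrib)
  out[order(match(names(out), c("S", "E", "H", "A", "D")))]
}

#' StDev*Coeff contour field
#'
#' Per kept descriptor column, the product of the PLS coefficient and the
#' column standard deviation, mapped back to its grid point and field kind;
#' filtered-out columns contribute zero. Display levels are percentiles of
#' the signed nonzero values per kind: `favoredLevel` at the `favored`
#' percentile of positive values, `disfavoredLevel` at the `disfavored`
#' percentile of negative values (defaults 80/20, the conventional
#' favored/disfavored contour levels).
#'
#' @param model a [PlsModel-class] fitted on `block`
#' @param block the [DescriptorBlock-class] (with its column filter applied)
#' @param favored favored-contour percentile (default 80)
#' @param disfavored disfavored-contour percentile (default 20)
#' @return a [ContourField-class]
#' @export
stdevCoeffField <- function(model, block, favored = 80, disfavored = 20) {
  stopifnot(is(block, "DescriptorBlock"))
  kinds <- unique(block@columnMeta$kind)
  np <- nGridPoints(block@grid)
  vals <- matrix(0, np, length(kinds), dimnames = list(NULL, kinds))
  sc <- coef(model) * model@colSD
  metaKept <- columnMeta(block)
  for (j in seq_along(sc))
    vals[metaKept$point[j], metaKept$kind[j]] <- sc[j]
  fav <- disf <- stats::setNames(rep(NA_real_, length(kinds)), kinds)
  for (k in kinds) {
    v <- vals[, k]
    if (any(v > 0)) fav[k] <- stats::quantile(v[v > 0], favored / 100)
    if (any(v < 0)) disf[k] <- stats::quantile(v[v < 0], disfavored / 100)
  }
  new("ContourField", values = vals, kinds = kinds, grid = block@grid,
      favoredLevel = fav, disfavoredLevel = disf)
}
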