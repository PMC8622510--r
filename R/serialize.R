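#' Serialize a fitted PLS model to JSON
#'
#' Plain-text serialization of everything [predictPls()] and the reporting
#' layer need: centering offsets, coefficient matrix, loadings/weights,
#' statistics and column metadata.
#'
#' @param model a [PlsModel-class]
#' @param path output JSON file path
#' @return `path`, invisibly
#' @export
writePlsModelJson <- function(model, path) {
  obj <- list(xMean = unname(model@xMean), yMean = model@yMean,
              weights = model@weights, loadings = model@loadings,
              yLoadings = model@yLoadings, coefMatrix = model@coefMatrix,
              ncomp = model@ncomp, r2 = model@r2, see = model@see,
              fvalue = model@fvalue, q2 = model@q2, sep = model@sep,
              onc = model@onc, colSD = unname(model@colSD),
              columnMeta = model@columnMeta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a PLS model serialized by [writePlsModelJson()]
#'
#' @param path JSON file path
#' @return a [PlsModel-class] (training scores and fitted values are not
#'   serialized and come back empty)
#' @export
readPlsModelJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(m) if (is.null(dim(m))) matrix(m, ncol = 1) else m
  new("PlsModel", xMean = as.numeric(o$xMean), yMean = as.numeric(o$yMean),
      weights = asMat(o$weights), loadings = asMat(o$loadings),
      yLoadings = as.numeric(o$yLoadings), scores = matrix(0, 0, 0),
      coefMatrix = asMat(o$coefMatrix), ncomp = as.integer(o$ncomp),
      fitted = numeric(0), r2 = as.numeric(o$r2), see = as.numeric(o$see),
      fvalue = as.numeric(o$fvalue), q2 = as.numeric(o$q2),
      sep = as.numeric(o$sep), onc = as.integer(o$onc),
      colSD = as.numeric(o$colSD),
      columnMeta = as.data.frame(o$columnMeta))
}
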