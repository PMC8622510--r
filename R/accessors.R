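#' Construct a Molecule
#'
#' @param id molecule identifier
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`; missing
#'   per-atom parameters (`charge`, `vdw_radius`, `lj_epsilon`,
#'   `hydrophobic_weight`, `donor_flag`, `acceptor_flag`) are filled from the
#'   built-in element table (see [atomParameterTable()]).
#' @param coreIdx integer indices of the shared-substructure atoms
#' @return a [Molecule-class]
#' @export
Molecule <- function(id, atoms, coreIdx = integer()) {
  atoms <- fillAtomParameters(atoms)
  new("Molecule", id = as.character(id), atoms = atoms,
      coreIdx = as.integer(coreIdx))
}

#' Construct a MoleculeSet
#' @param molecules list of [Molecule-class] objects
#' @return a [MoleculeSet-class]
#' @export
MoleculeSet <- function(molecules) {
  new("MoleculeSet", molecules = unname(molecules))
}

#' Construct a GridSpec
#' @param origin numeric(3) Angstrom
#' @param spacing numeric(1) Angstrom
#' @param dims integer(3)
#' @return a [GridSpec-class]
#' @export
GridSpec <- function(origin, spacing = 2, dims) {
  new("GridSpec", origin = as.numeric(origin), spacing = as.numeric(spacing),
      dims = as.integer(dims))
}

#' Construct a ProbeSpec
#'
#' Defaults describe the conventional sp3-carbon CoMFA probe: 1.52 Angstrom
#' radius, +1 e charge, unit CoMSIA property weight.
#'
#' @param vdwRadius Angstrom
#' @param ljEpsilon kcal/mol (default: sp3 carbon from the atom table)
#' @param charge elementary charges
#' @param propertyWeight unitless
#' @return a [ProbeSpec-class]
#' @export
ProbeSpec <- function(vdwRadius = 1.52, ljEpsilon = NULL, charge = 1,
                      propertyWeight = 1) {
  if (is.null(ljEpsilon))
    ljEpsilon <- atomParameterTable()["C", "lj_epsilon"]
  new("ProbeSpec", vdwRadius = vdwRadius, ljEpsilon = ljEpsilon,
      charge = charge, propertyWeight = propertyWeight)
}

#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' Molecule identifiers of a set
#' @param x a [MoleculeSet-class]
#' @return character vector
#' @exportMethod moleculeIds
setMethod("moleculeIds", "MoleculeSet", function(x)
  vapply(x@molecules, function(m) m@id, ""))

#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Per-atom table of a molecule
#' @param x a [Molecule-class]
#' @return data.frame with one row per atom
#' @exportMethod atomTable
setMethod("atomTable", "Molecule", function(x) x@atoms)

#' @export
setGeneric("coreIndices", function(x) standardGeneric("coreIndices"))

#' Shared-substructure atom indices
#' @param x a [Molecule-class]
#' @return integer vector
#' @exportMethod coreIndices
setMethod("coreIndices", "Molecule", function(x) x@coreIdx)

#' @export
setMethod("length", "MoleculeSet", function(x) length(x@molecules))

#' @export
setMethod("[[", "MoleculeSet", function(x, i) x@molecules[[i]])

#' Number of grid points in a GridSpec
#' @param x a [GridSpec-class]
#' @return integer
#' @export
nGridPoints <- function(x) prod(x@dims)

#' Cartesian coordinates of all grid points
#'
#' Ordering is x-fastest: the point index increments x first, then y, then z.
#'
#' @param grid a [GridSpec-class]
#' @return numeric matrix (points x 3)
#' @export
gridPoints <- function(grid) {
  ax <- lapply(1:3, function(k)
    grid@origin[k] + grid@spacing * (seq_len(grid@dims[k]) - 1))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' @export
setGeneric("descriptorMatrix",
           function(x, filtered = TRUE) standardGeneric("descriptorMatrix"))

#' Descriptor matrix of a block
#' @param x a [DescriptorBlock-class]
#' @param filtered return only columns surviving the column filter?
#' @return numeric matrix
#' @exportMethod descriptorMatrix
setMethod("descriptorMatrix", "DescriptorBlock", function(x, filtered = TRUE) {
  if (filtered) x@matrix[, x@keptMask, drop = FALSE] else x@matrix
})

#' @export
setGeneric("columnMeta", function(x, filtered = TRUE)
  standardGeneric("columnMeta"))

#' Column metadata (grid point index and field kind)
#' @param x a [DescriptorBlock-class] or [PlsModel-class]
#' @param filtered restrict to kept columns?
#' @return data.frame
#' @exportMethod columnMeta
setMethod("columnMeta", "DescriptorBlock", function(x, filtered = TRUE) {
  if (filtered) x@columnMeta[x@keptMask, , drop = FALSE] else x@columnMeta
})

#' @rdname columnMeta
#' @exportMethod columnMeta
setMethod("columnMeta", "PlsModel", function(x, filtered = TRUE) x@columnMeta)

#' Regression coefficients of a PLS model
#' @param object a [PlsModel-class]
#' @param ncomp component count (default: the model's reporting ncomp)
#' @param ... ignored
#' @return numeric vector, one coefficient per kept descriptor column
#' @importFrom stats coef
#' @exportMethod coef
setMethod("coef", "PlsModel", function(object, ncomp = NULL, ...) {
  if (is.null(ncomp)) ncomp <- object@ncomp
  object@coefMatrix[, ncomp]
})

#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' Metric values of a validation report
#' @param x a [ValidationReport-class]
#' @return named numeric
#' @exportMethod metrics
setMethod("metrics", "ValidationReport", function(x) x@metrics)

#' @export
setGeneric("passFlags", function(x) standardGeneric("passFlags"))

#' Threshold pass/fail flags of a validation report
#' @param x a [ValidationReport-class]
#' @return named logical
#' @exportMethod passFlags
setMethod("passFlags", "ValidationReport", function(x) x@passFlags)

#' Energy breakdown as a named numeric vector
#' @param x an [EnergyBreakdown-class]
#' @param digits round to this many decimals (NULL for full precision);
#'   printed tables conventionally use 2
#' @return named numeric (VDWAALS, E_EL, E_PBGB, E_SURF, DG_GAS, DG_SOLV,
#'   DTOTAL)
#' @export
breakdownVector <- function(x, digits = NULL) {
  stopifnot(is(x, "EnergyBreakdown"))
  v <- c(VDWAALS = x@vdwaals, E_EL = x@eEl, E_PBGB = x@ePbgb,
         E_SURF = x@eSurf, DG_GAS = x@dgGas, DG_SOLV = x@dgSolv,
         DTOTAL = x@dtotal)
  if (!is.null(digits)) v <- round(v, digits)
  v
}

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms (%d core)\n", object@id,
              nrow(object@atoms), length(object@coreIdx)))
})

setMethod("show", "MoleculeSet", function(object) {
  n <- length(object@molecules)
  cat(sprintf("MoleculeSet of %d molecule(s)\n", n))
  if (n) {
    na <- vapply(object@molecules, function(m) nrow(m@atoms), 1L)
    cat(sprintf("  atoms per molecule: %d-%d\n", min(na), max(na)))
  }
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d x %d points, spacing %.3g A, origin (%.3g, %.3g, %.3g)\n",
    object@dims[1], object@dims[2], object@dims[3], object@spacing,
    object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "DescriptorBlock", function(object) {
  kinds <- table(object@columnMeta$kind)
  cat(sprintf("DescriptorBlock (%s): %d molecules x %d columns (%d kept)\n",
              object@scheme, nrow(object@matrix), ncol(object@matrix),
              sum(object@keptMask)))
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds),
                        collapse = ", "), "\n")
})

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel: %d component(s), %d descriptor column(s)\n",
              object@ncomp, nrow(object@coefMatrix)))
  cat(sprintf("  r2 = %.3f, SEE = %.3f, F = %.2f\n",
              object@r2, object@see, object@fvalue))
  if (!is.na(object@q2))
    cat(sprintf("  LOO q2 = %.3f, SEP = %.3f\n", object@q2, object@sep))
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  for (nm in names(object@metrics)) {
    flag <- if (nm %in% names(object@passFlags))
      sprintf(" [%s]", if (object@passFlags[[nm]]) "pass" else "FAIL")
    else ""
    cat(sprintf("  %-16s %10.4f%s\n", nm, object@metrics[[nm]], flag))
  }
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf("EnergyBreakdown '%s' (%s, %d frames)\n", object@label,
              object@variant, object@nFrames))
  v <- breakdownVector(object, digits = 2)
  cat(paste(sprintf("  %-8s %8.2f", names(v), v), collapse = "\n"), "\n")
})

setMethod("show", "LieResult", function(object) {
  cat(sprintf(
    "LieResult: dG_bind = %.2f kcal/mol (alpha = %.3f, beta = %.3f)\n",
    object@dgBind, object@alpha, object@beta))
})

setMethod("show", "ScramblingResult", function(object) {
  cat("ScramblingResult (per component count)\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "AdReport", function(object) {
  cat(sprintf("AdReport: %d compounds, h* = %.3f, %d outlier(s)\n",
              nrow(object@table), object@warningLeverage,
              sum(object@table$outlier_flag)))
})

setMethod("show", "ContourField", function(object) {
  cat(sprintf("ContourField: %d grid points x kinds {%s}\n",
              nrow(object@values), paste(object@kinds, collapse = ",")))
})
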