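#' @import methods
NULL

## Atom tables are plain data.frames with a fixed column contract; the S4
## layer wraps the containers that cross module boundaries.

.ATOM_COLS <- c("element", "x", "y", "z", "charge", "vdw_radius",
                "lj_epsilon", "hydrophobic_weight", "donor_flag",
                "acceptor_flag")

#' Molecule: one aligned conformer with per-atom field parameters
#'
#' Holds a single pre-aligned 3D structure: element symbols, Cartesian
#' coordinates (Angstrom), partial charges (e), van der Waals radii
#' (Angstrom), Lennard-Jones well depths (kcal/mol), hydrophobic weights and
#' hydrogen-bond donor/acceptor flags, plus the indices of the atoms that
#' belong to the shared scaffold of the series. Molecules are consumed
#' pre-aligned; no conformer generation or alignment is performed here.
#'
#' @slot id character molecule identifier
#' @slot atoms data.frame with one row per atom (see [atomTable()])
#' @slot coreIdx integer indices of the common-substructure atoms
#' @exportClass Molecule
setClass("Molecule",
         representation(id = "character", atoms = "data.frame",
                        coreIdx = "integer"))

setValidity("Molecule", function(object) {
  a <- object@atoms
  missing <- setdiff(.ATOM_COLS, names(a))
  if (length(missing))
    return(paste("atoms lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a) == 0L) return("molecule has no atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) return("non-finite coordinates")
  if (!all(is.finite(a$charge))) return("missing partial charges")
  if (!all(a$vdw_radius > 0)) return("vdw_radius must be > 0")
  if (length(object@coreIdx) &&
      (min(object@coreIdx) < 1L || max(object@coreIdx) > nrow(a)))
    return("coreIdx out of range")
  TRUE
})

#' MoleculeSet: an aligned analog series
#'
#' Ordered collection of [Molecule-class] objects sharing a common
#' substructure; the number of core atoms must be identical across the set.
#'
#' @slot molecules list of Molecule
#' @exportClass MoleculeSet
setClass("MoleculeSet", representation(molecules = "list"))

setValidity("MoleculeSet", function(object) {
  if (!all(vapply(object@molecules, is, TRUE, "Molecule")))
    return("all elements must be Molecule objects")
  ncore <- vapply(object@molecules, function(m) length(m@coreIdx), 1L)
  if (length(ncore) && length(unique(ncore)) > 1L)
    return("core atom count differs across molecules")
  ids <- vapply(object@molecules, function(m) m@id, "")
  if (anyDuplicated(ids)) return("duplicated molecule ids")
  TRUE
})

#' GridSpec: rectangular field lattice
#'
#' Axis-aligned lattice on which probe fields are evaluated. Point ordering
#' is x-fastest: point k (1-based) has ix = (k-1) %% nx, iy varying next,
#' iz slowest.
#'
#' @slot origin numeric(3) lattice origin (Angstrom)
#' @slot spacing numeric(1) lattice spacing (Angstrom), default 2.0
#' @slot dims integer(3) number of points per axis
#' @exportClass GridSpec
setClass("GridSpec",
         representation(origin = "numeric", spacing = "numeric",
                        dims = "integer"))

setValidity("GridSpec", function(object) {
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    return("origin must be finite numeric(3)")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    return("spacing must be a single positive number")
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be integer(3), each >= 1")
  TRUE
})

#' ProbeSpec: field probe parameters
#'
#' The CoMFA probe is an sp3 carbon with +1 charge by convention: van der
#' Waals radius 1.52 Angstrom, Lennard-Jones epsilon from the built-in atom
#' table. CoMSIA similarity probes carry a unit property weight.
#'
#' @slot vdwRadius numeric(1) Angstrom
#' @slot ljEpsilon numeric(1) kcal/mol
#' @slot charge numeric(1) elementary charges
#' @slot propertyWeight numeric(1) unitless CoMSIA probe weight
#' @exportClass ProbeSpec
setClass("ProbeSpec",
         representation(vdwRadius = "numeric", ljEpsilon = "numeric",
                        charge = "numeric", propertyWeight = "numeric"))

setValidity("ProbeSpec", function(object) {
  if (object@vdwRadius <= 0) return("vdwRadius must be > 0")
  TRUE
})

#' DescriptorBlock: molecules x (grid points x field kinds) matrix
#'
#' Row order follows the molecule order; columns are grouped by field kind
#' then grid point index (x-fastest). `keptMask` records which columns
#' survive column filtering; `imputed` flags electrostatic values replaced
#' by their column mean at sterically excluded points.
#'
#' @slot matrix numeric matrix of field values
#' @slot columnMeta data.frame with columns `point` (grid point index) and
#'   `kind` (one of S, E, H, A, D)
#' @slot keptMask logical per column
#' @slot imputed logical matrix marking column-mean imputed entries
#' @slot scheme character, "comfa" or "comsia"
#' @slot grid the [GridSpec-class] the columns refer to
#' @exportClass DescriptorBlock
setClass("DescriptorBlock",
         representation(matrix = "matrix", columnMeta = "data.frame",
                        keptMask = "logical", imputed = "matrix",
                        scheme = "character", grid = "GridSpec"))

setValidity("DescriptorBlock", function(object) {
  if (nrow(object@columnMeta) != ncol(object@matrix))
    return("columnMeta rows must match matrix columns")
  if (length(object@keptMask) != ncol(object@matrix))
    return("keptMask length must match matrix columns")
  if (!all(object@columnMeta$kind %in% c("S", "E", "H", "A", "D")))
    return("unknown field kind in columnMeta")
  TRUE
})

#' PlsModel: fitted PLS1 regression on a descriptor block
#'
#' Mean-centered (no autoscaling) PLS1 fit. Coefficient vectors are stored
#' per cumulative component count so that predictions at any number of
#' components up to `ncomp` are available without refitting. `q2`, `sep` and
#' `onc` are filled by leave-one-out cross-validation / component selection.
#'
#' @slot xMean numeric per-column centering offsets
#' @slot yMean numeric(1)
#' @slot weights matrix p x A of PLS weights
#' @slot loadings matrix p x A of X loadings
#' @slot yLoadings numeric(A)
#' @slot scores matrix n x A of training scores
#' @slot coefMatrix matrix p x A; column a = coefficients using a components
#' @slot ncomp integer components used for reporting
#' @slot fitted numeric training fitted values at ncomp
#' @slot r2,see,fvalue numeric training statistics at ncomp
#' @slot q2,sep numeric LOO statistics (NA until computed)
#' @slot onc integer optimal number of components (NA until selected)
#' @slot colSD numeric per-column SD of the training matrix
#' @slot columnMeta data.frame carried over from the descriptor block
#' @exportClass PlsModel
setClass("PlsModel",
         representation(xMean = "numeric", yMean = "numeric",
                        weights = "matrix", loadings = "matrix",
                        yLoadings = "numeric", scores = "matrix",
                        coefMatrix = "matrix", ncomp = "integer",
                        fitted = "numeric", r2 = "numeric", see = "numeric",
                        fvalue = "numeric", q2 = "numeric", sep = "numeric",
                        onc = "integer", colSD = "numeric",
                        columnMeta = "data.frame"))

#' ContourField: StDev*Coeff display field
#'
#' Per grid point and field kind, the product of the PLS regression
#' coefficient and the descriptor column standard deviation; zero at
#' filtered-out columns. Favored/disfavored display levels are the
#' configured percentiles of the positive and negative contributions.
#'
#' @slot values matrix (grid points x kinds) of StDev*Coeff values
#' @slot kinds character field kinds (column order of `values`)
#' @slot grid the [GridSpec-class]
#' @slot favoredLevel,disfavoredLevel named numeric display levels per kind
#' @exportClass ContourField
setClass("ContourField",
         representation(values = "matrix", kinds = "character",
                        grid = "GridSpec", favoredLevel = "numeric",
                        disfavoredLevel = "numeric"))

#' ValidationReport: internal/external model-quality metrics
#'
#' Named metric values plus pass/fail flags against the conventional QSAR
#' acceptance thresholds (q2 > 0.5, r2 > 0.6, chi2 < 0.5, RMSE < 0.3,
#' 0.85 <= k, k' <= 1.15, |r0^2 - r'0^2| < 0.3, (r2 - r0^2)/r2 < 0.1,
#' rm2 > 0.5, QF3^2 > 0.6).
#'
#' @slot metrics named numeric
#' @slot passFlags named logical
#' @exportClass ValidationReport
setClass("ValidationReport",
         representation(metrics = "numeric", passFlags = "logical"))

#' EnergyBreakdown: MM-PB(GB)SA component means and totals
#'
#' Gas-phase molecular mechanics energy (van der Waals + electrostatic),
#' solvation free energy (polar PB or GB + non-polar surface term) and their
#' sum, the total binding free energy without the -T*dS entropy term (which
#' is structurally excluded). All values kcal/mol.
#'
#' @slot vdwaals,eEl,ePbgb,eSurf numeric component means
#' @slot dgGas,dgSolv,dtotal numeric derived totals
#' @slot nFrames integer frames averaged
#' @slot variant character "PB" or "GB"
#' @slot label character complex identifier
#' @exportClass EnergyBreakdown
setClass("EnergyBreakdown",
         representation(vdwaals = "numeric", eEl = "numeric",
                        ePbgb = "numeric", eSurf = "numeric",
                        dgGas = "numeric", dgSolv = "numeric",
                        dtotal = "numeric", nFrames = "integer",
                        variant = "character", label = "character"))

setValidity("EnergyBreakdown", function(object) {
  if (abs(object@dgGas - (object@vdwaals + object@eEl)) > 1e-9)
    return("dgGas must equal vdwaals + eEl")
  if (abs(object@dgSolv - (object@ePbgb + object@eSurf)) > 1e-9)
    return("dgSolv must equal ePbgb + eSurf")
  if (abs(object@dtotal - (object@dgGas + object@dgSolv)) > 1e-9)
    return("dtotal must equal dgGas + dgSolv")
  if (!object@variant %in% c("PB", "GB")) return("variant must be PB or GB")
  TRUE
})

#' LieResult: linear interaction energy estimate
#'
#' dG_bind = alpha * (<V_vdw>_bound - <V_vdw>_unbound) +
#'           beta  * (<V_ele>_bound - <V_ele>_unbound), kcal/mol.
#'
#' @slot boundVdw,unboundVdw,boundEle,unboundEle numeric ensemble means
#' @slot alpha,beta numeric scaling factors (defaults 0.181, 0.43)
#' @slot dgBind numeric estimate
#' @exportClass LieResult
setClass("LieResult",
         representation(boundVdw = "numeric", unboundVdw = "numeric",
                        boundEle = "numeric", unboundEle = "numeric",
                        alpha = "numeric", beta = "numeric",
                        dgBind = "numeric"))

setValidity("LieResult", function(object) {
  expect <- object@alpha * (object@boundVdw - object@unboundVdw) +
    object@beta * (object@boundEle - object@unboundEle)
  if (abs(object@dgBind - expect) > 1e-9)
    return("dgBind inconsistent with components and scaling factors")
  TRUE
})

#' ScramblingResult: progressive scrambling stability analysis
#'
#' @slot table data.frame per component count: q2_scrambled, csdep, slope
#'   (dq2/dr2yy' at the critical perturbation)
#' @slot details data.frame per scramble x component: r2yy, q2, csdep
#' @slot settings list (nScrambles, binMin, binMax, critical, seed)
#' @exportClass ScramblingResult
setClass("ScramblingResult",
         representation(table = "data.frame", details = "data.frame",
                        settings = "list"))

#' AdReport: applicability-domain (Williams plot) classification
#'
#' @slot table data.frame per compound: id, leverage, std_residual,
#'   set_label, outlier_flag
#' @slot warningLeverage numeric h* = 3(p+1)/n
#' @exportClass AdReport
setClass("AdReport",
         representation(table = "data.frame", warningLeverage = "numeric"))

setValidity("AdReport", function(object) {
  if (object@warningLeverage <= 0) return("warningLeverage must be > 0")
  tr <- object@table[object@table$set_label == "train", , drop = FALSE]
  if (nrow(tr) && any(tr$leverage < -1e-9 | tr$leverage > 1 + 1e-9))
    return("training leverages must lie in [0, 1]")
  TRUE
})
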