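## Grid molecular interaction fields.
##
## CoMFA: Lennard-Jones steric and Coulomb electrostatic probe energies at
## each lattice point, capped at +/- 30 kcal/mol after summation over atoms.
## CoMSIA: Gaussian similarity indices A_k(q) = -sum_i w_probe * w_ik *
## exp(-alpha * r_iq^2) with no distance cutoff.

.COULOMB <- 332.0636  # kcal * Angstrom / (mol * e^2)

#' Build the field lattice around a molecule set
#'
#' Axis-aligned box covering the union of all atom coordinates, expanded by
#' `margin` on every side and discretised at `spacing`. The result is
#' independent of molecule order.
#'
#' @param molecules a [MoleculeSet-class]
#' @param spacing lattice spacing, Angstrom (default 2.0)
#' @param margin box expansion on each side, Angstrom (default 4.0)
#' @return a [GridSpec-class]
#' @export
buildGrid <- function(molecules, spacing = 2, margin = 4) {
  stopifnot(is(molecules, "MoleculeSet"))
  if (length(molecules) == 0L) stop("empty molecule list")
  if (spacing <= 0) stop("spacing must be > 0")
  xyz <- do.call(rbind, lapply(molecules@molecules, function(m)
    as.matrix(m@atoms[, c("x", "y", "z")])))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L)
  GridSpec(origin = lo, spacing = spacing, dims = dims)
}

.distToAtoms <- function(pts, atoms) {
  ax <- as.matrix(atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pts^2), rowSums(ax^2), "+") - 2 * pts %*% t(ax)
  sqrt(pmax(d2, 0))
}

#' CoMFA steric field (Lennard-Jones probe energy)
#'
#' At each lattice point the probe-atom Lennard-Jones energy summed over
#' atoms: `eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with
#' `Rmin_ij = r_vdw(atom) + r_vdw(probe)` (arithmetic combination) and
#' `eps_ij = sqrt(eps_atom * eps_probe)` (geometric combination). The summed
#' value is clamped to `[-cap, +cap]`; a point coincident with an atom
#' centre clamps to `+cap` rather than propagating a singularity.
#'
#' @param molecule a [Molecule-class]
#' @param grid a [GridSpec-class]
#' @param probe a [ProbeSpec-class]
#' @param cap energy tolerance, kcal/mol (default 30)
#' @return numeric vector of field values, one per grid point
#' @export
comfaSteric <- function(molecule, grid, probe = ProbeSpec(), cap = 30) {
  a <- molecule@atoms
  r <- .distToAtoms(gridPoints(grid), a)
  rmin <- matrix(a$vdw_radius + probe@vdwRadius, nrow(r), ncol(r),
                 byrow = TRUE)
  eps <- matrix(sqrt(a$lj_epsilon * probe@ljEpsilon), nrow(r), ncol(r),
                byrow = TRUE)
  ratio6 <- (rmin / pmax(r, 1e-12))^6
  e <- rowSums(eps * (ratio6^2 - 2 * ratio6))
  e[!is.finite(e)] <- cap
  pmin(pmax(e, -cap), cap)
}

#' CoMFA electrostatic field (Coulomb probe energy)
#'
#' At each lattice point, `332.0636 * sum_i q_probe q_i / (eps(r_i) r_i)`.
#' The default dielectric is distance-dependent, `eps(r) = r`; a constant
#' dielectric of 1 is selectable. The summed value is clamped to
#' `[-cap, +cap]`. Replacement of values at sterically excluded points by
#' the column mean across molecules is applied during matrix assembly (see
#' [assembleDescriptorMatrix()]), not here.
#'
#' @param molecule a [Molecule-class]
#' @param grid a [GridSpec-class]
#' @param probe a [ProbeSpec-class]
#' @param cap energy tolerance, kcal/mol (default 30)
#' @param dielectric "distance" for eps(r) = r, or "constant" for eps = 1
#' @return numeric vector of field values, one per grid point
#' @export
comfaElectrostatic <- function(molecule, grid, probe = ProbeSpec(), cap = 30,
                               dielectric = c("distance", "constant")) {
  dielectric <- match.arg(dielectric)
  a <- molecule@atoms
  r <- .distToAtoms(gridPoints(grid), a)
  r <- pmax(r, 1e-12)
  denom <- if (dielectric == "distance") r^2 else r
  q <- matrix(a$charge, nrow(r), ncol(r), byrow = TRUE)
  e <- .COULOMB * probe@charge * rowSums(q / denom)
  e[!is.finite(e)] <- sign(e[!is.finite(e)]) * cap
  e[is.na(e)] <- cap
  pmin(pmax(e, -cap), cap)
}

.comsiaWeights <- function(atoms, kind) {
  switch(kind,
         S = atoms$vdw_radius^3,
         E = atoms$charge,
         H = atoms$hydrophobic_weight,
         D = as.numeric(atoms$donor_flag),
         A = as.numeric(atoms$acceptor_flag),
         stop("unknown CoMSIA field kind: ", kind))
}

#' CoMSIA similarity index field
#'
#' Gaussian-attenuated property similarity at each lattice point:
#' `A_k(q) = -sum_i w_probe * w_ik * exp(-alpha * r_iq^2)`, with no distance
#' cutoff. Atom property weights by kind: steric `r_vdw^3`, electrostatic
#' partial charge, hydrophobic the built-in atomic hydrophobicity, donor and
#' acceptor 0/1 flags.
#'
#' @param molecule a [Molecule-class]
#' @param grid a [GridSpec-class]
#' @param kind one of "S", "E", "H", "A", "D"
#' @param alpha Gaussian attenuation factor, 1/Angstrom^2 (default 0.3)
#' @param probeWeight probe property weight (default +1)
#' @return numeric vector of unitless field values, one per grid point
#' @export
comsiaField <- function(molecule, grid, kind, alpha = 0.3, probeWeight = 1) {
  w <- .comsiaWeights(molecule@atoms, kind)
  r <- .distToAtoms(gridPoints(grid), molecule@atoms)
  wm <- matrix(w, nrow(r), ncol(r), byrow = TRUE)
  -probeWeight * rowSums(wm * exp(-alpha * r^2))
}

#' Assemble the descriptor matrix for a molecule series
#'
#' Computes the requested fields for every molecule on a shared lattice and
#' stacks them into a molecules x (points x kinds) matrix, columns grouped
#' by field kind (in the order given) then grid point index. For the CoMFA
#' scheme (kinds restricted to S and E), electrostatic values at points
#' where a molecule's steric field is clamped at `+cap` are replaced by the
#' column mean over the non-excluded molecules (the classic convention of
#' not evaluating electrostatics inside atoms); replaced entries are flagged
#' in the block's `imputed` slot. Set `exclusion = "clamp"` to keep the
#' clamped Coulomb values instead.
#'
#' @param molecules a [MoleculeSet-class]
#' @param grid a [GridSpec-class]
#' @param kinds character subset of S, E, H, A, D (CoMFA: only S, E)
#' @param scheme "comfa" or "comsia"
#' @param probe a [ProbeSpec-class]
#' @param cap CoMFA energy tolerance, kcal/mol
#' @param alpha CoMSIA attenuation factor, 1/Angstrom^2
#' @param dielectric CoMFA electrostatic dielectric model
#' @param exclusion "impute" (column-mean at sterically excluded points) or
#'   "clamp"
#' @return a [DescriptorBlock-class] with all columns kept
#' @export
assembleDescriptorMatrix <- function(molecules, grid,
                                     kinds = c("S", "E"),
                                     scheme = c("comfa", "comsia"),
                                     probe = ProbeSpec(), cap = 30,
                                     alpha = 0.3,
                                     dielectric = c("distance", "constant"),
                                     exclusion = c("impute", "clamp")) {
  scheme <- match.arg(scheme)
  dielectric <- match.arg(dielectric)
  exclusion <- match.arg(exclusion)
  stopifnot(is(molecules, "MoleculeSet"), is(grid, "GridSpec"))
  kinds <- unique(toupper(kinds))
  if (!length(kinds)) stop("kinds must be non-empty")
  bad <- setdiff(kinds, c("S", "E", "H", "A", "D"))
  if (length(bad)) stop("unknown field kind(s): ", paste(bad, collapse = ", "))
  if (scheme == "comfa" && length(setdiff(kinds, c("S", "E"))))
    stop("CoMFA supports only steric (S) and electrostatic (E) fields")
  n <- length(molecules)
  np <- nGridPoints(grid)
  blocks <- list(); imputedBlocks <- list()
  if (scheme == "comfa") {
    ster <- t(vapply(molecules@molecules, comfaSteric, numeric(np),
                     grid = grid, probe = probe, cap = cap))
    excluded <- ster >= cap - 1e-9
    if ("S" %in% kinds) {
      blocks$S <- ster
      imputedBlocks$S <- matrix(FALSE, n, np)
    }
    if ("E" %in% kinds) {
      elec <- t(vapply(molecules@molecules, comfaElectrostatic, numeric(np),
                       grid = grid, probe = probe, cap = cap,
                       dielectric = dielectric))
      imp <- matrix(FALSE, n, np)
      if (exclusion == "impute" && any(excluded)) {
        elec[excluded] <- NA_real_
        cm <- colMeans(elec, na.rm = TRUE)
        cm[is.nan(cm)] <- 0
        idx <- which(is.na(elec), arr.ind = TRUE)
        elec[idx] <- cm[idx[, 2]]
        imp[idx] <- TRUE
      }
      blocks$E <- elec
      imputedBlocks$E <- imp
    }
    blocks <- blocks[intersect(kinds, names(blocks))]
  } else {
    for (k in kinds) {
      blocks[[k]] <- t(vapply(molecules@molecules, comsiaField, numeric(np),
                              grid = grid, kind = k, alpha = alpha,
                              probeWeight = probe@propertyWeight))
      imputedBlocks[[k]] <- matrix(FALSE, n, np)
    }
  }
  mat <- do.call(cbind, blocks[kinds])
  imputed <- do.call(cbind, imputedBlocks[kinds])
  meta <- data.frame(point = rep(seq_len(np), times = length(kinds)),
                     kind = rep(kinds, each = np), stringsAsFactors = FALSE)
  colnames(mat) <- paste0(meta$kind, meta$point)
  rownames(mat) <- moleculeIds(molecules)
  new("DescriptorBlock", matrix = mat, columnMeta = meta,
      keptMask = rep(TRUE, ncol(mat)), imputed = imputed, scheme = scheme,
      grid = grid)
}

#' Column filtering by minimum standard deviation
#'
#' Drops descriptor columns whose standard deviation across molecules falls
#' below `minSigma` (default 2.0, the conventional kcal/mol column-filter
#' value; CoMSIA columns apply the same numeric threshold to their unitless
#' values).
#'
#' @param block a [DescriptorBlock-class]
#' @param minSigma minimum column SD (default 2.0)
#' @return the block with `keptMask` updated
#' @export
columnFilter <- function(block, minSigma = 2) {
  stopifnot(is(block, "DescriptorBlock"))
  if (ncol(block@matrix) == 0L) stop("empty descriptor block")
  sds <- apply(block@matrix, 2, stats::sd)
  keep <- sds >= minSigma
  if (!any(keep))
    stop("column filter removed every column; lower minSigma (current ",
         minSigma, ", max column SD ", signif(max(sds), 4), ")")
  block@keptMask <- unname(keep)
  block
}
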