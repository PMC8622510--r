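## End-state binding free energy aggregation: MM-PB(GB)SA component
## averaging over the final trajectory window, LIE estimation, and
## per-residue decomposition filtering. This is the arithmetic/reporting
## layer over solver outputs; no PB/GB solver or trajectory processing.

#' Average MM-PB(GB)SA components over the final frames
#'
#' Arithmetic mean of each energy component over the last `lastN` frames of
#' the series (the conventional final-window average, default 200 frames =
#' the final 2 ns at 10 ps spacing).
#'
#' @param series per-frame component data.frame from
#'   [readEnergyComponents()] or [genEnergyFrames()]
#' @param lastN number of trailing frames to average (default 200)
#' @return named list of component means plus `n_frames`
#' @export
averageComponents <- function(series, lastN = 200) {
  n <- nrow(series)
  if (lastN < 1) stop("lastN must be >= 1")
  if (n < lastN)
    stop("series has only ", n, " frame(s); ", lastN, " requested")
  tail <- series[seq(n - lastN + 1, n), , drop = FALSE]
  list(vdwaals = mean(tail$vdwaals), e_el = mean(tail$e_el),
       e_pbgb = mean(tail$e_pbgb), e_surf = mean(tail$e_surf),
       n_frames = as.integer(lastN),
       variant = attr(series, "variant") %||% "GB",
       label = attr(series, "label") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total binding free energy breakdown from component means
#'
#' `dG_gas = VDWAALS + E_EL` (the gas-phase molecular-mechanics interaction
#' energy), `dG_solv = E_PB/GB + E_SURF` (polar + non-polar solvation), and
#' `dTOTAL = dG_gas + dG_solv` — the binding free energy without the -T*dS
#' entropy term, which is excluded by construction. Full precision is
#' stored; use `breakdownVector(x, digits = 2)` for table parity.
#'
#' @param means named list/vector with `vdwaals`, `e_el`, `e_pbgb`,
#'   `e_surf` (kcal/mol), e.g. from [averageComponents()]
#' @param variant "PB" or "GB" (default: taken from `means`, else "GB")
#' @param label complex identifier
#' @param nFrames frames behind the means (default: taken from `means`)
#' @return an [EnergyBreakdown-class]
#' @export
mmpbsaTotal <- function(means, variant = NULL, label = NULL, nFrames = NULL) {
  need <- c("vdwaals", "e_el", "e_pbgb", "e_surf")
  if (!all(need %in% names(means)))
    stop("means must contain: ", paste(need, collapse = ", "))
  v <- as.numeric(means[["vdwaals"]]); e <- as.numeric(means[["e_el"]])
  pg <- as.numeric(means[["e_pbgb"]]); s <- as.numeric(means[["e_surf"]])
  new("EnergyBreakdown", vdwaals = v, eEl = e, ePbgb = pg, eSurf = s,
      dgGas = v + e, dgSolv = pg + s, dtotal = v + e + pg + s,
      nFrames = as.integer(nFrames %||% means[["n_frames"]] %||% 1L),
      variant = as.character(variant %||% means[["variant"]] %||% "GB"),
      label = as.character(label %||% means[["label"]] %||% ""))
}

#' Linear interaction energy binding estimate
#'
#' `dG_bind = alpha (<V_vdw>_bound - <V_vdw>_unbound) +
#'  beta (<V_ele>_bound - <V_ele>_unbound)` with the empirical scaling
#' factors alpha = 0.181 and beta = 0.43 for neutral ligands.
#'
#' @param bound data.frame with per-frame `vdw` and `ele`
#'   ligand-surroundings energies in the bound state (kcal/mol)
#' @param unbound same for the unbound (free ligand) state
#' @param alpha van der Waals scaling factor (default 0.181)
#' @param beta electrostatic scaling factor (default 0.43)
#' @return a [LieResult-class]
#' @export
lieBinding <- function(bound, unbound, alpha = 0.181, beta = 0.43) {
  for (nm in c("vdw", "ele")) {
    if (!nm %in% names(bound) || !nm %in% names(unbound))
      stop("bound and unbound need columns 'vdw' and 'ele'")
  }
  if (nrow(bound) == 0 || nrow(unbound) == 0)
    stop("empty ensemble")
  bv <- mean(bound$vdw); uv <- mean(unbound$vdw)
  be <- mean(bound$ele); ue <- mean(unbound$ele)
  new("LieResult", boundVdw = bv, unboundVdw = uv, boundEle = be,
      unboundEle = ue, alpha = alpha, beta = beta,
      dgBind = alpha * (bv - uv) + beta * (be - ue))
}

#' Filter a per-residue decomposition table
#'
#' Applies the distance rule (residues whose minimum distance to the ligand
#' exceeds `cutoff`, default 4.0 Angstrom, are set to NA) and the
#' negligibility rule (contributions below `negligible` in magnitude,
#' default 0.05 kcal/mol, are set to NA). When the table has no distance
#' column only the negligibility rule applies. Rows are sorted by residue
#' number (digits extracted from the residue id).
#'
#' @param decomp data.frame with `residue_id`, `contribution` and
#'   optionally `min_distance`
#' @param cutoff distance cutoff, Angstrom (default 4.0)
#' @param negligible magnitude threshold, kcal/mol (default 0.05)
#' @return the filtered, sorted data.frame
#' @export
perResidueFilter <- function(decomp, cutoff = 4, negligible = 0.05) {
  if (nrow(decomp) == 0L) return(decomp)
  drop <- !is.na(decomp$contribution) &
    abs(decomp$contribution) < negligible
  if ("min_distance" %in% names(decomp))
    drop <- drop | (!is.na(decomp$min_distance) &
                      decomp$min_distance > cutoff)
  decomp$contribution[drop] <- NA_real_
  num <- suppressWarnings(as.numeric(gsub("\\D", "", decomp$residue_id)))
  decomp <- decomp[order(num, decomp$residue_id), , drop = FALSE]
  rownames(decomp) <- NULL
  decomp
}

#' Term-wise comparison of two energy breakdowns or decompositions
#'
#' For two [EnergyBreakdown-class] objects, returns the named term-wise
#' differences `a - b`. For two per-residue decomposition data.frames,
#' merges on `residue_id` and subtracts contributions NA-aware (NA minus
#' anything is NA).
#'
#' @param a,b two [EnergyBreakdown-class] objects or two decomposition
#'   data.frames with the same schema
#' @return named numeric differences, or a data.frame of per-residue
#'   differences
#' @export
compareBreakdowns <- function(a, b) {
  if (is(a, "EnergyBreakdown") && is(b, "EnergyBreakdown"))
    return(breakdownVector(a) - breakdownVector(b))
  if (is.data.frame(a) && is.data.frame(b)) {
    if (!all(c("residue_id", "contribution") %in% names(a)) ||
        !all(c("residue_id", "contribution") %in% names(b)))
      stop("decomposition tables need residue_id and contribution columns")
    m <- merge(a[, c("residue_id", "contribution")],
               b[, c("residue_id", "contribution")],
               by = "residue_id", all = TRUE, suffixes = c("_a", "_b"))
    m$difference <- m$contribution_a - m$contribution_b
    return(m)
  }
  stop("schema mismatch: a and b must both be EnergyBreakdown objects ",
       "or both decomposition data.frames")
}
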