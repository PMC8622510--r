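## Built-in per-element field parameters.
##
## vdw_radius: Bondi (1964) van der Waals radii, Angstrom.
## lj_epsilon: Lennard-Jones well depths in kcal/mol, GAFF/Amber-like values
##   by element (heavy-atom representative types).
## hydrophobic_weight: unitless atomic hydrophobicity in the spirit of
##   Ghose-Crippen atomic logP contributions, sign-coded (carbon and sulfur
##   hydrophobic, nitrogen/oxygen hydrophilic).
## donor/acceptor defaults: acceptors are N, O, F; donor status depends on
##   attached hydrogens, which element-only typing cannot see, so the default
##   marks N as donor-capable and O as non-donor; input files may override
##   these flags via data fields.

.ATOM_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
  lj_epsilon = c(0.0157, 0.1094, 0.1700, 0.2100, 0.0610, 0.2000, 0.2500,
                 0.2650, 0.3200, 0.4000),
  hydrophobic_weight = c(0.23, 1.00, -0.30, -0.40, 0.44, 0.10, 0.60, 0.72,
                         0.85, 0.90),
  donor_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE),
  acceptor_flag = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                    FALSE, FALSE),
  stringsAsFactors = FALSE)
rownames(.ATOM_PARAMS) <- .ATOM_PARAMS$element

#' Built-in per-element atom parameter table
#'
#' Parameters used to fill per-atom properties absent from input files:
#' Bondi van der Waals radii, element-level Lennard-Jones well depths,
#' atomic hydrophobicity weights, and default hydrogen-bond donor/acceptor
#' flags. Rows are named by element symbol. Values can be overridden per
#' call via the `overrides` argument of [readMolecules()].
#'
#' @return data.frame keyed by element symbol
#' @export
atomParameterTable <- function() .ATOM_PARAMS

#' Fill missing per-atom parameters from the element table
#'
#' @param atoms data.frame with at least `element`, `x`, `y`, `z`
#' @param overrides optional data.frame in the shape of
#'   [atomParameterTable()] whose rows replace the built-in entries
#' @return data.frame with the full atom column contract
#' @export
fillAtomParameters <- function(atoms, overrides = NULL) {
  tab <- .ATOM_PARAMS
  if (!is.null(overrides)) {
    tab[rownames(overrides), colnames(overrides)] <- overrides
  }
  el <- as.character(atoms$element)
  unknown <- setdiff(unique(el), rownames(tab))
  need <- setdiff(.ATOM_COLS, names(atoms))
  if (length(unknown) && length(intersect(
      need, c("vdw_radius", "lj_epsilon", "hydrophobic_weight",
              "donor_flag", "acceptor_flag"))))
    stop("no atom parameters for element(s): ",
         paste(unknown, collapse = ", "), " (atoms ",
         paste(which(el %in% unknown), collapse = ", "), ")")
  if ("charge" %in% need) atoms$charge <- 0
  for (col in setdiff(need, "charge")) atoms[[col]] <- tab[el, col]
  atoms[, .ATOM_COLS]
}
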