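## Seeded synthetic inputs with the statistical structure the analysis
## assumes: an aligned analog series sharing a rigid scaffold with
## randomised R-group decorations, activities linear in a small number of
## grid-field columns plus Gaussian noise, and stationary Gaussian
## energy-component time series.

#' Synthetic-data specification
#'
#' Defaults emulate the study conditions of a typical kinase-inhibitor
#' 3D-QSAR series: 40 aligned analogs sharing a common core, pIC50 spanning
#' about 3 log units, activity linear in a few grid-field values with 0.2
#' log units of Gaussian noise, and 200-frame stationary energy series.
#'
#' @param nMolecules number of molecules (default 40)
#' @param rgroupAtomRange integer(2), min/max R-group atoms per molecule
#' @param plantedCoefficients optional named numeric of planted weights
#'   keyed by kept descriptor column name (default: chosen automatically by
#'   [plantActivity()])
#' @param noiseSd activity noise SD, pIC50 log units (default 0.2)
#' @param activitySpan target activity range, log units (default 3)
#' @param baseline least-active pIC50 (default 4.8)
#' @param frameCount energy series length (default 200)
#' @param seed integer RNG seed
#' @return validated list of class "SynthSpec"
#' @export
synthSpec <- function(nMolecules = 40, rgroupAtomRange = c(2L, 8L),
                      plantedCoefficients = NULL, noiseSd = 0.2,
                      activitySpan = 3, baseline = 4.8, frameCount = 200,
                      seed = 1) {
  if (nMolecules < 1 || frameCount < 1) stop("counts must be positive")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (length(rgroupAtomRange) != 2 ||
      rgroupAtomRange[1] > rgroupAtomRange[2] || rgroupAtomRange[1] < 0)
    stop("rgroupAtomRange must be (min, max) with 0 <= min <= max")
  structure(list(nMolecules = as.integer(nMolecules),
                 rgroupAtomRange = as.integer(rgroupAtomRange),
                 plantedCoefficients = plantedCoefficients,
                 noiseSd = noiseSd, activitySpan = activitySpan,
                 baseline = baseline, frameCount = as.integer(frameCount),
                 seed = as.integer(seed)),
            class = "SynthSpec")
}

## Rigid diamino-pyrimidine-like scaffold: a planar six-membered ring
## (2 N, 4 C) with two exocyclic amine nitrogens; all molecules share these
## coordinates exactly.
.scaffoldAtoms <- function() {
  ang <- (0:5) * pi / 3
  ring <- data.frame(element = c("N", "C", "N", "C", "C", "C"),
                     x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0)
  exo <- data.frame(element = c("N", "N"),
                    x = 2.73 * cos(ang[c(4, 6)]),
                    y = 2.73 * sin(ang[c(4, 6)]), z = 0)
  at <- rbind(ring, exo)
  at$charge <- c(-0.25, 0.20, -0.25, 0.18, -0.10, 0.18, -0.32, -0.32)
  at
}

#' Generate a seeded aligned analog series
#'
#' All molecules share the scaffold coordinates exactly (the common
#' substructure); R-group atoms are placed in a bounded shell (1.5-4.0
#' Angstrom) around the two exocyclic attachment points with randomised
#' elements, charges (zero-sum per molecule) and donor flags. Bit
#' reproducible for a fixed seed.
#'
#' @param spec a [synthSpec()] specification
#' @return a [MoleculeSet-class]
#' @export
genMoleculeSeries <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  core <- .scaffoldAtoms()
  ncore <- nrow(core)
  anchors <- as.matrix(core[c(7, 8), c("x", "y", "z")])
  center <- colMeans(as.matrix(core[1:6, c("x", "y", "z")]))
  rng <- spec$rgroupAtomRange
  mols <- withr::with_seed(spec$seed, lapply(seq_len(spec$nMolecules),
                                             function(i) {
    nR <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
    atoms <- core
    if (nR > 0) {
      el <- sample(c("C", "C", "C", "N", "O", "F", "S"), nR, replace = TRUE)
      anchorIdx <- rep_len(1:2, nR)
      pos <- t(vapply(seq_len(nR), function(j) {
        repeat {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          anchor <- anchors[anchorIdx[j], ]
          # bias outward from the ring center
          if (sum(dir * (anchor - center)) > 0) break
        }
        anchor + dir * stats::runif(1, 1.5, 4.0)
      }, numeric(3)))
      rg <- data.frame(element = el, x = pos[, 1], y = pos[, 2],
                       z = pos[, 3],
                       charge = stats::runif(nR, -0.3, 0.3))
      atoms <- rbind(atoms, rg)
    }
    atoms$charge <- atoms$charge - mean(atoms$charge)  # zero net charge
    atoms <- fillAtomParameters(atoms)
    atoms$donor_flag <- FALSE
    atoms$donor_flag[7:8] <- TRUE                       # exocyclic amines
    if (nR > 0) {
      extra <- which(atoms$element %in% c("N", "O") &
                       seq_len(nrow(atoms)) > ncore)
      if (length(extra))
        atoms$donor_flag[extra] <- stats::runif(length(extra)) < 0.5
    }
    new("Molecule", id = sprintf("SYN%02d", i), atoms = atoms,
        coreIdx = seq_len(ncore))
  }))
  MoleculeSet(mols)
}

#' Plant a linear field-activity relationship
#'
#' Computes the CoMFA descriptor block of the series on `grid`, applies the
#' 2.0 column filter, and sets
#' `pIC50_i = baseline + sum_j w_j field_ij + eps_i` with
#' `eps ~ N(0, noiseSd^2)`, the weights rescaled so that the noise-free
#' activity range equals `activitySpan`. Planting operates on post-filter
#' columns so the signal is guaranteed to survive column filtering. When no
#' planted coefficients are supplied, the default weights follow the two
#' dominant latent directions of the filtered field matrix (each truncated
#' to its 20 largest loadings), i.e. activity driven by the series'
#' dominant substituent variation — a planted rank of 2. The
#' planted truth (column names, rescaled weights, baseline) is attached as
#' the `planted` attribute for recovery tests.
#'
#' @param molecules a [MoleculeSet-class] from [genMoleculeSeries()]
#' @param grid a [GridSpec-class] (e.g. [buildGrid()] of the series)
#' @param spec the [synthSpec()] used
#' @return activity data.frame (compound_id, ic50, pic50, set_label) with
#'   attribute `planted`
#' @export
plantActivity <- function(molecules, grid, spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  block <- columnFilter(
    assembleDescriptorMatrix(molecules, grid, c("S", "E"), "comfa"), 2)
  M <- descriptorMatrix(block)
  w <- spec$plantedCoefficients
  plantedRank <- NA_integer_
  if (is.null(w)) {
    # Default: activity follows the two dominant latent directions of the
    # post-filter field matrix (truncated to their 20 largest loadings
    # each), mimicking activity driven by the series' dominant, spatially
    # coherent substituent variation. Signs are fixed so the result is
    # deterministic across linear-algebra backends.
    sv <- svd(scale(M, scale = FALSE), nu = 0, nv = 2)
    fixSign <- function(v) v * sign(v[which.max(abs(v))])
    v1 <- fixSign(sv$v[, 1])
    v2 <- if (ncol(sv$v) > 1) fixSign(sv$v[, 2]) else rep(0, nrow(sv$v))
    ntop <- min(20L, ncol(M))
    wFull <- stats::setNames(rep(0, ncol(M)), colnames(M))
    k1 <- order(abs(v1), decreasing = TRUE)[seq_len(ntop)]
    k2 <- order(abs(v2), decreasing = TRUE)[seq_len(ntop)]
    wFull[k1] <- wFull[k1] + v1[k1]
    wFull[k2] <- wFull[k2] + 0.5 * v2[k2]
    w <- wFull[wFull != 0]
    plantedRank <- 2L
  }
  if (!all(names(w) %in% colnames(M)))
    stop("planted coefficients reference unknown post-filter columns: ",
         paste(setdiff(names(w), colnames(M)), collapse = ", "))
  if (all(w == 0) && spec$activitySpan > 0)
    stop("all planted weights are zero but a nonzero activity span ",
         "was requested")
  raw <- drop(M[, names(w), drop = FALSE] %*% w)
  spread <- diff(range(raw))
  if (spread < 1e-9) stop("planted signal has no variance across molecules")
  scale <- spec$activitySpan / spread
  noise <- withr::with_seed(spec$seed + 1L,
                            stats::rnorm(nrow(M), 0, spec$noiseSd))
  pic50 <- spec$baseline + scale * (raw - min(raw)) + noise
  out <- data.frame(compound_id = rownames(M), ic50 = pic50ToIc50(pic50),
                    pic50 = pic50, set_label = "unassigned",
                    stringsAsFactors = FALSE)
  attr(out, "planted") <- list(columns = names(w), weights = scale * w,
                               baseline = spec$baseline,
                               rank = if (is.na(plantedRank)) length(w)
                                      else plantedRank)
  out
}

#' Generate a stationary per-frame energy-component series
#'
#' Independent Gaussian frames about the stated component means, emulating
#' the equilibrated final window of an MD trajectory.
#'
#' @param means named (vdwaals, e_el, e_pbgb, e_surf) component means,
#'   kcal/mol
#' @param sds per-component SDs, kcal/mol (recycled if length 1)
#' @param nFrames series length (default 200)
#' @param seed integer RNG seed
#' @param label complex identifier
#' @param variant "PB" or "GB"
#' @return data.frame in the shape of [readEnergyComponents()] output
#' @export
genEnergyFrames <- function(means, sds, nFrames = 200, seed = 1,
                            label = "synthetic", variant = "GB") {
  need <- c("vdwaals", "e_el", "e_pbgb", "e_surf")
  if (!all(need %in% names(means)))
    stop("means must contain: ", paste(need, collapse = ", "))
  if (nFrames < 1) stop("nFrames must be >= 1")
  sds <- rep_len(sds, 4)
  if (any(sds < 0)) stop("sds must be >= 0")
  comp <- withr::with_seed(seed, lapply(seq_along(need), function(k)
    stats::rnorm(nFrames, as.numeric(means[[need[k]]]), sds[k])))
  out <- data.frame(frame = seq_len(nFrames), vdwaals = comp[[1]],
                    e_el = comp[[2]], e_pbgb = comp[[3]],
                    e_surf = comp[[4]])
  attr(out, "variant") <- variant
  attr(out, "label") <- label
  out
}

#' Randomly permute a fraction of response values
#'
#' Negative-control generator: permutes `round(fraction * n)` randomly
#' chosen entries among themselves, leaving the rest fixed.
#'
#' @param y response vector
#' @param fraction fraction of entries to permute, in [0, 1]
#' @param seed integer RNG seed
#' @return permuted response
#' @export
scrambleLabels <- function(y, fraction, seed) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  k <- round(fraction * length(y))
  if (k < 2) return(y)
  perm <- withr::with_seed(seed, {
    idx <- sample(seq_along(y), k)
    list(idx = idx, from = sample(idx))
  })
  y[perm$idx] <- y[perm$from]
  y
}
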