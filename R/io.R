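#' Read aligned molecules from SDF or MOL2
#'
#' SDF (V2000) files are parsed with \pkg{ChemmineR}; MOL2 files with
#' \pkg{bio3d}. Molecules must arrive pre-aligned: no conformer generation
#' or alignment is performed. Partial charges are taken from the MOL2 charge
#' column, or from an SDF data field named \code{PARTIAL_CHARGES}
#' (whitespace-separated, one value per atom); when absent, charges default
#' to zero. Optional SDF data fields \code{CORE_ATOMS}, \code{DONOR_ATOMS}
#' and \code{ACCEPTOR_ATOMS} carry 1-based atom indices for the shared
#' substructure and hydrogen-bond flags; per-atom parameters not present in
#' the file (van der Waals radius, Lennard-Jones epsilon, hydrophobic
#' weight, donor/acceptor defaults) are filled from the built-in element
#' table.
#'
#' @param path file path
#' @param format "sdf" or "mol2" (default: guessed from the file extension)
#' @param overrides optional atom-parameter override table, see
#'   [fillAtomParameters()]
#' @return a [MoleculeSet-class], one molecule per file entry, atom order
#'   preserved
#' @export
readMolecules <- function(path, format = NULL, overrides = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  format <- match.arg(format, c("sdf", "mol2"))
  mols <- if (format == "sdf") .readSdf(path, overrides)
          else .readMol2(path, overrides)
  MoleculeSet(mols)
}

.readSdf <- function(path, overrides = NULL) {
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("cannot parse SDF file '", path, "': ",
                             conditionMessage(e)))
  ids <- tryCatch(ChemmineR::sdfid(sdfs), error = function(e) NULL)
  out <- vector("list", length(sdfs))
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
    id <- if (!is.null(ids) && nzchar(ids[i])) ids[i] else sprintf("mol_%d", i)
    if (is.null(ab) || is.null(dim(ab)) || nrow(ab) == 0L || ncol(ab) < 3L)
      stop("SDF molecule ", i, " ('", id, "'): malformed or missing ",
           "coordinates block")
    xyz <- ab[, 1:3, drop = FALSE]
    if (!all(is.finite(xyz)))
      stop("SDF molecule ", i, " ('", id, "'): malformed coordinates block")
    element <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = element, x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], stringsAsFactors = FALSE,
                        row.names = NULL)
    db <- ChemmineR::datablock(sdf)
    nA <- nrow(atoms)
    getIdx <- function(field) {
      if (!field %in% names(db)) return(NULL)
      v <- suppressWarnings(as.integer(strsplit(trimws(db[[field]]),
                                                "\\s+")[[1]]))
      v[!is.na(v) & v >= 1 & v <= nA]
    }
    if ("PARTIAL_CHARGES" %in% names(db)) {
      q <- suppressWarnings(as.numeric(strsplit(
        trimws(.asciiMinus(db[["PARTIAL_CHARGES"]])), "\\s+")[[1]]))
      if (length(q) != nA || any(is.na(q)))
        stop("SDF molecule ", i, " ('", id,
             "'): PARTIAL_CHARGES field does not match atom count")
      atoms$charge <- q
    }
    atoms <- fillAtomParameters(atoms, overrides)
    don <- getIdx("DONOR_ATOMS"); acc <- getIdx("ACCEPTOR_ATOMS")
    if (!is.null(don)) atoms$donor_flag <- seq_len(nA) %in% don
    if (!is.null(acc)) atoms$acceptor_flag <- seq_len(nA) %in% acc
    core <- getIdx("CORE_ATOMS")
    out[[i]] <- new("Molecule", id = id, atoms = atoms,
                    coreIdx = as.integer(if (is.null(core)) integer() else core))
  }
  out
}

.readMol2 <- function(path, overrides = NULL) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("cannot parse MOL2 file '", path,
                                         "': ", conditionMessage(e)))
  recs <- if (!is.null(m$atom)) list(m) else m
  lapply(seq_along(recs), function(i) {
    at <- recs[[i]]$atom
    if (is.null(at) || nrow(at) == 0L)
      stop("MOL2 molecule ", i, ": no atom records")
    element <- sub("\\..*$", "", at$elety)
    atoms <- data.frame(element = element, x = at$x, y = at$y, z = at$z,
                        charge = if ("charge" %in% names(at)) at$charge else 0,
                        stringsAsFactors = FALSE)
    if (any(is.na(atoms$charge))) atoms$charge[is.na(atoms$charge)] <- 0
    id <- recs[[i]]$name
    if (is.null(id) || !nzchar(id)) id <- sprintf("mol_%d", i)
    new("Molecule", id = as.character(id),
        atoms = fillAtomParameters(atoms, overrides), coreIdx = integer())
  })
}

#' Write a MoleculeSet as an SDF (V2000) file
#'
#' Emits one V2000 entry per molecule with a zero-bond connection table and
#' data fields \code{PARTIAL_CHARGES}, \code{CORE_ATOMS},
#' \code{DONOR_ATOMS} and \code{ACCEPTOR_ATOMS} so that
#' [readMolecules()] round-trips coordinates, charges and flags. Output is
#' byte-deterministic for a given set.
#'
#' @param molset a [MoleculeSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeMoleculesSDF <- function(molset, path) {
  stopifnot(is(molset, "MoleculeSet"))
  con <- file(path, open = "wb")  # binary mode: fixed newlines
  on.exit(close(con))
  for (i in seq_len(length(molset))) {
    m <- molset[[i]]
    a <- m@atoms
    lines <- c(m@id, "  fieldqsar", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), 0L),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element),
               "M  END",
               ">  <PARTIAL_CHARGES>",
               paste(sprintf("%.6f", a$charge), collapse = " "), "",
               ">  <CORE_ATOMS>",
               paste(m@coreIdx, collapse = " "), "",
               ">  <DONOR_ATOMS>",
               paste(which(a$donor_flag), collapse = " "), "",
               ">  <ACCEPTOR_ATOMS>",
               paste(which(a$acceptor_flag), collapse = " "), "",
               "$$$$")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

.asciiMinus <- function(x) gsub("−", "-", x)

#' Convert IC50 (nM) to pIC50
#'
#' pIC50 is defined as -log10 of the molar IC50, i.e. `9 - log10(IC50[nM])`.
#'
#' @param ic50 IC50 in nanomolar, > 0
#' @return pIC50 (-log10 molar)
#' @export
ic50ToPic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be finite and > 0 (nM)")
  9 - log10(ic50)
}

#' Convert pIC50 back to IC50 (nM)
#' @param pic50 pIC50 (-log10 molar)
#' @return IC50 in nanomolar
#' @export
pic50ToIc50 <- function(pic50) 10^(9 - pic50)

#' Read an activity table
#'
#' CSV with a header containing `compound_id` and at least one of `ic50`
#' (nM) or `pic50`; a missing column is derived from the other. When both
#' are present each row must satisfy `pic50 = 9 - log10(ic50)` within 1e-6.
#' Unicode minus signs are normalised to ASCII.
#'
#' @param path CSV file path
#' @return data.frame with columns compound_id, ic50, pic50, set_label
#' @export
readActivityTable <- function(path) {
  txt <- .asciiMinus(readLines(path, warn = FALSE))
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"compound_id" %in% names(df)) stop("missing column: compound_id")
  hasIc <- "ic50" %in% names(df); hasP <- "pic50" %in% names(df)
  if (!hasIc && !hasP) stop("need at least one of ic50, pic50")
  if (!hasP) df$pic50 <- ic50ToPic50(df$ic50)
  if (!hasIc) df$ic50 <- pic50ToIc50(df$pic50)
  both <- is.finite(df$ic50) & is.finite(df$pic50)
  bad <- both & abs(df$pic50 - ic50ToPic50(pmax(df$ic50, .Machine$double.xmin))) > 1e-6
  if (any(bad))
    stop("inconsistent ic50/pic50 for compound(s): ",
         paste(df$compound_id[bad], collapse = ", "))
  df$ic50[!is.finite(df$ic50)] <- pic50ToIc50(df$pic50[!is.finite(df$ic50)])
  df$pic50[!is.finite(df$pic50)] <- ic50ToPic50(df$ic50[!is.finite(df$pic50)])
  if (!"set_label" %in% names(df)) df$set_label <- "unassigned"
  df[, c("compound_id", "ic50", "pic50", "set_label")]
}

#' Activity-stratified train/test split
#'
#' Rows are ranked by pIC50 and cut into three equal-as-possible tertile
#' groups (high/medium/low activity); test compounds are drawn from each
#' group proportionally to its size, uniformly at random under `seed`. The
#' split is bit-reproducible for a fixed seed. Structural diversity is not
#' enforced (documented limitation: activity stratification only).
#'
#' @param table data.frame with columns `compound_id` and `pic50`
#' @param nTest number of test compounds (< nrow(table))
#' @param seed integer RNG seed
#' @return `table` with `set_label` filled with "train"/"test"
#' @export
splitDataset <- function(table, nTest, seed) {
  n <- nrow(table)
  if (nTest >= n) stop("nTest must be smaller than the number of rows")
  if (any(!is.finite(table$pic50))) stop("pic50 required for all rows")
  table$set_label <- "train"
  if (nTest == 0) return(table)
  ord <- order(table$pic50, decreasing = TRUE)  # high -> low activity
  sizes <- diff(floor(seq(0, n, length.out = 4)))
  group <- rep(1:3, times = sizes)
  # proportional allocation, remainder to largest fractional parts
  frac <- nTest * sizes / n
  take <- floor(frac)
  rem <- nTest - sum(take)
  if (rem > 0) {
    extra <- order(frac - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  if (any(take >= sizes))
    stop("nTest leaves an activity tertile without training compounds")
  testIdx <- withr::with_seed(seed, unlist(lapply(1:3, function(g) {
    pool <- ord[group == g]
    sample(pool, take[g])
  })))
  table$set_label[testIdx] <- "test"
  table
}

#' Read per-frame MM-PB(GB)SA energy components
#'
#' Expects a CSV whose header contains (case-insensitively) `frame`,
#' `VDWAALS`, `EEL` (or `E_EL`), `EPB` or `EGB` (or `E_PB`/`E_GB`), and
#' `ESURF` (or `E_SURF`). Column order is irrelevant; both `EPB` and `EGB`
#' map to the polar solvation component with the variant recorded in the
#' `variant` attribute.
#'
#' @param path CSV file path
#' @param label complex identifier stored on the result
#' @return data.frame (frame, vdwaals, e_el, e_pbgb, e_surf) with
#'   attributes `variant` ("PB"/"GB") and `label`
#' @export
readEnergyComponents <- function(path, label = basename(path)) {
  txt <- .asciiMinus(readLines(path, warn = FALSE))
  df <- utils::read.csv(text = txt, stringsAsFactors = FALSE)
  names(df) <- gsub("[^a-z0-9]", "", tolower(names(df)))
  pick <- function(aliases) {
    hit <- intersect(aliases, names(df))
    if (length(hit)) hit[1] else NA_character_
  }
  fr <- pick(c("frame", "frameindex"))
  vd <- pick("vdwaals")
  el <- pick(c("eel", "eele"))
  pb <- pick(c("epb", "epbgb"))
  gb <- pick("egb")
  su <- pick(c("esurf", "esa"))
  need <- c(frame = fr, VDWAALS = vd, EEL = el, ESURF = su)
  if (any(is.na(need)))
    stop("missing mandatory column(s): ",
         paste(names(need)[is.na(need)], collapse = ", "))
  if (is.na(pb) && is.na(gb)) stop("missing mandatory column(s): EPB/EGB")
  variant <- if (!is.na(pb)) "PB" else "GB"
  polar <- if (!is.na(pb)) pb else gb
  if (nrow(df) == 0L) stop("no frames in ", path)
  out <- data.frame(frame = as.integer(df[[fr]]),
                    vdwaals = as.numeric(df[[vd]]),
                    e_el = as.numeric(df[[el]]),
                    e_pbgb = as.numeric(df[[polar]]),
                    e_surf = as.numeric(df[[su]]))
  if (any(!is.finite(as.matrix(out))))
    stop("non-finite energy component in ", path)
  if (any(diff(out$frame) <= 0))
    stop("frame indices must be strictly increasing in ", path)
  attr(out, "variant") <- variant
  attr(out, "label") <- label
  out
}

#' Write a scalar field as an OpenDX grid file
#'
#' Standard OpenDX regular-grid scalar field, readable by molecular viewers
#' (PyMOL, VMD, Chimera). Values are supplied in the package's internal
#' x-fastest point order and written in the OpenDX z-fastest convention.
#'
#' @param values numeric vector, one value per grid point
#' @param grid a [GridSpec-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeFieldGrid <- function(values, grid, path) {
  stopifnot(is(grid, "GridSpec"))
  n <- nGridPoints(grid)
  if (length(values) != n)
    stop("value count (", length(values), ") does not match grid point count (",
         n, ")")
  d <- grid@dims; s <- grid@spacing; o <- grid@origin
  arr <- array(values, dim = d)            # x-fastest in
  vz <- as.vector(aperm(arr, c(3, 2, 1)))  # z-fastest out
  pad <- (3 - length(vz) %% 3) %% 3
  rows <- matrix(c(sprintf("%.6e", vz), rep("", pad)), ncol = 3, byrow = TRUE)
  dataLines <- trimws(apply(rows, 1, paste, collapse = " "))
  lines <- c(
    "# OpenDX scalar field (fieldqsar)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", o[1], o[2], o[3]),
    sprintf("delta %.6f 0.000000 0.000000", s),
    sprintf("delta 0.000000 %.6f 0.000000", s),
    sprintf("delta 0.000000 0.000000 %.6f", s),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n),
    dataLines,
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3')
  writeLines(lines, path)
  invisible(path)
}

#' Read an OpenDX grid file written by [writeFieldGrid()]
#'
#' @param path OpenDX file path
#' @return list with elements `values` (x-fastest order) and `grid`
#'   (a [GridSpec-class])
#' @export
readFieldGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cnt <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(cnt)) stop("not an OpenDX gridpositions file: ", path)
  d <- as.integer(strsplit(sub(".*counts\\s+", "", cnt), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin\\s+", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- vapply(grep("^delta", lines, value = TRUE)[1:3], function(l)
    as.numeric(strsplit(sub("^delta\\s+", "", l), "\\s+")[[1]]),
    numeric(3))
  s <- c(deltas[1, 1], deltas[2, 2], deltas[3, 3])
  if (max(abs(s - s[1])) > 1e-9) stop("anisotropic grids not supported")
  start <- grep("data follows", lines)[1]
  n <- prod(d)
  vals <- numeric(0); i <- start + 1
  while (length(vals) < n && i <= length(lines)) {
    if (grepl("^(attribute|object|component)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != n)
    stop("expected ", n, " data values, found ", length(vals))
  arr <- array(vals, dim = rev(d))          # z-fastest on disk
  list(values = as.vector(aperm(arr, c(3, 2, 1))),
       grid = GridSpec(origin = org, spacing = s[1], dims = d))
}
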