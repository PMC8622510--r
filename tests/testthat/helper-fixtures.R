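# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A minimal molecule with fully specified parameters, for closed-form field
# checks.
singleAtomMolecule <- function(element = "C", charge = 0,
                               xyz = c(0, 0, 0)) {
  Molecule("m1", data.frame(element = element,
                            x = xyz[1], y = xyz[2], z = xyz[3],
                            charge = charge))
}

# Small deterministic synthetic series shared across PLS/validation tests.
smallSeries <- function(seed = 11, n = 40) {
  spec <- synthSpec(nMolecules = n, seed = seed)
  mols <- genMoleculeSeries(spec)
  grid <- buildGrid(mols)
  block <- columnFilter(
    assembleDescriptorMatrix(mols, grid, c("S", "E"), "comfa"), 2)
  act <- plantActivity(mols, grid, spec)
  list(spec = spec, mols = mols, grid = grid, block = block, act = act,
       M = descriptorMatrix(block))
}

# Memoised: building the 40-molecule series once keeps the suite fast.
.seriesCache <- new.env(parent = emptyenv())
cachedSeries <- function() {
  if (is.null(.seriesCache$s)) .seriesCache$s <- smallSeries()
  .seriesCache$s
}

# Tiny SDF text fixture written to a temp file.
writeTinySdf <- function(path, charges = TRUE) {
  lines <- c("tiny1", "  test", "",
             "  3  2  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    1.5000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
             "    0.0000    1.4000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0", "  1  3  1  0", "M  END")
  if (charges)
    lines <- c(lines, ">  <PARTIAL_CHARGES>", "0.10 -0.05 -0.05", "")
  writeLines(c(lines, "$$$$"), path)
  path
}

writeTinyMol2 <- function(path) {
  writeLines(c("@<TRIPOS>MOLECULE", "tinymol2", "3 2 1 0 0", "SMALL",
               "GASTEIGER", "@<TRIPOS>ATOM",
               "      1 C1          0.0000    0.0000    0.0000 C.3     1  LIG1        0.1000",
               "      2 N1          1.5000    0.0000    0.0000 N.3     1  LIG1       -0.0500",
               "      3 O1          0.0000    1.4000    0.0000 O.3     1  LIG1       -0.0500",
               "@<TRIPOS>BOND", "     1    1    2 1", "     2    1    3 1"),
             path)
  path
}
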