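probe <- ProbeSpec()

test_that("grid construction covers the series with the stated margin", {
  m <- singleAtomMolecule()
  g <- buildGrid(MoleculeSet(list(m)), spacing = 2, margin = 4)
  expect_equal(g@dims, c(5L, 5L, 5L))
  expect_equal(g@origin, c(-4, -4, -4))
  g0 <- buildGrid(MoleculeSet(list(m)), spacing = 2, margin = 0)
  expect_equal(g0@dims, c(1L, 1L, 1L))
  expect_equal(gridPoints(g0)[1, ], c(x = 0, y = 0, z = 0))
  # permutation invariance
  spec <- synthSpec(nMolecules = 5, seed = 3)
  mols <- genMoleculeSeries(spec)
  g1 <- buildGrid(mols)
  g2 <- buildGrid(MoleculeSet(rev(mols@molecules)))
  expect_equal(g1@origin, g2@origin)
  expect_equal(g1@dims, g2@dims)
  expect_error(buildGrid(MoleculeSet(list())), "empty")
})

test_that("steric field matches the Lennard-Jones closed form", {
  m <- singleAtomMolecule("C")
  rmin <- 1.70 + probe@vdwRadius
  eps <- sqrt(0.1094 * probe@ljEpsilon)
  # point exactly at the potential minimum distance
  g <- GridSpec(origin = c(rmin, 0, 0), spacing = 1, dims = c(1, 1, 1))
  expect_equal(comfaSteric(m, g, probe), -eps, tolerance = 1e-9)
  # far-field decay
  gFar <- GridSpec(origin = c(100, 0, 0), spacing = 1, dims = c(1, 1, 1))
  expect_lt(abs(comfaSteric(m, gFar, probe)), 1e-6)
  # point at the atom center clamps to +cap, no singularity
  gOn <- GridSpec(origin = c(0, 0, 0), spacing = 1, dims = c(1, 1, 1))
  expect_equal(comfaSteric(m, gOn, probe), 30)
  # all values capped in [-30, 30]
  g3 <- GridSpec(origin = c(-2, -2, -2), spacing = 1, dims = c(5, 5, 5))
  v <- comfaSteric(m, g3, probe)
  expect_true(all(v >= -30 & v <= 30))
})

test_that("electrostatic field matches the Coulomb closed form", {
  # q = +0.5 at 4 A with distance-dependent dielectric: 332.0636*0.5/16
  m <- singleAtomMolecule("C", charge = 0.5)
  g <- GridSpec(origin = c(4, 0, 0), spacing = 1, dims = c(1, 1, 1))
  expect_equal(comfaElectrostatic(m, g, probe), 332.0636 * 0.5 / 16,
               tolerance = 1e-6)
  expect_equal(comfaElectrostatic(m, g, probe, cap = 100,
                                  dielectric = "constant"),
               332.0636 * 0.5 / 4, tolerance = 1e-6)
  # without the larger cap the same value clamps at the tolerance
  expect_equal(comfaElectrostatic(m, g, probe, dielectric = "constant"), 30)
  # zero charges give a zero field
  m0 <- singleAtomMolecule("C", charge = 0)
  g3 <- GridSpec(origin = c(-3, -3, -3), spacing = 3, dims = c(3, 3, 3))
  expect_true(all(comfaElectrostatic(m0, g3, probe) == 0))
  # symmetric +q/-q pair cancels at the midpoint
  m2 <- Molecule("pair", data.frame(
    element = c("C", "C"), x = c(-2, 2), y = 0, z = 0,
    charge = c(0.4, -0.4)))
  gm <- GridSpec(origin = c(0, 1, 0), spacing = 1, dims = c(1, 1, 1))
  expect_equal(comfaElectrostatic(m2, gm, probe), 0, tolerance = 1e-9)
})

test_that("CoMSIA fields follow the Gaussian similarity form", {
  m <- singleAtomMolecule("C", charge = 0.2)
  a <- atomTable(m)
  gOn <- GridSpec(origin = c(0, 0, 0), spacing = 1, dims = c(1, 1, 1))
  g1 <- GridSpec(origin = c(1, 0, 0), spacing = 1, dims = c(1, 1, 1))
  # steric weight r_vdw^3, probe weight 1, r = 0
  expect_equal(comsiaField(m, gOn, "S"), -a$vdw_radius^3, tolerance = 1e-9)
  # unit weight at r = 1, alpha 0.3 -> -exp(-0.3)
  expect_equal(comsiaField(m, g1, "S") / a$vdw_radius^3, -exp(-0.3),
               tolerance = 1e-9)
  expect_equal(comsiaField(m, g1, "E"), -0.2 * exp(-0.3), tolerance = 1e-9)
  # no donors: donor field identically zero
  expect_true(all(comsiaField(m, g1, "D") == 0))
  expect_error(comsiaField(m, g1, "X"), "kind")
  # non-negative weights give non-positive fields
  g3 <- GridSpec(origin = c(-3, -3, -3), spacing = 2, dims = c(4, 4, 4))
  expect_true(all(comsiaField(m, g3, "S") <= 0))
})

test_that("fields are additive over atoms and translation invariant", {
  frag1 <- data.frame(element = c("C", "N"), x = c(0, 1.4), y = 0, z = 0,
                      charge = c(0.1, -0.1))
  frag2 <- data.frame(element = c("O", "S"), x = c(0, 1), y = 2.5, z = 1,
                      charge = c(-0.2, 0.2))
  mAll <- Molecule("all", rbind(frag1, frag2))
  m1 <- Molecule("f1", frag1); m2 <- Molecule("f2", frag2)
  g <- GridSpec(origin = c(4, -2, -2), spacing = 2, dims = c(3, 3, 3))
  for (fn in list(function(m, g) comfaElectrostatic(m, g, probe, cap = 1e9),
                  function(m, g) comsiaField(m, g, "S"),
                  function(m, g) comsiaField(m, g, "H"))) {
    expect_equal(fn(mAll, g), fn(m1, g) + fn(m2, g), tolerance = 1e-9)
  }
  # rigid translation of molecule and grid leaves the field unchanged
  shift <- c(3.2, -1.7, 0.4)
  at <- atomTable(mAll)
  at[, c("x", "y", "z")] <- sweep(as.matrix(at[, c("x", "y", "z")]), 2,
                                  -shift)
  mShift <- Molecule("s", at)
  gShift <- GridSpec(origin = g@origin + shift, spacing = g@spacing,
                     dims = g@dims)
  expect_equal(comfaSteric(mAll, g, probe), comfaSteric(mShift, gShift, probe),
               tolerance = 1e-9)
  expect_equal(comsiaField(mAll, g, "S"), comsiaField(mShift, gShift, "S"),
               tolerance = 1e-9)
  # atom-order invariance
  mPerm <- Molecule("p", rbind(frag2, frag1))
  expect_equal(comfaSteric(mAll, g, probe), comfaSteric(mPerm, g, probe),
               tolerance = 1e-12)
})

test_that("descriptor assembly shapes, ordering and imputation", {
  spec <- synthSpec(nMolecules = 4, seed = 5)
  mols <- genMoleculeSeries(spec)
  g <- GridSpec(origin = c(-2, -2, -2), spacing = 2, dims = c(2, 2, 2))
  b <- assembleDescriptorMatrix(mols, g, c("S", "E"), "comfa")
  expect_equal(dim(b@matrix), c(4L, 16L))
  expect_equal(columnMeta(b, filtered = FALSE)$kind, rep(c("S", "E"), each = 8))
  bc <- assembleDescriptorMatrix(mols, g, c("S", "E", "H", "D"), "comsia")
  expect_equal(ncol(bc@matrix), 32L)
  expect_error(assembleDescriptorMatrix(mols, g, c("S", "H"), "comfa"),
               "CoMFA")
  # duplicate molecules give identical rows
  dup <- MoleculeSet(list(mols[[1]], Molecule("copy", atomTable(mols[[1]]),
                                              coreIndices(mols[[1]]))))
  bd <- assembleDescriptorMatrix(dup, g, c("S", "E"), "comfa")
  expect_equal(unname(bd@matrix[1, ]), unname(bd@matrix[2, ]))
  # electrostatic entries at sterically excluded points are column means
  sIdx <- which(b@columnMeta$kind == "S")
  eIdx <- which(b@columnMeta$kind == "E")
  excluded <- b@matrix[, sIdx] >= 30 - 1e-9
  if (any(excluded)) {
    expect_true(any(b@imputed[, eIdx][excluded]))
    bClamp <- assembleDescriptorMatrix(mols, g, c("S", "E"), "comfa",
                                       exclusion = "clamp")
    expect_false(any(bClamp@imputed))
  }
})

test_that("column filtering drops low-variance columns", {
  mat <- cbind(const = rep(5, 6), low = seq(0, 1, length.out = 6),
               high = seq(0, 20, length.out = 6),
               edge = c(0, 0, 0, 6.3, 6.3, 6.3))
  blk <- new("DescriptorBlock", matrix = mat,
             columnMeta = data.frame(point = 1:4, kind = "S"),
             keptMask = rep(TRUE, 4), imputed = matrix(FALSE, 6, 4),
             scheme = "comfa", grid = GridSpec(c(0, 0, 0), 2, c(4, 1, 1)))
  f <- columnFilter(blk, 2)
  expect_equal(unname(f@keptMask), c(FALSE, FALSE, TRUE, TRUE))
  expect_gte(sd(mat[, "edge"]), 2)  # SD ~3.45: kept at threshold 2
  f0 <- columnFilter(blk, 0)
  expect_true(all(f0@keptMask))
  expect_error(columnFilter(blk, 100), "lower minSigma")
})
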