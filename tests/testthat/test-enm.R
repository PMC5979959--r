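# Elastic-network normal mode analysis.

test_that("a single spring yields a rank-1 two-node operator", {
  m <- structureModel(data.frame(chain = "A", resno = 1:2,
                                 resname = "ALA", x = c(0, 5), y = 0,
                                 z = 0))
  H <- suppressWarnings(buildHessian(m, cutoff = 10))
  expect_true(isSymmetric(H))
  expect_equal(sum(abs(eigen(H, symmetric = TRUE)$values) > 1e-10), 1)
})

test_that("node pairs beyond the cutoff contribute nothing", {
  m <- structureModel(data.frame(chain = "A", resno = 1:3,
                                 resname = "ALA", x = c(0, 5, 100),
                                 y = 0, z = 0))
  expect_warning(H <- buildHessian(m, cutoff = 10), "connected")
  expect_equal(H[1:3, 7:9], matrix(0, 3, 3))
})

test_that("the Hessian matches an independently assembled operator", {
  for (s in 1:5) {
    m <- makeStructure(8, "coil", seed = s)
    xyz <- as.matrix(caAtoms(m)[, c("x", "y", "z")])
    H <- suppressWarnings(buildHessian(m, cutoff = 10))
    Ho <- oracleHessian(xyz, cutoff = 10)
    expect_equal(H, Ho, tolerance = 1e-10, ignore_attr = TRUE)
    ev <- suppressWarnings(eigenValues(solveModes(H)))
    evo <- sort(eigen(Ho, symmetric = TRUE)$values)
    expect_equal(ev, evo, tolerance = 1e-8)
  }
})

test_that("connected synthetic structures have exactly six zero modes", {
  for (s in 1:200) {
    topo <- c("helix", "hairpin", "coil")[1 + s %% 3]
    m <- makeStructure(20, topo, seed = s)
    ms <- solveModes(buildHessian(m, cutoff = 12))
    v <- eigenValues(ms)
    expect_gt(v[7], 0)
    expect_equal(sum(v < 1e-8 * v[7]), 6)
  }
})

test_that("eigenvectors are orthonormal and scale-invariant in gamma", {
  m <- makeStructure(25, "helix")
  ms <- solveModes(buildHessian(m, cutoff = 10))
  V <- eigenVectors(ms)
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  v1 <- eigenValues(ms)
  v2 <- eigenValues(solveModes(buildHessian(m, cutoff = 10, gamma = 2.5)))
  expect_equal(v2, 2.5 * v1, tolerance = 1e-10)
})

test_that("rigid rotations leave the eigenvalue spectrum unchanged", {
  m <- makeStructure(20, "hairpin")
  v0 <- eigenValues(solveModes(buildHessian(m, cutoff = 10)))
  a <- caAtoms(m)
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% R
  a$x <- xyz[, 1] + 7; a$y <- xyz[, 2] - 3; a$z <- xyz[, 3]
  v1 <- eigenValues(solveModes(buildHessian(structureModel(a), 10)))
  int <- 7:length(v0)
  expect_equal(v1[int], v0[int], tolerance = 1e-8)
})

test_that("fluctuation profiles are non-negative and reject rigid modes", {
  m <- makeStructure(40, "hairpin")
  ms <- solveModes(buildHessian(m, cutoff = 10))
  fl <- modeFluctuations(ms, 7:11)
  expect_true(all(fl$fluct >= 0))
  expect_equal(nrow(fl), 40)
  expect_error(modeFluctuations(ms, 3), "rigid-body")
  # a uniform translation injected as a fake mode gives a flat profile
  fake <- ms
  v <- rep(c(1, 0, 0), 40) / sqrt(40)
  fake@vectors[, 7] <- v
  flFake <- modeFluctuations(fake, 7)
  expect_lt(diff(range(flFake$fluct)), 1e-12)
})

test_that("the flexible region locates the hairpin hinge", {
  m <- makeStructure(60, "hairpin")
  ms <- solveModes(buildHessian(m, cutoff = 10))
  fl <- modeFluctuations(ms, 7:11)
  fr <- flexibleRegion(fl, 11)
  hinge <- 30  # the turn between the two helix halves
  expect_true(fr$start <= hinge + 3 && fr$end >= hinge - 3)
  expect_error(flexibleRegion(fl, 100), "window")
  # single spike: interval centred on the spike
  prof <- data.frame(resno = 1:21, fluct = c(rep(0, 10), 1, rep(0, 10)))
  frs <- flexibleRegion(prof, 5)
  expect_true(11 >= frs$start && 11 <= frs$end)
  expect_equal(frs$peak, 11)
})

test_that("displaced conformers are symmetric about the input model", {
  m <- makeStructure(30, "hairpin")
  ms <- solveModes(buildHessian(m, cutoff = 10))
  dc <- displacedConformers(m, ms, mode = 8, amplitude = 2)
  orig <- as.matrix(caAtoms(m)[, c("x", "y", "z")])
  mid <- (as.matrix(caAtoms(dc$plus)[, c("x", "y", "z")]) +
            as.matrix(caAtoms(dc$minus)[, c("x", "y", "z")])) / 2
  expect_equal(mid, orig, tolerance = 1e-12, ignore_attr = TRUE)
  # per-residue displacement equals amplitude * eigenvector slice norm
  v <- matrix(eigenVectors(ms)[, 8], ncol = 3, byrow = TRUE)
  disp <- sqrt(rowSums((as.matrix(caAtoms(dc$plus)[, c("x", "y", "z")]) -
                          orig)^2))
  expect_equal(disp, 2 * sqrt(rowSums(v^2)), tolerance = 1e-12)
  expect_error(displacedConformers(m, ms, mode = 8, amplitude = 0),
               "amplitude")
  # trajectory file has MODEL blocks
  f <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(dc, f, nFrames = 5)
  lines <- readLines(f)
  expect_equal(sum(grepl("^MODEL", lines)), 5)
  expect_equal(sum(grepl("^ENDMDL", lines)), 5)
})

test_that("contact deviation is symmetric, zero-diagonal and hinge-peaked", {
  m <- makeStructure(60, "hairpin")
  ms <- solveModes(buildHessian(m, cutoff = 10))
  dc <- displacedConformers(m, ms, mode = 7, amplitude = 3)
  cd <- contactDeviation(dc$plus, dc$minus)
  expect_true(isSymmetric(cd))
  expect_equal(max(abs(diag(cd))), 0)
  # identical conformers: all-zero map
  cd0 <- contactDeviation(dc$plus, dc$plus)
  expect_equal(max(cd0), 0)
  # row-sum maxima co-locate with the fluctuation maxima
  fl <- modeFluctuations(ms, 7)
  topDev <- order(rowSums(cd), decreasing = TRUE)[1:8]
  topFl <- order(fl$fluct, decreasing = TRUE)[1:8]
  expect_gt(length(intersect(topDev, topFl)), 0)
  expect_error(contactDeviation(dc$plus,
                                makeStructure(30, "helix")), "residue set")
})

test_that("mode shapes agree with an independent ANM implementation", {
  # bio3d's ANM normal modes serve as an external cross-check
  m <- makeStructure(40, "helix", lysEvery = 1000L)
  f <- tempfile(fileext = ".pdb")
  writeStructurePDB(m, f)
  pdb <- bio3d::read.pdb(f)
  ref <- bio3d::nma(pdb, ff = "anm", cutoff = 10, mass = FALSE)
  ms <- solveModes(buildHessian(m, cutoff = 10))
  fl <- modeFluctuations(ms, 7)
  refFl <- sqrt(rowSums(matrix(ref$modes[, 7], ncol = 3, byrow = TRUE)^2))
  expect_gt(cor(fl$fluct, refFl), 0.95)
  # eigenvalue ratios (gamma-independent) also agree
  expect_equal(eigenValues(ms)[8] / eigenValues(ms)[7],
               ref$L[8] / ref$L[7], tolerance = 1e-4)
})
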