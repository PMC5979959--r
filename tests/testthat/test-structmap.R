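# Structure mapping: distances, constraint classification, model ranking,
# topology, restraint export.

test_that("C-alpha distances are a metric and match brute force", {
  m <- structureModel(data.frame(
    chain = "A", resno = 1:3, resname = "ALA",
    x = c(0, 3, 1), y = c(0, 4, 1), z = c(0, 0, 1)))
  expect_equal(caDistance(m, 1, 2), 5)          # 3-4-5 triangle
  expect_equal(caDistance(m, 1, 2), caDistance(m, 2, 1))
  expect_error(caDistance(m, 1, 99), "not in model")
  set.seed(10)
  r <- makeStructure(25, "coil", seed = 4)
  xyz <- as.matrix(caAtoms(r)[, c("x", "y", "z")])
  for (k in 1:20) {
    ij <- sample(25, 2)
    expect_equal(caDistance(r, ij[1], ij[2]),
                 sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2)),
                 tolerance = 1e-12)
    expect_gte(caDistance(r, ij[1], ij[2]), 0)
  }
})

test_that("PDB reading preserves author numbering and multiple chains", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  10      0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  LYS A  11      3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  CB  LYS A  11      4.500   1.000   0.000  1.00  0.00",
    "TER",
    "ATOM      4  CA  GLY B   5      0.000   5.000   0.000  1.00  0.00",
    "END"), f)
  m <- readStructurePDB(f, id = "hand")
  expect_equal(nrow(caAtoms(m)), 3)
  expect_setequal(chains(m), c("A", "B"))
  expect_equal(caDistance(m, 10, 11), 3.8, tolerance = 1e-9)
  expect_equal(caAtoms(m)$resno[caAtoms(m)$chain == "B"], 5)
  # empty file rejected
  f2 <- tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(readStructurePDB(f2))
  # a written synthetic model reads back identically (3 decimals)
  oligo <- makeOligomer(makeStructure(20, "helix"), 2, radius = 18)
  f3 <- tempfile(fileext = ".pdb")
  writeStructurePDB(oligo, f3)
  back <- readStructurePDB(f3)
  expect_equal(as.matrix(caAtoms(back)[, c("x", "y", "z")]),
               as.matrix(caAtoms(oligo)[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("constraint classes follow the 30/40 Angstrom policy", {
  pol <- constraintPolicy()
  expect_equal(xlmod:::classifyDistance(22.4, pol), "satisfied")
  expect_equal(xlmod:::classifyDistance(30.0, pol), "satisfied")  # inclusive
  expect_equal(xlmod:::classifyDistance(36.2, pol), "ambiguous")
  expect_equal(xlmod:::classifyDistance(40.0, pol), "ambiguous")
  expect_equal(xlmod:::classifyDistance(66.6, pol), "violated")
  expect_error(constraintPolicy(40, 30), "satisfied < violation")
  # loosening the satisfied threshold never decreases satisfied counts
  D <- monomerCandidateDistances()
  dist5 <- D$model_5
  for (s in c(20, 25, 30, 35)) {
    n1 <- sum(xlmod:::classifyDistance(dist5, constraintPolicy(s, 45)) ==
                "satisfied")
    n2 <- sum(xlmod:::classifyDistance(dist5, constraintPolicy(s + 5, 45))
              == "satisfied")
    expect_lte(n1, n2)
  }
})

test_that("same-residue constraints are inter-subunit only", {
  mono <- makeStructure(30, "helix")
  res <- evaluateConstraint(mono, 10, 10)
  expect_equal(res$class, "unevaluable")
  expect_match(res$realization, "inter-only")
  dimer <- makeOligomer(mono, 2, radius = 20)
  res2 <- evaluateConstraint(dimer, 10, 10)
  expect_true(is.finite(res2$distance))
  expect_equal(res2$realization, "inter-chain")
  # min-over-chains: dimer distance never exceeds the single-chain value
  for (pp in list(c(5, 25), c(3, 17), c(10, 28))) {
    expect_lte(evaluateConstraint(dimer, pp[1], pp[2])$distance,
               caDistance(mono, pp[1], pp[2]) + 1e-9)
  }
})

test_that("ranking prefers zero violations, then satisfied count", {
  # constructed distance matrix: columns are models
  D <- cbind(m1 = c(10, 50, 45), m2 = c(10, 20, 35), m3 = c(10, 20, 25))
  rk <- rankModels(D)
  expect_equal(rk$ranking$model, c("m3", "m2", "m1"))
  expect_equal(rk$selected, "m3")
  # single model, all satisfied
  rk1 <- rankModels(cbind(only = c(10, 12)))
  expect_equal(rk1$selected, "only")
  # no constraints: warning, all tied
  m <- makeStructure(10, "helix")
  expect_warning(rankModels(list(m), xlConstraints(integer(), integer())),
                 "no constraints")
})

test_that("rigid motions leave distances and rankings unchanged", {
  set.seed(20)
  m <- makeStructure(40, "coil", seed = 8)
  dec <- makeDecoys(m, rmsd = c(12, 16, 20), seed = 30)
  xls <- sampleCrosslinks(m, dmax = 25, count = 8, seed = 40)
  rk0 <- rankModels(dec, xls)
  # random rotation + translation applied to every model
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]),
                 cos(th[1])), 3, 3)
  Rz <- matrix(c(cos(th[2]), sin(th[2]), 0, -sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, 3)
  tr <- runif(3, -30, 30)
  move <- function(mod) {
    a <- caAtoms(mod)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% (Rx %*% Rz)
    a$x <- xyz[, 1] + tr[1]; a$y <- xyz[, 2] + tr[2]
    a$z <- xyz[, 3] + tr[3]
    structureModel(a, id = modelId(mod))
  }
  rk1 <- rankModels(lapply(dec, move), xls)
  expect_equal(rk1$ranking$model, rk0$ranking$model)
  expect_equal(rk1$ranking$meanDistance, rk0$ranking$meanDistance,
               tolerance = 1e-6)
})

test_that("the true model is recovered from decoy ensembles", {
  ok <- 0L
  for (s in 1:100) {
    m <- makeStructure(60, "coil", seed = s)
    dec <- makeDecoys(m, rmsd = c(15, 18, 22, 25), seed = s + 1000)
    xls <- sampleCrosslinks(m, dmax = 25, count = 8, seed = s + 2000)
    rk <- rankModels(dec, xls)
    ok <- ok + (rk$selected == modelId(m))
  }
  expect_gte(ok, 95)
})

test_that("topology classes separate domains and subunit evidence", {
  dm <- dnajb6Domains()
  t1 <- classifyTopology(189, 189, dm)
  expect_equal(t1$subunitClass, "inter-only")
  t2 <- classifyTopology(20, 25, dm)
  expect_equal(t2$domainClass, "intra-domain")
  expect_equal(t2$domainA, "NTD")
  expect_equal(t2$subunitClass, "intra-possible")
  t3 <- classifyTopology(225, 60, dm)
  expect_equal(t3$domainClass, "inter-domain")
  expect_setequal(c(t3$domainA, t3$domainB), c("CTD", "NTD"))
  t4 <- classifyTopology(250, 20, dm)
  expect_equal(t4$domainClass, "linker/unassigned")
  # same-to-same oligomer crosslinks are flagged inter-only
  oc <- oligomerCrosslinks()
  tt <- classifyTopology(oc$posA, oc$posB, dm)
  expect_equal(tt$subunitClass == "inter-only", oc$sameResidue)
})

test_that("restraint export writes TSV and assign statements that round-trip", {
  cons <- xlConstraints(c(189, 232), c(189, 232))
  base <- tempfile()
  out <- exportRestraints(cons, file = base)
  expect_length(out$air, 2)
  expect_match(out$air[1], "resid 189 .*name CA.* 30.0 30.0 0.0")
  expect_equal(out$tsv$upperBound, c(30, 30))
  tsv <- read.delim(paste0(base, ".tsv"))
  expect_equal(tsv$posA, cons$posA)
  expect_equal(tsv$posB, cons$posB)
  expect_error(exportRestraints(cons[0, ]), "no constraints")
  # constraint TSV io round-trip
  f <- tempfile(fileext = ".tsv")
  writeConstraints(cons, f)
  back <- readConstraints(f)
  expect_equal(back$posA, cons$posA)
  expect_equal(back$sameResidue, cons$sameResidue)
})
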