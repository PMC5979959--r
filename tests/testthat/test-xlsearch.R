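# Digestion, candidate enumeration, spectrum matching and scoring, and
# mixed-isotope hybrid detection.

test_that("digestion applies cleavage rules including the proline block", {
  out <- digestProtein("AKPGRSF", searchSettings(missedCleavages = 0))
  expect_setequal(out$sequence, c("AKPGR", "SF"))
  # zero-missed peptides concatenate back to the protein
  set.seed(11)
  for (i in 1:10) {
    s <- randomPeptide(30)
    d0 <- digestProtein(s, searchSettings(missedCleavages = 0))
    d0 <- d0[order(d0$start), ]
    expect_equal(paste(d0$sequence, collapse = ""), s)
  }
  # empty enzyme set returns the whole protein
  whole <- digestProtein("AKPGRSF", searchSettings(enzymes = character()))
  expect_equal(whole$sequence, "AKPGRSF")
})

test_that("digestion equals brute-force substring enumeration", {
  st <- searchSettings()
  res <- c("K", "R", "F", "W", "Y", "L", "M")
  set.seed(22)
  for (i in 1:50) {
    s <- randomPeptide(sample(15:30, 1))
    got <- digestProtein(s, st)
    expect_setequal(paste0(got$start, "-", got$end),
                    oracleDigest(s, res, st$missedCleavages))
  }
})

test_that("chymotryptic C-termini appear in the digest", {
  # a peptide ending in L followed by T is a legal chymotryptic product
  s <- paste0("MKR", "VEVEEDGQLKSL", "TKAAR")
  d <- digestProtein(s, searchSettings())
  expect_true("VEVEEDGQLKSL" %in% d$sequence)
})

test_that("candidate enumeration covers pairs, deadends and looplinks", {
  st <- searchSettings()
  # two internal peptides with one reactive K each -> exactly one
  # heteromeric pair candidate (self-pairs of each peptide remain legal)
  pep <- data.frame(sequence = c("AKAR", "GKGF"), start = c(10L, 30L),
                    end = c(13L, 33L), protein = c("p1", "p2"))
  cand <- enumerateCandidates(pep, crosslinker("BS3"), st)
  expect_equal(sum(cand$type == "crosslink" & cand$seqA != cand$seqB), 1)
  expect_true("deadend" %in% cand$type)
  # a peptide with no K and not protein N-terminal gets no candidates
  pepNoK <- data.frame(sequence = "GAGA", start = 10L, end = 13L,
                       protein = "p3")
  candNoK <- enumerateCandidates(pepNoK, crosslinker("BS3"), st)
  expect_equal(nrow(candNoK), 0)
  # same peptide x same peptide is a legal homodimeric candidate
  pepSame <- data.frame(sequence = "AKAR", start = 1L, end = 4L,
                        protein = "p1")
  candSame <- enumerateCandidates(pepSame, crosslinker("BS3"), st)
  self <- candSame[candSame$type == "crosslink" &
                     candSame$siteA == candSame$siteB, ]
  expect_gte(nrow(self), 1)
  expect_equal(self$mass[1],
               2 * oraclePeptideMass("AKAR") + crosslinker("BS3")@bridge,
               tolerance = 1e-4)
})

test_that("top-N peak filtering keeps order and is idempotent", {
  set.seed(33)
  sp <- spectrumRecord("s1", 800, 3, mz = sort(runif(200, 100, 1500)),
                       intensity = runif(200, 1, 1e5))
  f1 <- filterTopPeaks(sp, 125)
  expect_length(f1@mz, 125)
  expect_false(is.unsorted(f1@mz))
  f2 <- filterTopPeaks(f1, 125)
  expect_identical(f1@mz, f2@mz)
  small <- filterTopPeaks(sp, 500)
  expect_length(small@mz, 200)
})

test_that("precursor matching respects tolerance, charge and labels", {
  st <- searchSettings()
  cand <- toyCandidates(st)
  i <- which(cand$type == "crosslink")[5]
  m <- cand$mass[i]
  hit <- precursorMatch(spectrumRecord("hit", massToMz(m, 3), 3), cand, st)
  expect_true(cand$id[i] %in% hit$id)
  expect_lt(min(abs(hit$ppm[hit$id == cand$id[i]])), 1e-6)
  # +50 ppm offset: no match to this candidate
  off <- precursorMatch(
    spectrumRecord("off", massToMz(m * (1 + 50e-6), 3), 3), cand, st)
  expect_false(cand$id[i] %in% off$id)
  expect_true(all(abs(off$ppm) <= st$ms1Ppm))
  # 2+ precursors are skipped
  z2 <- precursorMatch(spectrumRecord("z2", massToMz(m, 2), 2), cand, st)
  expect_equal(nrow(z2), 0)
  # missing charge: skipped with a warning
  expect_warning(
    precursorMatch(spectrumRecord("nc", massToMz(m, 3)), cand, st),
    "charge")
  # 15N state matched only when labeling is on
  m15 <- m + 0.997035 * (cand$nA[i] + cand$nB[i])
  sp15 <- spectrumRecord("s15", massToMz(m15, 3), 3)
  expect_false(cand$id[i] %in% precursorMatch(sp15, cand, st)$id)
  lab <- precursorMatch(sp15, cand, st, labeling = TRUE)
  expect_true(any(lab$id == cand$id[i] & lab$isotope == "15/15"))
})

test_that("isotope states of a pair are spaced by the nitrogen shifts", {
  cand <- toyCandidates()
  xl <- cand[cand$type == "crosslink", ]
  for (i in head(seq_len(nrow(xl)), 20)) {
    st4 <- xlmod:::candidateStates(xl[i, ], labeling = TRUE)
    sh <- setNames(st4$shift, st4$isotope)
    expect_equal(sh[["14/15"]] - sh[["14/14"]], 0.997035 * xl$nB[i],
                 tolerance = 1e-9)
    expect_equal(sh[["15/14"]] - sh[["14/14"]], 0.997035 * xl$nA[i],
                 tolerance = 1e-9)
    expect_equal(sh[["15/15"]],
                 0.997035 * (xl$nA[i] + xl$nB[i]), tolerance = 1e-9)
  }
})

test_that("fragment series follow standard b/y arithmetic", {
  tab <- residueMassTable()
  # y1 of a peptide ending in K (unlinked side): K + water + proton
  fr <- xlmod:::fragmentSeries("GAVK", charges = 1L)
  y1 <- fr$mz[fr$ion == "y1"]
  expect_equal(y1, 128.09496 + 18.010565 + 1.00727646, tolerance = 1e-4)
  # complementarity: b_i + y_(n-i) = peptide mass + 2 protons (z = 1)
  s <- "SAMPLEK"
  fr <- xlmod:::fragmentSeries(s, charges = 1L)
  M <- oraclePeptideMass(s)
  n <- nchar(s)
  for (i in 1:(n - 1)) {
    b <- fr$mz[fr$ion == paste0("b", i)]
    y <- fr$mz[fr$ion == paste0("y", n - i)]
    expect_equal(b + y, M + 2 * 1.00727646, tolerance = 1e-4)
  }
})

test_that("crosslinked fragments carry the partner mass across the link", {
  bs3 <- crosslinker("BS3")
  pr <- crosslinkedPair(peptideSpec("KAYR", start = 21),
                        peptideSpec("GLK", start = 40), 21, 42, bs3)
  fr <- theoreticalFragments(pr, precursorCharge = 2)
  frA <- fr[fr$peptide == "A", ]
  # link at local position 1 of peptide A: every b ion spans it
  bIons <- frA[frA$type == "b", ]
  plain <- xlmod:::fragmentSeries("KAYR", charges = 1L)
  for (i in bIons$index) {
    expect_equal(bIons$mz[bIons$index == i],
                 plain$mz[plain$ion == paste0("b", i)] +
                   oraclePeptideMass("GLK") + bs3@bridge,
                 tolerance = 1e-4)
  }
  # y ions of A that do not span residue 1 have no linker mass
  yIons <- frA[frA$type == "y" & frA$index < nchar("KAYR"), ]
  for (i in yIons$index)
    expect_equal(yIons$mz[yIons$index == i],
                 plain$mz[plain$ion == paste0("y", i)], tolerance = 1e-6)
})

test_that("self-spectra score perfectly and partial spectra set flags", {
  st <- searchSettings()
  cand <- toyCandidates(st)
  i <- which(cand$type == "crosslink" & nchar(cand$seqA) > 4 &
               nchar(cand$seqB) > 4)[1]
  fr <- theoreticalFragments(cand[i, ], precursorCharge = 3)
  sp <- spectrumRecord("self", massToMz(cand$mass[i], 3), 3,
                       mz = fr$mz, intensity = rep(5000, nrow(fr)))
  sc <- scoreMatch(sp, fr, st)
  expect_true(sc$bothPeptides)
  expect_equal(sc$unexplainedTop, 0)
  expect_equal(sc$matchedFraction, 1)
  # peptide-A-only spectrum: bothPeptides flag false (a pair of disjoint
  # sequences, since overlapping digest peptides share fragment masses)
  prDisjoint <- crosslinkedPair(peptideSpec("KAYR", start = 21),
                                peptideSpec("GLK", start = 40), 21, 42,
                                crosslinker("BS3"))
  frD <- theoreticalFragments(prDisjoint, precursorCharge = 2)
  frDA <- frD[frD$peptide == "A", ]
  spA <- spectrumRecord("onlyA", massToMz(pairMass(prDisjoint), 3), 3,
                        mz = frDA$mz, intensity = rep(5000, nrow(frDA)))
  expect_false(scoreMatch(spA, frD, st)$bothPeptides)
  # score is monotonically non-increasing as the tolerance shrinks
  set.seed(44)
  spn <- spectrumRecord("noisy", massToMz(cand$mass[i], 3), 3,
                        mz = fr$mz + rnorm(nrow(fr), 0, 0.03),
                        intensity = runif(nrow(fr), 1000, 9000))
  tols <- c(0.2, 0.1, 0.05, 0.02, 0.01)
  scores <- vapply(tols, function(tol)
    scoreMatch(spn, fr, searchSettings(ms2Da = tol))$score, numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
})

test_that("simulated spectra are recovered as top-ranked candidates", {
  st <- searchSettings()
  cand <- toyCandidates(st)
  xl <- cand[cand$type == "crosslink", ]
  set.seed(55)
  idx <- sample(nrow(xl), 25)
  pairs <- lapply(idx, function(i) makeToyPair(xl[i, ]))
  sim <- simulateSpectra(pairs, charge = 3, noisePeaks = 50,
                         jitterPpm = 2, seed = 99)
  res <- searchSpectra(sim$spectra, cand, st, crosslinker("BS3"))
  got <- res$best$id[match(sim$truth$title, res$best$spectrum)]
  expect_gte(mean(got == xl$id[idx], na.rm = TRUE), 0.95)
  # hard postcondition: no reported match above tolerance
  expect_true(all(abs(res$matches$ppm) <= st$ms1Ppm))
})

test_that("hybrid crosslinks flag exchange in mixed but not control arms", {
  st <- searchSettings()
  cand <- toyCandidates(st)
  xl <- cand[cand$type == "crosslink", ]
  set.seed(66)
  idx <- sample(nrow(xl), 12)
  runArm <- function(exchange, seed) {
    sch <- labelingScheme(length(idx), exchange = exchange, seed = seed)
    pairs <- lapply(seq_along(idx), function(k)
      makeToyPair(xl[idx[k], ], c(sch$labelA[k], sch$labelB[k])))
    sim <- simulateSpectra(pairs, charge = 3, noisePeaks = 30,
                           jitterPpm = 1, seed = seed + 100)
    list(best = searchSpectra(sim$spectra, cand, st, crosslinker("BS3"),
                              labeling = TRUE)$best,
         truth = sim$truth)
  }
  mixed <- runArm(TRUE, 2)
  control <- runArm(FALSE, 3)
  v <- detectHybrids(mixed$best, control$best)
  expect_true(v$exchange)
  expect_gt(nrow(v$mixedHybrids), 0)
  expect_equal(nrow(v$controlHybrids), 0)
  # recovered isotope states agree with the simulation truth
  gotIso <- mixed$best$isotope[match(mixed$truth$title,
                                     mixed$best$spectrum)]
  expect_equal(gotIso, mixed$truth$isotope)
  # swapped arms: no exchange
  expect_false(detectHybrids(control$best, mixed$best)$exchange)
  # all-14N input yields zero hybrid candidates
  pairs14 <- lapply(idx[1:5], function(i) makeToyPair(xl[i, ]))
  sim14 <- simulateSpectra(pairs14, charge = 3, noisePeaks = 0, seed = 1)
  b14 <- searchSpectra(sim14$spectra, cand, st, crosslinker("BS3"),
                       labeling = TRUE)$best
  expect_false(any(b14$isotope %in% c("14/15", "15/14")))
  # unlabeled searches are rejected
  b0 <- searchSpectra(sim14$spectra, cand, st, crosslinker("BS3"))$best
  expect_error(detectHybrids(b0, b0), "labeling")
})

test_that("MGF files round-trip through the reader and writer", {
  set.seed(77)
  sp <- list(
    spectrumRecord("scan_a", 812.3456, 3, sort(runif(30, 100, 1500)),
                   runif(30, 10, 1e4)),
    spectrumRecord("scan_b", 1100.99, 4, sort(runif(10, 100, 1500)),
                   runif(10, 10, 1e4)))
  f <- tempfile(fileext = ".mgf")
  writeMGF(sp, f)
  back <- readMGF(f)
  expect_length(back, 2)
  expect_equal(back[[1]]@title, "scan_a")
  expect_equal(back[[1]]@pepmass, 812.3456, tolerance = 1e-6)
  expect_equal(back[[2]]@charge, 4L)
  expect_equal(back[[1]]@mz, sp[[1]]@mz, tolerance = 1e-6)
})

test_that("FASTA sequences read through Biostrings", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">toy some description", toyProtein()), f)
  seqs <- readFastaSequences(f)
  expect_named(seqs, "toy")
  expect_equal(unname(seqs["toy"]), toyProtein())
})
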