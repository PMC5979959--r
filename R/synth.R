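# Seeded generators for every input class used by the pipeline: toy
# structures and oligomers, decoy model ensembles, crosslink samples,
# crosslinked-peptide spectra (with isotope labelling schemes) and sphere
# scattering curves. Every generator is a pure function of its arguments:
# the same seed gives byte-identical output, and the caller's RNG state is
# left untouched.

#' Generate a toy C-alpha structure
#'
#' Topologies: an ideal alpha-helix (rise 1.5 Angstrom/residue, 100
#' degrees/residue, radius 2.3 Angstrom), a hinged two-helix hairpin
#' (helix halves joined by a short flexible turn), or a self-avoiding
#' random coil with 3.8 Angstrom steps. Every `lysEvery`-th residue is a
#' lysine (the crosslinkable sites of the toy systems); the rest are
#' alanines.
#'
#' @param nRes number of residues (>= 3)
#' @param topology "helix", "hairpin" or "coil"
#' @param seed RNG seed (used by "coil"; helix geometry is deterministic)
#' @param lysEvery spacing of lysine residues
#' @return a [StructureModel-class] (single chain "A")
#' @examples
#' makeStructure(20, "helix", seed = 1)
#' @export
makeStructure <- function(nRes, topology = c("helix", "hairpin", "coil"),
                          seed = 1L, lysEvery = 5L) {
  topology <- match.arg(topology)
  stopIfNot(nRes >= 3, "need at least 3 residues")
  helix <- function(n, phase = 0) {
    i <- seq_len(n) - 1L
    ang <- (100 * i + phase) * pi / 180
    cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
  }
  xyz <- switch(topology,
    helix = helix(nRes),
    hairpin = {
      n1 <- ceiling(nRes / 2)
      n2 <- nRes - n1
      up <- helix(n1)
      dn <- helix(n2)
      # fold the second helix back antiparallel, offset sideways
      dn <- cbind(x = 9 - dn[, "x"], y = dn[, "y"],
                  z = up[n1, "z"] - 1.5 * (seq_len(n2)))
      rbind(up, dn)
    },
    coil = withSeed(seed, {
      pos <- matrix(0, nRes, 3)
      for (i in 2:nRes) {
        repeat {
          step <- rnorm(3)
          cand <- pos[i - 1L, ] + 3.8 * step / sqrt(sum(step^2))
          dmin <- if (i > 2)
            min(sqrt(rowSums(sweep(pos[1:(i - 2L), , drop = FALSE], 2,
                                   cand)^2))) else Inf
          if (dmin > 3.0) break
        }
        pos[i, ] <- cand
      }
      colnames(pos) <- c("x", "y", "z")
      pos
    }))
  resname <- ifelse(seq_len(nRes) %% lysEvery == 0, "LYS", "ALA")
  structureModel(data.frame(chain = "A", resno = seq_len(nRes),
                            resname = resname, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE),
                 id = paste0(topology, nRes, "_s", seed))
}

#' Assemble a Cn-symmetric homo-oligomer from a monomer
#'
#' Places `copies` of the monomer by rotation about the z axis at the
#' given radius. Chains are labelled A, B, C, ... Raises an error (and
#' reports the minimum feasible radius) when any inter-chain C-alpha pair
#' comes closer than 2 Angstrom.
#'
#' @param monomer a [StructureModel-class] (single chain)
#' @param copies number of subunits (>= 2)
#' @param radius placement radius (Angstrom)
#' @return a multi-chain [StructureModel-class]
#' @export
makeOligomer <- function(monomer, copies = 2L, radius = 15) {
  stopIfNot(copies >= 2, "an oligomer needs at least 2 copies")
  a0 <- monomer@atoms
  ctr <- colMeans(as.matrix(a0[, c("x", "y", "z")]))
  base <- sweep(as.matrix(a0[, c("x", "y", "z")]), 2, ctr)
  build <- function(rad) {
    parts <- lapply(seq_len(copies) - 1L, function(k) {
      th <- 2 * pi * k / copies
      Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                   3, 3)
      xyz <- base %*% t(Rz)
      xyz[, 1] <- xyz[, 1] + rad * cos(th)
      xyz[, 2] <- xyz[, 2] + rad * sin(th)
      data.frame(chain = LETTERS[k + 1L], resno = a0$resno,
                 resname = a0$resname, x = xyz[, 1], y = xyz[, 2],
                 z = xyz[, 3], stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  minInter <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    d <- as.matrix(dist(xyz))
    same <- outer(at$chain, at$chain, `==`)
    min(d[!same])
  }
  at <- build(radius)
  if (minInter(at) < 2) {
    rad <- radius
    while (minInter(build(rad)) < 2) rad <- rad + 1
    stop(sprintf(
      "chains clash at radius %.1f A; minimum feasible radius ~ %.1f A",
      radius, rad), call. = FALSE)
  }
  structureModel(at, id = paste0(monomer@id, "_C", copies))
}

#' Sample crosslink constraints from true structure distances
#'
#' Uniformly samples pairs of reactive positions (default: lysines) whose
#' true minimum-over-chains C-alpha distance does not exceed `dmax`,
#' emulating the detectable crosslinks of a structure. The truth table
#' records the true distance of every sampled pair.
#'
#' @param model a [StructureModel-class]
#' @param reactive residue numbers of reactive positions (default: all
#'   lysines)
#' @param dmax maximum true distance of a sampled pair (Angstrom)
#' @param count number of pairs to draw; when fewer are eligible, all
#'   eligible pairs are returned with a warning
#' @param seed RNG seed
#' @return constraint data.frame (see [xlConstraints()]) with an extra
#'   `trueDistance` column
#' @export
sampleCrosslinks <- function(model, reactive = NULL, dmax = 25,
                             count = 8L, seed = 1L) {
  if (is.null(reactive))
    reactive <- sort(unique(model@atoms$resno[
      model@atoms$resname == "LYS"]))
  stopIfNot(length(reactive) >= 2, "need at least 2 reactive positions")
  prs <- combn(reactive, 2L)
  d <- vapply(seq_len(ncol(prs)), function(k)
    evaluateConstraint(model, prs[1, k], prs[2, k])$distance, numeric(1))
  ok <- which(!is.na(d) & d <= dmax)
  if (count == 0L)
    return(cbind(xlConstraints(integer(), integer()),
                 trueDistance = numeric()))
  if (length(ok) < count) {
    warning("only ", length(ok), " eligible pairs (requested ", count, ")")
    sel <- ok
  } else {
    sel <- withSeed(seed, sort(sample(ok, count)))
  }
  out <- xlConstraints(prs[1, sel], prs[2, sel])
  out$trueDistance <- d[sel]
  out
}

#' Generate decoy models around a true structure
#'
#' Perturbs the C-alpha coordinates with isotropic Gaussian noise rescaled
#' to hit each requested RMSD exactly, emulating an ensemble of candidate
#' models of varying quality. The unperturbed model is included first as
#' the ground truth.
#'
#' @param model the true [StructureModel-class]
#' @param rmsd numeric vector of target RMSD values (Angstrom, > 0)
#' @param seed RNG seed
#' @return named list of [StructureModel-class]: `true`, then one decoy
#'   per target
#' @export
makeDecoys <- function(model, rmsd = c(5, 10, 15, 20), seed = 1L) {
  stopIfNot(all(rmsd > 0), "RMSD targets must be positive")
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  out <- list(true = model)
  withSeed(seed, {
    for (k in seq_along(rmsd)) {
      d <- matrix(rnorm(length(xyz)), nrow(xyz), 3)
      achieved <- sqrt(mean(rowSums(d^2)))
      d <- d * rmsd[k] / achieved
      a <- model@atoms
      a[, c("x", "y", "z")] <- xyz + d
      out[[sprintf("decoy_%g", rmsd[k])]] <-
        structureModel(a, id = sprintf("%s_decoy%g", model@id, rmsd[k]))
    }
  })
  out
}

#' Root-mean-square C-alpha deviation between two models
#'
#' Computed without superposition (the generators build decoys in the same
#' frame).
#'
#' @param a,b two [StructureModel-class] objects over the same residues
#' @return RMSD in Angstrom
#' @export
caRMSD <- function(a, b) {
  xa <- as.matrix(a@atoms[, c("x", "y", "z")])
  xb <- as.matrix(b@atoms[, c("x", "y", "z")])
  stopIfNot(all(dim(xa) == dim(xb)), "models must match")
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Assign isotope labels for a subunit-exchange experiment
#'
#' In the exchange arm the 14N and 15N pools are mixed *before*
#' crosslinking, so the two peptides of any crosslinked pair draw their
#' labels independently (hybrids arise). In the control arm each pool is
#' crosslinked separately and mixed afterwards, so both peptides of a pair
#' always share a label (no hybrids).
#'
#' @param nPairs number of crosslinked pairs
#' @param exchange TRUE for the mixed-before-crosslinking arm
#' @param frac15 fraction of 15N-labelled material (1:1 mixing = 0.5)
#' @param seed RNG seed
#' @return data.frame with columns `labelA` and `labelB`
#' @export
labelingScheme <- function(nPairs, exchange = TRUE, frac15 = 0.5,
                           seed = 1L) {
  withSeed(seed, {
    if (exchange) {
      data.frame(labelA = ifelse(runif(nPairs) < frac15, "15N", "14N"),
                 labelB = ifelse(runif(nPairs) < frac15, "15N", "14N"),
                 stringsAsFactors = FALSE)
    } else {
      pool <- ifelse(runif(nPairs) < frac15, "15N", "14N")
      data.frame(labelA = pool, labelB = pool, stringsAsFactors = FALSE)
    }
  })
}

#' Simulate fragment spectra of crosslinked peptide pairs
#'
#' One spectrum per pair: the precursor at the pair's true m/z (optionally
#' jittered by a ppm-scale error), b/y fragment peaks of both peptides
#' (fragments spanning the link carry partner + bridge), and uniform-m/z
#' noise peaks with exponentially distributed intensities. Isotope labels
#' on the input pairs shift precursor and fragments per peptide. The truth
#' table links each scan title to its source pair.
#'
#' @param pairs list of [CrosslinkedPair-class] objects
#' @param charge precursor charge used for all spectra
#' @param noisePeaks number of noise peaks per spectrum
#' @param jitterPpm 1-sigma precursor and fragment mass error (ppm)
#' @param seed RNG seed
#' @return list with `spectra` (list of [SpectrumRecord-class]) and
#'   `truth` (data.frame: title, pairIndex, isotope, mass)
#' @export
simulateSpectra <- function(pairs, charge = 3L, noisePeaks = 50L,
                            jitterPpm = 0, seed = 1L) {
  stopIfNot(length(pairs) >= 1, "no pairs to simulate")
  withSeed(seed, {
    spectra <- vector("list", length(pairs))
    truth <- vector("list", length(pairs))
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      m <- pairMass(p)
      frag <- theoreticalFragments(p, precursorCharge = charge,
                                   linker = p@linker)
      fmz <- frag$mz * (1 + rnorm(nrow(frag)) * jitterPpm * 1e-6)
      fint <- runif(nrow(frag), 2000, 10000)
      if (noisePeaks > 0) {
        nmz <- runif(noisePeaks, 100, massToMz(m, charge))
        nint <- rexp(noisePeaks, rate = 1 / 500)
        fmz <- c(fmz, nmz)
        fint <- c(fint, nint)
      }
      title <- sprintf("synthscan_%03d", i)
      pmz <- massToMz(m, charge) * (1 + rnorm(1) * jitterPpm * 1e-6)
      spectra[[i]] <- spectrumRecord(title, pmz, charge, fmz, fint)
      iso <- paste(sub("N", "", p@peptideA@label),
                   sub("N", "", p@peptideB@label), sep = "/")
      truth[[i]] <- data.frame(title = title, pairIndex = i,
                               isotope = iso, mass = m,
                               stringsAsFactors = FALSE)
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
}

#' Scattering curve of a homogeneous sphere
#'
#' I(q) = I0 [3 (sin qR - qR cos qR)/(qR)^3]^2 with optional multiplicative
#' Gaussian noise; the sigma column records the noise level per point.
#'
#' @param R sphere radius (in 1/q units)
#' @param I0 forward scattering
#' @param q momentum-transfer grid
#' @param noise relative (multiplicative) Gaussian noise level, e.g. 0.02
#' @param seed RNG seed
#' @param qUnit unit tag for the curve
#' @return a [SAXSCurve-class]
#' @export
sphereSaxs <- function(R, I0 = 1, q = seq(0.004, 0.35, length.out = 500),
                       noise = 0, seed = 1L, qUnit = "A^-1") {
  stopIfNot(R > 0 && I0 > 0, "R and I0 must be positive")
  u <- q * R
  I <- I0 * (3 * (sin(u) - u * cos(u)) / u^3)^2
  sigma <- noise * I
  if (noise > 0)
    I <- withSeed(seed, I * (1 + noise * rnorm(length(q))))
  saxsCurve(q, I, sigma = sigma, qUnit = qUnit)
}
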