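# C-alpha anisotropic elastic-network normal mode analysis: Hessian
# assembly, eigendecomposition, per-residue fluctuation profiles, flexible
# region detection, mode-displaced conformers and contact-deviation maps.
# Modes 1-6 of a connected network are rigid-body; "mode 7" is the first
# internal deformation (the conventional numbering).

#' Build the anisotropic-network Hessian
#'
#' One node per C-alpha; every node pair within the interaction cutoff is
#' connected by a uniform spring. The 3x3 off-diagonal super-element for a
#' connected pair is -gamma / d^2 * (dr dr^T) (the second derivative of a
#' harmonic spring at its equilibrium length), and diagonal blocks are the
#' negative sum of the off-diagonal blocks, so the matrix is symmetric
#' positive semi-definite with (for a connected network) exactly six zero
#' eigenvalues.
#'
#' @param model a [StructureModel-class] (all chains are used)
#' @param cutoff interaction distance cutoff (Angstrom)
#' @param gamma uniform spring constant (arbitrary units)
#' @return 3N x 3N symmetric matrix with attributes `resno` and `n`
#' @export
buildHessian <- function(model, cutoff = 10, gamma = 1) {
  stopIfNot(cutoff > 0, "cutoff must be positive")
  xyz <- as.matrix(model@atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  stopIfNot(n >= 2, "need at least 2 C-alpha positions")
  H <- matrix(0, 3 * n, 3 * n)
  d2 <- as.matrix(dist(xyz))^2
  nEdges <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d2[i, j] > cutoff^2 || d2[i, j] == 0) next
    dr <- xyz[j, ] - xyz[i, ]
    blk <- -gamma * tcrossprod(dr) / d2[i, j]
    ii <- (3 * i - 2):(3 * i)
    jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
    nEdges <- nEdges + 1L
  }
  if (nEdges < n - 1L)
    warning("network cannot be connected (", nEdges, " springs for ", n,
            " nodes): expect more than 6 near-zero modes")
  attr(H, "resno") <- model@atoms$resno
  attr(H, "n") <- n
  H
}

#' Solve for the lowest normal modes
#'
#' Full symmetric eigendecomposition of the Hessian; eigenvalues are
#' returned ascending so that modes 1-6 are the rigid-body motions of a
#' connected network (numerically zero) and mode 7 is the first internal
#' mode. A warning is issued when more than six eigenvalues are
#' numerically zero (disconnected network).
#'
#' @param hessian matrix from [buildHessian()]
#' @param k number of lowest modes to keep (default: all)
#' @return a [ModeSet-class]
#' @export
solveModes <- function(hessian, k = NULL) {
  n <- attr(hessian, "n")
  resno <- attr(hessian, "resno")
  if (is.null(n)) n <- nrow(hessian) / 3L
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(k)) k <- nrow(hessian)
  stopIfNot(k <= nrow(hessian), "k exceeds the number of modes (3N)")
  e <- eigen(hessian, symmetric = TRUE)
  ord <- rev(seq_along(e$values))
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  values[abs(values) < .Machine$double.eps^0.5 * max(abs(values))] <-
    pmax(values[abs(values) < .Machine$double.eps^0.5 * max(abs(values))], 0)
  if (length(values) >= 7 && values[7] > 0 &&
      sum(values < 1e-8 * values[7]) > 6L)
    warning("more than six near-zero modes: disconnected network?")
  new("ModeSet", values = values[seq_len(k)],
      vectors = vectors[, seq_len(k), drop = FALSE], n = as.integer(n),
      resno = as.integer(resno))
}

#' Per-residue fluctuation profile of internal modes
#'
#' For a single mode, the magnitude of each residue's 3-component
#' eigenvector slice. For a range of modes, the thermal-amplitude weighted
#' mean of the per-mode magnitudes with weights proportional to 1/lambda
#' (softer modes contribute more). Rigid-body modes (1-6) are rejected.
#'
#' @param modes a [ModeSet-class]
#' @param which mode index or range, e.g. `9` or `7:11`
#' @return data.frame with columns `resno` and `fluct` (all >= 0)
#' @export
modeFluctuations <- function(modes, which = 7:11) {
  stopIfNot(all(which >= 7), "modes 1-6 are rigid-body: request modes >= 7")
  stopIfNot(max(which) <= length(modes@values),
            "requested mode not computed")
  mags <- sapply(which, function(m) {
    v <- matrix(modes@vectors[, m], ncol = 3, byrow = TRUE)
    sqrt(rowSums(v^2))
  })
  mags <- as.matrix(mags)
  if (length(which) == 1L) {
    fl <- mags[, 1]
  } else {
    w <- 1 / modes@values[which]
    w <- w / sum(w)
    fl <- as.numeric(mags %*% w)
  }
  data.frame(resno = modes@resno, fluct = fl)
}

#' Locate the most flexible region of a fluctuation profile
#'
#' Maximizes a w-residue sliding-window mean of the profile; ties go to the
#' window starting at the lower residue number. Reports the window interval
#' and the peak residue(s) within it.
#'
#' @param profile data.frame from [modeFluctuations()]
#' @param w window width (residues)
#' @return list with `start`, `end` (residue numbers of the best window),
#'   `peak` (residue(s) of maximal fluctuation inside the window) and
#'   `windowMean`
#' @export
flexibleRegion <- function(profile, w = 11L) {
  n <- nrow(profile)
  stopIfNot(w >= 1 && w <= n, "window must satisfy 1 <= w <= N")
  means <- vapply(seq_len(n - w + 1L), function(i)
    mean(profile$fluct[i:(i + w - 1L)]), numeric(1))
  i <- which.max(means)  # which.max takes the first maximum: lower resno
  win <- i:(i + w - 1L)
  peakIdx <- win[profile$fluct[win] == max(profile$fluct[win])]
  list(start = profile$resno[i], end = profile$resno[i + w - 1L],
       peak = profile$resno[peakIdx], windowMean = means[i])
}

#' Displace a model along a normal mode
#'
#' Generates the +/- amplitude conformer pair used for mode animation and
#' contact-deviation analysis: C-alpha coordinates +/- amplitude times the
#' mode eigenvector.
#'
#' @param model the [StructureModel-class] the modes were computed from
#' @param modes a [ModeSet-class]
#' @param mode internal mode index (>= 7)
#' @param amplitude displacement amplitude (Angstrom scale; > 0)
#' @return list with elements `plus` and `minus` ([StructureModel-class])
#' @export
displacedConformers <- function(model, modes, mode = 7L, amplitude = 1) {
  stopIfNot(amplitude > 0, "amplitude must be positive")
  stopIfNot(mode >= 7, "modes 1-6 are rigid-body: request an internal mode")
  v <- matrix(modes@vectors[, mode], ncol = 3, byrow = TRUE)
  mk <- function(sgn, tag) {
    a <- model@atoms
    a$x <- a$x + sgn * amplitude * v[, 1]
    a$y <- a$y + sgn * amplitude * v[, 2]
    a$z <- a$z + sgn * amplitude * v[, 3]
    structureModel(a, id = paste0(model@id, "_mode", mode, tag))
  }
  list(plus = mk(1, "+"), minus = mk(-1, "-"))
}

#' Write a multi-model PDB trajectory
#'
#' Interpolates between the two displaced conformers (through the original
#' structure) and writes a MODEL/ENDMDL trajectory suitable for animation.
#'
#' @param conformers list with `plus` and `minus` from
#'   [displacedConformers()]
#' @param file output path
#' @param nFrames number of frames (>= 2)
#' @export
writeTrajectoryPDB <- function(conformers, file, nFrames = 11L) {
  stopIfNot(nFrames >= 2, "need at least 2 frames")
  ap <- conformers$plus@atoms
  am <- conformers$minus@atoms
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames)) {
    t <- (f - 1) / (nFrames - 1)
    a <- ap
    for (cc in c("x", "y", "z")) a[[cc]] <- (1 - t) * am[[cc]] + t * ap[[cc]]
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(a)), substr(a$resname, 1, 3), a$chain, a$resno, a$x,
      a$y, a$z), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Residue-by-residue contact deviation between two conformers
#'
#' |d+(i,j) - d-(i,j)| over all residue pairs: regions whose pairwise
#' distances change most along a mode stand out as high-deviation rows.
#'
#' @param confPlus,confMinus two [StructureModel-class] objects over the
#'   same residue set (e.g. from [displacedConformers()])
#' @return symmetric matrix with zero diagonal, dimnames = residue numbers
#' @export
contactDeviation <- function(confPlus, confMinus) {
  ap <- confPlus@atoms
  am <- confMinus@atoms
  stopIfNot(nrow(ap) == nrow(am) &&
              all(ap$resno == am$resno & ap$chain == am$chain),
            "conformers must share an identical residue set")
  dp <- as.matrix(dist(as.matrix(ap[, c("x", "y", "z")])))
  dm <- as.matrix(dist(as.matrix(am[, c("x", "y", "z")])))
  dev <- abs(dp - dm)
  dimnames(dev) <- list(ap$resno, ap$resno)
  dev
}

#' Write a dense matrix as whitespace-separated text
#'
#' @param m matrix (e.g. from [contactDeviation()])
#' @param file output path
#' @export
writeMatrixText <- function(m, file) {
  write.table(format(m, digits = 6), file, sep = " ", quote = FALSE,
              col.names = NA)
  invisible(file)
}
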