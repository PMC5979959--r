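# Independent oracles used to validate the package implementations.
# Each is deliberately written from first principles (elemental
# compositions, brute-force enumeration, independent matrix assembly) and
# never calls the code path it checks.

# --- elemental-composition peptide mass ----------------------------------

elementMasses <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                   O = 15.9949146196, S = 31.97207100)

# residue formulas as (C, H, N, O, S) counts
residueFormulas <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

oraclePeptideMass <- function(sequence) {
  counts <- Reduce(`+`, residueFormulas[strsplit(sequence, "")[[1]]])
  counts <- counts + c(0, 2, 0, 1, 0)  # + H2O
  sum(counts * elementMasses[c("C", "H", "N", "O", "S")])
}

oracleNitrogens <- function(sequence) {
  sum(vapply(strsplit(sequence, "")[[1]],
             function(r) residueFormulas[[r]][3], numeric(1)))
}

randomPeptide <- function(len) {
  paste(sample(names(residueFormulas), len, replace = TRUE), collapse = "")
}

# --- brute-force digestion ----------------------------------------------

oracleDigest <- function(sequence, residues, maxMissed) {
  l <- strsplit(sequence, "")[[1]]
  n <- length(l)
  isSite <- function(i) i >= 1 && i < n && l[i] %in% residues &&
    l[i + 1] != "P"
  out <- character()
  for (i in 1:n) for (j in i:n) {
    if (!((i == 1 || isSite(i - 1)) && (j == n || isSite(j)))) next
    internal <- if (j > i) sum(vapply(i:(j - 1), isSite, logical(1)))
                else 0L
    if (internal <= maxMissed)
      out <- c(out, paste0(i, "-", j))
  }
  sort(unique(out))
}

# --- independent ANM Hessian assembly -----------------------------------

oracleHessian <- function(xyz, cutoff, gamma = 1) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(dr^2))
    if (d > cutoff || d == 0) next
    e <- dr / d
    blk <- gamma * outer(e, e)
    H[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- -blk
    H[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
      H[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] + blk
  }
  H
}

# --- shared fixtures ----------------------------------------------------

toyProtein <- function()
  "MKAVLDTKGSPEIRKLYDAMKGSFEKVNTLLKRAPDGSMKYVLEKQ"

toyCandidates <- function(settings = searchSettings()) {
  prot <- toyProtein()
  pep <- digestProtein(prot, settings, protein = "toy")
  enumerateCandidates(pep, crosslinker("BS3"), settings,
                      proteinLengths = c(toy = nchar(prot)))
}

makeToyPair <- function(row, labels = c("14N", "14N"),
                        linker = crosslinker("BS3")) {
  crosslinkedPair(
    peptideSpec(row$seqA, protein = row$protA, start = row$startA,
                label = labels[1]),
    peptideSpec(row$seqB, protein = row$protB, start = row$startB,
                label = labels[2]),
    row$siteA, row$siteB, linker)
}
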