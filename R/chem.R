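# Monoisotopic mass arithmetic for peptides, crosslinkers, isotope labels
# and charge states. All internal masses are neutral monoisotopic; m/z is
# used only at I/O boundaries.

# mass difference 15N - 14N per nitrogen atom (Da)
N15_SHIFT <- 0.997035
PROTON_MASS <- 1.00727646
WATER_MASS <- 18.010565

#' Monoisotopic residue mass table
#'
#' Standard monoisotopic residue masses (Da) of the 20 amino acids together
#' with the water and proton masses and the per-residue nitrogen atom count
#' (backbone nitrogen included). The nitrogen counts drive the 15N metabolic
#' label mass shift of 0.997035 Da per nitrogen.
#'
#' @return a list with components `mass` (named numeric, residue masses),
#'   `water`, `proton`, and `nitrogens` (named integer)
#' @examples
#' tab <- residueMassTable()
#' tab$mass[["G"]]       # glycine residue
#' tab$nitrogens[["K"]]  # lysine has 2 nitrogens
#' @export
residueMassTable <- function() {
  mass <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
            V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
            I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
            K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
            F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  nitrogens <- c(G = 1L, A = 1L, S = 1L, P = 1L, V = 1L, T = 1L, C = 1L,
                 L = 1L, I = 1L, N = 2L, D = 1L, Q = 2L, K = 2L, E = 1L,
                 M = 1L, H = 3L, F = 1L, R = 4L, Y = 1L, W = 2L)
  list(mass = mass, water = WATER_MASS, proton = PROTON_MASS,
       nitrogens = nitrogens)
}

#' Built-in crosslinker definitions
#'
#' Returns the mass chemistry of the supported amine-reactive NHS-ester
#' crosslinkers. The bridge masses follow from the reagent chemistry:
#' BS3/DSS adds a suberate bridge (C8H10O2, 138.06808 Da), BS2G a glutarate
#' bridge (C5H4O2, 96.02113 Da); a hydrolyzed deadend retains one
#' water-equivalent on top of the bridge. Tris-quenched deadends are
#' supported via [loadCrosslinkers()] but disabled by default. Both reagents
#' can bridge C-alpha pairs up to a nominal 30 Angstrom.
#'
#' @param name "BS3" or "BS2G"
#' @return a [CrosslinkerDef-class]
#' @examples
#' crosslinker("BS3")
#' @export
crosslinker <- function(name = c("BS3", "BS2G")) {
  name <- match.arg(name)
  if (name == "BS3")
    new("CrosslinkerDef", name = "BS3", bridge = 138.06808,
        deadendHydrolyzed = 156.07864, deadendTris = NA_real_, span = 30)
  else
    new("CrosslinkerDef", name = "BS2G", bridge = 96.02113,
        deadendHydrolyzed = 114.03169, deadendTris = NA_real_, span = 30)
}

#' Load crosslinker definitions from a plain-text config
#'
#' Reads a tab-separated table with columns `name`, `bridge`,
#' `deadend_hydrolyzed`, `deadend_tris` (may be NA) and `span`, allowing the
#' built-in reagent chemistry to be overridden or extended.
#'
#' @param file path to the TSV config
#' @return a named list of [CrosslinkerDef-class] objects
#' @export
loadCrosslinkers <- function(file) {
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "bridge", "deadend_hydrolyzed", "deadend_tris", "span")
  stopIfNot(all(need %in% names(tab)),
            paste("crosslinker config needs columns:",
                  paste(need, collapse = ", ")))
  out <- lapply(seq_len(nrow(tab)), function(i)
    new("CrosslinkerDef", name = tab$name[i], bridge = tab$bridge[i],
        deadendHydrolyzed = tab$deadend_hydrolyzed[i],
        deadendTris = as.numeric(tab$deadend_tris[i]), span = tab$span[i]))
  setNames(out, tab$name)
}

#' Construct a PeptideSpec
#'
#' @param sequence one-letter residue string
#' @param protein source protein id
#' @param start 1-based start position in the protein (the end position is
#'   implied by the sequence length)
#' @param mods data.frame with columns `kind` and `site`, or NULL
#' @param label "14N" or "15N"
#' @return a [PeptideSpec-class]
#' @examples
#' peptideSpec("KLALK", protein = "toy", start = 25)
#' @export
peptideSpec <- function(sequence, protein = "protein", start = 1L,
                        mods = NULL, label = "14N") {
  checkResidues(sequence)
  if (is.null(mods))
    mods <- data.frame(kind = character(), site = integer())
  if (any(mods$kind == "internal-looplink")) {
    nK <- countReactiveAmines(sequence, proteinStart = start)
    stopIfNot(nK >= 2L,
              "an internal looplink requires >= 2 reactive amines in the peptide")
  }
  new("PeptideSpec", sequence = sequence, protein = protein,
      start = as.integer(start),
      end = as.integer(start) + nchar(sequence) - 1L,
      mods = mods, label = label)
}

#' Construct a CrosslinkedPair
#'
#' @param peptideA,peptideB [PeptideSpec-class] objects (pass the same
#'   object twice for a homodimeric same-to-same link)
#' @param siteA,siteB linked residue positions, protein numbering; each must
#'   be a lysine, or the protein N-terminus, within its peptide's span
#' @param linker a [CrosslinkerDef-class]
#' @return a [CrosslinkedPair-class]
#' @export
crosslinkedPair <- function(peptideA, peptideB, siteA, siteB,
                            linker = crosslinker("BS3")) {
  checkReactiveSite(peptideA, siteA)
  checkReactiveSite(peptideB, siteB)
  new("CrosslinkedPair", peptideA = peptideA, peptideB = peptideB,
      siteA = as.integer(siteA), siteB = as.integer(siteB), linker = linker)
}

checkResidues <- function(sequence) {
  stopIfNot(is.character(sequence) && length(sequence) == 1L &&
              nzchar(sequence), "empty or invalid peptide sequence")
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters1, names(residueMassTable()$mass))
  if (length(bad))
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  invisible(letters1)
}

# a site is a reactive amine if it is a lysine inside the peptide, or the
# protein N-terminus (position 1). Peptide N-termini created by digestion
# are not reactive: crosslinking precedes digestion.
checkReactiveSite <- function(peptide, site) {
  stopIfNot(site >= peptide@start && site <= peptide@end,
            sprintf("linked position %d outside peptide span %d-%d", site,
                    peptide@start, peptide@end))
  res <- substr(peptide@sequence, site - peptide@start + 1L,
                site - peptide@start + 1L)
  stopIfNot(res == "K" || site == 1L,
            sprintf("linked position %d (%s) is not a reactive amine", site,
                    res))
  invisible(TRUE)
}

#' Count reactive primary amines in a peptide or protein sequence
#'
#' Counts lysine side-chain amines plus, when the sequence starts at the
#' protein N-terminus, the alpha-amino group of the first residue.
#'
#' @param sequence residue string
#' @param proteinStart 1-based position of the first residue in the source
#'   protein; the N-terminal alpha-amine is counted only when this is 1
#' @return integer amine count
#' @examples
#' countReactiveAmines("DAEFRHDSGYEVHHQK")  # N-terminus + K16
#' @export
countReactiveAmines <- function(sequence, proteinStart = 1L) {
  letters1 <- checkResidues(sequence)
  sum(letters1 == "K") + as.integer(proteinStart == 1L)
}

#' Total nitrogen atoms of a peptide
#'
#' Sums the per-residue nitrogen counts (backbone nitrogen included); this
#' is the number of mass units of 0.997035 Da by which full 15N metabolic
#' labelling shifts the peptide mass.
#'
#' @param p a [PeptideSpec-class] or a plain sequence string
#' @param table a residue mass table, see [residueMassTable()]
#' @return integer nitrogen count
#' @examples
#' peptideNitrogens("KLALK")  # 7
#' @export
peptideNitrogens <- function(p, table = residueMassTable()) {
  sequence <- if (is(p, "PeptideSpec")) p@sequence else p
  letters1 <- checkResidues(sequence)
  sum(table$nitrogens[letters1])
}

modMass <- function(kind, linker) {
  switch(kind,
    "hydrolyzed-deadend" = linker@deadendHydrolyzed,
    "tris-deadend" = {
      stopIfNot(!is.na(linker@deadendTris),
                paste("Tris-quenched deadend mass not defined for",
                      linker@name))
      linker@deadendTris
    },
    "internal-looplink" = linker@bridge,
    stop("unknown modification kind: ", kind))
}

#' Neutral monoisotopic peptide mass
#'
#' Residue masses + water + modification masses, plus 0.997035 Da per
#' nitrogen atom for 15N-labelled peptides. Modifications (deadends,
#' internal looplinks) take their mass from `linker`.
#'
#' @param p a [PeptideSpec-class] or plain sequence string (then unmodified)
#' @param table residue mass table
#' @param linker [CrosslinkerDef-class] providing modification masses
#'   (required when `p` carries modifications)
#' @return neutral monoisotopic mass (Da)
#' @examples
#' peptideMass("GG")  # 132.0535
#' @export
peptideMass <- function(p, table = residueMassTable(), linker = NULL) {
  if (!is(p, "PeptideSpec")) p <- peptideSpec(p)
  letters1 <- checkResidues(p@sequence)
  m <- sum(table$mass[letters1]) + table$water
  if (nrow(p@mods)) {
    stopIfNot(!is.null(linker),
              "peptide carries modifications: a 'linker' is required")
    m <- m + sum(vapply(p@mods$kind, modMass, numeric(1), linker = linker))
  }
  if (p@label == "15N") m <- m + N15_SHIFT * peptideNitrogens(p, table)
  m
}

#' Neutral mass of a crosslinked peptide pair
#'
#' mass(A) + mass(B) + bridge mass. Isotope labels apply per peptide
#' independently, so mixed 14N/15N hybrid pairs are handled naturally.
#'
#' @param x a [CrosslinkedPair-class]
#' @param table residue mass table
#' @return neutral monoisotopic mass (Da)
#' @export
pairMass <- function(x, table = residueMassTable()) {
  stopIfNot(is(x, "CrosslinkedPair"), "'x' must be a CrosslinkedPair")
  peptideMass(x@peptideA, table, x@linker) +
    peptideMass(x@peptideB, table, x@linker) + x@linker@bridge
}

#' Convert neutral mass to m/z and back
#'
#' @param mass neutral monoisotopic mass (Da)
#' @param mz observed m/z
#' @param charge positive integer charge state
#' @return `massToMz`: m/z; `mzToMass`: neutral mass (Da)
#' @examples
#' massToMz(1000, 1)            # 1001.00728
#' mzToMass(massToMz(2000, 4), 4)
#' @export
massToMz <- function(mass, charge) {
  stopIfNot(all(charge >= 1), "charge must be >= 1")
  (mass + charge * PROTON_MASS) / charge
}

#' @rdname massToMz
#' @export
mzToMass <- function(mz, charge) {
  stopIfNot(all(charge >= 1), "charge must be >= 1")
  mz * charge - charge * PROTON_MASS
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical masses (Da); `theoretical` must be positive
#' @return signed ppm error
#' @examples
#' ppmError(1000.010, 1000.000)  # +10
#' @export
ppmError <- function(observed, theoretical) {
  stopIfNot(all(theoretical > 0), "theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}
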