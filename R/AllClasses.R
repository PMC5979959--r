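#' Class "CrosslinkerDef": an amine-reactive homobifunctional crosslinker
#'
#' Describes the mass chemistry of an NHS-ester crosslinker such as BS3 or
#' BS2G: the bridge mass added when both ester ends react with primary
#' amines, the deadend (monolink) masses when one end is hydrolyzed or
#' quenched with Tris, and the nominal maximum C-alpha--C-alpha span the
#' reagent can bridge.
#'
#' @slot name reagent name ("BS3" or "BS2G" for the built-ins)
#' @slot bridge monoisotopic mass (Da) added by a two-ended crosslink
#' @slot deadendHydrolyzed monoisotopic mass (Da) of a hydrolyzed deadend
#' @slot deadendTris monoisotopic mass (Da) of a Tris-quenched deadend
#'   (`NA` when disabled)
#' @slot span nominal maximum C-alpha--C-alpha distance (Angstrom)
#' @seealso [crosslinker()]
#' @exportClass CrosslinkerDef
setClass("CrosslinkerDef",
  representation(name = "character", bridge = "numeric",
                 deadendHydrolyzed = "numeric", deadendTris = "numeric",
                 span = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (!(object@bridge > 0)) msg <- c(msg, "bridge mass must be positive")
    if (!(object@bridge < object@deadendHydrolyzed))
      msg <- c(msg, "bridge mass must be below the hydrolyzed deadend mass")
    if (!(object@span > 0)) msg <- c(msg, "span must be positive")
    if (length(msg)) msg else TRUE
  })

#' Class "PeptideSpec": a proteolytic peptide with modifications and label
#'
#' A peptide cut from a source protein, together with crosslinker-derived
#' modifications (hydrolyzed/Tris deadends, internal looplinks) and its
#' metabolic nitrogen-isotope label.
#'
#' @slot sequence one-letter residue string
#' @slot protein source protein identifier
#' @slot start,end 1-based inclusive positions in the source protein
#' @slot mods data.frame with columns `kind` (one of "hydrolyzed-deadend",
#'   "tris-deadend", "internal-looplink") and `site` (1-based protein
#'   position of the modified residue)
#' @slot label "14N" (natural) or "15N" (metabolically labelled)
#' @seealso [peptideSpec()], [peptideMass()]
#' @exportClass PeptideSpec
setClass("PeptideSpec",
  representation(sequence = "character", protein = "character",
                 start = "integer", end = "integer",
                 mods = "data.frame", label = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@sequence) != 1L || !nzchar(object@sequence))
      msg <- c(msg, "sequence must be a single non-empty string")
    else if (object@end - object@start + 1L != nchar(object@sequence))
      msg <- c(msg, "start/end positions inconsistent with sequence length")
    if (nrow(object@mods) > 3L)
      msg <- c(msg, "at most 3 modifications per peptide are allowed")
    if (nrow(object@mods) &&
        !all(object@mods$kind %in% c("hydrolyzed-deadend", "tris-deadend",
                                     "internal-looplink")))
      msg <- c(msg, "unknown modification kind")
    if (!object@label %in% c("14N", "15N"))
      msg <- c(msg, "label must be '14N' or '15N'")
    if (length(msg)) msg else TRUE
  })

#' Class "CrosslinkedPair": two peptides joined by a crosslinker
#'
#' Carrier of the mass arithmetic for a crosslinked peptide pair. The linked
#' positions are 1-based residue numbers in each peptide's source protein
#' and must be crosslinker-reactive amines (lysine side chains, or the
#' protein N-terminus).
#'
#' @slot peptideA,peptideB [PeptideSpec-class] objects
#' @slot siteA,siteB linked residue positions (protein numbering)
#' @slot linker a [CrosslinkerDef-class]
#' @seealso [crosslinkedPair()], [pairMass()]
#' @exportClass CrosslinkedPair
setClass("CrosslinkedPair",
  representation(peptideA = "PeptideSpec", peptideB = "PeptideSpec",
                 siteA = "integer", siteB = "integer",
                 linker = "CrosslinkerDef"))

#' Class "StructureModel": C-alpha coordinates of a structural model
#'
#' A light-weight C-alpha-only representation of a (possibly multi-chain)
#' structural model, keyed by chain identifier and author residue number.
#'
#' @slot id model identifier
#' @slot atoms data.frame with columns `chain`, `resno` (author numbering),
#'   `resname`, `x`, `y`, `z` (Angstrom), one row per residue
#' @seealso [readStructurePDB()], [caDistance()]
#' @exportClass StructureModel
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame"),
  validity = function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "resname", "x", "y", "z")
    if (!all(need %in% names(a)))
      return(paste("atoms must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(paste(a$chain, a$resno)))
      return("duplicated (chain, resno): each residue must have exactly one C-alpha")
    if (!all(is.finite(c(a$x, a$y, a$z))))
      return("non-finite coordinates")
    TRUE
  })

#' Class "ModeSet": eigenpairs of an elastic-network Hessian
#'
#' Normal modes of a C-alpha elastic network. Eigenvalues are sorted in
#' ascending order; for a connected network the first six are numerically
#' zero (rigid-body translations and rotations), and "mode 7" is the first
#' internal deformation.
#'
#' @slot values eigenvalues, ascending
#' @slot vectors matrix of eigenvectors (3N rows, one column per mode),
#'   mutually orthonormal
#' @slot n number of network nodes (residues)
#' @slot resno author residue numbers of the nodes
#' @seealso [solveModes()], [modeFluctuations()]
#' @exportClass ModeSet
setClass("ModeSet",
  representation(values = "numeric", vectors = "matrix", n = "integer",
                 resno = "integer"),
  validity = function(object) {
    if (is.unsorted(object@values, strictly = FALSE))
      return("eigenvalues must be sorted ascending")
    if (nrow(object@vectors) != 3L * object@n)
      return("eigenvector length must be 3N")
    if (ncol(object@vectors) != length(object@values))
      return("one eigenvector per eigenvalue required")
    TRUE
  })

#' Class "SAXSCurve": a 1-D small-angle scattering profile
#'
#' @slot q momentum transfer grid, strictly increasing and positive
#' @slot I scattered intensity
#' @slot sigma per-point uncertainty (may be all zero when unknown)
#' @slot qUnit "A^-1" or "nm^-1"
#' @seealso [saxsCurve()], [readSAXSCurve()], [guinierFit()]
#' @exportClass SAXSCurve
setClass("SAXSCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric",
                 qUnit = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@q) != length(object@I) ||
        length(object@q) != length(object@sigma))
      msg <- c(msg, "q, I and sigma must have equal length")
    if (any(object@q <= 0) || is.unsorted(object@q, strictly = TRUE))
      msg <- c(msg, "q must be strictly increasing and positive")
    if (!all(is.finite(object@I))) msg <- c(msg, "I must be finite")
    if (!object@qUnit %in% c("A^-1", "nm^-1"))
      msg <- c(msg, "qUnit must be 'A^-1' or 'nm^-1'")
    if (length(msg)) msg else TRUE
  })

#' Class "SpectrumRecord": an MS/MS scan with precursor and peak list
#'
#' @slot title scan title / identifier
#' @slot pepmass precursor m/z
#' @slot charge precursor charge (`NA` when absent from the source file)
#' @slot mz,intensity fragment peak list, sorted by m/z
#' @seealso [readMGF()], [filterTopPeaks()]
#' @exportClass SpectrumRecord
setClass("SpectrumRecord",
  representation(title = "character", pepmass = "numeric",
                 charge = "integer", mz = "numeric", intensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
      msg <- c(msg, "mz and intensity must have equal length")
    if (length(object@mz) && is.unsorted(object@mz))
      msg <- c(msg, "peaks must be sorted by m/z")
    if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Class "GuinierResult": result of a Guinier fit
#'
#' @slot rg radius of gyration, in the reciprocal unit of the fitted curve's q
#' @slot i0 forward scattering I(0)
#' @slot qRange fitted q window (min, max)
#' @slot qmaxRg q_max * Rg of the fitted window
#' @slot npts number of points in the fit
#' @slot aggregated TRUE when a low-q upturn inconsistent with the Guinier
#'   law was detected (possible aggregation)
#' @slot residualSd standard deviation of the fit residuals (in ln I)
#' @exportClass GuinierResult
setClass("GuinierResult",
  representation(rg = "numeric", i0 = "numeric", qRange = "numeric",
                 qmaxRg = "numeric", npts = "integer",
                 aggregated = "logical", residualSd = "numeric"))

#' Class "PrResult": a pair-distance distribution estimate
#'
#' @slot r distance grid (0..Dmax)
#' @slot pr estimated P(r), non-negative with P(0)=P(Dmax)=0
#' @slot dmax maximum particle dimension
#' @slot rg radius of gyration from the second moment of P(r)
#' @slot i0 forward scattering implied by P(r)
#' @slot score perceptual quality score of the chosen solution (smaller is
#'   better; combines misfit and roughness)
#' @slot alpha regularization weight used
#' @exportClass PrResult
setClass("PrResult",
  representation(r = "numeric", pr = "numeric", dmax = "numeric",
                 rg = "numeric", i0 = "numeric", score = "numeric",
                 alpha = "numeric"))

#' Class "PorodResult": Porod invariant and particle volume
#'
#' @slot invariant the Porod invariant Q = integral of q^2 I(q) dq
#' @slot volume Porod volume Vp = 2 pi^2 I(0) / Q
#' @slot settings list describing the extrapolation/background choices used
#' @exportClass PorodResult
setClass("PorodResult",
  representation(invariant = "numeric", volume = "numeric",
                 settings = "list"))

#' Class "SizeEstimate": oligomer mass and subunit count from volume
#'
#' @slot mwP mass (kDa) from the Porod volume, Vp / 1.6
#' @slot mwA mass (kDa) from an ab-initio model excluded volume, Va / 2
#'   (`NA` when no excluded volume is supplied)
#' @slot monomer monomer mass (kDa)
#' @slot subunits nearest-integer subunit count, mwP / monomer
#' @seealso [sizeEstimate()], [subunitCount()]
#' @exportClass SizeEstimate
setClass("SizeEstimate",
  representation(mwP = "numeric", mwA = "numeric", monomer = "numeric",
                 subunits = "numeric"),
  validity = function(object) {
    if (object@subunits < 1) return("subunit count must be >= 1")
    if (object@subunits != roundAway(object@mwP / object@monomer))
      return("subunit count must equal round(mwP / monomer)")
    TRUE
  })

## ---- show methods -------------------------------------------------------

setMethod("show", "CrosslinkerDef", function(object) {
  cat("CrosslinkerDef:", object@name,
      sprintf("| bridge %.5f Da | deadend %.5f Da | span %.0f A\n",
              object@bridge, object@deadendHydrolyzed, object@span))
})

setMethod("show", "PeptideSpec", function(object) {
  cat(sprintf("PeptideSpec %s [%d-%d] %s (%s)%s\n", object@protein,
              object@start, object@end, object@sequence, object@label,
              if (nrow(object@mods))
                paste0(" +", nrow(object@mods), " mod(s)") else ""))
})

setMethod("show", "CrosslinkedPair", function(object) {
  cat(sprintf("CrosslinkedPair %s x %s via %s (K%d x K%d)\n",
              object@peptideA@sequence, object@peptideB@sequence,
              object@linker@name, object@siteA, object@siteB))
})

setMethod("show", "StructureModel", function(object) {
  ch <- unique(object@atoms$chain)
  cat(sprintf("StructureModel '%s': %d residues in %d chain(s) [%s]\n",
              object@id, nrow(object@atoms), length(ch),
              paste(ch, collapse = ",")))
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet: %d modes over %d nodes; eigenvalues 7..%d start at %.4g\n",
              length(object@values), object@n,
              min(length(object@values), 9L),
              if (length(object@values) >= 7) object@values[7] else NA))
})

setMethod("show", "SAXSCurve", function(object) {
  cat(sprintf("SAXSCurve: %d points, q in [%.4g, %.4g] %s\n",
              length(object@q), min(object@q), max(object@q), object@qUnit))
})

setMethod("show", "SpectrumRecord", function(object) {
  cat(sprintf("SpectrumRecord '%s': precursor %.4f m/z (%s+), %d peaks\n",
              object@title, object@pepmass,
              ifelse(is.na(object@charge), "?", object@charge),
              length(object@mz)))
})

setMethod("show", "GuinierResult", function(object) {
  cat(sprintf("Guinier fit: Rg = %.4g, I(0) = %.4g, %d pts, qmax*Rg = %.3f%s\n",
              object@rg, object@i0, object@npts, object@qmaxRg,
              if (object@aggregated) " [AGGREGATION SUSPECTED]" else ""))
})

setMethod("show", "PrResult", function(object) {
  cat(sprintf("P(r): Dmax = %.4g, Rg = %.4g, score = %.3g (alpha = %.3g)\n",
              object@dmax, object@rg, object@score, object@alpha))
})

setMethod("show", "PorodResult", function(object) {
  cat(sprintf("Porod: Q = %.4g, Vp = %.4g\n", object@invariant,
              object@volume))
})

setMethod("show", "SizeEstimate", function(object) {
  cat(sprintf("SizeEstimate: MWp = %.0f kDa%s, monomer %.1f kDa -> %d subunits\n",
              roundAway(object@mwP),
              if (is.na(object@mwA)) "" else
                sprintf(", MWa = %.0f kDa", roundAway(object@mwA)),
              object@monomer, as.integer(object@subunits)))
})
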