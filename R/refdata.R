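# Literature-derived reference inputs for the DNAJB6 chaperone system:
# domain boundaries, the Abeta42 peptide sequence, the candidate-model
# crosslink distance table, the oligomer crosslink set, and the SEC-SAXS
# fraction parameters. These are the real-data inputs of the worked
# analyses; expected outputs are never stored here.

#' Domain boundaries of the DNAJB6 monomer
#'
#' The DNAJB6 (cytosolic isoform, 241 residues) monomer comprises the
#' N-terminal J-domain (NTD, residues 1-71), a disordered middle domain
#' (72-189) containing the S/T-rich region, and the C-terminal beta-strand
#' domain (CTD, 190-241).
#'
#' @return a [domainMap()] data.frame
#' @export
dnajb6Domains <- function() {
  domainMap(data.frame(domain = c("NTD", "middle", "CTD"),
                       start = c(1L, 72L, 190L), end = c(71L, 189L, 241L),
                       stringsAsFactors = FALSE))
}

#' The Abeta42 peptide sequence
#'
#' The 42-residue amyloid-beta peptide of human APP. It carries three
#' crosslinker-reactive primary amines: the N-terminal alpha-amino group
#' and the side chains of K16 and K28.
#'
#' @return character sequence
#' @examples
#' countReactiveAmines(ab42Sequence())  # 3
#' @export
ab42Sequence <- function() "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

#' Published C-alpha distances of DNAJB6 monomer crosslinks on five
#' candidate homology models
#'
#' The eight lysine-lysine crosslinks detected within DNAJB6 monomers,
#' with the C-alpha--C-alpha distance of each crosslinked pair in the five
#' candidate homology models of the monomer. The upper four crosslinks are
#' intra-domain (within the NTD); the lower four are inter-domain and are
#' the discriminating constraints for model selection. One published
#' residue number (printed as 296, beyond the 241-residue protein) is a
#' typographical slip for K29: the second peptide of that crosslink, ALKW,
#' spans residues 27-30.
#'
#' @return data.frame with columns `lysA`, `lysB`, `class` and `model_1`
#'   .. `model_5` (distances in Angstrom)
#' @examples
#' D <- monomerCandidateDistances()
#' rankModels(D[D$class == "inter-domain", grep("^model", names(D))])$selected
#' @export
monomerCandidateDistances <- function() {
  data.frame(
    lysA = c(20L, 21L, 34L, 60L, 196L, 225L, 225L, 225L),
    lysB = c(25L, 25L, 25L, 67L, 29L, 21L, 60L, 70L),
    class = rep(c("intra-domain", "inter-domain"), each = 4L),
    model_1 = c(8.7, 6.1, 11.9, 10.5, 66.6, 77.9, 58.2, 51.8),
    model_2 = c(8.7, 6.0, 11.9, 10.5, 34.4, 28.1, 46.9, 56.2),
    model_3 = c(8.7, 6.1, 11.9, 10.5, 37.3, 45.1, 55.3, 50.5),
    model_4 = c(8.7, 6.1, 12.0, 10.4, 44.5, 44.6, 50.5, 47.7),
    model_5 = c(8.7, 6.1, 11.9, 10.7, 22.4, 32.8, 36.2, 28.7),
    stringsAsFactors = FALSE)
}

#' Crosslinks detected within DNAJB6 oligomers
#'
#' Lysine-lysine crosslinks detected in unfractionated (oligomeric)
#' DNAJB6, with the C-alpha distance of each pair evaluated on the
#' selected monomer model where available. The same-to-same-residue
#' crosslinks K189-K189 and K232-K232 can only be inter-subunit (distance
#' NA on a monomer) and are the docking restraints for the dimer model.
#'
#' @return constraint data.frame with an extra `monomerDistance` column
#' @export
oligomerCrosslinks <- function() {
  tab <- data.frame(
    posA = c(20L, 20L, 20L, 20L, 34L, 34L, 47L, 60L, 70L, 70L, 70L, 189L,
             225L, 225L, 225L, 225L, 225L, 225L, 225L, 232L, 232L, 232L),
    posB = c(60L, 189L, 202L, 232L, 25L, 202L, 232L, 67L, 47L, 67L, 225L,
             189L, 20L, 34L, 60L, 67L, 196L, 202L, 232L, 67L, 202L, 232L),
    monomerDistance = c(16.6, 36.0, 29.6, 47.2, 12.0, 16.5, 36.4, 11.0,
                        21.6, 5.4, 28.3, NA, 33.1, 25.4, 36.8, 31.7,
                        14.5, 12.3, 16.1, 40.7, 25.2, NA),
    stringsAsFactors = FALSE)
  cbind(xlConstraints(tab$posA, tab$posB),
        monomerDistance = tab$monomerDistance)
}

#' Crosslinks between Abeta42 and DNAJB6
#'
#' The four crosslinks detected between the Abeta42 peptide and DNAJB6:
#' both lysine side chains of the peptide (K16, K28) link to four distinct
#' lysines in the DNAJB6 C-terminal region, implicating the CTD in peptide
#' binding.
#'
#' @return data.frame with columns `ab42Lys` and `dnajb6Lys`
#' @examples
#' length(unique(ab42CrosslinkTable()$dnajb6Lys))  # 4
#' @export
ab42CrosslinkTable <- function() {
  data.frame(ab42Lys = c(16L, 16L, 28L, 28L),
             dnajb6Lys = c(189L, 225L, 202L, 232L))
}

#' SEC-SAXS fraction parameters of DNAJB6 oligomers
#'
#' Radius of gyration, maximum dimension and Porod volume of the six
#' oligomer sub-populations separated by online size-exclusion
#' chromatography, ordered from earliest (largest) to latest (smallest)
#' eluting fraction. These feed the volume -> mass -> subunit-count chain
#' (see [sizeEstimate()]); the DNAJB6 monomer mass is 26.9 kDa.
#'
#' @return data.frame with columns `fraction`, `rg` (nm), `dmax` (nm) and
#'   `vp` (nm^3)
#' @examples
#' subunits(sizeEstimate(secSaxsFractions()$vp[1]))  # 55
#' @export
secSaxsFractions <- function() {
  data.frame(fraction = 1:6,
             rg = c(8.73, 8.50, 7.70, 7.43, 6.72, 6.88),
             dmax = c(29.6, 29.4, 27.5, 26.6, 22.5, 22.2),
             vp = c(2368, 2114, 1849, 1669, 1523, 1470))
}

#' DNAJB6 monomer mass in kDa
#' @return 26.9
#' @export
dnajb6MonomerKDa <- function() 26.9
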