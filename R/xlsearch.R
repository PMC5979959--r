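# In-silico digestion, crosslink candidate enumeration, precursor/fragment
# matching of MGF spectra, and mixed-isotope hybrid-crosslink detection.

#' Search settings for the crosslink spectrum search
#'
#' Defaults mirror a conservative crosslink search on high-resolution
#' precursor data: 10 ppm MS1 tolerance, 0.05 Da MS2 tolerance (0.2 Da for
#' lower-resolution fragment spectra), trypsin combined with chymotrypsin,
#' up to 2 missed cleavages and 3 modifications per peptide, the 125 most
#' intense peaks per scan, and precursor charges of 3+ and above (2+
#' spectra are skipped: crosslinked peptides are generally charged 3+ or
#' more).
#'
#' @param ms1Ppm precursor tolerance (ppm)
#' @param ms2Da fragment tolerance (Da)
#' @param enzymes any of "trypsin" (cleaves after K/R) and "chymotrypsin"
#'   (low-specificity variant, cleaves after F/W/Y/L/M); both obey the
#'   no-cleavage-before-proline rule
#' @param missedCleavages maximum missed cleavages
#' @param maxMods maximum modifications per peptide
#' @param topN peak-list filter: keep the topN most intense peaks
#' @param minCharge minimum considered precursor charge
#' @param minMatchedIntensity spectrum-acceptance threshold on summed
#'   matched intensity
#' @param requireBothPeptides spectrum-acceptance: fragments from both
#'   peptides required for crosslink candidates
#' @param maxUnexplained spectrum-acceptance: maximum fraction of the 20
#'   most intense peaks left unexplained
#' @return a list of class "SearchSettings"
#' @export
searchSettings <- function(ms1Ppm = 10, ms2Da = 0.05,
                           enzymes = c("trypsin", "chymotrypsin"),
                           missedCleavages = 2L, maxMods = 3L, topN = 125L,
                           minCharge = 3L, minMatchedIntensity = 1000,
                           requireBothPeptides = TRUE,
                           maxUnexplained = 0.5) {
  stopIfNot(ms1Ppm > 0 && ms2Da > 0, "tolerances must be positive")
  stopIfNot(missedCleavages >= 0, "missedCleavages must be >= 0")
  stopIfNot(topN >= 1, "topN must be >= 1")
  structure(list(ms1Ppm = ms1Ppm, ms2Da = ms2Da, enzymes = enzymes,
                 missedCleavages = as.integer(missedCleavages),
                 maxMods = as.integer(maxMods), topN = as.integer(topN),
                 minCharge = as.integer(minCharge),
                 minMatchedIntensity = minMatchedIntensity,
                 requireBothPeptides = requireBothPeptides,
                 maxUnexplained = maxUnexplained),
            class = "SearchSettings")
}

enzymeResidues <- function(enzymes) {
  sets <- list(trypsin = c("K", "R"),
               chymotrypsin = c("F", "W", "Y", "L", "M"))
  unknown <- setdiff(enzymes, names(sets))
  stopIfNot(length(unknown) == 0,
            paste("unknown enzyme(s):", paste(unknown, collapse = ", ")))
  unique(unlist(sets[enzymes]))
}

#' In-silico proteolytic digestion
#'
#' Cleaves C-terminally to the enzyme-specific residues (trypsin: K/R;
#' chymotrypsin low-specificity: F/W/Y/L/M), never before a proline, and
#' returns all peptides with up to `missedCleavages` internal cleavage
#' sites. With an empty enzyme set the whole protein is returned.
#'
#' @param sequence protein sequence (one-letter)
#' @param settings a [searchSettings()] list (enzymes and missed cleavages
#'   are taken from it)
#' @param protein protein identifier recorded on the peptides
#' @return data.frame with columns `sequence`, `start`, `end`, `protein`,
#'   `missed` (1-based inclusive protein positions)
#' @examples
#' digestProtein("AKPGRSF", searchSettings(missedCleavages = 0))
#' @export
digestProtein <- function(sequence, settings = searchSettings(),
                          protein = "protein") {
  letters1 <- checkResidues(sequence)
  n <- length(letters1)
  res <- enzymeResidues(settings$enzymes)
  sites <- which(letters1 %in% res & c(letters1[-1], "") != "P")
  sites <- sites[sites < n]
  bounds <- c(0L, sites, n)
  out <- list()
  for (j in seq_len(length(bounds) - 1L)) {
    for (mc in 0:settings$missedCleavages) {
      k <- j + mc + 1L
      if (k > length(bounds)) break
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, bounds[j] + 1L, bounds[k]),
        start = bounds[j] + 1L, end = bounds[k], protein = protein,
        missed = mc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# local indices of crosslinker-reactive amines in a digest peptide:
# internal lysines (a C-terminal lysine was, by construction, cleaved by
# trypsin and therefore unmodified, unless it is the protein C-terminus)
# and the protein N-terminal alpha-amine.
reactiveSiteIdx <- function(sequence, start, proteinLength = NA_integer_) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  idx <- which(letters1 == "K")
  end <- start + n - 1L
  if (length(idx) && idx[length(idx)] == n &&
      !(!is.na(proteinLength) && end == proteinLength))
    idx <- idx[-length(idx)]
  if (start == 1L) idx <- sort(unique(c(1L, idx)))
  idx
}

#' Enumerate crosslink search candidates
#'
#' From a digest peptide table, enumerates every crosslinked peptide pair
#' (including a peptide paired with a second copy of itself, the
#' homodimeric same-to-same link), every hydrolyzed-deadend peptide, and
#' every internal looplink for peptides with at least two reactive amines.
#' Reactive amines are internal lysines plus the protein N-terminus.
#'
#' @param peptides data.frame from [digestProtein()] (possibly several
#'   proteins row-bound)
#' @param linker a [CrosslinkerDef-class]
#' @param settings a [searchSettings()] list
#' @param proteinLengths optional named integer vector, used to recognise
#'   protein C-terminal lysines as reactive
#' @return data.frame with one row per candidate: `id`, `type` (crosslink /
#'   deadend / looplink), peptide sequences/positions, linked sites
#'   (protein numbering), the neutral 14N mass `mass`, and the nitrogen
#'   counts `nA`, `nB` that set the 15N label shifts
#' @export
enumerateCandidates <- function(peptides, linker = crosslinker("BS3"),
                                settings = searchSettings(),
                                proteinLengths = NULL) {
  tab <- residueMassTable()
  pep <- unique(peptides[, c("sequence", "start", "end", "protein")])
  pep$mass <- vapply(pep$sequence, function(s)
    sum(tab$mass[strsplit(s, "")[[1]]]) + tab$water, numeric(1))
  pep$nN <- vapply(pep$sequence, peptideNitrogens, numeric(1))
  sites <- lapply(seq_len(nrow(pep)), function(i) {
    pl <- if (!is.null(proteinLengths)) proteinLengths[[pep$protein[i]]]
          else NA_integer_
    reactiveSiteIdx(pep$sequence[i], pep$start[i], pl)
  })
  rows <- list()
  add <- function(type, iA, siteA, iB = NA, siteB = NA, mass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, seqA = pep$sequence[iA], startA = pep$start[iA],
      protA = pep$protein[iA], siteA = pep$start[iA] + siteA - 1L,
      seqB = if (is.na(iB)) NA_character_ else pep$sequence[iB],
      startB = if (is.na(iB)) NA_integer_ else pep$start[iB],
      protB = if (is.na(iB)) NA_character_ else pep$protein[iB],
      siteB = if (is.na(iB)) NA_integer_
              else pep$start[iB] + siteB - 1L,
      linker = linker@name, mass = mass, nA = pep$nN[iA],
      nB = if (is.na(iB)) 0 else pep$nN[iB], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pep))) {
    si <- sites[[i]]
    for (s in si)
      add("deadend", i, s, mass = pep$mass[i] + linker@deadendHydrolyzed)
    if (length(si) >= 2L) {
      cmb <- combn(si, 2L)
      for (k in seq_len(ncol(cmb)))
        add("looplink", i, cmb[1, k], iB = NA, siteB = NA,
            mass = pep$mass[i] + linker@bridge)
    }
  }
  for (i in seq_len(nrow(pep))) {
    si <- sites[[i]]
    if (!length(si)) next
    for (j in i:nrow(pep)) {
      sj <- sites[[j]]
      if (!length(sj)) next
      for (a in si) for (b in sj) {
        if (i == j && b < a) next
        add("crosslink", i, a, j, b,
            mass = pep$mass[i] + pep$mass[j] + linker@bridge)
      }
    }
  }
  if (!length(rows))
    return(data.frame(type = character(), seqA = character(),
                      startA = integer(), protA = character(),
                      siteA = integer(), seqB = character(),
                      startB = integer(), protB = character(),
                      siteB = integer(), linker = character(),
                      mass = numeric(), nA = numeric(), nB = numeric(),
                      id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$id <- ifelse(out$type == "crosslink",
                   sprintf("%s:%s@%d--%s@%d", out$type, out$seqA, out$siteA,
                           out$seqB, out$siteB),
                   sprintf("%s:%s@%d", out$type, out$seqA, out$siteA))
  unique(out)
}

#' Keep the top-N most intense peaks of a spectrum
#'
#' The m/z ordering of the surviving peaks is preserved; applying the
#' filter twice equals applying it once.
#'
#' @param spec a [SpectrumRecord-class]
#' @param n number of peaks to keep
#' @return the filtered [SpectrumRecord-class]
#' @export
filterTopPeaks <- function(spec, n = 125L) {
  stopIfNot(n >= 1, "n must be >= 1")
  if (length(spec@mz) <= n) return(spec)
  keep <- sort(order(spec@intensity, decreasing = TRUE)[seq_len(n)])
  spectrumRecord(spec@title, spec@pepmass, spec@charge, spec@mz[keep],
                 spec@intensity[keep])
}

# isotope states and their mass shifts for a candidate row
candidateStates <- function(cand, labeling) {
  if (!labeling)
    return(data.frame(isotope = if (cand$type == "crosslink") "14/14"
                      else "14", shift = 0))
  if (cand$type == "crosslink")
    data.frame(isotope = c("14/14", "14/15", "15/14", "15/15"),
               shift = c(0, N15_SHIFT * cand$nB, N15_SHIFT * cand$nA,
                         N15_SHIFT * (cand$nA + cand$nB)))
  else
    data.frame(isotope = c("14", "15"),
               shift = c(0, N15_SHIFT * cand$nA))
}

#' Match spectra precursors against candidate masses
#'
#' Spectra whose precursor charge is below `minCharge` are skipped, as are
#' spectra without a charge assignment (with a warning). When `labeling` is
#' TRUE all four isotope states (14/14, 14/15, 15/14, 15/15) of a
#' crosslinked pair, and both states of single-peptide candidates, are
#' considered.
#'
#' @param spectra list of [SpectrumRecord-class]
#' @param candidates candidate table from [enumerateCandidates()]
#' @param settings a [searchSettings()] list
#' @param labeling consider 15N metabolic-label states
#' @return data.frame of precursor-level matches: `spectrum`, `candidate`
#'   (row index), `id`, `type`, `isotope`, `theoMass`, `ppm`
#' @export
precursorMatch <- function(spectra, candidates,
                           settings = searchSettings(), labeling = FALSE) {
  if (is(spectra, "SpectrumRecord")) spectra <- list(spectra)
  states <- lapply(seq_len(nrow(candidates)), function(i)
    cbind(candidate = i, candidateStates(candidates[i, ], labeling)))
  states <- do.call(rbind, states)
  states$theoMass <- candidates$mass[states$candidate] + states$shift
  out <- list()
  for (s in spectra) {
    if (is.na(s@charge)) {
      warning("spectrum '", s@title, "' has no charge assignment: skipped")
      next
    }
    if (s@charge < settings$minCharge) next
    neutral <- mzToMass(s@pepmass, s@charge)
    ppm <- ppmError(neutral, states$theoMass)
    hit <- which(abs(ppm) <= settings$ms1Ppm)
    if (!length(hit)) next
    out[[length(out) + 1L]] <- data.frame(
      spectrum = s@title, candidate = states$candidate[hit],
      id = candidates$id[states$candidate[hit]],
      type = candidates$type[states$candidate[hit]],
      isotope = states$isotope[hit], theoMass = states$theoMass[hit],
      ppm = ppm[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(spectrum = character(), candidate = integer(),
                      id = character(), type = character(),
                      isotope = character(), theoMass = numeric(),
                      ppm = numeric()))
  do.call(rbind, out)
}

# b/y fragment m/z values of one peptide. `cover`: local residue indices
# that a fragment must cover completely to carry `addMass` (the partner
# peptide + bridge for a crosslink, the deadend mass for a monolink, the
# bridge for a looplink); fragments covering only part of `cover` are
# dropped (ring-opening fragments are not modelled).
fragmentSeries <- function(sequence, cover = NULL, addMass = 0,
                           label = "14N", charges = 1L,
                           table = residueMassTable()) {
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  m <- unname(table$mass[letters1])
  if (label == "15N") m <- m + N15_SHIFT * unname(table$nitrogens[letters1])
  cb <- cumsum(m)
  total <- cb[n]
  idx <- seq_len(n - 1L)
  frag <- function(ion, i) {
    ncov <- if (is.null(cover)) 0L
            else if (ion == "b") sum(cover <= i) else sum(cover >= n - i + 1L)
    full <- !is.null(cover) && ncov == length(cover)
    if (!is.null(cover) && ncov > 0L && !full) return(NULL)
    base <- if (ion == "b") cb[i] else total - cb[n - i] + table$water
    base + if (full) addMass else 0
  }
  empty <- data.frame(ion = character(), type = character(),
                      index = integer(), charge = integer(),
                      mz = numeric(), stringsAsFactors = FALSE)
  rows <- list(empty)
  for (ion in c("b", "y")) for (i in idx) {
    f <- frag(ion, i)
    if (is.null(f)) next
    for (z in charges)
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0(ion, i), type = ion, index = i, charge = z,
        mz = (f + z * table$proton) / z, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

addPeptideTag <- function(f, tag) {
  f$peptide <- rep(tag, nrow(f))
  f[, c("peptide", setdiff(names(f), "peptide"))]
}

#' Theoretical b/y fragment ions of a search candidate
#'
#' For crosslinked pairs, fragments that span the linked residue carry the
#' full partner peptide plus the bridge as a fixed added mass; fragments
#' N-terminal (b) or C-terminal (y) of the link site are plain peptide
#' fragments. Deadend and looplink candidates are handled analogously.
#' Fragment charges run from 1 to `precursorCharge - 1`.
#'
#' @param x a [CrosslinkedPair-class], or one row of an
#'   [enumerateCandidates()] table
#' @param precursorCharge precursor charge state
#' @param isotope isotope state: "14/14", "14/15", "15/14", "15/15" for
#'   pairs, "14"/"15" for single-peptide candidates
#' @param linker [CrosslinkerDef-class] (taken from `x` when it is a
#'   CrosslinkedPair)
#' @param table residue mass table
#' @return data.frame with columns `peptide` ("A"/"B"), `ion`, `type`,
#'   `index`, `charge`, `mz`
#' @export
theoreticalFragments <- function(x, precursorCharge = 3L, isotope = NULL,
                                 linker = crosslinker("BS3"),
                                 table = residueMassTable()) {
  charges <- seq_len(max(1L, precursorCharge - 1L))
  if (is(x, "CrosslinkedPair")) {
    lab <- c(x@peptideA@label, x@peptideB@label)
    x <- data.frame(type = "crosslink", seqA = x@peptideA@sequence,
                    startA = x@peptideA@start, siteA = x@siteA,
                    seqB = x@peptideB@sequence, startB = x@peptideB@start,
                    siteB = x@siteB, stringsAsFactors = FALSE)
    linker <- linker
    isotope <- paste(sub("N", "", lab[1]), sub("N", "", lab[2]), sep = "/")
  }
  if (is.null(isotope)) isotope <- if (x$type == "crosslink") "14/14" else "14"
  labs <- paste0(strsplit(isotope, "/")[[1]], "N")
  massOf <- function(seq, label) {
    m <- sum(unname(table$mass[strsplit(seq, "")[[1]]])) + table$water
    if (label == "15N") m + N15_SHIFT * peptideNitrogens(seq, table) else m
  }
  if (x$type == "crosslink") {
    localA <- x$siteA - x$startA + 1L
    localB <- x$siteB - x$startB + 1L
    addA <- massOf(x$seqB, labs[2]) + linker@bridge
    addB <- massOf(x$seqA, labs[1]) + linker@bridge
    fa <- fragmentSeries(x$seqA, cover = localA, addMass = addA,
                         label = labs[1], charges = charges, table = table)
    fb <- fragmentSeries(x$seqB, cover = localB, addMass = addB,
                         label = labs[2], charges = charges, table = table)
    rbind(addPeptideTag(fa, "A"), addPeptideTag(fb, "B"))
  } else if (x$type == "deadend") {
    localA <- x$siteA - x$startA + 1L
    fa <- fragmentSeries(x$seqA, cover = localA,
                         addMass = linker@deadendHydrolyzed,
                         label = labs[1], charges = charges, table = table)
    addPeptideTag(fa, "A")
  } else {
    loop <- sort(c(x$siteA, x$siteB)) - x$startA + 1L
    fa <- fragmentSeries(x$seqA, cover = loop, addMass = linker@bridge,
                         label = labs[1], charges = charges, table = table)
    addPeptideTag(fa, "A")
  }
}

#' Score a spectrum against theoretical fragments
#'
#' The score is the intensity-weighted matched fraction: the share of total
#' peak intensity explained by theoretical fragments, multiplied by the
#' fraction of theoretical fragments matched within the MS2 tolerance.
#' Separately, boolean acceptance flags mirror manual spectrum-validation
#' criteria: matched intensity above threshold, fragment ions from both
#' peptides, and no large fraction of major (top-20) peaks unexplained.
#'
#' @param spec a (typically top-N filtered) [SpectrumRecord-class]
#' @param fragments data.frame from [theoreticalFragments()]
#' @param settings a [searchSettings()] list
#' @return list with `score`, `matchedFraction`, `matchedIntensity`,
#'   `bothPeptides`, `unexplainedTop`, `nMatched`
#' @export
scoreMatch <- function(spec, fragments, settings = searchSettings()) {
  tol <- settings$ms2Da
  if (!length(spec@mz) || !nrow(fragments))
    return(list(score = 0, matchedFraction = 0, matchedIntensity = 0,
                bothPeptides = FALSE, unexplainedTop = 1, nMatched = 0L))
  nearest <- function(values, targets) {
    # for each value, distance to nearest target
    i <- findInterval(values, targets)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(targets))
    pmin(abs(values - targets[lo]), abs(values - targets[hi]))
  }
  fmz <- sort(fragments$mz)
  peakMatched <- nearest(spec@mz, fmz) <= tol
  pmz <- spec@mz
  fragMatched <- nearest(fragments$mz, pmz) <= tol
  matchedIntensity <- sum(spec@intensity[peakMatched])
  fracInt <- matchedIntensity / sum(spec@intensity)
  fracFrag <- mean(fragMatched)
  top <- order(spec@intensity, decreasing = TRUE)[
    seq_len(min(20L, length(spec@mz)))]
  unexplainedTop <- mean(!peakMatched[top])
  both <- if (!"peptide" %in% names(fragments) ||
              length(unique(fragments$peptide)) == 1L)
    any(fragMatched)
  else any(fragMatched[fragments$peptide == "A"]) &&
       any(fragMatched[fragments$peptide == "B"])
  list(score = fracInt * fracFrag, matchedFraction = fracFrag,
       matchedIntensity = matchedIntensity, bothPeptides = both,
       unexplainedTop = unexplainedTop, nMatched = sum(fragMatched))
}

#' Run the full crosslink spectrum search
#'
#' Filters each spectrum to the top-N peaks, matches precursors against
#' candidate masses (all isotope states when `labeling`), scores fragment
#' evidence, and ranks candidates per spectrum by score, then smaller
#' absolute ppm error, then candidate id (a deterministic tie-break).
#'
#' @param spectra list of [SpectrumRecord-class]
#' @param candidates table from [enumerateCandidates()]
#' @param settings a [searchSettings()] list
#' @param linker [CrosslinkerDef-class] used for fragment masses
#' @param labeling consider 15N label states
#' @return list with `matches` (all scored precursor matches, ranked) and
#'   `best` (the top-ranked match per spectrum)
#' @export
searchSpectra <- function(spectra, candidates, settings = searchSettings(),
                          linker = crosslinker("BS3"), labeling = FALSE) {
  if (is(spectra, "SpectrumRecord")) spectra <- list(spectra)
  spectra <- lapply(spectra, filterTopPeaks, n = settings$topN)
  pm <- precursorMatch(spectra, candidates, settings, labeling)
  if (!nrow(pm)) return(list(matches = pm, best = pm))
  titles <- vapply(spectra, function(s) s@title, character(1))
  scores <- vector("list", nrow(pm))
  for (k in seq_len(nrow(pm))) {
    s <- spectra[[match(pm$spectrum[k], titles)]]
    frags <- theoreticalFragments(candidates[pm$candidate[k], ],
                                  precursorCharge = s@charge,
                                  isotope = pm$isotope[k], linker = linker)
    scores[[k]] <- scoreMatch(s, frags, settings)
  }
  pm$score <- vapply(scores, `[[`, numeric(1), "score")
  pm$matchedIntensity <- vapply(scores, `[[`, numeric(1),
                                "matchedIntensity")
  pm$bothPeptides <- vapply(scores, `[[`, logical(1), "bothPeptides")
  pm$unexplainedTop <- vapply(scores, `[[`, numeric(1), "unexplainedTop")
  pm$accepted <- pm$matchedIntensity >= settings$minMatchedIntensity &
    (!settings$requireBothPeptides | pm$bothPeptides |
       pm$type != "crosslink") &
    pm$unexplainedTop <= settings$maxUnexplained
  ord <- order(pm$spectrum, -pm$score, abs(pm$ppm), pm$id)
  pm <- pm[ord, ]
  pm$rank <- unlist(lapply(split(seq_len(nrow(pm)), pm$spectrum)[
    unique(pm$spectrum)], seq_along))
  rownames(pm) <- NULL
  attr(pm, "labeling") <- labeling
  best <- pm[pm$rank == 1L, ]
  attr(best, "labeling") <- labeling
  list(matches = pm, best = best)
}

#' Detect subunit exchange from mixed-isotope hybrid crosslinks
#'
#' A hybrid crosslink joins a 14N and a 15N peptide (isotope state "14/15"
#' or "15/14"). When oligomer pools of unlabelled and labelled protein are
#' mixed *before* crosslinking, hybrids can only arise if the oligomers
#' exchange subunits; in a control where the pools are crosslinked
#' separately and mixed afterwards, hybrids must be absent. The verdict is
#' `exchange = TRUE` iff hybrids are present in the mixed experiment and
#' absent in the control.
#'
#' @param mixed match table (from [searchSpectra()]`$best` or `$matches`)
#'   of the mixed-before-crosslinking experiment
#' @param control match table of the crosslinked-separately control
#' @return list with `exchange` (logical verdict), `mixedHybrids` and
#'   `controlHybrids` (the hybrid-state subsets)
#' @export
detectHybrids <- function(mixed, control) {
  for (tab in list(mixed, control)) {
    stopIfNot("isotope" %in% names(tab),
              "matches carry no isotope annotation: run the search with labeling = TRUE")
    lab <- attr(tab, "labeling")
    stopIfNot(is.null(lab) || isTRUE(lab),
              "isotope labeling was disabled in this search: hybrid detection needs labeling = TRUE")
  }
  hyb <- function(tab) tab[tab$isotope %in% c("14/15", "15/14"), ,
                           drop = FALSE]
  mh <- hyb(mixed)
  ch <- hyb(control)
  list(exchange = nrow(mh) > 0 && nrow(ch) == 0, mixedHybrids = mh,
       controlHybrids = ch)
}

#' Write a crosslink match report as TSV
#'
#' @param matches match table from [searchSpectra()]
#' @param file output path
#' @export
writeMatchReport <- function(matches, file) {
  write.table(matches, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
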