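# Mapping crosslinks onto structural models: C-alpha distances,
# satisfied/ambiguous/violated classification, model ranking and selection,
# intra/inter-domain and intra/inter-subunit topology, docking-restraint
# export.

#' Distance policy for crosslink classification
#'
#' A lysine-specific NHS-ester crosslinker can bridge C-alpha pairs up to
#' roughly 30 Angstrom (linker arm plus side-chain and backbone dynamics);
#' distances above 40 Angstrom are implausible and count as violating
#' crosslinks. A crosslink is `satisfied` when d <= satisfied (inclusive),
#' `violated` when d > violation (strict), otherwise `ambiguous`.
#'
#' @param satisfied maximum satisfied C-alpha distance (Angstrom)
#' @param violation minimum violating distance (Angstrom)
#' @return list of class "ConstraintPolicy"
#' @export
constraintPolicy <- function(satisfied = 30, violation = 40) {
  stopIfNot(satisfied > 0 && satisfied < violation,
            "need 0 < satisfied < violation")
  structure(list(satisfied = satisfied, violation = violation),
            class = "ConstraintPolicy")
}

#' Construct a StructureModel from a coordinate table
#'
#' @param atoms data.frame with columns chain, resno, resname, x, y, z
#' @param id model identifier
#' @return a [StructureModel-class]
#' @export
structureModel <- function(atoms, id = "model") {
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", id = as.character(id), atoms = atoms)
}

#' Read a C-alpha structural model from a PDB file
#'
#' Parses standard ATOM records (via bio3d), keeps one C-alpha per residue
#' with author residue numbering, and supports multi-chain models. Residues
#' without a C-alpha are skipped with a warning.
#'
#' @param file path to a PDB file
#' @param id model identifier (defaults to the file name)
#' @return a [StructureModel-class]
#' @export
readStructurePDB <- function(file, id = NULL) {
  if (is.null(id)) id <- sub("\\.pdb$", "", basename(file))
  pdb <- tryCatch(bio3d::read.pdb(file, verbose = FALSE),
                  error = function(e)
                    stop("cannot read PDB '", file, "': ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  stopIfNot(nrow(at) > 0, paste("no ATOM records in", file))
  allRes <- unique(paste(at$chain, at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing <- setdiff(allRes, unique(paste(ca$chain, ca$resno)))
  if (length(missing))
    warning(length(missing), " residue(s) without a C-alpha skipped")
  stopIfNot(nrow(ca) > 0, paste("no C-alpha atoms in", file))
  ca <- ca[!duplicated(paste(ca$chain, ca$resno)), , drop = FALSE]
  chain <- ifelse(is.na(ca$chain) | ca$chain == "", "A", ca$chain)
  structureModel(data.frame(chain = chain, resno = ca$resno,
                            resname = ca$resid, x = ca$x, y = ca$y,
                            z = ca$z, stringsAsFactors = FALSE), id = id)
}

#' Write a StructureModel as a PDB file
#'
#' @param model a [StructureModel-class]
#' @param file output path
#' @export
writeStructurePDB <- function(model, file) {
  a <- model@atoms
  bio3d::write.pdb(file = file, xyz = as.vector(t(as.matrix(
    a[, c("x", "y", "z")]))), resno = a$resno, resid = a$resname,
    chain = a$chain, elety = rep("CA", nrow(a)))
  invisible(file)
}

caXYZ <- function(model, chain, resno) {
  a <- model@atoms
  i <- which(a$chain == chain & a$resno == resno)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' C-alpha to C-alpha Euclidean distance
#'
#' @param model a [StructureModel-class]
#' @param a,b author residue numbers
#' @param chainA,chainB chain identifiers (default: the model's first chain)
#' @return distance in Angstrom
#' @examples
#' m <- makeStructure(20, "helix", seed = 1)
#' caDistance(m, 1, 2)
#' @export
caDistance <- function(model, a, b, chainA = NULL, chainB = NULL) {
  ch <- chains(model)
  if (is.null(chainA)) chainA <- ch[1]
  if (is.null(chainB)) chainB <- ch[1]
  pa <- caXYZ(model, chainA, a)
  pb <- caXYZ(model, chainB, b)
  stopIfNot(!is.null(pa), sprintf("residue %s/%d not in model", chainA, a))
  stopIfNot(!is.null(pb), sprintf("residue %s/%d not in model", chainB, b))
  sqrt(sum((pa - pb)^2))
}

#' Evaluate one crosslink constraint on a model
#'
#' For multi-chain homo-oligomers the reported distance is the minimum over
#' all chain assignments of the two residues, and the realization records
#' whether that minimum is intra- or inter-chain. Same-residue constraints
#' (posA == posB) can only be inter-subunit and are evaluated across
#' distinct chains only; on a single-chain model they are marked
#' "inter-only, unevaluable".
#'
#' @param model a [StructureModel-class]
#' @param posA,posB residue numbers of the linked lysines
#' @param policy a [constraintPolicy()]
#' @return list with `distance`, `class` ("satisfied", "ambiguous",
#'   "violated" or "unevaluable") and `realization` ("intra-chain",
#'   "inter-chain" or "inter-only, unevaluable")
#' @export
evaluateConstraint <- function(model, posA, posB,
                               policy = constraintPolicy()) {
  ch <- chains(model)
  sameResidue <- posA == posB
  best <- Inf
  bestReal <- NA_character_
  for (c1 in ch) for (c2 in ch) {
    if (sameResidue && c1 == c2) next
    if (sameResidue && c1 > c2) next
    p1 <- caXYZ(model, c1, posA)
    p2 <- caXYZ(model, c2, posB)
    if (is.null(p1) || is.null(p2)) next
    d <- sqrt(sum((p1 - p2)^2))
    if (d < best) {
      best <- d
      bestReal <- if (c1 == c2) "intra-chain" else "inter-chain"
    }
  }
  if (!is.finite(best)) {
    stopIfNot(sameResidue,
              sprintf("residues %d/%d not present in model '%s'", posA,
                      posB, model@id))
    return(list(distance = NA_real_, class = "unevaluable",
                realization = "inter-only, unevaluable"))
  }
  list(distance = best, class = classifyDistance(best, policy),
       realization = bestReal)
}

classifyDistance <- function(d, policy = constraintPolicy()) {
  ifelse(is.na(d), "unevaluable",
         ifelse(d <= policy$satisfied, "satisfied",
                ifelse(d > policy$violation, "violated", "ambiguous")))
}

#' Per-model constraint report
#'
#' Evaluates a whole constraint table on a model and tallies the classes.
#'
#' @param model a [StructureModel-class]
#' @param constraints constraint data.frame, see [xlConstraints()]
#' @param policy a [constraintPolicy()]
#' @return list with `model`, `table` (per-constraint distance, class,
#'   realization), `nSatisfied`, `nAmbiguous`, `nViolated`, `meanDistance`
#' @export
evaluateModel <- function(model, constraints,
                          policy = constraintPolicy()) {
  rows <- lapply(seq_len(nrow(constraints)), function(i)
    evaluateConstraint(model, constraints$posA[i], constraints$posB[i],
                       policy))
  tab <- cbind(constraints,
               distance = vapply(rows, `[[`, numeric(1), "distance"),
               class = vapply(rows, `[[`, character(1), "class"),
               realization = vapply(rows, `[[`, character(1),
                                    "realization"))
  evaluable <- tab$class != "unevaluable"
  list(model = model@id, table = tab,
       nSatisfied = sum(tab$class == "satisfied"),
       nAmbiguous = sum(tab$class == "ambiguous"),
       nViolated = sum(tab$class == "violated"),
       meanDistance = mean(tab$distance[evaluable]))
}

#' Rank candidate models against crosslink constraints and select best-fit
#'
#' Models with zero violating crosslinks rank above any model with
#' violations; within a tier, models satisfying more constraints rank
#' higher; remaining ties break by lower mean crosslink distance, then by
#' model id (deterministic). The top-ranked model is the selection.
#'
#' `models` may be a list of [StructureModel-class] objects (distances are
#' computed from coordinates) or a precomputed numeric distance matrix with
#' one row per constraint and one column per model (as printed in published
#' crosslink tables), in which case `constraints` may be omitted.
#'
#' @param models list of models, or constraints-by-models distance matrix
#' @param constraints constraint data.frame (ignored for matrix input)
#' @param policy a [constraintPolicy()]
#' @return list with `ranking` (data.frame: model, nSatisfied, nAmbiguous,
#'   nViolated, meanDistance, rank), `selected` (model id of the best fit),
#'   and `reports` (per-model constraint tables, for list input)
#' @examples
#' D <- monomerCandidateDistances()
#' rankModels(D[D$class == "inter-domain", grep("^model", names(D))])
#' @export
rankModels <- function(models, constraints = NULL,
                       policy = constraintPolicy()) {
  if (is.matrix(models) || is.data.frame(models)) {
    D <- as.matrix(models)
    ids <- colnames(D)
    if (is.null(ids)) ids <- paste0("model_", seq_len(ncol(D)))
    stats <- data.frame(
      model = ids,
      nSatisfied = colSums(D <= policy$satisfied, na.rm = TRUE),
      nAmbiguous = colSums(D > policy$satisfied & D <= policy$violation,
                           na.rm = TRUE),
      nViolated = colSums(D > policy$violation, na.rm = TRUE),
      meanDistance = colMeans(D, na.rm = TRUE), stringsAsFactors = FALSE)
    reports <- NULL
  } else {
    stopIfNot(length(models) >= 1, "at least one model is required")
    if (is.null(constraints) || !nrow(constraints)) {
      warning("no constraints: all models tied")
      ids <- vapply(models, modelId, character(1))
      stats <- data.frame(model = ids, nSatisfied = 0, nAmbiguous = 0,
                          nViolated = 0, meanDistance = NA_real_)
      reports <- NULL
    } else {
      reports <- lapply(models, evaluateModel, constraints = constraints,
                        policy = policy)
      stats <- do.call(rbind, lapply(reports, function(r)
        data.frame(model = r$model, nSatisfied = r$nSatisfied,
                   nAmbiguous = r$nAmbiguous, nViolated = r$nViolated,
                   meanDistance = r$meanDistance,
                   stringsAsFactors = FALSE)))
      names(reports) <- stats$model
    }
  }
  ord <- order(stats$nViolated > 0, -stats$nSatisfied, stats$meanDistance,
               stats$model)
  stats <- stats[ord, , drop = FALSE]
  stats$rank <- seq_len(nrow(stats))
  rownames(stats) <- NULL
  list(ranking = stats, selected = stats$model[1], reports = reports)
}

#' Domain map constructor and topology classification
#'
#' `domainMap` builds a named set of residue ranges; `classifyTopology`
#' assigns each crosslink a domain class (intra-domain / inter-domain, with
#' the domain names) and a subunit class: a same-to-same-residue crosslink
#' can only be inter-subunit ("inter-only"), anything else may be either
#' ("intra-possible"). Positions outside all domains are labelled
#' "linker/unassigned".
#'
#' @param domains data.frame with columns `domain`, `start`, `end`
#'   (non-overlapping ranges)
#' @return `domainMap`: validated data.frame of class "DomainMap"
#' @examples
#' dm <- dnajb6Domains()
#' classifyTopology(189, 189, dm)  # inter-only
#' @export
domainMap <- function(domains) {
  stopIfNot(all(c("domain", "start", "end") %in% names(domains)),
            "need columns domain, start, end")
  stopIfNot(all(domains$start <= domains$end), "ranges must be valid")
  d <- domains[order(domains$start), ]
  if (nrow(d) > 1L)
    stopIfNot(all(d$start[-1] > d$end[-nrow(d)]),
              "domain ranges must not overlap")
  structure(d, class = c("DomainMap", "data.frame"))
}

lookupDomain <- function(pos, dm) {
  hit <- which(dm$start <= pos & pos <= dm$end)
  if (length(hit)) dm$domain[hit[1]] else "linker/unassigned"
}

#' @rdname domainMap
#' @param posA,posB crosslinked residue numbers
#' @param dm a [domainMap()] (or plain data.frame of ranges)
#' @return `classifyTopology`: data.frame with `domainA`, `domainB`,
#'   `domainClass` and `subunitClass`
#' @export
classifyTopology <- function(posA, posB, dm) {
  stopIfNot(length(posA) == length(posB), "posA/posB length mismatch")
  dA <- vapply(posA, lookupDomain, character(1), dm = dm)
  dB <- vapply(posB, lookupDomain, character(1), dm = dm)
  data.frame(posA = posA, posB = posB, domainA = dA, domainB = dB,
             domainClass = ifelse(dA == dB & dA != "linker/unassigned",
                                  "intra-domain",
                                  ifelse(dA == "linker/unassigned" |
                                           dB == "linker/unassigned",
                                         "linker/unassigned",
                                         "inter-domain")),
             subunitClass = ifelse(posA == posB, "inter-only",
                                   "intra-possible"),
             stringsAsFactors = FALSE)
}

#' Export crosslink constraints as docking restraints
#'
#' Writes (a) a TSV of residue pairs with an upper distance bound equal to
#' the policy's satisfied maximum and (b) an ambiguous-distance-restraint
#' text block (one `assign` statement per constraint between the C-alpha
#' atoms of two chains, allowed range 0 .. upper bound) suitable for
#' information-driven docking.
#'
#' @param constraints constraint data.frame, see [xlConstraints()]
#' @param policy a [constraintPolicy()]
#' @param file base output path: `<file>.tsv` and `<file>.air` are written;
#'   NULL returns the text without writing
#' @param segidA,segidB segment/chain identifiers used in the assign
#'   statements
#' @return invisibly, a list with `tsv` (data.frame written) and `air`
#'   (character vector of assign statements)
#' @export
exportRestraints <- function(constraints, policy = constraintPolicy(),
                             file = NULL, segidA = "A", segidB = "B") {
  stopIfNot(!is.null(constraints) && nrow(constraints) > 0,
            "no constraints to export")
  tsv <- data.frame(posA = constraints$posA, posB = constraints$posB,
                    linker = constraints$linker,
                    upperBound = policy$satisfied)
  air <- sprintf(
    "assign (segid %s and resid %d and name CA) (segid %s and resid %d and name CA) %.1f %.1f 0.0",
    segidA, constraints$posA, segidB, constraints$posB, policy$satisfied,
    policy$satisfied)
  if (!is.null(file)) {
    write.table(tsv, paste0(file, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(air, paste0(file, ".air"))
  }
  invisible(list(tsv = tsv, air = air))
}
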