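# File-format boundaries: MGF peak lists, FASTA sequences, SAXS .dat
# curves, constraint/report TSVs. FASTA goes through Biostrings; MGF is a
# small hand-written reader/writer (the format is line-oriented
# TITLE/PEPMASS/CHARGE blocks).

#' Read protein sequences from a FASTA file
#'
#' @param file path to a FASTA file
#' @return named character vector of sequences
#' @export
readFastaSequences <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Construct a SpectrumRecord
#'
#' Peaks are sorted by m/z on ingestion.
#'
#' @param title scan title
#' @param pepmass precursor m/z
#' @param charge precursor charge, or NA
#' @param mz,intensity peak list
#' @return a [SpectrumRecord-class]
#' @export
spectrumRecord <- function(title, pepmass, charge = NA_integer_,
                           mz = numeric(), intensity = numeric()) {
  ord <- order(mz)
  new("SpectrumRecord", title = as.character(title),
      pepmass = as.numeric(pepmass), charge = as.integer(charge),
      mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]))
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS and CHARGE headers
#' and (m/z, intensity) peak lines. Charges written as "3+" are read as 3.
#'
#' @param file path to an MGF file
#' @return list of [SpectrumRecord-class] objects
#' @export
readMGF <- function(file) {
  lines <- readLines(file)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  stopIfNot(length(starts) == length(ends) && all(ends > starts),
            "malformed MGF: unmatched BEGIN IONS/END IONS")
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[hdr])
    vals <- sub("^[^=]*=", "", block[hdr])
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)]
             else paste0("scan_", i)
    pepmass <- if ("PEPMASS" %in% keys)
      as.numeric(strsplit(vals[match("PEPMASS", keys)], "\\s+")[[1]][1])
      else NA_real_
    charge <- if ("CHARGE" %in% keys)
      as.integer(sub("\\+$", "", vals[match("CHARGE", keys)]))
      else NA_integer_
    pk <- block[!hdr & nzchar(trimws(block))]
    mzi <- if (length(pk)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), as.numeric))
      m
    } else matrix(numeric(), ncol = 2)
    spectrumRecord(title, pepmass, charge, mzi[, 1], mzi[, 2])
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [SpectrumRecord-class] objects
#' @param file output path
#' @return the path, invisibly
#' @export
writeMGF <- function(spectra, file) {
  if (is(spectra, "SpectrumRecord")) spectra <- list(spectra)
  con <- file(file, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS", paste0("TITLE=", s@title),
                 sprintf("PEPMASS=%.6f", s@pepmass),
                 if (!is.na(s@charge)) sprintf("CHARGE=%d+", s@charge)),
               con)
    if (length(s@mz))
      writeLines(sprintf("%.6f %.2f", s@mz, s@intensity), con)
    writeLines("END IONS", con)
  }
  invisible(file)
}

#' Read and write crosslink constraint tables
#'
#' A constraint table is a data.frame with one row per detected crosslink:
#' columns `posA`, `posB` (1-based residue numbers in the protein), `linker`
#' and the derived `sameResidue` flag; an optional `evidence` column carries
#' spectrum identifiers.
#'
#' @param posA,posB residue numbers
#' @param linker linker name(s)
#' @param evidence optional character vector of supporting spectrum ids
#' @return a constraint data.frame
#' @examples
#' xlConstraints(c(189, 232), c(189, 232))
#' @export
xlConstraints <- function(posA, posB, linker = "BS3", evidence = NA) {
  stopIfNot(length(posA) == length(posB),
            "posA and posB must have equal length")
  n <- length(posA)
  data.frame(posA = as.integer(posA), posB = as.integer(posB),
             linker = rep_len(linker, n),
             sameResidue = as.integer(posA) == as.integer(posB),
             evidence = rep_len(evidence, n), stringsAsFactors = FALSE)
}

#' @rdname xlConstraints
#' @param file path to a TSV with columns posA, posB and optionally linker,
#'   evidence
#' @export
readConstraints <- function(file) {
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  stopIfNot(all(c("posA", "posB") %in% names(tab)),
            "constraint TSV needs columns posA and posB")
  xlConstraints(tab$posA, tab$posB,
                linker = if ("linker" %in% names(tab)) tab$linker else "BS3",
                evidence = if ("evidence" %in% names(tab)) tab$evidence
                           else NA)
}

#' @rdname xlConstraints
#' @param constraints a constraint data.frame
#' @export
writeConstraints <- function(constraints, file) {
  write.table(constraints, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Read a 3-column SAXS curve
#'
#' Whitespace-separated columns q, I and (optionally) sigma; lines starting
#' with '#' are comments. The q unit is taken from a header comment
#' containing "1/nm", "nm^-1", "1/A" or "A^-1", or from the `qUnit`
#' argument.
#'
#' @param file path to the .dat file
#' @param qUnit "A^-1" or "nm^-1"; overrides any header declaration
#' @return a [SAXSCurve-class]
#' @export
readSAXSCurve <- function(file, qUnit = NULL) {
  lines <- readLines(file)
  com <- lines[startsWith(trimws(lines), "#")]
  if (is.null(qUnit)) {
    hdr <- paste(com, collapse = " ")
    qUnit <- if (grepl("1/nm|nm\\^-1", hdr)) "nm^-1"
             else if (grepl("1/A|A\\^-1", hdr)) "A^-1"
             else "A^-1"
  }
  dat <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "\\s+"), as.numeric))
  stopIfNot(ncol(m) >= 2, "SAXS file needs at least q and I columns")
  saxsCurve(m[, 1], m[, 2],
            sigma = if (ncol(m) >= 3) m[, 3] else NULL, qUnit = qUnit)
}

#' Write a SAXS curve as 3-column text
#'
#' @param curve a [SAXSCurve-class]
#' @param file output path
#' @export
writeSAXSCurve <- function(curve, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# q (%s)  I  sigma", curve@qUnit), con)
  writeLines(sprintf("%.8g %.8g %.8g", curve@q, curve@I, curve@sigma), con)
  invisible(file)
}
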