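# Average (not monoisotopic) residue masses in Da; SDS-PAGE-scale theoretical
# weights are conventionally computed with average masses.
AVG_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.01524

#' Theoretical average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, reported in kDa.  Additive:
#' \code{molecularWeight(paste0(a, b)) == molecularWeight(a) +
#' molecularWeight(b) - 0.01801524}.  The empty chain returns the mass of
#' water alone.
#'
#' @param aa_seq Protein sequence (character or \code{AAString}) over the 20
#'   standard residues; \code{X} and other symbols raise an alphabet error.
#' @return Mass in kDa (not rounded; round to 2 decimals for display).
#' @examples
#' round(1000 * molecularWeight("G"), 2)  # 75.07 Da
#' @export
molecularWeight <- function(aa_seq) {
  seq <- toupper(as.character(aa_seq))
  if (nchar(seq) == 0L) return(WATER_MASS / 1000)
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(res), names(AVG_RESIDUE_MASS))
  if (length(bad))
    pfStop("alphabetError", "non-standard residue(s): %s",
           paste(bad, collapse = ","))
  (sum(AVG_RESIDUE_MASS[res]) + WATER_MASS) / 1000
}

#' Map an antibody antigen peptide onto an isoform catalog
#'
#' Performs an exact substring search of the antigen against every isoform
#' sequence and records all occurrences with 1-based residue coordinates.
#' An isoform is "detected" by the probe iff it contains the antigen.
#'
#' @param antigen Antigen peptide sequence (non-empty character).
#' @param catalog An \code{\linkS4class{IsoformCatalog}}.
#' @param name Probe name (default \code{"probe"}).
#' @return An \code{\linkS4class{EpitopeProbe}}.
#' @importFrom Biostrings matchPattern
#' @export
mapEpitope <- function(antigen, catalog, name = "probe") {
  antigen <- toupper(as.character(antigen))
  if (!nzchar(antigen)) pfStop("configError", "antigen must be non-empty")
  rows <- list()
  for (iso in isoformNames(catalog)) {
    m <- Biostrings::matchPattern(antigen, catalog@isoforms[[iso]])
    if (length(m))
      rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
        isoform = iso, start = BiocGenerics::start(m),
        end = BiocGenerics::end(m))
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(isoform = character(0), start = integer(0),
                         end = integer(0))
  methods::new("EpitopeProbe", name = name, antigenSeq = antigen,
               matches = matches)
}

#' Probe-by-isoform detection specificity matrix
#'
#' @param probes A list of \code{\linkS4class{EpitopeProbe}} objects (row
#'   order preserved).
#' @param catalog The \code{\linkS4class{IsoformCatalog}} defining the
#'   column order.
#' @return A binary integer matrix, rows = probes, columns = isoforms;
#'   cell 1 iff the probe's antigen occurs in the isoform.
#' @export
specificityMatrix <- function(probes, catalog) {
  isos <- isoformNames(catalog)
  m <- matrix(0L, nrow = length(probes), ncol = length(isos),
              dimnames = list(vapply(probes, probeName, ""), isos))
  for (i in seq_along(probes))
    m[i, unique(probeMatches(probes[[i]])$isoform)] <- 1L
  m
}

# Identity substitution matrix over the residues present in the inputs.
aaSubstMatrix <- function(match, mismatch, letters) {
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Compare two allele protein sequences
#'
#' Globally aligns the alternative sequence to the reference (match +1,
#' mismatch -1, affine gaps) and classifies aligned columns into amino acid
#' substitutions, deletions (residues present in the reference but absent
#' from the alternative), and insertions.  Consecutive gap columns are
#' merged into single events.  All positions are 1-based coordinates in the
#' reference frame; an insertion's position is the reference residue before
#' which the inserted residues occur (length(ref)+1 for a C-terminal
#' insertion).
#'
#' @param ref_seq,alt_seq Non-empty protein sequences.
#' @param match,mismatch,gapOpening,gapExtension Alignment parameters
#'   (defaults +1/-1/5/1); gap penalties are positive costs.
#' @return A list of class \code{AlleleDiff} with data frame components
#'   \code{substitutions} (\code{pos}, \code{ref}, \code{alt}),
#'   \code{deletions} (\code{pos}, \code{ref}) and \code{insertions}
#'   (\code{pos}, \code{alt}).
#' @examples
#' compareAlleles("MKLV", "MKIV")$substitutions
#' @importFrom Biostrings pairwiseAlignment pattern subject
#' @export
compareAlleles <- function(ref_seq, alt_seq, match = 1, mismatch = -1,
                           gapOpening = 5, gapExtension = 1) {
  ref_seq <- checkProtein(ref_seq, "ref_seq")
  alt_seq <- checkProtein(alt_seq, "alt_seq")
  if (!nzchar(ref_seq) || !nzchar(alt_seq))
    pfStop("configError", "allele sequences must be non-empty")
  letters <- unique(c(strsplit(ref_seq, "")[[1L]], strsplit(alt_seq, "")[[1L]]))
  aln <- Biostrings::pairwiseAlignment(
    alt_seq, ref_seq, type = "global",
    substitutionMatrix = aaSubstMatrix(match, mismatch, letters),
    gapOpening = gapOpening, gapExtension = gapExtension)
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
  r <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
  subs <- list(); dels <- list(); ins <- list()
  rpos <- 0L
  i <- 1L
  while (i <= length(r)) {
    if (r[i] != "-" && a[i] != "-") {
      rpos <- rpos + 1L
      if (r[i] != a[i])
        subs[[length(subs) + 1L]] <- list(pos = rpos, ref = r[i], alt = a[i])
      i <- i + 1L
    } else if (a[i] == "-") {           # gap in alt: deletion of ref residues
      j <- i
      while (j <= length(r) && a[j] == "-" && r[j] != "-") j <- j + 1L
      dels[[length(dels) + 1L]] <- list(pos = rpos + 1L,
                                        ref = paste(r[i:(j - 1L)], collapse = ""))
      rpos <- rpos + (j - i)
      i <- j
    } else {                            # gap in ref: insertion in alt
      j <- i
      while (j <= length(r) && r[j] == "-" && a[j] != "-") j <- j + 1L
      ins[[length(ins) + 1L]] <- list(pos = rpos + 1L,
                                      alt = paste(a[i:(j - 1L)], collapse = ""))
      i <- j
    }
  }
  asDf <- function(lst, col) {
    if (!length(lst)) {
      out <- data.frame(pos = integer(0))
      for (cc in col) out[[cc]] <- character(0)
      return(out)
    }
    out <- data.frame(pos = vapply(lst, function(x) as.integer(x$pos),
                                   integer(1)))
    for (cc in col) out[[cc]] <- vapply(lst, `[[`, "", cc)
    out
  }
  structure(list(substitutions = asDf(subs, c("ref", "alt")),
                 deletions = asDf(dels, "ref"),
                 insertions = asDf(ins, "alt")),
            class = "AlleleDiff")
}

#' @export
print.AlleleDiff <- function(x, ...) {
  cat(sprintf("AlleleDiff: %d substitution(s), %d deletion(s), %d insertion(s)\n",
              nrow(x$substitutions), nrow(x$deletions), nrow(x$insertions)))
  invisible(x)
}

#' Detect a variant-induced 5' extension of the coding ORF
#'
#' Compares the coding ORFs of two transcript sequences (e.g. the same
#' transcript from two alleles).  If the alternative ORF initiates 5' of the
#' reference ORF while both translations share a stop-anchored C-terminal
#' end (assessed by global alignment), the extension is reported: the count
#' of extra N-terminal residues and how many of those are novel, i.e. do
#' not match any other catalog isoform at the C-terminally aligned position.
#'
#' @param ref_mrna,alt_mrna Transcript DNA sequences.
#' @param catalog Optional \code{\linkS4class{IsoformCatalog}} used to score
#'   novelty of the extension residues; with \code{NULL} all extension
#'   residues count as novel.
#' @param minCodons Passed to \code{\link{findOrfs}}.
#' @param variant Free-text description stored in the report.
#' @return \code{NULL} when the coding ORFs are equivalent (no 5'
#'   extension); otherwise a list of class \code{OrfExtensionReport} with
#'   \code{variant_description}, \code{ref_orf_start}, \code{alt_orf_start}
#'   (1-based transcript positions of the A of the initiating ATG),
#'   \code{extra_nterm_aa} and \code{novel_nterm_aa}.
#' @export
detectOrfExtension <- function(ref_mrna, alt_mrna, catalog = NULL,
                               minCodons = 1L, variant = "") {
  refOrf <- selectCodingOrf(findOrfs(ref_mrna, minCodons))
  altOrf <- selectCodingOrf(findOrfs(alt_mrna, minCodons))
  refProt <- translateOrf(refOrf)
  altProt <- translateOrf(altOrf)
  if (identical(refProt, altProt)) return(NULL)
  if (nchar(altProt) <= nchar(refProt)) return(NULL)
  letters <- unique(c(strsplit(refProt, "")[[1L]], strsplit(altProt, "")[[1L]]))
  # global in the reference, local in the extended protein: the reference
  # must be consumed entirely, while the alternative may overhang at its
  # N-terminus (the candidate extension)
  aln <- Biostrings::pairwiseAlignment(
    refProt, altProt, type = "global-local",
    substitutionMatrix = aaSubstMatrix(1, -1, letters),
    gapOpening = 5, gapExtension = 1)
  sa <- Biostrings::subject(aln)
  # both ORFs must share the stop-anchored 3' end
  if (BiocGenerics::end(sa) != nchar(altProt)) return(NULL)
  extra <- BiocGenerics::start(sa) - 1L
  if (extra <= 0L) return(NULL)
  novel <- extra
  if (!is.null(catalog)) {
    others <- isoformNames(catalog)[as.character(isoformSeqs(catalog)) !=
                                      altProt]
    LA <- nchar(altProt)
    matched <- logical(extra)
    for (o in others) {
      oseq <- as.character(isoformSeqs(catalog)[[o]])
      off <- LA - nchar(oseq)
      j <- seq_len(extra)
      p <- j - off
      ok <- p >= 1L & p <= nchar(oseq)
      if (any(ok))
        matched[j[ok]] <- matched[j[ok]] |
          substring(altProt, j[ok], j[ok]) == substring(oseq, p[ok], p[ok])
    }
    novel <- sum(!matched)
  }
  structure(list(variant_description = variant,
                 ref_orf_start = refOrf$nt_start,
                 alt_orf_start = altOrf$nt_start,
                 extra_nterm_aa = extra,
                 novel_nterm_aa = novel),
            class = "OrfExtensionReport")
}

#' @export
print.OrfExtensionReport <- function(x, ...) {
  cat(sprintf(
    "OrfExtensionReport: ORF start %d -> %d; +%d N-terminal aa (%d novel)\n",
    x$ref_orf_start, x$alt_orf_start, x$extra_nterm_aa, x$novel_nterm_aa))
  invisible(x)
}
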