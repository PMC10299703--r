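#' In-silico proteolytic digestion
#'
#' Trypsin cleaves C-terminal to K or R except when the next residue is P;
#' chymotrypsin (high-specificity rule) cleaves C-terminal to F, W or Y
#' except before P (set \code{extended = TRUE} to also cleave after L and
#' M).  All peptides with 0 to \code{maxMissed} missed cleavages are
#' returned with 1-based inclusive coordinates on the parent sequence; the
#' 0-missed peptides partition the sequence.
#'
#' @param aa_seq Non-empty protein sequence.
#' @param enzyme \code{"trypsin"} or \code{"chymotrypsin"}.
#' @param maxMissed Maximum number of missed cleavages (default 2).
#' @param extended Chymotrypsin only: also cleave after L/M (default FALSE).
#' @param parent Optional parent isoform name stored with each peptide.
#' @return A \code{data.frame} with columns \code{seq}, \code{parent},
#'   \code{start}, \code{end}, \code{missed}.
#' @examples
#' digestProtein("AKRP", "trypsin", maxMissed = 0)$seq  # "AK", "RP"
#' @export
digestProtein <- function(aa_seq, enzyme = c("trypsin", "chymotrypsin"),
                          maxMissed = 2L, extended = FALSE, parent = NA) {
  enzyme <- match.arg(enzyme)
  seq <- toupper(as.character(aa_seq))
  if (!nzchar(seq)) pfStop("configError", "sequence must be non-empty")
  if (maxMissed < 0L) pfStop("configError", "maxMissed must be >= 0")
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  cleaveAfter <- switch(enzyme,
    trypsin = c("K", "R"),
    chymotrypsin = if (extended) c("F", "W", "Y", "L", "M")
                   else c("F", "W", "Y"))
  sites <- which(res[-n] %in% cleaveAfter & res[-1L] != "P")
  bounds <- c(0L, sites, n)            # peptide i spans bounds[i]+1..bounds[i+1]
  nb <- length(bounds)
  out <- list()
  for (m in 0:maxMissed) {
    i <- seq_len(nb - 1L - m)
    if (!length(i)) break
    st <- bounds[i] + 1L
    en <- bounds[i + 1L + m]
    out[[m + 1L]] <- data.frame(
      seq = substring(seq, st, en), parent = parent,
      start = st, end = en, missed = m, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify peptides as isoform-discriminating or shared
#'
#' A peptide's carriers are all catalog isoforms that contain it as an
#' exact substring.  Status is \code{unique} (one carrier),
#' \code{class_specific} (several carriers, all in one N-terminal class) or
#' \code{shared} (carriers span classes).  A peptide found in no isoform is
#' reported as \code{unmapped}; peptides containing \code{X} are dropped,
#' since ambiguous residues cannot support attribution.
#'
#' @param peptides A \code{data.frame} from \code{\link{digestProtein}} (or
#'   any data frame with a \code{seq} column), or a character vector.
#' @param catalog A grouped \code{\linkS4class{IsoformCatalog}} (see
#'   \code{\link{groupNtermClasses}}).
#' @return A \code{data.frame} with columns \code{seq}, \code{status},
#'   \code{n_carriers} and \code{carriers} (comma-separated isoform names).
#' @export
classifyPeptides <- function(peptides, catalog) {
  seqs <- if (is.character(peptides)) peptides else peptides$seq
  seqs <- unique(seqs[!grepl("X", seqs, fixed = TRUE)])
  cls <- ntermClass(catalog)
  if (all(is.na(cls)))
    pfStop("configError",
           "catalog must be grouped with groupNtermClasses() first")
  isoSeq <- as.character(isoformSeqs(catalog))
  rows <- lapply(seqs, function(p) {
    carriers <- names(isoSeq)[vapply(isoSeq, function(s)
      grepl(p, s, fixed = TRUE), logical(1))]
    status <- if (length(carriers) == 0L) "unmapped"
      else if (length(carriers) == 1L) "unique"
      else if (length(unique(cls[carriers])) == 1L) "class_specific"
      else "shared"
    data.frame(seq = p, status = status, n_carriers = length(carriers),
               carriers = paste(carriers, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter peptides to an LC-MS/MS-observable length window
#'
#' @param peptides Output of \code{\link{digestProtein}}.
#' @param minLen,maxLen Inclusive residue-length bounds (defaults 6 and 40,
#'   emulating typical LC-MS/MS detectability).
#' @return The filtered \code{data.frame}.
#' @export
observablePeptides <- function(peptides, minLen = 6L, maxLen = 40L) {
  len <- nchar(peptides$seq)
  peptides[len >= minLen & len <= maxLen, , drop = FALSE]
}
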