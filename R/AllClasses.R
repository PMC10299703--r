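#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Catalog of distinct protein isoforms encoded by a transcript set
#'
#' An \code{IsoformCatalog} holds the distinct protein products obtained by
#' splicing each transcript model, selecting its coding ORF, and collapsing
#' identical translations.  Isoforms are named \code{P1}, \code{P2}, ... in
#' order of decreasing amino acid length (ties broken by first appearance in
#' the transcript input).  After \code{\link{groupNtermClasses}} the catalog
#' also records, for each isoform, its N-terminal class and (where the full
#' sequence is a suffix of a longer isoform starting at an internal
#' methionine) its nesting parent and 1-based start residue in that parent.
#'
#' @slot isoforms An \code{AAStringSet} of distinct isoform sequences, named.
#' @slot info A \code{DataFrame} with one row per isoform: \code{name},
#'   \code{length}, \code{ntermClass}, \code{nestedIn}, \code{nestedAt}.
#' @slot sourceTranscripts Named \code{list} mapping isoform name to the
#'   character vector of transcript ids that encode it.
#' @slot transcriptMap Named character vector mapping transcript id to
#'   isoform name (total over transcripts that contained a coding ORF).
#' @slot orfTable A \code{DataFrame} with one row per mapped transcript:
#'   \code{transcript}, \code{nt_start}, \code{nt_end} (1-based, on the
#'   spliced transcript), \code{isoform}.
#' @slot nesting A \code{DataFrame} of all nesting pairs (\code{child},
#'   \code{parent}, \code{start}); filled by \code{\link{groupNtermClasses}}.
#' @slot skipped Character vector of transcript ids that yielded no ORF.
#'
#' @seealso \code{\link{buildCatalog}}, \code{\link{groupNtermClasses}},
#'   \code{\link{isoformSeqs}}
#' @exportClass IsoformCatalog
setClass("IsoformCatalog",
  representation(
    isoforms = "AAStringSet",
    info = "DataFrame",
    sourceTranscripts = "list",
    transcriptMap = "character",
    orfTable = "DataFrame",
    nesting = "DataFrame",
    skipped = "character"
  )
)

setValidity("IsoformCatalog", function(object) {
  msgs <- character(0)
  seqs <- as.character(object@isoforms)
  if (anyDuplicated(seqs))
    msgs <- c(msgs, "isoform sequences must be pairwise distinct")
  if (!identical(names(object@isoforms), object@info$name))
    msgs <- c(msgs, "info rows must parallel isoform names")
  if (length(object@transcriptMap) &&
      !all(object@transcriptMap %in% names(object@isoforms)))
    msgs <- c(msgs, "transcriptMap values must be isoform names")
  if (!all(names(object@sourceTranscripts) %in% names(object@isoforms)))
    msgs <- c(msgs, "sourceTranscripts names must be isoform names")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn IsoformCatalog Number of distinct isoforms.
#' @param object,x An \code{IsoformCatalog}.
#' @export
nIsoforms <- function(x) length(x@isoforms)

#' Accessors for IsoformCatalog
#'
#' @param x An \code{IsoformCatalog}.
#' @return \code{isoformSeqs}: the \code{AAStringSet} of isoform sequences;
#'   \code{isoformNames}: their names; \code{isoformInfo}: the per-isoform
#'   \code{DataFrame}; \code{transcriptMap}: the transcript-to-isoform map;
#'   \code{ntermClass}: named character of class labels; \code{nestingPairs}:
#'   the \code{DataFrame} of all (child, parent, start) nesting relations.
#' @export
isoformSeqs <- function(x) x@isoforms

#' @rdname isoformSeqs
#' @export
isoformNames <- function(x) names(x@isoforms)

#' @rdname isoformSeqs
#' @export
isoformInfo <- function(x) x@info

#' @rdname isoformSeqs
#' @export
transcriptMap <- function(x) x@transcriptMap

#' @rdname isoformSeqs
#' @export
ntermClass <- function(x) stats::setNames(x@info$ntermClass, x@info$name)

#' @rdname isoformSeqs
#' @export
nestingPairs <- function(x) x@nesting

setMethod("show", "IsoformCatalog", function(object) {
  cat("IsoformCatalog with", nIsoforms(object), "isoform(s) from",
      length(object@transcriptMap), "transcript(s)\n")
  info <- object@info
  for (i in seq_len(nrow(info))) {
    nested <- if (!is.na(info$nestedIn[i]))
      sprintf(" nested in %s at M%d", info$nestedIn[i], info$nestedAt[i])
    else ""
    cat(sprintf("  %-4s %5d aa  class %-3s%s\n", info$name[i], info$length[i],
                ifelse(is.na(info$ntermClass[i]), "-", info$ntermClass[i]),
                nested))
  }
  if (length(object@skipped))
    cat("  skipped (no ORF):", paste(object@skipped, collapse = ", "), "\n")
})

#' Antibody antigen probe mapped onto an isoform catalog
#'
#' Records the exact-substring occurrences of an antigen peptide in each
#' isoform of a catalog.  An isoform is considered detectable by the probe
#' if and only if it contains the antigen sequence.
#'
#' @slot name Probe name.
#' @slot antigenSeq The antigen peptide sequence.
#' @slot matches \code{DataFrame} with columns \code{isoform}, \code{start},
#'   \code{end} (1-based inclusive residue coordinates of each occurrence).
#'
#' @seealso \code{\link{mapEpitope}}, \code{\link{specificityMatrix}}
#' @exportClass EpitopeProbe
setClass("EpitopeProbe",
  representation(name = "character", antigenSeq = "character",
                 matches = "DataFrame")
)

setValidity("EpitopeProbe", function(object) {
  if (!nzchar(object@antigenSeq)) return("antigen sequence must be non-empty")
  TRUE
})

setMethod("show", "EpitopeProbe", function(object) {
  hit <- unique(object@matches$isoform)
  cat(sprintf("EpitopeProbe %s (%d aa): detects %s\n", object@name,
              nchar(object@antigenSeq),
              if (length(hit)) paste(hit, collapse = ", ") else "<none>"))
})

#' @rdname mapEpitope
#' @param probe An \code{EpitopeProbe}.
#' @export
probeMatches <- function(probe) probe@matches

#' @rdname mapEpitope
#' @export
probeName <- function(probe) probe@name

#' @rdname mapEpitope
#' @export
antigenSeq <- function(probe) probe@antigenSeq
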