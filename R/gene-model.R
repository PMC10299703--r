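#' Splice a transcript model into its mature mRNA sequence
#'
#' Concatenates the exon subsequences of a transcript in 5' to 3' transcript
#' orientation.  Exons are given as a \code{GRanges} (1-based, closed
#' intervals) on a genome supplied as a named \code{DNAStringSet}; for minus
#' strand transcripts the concatenated sequence is reverse-complemented.
#'
#' @param genome A named \code{DNAStringSet} (or single named \code{DNAString}
#'   via a one-element set) holding the genomic sequence(s).
#' @param exons A \code{GRanges} of the transcript's exons.  All exons must
#'   share one seqname (present in \code{names(genome)}) and one strand.
#' @return A \code{DNAString}: the spliced mRNA.  Its length equals the sum
#'   of the exon widths.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr = "ATGCCC"))
#' ex <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 6), strand = "+")
#' spliceTranscript(g, ex)
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq xscat
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importFrom IRanges IRanges
#' @export
spliceTranscript <- function(genome, exons) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  sn <- unique(as.character(GenomicRanges::seqnames(exons)))
  if (length(sn) != 1L)
    pfStop("coordinateError", "exons must lie on a single sequence")
  if (!sn %in% names(genome))
    pfStop("coordinateError", "genome sequence '%s' not found", sn)
  gseq <- genome[[sn]]
  st <- unique(as.character(GenomicRanges::strand(exons)))
  st <- setdiff(st, "*")
  if (length(st) > 1L)
    pfStop("coordinateError", "exons must share one strand")
  if (length(st) == 0L) st <- "+"
  s <- GenomicRanges::start(exons); e <- GenomicRanges::end(exons)
  if (any(s < 1L) || any(e > length(gseq)))
    pfStop("coordinateError", "exon out of range for sequence '%s'", sn)
  o <- order(s)
  s <- s[o]; e <- e[o]
  if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
    pfStop("coordinateError", "exons overlap")
  gchar <- as.character(gseq)
  mrna <- Biostrings::DNAString(paste(substring(gchar, s, e), collapse = ""))
  checkDna(mrna, "spliced transcript")
  if (st == "-") mrna <- Biostrings::reverseComplement(mrna)
  mrna
}

#' Enumerate AUG-initiated open reading frames on an mRNA
#'
#' Finds every maximal ORF: for each stop codon in each frame, the 5'-most
#' in-frame ATG with no intervening stop defines one ORF, which runs from
#' the A of that ATG through the last base of the stop codon.  Codons
#' containing N never match ATG or a stop codon, so ambiguous bases cannot
#' invent starts or stops.
#'
#' @param mrna A \code{DNAString} or character DNA sequence over
#'   \{A,C,G,T,N\}.
#' @param minCodons Minimum protein length (codons, excluding the stop) for
#'   an ORF to be reported.  The enumerator default is 1; catalog building
#'   applies a stricter default (see \code{\link{buildCatalog}}).
#' @return A \code{DataFrame} with columns \code{nt_start}, \code{nt_end}
#'   (1-based, inclusive of the stop codon), \code{naa} (protein length) and
#'   \code{nt_seq}, sorted by decreasing ORF length then increasing
#'   \code{nt_start}.  Zero rows if no ORF exists.
#' @examples
#' findOrfs("ATGAAATAA")
#' @export
findOrfs <- function(mrna, minCodons = 1L) {
  seq <- checkDna(mrna, "mRNA")
  n <- nchar(seq)
  hits <- function(pat) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  atg <- hits("ATG")
  stp <- sort(c(hits("TAA"), hits("TAG"), hits("TGA")))
  out <- list()
  for (f in 0:2) {
    sf <- stp[(stp - 1L) %% 3L == f]
    af <- atg[(atg - 1L) %% 3L == f]
    if (!length(sf) || !length(af)) next
    prev <- 0L
    for (s in sf) {
      cand <- af[af > prev & af <= s - 3L]
      if (length(cand)) {
        a <- cand[1L]
        naa <- (s - a) %/% 3L
        if (naa >= minCodons)
          out[[length(out) + 1L]] <- c(a, s + 2L, naa)
      }
      prev <- s
    }
  }
  if (!length(out))
    return(S4Vectors::DataFrame(nt_start = integer(0), nt_end = integer(0),
                                naa = integer(0), nt_seq = character(0)))
  m <- do.call(rbind, out)
  df <- S4Vectors::DataFrame(nt_start = m[, 1L], nt_end = m[, 2L],
                             naa = m[, 3L])
  df$nt_seq <- substring(seq, df$nt_start, df$nt_end)
  df <- df[order(-(df$nt_end - df$nt_start), df$nt_start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select the coding ORF from an enumeration
#'
#' Returns the longest ORF; ties are broken by the smallest (5'-most) start
#' position.
#'
#' @param orfs A \code{DataFrame} as returned by \code{\link{findOrfs}}.
#' @return A one-row \code{DataFrame}.
#' @export
selectCodingOrf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L)
    pfStop("noOrfError", "no open reading frame available")
  len <- orfs$nt_end - orfs$nt_start + 1L
  best <- which(len == max(len))
  best <- best[which.min(orfs$nt_start[best])]
  orfs[best, , drop = FALSE]
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code translation, excluding the terminal stop codon.
#' Codons containing N are translated to \code{X}.
#'
#' @param orf A one-row \code{DataFrame} from \code{\link{selectCodingOrf}},
#'   or a character/\code{DNAString} ORF sequence (must begin with ATG, end
#'   with a stop codon, have length divisible by 3, and contain no internal
#'   in-frame stop).
#' @return The protein sequence as a character scalar (no stop symbol).
#' @examples
#' translateOrf("ATGAAATAA")
#' @importFrom Biostrings translate
#' @export
translateOrf <- function(orf) {
  seq <- if (is.character(orf) || methods::is(orf, "DNAString"))
    as.character(orf) else orf$nt_seq
  seq <- checkDna(seq, "ORF")
  n <- nchar(seq)
  if (n %% 3L != 0L || n < 6L)
    pfStop("malformedOrfError", "ORF length must be a positive multiple of 3")
  cod <- codonsFrom(seq, 1L)
  if (cod[1L] != "ATG")
    pfStop("malformedOrfError", "ORF must begin with ATG")
  if (!cod[length(cod)] %in% STOP_CODONS)
    pfStop("malformedOrfError", "ORF must end with a stop codon")
  if (any(cod[-length(cod)] %in% STOP_CODONS))
    pfStop("malformedOrfError", "ORF contains an internal in-frame stop")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Build a catalog of distinct protein isoforms from transcript models
#'
#' Splices each transcript, enumerates its AUG-initiated ORFs, selects the
#' coding (longest) ORF, translates it, and collapses identical translations
#' into one isoform.  Isoforms are named by decreasing length, then input
#' order; transcripts with no ORF passing \code{minCodons} are recorded in
#' the skipped list.
#'
#' @param transcripts A named \code{GRangesList} (or named list of
#'   \code{GRanges}) of exon models, one element per transcript.
#' @param genome A named \code{DNAStringSet}.
#' @param minCodons Minimum protein length for a coding ORF (default 30
#'   codons, suppressing spurious micro-ORFs).
#' @param aliases Optional named character vector renaming catalog isoforms
#'   (e.g. \code{c(P2 = "P1alpha")}); names are the automatically assigned
#'   labels.
#' @return An \code{\linkS4class{IsoformCatalog}} (N-terminal classes not
#'   yet assigned; see \code{\link{groupNtermClasses}}).
#' @importFrom Biostrings AAStringSet
#' @export
buildCatalog <- function(transcripts, genome, minCodons = 30L,
                         aliases = NULL) {
  ids <- names(transcripts)
  if (is.null(ids) || length(ids) == 0L)
    pfStop("configError", "transcripts must be a non-empty named list")
  prot <- character(0); skipped <- character(0)
  orfRows <- list()
  for (id in ids) {
    mrna <- spliceTranscript(genome, transcripts[[id]])
    orfs <- findOrfs(mrna, minCodons = minCodons)
    if (nrow(orfs) == 0L) { skipped <- c(skipped, id); next }
    orf <- selectCodingOrf(orfs)
    prot[[id]] <- translateOrf(orf)
    orfRows[[id]] <- c(orf$nt_start, orf$nt_end)
  }
  if (!length(prot))
    pfStop("noOrfError", "no transcript yielded a coding ORF")
  uniq <- unique(unname(prot))
  ord <- order(-nchar(uniq), match(uniq, unname(prot)))
  uniq <- uniq[ord]
  nm <- paste0("P", seq_along(uniq))
  if (!is.null(aliases)) {
    hit <- intersect(names(aliases), nm)
    nm[match(hit, nm)] <- unname(aliases[hit])
  }
  isoOf <- stats::setNames(nm[match(unname(prot), uniq)], names(prot))
  src <- split(names(isoOf), factor(unname(isoOf), levels = nm))
  src <- lapply(src, as.character)
  orfm <- do.call(rbind, orfRows[names(isoOf)])
  methods::new("IsoformCatalog",
    isoforms = Biostrings::AAStringSet(stats::setNames(uniq, nm)),
    info = S4Vectors::DataFrame(name = nm, length = nchar(uniq),
                                ntermClass = NA_character_,
                                nestedIn = NA_character_,
                                nestedAt = NA_integer_),
    sourceTranscripts = src,
    transcriptMap = isoOf,
    orfTable = S4Vectors::DataFrame(transcript = names(isoOf),
                                    nt_start = orfm[, 1L],
                                    nt_end = orfm[, 2L],
                                    isoform = unname(isoOf)),
    nesting = S4Vectors::DataFrame(child = character(0),
                                   parent = character(0),
                                   start = integer(0)),
    skipped = skipped)
}

#' Group catalog isoforms into N-terminal classes and record nesting
#'
#' Isoform B is nested in isoform A when B's full sequence equals a suffix
#' of A beginning at an internal methionine; B then differs from A only in
#' N-terminal extent.  N-terminal classes are the connected components of
#' the nesting relation: a chain of nested starts forms one class, while
#' isoforms with disjoint N-termini (even if they share a common C-terminal
#' region) fall in different classes.  Classes are labelled \code{C1},
#' \code{C2}, ... by decreasing length of their longest member.  For a
#' multiply nested isoform, \code{nestedIn} records the longest parent.
#'
#' @param catalog An \code{\linkS4class{IsoformCatalog}}.
#' @return The catalog with \code{ntermClass}, \code{nestedIn},
#'   \code{nestedAt} filled and all nesting pairs in
#'   \code{\link{nestingPairs}}.
#' @export
groupNtermClasses <- function(catalog) {
  seqs <- as.character(catalog@isoforms)
  nm <- names(seqs)
  k <- length(seqs)
  pairs <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    A <- seqs[i]; B <- seqs[j]
    if (nchar(B) < nchar(A)) {
      st <- nchar(A) - nchar(B) + 1L
      if (substring(A, st) == B)   # B starts with M, so A[st] == "M"
        pairs[[length(pairs) + 1L]] <- list(child = nm[j], parent = nm[i],
                                            start = st)
    }
  }
  parent <- seq_len(k)
  findRoot <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in pairs) {
    a <- findRoot(match(p$parent, nm)); b <- findRoot(match(p$child, nm))
    if (a != b) parent[b] <- a
  }
  root <- vapply(seq_len(k), findRoot, integer(1))
  comp <- split(seq_len(k), root)
  maxLen <- vapply(comp, function(ix) max(nchar(seqs[ix])), numeric(1))
  comp <- comp[order(-maxLen)]
  cls <- character(k)
  for (ci in seq_along(comp)) cls[comp[[ci]]] <- paste0("C", ci)
  info <- catalog@info
  info$ntermClass <- cls
  if (length(pairs)) {
    nest <- S4Vectors::DataFrame(
      child = vapply(pairs, `[[`, "", "child"),
      parent = vapply(pairs, `[[`, "", "parent"),
      start = vapply(pairs, function(p) as.integer(p$start), integer(1)))
    for (i in seq_len(k)) {
      mine <- nest[nest$child == nm[i], , drop = FALSE]
      if (nrow(mine)) {
        pick <- which.max(nchar(seqs[match(mine$parent, nm)]))
        info$nestedIn[i] <- mine$parent[pick]
        info$nestedAt[i] <- mine$start[pick]
      }
    }
    catalog@nesting <- nest
  }
  catalog@info <- info
  methods::validObject(catalog)
  catalog
}
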