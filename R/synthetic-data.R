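# Synthetic locus generator with known ground truth.
#
# The emulated gene has several alternative first exons that splice onto a
# shared 3' coding exon chain.  Proteins are designed first (as codon
# vectors) and the genome is assembled from blocks, so every downstream
# quantity (isoform set, nesting positions, classes, planted allele events,
# mixture, occupancies) is known by construction.  Non-coding filler uses
# the {A,C} alphabet only: such sequence can contain no ATG and no stop
# codon, including across any splice junction, so translation starts are
# exactly where the design places them.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

randCodons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)
randFiller <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                                collapse = "")

codonsToProtein <- function(codons)
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")

#' Configuration for the synthetic proteoform dataset
#'
#' Defaults describe a locus patterned on a structurally complex kinase
#' gene: a long full-length isoform with shorter isoforms nested at internal
#' methionines 170 and 346, a second N-terminal class encoded by its own
#' first exons, a transcript whose 5'UTR can acquire an ORF-extending
#' single-base insertion, and a proteoform mixture of the full-length
#' protein plus an N-terminal truncation starting at residue 477.
#'
#' @param seed Integer seed; fixed seed gives byte-identical datasets.
#' @param nFirstExons Number of alternative first-exon structures used
#'   (1 to 6, default 4).  The first four give, in order: the full-length
#'   isoform, the second-class isoform, the first nested isoform, and a
#'   duplicate full-length transcript (so collapsing is always exercised at
#'   the default); 5 and 6 add the deeper nested isoform's own first exon
#'   and the extended second-class isoform.
#' @param nTranscripts Total transcript count (default 10); transcripts
#'   beyond the structural set re-use first exons with an extra non-coding
#'   cassette exon and must collapse to existing isoforms.
#' @param firstExonUtrRange 5'UTR length range (nt) for first exons.
#' @param protLen Full-length protein length in residues (default 1087).
#' @param nestedStarts Internal methionine start positions of the nested
#'   isoforms, in full-length coordinates (default 170 and 346).
#' @param commonSuffixStart Full-length position where the coding region
#'   shared with the second class begins (default 608).
#' @param class2NtermLen,class2ExtraLen Residues of second-class-specific
#'   N-terminus (default 429) and of the extended variant's extra
#'   N-terminus before its internal methionine (default 39).
#' @param minCodons Catalog ORF-length floor (default 30).
#' @param nSubstitutions,nDeletions Allele events planted by
#'   \code{\link{mutateAllele}} (defaults 6 and 1).
#' @param plantOrfExtension Plant the 5'UTR adenosine insertion that joins
#'   an upstream in-frame ATG to the coding ORF (default TRUE).
#' @param extensionCodons Extra N-terminal residues the insertion adds
#'   (default 67).
#' @param mixture Data frame (\code{component}, \code{truncation},
#'   \code{weight}): proteoforms present, as full-length (\code{truncation}
#'   NA) or N-terminal truncations of the full-length sequence.
#' @param depth Expected total spectra per sample (default 100).
#' @param phosphoSites Data frame (\code{site}, \code{theta}): true
#'   phosphosite occupancies, positions in full-length coordinates.
#' @param enzyme,maxMissed,pepLenRange Digestion settings used when
#'   simulating counts.
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L, nFirstExons = 4L, nTranscripts = 10L,
                      firstExonUtrRange = c(80L, 200L),
                      protLen = 1087L, nestedStarts = c(170L, 346L),
                      commonSuffixStart = 608L,
                      class2NtermLen = 429L, class2ExtraLen = 39L,
                      minCodons = 30L,
                      nSubstitutions = 6L, nDeletions = 1L,
                      plantOrfExtension = TRUE, extensionCodons = 67L,
                      mixture = data.frame(
                        component = c("full_length", "truncated"),
                        truncation = c(NA_integer_, 477L),
                        weight = c(1, 1)),
                      depth = 100, phosphoSites = data.frame(
                        site = c(436L, 934L), theta = c(0.11, 0.65)),
                      enzyme = "trypsin", maxMissed = 2L,
                      pepLenRange = c(6L, 40L)) {
  cfg <- as.list(environment())
  if (nFirstExons < 1L || nFirstExons > 6L)
    pfStop("configError", "nFirstExons must be in 1..6")
  if (nTranscripts < nFirstExons)
    pfStop("configError", "nTranscripts must be >= nFirstExons")
  if (any(cfg$nestedStarts >= cfg$commonSuffixStart) ||
      cfg$commonSuffixStart >= cfg$protLen)
    pfStop("configError",
           "need nestedStarts < commonSuffixStart < protLen")
  if (any(cfg$nestedStarts < 2L))
    pfStop("configError", "nested starts must be internal methionines")
  if (cfg$extensionCodons < 5L)
    pfStop("configError", "extensionCodons must be >= 5")
  if (!all(cfg$mixture$weight >= 0) || sum(cfg$mixture$weight) <= 0)
    pfStop("configError", "mixture weights must be >= 0 with a positive sum")
  if (!all(cfg$phosphoSites$theta >= 0 & cfg$phosphoSites$theta <= 1))
    pfStop("configError", "phospho occupancies must lie in [0, 1]")
  structure(cfg, class = "SimConfig")
}

# Exon chain structures, in deterministic order.  Each exon is
# (block, from, to) relative to the block sequence.
simStructures <- function(blocks, cfg) {
  # to = NA means "to the end of the block", so exon ends track any
  # indel planted into a block by mutateAllele
  full <- function(b) list(block = b, from = 1L, to = NA)
  lu4 <- attr(blocks, "utrLens")[["E4"]]
  list(
    t_full_a  = list(full("U1"), full("C1"), full("C2a"), full("C2b"),
                     full("C3")),
    t_class2  = list(full("E4"), full("C3")),
    t_nested1 = list(full("U3"), full("C2a"), full("C2b"), full("C3")),
    t_full_b  = list(full("U2"), full("C1"), full("C2a"), full("C2b"),
                     full("C3")),
    t_nested2 = list(full("U4"), full("C2b"), full("C3")),
    t_class2x = list(full("E4x"),
                     list(block = "E4", from = lu4 + 1L, to = NA),
                     full("C3"))
  )
}

simCassetteVariants <- function(structures) {
  list(
    t_full_a_cass  = append(structures$t_full_a,
                            list(list(block = "Ucass", from = 1L, to = NA)),
                            after = 1L),
    t_full_b_cass  = append(structures$t_full_b,
                            list(list(block = "Ucass", from = 1L, to = NA)),
                            after = 1L),
    t_nested1_cass = append(structures$t_nested1,
                            list(list(block = "Ucass2", from = 1L, to = NA)),
                            after = 1L)
  )
}

assembleGenome <- function(blocks, layout, spacer = 30L) {
  starts <- integer(0)
  pos <- 1L
  pieces <- character(0)
  for (b in layout) {
    if (length(pieces)) {
      pieces <- c(pieces, strrep("C", spacer))
      pos <- pos + spacer
    }
    starts[[b]] <- pos
    pieces <- c(pieces, blocks[[b]])
    pos <- pos + nchar(blocks[[b]])
  }
  list(seq = paste(pieces, collapse = ""), starts = starts)
}

exonGRanges <- function(chain, starts, blocks, seqname, strand, glen) {
  abs <- lapply(chain, function(e) {
    to <- if (is.na(e$to)) nchar(blocks[[e$block]]) else e$to
    c(starts[[e$block]] + e$from - 1L, starts[[e$block]] + to - 1L)
  })
  m <- do.call(rbind, abs)
  s <- m[, 1L]; e <- m[, 2L]
  if (strand == "-") { ns <- glen - e + 1L; e <- glen - s + 1L; s <- ns }
  GenomicRanges::GRanges(seqname, IRanges::IRanges(s, e), strand = strand)
}

#' Generate the synthetic gene locus
#'
#' Builds a genome, transcript exon models and a ground-truth record.  The
#' construction guarantees: (i) at least one pair of transcripts encodes an
#' identical ORF; (ii) internal in-frame ATGs create nested shorter
#' isoforms; (iii) at the default configuration the catalog has two
#' N-terminal classes; (iv) one transcript's 5'UTR is primed (upstream ATG
#' plus an in-frame stop) so that \code{\link{mutateAllele}} can plant a
#' single-base insertion that extends the coding ORF at its 5' end.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param strand Genome strand carrying the gene ("+" or "-").
#' @return A list: \code{genome} (named \code{DNAStringSet}),
#'   \code{transcripts} (named \code{GRangesList}), \code{truth} (ground
#'   truth: per-transcript proteins, expected distinct isoform sequences,
#'   nesting positions, block table and extension-priming coordinates).
#' @export
makeGene <- function(cfg = simConfig(), strand = "+") {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  ns <- cfg$nestedStarts
  css <- cfg$commonSuffixStart
  # full-length protein as codons, forced methionines at 1 and nested starts
  flCod <- randCodons(cfg$protLen)
  flCod[c(1L, ns)] <- "ATG"
  flProt <- codonsToProtein(flCod)
  n2Cod <- c("ATG", randCodons(cfg$class2NtermLen))
  exCod <- c("ATG", randCodons(cfg$class2ExtraLen))
  utrLen <- function() sample(seq(cfg$firstExonUtrRange[1L],
                                  cfg$firstExonUtrRange[2L]), 1L)
  luRM <- 3L * cfg$extensionCodons + 39L
  uRM <- strsplit(randFiller(luRM), "")[[1L]]
  # prime the extension: upstream ATG at uT, in-frame (pre-insertion) stop
  uT <- luRM + 2L - 3L * cfg$extensionCodons
  uRM[uT:(uT + 2L)] <- c("A", "T", "G")
  uRM[(uT + 9L):(uT + 11L)] <- c("T", "A", "A")
  insT <- uT + 5L
  lu4 <- utrLen(); lux <- utrLen()
  blocks <- list(
    U1 = randFiller(utrLen()), U2 = randFiller(utrLen()),
    Ucass = randFiller(60L), C1 = paste(flCod[1:(ns[1L] - 1L)], collapse = ""),
    U3 = randFiller(utrLen()), U4 = randFiller(utrLen()),
    Ucass2 = randFiller(60L), URM = paste(uRM, collapse = ""),
    C2a = paste(flCod[ns[1L]:(ns[2L] - 1L)], collapse = ""),
    C2b = paste(flCod[ns[2L]:(css - 1L)], collapse = ""),
    E4x = paste0(randFiller(lux), paste(exCod, collapse = "")),
    E4 = paste0(randFiller(lu4), paste(n2Cod, collapse = "")),
    C3 = paste0(paste(flCod[css:cfg$protLen], collapse = ""), "TAA")
  )
  attr(blocks, "utrLens") <- c(E4 = lu4, E4x = lux)
  layout <- c("U1", "U2", "Ucass", "C1", "U3", "U4", "Ucass2", "URM",
              "C2a", "C2b", "E4x", "E4", "C3")
  structures <- simStructures(blocks, cfg)
  chains <- structures[seq_len(cfg$nFirstExons)]
  if (cfg$nTranscripts > cfg$nFirstExons)
    chains <- c(chains, list(t_rm = list(
      list(block = "URM", from = 1L, to = NA),
      list(block = "C2b", from = 1L, to = NA),
      list(block = "C3", from = 1L, to = NA))))
  extras <- simCassetteVariants(structures)
  extras <- extras[c("t_full_a_cass", "t_full_b_cass", "t_nested1_cass") %in%
                     paste0(names(structures)[seq_len(cfg$nFirstExons)],
                            "_cass")]
  k <- 0L
  while (length(chains) < cfg$nTranscripts && length(extras)) {
    k <- k + 1L
    ix <- (k - 1L) %% length(extras) + 1L
    nm <- paste0(names(extras)[ix], if (k > length(extras))
      paste0("_", (k - 1L) %/% length(extras) + 1L) else "")
    chains[[nm]] <- extras[[ix]]
  }
  chains <- chains[seq_len(min(length(chains), cfg$nTranscripts))]
  asm <- assembleGenome(blocks, layout)
  glen <- nchar(asm$seq)
  gseq <- if (strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(asm$seq)))
  else asm$seq
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, "synthLocus"))
  grl <- GenomicRanges::GRangesList(lapply(chains, exonGRanges,
    starts = asm$starts, blocks = blocks, seqname = "synthLocus",
    strand = strand, glen = glen))
  # per-transcript proteins, by construction
  protOf <- function(name) {
    switch(sub("_cass.*$", "_cass", name),
      t_full_a = flProt, t_full_b = flProt,
      t_full_a_cass = flProt, t_full_b_cass = flProt,
      t_nested1 = substring(flProt, ns[1L]),
      t_nested1_cass = substring(flProt, ns[1L]),
      t_nested2 = substring(flProt, ns[2L]),
      t_rm = substring(flProt, ns[2L]),
      t_class2 = paste0(codonsToProtein(n2Cod), substring(flProt, css)),
      t_class2x = paste0(codonsToProtein(exCod), codonsToProtein(n2Cod),
                         substring(flProt, css)))
  }
  proteins <- vapply(names(chains), protOf, "")
  uniq <- unique(unname(proteins))
  nClasses <- length(unique(vapply(uniq, function(p) {
    if (endsWith(flProt, p) || endsWith(p, flProt)) "class1" else "class2"
  }, "")))
  truth <- list(
    config = cfg, strand = strand, blocks = blocks, layout = layout,
    blockStarts = asm$starts, chains = chains,
    flProtein = flProt, proteins = proteins,
    expectedIsoforms = uniq[order(-nchar(uniq))],
    expectedClasses = nClasses,
    nestedStarts = ns, commonSuffixStart = css,
    rm = list(transcript = "t_rm", uT = uT, insT = insT,
              mainStartT = luRM + 1L,
              present = "t_rm" %in% names(chains))
  )
  list(genome = genome, transcripts = grl, truth = truth)
}

# genome block/offset of a full-length codon position
flCodonBlock <- function(p, ns, css) {
  if (p < ns[1L]) list(block = "C1", off = 3L * (p - 1L) + 1L)
  else if (p < ns[2L]) list(block = "C2a", off = 3L * (p - ns[1L]) + 1L)
  else if (p < css) list(block = "C2b", off = 3L * (p - ns[2L]) + 1L)
  else list(block = "C3", off = 3L * (p - css) + 1L)
}

#' Plant allele events into a synthetic gene
#'
#' Creates an alternative allele of a \code{\link{makeGene}} locus by
#' planting amino acid substitutions and in-frame codon deletions at
#' recorded, well-separated positions of the full-length protein, and
#' (optionally) a single adenosine insertion in the primed 5'UTR that
#' joins the upstream ATG in frame with the coding ORF, extending it at
#' its 5' end by \code{extensionCodons} residues.
#'
#' @param gene Output of \code{\link{makeGene}}.
#' @param cfg The \code{\link{simConfig}} (default: the one inside
#'   \code{gene}).
#' @return A list: \code{genome}, \code{transcripts} (coordinates adjusted
#'   for the planted indels), \code{truth} (the input truth extended with
#'   \code{events}: substitution/deletion tables in reference full-length
#'   coordinates, the alternative proteins, and the expected extension
#'   report).
#' @export
mutateAllele <- function(gene, cfg = gene$truth$config) {
  truth <- gene$truth
  set.seed(cfg$seed + 1L)
  ns <- truth$nestedStarts; css <- truth$commonSuffixStart
  flProt <- truth$flProtein
  res <- strsplit(flProt, "")[[1L]]
  # candidate positions: keep forced ATGs; deletions also need neighbours
  # that differ, so the alignment gap position is unambiguous
  protected <- c(1L, ns)
  nEvents <- cfg$nSubstitutions + cfg$nDeletions
  pool <- setdiff(seq(5L, css - 10L), unlist(lapply(protected, function(p)
    (p - 10L):(p + 10L))))
  pos <- integer(0)
  for (cand in sample(pool)) {
    if (all(abs(cand - pos) >= 10L)) pos <- c(pos, cand)
    if (length(pos) == nEvents + 4L) break   # spares for the neighbour check
  }
  delPos <- integer(0)
  for (p in pos) {
    if (length(delPos) == cfg$nDeletions) break
    if (res[p] != res[p - 1L] && res[p] != res[p + 1L]) delPos <- c(delPos, p)
  }
  if (length(delPos) < cfg$nDeletions)
    pfStop("configError", "could not place the requested deletions")
  subPos <- sort(setdiff(pos, delPos)[seq_len(cfg$nSubstitutions)])
  delPos <- sort(delPos)
  blocks <- truth$blocks
  subs <- list()
  for (p in subPos) {
    loc <- flCodonBlock(p, ns, css)
    old <- substr(blocks[[loc$block]], loc$off, loc$off + 2L)
    oldAa <- unname(Biostrings::GENETIC_CODE[old])
    newCod <- sample(SENSE_CODONS[Biostrings::GENETIC_CODE[SENSE_CODONS] !=
                                    oldAa &
                                  SENSE_CODONS != "ATG"], 1L)
    substr(blocks[[loc$block]], loc$off, loc$off + 2L) <- newCod
    subs[[length(subs) + 1L]] <- data.frame(
      pos = p, ref = oldAa, alt = unname(Biostrings::GENETIC_CODE[newCod]))
  }
  dels <- list()
  for (p in rev(delPos)) {   # edit right-to-left so offsets stay valid
    loc <- flCodonBlock(p, ns, css)
    s <- blocks[[loc$block]]
    dels[[length(dels) + 1L]] <- data.frame(pos = p, ref = res[p])
    blocks[[loc$block]] <- paste0(substr(s, 1L, loc$off - 1L),
                                  substring(s, loc$off + 3L))
  }
  extension <- NULL
  if (cfg$plantOrfExtension) {
    if (!truth$rm$present)
      pfStop("configError",
             "extension requested but the primed transcript is absent")
    s <- blocks[["URM"]]
    blocks[["URM"]] <- paste0(substr(s, 1L, truth$rm$insT - 1L), "A",
                              substring(s, truth$rm$insT))
    extension <- list(extensionCodons = cfg$extensionCodons,
                      ref_orf_start = truth$rm$mainStartT,
                      alt_orf_start = truth$rm$uT)
  }
  attr(blocks, "utrLens") <- attr(truth$blocks, "utrLens")
  asm <- assembleGenome(blocks, truth$layout)
  glen <- nchar(asm$seq)
  gseq <- if (truth$strand == "-")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(asm$seq)))
  else asm$seq
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, "synthLocus"))
  grl <- GenomicRanges::GRangesList(lapply(truth$chains, exonGRanges,
    starts = asm$starts, blocks = blocks, seqname = "synthLocus",
    strand = truth$strand, glen = glen))
  # alternative full-length protein, by construction
  altRes <- res
  for (s in subs) altRes[s$pos] <- s$alt
  if (length(delPos)) altRes <- altRes[-delPos]
  emptyEv <- function(cols) {
    d <- data.frame(pos = integer(0))
    for (cc in cols) d[[cc]] <- character(0)
    d
  }
  truth$altBlocks <- blocks
  truth$events <- list(
    substitutions = if (length(subs)) do.call(rbind, subs)
      else emptyEv(c("ref", "alt")),
    deletions = if (length(dels)) do.call(rbind, rev(dels))
      else emptyEv("ref"),
    extension = extension)
  truth$altFlProtein <- paste(altRes, collapse = "")
  list(genome = genome, transcripts = grl, truth = truth)
}

#' Expected peptide counts for a proteoform mixture
#'
#' Digests each mixture component, applies the observable-length filter,
#' and distributes the expected sample depth across components by weight
#' and uniformly across each component's observable peptides.  Expected
#' counts sum exactly to \code{depth}.
#'
#' @param flProtein Full-length reference protein sequence.
#' @param mixture Data frame (\code{component}, \code{truncation},
#'   \code{weight}); truncations are N-terminal, in reference coordinates.
#' @param depth Expected total spectra.
#' @param enzyme,maxMissed,pepLenRange Digestion settings.
#' @return A data frame with \code{component}, \code{peptide}, \code{start},
#'   \code{end} (reference coordinates), \code{expected}.
#' @export
expectedPeptideCounts <- function(flProtein, mixture, depth,
                                  enzyme = "trypsin", maxMissed = 0L,
                                  pepLenRange = c(6L, 40L)) {
  w <- mixture$weight / sum(mixture$weight)
  out <- list()
  for (i in seq_len(nrow(mixture))) {
    b <- mixture$truncation[i]
    if (is.na(b)) b <- 1L
    comp <- substring(flProtein, b)
    pep <- observablePeptides(
      digestProtein(comp, enzyme, maxMissed = maxMissed),
      pepLenRange[1L], pepLenRange[2L])
    if (!nrow(pep)) next
    out[[i]] <- data.frame(
      component = mixture$component[i], peptide = pep$seq,
      start = pep$start + b - 1L, end = pep$end + b - 1L,
      expected = depth * w[i] / nrow(pep), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a spectral-count table for a proteoform mixture
#'
#' Draws Poisson counts around the expected peptide counts of
#' \code{\link{expectedPeptideCounts}} and splits counts of peptides
#' covering each configured phosphosite binomially by its true occupancy.
#'
#' @param flProtein Full-length reference protein.
#' @param mixture,depth,enzyme,maxMissed,pepLenRange As in
#'   \code{\link{expectedPeptideCounts}}.
#' @param phosphoSites Data frame (\code{site}, \code{theta}).
#' @param sample Sample label for the emitted rows.
#' @param refIsoform Reference isoform name recorded in the table.
#' @param seed Optional seed set before drawing.
#' @return A spectral-count table (see
#'   \code{\link{validateSpectralCounts}}); rows with zero count are
#'   dropped.
#' @importFrom stats rpois rbinom
#' @export
simulateCounts <- function(flProtein, mixture, depth, phosphoSites = NULL,
                           sample = "sample1", refIsoform = "P1",
                           enzyme = "trypsin", maxMissed = 0L,
                           pepLenRange = c(6L, 40L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exp <- expectedPeptideCounts(flProtein, mixture, depth, enzyme, maxMissed,
                               pepLenRange)
  if (is.null(exp) || !nrow(exp))
    pfStop("configError", "mixture yields no observable peptides")
  exp$count <- stats::rpois(nrow(exp), exp$expected)
  rows <- list()
  for (i in seq_len(nrow(exp))) {
    cnt <- exp$count[i]
    if (cnt == 0L) next
    sites <- if (!is.null(phosphoSites))
      phosphoSites[phosphoSites$site >= exp$start[i] &
                     phosphoSites$site <= exp$end[i], , drop = FALSE]
    else NULL
    nPhos <- 0L
    if (!is.null(sites) && nrow(sites)) {
      for (j in seq_len(nrow(sites))) {
        k <- stats::rbinom(1L, cnt - nPhos, sites$theta[j])
        if (k > 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample, peptide = exp$peptide[i],
            ref_isoform = refIsoform, start = exp$start[i], end = exp$end[i],
            phospho_site = sites$site[j], is_phospho = TRUE, count = k,
            stringsAsFactors = FALSE)
        nPhos <- nPhos + k
      }
    }
    if (cnt - nPhos > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample, peptide = exp$peptide[i], ref_isoform = refIsoform,
        start = exp$start[i], end = exp$end[i],
        phospho_site = NA_integer_, is_phospho = FALSE, count = cnt - nPhos,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sample = character(0), peptide = character(0),
                      ref_isoform = character(0), start = integer(0),
                      end = integer(0), phospho_site = integer(0),
                      is_phospho = logical(0), count = integer(0)))
  do.call(rbind, rows)
}

#' Antibody antigen designs for the synthetic locus
#'
#' Five antigen peptides cut from the designed proteins: one unique to the
#' full-length N-terminus, one shared by the two longest class-1 isoforms,
#' one shared by the whole nested trio, one in the common C-terminal region
#' (all isoforms), and one specific to the second N-terminal class (when
#' that class is present).
#'
#' @param truth Ground truth from \code{\link{makeGene}}.
#' @return Named character vector of antigen sequences.
#' @export
makeAntigens <- function(truth) {
  fl <- truth$flProtein
  ns <- truth$nestedStarts
  ag <- c(
    abFull = substring(fl, 25L, 171L),
    abPair = substring(fl, ns[1L] + 108L, ns[1L] + 170L),
    abTrio = substring(fl, ns[2L] + 5L, ns[2L] + 146L),
    abCommon = substring(fl, truth$commonSuffixStart + 92L,
                         truth$commonSuffixStart + 135L))
  class2 <- Filter(function(p) !endsWith(fl, p) && !endsWith(p, fl),
                   truth$expectedIsoforms)
  if (length(class2)) {
    shortest <- class2[[which.min(nchar(class2))]]
    ag <- c(ag, abClass2 = substring(shortest, 20L, 90L))
  }
  ag
}

#' Generate a complete synthetic dataset
#'
#' Runs \code{\link{makeGene}}, designs antigens, simulates one
#' spectral-count sample per mixture component (each component is one gel
#' band, as proteoforms of different mass separate on a gel), and builds
#' the band-evidence table with apparent masses near the component's
#' theoretical weight and antibody detections computed from true epitope
#' content.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param strand Genome strand.
#' @return A list of class \code{SimulatedDataset}: \code{genome},
#'   \code{transcripts}, \code{truth}, \code{antigens}, \code{counts},
#'   \code{bands} (list of band evidence lists).
#' @export
simulateDataset <- function(cfg = simConfig(), strand = "+") {
  gene <- makeGene(cfg, strand = strand)
  truth <- gene$truth
  antigens <- makeAntigens(truth)
  fl <- truth$flProtein
  counts <- list(); bands <- list()
  for (i in seq_len(nrow(cfg$mixture))) {
    comp <- cfg$mixture[i, , drop = FALSE]
    id <- paste0("band_", comp$component)
    counts[[i]] <- simulateCounts(
      fl, comp, depth = cfg$depth, phosphoSites = cfg$phosphoSites,
      sample = id, enzyme = cfg$enzyme, maxMissed = cfg$maxMissed,
      pepLenRange = cfg$pepLenRange, seed = cfg$seed + 100L + i)
    b <- comp$truncation
    compSeq <- substring(fl, if (is.na(b)) 1L else b)
    # gel bands run slightly above theoretical weight
    set.seed(cfg$seed + 200L + i)
    apparent <- molecularWeight(compSeq) * stats::runif(1L, 1.01, 1.07)
    bands[[i]] <- list(
      band_id = id, apparent_mass_kda = apparent,
      detections = vapply(antigens, function(a)
        grepl(a, compSeq, fixed = TRUE), logical(1)),
      truth_component = comp$component,
      truth_truncation = comp$truncation,
      truth_seq = compSeq)
  }
  structure(list(genome = gene$genome, transcripts = gene$transcripts,
                 truth = truth, antigens = antigens,
                 counts = do.call(rbind, counts), bands = bands),
            class = "SimulatedDataset")
}
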