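test_that("spliceTranscript handles single exons, strands, and multi-exon slicing", {
  g <- Biostrings::DNAStringSet(c(chr = "ATGCCC"))
  ex <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 6), strand = "+")
  expect_equal(as.character(spliceTranscript(g, ex)), "ATGCCC")
  exm <- GenomicRanges::GRanges("chr", IRanges::IRanges(1, 6), strand = "-")
  expect_equal(as.character(spliceTranscript(g, exm)), "GGGCAT")

  g2 <- Biostrings::DNAStringSet(c(chr = "AAATGGCCTAAGGC"))
  ex2 <- GenomicRanges::GRanges("chr", IRanges::IRanges(c(3, 10), c(8, 12)),
                                strand = "+")
  manual <- paste0(substr("AAATGGCCTAAGGC", 3, 8),
                   substr("AAATGGCCTAAGGC", 10, 12))
  expect_equal(as.character(spliceTranscript(g2, ex2)), manual)
})

test_that("splice length conservation and strand complementarity hold", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(60:200, 1)
    g <- Biostrings::DNAStringSet(stats::setNames(randomDna(n), "chr"))
    k <- sample(1:4, 1)
    starts <- sort(sample(seq(1, n - 10), k))
    ends <- pmin(starts + sample(3:9, k, replace = TRUE), n)
    keep <- c(TRUE, starts[-1] > ends[-k])
    starts <- starts[keep]; ends <- ends[keep]
    exP <- GenomicRanges::GRanges("chr", IRanges::IRanges(starts, ends),
                                  strand = "+")
    exM <- GenomicRanges::GRanges("chr", IRanges::IRanges(starts, ends),
                                  strand = "-")
    sp <- spliceTranscript(g, exP)
    expect_equal(length(sp), sum(ends - starts + 1))
    expect_equal(as.character(Biostrings::reverseComplement(sp)),
                 as.character(spliceTranscript(g, exM)))
  }
})

test_that("spliceTranscript rejects bad coordinates and alphabets", {
  g <- Biostrings::DNAStringSet(c(chr = "ATGCCC"))
  exBad <- GenomicRanges::GRanges("chr", IRanges::IRanges(2, 9), strand = "+")
  expect_error(spliceTranscript(g, exBad), class = "coordinateError")
  exWrong <- GenomicRanges::GRanges("nope", IRanges::IRanges(1, 3),
                                    strand = "+")
  expect_error(spliceTranscript(g, exWrong), class = "coordinateError")
})

test_that("findOrfs reports minimal and offset ORFs and respects N codons", {
  o <- findOrfs("ATGAAATAA")
  expect_equal(nrow(o), 1L)
  expect_equal(o$nt_start, 1L)
  expect_equal(o$nt_end, 9L)

  o2 <- findOrfs("CCATGTAA")
  expect_equal(o2$nt_start, 3L)

  # N-containing codons never act as start or stop
  expect_equal(nrow(findOrfs("ATNAAATAA")), 0L)
  expect_equal(nrow(findOrfs("ATGAAATAN")), 0L)
})

test_that("findOrfs agrees with the brute-force oracle on random sequences", {
  set.seed(42)
  for (i in 1:60) {
    s <- randomDna(sample(30:400, 1))
    got <- as.data.frame(findOrfs(s))[, c("nt_start", "nt_end", "naa")]
    want <- bruteOrfs(s)
    expect_equal(got, as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("selectCodingOrf picks the longest ORF, ties to the 5'-most", {
  orfs <- S4Vectors::DataFrame(nt_start = c(10L, 100L),
                               nt_end = c(99L, 399L),
                               naa = c(29L, 99L))
  expect_equal(selectCodingOrf(orfs)$nt_start, 100L)
  ties <- S4Vectors::DataFrame(nt_start = c(40L, 10L),
                               nt_end = c(129L, 99L),
                               naa = c(29L, 29L))
  expect_equal(selectCodingOrf(ties)$nt_start, 10L)
  expect_error(selectCodingOrf(ties[0, ]), class = "noOrfError")
})

test_that("translateOrf matches a hand-written codon table and the length law", {
  expect_equal(translateOrf("ATGAAATAA"), "MK")
  expect_equal(translateOrf("ATGTAA"), "M")
  set.seed(7)
  for (i in 1:15) {
    body <- sample(setdiff(names(oracleCodonTable),
                           c("TAA", "TAG", "TGA")), 59, replace = TRUE)
    orf <- paste0("ATG", paste(body, collapse = ""), "TGA")
    aa <- translateOrf(orf)
    expect_equal(aa, oracleTranslate(orf))
    expect_equal(nchar(aa), nchar(orf) / 3 - 1)
  }
  expect_error(translateOrf("ATGTAAAAATAA"), class = "malformedOrfError")
  expect_error(translateOrf("ATGAAA"), class = "malformedOrfError")
})

test_that("buildCatalog collapses identical translations and maps transcripts", {
  cat <- tinyCatalog()
  expect_equal(nIsoforms(cat), 3L)
  expect_equal(unname(transcriptMap(cat)[c("tA", "tB", "tD")]),
               c("P1", "P2", "P3"))  # named by descending length, then order
  expect_setequal(names(transcriptMap(cat)), c("tA", "tB", "tD"))

  # a duplicated transcript collapses into the same isoform
  g <- makeGene(simConfig(seed = 3))
  cat2 <- buildCatalog(g$transcripts, g$genome)
  expect_equal(nIsoforms(cat2), length(g$truth$expectedIsoforms))
  expect_setequal(as.character(isoformSeqs(cat2)), g$truth$expectedIsoforms)
  dupSets <- Filter(function(x) length(x) > 1, cat2@sourceTranscripts)
  expect_gt(length(dupSets), 0L)
})

test_that("single-transcript catalog is total", {
  cfg <- simConfig(seed = 5, nFirstExons = 1L, nTranscripts = 1L)
  g <- makeGene(cfg)
  cat <- buildCatalog(g$transcripts, g$genome)
  expect_equal(nIsoforms(cat), 1L)
  expect_equal(length(transcriptMap(cat)), 1L)
})

test_that("catalog rebuild from its own expansion is idempotent", {
  g <- makeGene(simConfig(seed = 9))
  cat1 <- groupNtermClasses(buildCatalog(g$transcripts, g$genome))
  # re-encode each isoform as a bare single-exon transcript and rebuild
  seqs <- as.character(isoformSeqs(cat1))
  genome2 <- Biostrings::DNAStringSet(c(chr2 = dnaFor(seqs)))
  lens <- nchar(seqs) * 3L + 3L
  offs <- cumsum(c(1L, lens[-length(lens)]))
  grl <- GenomicRanges::GRangesList(stats::setNames(lapply(seq_along(seqs),
    function(i) GenomicRanges::GRanges("chr2",
      IRanges::IRanges(offs[i], offs[i] + lens[i] - 1L), strand = "+")),
    paste0("t", seq_along(seqs))))
  cat2 <- groupNtermClasses(buildCatalog(grl, genome2, minCodons = 1L))
  expect_equal(as.character(isoformSeqs(cat2)), as.character(isoformSeqs(cat1)))
  expect_equal(ntermClass(cat2), ntermClass(cat1))
})

test_that("nesting is detected with positions, and classes split on N-termini", {
  cat <- tinyCatalog()
  info <- isoformInfo(cat)
  nested <- info[!is.na(info$nestedIn), ]
  expect_equal(nrow(nested), 1L)
  expect_equal(nested$nestedIn, "P1")
  expect_equal(nested$nestedAt, 9L)
  cls <- ntermClass(cat)
  expect_equal(length(unique(cls)), 2L)
  expect_equal(cls[["P1"]], cls[[nested$name]])
})

test_that("nesting is transitive through chained internal starts", {
  g <- makeGene(simConfig(seed = 2))
  cat <- groupNtermClasses(buildCatalog(g$transcripts, g$genome))
  np <- as.data.frame(nestingPairs(cat))
  seqs <- as.character(isoformSeqs(cat))
  for (i in seq_len(nrow(np))) {
    child <- seqs[np$child[i]]; parent <- seqs[np$parent[i]]
    expect_equal(unname(substring(parent, np$start[i])), unname(child))
  }
  # chain: if C in B at p and B in A at q then C occurs in A at q + p - 1
  for (i in seq_len(nrow(np))) for (j in seq_len(nrow(np))) {
    if (np$parent[i] == np$child[j]) {
      k <- np[np$child == np$child[i] & np$parent == np$parent[j], ]
      expect_equal(k$start, np$start[j] + np$start[i] - 1L)
    }
  }
})
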