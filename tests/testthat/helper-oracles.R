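# Independent oracles, deliberately naive and separate from the package code.

# Brute-force ORF enumeration: scan forward from every ATG until the first
# in-frame stop; keep the 5'-most ATG per stop.
bruteOrfs <- function(seq, minCodons = 1L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  pairs <- list()
  if (n >= 3L) for (i in seq_len(n - 2L)) {
    if (substr(seq, i, i + 2L) != "ATG") next
    j <- i
    while (j + 2L <= n) {
      cod <- substr(seq, j, j + 2L)
      if (j > i && cod %in% stops) {
        pairs[[length(pairs) + 1L]] <- c(start = i, end = j + 2L)
        break
      }
      j <- j + 3L
    }
  }
  if (!length(pairs))
    return(data.frame(nt_start = integer(0), nt_end = integer(0),
                      naa = integer(0)))
  m <- as.data.frame(do.call(rbind, pairs))
  out <- do.call(rbind, lapply(split(m, m$end), function(d)
    data.frame(nt_start = min(d$start), nt_end = d$end[1L])))
  out$naa <- (out$nt_end - out$nt_start + 1L) %/% 3L - 1L
  out <- out[out$naa >= minCodons, , drop = FALSE]
  out <- out[order(-(out$nt_end - out$nt_start), out$nt_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Hand-written standard genetic code (independent of Biostrings).
oracleCodonTable <- local({
  bases <- c(T = "T", C = "C", A = "A", G = "G")
  aas <- paste0(
    "FFLLSSSSYY**CC*W",   # TTT TTC TTA TTG TCT ... TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG")
  tab <- character(0)
  k <- 0L
  for (b1 in names(bases)) for (b2 in names(bases)) for (b3 in names(bases)) {
    k <- k + 1L
    tab[paste0(b1, b2, b3)] <- substr(aas, k, k)
  }
  tab
})

oracleTranslate <- function(orfSeq) {
  cods <- substring(orfSeq, seq(1, nchar(orfSeq) - 2, 3),
                    seq(3, nchar(orfSeq), 3))
  aa <- oracleCodonTable[cods]
  paste(aa[aa != "*"], collapse = "")
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
randomProtein <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE), collapse = "")

# antigen fixture shared by several tests
antigenFixture <- function() {
  path <- system.file("extdata", "antibody_antigens.tsv",
                      package = "ProteoformTools")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# small two-class catalog built from first principles (no generator)
tinyCatalog <- function() {
  common <- "ELKIQEMQRALQFKDNEIAELKSHLDK"
  a <- paste0("MAGLWPTC", "MKWVYHHR", common)   # internal M at 9
  b <- paste0("MKWVYHHR", common)               # nested in a at 9
  d <- paste0("MQQSPDNT", common)               # own N-terminus: second class
  genome <- Biostrings::DNAStringSet(c(chr = dnaFor(c(a, b, d))))
  # encode each protein as a single-exon transcript laid head to tail
  lens <- nchar(c(a, b, d)) * 3L + 3L
  offs <- cumsum(c(1L, lens[-3L]))
  grl <- GenomicRanges::GRangesList(
    tA = GenomicRanges::GRanges("chr",
      IRanges::IRanges(offs[1], offs[1] + lens[1] - 1L), strand = "+"),
    tB = GenomicRanges::GRanges("chr",
      IRanges::IRanges(offs[2], offs[2] + lens[2] - 1L), strand = "+"),
    tD = GenomicRanges::GRanges("chr",
      IRanges::IRanges(offs[3], offs[3] + lens[3] - 1L), strand = "+"))
  groupNtermClasses(buildCatalog(grl, genome, minCodons = 1L))
}

# reverse-translate proteins into concatenated minimal ORFs
dnaFor <- function(prots) {
  inv <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
           G="GGT", H="CAT", I="ATT", L="CTT", K="AAA", M="ATG", F="TTT",
           P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT")
  paste(vapply(prots, function(p) {
    paste0(paste(inv[strsplit(p, "")[[1]]], collapse = ""), "TAA")
  }, ""), collapse = "")
}
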