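test_that("molecularWeight reproduces standard average masses", {
  expect_equal(molecularWeight(""), 0.01801524, tolerance = 1e-6)
  expect_equal(1000 * molecularWeight("G"), 75.07, tolerance = 0.01)
  # additivity: MW(ab) = MW(a) + MW(b) - water
  set.seed(13)
  for (i in 1:10) {
    a <- randomProtein(sample(5:60, 1)); b <- randomProtein(sample(5:60, 1))
    expect_equal(molecularWeight(paste0(a, b)),
                 molecularWeight(a) + molecularWeight(b) - 0.01801524,
                 tolerance = 1e-9)
    # monotonicity: appending any residue strictly increases the mass
    expect_gt(molecularWeight(paste0(a, "G")), molecularWeight(a))
  }
  expect_error(molecularWeight("MKXV"), class = "alphabetError")
})

test_that("molecularWeight agrees with an independent mass calculator", {
  skip_if_not_installed("seqinr")
  ags <- antigenFixture()
  for (s in ags$sequence) {
    expect_equal(1000 * molecularWeight(s),
                 seqinr::pmw(seqinr::s2c(s)), tolerance = 0.2)
  }
})

test_that("mapEpitope finds exact matches with verifiable coordinates", {
  cat <- tinyCatalog()
  seqs <- as.character(isoformSeqs(cat))
  # full-isoform antigen matches that isoform at position 1
  p <- mapEpitope(seqs[["P2"]], cat, name = "full")
  m <- probeMatches(p)
  expect_true("P2" %in% m$isoform)
  expect_equal(m$start[m$isoform == "P2"], 1L)
  # every reported coordinate recovers the antigen
  for (i in seq_len(nrow(m)))
    expect_equal(substring(seqs[[m$isoform[i]]], m$start[i], m$end[i]),
                 antigenSeq(p))
  # absent antigen yields an empty match set
  expect_equal(nrow(probeMatches(mapEpitope("WWWWWWWW", cat))), 0L)
})

test_that("specificityMatrix rows reflect probe reach, including nesting", {
  cat <- tinyCatalog()
  seqs <- as.character(isoformSeqs(cat))
  common <- substring(seqs[["P3"]], 10)      # shared C-terminal region
  probes <- list(mapEpitope(common, cat, "all"),
                 mapEpitope("WWWWWWWW", cat, "none"),
                 mapEpitope(substring(seqs[["P2"]], 1, 8), cat, "pairOnly"))
  m <- specificityMatrix(probes, cat)
  expect_equal(unname(m["all", ]), rep(1L, 3))
  expect_equal(unname(m["none", ]), rep(0L, 3))
  # a probe matching a nested child also matches every containing parent
  np <- as.data.frame(nestingPairs(cat))
  for (i in seq_len(nrow(np)))
    expect_true(all(m[m[, np$child[i]] == 1L, np$parent[i]] == 1L))
})

test_that("compareAlleles classifies substitutions and is symmetric", {
  d0 <- compareAlleles("MKLV", "MKLV")
  expect_equal(nrow(d0$substitutions) + nrow(d0$deletions) +
                 nrow(d0$insertions), 0L)
  d1 <- compareAlleles("MKLV", "MKIV")
  expect_equal(d1$substitutions,
               data.frame(pos = 3L, ref = "L", alt = "I"))

  set.seed(19)
  a <- randomProtein(120)
  b <- paste0(substr(a, 1, 49), substr(a, 53, 120))  # drop residues 50..52
  fwd <- compareAlleles(a, b)
  rev <- compareAlleles(b, a)
  expect_equal(nrow(fwd$deletions), 1L)
  expect_equal(fwd$deletions$pos, 50L)
  expect_equal(fwd$deletions$ref, substr(a, 50, 52))
  expect_equal(rev$insertions$alt, fwd$deletions$ref)
  expect_equal(nrow(rev$deletions), 0L)
  # substitution symmetry swaps residue order
  s1 <- compareAlleles("MKLVHG", "MKIVHG")$substitutions
  s2 <- compareAlleles("MKIVHG", "MKLVHG")$substitutions
  expect_equal(s1$ref, s2$alt)
  expect_equal(s1$alt, s2$ref)
})

test_that("planted substitutions and deletions are recovered exactly", {
  g <- makeGene(simConfig(seed = 21))
  alt <- mutateAllele(g)
  d <- compareAlleles(g$truth$flProtein, alt$truth$altFlProtein)
  ev <- alt$truth$events
  expect_equal(d$substitutions, ev$substitutions, ignore_attr = TRUE)
  expect_equal(d$deletions, ev$deletions, ignore_attr = TRUE)
  expect_equal(nrow(d$insertions), 0L)
})

test_that("detectOrfExtension reports planted 5' extensions and ignores equivalents", {
  cfg <- simConfig(seed = 23, extensionCodons = 20L)
  g <- makeGene(cfg)
  alt <- mutateAllele(g)
  catal <- groupNtermClasses(buildCatalog(g$transcripts, g$genome))
  refM <- as.character(spliceTranscript(g$genome, g$transcripts[["t_rm"]]))
  altM <- as.character(spliceTranscript(alt$genome, alt$transcripts[["t_rm"]]))
  rep <- detectOrfExtension(refM, altM, catalog = catal)
  expect_false(is.null(rep))
  expect_equal(rep$extra_nterm_aa, 20L)
  expect_lte(rep$novel_nterm_aa, rep$extra_nterm_aa)
  expect_lt(rep$alt_orf_start, rep$ref_orf_start)
  # identical transcripts: no report
  expect_null(detectOrfExtension(refM, refM))
  # insertion that creates no upstream in-frame ATG: no report
  ref2 <- "CCCCCCATGAAACCCGGGTAA"
  alt2 <- "CCCCCACCATGAAACCCGGGTAA"
  expect_null(detectOrfExtension(ref2, alt2))
  expect_error(detectOrfExtension("CCCCCC", "CCCCCC"), class = "noOrfError")
})
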