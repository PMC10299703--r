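mkCounts <- function(pep, start, count, sample = "s", phospho = NULL,
                     site = NA_integer_) {
  data.frame(sample = sample, peptide = pep, ref_isoform = "P1",
             start = start, end = start + nchar(pep) - 1L,
             phospho_site = if (is.null(phospho)) NA_integer_ else
               ifelse(phospho, site, NA_integer_),
             is_phospho = if (is.null(phospho)) FALSE else phospho,
             count = count, stringsAsFactors = FALSE)
}

test_that("relative abundance is max-normalized with per-residue max coverage", {
  tab <- mkCounts(c("AAAAAA", "CCCCCC"), c(1L, 11L), c(4L, 2L))
  prof <- relativeAbundance(tab, "s")
  expect_equal(prof$peptides$r, c(1, 0.5))
  expect_equal(prof$coverage[1:6], rep(1, 6))
  expect_equal(prof$coverage[11:16], rep(0.5, 6))
  expect_equal(prof$coverage[7:10], rep(0, 4))
  # single peptide gets r = 1
  expect_equal(relativeAbundance(mkCounts("DDDDD", 5L, 7L), "s")$peptides$r, 1)
  expect_error(relativeAbundance(tab, "absent"), class = "emptySampleError")
})

test_that("relative abundance matches a brute-force oracle and is scale invariant", {
  set.seed(41)
  for (i in 1:10) {
    n <- 50
    pep <- vapply(1:n, function(j) randomProtein(sample(6:20, 1)), "")
    start <- sample(1:400, n)
    count <- rpois(n, 5) + 1L
    tab <- mkCounts(pep, start, count)
    prof <- relativeAbundance(tab, "s")
    # oracle: per-position maximum of count/max(count)
    agg <- tapply(tab$count, tab$peptide, sum)
    r <- agg / max(agg)
    covOracle <- numeric(max(tab$end))
    for (j in 1:n) {
      ix <- tab$start[j]:tab$end[j]
      covOracle[ix] <- pmax(covOracle[ix], r[[tab$peptide[j]]])
    }
    expect_equal(prof$coverage, covOracle)
    expect_equal(max(prof$peptides$r), 1)
    expect_true(all(prof$peptides$r >= 0 & prof$peptides$r <= 1))
    # scaling every count by a constant leaves the profile unchanged
    tab2 <- tab; tab2$count <- tab2$count * 7L
    expect_equal(relativeAbundance(tab2, "s")$coverage, prof$coverage)
  }
})

test_that("phospho occupancy is a rounded percentage of covering counts", {
  tab <- rbind(mkCounts("AASPK", 430L, 8L),
               mkCounts("AASPK", 430L, 1L, phospho = TRUE, site = 432L))
  o <- phosphoOccupancy(tab, 432L, "s")
  expect_equal(o$percent, 11)
  expect_equal(o$phospho_count, 1L)
  expect_equal(o$total_count, 9L)

  expect_equal(phosphoOccupancy(mkCounts("AAAAA", 1L, 5L), 3L, "s")$percent, 0)
  half <- rbind(mkCounts("AAAAA", 1L, 5L),
                mkCounts("AAAAA", 1L, 5L, phospho = TRUE, site = 3L))
  expect_equal(phosphoOccupancy(half, 3L, "s")$percent, 50)
  expect_error(phosphoOccupancy(mkCounts("AAAAA", 1L, 5L), 99L, "s"),
               class = "noCoverageError")
})

test_that("occupancy estimator is unbiased under binomial sampling", {
  set.seed(43)
  for (theta in c(0.2, 0.8)) {
    n <- 40L
    est <- replicate(400, {
      k <- rbinom(1, n, theta)
      tab <- rbind(mkCounts("AAAAA", 1L, n - k),
                   mkCounts("AAAAA", 1L, k, phospho = TRUE, site = 3L))
      tab <- tab[tab$count > 0, ]
      phosphoOccupancy(tab, 3L, "s")$percent
    })
    se <- 100 * sqrt(theta * (1 - theta) / n) / sqrt(400)
    expect_lt(abs(mean(est) - 100 * theta), 3 * se + 0.5)
  }
})

test_that("boundary inference is exact on noiseless steps", {
  expect_equal(inferStartBoundary(c(rep(0, 99), rep(1, 101)))$boundary, 100L)
  expect_equal(inferStartBoundary(rep(1, 80))$boundary, 1L)
  # step height does not matter
  expect_equal(inferStartBoundary(c(rep(0, 49), rep(0.3, 51)))$boundary, 50L)
  expect_error(inferStartBoundary(rep(0, 10)), class = "noSignalError")
})

test_that("boundary error shrinks with depth on sampled step profiles", {
  set.seed(47)
  bStar <- 120L
  errAt <- function(depth) {
    counts <- rpois(80, depth)          # one peptide per 5-residue window
    pep <- vapply(1:80, function(j) randomProtein(5), "")
    tab <- mkCounts(pep, seq(bStar, by = 5, length.out = 80), counts)
    tab <- tab[tab$count > 0, ]
    prof <- relativeAbundance(tab, "s", refLen = 600)
    abs(inferStartBoundary(prof)$boundary - bStar)
  }
  lo <- mean(replicate(20, errAt(2)))
  hi <- mean(replicate(20, errAt(50)))
  expect_lte(hi, lo)
  expect_lt(hi, 5)
})

test_that("assignBand respects epitope constraints and mass tolerance", {
  cat <- tinyCatalog()
  seqs <- as.character(isoformSeqs(cat))
  probes <- list(mapEpitope(substring(seqs[["P1"]], 1, 8), cat, "p1only"),
                 mapEpitope(substring(seqs[["P3"]], 12, 30), cat, "common"))
  m <- specificityMatrix(probes, cat)

  # unambiguous band: exact mass of P1, detected by its unique probe
  band <- list(band_id = "b1", apparent_mass_kda = molecularWeight(seqs[["P1"]]),
               detections = c(p1only = TRUE, common = TRUE))
  res <- assignBand(band, cat, m, probes = probes)
  expect_equal(res$candidate[1], "P1")
  expect_equal(res$type[1], "full_length")
  expect_equal(res$rel_mass_err[1], 0)

  # no detecting probe: empty candidate list with a diagnostic
  none <- list(band_id = "b2", apparent_mass_kda = 3,
               detections = c(p1only = FALSE, common = FALSE))
  res0 <- assignBand(none, cat, m, probes = probes)
  expect_equal(nrow(res0), 0L)
  expect_true(nzchar(attr(res0, "diagnostics")[1]))

  # isoforms lacking a detecting epitope are never proposed
  bandP1 <- list(band_id = "b3", apparent_mass_kda = 2.5,
                 detections = c(p1only = TRUE, common = FALSE))
  res1 <- assignBand(bandP1, cat, m, probes = probes)
  expect_true(all(res1$candidate == "P1"))
  # soundness: every candidate carries the epitope of each detecting probe
  for (cand in res1$candidate)
    expect_true(grepl(antigenSeq(probes[[1]]), seqs[[cand]], fixed = TRUE))
})

test_that("sub-mass bands become truncation candidates of epitope-consistent isoforms", {
  cat <- tinyCatalog()
  seqs <- as.character(isoformSeqs(cat))
  common <- substring(seqs[["P3"]], 12, 30)
  probes <- list(mapEpitope(common, cat, "common"))
  m <- specificityMatrix(probes, cat)
  # apparent mass of the shared C-terminal region only
  target <- molecularWeight(substring(seqs[["P1"]], 17))
  band <- list(band_id = "b", apparent_mass_kda = target,
               detections = c(common = TRUE))
  res <- assignBand(band, cat, m, probes = probes)
  expect_true(all(res$type == "truncated"))
  expect_equal(nrow(res), 3L)
  # each candidate's truncated suffix still contains the detecting epitope
  for (i in seq_len(nrow(res)))
    expect_true(grepl(common, substring(seqs[[res$candidate[i]]],
                                        res$truncation_start[i]), fixed = TRUE))
})
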