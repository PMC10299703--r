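SPECTRAL_COLS <- c("sample", "peptide", "ref_isoform", "start", "end",
                   "phospho_site", "is_phospho", "count")

#' Validate a spectral-count table
#'
#' A spectral-count table is a \code{data.frame} with one row per
#' (sample, peptide, modification state): columns \code{sample},
#' \code{peptide}, \code{ref_isoform}, \code{start}, \code{end} (1-based
#' inclusive residue coordinates on the reference isoform),
#' \code{phospho_site} (NA for unmodified rows), \code{is_phospho} and
#' \code{count} (non-negative integer spectral count).
#'
#' @param x A data frame.
#' @return \code{x}, invisibly, after validation.
#' @export
validateSpectralCounts <- function(x) {
  if (!is.data.frame(x) || !all(SPECTRAL_COLS %in% names(x)))
    pfStop("schemaError", "spectral-count table must have columns: %s",
           paste(SPECTRAL_COLS, collapse = ", "))
  if (any(x$count < 0))
    pfStop("schemaError", "spectral counts must be non-negative")
  if (any(x$start > x$end))
    pfStop("schemaError", "peptide start must be <= end")
  ph <- which(x$is_phospho)
  if (length(ph) && any(is.na(x$phospho_site[ph])))
    pfStop("schemaError", "phospho rows must carry a phospho_site")
  if (length(ph) && any(x$phospho_site[ph] < x$start[ph] |
                        x$phospho_site[ph] > x$end[ph]))
    pfStop("schemaError", "phospho_site must lie within [start, end]")
  invisible(x)
}

#' Per-sample relative abundance profile from spectral counts
#'
#' For each peptide sequence, the relative abundance r is its spectral
#' count divided by the highest spectral count of any sequence in the same
#' sample, so r ranges from 0.0 to 1.0 and the most-observed sequence has
#' r = 1.  Modification states of the same sequence are pooled.  The
#' per-residue coverage c(pos) is the maximum r over peptides covering the
#' position, preserving the 0-1 scale.
#'
#' @param table A spectral-count table (see
#'   \code{\link{validateSpectralCounts}}).
#' @param sample Sample name to profile.
#' @param refLen Reference isoform length for the coverage vector (default:
#'   the largest peptide \code{end} in the sample).
#' @return A list of class \code{RelAbundanceProfile}: \code{sample},
#'   \code{peptides} (data frame with \code{peptide}, \code{start},
#'   \code{end}, \code{count}, \code{r}), \code{coverage} (numeric vector
#'   of length \code{refLen}).
#' @export
relativeAbundance <- function(table, sample, refLen = NULL) {
  validateSpectralCounts(table)
  rows <- table[table$sample == sample & table$count > 0, , drop = FALSE]
  if (nrow(rows) == 0L)
    pfStop("emptySampleError",
           "sample '%s' absent or has no non-zero counts", sample)
  agg <- stats::aggregate(count ~ peptide + start + end, data = rows, FUN = sum)
  agg$r <- agg$count / max(agg$count)
  agg <- agg[order(agg$start, agg$end, agg$peptide), , drop = FALSE]
  rownames(agg) <- NULL
  if (is.null(refLen)) refLen <- max(agg$end)
  cov <- numeric(refLen)
  for (i in seq_len(nrow(agg))) {
    ix <- agg$start[i]:min(agg$end[i], refLen)
    cov[ix] <- pmax(cov[ix], agg$r[i])
  }
  structure(list(sample = sample, peptides = agg, coverage = cov),
            class = "RelAbundanceProfile")
}

#' @export
print.RelAbundanceProfile <- function(x, ...) {
  cat(sprintf(
    "RelAbundanceProfile for sample '%s': %d peptide(s), max r = %.2f, %d residues\n",
    x$sample, nrow(x$peptides), max(x$peptides$r), length(x$coverage)))
  invisible(x)
}

#' Flag possible carry-over peptides in a profile
#'
#' Peptides whose relative abundance is below a fraction of the sample
#' maximum may reflect contamination from previous runs rather than genuine
#' band content.
#'
#' @param profile A \code{RelAbundanceProfile}.
#' @param threshold Fraction of the sample maximum (default 0.1).
#' @return The profile's peptide data frame with a logical
#'   \code{possible_carryover} column.
#' @export
flagContamination <- function(profile, threshold = 0.1) {
  pep <- profile$peptides
  pep$possible_carryover <- pep$r < threshold
  pep
}

#' Phosphosite occupancy from spectral counts
#'
#' Occupancy is the percentage of spectral counts covering the site that
#' carry the phosphorylated form, rounded to the nearest integer percent
#' (halves up).
#'
#' @param table A spectral-count table.
#' @param site 1-based residue position on the reference isoform.
#' @param sample Sample name.
#' @return A list of class \code{OccupancyEstimate}: \code{site},
#'   \code{sample}, \code{phospho_count}, \code{total_count},
#'   \code{percent}.
#' @examples
#' tab <- data.frame(sample = "b", peptide = c("AASPK", "AASPK"),
#'   ref_isoform = "P1", start = 430, end = 434,
#'   phospho_site = c(NA, 432), is_phospho = c(FALSE, TRUE),
#'   count = c(8, 1))
#' phosphoOccupancy(tab, 432, "b")$percent  # 11
#' @export
phosphoOccupancy <- function(table, site, sample) {
  validateSpectralCounts(table)
  rows <- table[table$sample == sample & table$start <= site &
                  table$end >= site, , drop = FALSE]
  total <- sum(rows$count)
  if (total == 0)
    pfStop("noCoverageError",
           "no spectral counts cover site %d in sample '%s'", site, sample)
  phospho <- sum(rows$count[rows$is_phospho &
                              !is.na(rows$phospho_site) &
                              rows$phospho_site == site])
  structure(list(site = site, sample = sample, phospho_count = phospho,
                 total_count = total,
                 percent = floor(100 * phospho / total + 0.5)),
            class = "OccupancyEstimate")
}

#' @export
print.OccupancyEstimate <- function(x, ...) {
  cat(sprintf("OccupancyEstimate: site %d, sample '%s': %d%% (%d of %d counts)\n",
              x$site, x$sample, x$percent, x$phospho_count, x$total_count))
  invisible(x)
}

#' Infer an N-terminal truncation boundary from a coverage profile
#'
#' Fits a two-level step model to the per-residue coverage c(pos): level 0
#' for pos < b and a constant level (the mean coverage of the covered
#' region) for pos >= b.  The boundary b minimizing the sum of squared
#' errors over all candidate positions is returned; ties go to the smallest
#' b, so a uniformly covered protein yields b = 1 (a full-length call).
#'
#' @param profile A \code{RelAbundanceProfile}, or a numeric coverage
#'   vector.
#' @param refLen Optional reference length; the coverage vector is padded
#'   with zeros or truncated to this length.
#' @return A list of class \code{BoundaryCall}: \code{boundary} (1-based
#'   residue), \code{nearest_peptide} (observed peptide whose start is
#'   closest to the boundary; NA for bare vectors), \code{sse}.
#' @export
inferStartBoundary <- function(profile, refLen = NULL) {
  cov <- if (is.numeric(profile)) profile else profile$coverage
  if (!is.null(refLen)) {
    cov <- cov[seq_len(min(length(cov), refLen))]
    if (length(cov) < refLen) cov <- c(cov, numeric(refLen - length(cov)))
  }
  n <- length(cov)
  if (n == 0L || all(cov == 0))
    pfStop("noSignalError", "coverage profile is uniformly zero")
  mu <- mean(cov[cov > 0])              # step level: mean of covered region
  # SSE(b) = sum_{pos<b} c^2 + sum_{pos>=b} (c - mu)^2, evaluated for all b
  lhs <- c(0, cumsum(cov^2))            # lhs[b] = sum_{pos<b} c^2
  rhs <- rev(c(0, cumsum(rev((cov - mu)^2))))  # rhs[b] = sum_{pos>=b} (c-mu)^2
  sseAll <- (lhs + rhs)[seq_len(n)]     # candidate b in [1, n]
  b <- which.min(sseAll)
  sse <- sseAll[b]
  nearest <- NA_character_
  if (!is.numeric(profile) && nrow(profile$peptides)) {
    pep <- profile$peptides
    nearest <- pep$peptide[which.min(abs(pep$start - b))]
  }
  structure(list(boundary = b, nearest_peptide = nearest, sse = sse),
            class = "BoundaryCall")
}

#' @export
print.BoundaryCall <- function(x, ...) {
  cat(sprintf("BoundaryCall: residue %d (nearest peptide %s), step-fit SSE %.3f\n",
              x$boundary, x$nearest_peptide, x$sse))
  invisible(x)
}

# cumulative prefix residue masses (kDa) for fast suffix-MW queries
prefixMassKda <- function(seq) {
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cumsum(AVG_RESIDUE_MASS[res]) / 1000
}

#' Assign a gel band to full-length or truncated isoform candidates
#'
#' Candidates are isoforms that carry the epitope of every detecting
#' antibody (non-detection excludes nothing: it may simply reflect low
#' abundance, and is applied as a configurable score penalty instead).  A
#' candidate explains the band's apparent mass either full-length (relative
#' mass error within \code{massTolFrac}) or as an N-terminal truncation:
#' when spectral counts for the band are supplied, the truncation start is
#' taken from \code{\link{inferStartBoundary}}; otherwise it is solved from
#' the apparent mass.  Candidates whose mass cannot be explained within
#' tolerance are reported flagged \code{modified_unexplained} rather than
#' silently dropped (a band running far above its theoretical weight
#' suggests post-translational modification).
#'
#' Scores combine mass closeness, the fraction of the band's spectral
#' counts carried by the candidate form, and the epitope penalty for
#' non-detecting probes; ties rank alphabetically.
#'
#' @param band A list with \code{band_id}, \code{apparent_mass_kda} (> 0)
#'   and \code{detections}, a named logical vector over probe names.
#' @param catalog A grouped \code{\linkS4class{IsoformCatalog}}.
#' @param specMat Specificity matrix from \code{\link{specificityMatrix}}
#'   covering all probes named in \code{detections}.
#' @param massTolFrac Relative mass tolerance (default 0.15).
#' @param counts Optional spectral-count table whose sample
#'   \code{band$band_id} holds the band's peptide observations.
#' @param refIsoform Reference isoform of the count coordinates (default:
#'   the longest isoform).
#' @param probes Optional list of \code{\linkS4class{EpitopeProbe}}s; when
#'   given, truncated candidates must retain every detecting antigen and
#'   the non-detection penalty is epitope-aware.
#' @param penaltyWeight Score penalty per non-detecting probe whose epitope
#'   the candidate carries (default 0.25).
#' @param weights Two weights, \code{mass} and \code{peptides}, for the
#'   score components (default 0.5 each).
#' @return A \code{data.frame} ranked by decreasing score: \code{candidate},
#'   \code{type} (\code{full_length}, \code{truncated},
#'   \code{modified_unexplained}), \code{truncation_start} (candidate
#'   coordinates), \code{theoretical_kda}, \code{rel_mass_err},
#'   \code{score}.  Zero rows if no isoform satisfies the detecting
#'   probes; eliminated isoforms are explained in
#'   \code{attr(, "diagnostics")}.
#' @export
assignBand <- function(band, catalog, specMat, massTolFrac = 0.15,
                       counts = NULL, refIsoform = NULL, probes = NULL,
                       penaltyWeight = 0.25,
                       weights = c(mass = 0.5, peptides = 0.5)) {
  if (is.null(band$apparent_mass_kda) || band$apparent_mass_kda <= 0)
    pfStop("schemaError", "band apparent mass must be positive")
  det <- band$detections
  if (is.null(names(det)) || !all(names(det) %in% rownames(specMat)))
    pfStop("schemaError", "specificity matrix must cover all band probes")
  A <- band$apparent_mass_kda
  isos <- isoformNames(catalog)
  seqs <- as.character(isoformSeqs(catalog))
  detecting <- names(det)[det]
  diag <- character(0)
  empty <- data.frame(candidate = character(0), type = character(0),
                      truncation_start = integer(0),
                      theoretical_kda = numeric(0), rel_mass_err = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(detecting) == 0L) {
    attr(empty, "diagnostics") <- "no detecting probe for this band"
    return(empty)
  }
  keep <- isos[colSums(specMat[detecting, isos, drop = FALSE] == 0L) == 0L]
  for (i in setdiff(isos, keep)) {
    miss <- detecting[specMat[detecting, i] == 0L]
    diag <- c(diag, sprintf("%s: lacks epitope of %s", i,
                            paste(miss, collapse = ",")))
  }
  if (is.null(refIsoform)) refIsoform <- isos[which.max(nchar(seqs))]
  refLenAa <- nchar(seqs[refIsoform])
  bRef <- NA_integer_
  bandCounts <- NULL
  if (!is.null(counts)) {
    bandCounts <- counts[counts$sample == band$band_id, , drop = FALSE]
    if (nrow(bandCounts) && sum(bandCounts$count) > 0) {
      prof <- relativeAbundance(counts, band$band_id, refLen = refLenAa)
      bRef <- inferStartBoundary(prof)$boundary
    } else bandCounts <- NULL
  }
  rows <- list()
  for (i in keep) {
    s <- seqs[i]
    L <- nchar(s)
    mw <- molecularWeight(s)
    relErr <- abs(mw - A) / mw
    type <- NA_character_; trunc <- NA_integer_; useMw <- mw; useSeq <- s
    if (relErr <= massTolFrac) {
      type <- "full_length"
    } else if (A < mw) {
      pm <- prefixMassKda(s)
      total <- pm[L] + WATER_MASS / 1000
      bCand <- NA_integer_
      if (!is.na(bRef)) {
        cand <- bRef - (refLenAa - L)   # map ref boundary via C-anchor
        if (cand >= 1L && cand <= L) bCand <- cand
      }
      if (is.na(bCand)) {
        suffMw <- total - c(0, pm[seq_len(L - 1L)])  # MW of suffix from b
        bCand <- which.min(abs(suffMw - A))
      }
      useMw <- total - if (bCand > 1L) pm[bCand - 1L] else 0
      relErr <- abs(useMw - A) / useMw
      if (relErr <= massTolFrac) {
        type <- "truncated"; trunc <- bCand
        useSeq <- substring(s, bCand)
      } else {
        type <- "modified_unexplained"; useMw <- mw
        relErr <- abs(mw - A) / mw
      }
    } else {
      type <- "modified_unexplained"
    }
    if (type == "truncated" && !is.null(probes)) {
      ok <- all(vapply(probes[vapply(probes, probeName, "") %in% detecting],
                       function(p) grepl(antigenSeq(p), useSeq, fixed = TRUE),
                       logical(1)))
      if (!ok) {
        diag <- c(diag, sprintf(
          "%s: truncation at %d removes a detecting epitope", i, trunc))
        next
      }
    }
    massScore <- max(0, 1 - relErr / massTolFrac)
    pepFrac <- 0
    if (!is.null(bandCounts)) {
      carried <- vapply(bandCounts$peptide, function(p)
        grepl(p, useSeq, fixed = TRUE), logical(1))
      pepFrac <- sum(bandCounts$count[carried]) / sum(bandCounts$count)
    }
    penalty <- 0
    if (!is.null(probes)) {
      nondet <- names(det)[!det]
      for (p in probes)
        if (probeName(p) %in% nondet &&
            grepl(antigenSeq(p), useSeq, fixed = TRUE))
          penalty <- penalty + penaltyWeight
    }
    score <- unname(weights["mass"]) * massScore +
      unname(weights["peptides"]) * pepFrac - penalty
    rows[[length(rows) + 1L]] <- data.frame(
      candidate = i, type = type, truncation_start = trunc,
      theoretical_kda = round(useMw, 2), rel_mass_err = relErr,
      score = score, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out)) {
    out <- out[order(-out$score, out$candidate), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "diagnostics") <- diag
  out
}
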