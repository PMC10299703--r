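checkFile <- function(path) {
  if (!file.exists(path))
    pfStop("fileError", "file not found: %s", path)
  path
}

#' Read and write the pipeline's file formats
#'
#' Genomes and protein sets travel as FASTA, transcript exon structures as
#' GFF3 (mRNA features with exon children linked by ID/Parent), tables as
#' header-carrying TSV, and ground truth as JSON.  All writers produce
#' files their readers restore to an equivalent in-memory representation.
#'
#' @param path File path.
#' @param x,genome,catalog,counts,bands,antigens Objects to write.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @return \code{readGenomeFasta}: a named \code{DNAStringSet}.
#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @export
readGenomeFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(checkFile(path))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname pipeline-io
#' @export
writeGenomeFasta <- function(genome, path)
  Biostrings::writeXStringSet(genome, path)

#' @rdname pipeline-io
#' @param transcripts A named \code{GRangesList} of exon models.
#' @importFrom rtracklayer export import
#' @importFrom GenomicRanges GRangesList mcols
#' @importFrom S4Vectors mcols<-
#' @export
writeTranscriptsGff3 <- function(transcripts, path) {
  rows <- list()
  for (id in names(transcripts)) {
    ex <- transcripts[[id]]
    mrna <- range(ex)
    S4Vectors::mcols(mrna) <- S4Vectors::DataFrame(
      type = "mRNA", ID = id, Parent = IRanges::CharacterList(list(character(0))))
    S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
      type = rep("exon", length(ex)), ID = rep(NA_character_, length(ex)),
      Parent = IRanges::CharacterList(as.list(rep(id, length(ex)))))
    rows[[length(rows) + 1L]] <- mrna
    rows[[length(rows) + 1L]] <- ex
  }
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname pipeline-io
#' @return \code{readTranscriptsGff3}: a named \code{GRangesList} of exons.
#' @export
readTranscriptsGff3 <- function(path) {
  gr <- rtracklayer::import(checkFile(path), format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L)
    pfStop("schemaError", "no exon features in %s", path)
  par <- as.character(unlist(ex$Parent))
  if (length(par) != length(ex))
    pfStop("schemaError", "every exon needs exactly one Parent attribute")
  S4Vectors::mcols(ex) <- NULL
  grl <- GenomicRanges::GRangesList(split(ex, par))
  # preserve mRNA declaration order where available
  mrna <- gr[gr$type == "mRNA"]
  if (length(mrna) && all(names(grl) %in% as.character(mrna$ID)))
    grl <- grl[as.character(mrna$ID)[as.character(mrna$ID) %in% names(grl)]]
  grl
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, required) {
  x <- utils::read.delim(checkFile(path), stringsAsFactors = FALSE)
  if (!all(required %in% names(x)))
    pfStop("schemaError", "%s must have columns: %s", path,
           paste(required, collapse = ", "))
  x
}

#' @rdname pipeline-io
#' @export
writeSpectralCounts <- function(counts, path) {
  validateSpectralCounts(counts)
  writeTsv(counts[SPECTRAL_COLS], path)
}

#' @rdname pipeline-io
#' @return \code{readSpectralCounts}: a validated spectral-count table.
#' @export
readSpectralCounts <- function(path) {
  x <- readTsv(path, SPECTRAL_COLS)
  x$is_phospho <- as.logical(x$is_phospho)
  validateSpectralCounts(x)
  x
}

#' @rdname pipeline-io
#' @export
writeAntigenTable <- function(antigens, path)
  writeTsv(data.frame(name = names(antigens), sequence = unname(antigens),
                      stringsAsFactors = FALSE), path)

#' @rdname pipeline-io
#' @return \code{readAntigenTable}: named character vector of antigens.
#' @export
readAntigenTable <- function(path) {
  x <- readTsv(path, c("name", "sequence"))
  stats::setNames(toupper(x$sequence), x$name)
}

#' @rdname pipeline-io
#' @export
writeBandTable <- function(bands, path) {
  rows <- lapply(bands, function(b) data.frame(
    band_id = b$band_id, apparent_mass_kda = b$apparent_mass_kda,
    detected = paste(names(b$detections)[b$detections], collapse = ","),
    not_detected = paste(names(b$detections)[!b$detections], collapse = ","),
    stringsAsFactors = FALSE))
  writeTsv(do.call(rbind, rows), path)
}

#' @rdname pipeline-io
#' @return \code{readBandTable}: a list of band-evidence lists
#'   (\code{band_id}, \code{apparent_mass_kda}, \code{detections}).
#' @export
readBandTable <- function(path) {
  x <- readTsv(path, c("band_id", "apparent_mass_kda", "detected",
                       "not_detected"))
  lapply(seq_len(nrow(x)), function(i) {
    det <- strsplit(x$detected[i], ",", fixed = TRUE)[[1L]]
    nod <- strsplit(x$not_detected[i], ",", fixed = TRUE)[[1L]]
    det <- det[nzchar(det)]; nod <- nod[nzchar(nod)]
    list(band_id = x$band_id[i],
         apparent_mass_kda = x$apparent_mass_kda[i],
         detections = stats::setNames(c(rep(TRUE, length(det)),
                                        rep(FALSE, length(nod))),
                                      c(det, nod)))
  })
}

#' @rdname pipeline-io
#' @export
writeCatalogFasta <- function(catalog, path)
  Biostrings::writeXStringSet(isoformSeqs(catalog), path)

#' @rdname pipeline-io
#' @export
writeCatalogTsv <- function(catalog, path) {
  info <- as.data.frame(isoformInfo(catalog))
  info$source_transcripts <- vapply(
    catalog@sourceTranscripts[info$name], paste, "", collapse = ",")
  info$nested_in <- ifelse(is.na(info$nestedIn), "",
                           paste0(info$nestedIn, ":", info$nestedAt))
  writeTsv(info[, c("name", "length", "ntermClass", "nested_in",
                    "source_transcripts")], path)
}

#' Write a simulated dataset to a directory
#'
#' Emits \code{genome.fa}, \code{transcripts.gff3}, \code{antigens.tsv},
#' \code{counts.tsv}, \code{bands.tsv} and \code{truth.json} — the file set
#' \code{\link{runPipeline}} consumes.
#'
#' @param sim A \code{\link{simulateDataset}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @importFrom jsonlite write_json read_json
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeFasta(sim$genome, file.path(dir, "genome.fa"))
  writeTranscriptsGff3(sim$transcripts, file.path(dir, "transcripts.gff3"))
  writeAntigenTable(sim$antigens, file.path(dir, "antigens.tsv"))
  writeSpectralCounts(sim$counts, file.path(dir, "counts.tsv"))
  writeBandTable(sim$bands, file.path(dir, "bands.tsv"))
  truth <- sim$truth
  jsonlite::write_json(list(
    flProtein = truth$flProtein,
    proteins = as.list(truth$proteins),
    expectedIsoforms = truth$expectedIsoforms,
    expectedClasses = truth$expectedClasses,
    nestedStarts = truth$nestedStarts,
    commonSuffixStart = truth$commonSuffixStart,
    mixture = truth$config$mixture,
    phosphoSites = truth$config$phosphoSites,
    bands = lapply(sim$bands, function(b) list(
      band_id = b$band_id, component = b$truth_component,
      truncation = b$truth_truncation))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis chain on a dataset directory
#'
#' Reads the genome, transcript models, antigen table, spectral counts and
#' band table; builds and groups the isoform catalog; maps every antigen
#' and forms the specificity matrix; computes per-band relative abundance
#' profiles, truncation-boundary calls and phosphosite occupancies; and
#' ranks isoform candidates for every band.
#'
#' @param dir Directory holding \code{genome.fa}, \code{transcripts.gff3},
#'   \code{antigens.tsv} and optionally \code{counts.tsv} / \code{bands.tsv}
#'   (see \code{\link{writeSimulatedData}}).
#' @param minCodons Catalog ORF-length floor.
#' @param massTolFrac Band-assignment mass tolerance.
#' @param outDir Optional directory for TSV reports (catalog, specificity
#'   matrix, boundary calls, occupancy table, per-band candidates).
#' @return A list: \code{catalog}, \code{probes}, \code{matrix},
#'   \code{profiles}, \code{boundaries}, \code{occupancy} (data frame),
#'   \code{assignments} (named list of ranked candidate data frames).
#' @export
runPipeline <- function(dir, minCodons = 30L, massTolFrac = 0.15,
                        outDir = NULL) {
  genome <- readGenomeFasta(file.path(dir, "genome.fa"))
  transcripts <- readTranscriptsGff3(file.path(dir, "transcripts.gff3"))
  antigens <- readAntigenTable(file.path(dir, "antigens.tsv"))
  catalog <- groupNtermClasses(buildCatalog(transcripts, genome,
                                            minCodons = minCodons))
  probes <- lapply(names(antigens), function(nm)
    mapEpitope(antigens[[nm]], catalog, name = nm))
  mat <- specificityMatrix(probes, catalog)
  res <- list(catalog = catalog, probes = probes, matrix = mat,
              profiles = list(), boundaries = list(),
              occupancy = NULL, assignments = list())
  countsPath <- file.path(dir, "counts.tsv")
  bandsPath <- file.path(dir, "bands.tsv")
  counts <- if (file.exists(countsPath)) readSpectralCounts(countsPath)
            else NULL
  refIso <- isoformNames(catalog)[which.max(nchar(as.character(
    isoformSeqs(catalog))))]
  refLen <- max(nchar(as.character(isoformSeqs(catalog))))
  if (!is.null(counts)) {
    occ <- list()
    for (s in unique(counts$sample)) {
      prof <- relativeAbundance(counts, s, refLen = refLen)
      res$profiles[[s]] <- prof
      res$boundaries[[s]] <- inferStartBoundary(prof)
      sites <- unique(counts$phospho_site[counts$sample == s &
                                            !is.na(counts$phospho_site)])
      for (site in sort(sites)) {
        o <- phosphoOccupancy(counts, site, s)
        occ[[length(occ) + 1L]] <- data.frame(
          sample = s, site = site, phospho = o$phospho_count,
          total = o$total_count, percent = o$percent)
      }
    }
    if (length(occ)) res$occupancy <- do.call(rbind, occ)
  }
  if (file.exists(bandsPath)) {
    for (band in readBandTable(bandsPath))
      res$assignments[[band$band_id]] <- assignBand(
        band, catalog, mat, massTolFrac = massTolFrac, counts = counts,
        refIsoform = refIso, probes = probes)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCatalogFasta(catalog, file.path(outDir, "isoforms.fa"))
    writeCatalogTsv(catalog, file.path(outDir, "isoforms.tsv"))
    writeTsv(data.frame(probe = rownames(mat), mat, check.names = FALSE),
             file.path(outDir, "specificity_matrix.tsv"))
    if (!is.null(res$occupancy))
      writeTsv(res$occupancy, file.path(outDir, "occupancy.tsv"))
    if (length(res$boundaries))
      writeTsv(data.frame(
        sample = names(res$boundaries),
        boundary = vapply(res$boundaries, `[[`, 0, "boundary"),
        nearest_peptide = vapply(res$boundaries, `[[`, "", "nearest_peptide")),
        file.path(outDir, "boundaries.tsv"))
    for (id in names(res$assignments))
      writeTsv(res$assignments[[id]],
               file.path(outDir, paste0("candidates_", id, ".tsv")))
  }
  res
}
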