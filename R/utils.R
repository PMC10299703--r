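# Internal helpers: classed errors and sequence checks.

pfStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "proteoformError", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")
AA_STANDARD20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

checkDna <- function(seq, what = "sequence") {
  seq <- toupper(as.character(seq))
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]),
                 DNA_ALPHABET_STRICT)
  if (length(bad))
    pfStop("alphabetError", "%s contains non-{A,C,G,T,N} base(s): %s",
           what, paste(bad, collapse = ","))
  seq
}

checkProtein <- function(seq, what = "sequence", allowX = TRUE) {
  seq <- toupper(as.character(seq))
  ok <- AA_STANDARD20
  if (allowX) ok <- c(ok, "X")
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), ok)
  if (length(bad))
    pfStop("alphabetError", "%s contains non-standard residue(s): %s",
           what, paste(bad, collapse = ","))
  seq
}

# codon vector of `seq` starting at 1-based `from`
codonsFrom <- function(seq, from) {
  n <- nchar(seq)
  starts <- seq.int(from, n - 2L, by = 3L)
  if (from > n - 2L) return(character(0))
  substring(seq, starts, starts + 2L)
}
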