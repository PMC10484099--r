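DNA_BASES <- c("A", "C", "G", "T")

clip01 <- function(x) pmin(1, pmax(0, x))

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Accept a sim_reference, a DNAStringSet or a named character vector and
# return the sequences as a named character vector.
ref_sequences <- function(reference) {
  if (inherits(reference, "sim_reference")) {
    return(reference$sequences)
  }
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
    if (is.null(names(out))) stop("reference sequences must be named", call. = FALSE)
    return(out)
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) stop("reference sequences must be named", call. = FALSE)
    return(reference)
  }
  stop("`reference` must be a sim_reference, DNAStringSet or named character vector",
    call. = FALSE
  )
}

chrom_lengths <- function(reference) {
  seqs <- ref_sequences(reference)
  stats::setNames(nchar(seqs), names(seqs))
}

# 0-based half-open substring of a reference chromosome.
seq_at <- function(seqs, chrom, start, end) {
  substr(seqs[[chrom]], start + 1L, end)
}

#' GC fraction of DNA strings
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector of GC fractions.
#' @export
gc_fraction_of <- function(seq) {
  stringr::str_count(seq, "[GCgc]") / nchar(seq)
}

fmt_interval <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start, end)
}
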