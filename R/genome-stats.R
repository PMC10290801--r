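# Assembly summary statistics.

#' GC content of a set of sequences
#'
#' (G + C) / (A + C + G + T) over all sequences pooled; ambiguity codes and N
#' are excluded from the denominator. Case-insensitive and invariant to how
#' the sequence is split across records.
#'
#' @param x A `Biostrings::DNAStringSet`, a character vector of sequences, or
#'   the path to a FASTA file.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (is.character(x))
    x <- Biostrings::DNAStringSet(toupper(x))
  if (length(x) == 0L || sum(Biostrings::width(x)) == 0L)
    stop("empty sequence input")
  freq <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  denom <- sum(freq)
  if (denom == 0) stop("no unambiguous A/C/G/T bases in input")
  unname((freq[["G"]] + freq[["C"]]) / denom)
}

#' N50 of an assembly
#'
#' The largest length L such that scaffolds of length >= L together cover at
#' least half of the total assembly (sorted-descending cumulative
#' convention).
#'
#' @param contig_lengths Positive integer vector of scaffold/contig lengths.
#' @return N50 length.
#' @export
n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) stop("empty length vector")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  len <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  len[which(cumsum(len) >= sum(len) / 2)[1]]
}

#' Assembly summary (scaffold count, total size, GC, N50)
#'
#' @param fasta Path to a genome FASTA, or a `DNAStringSet`.
#' @return A one-row data.frame: `n_scaffolds`, `total_bp`, `gc`, `n50`.
#' @export
assembly_stats <- function(fasta) {
  x <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  data.frame(
    n_scaffolds = length(x),
    total_bp = sum(Biostrings::width(x)),
    gc = gc_content(x),
    n50 = n50(Biostrings::width(x))
  )
}
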