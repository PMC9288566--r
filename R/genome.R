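#' Genome sequence container
#'
#' A light wrapper around a set of named chromosome sequences. Sequences are
#' stored as uppercase character strings over the alphabet A, C, G, T, N, and
#' all coordinates used throughout the package are 1-based and closed.
#'
#' @param seqs named character vector, one uppercase DNA string per chromosome.
#' @return An object of class `genome_sequence` with elements `seq` (named
#'   character vector), `chrom_names`, `lengths` (named integer vector) and
#'   `total_length`.
#' @export
genome_sequence <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosome sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name: ", names(seqs)[duplicated(names(seqs))][1])
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record: ", names(seqs)[nchar(seqs) == 0L][1])
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in chromosome ", names(seqs)[bad][1])
  lens <- nchar(seqs)
  names(lens) <- names(seqs)
  structure(
    list(seq = seqs, chrom_names = names(seqs), lengths = lens,
         total_length = sum(as.numeric(lens))),
    class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("Genome:", length(x$chrom_names), "chromosome(s),",
      format(x$total_length, big.mark = ","), "bp total\n")
  for (ch in utils::head(x$chrom_names, 10))
    cat("  ", ch, ": ", format(x$lengths[[ch]], big.mark = ","), " bp\n", sep = "")
  if (length(x$chrom_names) > 10) cat("  ...\n")
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' @param path path to a FASTA file.
#' @return A [genome_sequence()] object; sequences are uppercased and record
#'   order is preserved. Duplicate record names or empty records are errors.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- nm
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome a [genome_sequence()].
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Extract a genomic subsequence
#'
#' @param genome a [genome_sequence()].
#' @param chrom chromosome name.
#' @param start,end 1-based closed coordinates; both must lie within the
#'   chromosome.
#' @return Character string of length `end - start + 1`.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% genome$chrom_names) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 1L || end > len || start > end)
    stop(sprintf("coordinates [%d,%d] outside [1,%d] on %s", start, end, len, chrom))
  substring(genome$seq[[chrom]], start, end)
}

#' Single-base lookup, vectorized over positions
#'
#' @param genome a [genome_sequence()].
#' @param chrom chromosome name (scalar) or vector parallel to `pos`.
#' @param pos 1-based positions.
#' @return Character vector of single bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (!ch %in% genome$chrom_names) stop("unknown chromosome: ", ch)
    len <- genome$lengths[[ch]]
    if (any(pos[i] < 1L | pos[i] > len))
      stop("position outside [1,", len, "] on ", ch)
    out[i] <- substring(genome$seq[[ch]], pos[i], pos[i])
  }
  out
}

#' Base composition of a genome
#'
#' @param genome a [genome_sequence()].
#' @return Named numeric vector of A/C/G/T frequencies among non-N bases.
#' @export
genome_composition <- function(genome) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (ch in genome$chrom_names) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(genome$seq[[ch]]),
                                     c("A", "C", "G", "T"))
    counts <- counts + as.numeric(f)
  }
  counts / sum(counts)
}

REV_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings.
#' @return Reverse complements, preserving case-insensitivity by uppercasing.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    b <- rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])
    paste(REV_COMP[b], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
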