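#' Genome sequence container
#'
#' A lightweight accessor around a set of chromosome sequences. Sequences are
#' held as uppercase character strings so that many short windows can be
#' extracted quickly; soft-masked (lowercase) bases are uppercased on load and
#' masking is not interpreted.
#'
#' @param seqs named character vector or named list of DNA strings, or a
#'   [Biostrings::DNAStringSet].
#' @return An object of class `tfbs_genome` with elements `seqs` (named
#'   character vector) and `lengths` (named integer vector).
#' @examples
#' g <- genome_from_seqs(c(chr1 = "ACGTACGT"))
#' genome_context(g, "chr1", 4, flank = 2)
#' @export
genome_from_seqs <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  seqs <- vapply(seqs, function(s) toupper(as.character(s)), character(1))
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("genome sequences must be named by chromosome")
  }
  structure(
    list(seqs = seqs, lengths = vapply(seqs, nchar, integer(1))),
    class = "tfbs_genome"
  )
}

#' Read a genome from a FASTA file
#'
#' @param path path to an (uncompressed or gzipped) FASTA file.
#' @return A `tfbs_genome`.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the first token
  names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  genome_from_seqs(ss)
}

#' Write a genome to FASTA
#'
#' @param genome a `tfbs_genome`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @exportS3Method base::print
print.tfbs_genome <- function(x, ...) {
  cat("tfbs_genome:", length(x$seqs), "sequence(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

genome_chrom <- function(genome, chrom) {
  s <- genome$seqs[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  s
}

#' Extract the context window around a genomic position
#'
#' Returns the sequence from `pos - flank` to `pos + flank` (1-based,
#' inclusive); positions beyond the chromosome ends are padded with `N` so the
#' result always has width `2 * flank + 1`.
#'
#' @param genome a `tfbs_genome`.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param flank number of bases on each side.
#' @return A character string of length `2 * flank + 1`.
#' @export
genome_context <- function(genome, chrom, pos, flank) {
  extract_contexts(genome, chrom, pos, flank)
}

# vectorised context extraction for many positions on one chromosome
extract_contexts <- function(genome, chrom, pos, flank) {
  s <- genome_chrom(genome, chrom)
  L <- nchar(s)
  start <- pos - flank
  end <- pos + flank
  core <- substring(s, pmax(start, 1L), pmin(end, L))
  lp <- pmax(0L, 1L - start)
  rp <- pmax(0L, end - L)
  needs_pad <- lp > 0L | rp > 0L
  if (any(needs_pad)) {
    core[needs_pad] <- paste0(strrep("N", lp[needs_pad]), core[needs_pad],
                              strrep("N", rp[needs_pad]))
  }
  core
}

# reference base codes at 1-based positions of one chromosome
genome_base_codes <- function(genome, chrom, pos) {
  s <- genome_chrom(genome, chrom)
  .CODE_TABLE[utf8ToInt(s)][pos]
}

# replace single bases; `pos` 1-based, `base` character vector
genome_substitute <- function(genome, chrom, pos, base) {
  s <- genome_chrom(genome, chrom)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  ch[pos] <- base
  genome$seqs[[chrom]] <- paste(ch, collapse = "")
  genome
}
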