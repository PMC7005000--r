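#' Construct a genome object
#'
#' A genome is the coordinate frame for every downstream table: a replicon
#' identifier, its length in bp, an optional nucleotide sequence and a
#' circularity flag. All package coordinates are 0-based half-open;
#' conversions to the 1-based conventions of GenBank and SAM happen only at
#' file boundaries.
#'
#' @param length Genome length in bp (positive integer).
#' @param sequence Optional nucleotide string over A/C/G/T of exactly
#'   `length` characters.
#' @param id Replicon label.
#' @param circular Logical; circular replicons join the terminal intergenic
#'   gap across the origin.
#' @return An object of class `tn_genome`.
#' @export
#' @examples
#' g <- tn_genome(1000)
#' g$length
tn_genome <- function(length, sequence = NULL, id = "genome", circular = FALSE) {
  assert_that(is.numeric(length) && length(length) == 1 && length >= 1,
              "genome `length` must be a positive integer",
              class = "tnseqsi_invalid_argument")
  length <- as.integer(length)
  if (!is.null(sequence)) {
    assert_that(nchar(sequence) == length,
                sprintf("sequence has %d characters but length is %d",
                        nchar(sequence), length),
                class = "tnseqsi_invalid_argument")
    assert_that(!grepl("[^ACGT]", sequence),
                "sequence may contain only A, C, G, T",
                class = "tnseqsi_invalid_argument")
  }
  structure(list(id = id, length = length, sequence = sequence,
                 circular = isTRUE(circular)),
            class = "tn_genome")
}

#' @export
print.tn_genome <- function(x, ...) {
  cat(sprintf("<tn_genome> %s: %s bp, %s, sequence %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

#' Simulate a random genome sequence
#'
#' Draws an i.i.d. nucleotide sequence with a target GC fraction. Used by the
#' selection-screen simulator so that emitted reads can be located back onto
#' the genome without external data.
#'
#' @param length Genome length in bp.
#' @param gc Expected GC fraction in \[0, 1\].
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @inheritParams tn_genome
#' @return A `tn_genome` with a sequence.
#' @export
#' @examples
#' make_genome(100, gc = 0.5, seed = 1)
make_genome <- function(length, gc = 0.5, seed = 1L, id = "sim_genome",
                        circular = FALSE) {
  assert_that(is.numeric(length) && length(length) == 1 && length >= 1,
              "genome `length` must be a positive integer",
              class = "tnseqsi_invalid_argument")
  assert_that(gc >= 0 && gc <= 1, "`gc` must lie in [0, 1]",
              class = "tnseqsi_invalid_argument")
  length <- as.integer(length)
  seq <- with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  tn_genome(length, sequence = seq, id = id, circular = circular)
}

# Extract genome[start0, start0 + len) in 0-based half-open coordinates,
# truncating at linear ends and wrapping on circular genomes.
genome_subseq <- function(genome, start0, len) {
  L <- genome$length
  if (genome$circular) {
    idx <- (seq.int(start0, length.out = len) %% L) + 1L
    return(paste(strsplit(genome$sequence, "")[[1]][idx], collapse = ""))
  }
  from <- max(0L, start0)
  to <- min(L, start0 + len)
  if (to <= from) return("")
  substr(genome$sequence, from + 1L, to)
}

#' Write a genome to FASTA
#'
#' @param genome A `tn_genome` with a sequence.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  assert_that(!is.null(genome$sequence), "genome has no sequence to write")
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a single-replicon genome from FASTA
#'
#' @param path FASTA file with exactly one record.
#' @param circular Circularity flag (FASTA does not carry one).
#' @return A `tn_genome`.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  assert_that(length(x) == 1,
              "multi-record FASTA: single-replicon genomes only",
              class = "tnseqsi_format_error")
  tn_genome(Biostrings::width(x)[1], sequence = as.character(x[[1]]),
            id = sub("\\s.*$", "", names(x)[1]), circular = circular)
}
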