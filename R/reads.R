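#' Default transposon-junction sequence
#'
#' The transposon-genome junction that prefixes every sequencing read. Real
#' libraries define this through their junction PCR primers; the constant
#' here is a placeholder used consistently by the simulator and the trimmer
#' and should be overridden with the experiment's own junction for real
#' data.
#'
#' @return A nucleotide string.
#' @export
tn_junction <- function() "TGACTCGCAA"

#' Emit transposon-junction sequencing reads
#'
#' Converts simulated site tables into FASTQ-style reads mimicking the
#' junction-PCR library structure: each read is the junction sequence,
#' followed by the genomic sequence starting at the insertion position and
#' extending in the site orientation (reverse-orientation sites yield the
#' reverse complement), followed by a poly(C) tail from the terminal
#' transferase step, all truncated to the read length. A site with count k
#' yields exactly k reads. Fragments running past a linear genome end are
#' truncated (with a message), never an error.
#'
#' @param sites Site-count tibble (`sample_id`, `position`, `orientation`,
#'   `count`), e.g. from [simulate_selection()].
#' @param genome A `tn_genome` with a sequence.
#' @param junction Junction nucleotide string prefixing every read.
#' @param fragment_len_range Sonication fragment length range in bp
#'   (default 200-600).
#' @param polyc_len_range Poly(C) tail length range (default 5-20; tail
#'   lengths are drawn uniformly — real tail lengths are not observable, only
#'   the tail's presence).
#' @param read_len Read length in bp (default 50).
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `read_id`, `sequence`,
#'   `quality` (constant qualities).
#' @export
emit_reads <- function(sites, genome, junction = tn_junction(),
                       fragment_len_range = c(200L, 600L),
                       polyc_len_range = c(5L, 20L),
                       read_len = 50L, seed = 1L) {
  stopifnot(inherits(genome, "tn_genome"))
  assert_that(!is.null(genome$sequence), "genome needs a sequence to emit reads",
              class = "tnseqsi_invalid_argument")
  assert_that(nchar(junction) > 0, "junction must be non-empty",
              class = "tnseqsi_invalid_argument")
  assert_that(read_len > nchar(junction),
              "read_len must exceed the junction length",
              class = "tnseqsi_invalid_argument")
  sites <- as_tibble(sites)
  reads <- filter(sites, .data$count > 0)
  if (nrow(reads) == 0) {
    return(tibble(sample_id = character(0), read_id = character(0),
                  sequence = character(0), quality = character(0)))
  }
  reads <- tidyr::uncount(reads, weights = .data$count, .id = "copy")
  L <- genome$length
  jlen <- nchar(junction)
  with_seed(seed, {
    frag_len <- sample(seq(fragment_len_range[1], fragment_len_range[2]),
                       nrow(reads), replace = TRUE)
    polyc <- sample(seq(polyc_len_range[1], polyc_len_range[2]),
                    nrow(reads), replace = TRUE)
    # genomic bases that can appear in the read
    gmax <- pmin(frag_len, read_len - jlen)
    fwd <- reads$orientation == "+"
    from <- ifelse(fwd, reads$position, pmax(0L, reads$position - gmax + 1L))
    to <- ifelse(fwd, pmin(L, reads$position + gmax), reads$position + 1L)
    if (!genome$circular && any(ifelse(fwd, reads$position + gmax > L, reads$position - gmax + 1L < 0))) {
      message("some fragments extend past a linear genome end; truncated")
    }
    frag <- substring(genome$sequence, from + 1L, to)
    frag[!fwd] <- revcomp(frag[!fwd])
    seqs <- substr(paste0(junction, frag, strrep("C", polyc)), 1L, read_len)
    tibble(sample_id = reads$sample_id,
           read_id = sprintf("%s_%d_%s_%d", reads$sample_id, reads$position,
                             ifelse(fwd, "f", "r"), reads$copy),
           sequence = seqs,
           quality = strrep("I", nchar(seqs)))
  })
}

#' Write reads to FASTQ (one file per sample)
#'
#' @param reads Tibble from [emit_reads()].
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix.
#' @return A named character vector of written paths, invisibly.
#' @export
write_fastq <- function(reads, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (sm in unique(reads$sample_id)) {
    r <- filter(reads, .data$sample_id == sm)
    path <- file.path(dir, sprintf("%s_%s.fastq", prefix, sm))
    x <- Biostrings::DNAStringSet(r$sequence)
    names(x) <- r$read_id
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(r$quality))
    paths[sm] <- path
  }
  invisible(paths)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (gzipped accepted).
#' @param sample_id Sample label to attach.
#' @return A tibble with `sample_id`, `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(sample_id = sample_id,
         read_id = sub("\\s.*$", "", names(x)),
         sequence = as.character(x),
         quality = as.character(S4Vectors::mcols(x)$qualities))
}
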