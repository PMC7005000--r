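#' Trim junction and poly(C) tail from transposon-junction reads
#'
#' Each sequencing read is expected to start with the transposon-genome
#' junction and may end in the poly(C) tail added by terminal transferase.
#' Trimming removes the junction prefix (which must match within
#' `max_junction_mismatch` substitutions, otherwise the read is rejected as
#' `no_junction`), then strips the maximal 3' run of C when that run is at
#' least `min_polyc_run` long (shorter or absent runs are left untouched —
#' they are indistinguishable from genomic C's). Reads whose remaining
#' genomic fragment is shorter than `min_fragment_len` are rejected as
#' `too_short`. Empty or junction-less reads are rejections, never errors.
#'
#' @param reads A tibble with at least `read_id` and `sequence` columns
#'   (e.g. from [read_fastq()] or [emit_reads()]).
#' @param junction Junction nucleotide string.
#' @param max_junction_mismatch Maximum substitutions tolerated in the
#'   junction prefix (default 1).
#' @param min_polyc_run Minimum length of a 3' C run for it to be treated as
#'   tail and removed (default 5).
#' @param min_fragment_len Minimum genomic fragment length after trimming
#'   (default 20).
#' @return The input tibble with added columns `fragment` (NA unless kept)
#'   and `trim_status` (`"pass"`, `"no_junction"`, `"too_short"`).
#' @export
trim_reads <- function(reads, junction = tn_junction(),
                       max_junction_mismatch = 1L, min_polyc_run = 5L,
                       min_fragment_len = 20L) {
  assert_that(nchar(junction) > 0, "junction must be non-empty",
              class = "tnseqsi_invalid_argument")
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    return(mutate(reads, fragment = character(0), trim_status = character(0)))
  }
  seqs <- reads$sequence %||% ""
  mism <- prefix_mismatches(seqs, junction)
  rest <- substr(seqs, nchar(junction) + 1L, nchar(seqs))
  run <- nchar(rest) - nchar(sub("C*$", "", rest))
  frag <- ifelse(run >= min_polyc_run,
                 substr(rest, 1L, nchar(rest) - run), rest)
  status <- dplyr::case_when(
    mism > max_junction_mismatch ~ "no_junction",
    nchar(frag) < min_fragment_len ~ "too_short",
    TRUE ~ "pass")
  mutate(reads,
         fragment = ifelse(status == "pass", frag, NA_character_),
         trim_status = status)
}

#' Place genomic fragments on a genome by exact search
#'
#' A desk-scale stand-in for an external aligner: each fragment is searched
#' exactly against the genome and its reverse complement. A unique hit is a
#' placement; the reported position is the coordinate of the fragment's
#' first base — the genomic base adjacent to the transposon junction — so a
#' reverse-complement hit reports the *last* coordinate of the match with
#' orientation `-`. Zero hits give `unmapped`, multiple hits `ambiguous`.
#' Real genome-scale data should go through an aligner and enter via
#' [ingest_alignments()] instead.
#'
#' @param trimmed Tibble from [trim_reads()] (rows with `trim_status !=
#'   "pass"` are carried through with their rejection status), or any tibble
#'   with `read_id` and `fragment` columns.
#' @param genome A `tn_genome` with a sequence.
#' @return A placement tibble: `read_id`, `position` (0-based, NA unless
#'   placed), `orientation`, `status` (`placed`, `unmapped`, `ambiguous`,
#'   `no_junction`, `too_short`).
#' @export
locate_fragments <- function(trimmed, genome) {
  stopifnot(inherits(genome, "tn_genome"))
  assert_that(!is.null(genome$sequence), "genome needs a sequence",
              class = "tnseqsi_invalid_argument")
  trimmed <- as_tibble(trimmed)
  if (!"trim_status" %in% names(trimmed)) trimmed$trim_status <- "pass"
  subject <- Biostrings::DNAString(genome$sequence)

  todo <- filter(trimmed, .data$trim_status == "pass")
  uniq <- unique(todo$fragment)
  hit_tab <- purrr::map(uniq, function(fr) {
    fwd <- Biostrings::start(Biostrings::matchPattern(fr, subject))
    rev <- Biostrings::matchPattern(revcomp(fr), subject)
    nh <- length(fwd) + length(rev)
    if (nh == 1L) {
      if (length(fwd) == 1L) {
        list(status = "placed", position = fwd - 1L, orientation = "+")
      } else {
        list(status = "placed",
             position = Biostrings::start(rev) + Biostrings::width(rev) - 2L,
             orientation = "-")
      }
    } else if (nh == 0L) {
      list(status = "unmapped", position = NA_integer_, orientation = NA_character_)
    } else {
      list(status = "ambiguous", position = NA_integer_, orientation = NA_character_)
    }
  })
  lut <- tibble(fragment = uniq,
                position = purrr::map_int(hit_tab, ~ as.integer(.x$position)),
                orientation = purrr::map_chr(hit_tab, "orientation"),
                status = purrr::map_chr(hit_tab, "status"))
  placed <- todo |>
    left_join(lut, by = "fragment") |>
    select("read_id", "position", "orientation", "status")
  rejected <- trimmed |>
    filter(.data$trim_status != "pass") |>
    transmute(.data$read_id, position = NA_integer_,
              orientation = NA_character_, status = .data$trim_status)
  bind_rows(placed, rejected)
}

# Reference-space span of a CIGAR string (M/=/X/D/N consume reference).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    if (length(ops) == 0 || nchar(cg) != sum(nchar(ops))) return(NA_integer_)
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    type <- sub("^\\d+", "", ops)
    sum(n[type %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Ingest external alignments (SAM or BED6)
#'
#' The entry point for real data mapped with an external aligner such as
#' Bowtie. Primary mapped records are converted to insertion placements:
#' for a forward-strand alignment the insertion position is the leftmost
#' aligned base (SAM `POS` - 1); for a reverse-strand alignment it is the
#' rightmost aligned base, because the junction-adjacent genomic base is the
#' one nearest the transposon regardless of strand. Unmapped, secondary and
#' supplementary records are dropped and counted. BED6 intervals (0-based
#' half-open) map to their `start` (`+`) or `end - 1` (`-`).
#'
#' @param path Path to a SAM or 6-column BED file.
#' @param format `"auto"` (by extension), `"sam"` or `"bed"`.
#' @return A placement tibble (`read_id`, `position`, `orientation`,
#'   `status = "placed"`), with attribute `dropped` giving counts of
#'   discarded records by reason (`conservation: placed + dropped = input
#'   records`).
#' @export
ingest_alignments <- function(path, format = c("auto", "sam", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "sam"
  }
  if (format == "sam") ingest_sam(path) else ingest_bed(path)
}

ingest_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body_idx <- which(!startsWith(lines, "@"))
  dropped <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort(sprintf("malformed SAM record at line %d: %d fields", i, length(f)),
            class = c("tnseqsi_format_error", "tnseqsi_error"))
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) {
      abort(sprintf("malformed SAM record at line %d: bad FLAG or POS", i),
            class = c("tnseqsi_format_error", "tnseqsi_error"))
    }
    if (bitwAnd(flag, 4L) != 0L) { dropped["unmapped"] <- dropped["unmapped"] + 1L; next }
    if (bitwAnd(flag, 256L) != 0L) { dropped["secondary"] <- dropped["secondary"] + 1L; next }
    if (bitwAnd(flag, 2048L) != 0L) { dropped["supplementary"] <- dropped["supplementary"] + 1L; next }
    span <- cigar_ref_span(f[6])
    if (is.na(span) || span < 1L) {
      abort(sprintf("malformed SAM record at line %d: unparseable CIGAR '%s'", i, f[6]),
            class = c("tnseqsi_format_error", "tnseqsi_error"))
    }
    minus <- bitwAnd(flag, 16L) != 0L
    rows[[k]] <- tibble(read_id = f[1],
                        position = if (minus) pos - 1L + span - 1L else pos - 1L,
                        orientation = if (minus) "-" else "+",
                        status = "placed")
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(read_id = character(0), position = integer(0),
                  orientation = character(0), status = character(0))
  }
  if (sum(dropped) > 0) {
    message(sprintf("dropped %d records (%d unmapped, %d secondary, %d supplementary)",
                    sum(dropped), dropped["unmapped"], dropped["secondary"],
                    dropped["supplementary"]))
  }
  structure(out, dropped = dropped, n_input = length(body_idx))
}

ingest_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         col_types = "ciicdc", progress = FALSE)
  bad <- which(is.na(bed$start) | is.na(bed$end) | !bed$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED record at line %d", bad[1]),
          class = c("tnseqsi_format_error", "tnseqsi_error"))
  }
  out <- tibble(read_id = bed$name,
                position = as.integer(ifelse(bed$strand == "+", bed$start,
                                             bed$end - 1L)),
                orientation = bed$strand,
                status = "placed")
  structure(out, dropped = c(unmapped = 0L, secondary = 0L, supplementary = 0L),
            n_input = nrow(bed))
}
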