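# GenBank flat-file I/O. Only what a Tn-seq aggregation needs is handled:
# the LOCUS length, gene/CDS feature spans (with complement/join locations
# resolved to their min..max extent) and locus_tag/gene qualifiers, plus the
# ORIGIN sequence when present. No installed R package parses GenBank
# feature tables, so this is a purpose-built minimal parser.

#' Read a GenBank annotation
#'
#' Parses a single-replicon GenBank flat file into an annotation set: one
#' feature per gene, identified by `locus_tag` (falling back to the `gene`
#' qualifier, then a positional id). When a gene and a CDS share an id the
#' gene span is preferred. `join(...)`/`complement(...)` locations are
#' resolved to their min..max span with the feature's strand. GenBank's
#' 1-based inclusive coordinates are converted to the package's 0-based
#' half-open convention. Intergenic regions are not derived here; call
#' [derive_intergenic()] on the result.
#'
#' @param path Path to a GenBank flat file.
#' @return A `tn_annotation` containing gene features only.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  assert_that(length(locus) >= 1, "no LOCUS line found",
              class = "tnseqsi_format_error")
  m <- regmatches(locus[1], regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp", locus[1]))[[1]]
  assert_that(length(m) == 3, "cannot parse LOCUS line for genome length",
              class = "tnseqsi_format_error")
  id <- m[2]
  L <- as.integer(m[3])
  circular <- grepl("\\bcircular\\b", locus[1], ignore.case = TRUE)

  fstart <- grep("^FEATURES", lines)
  assert_that(length(fstart) >= 1, "no FEATURES section found",
              class = "tnseqsi_format_error")
  fend <- c(grep("^(ORIGIN|CONTIG|//)", lines), length(lines) + 1L)
  fend <- min(fend[fend > fstart[1]])
  flines <- lines[seq(fstart[1] + 1L, fend - 1L)]

  feats <- list()
  cur <- NULL
  for (i in seq_along(flines)) {
    ln <- flines[i]
    if (grepl("^ {5}\\S", ln)) {                     # new feature key
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- trimws(substr(ln, 6, 20))
      cur <- list(key = key, loc = trimws(substr(ln, 21, nchar(ln))),
                  quals = character(0), in_loc = TRUE)
    } else if (!is.null(cur) && grepl("^ +/", ln)) { # qualifier
      cur$quals <- c(cur$quals, trimws(ln))
      cur$in_loc <- FALSE
    } else if (!is.null(cur)) {                      # continuation
      if (cur$in_loc) {
        cur$loc <- paste0(cur$loc, trimws(ln))
      } else if (length(cur$quals) > 0) {
        cur$quals[length(cur$quals)] <-
          paste0(cur$quals[length(cur$quals)], trimws(ln))
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur

  qual_value <- function(quals, name) {
    hit <- grep(sprintf("^/%s=", name), quals, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    gsub('^/[^=]+="?|"$', "", hit[1])
  }
  parse_location <- function(loc, key) {
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- suppressWarnings(as.integer(
      regmatches(loc, gregexpr("[0-9]+", loc))[[1]]))
    assert_that(length(nums) >= 1 && !anyNA(nums),
                sprintf("unparseable location '%s' in %s feature", loc, key),
                class = "tnseqsi_format_error")
    list(start = min(nums) - 1L, end = max(nums), strand = strand)
  }

  rows <- purrr::map(feats, function(f) {
    if (!f$key %in% c("gene", "CDS")) return(NULL)
    loc <- parse_location(f$loc, f$key)
    tibble(feature_id = qual_value(f$quals, "locus_tag"),
           gene_name = qual_value(f$quals, "gene"),
           key = f$key, kind = "gene",
           start = loc$start, end = loc$end, strand = loc$strand)
  })
  genes <- bind_rows(rows)
  assert_that(nrow(genes) > 0, "no gene or CDS features found",
              class = "tnseqsi_format_error")
  genes <- genes |>
    mutate(feature_id = coalesce(.data$feature_id, .data$gene_name,
                                 sprintf("feat_%04d", row_number()))) |>
    # gene preferred over CDS when both carry the same id
    arrange(.data$feature_id, match(.data$key, c("gene", "CDS"))) |>
    distinct(.data$feature_id, .keep_all = TRUE) |>
    arrange(.data$start) |>
    select("feature_id", "kind", "start", "end", "strand")

  seq <- NULL
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) >= 1) {
    oend <- grep("^//", lines)
    oend <- if (any(oend > ostart[1])) min(oend[oend > ostart[1]]) else length(lines) + 1L
    body <- lines[seq(ostart[1] + 1L, oend - 1L)]
    seq <- toupper(gsub("[^acgtACGT]", "", paste(body, collapse = "")))
    if (nchar(seq) != L) seq <- NULL   # tolerate ambiguity codes by dropping
  }
  tn_annotation(tn_genome(L, sequence = seq, id = id, circular = circular),
                genes)
}

#' Write a minimal GenBank flat file
#'
#' Emits a LOCUS line, a FEATURES table (genes as `gene` records, intergenic
#' regions as `misc_feature` records, both with a `/locus_tag`), and the
#' ORIGIN sequence when the genome carries one. Coordinates are converted
#' back to GenBank's 1-based inclusive convention.
#'
#' @param annotation A `tn_annotation`.
#' @param path Output file path.
#' @param include_intergenic Write intergenic features as well as genes.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(annotation, path, include_intergenic = TRUE) {
  stopifnot(inherits(annotation, "tn_annotation"))
  g <- annotation$genome
  f <- annotation$features
  if (!include_intergenic) f <- filter(f, .data$kind == "gene")
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   UNA",
                   g$id, g$length, if (g$circular) "circular" else "linear"),
           sprintf("DEFINITION  %s", g$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", g$length))
  for (i in seq_len(nrow(f))) {
    key <- if (f$kind[i] == "gene") "gene" else "misc_feature"
    end1 <- min(f$end[i], g$length)   # wrap-around features clamp at origin
    loc <- sprintf("%d..%d", f$start[i] + 1L, end1)
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    out <- c(out,
             sprintf("     %-15s %s", key, loc),
             sprintf("                     /locus_tag=\"%s\"", f$feature_id[i]))
  }
  if (!is.null(g$sequence)) {
    out <- c(out, "ORIGIN")
    starts <- seq(1L, g$length, by = 60L)
    rows <- vapply(starts, function(s) {
      chunk <- substr(g$sequence, s, min(s + 59L, g$length))
      blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      sprintf("%9d %s", s, tolower(paste(blocks, collapse = " ")))
    }, character(1))
    out <- c(out, rows)
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write an annotation as GFF3
#'
#' @param annotation A `tn_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "tn_annotation"))
  g <- annotation$genome
  f <- annotation$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", g$id, g$length))
  type <- ifelse(f$kind == "gene", "gene", "region")
  strand <- ifelse(f$strand %in% c("+", "-"), f$strand, ".")
  lines <- c(lines, sprintf("%s\ttnseqsi\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                            g$id, type, f$start + 1L,
                            pmin(f$end, g$length), strand, f$feature_id))
  writeLines(lines, path)
  invisible(path)
}
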