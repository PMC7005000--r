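#' Enumerate insertion sites from placements
#'
#' Collapses placed reads into the unit of Tn-seq analysis: the insertion
#' site, keyed by (position, orientation), with its read count. Total reads
#' are conserved: counts sum to the number of placed reads.
#'
#' @param placements Placement tibble; every row must have
#'   `status == "placed"` (filter rejections out first — passing them in is
#'   a contract violation and errors).
#' @param sample_id Sample label for the resulting table.
#' @return A site tibble: `sample_id`, `position`, `orientation`, `count`.
#' @export
#' @examples
#' pl <- tibble::tibble(read_id = c("a", "b", "c"),
#'                      position = c(5L, 5L, 9L),
#'                      orientation = c("+", "+", "-"),
#'                      status = "placed")
#' enumerate_sites(pl, "s1")
enumerate_sites <- function(placements, sample_id) {
  placements <- as_tibble(placements)
  assert_that(all(placements$status == "placed"),
              "enumerate_sites() requires placed records only",
              class = "tnseqsi_contract_error")
  placements |>
    count(.data$position, .data$orientation, name = "count") |>
    mutate(sample_id = sample_id, .before = 1) |>
    arrange(.data$position, .data$orientation)
}

#' Aggregate site counts onto genes and intergenic regions
#'
#' Assigns every insertion site to each feature whose half-open interval
#' \[start, end) contains its position — membership uses only the position,
#' never the orientation — and tallies, per feature and sample, the number
#' of distinct sites with at least one read (`n_sites`) and the summed
#' reads (`actual_reads`). With a gene + intergenic tiling every site is
#' assigned; sites covered by no feature are counted into an `unassigned`
#' attribute. A site under overlapping features counts fully toward each of
#' them (per-feature completeness matters more for the survival index than
#' global additivity; read conservation is then relaxed).
#'
#' @param sites Site tibble (`sample_id`, `position`, `orientation`,
#'   `count`), one or more samples.
#' @param annotation A `tn_annotation`.
#' @return A tibble with one row per feature per sample: `feature_id`,
#'   `kind`, `sample_id`, `n_sites`, `actual_reads`; attributes
#'   `unassigned` (per-sample reads in no feature) and `sample_totals`
#'   (per-sample total reads). Positions at or beyond the genome length are
#'   a contract violation.
#' @export
aggregate_counts <- function(sites, annotation) {
  stopifnot(inherits(annotation, "tn_annotation"))
  sites <- as_tibble(sites)
  L <- annotation$genome$length
  assert_that(all(sites$position >= 0 & sites$position < L),
              "site position outside [0, genome length)",
              class = "tnseqsi_contract_error")
  f <- annotation$features
  fr <- feature_ranges(annotation)

  usite <- distinct(sites, .data$sample_id, .data$position, .data$orientation,
                    .data$count)
  hits <- IRanges::findOverlaps(IRanges::IRanges(usite$position + 1L, width = 1L),
                                fr$ranges)
  assigned <- tibble(row = S4Vectors::queryHits(hits),
                     feature_row = fr$feature_row[S4Vectors::subjectHits(hits)])
  tallies <- assigned |>
    mutate(sample_id = usite$sample_id[.data$row],
           count = usite$count[.data$row],
           feature_id = f$feature_id[.data$feature_row]) |>
    group_by(.data$feature_id, .data$sample_id) |>
    summarise(n_sites = sum(.data$count > 0),
              actual_reads = sum(.data$count), .groups = "drop")

  grid <- tidyr::expand_grid(feature_id = f$feature_id,
                             sample_id = unique(sites$sample_id))
  out <- grid |>
    left_join(tallies, by = c("feature_id", "sample_id")) |>
    mutate(n_sites = as.integer(coalesce(.data$n_sites, 0L)),
           actual_reads = as.integer(coalesce(.data$actual_reads, 0L))) |>
    left_join(select(f, "feature_id", "kind"), by = "feature_id") |>
    select("feature_id", "kind", "sample_id", "n_sites", "actual_reads") |>
    arrange(match(.data$feature_id, f$feature_id), .data$sample_id)

  covered <- unique(S4Vectors::queryHits(hits))
  unassigned <- usite[setdiff(seq_len(nrow(usite)), covered), ] |>
    group_by(.data$sample_id) |>
    summarise(reads = sum(.data$count), n_sites = sum(.data$count > 0),
              .groups = "drop")
  totals <- sites |>
    group_by(.data$sample_id) |>
    summarise(total_reads = sum(.data$count), .groups = "drop")
  if (nrow(unassigned) > 0 && sum(unassigned$reads) > 0) {
    message(sprintf("%d reads at sites outside every feature (unassigned)",
                    sum(unassigned$reads)))
  }
  structure(out, unassigned = unassigned, sample_totals = totals,
            genome_length = L)
}

#' Write per-sample site tables as TSV
#'
#' One file per sample with columns `position`, `orientation`, `count`.
#'
#' @param sites Site tibble.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Named vector of paths, invisibly.
#' @export
write_site_tables <- function(sites, dir, prefix = "sites") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (sm in unique(sites$sample_id)) {
    path <- file.path(dir, sprintf("%s_%s.tsv", prefix, sm))
    sites |>
      filter(.data$sample_id == sm) |>
      select("position", "orientation", "count") |>
      readr::write_tsv(path, progress = FALSE)
    paths[sm] <- path
  }
  invisible(paths)
}

#' Read a site table written by [write_site_tables()]
#'
#' @param path TSV with columns `position`, `orientation`, `count`.
#' @param sample_id Sample label to attach.
#' @return A site tibble.
#' @export
read_site_table <- function(path, sample_id) {
  readr::read_tsv(path, col_types = "icd", progress = FALSE) |>
    mutate(sample_id = sample_id, count = as.integer(.data$count), .before = 1)
}
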