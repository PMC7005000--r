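#' Construct an annotation set
#'
#' An annotation set pairs a genome with a feature table: gene features (from
#' an annotation file or the simulator) plus derived intergenic features, all
#' as 0-based half-open intervals. It is the frame onto which insertion sites
#' are aggregated.
#'
#' On circular genomes a single intergenic feature may wrap across the
#' origin; such a feature is stored with `end > genome length`, meaning the
#' interval \[start, end) taken modulo the genome length. `feature_length()`
#' is `end - start` in all cases.
#'
#' @param genome A `tn_genome`.
#' @param features A data frame with columns `feature_id`, `kind`
#'   (`"gene"` or `"intergenic"`), `start`, `end`, `strand` (`"+"`, `"-"`
#'   or `"."`).
#' @return An object of class `tn_annotation`.
#' @export
tn_annotation <- function(genome, features) {
  stopifnot(inherits(genome, "tn_genome"))
  features <- as_tibble(features)
  needed <- c("feature_id", "kind", "start", "end", "strand")
  assert_that(all(needed %in% names(features)),
              paste("features must have columns:", paste(needed, collapse = ", ")),
              class = "tnseqsi_invalid_argument")
  features <- features[, needed]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  assert_that(!anyDuplicated(features$feature_id),
              "feature_id values must be unique",
              class = "tnseqsi_invalid_argument")
  assert_that(all(features$start >= 0) && all(features$end > features$start),
              "features need 0 <= start < end",
              class = "tnseqsi_invalid_argument")
  limit <- if (genome$circular) 2L * genome$length else genome$length
  assert_that(all(features$end <= limit),
              "feature end beyond genome length",
              class = "tnseqsi_invalid_argument")
  assert_that(all(features$kind %in% c("gene", "intergenic")),
              "feature kind must be 'gene' or 'intergenic'",
              class = "tnseqsi_invalid_argument")
  structure(list(genome = genome, features = features),
            class = "tn_annotation")
}

#' @export
print.tn_annotation <- function(x, ...) {
  k <- table(factor(x$features$kind, levels = c("gene", "intergenic")))
  cat(sprintf("<tn_annotation> %s (%s bp): %d genes, %d intergenic regions\n",
              x$genome$id, format(x$genome$length, big.mark = ","),
              k[["gene"]], k[["intergenic"]]))
  invisible(x)
}

#' Feature table of an annotation set
#'
#' @param annotation A `tn_annotation`.
#' @return A tibble of features with a `length` column (`end - start`).
#' @export
features <- function(annotation) {
  stopifnot(inherits(annotation, "tn_annotation"))
  mutate(annotation$features, length = .data$end - .data$start)
}

# IRanges view of the feature table, 1-based, with origin-wrapping features
# split into their two genomic arcs. Returns list(ranges, feature_row).
feature_ranges <- function(annotation) {
  f <- annotation$features
  L <- annotation$genome$length
  wrap <- f$end > L
  starts <- c(f$start[!wrap] + 1L, f$start[wrap] + 1L, rep(1L, sum(wrap)))
  ends <- c(f$end[!wrap], rep(L, sum(wrap)), f$end[wrap] - L)
  rows <- c(which(!wrap), which(wrap), which(wrap))
  list(ranges = IRanges::IRanges(start = starts, end = ends),
       feature_row = rows)
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping genes with geometric-like length spread
#' around `mean_gene_len`, random strands, and at least 1 bp between adjacent
#' genes; the remaining gaps become intergenic features via
#' [derive_intergenic()].
#'
#' @param genome A `tn_genome`.
#' @param n_genes Number of genes (0 allowed).
#' @param mean_gene_len Mean gene length in bp.
#' @param seed Integer seed.
#' @param min_gene_len Minimum gene length in bp.
#' @param gene_len_spread If `TRUE` (default) lengths follow a shifted
#'   geometric distribution with the requested mean; if `FALSE` all genes
#'   have exactly `mean_gene_len` bp.
#' @return A `tn_annotation` holding genes and intergenic regions.
#' @export
#' @examples
#' ann <- make_annotation(make_genome(10000, seed = 1), n_genes = 5,
#'                        mean_gene_len = 800, seed = 1)
#' features(ann)
make_annotation <- function(genome, n_genes, mean_gene_len = 1000, seed = 1L,
                            min_gene_len = 50L, gene_len_spread = TRUE) {
  stopifnot(inherits(genome, "tn_genome"))
  L <- genome$length
  assert_that(n_genes >= 0, "`n_genes` must be non-negative",
              class = "tnseqsi_invalid_argument")
  if (n_genes > 0) {
    assert_that(n_genes * mean_gene_len < L,
                "infeasible packing: n_genes * mean_gene_len must be < genome length",
                class = "tnseqsi_invalid_argument")
    assert_that(mean_gene_len >= min_gene_len,
                "`mean_gene_len` must be >= `min_gene_len`",
                class = "tnseqsi_invalid_argument")
  }
  genes <- with_seed(seed, {
    if (n_genes == 0) {
      tibble(feature_id = character(0), kind = character(0),
             start = integer(0), end = integer(0), strand = character(0))
    } else {
      lens <- if (gene_len_spread) {
        min_gene_len + stats::rgeom(n_genes, 1 / (mean_gene_len - min_gene_len + 1))
      } else {
        rep(as.integer(mean_gene_len), n_genes)
      }
      gaps_needed <- n_genes - 1L
      # Rescale drawn lengths if the draw happened to overflow the genome.
      if (sum(lens) + gaps_needed > L) {
        lens <- pmax(min_gene_len,
                     floor(lens * (L - gaps_needed - n_genes) / sum(lens)))
      }
      assert_that(sum(lens) + gaps_needed <= L,
                  "infeasible packing: drawn gene lengths exceed genome",
                  class = "tnseqsi_invalid_argument")
      free <- L - sum(lens) - gaps_needed
      # Spread the free space over n_genes + 1 gap slots (both ends may be 0).
      extra <- as.vector(stats::rmultinom(1, free, rep(1, n_genes + 1L)))
      gap <- extra + c(0L, rep(1L, gaps_needed), 0L)
      starts <- cumsum(gap[seq_len(n_genes)]) +
        c(0L, cumsum(lens))[seq_len(n_genes)]
      tibble(feature_id = sprintf("gene_%04d", seq_len(n_genes)),
             kind = "gene",
             start = as.integer(starts),
             end = as.integer(starts + lens),
             strand = sample(c("+", "-"), n_genes, replace = TRUE))
    }
  })
  derive_intergenic(tn_annotation(genome, genes))
}

#' Derive intergenic features
#'
#' Adds one intergenic feature per maximal interval not covered by any gene,
#' with ids `IG_<start>_<end>`. On a circular genome the gaps flanking the
#' origin are joined into a single wrap-around feature (stored with
#' `end > genome length`; its id uses the modular end coordinate). Together
#' with non-overlapping genes the result tiles the genome: gene lengths plus
#' intergenic lengths sum to the genome length.
#'
#' @param annotation A `tn_annotation` (any previous intergenic features are
#'   recomputed).
#' @return A `tn_annotation` with gene and intergenic features.
#' @export
derive_intergenic <- function(annotation) {
  stopifnot(inherits(annotation, "tn_annotation"))
  genome <- annotation$genome
  L <- genome$length
  genes <- filter(annotation$features, .data$kind == "gene")
  if (nrow(genes) == 0) {
    ig <- tibble(feature_id = sprintf("IG_%d_%d", 0L, L), kind = "intergenic",
                 start = 0L, end = L, strand = ".")
    return(tn_annotation(genome, ig))
  }
  covered <- IRanges::reduce(IRanges::IRanges(genes$start + 1L, genes$end))
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), covered)
  ig <- tibble(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
  if (genome$circular && nrow(ig) >= 2 &&
      ig$start[1] == 0L && ig$end[nrow(ig)] == L) {
    # Join the two arcs flanking the origin into one wrap-around feature.
    first <- ig[1, ]
    last <- ig[nrow(ig), ]
    ig <- ig[-c(1, nrow(ig)), ]
    ig <- bind_rows(ig, tibble(start = last$start, end = L + first$end))
  }
  if (nrow(ig) > 0) {
    ig <- ig |>
      mutate(feature_id = sprintf("IG_%d_%d", .data$start,
                                  ifelse(.data$end > L, .data$end - L, .data$end)),
             kind = "intergenic", strand = ".") |>
      select("feature_id", "kind", "start", "end", "strand")
  } else {
    ig <- tibble(feature_id = character(0), kind = character(0),
                 start = integer(0), end = integer(0), strand = character(0))
  }
  tn_annotation(genome, bind_rows(genes, ig))
}
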