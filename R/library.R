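#' Simulate a saturated transposon insertion library
#'
#' Draws insertion sites uniformly at random over genomic positions and
#' orientations, emulating a highly saturated mini-Tn10 library with about
#' one insert per 20 bp and therefore roughly 25 distinct mutants in a
#' typical 500-bp gene or intergenic region. The number of insertion events
#' is `round(density * genome length)` — a pooled library of known size —
#' and events landing on an already-occupied (position, orientation) pair
#' collapse into one site, so
#' returned sites are unique. A site is keyed by position *and* orientation:
#' the transposon is an oriented element, so the two orientations at one
#' base are distinct mutants.
#'
#' @param annotation A `tn_annotation` (supplies the genome; features are
#'   not consulted here).
#' @param density Expected insertions per bp (default 1/20).
#' @param seed Integer seed.
#' @return A tibble with columns `position` (0-based bp) and `orientation`
#'   (`"+"`/`"-"`), one row per unique insertion site, sorted by position.
#' @export
#' @examples
#' ann <- make_annotation(make_genome(4000, seed = 2), 5, 400, seed = 2)
#' lib <- make_library(ann, density = 1 / 20, seed = 5)
#' nrow(lib)  # ~200 sites
make_library <- function(annotation, density = 1 / 20, seed = 1L) {
  stopifnot(inherits(annotation, "tn_annotation"))
  assert_that(density > 0, "`density` must be positive",
              class = "tnseqsi_invalid_argument")
  L <- annotation$genome$length
  with_seed(seed, {
    n <- max(1L, as.integer(round(density * L)))
    tibble(position = sample.int(L, n, replace = TRUE) - 1L,
           orientation = sample(c("+", "-"), n, replace = TRUE)) |>
      distinct() |>
      arrange(.data$position, .data$orientation)
  })
}
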