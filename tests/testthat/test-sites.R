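test_that("enumerate_sites tallies (position, orientation) and conserves reads", {
  pl <- tibble::tibble(read_id = c("a", "b", "c"),
                       position = c(5L, 5L, 9L),
                       orientation = c("+", "+", "-"),
                       status = "placed")
  tab <- enumerate_sites(pl, "s1")
  expect_equal(tab$count[tab$position == 5], 2L)
  expect_equal(tab$count[tab$position == 9], 1L)
  expect_equal(sum(tab$count), nrow(pl))

  empty <- enumerate_sites(pl[0, ], "s1")
  expect_equal(nrow(empty), 0)

  expect_error(enumerate_sites(dplyr::mutate(pl, status = "unmapped"), "s1"),
               class = "tnseqsi_contract_error")
})

test_that("enumerate_sites matches a nested-loop tally on random placements", {
  set.seed(17)
  n <- 10000
  pl <- tibble::tibble(read_id = sprintf("r%05d", 1:n),
                       position = sample(0:499, n, replace = TRUE),
                       orientation = sample(c("+", "-"), n, replace = TRUE),
                       status = "placed")
  tab <- enumerate_sites(pl, "s")
  # brute-force: count matching rows for every unique key
  for (i in sample(nrow(tab), 50)) {
    manual <- 0L
    for (j in seq_len(n)) {
      if (pl$position[j] == tab$position[i] &&
          pl$orientation[j] == tab$orientation[i]) manual <- manual + 1L
    }
    expect_equal(tab$count[i], manual)
  }
  expect_equal(sum(tab$count), n)
})

test_that("read_genbank converts coordinates, strands and joins", {
  gb <- write_toy_genbank(withr::local_tempfile(fileext = ".gb"))
  ann <- read_genbank(gb)
  expect_equal(ann$genome$length, 500L)
  f <- ann$features
  expect_equal(nrow(f), 3)
  # gene 101..200 -> [100, 200), + ; gene preferred over its CDS twin
  expect_equal(f$start[f$feature_id == "tg001"], 100L)
  expect_equal(f$end[f$feature_id == "tg001"], 200L)
  expect_equal(f$strand[f$feature_id == "tg001"], "+")
  # complement(251..310) -> [250, 310), -
  expect_equal(f$start[f$feature_id == "tg002"], 250L)
  expect_equal(f$end[f$feature_id == "tg002"], 310L)
  expect_equal(f$strand[f$feature_id == "tg002"], "-")
  # join(351..380,401..450) -> min..max span [350, 450)
  expect_equal(f$start[f$feature_id == "tg003"], 350L)
  expect_equal(f$end[f$feature_id == "tg003"], 450L)
})

test_that("GenBank writer round-trips through the reader", {
  w <- toy_world(len = 3000, n_genes = 4, mean_gene_len = 300)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(w$ann, gb, include_intergenic = FALSE)
  back <- read_genbank(gb)
  genes <- dplyr::filter(w$ann$features, kind == "gene")
  expect_equal(back$genome$length, w$genome$length)
  expect_equal(back$genome$sequence, w$genome$sequence)
  expect_equal(dplyr::arrange(back$features, start)[c("feature_id", "start", "end", "strand")],
               dplyr::arrange(genes, start)[c("feature_id", "start", "end", "strand")])
})

test_that("derive_intergenic fills gaps, handles tilings and circular wrap", {
  g <- tn_genome(500)
  genes <- tibble::tibble(feature_id = c("gA", "gB"), kind = "gene",
                          start = c(100L, 300L), end = c(200L, 400L),
                          strand = "+")
  ann <- derive_intergenic(tn_annotation(g, genes))
  ig <- dplyr::filter(ann$features, kind == "intergenic")
  expect_equal(ig$start, c(0L, 200L, 400L))
  expect_equal(ig$end, c(100L, 300L, 500L))
  expect_equal(ig$feature_id, c("IG_0_100", "IG_200_300", "IG_400_500"))

  # genes tiling the whole genome -> no intergenic features
  tiled <- derive_intergenic(tn_annotation(g, tibble::tibble(
    feature_id = "g1", kind = "gene", start = 0L, end = 500L, strand = "+")))
  expect_equal(sum(tiled$features$kind == "intergenic"), 0)

  # circular genome: terminal gaps join across the origin
  gc <- tn_genome(500, circular = TRUE)
  annc <- derive_intergenic(tn_annotation(gc, genes))
  igc <- dplyr::filter(annc$features, kind == "intergenic")
  expect_equal(nrow(igc), 2)
  wrap <- igc[igc$start == 400, ]
  expect_equal(wrap$end, 600L)                  # [400,500) + [0,100)
  expect_equal(wrap$end - wrap$start, 200L)
  expect_equal(wrap$feature_id, "IG_400_100")
  expect_equal(sum(features(annc)$length), 500)
})

test_that("aggregate_counts assigns by half-open position intervals", {
  g <- tn_genome(500)
  ann <- derive_intergenic(tn_annotation(g, tibble::tibble(
    feature_id = "gA", kind = "gene", start = 100L, end = 200L, strand = "+")))
  sites <- tibble::tibble(sample_id = "s",
                          position = c(150L, 155L, 199L, 200L),
                          orientation = c("+", "-", "+", "+"),
                          count = c(4L, 1L, 2L, 7L))
  out <- aggregate_counts(sites, ann)
  ga <- out[out$feature_id == "gA", ]
  expect_equal(ga$n_sites, 3L)        # 150, 155, 199 inside; 200 outside
  expect_equal(ga$actual_reads, 7L)
  ig <- out[out$feature_id == "IG_200_500", ]
  expect_equal(ig$actual_reads, 7L)   # the site at end sits in the next IG
  # read conservation under the tiling
  expect_equal(sum(out$actual_reads), sum(sites$count))

  expect_error(
    aggregate_counts(dplyr::mutate(sites, position = position + 400L), ann),
    class = "tnseqsi_contract_error")
})

test_that("aggregate_counts matches the nested-loop oracle on random instances", {
  for (seed in c(3, 4)) {
    w <- toy_world(len = 5000, n_genes = 6, mean_gene_len = 400, seed = seed)
    set.seed(seed + 100)
    n <- 2000
    sites <- tibble::tibble(
      sample_id = sample(c("a", "b"), n, replace = TRUE),
      position = sample(0:(w$genome$length - 1), n, replace = TRUE),
      orientation = sample(c("+", "-"), n, replace = TRUE),
      count = rpois(n, 3)) |>
      dplyr::distinct(sample_id, position, orientation, .keep_all = TRUE)
    got <- aggregate_counts(sites, w$ann) |>
      dplyr::select(-kind) |>
      dplyr::arrange(feature_id, sample_id)
    want <- oracle_aggregate(sites, w$ann)
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
  }
})

test_that("site membership ignores orientation and input order", {
  w <- toy_world(len = 4000, n_genes = 4, mean_gene_len = 300, seed = 8)
  set.seed(9)
  sites <- tibble::tibble(sample_id = "s",
                          position = sample(0:3999, 300),
                          orientation = sample(c("+", "-"), 300, TRUE),
                          count = rpois(300, 5) + 1L)
  base <- aggregate_counts(sites, w$ann)
  flipped <- aggregate_counts(
    dplyr::mutate(sites, orientation = ifelse(orientation == "+", "-", "+")),
    w$ann)
  expect_equal(as.data.frame(base), as.data.frame(flipped),
               ignore_attr = TRUE)
  shuffled <- aggregate_counts(sites[sample(nrow(sites)), ], w$ann)
  expect_equal(as.data.frame(base), as.data.frame(shuffled),
               ignore_attr = TRUE)
})
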