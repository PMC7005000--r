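test_that("make_genome is deterministic, honours gc bounds and gc target", {
  g1 <- make_genome(1000, gc = 0.5, seed = 7)
  g2 <- make_genome(1000, gc = 0.5, seed = 7)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence, make_genome(1000, 0.5, seed = 8)$sequence))

  at_only <- make_genome(10, gc = 0, seed = 1)
  expect_false(grepl("[GC]", at_only$sequence))

  # observed GC at 100 kb: binomial SD = sqrt(0.25/1e5) ~ 0.0016
  g <- make_genome(100000, gc = 0.5, seed = 3)
  gc_obs <- mean(strsplit(g$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5), 0.01)

  expect_error(make_genome(0), class = "tnseqsi_invalid_argument")
})

test_that("make_annotation packs disjoint genes and tiles the genome", {
  g <- make_genome(10000, seed = 1)
  ann <- make_annotation(g, n_genes = 5, mean_gene_len = 800, seed = 1)
  genes <- dplyr::filter(features(ann), kind == "gene")
  expect_equal(nrow(genes), 5)
  # pairwise disjoint with >= 1 bp between consecutive genes
  ord <- dplyr::arrange(genes, start)
  expect_true(all(ord$start[-1] > ord$end[-nrow(ord)]))
  igs <- dplyr::filter(features(ann), kind == "intergenic")
  expect_lte(nrow(igs), 6)
  # tiling identity, across several seeds and gene numbers
  for (seed in 1:5) {
    ann2 <- make_annotation(g, n_genes = seed * 3, mean_gene_len = 300,
                            seed = seed)
    expect_equal(sum(features(ann2)$length), g$length)
    expect_false(anyDuplicated(features(ann2)$feature_id) > 0)
  }
})

test_that("make_annotation handles the empty case and infeasible packing", {
  g <- make_genome(5000, seed = 2)
  ann0 <- make_annotation(g, n_genes = 0, seed = 1)
  expect_equal(nrow(ann0$features), 1)
  expect_equal(ann0$features$kind, "intergenic")
  expect_equal(ann0$features$start, 0L)
  expect_equal(ann0$features$end, 5000L)

  expect_error(make_annotation(g, n_genes = 10, mean_gene_len = 600, seed = 1),
               class = "tnseqsi_invalid_argument")
})

test_that("make_library density matches one insert per 20 bp", {
  w <- toy_world(len = 4000, n_genes = 3, mean_gene_len = 500)
  lib <- make_library(w$ann, density = 1 / 20, seed = 5)
  expect_gt(nrow(lib), 150)
  expect_lt(nrow(lib), 220)
  expect_false(anyDuplicated(lib[c("position", "orientation")]) > 0)
  # mean nearest-neighbour spacing ~ 20 bp
  spacing <- w$genome$length / nrow(lib)
  expect_lt(abs(spacing - 20), 2.5)
  expect_identical(lib, make_library(w$ann, density = 1 / 20, seed = 5))
})

test_that("a 500-bp gene holds ~25 mutants and saturation is bounded", {
  g <- make_genome(120000, seed = 9)
  # tile genes of exactly 500 bp separated by 100 bp gaps
  n <- 200
  starts <- (seq_len(n) - 1) * 600
  ann <- tn_annotation(g, tibble::tibble(
    feature_id = sprintf("g%03d", seq_len(n)), kind = "gene",
    start = starts, end = starts + 500, strand = "+")) |>
    derive_intergenic()
  lib <- make_library(ann, density = 1 / 20, seed = 3)
  cnt <- aggregate_counts(
    dplyr::mutate(lib, sample_id = "s", count = 1L), ann) |>
    dplyr::filter(kind == "gene")
  expect_lt(abs(mean(cnt$n_sites) - 25), 2.5)

  # pigeonhole: unique sites cannot exceed 2 x genome length
  tiny <- toy_world(len = 300, n_genes = 2, mean_gene_len = 60)
  sat <- make_library(tiny$ann, density = 50, seed = 1)
  expect_lte(nrow(sat), 2 * 300)
})

test_that("neutral selection leaves site frequencies equal across samples", {
  w <- toy_world()
  sc <- two_sample_scenario(baseline = 0.5, depth = c(control = 1e6,
                                                      treated = 1e6),
                            seed = 21)
  sim <- simulate_selection(w$lib, w$ann, sc)
  wide <- tidyr::pivot_wider(sim, names_from = sample_id,
                             values_from = count)
  # per-site frequency difference within 3 multinomial SDs
  n <- nrow(wide)
  p <- 1 / n
  sd_freq <- sqrt(p * (1 - p)) * sqrt(1 / 1e6 + 1 / 1e6)
  dfreq <- wide$treated / sum(wide$treated) - wide$control / sum(wide$control)
  # allow a small number of 3-sigma excursions by chance (multiplicity)
  expect_lt(mean(abs(dfreq) > 3 * sd_freq + 3 * sqrt(p / 5e4)), 0.01)
  expect_lt(abs(mean(dfreq)), 1e-9)
})

test_that("a lethal feature has zero treated reads; fitness effects follow the frequency-ratio law", {
  w <- toy_world(seed = 7)
  gene1 <- w$ann$features$feature_id[w$ann$features$kind == "gene"][1]
  sc0 <- two_sample_scenario(baseline = 0.5, plating = c(control = 1e5,
                                                         treated = 1000),
                             survival_factor = setNames(1e-12, gene1),
                             seed = 3)
  sim0 <- simulate_selection(w$lib, w$ann, sc0)
  f <- w$ann$features[w$ann$features$feature_id == gene1, ]
  in_g <- sim0$position >= f$start & sim0$position < f$end
  expect_equal(sum(sim0$count[in_g & sim0$sample_id == "treated"]), 0)
  expect_gt(sum(sim0$count[in_g & sim0$sample_id == "control"]), 0)

  # s = 50 on one gene, baseline 0.01, large depth: observed treated/control
  # frequency ratio matches the brute-force expectation
  sf <- setNames(50, gene1)
  sc <- two_sample_scenario(baseline = 0.01, survival_factor = sf,
                            plating = c(control = 2e5, treated = 2e5),
                            depth = c(control = 4e6, treated = 4e6), seed = 5)
  sim <- simulate_selection(w$lib, w$ann, sc)
  expected <- oracle_freq_ratio(w$lib, w$ann, sf, 0.01)
  j <- which(w$ann$features$feature_id == gene1)
  wide <- tidyr::pivot_wider(sim, names_from = sample_id, values_from = count)
  in_g <- wide$position >= f$start & wide$position < f$end
  obs <- (sum(wide$treated[in_g]) / sum(wide$treated)) /
    (sum(wide$control[in_g]) / sum(wide$control))
  expect_lt(abs(obs / expected[j] - 1), 0.15)

  expect_error(
    selection_scenario(plating_counts = c(a = 10),
                       read_depth = c(b = 10), control = "a"),
    class = "tnseqsi_config_error")
})

test_that("simulator outputs are bit-identical for a fixed seed", {
  w <- toy_world(len = 5000, n_genes = 4, mean_gene_len = 400)
  sc <- two_sample_scenario(seed = 99)
  s1 <- simulate_selection(w$lib, w$ann, sc)
  s2 <- simulate_selection(w$lib, w$ann, sc)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  r1 <- emit_reads(s1, w$genome, seed = 4)
  r2 <- emit_reads(s2, w$genome, seed = 4)
  expect_identical(r1, r2)
})

test_that("emit_reads builds junction + genomic prefix + poly(C) per count", {
  g <- make_genome(2000, seed = 11)
  tab <- tibble::tibble(sample_id = "s",
                        position = c(100L, 900L),
                        orientation = c("+", "-"),
                        count = c(3L, 2L))
  reads <- emit_reads(tab, g, junction = "TGACT", read_len = 50, seed = 2)
  expect_equal(nrow(reads), 5)
  fwd <- reads[grepl("_100_f_", reads$read_id), ]
  expect_equal(nrow(fwd), 3)
  k <- 50 - 5
  expect_true(all(fwd$sequence ==
                    paste0("TGACT", substr(g$sequence, 101, 100 + k))))
  # reverse-orientation read: reverse complement ending at the site position
  rev <- reads[grepl("_900_r_", reads$read_id), ]
  expect_equal(substr(rev$sequence[1], 1, 5), "TGACT")
  genomic <- substr(rev$sequence[1], 6, 50)
  expect_equal(
    genomic,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(g$sequence, 901 - nchar(genomic) + 1, 901)))))

  empty <- emit_reads(dplyr::mutate(tab, count = 0L), g)
  expect_equal(nrow(empty), 0)

  # fragment past the linear end truncates instead of erroring
  edge <- tibble::tibble(sample_id = "s", position = 1995L,
                         orientation = "+", count = 1L)
  r <- emit_reads(edge, g, junction = "TGACT", read_len = 50, seed = 1)
  expect_equal(nrow(r), 1)
  expect_match(r$sequence, paste0("^TGACT", substr(g$sequence, 1996, 2000)))
})
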