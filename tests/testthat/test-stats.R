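test_that("predicted_reads is the feature's genomic share of total reads", {
  expect_equal(predicted_reads(100, 1000, 1000), 100)
  expect_equal(predicted_reads(4641652, 4641652, 2.5e6), 2.5e6)
  expect_equal(predicted_reads(337, 4641652, 2500000),
               2500000 * 337 / 4641652)
  expect_error(predicted_reads(0, 1000, 10), class = "tnseqsi_invalid_argument")
  expect_error(predicted_reads(10, 5, 10), class = "tnseqsi_invalid_argument")
})

test_that("dval and survival_index follow their definitions and edge cases", {
  expect_equal(dval(200, 100), 2)
  expect_equal(dval(0, 100), 0)
  expect_true(is.na(dval(5, 0)))

  expect_equal(survival_index(3, 1.5), 2)
  expect_equal(survival_index(0, 2), 0)
  expect_true(is.na(survival_index(2, 0)))
  expect_true(is.na(survival_index(2, NA)))
})

test_that("Dval is invariant to depth rescaling and identical tables give SI = 1", {
  w <- toy_world(seed = 5)
  set.seed(6)
  tab <- dplyr::mutate(w$lib, sample_id = "control",
                       count = rpois(nrow(w$lib), 50))
  both <- dplyr::bind_rows(tab,
                           dplyr::mutate(tab, sample_id = "treated"))
  dv <- add_dval(aggregate_counts(both, w$ann), w$ann)
  res <- survival_results(dv, "control", "treated")
  expect_true(all(abs(res$si[!is.na(res$si)] - 1) < 1e-12))

  # multiply every count in the treated sample by 10: Dval and SI unchanged
  both10 <- dplyr::bind_rows(tab,
                             dplyr::mutate(tab, sample_id = "treated",
                                           count = count * 10L))
  res10 <- survival_results(add_dval(aggregate_counts(both10, w$ann), w$ann),
                            "control", "treated")
  expect_equal(res10$si, res$si, tolerance = 1e-12)
  expect_equal(res10$dval_control, res$dval_control, tolerance = 1e-12)
})

test_that("filter_min_sites keeps features at or above the threshold", {
  res <- tibble::tibble(feature_id = letters[1:4], kind = "gene",
                        n_sites = c(0L, 2L, 3L, 7L), si = 1)
  expect_equal(suppressMessages(filter_min_sites(res, 3))$feature_id,
               c("c", "d"))
  expect_equal(nrow(suppressMessages(filter_min_sites(res, 0))), 4)

  # brute-force count on a fixture of 10 features
  set.seed(2)
  fx <- tibble::tibble(feature_id = sprintf("f%02d", 1:10), kind = "gene",
                       n_sites = sample(0:8, 10, replace = TRUE))
  for (m in 0:5) {
    expect_equal(nrow(suppressMessages(filter_min_sites(fx, m))),
                 sum(fx$n_sites >= m))
  }
})

test_that("combine_replicates averages defined SIs with textbook SEM", {
  mk <- function(si, n_sites = 5L) {
    structure(tibble::tibble(feature_id = "f1", kind = "gene", length = 100L,
                             n_sites = n_sites, dval_control = 1,
                             dval_treated = si, si = si,
                             passes_filter = n_sites >= 3),
              class = c("tn_si", "tbl_df", "tbl", "data.frame"))
  }
  cb <- combine_replicates(list(mk(2), mk(4), mk(6)))
  expect_equal(cb$si_mean, 4)
  expect_equal(cb$si_sem, 2 / sqrt(3))
  expect_equal(cb$n_replicates_defined, 3L)

  cb1 <- combine_replicates(list(mk(1), mk(1), mk(1)))
  expect_equal(cb1$si_mean, 1)
  expect_equal(cb1$si_sem, 0)

  # one replicate undefined: mean over the two defined values
  cbna <- combine_replicates(list(mk(NA_real_), mk(2), mk(4)))
  expect_equal(cbna$si_mean, 3)
  expect_equal(cbna$n_replicates_defined, 2L)

  # all undefined: reported, not dropped
  cb0 <- combine_replicates(list(mk(NA_real_), mk(NA_real_)))
  expect_equal(cb0$n_replicates_defined, 0L)
  expect_true(is.na(cb0$si_mean))

  # geometric mode on a ratio scale
  cbg <- combine_replicates(list(mk(0.5), mk(2), mk(1)),
                            mean_type = "geometric")
  expect_equal(cbg$si_mean, 1)
})

test_that("rank_report orders by SI with lexicographic ties and NA last", {
  cb <- tibble::tibble(feature_id = c("a", "b", "c", "y", "x", "z"),
                       kind = "gene",
                       si_mean = c(5, 1, 0.2, 2, 2, NA))
  up <- rank_report(cb, "resistant")
  expect_equal(up$feature_id, c("a", "x", "y", "b", "c", "z"))
  expect_equal(up$rank, 1:6)
  down <- rank_report(cb, "sensitive")
  expect_equal(down$feature_id, c("c", "b", "x", "y", "a", "z"))
})

test_that("planted resistant features rise to the top of the ranking", {
  w <- toy_world(len = 50000, n_genes = 40, mean_gene_len = 700, seed = 30)
  genes <- w$ann$features$feature_id[w$ann$features$kind == "gene"]
  planted <- genes[seq(4, 40, by = 8)]   # 5 designated resistant genes
  sf <- setNames(rep(50, 5), planted)
  reps <- lapply(1:3, function(r) {
    sc <- two_sample_scenario(baseline = 0.01, survival_factor = sf,
                              plating = c(control = 1e5, treated = 5e4),
                              seed = 400 + r)
    sim <- simulate_selection(w$lib, w$ann, sc)
    survival_results(add_dval(aggregate_counts(sim, w$ann), w$ann),
                     "control", "treated")
  })
  top <- rank_report(combine_replicates(reps), "resistant")
  expect_true(all(planted %in% top$feature_id[1:10]))
})

test_that("tidy, glance and the replicate test summarise combined results", {
  w <- toy_world(seed = 12)
  reps <- lapply(1:2, function(r) {
    sc <- two_sample_scenario(seed = 500 + r)
    sim <- simulate_selection(w$lib, w$ann, sc)
    survival_results(add_dval(aggregate_counts(sim, w$ann), w$ann),
                     "control", "treated")
  })
  cb <- combine_replicates(reps)
  td <- tidy(cb)
  expect_equal(nrow(td), 2 * nrow(cb))
  expect_true(all(c("feature_id", "replicate", "si") %in% names(td)))
  gl <- glance(cb)
  expect_equal(gl$n_features, nrow(cb))
  expect_equal(gl$n_replicates, 2)
  expect_gt(gl$genes_pass_filter, 0)

  tt <- si_replicate_test(cb)
  expect_true("log_si_p" %in% names(tt))
  ok <- !is.na(tt$log_si_p)
  expect_true(any(ok))
  expect_true(all(tt$log_si_p[ok] >= 0 & tt$log_si_p[ok] <= 1))

  p <- ggplot2::autoplot(cb)
  expect_s3_class(p, "ggplot")
})
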