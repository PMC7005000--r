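#' Define a selection-screen scenario
#'
#' A scenario bundles the ground truth and the sampling parameters of one
#' simulated screen: per-feature survival factors under treatment, the
#' survival of a neutral mutant at each treated dose, deterministic growth
#' of the control culture, the inoculum size, and per-sample colony-plating
#' and sequencing-depth numbers.
#'
#' The defaults reproduce the screen conditions the package targets: a
#' control culture growing ~40-fold in 3 h, a bacteriostatic dose killing
#' ~50% of cells and a bactericidal dose killing >99%, with roughly
#' 100,000 / 50,000 / 1,000 colonies pooled from the three groups.
#'
#' @param survival_factor Named numeric vector mapping `feature_id` to a
#'   positive relative survival factor s under treatment; features absent
#'   from the vector are neutral (s = 1). Insertion mutants in a feature
#'   with s > 1 survive treatment better than neutral mutants; s < 1 worse.
#' @param baseline_survival Named numeric vector giving, for each treated
#'   sample, the survival fraction of a *neutral* mutant (in (0, 1]).
#' @param control_growth Fold-change of CFU in the control culture over the
#'   incubation (deterministic; default 40).
#' @param inoculum_cfu Total CFU inoculated (default 1.25e5, i.e. 2.5e6
#'   CFU/ml in a 50 ul culture).
#' @param plating_counts Named integer vector: colonies pooled per sample.
#' @param read_depth Named integer vector: sequencing reads per sample.
#' @param control Name of the control sample.
#' @param seed Integer seed; a single RNG stream drives the whole scenario.
#' @return An object of class `tn_scenario`.
#' @export
#' @examples
#' selection_scenario(survival_factor = c(gene_0001 = 50), seed = 7)
selection_scenario <- function(survival_factor = numeric(0),
                               baseline_survival = c(treated_50 = 0.5,
                                                     treated_1 = 0.01),
                               control_growth = 40,
                               inoculum_cfu = 1.25e5,
                               plating_counts = c(control = 100000,
                                                  treated_50 = 50000,
                                                  treated_1 = 1000),
                               read_depth = c(control = 1e6,
                                              treated_50 = 1e6,
                                              treated_1 = 1e6),
                               control = "control",
                               seed = 1L) {
  assert_that(all(survival_factor > 0), "survival factors must be > 0",
              class = "tnseqsi_invalid_argument")
  assert_that(all(baseline_survival > 0 & baseline_survival <= 1),
              "baseline_survival values must lie in (0, 1]",
              class = "tnseqsi_invalid_argument")
  assert_that(control_growth > 0, "control_growth must be > 0",
              class = "tnseqsi_invalid_argument")
  assert_that(all(plating_counts >= 1) && all(read_depth >= 1),
              "plating counts and read depths must be >= 1",
              class = "tnseqsi_invalid_argument")
  samples <- names(plating_counts)
  assert_that(!is.null(samples) && !anyDuplicated(samples),
              "plating_counts must be uniquely named by sample",
              class = "tnseqsi_config_error")
  assert_that(control %in% samples,
              sprintf("control sample '%s' missing from plating_counts", control),
              class = "tnseqsi_config_error")
  assert_that(setequal(samples, names(read_depth)),
              "plating_counts and read_depth must name the same samples",
              class = "tnseqsi_config_error")
  treated <- setdiff(samples, control)
  assert_that(all(treated %in% names(baseline_survival)),
              "every treated sample needs a baseline_survival entry",
              class = "tnseqsi_config_error")
  structure(list(survival_factor = survival_factor,
                 baseline_survival = baseline_survival[treated],
                 control_growth = control_growth,
                 inoculum_cfu = inoculum_cfu,
                 plating_counts = plating_counts,
                 read_depth = read_depth[samples],
                 control = control,
                 samples = samples,
                 seed = as.integer(seed)),
            class = "tn_scenario")
}

#' @export
print.tn_scenario <- function(x, ...) {
  cat(sprintf("<tn_scenario> %d samples (control: %s), %d non-neutral features, seed %d\n",
              length(x$samples), x$control, length(x$survival_factor), x$seed))
  invisible(x)
}

# Per-site survival factor: product of the explicit factors of every feature
# containing the site (multiplicative effects on the rare overlap); 1 when
# no containing feature has an explicit factor.
site_survival_factors <- function(library, annotation, survival_factor) {
  s <- rep(1, nrow(library))
  if (length(survival_factor) == 0) return(s)
  missing <- setdiff(names(survival_factor), annotation$features$feature_id)
  assert_that(length(missing) == 0,
              paste("survival_factor names not in annotation:",
                    paste(missing, collapse = ", ")),
              class = "tnseqsi_config_error")
  fr <- feature_ranges(annotation)
  keep <- annotation$features$feature_id[fr$feature_row] %in% names(survival_factor)
  if (!any(keep)) return(s)
  hits <- IRanges::findOverlaps(IRanges::IRanges(library$position + 1L, width = 1L),
                                fr$ranges[keep])
  fid <- annotation$features$feature_id[fr$feature_row[keep]][S4Vectors::subjectHits(hits)]
  fac <- survival_factor[fid]
  for (k in seq_along(fac)) {
    i <- S4Vectors::queryHits(hits)[k]
    s[i] <- s[i] * fac[k]
  }
  s
}

#' Simulate selection, plating and sequencing of a Tn library
#'
#' Pushes a library of insertion mutants through the simulated screen. Each
#' site starts with an equal share of the inoculum. Growth and killing are
#' deterministic: in the control sample every site's abundance is multiplied
#' by `control_growth`; in a treated sample by
#' `baseline_survival * s(feature)`, where s is the survival factor of the
#' feature(s) containing the site (1 if neutral). Stochasticity enters at
#' the two sampling steps that dominate real screens: the colony-plating
#' bottleneck (a multinomial of the per-sample plating count over site
#' abundances) and sequencing (a multinomial of the read depth over plated
#' colony counts).
#'
#' @param library Site tibble from [make_library()].
#' @param annotation A `tn_annotation`.
#' @param scenario A `tn_scenario`.
#' @return A tibble of class `tn_sites` with columns `sample_id`,
#'   `position`, `orientation`, `count` (reads), covering every library site
#'   in every sample (zero counts retained). Pre-plating population sizes
#'   are attached and available via [selection_cfu()].
#' @export
#' @examples
#' ann <- make_annotation(make_genome(20000, seed = 1), 10, 800, seed = 1)
#' lib <- make_library(ann, seed = 1)
#' sim <- simulate_selection(lib, ann, selection_scenario(seed = 1))
#' selection_cfu(sim)
simulate_selection <- function(library, annotation, scenario) {
  stopifnot(inherits(annotation, "tn_annotation"),
            inherits(scenario, "tn_scenario"))
  assert_that(nrow(library) > 0, "library has no insertion sites",
              class = "tnseqsi_invalid_argument")
  s_site <- site_survival_factors(library, annotation, scenario$survival_factor)
  n_i <- scenario$inoculum_cfu / nrow(library)
  # Fixed sample order: control first, treated samples in declared order.
  samples <- c(scenario$control, setdiff(scenario$samples, scenario$control))

  out <- with_seed(scenario$seed, {
    purrr::map(samples, function(sm) {
      abundance <- if (sm == scenario$control) {
        rep(n_i * scenario$control_growth, nrow(library))
      } else {
        n_i * scenario$baseline_survival[[sm]] * s_site
      }
      total_cfu <- sum(abundance)
      if (total_cfu <= 0) {
        colonies <- rep(0L, nrow(library))
        reads <- rep(0L, nrow(library))
      } else {
        colonies <- as.vector(stats::rmultinom(1, scenario$plating_counts[[sm]],
                                               abundance / total_cfu))
        reads <- if (sum(colonies) > 0) {
          as.vector(stats::rmultinom(1, scenario$read_depth[[sm]],
                                     colonies / sum(colonies)))
        } else {
          rep(0L, nrow(library))
        }
      }
      list(tab = tibble(sample_id = sm, position = library$position,
                        orientation = library$orientation,
                        count = as.integer(reads)),
           cfu = tibble(sample_id = sm, cfu = total_cfu,
                        colonies = sum(colonies)))
    })
  })
  tabs <- bind_rows(purrr::map(out, "tab"))
  cfu <- bind_rows(tibble(sample_id = "inoculum", cfu = scenario$inoculum_cfu,
                          colonies = NA_integer_),
                   bind_rows(purrr::map(out, "cfu")))
  structure(tabs, cfu = cfu, control = scenario$control,
            class = c("tn_sites", class(tabs)))
}

#' Pre-plating population sizes of a simulated screen
#'
#' @param sites The `tn_sites` tibble returned by [simulate_selection()].
#' @return A tibble with one row per sample (plus the inoculum): total CFU
#'   entering the plating step and the number of colonies pooled.
#' @export
selection_cfu <- function(sites) {
  cfu <- attr(sites, "cfu")
  assert_that(!is.null(cfu),
              "no CFU record attached; was this produced by simulate_selection()?")
  cfu
}
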