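#' Predicted reads for a feature
#'
#' The expected read count of a feature under a uniform library: the
#' feature's share of the genome times the sample's total reads,
#' `total_reads * feature_len / genome_len`. This is the denominator of the
#' Dval statistic.
#'
#' @param feature_len Feature length in bp (>= 1).
#' @param genome_len Genome length in bp (>= feature_len).
#' @param total_reads Total reads in the sample (>= 0).
#' @return Predicted read count (vectorised).
#' @export
#' @examples
#' predicted_reads(100, 1000, 1000)  # 100
predicted_reads <- function(feature_len, genome_len, total_reads) {
  assert_that(all(feature_len >= 1), "feature_len must be >= 1",
              class = "tnseqsi_invalid_argument")
  assert_that(all(genome_len >= feature_len),
              "genome_len must be >= feature_len",
              class = "tnseqsi_invalid_argument")
  assert_that(all(total_reads >= 0), "total_reads must be >= 0",
              class = "tnseqsi_invalid_argument")
  as.numeric(total_reads) * as.numeric(feature_len) / as.numeric(genome_len)
}

#' Dval: length- and depth-normalised feature abundance
#'
#' Actual reads divided by predicted reads. Dval = 1 means the feature holds
#' exactly its genomic share of the library; it is invariant to rescaling
#' the sequencing depth. Undefined (NA) when predicted reads are not
#' positive.
#'
#' @param actual_reads Observed reads for the feature.
#' @param predicted Predicted reads from [predicted_reads()].
#' @return Dval (vectorised; NA where `predicted <= 0`).
#' @export
#' @examples
#' dval(200, 100)  # 2
dval <- function(actual_reads, predicted) {
  ifelse(predicted > 0, actual_reads / predicted, NA_real_)
}

#' Survival index of a feature
#'
#' SI = treated Dval / control Dval: the change in a feature's library
#' frequency caused by the treatment. SI = 1 is neutral; SI > 1 marks
#' insertions that make the strain *more resistant* to the treatment (the
#' intact gene promotes killing); SI < 1 marks sensitising insertions.
#' Undefined (NA) when the control Dval is zero — no pseudocount is applied
#' by default.
#'
#' @param dval_treated Treated-sample Dval.
#' @param dval_control Control-sample Dval.
#' @return SI (vectorised; NA where `dval_control` is 0 or NA).
#' @export
#' @examples
#' survival_index(3, 1.5)  # 2
survival_index <- function(dval_treated, dval_control) {
  ifelse(!is.na(dval_control) & dval_control > 0,
         dval_treated / dval_control, NA_real_)
}

#' Add predicted reads and Dval to an aggregated count table
#'
#' @param counts Output of [aggregate_counts()].
#' @param annotation The `tn_annotation` used for aggregation.
#' @param total_reads Optional named vector of per-sample total reads;
#'   defaults to the totals recorded by [aggregate_counts()] (all reads in
#'   the sample, assigned or not).
#' @return `counts` with `length`, `predicted_reads` and `dval` columns.
#' @export
add_dval <- function(counts, annotation, total_reads = NULL) {
  stopifnot(inherits(annotation, "tn_annotation"))
  L <- annotation$genome$length
  if (is.null(total_reads)) {
    tot <- attr(counts, "sample_totals")
    assert_that(!is.null(tot),
                "no sample totals recorded; pass `total_reads` explicitly")
    total_reads <- stats::setNames(tot$total_reads, tot$sample_id)
  }
  lens <- stats::setNames(features(annotation)$length,
                          features(annotation)$feature_id)
  counts |>
    as_tibble() |>
    mutate(length = lens[.data$feature_id],
           predicted_reads = predicted_reads(.data$length, L,
                                             total_reads[.data$sample_id]),
           dval = dval(.data$actual_reads, .data$predicted_reads))
}

#' Per-feature survival results for one replicate
#'
#' Pairs one treated sample with the control sample of the same replicate
#' and computes, per feature, the control and treated Dvals, the survival
#' index, and the minimum-insertion-site filter. The site filter counts
#' sites in the control sample by default (`site_filter = "control"`): the
#' control library is the pre-selection representation of each mutant, and
#' treatment removes sites rather than adding them. `site_filter = "union"`
#' instead counts sites with reads in either sample.
#'
#' @param dvals Output of [add_dval()] containing both samples.
#' @param control,treated Sample ids to compare.
#' @param min_sites Minimum distinct insertion sites for a feature to pass
#'   the filter (default 3).
#' @param site_filter `"control"` or `"union"` (see above).
#' @param pseudocount Reads added to every feature's `actual_reads` in both
#'   samples before Dval (default 0 = off; the core statistic uses none).
#' @return A tibble of class `tn_si`: `feature_id`, `kind`, `length`,
#'   `n_sites`, `dval_control`, `dval_treated`, `si`, `passes_filter`.
#' @export
survival_results <- function(dvals, control, treated, min_sites = 3L,
                             site_filter = c("control", "union"),
                             pseudocount = 0) {
  site_filter <- match.arg(site_filter)
  dvals <- as_tibble(dvals)
  assert_that(all(c(control, treated) %in% dvals$sample_id),
              sprintf("samples '%s' and '%s' must both be present in `dvals`",
                      control, treated),
              class = "tnseqsi_config_error")
  d <- filter(dvals, .data$sample_id %in% c(control, treated))
  if (pseudocount > 0) {
    d <- d |>
      mutate(actual_reads = .data$actual_reads + pseudocount,
             dval = dval(.data$actual_reads, .data$predicted_reads))
  }
  wide <- d |>
    mutate(role = ifelse(.data$sample_id == control, "control", "treated")) |>
    select("feature_id", "kind", "length", "role", "n_sites", "dval") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("n_sites", "dval"))
  n_sites <- switch(site_filter,
                    control = wide$n_sites_control,
                    union = pmax(wide$n_sites_control, wide$n_sites_treated))
  out <- wide |>
    transmute(.data$feature_id, .data$kind, .data$length,
              n_sites = as.integer(n_sites),
              dval_control = .data$dval_control,
              dval_treated = .data$dval_treated,
              si = survival_index(.data$dval_treated, .data$dval_control),
              passes_filter = n_sites >= min_sites)
  attr(out, "min_sites") <- as.integer(min_sites)
  class(out) <- c("tn_si", class(out))
  out
}

#' Apply the minimum-insertion-site filter
#'
#' Keeps features with at least `min_sites` distinct insertion sites —
#' features sampled by too few independent mutants give unreliable
#' frequency changes. Reports the kept gene and intergenic counts.
#'
#' @param results A `tn_si` (or combined) tibble with `n_sites`.
#' @param min_sites Threshold (default 3; 0 keeps everything).
#' @return The filtered tibble.
#' @export
filter_min_sites <- function(results, min_sites = 3L) {
  assert_that(min_sites >= 0, "min_sites must be >= 0",
              class = "tnseqsi_invalid_argument")
  kept <- filter(as_tibble(results), .data$n_sites >= min_sites)
  if ("kind" %in% names(kept)) {
    message(sprintf("kept %d genes and %d intergenic regions with >= %d sites",
                    sum(kept$kind == "gene"), sum(kept$kind == "intergenic"),
                    min_sites))
  }
  kept
}

#' Combine survival indices across biological replicates
#'
#' Per feature, the mean and standard error of the replicate SIs, computed
#' over replicates where SI is defined. The default is the arithmetic mean;
#' since SI is a ratio a geometric mean (over strictly positive SIs) is
#' available. A feature passes the combined filter when it passes in every
#' replicate.
#'
#' @param replicates A list of `tn_si` tibbles, one per replicate.
#' @param mean_type `"arithmetic"` or `"geometric"`.
#' @return A tibble of class `tn_si_combined`: `feature_id`, `kind`,
#'   `n_sites` (minimum over replicates), `si` (list column of per-replicate
#'   values), `si_mean`, `si_sem` (SEM of the defined SIs),
#'   `n_replicates_defined`, `passes_filter`.
#' @export
combine_replicates <- function(replicates,
                               mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  assert_that(length(replicates) >= 1, "need at least one replicate",
              class = "tnseqsi_invalid_argument")
  long <- bind_rows(lapply(seq_along(replicates), function(i) {
    mutate(as_tibble(replicates[[i]]), replicate = i)
  }))
  out <- long |>
    group_by(.data$feature_id, .data$kind) |>
    summarise(
      n_sites = min(.data$n_sites),
      n_replicates_defined = sum(!is.na(.data$si)),
      si_mean = if (mean_type == "arithmetic") {
        mean(.data$si[!is.na(.data$si)])
      } else {
        x <- .data$si[!is.na(.data$si)]
        if (length(x) == 0) NaN else if (any(x == 0)) 0 else exp(mean(log(x)))
      },
      si_sem = {
        x <- .data$si[!is.na(.data$si)]
        if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
      },
      passes_filter = all(.data$passes_filter),
      si = list(stats::setNames(.data$si, .data$replicate)),
      .groups = "drop") |>
    mutate(si_mean = ifelse(.data$n_replicates_defined == 0, NA_real_,
                            .data$si_mean))
  attr(out, "n_replicates") <- length(replicates)
  attr(out, "mean_type") <- mean_type
  class(out) <- c("tn_si_combined", class(out))
  out
}

#' Rank features by combined survival index
#'
#' Orders features by mean SI — descending for `direction = "resistant"`
#' (insertions that most increased in frequency under treatment, i.e. genes
#' whose loss confers resistance), ascending for `"sensitive"`. Ties break
#' lexicographically on `feature_id`; features with undefined SI sort last.
#'
#' @param combined A `tn_si_combined` (or any tibble with `si_mean`).
#' @param direction `"resistant"` or `"sensitive"`.
#' @return The input tibble, sorted, with a `rank` column.
#' @export
rank_report <- function(combined, direction = c("resistant", "sensitive")) {
  direction <- match.arg(direction)
  combined <- as_tibble(combined)
  assert_that(nrow(combined) > 0, "empty result table",
              class = "tnseqsi_invalid_argument")
  key <- if (direction == "resistant") -1 else 1
  out <- combined |>
    arrange(is.na(.data$si_mean), key * .data$si_mean, .data$feature_id) |>
    mutate(rank = row_number())
  out
}

#' Optional replicate-level test on log SI
#'
#' A convenience one-sample t-test of ln(SI) against 0 across replicates,
#' per feature — an add-on for exploratory triage, not part of the core
#' survival-index statistic (which reports replicate means and SEMs only).
#' Requires at least two replicates with defined, positive SI; other
#' features get NA.
#'
#' @param combined A `tn_si_combined` with the `si` list column.
#' @return The input with `log_si_p` added.
#' @export
si_replicate_test <- function(combined) {
  combined |>
    as_tibble() |>
    mutate(log_si_p = purrr::map_dbl(.data$si, function(x) {
      x <- x[!is.na(x) & x > 0]
      if (length(x) < 2 || stats::sd(log(x)) == 0) return(NA_real_)
      stats::t.test(log(x), mu = 0)$p.value
    }))
}

#' Write a ranked survival-index report as TSV
#'
#' Flattens the per-replicate SI list column into `si_rep_<i>` columns.
#'
#' @param combined A `tn_si_combined` tibble (ranked or not).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_si_report <- function(combined, path) {
  flat <- combined |>
    as_tibble() |>
    mutate(rep = purrr::map(.data$si, function(x) {
      tibble(replicate = sprintf("si_rep_%s", names(x) %||% seq_along(x)),
             value = unname(x))
    })) |>
    select(-"si") |>
    tidyr::unnest("rep") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "value")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
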