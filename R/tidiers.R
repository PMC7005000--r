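#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a combined survival-index table
#'
#' Unnests the per-replicate SI list column into one row per feature per
#' replicate.
#'
#' @param x A `tn_si_combined`.
#' @param ... Unused.
#' @return A long tibble: `feature_id`, `kind`, `replicate`, `si`, plus the
#'   combined columns.
#' @method tidy tn_si_combined
#' @export
tidy.tn_si_combined <- function(x, ...) {
  x |>
    as_tibble() |>
    mutate(rep = purrr::map(.data$si, function(v) {
      tibble(replicate = as.integer(names(v) %||% seq_along(v)),
             si = unname(v))
    })) |>
    select(-"si") |>
    tidyr::unnest("rep") |>
    select("feature_id", "kind", "replicate", "si", everything())
}

#' One-row summary of a combined survival-index table
#'
#' @param x A `tn_si_combined`.
#' @param ... Unused.
#' @return A tibble with feature totals, filter-passing counts and the mean
#'   SI over filter-passing features.
#' @method glance tn_si_combined
#' @export
glance.tn_si_combined <- function(x, ...) {
  pass <- filter(as_tibble(x), .data$passes_filter)
  tibble(n_features = nrow(x),
         n_genes = sum(x$kind == "gene"),
         n_intergenic = sum(x$kind == "intergenic"),
         genes_pass_filter = sum(pass$kind == "gene"),
         intergenic_pass_filter = sum(pass$kind == "intergenic"),
         mean_si_pass = mean(pass$si_mean, na.rm = TRUE),
         n_replicates = attr(x, "n_replicates") %||% NA_integer_)
}

#' Plot combined survival indices
#'
#' Features ordered by mean SI on a log2 axis, with replicate-SEM error
#' bars; filter-failing features are dimmed. SI = 1 (neutral) is marked.
#'
#' @param object A `tn_si_combined`.
#' @param top Label the `top` highest-SI filter-passing features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tn_si_combined
#' @export
autoplot.tn_si_combined <- function(object, top = 5, ...) {
  d <- object |>
    as_tibble() |>
    filter(!is.na(.data$si_mean), .data$si_mean > 0) |>
    arrange(.data$si_mean) |>
    mutate(ord = row_number())
  lab <- d |>
    filter(.data$passes_filter) |>
    slice_max(.data$si_mean, n = top)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ord, y = .data$si_mean)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$si_mean - .data$si_sem, .Machine$double.eps),
      ymax = .data$si_mean + .data$si_sem,
      alpha = .data$passes_filter), size = 0.2) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$feature_id),
                       hjust = -0.1, size = 2.8) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25),
                                guide = "none") +
    ggplot2::labs(x = "features (ranked)", y = "survival index (log2 scale)")
}

#' Plot insertion-site read counts along the genome
#'
#' @param object A site tibble (`tn_sites` or compatible).
#' @param ... Unused.
#' @return A ggplot object, one panel per sample.
#' @method autoplot tn_sites
#' @export
autoplot.tn_sites <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0),
                          linewidth = 0.2) +
    ggplot2::facet_wrap(~sample_id, ncol = 1) +
    ggplot2::labs(x = "genomic position (bp)", y = "reads per insertion site")
}
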