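#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy gene_fates
#' @export
tidy.gene_fates <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance gene_fates
#' @export
glance.gene_fates <- function(x, ...) {
  counts <- table(factor(x$category,
                         levels = c("matched", "rescued_overlapping",
                                    "rescued_intergenic", "unmapped")))
  tibble::tibble(
    n_query = nrow(x),
    n_matched = as.integer(counts[["matched"]]),
    n_rescued_overlapping = as.integer(counts[["rescued_overlapping"]]),
    n_rescued_intergenic = as.integer(counts[["rescued_intergenic"]]),
    n_unmapped = as.integer(counts[["unmapped"]]),
    median_best_f = stats::median(x$best_f[!is.na(x$chosen_variant)]))
}

#' @method tidy unified_annotation
#' @export
tidy.unified_annotation <- function(x, ...) {
  gene_spans(x$aset)
}

#' @method glance unified_annotation
#' @export
glance.unified_annotation <- function(x, ...) {
  tibble::tibble(n_target = x$counts$n_target,
                 n_rescued = x$counts$n_rescued,
                 n_collapsed = x$counts$n_collapsed,
                 n_unified = x$counts$n_unified)
}

#' @method tidy threshold_sweep
#' @export
tidy.threshold_sweep <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance threshold_sweep
#' @export
glance.threshold_sweep <- function(x, ...) {
  tibble::tibble(
    n_thresholds = nrow(x),
    f_min = min(x$f_value), f_max = max(x$f_value),
    max_concordance = if (all(is.na(x$pair_concordance))) NA_real_
                      else max(x$pair_concordance, na.rm = TRUE))
}

#' Plot a threshold sweep
#'
#' Matched-gene counts and pair concordance (when available) against the
#' coverage threshold, on a log-scaled threshold axis.
#'
#' @param object A `threshold_sweep` from [sweep_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(frac_matched = .data$n_query_matched /
                    max(.data$n_query_matched)) |>
    tidyr::pivot_longer(dplyr::any_of(c("frac_matched", "pair_concordance")),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f_value, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "coverage fraction threshold F", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot gene-fate composition
#'
#' Stacked counts of gene fates per query source.
#'
#' @param object A `gene_fates` tibble from [classify_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_fates
#' @export
autoplot.gene_fates <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(source = dplyr::coalesce(.data$source, "unknown"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "query source", y = "genes", fill = "fate") +
    ggplot2::theme_minimal()
}

#' Plot a synteny link table
#'
#' Tile heatmap of overlap-record counts per (query seqid, target seqid)
#' pair — the tabular form of an inter-annotation synteny chord diagram.
#'
#' @param links A tibble from [synteny_links()].
#' @return A ggplot object.
#' @export
plot_synteny_links <- function(links) {
  lv_q <- unique(links$query_seqid[order(natural_key(links$query_seqid))])
  lv_t <- unique(links$target_seqid[order(natural_key(links$target_seqid))])
  ggplot2::ggplot(links, ggplot2::aes(
    x = factor(.data$target_seqid, lv_t),
    y = factor(.data$query_seqid, rev(lv_q)),
    fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::labs(x = "target seqid", y = "query seqid", fill = "links") +
    ggplot2::theme_minimal()
}
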