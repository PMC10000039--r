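#' Read a differential-expression results table
#'
#' Reads a TSV with columns `gene_id`, `log2fc` and `p_value` — the shape
#' of a DESeq2 results export (here oriented as high-fat vs low-fat breed).
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns `gene_id`, `log2fc`, `p_value`.
#' @export
read_de_results <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    log2fc = readr::col_double(),
    p_value = readr::col_double()
  ))
  tibble::as_tibble(df[, c("gene_id", "log2fc", "p_value")])
}

#' Filter differential-expression results
#'
#' Keeps rows with `p_value < alpha` (strict, matching the usual
#' "p < 0.05" convention) and `|log2fc| >= min_abs_lfc`. Rows with a
#' p-value outside \[0, 1\] or non-finite log2fc are dropped with a
#' warning. Optionally applies Benjamini-Hochberg adjustment before
#' thresholding; raw p-values are the default because upstream tables in
#' this workflow report raw p-values.
#'
#' @param results Tibble with `gene_id`, `log2fc`, `p_value`.
#' @param alpha Significance threshold in (0, 1]; default 0.05.
#' @param min_abs_lfc Minimum absolute log2 fold change; default 0.
#' @param adjust If TRUE, threshold Benjamini-Hochberg adjusted p-values
#'   instead of raw ones. Default FALSE.
#' @return The filtered tibble (same columns; plus `p_adjusted` when
#'   `adjust = TRUE`).
#' @export
filter_de <- function(results, alpha = 0.05, min_abs_lfc = 0, adjust = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, min_abs_lfc >= 0)
  valid <- !is.na(results$p_value) & results$p_value >= 0 & results$p_value <= 1 &
    is.finite(results$log2fc)
  if (any(!valid)) {
    warning(sum(!valid), " row(s) with invalid p-value or log2fc rejected",
            call. = FALSE)
    results <- results[valid, , drop = FALSE]
  }
  p <- results$p_value
  if (adjust) {
    results$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- results$p_adjusted
  }
  results[p < alpha & abs(results$log2fc) >= min_abs_lfc, , drop = FALSE]
}

#' Intersect differential-expression results with prioritized genes
#'
#' Restricts a DE table to genes in the hub/bottleneck union and flags
#' each retained gene's membership, yielding the differentially expressed
#' hub and bottleneck gene table. Direction counts use the sign of
#' `log2fc` (zero counts as neither up nor down).
#'
#' @param prioritized A `prioritized_genes` object from [prioritize()], or
#'   a list with character elements `hubs` and `bottlenecks`.
#' @param de Tibble with `gene_id`, `log2fc`, `p_value` (typically already
#'   passed through [filter_de()]).
#' @return An object of class `de_hub_bottleneck`: a tibble with columns
#'   `gene_id`, `log2fc`, `p_value`, `is_hub`, `is_bottleneck`, carrying a
#'   `summary` attribute with counts `n_union`, `n_hub`, `n_bottleneck`,
#'   `n_both`, `n_up`, `n_down`. Retrieve the counts with [glance()].
#' @export
integrate_de <- function(prioritized, de) {
  stopifnot(is.list(prioritized), all(c("hubs", "bottlenecks") %in% names(prioritized)))
  hubs <- prioritized$hubs
  bottlenecks <- prioritized$bottlenecks
  rows <- de |>
    dplyr::filter(.data$gene_id %in% union(hubs, bottlenecks)) |>
    dplyr::mutate(
      is_hub = .data$gene_id %in% hubs,
      is_bottleneck = .data$gene_id %in% bottlenecks
    )
  summary <- tibble::tibble(
    n_union = nrow(rows),
    n_hub = sum(rows$is_hub),
    n_bottleneck = sum(rows$is_bottleneck),
    n_both = sum(rows$is_hub & rows$is_bottleneck),
    n_up = sum(rows$log2fc > 0),
    n_down = sum(rows$log2fc < 0)
  )
  structure(rows, summary = summary,
            class = c("de_hub_bottleneck", class(rows)))
}

#' @export
glance.de_hub_bottleneck <- function(x, ...) {
  attr(x, "summary")
}

#' Volcano-style plot of a DE hub/bottleneck table
#'
#' @param object A `de_hub_bottleneck` table from [integrate_de()].
#' @param ... Unused.
#' @return A ggplot of log2 fold change versus -log10 p-value, coloured by
#'   hub / bottleneck / both membership.
#' @export
autoplot.de_hub_bottleneck <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$is_hub & .data$is_bottleneck ~ "both",
      .data$is_hub ~ "hub",
      TRUE ~ "bottleneck"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(
      hub = "#D55E00", bottleneck = "#0072B2", both = "#009E73"
    )) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ "p-value"), colour = NULL,
                  title = "Differentially expressed hub/bottleneck genes") +
    ggplot2::theme_minimal()
}
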