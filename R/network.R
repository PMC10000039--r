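#' Read a scored protein-interaction edge list
#'
#' Reads a TSV with columns `protein_a`, `protein_b` and `combined_score`.
#' Scores may be reals in \[0, 1\] or STRING-style millesimal integers in
#' \[0, 1000\]; if any score exceeds 1 the whole column is interpreted as
#' millesimal and divided by 1000 (a message is emitted).
#'
#' @param path Path to a tab-separated edge list with a header row.
#' @return A tibble with columns `a`, `b` and `score` (real in \[0, 1\]).
#' @export
read_interaction_edges <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein_a = readr::col_character(),
    protein_b = readr::col_character(),
    combined_score = readr::col_double()
  ))
  bad <- which(is.na(df$protein_a) | is.na(df$protein_b) | is.na(df$combined_score))
  if (length(bad) > 0) {
    stop("Malformed edge row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  score <- df$combined_score
  if (any(score > 1)) {
    message("Scores > 1 detected; interpreting 'combined_score' as STRING millesimal (0-1000) and dividing by 1000")
    score <- score / 1000
  }
  if (any(score < 0 | score > 1)) {
    stop("Scores outside [0, 1] after normalization", call. = FALSE)
  }
  tibble::tibble(a = df$protein_a, b = df$protein_b, score = score)
}

#' Build a simple undirected gene network from scored edges
#'
#' Normalizes a scored edge list into a simple undirected graph: edges
#' below the confidence threshold are dropped, self-loops are dropped,
#' duplicate pairs (in either orientation) are collapsed keeping the
#' maximum score. Nodes are exactly the endpoints of retained edges;
#' endpoints appearing only in dropped edges are not kept as isolates.
#'
#' @param edges Tibble with columns `a`, `b`, `score` (see
#'   [read_interaction_edges()]).
#' @param min_score Minimum confidence score in \[0, 1\]; edges with
#'   `score < min_score` are discarded. Default 0.5, the usual
#'   medium-confidence STRING cutoff.
#' @return An object of class `gene_network`: a list with `nodes`
#'   (character) and `edges` (tibble `a`, `b`, `score` with `a < b`).
#' @export
build_network <- function(edges, min_score = 0.5) {
  stopifnot(is.data.frame(edges), all(c("a", "b", "score") %in% names(edges)))
  if (!is.numeric(min_score) || length(min_score) != 1 || min_score < 0 || min_score > 1) {
    stop("'min_score' must be a single value in [0, 1]", call. = FALSE)
  }
  kept <- edges |>
    dplyr::filter(.data$score >= min_score, .data$a != .data$b) |>
    dplyr::mutate(
      lo = pmin(.data$a, .data$b),
      hi = pmax(.data$a, .data$b)
    )
  kept <- if (nrow(kept) == 0) {
    tibble::tibble(a = character(), b = character(), score = double())
  } else {
    kept |>
      dplyr::summarise(score = max(.data$score), .by = c("lo", "hi")) |>
      dplyr::arrange(.data$lo, .data$hi) |>
      dplyr::rename(a = "lo", b = "hi")
  }
  structure(
    list(nodes = sort(unique(c(kept$a, kept$b))), edges = kept),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("a", "b")],
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Node centralities of a gene network
#'
#' Degree is the unweighted incident-edge count. Betweenness is standard
#' shortest-path node betweenness on the unweighted graph: unnormalized,
#' endpoints excluded, each unordered pair of distinct endpoints counted
#' once. Confidence scores are used only when thresholding the network,
#' never as path weights.
#'
#' @param net A `gene_network` from [build_network()].
#' @return A tibble with columns `gene_id`, `degree` and `betweenness`,
#'   one row per node.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (length(net$nodes) == 0) {
    return(tibble::tibble(gene_id = character(), degree = integer(), betweenness = double()))
  }
  g <- as_igraph(net)
  tibble::tibble(
    gene_id = net$nodes,
    degree = as.integer(igraph::degree(g)[net$nodes]),
    betweenness = unname(igraph::betweenness(g, directed = FALSE, weights = NA)[net$nodes])
  )
}

#' Top-k genes by a centrality metric
#'
#' Deterministic selection: nodes are sorted by the metric in decreasing
#' order with ties broken by `gene_id` ascending, and the first
#' `min(k, n)` are returned.
#'
#' @param table Centrality tibble from [centralities()] (or any tibble
#'   with `gene_id` plus the metric column).
#' @param metric `"degree"` or `"betweenness"`.
#' @param k Number of genes to select (>= 1).
#' @return Character vector of gene identifiers, highest-ranked first.
#' @export
select_top <- function(table, metric = c("degree", "betweenness"), k) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(k), length(k) == 1, k >= 1)
  ord <- order(-table[[metric]], table$gene_id)
  utils::head(table$gene_id[ord], min(k, nrow(table)))
}

#' Select hub and bottleneck genes from an interaction network
#'
#' Hubs are the top `k_hub` nodes by degree. Bottlenecks are the top
#' `k_bottleneck` nodes by betweenness centrality — the key connectors
#' between network clusters. When `degree_prefilter` is set, bottleneck
#' candidates are first restricted to nodes at or above the
#' `1 - degree_prefilter` quantile of the degree distribution (the
#' "top 20% of the degree distribution" reading, with default 0.20);
#' `degree_prefilter = 1` disables the restriction and NULL skips it
#' entirely.
#'
#' @param net A `gene_network`.
#' @param k_hub,k_bottleneck Number of hub / bottleneck genes (default 50).
#' @param degree_prefilter Optional fraction in (0, 1]; default 0.20.
#' @return An object of class `prioritized_genes`: list with `hubs`,
#'   `bottlenecks` (ordered character vectors), `union`, `intersection`
#'   (character), and `centrality` (the full centrality tibble).
#' @export
prioritize <- function(net, k_hub = 50, k_bottleneck = 50, degree_prefilter = 0.20) {
  stopifnot(inherits(net, "gene_network"))
  if (length(net$nodes) == 0) stop("Cannot prioritize an empty network", call. = FALSE)
  stopifnot(k_hub >= 1, k_bottleneck >= 1)
  if (!is.null(degree_prefilter) &&
      (degree_prefilter <= 0 || degree_prefilter > 1)) {
    stop("'degree_prefilter' must be in (0, 1] or NULL", call. = FALSE)
  }
  ct <- centralities(net)
  hubs <- select_top(ct, "degree", k_hub)
  cand <- ct
  if (!is.null(degree_prefilter)) {
    cut <- stats::quantile(ct$degree, probs = 1 - degree_prefilter, names = FALSE)
    cand <- dplyr::filter(ct, .data$degree >= cut)
  }
  bottlenecks <- select_top(cand, "betweenness", k_bottleneck)
  structure(
    list(
      hubs = hubs,
      bottlenecks = bottlenecks,
      union = union(hubs, bottlenecks),
      intersection = intersect(hubs, bottlenecks),
      centrality = ct
    ),
    class = "prioritized_genes"
  )
}

#' @export
print.prioritized_genes <- function(x, ...) {
  cat("<prioritized_genes> ", length(x$hubs), " hubs, ",
      length(x$bottlenecks), " bottlenecks (union ", length(x$union),
      ", both ", length(x$intersection), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prioritized-gene selection into one row per selected gene
#'
#' @param x A `prioritized_genes` object.
#' @param ... Unused.
#' @return A tibble with `gene_id`, `degree`, `betweenness`, `is_hub`,
#'   `is_bottleneck`, `hub_rank` and `bottleneck_rank` (NA when not
#'   selected under that metric), one row per gene in the union.
#' @export
tidy.prioritized_genes <- function(x, ...) {
  x$centrality |>
    dplyr::filter(.data$gene_id %in% x$union) |>
    dplyr::mutate(
      is_hub = .data$gene_id %in% x$hubs,
      is_bottleneck = .data$gene_id %in% x$bottlenecks,
      hub_rank = match(.data$gene_id, x$hubs),
      bottleneck_rank = match(.data$gene_id, x$bottlenecks)
    ) |>
    dplyr::arrange(.data$hub_rank, .data$bottleneck_rank)
}

#' One-row summary of a prioritized-gene selection
#'
#' @param x A `prioritized_genes` object.
#' @param ... Unused.
#' @export
glance.prioritized_genes <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$centrality),
    n_hubs = length(x$hubs),
    n_bottlenecks = length(x$bottlenecks),
    n_union = length(x$union),
    n_both = length(x$intersection)
  )
}

#' Degree-betweenness scatter of a prioritized network
#'
#' @param object A `prioritized_genes` object.
#' @param ... Unused.
#' @return A ggplot: all nodes in grey, selected genes coloured by
#'   hub / bottleneck / both status.
#' @export
autoplot.prioritized_genes <- function(object, ...) {
  ct <- object$centrality |>
    dplyr::mutate(status = dplyr::case_when(
      .data$gene_id %in% object$intersection ~ "both",
      .data$gene_id %in% object$hubs ~ "hub",
      .data$gene_id %in% object$bottlenecks ~ "bottleneck",
      TRUE ~ "other"
    ))
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$degree, y = .data$betweenness + 1,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      other = "grey70", hub = "#D55E00", bottleneck = "#0072B2", both = "#009E73"
    )) +
    ggplot2::labs(x = "degree", y = "betweenness + 1 (log scale)",
                  colour = NULL, title = "Hub and bottleneck genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
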