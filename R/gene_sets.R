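#' Milk-trait codes recognised in trait-gene annotation tables
#'
#' The controlled vocabulary of quantitative milk-trait codes: milk fat
#' yield (MFY), milk fat percentage (MFP), milk protein yield (MPY), milk
#' protein percentage (MPP), milk yield (MY), milk kappa-casein percentage
#' (MKCP) and test-day milk yield (TDMY).
#'
#' @format Character vector of length 7.
#' @export
trait_codes <- c("MFY", "MFP", "MPY", "MPP", "MY", "MKCP", "TDMY")

check_trait_codes <- function(traits, what = "traits") {
  bad <- setdiff(unique(unlist(traits)), trait_codes)
  if (length(bad) > 0) {
    stop("Unknown trait code(s) in ", what, ": ", paste(bad, collapse = ", "),
         ". Valid codes: ", paste(trait_codes, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a trait-gene annotation table
#'
#' Reads a TSV with columns `gene_id`, optional `symbol`, and `traits`
#' (semicolon-separated trait codes), the layout of an Animal QTLdb-style
#' extract of genes annotated to milk traits.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with columns `gene_id`, `symbol` and `traits`
#'   (a list-column of character vectors).
#' @export
read_trait_genes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "traits") %in% names(df))) {
    stop("Trait-gene table must have columns 'gene_id' and 'traits'", call. = FALSE)
  }
  if (!"symbol" %in% names(df)) df$symbol <- NA_character_
  out <- tibble::tibble(
    gene_id = df$gene_id,
    symbol  = df$symbol,
    traits  = stringr::str_split(df$traits, ";\\s*")
  )
  out$traits <- purrr::map(out$traits, function(x) unique(x[nzchar(x)]))
  bad <- which(is.na(out$gene_id) | !nzchar(out$gene_id))
  if (length(bad) > 0) {
    stop("Empty gene_id at data row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_trait_codes(out$traits)
  out
}

#' Collapse duplicate gene records, merging their trait annotations
#'
#' Trait-gene extracts typically list one row per (gene, QTL) association,
#' so the same gene recurs under several traits. This collapses the table
#' to one row per `gene_id`, taking the union of the trait sets and keeping
#' the order of first occurrence. Merging (rather than keeping the first
#' row) makes deduplication order-independent and loses no annotation.
#'
#' @param records Tibble with columns `gene_id` and `traits` (list-column),
#'   as returned by [read_trait_genes()].
#' @return A tibble of the same shape with unique `gene_id`s.
#' @export
deduplicate_genes <- function(records) {
  stopifnot(is.data.frame(records), all(c("gene_id", "traits") %in% names(records)))
  bad <- which(is.na(records$gene_id) | !nzchar(records$gene_id))
  if (length(bad) > 0) {
    stop("Empty gene_id at row(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  records |>
    dplyr::mutate(.first = dplyr::row_number()) |>
    dplyr::summarise(
      traits = list(unique(unlist(.data$traits))),
      dplyr::across(dplyr::any_of("symbol"), ~ .x[!is.na(.x)][1]),
      .first = min(.data$.first),
      .by = "gene_id"
    ) |>
    dplyr::arrange(.data$.first) |>
    dplyr::select(-".first")
}

#' Two-set overlap counts with inclusion-exclusion
#'
#' Computes the Venn decomposition of two gene-identifier sets, e.g. the
#' genes annotated to milk fat yield versus milk fat percentage.
#'
#' @param a,b Character vectors of gene identifiers (duplicates ignored).
#' @return A one-row tibble with columns `only_a`, `only_b`, `both` and
#'   `union`; `union = only_a + only_b + both` always holds.
#' @export
venn_counts <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  both <- length(intersect(a, b))
  tibble::tibble(
    only_a = length(a) - both,
    only_b = length(b) - both,
    both   = both,
    union  = length(union(a, b))
  )
}

#' Genes annotated to exactly a given trait combination
#'
#' Returns genes whose trait set equals `required` exactly — no missing and
#' no extra traits. Used, for instance, to count genes associated with both
#' fat yield and fat percentage *only*.
#'
#' @param records Deduplicated trait-gene tibble (see [deduplicate_genes()]).
#' @param required Character vector of trait codes, non-empty, drawn from
#'   [trait_codes].
#' @return Character vector of gene identifiers.
#' @export
exclusive_trait_genes <- function(records, required) {
  if (length(required) == 0) stop("'required' must be a non-empty trait set", call. = FALSE)
  check_trait_codes(required, what = "'required'")
  required <- unique(required)
  keep <- purrr::map_lgl(records$traits, ~ setequal(.x, required))
  records$gene_id[keep]
}

#' Gene identifiers carrying a given trait
#'
#' @param records Trait-gene tibble.
#' @param trait A single trait code from [trait_codes].
#' @return Character vector of gene identifiers annotated with `trait`.
#' @export
genes_with_trait <- function(records, trait) {
  stopifnot(length(trait) == 1)
  check_trait_codes(trait, what = "'trait'")
  records$gene_id[purrr::map_lgl(records$traits, ~ trait %in% .x)]
}
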