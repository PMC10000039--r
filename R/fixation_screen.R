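#' Pattern categories assigned by the fixation screen
#'
#' @format Character vector of the six site categories.
#' @export
pattern_categories <- c(
  "FIXED_HIGH_VARIABLE_LOW", "FIXED_LOW_VARIABLE_HIGH",
  "FIXED_BOTH_CONCORDANT", "FIXED_BOTH_DISCORDANT",
  "VARIABLE_BOTH", "INSUFFICIENT_DATA"
)

#' Read a sample-to-group assignment table
#'
#' TSV with columns `sample_id` and `group`, where group is `HIGH` or
#' `LOW` (the high- and low-milk-yield breed groups).
#'
#' @param path Path to the TSV.
#' @return A tibble with `sample_id` and `group`.
#' @export
read_group_map <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character()
  ))
  check_groups(df)
  df
}

check_groups <- function(groups) {
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  bad <- setdiff(unique(groups$group), c("HIGH", "LOW"))
  if (length(bad) > 0) {
    stop("Unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected HIGH/LOW)", call. = FALSE)
  }
  if (!all(c("HIGH", "LOW") %in% groups$group)) {
    stop("Both HIGH and LOW groups must be non-empty", call. = FALSE)
  }
  invisible(TRUE)
}

# normalize "G/A" and "A/G" to the same allele pair
sort_genotype <- function(g) {
  purrr::map_chr(g, function(x) {
    if (is.na(x)) return(NA_character_)
    paste(sort(strsplit(x, "/", fixed = TRUE)[[1]]), collapse = "/")
  })
}

genotype_alleles <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]

#' Summarize one group's genotype evidence at a site
#'
#' Tallies the called and missing genotypes of one breed group at one
#' site. The group is *fixed* when every called animal is homozygous for
#' the same allele and at least `min_called` animals are called; a
#' uniformly heterozygous group is not fixed.
#'
#' @param gm A `genotype_matrix`.
#' @param site Row index of the site in `variant_sites(gm)`.
#' @param groups Group assignment tibble (`sample_id`, `group`).
#' @param which `"HIGH"` or `"LOW"`.
#' @param min_called Minimum called animals needed to declare fixation;
#'   default 2.
#' @return A one-row tibble: `group`, `n_called`, `n_missing`,
#'   `genotypes` (list of normalized called genotype strings) and
#'   `fixed_allele` (`NA` when the group is not fixed).
#' @export
summarize_group <- function(gm, site, groups, which = c("HIGH", "LOW"),
                            min_called = 2) {
  which <- match.arg(which)
  check_groups(groups)
  stopifnot(site >= 1, site <= nrow(gm$sites))
  members <- groups$sample_id[groups$group == which]
  missing_samples <- setdiff(members, gm$samples)
  if (length(missing_samples) > 0) {
    stop("Sample(s) not in genotype matrix: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  calls <- gm$geno[site, members]
  called <- sort_genotype(calls[!is.na(calls)])
  fixed <- NA_character_
  if (length(called) >= min_called) {
    alleles <- unique(unlist(strsplit(called, "/", fixed = TRUE)))
    if (length(alleles) == 1) fixed <- alleles
  }
  tibble::tibble(
    group = which,
    n_called = length(called),
    n_missing = sum(is.na(calls)),
    genotypes = list(unname(called)),
    fixed_allele = fixed
  )
}

#' Classify one site's between-group genotype pattern
#'
#' Applies the categorical fixation rule: a site where one group is fixed
#' (all called animals homozygous for one allele) while the other group
#' carries at least one differing genotype is `FIXED_HIGH_VARIABLE_LOW`
#' or `FIXED_LOW_VARIABLE_HIGH`; both groups fixed gives
#' `FIXED_BOTH_CONCORDANT`/`_DISCORDANT` depending on whether the fixed
#' alleles agree; neither fixed is `VARIABLE_BOTH`; and a group with
#' fewer than `min_called` called animals gives `INSUFFICIENT_DATA`.
#' Variability is judged against the fixed group's homozygous genotype,
#' so alleles outside the declared REF/ALT pair still count as variable.
#'
#' @inheritParams summarize_group
#' @return A one-row tibble: site columns (`chrom`, `pos`, `ref`, `alt`,
#'   plus `gene`/`protein_change` when present), `category`,
#'   `high_genotypes`, `low_genotypes` (comma-collapsed), `n_called_high`,
#'   `n_called_low`, `n_missing_high`, `n_missing_low`.
#' @export
classify_site <- function(gm, site, groups, min_called = 2) {
  s <- gm$sites[site, , drop = FALSE]
  if (!is_biallelic_site(s$alt)) {
    stop("classify_site() handles biallelic sites only; pre-filter with ",
         "filter_variants(biallelic_only = TRUE) (site ", s$chrom, ":",
         s$pos, " has ALT '", s$alt, "')", call. = FALSE)
  }
  h <- summarize_group(gm, site, groups, "HIGH", min_called)
  l <- summarize_group(gm, site, groups, "LOW", min_called)
  h_fixed <- !is.na(h$fixed_allele)
  l_fixed <- !is.na(l$fixed_allele)
  category <- if (h$n_called < min_called || l$n_called < min_called) {
    "INSUFFICIENT_DATA"
  } else if (h_fixed && l_fixed) {
    if (h$fixed_allele == l$fixed_allele) "FIXED_BOTH_CONCORDANT"
    else "FIXED_BOTH_DISCORDANT"
  } else if (h_fixed) {
    hom <- paste(h$fixed_allele, h$fixed_allele, sep = "/")
    stopifnot(any(h$genotypes[[1]] != hom) == FALSE,
              any(l$genotypes[[1]] != hom))
    "FIXED_HIGH_VARIABLE_LOW"
  } else if (l_fixed) {
    hom <- paste(l$fixed_allele, l$fixed_allele, sep = "/")
    stopifnot(any(h$genotypes[[1]] != hom))
    "FIXED_LOW_VARIABLE_HIGH"
  } else {
    "VARIABLE_BOTH"
  }
  out <- tibble::tibble(
    chrom = s$chrom, pos = s$pos,
    gene = if ("gene" %in% names(s)) s$gene else NA_character_,
    ref = s$ref, alt = s$alt,
    protein_change = if ("protein_change" %in% names(s)) s$protein_change else NA_character_,
    category = category,
    high_genotypes = paste(h$genotypes[[1]], collapse = ","),
    low_genotypes = paste(l$genotypes[[1]], collapse = ","),
    n_called_high = h$n_called, n_called_low = l$n_called,
    n_missing_high = h$n_missing, n_missing_low = l$n_missing
  )
  out
}

#' Screen every site of a cohort for group-differential fixation patterns
#'
#' Runs [classify_site()] across all (biallelic SNP) sites of a genotype
#' matrix and collates the calls into a report: the long per-site table,
#' a per-gene roll-up of categories, and wide genotype matrices (samples
#' as rows, sites as columns) per informative category.
#'
#' @inheritParams summarize_group
#' @return An object of class `fixation_report`: list with `calls` (long
#'   tibble), `by_gene` (tibble `gene`, `category`, `n_sites`), and
#'   `wide` (named list of sample-by-site genotype tibbles, one per
#'   category present). Use [tidy()] / [glance()] / [autoplot()].
#' @export
screen_fixation <- function(gm, groups, min_called = 2) {
  check_groups(groups)
  calls <- purrr::map(seq_len(nrow(gm$sites)),
                      ~ classify_site(gm, .x, groups, min_called)) |>
    purrr::list_rbind()
  by_gene <- calls |>
    dplyr::summarise(n_sites = dplyr::n(), .by = c("gene", "category"))
  ord <- order(match(groups$group, c("HIGH", "LOW")))
  sample_order <- intersect(groups$sample_id[ord], gm$samples)
  wide <- purrr::map(split(seq_len(nrow(calls)), calls$category), function(idx) {
    labels <- ifelse(is.na(calls$gene[idx]), calls$chrom[idx], calls$gene[idx])
    cols <- paste0(labels, "_", calls$pos[idx])
    m <- t(gm$geno[idx, sample_order, drop = FALSE])
    colnames(m) <- cols
    dplyr::bind_cols(tibble::tibble(sample_id = sample_order),
                     tibble::as_tibble(m))
  })
  structure(list(calls = calls, by_gene = by_gene, wide = wide,
                 groups = groups, geno = gm$geno, sample_order = sample_order),
            class = "fixation_report")
}

#' @export
print.fixation_report <- function(x, ...) {
  cat("<fixation_report> ", nrow(x$calls), " sites\n", sep = "")
  print(table(x$calls$category))
  invisible(x)
}

#' @rdname screen_fixation
#' @param x A `fixation_report`.
#' @param ... Unused.
#' @export
tidy.fixation_report <- function(x, ...) {
  x$calls
}

#' @rdname screen_fixation
#' @export
glance.fixation_report <- function(x, ...) {
  counts <- table(factor(x$calls$category, levels = pattern_categories))
  out <- tibble::as_tibble(as.list(counts))
  names(out) <- tolower(names(out))
  dplyr::mutate(out, n_sites = nrow(x$calls), .before = 1)
}

#' Genotype-pattern tile plot of a fixation screen
#'
#' @param object A `fixation_report`.
#' @param ... Unused.
#' @return A ggplot tiling samples by sites, coloured by genotype class
#'   (hom-ref / het / hom-alt / other / missing) and faceted by category.
#' @export
autoplot.fixation_report <- function(object, ...) {
  calls <- object$calls
  long <- purrr::map(seq_len(nrow(calls)), function(i) {
    gt <- object$geno[i, object$sample_order]
    ref <- calls$ref[i]
    alt <- calls$alt[i]
    cls <- dplyr::case_when(
      is.na(gt) ~ "missing",
      sort_genotype(gt) == paste(ref, ref, sep = "/") ~ "hom-ref",
      sort_genotype(gt) == sort_genotype(paste(alt, alt, sep = "/")) ~ "hom-alt",
      purrr::map_lgl(gt, ~ length(unique(genotype_alleles(.x))) == 2) ~ "het",
      TRUE ~ "other"
    )
    tibble::tibble(
      site = paste0(ifelse(is.na(calls$gene[i]), calls$chrom[i], calls$gene[i]),
                    "_", calls$pos[i]),
      category = calls$category[i],
      sample_id = object$sample_order,
      genotype = cls
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = rev(object$sample_order)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site, y = .data$sample_id,
                                     fill = .data$genotype)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(. ~ category, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(
      "hom-ref" = "#DDEEFF", het = "#E69F00", "hom-alt" = "#D55E00",
      other = "#CC79A7", missing = "grey85"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "genotype",
                  title = "Between-group SNP fixation patterns") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
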