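fixture_names <- c("table1", "table2", "table3", "table4", "group_map")

fixture_path <- function(name) {
  system.file("extdata", paste0(name, ".tsv"), package = "fixscreen",
              mustWork = TRUE)
}

read_pattern_table <- function(path, table2) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  meta_fields <- c("gene", "location", "ref", "alt", "protein")
  meta <- raw[match(meta_fields, raw$field), -1, drop = FALSE]
  row_of <- function(i) unlist(meta[i, ], use.names = FALSE)
  chrom_by_symbol <- stats::setNames(table2$chrom, table2$symbol)
  sites <- tibble::tibble(
    chrom = unname(chrom_by_symbol[row_of(1)]),
    pos = as.integer(row_of(2)),
    ref = row_of(3),
    alt = row_of(4),
    qual = NA_real_,
    gene = row_of(1),
    protein_change = row_of(5)
  )
  sample_rows <- raw[!raw$field %in% meta_fields, , drop = FALSE]
  geno <- t(as.matrix(sample_rows[, -1, drop = FALSE]))
  geno[geno %in% c("-", "")] <- NA_character_
  dimnames(geno) <- list(NULL, sample_rows$field)
  new_genotype_matrix(sites, sample_rows$field, geno)
}

#' Load a packaged reference-table fixture
#'
#' The package ships machine-readable transcriptions of the reference
#' result tables: `table1` (differentially expressed hub/bottleneck genes
#' with log2FC, p-value and trait codes), `table2` (per-gene SNP summary
#' with gene intervals), `table3` / `table4` (sample-by-site genotype
#' matrices of the fixed-in-high and fixed-in-low pattern sites) and
#' `group_map` (the 14-animal breed-group assignment).
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table4"`,
#'   `"group_map"`.
#' @return `table1`, `table2`, `group_map`: a tibble. `table3`/`table4`:
#'   a `genotype_matrix` whose sites carry `gene` and `protein_change`
#'   columns (chromosomes joined from the `table2` intervals; QUAL is
#'   absent, as these sites are already caller-intersected).
#' @export
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% fixture_names) {
    stop("Unknown fixture '", paste(name, collapse = ","), "'. Valid fixtures: ",
         paste(fixture_names, collapse = ", "), call. = FALSE)
  }
  path <- fixture_path(name)
  switch(name,
    table1 = {
      df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
        section = readr::col_character(),
        gene_id = readr::col_character(),
        symbol = readr::col_character(),
        log2fc = readr::col_double(),
        p_value = readr::col_double(),
        traits = readr::col_character(),
        description = readr::col_character()
      ))
      df$traits <- stringr::str_split(df$traits, ";")
      check_trait_codes(df$traits)
      df
    },
    table2 = readr::read_tsv(path, comment = "#", col_types = readr::cols(
      gene_id = readr::col_character(),
      symbol = readr::col_character(),
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      snp_count = readr::col_integer(),
      bisnp_count = readr::col_integer()
    )),
    table3 = read_pattern_table(path, load_fixture("table2")),
    table4 = read_pattern_table(path, load_fixture("table2")),
    group_map = read_group_map(path)
  )
}
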