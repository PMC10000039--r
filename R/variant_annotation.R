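DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

new_genotype_matrix <- function(sites, samples, geno) {
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == length(samples))
  rownames(geno) <- NULL
  colnames(geno) <- samples
  structure(list(sites = sites, samples = samples, geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' Variant sites of a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @return The site tibble (`chrom`, `pos`, `ref`, `alt`, `qual`, plus any
#'   annotation columns such as `gene`). `alt` holds comma-separated
#'   alternate alleles for multi-allelic sites.
#' @export
variant_sites <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$sites
}

subset_sites <- function(gm, idx) {
  new_genotype_matrix(gm$sites[idx, , drop = FALSE], gm$samples,
                      gm$geno[idx, , drop = FALSE])
}

split_alts <- function(alt) strsplit(alt, ",", fixed = TRUE)

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file with per-sample GT fields into site-by-sample
#' diploid genotype calls. `./.` becomes a missing call; phased separators
#' (`|`) are treated as unphased; genotype allele indices (including
#' multi-allelic ones) are resolved against the site's REF/ALT alleles.
#'
#' @param path Path to an uncompressed or gzipped VCF file.
#' @return A `genotype_matrix`: sites tibble (`chrom`, `pos`, `ref`,
#'   `alt`, `qual`), sample names, and a character matrix of `"A1/A2"`
#'   genotype strings with `NA` for missing calls.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (ncol(v@gt) < 2 || !all(grepl("GT", v@gt[, "FORMAT"]))) {
    stop("VCF must carry a GT field for at least one sample", call. = FALSE)
  }
  sites <- tibble::tibble(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"]))
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  alleles <- purrr::map2(sites$ref, split_alts(sites$alt), c)
  geno <- matrix(NA_character_, nrow = nrow(sites), ncol = length(samples))
  for (j in seq_along(samples)) {
    parts <- strsplit(gt[, j], "[/|]")
    for (i in seq_len(nrow(sites))) {
      p <- parts[[i]]
      if (length(p) == 1 && (is.na(p) || p == ".")) next
      if (length(p) != 2) {
        stop("Non-diploid genotype '", gt[i, j], "' for sample ", samples[j],
             " at ", sites$chrom[i], ":", sites$pos[i], call. = FALSE)
      }
      if (all(p == ".")) next
      if (any(p == ".")) {
        stop("Half-missing genotype '", gt[i, j], "' for sample ", samples[j],
             " at ", sites$chrom[i], ":", sites$pos[i], call. = FALSE)
      }
      idx <- as.integer(p) + 1L
      if (any(is.na(idx)) || any(idx > length(alleles[[i]]))) {
        stop("Genotype index out of range ('", gt[i, j], "') for sample ",
             samples[j], " at ", sites$chrom[i], ":", sites$pos[i], call. = FALSE)
      }
      geno[i, j] <- paste(alleles[[i]][idx], collapse = "/")
    }
  }
  new_genotype_matrix(sites, samples, geno)
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with GT-only FORMAT. Genotype alleles not
#' among the site's REF/ALT (possible in hand-transcribed tables) are
#' appended to ALT with a message so every call remains representable.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sites <- gm$sites
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fixscreen",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  rows <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    alleles <- c(sites$ref[i], split_alts(sites$alt[i])[[1]])
    gts <- character(length(gm$samples))
    for (j in seq_along(gm$samples)) {
      g <- gm$geno[i, j]
      if (is.na(g)) {
        gts[j] <- "./."
        next
      }
      ab <- strsplit(g, "/", fixed = TRUE)[[1]]
      extra <- setdiff(ab, alleles)
      if (length(extra) > 0) {
        message("Site ", sites$chrom[i], ":", sites$pos[i],
                ": observed allele(s) ", paste(extra, collapse = ","),
                " outside REF/ALT; extending ALT")
        alleles <- c(alleles, extra)
      }
      gts[j] <- paste(match(ab, alleles) - 1L, collapse = "/")
    }
    rows[i] <- paste(c(
      sites$chrom[i], sites$pos[i], ".", alleles[1],
      paste(alleles[-1], collapse = ","),
      ifelse(is.na(sites$qual[i]), ".", format(sites$qual[i])),
      "PASS", ".", "GT", gts
    ), collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

is_snp_site <- function(ref, alt) {
  ok_alt <- purrr::map_lgl(split_alts(alt),
                           ~ length(.x) >= 1 && all(.x %in% DNA_BASES))
  ref %in% DNA_BASES & ok_alt
}

is_biallelic_site <- function(alt) {
  lengths(split_alts(alt)) == 1L
}

#' Filter variant sites to quality-passing SNPs
#'
#' Keeps sites where the reference and every alternate allele are single
#' bases (SNPs only — indels and MNVs are discarded) and whose quality
#' strictly exceeds `min_qual` (the vcftools-style Q > 20 filter). Sites
#' with a missing QUAL pass the quality filter, since caller-intersected
#' inputs may lack it. With `biallelic_only`, additionally requires
#' exactly one alternate allele.
#'
#' @param gm A `genotype_matrix` (or a site tibble with `chrom`, `pos`,
#'   `ref`, `alt`, `qual`).
#' @param min_qual Strict phred-quality lower bound; default 20.
#' @param biallelic_only Keep only biallelic SNPs. Default FALSE.
#' @return Object of the same type with the non-passing sites removed.
#' @export
filter_variants <- function(gm, min_qual = 20, biallelic_only = FALSE) {
  sites <- if (inherits(gm, "genotype_matrix")) gm$sites else gm
  keep <- is_snp_site(sites$ref, sites$alt)
  if (!is.null(min_qual)) {
    keep <- keep & (is.na(sites$qual) | sites$qual > min_qual)
  }
  if (biallelic_only) keep <- keep & is_biallelic_site(sites$alt)
  if (inherits(gm, "genotype_matrix")) subset_sites(gm, which(keep))
  else sites[keep, , drop = FALSE]
}

site_key <- function(sites) {
  alt_sorted <- purrr::map_chr(split_alts(sites$alt),
                               ~ paste(sort(.x), collapse = ","))
  paste(sites$chrom, sites$pos, sites$ref, alt_sorted, sep = ":")
}

#' Intersect two variant callsets
#'
#' Keeps sites whose (chromosome, position, reference allele, sorted
#' alternate-allele set) occur in both callsets — the caller-concordance
#' step of a dual-caller workflow. Genotypes and site metadata are taken
#' from the first callset.
#'
#' @param a,b `genotype_matrix` objects or site tibbles.
#' @return `a` restricted to the sites shared with `b`.
#' @export
intersect_callsets <- function(a, b) {
  sa <- if (inherits(a, "genotype_matrix")) a$sites else a
  sb <- if (inherits(b, "genotype_matrix")) b$sites else b
  keep <- site_key(sa) %in% site_key(sb)
  if (inherits(a, "genotype_matrix")) subset_sites(a, which(keep))
  else sa[keep, , drop = FALSE]
}

#' Read a gene interval table
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end` (1-based inclusive),
#' optionally `symbol`.
#'
#' @param path Path to the TSV.
#' @return A tibble of gene intervals.
#' @export
read_gene_intervals <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    .default = readr::col_character()
  ))
  stopifnot(all(df$start <= df$end))
  tibble::as_tibble(df)
}

#' Assign variant sites to gene intervals
#'
#' A site belongs to a gene iff the chromosome matches and
#' `start <= pos <= end` (1-based inclusive, so both boundaries count).
#' A site can belong to several overlapping genes.
#'
#' @param gm A `genotype_matrix` or site tibble.
#' @param intervals Gene interval tibble (`gene_id`, `chrom`, `start`,
#'   `end`), see [read_gene_intervals()].
#' @return A tibble pairing each contained site with its gene:
#'   columns of the site plus `gene_id`.
#' @export
assign_sites_to_genes <- function(gm, intervals) {
  sites <- if (inherits(gm, "genotype_matrix")) gm$sites else gm
  if (nrow(sites) == 0 || nrow(intervals) == 0) {
    return(dplyr::mutate(sites[0, , drop = FALSE], gene_id = character()))
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  gene_gr <- GenomicRanges::GRanges(intervals$chrom,
                                    IRanges::IRanges(intervals$start, intervals$end))
  # sites and intervals may legitimately name disjoint chromosome sets;
  # silence the seqinfo-merge notice that would otherwise raise
  hits <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, gene_gr))
  out <- sites[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- intervals$gene_id[S4Vectors::subjectHits(hits)]
  tibble::as_tibble(out)
}

#' Per-gene SNP summary table
#'
#' Counts, for every gene interval, the contained SNP sites and the
#' biallelic subset, in the layout of a per-gene variant summary
#' (`gene_id`, `chrom`, `start`, `end`, `snp_count`, `bisnp_count`).
#' `bisnp_count <= snp_count` by construction.
#'
#' @inheritParams assign_sites_to_genes
#' @return A tibble with one row per gene in `intervals` (genes with no
#'   contained SNPs get zero counts).
#' @export
gene_snp_summary <- function(gm, intervals) {
  assigned <- assign_sites_to_genes(gm, intervals)
  counts <- assigned |>
    dplyr::filter(is_snp_site(.data$ref, .data$alt)) |>
    dplyr::summarise(
      snp_count = dplyr::n(),
      bisnp_count = sum(is_biallelic_site(.data$alt)),
      .by = "gene_id"
    )
  intervals |>
    dplyr::select("gene_id", "chrom", "start", "end") |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::mutate(dplyr::across(c("snp_count", "bisnp_count"),
                                ~ dplyr::coalesce(.x, 0L)))
}

#' Read gene models (CDS structure) from a TSV
#'
#' Columns: `gene_id`, `chrom`, `strand` (`+`/`-`) and `cds_segments` as
#' semicolon-separated `start-end` 1-based inclusive intervals in genomic
#' coordinate order.
#'
#' @param path Path to the TSV.
#' @return A tibble with a `cds` list-column of `start`/`end` tibbles.
#' @export
read_gene_models <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    chrom = readr::col_character(),
    strand = readr::col_character(),
    cds_segments = readr::col_character()
  ))
  stopifnot(all(df$strand %in% c("+", "-")))
  df$cds <- purrr::map(df$cds_segments, function(s) {
    parts <- stringr::str_split(stringr::str_split_1(s, ";"), "-", simplify = TRUE)
    seg <- tibble::tibble(start = as.integer(parts[, 1]), end = as.integer(parts[, 2]))
    stopifnot(all(seg$start <= seg$end))
    dplyr::arrange(seg, .data$start)
  })
  dplyr::select(df, "gene_id", "chrom", "strand", "cds")
}

#' Read a genome FASTA as a named sequence set
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

model_cds_seq <- function(model, genome) {
  if (!model$chrom %in% names(genome)) {
    stop("Chromosome ", model$chrom, " not in genome", call. = FALSE)
  }
  chrom_seq <- genome[[model$chrom]]
  segs <- model$cds[[1]]
  pieces <- purrr::map2_chr(segs$start, segs$end,
                            ~ as.character(Biostrings::subseq(chrom_seq, .x, .y)))
  cds <- paste(pieces, collapse = "")
  if (nchar(cds) %% 3 != 0) {
    stop("CDS length of ", model$gene_id, " (", nchar(cds),
         ") not divisible by 3", call. = FALSE)
  }
  if (model$strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  cds
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify the coding effect of biallelic SNPs against one gene model
#'
#' Maps each genomic SNP position into the model's coding sequence
#' (reverse-complementing alleles and coordinates for minus-strand genes),
#' substitutes the alternate base into the affected codon, translates both
#' codons with the standard nuclear genetic code, and classifies the
#' change. Sites outside the CDS segments are NONCODING. The protein
#' position is the 1-based codon index, rendered `"pos(Ref/Alt)"`.
#'
#' @param sites Site tibble (`chrom`, `pos`, `ref`, `alt`) of biallelic
#'   SNPs, or a `genotype_matrix`.
#' @param model One row of a gene-model tibble from [read_gene_models()].
#' @param genome A named [Biostrings::DNAStringSet] or FASTA path.
#' @return A tibble with columns `gene_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `cds_pos`, `protein_pos`, `ref_aa`, `alt_aa`, `effect` (one of
#'   NONSYNONYMOUS, SYNONYMOUS, STOP_GAINED, STOP_LOST, NONCODING) and
#'   `protein_change`.
#' @export
annotate_coding_effect <- function(sites, model, genome) {
  if (inherits(sites, "genotype_matrix")) sites <- sites$sites
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1)
    model <- as.list(model)
  }
  bad <- !(is_snp_site(sites$ref, sites$alt) & is_biallelic_site(sites$alt))
  if (any(bad)) {
    stop("annotate_coding_effect() requires biallelic SNP sites; ",
         "pre-filter with filter_variants(biallelic_only = TRUE). Offending site(s): ",
         paste(sites$chrom[bad], sites$pos[bad], sep = ":", collapse = ", "),
         call. = FALSE)
  }
  segs <- model$cds[[1]]
  seg_len <- segs$end - segs$start + 1L
  cds_len <- sum(seg_len)
  cds_seq <- model_cds_seq(model, genome)
  chrom_seq <- genome[[model$chrom]]


  one <- function(chrom, pos, ref, alt) {
    res <- tibble::tibble(
      gene_id = model$gene_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
      cds_pos = NA_integer_, protein_pos = NA_integer_,
      ref_aa = NA_character_, alt_aa = NA_character_,
      effect = "NONCODING", protein_change = NA_character_
    )
    if (chrom != model$chrom) return(res)
    seg_i <- which(pos >= segs$start & pos <= segs$end)
    if (length(seg_i) == 0) return(res)
    genome_base <- as.character(Biostrings::subseq(chrom_seq, pos, pos))
    if (genome_base != ref) {
      stop("Reference allele mismatch at ", chrom, ":", pos, " (VCF ", ref,
           ", genome ", genome_base, ")", call. = FALSE)
    }
    offset <- sum(seg_len[seq_len(seg_i - 1)]) + (pos - segs$start[seg_i] + 1L)
    if (model$strand == "+") {
      cds_pos <- offset
      ref_b <- ref
      alt_b <- alt
    } else {
      cds_pos <- cds_len - offset + 1L
      ref_b <- DNA_COMPLEMENT[[ref]]
      alt_b <- DNA_COMPLEMENT[[alt]]
    }
    codon_idx <- ceiling(cds_pos / 3)
    within <- (cds_pos - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq, 3 * codon_idx - 2, 3 * codon_idx)
    stopifnot(substr(ref_codon, within, within) == ref_b)
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt_b
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    effect <- if (ref_aa == alt_aa) "SYNONYMOUS"
      else if (alt_aa == "*") "STOP_GAINED"
      else if (ref_aa == "*") "STOP_LOST"
      else "NONSYNONYMOUS"
    res$cds_pos <- as.integer(cds_pos)
    res$protein_pos <- as.integer(codon_idx)
    res$ref_aa <- ref_aa
    res$alt_aa <- alt_aa
    res$effect <- effect
    res$protein_change <- sprintf("%d(%s/%s)", codon_idx, ref_aa, alt_aa)
    res
  }
  purrr::pmap(list(sites$chrom, sites$pos, sites$ref, sites$alt), one) |>
    purrr::list_rbind()
}

#' Annotate sites against a table of gene models
#'
#' Convenience wrapper over [annotate_coding_effect()]: each site is
#' annotated against every model whose chromosome matches and whose CDS
#' footprint (first to last CDS base) spans the position. Sites matching
#' no model are returned as NONCODING with `gene_id = NA`.
#'
#' @param sites Site tibble of biallelic SNPs or a `genotype_matrix`.
#' @param models Gene-model tibble from [read_gene_models()].
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @return Row-bound annotation tibble (see [annotate_coding_effect()]).
#' @export
annotate_variants <- function(sites, models, genome) {
  if (inherits(sites, "genotype_matrix")) sites <- sites$sites
  if (is.character(genome)) genome <- read_genome(genome)
  foot <- models |>
    dplyr::mutate(
      fstart = purrr::map_int(.data$cds, ~ min(.x$start)),
      fend = purrr::map_int(.data$cds, ~ max(.x$end))
    )
  out <- vector("list", nrow(models))
  matched <- rep(FALSE, nrow(sites))
  for (m in seq_len(nrow(models))) {
    hit <- sites$chrom == foot$chrom[m] &
      sites$pos >= foot$fstart[m] & sites$pos <= foot$fend[m]
    matched <- matched | hit
    if (!any(hit)) next
    out[[m]] <- annotate_coding_effect(sites[hit, , drop = FALSE],
                                       models[m, , drop = FALSE], genome)
  }
  res <- purrr::list_rbind(purrr::compact(out))
  if (any(!matched)) {
    unhit <- sites[!matched, , drop = FALSE]
    res <- dplyr::bind_rows(res, tibble::tibble(
      gene_id = NA_character_, chrom = unhit$chrom, pos = unhit$pos,
      ref = unhit$ref, alt = unhit$alt,
      cds_pos = NA_integer_, protein_pos = NA_integer_,
      ref_aa = NA_character_, alt_aa = NA_character_,
      effect = "NONCODING", protein_change = NA_character_
    ))
  }
  dplyr::arrange(res, .data$chrom, .data$pos)
}
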