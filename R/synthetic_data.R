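#' Configuration for the synthetic-data generators
#'
#' Bundles the knobs of the four generators with defaults that mirror the
#' study conditions the pipeline was designed around: a trait-gene
#' universe realizing a 161/125/131 fat-yield vs fat-percentage Venn
#' (union 417), a sparse scale-free-ish interaction network of roughly
#' 403 nodes and 671 edges with planted hubs, DE effects on the scale of
#' the reference table (|log2FC| roughly 1-7), and a two-group cohort of
#' 8 high-yield and 6 low-yield animals with planted per-site fixation
#' categories (14 fixed-in-high, 9 fixed-in-low, 1 variable-in-both).
#'
#' @param seed Integer seed; each generator derives its own fixed stream
#'   from it, so identical configs give byte-identical outputs.
#' @param n_genes Total genes in the trait-gene universe.
#' @param venn_sizes Named vector `only_a`, `both`, `only_b`: genes with
#'   MFY only, both MFY and MFP, MFP only.
#' @param n_network_nodes,n_network_edges Network size.
#' @param n_planted_hubs Number of planted high-degree hub nodes.
#' @param de_effect_mean,de_effect_sd Absolute mean and sd of target-gene
#'   log2 fold changes (sign randomized per gene).
#' @param de_null_sd Sd of background log2 fold changes around zero.
#' @param n_high,n_low Cohort group sizes.
#' @param sites_per_category Named integer vector mapping pattern
#'   categories (see [pattern_categories]) to planted site counts.
#' @param missing_rate Per-call missing-genotype rate in \[0, 1).
#' @param genome_length Synthetic genome length in bases.
#' @param genes_per_genome Number of gene models placed on the genome.
#' @param min_called Fixation evidence floor the generator must respect
#'   when injecting missing calls; default 2.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes = 600,
                             venn_sizes = c(only_a = 161, both = 125, only_b = 131),
                             n_network_nodes = 403,
                             n_network_edges = 671,
                             n_planted_hubs = 10,
                             de_effect_mean = 2.5,
                             de_effect_sd = 0.6,
                             de_null_sd = 0.4,
                             n_high = 8,
                             n_low = 6,
                             sites_per_category = c(FIXED_HIGH_VARIABLE_LOW = 14,
                                                    FIXED_LOW_VARIABLE_HIGH = 9,
                                                    VARIABLE_BOTH = 1),
                             missing_rate = 0,
                             genome_length = 60000,
                             genes_per_genome = 20,
                             min_called = 2) {
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_genes >= 0, n_high >= 1, n_low >= 1,
    all(venn_sizes >= 0), all(c("only_a", "both", "only_b") %in% names(venn_sizes)),
    n_network_nodes >= 0, n_network_edges >= 0, n_planted_hubs >= 0,
    de_effect_sd > 0, de_null_sd > 0,
    missing_rate >= 0, missing_rate < 1,
    genome_length >= 1, genes_per_genome >= 0
  )
  bad <- setdiff(names(sites_per_category),
                 setdiff(pattern_categories, "INSUFFICIENT_DATA"))
  if (length(bad) > 0) {
    stop("sites_per_category has unknown categor(ies): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a trait-gene annotation universe
#'
#' Emits gene records whose MFY/MFP memberships realize exactly the
#' requested Venn sizes; genes may additionally carry other milk-trait
#' codes at random, and background genes carry only non-MFY/MFP traits.
#'
#' @param config A [synthetic_config()].
#' @return A trait-gene tibble (`gene_id`, `symbol`, `traits`) as from
#'   [read_trait_genes()].
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  v <- config$venn_sizes
  n_union <- sum(v)
  if (n_union > config$n_genes) {
    stop("venn_sizes sum (", n_union, ") exceeds n_genes (", config$n_genes, ")",
         call. = FALSE)
  }
  set.seed(config$seed)
  ids <- sprintf("SYNG%04d", seq_len(config$n_genes))
  other <- setdiff(trait_codes, c("MFY", "MFP"))
  core <- c(rep(list("MFY"), v[["only_a"]]),
            rep(list(c("MFY", "MFP")), v[["both"]]),
            rep(list("MFP"), v[["only_b"]]),
            rep(list(character()), config$n_genes - n_union))
  traits <- purrr::map(core, function(tr) {
    extra <- other[stats::runif(length(other)) < 0.25]
    out <- union(tr, extra)
    if (length(out) == 0) out <- sample(other, 1)
    out
  })
  tibble::tibble(gene_id = ids, symbol = ids, traits = traits)
}

#' Simulate a scored interaction network with planted hubs
#'
#' Grows a preferential-attachment-style simple graph in which the first
#' `n_planted_hubs` nodes receive a large attachment bonus, concentrating
#' the top of the degree distribution on them. Edge confidence scores are
#' drawn uniformly from \[0.5, 1\] so the whole edge list survives the
#' default confidence threshold.
#'
#' @param config A [synthetic_config()].
#' @param nodes Optional character vector of node ids to draw from;
#'   default `SYNG`-style ids matching [simulate_universe()].
#' @return A list with `edges` (tibble `a`, `b`, `score`) and `hubs`
#'   (character vector of planted hub ids).
#' @export
simulate_network <- function(config, nodes = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_network_nodes
  m <- config$n_network_edges
  if (is.null(nodes)) nodes <- sprintf("SYNG%04d", seq_len(n))
  stopifnot(length(nodes) >= n)
  nodes <- nodes[seq_len(n)]
  if (m > n * (n - 1) / 2) stop("Requested more edges than a simple graph allows", call. = FALSE)
  set.seed(config$seed + 1L)
  hubs <- nodes[seq_len(min(config$n_planted_hubs, n))]
  if (m == 0) {
    return(list(edges = tibble::tibble(a = character(), b = character(),
                                       score = double()),
                hubs = hubs))
  }
  deg <- stats::setNames(rep(0, n), nodes)
  boost <- stats::setNames(rep(1, n), nodes)
  boost[hubs] <- 40
  seen <- character(0)
  a_out <- b_out <- character(m)
  e <- 0L
  while (e < m) {
    w <- deg + boost
    p1 <- sample(nodes, 1, prob = w)
    w2 <- w
    w2[p1] <- 0
    p2 <- sample(nodes, 1, prob = w2)
    key <- paste(min(p1, p2), max(p1, p2))
    if (key %in% seen) next
    e <- e + 1L
    seen <- c(seen, key)
    a_out[e] <- p1
    b_out[e] <- p2
    deg[p1] <- deg[p1] + 1
    deg[p2] <- deg[p2] + 1
  }
  list(
    edges = tibble::tibble(a = a_out, b = b_out,
                           score = stats::runif(m, 0.5, 1)),
    hubs = hubs
  )
}

#' Simulate a differential-expression results table
#'
#' Target genes receive log2 fold changes of magnitude
#' `Normal(de_effect_mean, de_effect_sd)` with a random sign and small
#' p-values (uniform below 0.01); background genes receive
#' `Normal(0, de_null_sd)` fold changes and uniform p-values.
#'
#' @param config A [synthetic_config()].
#' @param target_genes Character vector of genes planted as differentially
#'   expressed.
#' @param gene_ids All gene ids in the table; defaults to the universe ids
#'   implied by `config$n_genes`.
#' @return A tibble `gene_id`, `log2fc`, `p_value`, `is_target`.
#' @export
simulate_de <- function(config, target_genes, gene_ids = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(gene_ids)) gene_ids <- sprintf("SYNG%04d", seq_len(config$n_genes))
  stopifnot(all(target_genes %in% gene_ids))
  set.seed(config$seed + 2L)
  n <- length(gene_ids)
  is_target <- gene_ids %in% target_genes
  sign <- sample(c(-1, 1), n, replace = TRUE)
  lfc <- ifelse(
    is_target,
    sign * abs(stats::rnorm(n, config$de_effect_mean, config$de_effect_sd)),
    stats::rnorm(n, 0, config$de_null_sd)
  )
  p <- ifelse(is_target, stats::runif(n, 0, 0.01), stats::runif(n))
  tibble::tibble(gene_id = gene_ids, log2fc = lfc, p_value = p,
                 is_target = is_target)
}

# Map a 1-based mRNA-sense CDS offset to its genomic position for a model
# whose segments are stored in genomic order. Written as the inverse of the
# forward mapping used by the annotator so the two can cross-check.
cds_to_genomic <- function(cds_pos, segs, strand) {
  seg_len <- segs$end - segs$start + 1L
  total <- sum(seg_len)
  offset <- if (strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(seg_len)
  seg_i <- which(offset <= cum)[1]
  prev <- if (seg_i == 1) 0L else cum[seg_i - 1]
  as.integer(segs$start[seg_i] + (offset - prev) - 1L)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a two-group genotyped cohort with planted fixation patterns
#'
#' Builds a random genome, lays out non-overlapping single-transcript gene
#' models (CDS length divisible by 3, random strand), and for every
#' requested pattern category plants biallelic coding SNPs whose
#' per-sample genotypes realize that category. Alternate alleles are
#' chosen so the coding effect is non-synonymous. The reference allele is
#' always the fixed (or majority) group's allele. Missing calls are
#' injected at `missing_rate` but only on homozygous calls and never
#' below `min_called` called animals per group, so planted categories
#' stay recoverable. The VCF is written with QUAL above 20.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `gene_models.tsv`, `gene_intervals.tsv`, `cohort.vcf`, `truth.tsv`
#'   and `group_map.tsv` there.
#' @return A list with `genome` ([Biostrings::DNAStringSet]), `models`,
#'   `intervals`, `gm` (a `genotype_matrix`), `groups` (sample-group
#'   tibble) and `truth` (one row per planted site: `chrom`, `pos`,
#'   `gene_id`, `ref`, `alt`, `category`, `effect`, `protein_pos`).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  spc <- config$sites_per_category
  spc <- spc[spc > 0]
  n_sites <- sum(spc)
  if (n_sites > 0 && config$genes_per_genome == 0) {
    stop("Cannot plant sites with genes_per_genome = 0", call. = FALSE)
  }
  if (any(names(spc) %in% c("FIXED_HIGH_VARIABLE_LOW", "VARIABLE_BOTH")) &&
      config$n_low < 1 ||
      any(names(spc) %in% c("FIXED_LOW_VARIABLE_HIGH", "VARIABLE_BOTH")) &&
      config$n_high < 1) {
    stop("A variable group of size 0 cannot realize the requested category",
         call. = FALSE)
  }
  set.seed(config$seed + 3L)
  chrom <- "chrS1"
  genome_chars <- strsplit(random_dna(config$genome_length), "")[[1]]

  samples <- c(sprintf("H%d", seq_len(config$n_high)),
               sprintf("L%d", seq_len(config$n_low)))
  groups <- tibble::tibble(
    sample_id = samples,
    group = rep(c("HIGH", "LOW"), c(config$n_high, config$n_low))
  )

  # non-overlapping gene slots across the genome
  n_genes <- config$genes_per_genome
  slot <- floor(config$genome_length / max(n_genes, 1))
  if (n_genes > 0 && slot < 260) {
    stop("Genome too short for ", n_genes, " gene models", call. = FALSE)
  }
  models <- purrr::map(seq_len(n_genes), function(g) {
    slot_start <- (g - 1L) * slot + 1L
    n_codons <- sample(50:70, 1)
    total <- 3L * n_codons
    n_seg <- sample(1:2, 1)
    strand <- sample(c("+", "-"), 1)
    if (n_seg == 1) {
      s1 <- slot_start + sample(10:30, 1)
      segs <- tibble::tibble(start = s1, end = s1 + total - 1L)
    } else {
      l1 <- 3L * sample(10:(n_codons - 10), 1)
      s1 <- slot_start + sample(5:15, 1)
      gap <- sample(10:30, 1)
      s2 <- s1 + l1 + gap
      segs <- tibble::tibble(start = c(s1, s2),
                             end = c(s1 + l1 - 1L, s2 + (total - l1) - 1L))
    }
    # write an mRNA-sense CDS into the genome so codons are known by design
    cds_seq <- random_dna(total)
    genomic <- if (strand == "+") cds_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    gpos <- unlist(purrr::map2(segs$start, segs$end, seq))
    genome_chars[gpos] <<- strsplit(genomic, "")[[1]]
    tibble::tibble(gene_id = sprintf("GENE%02d", g), chrom = chrom,
                   strand = strand, cds = list(segs),
                   cds_mrna = cds_seq)
  }) |>
    purrr::list_rbind()

  intervals <- if (n_genes > 0) {
    models |>
      dplyr::mutate(
        start = purrr::map_int(.data$cds, ~ min(.x$start)) - 5L,
        end = purrr::map_int(.data$cds, ~ max(.x$end)) + 5L
      ) |>
      dplyr::select("gene_id", "chrom", "start", "end")
  } else {
    tibble::tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer())
  }

  # plant sites: round-robin over genes, one codon per site, nonsynonymous alt
  categories <- rep(names(spc), spc)
  truth_rows <- list()
  site_rows <- list()
  geno <- NULL
  if (n_sites > 0) {
    geno <- matrix(NA_character_, nrow = n_sites, ncol = length(samples),
                   dimnames = list(NULL, samples))
    used_codons <- purrr::map(seq_len(n_genes), ~ integer(0))
    for (i in seq_len(n_sites)) {
      g <- (i - 1L) %% n_genes + 1L
      model <- models[g, ]
      segs <- model$cds[[1]]
      n_codons <- nchar(model$cds_mrna) / 3
      # pick an unused codon, a position within it and an alt base giving a
      # missense (non-stop) change; stop codons cannot, so skip them
      resample <- function(x) x[sample.int(length(x))]
      found <- FALSE
      for (ci in resample(setdiff(seq_len(n_codons), used_codons[[g]]))) {
        codon <- substr(model$cds_mrna, 3 * ci - 2, 3 * ci)
        ref_aa <- translate_codon(codon)
        if (ref_aa == "*") next
        for (within in sample(1:3)) {
          for (alt_b in resample(setdiff(DNA_BASES, substr(codon, within, within)))) {
            alt_codon <- codon
            substr(alt_codon, within, within) <- alt_b
            if (translate_codon(alt_codon) != ref_aa &&
                translate_codon(alt_codon) != "*") {
              found <- TRUE
              break
            }
          }
          if (found) break
        }
        if (found) {
          codon_idx <- ci
          break
        }
      }
      if (!found) {
        stop("Could not place a missense site in ", model$gene_id, call. = FALSE)
      }
      used_codons[[g]] <- c(used_codons[[g]], codon_idx)
      cds_pos <- 3L * (codon_idx - 1L) + within
      pos <- cds_to_genomic(cds_pos, segs, model$strand)
      ref_g <- genome_chars[pos]
      alt_g <- if (model$strand == "+") alt_b else DNA_COMPLEMENT[[alt_b]]
      stopifnot(ref_g != alt_g)

      cat_i <- categories[i]
      hom_ref <- paste(ref_g, ref_g, sep = "/")
      het <- paste(ref_g, alt_g, sep = "/")
      hom_alt <- paste(alt_g, alt_g, sep = "/")
      gt_high <- rep(hom_ref, config$n_high)
      gt_low <- rep(hom_ref, config$n_low)
      variable_fill <- function(n) {
        # at least one het carrier, remaining calls a random mix
        out <- rep(hom_ref, n)
        out[1] <- het
        extra <- which(stats::runif(n) < 0.3)
        out[setdiff(extra, 1)] <- sample(c(het, hom_alt),
                                         length(setdiff(extra, 1)), replace = TRUE)
        sample(out)
      }
      if (cat_i == "FIXED_HIGH_VARIABLE_LOW") {
        gt_low <- variable_fill(config$n_low)
      } else if (cat_i == "FIXED_LOW_VARIABLE_HIGH") {
        gt_high <- variable_fill(config$n_high)
      } else if (cat_i == "FIXED_BOTH_DISCORDANT") {
        gt_low <- rep(hom_alt, config$n_low)
      } else if (cat_i == "VARIABLE_BOTH") {
        gt_high <- variable_fill(config$n_high)
        gt_low <- variable_fill(config$n_low)
      } # FIXED_BOTH_CONCORDANT: all hom_ref already
      calls <- c(gt_high, gt_low)

      if (config$missing_rate > 0) {
        for (grp in c("HIGH", "LOW")) {
          idx <- which(groups$group == grp)
          hom <- idx[calls[idx] %in% c(hom_ref, hom_alt)]
          mask <- hom[stats::runif(length(hom)) < config$missing_rate]
          excess <- length(idx) - length(mask) - config$min_called
          if (excess < 0) mask <- utils::head(mask, length(mask) + excess)
          calls[mask] <- NA_character_
        }
      }
      geno[i, ] <- calls
      site_rows[[i]] <- tibble::tibble(
        chrom = chrom, pos = pos, ref = ref_g, alt = alt_g,
        qual = round(stats::runif(1, 25, 60), 1), gene = model$gene_id
      )
      truth_rows[[i]] <- tibble::tibble(
        chrom = chrom, pos = pos, gene_id = model$gene_id,
        ref = ref_g, alt = alt_g, category = cat_i,
        effect = "NONSYNONYMOUS", protein_pos = codon_idx
      )
    }
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(paste(genome_chars, collapse = ""), chrom))
  sites <- if (n_sites > 0) purrr::list_rbind(site_rows) else
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), qual = double(), gene = character())
  truth <- if (n_sites > 0) purrr::list_rbind(truth_rows) else
    tibble::tibble(chrom = character(), pos = integer(), gene_id = character(),
                   ref = character(), alt = character(), category = character(),
                   effect = character(), protein_pos = integer())
  ord <- order(sites$pos)
  sites <- sites[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  gm <- new_genotype_matrix(sites, samples,
                            if (n_sites > 0) geno[ord, , drop = FALSE] else
                              matrix(character(), 0, length(samples)))

  out <- list(genome = genome, models = dplyr::select(models, -"cds_mrna"),
              intervals = intervals, gm = gm, groups = groups, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    write_gene_models(out$models, file.path(dir, "gene_models.tsv"))
    readr::write_tsv(intervals, file.path(dir, "gene_intervals.tsv"))
    write_vcf(gm, file.path(dir, "cohort.vcf"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
    readr::write_tsv(groups, file.path(dir, "group_map.tsv"))
    out$dir <- dir
  }
  out
}

#' Write gene models to the package's TSV layout
#'
#' @param models Gene-model tibble with a `cds` list-column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  df <- tibble::tibble(
    gene_id = models$gene_id, chrom = models$chrom, strand = models$strand,
    cds_segments = purrr::map_chr(models$cds,
                                  ~ paste(paste0(.x$start, "-", .x$end), collapse = ";"))
  )
  readr::write_tsv(df, path)
  invisible(path)
}
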