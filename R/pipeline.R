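#' Configuration for the end-to-end prioritization and screening pipeline
#'
#' Collects input paths and stage thresholds. All thresholds default to
#' the pipeline's reference settings: STRING-style confidence 0.5, 50 hub
#' and 50 bottleneck genes with a 0.20 degree-percentile bottleneck
#' prefilter, DE significance p < 0.05 with no fold-change cut, SNP
#' quality Q > 20, and a two-animal fixation evidence floor.
#'
#' @param trait_genes,edges,de,vcf,genome,gene_models,intervals,group_map
#'   Input file paths (see the `read_*` functions for formats).
#' @param vcf2 Optional second caller's VCF; when given, sites are
#'   intersected across callers before annotation.
#' @param out_dir Output directory for report TSVs; NULL to skip writing.
#' @param min_score,k_hub,k_bottleneck,degree_prefilter,alpha,min_abs_lfc,min_qual,min_called
#'   Stage parameters, as documented in the stage functions.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trait_genes, edges, de, vcf, genome, gene_models,
                            intervals, group_map, vcf2 = NULL, out_dir = NULL,
                            min_score = 0.5, k_hub = 50, k_bottleneck = 50,
                            degree_prefilter = 0.20, alpha = 0.05,
                            min_abs_lfc = 0, min_qual = 20, min_called = 2) {
  stopifnot(
    min_score >= 0, min_score <= 1, k_hub >= 1, k_bottleneck >= 1,
    is.null(degree_prefilter) || (degree_prefilter > 0 && degree_prefilter <= 1),
    alpha > 0, alpha <= 1, min_abs_lfc >= 0, min_called >= 1
  )
  structure(as.list(environment()), class = "pipeline_config")
}

log_stage <- function(...) message("[fixscreen] ", ...)

#' Run the full prioritization and fixation-screen pipeline
#'
#' Executes the stages in order — trait-gene set accounting, network
#' prioritization, DE integration, variant filtering/intersection/
#' annotation, and the fixation-pattern screen — logging before/after
#' counts at every filter and writing report tables to
#' `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `venn`, `prioritized`, `de_table`,
#'   `snp_summary`, `annotation`, `report` (a `fixation_report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- gene sets ------------------------------------------------------------
  res <- list()
  res$venn <- run_stage("gene_sets", {
    records <- read_trait_genes(config$trait_genes)
    n_raw <- nrow(records)
    records <- deduplicate_genes(records)
    log_stage("gene_sets: ", n_raw, " records -> ", nrow(records),
              " unique genes after deduplication")
    v <- venn_counts(genes_with_trait(records, "MFY"),
                     genes_with_trait(records, "MFP"))
    log_stage("gene_sets: MFY/MFP venn only_a=", v$only_a, " both=", v$both,
              " only_b=", v$only_b, " union=", v$union)
    v
  })

  # -- network prioritization ----------------------------------------------
  res$prioritized <- run_stage("network_prioritization", {
    edges <- read_interaction_edges(config$edges)
    net <- build_network(edges, min_score = config$min_score)
    log_stage("network: ", nrow(edges), " input edges -> ", nrow(net$edges),
              " edges / ", length(net$nodes), " nodes at score >= ",
              config$min_score)
    prioritize(net, k_hub = config$k_hub, k_bottleneck = config$k_bottleneck,
               degree_prefilter = config$degree_prefilter)
  })
  log_stage("network: ", length(res$prioritized$hubs), " hubs, ",
            length(res$prioritized$bottlenecks), " bottlenecks, union ",
            length(res$prioritized$union))

  # -- DE integration -------------------------------------------------------
  res$de_table <- run_stage("de_integration", {
    de <- read_de_results(config$de)
    kept <- filter_de(de, alpha = config$alpha, min_abs_lfc = config$min_abs_lfc)
    log_stage("de: ", nrow(de), " results -> ", nrow(kept), " at p < ",
              config$alpha, ", |log2FC| >= ", config$min_abs_lfc)
    integrate_de(res$prioritized, kept)
  })
  s <- glance(res$de_table)
  log_stage("de: ", s$n_union, " DE hub/bottleneck genes (", s$n_both,
            " both, ", s$n_up, " up / ", s$n_down, " down)")

  # -- variant annotation ---------------------------------------------------
  ann <- run_stage("variant_annotation", {
    gm <- read_vcf(config$vcf)
    log_stage("variants: ", nrow(gm$sites), " sites read from ", config$vcf)
    if (!is.null(config$vcf2)) {
      gm2 <- read_vcf(config$vcf2)
      n0 <- nrow(gm$sites)
      gm <- intersect_callsets(gm, gm2)
      log_stage("variants: caller intersection ", n0, " x ", nrow(gm2$sites),
                " -> ", nrow(gm$sites), " common sites")
    }
    n0 <- nrow(gm$sites)
    gm <- filter_variants(gm, min_qual = config$min_qual)
    log_stage("variants: SNP + Q > ", config$min_qual, " filter: ", n0,
              " -> ", nrow(gm$sites), " sites")
    intervals <- read_gene_intervals(config$intervals)
    snp_summary <- gene_snp_summary(gm, intervals)
    bi <- filter_variants(gm, min_qual = NULL, biallelic_only = TRUE)
    log_stage("variants: ", nrow(bi$sites), " biallelic SNPs for annotation")
    models <- read_gene_models(config$gene_models)
    genome <- read_genome(config$genome)
    annotation <- annotate_variants(bi, models, genome)
    list(gm = bi, snp_summary = snp_summary, annotation = annotation)
  })
  res$snp_summary <- ann$snp_summary
  res$annotation <- ann$annotation

  # -- fixation screen ------------------------------------------------------
  res$report <- run_stage("fixation_screen", {
    ns <- dplyr::filter(ann$annotation, .data$effect == "NONSYNONYMOUS")
    log_stage("screen: ", nrow(ns), " non-synonymous SNPs of ",
              nrow(ann$annotation), " annotated")
    keep <- paste(ann$gm$sites$chrom, ann$gm$sites$pos) %in%
      paste(ns$chrom, ns$pos)
    gm <- subset_sites(ann$gm, which(keep))
    gm$sites$gene <- ns$gene_id[match(paste(gm$sites$chrom, gm$sites$pos),
                                      paste(ns$chrom, ns$pos))]
    gm$sites$protein_change <- ns$protein_change[
      match(paste(gm$sites$chrom, gm$sites$pos), paste(ns$chrom, ns$pos))]
    groups <- read_group_map(config$group_map)
    screen_fixation(gm, groups, min_called = config$min_called)
  })
  log_stage("screen: categories — ",
            paste(names(table(res$report$calls$category)),
                  table(res$report$calls$category),
                  sep = "=", collapse = ", "))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) readr::write_tsv(x, file.path(config$out_dir, f))
    w(res$venn, "venn_summary.tsv")
    w(tidy(res$prioritized), "prioritized_genes.tsv")
    w(tibble::as_tibble(res$de_table), "de_hub_bottleneck.tsv")
    w(glance(res$de_table), "de_summary.tsv")
    w(res$snp_summary, "gene_snp_summary.tsv")
    w(res$annotation, "coding_effects.tsv")
    w(res$report$calls, "fixation_calls.tsv")
    purrr::iwalk(res$report$wide,
                 ~ w(.x, paste0("pattern_", tolower(.y), ".tsv")))
    log_stage("reports written to ", config$out_dir)
  }
  invisible(res)
}

#' Write a complete set of simulated pipeline inputs
#'
#' Generates every input [run_pipeline()] consumes — trait-gene table,
#' scored edge list, DE results, cohort VCF with genome, gene models,
#' intervals and group map — from one [synthetic_config()], with ground
#' truth, so the whole pipeline can run without any external data.
#' The network is built over the simulated gene universe and the DE
#' targets are the planted hubs, so downstream intersections are
#' non-trivial by construction.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return A [pipeline_config()] pointing at the written files, with the
#'   simulation truth attached as attribute `"truth"` (list with
#'   `universe`, `network_hubs`, `de`, `cohort`).
#' @export
simulate_pipeline_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  universe <- simulate_universe(config)
  ut <- tibble::tibble(
    gene_id = universe$gene_id, symbol = universe$symbol,
    traits = purrr::map_chr(universe$traits, paste, collapse = ";")
  )
  readr::write_tsv(ut, file.path(dir, "trait_genes.tsv"))
  net <- simulate_network(config, nodes = universe$gene_id)
  readr::write_tsv(
    tibble::tibble(protein_a = net$edges$a, protein_b = net$edges$b,
                   combined_score = net$edges$score),
    file.path(dir, "edges.tsv")
  )
  de <- simulate_de(config, target_genes = net$hubs,
                    gene_ids = universe$gene_id)
  readr::write_tsv(de[, c("gene_id", "log2fc", "p_value")],
                   file.path(dir, "de_results.tsv"))
  cohort <- simulate_cohort(config, dir = dir)
  pc <- pipeline_config(
    trait_genes = file.path(dir, "trait_genes.tsv"),
    edges = file.path(dir, "edges.tsv"),
    de = file.path(dir, "de_results.tsv"),
    vcf = file.path(dir, "cohort.vcf"),
    genome = file.path(dir, "genome.fa"),
    gene_models = file.path(dir, "gene_models.tsv"),
    intervals = file.path(dir, "gene_intervals.tsv"),
    group_map = file.path(dir, "group_map.tsv"),
    out_dir = file.path(dir, "reports"),
    min_called = config$min_called
  )
  attr(pc, "truth") <- list(universe = universe, network_hubs = net$hubs,
                            de = de, cohort = cohort$truth)
  pc
}
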