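write_mini_vcf <- function(lines, samples = c("S1", "S2")) {
  tf <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines
  ), tf)
  tf
}

test_that("VCF genotypes are resolved against site alleles", {
  tf <- write_mini_vcf("chr1\t100\t.\tC\tG\t50\tPASS\t.\tGT\t0/1\t1/1")
  gm <- read_vcf(tf)
  expect_equal(gm$samples, c("S1", "S2"))
  expect_equal(unname(gm$geno[1, ]), c("C/G", "G/G"))
  expect_equal(gm$sites$qual, 50)

  # missing, phased, and multi-allelic index resolution
  tf2 <- write_mini_vcf(c(
    "chr1\t100\t.\tC\tG,T\t50\tPASS\t.\tGT\t./.\t1|2",
    "chr1\t200\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t./."
  ))
  gm2 <- read_vcf(tf2)
  expect_equal(unname(gm2$geno[1, ]), c(NA, "G/T"))
  expect_equal(unname(gm2$geno[2, ]), c("A/A", NA))
  expect_true(is.na(gm2$sites$qual[2]))
})

test_that("malformed genotypes are rejected with sample and site named", {
  tf <- write_mini_vcf("chr1\t100\t.\tC\tG\t50\tPASS\t.\tGT\t0/1/1\t0/0")
  expect_error(read_vcf(tf), "Non-diploid.*S1.*chr1:100")
  tf2 <- write_mini_vcf("chr1\t100\t.\tC\tG\t50\tPASS\t.\tGT\t./0\t0/0")
  expect_error(read_vcf(tf2), "Half-missing")
})

test_that("VCF write/read round-trips sites, quals and genotypes", {
  co <- simulate_cohort(small_cohort_config(101, missing_rate = 0.1))
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(co$gm, tf)
  expect_no_warning(gm2 <- read_vcf(tf))
  expect_equal(gm2$sites$chrom, co$gm$sites$chrom)
  expect_equal(gm2$sites$pos, co$gm$sites$pos)
  expect_equal(gm2$sites$ref, co$gm$sites$ref)
  expect_equal(gm2$sites$alt, co$gm$sites$alt)
  expect_equal(gm2$sites$qual, co$gm$sites$qual)
  expect_equal(gm2$geno, co$gm$geno)
  expect_equal(gm2$samples, co$gm$samples)
})

test_that("variant filtering applies SNP, quality and biallelic predicates", {
  sites <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    ref = c("C", "C", "CT", "A"),
    alt = c("G", "G,T", "C", "G"),
    qual = c(30, 30, 50, 15)
  )
  expect_equal(filter_variants(sites, min_qual = 20)$pos, c(10L, 20L))
  expect_equal(filter_variants(sites, min_qual = 20, biallelic_only = TRUE)$pos, 10L)
  # strictness: qual exactly at the bound is dropped; missing qual passes
  sites$qual <- c(20, NA, 50, 21)
  expect_equal(filter_variants(sites, min_qual = 20)$pos, c(20L, 40L))

  set.seed(29)
  rand <- tibble::tibble(
    chrom = "chr1", pos = seq_len(200),
    ref = sample(c("A", "C", "G", "T", "AT"), 200, replace = TRUE),
    alt = sample(c("A", "G", "T", "G,T", "GA"), 200, replace = TRUE),
    qual = sample(c(NA, 10, 20.5, 45), 200, replace = TRUE)
  )
  got <- filter_variants(rand, min_qual = 20, biallelic_only = TRUE)
  oracle <- rand[
    rand$ref %in% c("A", "C", "G", "T") &
      rand$alt %in% c("A", "G", "T") &
      (is.na(rand$qual) | rand$qual > 20), ]
  expect_equal(got, oracle)
  expect_true(all(got$pos %in% rand$pos))
})

test_that("callset intersection keys on chrom, pos and allele set", {
  a <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L),
                      ref = c("C", "A", "G"), alt = c("G", "T", "A,C"),
                      qual = 30)
  expect_equal(intersect_callsets(a, a), a)
  b <- a
  b$alt[2] <- "C"  # same position, different alt: excluded
  expect_equal(intersect_callsets(a, b)$pos, c(10L, 30L))
  # alt order must not matter
  b2 <- a
  b2$alt[3] <- "C,A"
  expect_equal(intersect_callsets(a, b2), a)

  set.seed(37)
  for (i in 1:20) {
    x <- tibble::tibble(chrom = sample(c("c1", "c2"), 40, replace = TRUE),
                        pos = sample(1:30, 40, replace = TRUE),
                        ref = sample(c("A", "C"), 40, replace = TRUE),
                        alt = sample(c("G", "T"), 40, replace = TRUE),
                        qual = 30)
    y <- x[sample(40, 25), ]
    got <- intersect_callsets(x, y)
    key <- function(s) paste(s$chrom, s$pos, s$ref, s$alt)
    expect_equal(got, x[key(x) %in% key(y), ])
  }
})

test_that("site-to-gene assignment is 1-based inclusive on both boundaries", {
  intervals <- tibble::tibble(gene_id = c("G1", "G2"), chrom = c("chr1", "chr2"),
                              start = c(100L, 50L), end = c(200L, 60L))
  sites <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr3"),
                          pos = c(100L, 200L, 201L, 100L),
                          ref = "A", alt = "G", qual = 30)
  got <- assign_sites_to_genes(sites, intervals)
  expect_equal(got$pos, c(100L, 200L))
  expect_equal(unique(got$gene_id), "G1")

  set.seed(41)
  rand_sites <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample(1:5000, 1000, replace = TRUE), ref = "A", alt = "G", qual = 30
  )
  rand_iv <- tibble::tibble(
    gene_id = sprintf("G%02d", 1:20),
    chrom = sample(c("chr1", "chr2"), 20, replace = TRUE),
    start = sample(1:4500, 20)
  )
  rand_iv$end <- rand_iv$start + sample(50:500, 20)
  got <- assign_sites_to_genes(rand_sites, rand_iv)
  oracle_n <- 0L
  for (i in seq_len(nrow(rand_sites))) {
    for (j in seq_len(nrow(rand_iv))) {
      if (rand_sites$chrom[i] == rand_iv$chrom[j] &&
          rand_sites$pos[i] >= rand_iv$start[j] &&
          rand_sites$pos[i] <= rand_iv$end[j]) {
        oracle_n <- oracle_n + 1L
      }
    }
  }
  expect_equal(nrow(got), oracle_n)

  summ <- gene_snp_summary(rand_sites, rand_iv)
  expect_equal(nrow(summ), 20)
  expect_true(all(summ$bisnp_count <= summ$snp_count))
})

hand_model <- function(strand = "+", segs = tibble::tibble(start = 1L, end = 9L)) {
  tibble::tibble(gene_id = "TOY", chrom = "chrT", strand = strand,
                 cds = list(segs))
}

hand_genome <- function(seq) {
  Biostrings::DNAStringSet(stats::setNames(seq, "chrT"))
}

snp <- function(pos, ref, alt) {
  tibble::tibble(chrom = "chrT", pos = as.integer(pos), ref = ref, alt = alt,
                 qual = 30)
}

test_that("coding effects match hand translation on a toy gene", {
  genome <- hand_genome("ATGGCTTAA")  # M-A-stop
  # codon 2 GCT(Ala); pos 5 C>G makes GGT(Gly): missense, rendered 2(A/G)
  eff <- annotate_coding_effect(snp(5, "C", "G"), hand_model(), genome)
  expect_equal(eff$effect, "NONSYNONYMOUS")
  expect_equal(eff$protein_pos, 2L)
  expect_equal(eff$ref_aa, "A")
  expect_equal(eff$alt_aa, "G")
  expect_equal(eff$protein_change, "2(A/G)")
  # pos 6 T>C keeps Ala: synonymous
  eff2 <- annotate_coding_effect(snp(6, "T", "C"), hand_model(), genome)
  expect_equal(eff2$effect, "SYNONYMOUS")
  # stop gained and lost
  eff3 <- annotate_coding_effect(snp(6, "T", "A"), hand_model(), genome)  # GCA: missense? GCT->GCA = Ala: synonymous
  expect_equal(eff3$effect, "SYNONYMOUS")
  eff4 <- annotate_coding_effect(snp(4, "G", "T"), hand_model(), genome)  # GCT->TCT = Ser
  expect_equal(eff4$effect, "NONSYNONYMOUS")
  eff5 <- annotate_coding_effect(snp(7, "T", "C"), hand_model(), genome)  # TAA->CAA = Gln
  expect_equal(eff5$effect, "STOP_LOST")
  genome2 <- hand_genome("ATGTGGTAA")  # M-W-stop
  eff6 <- annotate_coding_effect(snp(6, "G", "A"), hand_model(), genome2)  # TGG->TGA
  expect_equal(eff6$effect, "STOP_GAINED")
})

test_that("minus-strand annotation equals the reverse-complemented construct", {
  genome_fwd <- "ATGGCTTAA"
  genome_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome_fwd)))
  fwd <- annotate_coding_effect(snp(5, "C", "G"), hand_model("+"), hand_genome(genome_fwd))
  # mirrored site: position 9 - 5 + 1 = 5, alleles complemented
  rev <- annotate_coding_effect(snp(5, "G", "C"), hand_model("-"), hand_genome(genome_rev))
  expect_equal(rev$effect, fwd$effect)
  expect_equal(rev$protein_pos, fwd$protein_pos)
  expect_equal(rev$ref_aa, fwd$ref_aa)
  expect_equal(rev$alt_aa, fwd$alt_aa)
  expect_equal(rev$protein_change, fwd$protein_change)
})

test_that("annotation rejects bad inputs and flags non-coding sites", {
  genome <- hand_genome("ATGGCTTAACCC")
  expect_error(annotate_coding_effect(snp(5, "T", "G"), hand_model(), genome),
               "mismatch")
  bad_model <- hand_model(segs = tibble::tibble(start = 1L, end = 8L))
  expect_error(annotate_coding_effect(snp(5, "C", "G"), bad_model, genome),
               "divisible")
  out <- annotate_coding_effect(snp(11, "C", "A"), hand_model(), genome)
  expect_equal(out$effect, "NONCODING")
  expect_error(annotate_coding_effect(snp(5, "C", "G,T"), hand_model(), genome),
               "biallelic")
})

test_that("split-CDS and minus-strand models round-trip through the simulator", {
  co <- simulate_cohort(small_cohort_config(71))
  ann <- annotate_variants(co$gm, co$models, co$genome)
  expect_equal(nrow(ann), nrow(co$truth))
  ord_a <- order(ann$pos)
  ord_t <- order(co$truth$pos)
  expect_equal(ann$effect[ord_a], co$truth$effect[ord_t])
  expect_equal(ann$protein_pos[ord_a], co$truth$protein_pos[ord_t])
  expect_equal(ann$gene_id[ord_a], co$truth$gene_id[ord_t])
  # at least one multi-segment and one minus-strand model exercised
  expect_true(any(vapply(co$models$cds, nrow, 1L) > 1))
  expect_true(any(co$models$strand == "-"))
})
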