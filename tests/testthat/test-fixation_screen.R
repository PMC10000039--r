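test_that("group summaries tally calls, missingness and fixation", {
  t4 <- load_fixture("table4")
  gmap <- load_fixture("group_map")
  fgf2 <- which(t4$sites$gene == "FGF2")
  h <- summarize_group(t4, fgf2, gmap, "HIGH")
  expect_equal(h$n_called, 5L)
  expect_equal(h$n_missing, 3L)
  expect_true(is.na(h$fixed_allele))  # Sahiwal 3 is G/A

  gm <- make_gm(matrix("C/C", 1, 5), sprintf("H%d", 1:5), ref = "C", alt = "T")
  groups <- tibble::tibble(sample_id = c(sprintf("H%d", 1:5), "L1", "L2"),
                           group = c(rep("HIGH", 5), "LOW", "LOW"))
  expect_equal(summarize_group(gm, 1, groups, "HIGH")$fixed_allele, "C")

  # a uniformly heterozygous group is not fixed
  het <- make_gm(matrix("C/T", 1, 5), sprintf("H%d", 1:5), ref = "C", alt = "T")
  expect_true(is.na(summarize_group(het, 1, groups, "HIGH")$fixed_allele))

  # below min_called, no fixation is declared
  thin <- make_gm(matrix(c("C/C", NA, NA, NA, NA), 1, 5),
                  sprintf("H%d", 1:5), ref = "C", alt = "T")
  expect_true(is.na(summarize_group(thin, 1, groups, "HIGH")$fixed_allele))
})

test_that("group summaries equal a brute-force tally on random slices", {
  set.seed(53)
  gmap <- two_group_map(8, 6)
  for (i in 1:20) {
    calls <- sample(c("C/C", "C/T", "T/T", NA), 14, replace = TRUE)
    gm <- make_gm(matrix(calls, 1, 14), gmap$sample_id, ref = "C", alt = "T")
    for (grp in c("HIGH", "LOW")) {
      s <- summarize_group(gm, 1, gmap, grp)
      members <- gmap$sample_id[gmap$group == grp]
      slice <- calls[match(members, gmap$sample_id)]
      expect_equal(s$n_called, sum(!is.na(slice)))
      expect_equal(s$n_missing, sum(is.na(slice)))
      expect_equal(sort(s$genotypes[[1]]), sort(slice[!is.na(slice)]))
      is_fixed <- sum(!is.na(slice)) >= 2 &&
        length(unique(stats::na.omit(slice))) == 1 &&
        stats::na.omit(slice)[1] %in% c("C/C", "T/T")
      expect_equal(!is.na(s$fixed_allele), is_fixed)
    }
  }
})

test_that("the classification rule reproduces the reference calls", {
  t3 <- load_fixture("table3")
  gmap <- load_fixture("group_map")
  ghr <- which(t3$sites$pos == 31685773)
  call <- classify_site(t3, ghr, gmap)
  expect_equal(call$category, "FIXED_HIGH_VARIABLE_LOW")

  # the anomalous column: one low-yield animal homozygous for the other
  # allele breaks fixation in both groups
  t4 <- load_fixture("table4")
  zbtb <- which(t4$sites$pos == 59718206)
  expect_equal(classify_site(t4, zbtb, gmap)$category, "VARIABLE_BOTH")

  allsame <- make_gm(matrix("G/G", 1, 14), gmap$sample_id, ref = "G", alt = "A")
  expect_equal(classify_site(allsame, 1, gmap)$category, "FIXED_BOTH_CONCORDANT")

  multi <- make_gm(matrix("G/G", 1, 14), gmap$sample_id, ref = "G", alt = "A,T")
  expect_error(classify_site(multi, 1, gmap), "biallelic")
})

test_that("insufficient data and discordant fixation are recognised", {
  gmap <- two_group_map(4, 3)
  gm <- make_gm(matrix(c(rep("A/A", 4), "G/G", NA, NA), 1, 7),
                gmap$sample_id, ref = "A", alt = "G")
  expect_equal(classify_site(gm, 1, gmap)$category, "INSUFFICIENT_DATA")
  gm2 <- make_gm(matrix(c(rep("A/A", 4), rep("G/G", 3)), 1, 7),
                 gmap$sample_id, ref = "A", alt = "G")
  expect_equal(classify_site(gm2, 1, gmap)$category, "FIXED_BOTH_DISCORDANT")
})

test_that("alleles outside the declared pair still count as variable", {
  gmap <- load_fixture("group_map")
  t3 <- load_fixture("table3")
  lpin <- which(t3$sites$pos == 85211528)  # Pulikulam C/T with ALT = G
  expect_true("C/T" %in% unlist(strsplit(
    classify_site(t3, lpin, gmap)$low_genotypes, ",")))
  expect_equal(classify_site(t3, lpin, gmap)$category, "FIXED_HIGH_VARIABLE_LOW")
})

test_that("screening the reference matrices reproduces both pattern tables", {
  gmap <- load_fixture("group_map")
  r3 <- screen_fixation(load_fixture("table3"), gmap)
  expect_equal(nrow(r3$calls), 14)
  expect_true(all(r3$calls$category == "FIXED_HIGH_VARIABLE_LOW"))
  expect_setequal(unique(r3$calls$gene),
                  c("GHR", "TLR4", "LPIN1", "CACNA1C", "ZBTB16", "ITGA1",
                    "ANK1", "NT5E"))
  # every high-yield summary is complete and fixed on this table
  expect_true(all(r3$calls$n_missing_high == 0))

  r4 <- screen_fixation(load_fixture("table4"), gmap)
  expect_equal(sum(r4$calls$category == "FIXED_LOW_VARIABLE_HIGH"), 9)
  expect_equal(sum(r4$calls$category == "VARIABLE_BOTH"), 1)
  # exactly one column (FGF2) carries high-group missingness
  expect_equal(unique(r4$calls$gene[r4$calls$n_missing_high > 0]), "FGF2")
  expect_s3_class(autoplot(r4), "ggplot")
  expect_equal(tidy(r4), r4$calls)
  expect_equal(glance(r4)$fixed_low_variable_high, 9L)
})

test_that("swapping group labels mirrors the directional categories", {
  gmap <- load_fixture("group_map")
  swapped <- dplyr::mutate(gmap, group = ifelse(group == "HIGH", "LOW", "HIGH"))
  for (fixture in c("table3", "table4")) {
    gm <- load_fixture(fixture)
    orig <- screen_fixation(gm, gmap)$calls$category
    flip <- screen_fixation(gm, swapped)$calls$category
    map <- c(FIXED_HIGH_VARIABLE_LOW = "FIXED_LOW_VARIABLE_HIGH",
             FIXED_LOW_VARIABLE_HIGH = "FIXED_HIGH_VARIABLE_LOW",
             FIXED_BOTH_CONCORDANT = "FIXED_BOTH_CONCORDANT",
             FIXED_BOTH_DISCORDANT = "FIXED_BOTH_DISCORDANT",
             VARIABLE_BOTH = "VARIABLE_BOTH",
             INSUFFICIENT_DATA = "INSUFFICIENT_DATA")
    expect_equal(flip, unname(map[orig]))
  }
})

test_that("pattern calls are invariant to sample order", {
  set.seed(59)
  gmap <- load_fixture("group_map")
  gm <- load_fixture("table3")
  perm <- sample(length(gm$samples))
  gm_p <- gm
  gm_p$samples <- gm$samples[perm]
  gm_p$geno <- gm$geno[, perm, drop = FALSE]
  r1 <- screen_fixation(gm, gmap)$calls
  r2 <- screen_fixation(gm_p, gmap)$calls
  expect_equal(r1$category, r2$category)
})

test_that("masking a homozygous call only ever degrades to insufficient data", {
  # (masking a group's only het carrier can genuinely change the pattern, so
  # the invariant is over calls that carry no variability evidence)
  set.seed(61)
  co <- simulate_cohort(small_cohort_config(61))
  base <- screen_fixation(co$gm, co$groups)$calls$category
  hom <- function(g) !is.na(g) & vapply(strsplit(g, "/"), function(x)
    x[1] == x[2], logical(1))
  for (i in 1:30) {
    gm <- co$gm
    site <- sample(nrow(gm$sites), 1)
    cand <- which(hom(gm$geno[site, ]))
    if (length(cand) == 0) next
    gm$geno[site, cand[sample.int(length(cand), 1)]] <- NA_character_
    got <- screen_fixation(gm, co$groups)$calls$category[site]
    expect_true(got == base[site] || got == "INSUFFICIENT_DATA")
  }
})
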