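test_that("basic quality rules use strict inequalities at the thresholds", {
  meta <- tiny_meta("S1", median_depth = 30000, depth_sd = 1000)
  # exactly at every threshold: passes (rules are strict "greater than")
  v <- variant_row(mean_mismatches = 4.0, n_fraction = 0.05, depth = 30000L,
                   alt_count = 2L)
  expect_identical(basicQualityFilter(v, meta)$status, "pass")
  v2 <- variant_row(mean_mismatches = 4.01)
  expect_identical(basicQualityFilter(v2, meta)$failed_rules, "mismatches")
  v3 <- variant_row(n_fraction = 0.051)
  expect_identical(basicQualityFilter(v3, meta)$failed_rules, "n_fraction")
  # coverage: median - 3.5 sd fails, median - 2.9 sd passes
  v4 <- variant_row(depth = 30000L - 3500L, alt_count = 1L)
  expect_identical(basicQualityFilter(v4, meta)$failed_rules, "coverage")
  v5 <- variant_row(depth = 30000L - 2900L, alt_count = 1L)
  expect_identical(basicQualityFilter(v5, meta)$status, "pass")
})

test_that("indel rules: MSI > 5 fails, indel-specific N fraction applies", {
  meta <- tiny_meta("S1")
  ind <- variant_row(var_type = "INDEL", ref = "CT", alt = "C", msi_len = 6L)
  expect_identical(basicQualityFilter(ind, meta)$failed_rules, "msi")
  ind5 <- variant_row(var_type = "INDEL", ref = "CT", alt = "C", msi_len = 5L)
  expect_identical(basicQualityFilter(ind5, meta)$status, "pass")
  # indels tolerate N fraction up to 0.10 and ignore the mismatch rule
  ind2 <- variant_row(var_type = "INDEL", ref = "CT", alt = "C", msi_len = 1L,
                      n_fraction = 0.08, mean_mismatches = 6)
  expect_identical(basicQualityFilter(ind2, meta)$status, "pass")
  ind3 <- variant_row(var_type = "INDEL", ref = "CT", alt = "C", msi_len = 1L,
                      n_fraction = 0.11)
  expect_identical(basicQualityFilter(ind3, meta)$failed_rules, "n_fraction")
  # missing QC fields are named
  bad <- variant_row(); bad$n_fraction <- NA_real_
  expect_error(basicQualityFilter(bad, meta), "n_fraction")
})

test_that("KS read-position filter matches a brute-force oracle", {
  # 30 supporting reads all at offset 5, read length 130
  v <- variant_row(alt_count = 30L,
                   read_positions = paste(rep(5L, 30), collapse = ","))
  res <- ksReadPositionFilter(v)
  expect_true(res$tested)
  expect_lt(res$p, 1e-6)
  expect_identical(res$status, "fail")
  # brute-force statistic: sup |ECDF - F| under uniform on [0.5, 130.5]
  F <- function(x) (x - 0.5) / 130
  D_manual <- max(abs(1 - F(5)), abs(0 - F(5)))
  kt <- suppressWarnings(stats::ks.test(rep(5, 30), "punif", 0.5, 130.5))
  expect_equal(unname(kt$statistic), D_manual, tolerance = 1e-12)
  # asymptotic Kolmogorov tail as an independent bound
  p_kolm <- 2 * sum((-1)^(1:100 - 1) * exp(-2 * (1:100)^2 * 30 * D_manual^2))
  expect_lt(p_kolm, 1e-6)
})

test_that("KS filter type-I error stays below 7% on uniform positions", {
  set.seed(101)
  rows <- lapply(1:1000, function(i) {
    variant_row(pos = i, alt_count = 30L,
                read_positions = paste(sample.int(130, 30, replace = TRUE),
                                       collapse = ","))
  })
  v <- do.call(rbind, rows)
  res <- ksReadPositionFilter(v)
  expect_true(all(res$tested))
  expect_lte(mean(res$status == "fail"), 0.07)
})

test_that("variants with fewer than five pooled positions are untested", {
  v <- variant_row(alt_count = 2L, read_positions = "5,5")
  res <- ksReadPositionFilter(v)
  expect_false(res$tested)
  expect_identical(res$status, "pass")
  expect_identical(res$note, "untested")
  # pooling across occurrences pushes a recurrent variant over the minimum
  v2 <- rbind(variant_row(sample_id = "S1", alt_count = 3L,
                          read_positions = "5,5,5"),
              variant_row(sample_id = "S2", alt_count = 3L,
                          read_positions = "5,5,5"))
  res2 <- ksReadPositionFilter(v2)
  expect_true(res2$tested)
})

test_that("SNP identification follows the all-sample VAF rules", {
  mk <- function(vafs, pos = 10L) {
    do.call(rbind, lapply(seq_along(vafs), function(i) {
      variant_row(sample_id = paste0("S", i), pos = pos,
                  alt_count = as.integer(round(vafs[i] * 10000)),
                  depth = 10000L)
    }))
  }
  hom <- identifySnps(mk(c(0.97, 0.98, 0.96)), n_samples = 3)
  expect_identical(hom$classification, "hom_snp")
  het <- identifySnps(mk(c(0.40, 0.42, 0.38)), n_samples = 3)
  expect_identical(het$classification, "het_snp")
  som <- identifySnps(mk(0.0003), n_samples = 3)  # one sample only
  expect_identical(som$classification, "somatic")
  # boundary: VAF 0.85 inclusive for het, 0.95 strict for hom
  expect_identical(identifySnps(mk(c(0.85, 0.85)), n_samples = 2)$classification,
                   "het_snp")
  expect_identical(identifySnps(mk(c(0.95, 0.95)), n_samples = 2)$classification,
                   "somatic")
})

test_that("cohort contamination filter tests only variants seen > 20 times", {
  mk_cohort <- function(n_occ, alt = 30L, pos = 10L) {
    do.call(rbind, lapply(seq_len(n_occ), function(i) {
      variant_row(sample_id = paste0("S", i), pos = pos, alt_count = alt,
                  depth = 30000L)
    }))
  }
  background <- do.call(rbind, lapply(1:50, function(i) {
    variant_row(sample_id = paste0("B", i), pos = 1000L + i, alt_count = 1L)
  }))
  v20 <- rbind(mk_cohort(20), background)
  res20 <- cohortContaminationFilter(v20)
  row20 <- res20[res20$occurrences == 20, ]
  expect_false(row20$tested)
  expect_identical(row20$status, "pass")
  v25 <- rbind(mk_cohort(25), background)
  res25 <- cohortContaminationFilter(v25)
  row25 <- res25[res25$occurrences == 25, ]
  expect_true(row25$tested)
  expect_identical(row25$status, "fail")
  expect_error(cohortContaminationFilter(emptyVariantTable()), "empty")
})

test_that("contamination binomial tail equals an exact summation oracle", {
  set.seed(7)
  occ <- lapply(1:25, function(i) {
    variant_row(sample_id = paste0("S", i), pos = 10L,
                alt_count = sample(2:6, 1), depth = 30000L)
  })
  background <- do.call(rbind, lapply(1:50, function(i) {
    variant_row(sample_id = paste0("B", i), pos = 1000L + i, alt_count = 1L)
  }))
  v <- rbind(do.call(rbind, occ), background)
  res <- cohortContaminationFilter(v)
  tested <- res[res$tested, ]
  # oracle: direct upper-tail summation term by term in log space (the tail
  # decays fast; 600 terms are far beyond double precision)
  rate <- mean(v$vaf)
  alt_tot <- sum(vapply(occ, function(x) x$alt_count, integer(1)))
  dep_tot <- sum(vapply(occ, function(x) x$depth, integer(1)))
  k <- alt_tot:(alt_tot + 600)
  upper <- sum(exp(lchoose(dep_tot, k) + k * log(rate) +
                     (dep_tot - k) * log(1 - rate)))
  expect_lt(abs(tested$p - upper), 1e-12)
})

test_that("bona fide hotspots are exempt from the contamination filter", {
  occ <- do.call(rbind, lapply(1:40, function(i) {
    variant_row(sample_id = paste0("S", i), pos = 10L, ref = "CA", alt = "C",
                var_type = "INDEL", msi_len = 1L, alt_count = 40L,
                depth = 30000L)
  }))
  background <- do.call(rbind, lapply(1:50, function(i) {
    variant_row(sample_id = paste0("B", i), pos = 1000L + i, alt_count = 1L)
  }))
  hotspots <- data.frame(chrom = "chr1", pos = 10L, ref = "CA", alt = "C",
                         gene = "PPM1D", protein_change = NA)
  res <- cohortContaminationFilter(rbind(occ, background), hotspots)
  row <- res[res$occurrences == 40, ]
  expect_true(row$tested)
  expect_lt(row$p, 1e-10)
  expect_true(row$hotspot_exempt)
  expect_identical(row$status, "pass")
})

test_that("blood-like classification follows the sharing rules strictly", {
  meta <- rbind(tiny_meta("BL", is_blood = TRUE),
                tiny_meta(paste0("N", 1:10)))
  meta$patient_id <- "P1"
  mk <- function(samples, pos = 10L) {
    do.call(rbind, lapply(samples, function(s) {
      variant_row(sample_id = s, pos = pos)
    }))
  }
  # in blood and 3/10 non-blood: 30% > 25% -> blood_like
  r1 <- classifyBloodLike(mk(c("BL", "N1", "N2", "N3")), meta)
  expect_identical(r1$classification, "blood_like")
  # in blood and exactly 25%: strict inequality -> somatic
  r1b <- classifyBloodLike(mk(c("BL", "N1", "N2")), meta)
  expect_lte(r1b$n_nonblood_with / 10, 0.25)
  expect_identical(r1b$classification, "somatic")
  # not in blood, 6/10 non-blood -> suspicious
  r2 <- classifyBloodLike(mk(paste0("N", 1:6)), meta)
  expect_identical(r2$classification, "suspicious")
  expect_false(r2$usable_for_selection)
  # EGFR hotspot in blood and 4/10 -> suspicious, not blood_like
  hot <- data.frame(chrom = "chr1", pos = 10L, ref = "C", alt = "T",
                    gene = "EGFR", protein_change = NA)
  r3 <- classifyBloodLike(mk(c("BL", paste0("N", 1:4))), meta, hot)
  expect_identical(r3$classification, "suspicious")
  # patient without blood: > 50% of samples -> blood_like
  meta_nb <- tiny_meta(paste0("N", 1:10)); meta_nb$patient_id <- "P2"
  r4 <- classifyBloodLike(mk(paste0("N", 1:6)), meta_nb)
  expect_identical(r4$classification, "blood_like")
  expect_error(classifyBloodLike(mk("BL"), meta[0, ]), "zero samples")
})

test_that("the cascade conserves counts and is order-independent", {
  coh <- small_cohort()
  v <- coh$variants
  res <- runFilterCascade(v, coh$meta, coh$hotspots)
  expect_identical(sum(res$verdicts$status == "pass") +
                     sum(res$verdicts$status == "fail"), nrow(v))
  # shuffling the input rows leaves per-(sample, key) verdicts unchanged
  set.seed(1)
  perm <- sample.int(nrow(v))
  res2 <- runFilterCascade(v[perm, ], coh$meta, coh$hotspots)
  id1 <- paste(res$verdicts$sample_id, res$verdicts$key)
  id2 <- paste(res2$verdicts$sample_id, res2$verdicts$key)
  m <- match(id1, id2)
  expect_identical(res2$verdicts$status[m], res$verdicts$status)
  srt <- function(x) vapply(strsplit(x, ","), function(r)
    paste(sort(r), collapse = ","), character(1))
  expect_identical(srt(res2$verdicts$failed_rules[m]),
                   srt(res$verdicts$failed_rules))
})

test_that("on synthetic truth: artefacts, SNPs and blood sharing are handled", {
  coh <- small_cohort()
  res <- runFilterCascade(coh$variants, coh$meta, coh$hotspots)
  v <- coh$variants
  tm <- coh$truth$mutations
  id_v <- paste(v$sample_id, paste(v$chrom, v$pos, v$ref, v$alt, sep = "_"))
  origin <- tm$origin[match(id_v, paste(tm$sample_id, tm$key))]
  verd <- res$verdicts
  art <- origin == "artefact"
  expect_gte(mean(grepl("ks_position", verd$failed_rules[art])), 0.95)
  snp <- origin %in% c("het_snp", "hom_snp")
  expect_identical(sum(verd$classification[snp] == "somatic"), 0L)
  shared <- origin == "blood_shared"
  expect_gte(mean(verd$classification[shared] == "blood_like"), 0.9)
  qcf <- origin == "qc_fail"
  expect_gte(mean(verd$status[qcf] == "fail"), 0.95)
  # blacklist holds every non-KS-only failure site
  non_ks <- verd$key[verd$status == "fail" &
                       !grepl("^ks_position$", verd$failed_rules)]
  expect_true(all(non_ks %in% res$blacklist_keys))
})
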