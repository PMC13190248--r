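test_that("exact two-sided binomial p matches full tail-summation oracles", {
  # symmetric case: p = 1 exactly
  expect_equal(binomTwoSided(5000, 10000, 0.5), 1, tolerance = 1e-15)
  # 5500/10000: oracle sums every outcome probability <= the observed one
  oracle2sided <- function(x, n, p) {
    d <- stats::dbinom(0:n, n, p)
    sum(d[d <= d[x + 1] * (1 + 1e-7)])
  }
  expect_equal(binomTwoSided(5500, 10000, 0.5),
               oracle2sided(5500, 10000, 0.5), tolerance = 1e-12)
  # asymmetric null probabilities and a spread of cases
  set.seed(31)
  for (i in 1:50) {
    n <- sample(c(10, 100, 2000), 1)
    p <- runif(1, 0.05, 0.95)
    x <- rbinom(1, n, runif(1, 0.05, 0.95))
    expect_equal(binomTwoSided(x, n, p), oracle2sided(x, n, p),
                 tolerance = 1e-12, info = paste(x, n, p))
    expect_equal(binomTwoSided(x, n, p), stats::binom.test(x, n, p)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("allelic imbalance assessment flags shifted samples only", {
  set.seed(9)
  n_snp <- 120
  depth <- rep(30000L, n_snp)
  mk_prof <- function(baf_true) {
    alt <- rbinom(n_snp, depth, baf_true)
    data.frame(sample_id = "S", key = paste0("k", 1:n_snp), alt_count = alt,
               depth = depth, baf = alt / depth, ref_baf = 0.5)
  }
  clean <- assessAllelicImbalance(mk_prof(rep(0.5, n_snp)))
  expect_false(clean$flagged)
  shifted <- assessAllelicImbalance(
    mk_prof(c(rep(0.6, 36), rep(0.5, n_snp - 36))))
  expect_true(shifted$flagged)
  expect_gt(shifted$frac_dev_half, 0.15)
  # zero-depth SNPs are skipped with a warning
  prof <- mk_prof(rep(0.5, n_snp)); prof$depth[1] <- 0L
  expect_warning(assessAllelicImbalance(prof), "zero-depth")
})

test_that("shared-imbalance rank test matches exhaustive enumeration", {
  # spec worked example: high {0.55, 0.56, 0.54} vs low {0.45, 0.44, 0.46}
  tum <- data.frame(key = paste0("k", 1:6),
                    alt_count = c(16500, 16800, 16200, 13500, 13200, 13800),
                    depth = 30000L)
  tum$baf <- tum$alt_count / tum$depth
  nor <- data.frame(key = paste0("k", 1:6),
                    baf = c(0.55, 0.56, 0.54, 0.45, 0.44, 0.46))
  res <- sharedImbalanceTest(tum, nor)
  expect_true(res$applicable)
  expect_equal(res$p_value, 1 / 20, tolerance = 1e-12)
  # exhaustive enumeration oracle over all n <= 8 splits
  enum_p <- function(high, low) {
    pool <- c(high, low); nh <- length(high)
    obs <- sum(vapply(high, function(h) sum(h > low) + 0.5 * sum(h == low),
                      numeric(1)))
    combos <- utils::combn(length(pool), nh, simplify = FALSE)
    stats_all <- vapply(combos, function(ix) {
      hh <- pool[ix]; ll <- pool[-ix]
      sum(vapply(hh, function(h) sum(h > ll) + 0.5 * sum(h == ll),
                 numeric(1)))
    }, numeric(1))
    mean(stats_all >= obs - 1e-12)
  }
  set.seed(12)
  for (i in 1:12) {
    nh <- sample(2:4, 1); nl <- sample(2:4, 1)
    high <- round(runif(nh, 0.4, 0.6), 3)
    low <- round(runif(nl, 0.4, 0.6), 3)
    if (anyDuplicated(c(high, low))) next
    wt <- stats::wilcox.test(high, low, alternative = "greater", exact = TRUE)
    expect_equal(wt$p.value, enum_p(high, low), tolerance = 1e-12,
                 info = paste(i))
  }
  # no imbalanced SNPs: not applicable, distinct from a pass
  tum0 <- data.frame(key = "k1", alt_count = 15000, depth = 30000, baf = 0.5)
  expect_false(sharedImbalanceTest(tum0, nor)$applicable)
})

test_that("no shift between groups yields p >= 0.5", {
  tum <- data.frame(key = paste0("k", 1:6),
                    alt_count = c(rep(16500, 3), rep(13500, 3)),
                    depth = 30000L)
  tum$baf <- tum$alt_count / tum$depth
  nor <- data.frame(key = paste0("k", 1:6), baf = rep(0.5, 6))
  res <- sharedImbalanceTest(tum, nor)
  expect_gte(res$p_value, 0.5)
})

test_that("contamination never loosens with a larger fraction", {
  # the contamination transform is deterministic given the base cohort, so
  # the rank-test p must be non-increasing along a fraction grid
  set.seed(21)
  n_snp <- 150
  depth <- rep(30000L, n_snp)
  tum_baf <- c(rep(0.7, 50), rep(0.3, 50), rep(0.5, 50))
  tum_alt <- rbinom(n_snp, depth, tum_baf)
  tum <- data.frame(key = paste0("k", 1:n_snp), alt_count = tum_alt,
                    depth = depth, baf = tum_alt / depth)
  base_alt <- rbinom(n_snp, depth, 0.5)
  prof <- data.frame(key = paste0("k", 1:n_snp), true_baf = tum_baf)
  p_at <- function(f) {
    v <- variant_row(sample_id = "N", pos = 1L)[rep(1, n_snp), ]
    v$pos <- 1:n_snp
    v$alt_count <- base_alt; v$depth <- depth; v$vaf <- base_alt / depth
    keys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
    prof2 <- prof; prof2$key <- keys
    out <- injectContamination(v, "N", prof2, f)
    nor <- data.frame(key = keys, baf = out$vaf)
    tum2 <- tum; tum2$key <- keys
    sharedImbalanceTest(tum2, nor)$p_value
  }
  ps <- vapply(c(0.02, 0.05, 0.1, 0.2), p_at, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_lt(ps[4], 0.05)
})

test_that("BAF cosine clustering separates duplicates from noise", {
  set.seed(5)
  n_loci <- 40
  keys <- paste0("k", 1:n_loci)
  mk <- function(id, baf) data.frame(sample_id = id, key = keys,
                                     alt_count = round(baf * 30000),
                                     depth = 30000, baf = baf)
  shared <- 0.5 + c(rep(0.15, 15), rep(-0.15, 15), rep(0, 10)) +
    rnorm(n_loci, 0, 0.003)
  prof <- rbind(mk("TUM", shared), mk("DUP", shared),
                mk("N1", 0.5 + rnorm(n_loci, 0, 0.003)),
                mk("N2", 0.5 + rnorm(n_loci, 0, 0.003)))
  res <- bafCosineClustering(prof, tumour_samples = "TUM")
  expect_true(res$applicable)
  expect_gt(res$similarity["TUM", "DUP"], 0.99)
  expect_lt(abs(res$similarity["N1", "N2"]), 0.5)
  expect_identical(res$excluded, "DUP")
  # too few shared loci -> explicit "insufficient loci" result
  res2 <- bafCosineClustering(prof[prof$key %in% keys[1:10], ],
                              tumour_samples = "TUM")
  expect_false(res2$applicable)
  expect_identical(res2$reason, "insufficient loci")
})

test_that("sample QC recovers injected contamination end-to-end", {
  cfg <- cohortConfig(
    seed = 77L, patients = defaultPatients(3),
    tissues = c("blood", "lung", "liver"),
    panelSpec = list(n_genes = 8, gene_length = 900,
                     n_neutral = 6, neutral_length = 900),
    snpSpec = list(n_het = 120, n_hom = 10),
    artefactSpec = list(n_artefacts = 0, skew = 1, occurrence_prob = 0,
                        mean_alt = 2),
    bloodSharing = list(rate = 0, carrier_fraction = 0),
    contaminationSpec = list(patient_id = "P02", tissue = "liver",
                             fraction = 0.2, n_imbalanced = 80, delta = 0.2))
  coh <- generateCohort(cfg)
  qc <- runSampleQC(coh$variants, coh$meta)
  expect_true(coh$truth$contaminated_sample %in% qc$excluded)
  # untouched samples from other patients remain
  clean <- coh$meta$sample_id[coh$meta$patient_id == "P01"]
  expect_false(any(clean %in% qc$excluded))
})
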