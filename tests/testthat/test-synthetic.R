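test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- cohortConfig(seed = 11L, patients = defaultPatients(3),
                      panelSpec = list(n_genes = 6, gene_length = 900,
                                       n_neutral = 5, neutral_length = 900),
                      snpSpec = list(n_het = 20, n_hom = 5))
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$mutations, b$truth$mutations)
  # a different seed changes the data
  cfg2 <- cohortConfig(seed = 12L, patients = defaultPatients(3),
                       panelSpec = list(n_genes = 6, gene_length = 900,
                                        n_neutral = 5, neutral_length = 900),
                       snpSpec = list(n_het = 20, n_hom = 5))
  expect_false(identical(generateCohort(cfg2)$variants, a$variants))
})

test_that("per-signature generated counts conserve the total", {
  coh <- small_cohort()
  tm <- coh$truth$mutations
  som <- tm[tm$origin %in% c("somatic", "selection_extra") &
              !tm$signature %in% c("indel_background", "dbs_background"), ]
  expect_identical(sum(table(som$signature)), nrow(som))
  # every somatic truth row corresponds to a variant row
  v <- coh$variants
  keys <- paste(v$sample_id, paste(v$chrom, v$pos, v$ref, v$alt, sep = "_"))
  expect_true(all(paste(som$sample_id, som$key) %in% keys))
})

test_that("generated channel frequencies converge to the configured mixture", {
  # one extreme-burden sample gives a large channel sample for a goodness-of-
  # fit check against the catalogue-implied mixture
  procs <- list(list(name = "ageing_clock", covariate = "age",
                     slopes = c(lung = 45000),
                     signatures = c(SBS5 = 0.6, SBS4 = 0.4)))
  cfg <- cohortConfig(seed = 5L,
                      patients = defaultPatients(1),
                      tissues = "lung", processes = procs,
                      panelSpec = list(n_genes = 8, gene_length = 900,
                                       n_neutral = 8, neutral_length = 1200),
                      snpSpec = list(n_het = 0, n_hom = 0),
                      artefactSpec = list(n_artefacts = 0, skew = 1,
                                          occurrence_prob = 0, mean_alt = 2),
                      bloodSharing = list(rate = 0, carrier_fraction = 0),
                      indelFraction = 0, dbsFraction = 0, qcFailRate = 0)
  coh <- generateCohort(cfg)
  v <- channelizeVariants(coh$variants, coh$panel)
  counts <- countChannels(v, "SBS96")
  expect_gt(sum(counts), 10000)
  S <- signatureProfiles(bundledCatalog())
  expected <- as.numeric(S %*% c(SBS5 = 0.6, SBS4 = 0.4)[colnames(S)] *
                           sum(counts))
  expected[is.na(expected)] <- 0
  mix <- c(SBS5 = 0.6, SBS4 = 0.4)
  expected <- as.numeric(S[, names(mix)] %*% mix) * sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  expect_lt(stat, stats::qchisq(0.999, df = 95))
})

test_that("burden estimates recover the configured ageing slope", {
  # all processes off except the clock; per-sample burden should sit within
  # three standard errors of age x slope
  procs <- list(list(name = "ageing_clock", covariate = "age",
                     slopes = c(lung = 43), signatures = c(SBS5 = 1)))
  patients <- defaultPatients(12)
  patients$age <- 60
  cfg <- cohortConfig(seed = 8L, patients = patients, tissues = "lung",
                      processes = procs,
                      snpSpec = list(n_het = 0, n_hom = 0),
                      artefactSpec = list(n_artefacts = 0, skew = 1,
                                          occurrence_prob = 0, mean_alt = 2),
                      bloodSharing = list(rate = 0, carrier_fraction = 0),
                      indelFraction = 0, dbsFraction = 0, qcFailRate = 0)
  coh <- generateCohort(cfg)
  betas <- vapply(coh$meta$sample_id, function(s) {
    estimateBurden(coh$variants[coh$variants$sample_id == s, ],
                   coh$panel)$beta_genome
  }, numeric(1))
  truth <- 60 * 43
  se <- stats::sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - truth), 3 * se)
})

test_that("artefact injection honours identity and validation contracts", {
  coh <- small_cohort()
  spec0 <- list(n_artefacts = 0, skew = 1, occurrence_prob = 0.5, mean_alt = 2)
  out <- injectArtefacts(coh$variants, coh$meta, coh$panel, spec0)
  expect_identical(out$variants, coh$variants)
  expect_null(out$truth)
  spec_bad <- list(n_artefacts = 5, skew = 1.2, occurrence_prob = 0.5,
                   mean_alt = 2)
  expect_error(injectArtefacts(coh$variants, coh$meta, coh$panel, spec_bad),
               "skew")
})

test_that("contamination injection honours identity, error and shift contracts", {
  coh <- small_cohort()
  prof <- data.frame(key = paste("chr1", 1:3, "A", "C", sep = "_"),
                     true_baf = c(0.7, 0.3, 0.6))
  expect_identical(injectContamination(coh$variants, "S", prof, 0),
                   coh$variants)
  expect_error(injectContamination(coh$variants, "S", prof, 1), "fraction")
  expect_error(injectContamination(coh$variants, "S", prof, -0.1), "fraction")
  # a real shift moves the BAF toward the tumour value deterministically
  v <- coh$variants
  s1 <- coh$meta$sample_id[1]
  keys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
  het <- which(v$sample_id == s1 & abs(v$vaf - 0.5) < 0.1)[1]
  prof2 <- data.frame(key = keys[het], true_baf = 0.9)
  out <- injectContamination(v, s1, prof2, 0.2)
  expect_gt(out$vaf[het], v$vaf[het])
  expect_equal(out$vaf[het], round(v$depth[het] *
                                     (0.8 * v$vaf[het] + 0.2 * 0.9)) /
                 v$depth[het], tolerance = 1e-12)
})

test_that("cohort configuration validity catches bad parameters", {
  expect_error(cohortConfig(processes = list(
    list(name = "x", covariate = "age", slopes = c(lung = -1),
         signatures = c(SBS5 = 1)))), "slopes")
  expect_error(cohortConfig(processes = list(
    list(name = "x", covariate = "age", slopes = c(lung = 1),
         signatures = c(SBS5 = 0.5)))), "sum to 1")
  expect_error(cohortConfig(vafRange = c(0, 1e-3)), "vafRange")
  expect_error(cohortConfig(contaminationSpec = list(
    patient_id = "P01", tissue = "lung", fraction = 1.2,
    n_imbalanced = 10, delta = 0.2)), "fraction")
})

test_that("a shared panelSeed reuses one panel across cohort seeds", {
  cfg1 <- cohortConfig(seed = 1L, patients = defaultPatients(2),
                       panelSpec = list(n_genes = 4, gene_length = 900,
                                        n_neutral = 3, neutral_length = 900),
                       snpSpec = list(n_het = 10, n_hom = 2), panelSeed = 99L)
  cfg2 <- cohortConfig(seed = 2L, patients = defaultPatients(2),
                       panelSpec = list(n_genes = 4, gene_length = 900,
                                        n_neutral = 3, neutral_length = 900),
                       snpSpec = list(n_het = 10, n_hom = 2), panelSeed = 99L)
  cache <- panelCache(cfg1)
  a <- generateCohort(cfg1, cache = cache)
  b <- generateCohort(cfg2, cache = cache)
  expect_identical(as.character(panelGenome(a$panel)[[1]]),
                   as.character(panelGenome(b$panel)[[1]]))
  expect_false(identical(a$variants, b$variants))
  # cache is equivalent to building from the config alone
  a2 <- generateCohort(cfg1)
  expect_identical(a$variants, a2$variants)
})

test_that("writeCohort emits every interchange format readably", {
  coh <- small_cohort()
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  expect_true(all(file.exists(file.path(d, c(
    "variants.tsv", "panel.bed", "reference.fasta", "coverage.tsv",
    "meta.tsv", "hotspots.tsv", "blacklist.bed", "truth.tsv")))))
  vs <- readVariantTable(file.path(d, "variants.tsv"))
  expect_identical(nrow(variantCalls(vs)), nrow(coh$variants))
  panel <- readPanelBed(file.path(d, "panel.bed"),
                        file.path(d, "reference.fasta"))
  expect_equal(effectiveLengthMb(panel), effectiveLengthMb(coh$panel))
})
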