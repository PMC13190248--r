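# Build a variant row for a specific site-substitution of a toy-panel gene.
.gene_variant <- function(panel, gene, row, sample_id = "S1") {
  gm <- geneModels(panel)[[gene]]
  galt <- if (gm$strand == "-") duplexsoma:::.comp[[row$alt]] else row$alt
  genome_str <- as.character(panelGenome(panel)[[gm$chrom]])
  gref <- substr(genome_str, row$gpos, row$gpos)
  variant_row(sample_id = sample_id, pos = row$gpos, ref = gref, alt = galt,
              gene = gene, impact = row$impact)
}

test_that("impact classification agrees with an independent translation oracle", {
  panel <- toy_panel()
  tabs <- impactTables(panel)
  for (g in c("G1", "G2")) {
    gm <- geneModels(panel)[[g]]
    tab <- tabs[[g]]
    expect_identical(nrow(tab), 27L * 3L)
    # oracle: mutate the CDS string, translate both with Biostrings, and
    # compare the amino acid at the mutated codon
    aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(gm$cds),
                                                 no.init.codon = TRUE))
    for (i in seq_len(nrow(tab))) {
      mut <- gm$cds
      substr(mut, tab$site[i], tab$site[i]) <- tab$alt[i]
      aa_mut <- as.character(Biostrings::translate(
        Biostrings::DNAString(mut), no.init.codon = TRUE))
      cd <- (tab$site[i] - 1) %/% 3 + 1
      a0 <- substr(aa_ref, cd, cd); a1 <- substr(aa_mut, cd, cd)
      expected <- if (a0 == a1) "synonymous"
        else if (a1 == "*" && a0 != "*") "nonsense"
        else "missense"
      expect_identical(tab$impact[i], expected,
                       info = paste(g, tab$site[i], tab$alt[i]))
    }
  }
})

test_that("opportunities conserve counts and respect coverage weighting", {
  panel <- toy_panel()
  cov <- uniform_coverage(panel, "S1", depth = 30000)
  opp <- buildOpportunityMatrix(panel, cov, provenance = "sample")
  # uniform coverage equal to the normalising depth: weights are 1
  expect_equal(opp@opportunities, opp@raw, tolerance = 1e-12)
  # conservation: 3 substitutions per coding site
  total_sites <- 2 * 27
  expect_equal(sum(opp@raw), 3 * total_sites, tolerance = 1e-12)
  # doubling coverage changes nothing (relative normalization)
  cov2 <- uniform_coverage(panel, "S1", depth = 60000)
  opp2 <- buildOpportunityMatrix(panel, cov2, provenance = "sample")
  expect_equal(opp2@opportunities, opp@opportunities, tolerance = 1e-12)
})

test_that("a fully blacklisted gene has zero opportunities", {
  panel <- toy_panel()
  gm <- geneModels(panel)$G1
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gm$start, gm$end))
  cov <- uniform_coverage(panel, "S1", blacklist = bl)
  opp <- buildOpportunityMatrix(panel, cov)
  expect_identical(sum(opp@opportunities["G1", , ]), 0)
  expect_gt(sum(opp@opportunities["G2", , ]), 0)
})

test_that("a saturated neutral fixture yields w = 1 with p = 1", {
  # one variant for every possible site-substitution: observed == opportunity
  panel <- toy_panel()
  tabs <- impactTables(panel)
  rows <- list()
  for (g in c("G1", "G2")) {
    tab <- tabs[[g]]
    for (i in seq_len(nrow(tab))) {
      rows[[length(rows) + 1]] <- .gene_variant(panel, g, tab[i, ],
                                                sample_id = "S1")
    }
  }
  v <- do.call(rbind, rows)
  cov <- uniform_coverage(panel, "S1")
  opp <- buildOpportunityMatrix(panel, cov)
  fit <- fitDnds(v, opp, panel)
  expect_equal(fit$global$w, 1, tolerance = 1e-5)
  expect_equal(fit$results$w_missense, rep(1, 2), tolerance = 1e-5)
  expect_equal(fit$results$w_nonsense[fit$results$exp_nonsense > 0],
               rep(1, sum(fit$results$exp_nonsense > 0)), tolerance = 1e-5)
  expect_gte(min(fit$results$p_missense), 0.5 - 1e-6)
})

test_that("zero observed counts give profile-likelihood upper bounds", {
  panel <- toy_panel()
  tabs <- impactTables(panel)
  # keep only synonymous saturation; no nonsynonymous observations
  rows <- list()
  for (g in c("G1", "G2")) {
    tab <- tabs[[g]]
    syn <- tab[tab$impact == "synonymous", ]
    for (i in seq_len(nrow(syn))) {
      rows[[length(rows) + 1]] <- .gene_variant(panel, g, syn[i, ],
                                                sample_id = "S1")
    }
  }
  v <- do.call(rbind, rows)
  cov <- uniform_coverage(panel, "S1")
  opp <- buildOpportunityMatrix(panel, cov)
  fit <- fitDnds(v, opp, panel)
  res <- fit$results[fit$results$gene == "G1", ]
  expect_identical(res$obs_missense, 0)
  expect_identical(res$w_missense, 0)
  expect_identical(res$ci_low_missense, 0)
  # grid-scan oracle for the upper bound: 2*(0 - (-wE)) = chi2_95
  E <- res$exp_missense
  grid <- seq(1e-6, 10, by = 1e-6)
  lrt <- 2 * grid * E
  oracle_up <- grid[which.min(abs(lrt - stats::qchisq(0.95, 1)))]
  expect_equal(res$ci_high_missense, oracle_up, tolerance = 1e-4)
  expect_equal(res$ci_high_missense, stats::qchisq(0.95, 1) / (2 * E),
               tolerance = 1e-6)
})

test_that("the reporting filter implements both suppression rules", {
  # missense: expected 3, observed 2, total observed 3 -> suppressed
  r1 <- reportingFilter(exp_missense = 3, obs_missense = 2, total_observed = 3,
                        exp_nonsense = 5, obs_nonsense = 5,
                        exp_synonymous = 5, obs_syn_nonsense = 5)
  expect_false(r1$keep_missense)
  # expected 5, observed 0, total observed 2 -> retained
  r2 <- reportingFilter(exp_missense = 5, obs_missense = 0, total_observed = 2,
                        exp_nonsense = 5, obs_nonsense = 5,
                        exp_synonymous = 5, obs_syn_nonsense = 5)
  expect_true(r2$keep_missense)
  # total observed 1 -> suppressed regardless
  r3 <- reportingFilter(exp_missense = 10, obs_missense = 1, total_observed = 1,
                        exp_nonsense = 5, obs_nonsense = 5,
                        exp_synonymous = 5, obs_syn_nonsense = 5)
  expect_false(r3$keep_missense)
  # nonsense rules
  r4 <- reportingFilter(exp_missense = 5, obs_missense = 5, total_observed = 10,
                        exp_nonsense = 1, obs_nonsense = 1,
                        exp_synonymous = 5, obs_syn_nonsense = 5)
  expect_false(r4$keep_nonsense)
  r5 <- reportingFilter(exp_missense = 5, obs_missense = 5, total_observed = 10,
                        exp_nonsense = 1, obs_nonsense = 3,
                        exp_synonymous = 1.5, obs_syn_nonsense = 1)
  expect_false(r5$keep_nonsense)  # combined syn+non expectation < 3, < 2 seen
})

test_that("driver calling honours the q-value and score thresholds", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    q_global = c(0.09, 0.5, 0.2, NA),
                    q_sub = c(0.5, 0.04, 0.2, 0.5),
                    q_indel = c(0.5, 0.5, 0.04, 0.5))
  expect_setequal(callDrivers(res), c("A", "B", "C"))
  res$q_global[4] <- 0.5
  expect_setequal(callDrivers(res), c("A", "B", "C"))
  # mutation labelling: strict > 0.56 on the pathogenicity score
  v <- rbind(variant_row(gene = "A", impact = "missense", driver_score = 0.56),
             variant_row(gene = "A", impact = "missense", driver_score = 0.561),
             variant_row(gene = "A", impact = "nonsense"),
             variant_row(gene = "A", var_type = "INDEL", ref = "CT", alt = "C",
                         msi_len = 1L),
             variant_row(gene = "Z", impact = "missense", driver_score = 0.99))
  flags <- labelDriverMutations(v, "A")
  expect_identical(flags, c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("hotspot spectra flag injected codon enrichment only", {
  panel <- toy_panel()
  tabs <- impactTables(panel)
  tab <- tabs$G1
  cov <- uniform_coverage(panel, "S1")
  opp <- buildOpportunityMatrix(panel, cov)
  # neutral-ish background: a variant at every synonymous + every 4th
  # nonsynonymous site
  rows <- list()
  for (g in c("G1", "G2")) {
    tg <- tabs[[g]]
    pick <- c(which(tg$impact == "synonymous"),
              which(tg$impact != "synonymous")[c(TRUE, FALSE, FALSE, FALSE)])
    for (i in pick) {
      rows[[length(rows) + 1]] <- .gene_variant(panel, g, tg[i, ])
    }
  }
  v <- do.call(rbind, rows)
  fit <- fitDnds(v, opp, panel)
  spec <- hotspotSpectrum("G1", v, opp, fit$rates, panel)
  expect_identical(nrow(spec), 9L)
  expect_true(all(is.na(spec$ratio[spec$expected == 0])))
  # inject a 10x pile-up at one codon with nonsynonymous opportunity
  codon <- spec$codon[which(spec$expected > 0)[1]]
  site_rows <- tab[(tab$site - 1) %/% 3 + 1 == codon &
                     tab$impact != "synonymous", ]
  extra <- do.call(rbind, lapply(1:12, function(i) {
    .gene_variant(panel, "G1", site_rows[1, ], sample_id = paste0("E", i))
  }))
  spec2 <- hotspotSpectrum("G1", rbind(v, extra), opp, fit$rates, panel)
  hot <- spec2[spec2$codon == codon, ]
  expect_lt(hot$p_enrich, 0.05 / nrow(spec2))
  expect_error(hotspotSpectrum("NOPE", v, opp, fit$rates, panel), "absent")
})

test_that("selection recovery on generator truth calls the selected gene", {
  coh <- small_cohort()
  filt <- runFilterCascade(coh$variants, coh$meta, coh$hotspots)
  usable_keys <- filt$verdicts$key[filt$verdicts$classification != "somatic"]
  v <- filt$passed
  keys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
  usable <- v[!(keys %in% usable_keys) & !is.na(v$gene), ]
  opp <- buildOpportunityMatrix(coh$panel, coh$coverage,
                                sample_ids = coh$meta$sample_id)
  fit <- fitDnds(usable, opp, coh$panel)
  drivers <- callDrivers(fit$results)
  expect_true("TP53" %in% drivers)
  tp53 <- fit$results[fit$results$gene == "TP53", ]
  expect_gt(tp53$w_missense, 1.5)
  expect_lt(tp53$q_sub, 0.01)
})
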