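## B-allele-frequency sample QC: detection of somatic copy-number change /
## clonal expansion from heterozygous-SNP allelic imbalance, a one-sided rank
## test for shared imbalance (tumour contamination), and cosine clustering of
## BAF vectors against sequenced tumour samples.

#' Exact two-sided binomial p-value
#'
#' Same definition as \code{stats::binom.test} (sum of all outcome
#' probabilities not exceeding the observed one, with the same 1e-7 relative
#' tolerance), computed with tail sums and a binary search over the opposite
#' tail instead of a full scan of the support, so it stays fast at duplex
#' depths. Vectorised over \code{x}, \code{n}, \code{p}.
#'
#' @param x Observed successes.
#' @param n Trials.
#' @param p Null success probability.
#' @return Two-sided exact p-values.
#' @export
binomTwoSided <- function(x, n, p) {
  mapply(function(x, n, p) {
    if (p <= 0) return(as.numeric(x == 0))
    if (p >= 1) return(as.numeric(x == n))
    d0 <- stats::dbinom(x, n, p) * (1 + 1e-7)
    mode <- floor((n + 1) * p)
    if (x < mode) {
      lower <- stats::pbinom(x, n, p)
      # smallest y in [mode, n] with dbinom(y) <= d0 (dbinom decreasing there)
      lo <- mode; hi <- n
      if (stats::dbinom(n, n, p) > d0) return(min(1, lower))
      while (lo < hi) {
        mid <- (lo + hi) %/% 2
        if (stats::dbinom(mid, n, p) <= d0) hi <- mid else lo <- mid + 1
      }
      upper <- stats::pbinom(lo - 1, n, p, lower.tail = FALSE)
      min(1, lower + upper)
    } else if (x > mode) {
      upper <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
      # largest y in [0, mode] with dbinom(y) <= d0 (dbinom increasing there)
      if (stats::dbinom(0, n, p) > d0) return(min(1, upper))
      lo <- 0; hi <- mode
      while (lo < hi) {
        mid <- (lo + hi + 1) %/% 2
        if (stats::dbinom(mid, n, p) <= d0) lo <- mid else hi <- mid - 1
      }
      lower <- stats::pbinom(lo, n, p)
      min(1, lower + upper)
    } else {
      1
    }
  }, x, n, p)
}

#' Sample QC configuration
#'
#' @param alpha Per-SNP significance level for the exact binomial deviation
#'   test (0.05).
#' @param deviation_multiplier A sample is flagged when its fraction of
#'   deviating SNPs exceeds \code{deviation_multiplier * alpha}, i.e. three
#'   times the fraction expected under the null at alpha = 0.05.
#' @param min_shared_loci Minimum shared het-SNP loci for BAF clustering (20).
#' @param cosine_threshold Similarity above which samples "cluster together"
#'   in the average-linkage tree (0.5).
#' @param rank_alpha Significance level of the shared-imbalance rank test.
#' @return Named list.
#' @export
qcConfig <- function(alpha = 0.05, deviation_multiplier = 3,
                     min_shared_loci = 20, cosine_threshold = 0.5,
                     rank_alpha = 0.05) {
  as.list(environment())
}

#' Extract per-patient heterozygous-SNP BAF profiles
#'
#' Uses \link{identifySnps} to locate heterozygous SNP loci and returns, per
#' patient, a table of per-sample BAFs at shared loci together with the
#' per-locus median across the patient's samples (the alignment-bias-robust
#' reference).
#'
#' @param variants Cohort variant table (pre-filter, so SNPs are present).
#' @param meta Sample metadata.
#' @param config \link{filterConfig} (SNP thresholds).
#' @return Named list per patient: data.frame(sample_id, key, alt_count,
#'   depth, baf, ref_baf).
#' @export
bafProfiles <- function(variants, meta, config = filterConfig()) {
  v <- asVariantTable(variants)
  patients <- stats::setNames(meta$patient_id, meta$sample_id)
  v_patient <- patients[v$sample_id]
  out <- list()
  for (p in unique(meta$patient_id)) {
    sel <- which(v_patient == p)
    if (!length(sel)) next
    pv <- v[sel, , drop = FALSE]
    n_samp <- sum(meta$patient_id == p)
    snps <- identifySnps(pv, n_samples = n_samp, config = config)
    het_keys <- snps$key[snps$classification == "het_snp"]
    if (!length(het_keys)) next
    keys <- .variant_key(pv)
    keep <- keys %in% het_keys
    df <- data.frame(sample_id = pv$sample_id[keep], key = keys[keep],
                     alt_count = pv$alt_count[keep], depth = pv$depth[keep],
                     baf = pv$vaf[keep], stringsAsFactors = FALSE)
    med <- tapply(df$baf, df$key, stats::median)
    df$ref_baf <- as.numeric(med[df$key])
    out[[p]] <- df
  }
  out
}

#' Assess allelic imbalance of one sample's het SNPs
#'
#' Exact two-sided binomial tests of each SNP's alt count against 0.5 and
#' against the per-locus median BAF across the patient's samples. The sample
#' is flagged when the fraction of SNPs deviating (at \code{alpha}) from
#' either reference exceeds \code{deviation_multiplier * alpha}.
#'
#' @param profile One sample's rows from \link{bafProfiles} (columns
#'   alt_count, depth, baf, ref_baf). Zero-depth SNPs are skipped with a
#'   warning.
#' @param config \link{qcConfig}.
#' @return list(p_vs_half, p_vs_median, frac_dev_half, frac_dev_median,
#'   flagged, n_snps).
#' @export
assessAllelicImbalance <- function(profile, config = qcConfig()) {
  if (any(profile$depth == 0)) {
    warning("skipping ", sum(profile$depth == 0), " zero-depth SNP(s)")
    profile <- profile[profile$depth > 0, , drop = FALSE]
  }
  if (!nrow(profile)) stop("no het SNPs with positive depth")
  p_half <- binomTwoSided(profile$alt_count, profile$depth, 0.5)
  p_med <- binomTwoSided(profile$alt_count, profile$depth,
                         pmin(pmax(profile$ref_baf, 1e-12), 1 - 1e-12))
  frac_half <- mean(p_half < config$alpha)
  frac_med <- mean(p_med < config$alpha)
  threshold <- config$deviation_multiplier * config$alpha
  list(p_vs_half = p_half, p_vs_median = p_med,
       frac_dev_half = frac_half, frac_dev_median = frac_med,
       flagged = frac_half > threshold || frac_med > threshold,
       n_snps = nrow(profile))
}

#' One-sided rank test for shared allelic imbalance
#'
#' Loci at which the tumour (or clonally expanded) sample shows significant
#' allelic imbalance (exact binomial p < 0.05 against 0.5) are split into
#' "high" and "low" groups by whether the tumour BAF lies above its median. A
#' contaminated normal inherits the direction of the imbalance, so its BAFs in
#' the high group should exceed those in the low group: a one-sided
#' Mann-Whitney test (exact for small groups) evaluates this.
#'
#' @param tumour One sample's profile rows (alt_count, depth, baf, key).
#' @param normal The normal sample's rows at (a superset of) the same loci.
#' @param config \link{qcConfig}.
#' @return list(applicable, p_value, n_high, n_low); \code{applicable} FALSE
#'   (with NA p) when the tumour shows no imbalanced SNPs or a group is empty.
#' @export
sharedImbalanceTest <- function(tumour, normal, config = qcConfig()) {
  p_imb <- binomTwoSided(tumour$alt_count, tumour$depth, 0.5)
  imb <- p_imb < config$rank_alpha
  if (!any(imb)) {
    return(list(applicable = FALSE, p_value = NA_real_,
                n_high = 0L, n_low = 0L))
  }
  med <- stats::median(tumour$baf)
  high_keys <- tumour$key[imb & tumour$baf > med]
  low_keys <- tumour$key[imb & tumour$baf <= med]
  nh <- normal$baf[match(high_keys, normal$key)]
  nl <- normal$baf[match(low_keys, normal$key)]
  nh <- nh[!is.na(nh)]; nl <- nl[!is.na(nl)]
  if (!length(nh) || !length(nl)) {
    return(list(applicable = FALSE, p_value = NA_real_,
                n_high = length(nh), n_low = length(nl)))
  }
  wt <- suppressWarnings(stats::wilcox.test(nh, nl, alternative = "greater",
                                            exact = (length(nh) < 50 &&
                                                     length(nl) < 50)))
  list(applicable = TRUE, p_value = wt$p.value,
       n_high = length(nh), n_low = length(nl))
}

#' Cosine clustering of BAF vectors within a patient
#'
#' BAF vectors over shared het-SNP loci are mean-centred (removing the common
#' 0.5 baseline) and compared by cosine similarity; average-linkage
#' hierarchical clustering cut at the similarity threshold groups samples.
#' Samples sharing a cluster with a sequenced tumour sample are excluded.
#'
#' @param profile A patient's \link{bafProfiles} table.
#' @param tumour_samples Character vector of tumour sample ids.
#' @param config \link{qcConfig}.
#' @return list(applicable, clusters, similarity, excluded); applicable FALSE
#'   with reason "insufficient loci" when fewer than \code{min_shared_loci}
#'   loci are shared by all samples.
#' @export
bafCosineClustering <- function(profile, tumour_samples = character(0),
                                config = qcConfig()) {
  samples <- unique(profile$sample_id)
  if (length(samples) < 2) {
    return(list(applicable = FALSE, reason = "need >= 2 samples",
                clusters = NULL, similarity = NULL, excluded = character(0)))
  }
  keys <- Reduce(intersect, lapply(samples, function(s) {
    profile$key[profile$sample_id == s]
  }))
  if (length(keys) < config$min_shared_loci) {
    return(list(applicable = FALSE, reason = "insufficient loci",
                clusters = NULL, similarity = NULL, excluded = character(0)))
  }
  M <- sapply(samples, function(s) {
    rows <- profile[profile$sample_id == s, ]
    rows$baf[match(keys, rows$key)]
  })
  M <- t(M)                       # samples x loci
  M <- M - rowMeans(M)            # centre out the 0.5 baseline
  norms <- sqrt(rowSums(M^2))
  norms[norms == 0] <- 1
  sim <- (M %*% t(M)) / outer(norms, norms)
  rownames(sim) <- colnames(sim) <- samples
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "average")
  clusters <- stats::cutree(hc, h = 1 - config$cosine_threshold)
  tum_clusters <- unique(clusters[names(clusters) %in% tumour_samples])
  excluded <- setdiff(names(clusters)[clusters %in% tum_clusters],
                      tumour_samples)
  list(applicable = TRUE, clusters = clusters, similarity = sim,
       excluded = excluded)
}

#' Run sample-level QC over a cohort
#'
#' Builds per-patient het-SNP BAF profiles, assesses per-sample allelic
#' imbalance, tests every normal sample against the patient's tumour samples
#' (or imbalance-flagged samples) with the shared-imbalance rank test, and
#' clusters BAF vectors against tumours. Any flagged sample is excluded.
#'
#' @param variants Cohort variant table (pre-filter; SNPs required).
#' @param meta Sample metadata.
#' @param filter_config \link{filterConfig}.
#' @param config \link{qcConfig}.
#' @return list(report = per-sample data.frame with verdicts and reasons,
#'   excluded = character vector of excluded sample ids).
#' @export
runSampleQC <- function(variants, meta, filter_config = filterConfig(),
                        config = qcConfig()) {
  profiles <- bafProfiles(variants, meta, filter_config)
  report <- data.frame(sample_id = meta$sample_id,
                       patient_id = meta$patient_id,
                       is_tumour = meta$is_tumour,
                       imbalance_flagged = FALSE,
                       contamination_p = NA_real_,
                       clustered_with_tumour = FALSE,
                       excluded = FALSE, reason = "",
                       stringsAsFactors = FALSE)
  for (p in names(profiles)) {
    prof <- profiles[[p]]
    pmeta <- meta[meta$patient_id == p, , drop = FALSE]
    tumour_samples <- pmeta$sample_id[pmeta$is_tumour]
    for (s in unique(prof$sample_id)) {
      rows <- prof[prof$sample_id == s, , drop = FALSE]
      res <- assessAllelicImbalance(rows, config)
      i <- match(s, report$sample_id)
      if (s %in% tumour_samples) next   # tumours are not "excluded"; they anchor
      if (res$flagged) {
        report$imbalance_flagged[i] <- TRUE
        report$excluded[i] <- TRUE
        report$reason[i] <- paste0(report$reason[i], "allelic_imbalance;")
      }
    }
    if (length(tumour_samples)) {
      for (tum in tumour_samples) {
        tum_rows <- prof[prof$sample_id == tum, , drop = FALSE]
        for (s in setdiff(unique(prof$sample_id), tumour_samples)) {
          rows <- prof[prof$sample_id == s, , drop = FALSE]
          res <- sharedImbalanceTest(tum_rows, rows, config)
          i <- match(s, report$sample_id)
          if (res$applicable) {
            report$contamination_p[i] <-
              min(report$contamination_p[i], res$p_value, na.rm = TRUE)
            if (res$p_value < config$rank_alpha) {
              report$excluded[i] <- TRUE
              report$reason[i] <- paste0(report$reason[i], "shared_imbalance;")
            }
          }
        }
      }
      cl <- bafCosineClustering(prof, tumour_samples, config)
      if (cl$applicable && length(cl$excluded)) {
        i <- match(cl$excluded, report$sample_id)
        report$excluded[i] <- TRUE
        report$clustered_with_tumour[i] <- TRUE
        report$reason[i] <- paste0(report$reason[i], "baf_clustering;")
      }
    }
  }
  report$reason <- sub(";$", "", report$reason)
  list(report = report, excluded = report$sample_id[report$excluded])
}
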