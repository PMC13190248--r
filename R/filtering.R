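## Post-consensus variant exclusion cascade: per-variant quality rules, the
## Kolmogorov-Smirnov read-position artefact filter, germline SNP
## identification, the cohort-level binomial contamination filter and
## blood-like classification. Rules are evaluated independently, so the set of
## failed rules per variant does not depend on evaluation order.

#' Filter configuration with study defaults
#'
#' All thresholds of the exclusion cascade, with the defaults used in the
#' analyses this package implements. Strict inequalities throughout ("greater
#' than" thresholds pass at equality).
#'
#' @param max_mean_mismatches Max mean mismatches in supporting reads (4).
#' @param max_n_fraction_sbs Max no-consensus fraction for point mutations (0.05).
#' @param max_n_fraction_indel Max no-consensus fraction for indels (0.10).
#' @param coverage_sd_multiplier Coverage rule: fail when depth < sample median
#'   depth - multiplier * depth SD (3).
#' @param max_msi Max microsatellite run length for indels (5).
#' @param ks_min_positions Minimum pooled supporting-read positions for the KS
#'   test (5); variants below it are recorded untested and pass.
#' @param ks_fdr FDR threshold of the KS family (0.05).
#' @param contamination_min_occurrences Variants observed strictly more often
#'   than this cohort-wide are tested (20).
#' @param contamination_fdr FDR threshold of the contamination family (0.05).
#' @param blood_like_fraction Blood-sharing fraction above which a variant seen
#'   in blood is blood-like (0.25, strict).
#' @param suspicious_fraction Non-blood sharing fraction above which a variant
#'   absent from blood is suspicious, and (for patients without blood) the
#'   blood-like fraction (0.50, strict).
#' @param hom_snp_vaf Homozygous SNP VAF threshold (0.95, strict, all samples).
#' @param het_snp_range Heterozygous SNP VAF range (inclusive, all samples).
#' @param exempt_hotspot_genes Genes whose bona fide hotspots are labelled
#'   suspicious rather than blood-like.
#' @return Named list of thresholds.
#' @export
filterConfig <- function(max_mean_mismatches = 4,
                         max_n_fraction_sbs = 0.05,
                         max_n_fraction_indel = 0.10,
                         coverage_sd_multiplier = 3,
                         max_msi = 5,
                         ks_min_positions = 5,
                         ks_fdr = 0.05,
                         contamination_min_occurrences = 20,
                         contamination_fdr = 0.05,
                         blood_like_fraction = 0.25,
                         suspicious_fraction = 0.50,
                         hom_snp_vaf = 0.95,
                         het_snp_range = c(0.01, 0.85),
                         exempt_hotspot_genes = c("EGFR", "PIK3CA", "KRAS")) {
  as.list(environment())
}

.variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")

#' Basic per-variant quality filter
#'
#' Point mutations (SBS/DBS) fail when mean mismatches in supporting reads
#' exceed 4, the no-consensus fraction exceeds 0.05, or duplex depth falls
#' below the sample median minus three depth standard deviations. Indels fail
#' on a no-consensus fraction above 0.10, the same coverage rule, or a
#' microsatellite run longer than 5. All inequalities strict.
#'
#' @param variants Variant table.
#' @param meta Sample metadata (median_depth, depth_sd per sample).
#' @param config \link{filterConfig}.
#' @return data.frame with key, sample_id, status ("pass"/"fail") and
#'   failed_rules (comma-separated).
#' @export
basicQualityFilter <- function(variants, meta, config = filterConfig()) {
  v <- asVariantTable(variants)
  need <- c("mean_mismatches", "n_fraction", "depth", "msi_len")
  for (f in c("mean_mismatches", "n_fraction", "depth")) {
    if (any(is.na(v[[f]]))) {
      stop("missing QC field '", f, "' for ",
           sum(is.na(v[[f]])), " variant(s)")
    }
  }
  med <- stats::setNames(meta$median_depth, meta$sample_id)
  sdd <- stats::setNames(meta$depth_sd, meta$sample_id)
  if (any(!v$sample_id %in% names(med))) {
    stop("variants from samples absent in metadata")
  }
  cov_floor <- med[v$sample_id] - config$coverage_sd_multiplier * sdd[v$sample_id]
  is_indel <- v$var_type == "INDEL"
  if (any(is_indel & is.na(v$msi_len))) {
    stop("missing QC field 'msi_len' for indel variant(s)")
  }
  rules <- character(nrow(v))
  add <- function(rules, hit, name) ifelse(hit, paste0(rules, name, ","), rules)
  rules <- add(rules, !is_indel & v$mean_mismatches > config$max_mean_mismatches,
               "mismatches")
  rules <- add(rules, !is_indel & v$n_fraction > config$max_n_fraction_sbs,
               "n_fraction")
  rules <- add(rules, is_indel & v$n_fraction > config$max_n_fraction_indel,
               "n_fraction")
  rules <- add(rules, v$depth < cov_floor, "coverage")
  rules <- add(rules, is_indel & v$msi_len > config$max_msi, "msi")
  rules <- sub(",$", "", rules)
  data.frame(key = .variant_key(v), sample_id = v$sample_id,
             status = ifelse(nzchar(rules), "fail", "pass"),
             failed_rules = rules, stringsAsFactors = FALSE)
}

## One-sample KS statistic and asymptotic p against the uniform distribution
## on [0.5, read_length + 0.5] (integer positions centred in unit cells).
.ks_uniform <- function(positions, read_length) {
  suppressWarnings(
    stats::ks.test(positions, "punif", 0.5, read_length + 0.5)
  )
}

#' Kolmogorov-Smirnov read-position artefact filter
#'
#' Recurrent artefacts concentrate the mutant base at a fixed offset within
#' reads. For each distinct variant, supporting-read positions are pooled
#' across all its occurrences and tested against the uniform distribution on
#' the read span with a one-sample KS test; Benjamini-Hochberg correction is
#' applied across all tested variants and q < ks_fdr flags the variant.
#' Variants with fewer than \code{ks_min_positions} pooled positions are not
#' tested and pass with an "untested" note.
#'
#' @param variants Variant table.
#' @param config \link{filterConfig}.
#' @return data.frame per distinct variant key: n_positions, tested, p, q,
#'   status ("pass"/"fail"), note.
#' @export
ksReadPositionFilter <- function(variants, config = filterConfig()) {
  v <- asVariantTable(variants)
  keys <- .variant_key(v)
  pos_by_key <- tapply(v$read_positions, keys, function(x) {
    unlist(lapply(x, .parse_positions))
  }, simplify = FALSE)
  rl_by_key <- tapply(v$read_length, keys, function(x) max(x, na.rm = TRUE))
  out <- data.frame(key = names(pos_by_key),
                    n_positions = vapply(pos_by_key, length, 1L),
                    tested = FALSE, p = NA_real_, q = NA_real_,
                    status = "pass", note = "", stringsAsFactors = FALSE)
  test_idx <- which(out$n_positions >= config$ks_min_positions)
  for (i in test_idx) {
    kt <- .ks_uniform(pos_by_key[[out$key[i]]], rl_by_key[[out$key[i]]])
    out$p[i] <- kt$p.value
    out$tested[i] <- TRUE
  }
  out$note[!out$tested] <- "untested"
  if (length(test_idx)) {
    out$q[test_idx] <- stats::p.adjust(out$p[test_idx], method = "BH")
    out$status[test_idx] <- ifelse(out$q[test_idx] < config$ks_fdr,
                                   "fail", "pass")
  }
  out
}

#' Identify germline SNPs from a patient's samples
#'
#' A variant is a homozygous SNP when its VAF exceeds 0.95 in every one of the
#' patient's samples, and a heterozygous SNP when it is present in every
#' sample with VAF within [0.01, 0.85]. Everything else remains a somatic
#' candidate. For single-sample patients the rules degenerate to that sample.
#'
#' @param variants Variant table for one patient (all samples).
#' @param n_samples Number of samples sequenced for the patient (defaults to
#'   the number of distinct sample ids present in \code{variants}).
#' @param config \link{filterConfig}.
#' @return data.frame per distinct variant key: n_samples_with_variant,
#'   classification ("hom_snp"/"het_snp"/"somatic").
#' @export
identifySnps <- function(variants, n_samples = NULL, config = filterConfig()) {
  v <- asVariantTable(variants)
  if (is.null(n_samples)) n_samples <- length(unique(v$sample_id))
  keys <- .variant_key(v)
  vaf_by_key <- tapply(v$vaf, keys, identity, simplify = FALSE)
  n_by_key <- tapply(v$sample_id, keys, function(x) length(unique(x)))
  classification <- vapply(names(vaf_by_key), function(k) {
    vafs <- vaf_by_key[[k]]
    in_all <- n_by_key[[k]] == n_samples
    if (in_all && all(vafs > config$hom_snp_vaf)) return("hom_snp")
    if (in_all && all(vafs >= config$het_snp_range[1] &
                      vafs <= config$het_snp_range[2])) return("het_snp")
    "somatic"
  }, character(1))
  data.frame(key = names(vaf_by_key),
             n_samples_with_variant = as.integer(n_by_key),
             classification = classification, stringsAsFactors = FALSE)
}

#' Cohort-level binomial contamination filter
#'
#' For each variant observed strictly more than
#' \code{contamination_min_occurrences} times in the cohort, the total alt
#' molecule count is tested against a global binomial model: p = P(X >=
#' observed total alt | Binomial(total molecules at the site across
#' occurrences, cohort mean per-call VAF)). Benjamini-Hochberg correction is
#' applied within this family and q < contamination_fdr removes the variant
#' unless it is a bona fide driver hotspot.
#'
#' @param variants Cohort-wide somatic variant table.
#' @param hotspots Hotspot data.frame (chrom, pos, ref, alt) or NULL.
#' @param config \link{filterConfig}.
#' @return data.frame per distinct variant key: occurrences, tested, p, q,
#'   status, hotspot_exempt.
#' @export
cohortContaminationFilter <- function(variants, hotspots = NULL,
                                      config = filterConfig()) {
  v <- asVariantTable(variants)
  if (!nrow(v)) stop("empty cohort")
  keys <- .variant_key(v)
  occ <- tapply(rep(1L, nrow(v)), keys, sum)
  alt_tot <- tapply(v$alt_count, keys, sum)
  dep_tot <- tapply(v$depth, keys, sum)
  global_rate <- mean(v$vaf)
  out <- data.frame(key = names(occ), occurrences = as.integer(occ),
                    tested = FALSE, p = NA_real_, q = NA_real_,
                    status = "pass", hotspot_exempt = FALSE,
                    stringsAsFactors = FALSE)
  hot_keys <- if (!is.null(hotspots) && nrow(hotspots)) {
    paste(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt, sep = "_")
  } else character(0)
  test_idx <- which(out$occurrences > config$contamination_min_occurrences)
  for (i in test_idx) {
    k <- out$key[i]
    out$p[i] <- stats::pbinom(alt_tot[[k]] - 1L, dep_tot[[k]], global_rate,
                              lower.tail = FALSE)
    out$tested[i] <- TRUE
  }
  if (length(test_idx)) {
    out$q[test_idx] <- stats::p.adjust(out$p[test_idx], method = "BH")
    flag <- out$q[test_idx] < config$contamination_fdr
    exempt <- out$key[test_idx] %in% hot_keys
    out$hotspot_exempt[test_idx] <- exempt
    out$status[test_idx] <- ifelse(flag & !exempt, "fail", "pass")
  }
  out
}

#' Classify variants as blood-like or suspicious
#'
#' For a patient with a blood sample: a variant found in blood and in strictly
#' more than 25% of non-blood samples is blood-like (unless it is a bona fide
#' EGFR/PIK3CA/KRAS driver hotspot, in which case it is suspicious); a variant
#' absent from blood but in strictly more than 50% of non-blood samples is
#' suspicious. For patients without blood, a variant in strictly more than 50%
#' of samples is blood-like. Everything else is usable for selection analyses.
#'
#' @param variants Variant table for one patient.
#' @param meta Metadata rows for the patient's samples (is_blood flags).
#' @param hotspots Hotspot data.frame or NULL.
#' @param config \link{filterConfig}.
#' @return data.frame per distinct key: in_blood, n_nonblood_with,
#'   classification ("blood_like"/"suspicious"/"somatic"),
#'   usable_for_selection.
#' @export
classifyBloodLike <- function(variants, meta, hotspots = NULL,
                              config = filterConfig()) {
  v <- asVariantTable(variants)
  if (!nrow(meta)) stop("patient with zero samples")
  blood_samples <- meta$sample_id[meta$is_blood]
  nonblood_samples <- meta$sample_id[!meta$is_blood & !meta$is_tumour]
  keys <- .variant_key(v)
  hot_keys <- if (!is.null(hotspots) && nrow(hotspots)) {
    paste(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt, sep = "_")
  } else character(0)
  hot_genes_keys <- if (!is.null(hotspots) && nrow(hotspots)) {
    hk <- paste(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt, sep = "_")
    hk[hotspots$gene %in% config$exempt_hotspot_genes]
  } else character(0)
  uk <- unique(keys)
  in_blood <- vapply(uk, function(k) {
    any(v$sample_id[keys == k] %in% blood_samples)
  }, logical(1))
  n_nb <- vapply(uk, function(k) {
    length(unique(v$sample_id[keys == k & v$sample_id %in% nonblood_samples]))
  }, integer(1))
  has_blood <- length(blood_samples) > 0
  n_nonblood <- length(nonblood_samples)
  classification <- rep("somatic", length(uk))
  if (has_blood) {
    frac_nb <- if (n_nonblood > 0) n_nb / n_nonblood else 0
    bl <- in_blood & frac_nb > config$blood_like_fraction
    classification[bl] <- "blood_like"
    classification[bl & uk %in% hot_genes_keys] <- "suspicious"
    susp <- !in_blood & frac_nb > config$suspicious_fraction
    classification[susp] <- "suspicious"
  } else {
    frac_all <- n_nb / max(n_nonblood, 1L)
    classification[frac_all > config$suspicious_fraction] <- "blood_like"
  }
  data.frame(key = uk, in_blood = in_blood, n_nonblood_with = n_nb,
             classification = classification,
             usable_for_selection = classification == "somatic",
             stringsAsFactors = FALSE)
}

#' Run the full filter cascade
#'
#' Evaluates, independently per rule family: the basic quality rules, the KS
#' read-position filter, germline SNP identification per patient, the cohort
#' contamination filter and blood-like classification. Sites failing any
#' filter except the KS test alone are aggregated into the site blacklist used
#' downstream by the selection analyses.
#'
#' @param variants Cohort variant table.
#' @param meta Sample metadata.
#' @param hotspots Hotspot data.frame or NULL.
#' @param config \link{filterConfig}.
#' @return list with \code{verdicts} (per variant row: status, failed_rules,
#'   classification), \code{passed} (somatic calls passing everything),
#'   \code{blacklist_keys} (site keys for the selection blacklist) and the
#'   per-family tables.
#' @export
runFilterCascade <- function(variants, meta, hotspots = NULL,
                             config = filterConfig()) {
  v <- asVariantTable(variants)
  keys <- .variant_key(v)
  basic <- basicQualityFilter(v, meta, config)
  ks <- ksReadPositionFilter(v, config)
  contam <- cohortContaminationFilter(v, hotspots, config)

  patients <- stats::setNames(meta$patient_id, meta$sample_id)
  v_patient <- patients[v$sample_id]
  snp_class <- rep("somatic", nrow(v))
  blood_class <- rep("somatic", nrow(v))
  for (p in unique(v_patient)) {
    sel <- which(v_patient == p)
    pmeta <- meta[meta$patient_id == p, , drop = FALSE]
    snps <- identifySnps(v[sel, , drop = FALSE],
                         n_samples = nrow(pmeta), config = config)
    snp_class[sel] <- snps$classification[match(keys[sel], snps$key)]
    bl <- classifyBloodLike(v[sel, , drop = FALSE], pmeta, hotspots, config)
    blood_class[sel] <- bl$classification[match(keys[sel], bl$key)]
  }

  ks_fail <- ks$key[ks$status == "fail"]
  contam_fail <- contam$key[contam$status == "fail"]
  failed_rules <- basic$failed_rules
  app <- function(fr, hit, name) ifelse(hit, paste0(fr, ",", name), fr)
  failed_rules <- app(failed_rules, keys %in% ks_fail, "ks_position")
  failed_rules <- app(failed_rules, keys %in% contam_fail, "contamination")
  failed_rules <- app(failed_rules, snp_class != "somatic", "germline_snp")
  failed_rules <- sub("^,+", "", failed_rules)

  classification <- ifelse(snp_class != "somatic", snp_class, blood_class)
  status <- ifelse(nzchar(failed_rules), "fail", "pass")

  # blacklist: sites failing anything except *only* the KS test
  fr_list <- strsplit(failed_rules, ",", fixed = TRUE)
  non_ks_fail <- vapply(fr_list, function(r) {
    r <- setdiff(r, ""); length(setdiff(r, "ks_position")) > 0
  }, logical(1))
  blacklist_keys <- unique(keys[non_ks_fail])

  verdicts <- data.frame(key = keys, sample_id = v$sample_id,
                         status = status, failed_rules = failed_rules,
                         classification = classification,
                         blacklist_member = keys %in% blacklist_keys,
                         stringsAsFactors = FALSE)
  # blood-like calls are real mutations of the blood itself: they are removed
  # from non-blood samples (infiltration) and from selection analyses, but
  # retained in the blood sample's own somatic set
  blood_samples <- meta$sample_id[meta$is_blood]
  keep <- status == "pass" &
    (classification == "somatic" |
       (classification == "blood_like" & v$sample_id %in% blood_samples))
  passed <- v[keep, , drop = FALSE]
  list(verdicts = verdicts, passed = passed, blacklist_keys = blacklist_keys,
       basic = basic, ks = ks, contamination = contam)
}
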