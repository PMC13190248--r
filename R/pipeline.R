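## End-to-end orchestration: filtering -> sample QC -> signature refitting ->
## burden & dose-response -> selection, with a reproducibility manifest of
## per-stage counts and output checksums.

#' Run the full analysis pipeline
#'
#' Stages: (1) variant filter cascade; (2) BAF-based sample QC with exclusion
#' of contaminated / allelically imbalanced samples; (3) signature exposure
#' refitting and per-mutation attribution on SBS-96 counts; (4) per-sample
#' burden (per variant type) with per-signature components and standard
#' dose-response fits (clock-like vs age per tissue, smoking vs pack years,
#' platinum vs cycles); (5) coverage-adjusted dN/dS with driver calls. Every
#' exclusion is logged in the manifest; an empty variant table yields zeroed
#' summaries rather than an error.
#'
#' @param variants Cohort variant table (pre-filter).
#' @param meta Sample metadata.
#' @param panel A \linkS4class{Panel}.
#' @param coverage A \linkS4class{CoverageProfile}.
#' @param hotspots Hotspot data.frame or NULL.
#' @param catalog \linkS4class{SignatureCatalog}.
#' @param filter_config \link{filterConfig}.
#' @param qc_config \link{qcConfig}.
#' @param out_dir Directory for stage outputs (default a temporary directory);
#'   output files are checksummed into the manifest.
#' @param resume When TRUE and \code{out_dir} already holds the filter stage's
#'   outputs (filtered.tsv, verdicts.tsv), the filter cascade is restored
#'   from them instead of being recomputed.
#' @return list(filter, sample_qc, exposures, attribution, burden,
#'   dose_response, selection, manifest).
#' @export
runPipeline <- function(variants, meta, panel, coverage, hotspots = NULL,
                        catalog = bundledCatalog(),
                        filter_config = filterConfig(),
                        qc_config = qcConfig(),
                        out_dir = tempfile("duplexsoma_run"),
                        resume = FALSE) {
  v <- asVariantTable(variants)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(counts = list(variants_in = nrow(v)))
  manifest$package_version <- as.character(utils::packageVersion("duplexsoma"))
  manifest$input_checksum <- .object_md5(v)
  manifest$config_checksum <- .object_md5(list(filter_config, qc_config))

  if (!nrow(v)) {
    manifest$counts$variants_passed <- 0L
    return(list(filter = NULL, sample_qc = NULL, exposures = NULL,
                attribution = NULL, burden = empty_burden_table(),
                dose_response = list(), selection = NULL,
                manifest = manifest))
  }

  ## stage 1: filter cascade (restorable from a previous run's outputs)
  filt_files <- file.path(out_dir, c("filtered.tsv", "verdicts.tsv"))
  if (resume && all(file.exists(filt_files))) {
    passed_disk <- variantCalls(readVariantTable(filt_files[1]))
    verdicts_disk <- .read_tsv(filt_files[2])
    verdicts_disk$failed_rules[is.na(verdicts_disk$failed_rules)] <- ""
    filt <- list(verdicts = verdicts_disk, passed = passed_disk,
                 blacklist_keys = unique(
                   verdicts_disk$key[verdicts_disk$blacklist_member]),
                 ks = NULL, contamination = NULL, basic = NULL)
    manifest$resumed_from <- out_dir
  } else {
    filt <- runFilterCascade(v, meta, hotspots, filter_config)
  }
  manifest$counts$variants_passed <- nrow(filt$passed)
  manifest$counts$variants_failed <- nrow(v) - nrow(filt$passed)
  stopifnot(sum(filt$verdicts$status == "pass") +
              sum(filt$verdicts$status == "fail") == nrow(v))

  ## stage 2: sample QC on the pre-filter table (SNPs required)
  qc <- runSampleQC(v, meta, filter_config, qc_config)
  excluded <- qc$excluded
  manifest$counts$samples_excluded <- length(excluded)
  manifest$excluded_samples <- excluded
  keep_meta <- meta[!meta$sample_id %in% excluded & !meta$is_tumour, ,
                    drop = FALSE]
  passed <- filt$passed[!filt$passed$sample_id %in% excluded &
                          filt$passed$sample_id %in% keep_meta$sample_id, ,
                        drop = FALSE]

  ## stage 3: signatures
  passed <- channelizeVariants(passed, panel)
  sbs <- passed[passed$var_type == "SBS", , drop = FALSE]
  exposure_fit <- NULL
  attribution <- NULL
  if (nrow(sbs)) {
    samples <- unique(sbs$sample_id)
    counts <- t(vapply(samples, function(s) {
      countChannels(sbs[sbs$sample_id == s, , drop = FALSE], "SBS96")
    }, numeric(96)))
    rownames(counts) <- samples
    tissue_of <- stats::setNames(keep_meta$tissue, keep_meta$sample_id)
    exposure_fit <- fitExposuresRestricted(counts, catalog,
                                           groups = tissue_of[samples])
    attribution <- attributeMutations(sbs, exposure_fit, catalog)
  }

  ## stage 4: burden and dose-response
  burden <- cohortBurden(passed, panel, meta = keep_meta,
                         exposure_fit = exposure_fit)
  fits <- standardDoseResponseFits(burden, keep_meta)

  ## stage 5: selection on non-blood-like, QC-passing variants
  selection <- NULL
  sel_keys <- filt$verdicts$key[filt$verdicts$classification != "somatic"]
  usable <- passed[!(.variant_key(passed) %in% sel_keys) &
                     !is.na(passed$gene), , drop = FALSE]
  bl <- coverage@blacklist
  if (length(filt$blacklist_keys)) {
    parts <- strsplit(filt$blacklist_keys, "_", fixed = TRUE)
    bl_pos <- vapply(parts, function(x) as.integer(x[2]), integer(1))
    bl_chr <- vapply(parts, `[`, "", 1)
    bl <- c(bl, GenomicRanges::GRanges(bl_chr,
                                       IRanges::IRanges(bl_pos, bl_pos)))
  }
  cov_bl <- CoverageProfile(coverage@table, blacklist = bl)
  if (length(geneModels(panel)) && nrow(usable)) {
    opp <- buildOpportunityMatrix(panel, cov_bl,
                                  sample_ids = keep_meta$sample_id,
                                  provenance = "cohort")
    selection <- tryCatch(fitDnds(usable, opp, panel), error = function(e) {
      warning("selection stage skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(selection)) {
      selection$drivers <- callDrivers(selection$results)
      selection$driver_mutation <- labelDriverMutations(usable,
                                                        selection$drivers)
      selection$usable <- usable
    }
  }

  ## manifest: write stage outputs and checksum them
  writeVariantTable(passed[, VARIANT_COLUMNS], file.path(out_dir, "filtered.tsv"))
  .write_tsv(filt$verdicts, file.path(out_dir, "verdicts.tsv"))
  .write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  .write_tsv(burden, file.path(out_dir, "burden.tsv"))
  if (!is.null(selection)) {
    .write_tsv(selection$results, file.path(out_dir, "selection.tsv"))
  }
  files <- list.files(out_dir, full.names = TRUE)
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  manifest$out_dir <- out_dir

  list(filter = filt, sample_qc = qc, exposures = exposure_fit,
       attribution = attribution, burden = burden, dose_response = fits,
       selection = selection, manifest = manifest)
}

## md5 of a serialised R object (stable within a package version)
.object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Empty burden table
#' @return Zero-row burden data.frame.
#' @export
empty_burden_table <- function() {
  data.frame(sample_id = character(0), var_type = character(0),
             beta_per_mb = numeric(0), beta_genome = numeric(0),
             n_variants = integer(0), stringsAsFactors = FALSE)
}

#' Per-sample burden table for a cohort
#'
#' Computes beta per sample and variant type, and (for SBS) per-signature
#' genome-scale components from fitted exposures.
#'
#' @param variants Filtered variant table.
#' @param panel Panel or numeric L_Mb.
#' @param meta Metadata restricted to retained samples.
#' @param exposure_fit Optional \linkS4class{ExposureMatrix} for SBS splits.
#' @param genomeMb Haploid genome Mb.
#' @return data.frame: sample_id, var_type, beta_per_mb, beta_genome,
#'   n_variants, plus one sig_<name> column per signature (SBS rows).
#' @export
cohortBurden <- function(variants, panel, meta, exposure_fit = NULL,
                         genomeMb = 3000) {
  v <- asVariantTable(variants)
  rows <- list()
  sig_names <- if (!is.null(exposure_fit)) colnames(exposures(exposure_fit))
  for (s in meta$sample_id) {
    for (vt in c("SBS", "DBS", "INDEL")) {
      sv <- v[v$sample_id == s & v$var_type == vt, , drop = FALSE]
      b <- estimateBurden(sv, panel, genomeMb = genomeMb)
      row <- data.frame(sample_id = s, var_type = vt,
                        beta_per_mb = b$beta_per_mb,
                        beta_genome = b$beta_genome,
                        n_variants = b$n_variants, stringsAsFactors = FALSE)
      if (!is.null(sig_names)) {
        comp <- stats::setNames(rep(NA_real_, length(sig_names)),
                                paste0("sig_", sig_names))
        if (vt == "SBS" && s %in% rownames(exposures(exposure_fit))) {
          comp[] <- b$beta_genome * exposures(exposure_fit)[s, ]
        }
        row <- cbind(row, as.data.frame(as.list(comp), check.names = FALSE))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard dose-response fits over a burden table
#'
#' Fits, where at least four patients with covariate variation exist: the
#' clock-like (SBS5) genome burden against age per tissue; smoking (SBS4)
#' burden against pack years in smoking-affected tissues; platinum
#' (SBS31+SBS35) burden against platinum cycles per tissue; alcohol (SBS-B)
#' burden against drink years in liver/kidney.
#'
#' @param burden Output of \link{cohortBurden} (with signature columns).
#' @param meta Sample metadata for retained samples.
#' @return Named list of \link{robustDoseResponse} results.
#' @export
standardDoseResponseFits <- function(burden, meta) {
  b <- burden[burden$var_type == "SBS", , drop = FALSE]
  b <- merge(b, meta, by = "sample_id")
  b$platinum_cycles <- vapply(b$treatments, function(t) {
    tr <- parseTreatments(t); sum(tr$cycles[tr$class == "platinum"])
  }, numeric(1))
  specs <- list()
  for (ts in unique(b$tissue)) {
    specs[[paste0("sbs5_age_", ts)]] <-
      list(tissue = ts, col = "sig_SBS5", covariate = "age")
    specs[[paste0("platinum_cycles_", ts)]] <-
      list(tissue = ts, col = c("sig_SBS31", "sig_SBS35"),
           covariate = "platinum_cycles")
  }
  specs$sbs4_pack_years_lung <-
    list(tissue = "lung", col = "sig_SBS4", covariate = "pack_years")
  specs$alcohol_drink_years_liver <-
    list(tissue = "liver", col = "sig_SBS-B", covariate = "drink_years")
  fits <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    d <- b[b$tissue == sp$tissue, , drop = FALSE]
    if (nrow(d) < 4) next
    cols <- intersect(sp$col, names(d))
    if (!length(cols)) next
    y <- rowSums(d[, cols, drop = FALSE])
    x <- d[[sp$covariate]]
    if (any(is.na(y)) || length(unique(d$patient_id)) < 4 ||
        stats::var(x) == 0) next
    fits[[nm]] <- tryCatch(
      robustDoseResponse(y, x, d$patient_id, tissue = sp$tissue,
                         process = nm),
      error = function(e) NULL)
  }
  fits[!vapply(fits, is.null, logical(1))]
}
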