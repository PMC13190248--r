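## Synthetic cohort generator. Emulates the statistical structure of a deep
## duplex-sequencing study of normal tissue: multi-patient multi-tissue
## sampling, low-VAF somatic mutations whose burden is a sum of
## process-specific dose-response terms (ageing, smoking, alcohol, platinum,
## alkylating treatment), tissue-specific signature mixtures, germline SNPs,
## recurrent read-position artefacts, blood infiltration, genes under positive
## selection and optional tumour contamination. Every latent quantity is
## recorded in a truth table; a fixed seed fully determines the output.

#' SyntheticCohortConfig: generative parameters for a synthetic cohort
#'
#' @slot params Named list of generator parameters (see \link{cohortConfig}).
#' @export
setClass("SyntheticCohortConfig", representation(params = "list"))

setValidity("SyntheticCohortConfig", function(object) {
  p <- object@params
  for (pr in p$processes) {
    if (any(pr$slopes < 0)) return("process slopes must be >= 0")
    if (abs(sum(pr$signatures) - 1) > 1e-9) {
      return(paste("signature mixture of process", pr$name, "must sum to 1"))
    }
  }
  if (!is.null(p$artefactSpec)) {
    if (p$artefactSpec$skew < 0 || p$artefactSpec$skew > 1) {
      return("artefact skew must be in [0, 1]")
    }
  }
  if (!is.null(p$contaminationSpec)) {
    f <- p$contaminationSpec$fraction
    if (f < 0 || f >= 1) return("contamination fraction must be in [0, 1)")
  }
  if (p$vafRange[1] <= 0 || p$vafRange[2] <= p$vafRange[1]) {
    return("vafRange must be an increasing positive interval")
  }
  TRUE
})

setMethod("show", "SyntheticCohortConfig", function(object) {
  p <- object@params
  cat("SyntheticCohortConfig: seed", p$seed, "-", nrow(p$patients),
      "patients x", paste(p$tissues, collapse = "/"),
      "-", length(p$processes), "mutational processes\n")
})

#' Build a synthetic cohort configuration
#'
#' @param seed Integer seed; fully determines the generated cohort.
#' @param patients data.frame with patient_id, age, sex, pack_years,
#'   units_per_week, treatments (encoded as in \link{parseTreatments}).
#' @param tissues Tissues sampled per patient ("blood" marks the blood sample).
#' @param samplesPerTissue Replicates per tissue.
#' @param processes list of mutational processes; each a list(name, covariate,
#'   slopes = named vector of mutations per cell per covariate unit by tissue,
#'   signatures = named mixture over the catalogue). Covariates: "age",
#'   "pack_years", "drink_years", "platinum_cycles", "alkylating_days".
#' @param panelSpec list(n_genes, gene_length, n_neutral, neutral_length,
#'   gene_names optional).
#' @param depthSpec list(median, median_sd, nb_size) duplex molecule depth.
#' @param vafRange Log-uniform VAF interval for clone sizes (default
#'   c(1e-5, 1e-3); VAF is half the clone cell fraction).
#' @param minAltDetect Minimum alt molecules for a mutation to be observed;
#'   draws below it are dropped (thinning), keeping the burden estimator
#'   unbiased.
#' @param snpSpec list(n_het, n_hom) germline SNP loci per patient.
#' @param selectionSpec Named list gene -> c(w_mis, w_non) selection
#'   coefficients (1 = neutral).
#' @param artefactSpec list(n_artefacts, skew, occurrence_prob, mean_alt) or
#'   NULL; skew 1 puts every supporting read at one fixed offset.
#' @param contaminationSpec list(patient_id, tissue, fraction, n_imbalanced,
#'   delta) or NULL; adds a tumour sample with allelic imbalance and mixes its
#'   BAF profile into the chosen normal sample.
#' @param bloodSharing list(rate, carrier_fraction): fraction of blood
#'   mutations that infiltrate other tissues, and the fraction of non-blood
#'   samples carrying each infiltrating mutation.
#' @param indelFraction,dbsFraction Indel/DBS counts relative to SBS counts.
#' @param qcFailRate Fraction of variants given failing QC metadata (labelled
#'   in truth).
#' @param genomeMb Haploid genome size in Mb (3000).
#' @param readLength Consensus read length (130 after clipping).
#' @param catalog \linkS4class{SignatureCatalog} (default \link{bundledCatalog}).
#' @param panelSeed Optional separate seed for the toy panel and SNP loci;
#'   when set, cohorts with different \code{seed} values share one panel
#'   (and \link{panelCache} can precompute it once).
#' @return A \linkS4class{SyntheticCohortConfig}.
#' @export
cohortConfig <- function(seed = 1L,
                         patients = defaultPatients(6),
                         tissues = c("blood", "lung", "liver", "brain", "kidney"),
                         samplesPerTissue = 1L,
                         processes = defaultProcesses(),
                         panelSpec = list(n_genes = 30, gene_length = 1500,
                                          n_neutral = 25, neutral_length = 1500),
                         depthSpec = list(median = 30000, median_sd = 2500,
                                          nb_size = 60),
                         vafRange = c(1e-5, 1e-3),
                         minAltDetect = 1L,
                         snpSpec = list(n_het = 120, n_hom = 25),
                         selectionSpec = list(),
                         artefactSpec = list(n_artefacts = 50, skew = 1,
                                             occurrence_prob = 0.4,
                                             mean_alt = 2),
                         contaminationSpec = NULL,
                         bloodSharing = list(rate = 0.03,
                                             carrier_fraction = 0.4),
                         indelFraction = 0.08,
                         dbsFraction = 0.015,
                         qcFailRate = 0.01,
                         genomeMb = 3000,
                         readLength = 130L,
                         catalog = bundledCatalog(),
                         panelSeed = NULL) {
  new("SyntheticCohortConfig", params = as.list(environment()))
}

#' Precompute the panel objects of a configuration
#'
#' Builds the toy panel, its site index and its annotation index once, for
#' reuse across \link{generateCohort} calls that share a \code{panelSeed}.
#'
#' @param config A \linkS4class{SyntheticCohortConfig} with a non-NULL
#'   \code{panelSeed}.
#' @return list(panel, site_index, annotation) accepted by
#'   \link{generateCohort}'s \code{cache} argument.
#' @export
panelCache <- function(config) {
  p <- config@params
  if (is.null(p$panelSeed)) stop("panelCache requires a panelSeed")
  set.seed(p$panelSeed)
  panel <- .make_toy_panel(p$panelSpec)
  idx <- .panel_site_index(panel)
  ann <- .panel_annotation_index(panel)
  list(panel = panel, site_index = idx, annotation = ann)
}

#' Default synthetic patient roster
#'
#' Deterministic roster spanning the study's age range (29-78), with smokers,
#' drinkers, platinum-treated, alkylating-treated and untreated/immunotherapy
#' patients represented.
#'
#' @param n Number of patients.
#' @return data.frame suitable for \link{cohortConfig}.
#' @export
defaultPatients <- function(n = 22) {
  i <- seq_len(n)
  age <- round(seq(29, 78, length.out = n))
  pack_years <- ifelse(i %% 2 == 0, round(seq(5, 60, length.out = n)), 0)
  units_per_week <- c(0, 7, 14, 28, 42)[(i %% 5) + 1]
  cycles <- ((i * 3) %% 11)
  tmz_days <- ifelse(i %% 4 == 0, 100 + 40 * (i %% 7), 0)
  treatments <- character(n)
  for (k in i) {
    tr <- character(0)
    if (cycles[k] > 0) {
      tr <- c(tr, sprintf("cisplatin:platinum:%d:%d", cycles[k],
                          cycles[k] * 21L))
    }
    if (tmz_days[k] > 0) {
      tr <- c(tr, sprintf("temozolomide:mutagenic_alkylating:%d:%d",
                          max(1L, tmz_days[k] %/% 28L), tmz_days[k]))
    }
    if (k %% 6 == 0) tr <- c(tr, "pembrolizumab:immunotherapy_antiPD1:4:84")
    treatments[k] <- paste(tr, collapse = ";")
  }
  data.frame(patient_id = sprintf("P%02d", i), age = age,
             sex = rep(c("F", "M"), length.out = n),
             pack_years = pack_years, units_per_week = units_per_week,
             treatments = treatments, stringsAsFactors = FALSE)
}

#' Default mutational processes (study-calibrated profile)
#'
#' Slopes are mutations per genome per cell per covariate unit. Clock-like
#' rates: lung 43/yr, blood 24/yr, brain 21/yr (plus chosen values for
#' tissues whose rates the source figures do not print); smoking 20
#' mutations/pack-year in lung, ~5 in heart and liver; platinum 89
#' mutations/cycle in blood, 32 in lung; an alcohol-associated liver process;
#' a temozolomide-like process driven by treatment days.
#'
#' @return list of process specifications for \link{cohortConfig}.
#' @export
defaultProcesses <- function() {
  list(
    list(name = "ageing_clock", covariate = "age",
         slopes = c(lung = 43, blood = 24, brain = 21, liver = 50,
                    kidney = 35, spleen = 30, heart = 20, pituitary = 18),
         signatures = c(SBS5 = 1)),
    list(name = "ageing_flat", covariate = "age",
         slopes = c(lung = 6, blood = 6, brain = 6, liver = 6, kidney = 6,
                    spleen = 6, heart = 6, pituitary = 6),
         signatures = c(SBS40 = 1)),
    list(name = "blood_background", covariate = "age",
         slopes = c(blood = 12),
         signatures = c(`SBS-A` = 1)),
    list(name = "neuronal_background", covariate = "age",
         slopes = c(brain = 10, pituitary = 10),
         signatures = c(`SBS-E` = 1)),
    list(name = "smoking", covariate = "pack_years",
         slopes = c(lung = 20, heart = 5, liver = 5),
         signatures = c(SBS4 = 1)),
    list(name = "alcohol", covariate = "drink_years",
         slopes = c(liver = 25, kidney = 8),
         signatures = c(`SBS-B` = 1)),
    list(name = "platinum", covariate = "platinum_cycles",
         slopes = c(blood = 89, lung = 32, liver = 40, kidney = 50,
                    spleen = 45, heart = 30, brain = 20, pituitary = 20),
         signatures = c(SBS31 = 0.7, SBS35 = 0.3)),
    list(name = "alkylating", covariate = "alkylating_days",
         slopes = c(blood = 1.0, spleen = 1.5, pituitary = 1.5, heart = 1.2,
                    lung = 0.5, liver = 0.5, kidney = 0.5, brain = 0.8),
         signatures = c(`SBS-F` = 1))
  )
}

#' Study-calibrated synthetic cohort configuration
#'
#' The default parameter set emulating the study conditions: 22 patients aged
#' 29-78, five tissues each, ~30,000x duplex depth, an 82.5-kb panel of 30
#' toy cancer genes plus neutral regions, the calibrated process slopes of
#' \link{defaultProcesses}, positive selection on TP53 (missense) and NOTCH2
#' (nonsense), and fixed-offset read-position artefacts.
#'
#' @param seed Integer seed.
#' @param nPatients Number of patients (default 22).
#' @param ... Overrides passed to \link{cohortConfig}.
#' @return A \linkS4class{SyntheticCohortConfig}.
#' @export
paperCalibratedConfig <- function(seed = 1L, nPatients = 22, ...) {
  args <- list(seed = seed, patients = defaultPatients(nPatients),
               selectionSpec = list(TP53 = c(w_mis = 4, w_non = 4),
                                    NOTCH2 = c(w_mis = 1, w_non = 4)),
               ...)
  do.call(cohortConfig, args)
}

TOY_GENE_NAMES <- c(
  "TP53", "EGFR", "KRAS", "BRAF", "PIK3CA", "PTEN", "NOTCH2", "NFE2L2",
  "CTNNB1", "PPM1D", "CHEK2", "DNMT3A", "ARID1A", "B2M", "TET2", "ASXL1",
  "STK11", "KEAP1", "RB1", "APC", "SMAD4", "FBXW7", "GNAS", "IDH1", "IDH2",
  "SF3B1", "U2AF1", "JAK2", "NRAS", "ATM", "CDKN2A", "ERBB2", "MET", "ALK",
  "ROS1", "RET", "KIT", "PDGFRA", "VHL", "MTOR"
)

## Toy genome + panel from a panel spec. Uses the current RNG stream.
.make_toy_panel <- function(spec) {
  n_genes <- spec$n_genes
  gene_len <- spec$gene_length
  if (gene_len %% 3L != 0L) stop("gene_length must be divisible by 3")
  n_neu <- spec$n_neutral
  neu_len <- spec$neutral_length
  gene_names <- if (!is.null(spec$gene_names)) spec$gene_names else
    TOY_GENE_NAMES[seq_len(n_genes)]
  gap <- 200L
  margin <- 100L
  lens <- c(rep(gene_len, n_genes), rep(neu_len, n_neu))
  starts <- margin + cumsum(c(0L, (lens + gap)[-length(lens)])) + 1L
  ends <- starts + lens - 1L
  total <- ends[length(ends)] + margin
  genome_chars <- sample(BASES, total, replace = TRUE)
  genome_str <- paste(genome_chars, collapse = "")
  genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
  gms <- list()
  strands <- rep(c("+", "-"), length.out = n_genes)
  for (g in seq_len(n_genes)) {
    seq <- substr(genome_str, starts[g], ends[g])
    if (strands[g] == "-") seq <- .revcomp(seq)
    gms[[gene_names[g]]] <- list(gene = gene_names[g], chrom = "chr1",
                                 start = starts[g], end = ends[g],
                                 strand = strands[g], cds = seq)
  }
  Panel(gr, geneModels = gms, genome = genome)
}

## Index every panel position by its pyrimidine-collapsed trinucleotide
## context; returns positions, the 32-class context of each, and whether the
## genomic base is itself a pyrimidine.
.panel_site_index <- function(panel) {
  genome_str <- as.character(panelGenome(panel)[[1]])
  gr <- panelIntervals(panel)
  pos <- unlist(lapply(seq_along(gr), function(i) {
    GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]
  }))
  pos <- pos[pos > 1 & pos < nchar(genome_str)]
  tri <- substring(genome_str, pos - 1L, pos + 1L)
  centre <- substring(genome_str, pos, pos)
  pyr <- centre %in% c("C", "T")
  cls <- tri
  cls[!pyr] <- .revcomp(cls[!pyr])
  list(pos = pos, class32 = cls, pyr = pyr, genome = genome_str,
       by_class = split(seq_along(pos), cls))
}

## gene/impact lookup: genomic position+alt -> gene, impact, codon
.panel_annotation_index <- function(panel) {
  gms <- geneModels(panel)
  keys <- character(0); gene <- character(0); impact <- character(0)
  codon <- integer(0); chan96 <- character(0)
  for (g in names(gms)) {
    tab <- .gene_impact_table(panel, g)
    gm <- gms[[g]]
    galt <- if (gm$strand == "-") unname(.comp[tab$alt]) else tab$alt
    keys <- c(keys, paste(tab$gpos, galt))
    gene <- c(gene, rep(g, nrow(tab)))
    impact <- c(impact, tab$impact)
    codon <- c(codon, (tab$site - 1L) %/% 3L + 1L)
  }
  list(keys = keys, gene = gene, impact = impact, codon = codon,
       map = stats::setNames(seq_along(keys), keys))
}

.covariate_value <- function(cov, meta_row) {
  tr <- parseTreatments(meta_row$treatments)
  switch(cov,
         age = meta_row$age,
         pack_years = meta_row$pack_years,
         drink_years = meta_row$drink_years,
         platinum_cycles = sum(tr$cycles[tr$class == "platinum"]),
         alkylating_days = sum(tr$days[tr$class == "mutagenic_alkylating"]),
         stop("unknown covariate: ", cov))
}

## SBS96 channel name from a 192-style name (coding-strand trinuc>alt).
.chan192_to_96 <- function(chan) {
  tri <- substr(chan, 1, 3)
  alt <- substr(chan, 5, 5)
  ref <- substr(tri, 2, 2)
  channelizeSBS96(ref, alt, tri)
}

## Draw mutation rows for one sample given per-signature genome burdens.
.draw_sample_mutations <- function(sample_id, B_k, p, panel, idx, ann, S) {
  v1 <- p$vafRange[1]; v2 <- p$vafRange[2]
  e_vaf <- (v2 - v1) / log(v2 / v1)
  l_mb <- effectiveLengthMb(panel)
  B <- sum(B_k)
  if (B <= 0) return(list(rows = NULL, truth = NULL))
  n_mean <- (B / p$genomeMb) * l_mb / (2 * e_vaf)
  N <- stats::rpois(1, n_mean)
  if (N == 0) return(list(rows = NULL, truth = NULL))
  sig <- sample(names(B_k), N, replace = TRUE, prob = B_k)
  chans <- sbs96Channels()
  chan <- character(N)
  for (k in unique(sig)) {
    nk <- sum(sig == k)
    chan[sig == k] <- sample(chans, nk, replace = TRUE, prob = S[, k])
  }
  cls <- paste0(substr(chan, 1, 1), substr(chan, 3, 3), substr(chan, 7, 7))
  alt_pyr <- substr(chan, 5, 5)
  site_i <- integer(N)
  for (cl in unique(cls)) {
    cand <- idx$by_class[[cl]]
    if (is.null(cand)) stop("context class ", cl, " absent from panel")
    sel <- cls == cl
    site_i[sel] <- sample(cand, sum(sel), replace = TRUE)
  }
  gpos <- idx$pos[site_i]
  pyr <- idx$pyr[site_i]
  gref <- substring(idx$genome, gpos, gpos)
  galt <- ifelse(pyr, alt_pyr, unname(.comp[alt_pyr]))
  list(rows = data.frame(gpos = gpos, ref = gref, alt = galt,
                         channel96 = chan, stringsAsFactors = FALSE),
       truth = sig)
}

## Observation model: depth, alt count, detection thinning, QC metadata.
.observe <- function(n, p, med_depth) {
  v1 <- p$vafRange[1]; v2 <- p$vafRange[2]
  true_vaf <- exp(stats::runif(n, log(v1), log(v2)))
  depth <- stats::rnbinom(n, mu = med_depth, size = p$depthSpec$nb_size)
  depth[depth < 1] <- 1L
  alt <- stats::rbinom(n, depth, true_vaf)
  keep <- alt >= p$minAltDetect
  list(true_vaf = true_vaf, depth = depth, alt = alt, keep = keep)
}

.qc_fields <- function(n, p) {
  data.frame(n_fraction = round(stats::runif(n, 0, 0.04), 4),
             mean_mismatches = round(stats::runif(n, 0, 3), 2))
}

.read_positions_string <- function(alt, read_length) {
  if (!length(alt)) return(character(0))
  draws <- sample.int(read_length, sum(alt), replace = TRUE)
  f <- factor(rep(seq_along(alt), alt), levels = seq_along(alt))
  out <- vapply(split(draws, f), paste, character(1), collapse = ",")
  unname(out)
}

#' Generate a complete synthetic cohort
#'
#' Produces per-sample variant tables, the toy panel, a coverage profile, the
#' clinical metadata, a hotspot list, a blacklist and a truth record holding
#' every latent quantity (per-sample expected burdens, per-mutation generating
#' signature, artefact / blood-shared / SNP / QC-fail labels, contamination).
#'
#' @param config A \linkS4class{SyntheticCohortConfig}.
#' @param cache Optional \link{panelCache} result (requires a matching
#'   \code{panelSeed} in the configuration).
#' @return list(variants, panel, coverage, meta, hotspots, blacklist, truth).
#' @export
generateCohort <- function(config, cache = NULL) {
  p <- config@params
  if (!is.null(p$panelSeed)) {
    if (is.null(cache)) cache <- panelCache(config)
    panel <- cache$panel
    idx <- cache$site_index
    ann <- cache$annotation
    set.seed(p$seed)
  } else {
    set.seed(p$seed)
    panel <- .make_toy_panel(p$panelSpec)
    idx <- .panel_site_index(panel)
    ann <- .panel_annotation_index(panel)
  }
  S <- signatureProfiles(p$catalog)
  sig_names <- colnames(S)
  genome_str <- idx$genome
  rl <- p$readLength

  ## sample roster
  meta <- do.call(rbind, lapply(seq_len(nrow(p$patients)), function(i) {
    pr <- p$patients[i, ]
    do.call(rbind, lapply(p$tissues, function(ts) {
      do.call(rbind, lapply(seq_len(p$samplesPerTissue), function(r) {
        data.frame(sample_id = sprintf("%s_%s_%d", pr$patient_id, ts, r),
                   patient_id = pr$patient_id, tissue = ts,
                   is_blood = ts == "blood", is_tumour = FALSE,
                   age = pr$age, sex = pr$sex, pack_years = pr$pack_years,
                   units_per_week = pr$units_per_week,
                   drink_years = drinkYears(pr$units_per_week, age = pr$age),
                   treatments = pr$treatments,
                   median_depth = NA_real_, depth_sd = NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(meta) <- NULL
  meta$median_depth <- round(pmax(
    stats::rnorm(nrow(meta), p$depthSpec$median, p$depthSpec$median_sd), 5000))
  meta$depth_sd <- round(sqrt(meta$median_depth +
                                meta$median_depth^2 / p$depthSpec$nb_size))

  ## germline SNP loci per patient
  snp_loci <- list()
  snp_df <- function(pos) {
    if (!length(pos)) {
      return(data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE))
    }
    ref <- substring(genome_str, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                  character(1), USE.NAMES = FALSE)
    data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  for (pid in p$patients$patient_id) {
    het <- if (p$snpSpec$n_het > 0) sample(idx$pos, p$snpSpec$n_het) else integer(0)
    hom <- if (p$snpSpec$n_hom > 0) sample(setdiff(idx$pos, het), p$snpSpec$n_hom) else integer(0)
    snp_loci[[pid]] <- list(het = snp_df(het), hom = snp_df(hom))
  }
  # somatic mutations are not placed on a patient's own SNP loci (a caller
  # would fold them into the germline allele), and artefact loci avoid every
  # SNP locus so recurrence sets stay interpretable
  snp_pos_by_patient <- lapply(snp_loci, function(l) c(l$het$pos, l$hom$pos))
  all_snp_pos <- unique(unlist(snp_pos_by_patient))

  all_rows <- list()
  truth_rows <- list()
  burden_truth <- list()

  emit <- function(df, truth) {
    all_rows[[length(all_rows) + 1L]] <<- df
    truth_rows[[length(truth_rows) + 1L]] <<- truth
  }

  blood_mutations <- list()   # per patient: blood rows for infiltration

  for (si in seq_len(nrow(meta))) {
    m <- meta[si, ]
    sid <- m$sample_id
    ## per-signature genome burden
    B_k <- stats::setNames(numeric(length(sig_names)), sig_names)
    for (pr in p$processes) {
      slope <- pr$slopes[m$tissue]
      if (is.na(slope) || slope == 0) next
      cov <- .covariate_value(pr$covariate, m)
      if (cov <= 0) next
      b <- slope * cov
      B_k[names(pr$signatures)] <- B_k[names(pr$signatures)] +
        b * pr$signatures
    }
    burden_truth[[sid]] <- B_k
    drawn <- .draw_sample_mutations(sid, B_k, p, panel, idx, ann, S)
    if (!is.null(drawn$rows)) {
      on_snp <- drawn$rows$gpos %in% snp_pos_by_patient[[m$patient_id]]
      drawn$rows <- drawn$rows[!on_snp, , drop = FALSE]
      drawn$truth <- drawn$truth[!on_snp]
      rows <- drawn$rows
      n0 <- nrow(rows)
      obs <- .observe(n0, p, m$median_depth)
      keep <- obs$keep
      rows <- rows[keep, , drop = FALSE]
      nk <- nrow(rows)
      if (nk) {
        akey <- paste(rows$gpos, rows$alt)
        hit <- unname(ann$map[akey])
        gene <- ifelse(is.na(hit), NA_character_, ann$gene[hit])
        impact <- ifelse(is.na(hit), "noncoding", ann$impact[hit])
        codon <- ifelse(is.na(hit), NA_integer_, ann$codon[hit])
        qc <- .qc_fields(nk, p)
        df <- data.frame(
          sample_id = sid, chrom = "chr1", pos = rows$gpos,
          ref = rows$ref, alt = rows$alt, var_type = "SBS",
          alt_count = obs$alt[keep], depth = obs$depth[keep],
          vaf = obs$alt[keep] / obs$depth[keep],
          n_fraction = qc$n_fraction, mean_mismatches = qc$mean_mismatches,
          msi_len = NA_integer_,
          read_positions = .read_positions_string(obs$alt[keep], rl),
          read_length = rl, gene = gene, impact = impact,
          protein_change = ifelse(is.na(codon), NA_character_,
                                  paste0("p.", codon)),
          driver_score = ifelse(impact == "missense",
                                round(stats::runif(nk), 3), NA_real_),
          stringsAsFactors = FALSE)
        tr <- data.frame(sample_id = sid, key = .variant_key(df),
                         signature = drawn$truth[keep],
                         true_vaf = obs$true_vaf[keep],
                         origin = "somatic", stringsAsFactors = FALSE)

        ## positive selection: extra nonsynonymous mutations in selected
        ## genes. The excess is drawn against the *expected* neutral count of
        ## the class in the gene (detected-scale), so the realised selection
        ## coefficient is w in expectation and carries independent Poisson
        ## noise rather than w times the gene's neutral fluctuation.
        for (g in names(p$selectionSpec)) {
          w <- p$selectionSpec[[g]]
          for (cls in c("missense", "nonsense")) {
            wf <- if (cls == "missense") w[["w_mis"]] else w[["w_non"]]
            if (is.null(wf) || wf <= 1) next
            lam <- .expected_class_count(g, cls, nk, B_k, S, panel, idx,
                                         snp_pos_by_patient[[m$patient_id]])
            n_extra <- stats::rpois(1, (wf - 1) * lam)
            if (n_extra == 0) next
            ex <- .draw_selection_extras(g, cls, n_extra, B_k, S, panel, p,
                                         m$median_depth, rl,
                                         exclude_pos = snp_pos_by_patient[[m$patient_id]])
            if (!is.null(ex$df)) {
              ex$df$sample_id <- sid
              ex$truth$sample_id <- sid
              df <- rbind(df, ex$df)
              tr <- rbind(tr, ex$truth)
            }
          }
        }
        emit(df, tr)
        if (m$is_blood) blood_mutations[[m$patient_id]] <- df
      }
    }

    ## indels and DBS (small neutral background tied to total burden)
    e_vaf <- (p$vafRange[2] - p$vafRange[1]) /
      log(p$vafRange[2] / p$vafRange[1])
    n_sbs_mean <- (sum(B_k) / p$genomeMb) * effectiveLengthMb(panel) /
      (2 * e_vaf)
    n_ind <- stats::rpois(1, p$indelFraction * n_sbs_mean)
    if (n_ind > 0) {
      ipos <- sample(idx$pos[idx$pos < nchar(genome_str) - 40], n_ind,
                     replace = TRUE)
      obs <- .observe(n_ind, p, m$median_depth)
      keep <- obs$keep
      if (any(keep)) {
        ipos <- ipos[keep]
        anchor <- substring(genome_str, ipos, ipos)
        delbase <- substring(genome_str, ipos + 1L, ipos + 1L)
        # homopolymer run length of the deleted base (VarDict-style MSI)
        msi <- vapply(seq_along(ipos), function(j) {
          r <- 1L
          while (substring(genome_str, ipos[j] + 1L + r, ipos[j] + 1L + r) ==
                 delbase[j]) r <- r + 1L
          r
        }, integer(1))
        keys4 <- paste(rep(ipos + 1L, each = 4L), BASES)
        hits4 <- matrix(unname(ann$gene[ann$map[keys4]]), nrow = 4L)
        in_gene <- apply(hits4, 2, function(h) {
          h <- h[!is.na(h)]
          if (length(h)) h[1] else NA_character_
        })
        nkept <- sum(keep)
        df <- data.frame(
          sample_id = sid, chrom = "chr1", pos = ipos,
          ref = paste0(anchor, delbase), alt = anchor, var_type = "INDEL",
          alt_count = obs$alt[keep], depth = obs$depth[keep],
          vaf = obs$alt[keep] / obs$depth[keep],
          n_fraction = round(stats::runif(nkept, 0, 0.06), 4),
          mean_mismatches = round(stats::runif(nkept, 0, 3), 2),
          msi_len = msi,
          read_positions = .read_positions_string(obs$alt[keep], rl),
          read_length = rl, gene = in_gene,
          impact = ifelse(is.na(in_gene), NA_character_, "indel"),
          protein_change = NA_character_, driver_score = NA_real_,
          stringsAsFactors = FALSE)
        emit(df, data.frame(sample_id = sid, key = .variant_key(df),
                            signature = "indel_background",
                            true_vaf = obs$true_vaf[keep],
                            origin = "somatic", stringsAsFactors = FALSE))
      }
    }
    n_dbs <- stats::rpois(1, p$dbsFraction * n_sbs_mean)
    if (n_dbs > 0) {
      dpos <- sample(idx$pos[idx$pos < nchar(genome_str) - 2], n_dbs,
                     replace = TRUE)
      obs <- .observe(n_dbs, p, m$median_depth)
      keep <- obs$keep
      if (any(keep)) {
        dpos <- dpos[keep]
        ref2 <- substring(genome_str, dpos, dpos + 1L)
        alt2 <- vapply(ref2, function(r) {
          paste0(sample(setdiff(BASES, substr(r, 1, 1)), 1),
                 sample(setdiff(BASES, substr(r, 2, 2)), 1))
        }, character(1))
        nkept <- sum(keep)
        df <- data.frame(
          sample_id = sid, chrom = "chr1", pos = dpos,
          ref = ref2, alt = alt2, var_type = "DBS",
          alt_count = obs$alt[keep], depth = obs$depth[keep],
          vaf = obs$alt[keep] / obs$depth[keep],
          n_fraction = round(stats::runif(nkept, 0, 0.04), 4),
          mean_mismatches = round(stats::runif(nkept, 0, 3), 2),
          msi_len = NA_integer_,
          read_positions = .read_positions_string(obs$alt[keep], rl),
          read_length = rl, gene = NA_character_, impact = NA_character_,
          protein_change = NA_character_, driver_score = NA_real_,
          stringsAsFactors = FALSE)
        emit(df, data.frame(sample_id = sid, key = .variant_key(df),
                            signature = "dbs_background",
                            true_vaf = obs$true_vaf[keep],
                            origin = "somatic", stringsAsFactors = FALSE))
      }
    }

    ## germline SNPs
    loci <- snp_loci[[m$patient_id]]
    for (kind in c("het", "hom")) {
      ld <- loci[[kind]]
      n <- nrow(ld)
      if (n == 0L) next
      depth <- stats::rnbinom(n, mu = m$median_depth, size = p$depthSpec$nb_size)
      depth[depth < 100] <- 100L
      prob <- if (kind == "het") 0.5 else 0.997
      alt <- stats::rbinom(n, depth, prob)
      alt[alt < 1] <- 1L
      df <- data.frame(
        sample_id = sid, chrom = "chr1", pos = ld$pos, ref = ld$ref,
        alt = ld$alt, var_type = "SBS", alt_count = alt, depth = depth,
        vaf = alt / depth,
        n_fraction = round(stats::runif(n, 0, 0.02), 4),
        mean_mismatches = round(stats::runif(n, 0, 2), 2),
        msi_len = NA_integer_,
        read_positions = NA_character_,
        read_length = rl, gene = NA_character_, impact = NA_character_,
        protein_change = NA_character_, driver_score = NA_real_,
        stringsAsFactors = FALSE)
      emit(df, data.frame(sample_id = sid, key = .variant_key(df),
                          signature = NA_character_, true_vaf = prob,
                          origin = paste0(kind, "_snp"),
                          stringsAsFactors = FALSE))
    }
  }

  variants <- do.call(rbind, all_rows)
  truth_mut <- do.call(rbind, truth_rows)

  ## blood infiltration: a fraction of blood mutations recur in a fixed
  ## fraction of the patient's non-blood samples
  if (p$bloodSharing$rate > 0) {
    shared_rows <- list(); shared_truth <- list()
    for (pid in names(blood_mutations)) {
      bm <- blood_mutations[[pid]]
      n_inf <- stats::rbinom(1, nrow(bm), p$bloodSharing$rate)
      if (n_inf == 0) next
      inf_rows <- bm[sample.int(nrow(bm), n_inf), , drop = FALSE]
      nb <- meta$sample_id[meta$patient_id == pid & !meta$is_blood]
      n_carriers <- max(1L, round(p$bloodSharing$carrier_fraction * length(nb)))
      carrier_of <- lapply(seq_len(nrow(inf_rows)), function(r) sample(nb, n_carriers))
      rows <- inf_rows[rep(seq_len(nrow(inf_rows)), each = n_carriers), ,
                       drop = FALSE]
      rows$sample_id <- unlist(carrier_of)
      med <- stats::setNames(meta$median_depth, meta$sample_id)[rows$sample_id]
      nr <- nrow(rows)
      depth <- pmax(100L, stats::rnbinom(nr, mu = med,
                                         size = p$depthSpec$nb_size))
      tv <- exp(stats::runif(nr, log(2e-5), log(2e-4)))
      alt <- pmax(1L, stats::rbinom(nr, depth, tv))
      rows$alt_count <- alt; rows$depth <- depth; rows$vaf <- alt / depth
      rows$read_positions <- .read_positions_string(alt, rl)
      shared_rows[[pid]] <- rows
      shared_truth[[pid]] <- data.frame(sample_id = rows$sample_id,
                                        key = .variant_key(rows),
                                        signature = NA_character_,
                                        true_vaf = tv,
                                        origin = "blood_shared",
                                        stringsAsFactors = FALSE)
      truth_mut$origin[truth_mut$sample_id %in%
                         meta$sample_id[meta$is_blood & meta$patient_id == pid] &
                         truth_mut$key %in% .variant_key(inf_rows)] <-
        "blood_infiltrating_source"
    }
    if (length(shared_rows)) {
      variants <- rbind(variants, do.call(rbind, shared_rows))
      truth_mut <- rbind(truth_mut, do.call(rbind, shared_truth))
    }
  }

  ## QC failures: corrupt the metadata of a small labelled fraction
  if (p$qcFailRate > 0 && nrow(variants)) {
    som <- which(truth_mut$origin == "somatic")
    n_fail <- stats::rbinom(1, length(som), p$qcFailRate)
    if (n_fail > 0) {
      pick <- sample(som, n_fail)
      mode <- sample(c("mismatches", "n_fraction"), n_fail, replace = TRUE)
      # the mismatch rule applies to point mutations only
      mode[variants$var_type[pick] == "INDEL"] <- "n_fraction"
      variants$mean_mismatches[pick[mode == "mismatches"]] <-
        round(stats::runif(sum(mode == "mismatches"), 4.5, 9), 2)
      variants$n_fraction[pick[mode == "n_fraction"]] <-
        round(stats::runif(sum(mode == "n_fraction"), 0.12, 0.3), 4)
      truth_mut$origin[pick] <- "qc_fail"
    }
  }

  ## recurrent read-position artefacts
  art <- NULL
  if (!is.null(p$artefactSpec) && p$artefactSpec$n_artefacts > 0) {
    art <- injectArtefacts(variants, meta, panel, p$artefactSpec, rl,
                           site_index = idx, exclude_pos = all_snp_pos)
    variants <- art$variants
    truth_mut <- rbind(truth_mut, art$truth)
  }

  ## optional tumour sample + contamination
  contaminated_sample <- NA_character_
  tumour_sample <- NA_character_
  tumour_profile <- NULL
  if (!is.null(p$contaminationSpec)) {
    cs <- p$contaminationSpec
    pid <- cs$patient_id
    pm <- meta[meta$patient_id == pid, , drop = FALSE][1, ]
    tumour_sample <- paste0(pid, "_tumour_1")
    med <- round(stats::rnorm(1, p$depthSpec$median, p$depthSpec$median_sd))
    het <- snp_loci[[pid]]$het
    n_imb <- min(cs$n_imbalanced, nrow(het))
    imb_idx <- sample.int(nrow(het), n_imb)
    true_baf <- rep(0.5, nrow(het))
    true_baf[imb_idx] <- 0.5 + sample(c(-1, 1), n_imb, replace = TRUE) * cs$delta
    depth <- stats::rnbinom(nrow(het), mu = med, size = p$depthSpec$nb_size)
    depth[depth < 100] <- 100L
    alt <- stats::rbinom(nrow(het), depth, true_baf)
    alt[alt < 1] <- 1L
    tum_df <- data.frame(
      sample_id = tumour_sample, chrom = "chr1", pos = het$pos, ref = het$ref,
      alt = het$alt, var_type = "SBS", alt_count = alt, depth = depth,
      vaf = alt / depth, n_fraction = 0.01, mean_mismatches = 1,
      msi_len = NA_integer_, read_positions = NA_character_,
      read_length = rl, gene = NA_character_, impact = NA_character_,
      protein_change = NA_character_, driver_score = NA_real_,
      stringsAsFactors = FALSE)
    # hom SNPs so the tumour shares the patient's SNP roster
    hom <- snp_loci[[pid]]$hom
    dh <- stats::rnbinom(nrow(hom), mu = med, size = p$depthSpec$nb_size)
    dh[dh < 100] <- 100L
    ah <- pmax(1L, stats::rbinom(nrow(hom), dh, 0.997))
    tum_hom <- tum_df[rep(1, nrow(hom)), , drop = FALSE]
    tum_hom$pos <- hom$pos; tum_hom$ref <- hom$ref; tum_hom$alt <- hom$alt
    tum_hom$alt_count <- ah; tum_hom$depth <- dh; tum_hom$vaf <- ah / dh
    variants <- rbind(variants, tum_df, tum_hom)
    meta <- rbind(meta, data.frame(
      sample_id = tumour_sample, patient_id = pid, tissue = "tumour",
      is_blood = FALSE, is_tumour = TRUE, age = pm$age, sex = pm$sex,
      pack_years = pm$pack_years, units_per_week = pm$units_per_week,
      drink_years = pm$drink_years, treatments = pm$treatments,
      median_depth = med,
      depth_sd = round(sqrt(med + med^2 / p$depthSpec$nb_size)),
      stringsAsFactors = FALSE))
    tumour_profile <- data.frame(
      key = paste("chr1", het$pos, het$ref, het$alt, sep = "_"),
      true_baf = true_baf, stringsAsFactors = FALSE)
    target <- meta$sample_id[meta$patient_id == pid &
                               meta$tissue == cs$tissue][1]
    contaminated_sample <- target
    variants <- injectContamination(variants, target, tumour_profile,
                                    cs$fraction)
  }

  rownames(variants) <- NULL
  rownames(truth_mut) <- NULL

  ## coverage profile + blacklist
  gr <- panelIntervals(panel)
  cov_rows <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    data.frame(sample_id = meta$sample_id[i],
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               coverage = round(meta$median_depth[i] *
                                  stats::rlnorm(length(gr), 0, 0.08)),
               stringsAsFactors = FALSE)
  }))
  bl_pos <- sort(sample(idx$pos, 30))
  blacklist <- GenomicRanges::GRanges("chr1", IRanges::IRanges(bl_pos, bl_pos))
  coverage <- CoverageProfile(cov_rows, blacklist = blacklist)

  ## hotspot list: a couple of coding loci in exemption-relevant genes
  hotspots <- .toy_hotspots(panel, ann)

  truth <- list(
    expected_burden = do.call(rbind, lapply(names(burden_truth), function(s) {
      data.frame(sample_id = s, signature = names(burden_truth[[s]]),
                 burden_genome = as.numeric(burden_truth[[s]]),
                 stringsAsFactors = FALSE)
    })),
    mutations = truth_mut,
    contaminated_sample = contaminated_sample,
    tumour_sample = tumour_sample,
    tumour_profile = tumour_profile,
    selection = p$selectionSpec,
    seed = p$seed
  )
  list(variants = variants, panel = panel, coverage = coverage, meta = meta,
       hotspots = hotspots, blacklist = blacklist, truth = truth)
}

## Expected number of detected mutations of one impact class in a gene, given
## the sample's detected total: each (site, alt) carries probability
## p(channel96) / n_sites(context class) under the placement model.
.expected_class_count <- function(gene, cls, n_detected, B_k, S, panel, idx,
                                  exclude_pos = integer(0)) {
  tab <- .gene_impact_table(panel, gene)
  cand <- tab[tab$impact == cls & !(tab$gpos %in% exclude_pos), , drop = FALSE]
  if (!nrow(cand)) return(0)
  chan96 <- .chan192_to_96(cand$channel)
  p_ch <- as.numeric(S[chan96, , drop = FALSE] %*% (B_k / max(sum(B_k), 1e-12)))
  cls32 <- paste0(substr(chan96, 1, 1), substr(chan96, 3, 3),
                  substr(chan96, 7, 7))
  n_class <- lengths(idx$by_class)[cls32]
  n_detected * sum(p_ch / pmax(n_class, 1L))
}

## Extra nonsynonymous mutations in a selected gene, channel-weighted by the
## sample's signature intensity.
.draw_selection_extras <- function(gene, cls, n, B_k, S, panel, p,
                                   med_depth, rl, exclude_pos = integer(0)) {
  tab <- .gene_impact_table(panel, gene)
  gm <- geneModels(panel)[[gene]]
  cand <- tab[tab$impact == cls & !(tab$gpos %in% exclude_pos), , drop = FALSE]
  if (!nrow(cand)) return(list(df = NULL, truth = NULL))
  chan96 <- .chan192_to_96(cand$channel)
  intensity <- as.numeric(S[chan96, , drop = FALSE] %*%
                            (B_k / max(sum(B_k), 1e-12)))
  if (all(intensity <= 0)) return(list(df = NULL, truth = NULL))
  pick <- sample.int(nrow(cand), n, replace = TRUE, prob = intensity)
  # the excess count is calibrated against *detected* neutral events, so the
  # extras are drawn conditional on detection (rejection on the observation
  # model) rather than thinned a second time
  obs <- .observe(n, p, med_depth)
  tries <- 0L
  while (any(!obs$keep) && tries < 50L) {
    redo <- which(!obs$keep)
    obs2 <- .observe(length(redo), p, med_depth)
    for (f in c("true_vaf", "depth", "alt", "keep")) {
      obs[[f]][redo] <- obs2[[f]]
    }
    tries <- tries + 1L
  }
  keep <- obs$keep
  if (!any(keep)) return(list(df = NULL, truth = NULL))
  cand <- cand[pick[keep], , drop = FALSE]
  chan96 <- chan96[pick[keep]]
  galt <- if (gm$strand == "-") unname(.comp[cand$alt]) else cand$alt
  genome_str <- as.character(panelGenome(panel)[[gm$chrom]])
  gref <- substring(genome_str, cand$gpos, cand$gpos)
  nk <- nrow(cand)
  # posterior over generating signature given the channel
  sig <- vapply(chan96, function(ch) {
    pr <- B_k * S[ch, ]
    sample(names(B_k), 1, prob = pr)
  }, character(1))
  df <- data.frame(
    sample_id = NA_character_, chrom = gm$chrom, pos = cand$gpos,
    ref = gref, alt = galt, var_type = "SBS",
    alt_count = obs$alt[keep], depth = obs$depth[keep],
    vaf = obs$alt[keep] / obs$depth[keep],
    n_fraction = round(stats::runif(nk, 0, 0.04), 4),
    mean_mismatches = round(stats::runif(nk, 0, 3), 2),
    msi_len = NA_integer_,
    read_positions = .read_positions_string(obs$alt[keep], rl),
    read_length = rl, gene = gene, impact = cls,
    protein_change = paste0("p.", (cand$site - 1L) %/% 3L + 1L),
    driver_score = ifelse(cls == "missense",
                          round(stats::runif(nk, 0.57, 1), 3), NA_real_),
    stringsAsFactors = FALSE)
  tr <- data.frame(sample_id = NA_character_, key = .variant_key(df),
                   signature = sig, true_vaf = obs$true_vaf[keep],
                   origin = "selection_extra", stringsAsFactors = FALSE)
  list(df = df, truth = tr)
}

.toy_hotspots <- function(panel, ann) {
  gms <- geneModels(panel)
  want <- intersect(c("EGFR", "PIK3CA", "KRAS", "PPM1D", "BRAF"), names(gms))
  rows <- list()
  genome_str <- as.character(panelGenome(panel)[[1]])
  for (g in want) {
    tab <- .gene_impact_table(panel, g)
    mis <- tab[tab$impact == "missense", , drop = FALSE]
    if (!nrow(mis)) next
    r <- mis[nrow(mis) %/% 2L, ]
    gm <- gms[[g]]
    galt <- if (gm$strand == "-") unname(.comp[r$alt]) else r$alt
    gref <- substring(genome_str, r$gpos, r$gpos)
    rows[[g]] <- data.frame(chrom = gm$chrom, pos = r$gpos, ref = gref,
                            alt = galt, gene = g,
                            protein_change = paste0("p.", (r$site - 1L) %/% 3L + 1L),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inject recurrent read-position artefacts
#'
#' Creates artefact loci that recur across samples with supporting-read
#' positions concentrated at a fixed per-artefact offset (probability
#' \code{skew}; the remainder uniform). With skew 0 the positions are uniform;
#' with a zero artefact count the input is returned unchanged.
#'
#' @param variants Cohort variant table.
#' @param meta Sample metadata.
#' @param panel A \linkS4class{Panel} (artefact sites are panel positions).
#' @param spec list(n_artefacts, skew, occurrence_prob, mean_alt).
#' @param read_length Consensus read length.
#' @param site_index Optional precomputed panel site index (internal reuse).
#' @param exclude_pos Positions (e.g. SNP loci) artefacts must avoid.
#' @return list(variants = table with artefact rows appended, truth =
#'   truth rows labelled "artefact").
#' @export
injectArtefacts <- function(variants, meta, panel, spec, read_length = 130L,
                            site_index = NULL, exclude_pos = integer(0)) {
  if (spec$skew < 0 || spec$skew > 1) stop("artefact skew must be in [0, 1]")
  if (spec$n_artefacts == 0) {
    return(list(variants = variants, truth = NULL))
  }
  idx <- if (is.null(site_index)) .panel_site_index(panel) else site_index
  genome_str <- idx$genome
  art_pos <- sample(setdiff(idx$pos, exclude_pos), spec$n_artefacts)
  offsets <- sample.int(read_length, spec$n_artefacts, replace = TRUE)
  normal_samples <- meta$sample_id[!meta$is_tumour]
  med <- stats::setNames(meta$median_depth, meta$sample_id)
  ref_a <- substring(genome_str, art_pos, art_pos)
  alt_a <- vapply(ref_a, function(r) sample(setdiff(BASES, r), 1),
                  character(1), USE.NAMES = FALSE)
  samp <- character(0); aidx <- integer(0)
  for (a in seq_len(spec$n_artefacts)) {
    carriers <- normal_samples[stats::runif(length(normal_samples)) <
                                 spec$occurrence_prob]
    samp <- c(samp, carriers)
    aidx <- c(aidx, rep(a, length(carriers)))
  }
  if (!length(samp)) return(list(variants = variants, truth = NULL))
  n <- length(samp)
  depth <- pmax(100L, stats::rpois(n, med[samp]))
  alt_n <- 1L + stats::rpois(n, spec$mean_alt - 1)
  read_pos <- vapply(seq_len(n), function(i) {
    at_offset <- stats::runif(alt_n[i]) < spec$skew
    posv <- ifelse(at_offset, offsets[aidx[i]],
                   sample.int(read_length, alt_n[i], replace = TRUE))
    paste(posv, collapse = ",")
  }, character(1))
  df <- data.frame(
    sample_id = samp, chrom = "chr1", pos = art_pos[aidx],
    ref = ref_a[aidx], alt = alt_a[aidx], var_type = "SBS",
    alt_count = alt_n, depth = depth, vaf = alt_n / depth,
    n_fraction = round(stats::runif(n, 0, 0.04), 4),
    mean_mismatches = round(stats::runif(n, 0, 3), 2),
    msi_len = NA_integer_, read_positions = read_pos,
    read_length = read_length, gene = NA_character_,
    impact = NA_character_, protein_change = NA_character_,
    driver_score = NA_real_, stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = samp, key = .variant_key(df),
                      signature = NA_character_, true_vaf = NA_real_,
                      origin = "artefact", stringsAsFactors = FALSE)
  list(variants = rbind(variants, df), truth = truth)
}

#' Inject tumour contamination into a sample's BAF profile
#'
#' Shifts the target sample's heterozygous-SNP BAFs toward the tumour BAFs in
#' proportion to the contaminating fraction: the new alt count is
#' round(depth * ((1 - f) * baf + f * tumour_baf)). Fraction 0 leaves the
#' sample unchanged.
#'
#' @param variants Cohort variant table.
#' @param sample_id Target (normal) sample.
#' @param tumour_profile data.frame(key, true_baf) of the tumour's het-SNP
#'   B-allele frequencies.
#' @param fraction Contaminating cell fraction in [0, 1).
#' @return The variant table with the target sample's SNP rows adjusted.
#' @export
injectContamination <- function(variants, sample_id, tumour_profile, fraction) {
  if (fraction < 0 || fraction >= 1) {
    stop("contamination fraction must be in [0, 1)")
  }
  if (fraction == 0) return(variants)
  keys <- .variant_key(variants)
  sel <- which(variants$sample_id == sample_id &
                 keys %in% tumour_profile$key)
  if (!length(sel)) return(variants)
  tb <- tumour_profile$true_baf[match(keys[sel], tumour_profile$key)]
  new_baf <- (1 - fraction) * variants$vaf[sel] + fraction * tb
  new_alt <- pmax(1L, as.integer(round(variants$depth[sel] * new_baf)))
  variants$alt_count[sel] <- new_alt
  variants$vaf[sel] <- new_alt / variants$depth[sel]
  variants
}

#' Write a generated cohort to a directory
#'
#' Emits every interchange format: variants.tsv, panel.bed, reference.fasta,
#' coverage.tsv, meta.tsv, hotspots.tsv, blacklist.bed and truth.tsv.
#'
#' @param cohort Result of \link{generateCohort}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeVariantTable(cohort$variants, file.path(dir, "variants.tsv"))
  writePanelBed(cohort$panel, file.path(dir, "panel.bed"))
  Biostrings::writeXStringSet(panelGenome(cohort$panel),
                              file.path(dir, "reference.fasta"))
  writeCoverageProfile(cohort$coverage, file.path(dir, "coverage.tsv"))
  writeSampleMeta(cohort$meta, file.path(dir, "meta.tsv"))
  writeHotspotList(cohort$hotspots, file.path(dir, "hotspots.tsv"))
  writeBedIntervals(cohort$blacklist, file.path(dir, "blacklist.bed"))
  .write_tsv(cohort$truth$mutations, file.path(dir, "truth.tsv"))
  invisible(dir)
}
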