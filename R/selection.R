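## Coverage-adjusted selection inference on the panel. Every coding site
## contributes its three possible substitutions, classified by codon
## translation into synonymous / missense / nonsense and assigned to a
## strand-specific trinucleotide channel (192 channels, read on the coding
## strand). Opportunities are weighted by the median duplex coverage of each
## channel's sites within the gene, normalised by the overall median depth;
## blacklisted sites carry zero coverage. Channel mutation rates are estimated
## from synonymous counts across the whole panel under a Poisson model with
## opportunity offsets, and per-gene dN/dS ratios are observed/expected counts
## with profile-likelihood confidence intervals and likelihood-ratio tests.

IMPACT_CLASSES <- c("synonymous", "missense", "nonsense")

#' OpportunityMatrix: per-gene, per-channel, per-impact mutation opportunities
#'
#' @slot opportunities numeric array genes x 192 channels x impact classes,
#'   coverage-weighted.
#' @slot raw Unweighted site-substitution counts (same shape).
#' @slot indelOpportunity Coverage-weighted length per gene (indel model).
#' @slot provenance Grouping the coverage came from (sample/tissue/cohort id).
#' @export
setClass("OpportunityMatrix", representation(
  opportunities = "array",
  raw = "array",
  indelOpportunity = "numeric",
  provenance = "character"
))

setValidity("OpportunityMatrix", function(object) {
  if (any(object@opportunities < 0)) return("opportunities must be >= 0")
  TRUE
})

setMethod("show", "OpportunityMatrix", function(object) {
  d <- dim(object@opportunities)
  cat("OpportunityMatrix:", d[1], "genes x", d[2], "channels x", d[3],
      "impact classes (", object@provenance, ")\n")
})

## Per-gene site-substitution table: one row per (coding site, alt base) with
## genomic coordinates, coding-strand channel and translated impact.
.gene_impact_table <- function(panel, gene) {
  gm <- geneModels(panel)[[gene]]
  if (is.null(gm)) stop("gene ", gene, " absent from panel")
  cds <- gm$cds
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("gene ", gene, " length not divisible by 3")
  genome_seq <- as.character(panelGenome(panel)[[gm$chrom]])
  # flanking bases on the coding strand for edge trinucleotides
  if (gm$strand == "+") {
    f5 <- if (gm$start > 1) substr(genome_seq, gm$start - 1, gm$start - 1) else "N"
    f3 <- if (gm$end < nchar(genome_seq)) substr(genome_seq, gm$end + 1, gm$end + 1) else "N"
  } else {
    f5 <- if (gm$end < nchar(genome_seq))
      unname(.comp[substr(genome_seq, gm$end + 1, gm$end + 1)]) else "N"
    f3 <- if (gm$start > 1)
      unname(.comp[substr(genome_seq, gm$start - 1, gm$start - 1)]) else "N"
  }
  padded <- paste0(f5, cds, f3)
  i <- seq_len(L)
  ref <- substring(cds, i, i)
  tri <- substring(padded, i, i + 2L)      # coding-strand trinucleotide
  codon_idx <- (i - 1L) %/% 3L + 1L
  within <- (i - 1L) %% 3L + 1L
  codons <- substring(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[codons])
  # genomic position of each coding site
  gpos <- if (gm$strand == "+") gm$start + i - 1L else gm$end - i + 1L
  # expand to the three alternates
  ALT_MAT <- matrix(c("C", "G", "T",   # alternates of A
                      "A", "G", "T",   # of C
                      "A", "C", "T",   # of G
                      "A", "C", "G"),  # of T
                    nrow = 4, byrow = TRUE,
                    dimnames = list(BASES, NULL))
  rows <- do.call(rbind, lapply(1:3, function(a) {
    alt <- unname(ALT_MAT[ref, a])
    mut_codon <- codons
    substr(mut_codon, within, within) <- alt
    alt_aa <- unname(gc[mut_codon])
    impact <- ifelse(alt_aa == ref_aa, "synonymous",
                     ifelse(alt_aa == "*", "nonsense", "missense"))
    # a reference stop codon (should not occur in clean models): treat any
    # change as missense unless synonymous
    impact[ref_aa == "*" & alt_aa != "*"] <- "missense"
    data.frame(site = i, gpos = gpos, ref = ref, alt = alt,
               channel = paste0(tri, ">", alt), impact = impact,
               stringsAsFactors = FALSE)
  }))
  rows
}

#' Build the coverage-adjusted opportunity matrix
#'
#' @param panel A \linkS4class{Panel} with gene models.
#' @param coverage A \linkS4class{CoverageProfile}; blacklisted sites report
#'   zero coverage.
#' @param sample_ids Samples whose coverage defines the weights (median across
#'   samples per site); NULL uses every sample in the profile.
#' @param provenance Label recorded on the result.
#' @param impact_tables Optional precomputed \code{impactTables(panel)} for
#'   reuse across calls.
#' @return An \linkS4class{OpportunityMatrix}.
#' @export
buildOpportunityMatrix <- function(panel, coverage, sample_ids = NULL,
                                   provenance = "cohort",
                                   impact_tables = NULL) {
  gms <- geneModels(panel)
  genes <- names(gms)
  chans <- sbs192Channels()
  if (is.null(sample_ids)) sample_ids <- unique(coverage@table$sample_id)
  if (is.null(impact_tables)) impact_tables <- impactTables(panel)
  # overall normalising depth: median of the per-sample interval coverages
  covtab <- coverage@table[coverage@table$sample_id %in% sample_ids, ,
                           drop = FALSE]
  norm_depth <- stats::median(covtab$coverage)
  if (!is.finite(norm_depth) || norm_depth <= 0) {
    stop("coverage profile has no usable coverage for the requested samples")
  }
  ## per-site coverage (median across the requested samples) for all coding
  ## sites at once; blacklisted sites are zero. Panel genes do not overlap,
  ## so per-gene slices of the site vector can be indexed directly.
  gene_sites <- lapply(genes, function(g) sort(unique(impact_tables[[g]]$gpos)))
  gene_chrom <- vapply(genes, function(g) gms[[g]]$chrom, character(1))
  site_chrom <- rep(gene_chrom, lengths(gene_sites))
  site_pos <- unlist(gene_sites, use.names = FALSE)
  ## coverage is per interval per sample, so the cross-sample median can be
  ## taken per distinct interval and mapped onto sites; blacklisted sites are
  ## then forced to zero (they are zero in every sample)
  q <- GenomicRanges::GRanges(site_chrom, IRanges::IRanges(site_pos, site_pos))
  int_key <- paste(covtab$chrom, covtab$start, covtab$end)
  ints <- !duplicated(int_key)
  int_tab <- covtab[ints, c("chrom", "start", "end"), drop = FALSE]
  int_id <- match(int_key, int_key[ints])
  int_mat <- matrix(0, nrow(int_tab), length(sample_ids),
                    dimnames = list(NULL, sample_ids))
  int_mat[cbind(int_id, match(covtab$sample_id, sample_ids))] <- covtab$coverage
  int_med <- if (ncol(int_mat) == 1L) int_mat[, 1] else
    apply(int_mat, 1, stats::median)
  subj <- GenomicRanges::GRanges(int_tab$chrom,
                                 IRanges::IRanges(int_tab$start, int_tab$end))
  hit <- GenomicRanges::findOverlaps(q, subj, select = "first")
  med_cov <- numeric(length(site_pos))
  med_cov[!is.na(hit)] <- int_med[hit[!is.na(hit)]]
  if (length(coverage@blacklist)) {
    med_cov[IRanges::overlapsAny(q, coverage@blacklist)] <- 0
  }
  offsets <- c(0L, cumsum(lengths(gene_sites)))

  L <- array(0, dim = c(length(genes), length(chans), length(IMPACT_CLASSES)),
             dimnames = list(genes, chans, IMPACT_CLASSES))
  RAW <- L
  indel_opp <- stats::setNames(numeric(length(genes)), genes)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    tab <- impact_tables[[g]]
    sites_g <- gene_sites[[gi]]
    cov_g <- med_cov[(offsets[gi] + 1L):offsets[gi + 1L]]
    site_cov_of_row <- cov_g[match(tab$gpos, sites_g)]
    # median coverage of each channel's sites within the gene; constant
    # coverage across the gene (one interval, no blacklist) short-circuits
    if (length(unique(cov_g)) == 1L) {
      ch_w <- stats::setNames(rep(cov_g[1] / norm_depth,
                                  length(unique(tab$channel))),
                              unique(tab$channel))
    } else {
      ch_w <- tapply(site_cov_of_row, tab$channel, stats::median) / norm_depth
    }
    cnt <- table(tab$channel, tab$impact)
    for (m in intersect(colnames(cnt), IMPACT_CLASSES)) {
      chs <- rownames(cnt)
      RAW[g, chs, m] <- RAW[g, chs, m] + as.numeric(cnt[, m])
      L[g, chs, m] <- as.numeric(cnt[, m]) * as.numeric(ch_w[chs])
    }
    indel_opp[g] <- sum(cov_g) / norm_depth
  }
  new("OpportunityMatrix", opportunities = L, raw = RAW,
      indelOpportunity = indel_opp, provenance = provenance)
}

#' Per-gene site-substitution impact tables
#'
#' One row per (coding site, alternate base) with genomic position,
#' coding-strand SBS-192 channel and translated impact. Computed once and
#' reusable across \link{buildOpportunityMatrix}, \link{annotateCodingChannels}
#' and \link{fitDnds} calls.
#'
#' @param panel A \linkS4class{Panel}.
#' @return Named list of data.frames, one per gene.
#' @export
impactTables <- function(panel) {
  gms <- geneModels(panel)
  stats::setNames(lapply(names(gms), function(g) .gene_impact_table(panel, g)),
                  names(gms))
}

#' Strand-specific channel and impact annotation of coding variants
#'
#' Assigns each SBS falling in a modelled gene its coding-strand SBS-192
#' channel (and recomputes the translated impact, which should agree with the
#' annotation column when one is present).
#'
#' @param variants Variant table.
#' @param panel A \linkS4class{Panel}.
#' @param impact_tables Optional precomputed \link{impactTables} result.
#' @return The table with columns channel192 and impact_cds for rows in genes.
#' @export
annotateCodingChannels <- function(variants, panel, impact_tables = NULL) {
  v <- asVariantTable(variants)
  v$channel192 <- NA_character_
  v$impact_cds <- NA_character_
  gms <- geneModels(panel)
  if (is.null(impact_tables)) impact_tables <- impactTables(panel)
  for (g in names(gms)) {
    gm <- gms[[g]]
    sel <- which(v$var_type == "SBS" & !is.na(v$gene) & v$gene == g)
    if (!length(sel)) next
    tab <- impact_tables[[g]]
    # genomic alt must be flipped to the coding strand for minus-strand genes
    galt <- v$alt[sel]
    if (gm$strand == "-") galt <- unname(.comp[galt])
    key_v <- paste(v$pos[sel], galt)
    key_t <- paste(tab$gpos, tab$alt)
    m <- match(key_v, key_t)
    v$channel192[sel] <- tab$channel[m]
    v$impact_cds[sel] <- tab$impact[m]
  }
  v
}

## Profile-likelihood CI for w where O ~ Poisson(w * E), E fixed.
.poisson_w_ci <- function(O, E, level = 0.95) {
  if (E <= 0) return(c(NA_real_, NA_real_))
  crit <- stats::qchisq(level, 1) / 2
  w_hat <- O / E
  ll <- function(w) ifelse(w <= 0, ifelse(O == 0, 0, -Inf),
                           O * log(w * E) - w * E)
  ll_hat <- ll(max(w_hat, .Machine$double.xmin))
  if (O == 0) ll_hat <- 0
  f <- function(w) ll_hat - ll(w) - crit
  lo <- if (O == 0) 0 else stats::uniroot(f, c(1e-12, w_hat))$root
  hi_bracket <- max(w_hat, 1e-8)
  up <- hi_bracket + 1
  while (f(up) < 0) up <- up * 2
  hi <- stats::uniroot(f, c(hi_bracket, up))$root
  c(lo, hi)
}

## One-sided (positive-selection) exact Poisson tail p for w = 1 under
## O ~ Poisson(w E): P(X >= O | E). Exact tails keep the neutral false-
## discovery proportion controlled where the chi-squared right tail is
## liberal at moderate expectations.
.poisson_w_test <- function(O, E) {
  if (E <= 0) return(NA_real_)
  stats::ppois(O - 1, E, lower.tail = FALSE)
}

#' Fit coverage-adjusted dN/dS per gene
#'
#' Channel rates are the maximum-likelihood Poisson rates from synonymous
#' counts over the whole panel with coverage-adjusted opportunities as
#' offsets. Per gene, expected missense/nonsense counts follow by summing
#' rate x opportunity over channels; the selection coefficient w is
#' observed/expected with a profile-likelihood 95% CI and a one-sided exact
#' Poisson tail test against w = 1 (positive selection). Indels use a
#' single panel-wide rate against coverage-weighted gene length. q-values are
#' Benjamini-Hochberg within each test family across genes.
#'
#' @param variants Filtered somatic variant table for the grouping (sample,
#'   tissue or cohort).
#' @param opportunity An \linkS4class{OpportunityMatrix} for the same grouping.
#' @param panel A \linkS4class{Panel}.
#' @param impact_tables Optional precomputed \link{impactTables} result.
#' @return list with \code{results} (per-gene data.frame), \code{rates}
#'   (per-channel synonymous rates), \code{global} (cohort-wide dN/dS with
#'   profile-likelihood CI accounting for rate uncertainty).
#' @export
fitDnds <- function(variants, opportunity, panel, impact_tables = NULL) {
  v <- annotateCodingChannels(variants, panel, impact_tables)
  L <- opportunity@opportunities
  genes <- dimnames(L)[[1]]
  chans <- dimnames(L)[[2]]
  coding <- v[!is.na(v$channel192), , drop = FALSE]
  obs <- array(0L, dim = dim(L), dimnames = dimnames(L))
  if (nrow(coding)) {
    tt <- table(factor(coding$gene, levels = genes),
                factor(coding$channel192, levels = chans),
                factor(coding$impact_cds, levels = IMPACT_CLASSES))
    obs <- obs + unclass(tt)
  }
  indel_obs <- table(factor(v$gene[v$var_type == "INDEL" & !is.na(v$gene)],
                            levels = genes))
  slice <- function(A, m) {
    S <- A[, , m, drop = FALSE]
    dim(S) <- dim(A)[1:2]
    dimnames(S) <- dimnames(A)[1:2]
    S
  }
  syn_counts <- colSums(slice(obs, "synonymous"))
  syn_opp <- colSums(slice(L, "synonymous"))
  if (sum(syn_opp) <= 0) stop("zero total synonymous opportunity")
  if (sum(syn_counts) == 0) stop("no synonymous mutations to anchor rates")
  ## cohort-wide dN/dS by joint profile likelihood in w, with each channel
  ## rate profiled out as (S_c + N_c) / (Lsyn_c + w * Lnon_c). Estimating
  ## rates jointly (rather than from synonymous counts alone) is essential:
  ## many strand-specific channels carry little or no synonymous opportunity,
  ## and a synonymous-only plug-in rate of zero there would systematically
  ## understate nonsynonymous expectations.
  Lsyn <- syn_opp
  Lnon <- colSums(slice(L, "missense")) + colSums(slice(L, "nonsense"))
  S_c <- syn_counts
  N_c <- colSums(slice(obs, "missense")) + colSums(slice(obs, "nonsense"))
  prof_ll <- function(w) {
    r <- (S_c + N_c) / (Lsyn + w * Lnon)
    keep <- (S_c + N_c) > 0 & (Lsyn + w * Lnon) > 0
    sum(S_c[keep] * log(r[keep]) + N_c[keep] * log(w * r[keep]) -
          r[keep] * Lsyn[keep] - w * r[keep] * Lnon[keep])
  }
  opt <- stats::optimize(function(w) -prof_ll(w), interval = c(1e-3, 20),
                         tol = 1e-8)
  w_glob <- opt$minimum
  ll_max <- -opt$objective
  crit <- stats::qchisq(0.95, 1) / 2
  gfun <- function(w) ll_max - prof_ll(w) - crit
  glo <- tryCatch(stats::uniroot(gfun, c(1e-4, w_glob))$root,
                  error = function(e) NA_real_)
  gup <- w_glob * 2
  while (gfun(gup) < 0 && gup < w_glob * 200) gup <- gup * 2
  ghi <- tryCatch(stats::uniroot(gfun, c(w_glob, gup))$root,
                  error = function(e) NA_real_)

  ## channel rates at the profiled optimum; used for all per-gene expectations
  rates <- (S_c + N_c) / (Lsyn + w_glob * Lnon)
  rates[!is.finite(rates)] <- 0
  names(rates) <- chans
  global <- list(w = w_glob, ci95 = c(glo, ghi),
                 obs_nonsyn = sum(N_c),
                 exp_nonsyn = sum(Lnon * rates))

  res <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (m in c("missense", "nonsense")) {
    E <- as.numeric(slice(L, m) %*% rates)
    O <- rowSums(slice(obs, m))
    w <- ifelse(E > 0, O / E, NA_real_)
    ci <- t(mapply(.poisson_w_ci, O, E))
    p <- mapply(.poisson_w_test, O, E)
    res[[paste0("obs_", m)]] <- O
    res[[paste0("exp_", m)]] <- E
    res[[paste0("w_", m)]] <- w
    res[[paste0("ci_low_", m)]] <- ci[, 1]
    res[[paste0("ci_high_", m)]] <- ci[, 2]
    res[[paste0("p_", m)]] <- p
  }
  res$obs_synonymous <- rowSums(slice(obs, "synonymous"))
  res$exp_synonymous <- as.numeric(slice(L, "synonymous") %*% rates)

  # pooled nonsynonymous substitutions (the "sub" family)
  E_sub <- res$exp_missense + res$exp_nonsense
  O_sub <- res$obs_missense + res$obs_nonsense
  res$w_sub <- ifelse(E_sub > 0, O_sub / E_sub, NA_real_)
  res$p_sub <- mapply(.poisson_w_test, O_sub, E_sub)

  # indel family: single panel-wide rate over coverage-weighted gene length
  ind_opp <- opportunity@indelOpportunity[genes]
  ind_O <- as.numeric(indel_obs[genes])
  ind_rate <- if (sum(ind_opp) > 0) sum(ind_O) / sum(ind_opp) else 0
  E_ind <- ind_rate * ind_opp
  res$obs_indel <- ind_O
  res$exp_indel <- E_ind
  res$w_indel <- ifelse(E_ind > 0, ind_O / E_ind, NA_real_)
  res$p_indel <- mapply(.poisson_w_test, ind_O, E_ind)

  # global family: substitutions plus indels
  E_glob <- E_sub + E_ind
  O_glob <- O_sub + ind_O
  res$p_global <- mapply(.poisson_w_test, O_glob, E_glob)

  res$q_global <- stats::p.adjust(res$p_global, method = "BH")
  res$q_sub <- stats::p.adjust(res$p_sub, method = "BH")
  res$q_indel <- stats::p.adjust(res$p_indel, method = "BH")

  list(results = res, rates = rates, global = global)
}

#' Reporting filter for gene:sample dN/dS values
#'
#' Suppresses (for reporting only) missense dN/dS when fewer than 4 expected
#' and fewer than 3 observed missense variants, or fewer than 2 total observed
#' variants; and nonsense dN/dS when fewer than 2 expected and observed
#' nonsense variants, or when the combined synonymous and nonsense expectation
#' is below 3 with fewer than 2 observed events.
#'
#' @param exp_missense,obs_missense,total_observed Missense expectation,
#'   observation and total observed variant count for the gene:sample.
#' @param exp_nonsense,obs_nonsense Nonsense expectation and observation.
#' @param exp_synonymous,obs_syn_nonsense Synonymous expectation and combined
#'   observed synonymous+nonsense events.
#' @return list(keep_missense, keep_nonsense).
#' @export
reportingFilter <- function(exp_missense, obs_missense, total_observed,
                            exp_nonsense, obs_nonsense,
                            exp_synonymous, obs_syn_nonsense) {
  suppress_mis <- (exp_missense < 4 & obs_missense < 3) | total_observed < 2
  suppress_non <- (exp_nonsense < 2 & obs_nonsense < 2) |
    ((exp_synonymous + exp_nonsense) < 3 & obs_syn_nonsense < 2)
  list(keep_missense = !suppress_mis, keep_nonsense = !suppress_non)
}

#' Call driver genes from selection q-values
#'
#' A gene is a driver when its global q < 0.1, or its substitution q < 0.05,
#' or its indel q < 0.05.
#'
#' @param results Per-gene results from \link{fitDnds}.
#' @param q_global,q_sub,q_indel Thresholds.
#' @return Character vector of driver genes.
#' @export
callDrivers <- function(results, q_global = 0.1, q_sub = 0.05,
                        q_indel = 0.05) {
  if (any(is.na(results$q_global) & is.na(results$q_sub) &
          is.na(results$q_indel))) {
    stop("missing q-values")
  }
  flag <- (!is.na(results$q_global) & results$q_global < q_global) |
    (!is.na(results$q_sub) & results$q_sub < q_sub) |
    (!is.na(results$q_indel) & results$q_indel < q_indel)
  results$gene[flag]
}

#' Label putative driver mutations
#'
#' A mutation is a putative driver when its gene is under positive selection
#' and it is either truncating (nonsense, splice or an indel) or a missense
#' mutation with pathogenicity score strictly greater than 0.56.
#'
#' @param variants Variant table.
#' @param driver_genes Genes called by \link{callDrivers}.
#' @param score_threshold Pathogenicity threshold (0.56, strict).
#' @return Logical vector along the variant rows.
#' @export
labelDriverMutations <- function(variants, driver_genes,
                                 score_threshold = 0.56) {
  v <- asVariantTable(variants)
  in_gene <- !is.na(v$gene) & v$gene %in% driver_genes
  truncating <- v$var_type == "INDEL" |
    (!is.na(v$impact) & v$impact %in% c("nonsense", "splice"))
  damaging_mis <- !is.na(v$impact) & v$impact == "missense" &
    !is.na(v$driver_score) & v$driver_score > score_threshold
  in_gene & (truncating | damaging_mis)
}

#' Per-codon hotspot spectrum for a gene
#'
#' Observed mutation counts per codon against rate-model expectations
#' (synonymous-anchored channel rates times the codon's coverage-weighted
#' opportunities), with exact Poisson enrichment/deficit p-values.
#'
#' @param gene Gene symbol (must be in the panel).
#' @param variants Variant table (SBS in the gene are used).
#' @param opportunity An \linkS4class{OpportunityMatrix}.
#' @param rates Channel rates from \link{fitDnds}.
#' @param panel A \linkS4class{Panel}.
#' @param impacts Impact classes included (default nonsynonymous).
#' @return data.frame per codon: observed, expected, ratio, p_enrich,
#'   p_deficit (ratio NA where expected is 0).
#' @export
hotspotSpectrum <- function(gene, variants, opportunity, rates, panel,
                            impacts = c("missense", "nonsense")) {
  gms <- geneModels(panel)
  if (!gene %in% names(gms)) stop("gene ", gene, " absent from panel")
  tab <- .gene_impact_table(panel, gene)
  tab$codon <- (tab$site - 1L) %/% 3L + 1L
  # per-(gene, channel) coverage weight implied by the opportunity matrix
  L <- opportunity@opportunities[gene, , ]
  RAW <- opportunity@raw[gene, , ]
  w_ch <- ifelse(rowSums(RAW) > 0, rowSums(L) / rowSums(RAW), 0)
  tab$rate <- rates[tab$channel] * w_ch[tab$channel]
  use <- tab$impact %in% impacts
  expected <- tapply(tab$rate[use], tab$codon[use], sum)
  codons <- sort(unique(tab$codon))
  E <- stats::setNames(numeric(length(codons)), codons)
  E[names(expected)] <- expected
  v <- annotateCodingChannels(variants, panel)
  vg <- v[!is.na(v$gene) & v$gene == gene & !is.na(v$impact_cds) &
            v$impact_cds %in% impacts, , drop = FALSE]
  gm <- gms[[gene]]
  site <- if (gm$strand == "+") vg$pos - gm$start + 1L else gm$end - vg$pos + 1L
  codon_of <- (site - 1L) %/% 3L + 1L
  O <- stats::setNames(numeric(length(codons)), codons)
  ot <- table(codon_of)
  O[names(ot)] <- as.numeric(ot)
  ratio <- ifelse(E > 0, O / E, NA_real_)
  p_enrich <- ifelse(E > 0, stats::ppois(O - 1, E, lower.tail = FALSE), NA_real_)
  p_deficit <- ifelse(E > 0, stats::ppois(O, E), NA_real_)
  data.frame(codon = codons, observed = as.numeric(O), expected = as.numeric(E),
             ratio = ratio, p_enrich = p_enrich, p_deficit = p_deficit)
}
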