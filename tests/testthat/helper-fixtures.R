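# Shared fixtures, built in code and cached across test files.

.fixture_env <- new.env(parent = emptyenv())

# A mid-sized cohort exercising every generator feature (SNPs, artefacts,
# blood sharing, selection, QC failures).
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- cohortConfig(
      seed = 42L, patients = defaultPatients(6),
      samplesPerTissue = 1L,
      panelSpec = list(n_genes = 12, gene_length = 900,
                       n_neutral = 10, neutral_length = 1200),
      snpSpec = list(n_het = 60, n_hom = 12),
      selectionSpec = list(TP53 = c(w_mis = 4, w_non = 4))
    )
    .fixture_env$small <- generateCohort(cfg)
  }
  .fixture_env$small
}

# Three hand-written variant rows for IO tests.
tiny_variant_table <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S2"),
    chrom = "chr1",
    pos = c(101L, 205L, 101L),
    ref = c("C", "CT", "C"),
    alt = c("T", "C", "A"),
    var_type = c("SBS", "INDEL", "SBS"),
    alt_count = c(2L, 1L, 3L),
    depth = c(30000L, 28000L, 31000L),
    vaf = c(2 / 30000, 1 / 28000, 3 / 31000),
    n_fraction = c(0.01, 0.02, 0),
    mean_mismatches = c(1.5, 2, 0.5),
    msi_len = c(NA_integer_, 2L, NA_integer_),
    read_positions = c("10,120", "55", "1,64,130"),
    read_length = 130L,
    gene = c("TP53", NA, "TP53"),
    impact = c("missense", NA, "synonymous"),
    protein_change = c("p.12", NA, "p.12"),
    driver_score = c(0.8, NA, NA),
    stringsAsFactors = FALSE
  )
}

# A toy panel with one 9-codon gene on each strand plus a neutral region.
toy_panel <- function() {
  if (is.null(.fixture_env$toy_panel)) {
    set.seed(7)
    n <- 400L
    genome_str <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_str, "chr1"))
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(51L, 151L, 251L), c(77L, 177L, 330L)))
    gms <- list(
      G1 = list(gene = "G1", chrom = "chr1", start = 51L, end = 77L,
                strand = "+", cds = substr(genome_str, 51, 77)),
      G2 = list(gene = "G2", chrom = "chr1", start = 151L, end = 177L,
                strand = "-",
                cds = duplexsoma:::.revcomp(substr(genome_str, 151, 177)))
    )
    .fixture_env$toy_panel <- Panel(gr, geneModels = gms, genome = genome)
  }
  .fixture_env$toy_panel
}

# Uniform coverage profile over a panel for the given samples.
uniform_coverage <- function(panel, sample_ids, depth = 30000,
                             blacklist = GenomicRanges::GRanges()) {
  gr <- panelIntervals(panel)
  tab <- do.call(rbind, lapply(sample_ids, function(s) {
    data.frame(sample_id = s,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               coverage = depth, stringsAsFactors = FALSE)
  }))
  CoverageProfile(tab, blacklist = blacklist)
}

# Minimal metadata for ad-hoc variant tables.
tiny_meta <- function(sample_ids, patient_id = "P1", is_blood = FALSE,
                      median_depth = 30000, depth_sd = 4000) {
  data.frame(sample_id = sample_ids, patient_id = patient_id,
             tissue = "lung", is_blood = is_blood, is_tumour = FALSE,
             age = 60, sex = "F", pack_years = 0, units_per_week = 0,
             drink_years = 0, treatments = "",
             median_depth = median_depth, depth_sd = depth_sd,
             stringsAsFactors = FALSE)
}

# One somatic SBS row with sensible defaults.
variant_row <- function(sample_id = "S1", pos = 101L, ref = "C", alt = "T",
                        alt_count = 2L, depth = 30000L,
                        n_fraction = 0.01, mean_mismatches = 1,
                        msi_len = NA_integer_, var_type = "SBS",
                        read_positions = "10,120", read_length = 130L,
                        gene = NA_character_, impact = NA_character_,
                        protein_change = NA_character_,
                        driver_score = NA_real_) {
  data.frame(sample_id = sample_id, chrom = "chr1", pos = pos, ref = ref,
             alt = alt, var_type = var_type, alt_count = alt_count,
             depth = depth, vaf = alt_count / depth, n_fraction = n_fraction,
             mean_mismatches = mean_mismatches, msi_len = msi_len,
             read_positions = read_positions, read_length = read_length,
             gene = gene, impact = impact, protein_change = protein_change,
             driver_score = driver_score, stringsAsFactors = FALSE)
}
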