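## Readers and writers for every external format the pipeline touches.
## Variant tables, clinical metadata, signature catalogues, hotspot lists and
## coverage tables are TSV; panel/blacklist intervals are BED (half-open
## 0-based on disk, 1-based closed in memory); the reference is FASTA.

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA, comment.char = "")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a variant table
#'
#' Tab-separated with the canonical header (see \link{emptyVariantTable}).
#' Malformed rows are reported with their line numbers; a missing mandatory
#' column is a format error naming the column.
#'
#' @param path Path to a TSV variant table.
#' @return A \linkS4class{VariantSet}.
#' @export
readVariantTable <- function(path) {
  df <- .read_tsv(path)
  missing_cols <- setdiff(VARIANT_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("variant table ", path, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, VARIANT_COLUMNS]
  num_cols <- c("pos", "alt_count", "depth", "vaf", "n_fraction",
                "mean_mismatches", "msi_len", "read_length", "driver_score")
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  chr_cols <- setdiff(VARIANT_COLUMNS, num_cols)
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  bad <- which(is.na(df$pos) | is.na(df$depth) | df$depth <= 0 |
               is.na(df$alt_count) | df$alt_count <= 0)
  if (length(bad)) {
    stop("malformed variant rows (file line numbers): ",
         paste(bad + 1L, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$alt_count <- as.integer(df$alt_count)
  df$depth <- as.integer(df$depth)
  df$msi_len <- as.integer(df$msi_len)
  df$read_length <- as.integer(df$read_length)
  VariantSet(df)
}

#' Write a variant table
#' @param variants \linkS4class{VariantSet} or canonical data.frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  .write_tsv(asVariantTable(variants), path)
}

.read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' Read BED intervals
#'
#' BED is half-open 0-based on disk; the returned GRanges is 1-based closed.
#'
#' @param path BED3+ file.
#' @return GRanges.
#' @export
readBedIntervals <- function(path) {
  df <- .read_bed(path)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Write GRanges as BED
#' @param gr GRanges (1-based closed in memory).
#' @param path Output BED path (written half-open 0-based).
#' @return The path, invisibly.
#' @export
writeBedIntervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a panel definition from BED
#'
#' Merges touching/overlapping intervals, attaches gene models for intervals
#' whose BED name column is a gene symbol (the named interval is taken as a
#' contiguous CDS span; column 5, if present, gives the strand), and computes
#' the effective length.
#'
#' @param path BED file; column 4 optionally names a gene ("." or "neutral"
#'   rows contribute sequence context only), column 5 optionally a strand.
#' @param genome Named \code{DNAStringSet} (or path to a FASTA file) supplying
#'   reference context.
#' @param effectiveLengthMb Optional L_Mb override.
#' @return A \linkS4class{Panel}.
#' @export
readPanelBed <- function(path, genome, effectiveLengthMb = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  df <- .read_bed(path)
  contig_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!df$chrom %in% names(genome))) {
    stop("panel interval on unknown contig: ",
         paste(unique(setdiff(df$chrom, names(genome))), collapse = ", "))
  }
  if (any(df$end > contig_len[df$chrom])) {
    stop("panel interval beyond contig end")
  }
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  gene_models <- list()
  if (ncol(df) >= 4L) {
    named <- !(df[[4]] %in% c(".", "", "neutral")) & !is.na(df[[4]])
    for (i in which(named)) {
      gene <- df[[4]][i]
      strand <- if (ncol(df) >= 5L && df[[5]][i] %in% c("+", "-")) df[[5]][i] else "+"
      start1 <- df$start[i] + 1L
      seq <- as.character(Biostrings::subseq(genome[[df$chrom[i]]], start1, df$end[i]))
      if (strand == "-") seq <- .revcomp(seq)
      gene_models[[gene]] <- list(gene = gene, chrom = df$chrom[i],
                                  start = start1, end = df$end[i],
                                  strand = strand, cds = seq)
    }
  }
  Panel(gr, geneModels = gene_models, genome = genome,
        effectiveLengthMb = effectiveLengthMb)
}

#' Write a panel definition as BED
#' @param panel A \linkS4class{Panel}.
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
writePanelBed <- function(panel, path) {
  gr <- panelIntervals(panel)
  gms <- geneModels(panel)
  name <- rep(".", length(gr))
  strand <- rep(".", length(gr))
  for (gm in gms) {
    hit <- as.character(GenomicRanges::seqnames(gr)) == gm$chrom &
      GenomicRanges::start(gr) <= gm$start & GenomicRanges::end(gr) >= gm$end
    # a merged interval may contain the gene span; emit the gene's own row
    if (!any(hit)) next
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, strand = strand)
  # gene spans written as additional named rows so readPanelBed round-trips
  for (gm in gms) {
    df <- rbind(df, data.frame(chrom = gm$chrom, start = gm$start - 1L,
                               end = gm$end, name = gm$gene, strand = gm$strand))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read clinical sample metadata
#'
#' TSV with columns sample_id, patient_id, tissue, is_blood, is_tumour, age,
#' sex, pack_years, units_per_week, drink_years, treatments, median_depth,
#' depth_sd. Treatments are encoded agent:class:cycles:days separated by ";".
#'
#' @param path TSV path.
#' @return data.frame of sample metadata.
#' @export
readSampleMeta <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "patient_id", "tissue", "is_blood", "is_tumour",
            "age", "sex", "pack_years", "units_per_week", "drink_years",
            "treatments", "median_depth", "depth_sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("sample metadata missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$is_blood <- as.logical(df$is_blood)
  df$is_tumour <- as.logical(df$is_tumour)
  if (any(df$pack_years < 0, na.rm = TRUE)) stop("pack_years must be >= 0")
  df
}

#' Write clinical sample metadata
#' @param meta data.frame of sample metadata.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeSampleMeta <- function(meta, path) .write_tsv(meta, path)

#' Parse the treatments field of a metadata row
#' @param x Encoded string "agent:class:cycles:days;..." (empty/NA for none).
#' @return data.frame with agent, class, cycles, days.
#' @export
parseTreatments <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(agent = character(0), class = character(0),
                      cycles = integer(0), days = integer(0)))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(agent = vapply(parts, `[`, "", 1),
             class = vapply(parts, `[`, "", 2),
             cycles = as.integer(vapply(parts, `[`, "", 3)),
             days = as.integer(vapply(parts, `[`, "", 4)))
}

#' Read a signature catalogue
#'
#' TSV whose first column ("channel") lists channel names and remaining
#' columns are signatures; the channel set is inferred from the row count.
#'
#' @param path TSV path.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
readSignatureCatalog <- function(path) {
  df <- .read_tsv(path)
  chans <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- chans
  cs <- switch(as.character(nrow(m)), "96" = "SBS96", "78" = "DBS78",
               "83" = "ID83", "192" = "SBS192",
               stop("cannot infer channel set from ", nrow(m), " rows"))
  SignatureCatalog(m, channelSet = cs)
}

#' Write a signature catalogue
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeSignatureCatalog <- function(catalog, path) {
  m <- signatureProfiles(catalog)
  df <- data.frame(channel = rownames(m), m, check.names = FALSE)
  .write_tsv(df, path)
}

#' Read a hotspot list
#' @param path TSV with chrom, pos, ref, alt, gene, protein_change.
#' @return data.frame of unique hotspot entries.
#' @export
readHotspotList <- function(path) {
  df <- .read_tsv(path)
  unique(df)
}

#' Write a hotspot list
#' @param hotspots data.frame of hotspots.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeHotspotList <- function(hotspots, path) .write_tsv(hotspots, path)

#' Read a per-interval coverage table
#' @param path TSV with sample_id, chrom, start, end (1-based closed),
#'   coverage.
#' @param blacklist Optional GRanges of blacklisted sites.
#' @return A \linkS4class{CoverageProfile}.
#' @export
readCoverageProfile <- function(path, blacklist = GenomicRanges::GRanges()) {
  CoverageProfile(.read_tsv(path), blacklist = blacklist)
}

#' Write a coverage table
#' @param coverage A \linkS4class{CoverageProfile}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
writeCoverageProfile <- function(coverage, path) .write_tsv(coverage@table, path)
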