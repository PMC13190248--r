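## Central S4 containers. Coordinates are BED half-open 0-based on disk and
## 1-based in memory; every reader/writer documents the conversion.

#' @import methods
#' @importFrom GenomicRanges GRanges reduce start end seqnames width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement GENETIC_CODE
NULL

#' Mandatory columns of the canonical variant interchange table (TSV)
#' @format Character vector of column names.
#' @export
VARIANT_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "var_type", "alt_count",
  "depth", "vaf", "n_fraction", "mean_mismatches", "msi_len",
  "read_positions", "read_length", "gene", "impact", "protein_change",
  "driver_score"
)

#' VariantSet: a table of called somatic variants
#'
#' Thin validated container around the canonical variant table. One row per
#' called mutation with QC metadata (duplex depth, no-consensus fraction,
#' supporting-read mismatches, mutant-base read offsets), annotation (gene,
#' impact, protein change, pathogenicity score) and the variant allele
#' frequency. Positions are 1-based.
#'
#' @slot calls data.frame with the columns in \code{duplexsoma:::VARIANT_COLUMNS}.
#' @export
setClass("VariantSet", representation(calls = "data.frame"))

setValidity("VariantSet", function(object) {
  v <- object@calls
  missing_cols <- setdiff(VARIANT_COLUMNS, names(v))
  if (length(missing_cols)) {
    return(paste("missing variant columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(v)) return(TRUE)
  if (any(v$depth <= 0)) return("depth must be positive")
  if (any(v$alt_count <= 0)) return("alt_count must be positive")
  if (any(abs(v$vaf - v$alt_count / v$depth) > 1e-6)) {
    return("vaf inconsistent with alt_count/depth")
  }
  if (any(v$vaf <= 0 | v$vaf > 1)) return("vaf must be in (0, 1]")
  if (!all(v$var_type %in% c("SBS", "DBS", "INDEL"))) {
    return("var_type must be SBS, DBS or INDEL")
  }
  is_sbs <- v$var_type == "SBS"
  if (any(is_sbs & (nchar(v$ref) != 1L | nchar(v$alt) != 1L))) {
    return("SBS rows must have single-base ref and alt")
  }
  is_dbs <- v$var_type == "DBS"
  if (any(is_dbs & (nchar(v$ref) != 2L | nchar(v$alt) != 2L))) {
    return("DBS rows must have dinucleotide ref and alt")
  }
  is_ind <- v$var_type == "INDEL"
  if (any(is_ind & nchar(v$ref) == nchar(v$alt))) {
    return("INDEL rows must change length")
  }
  pos_ok <- mapply(function(rp, rl) {
    p <- .parse_positions(rp)
    !length(p) || (all(p >= 1L) && all(p <= rl))
  }, v$read_positions, v$read_length)
  if (!all(pos_ok)) return("read_positions outside [1, read_length]")
  TRUE
})

#' Construct a VariantSet
#' @param calls data.frame of variant calls (canonical columns; missing
#'   optional annotation columns are filled with NA).
#' @return A \linkS4class{VariantSet}.
#' @export
VariantSet <- function(calls = emptyVariantTable()) {
  for (col in setdiff(VARIANT_COLUMNS, names(calls))) {
    calls[[col]] <- if (col %in% c("gene", "impact", "protein_change",
                                   "read_positions")) NA_character_ else NA_real_
  }
  calls <- calls[, VARIANT_COLUMNS, drop = FALSE]
  new("VariantSet", calls = calls)
}

#' Empty canonical variant table
#' @return Zero-row data.frame with the canonical columns.
#' @export
emptyVariantTable <- function() {
  data.frame(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), var_type = character(0),
    alt_count = integer(0), depth = integer(0), vaf = numeric(0),
    n_fraction = numeric(0), mean_mismatches = numeric(0),
    msi_len = integer(0), read_positions = character(0),
    read_length = integer(0), gene = character(0), impact = character(0),
    protein_change = character(0), driver_score = numeric(0),
    stringsAsFactors = FALSE
  )
}

.parse_positions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Coerce to the canonical variant data.frame
#' @param x A \linkS4class{VariantSet} or a data.frame.
#' @return data.frame of calls.
#' @export
asVariantTable <- function(x) {
  if (is(x, "VariantSet")) x@calls else as.data.frame(x)
}

#' Variant calls accessor
#' @param object A \linkS4class{VariantSet}.
#' @return data.frame of calls.
#' @export
setGeneric("variantCalls", function(object) standardGeneric("variantCalls"))

#' @rdname variantCalls
#' @export
setMethod("variantCalls", "VariantSet", function(object) object@calls)

setMethod("show", "VariantSet", function(object) {
  v <- object@calls
  cat("VariantSet with", nrow(v), "calls across",
      length(unique(v$sample_id)), "samples\n")
  if (nrow(v)) {
    cat("  types:", paste(names(table(v$var_type)),
                          table(v$var_type), sep = "=", collapse = " "), "\n")
    cat("  median VAF:", format(stats::median(v$vaf), digits = 3), "\n")
  }
})

#' Panel: sequenced intervals, gene models and reference context
#'
#' @slot intervals GRanges of merged panel intervals (1-based in memory).
#' @slot geneModels named list; each element has \code{gene}, \code{chrom},
#'   \code{start} (1-based genomic start of the CDS span), \code{end},
#'   \code{strand} ("+"/"-") and \code{cds} (coding sequence, a character
#'   string whose length is divisible by 3).
#' @slot genome DNAStringSet reference (toy or real) providing context.
#' @slot effectiveLengthMb Megabases sequenced with adequate coverage (L_Mb).
#' @export
setClass("Panel", representation(
  intervals = "GRanges",
  geneModels = "list",
  genome = "DNAStringSet",
  effectiveLengthMb = "numeric"
))

setValidity("Panel", function(object) {
  gr <- GenomicRanges::reduce(object@intervals)
  if (length(gr) != length(object@intervals)) {
    return("intervals must be non-overlapping after merge")
  }
  total_mb <- sum(GenomicRanges::width(object@intervals)) / 1e6
  if (object@effectiveLengthMb > total_mb + 1e-12) {
    return("effectiveLengthMb exceeds total interval length")
  }
  for (gm in object@geneModels) {
    if (nchar(gm$cds) %% 3L != 0L) {
      return(paste0("gene model ", gm$gene, " length not divisible by 3"))
    }
  }
  TRUE
})

#' Construct a Panel
#' @param intervals GRanges (1-based closed, in memory).
#' @param geneModels list of gene models (see \linkS4class{Panel}).
#' @param genome DNAStringSet reference.
#' @param effectiveLengthMb Effective length in Mb; defaults to the summed
#'   interval width.
#' @return A \linkS4class{Panel}.
#' @export
Panel <- function(intervals, geneModels = list(), genome = DNAStringSet(),
                  effectiveLengthMb = NULL) {
  intervals <- GenomicRanges::reduce(intervals)
  if (is.null(effectiveLengthMb)) {
    effectiveLengthMb <- sum(GenomicRanges::width(intervals)) / 1e6
  }
  new("Panel", intervals = intervals, geneModels = geneModels,
      genome = genome, effectiveLengthMb = effectiveLengthMb)
}

#' @rdname panelAccessors
#' @export
setGeneric("panelIntervals", function(object) standardGeneric("panelIntervals"))
#' Panel accessors
#' @param object A \linkS4class{Panel}.
#' @return Intervals (GRanges), gene-model list, genome (DNAStringSet) or
#'   effective length in Mb respectively.
#' @name panelAccessors
#' @export
setMethod("panelIntervals", "Panel", function(object) object@intervals)

#' @rdname panelAccessors
#' @export
setGeneric("geneModels", function(object) standardGeneric("geneModels"))
#' @rdname panelAccessors
#' @export
setMethod("geneModels", "Panel", function(object) object@geneModels)

#' @rdname panelAccessors
#' @export
setGeneric("panelGenome", function(object) standardGeneric("panelGenome"))
#' @rdname panelAccessors
#' @export
setMethod("panelGenome", "Panel", function(object) object@genome)

#' @rdname panelAccessors
#' @export
setGeneric("effectiveLengthMb", function(object) standardGeneric("effectiveLengthMb"))
#' @rdname panelAccessors
#' @export
setMethod("effectiveLengthMb", "Panel", function(object) object@effectiveLengthMb)

setMethod("show", "Panel", function(object) {
  cat("Panel:", length(object@intervals), "intervals,",
      sum(GenomicRanges::width(object@intervals)), "bp,",
      length(object@geneModels), "gene models; L_Mb =",
      format(object@effectiveLengthMb, digits = 4), "\n")
})

#' SignatureCatalog: channel-by-signature probability matrix
#'
#' @slot channelSet One of "SBS96", "DBS78", "ID83".
#' @slot profiles numeric matrix, channels x signatures; columns sum to 1.
#' @export
setClass("SignatureCatalog", representation(
  channelSet = "character",
  profiles = "matrix"
))

setValidity("SignatureCatalog", function(object) {
  m <- object@profiles
  chans <- channelNames(object@channelSet)
  if (nrow(m) != length(chans)) {
    return(sprintf("profile matrix has %d rows; %s needs %d",
                   nrow(m), object@channelSet, length(chans)))
  }
  if (any(m < 0)) return("signature probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-9)) return("signature columns must sum to 1")
  TRUE
})

#' Construct a SignatureCatalog
#' @param profiles channels x signatures matrix (columns sum to 1); rownames
#'   must match the channel set order.
#' @param channelSet Channel set of the rows.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
SignatureCatalog <- function(profiles, channelSet = "SBS96") {
  chans <- channelNames(channelSet)
  if (!is.null(rownames(profiles))) {
    profiles <- profiles[chans, , drop = FALSE]
  } else {
    rownames(profiles) <- chans
  }
  new("SignatureCatalog", channelSet = channelSet, profiles = profiles)
}

#' @rdname catalogAccessors
#' @export
setGeneric("signatureProfiles", function(object) standardGeneric("signatureProfiles"))
#' SignatureCatalog accessors
#' @param object A \linkS4class{SignatureCatalog}.
#' @return The profile matrix / signature names / channel set.
#' @name catalogAccessors
#' @export
setMethod("signatureProfiles", "SignatureCatalog", function(object) object@profiles)

#' @rdname catalogAccessors
#' @export
setGeneric("signatureNames", function(object) standardGeneric("signatureNames"))
#' @rdname catalogAccessors
#' @export
setMethod("signatureNames", "SignatureCatalog", function(object) colnames(object@profiles))

#' @rdname catalogAccessors
#' @export
setGeneric("channelSet", function(object) standardGeneric("channelSet"))
#' @rdname catalogAccessors
#' @export
setMethod("channelSet", "SignatureCatalog", function(object) object@channelSet)

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog (", object@channelSet, "): ",
      ncol(object@profiles), " signatures: ",
      paste(colnames(object@profiles), collapse = ", "), "\n", sep = "")
})

#' CoverageProfile: per-interval median duplex coverage per sample
#'
#' Coverage is stored per merged panel interval per sample; blacklisted sites
#' report zero through \link{coverageAt}.
#'
#' @slot table data.frame with sample_id, chrom, start, end (1-based closed),
#'   coverage.
#' @slot blacklist GRanges of blacklisted sites (coverage forced to 0).
#' @export
setClass("CoverageProfile", representation(
  table = "data.frame",
  blacklist = "GRanges"
))

setValidity("CoverageProfile", function(object) {
  if (nrow(object@table) && any(object@table$coverage < 0)) {
    return("coverage must be non-negative")
  }
  TRUE
})

#' Construct a CoverageProfile
#' @param table data.frame with sample_id, chrom, start, end, coverage.
#' @param blacklist GRanges of blacklisted sites (optional).
#' @return A \linkS4class{CoverageProfile}.
#' @export
CoverageProfile <- function(table, blacklist = GRanges()) {
  new("CoverageProfile", table = table, blacklist = blacklist)
}

#' Coverage lookup
#'
#' @param object A \linkS4class{CoverageProfile}.
#' @param sample_id Sample identifier.
#' @param chrom,pos Vectors of 1-based genomic coordinates.
#' @return Numeric coverage; blacklisted positions return 0.
#' @export
coverageAt <- function(object, sample_id, chrom, pos) {
  tab <- object@table[object@table$sample_id == sample_id, , drop = FALSE]
  out <- numeric(length(pos))
  if (nrow(tab) && length(pos)) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    subj <- GenomicRanges::GRanges(tab$chrom,
                                   IRanges::IRanges(tab$start, tab$end))
    ov <- GenomicRanges::findOverlaps(q, subj, select = "first")
    hit <- !is.na(ov)
    out[hit] <- tab$coverage[ov[hit]]
  }
  if (length(object@blacklist)) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hits <- IRanges::overlapsAny(q, object@blacklist)
    out[hits] <- 0
  }
  out
}

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile:", length(unique(object@table$sample_id)), "samples,",
      nrow(object@table), "intervals,", length(object@blacklist),
      "blacklisted ranges\n")
})
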