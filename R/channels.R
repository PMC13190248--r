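## Mutation channel catalogues and classifiers (COSMIC conventions):
## SBS-96 pyrimidine-centred substitution classes, strand-specific SBS-192
## classes used for selection, DBS-78 doublet classes and ID-83 indel classes.

BASES <- c("A", "C", "G", "T")

.comp <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(x) {
  # vectorised reverse complement for short plain-character DNA strings
  comp <- chartr("ACGT", "TGCA", x)
  n <- nchar(comp)
  if (all(n == 1L)) return(comp)
  if (all(n == 2L)) {
    return(paste0(substr(comp, 2, 2), substr(comp, 1, 1)))
  }
  if (all(n == 3L)) {
    return(paste0(substr(comp, 3, 3), substr(comp, 2, 2), substr(comp, 1, 1)))
  }
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

#' SBS-96 channel names
#'
#' Pyrimidine-centred single-base-substitution classes in the standard order:
#' six substitution types (C>A, C>G, C>T, T>A, T>C, T>G), within each the 16
#' flanking-base combinations sorted A, C, G, T on either side. Names look
#' like \code{"A[C>T]G"}.
#'
#' @return Character vector of length 96.
#' @export
sbs96Channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (p5 in BASES) for (p3 in BASES) {
      out <- c(out, paste0(p5, "[", s, "]", p3))
    }
  }
  out
}

#' SBS-192 strand-specific channel names
#'
#' All 64 reference trinucleotides (no pyrimidine collapsing; read on the
#' coding strand) times the three possible alternate bases of the central
#' position, named \code{"ACA>T"} (trinucleotide, then alt). Used for the
#' coverage-adjusted selection opportunity matrix.
#'
#' @return Character vector of length 192.
#' @export
sbs192Channels <- function() {
  out <- character(0)
  for (p5 in BASES) for (ref in BASES) for (p3 in BASES) {
    for (alt in setdiff(BASES, ref)) {
      out <- c(out, paste0(p5, ref, p3, ">", alt))
    }
  }
  out
}

#' DBS-78 channel names
#'
#' Canonical doublet-substitution classes: ten canonical reference dinucleotides
#' (AC, AT, CC, CG, CT, GC, TA, TC, TG, TT); alternates exclude matches at
#' either position, and for reverse-complement-palindromic references (AT, CG,
#' GC, TA) alternates are collapsed with their reverse complements.
#'
#' @return Character vector of length 78 with names like \code{"CC>TT"}.
#' @export
dbs78Channels <- function() {
  canon_refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  palindromic <- c("AT", "CG", "GC", "TA")
  out <- character(0)
  for (ref in canon_refs) {
    r1 <- substr(ref, 1, 1); r2 <- substr(ref, 2, 2)
    alts <- character(0)
    for (a1 in setdiff(BASES, r1)) for (a2 in setdiff(BASES, r2)) {
      alt <- paste0(a1, a2)
      if (ref %in% palindromic) {
        rc <- .revcomp(alt)
        alt <- if (rc < alt) rc else alt
      }
      alts <- c(alts, alt)
    }
    out <- c(out, paste0(ref, ">", unique(sort(alts))))
  }
  out
}

#' ID-83 channel names
#'
#' Standard indel classes: 1-bp deletions and insertions at C/T homopolymers
#' stratified by the number of additional repeat copies (0..5+), longer
#' deletions/insertions at repeats (length 2..5+, repeat copies 0..5+), and
#' microhomology deletions. Names follow the
#' \code{"<len>:<Del|Ins>:<C|T|R|M>:<n>"} convention.
#'
#' @return Character vector of length 83.
#' @export
id83Channels <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Del:R:", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Ins:R:", 0:5))
  out <- c(out, "2:Del:M:1",
           paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3),
           paste0("5:Del:M:", 1:5))
  out
}

#' Channel names for a channel set
#' @param channelSet One of \code{"SBS96"}, \code{"SBS192"}, \code{"DBS78"},
#'   \code{"ID83"}.
#' @return Character vector of channel names.
#' @export
channelNames <- function(channelSet) {
  switch(channelSet,
         SBS96  = sbs96Channels(),
         SBS192 = sbs192Channels(),
         DBS78  = dbs78Channels(),
         ID83   = id83Channels(),
         stop("unknown channel set: ", channelSet))
}

.check_bases <- function(x, what) {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop("ambiguous or non-ACGT base in ", what, ": ",
         paste(unique(x[bad]), collapse = ", "))
  }
}

#' Classify single-base substitutions into SBS-96 channels
#'
#' @param ref,alt Single reference/alternate bases.
#' @param context Trinucleotide with the mutated base in the middle; the
#'   strand is irrelevant (purine-centred contexts are reverse-complemented).
#' @return Character vector of SBS-96 channel names.
#' @export
channelizeSBS96 <- function(ref, alt, context) {
  .check_bases(ref, "ref"); .check_bases(alt, "alt"); .check_bases(context, "context")
  if (any(nchar(context) != 3L)) stop("context must be a trinucleotide")
  if (any(substr(context, 2, 2) != ref)) {
    stop("context centre does not match ref")
  }
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    context[flip] <- .revcomp(context[flip])
    ref[flip] <- unname(.comp[ref[flip]])
    alt[flip] <- unname(.comp[alt[flip]])
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

#' Classify single-base substitutions into strand-specific SBS-192 channels
#'
#' @param ref,alt Single bases on the coding strand.
#' @param context Coding-strand trinucleotide centred on the mutated base.
#' @return Character vector of SBS-192 channel names (\code{"ACA>T"}).
#' @export
channelizeSBS192 <- function(ref, alt, context) {
  .check_bases(ref, "ref"); .check_bases(alt, "alt"); .check_bases(context, "context")
  if (any(substr(context, 2, 2) != ref)) stop("context centre does not match ref")
  paste0(context, ">", alt)
}

#' Classify doublet substitutions into DBS-78 channels
#'
#' @param ref,alt Reference and alternate dinucleotides.
#' @return Character vector of DBS-78 channel names.
#' @export
channelizeDBS78 <- function(ref, alt) {
  .check_bases(ref, "ref"); .check_bases(alt, "alt")
  if (any(nchar(ref) != 2L | nchar(alt) != 2L)) stop("DBS requires dinucleotides")
  if (any(substr(ref, 1, 1) == substr(alt, 1, 1) |
          substr(ref, 2, 2) == substr(alt, 2, 2))) {
    stop("DBS alt must differ from ref at both positions")
  }
  canon_refs <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  palindromic <- c("AT", "CG", "GC", "TA")
  flip <- !(ref %in% canon_refs)
  if (any(flip)) {
    ref[flip] <- .revcomp(ref[flip])
    alt[flip] <- .revcomp(alt[flip])
  }
  pal <- ref %in% palindromic
  if (any(pal)) {
    rc <- .revcomp(alt[pal])
    alt[pal] <- ifelse(rc < alt[pal], rc, alt[pal])
  }
  paste0(ref, ">", alt)
}

## Longest run of `motif` repeats in `seq` starting at position 1.
.count_repeats <- function(seq, motif) {
  k <- nchar(motif)
  n <- 0L
  while (substr(seq, n * k + 1L, (n + 1L) * k) == motif) n <- n + 1L
  n
}

## Longest shared prefix length of two strings.
.shared_prefix <- function(a, b) {
  m <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < m && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L)) i <- i + 1L
  i
}

.shared_suffix <- function(a, b) {
  ra <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  rb <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
  .shared_prefix(ra, rb)
}

#' Classify an indel into its ID-83 channel
#'
#' Implements the standard decision tree: 1-bp events at C/T homopolymers
#' (G/A events are complemented) stratified by additional repeat copies;
#' longer events classified as repeat-mediated when at least one additional
#' copy of the indel motif flanks the site, as microhomology deletions when
#' partial flanking homology exists, and as non-repeat otherwise.
#'
#' @param indel_seq Inserted or deleted sequence (no anchor base).
#' @param is_deletion Logical.
#' @param flank5,flank3 Reference sequence immediately before/after the
#'   affected reference span (for insertions, before/after the insertion
#'   point). At least 25 bp of 3' flank is recommended.
#' @return ID-83 channel name.
#' @export
channelizeID83 <- function(indel_seq, is_deletion, flank5, flank3) {
  .check_bases(indel_seq, "indel sequence")
  len <- nchar(indel_seq)
  kind <- if (is_deletion) "Del" else "Ins"
  if (len == 1L) {
    b <- indel_seq
    if (b %in% c("A", "G")) {
      # complement so the class is pyrimidine-labelled; flanks flip strand
      b <- unname(.comp[b])
      tmp <- .revcomp(flank5); flank5 <- .revcomp(flank3); flank3 <- tmp
    }
    reps <- .count_repeats(flank3, b) + .count_repeats(.revcomp_keep(flank5), b)
    return(paste0("1:", kind, ":", b, ":", min(reps, 5L)))
  }
  lcat <- min(len, 5L)
  reps <- .count_repeats(flank3, indel_seq) +
    .count_repeats_backward(flank5, indel_seq)
  if (reps >= 1L) return(paste0(lcat, ":", kind, ":R:", min(reps, 5L)))
  if (is_deletion) {
    mh <- max(.shared_prefix(indel_seq, flank3), .shared_suffix(indel_seq, flank5))
    if (mh >= 1L) {
      return(paste0(lcat, ":Del:M:", min(mh, len - 1L, 5L)))
    }
  }
  paste0(lcat, ":", kind, ":R:0")
}

## Reverse (not complement) a string: used to scan the 5' flank outward.
.revcomp_keep <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(b), collapse = ""), character(1))
}

## Count copies of `motif` ending exactly at the end of `flank5`.
.count_repeats_backward <- function(flank5, motif) {
  k <- nchar(motif)
  n <- 0L
  L <- nchar(flank5)
  while (L - (n + 1L) * k + 1L >= 1L &&
         substr(flank5, L - (n + 1L) * k + 1L, L - n * k) == motif) {
    n <- n + 1L
  }
  n
}

#' Channelize a variant table
#'
#' Adds SBS-96 (and, where a gene model applies, strand-specific SBS-192),
#' DBS-78 and ID-83 channel columns to a variant table, using the panel's
#' reference genome for flanking context.
#'
#' @param variants Variant table (\code{data.frame} or \link{VariantSet}).
#' @param panel A \link{Panel}.
#' @return The variant table with a \code{channel} column (per-type channel
#'   name) and a \code{channel_set} column.
#' @export
channelizeVariants <- function(variants, panel) {
  v <- asVariantTable(variants)
  genome <- panelGenome(panel)
  n <- nrow(v)
  v$channel <- NA_character_
  v$channel_set <- NA_character_
  if (n == 0L) return(v)
  seqs <- lapply(genome, as.character)
  # SBS and DBS channelization is fully vectorised; indels take the per-row
  # decision tree
  is_sbs <- v$var_type == "SBS"
  if (any(is_sbs)) {
    for (ch in unique(v$chrom[is_sbs])) {
      sel <- which(is_sbs & v$chrom == ch)
      ctx <- substring(seqs[[ch]], v$pos[sel] - 1L, v$pos[sel] + 1L)
      v$channel[sel] <- channelizeSBS96(v$ref[sel], v$alt[sel], ctx)
      v$channel_set[sel] <- "SBS96"
    }
  }
  is_dbs <- v$var_type == "DBS"
  if (any(is_dbs)) {
    v$channel[is_dbs] <- channelizeDBS78(v$ref[is_dbs], v$alt[is_dbs])
    v$channel_set[is_dbs] <- "DBS78"
  }
  for (i in which(v$var_type == "INDEL")) {
    ref <- v$ref[i]; alt <- v$alt[i]
    chrom <- v$chrom[i]; pos <- v$pos[i]
    {
      # VCF-style anchored representation: ref/alt share first base
      if (nchar(ref) > nchar(alt)) {
        del <- substr(ref, nchar(alt) + 1L, nchar(ref))
        s <- seqs[[chrom]]
        start3 <- pos + nchar(ref)
        f3 <- substr(s, start3, min(nchar(s), start3 + 29L))
        f5 <- substr(s, max(1L, pos - 29L), pos)
        v$channel[i] <- channelizeID83(del, TRUE, f5, f3)
      } else {
        ins <- substr(alt, nchar(ref) + 1L, nchar(alt))
        s <- seqs[[chrom]]
        start3 <- pos + nchar(ref)
        f3 <- substr(s, start3, min(nchar(s), start3 + 29L))
        f5 <- substr(s, max(1L, pos - 29L), pos)
        v$channel[i] <- channelizeID83(ins, FALSE, f5, f3)
      }
      v$channel_set[i] <- "ID83"
    }
  }
  v
}

#' Count channelized mutations into a channel-set vector
#'
#' @param variants Variant table with \code{channel}/\code{channel_set}
#'   columns (see \link{channelizeVariants}).
#' @param channelSet Channel set to tabulate.
#' @return Named integer vector over the full channel catalogue.
#' @export
countChannels <- function(variants, channelSet = "SBS96") {
  v <- asVariantTable(variants)
  chans <- channelNames(channelSet)
  counts <- integer(length(chans))
  names(counts) <- chans
  if (!nrow(v)) return(counts)
  keep <- !is.na(v$channel_set) & v$channel_set == channelSet
  tab <- table(v$channel[keep])
  counts[names(tab)] <- as.integer(tab)
  counts
}
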