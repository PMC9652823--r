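#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet subseq
#'   reverseComplement letterFrequency
NULL

CANONICAL_MOTIFS <- c("GT-AG", "GC-AG", "AT-AC")

#' Parse a GTF annotation into transcript models
#'
#' Reads exon features from a GENCODE-dialect GTF (1-based closed
#' coordinates), converts to the internal 0-based half-open convention, and
#' derives each transcript's introns as the sorted gaps between consecutive
#' exons.  Single-exon transcripts yield zero introns.
#'
#' @param path path to a GTF file, or a character vector of GTF lines when
#'   `text = TRUE`.
#' @param text logical; treat `path` as GTF text lines.
#' @return a `transcript_set`: list with elements
#'   \describe{
#'     \item{transcripts}{one row per transcript: `transcript_id`, `gene_id`,
#'       `chrom`, `strand`, `start`, `end`, `tx_length` (sum of exon widths),
#'       `n_exons`, `n_introns`.}
#'     \item{exons}{per-transcript exons, sorted by genomic coordinate, with
#'       `exon_rank` in genomic order.}
#'     \item{introns}{per-transcript introns with genomic `rank` and
#'       strand-aware `rank_tx` (1 = transcript 5' end).}
#'     \item{index}{an [exon_index()] over all exons.}
#'   }
#' @export
parse_annotation <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(build_transcript_set(
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character(), transcript_id = character(),
                 gene_id = character())))
  }
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fields) < 9)
    stop("malformed GTF: fewer than 9 tab-separated fields at line ",
         lineno[1])
  short <- is.na(fields[[9]])
  if (any(short))
    stop("malformed GTF: fewer than 9 tab-separated fields at line ",
         lineno[which(short)[1]])
  feature <- fields[[3]]
  ex <- which(feature == "exon")
  if (!length(ex)) {
    return(build_transcript_set(
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character(), transcript_id = character(),
                 gene_id = character())))
  }
  attr_str <- fields[[9]][ex]
  tx <- gtf_attribute(attr_str, "transcript_id")
  gid <- gtf_attribute(attr_str, "gene_id")
  if (anyNA(tx))
    stop("malformed GTF: exon feature without transcript_id attribute at line ",
         lineno[ex[which(is.na(tx))[1]]])
  if (anyNA(gid))
    stop("malformed GTF: exon feature without gene_id attribute at line ",
         lineno[ex[which(is.na(gid))[1]]])
  start1 <- suppressWarnings(as.integer(fields[[4]][ex]))
  end1 <- suppressWarnings(as.integer(fields[[5]][ex]))
  if (anyNA(start1) || anyNA(end1))
    stop("malformed GTF: non-numeric coordinate at line ",
         lineno[ex[which(is.na(start1) | is.na(end1))[1]]])
  exons <- data.table(
    chrom = fields[[1]][ex],
    start = start1 - 1L,            # 1-based closed -> 0-based half-open
    end = end1,
    strand = fields[[7]][ex],
    transcript_id = tx,
    gene_id = gid)
  build_transcript_set(exons)
}

gtf_attribute <- function(attrs, key) {
  pat <- paste0('(^|; ?)', key, ' "([^"]*)"')
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs)
  out[hit] <- sub(pat, "\\2", regmatches(attrs, regexpr(pat, attrs)))
  out
}

#' Build a transcript set from an exon table
#'
#' The programmatic counterpart of [parse_annotation()]: takes exons already
#' in the internal 0-based half-open convention and derives transcripts,
#' introns and the exon overlap index.
#'
#' @param exons data.table with `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`.
#' @return a `transcript_set`.
#' @export
build_transcript_set <- function(exons) {
  exons <- validate_intervals(exons, "exon table")
  setorder(exons, transcript_id, start)
  if (nrow(exons)) {
    exons[, exon_rank := seq_len(.N), by = transcript_id]
    bad <- exons[, any(start[-1] < end[-.N]), by = transcript_id][V1 == TRUE]
    if (nrow(bad))
      stop("overlapping exons within transcript ", bad$transcript_id[1])
  } else {
    exons[, exon_rank := integer()]
  }
  if (nrow(exons)) {
    transcripts <- exons[, list(
      gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
      start = min(start), end = max(end),
      tx_length = sum(end - start), n_exons = .N), by = transcript_id]
  } else {
    transcripts <- data.table(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), start = integer(),
      end = integer(), tx_length = integer(), n_exons = integer())
  }
  transcripts[, n_introns := n_exons - 1L]
  introns <- exons[, if (.N > 1L) list(
    gene_id = gene_id[1], chrom = chrom[1],
    start = end[-.N], end = start[-1], strand = strand[1]),
    by = transcript_id]
  if (!nrow(introns))
    introns <- data.table(transcript_id = character(), gene_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character())
  setorder(introns, transcript_id, start)
  if (nrow(introns)) {
    introns[, rank := seq_len(.N), by = transcript_id]
    introns[, rank_tx := ifelse(strand == "+", rank, .N + 1L - rank),
            by = transcript_id]
  } else {
    introns[, `:=`(rank = integer(), rank_tx = integer())]
  }
  structure(list(transcripts = transcripts, exons = exons, introns = introns,
                 index = exon_index(exons)),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  invisible(x)
}

#' Write transcript models back to GTF
#'
#' Emits one exon feature per exon in 1-based closed coordinates (the inverse
#' of [parse_annotation()]), so that a parse/write/parse round trip reproduces
#' identical intron sets.
#'
#' @param tx_set a `transcript_set`.
#' @param path output path; when `NULL` the GTF lines are returned.
#' @export
write_gtf <- function(tx_set, path = NULL) {
  e <- tx_set$exons
  lines <- sprintf(
    '%s\tripbench\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    e$chrom, e$start + 1L, e$end, e$strand, e$gene_id, e$transcript_id)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return named `DNAStringSet` (names truncated at first whitespace, the
#'   convention used by aligners for chromosome names).
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

genome_chrom <- function(genome, chrom) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  genome[[chrom]]
}

#' Splice-site motif of an intron
#'
#' Reads the donor and acceptor dinucleotides 5' to 3' on the transcript
#' strand (reverse complement for minus-strand introns) and classifies the
#' pair as one of the canonical motifs `GT-AG`, `GC-AG`, `AT-AC`, or
#' `"other"`.  Comparison is case-insensitive.
#'
#' @param genome named `DNAStringSet`.
#' @param chrom,start,end intron interval, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return motif label.
#' @export
splice_motif <- function(genome, chrom, start, end, strand) {
  seq <- genome_chrom(genome, chrom)
  if (start < 0 || end > length(seq))
    stop("intron [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", length(seq), ")")
  if (end - start < 4L) return("other")
  left <- toupper(as.character(Biostrings::subseq(seq, start + 1L, start + 2L)))
  right <- toupper(as.character(Biostrings::subseq(seq, end - 1L, end)))
  if (strand == "+") {
    donor <- left; acceptor <- right
  } else {
    donor <- revcomp(right); acceptor <- revcomp(left)
  }
  motif <- paste0(donor, "-", acceptor)
  if (motif %in% CANONICAL_MOTIFS) motif else "other"
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' GC fraction of an interval
#'
#' (#G + #C) / length, case-insensitive; ambiguous bases (e.g. N) count as
#' non-GC.
#'
#' @inheritParams splice_motif
#' @return fraction in `[0, 1]`.
#' @export
gc_fraction <- function(genome, chrom, start, end) {
  if (end <= start) stop("empty interval [", start, ",", end, ")")
  seq <- genome_chrom(genome, chrom)
  if (start < 0 || end > length(seq))
    stop("interval [", start, ",", end, ") out of bounds for ", chrom)
  sub <- Biostrings::subseq(seq, start + 1L, end)
  gc <- sum(Biostrings::letterFrequency(sub, c("G", "C")))
  gc / (end - start)
}

#' Relative position of an intron along its transcript
#'
#' Intron-count-normalized fraction where 0 is the transcript's 5' end and 1
#' the 3' end: `(rank - 1) / (n_introns - 1)` for two or more introns.
#' Single-intron transcripts return 0.5 (no orientation information exists in
#' a one-point scale).  `rank` must already be counted in transcript
#' orientation (see `rank_tx` from [parse_annotation()]).
#'
#' @param rank 1-based intron rank, 5' to 3' on the transcript.
#' @param n_introns number of introns in the transcript.
#' @return value in `[0, 1]`.
#' @export
relative_position <- function(rank, n_introns) {
  if (any(rank < 1L | rank > n_introns))
    stop("intron rank out of range 1..n_introns")
  n <- rep_len(n_introns, max(length(rank), length(n_introns)))
  r <- rep_len(rank, length(n))
  ifelse(n == 1L, 0.5, (r - 1) / (n - 1))
}

#' Exon overlap statistics for an intron
#'
#' Counts annotated exons from *other* transcripts (any transcript id
#' different from `own_transcript`, including same-gene isoforms) that
#' overlap the intron: the total number of such exons, the percent of intron
#' bases with at least one overlapping exon, and the maximum number of exons
#' stacked on a single base.
#'
#' @param chrom,start,end intron interval, 0-based half-open.
#' @param index an [exon_index()].
#' @param own_transcript transcript id whose exons are excluded.
#' @return list with `n_overlapping_exons`, `pct_bases_overlapped`,
#'   `max_overlap_depth`.
#' @export
exon_overlap_stats <- function(chrom, start, end, index, own_transcript) {
  hits <- query_exons(index, chrom, start, end)
  hits <- hits[transcript_id != own_transcript]
  if (!nrow(hits))
    return(list(n_overlapping_exons = 0L, pct_bases_overlapped = 0,
                max_overlap_depth = 0L))
  len <- end - start
  rel <- IRanges::IRanges(start = pmax(hits$start, start) - start + 1L,
                          end = pmin(hits$end, end) - start)
  cov <- IRanges::coverage(rel, width = len)
  covered <- sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) > 0L])
  list(n_overlapping_exons = nrow(hits),
       pct_bases_overlapped = 100 * covered / len,
       max_overlap_depth = max(S4Vectors::runValue(cov)))
}

#' Read a BED file of intervals
#'
#' 0-based half-open, first three columns used; no conversion needed for the
#' internal convention.
#'
#' @param path BED path.
#' @return data.table with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  bed <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  setnames(bed, seq_len(min(3L, ncol(bed))), c("chrom", "start", "end")[seq_len(min(3L, ncol(bed)))])
  bed[, list(chrom, start = as.integer(start), end = as.integer(end))]
}

#' Spliceosome class of an intron
#'
#' Labels the intron `"U2"` or `"U12"` if it overlaps ranges from exactly one
#' of the two spliceosome annotation sets; introns overlapping both sets or
#' neither are `"other"`.
#'
#' @param chrom,start,end intron interval, 0-based half-open.
#' @param u2,u12 interval tables (`chrom`, `start`, `end`), e.g. from
#'   [read_bed()].
#' @return one of `"U2"`, `"U12"`, `"other"`.
#' @export
spliceosome_class <- function(chrom, start, end, u2, u12) {
  hit <- function(bed) {
    if (is.null(bed) || !nrow(bed)) return(FALSE)
    b <- as.data.frame(bed)[bed$chrom == chrom, , drop = FALSE]
    any(overlap_width(b$start, b$end, start, end) > 0L)
  }
  in_u2 <- hit(u2); in_u12 <- hit(u12)
  if (in_u2 && !in_u12) "U2" else if (in_u12 && !in_u2) "U12" else "other"
}

#' Intron feature table
#'
#' Computes, for every intron of every transcript in the set, the properties
#' analyzed downstream: length, GC fraction, relative transcript position,
#' exon overlap statistics, splice motif and spliceosome class.
#'
#' @param tx_set a `transcript_set`.
#' @param genome named `DNAStringSet` (`NULL` skips motif/GC columns).
#' @param u2,u12 optional interval tables of minor/major spliceosome introns.
#' @return data.table with one row per transcript intron: `chrom`, `start`,
#'   `end`, `strand`, `gene_id`, `transcript_id`, `rank` (transcript
#'   orientation), `length`, `gc_fraction`, `relative_position`,
#'   `n_overlapping_exons`, `pct_bases_overlapped`, `max_overlap_depth`,
#'   `motif`, `spliceosome`.
#' @export
annotate_introns <- function(tx_set, genome = NULL, u2 = NULL, u12 = NULL) {
  ii <- copy(tx_set$introns)
  if (!nrow(ii)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      transcript_id = character(), rank = integer(),
                      length = integer(), gc_fraction = numeric(),
                      relative_position = numeric(),
                      n_overlapping_exons = integer(),
                      pct_bases_overlapped = numeric(),
                      max_overlap_depth = integer(), motif = character(),
                      spliceosome = character()))
  }
  ii[, length := end - start]
  ii[, n_in_tx := .N, by = transcript_id]
  ii[, relative_position := relative_position(rank_tx, n_in_tx[1]),
     by = transcript_id]
  ov <- mapply(exon_overlap_stats, ii$chrom, ii$start, ii$end,
               MoreArgs = list(index = tx_set$index),
               own_transcript = ii$transcript_id, SIMPLIFY = FALSE)
  ii[, n_overlapping_exons := vapply(ov, `[[`, integer(1), "n_overlapping_exons")]
  ii[, pct_bases_overlapped := vapply(ov, `[[`, numeric(1), "pct_bases_overlapped")]
  ii[, max_overlap_depth := vapply(ov, `[[`, integer(1), "max_overlap_depth")]
  if (!is.null(genome)) {
    ii[, motif := mapply(splice_motif, chrom, start, end, strand,
                         MoreArgs = list(genome = genome))]
    ii[, gc_fraction := mapply(gc_fraction, chrom, start, end,
                               MoreArgs = list(genome = genome))]
  } else {
    ii[, motif := NA_character_]
    ii[, gc_fraction := NA_real_]
  }
  ii[, spliceosome := mapply(spliceosome_class, chrom, start, end,
                             MoreArgs = list(u2 = u2, u12 = u12))]
  ii[, list(chrom, start, end, strand, gene_id, transcript_id, rank = rank_tx,
            length, gc_fraction, relative_position, n_overlapping_exons,
            pct_bases_overlapped, max_overlap_depth, motif, spliceosome)]
}
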