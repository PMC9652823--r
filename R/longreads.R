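# Long-read spliced alignments -> per-transcript retention matrices.
#
# A read's intron chain is the set of skip gaps (CIGAR N) of its spliced
# alignment, in reference coordinates.  Chains are carried as a compact
# string "start-end,start-end" (0-based half-open, sorted by start) so that
# exact set matching is a string comparison.

STATE_UNCOVERED <- 0L
STATE_RETAINED <- 1L
STATE_SPLICED <- 2L

chain_format <- function(start, end) {
  if (!length(start)) return("")
  o <- order(start)
  paste(paste0(start[o], "-", end[o]), collapse = ",")
}

chain_parse <- function(chain) {
  if (is.na(chain) || !nzchar(chain))
    return(data.table(start = integer(), end = integer()))
  parts <- strsplit(chain, ",", fixed = TRUE)[[1]]
  se <- data.table::tstrsplit(parts, "-", fixed = TRUE)
  data.table(start = as.integer(se[[1]]), end = as.integer(se[[2]]))
}

#' Extract the intron chain from a spliced alignment
#'
#' Walks a CIGAR string: skip gaps (`N`) become chain intervals in reference
#' coordinates; matches/mismatches (`M`, `=`, `X`) and deletions (`D`)
#' advance the reference without creating chain intervals; insertions and
#' clips do not advance the reference.
#'
#' @param pos 0-based reference start of the alignment.
#' @param cigar CIGAR string.
#' @return list with `span_start`, `span_end` (aligned reference span) and
#'   `chain` (data.table of `start`, `end`).
#' @export
extract_intron_chain <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) stop("unparseable CIGAR: ", cigar)
  len <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  ref_consume <- op %in% c("M", "D", "N", "=", "X")
  at <- pos
  starts <- integer(); ends <- integer()
  for (k in seq_along(op)) {
    if (op[k] == "N") {
      starts <- c(starts, at); ends <- c(ends, at + len[k])
    }
    if (ref_consume[k]) at <- at + len[k]
  }
  list(span_start = pos, span_end = at,
       chain = data.table(start = starts, end = ends))
}

#' Read long-read alignments from a plain-text table
#'
#' Fixture format: TSV with columns `read_id`, `chrom`, `strand`,
#' `span_start`, `span_end`, `introns` (comma-separated `start-end` pairs,
#' empty for an unspliced read).  All coordinates 0-based half-open.
#'
#' @param path TSV path.
#' @return data.table of long reads with a `chain` string column.
#' @export
read_long_reads_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = "introns"))
  setnames(dt, "introns", "chain")
  dt[is.na(chain), chain := ""]
  dt[, chain := vapply(chain, function(ch) {
    p <- chain_parse(ch); chain_format(p$start, p$end)
  }, character(1))]
  dt[, list(read_id, chrom, strand, span_start = as.integer(span_start),
            span_end = as.integer(span_end), chain)]
}

#' Read long-read alignments from SAM text
#'
#' Keeps primary mapped alignments only (FLAG bits 0x4, 0x100, 0x800 all
#' unset); secondary/supplementary and unmapped records are counted and
#' reported in a message.  Transcript strand is taken from an `XS:A` tag when
#' present, else from the alignment orientation (FLAG 0x10).
#'
#' @param path SAM path.
#' @return data.table as in [read_long_reads_tsv()].
#' @export
read_long_reads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table(read_id = character(), chrom = character(),
                      strand = character(), span_start = integer(),
                      span_end = integer(), chain = character()))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  flag <- as.integer(f[[2]])
  drop <- bitwAnd(flag, 0x4L) != 0L | bitwAnd(flag, 0x100L) != 0L |
    bitwAnd(flag, 0x800L) != 0L
  if (any(drop))
    message(sum(drop), " unmapped/secondary/supplementary record(s) skipped")
  keep <- which(!drop)
  xs <- rep(NA_character_, length(lines))
  m <- regexpr("XS:A:[+-]", lines)
  xs[m > 0] <- substring(regmatches(lines, m), 6, 6)
  out <- data.table(
    read_id = f[[1]][keep],
    chrom = f[[3]][keep],
    strand = ifelse(!is.na(xs[keep]), xs[keep],
                    ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+")),
    pos = as.integer(f[[4]][keep]) - 1L,
    cigar = f[[6]][keep])
  walked <- mapply(extract_intron_chain, out$pos, out$cigar, SIMPLIFY = FALSE)
  out[, span_start := vapply(walked, `[[`, numeric(1), "span_start")]
  out[, span_end := vapply(walked, `[[`, numeric(1), "span_end")]
  out[, chain := vapply(walked, function(w) chain_format(w$chain$start, w$chain$end),
                        character(1))]
  out[, list(read_id, chrom, strand, span_start = as.integer(span_start),
             span_end = as.integer(span_end), chain)]
}

#' Read long-read alignments from BAM
#'
#' Uses `GenomicAlignments` junction extraction; equivalent to the SAM text
#' route and cross-checked against it in the test suite.
#'
#' @param path BAM path (indexed or not).
#' @return data.table as in [read_long_reads_tsv()].
#' @export
read_long_reads_bam <- function(path) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag"), tag = "XS")
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  jx <- GenomicAlignments::junctions(ga)
  chain <- vapply(seq_along(jx), function(k) {
    r <- jx[[k]]
    chain_format(BiocGenerics::start(r) - 1L, BiocGenerics::end(r))
  }, character(1))
  xs <- S4Vectors::mcols(ga)$XS
  data.table(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = ifelse(!is.na(xs), as.character(xs),
                    as.character(BiocGenerics::strand(ga))),
    span_start = BiocGenerics::start(ga) - 1L,
    span_end = BiocGenerics::end(ga),
    chain = chain)
}

#' Pick the best-matching transcript among candidates
#'
#' Minimizes the absolute difference between transcript exonic length and the
#' read's exonic footprint (aligned span minus total skip-gap length).  Ties
#' are broken by lexicographically smallest transcript id, for determinism.
#'
#' @param read_length read exonic footprint in bases.
#' @param candidates data.table with `transcript_id`, `tx_length`.
#' @return the chosen transcript id.
#' @export
select_best_transcript <- function(read_length, candidates) {
  stopifnot(nrow(candidates) >= 1L)
  d <- abs(candidates$tx_length - read_length)
  best <- candidates$transcript_id[d == min(d)]
  sort(best)[1]
}

#' Classify a read's span against its transcript
#'
#' `full_length` iff the aligned span encompasses every intron of the
#' transcript (span start at or before the first intron start and span end at
#' or after the last intron end); `partial` otherwise.  Intronless
#' transcripts are vacuously `full_length`.
#'
#' @param span_start,span_end aligned span, 0-based half-open.
#' @param tx_introns data.table of the transcript's introns (`start`, `end`).
#' @return `"full_length"` or `"partial"`.
#' @export
classify_span <- function(span_start, span_end, tx_introns) {
  if (!nrow(tx_introns)) return("full_length")
  if (span_start <= min(tx_introns$start) && span_end >= max(tx_introns$end))
    "full_length" else "partial"
}

#' Assign long reads to best-match transcripts
#'
#' For each read, candidate transcripts share chromosome and strand.  If any
#' transcript's intron set exactly equals the read's chain, those are the
#' candidates (`all_introns`); otherwise transcripts whose intron sets
#' contain the chain as a subset are candidates (`skipped_splicing`); a read
#' whose chain holds an interval absent from every transcript is discarded.
#' Among candidates the best match minimizes |transcript length - read
#' length| (see [select_best_transcript()]).
#'
#' @param reads long-read table (see [read_long_reads_tsv()]).
#' @param tx_set a `transcript_set`.
#' @return data.table: `read_id`, `transcript_id`, `match_class`,
#'   `span_class`; discarded reads are absent.
#' @export
assign_reads <- function(reads, tx_set) {
  tx <- tx_set$transcripts
  introns <- tx_set$introns
  tx_chain <- introns[, list(chain = chain_format(start, end)), by = transcript_id]
  tx <- merge(tx, tx_chain, by = "transcript_id", all.x = TRUE)
  tx[is.na(chain), chain := ""]
  tx[, group := paste(chrom, strand)]
  # per chromosome/strand: map each intron element -> transcripts containing it
  groups <- split(tx, by = "group")
  elem_maps <- lapply(groups, function(g) {
    el <- lapply(strsplit(g$chain, ",", fixed = TRUE), function(x) x[nzchar(x)])
    map <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(g))) {
      for (e in el[[k]]) {
        assign(e, c(get0(e, envir = map, ifnotfound = character()),
                    g$transcript_id[k]), envir = map)
      }
    }
    exact <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(g))) {
      key <- if (nzchar(g$chain[k])) g$chain[k] else ".empty"
      assign(key, c(get0(key, envir = exact, ifnotfound = character()),
                    g$transcript_id[k]), envir = exact)
    }
    list(table = g, elems = map, exact = exact)
  })
  reads <- as.data.table(reads)
  setorder(reads, read_id)
  res <- vector("list", nrow(reads))
  tx_len <- stats::setNames(tx$tx_length, tx$transcript_id)
  for (k in seq_len(nrow(reads))) {
    grp <- elem_maps[[paste(reads$chrom[k], reads$strand[k])]]
    if (is.null(grp)) next
    ch <- reads$chain[k]
    elems <- if (nzchar(ch)) strsplit(ch, ",", fixed = TRUE)[[1]] else character()
    exact_ids <- get0(if (nzchar(ch)) ch else ".empty", envir = grp$exact,
                      ifnotfound = character())
    if (length(exact_ids)) {
      cand <- exact_ids; mclass <- "all_introns"
    } else if (!length(elems)) {
      cand <- grp$table$transcript_id; mclass <- "skipped_splicing"
    } else {
      sets <- lapply(elems, function(e)
        get0(e, envir = grp$elems, ifnotfound = character()))
      cand <- Reduce(intersect, sets)
      mclass <- "skipped_splicing"
    }
    if (!length(cand)) next
    read_len <- (reads$span_end[k] - reads$span_start[k]) -
      sum(chain_parse(ch)[, end - start])
    best <- select_best_transcript(
      read_len, data.table(transcript_id = cand, tx_length = tx_len[cand]))
    sp <- classify_span(reads$span_start[k], reads$span_end[k],
                        introns[transcript_id == best])
    res[[k]] <- data.table(read_id = reads$read_id[k], transcript_id = best,
                           match_class = mclass, span_class = sp)
  }
  out <- rbindlist(res)
  if (!nrow(out))
    out <- data.table(read_id = character(), transcript_id = character(),
                      match_class = character(), span_class = character())
  out
}

#' Build the reads-by-introns retention matrix for one transcript
#'
#' Each row is a read assigned to the transcript as best match, each column
#' one of the transcript's introns.  A cell is `spliced` when the intron is
#' in the read's chain, `retained` when the read's span wholly contains the
#' intron but the intron is not spliced out, and `uncovered` otherwise.
#'
#' @param reads long-read table restricted to reads assigned to `transcript_id`
#'   (must contain `read_id`, `span_start`, `span_end`, `chain`).
#' @param tx_set a `transcript_set`.
#' @param transcript_id the transcript.
#' @return object of class `retention_matrix`: list with `transcript_id`,
#'   `gene_id`, `introns` (data.table), `read_ids`, and `states` (integer
#'   matrix; 0 uncovered, 1 retained, 2 spliced).
#' @export
build_retention_matrix <- function(reads, tx_set, transcript_id) {
  tid <- transcript_id
  ii <- tx_set$introns[transcript_id == tid][order(start)]
  reads <- as.data.table(reads)
  setorder(reads, read_id)
  if (!nrow(reads)) stop("no reads assigned to transcript ", tid)
  states <- matrix(STATE_UNCOVERED, nrow = nrow(reads), ncol = nrow(ii),
                   dimnames = list(reads$read_id,
                                   if (nrow(ii)) paste0(ii$start, "-", ii$end)))
  for (r in seq_len(nrow(reads))) {
    if (!nrow(ii)) break
    ch <- chain_parse(reads$chain[r])
    in_chain <- paste0(ii$start, "-", ii$end) %in% paste0(ch$start, "-", ch$end)
    contained <- reads$span_start[r] <= ii$start & reads$span_end[r] >= ii$end
    states[r, in_chain] <- STATE_SPLICED
    states[r, contained & !in_chain] <- STATE_RETAINED
  }
  structure(list(transcript_id = tid,
                 gene_id = if (nrow(ii)) ii$gene_id[1] else
                   tx_set$transcripts[transcript_id == tid]$gene_id[1],
                 introns = ii, read_ids = reads$read_id, states = states),
            class = "retention_matrix")
}

#' Construct a retention matrix from a state matrix
#'
#' Programmatic constructor for workflows (and tests) that already hold the
#' reads-by-introns states: 0 uncovered, 1 retained, 2 spliced.
#'
#' @param states integer matrix, reads x introns.
#' @param introns optional data.table of intron keys (`chrom`, `start`,
#'   `end`, `strand`), one row per column; placeholder keys are generated
#'   when omitted.
#' @param transcript_id,gene_id identifiers attached to the records.
#' @return a `retention_matrix`.
#' @export
retention_matrix <- function(states, introns = NULL, transcript_id = "tx1",
                             gene_id = "gene1") {
  states <- as.matrix(states)
  mode(states) <- "integer"
  stopifnot(all(states %in% c(STATE_UNCOVERED, STATE_RETAINED, STATE_SPLICED)))
  if (is.null(introns)) {
    introns <- data.table(chrom = "chr1",
                          start = 1000L * seq_len(ncol(states)),
                          end = 1000L * seq_len(ncol(states)) + 100L,
                          strand = "+")
  }
  introns <- as.data.table(introns)
  stopifnot(nrow(introns) == ncol(states))
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("r%03d", seq_len(nrow(states)))
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 introns = introns, read_ids = rownames(states),
                 states = states),
            class = "retention_matrix")
}

#' @export
print.retention_matrix <- function(x, ...) {
  cat("retention_matrix:", x$transcript_id, "-", length(x$read_ids), "reads x",
      nrow(x$introns), "introns\n")
  invisible(x)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph path (0-based half-open, 4th column value).
#' @return data.table `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  dt[, list(chrom, start = as.integer(start), end = as.integer(end),
            value = as.numeric(value))]
}

# weighted median: sort values ascending; first value whose cumulative weight
# reaches half the total; exact half -> midpoint with the next distinct value.
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights > 0))
  dt <- data.table(v = values, w = weights)[, list(w = sum(w)), by = v]
  setorder(dt, v)
  cw <- cumsum(dt$w)
  half <- sum(dt$w) / 2
  k <- which(cw >= half)[1]
  if (isTRUE(all.equal(cw[k], half)) && k < nrow(dt))
    (dt$v[k] + dt$v[k + 1]) / 2 else dt$v[k]
}

# median per-base coverage over [start, end); bases without a bedGraph record
# count as zero.  NULL when no record overlaps the span at all.
gene_median_coverage <- function(coverage, chrom, start, end) {
  keep <- coverage$chrom == chrom & coverage$end > start & coverage$start < end
  cv <- as.data.table(coverage)[which(keep)]
  if (!nrow(cv)) return(NULL)
  w <- overlap_width(cv$start, cv$end, start, end)
  vals <- cv$value
  zero_bases <- (end - start) - sum(w)
  if (zero_bases > 0) { vals <- c(vals, 0); w <- c(w, zero_bases) }
  weighted_median(vals, w)
}

#' Select adequately covered target genes and eligible transcripts
#'
#' A gene is kept when its median gene-wide per-base short-read coverage
#' (intronic and exonic bases alike) reaches `min_coverage` and at least one
#' of its transcripts has `min_reads` assigned full-length reads whose
#' aligned ends each fall within `end_tolerance` bases of the transcript's
#' annotated ends.  Eligible transcripts are those with `min_reads` such
#' coordinate-matched full-length reads in kept genes.
#'
#' @param assignments output of [assign_reads()].
#' @param reads long-read table.
#' @param tx_set a `transcript_set`.
#' @param coverage bedGraph coverage table ([read_bedgraph()]).
#' @param min_coverage median reads/base required (default 2).
#' @param min_reads full-length read count required (default 5).
#' @param end_tolerance bases of slack at each transcript end (default 50).
#' @return list with `genes`, `transcripts`, and a `gene_stats` data.table.
#' @export
select_target_genes <- function(assignments, reads, tx_set, coverage,
                                min_coverage = 2, min_reads = 5L,
                                end_tolerance = 50L) {
  tx <- tx_set$transcripts
  a <- merge(as.data.table(assignments), as.data.table(reads),
             by = "read_id")[span_class == "full_length"]
  a <- merge(a, tx[, list(transcript_id, tx_start = start, tx_end = end)],
             by = "transcript_id")
  a <- a[abs(span_start - tx_start) <= end_tolerance &
           abs(span_end - tx_end) <= end_tolerance]
  per_tx <- a[, .N, by = transcript_id]
  per_tx <- merge(per_tx, tx[, list(transcript_id, gene_id)], by = "transcript_id")
  genes <- tx[, list(chrom = chrom[1], start = min(start), end = max(end)),
              by = gene_id]
  med <- numeric(nrow(genes))
  missing_cov <- logical(nrow(genes))
  for (k in seq_len(nrow(genes))) {
    m <- gene_median_coverage(coverage, genes$chrom[k], genes$start[k],
                              genes$end[k])
    if (is.null(m)) { missing_cov[k] <- TRUE; med[k] <- NA_real_ }
    else med[k] <- m
  }
  if (any(missing_cov))
    warning("no coverage for gene(s): ",
            paste(genes$gene_id[missing_cov], collapse = ", "),
            "; excluded")
  genes[, median_coverage := med]
  nfl <- per_tx[N >= min_reads, list(n_eligible_tx = .N), by = gene_id]
  genes <- merge(genes, nfl, by = "gene_id", all.x = TRUE)
  genes[is.na(n_eligible_tx), n_eligible_tx := 0L]
  genes[, kept := !is.na(median_coverage) & median_coverage >= min_coverage &
          n_eligible_tx > 0L]
  kept_genes <- genes[kept == TRUE, gene_id]
  eligible <- per_tx[N >= min_reads & gene_id %in% kept_genes, transcript_id]
  list(genes = kept_genes, transcripts = sort(eligible), gene_stats = genes[])
}
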