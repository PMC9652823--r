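# Fixture builders: everything is constructed in code, no files shipped.

# GTF lines (1-based closed) for a list of transcripts given as data.frames
# with columns start, end (internal 0-based half-open exon coordinates)
make_gtf_lines <- function(transcripts, chrom = "chr1", strand = "+",
                           gene_ids = NULL) {
  lines <- character()
  for (k in seq_along(transcripts)) {
    tid <- names(transcripts)[k]
    gid <- if (is.null(gene_ids)) paste0("g", k) else gene_ids[k]
    ex <- transcripts[[k]]
    st <- if (length(strand) > 1) strand[k] else strand
    lines <- c(lines, sprintf(
      '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      chrom, ex$start + 1L, ex$end, st, gid, tid))
  }
  lines
}

# two-isoform toy gene: t1 has exons A,B,C; t2 skips B
toy_two_isoform <- function() {
  parse_annotation(make_gtf_lines(list(
    t1 = data.frame(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
    t2 = data.frame(start = c(0L, 400L), end = c(100L, 500L))),
    gene_ids = c("g1", "g1")), text = TRUE)
}

# reads table row
read_row <- function(read_id, span_start, span_end, chain_dt,
                     chrom = "chr1", strand = "+") {
  data.table::data.table(
    read_id = read_id, chrom = chrom, strand = strand,
    span_start = as.integer(span_start), span_end = as.integer(span_end),
    chain = if (nrow(chain_dt))
      paste(paste0(chain_dt$start, "-", chain_dt$end), collapse = ",") else "")
}

ch <- function(...) {
  v <- c(...)
  if (!length(v)) return(data.table::data.table(start = integer(), end = integer()))
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.table::data.table(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# random state matrix for oracle-equivalence checks; guarantees >= 1 read
random_states <- function(n_reads, n_introns) {
  matrix(sample(0:2, n_reads * n_introns, replace = TRUE,
                prob = c(0.2, 0.3, 0.5)),
         nrow = n_reads)
}

# the worked 5-read x 3-intron example: r1, r2 retain intron 1 only,
# r3, r4 splice everything, r5 retains everything (full coverage)
worked_example_states <- function() {
  rbind(c(1L, 2L, 2L),
        c(1L, 2L, 2L),
        c(2L, 2L, 2L),
        c(2L, 2L, 2L),
        c(1L, 1L, 1L))
}
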