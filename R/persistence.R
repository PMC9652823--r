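# Intron persistence.
#
# For intron i of transcript t with best-match read set M^t:
#
#   P_{i,t} = d_i * sum_{r in M^t} R_{r,i} * SF_{r,i} * H_{r,i} / D
#
# where d_i is the information density (fraction of M^t covering i), R is the
# binary retention indicator, SF the spliced fraction of the read with the
# target excluded, H the scaled Hamming similarity of the read's splicing
# pattern to reads sharing its state at i, and D = |M^t| (the displayed
# equation) or the number of reads spanning i (the Methods-prose reading) --
# both are supported via `mean_denominator`.  Gene-level persistence is
# P_i = max over isoforms containing i of P_{i,t}.

#' Persistence parameters
#'
#' @param min_reads_per_transcript minimum best-match reads for a transcript
#'   to enter persistence calculation (default 5).
#' @param persistent_threshold P_i cutoff (inclusive) defining a persistent
#'   intron (default 0.1).
#' @param mean_denominator `"assigned"` divides the retention sum by all
#'   reads assigned to the transcript (the displayed equation; default);
#'   `"spanning"` divides by the reads spanning the target intron.
#' @param sf_single_intron_value spliced fraction returned for reads spanning
#'   only the target intron, where the defining ratio is 0/0 (default 1: such
#'   a read carries no contrary splicing evidence; 0 gives a conservative
#'   variant).
#' @return list of validated parameters.
#' @export
persistence_params <- function(min_reads_per_transcript = 5L,
                               persistent_threshold = 0.1,
                               mean_denominator = c("assigned", "spanning"),
                               sf_single_intron_value = 1) {
  mean_denominator <- match.arg(mean_denominator)
  stopifnot(min_reads_per_transcript >= 1L,
            persistent_threshold >= 0, persistent_threshold <= 1,
            sf_single_intron_value >= 0, sf_single_intron_value <= 1)
  list(min_reads_per_transcript = as.integer(min_reads_per_transcript),
       persistent_threshold = persistent_threshold,
       mean_denominator = mean_denominator,
       sf_single_intron_value = sf_single_intron_value)
}

#' Information density of an intron
#'
#' Proportion of the transcript's best-match reads whose span covers the
#' intron (state not `uncovered`).
#'
#' @param rmat a `retention_matrix`.
#' @param intron_index column index of the target intron.
#' @return d_i in `[0, 1]`.
#' @export
information_density <- function(rmat, intron_index) {
  states <- rmat$states
  if (!nrow(states)) stop("empty retention matrix")
  mean(states[, intron_index] != STATE_UNCOVERED)
}

#' Spliced fraction of a read for a target intron
#'
#' Fraction of introns spliced out in the read with the target intron
#' excluded: `(#spliced in I + R - 1) / (|I| - 1)` over I, the set of introns
#' spanned by the read, with R = 1 iff the target is retained.  Reads
#' spanning only the target return `sf_single_intron_value` (the ratio is
#' 0/0).
#'
#' @param read_states integer state vector for one read over the transcript's
#'   introns (0 uncovered, 1 retained, 2 spliced).
#' @param target_index index of the target intron.
#' @param sf_single_intron_value convention for single-spanned-intron reads.
#' @return SF in `[0, 1]`.
#' @export
spliced_fraction <- function(read_states, target_index,
                             sf_single_intron_value = 1) {
  if (read_states[target_index] == STATE_UNCOVERED)
    stop("target intron is uncovered in this read; exclude the read upstream")
  spanned <- read_states != STATE_UNCOVERED
  n_span <- sum(spanned)
  if (n_span == 1L) return(sf_single_intron_value)
  R <- as.integer(read_states[target_index] == STATE_RETAINED)
  n_spliced <- sum(read_states[spanned] == STATE_SPLICED)
  (n_spliced + R - 1) / (n_span - 1)
}

#' Scaled Hamming similarity of a read for a target intron
#'
#' Average, over the comparison set of reads spanning the target intron with
#' the same retention state there as the query read (the query included), of
#' the fraction of jointly covered introns whose states agree.  Reads not
#' spanning the target are excluded from the comparison set.
#'
#' @param states integer state matrix (reads x introns).
#' @param read_index row index of the query read (must span the target).
#' @param target_index column index of the target intron.
#' @return H in `[0, 1]`.
#' @export
hamming_similarity <- function(states, read_index, target_index) {
  q <- states[read_index, ]
  if (q[target_index] == STATE_UNCOVERED)
    stop("query read does not span the target intron")
  comp <- which(states[, target_index] == q[target_index])
  stopifnot(length(comp) >= 1L)
  sims <- vapply(comp, function(r2) {
    o <- states[r2, ]
    shared <- q != STATE_UNCOVERED & o != STATE_UNCOVERED
    # both reads span the target, so the shared set is never empty
    sum(q[shared] == o[shared]) / sum(shared)
  }, numeric(1))
  mean(sims)
}

#' Per-transcript intron persistence
#'
#' Computes `d_i` and `P_it` for every intron of the transcript from its
#' retention matrix.  Transcripts with fewer best-match reads than
#' `params$min_reads_per_transcript` are skipped (returns `NULL`).
#'
#' @param rmat a `retention_matrix` from [build_retention_matrix()].
#' @param params a [persistence_params()] list.
#' @return data.table with one row per intron: intron key columns, `d_i`,
#'   `P_it`, `n_reads`, `n_spanning`; or `NULL` when skipped.
#' @export
transcript_persistence <- function(rmat, params = persistence_params()) {
  states <- rmat$states
  n_reads <- nrow(states)
  if (n_reads < params$min_reads_per_transcript) return(NULL)
  ii <- rmat$introns
  if (!nrow(ii)) return(NULL)
  out <- vector("list", nrow(ii))
  for (i in seq_len(nrow(ii))) {
    spanning <- which(states[, i] != STATE_UNCOVERED)
    d <- length(spanning) / n_reads
    retaining <- which(states[, i] == STATE_RETAINED)
    total <- 0
    for (r in retaining) {
      sf <- spliced_fraction(states[r, ], i, params$sf_single_intron_value)
      h <- hamming_similarity(states, r, i)
      total <- total + sf * h
    }
    D <- if (params$mean_denominator == "assigned") n_reads
         else max(length(spanning), 1L)
    p <- d * total / D
    out[[i]] <- data.table(
      chrom = ii$chrom[i], start = ii$start[i], end = ii$end[i],
      strand = ii$strand[i], gene_id = rmat$gene_id,
      transcript_id = rmat$transcript_id,
      d_i = d, P_it = min(max(p, 0), 1),
      n_reads = n_reads, n_spanning = length(spanning))
  }
  rbindlist(out)
}

#' Gene-level intron persistence
#'
#' Collapses per-transcript records sharing an intron key
#' (chrom, start, end, strand) to `P_i`, the maximum `P_it` across all
#' isoforms containing the intron -- introns recur across isoforms and even
#' genes, and short reads cannot distinguish the isoform of origin.
#'
#' @param records row-bound [transcript_persistence()] outputs.
#' @param params a [persistence_params()] list (supplies the persistence
#'   threshold for the `persistent` flag).
#' @return data.table keyed by intron: `P_i`, `transcript_id` (argmax,
#'   smallest id on ties), `transcripts` (all argmax ids, comma-joined),
#'   `d_i`, `n_reads`, `n_spanning` (from the argmax record), `persistent`.
#' @export
intron_persistence <- function(records, params = persistence_params()) {
  records <- as.data.table(records)
  if (!nrow(records)) stop("no persistence records supplied")
  out <- records[, {
    p <- max(P_it)
    amax <- sort(transcript_id[P_it == p])
    k <- which(transcript_id == amax[1])[1]
    list(gene_id = gene_id[k], P_i = p, transcript_id = amax[1],
         transcripts = paste(amax, collapse = ","),
         d_i = d_i[k], n_reads = n_reads[k], n_spanning = n_spanning[k])
  }, by = list(chrom, start, end, strand)]
  out[, persistent := classify_persistent(P_i, params$persistent_threshold)]
  out[]
}

#' Persistent-intron classification
#'
#' @param P_i persistence value(s) in `[0, 1]`.
#' @param threshold inclusive cutoff (default 0.1).
#' @return logical vector: `P_i >= threshold`.
#' @export
classify_persistent <- function(P_i, threshold = 0.1) {
  stopifnot(all(P_i >= 0 & P_i <= 1))
  P_i >= threshold
}

#' Full persistence pipeline over assigned reads
#'
#' Builds a retention matrix per transcript with enough best-match reads and
#' returns both the per-transcript records and the gene-level table.
#'
#' @param reads long-read table.
#' @param assignments output of [assign_reads()].
#' @param tx_set a `transcript_set`.
#' @param params a [persistence_params()] list.
#' @param transcripts optional restriction to eligible transcript ids.
#' @return list with `records` (per transcript x intron) and `introns`
#'   (gene-level, from [intron_persistence()]).
#' @export
persistence_pipeline <- function(reads, assignments, tx_set,
                                 params = persistence_params(),
                                 transcripts = NULL) {
  a <- as.data.table(assignments)
  if (!is.null(transcripts)) a <- a[transcript_id %in% transcripts]
  counts <- a[, .N, by = transcript_id][N >= params$min_reads_per_transcript]
  reads <- as.data.table(reads)
  recs <- lapply(counts$transcript_id, function(tid) {
    rr <- merge(a[transcript_id == tid, list(read_id)], reads, by = "read_id")
    rmat <- build_retention_matrix(rr, tx_set, tid)
    transcript_persistence(rmat, params)
  })
  records <- rbindlist(recs)
  if (!nrow(records))
    return(list(records = records, introns = data.table()))
  list(records = records, introns = intron_persistence(records, params))
}
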