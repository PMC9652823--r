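# Deterministic splicing simulator.
#
# Generates a small genome + multi-isoform annotation, long reads with
# stochastic splicing progression and partial spans, a short-read coverage
# track, and mock caller outputs with controlled sensitivity/specificity, so
# that the whole persistence/benchmark pipeline runs with known ground truth
# and no external data.

# evaluate code under a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() treats a scalar first argument as 1:n; draw from a range safely
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep(lo, n) else sample(seq.int(lo, hi), n, replace = TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intron sequence whose transcript-strand motif is GT-AG
intron_dna <- function(n, strand) {
  core <- if (n > 4) random_dna(n - 4) else ""
  if (strand == "+") paste0("GT", core, "AG") else paste0("CT", core, "AC")
}

#' Simulation configuration
#'
#' Defaults describe the emulated world: transcripts with a handful of
#' introns, a background in which roughly three quarters of introns are
#' always spliced (retention probability 0) and a thin tail is constitutively
#' retained, up to 20% of molecules sampled before splicing has completed
#' (pre-mRNA contamination), a minority of reads truncated at one end, and
#' mock callers that detect persistent introns with imperfect
#' sensitivity/specificity.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene isoforms per gene (additional isoforms skip one
#'   internal exon each, giving exon-over-intron overlaps between isoforms).
#' @param introns_per_transcript length-2 range of intron counts for the
#'   primary isoform.
#' @param exon_length_range,intron_length_range length-2 base ranges.
#' @param retention_probs `NULL` to sample each unique intron's retention
#'   probability rho from the background mixture, or a numeric vector
#'   recycled over unique introns in generation order (`NA` entries fall
#'   back to the mixture).
#' @param zero_fraction,one_fraction mixture weights of the rho background:
#'   probability of rho = 0 and rho = 1; the remainder is uniform on (0, 1).
#' @param pre_mrna_fraction fraction of reads drawn from incompletely
#'   spliced molecules (default 0.2).
#' @param pre_mrna_model `"contiguous3p"` retains a contiguous 3' run of
#'   introns (5' to 3' splicing progression stopped at a uniform point);
#'   `"random_subset"` retains each intron independently with probability
#'   1/2.
#' @param partial_fraction fraction of reads truncated uniformly at random
#'   from one end (default 0.1).
#' @param reads_per_transcript long reads emitted per transcript (default
#'   50).
#' @param coverage_depth flat short-read coverage depth (default 10).
#' @param coverage_decay linear 5' to 3' coverage decay inside introns
#'   (0 = flat).
#' @param sensitivity,specificity per-mock-tool call probabilities; scalars
#'   or vectors named by tool.
#' @param tools mock tool names (default: the eight shipped rules).
#' @param intergenic_gap bases between genes.
#' @param seed integer seed fixing every downstream draw.
#' @return validated config list.
#' @export
simulation_config <- function(n_genes = 20L, isoforms_per_gene = 2L,
                              introns_per_transcript = c(3L, 5L),
                              exon_length_range = c(100L, 300L),
                              intron_length_range = c(80L, 400L),
                              retention_probs = NULL,
                              zero_fraction = 0.767, one_fraction = 0.0013,
                              pre_mrna_fraction = 0.2,
                              pre_mrna_model = c("contiguous3p", "random_subset"),
                              partial_fraction = 0.1,
                              reads_per_transcript = 50L,
                              coverage_depth = 10, coverage_decay = 0,
                              sensitivity = 0.8, specificity = 0.9,
                              tools = names(default_call_rules()),
                              intergenic_gap = 500L, seed = 1L) {
  pre_mrna_model <- match.arg(pre_mrna_model)
  probs <- c(zero_fraction, one_fraction, pre_mrna_fraction, partial_fraction,
             sensitivity, specificity)
  if (any(probs < 0 | probs > 1)) stop("config: probabilities must be in [0, 1]")
  if (any(c(exon_length_range, intron_length_range) <= 0))
    stop("config: length ranges must be positive")
  if (intron_length_range[1] < 4L)
    stop("config: introns need >= 4 bases for splice motifs")
  if (introns_per_transcript[1] < 2L)
    stop("config: need >= 2 introns per transcript so isoforms can skip exons")
  list(n_genes = as.integer(n_genes),
       isoforms_per_gene = as.integer(isoforms_per_gene),
       introns_per_transcript = as.integer(introns_per_transcript),
       exon_length_range = as.integer(exon_length_range),
       intron_length_range = as.integer(intron_length_range),
       retention_probs = retention_probs,
       zero_fraction = zero_fraction, one_fraction = one_fraction,
       pre_mrna_fraction = pre_mrna_fraction, pre_mrna_model = pre_mrna_model,
       partial_fraction = partial_fraction,
       reads_per_transcript = as.integer(reads_per_transcript),
       coverage_depth = coverage_depth, coverage_decay = coverage_decay,
       sensitivity = sensitivity, specificity = specificity, tools = tools,
       intergenic_gap = as.integer(intergenic_gap), seed = as.integer(seed))
}

#' Generate a synthetic genome and annotation
#'
#' Lays genes along one chromosome, alternating strands.  Each gene's
#' primary isoform has all exons; each additional isoform skips one internal
#' exon, so its merged intron overlaps the skipped exon of the sibling
#' isoform.  Intron boundaries carry canonical GT-AG motifs on the
#' transcript strand.
#'
#' @param config a [simulation_config()].
#' @return list: `genome` (`DNAStringSet`), `tx_set` (a `transcript_set`),
#'   `truth_introns` (unique introns with `rho` and `expected_persistent`),
#'   `config`.
#' @export
generate_annotation <- function(config = simulation_config()) {
  with_seed(config$seed, {
    exon_rows <- list(); seqs <- character(config$n_genes)
    cursor <- config$intergenic_gap
    for (g in seq_len(config$n_genes)) {
      gid <- sprintf("gene%03d", g)
      strand <- if (g %% 2L == 1L) "+" else "-"
      n_int <- sample_range(config$introns_per_transcript[1],
                            config$introns_per_transcript[2])
      n_ex <- n_int + 1L
      ex_len <- sample_range(config$exon_length_range[1],
                             config$exon_length_range[2], n_ex)
      in_len <- sample_range(config$intron_length_range[1],
                             config$intron_length_range[2], n_int)
      # genomic layout: e1 i1 e2 i2 ... e_n
      parts <- character(n_ex + n_int)
      at <- cursor
      ex_start <- integer(n_ex); ex_end <- integer(n_ex)
      for (k in seq_len(n_ex)) {
        parts[2L * k - 1L] <- random_dna(ex_len[k])
        ex_start[k] <- at; at <- at + ex_len[k]; ex_end[k] <- at
        if (k <= n_int) {
          parts[2L * k] <- intron_dna(in_len[k], strand)
          at <- at + in_len[k]
        }
      }
      seqs[g] <- paste(parts, collapse = "")
      tid1 <- paste0(gid, ".t1")
      exon_rows[[length(exon_rows) + 1L]] <- data.table(
        chrom = "chr1", start = ex_start, end = ex_end, strand = strand,
        transcript_id = tid1, gene_id = gid)
      n_iso <- min(config$isoforms_per_gene, 1L + (n_ex - 2L))
      if (n_iso > 1L) {
        internal <- seq.int(2L, n_ex - 1L)
        skippable <- if (length(internal) == 1L) internal
                     else sample(internal)[seq_len(n_iso - 1L)]
        for (s in seq_along(skippable)) {
          keep <- setdiff(seq_len(n_ex), skippable[s])
          exon_rows[[length(exon_rows) + 1L]] <- data.table(
            chrom = "chr1", start = ex_start[keep], end = ex_end[keep],
            strand = strand, transcript_id = paste0(gid, ".t", s + 1L),
            gene_id = gid)
        }
      }
      cursor <- at + config$intergenic_gap
    }
    # assemble the chromosome: intergenic gaps + gene sequences in order
    pieces <- character(2L * config$n_genes + 1L)
    pos <- 0L; piece_at <- 1L
    all_rows <- rbindlist(exon_rows)
    gene_bounds <- all_rows[, list(gs = min(start), ge = max(end)),
                            by = gene_id]
    setorder(gene_bounds, gs)
    for (g in seq_len(nrow(gene_bounds))) {
      pieces[piece_at] <- random_dna(gene_bounds$gs[g] - pos); piece_at <- piece_at + 1L
      pieces[piece_at] <- seqs[g]; piece_at <- piece_at + 1L
      pos <- gene_bounds$ge[g]
    }
    pieces[piece_at] <- random_dna(config$intergenic_gap)
    genome <- Biostrings::DNAStringSet(paste(pieces[seq_len(piece_at)],
                                             collapse = ""))
    names(genome) <- "chr1"
    tx_set <- build_transcript_set(all_rows)
    truth <- assign_retention_probs(tx_set, config)
    list(genome = genome, tx_set = tx_set, truth_introns = truth,
         config = config)
  })
}

# rho per unique intron key; retention_probs recycled in generation order
assign_retention_probs <- function(tx_set, config) {
  uniq <- unique(tx_set$introns[, list(chrom, start, end, strand, gene_id)])
  setorder(uniq, start)
  n <- nrow(uniq)
  u <- stats::runif(n); mix <- stats::runif(n)
  rho <- ifelse(mix < config$zero_fraction, 0,
                ifelse(mix < config$zero_fraction + config$one_fraction, 1, u))
  if (!is.null(config$retention_probs)) {
    given <- rep_len(as.numeric(config$retention_probs), n)
    rho <- ifelse(is.na(given), rho, given)
  }
  uniq[, rho := rho]
  uniq[, expected_persistent := rho >= 0.1]
  uniq[]
}

#' Simulate spliced long reads
#'
#' Mature reads splice each intron independently with probability
#' `1 - rho_i`; pre-mRNA reads follow the configured splicing-progression
#' model and ignore rho; partial reads are truncated at a uniformly random
#' molecule position from a uniformly chosen end.  Coordinates are
#' consistent spliced alignments against the synthetic genome.
#'
#' @param ann output of [generate_annotation()].
#' @param config a [simulation_config()] (defaults to the one inside `ann`).
#' @return list: `reads` (long-read table as in [read_long_reads_tsv()]),
#'   `read_truth` (per read: source transcript, maturity, truncation).
#' @export
simulate_long_reads <- function(ann, config = ann$config) {
  tx_set <- ann$tx_set
  rho_map <- stats::setNames(ann$truth_introns$rho,
                             intron_key(ann$truth_introns))
  with_seed(config$seed + 1L, {
    out <- list(); truth <- list(); rid <- 0L
    for (tid in sort(tx_set$transcripts$transcript_id)) {
      tx <- tx_set$transcripts[transcript_id == tid]
      ii <- tx_set$introns[transcript_id == tid][order(start)]
      n_int <- nrow(ii)
      rho <- if (n_int) rho_map[intron_key(ii)] else numeric()
      for (r in seq_len(config$reads_per_transcript)) {
        rid <- rid + 1L
        is_pre <- stats::runif(1) < config$pre_mrna_fraction
        if (!n_int) {
          retained <- logical()
        } else if (!is_pre) {
          retained <- stats::runif(n_int) < rho
        } else if (config$pre_mrna_model == "contiguous3p") {
          k <- sample(0:n_int, 1L)        # introns spliced so far, 5'->3'
          retained <- if (tx$strand == "+") seq_len(n_int) > k
                      else seq_len(n_int) <= n_int - k
        } else {
          retained <- stats::runif(n_int) < 0.5
        }
        span <- c(tx$start, tx$end)
        spliced <- ii[!retained]
        truncated <- stats::runif(1) < config$partial_fraction
        if (truncated) {
          cut <- truncate_span(tx, spliced, sample(c("left", "right"), 1L))
          span <- cut$span
          spliced <- spliced[start >= span[1] & end <= span[2]]
        }
        out[[rid]] <- data.table(
          read_id = sprintf("r%06d", rid), chrom = tx$chrom,
          strand = tx$strand, span_start = span[1], span_end = span[2],
          chain = chain_format(spliced$start, spliced$end))
        truth[[rid]] <- data.table(
          read_id = sprintf("r%06d", rid), transcript_id = tid,
          maturity = if (is_pre) "pre_mRNA" else "mature",
          truncated = truncated)
      }
    }
    list(reads = rbindlist(out), read_truth = rbindlist(truth))
  })
}

# truncate the molecule (span minus spliced gaps) at a uniform interior
# molecule coordinate; returns the new genomic span
truncate_span <- function(tx, spliced, side) {
  segs <- molecule_segments(tx$start, tx$end, spliced)
  mol_len <- sum(segs$end - segs$start)
  if (mol_len < 2L) return(list(span = c(tx$start, tx$end)))
  cut_mol <- sample(seq_len(mol_len - 1L), 1L)
  cut_gen <- mol_to_genomic(segs, cut_mol)
  if (side == "left") list(span = c(cut_gen, tx$end))
  else list(span = c(tx$start, cut_gen))
}

molecule_segments <- function(span_start, span_end, spliced) {
  if (!nrow(spliced))
    return(data.table(start = span_start, end = span_end))
  s <- c(span_start, spliced$end)
  e <- c(spliced$start, span_end)
  data.table(start = s, end = e)[end > start]
}

mol_to_genomic <- function(segs, mol_pos) {
  at <- 0L
  for (k in seq_len(nrow(segs))) {
    w <- segs$end[k] - segs$start[k]
    if (mol_pos <= at + w) return(segs$start[k] + (mol_pos - at))
    at <- at + w
  }
  segs$end[nrow(segs)]
}

#' Write long reads as SAM text
#'
#' Spliced alignments with skip gaps (`N`) for the chain intervals, FLAG bit
#' 0x10 for minus-strand reads, and an `XS:A` transcript-strand tag.
#'
#' @param reads long-read table.
#' @param genome named `DNAStringSet` (for `@SQ` header lengths).
#' @param path output path.
#' @export
write_sam <- function(reads, genome, path) {
  reads <- as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  recs <- vapply(seq_len(nrow(reads)), function(k) {
    ch <- chain_parse(reads$chain[k])
    segs <- molecule_segments(reads$span_start[k], reads$span_end[k], ch)
    cig <- character(0)
    for (s in seq_len(nrow(segs))) {
      cig <- c(cig, paste0(segs$end[s] - segs$start[s], "M"))
      if (s < nrow(segs))
        cig <- c(cig, paste0(segs$start[s + 1] - segs$end[s], "N"))
    }
    paste(reads$read_id[k],
          if (reads$strand[k] == "-") 16L else 0L,
          reads$chrom[k], reads$span_start[k] + 1L, 60L,
          paste(cig, collapse = ""), "*", 0L, 0L, "*", "*",
          paste0("XS:A:", reads$strand[k]), sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Simulate a short-read coverage track
#'
#' Flat coverage at `depth` over every gene span, with an optional linear
#' 5' to 3' (positive-strand) decay inside introns: coverage at the intron
#' end equals `depth * (1 - decay)`.
#'
#' @param ann output of [generate_annotation()].
#' @param depth per-base depth.
#' @param decay_5to3 fractional decay across each intron (default from
#'   config).
#' @return bedGraph-style data.table `chrom`, `start`, `end`, `value`.
#' @export
simulate_coverage <- function(ann, depth = ann$config$coverage_depth,
                              decay_5to3 = ann$config$coverage_decay) {
  stopifnot(depth > 0)
  tx <- ann$tx_set$transcripts
  genes <- tx[, list(chrom = chrom[1], start = min(start), end = max(end)),
              by = gene_id]
  if (decay_5to3 == 0) {
    return(genes[, list(chrom, start, end, value = depth)][order(start)])
  }
  uniq <- unique(ann$tx_set$introns[, list(chrom, start, end)])
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    gs <- genes$start[g]; ge <- genes$end[g]
    ig <- uniq[chrom == genes$chrom[g] & start >= gs & end <= ge]
    # exonic bases stay flat; intron bases decay linearly 5'->3'; where
    # isoform-merged introns overlap, the deeper decay wins (per-base min)
    v <- rep(depth, ge - gs)
    for (k in seq_len(nrow(ig))) {
      L <- ig$end[k] - ig$start[k]
      frac <- (seq_len(L) - 1) / max(L - 1, 1)
      at <- (ig$start[k] - gs) + seq_len(L)
      v[at] <- pmin(v[at], depth * (1 - decay_5to3 * frac))
    }
    r <- S4Vectors::Rle(v)
    ends <- cumsum(S4Vectors::runLength(r))
    rows[[length(rows) + 1L]] <- data.table(
      chrom = genes$chrom[g],
      start = gs + c(0L, ends[-length(ends)]),
      end = gs + ends, value = S4Vectors::runValue(r))
  }
  rbindlist(rows)[order(start)]
}

#' Simulate mock caller outputs
#'
#' Each mock tool calls a persistent intron with probability `sensitivity`
#' and a non-persistent intron with probability `1 - specificity`; scores
#' and auxiliary columns are drawn above or below that tool's shipped
#' calling-rule thresholds accordingly, so the downstream rule reproduces
#' the drawn call exactly.  Every universe intron receives a record (the
#' tool's "potential" set is the whole universe).
#'
#' @param universe intron universe (`chrom`, `start`, `end`, `strand`).
#' @param persistent logical vector along `universe` (or a data.table of
#'   persistent intron keys).
#' @param config a [simulation_config()] (supplies tools,
#'   sensitivity/specificity and the seed).
#' @return list: `calls` (named list of per-tool score tables),
#'   `intended` (data.table intron x tool with the drawn call).
#' @export
simulate_caller_outputs <- function(universe, persistent,
                                    config = simulation_config()) {
  universe <- as.data.table(universe)
  if (is.data.frame(persistent))
    persistent <- intron_key(universe) %in% intron_key(as.data.table(persistent))
  stopifnot(length(persistent) == nrow(universe))
  tools <- config$tools
  sens <- rep_len(config$sensitivity, length(tools))
  spec <- rep_len(config$specificity, length(tools))
  names(sens) <- names(spec) <- tools
  with_seed(config$seed + 3L, {
    calls <- list(); intended <- list()
    for (tool in tools) {
      p_call <- ifelse(persistent, sens[tool], 1 - spec[tool])
      called <- stats::runif(nrow(universe)) < p_call
      u <- stats::runif(nrow(universe))
      rec <- data.table(universe[, list(chrom, start, end, strand)])
      rec[, score := mock_score(tool, called, u)]
      aux <- mock_aux(tool, called, u)
      for (col in names(aux)) rec[, (col) := aux[[col]]]
      calls[[tool]] <- rec
      intended[[tool]] <- data.table(universe[, list(chrom, start, end, strand)],
                                     tool = tool, called = called)
    }
    list(calls = calls, intended = rbindlist(intended))
  })
}

mock_score <- function(tool, called, u) {
  switch(tool,
    interest = ifelse(called, 45 + 50 * u, 44 * u),
    kma = 1 + 10 * u,
    iread = ifelse(called, 3.5 + 10 * u, 0.9 * u),
    superintronic = ifelse(called, 3 + 5 * u, 2.9 * u),
    irfinder = ifelse(called, 0.5 + 0.5 * u, 0.49 * u),
    majiq = ifelse(called, 0.51 + 0.49 * u, 0.5 * u),
    rmats = ifelse(called, 0.81 + 0.19 * u, 0.8 * u),
    suppa2 = ifelse(called, 0.81 + 0.19 * u, 0.8 * u),
    stop("no mock score model for tool ", tool))
}

mock_aux <- function(tool, called, u) {
  switch(tool,
    kma = list(unique_counts = ifelse(called, 10L + as.integer(20 * u),
                                      as.integer(10 * u))),
    iread = list(entropy = ifelse(called, 0.9 + 0.1 * u, 0.89 * u),
                 junction_reads = ifelse(called, 1L + as.integer(4 * u), 0L),
                 fragments = ifelse(called, 20L + as.integer(30 * u),
                                    as.integer(9 * u))),
    irfinder = list(flags = rep(0L, length(called))),
    list())
}

#' Simulate a complete dataset
#'
#' Annotation + genome, long reads, coverage and caller outputs under one
#' seed, plus ground truth.
#'
#' @param config a [simulation_config()].
#' @return list with `genome`, `tx_set`, `truth_introns`, `reads`,
#'   `read_truth`, `coverage`, `caller` (from
#'   [simulate_caller_outputs()], over the unique intron universe), and
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  ann <- generate_annotation(config)
  lr <- simulate_long_reads(ann, config)
  cov <- simulate_coverage(ann)
  universe <- unique(ann$tx_set$introns[, list(chrom, start, end, strand)])
  setorder(universe, chrom, start, end)
  persistent <- universe[ann$truth_introns[expected_persistent == TRUE],
                         on = c("chrom", "start", "end", "strand"),
                         nomatch = NULL]
  caller <- simulate_caller_outputs(universe, persistent, config)
  c(ann, list(reads = lr$reads, read_truth = lr$read_truth, coverage = cov,
              caller = caller, universe = universe))
}
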