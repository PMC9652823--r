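test_that("CIGAR walks produce reference-coordinate intron chains", {
  w <- extract_intron_chain(0L, "50M100N50M")
  expect_equal(c(w$span_start, w$span_end), c(0L, 200L))
  expect_equal(as.data.frame(w$chain), data.frame(start = 50L, end = 150L))

  w <- extract_intron_chain(0L, "100M")
  expect_equal(nrow(w$chain), 0L)
  expect_equal(w$span_end, 100L)

  w <- extract_intron_chain(0L, "10M20N10M30N10M")
  expect_equal(as.data.frame(w$chain),
               data.frame(start = c(10L, 40L), end = c(30L, 70L)))
  expect_equal(c(w$span_start, w$span_end), c(0L, 80L))

  # clips and insertions do not consume reference; deletions do
  w <- extract_intron_chain(100L, "5S10M2I10M3D5M4H")
  expect_equal(nrow(w$chain), 0L)
  expect_equal(c(w$span_start, w$span_end), c(100L, 128L))
})

test_that("reads match transcripts by exact set, then subset, else discard", {
  ts <- parse_annotation(make_gtf_lines(list(
    t1 = data.frame(start = c(0L, 200L, 400L), end = c(100L, 300L, 500L)),
    t2 = data.frame(start = c(0L, 400L), end = c(100L, 500L))),
    gene_ids = c("g1", "g1")), text = TRUE)
  # t1 introns {[100,200),[300,400)}; t2 intron {[100,400)}
  reads <- rbind(
    read_row("exact", 0, 500, ch(100, 200, 300, 400)),
    read_row("skip", 0, 500, ch(100, 200)),          # subset of t1 only
    read_row("unspliced", 0, 500, ch()),             # subset of both
    read_row("foreign", 0, 500, ch(120, 200)))       # shifted donor
  a <- assign_reads(reads, ts)
  expect_equal(a[read_id == "exact", transcript_id], "t1")
  expect_equal(a[read_id == "exact", match_class], "all_introns")
  expect_equal(a[read_id == "skip", transcript_id], "t1")
  expect_equal(a[read_id == "skip", match_class], "skipped_splicing")
  expect_false("foreign" %in% a$read_id)
  # unspliced read footprint 500 is closest to t1 exonic length 300? t2 = 200
  expect_equal(a[read_id == "unspliced", transcript_id], "t1")
  expect_equal(a[read_id == "unspliced", match_class], "skipped_splicing")
})

test_that("exact matches beat subset matches even when length prefers another", {
  ts <- parse_annotation(make_gtf_lines(list(
    t1 = data.frame(start = c(0L, 200L), end = c(100L, 300L)),
    t2 = data.frame(start = c(0L, 200L, 4000L), end = c(100L, 300L, 4100L))),
    gene_ids = c("g1", "g1")), text = TRUE)
  # read chain equals t1's introns exactly; t2 contains them as a subset
  r <- read_row("r1", 0, 300, ch(100, 200))
  a <- assign_reads(r, ts)
  expect_equal(a$transcript_id, "t1")
  expect_equal(a$match_class, "all_introns")
})

test_that("best match minimizes length difference with id tie-break", {
  cand <- data.table::data.table(transcript_id = c("a", "b", "c"),
                                 tx_length = c(112L, 103L, 140L))
  expect_equal(select_best_transcript(100L, cand), "b")
  tie <- data.table::data.table(transcript_id = c("zz", "aa"),
                                tx_length = c(95L, 105L))
  expect_equal(select_best_transcript(100L, tie), "aa")
  expect_equal(select_best_transcript(
    7L, data.table::data.table(transcript_id = "only", tx_length = 1L)),
    "only")
})

test_that("assignment is invariant to read order and respects chain subset", {
  sim <- simulate_dataset(simulation_config(n_genes = 5, seed = 21))
  a1 <- assign_reads(sim$reads, sim$tx_set)
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads)))]
  a2 <- assign_reads(shuffled, sim$tx_set)
  expect_equal(as.data.frame(a1), as.data.frame(a2))
  merged <- merge(a1, sim$reads, by = "read_id")
  for (k in seq_len(nrow(merged))) {
    tx_introns <- sim$tx_set$introns[transcript_id == merged$transcript_id[k]]
    read_introns <- strsplit(merged$chain[k], ",")[[1]]
    expect_true(all(read_introns %in%
                      paste0(tx_introns$start, "-", tx_introns$end)))
  }
})

test_that("clean full-length reads all recover their source isoform", {
  cfg <- simulation_config(n_genes = 8, retention_probs = 0,
                           pre_mrna_fraction = 0, partial_fraction = 0,
                           reads_per_transcript = 10, seed = 5)
  sim <- simulate_dataset(cfg)
  a <- assign_reads(sim$reads, sim$tx_set)
  m <- merge(a, sim$read_truth, by = "read_id")
  expect_equal(nrow(m), nrow(sim$reads))
  expect_true(all(m$transcript_id.x == m$transcript_id.y))
  expect_true(all(m$match_class == "all_introns"))
  expect_true(all(m$span_class == "full_length"))
})

test_that("span classification requires encompassing every intron", {
  introns <- data.table::data.table(start = c(100L, 300L), end = c(200L, 400L))
  expect_equal(classify_span(0L, 500L, introns), "full_length")
  expect_equal(classify_span(0L, 350L, introns), "partial")
  expect_equal(classify_span(150L, 500L, introns), "partial")
  expect_equal(classify_span(100L, 400L, introns), "full_length")
  none <- data.table::data.table(start = integer(), end = integer())
  expect_equal(classify_span(10L, 20L, none), "full_length")
})

test_that("retention states follow the span/chain rules", {
  ts <- parse_annotation(make_gtf_lines(list(
    t1 = data.frame(start = c(0L, 200L, 400L, 600L),
                    end = c(100L, 300L, 500L, 700L)))), text = TRUE)
  reads <- rbind(
    read_row("all_spliced", 0, 700, ch(100, 200, 300, 400, 500, 600)),
    read_row("retain1", 0, 700, ch(300, 400, 500, 600)),
    read_row("partial3", 0, 450, ch(100, 200, 300, 400)))
  rmat <- build_retention_matrix(reads, ts, "t1")
  # states: 0 uncovered / 1 retained / 2 spliced; columns in genomic order
  expect_equal(unname(rmat$states["all_spliced", ]), c(2L, 2L, 2L))
  expect_equal(unname(rmat$states["retain1", ]), c(1L, 2L, 2L))
  expect_equal(unname(rmat$states["partial3", ]), c(2L, 2L, 0L))
})

test_that("target gene selection enforces coverage and matched-end rules", {
  ts <- parse_annotation(make_gtf_lines(list(
    t1 = data.frame(start = c(0L, 600L), end = c(400L, 1000L)))), text = TRUE)
  fl <- function(id, s = 0, e = 1000)
    read_row(id, s, e, ch(400, 600))
  reads <- rbindlist(lapply(sprintf("r%d", 1:5), fl))
  a <- assign_reads(reads, ts)
  cov2 <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                                 value = 2)
  sel <- select_target_genes(a, reads, ts, cov2)
  expect_equal(sel$genes, "g1")
  expect_equal(sel$transcripts, "t1")

  cov19 <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                                  value = 1.9)
  expect_equal(length(select_target_genes(a, reads, ts, cov19)$genes), 0L)

  # a read starting 60 bases inside the annotated start is not counted
  reads2 <- rbindlist(c(lapply(sprintf("r%d", 1:4), fl),
                        list(fl("r5", s = 60))))
  a2 <- assign_reads(reads2, ts)
  sel2 <- select_target_genes(a2, reads2, ts, cov2)
  expect_equal(length(sel2$transcripts), 0L)

  expect_warning(select_target_genes(a, reads, ts,
                                     cov2[chrom == "nowhere"]),
                 "no coverage")
})

test_that("median gene coverage treats uncovered bases as zero", {
  ts <- parse_annotation(make_gtf_lines(list(
    t1 = data.frame(start = c(0L, 600L), end = c(400L, 1000L)))), text = TRUE)
  reads <- rbindlist(lapply(sprintf("r%d", 1:5), function(id)
    read_row(id, 0, 1000, ch(400, 600))))
  a <- assign_reads(reads, ts)
  # 40% of the gene at 5x, the rest unreported -> median 0 -> excluded
  cov <- data.table::data.table(chrom = "chr1", start = 0L, end = 400L,
                                value = 5)
  expect_equal(length(select_target_genes(a, reads, ts, cov)$genes), 0L)
})

test_that("SAM text, BAM and simulator tables agree", {
  sim <- simulate_dataset(simulation_config(n_genes = 4, seed = 13,
                                            reads_per_transcript = 8))
  sam <- file.path(tempdir(), "lr_agree.sam")
  write_sam(sim$reads, sim$genome, sam)
  from_sam <- read_long_reads_sam(sam)
  key <- function(x) as.data.frame(x[order(read_id)])
  expect_equal(key(from_sam), key(sim$reads))

  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  from_bam <- read_long_reads_bam(bam)
  expect_equal(key(from_bam), key(sim$reads))
})

test_that("secondary and unmapped SAM records are skipped", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:chr1\tLN:10000",
           "r1\t0\tchr1\t1\t60\t50M100N50M\t*\t0\t0\t*\t*\tXS:A:+",
           "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
           "r3\t256\tchr1\t1\t60\t100M\t*\t0\t0\t*\t*")
  path <- file.path(tempdir(), "skip.sam")
  writeLines(sam, path)
  expect_message(reads <- read_long_reads_sam(path), "2 unmapped")
  expect_equal(reads$read_id, "r1")
  expect_equal(reads$chain, "50-150")
})
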