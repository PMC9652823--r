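dt <- data.table::data.table

test_that("length-weighted median follows the cumulative-weight convention", {
  expect_equal(length_weighted_median(0L, 100L,
                                      dt(start = 0L, end = 100L, score = 7)), 7)
  eq <- dt(start = c(0L, 40L, 80L), end = c(40L, 80L, 120L),
           score = c(9, 1, 5))
  expect_equal(length_weighted_median(0L, 120L, eq), 5)   # plain median
  # 80/20 weights: the low-weighted-median walk stops at score 2
  two <- dt(start = c(0L, 80L), end = c(80L, 100L), score = c(2, 10))
  expect_equal(length_weighted_median(0L, 100L, two), 2)
  # exact half-weight split: midpoint of the straddling scores
  half <- dt(start = c(0L, 50L), end = c(50L, 100L), score = c(1, 9))
  expect_equal(length_weighted_median(0L, 100L, half), 5)
  expect_true(is.na(length_weighted_median(200L, 300L, two)))
  expect_true(is.na(length_weighted_median(0L, 10L,
                                           dt(start = integer(),
                                              end = integer(),
                                              score = numeric()))))
})

test_that("LWM is record-order invariant and matches the unweighted median", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:9, 1)
    rec <- dt(start = seq(0L, by = 10L, length.out = n),
              end = seq(10L, by = 10L, length.out = n),
              score = round(stats::runif(n), 3))
    got <- length_weighted_median(0L, n * 10L, rec)
    expect_equal(got, stats::median(rec$score))
    expect_equal(length_weighted_median(0L, n * 10L, rec[sample(n)]), got)
  }
})

test_that("shipped calling rules behave as documented", {
  rules <- default_call_rules()
  expect_true(apply_call_rule(0.6, list(flags = 0), rules$irfinder))
  expect_false(apply_call_rule(0.6, list(flags = 1), rules$irfinder))
  expect_false(apply_call_rule(44.9, list(), rules$interest))
  expect_true(apply_call_rule(45, list(), rules$interest))
  expect_false(apply_call_rule(NA_real_, list(flags = 0), rules$irfinder))
  expect_error(apply_call_rule(0.6, list(), rules$irfinder), "flags")
  expect_true(apply_call_rule(5, list(unique_counts = 10), rules$kma))
  expect_false(apply_call_rule(5, list(unique_counts = 9), rules$kma))
  # PSI-style rules are strict inequalities
  expect_false(apply_call_rule(0.5, list(), rules$majiq))
  expect_false(apply_call_rule(0.8, list(), rules$suppa2))
  # iREAD sample profiles move the FPKM/fragment floors
  aux <- list(entropy = 0.95, junction_reads = 2, fragments = 12)
  expect_false(apply_call_rule(2, aux, rules$iread))
  expect_true(apply_call_rule(2, aux, default_call_rules("lenient")$iread))
})

test_that("truth categories and performance metrics follow the 2x2 rules", {
  uni <- dt(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
            end = c(50L, 150L, 250L, 350L), strand = "+")
  harm <- dt(uni, tool = "toolA", lwm = c(1, 2, NA, 4),
             potential = c(TRUE, TRUE, FALSE, TRUE),
             called = c(TRUE, FALSE, FALSE, TRUE))
  pers <- uni[c(1, 2)]
  tr <- assign_truth(harm, pers, uni)
  expect_equal(tr$category, c("TP", "FN", "TN", "FP"))

  perf <- performance(dt(tool = "t", tp = 2L, fp = 2L, fn = 2L, tn = 0L))
  expect_equal(perf$precision, 0.5)
  expect_equal(perf$recall, 0.5)
  expect_equal(perf$f1, 0.5)
  und <- performance(dt(tool = "t", tp = 0L, fp = 0L, fn = 5L, tn = 1L))
  expect_true(is.na(und$precision))
  expect_equal(und$recall, 0)
  expect_true(is.na(und$f1))
  frac <- performance(dt(tool = "t", tp = 6L, fp = 2L, fn = 3L, tn = 0L))
  expect_equal(frac$precision, 0.75)
  expect_equal(frac$recall, 2 / 3)
  expect_equal(frac$f1, 12 / 17)
})

test_that("the threshold sweep recomputes the persistent set per cutoff", {
  set.seed(11)
  n <- 40L
  uni <- dt(chrom = "chr1", start = seq(0L, by = 200L, length.out = n),
            end = seq(100L, by = 200L, length.out = n), strand = "+")
  pers <- dt(uni, P_i = round(stats::runif(n), 2))
  harm <- rbindlist(lapply(c("a", "b"), function(tool)
    dt(uni, tool = tool, lwm = stats::runif(n), potential = TRUE,
       called = stats::runif(n) < 0.5)))
  sweep <- threshold_sweep(pers, harm)
  expect_equal(nrow(sweep), 9L * 2L)
  expect_equal(nrow(threshold_sweep(pers, harm, 0.1)), 2L)
  # persistent universe shrinks: TP+FN non-increasing in the threshold
  tpfn <- sweep[tool == "a", tp + fn]
  expect_true(all(diff(tpfn) <= 0))
  # TP+FN (the persistent count) is identical across tools at any threshold
  wide <- sweep[, list(v = unique(tp + fn)), by = threshold]
  expect_equal(nrow(wide), 9L)
  # every cell count sums to the universe size
  expect_true(all(sweep[, tp + fp + fn + tn] == n))
})

test_that("potential and called summaries pair up as stated", {
  uni <- dt(chrom = "chr1", start = c(0L, 100L, 200L), end = c(50L, 150L, 250L),
            strand = "+")
  pers <- dt(uni, P_i = c(0.5, 0.0, 0.9))
  # a tool whose rule passes everything it expressed: pairs identical
  harm <- dt(uni, tool = "yes", lwm = c(1, 2, 3), potential = TRUE,
             called = TRUE)
  pvc <- potential_vs_called(pers, harm, 0.1)
  expect_equal(pvc[set == "potential", list(precision, recall, f1)],
               pvc[set == "called", list(precision, recall, f1)])
  # a tool that calls nothing: called-recall 0, potential unchanged
  none <- dt(uni, tool = "no", lwm = c(1, 2, 3), potential = TRUE,
             called = FALSE)
  pvc2 <- potential_vs_called(pers, none, 0.1)
  expect_equal(pvc2[set == "called", recall], 0)
  expect_equal(pvc2[set == "potential", recall], 1)
})

test_that("Fleiss' kappa matches hand and oracle computations", {
  # unanimous raters over a mixed intron set
  mixed <- cbind(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))
  expect_equal(fleiss_kappa(mixed), 1)
  # hand-evaluated 4 subjects x 3 raters: kappa = 1/3
  hand <- rbind(c(1, 1, 1), c(1, 0, 1), c(0, 0, 0), c(1, 0, 0))
  expect_equal(fleiss_kappa(hand), 1 / 3, tolerance = 1e-12)
  expect_equal(fleiss_kappa(hand), oracle_fleiss(hand), tolerance = 1e-12)
  # independent fair coins: kappa ~ 0
  set.seed(2024)
  coins <- matrix(stats::rbinom(1000 * 8, 1, 0.5), ncol = 8)
  expect_lt(abs(fleiss_kappa(coins)), 0.05)
  # degenerate: a single category everywhere -> undefined
  expect_true(is.na(fleiss_kappa(matrix(1, 5, 3))))
  # oracle equivalence on random matrices
  set.seed(77)
  for (rep in 1:100) {
    m <- matrix(stats::rbinom(40, 1, stats::runif(1, 0.2, 0.8)), ncol = 4)
    if (sum(m) %in% c(0, length(m))) next
    expect_equal(fleiss_kappa(m), oracle_fleiss(m), tolerance = 1e-12)
  }
})

test_that("consensus counts apply the >= min_tools rule per category", {
  uni <- dt(chrom = "chr1", start = c(0L, 100L), end = c(50L, 150L),
            strand = "+")
  # intron 1: TP for 3 tools of 8; intron 2: TP for 1 tool
  mk <- function(tool, cats) dt(uni, tool = tool, called = TRUE,
                                persistent = TRUE, category = cats)
  truth <- rbindlist(lapply(1:8, function(k)
    mk(paste0("t", k), c(if (k <= 3) "TP" else "TN",
                         if (k == 1) "TP" else "FN"))))
  expect_equal(consensus_counts(truth, "TP", 3L), 1L)
  expect_equal(consensus_counts(truth, "TP", 1L), 2L)
  expect_equal(consensus_counts(truth, "TP", 9L), 0L)
  expect_equal(consensus_counts(truth, "FN", 3L), 1L)
  ks <- vapply(1:8, function(k) consensus_counts(truth, "TP", k), integer(1))
  expect_true(all(diff(ks) <= 0))
  expect_equal(as.data.frame(consensus_introns(truth, "TP", 3L)),
               as.data.frame(uni[1]))
})

test_that("length windows and binned performance use sliding half-open bins", {
  win <- length_windows()
  expect_equal(nrow(win), 41L)
  expect_equal(win$window_start[1], 0L)
  expect_equal(win$window_end[41], 4300L)
  expect_equal(nrow(win),
               floor((4300 - 300) / 100) + 1)

  truth <- dt(chrom = "chr1", start = 0L, end = 250L, strand = "+",
              tool = "a", called = TRUE, persistent = TRUE, category = "TP")
  bp <- binned_performance(truth)
  hit <- bp[tp > 0, window_start]
  expect_equal(hit, c(0L, 100L, 200L))          # windows containing length 250
  empty <- bp[window_start == 1000L]
  expect_equal(empty$tp + empty$fp + empty$fn + empty$tn, 0L)
  expect_true(is.na(empty$precision))
})

test_that("binned intron profiles rescale coverage and exon overlap", {
  introns <- dt(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1400L))
  idx <- exon_index(dt(chrom = "chr1", start = 0L, end = 250L, strand = "+",
                       transcript_id = "tx"))
  flat <- dt(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1400L),
             value = 9)
  prof <- binned_intron_profile(introns, flat, idx, n_bins = 10L)
  expect_equal(prof$log10_median_coverage, rep(log10(10), 10))
  # the exon covers exactly the first half of intron 1 and none of intron 2
  expect_equal(prof$exon_overlap_fraction, rep(c(0.5, 0), each = 5))

  # linearly decreasing coverage gives strictly decreasing bin medians
  dec <- dt(chrom = "chr1", start = 0:499, end = 1:500,
            value = seq(100, 1, length.out = 500))
  prof2 <- binned_intron_profile(introns[1], dec, idx, n_bins = 20L)
  expect_true(all(diff(prof2$log10_median_coverage) < 0))

  # fractional-bin handling: intron shorter than the bin count
  tiny <- dt(chrom = "chr1", start = 0L, end = 7L)
  prof3 <- binned_intron_profile(tiny, flat, idx, n_bins = 10L)
  expect_equal(prof3$log10_median_coverage, rep(1, 10))
})

test_that("unknown tools are rejected with the known-tool list", {
  uni <- dt(chrom = "chr1", start = 0L, end = 50L, strand = "+")
  expect_error(harmonize_calls(uni, list(mystery = dt(chrom = "chr1",
                                                      start = 0L, end = 50L,
                                                      score = 1))),
               "mystery.*known tools")
})

test_that("LOESS smoothing is monotone-preserving on clean trends", {
  x <- 1:50
  y <- 2 * x + 5
  expect_equal(loess_smooth(x, y), y, tolerance = 1e-6)
})
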