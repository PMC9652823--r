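# Benchmarking short-read retained-intron callers against persistent introns.
#
# Caller outputs arrive as scored interval tables in each tool's native
# units; they are harmonized onto the long-read intron ranges by
# length-weighted medians (LWM), thresholded by per-tool calling rules, and
# compared with the persistent-intron set to form TP/FP/FN/TN categories and
# precision/recall/F1 summaries.

#' Length-weighted median score over a target interval
#'
#' Among records overlapping the target, each score is weighted by its
#' overlap length in bases and the weighted median is returned: scores are
#' sorted ascending and the first score whose cumulative weight reaches half
#' the total weight is taken; when the cumulative weight hits exactly half,
#' the midpoint of the straddling scores is returned (so the LWM reduces to
#' the plain median under equal weights).  `NA` when nothing overlaps.
#'
#' @param target_start,target_end target interval, 0-based half-open.
#' @param records data.table with `start`, `end`, `score` (same chromosome
#'   as the target).
#' @return numeric score or `NA`.
#' @export
length_weighted_median <- function(target_start, target_end, records) {
  records <- as.data.table(records)
  if (!nrow(records)) return(NA_real_)
  w <- overlap_width(records$start, records$end, target_start, target_end)
  keep <- w > 0L
  if (!any(keep)) return(NA_real_)
  weighted_median(records$score[keep], w[keep])
}

#' Per-tool calling rules
#'
#' Ships the default rule for each of the eight benchmarked callers, as
#' threshold predicates over the harmonized LWM score and auxiliary columns:
#' \describe{
#'   \item{interest}{FPKM (LWM) >= 45.}
#'   \item{kma}{unique counts >= 10.}
#'   \item{iread}{entropy >= 0.9, junction reads >= 1, plus sample-profile
#'     FPKM and fragment floors (`strict`: FPKM >= 3, fragments >= 20;
#'     `lenient`: FPKM >= 1, fragments >= 10).}
#'   \item{superintronic}{log2 coverage (LWM) >= 3.}
#'   \item{irfinder}{IRratio (LWM) >= 0.5 with no expression-profile flags.}
#'   \item{majiq}{PSI (LWM) > 0.5.}
#'   \item{rmats}{inclusion level (LWM) > 0.8.}
#'   \item{suppa2}{PSI (LWM) > 0.8.}
#' }
#'
#' @param profile iREAD sample profile: `"strict"` or `"lenient"`.
#' @return named list of rules; each rule has `tool`, `requires` (aux column
#'   names) and `fn(lwm, aux)`.
#' @export
default_call_rules <- function(profile = c("strict", "lenient")) {
  profile <- match.arg(profile)
  iread_fpkm <- if (profile == "strict") 3 else 1
  iread_frag <- if (profile == "strict") 20 else 10
  rule <- function(tool, requires, fn) list(tool = tool, requires = requires, fn = fn)
  list(
    interest = rule("interest", character(),
                    function(lwm, aux) lwm >= 45),
    kma = rule("kma", "unique_counts",
               function(lwm, aux) aux$unique_counts >= 10),
    iread = rule("iread", c("entropy", "junction_reads", "fragments"),
                 function(lwm, aux) aux$entropy >= 0.9 &
                   aux$junction_reads >= 1 & lwm >= iread_fpkm &
                   aux$fragments >= iread_frag),
    superintronic = rule("superintronic", character(),
                         function(lwm, aux) lwm >= 3),
    irfinder = rule("irfinder", "flags",
                    function(lwm, aux) lwm >= 0.5 & aux$flags == 0),
    majiq = rule("majiq", character(), function(lwm, aux) lwm > 0.5),
    rmats = rule("rmats", character(), function(lwm, aux) lwm > 0.8),
    suppa2 = rule("suppa2", character(), function(lwm, aux) lwm > 0.8))
}

#' Apply a calling rule to one harmonized record
#'
#' @param lwm harmonized LWM score (`NA` when the tool reported nothing
#'   overlapping the intron; always yields `FALSE`).
#' @param aux named list of harmonized auxiliary values.
#' @param rule one element of [default_call_rules()].
#' @return logical call.
#' @export
apply_call_rule <- function(lwm, aux, rule) {
  miss <- setdiff(rule$requires, names(aux))
  if (length(miss))
    stop("call rule '", rule$tool, "' requires missing auxiliary field(s): ",
         paste(miss, collapse = ", "))
  if (is.na(lwm)) return(FALSE)
  isTRUE(rule$fn(lwm, aux))
}

#' Harmonize caller outputs onto the long-read intron universe
#'
#' For each intron of the universe and each tool, computes the LWM of the
#' tool's scores over the intron (and the LWM of every auxiliary column the
#' tool's rule requires), then applies the tool's calling rule.
#'
#' @param universe data.table of intron ranges: `chrom`, `start`, `end`,
#'   `strand`.
#' @param call_sets named list (tool -> data.table with `chrom`, `start`,
#'   `end`, `score` and any auxiliary columns).
#' @param rules named list of rules, as [default_call_rules()]; must cover
#'   `names(call_sets)`.
#' @return data.table: intron key columns, `tool`, `lwm`, `potential`
#'   (LWM present), `called`.
#' @export
harmonize_calls <- function(universe, call_sets, rules = default_call_rules()) {
  universe <- as.data.table(universe)
  unknown <- setdiff(names(call_sets), names(rules))
  if (length(unknown))
    stop("no calling rule for tool(s): ", paste(unknown, collapse = ", "),
         "; known tools: ", paste(names(rules), collapse = ", "))
  out <- vector("list", length(call_sets))
  for (t in seq_along(call_sets)) {
    tool <- names(call_sets)[t]
    rec <- as.data.table(call_sets[[t]])
    rule <- rules[[tool]]
    have_aux <- intersect(rule$requires, names(rec))
    lwm <- numeric(nrow(universe))
    called <- logical(nrow(universe))
    for (k in seq_len(nrow(universe))) {
      on_chrom <- rec[rec$chrom == universe$chrom[k], ]
      l <- length_weighted_median(universe$start[k], universe$end[k], on_chrom)
      aux <- lapply(stats::setNames(have_aux, have_aux), function(col) {
        r2 <- data.table(start = on_chrom$start, end = on_chrom$end,
                         score = on_chrom[[col]])
        length_weighted_median(universe$start[k], universe$end[k], r2)
      })
      lwm[k] <- l
      called[k] <- apply_call_rule(l, aux, rule)
    }
    out[[t]] <- data.table(universe[, list(chrom, start, end, strand)],
                           tool = tool, lwm = lwm,
                           potential = !is.na(lwm), called = called)
  }
  rbindlist(out)
}

intron_key <- function(dt) paste(dt$chrom, dt$start, dt$end, dt$strand)

#' Assign truth categories
#'
#' Per intron of the universe and per tool: TP when persistent and called,
#' FP when called but not persistent, FN when persistent but not called, TN
#' when neither.
#'
#' @param harmonized output of [harmonize_calls()] (uses `called`).
#' @param persistent data.table of persistent intron keys (`chrom`, `start`,
#'   `end`, `strand`).
#' @param universe intron universe; harmonized rows outside it are dropped.
#' @return data.table: intron key columns, `tool`, `called`, `persistent`,
#'   `category`.
#' @export
assign_truth <- function(harmonized, persistent, universe) {
  h <- as.data.table(harmonized)
  h <- h[intron_key(h) %in% intron_key(as.data.table(universe))]
  pk <- intron_key(as.data.table(persistent))
  h[, persistent := intron_key(h) %in% pk]
  h[, category := fifelse(persistent & called, "TP",
                  fifelse(!persistent & called, "FP",
                  fifelse(persistent & !called, "FN", "TN")))]
  h[, list(chrom, start, end, strand, tool, called, persistent, category)]
}

#' Precision / recall / F1 from a truth table
#'
#' Undefined ratios (zero denominators) are reported as `NA`, not 0; F1 is
#' `NA` whenever precision or recall is.
#'
#' @param truth output of [assign_truth()], or a data.table of counts with
#'   columns `tp`, `fp`, `fn`, `tn` (one row per tool).
#' @return data.table: `tool`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`.
#' @export
performance <- function(truth) {
  truth <- as.data.table(truth)
  if (all(c("tp", "fp", "fn", "tn") %in% names(truth))) {
    counts <- copy(truth)
  } else {
    counts <- truth[, list(tp = sum(category == "TP"),
                           fp = sum(category == "FP"),
                           fn = sum(category == "FN"),
                           tn = sum(category == "TN")), by = tool]
  }
  counts[, precision := ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)]
  counts[, recall := ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)]
  counts[, f1 := ifelse(!is.na(precision) & !is.na(recall) &
                          precision + recall > 0,
                        2 * precision * recall / (precision + recall),
                        NA_real_)]
  counts[]
}

#' Performance across persistence thresholds
#'
#' Recomputes the persistent set at each threshold (`P_i >= threshold`,
#' inclusive) and summarizes every tool at every threshold.
#'
#' @param persistence gene-level persistence table ([intron_persistence()]):
#'   intron keys plus `P_i`.
#' @param harmonized output of [harmonize_calls()].
#' @param thresholds ascending persistence cutoffs (default 0.1 to 0.9 by
#'   0.1, the sweep analyzed in the benchmark).
#' @param use column defining a positive call: `"called"` (rule-passing,
#'   default) or `"potential"` (any overlapping expression evidence).
#' @return data.table: `threshold`, `tool`, counts and metrics.
#' @export
threshold_sweep <- function(persistence, harmonized,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            use = c("called", "potential")) {
  use <- match.arg(use)
  stopifnot(!is.unsorted(thresholds))
  persistence <- as.data.table(persistence)
  h <- copy(as.data.table(harmonized))
  if (use == "potential") h[, called := potential]
  universe <- unique(h[, list(chrom, start, end, strand)])
  out <- lapply(thresholds, function(th) {
    keep <- persistence[P_i >= th, list(chrom, start, end, strand)]
    perf <- performance(assign_truth(h, keep, universe))
    perf[, threshold := th]
    perf
  })
  res <- rbindlist(out)
  data.table::setcolorder(res, c("threshold", "tool"))
  res[]
}

#' Potential vs. called performance pairs
#'
#' For each tool and threshold, pairs the performance of the raw set of all
#' potential RIs (every intron with any overlapping expression evidence,
#' i.e. LWM present) with the performance of the rule-passing called subset.
#'
#' @inheritParams threshold_sweep
#' @return data.table with a `set` column (`"potential"` / `"called"`).
#' @export
potential_vs_called <- function(persistence, harmonized,
                                thresholds = seq(0.1, 0.9, by = 0.1)) {
  pot <- threshold_sweep(persistence, harmonized, thresholds, use = "potential")
  cal <- threshold_sweep(persistence, harmonized, thresholds, use = "called")
  pot[, set := "potential"]; cal[, set := "called"]
  rbindlist(list(pot, cal))
}

#' Fleiss' kappa for binary call agreement
#'
#' Standard Fleiss' kappa with raters = tools and two categories
#' (called / not called) over a common intron universe.  When the expected
#' agreement is 1 (every rating in one category) kappa is undefined and `NA`
#' is returned.
#'
#' @param calls logical or 0/1 matrix, introns x tools.
#' @return kappa, or `NA` when undefined.
#' @export
fleiss_kappa <- function(calls) {
  calls <- as.matrix(calls)
  stopifnot(ncol(calls) >= 2L, nrow(calls) >= 2L)
  mode(calls) <- "integer"
  n <- ncol(calls)                      # raters per subject
  c1 <- rowSums(calls)
  c0 <- n - c1
  P_subject <- (c1^2 + c0^2 - n) / (n * (n - 1))
  p1 <- sum(c1) / (length(c1) * n)
  pe <- p1^2 + (1 - p1)^2
  if (pe >= 1) return(NA_real_)
  (mean(P_subject) - pe) / (1 - pe)
}

#' Consensus counts across tools
#'
#' Number of introns belonging to a truth category for at least `min_tools`
#' tools (e.g. a "TP 3+" intron is TP for >= 3 of the 8 tools).  Categories
#' are counted independently: an intron can satisfy the rule for TP under
#' some tools and FP under others.
#'
#' @param truth output of [assign_truth()] over all tools.
#' @param category one of `"TP"`, `"FP"`, `"FN"`.
#' @param min_tools minimum number of agreeing tools (default 3).
#' @return integer count.
#' @export
consensus_counts <- function(truth, category = c("TP", "FP", "FN"),
                             min_tools = 3L) {
  wanted <- match.arg(category)
  truth <- as.data.table(truth)
  per <- truth[category == wanted,
               list(n_tools = .N), by = list(chrom, start, end, strand)]
  sum(per$n_tools >= min_tools)
}

#' Consensus introns in a category
#'
#' The intron keys counted by [consensus_counts()].
#'
#' @inheritParams consensus_counts
#' @return data.table of intron keys.
#' @export
consensus_introns <- function(truth, category = c("TP", "FP", "FN"),
                              min_tools = 3L) {
  wanted <- match.arg(category)
  truth <- as.data.table(truth)
  per <- truth[category == wanted,
               list(n_tools = .N), by = list(chrom, start, end, strand)]
  per[n_tools >= min_tools, list(chrom, start, end, strand)]
}

#' Sliding intron-length windows
#'
#' @param window_width window width in bases (default 300).
#' @param step window step (default 100).
#' @param min_len,max_len length range (defaults 0 and 4300); windows are
#'   `[s, s + width)` for every s with `s + width <= max_len`.
#' @return data.table `window_start`, `window_end` (41 windows under the
#'   defaults).
#' @export
length_windows <- function(window_width = 300L, step = 100L, min_len = 0L,
                           max_len = 4300L) {
  stopifnot(window_width > 0L, step > 0L)
  starts <- seq.int(min_len, max_len - window_width, by = step)
  data.table(window_start = starts, window_end = starts + window_width)
}

#' Performance by intron-length windows
#'
#' Assigns each intron to every sliding window containing its length and
#' summarizes precision/recall/F1 per window per tool.  Empty windows report
#' `NA` metrics.
#'
#' @param truth output of [assign_truth()] (intron keys give lengths as
#'   `end - start`).
#' @inheritParams length_windows
#' @return data.table: `window_start`, `window_end`, `tool`, counts,
#'   metrics.
#' @export
binned_performance <- function(truth, window_width = 300L, step = 100L,
                               min_len = 0L, max_len = 4300L) {
  truth <- copy(as.data.table(truth))
  win <- length_windows(window_width, step, min_len, max_len)
  truth[, length := end - start]
  tools <- unique(truth$tool)
  out <- lapply(seq_len(nrow(win)), function(k) {
    sub <- truth[length >= win$window_start[k] & length < win$window_end[k]]
    if (nrow(sub)) {
      perf <- performance(sub)
    } else {
      perf <- data.table(tool = tools, tp = 0L, fp = 0L, fn = 0L, tn = 0L,
                         precision = NA_real_, recall = NA_real_,
                         f1 = NA_real_)
    }
    perf[, `:=`(window_start = win$window_start[k],
                window_end = win$window_end[k])]
    perf
  })
  res <- rbindlist(out)
  data.table::setcolorder(res, c("window_start", "window_end", "tool"))
  res[]
}

# per-base coverage vector over [start, end); bases without a record are 0
coverage_vector <- function(coverage, chrom, start, end) {
  v <- numeric(end - start)
  keep <- coverage$chrom == chrom & coverage$end > start & coverage$start < end
  cv <- as.data.table(coverage)[which(keep)]
  for (k in seq_len(nrow(cv))) {
    a <- max(cv$start[k], start) - start + 1L
    b <- min(cv$end[k], end) - start
    v[a:b] <- v[a:b] + cv$value[k]
  }
  v
}

#' Binned intron coverage and exon-overlap profile
#'
#' Rescales every intron of a group (typically a >=3-of-8 consensus truth
#' category) to `n_bins` equal bins oriented 5' to 3' on the positive
#' genomic strand (minus-strand introns are deliberately not flipped,
#' matching the positive-strand axis convention of the profile plots) and
#' reports, per bin, the log10 of the median across introns of the mean
#' per-base short-read coverage (pseudocount added before the log), and the
#' fraction of introns whose bin overlaps at least one annotated exon.
#' Introns shorter than `n_bins` are handled by proportional (fractional
#' base) weighting.
#'
#' @param introns data.table of intron keys (`chrom`, `start`, `end`).
#' @param coverage bedGraph coverage table.
#' @param index an [exon_index()] over the annotation.
#' @param n_bins number of bins (default 1000).
#' @param pseudocount added before the log10 transform (default 1).
#' @return data.table: `bin`, `log10_median_coverage`,
#'   `exon_overlap_fraction`.
#' @export
binned_intron_profile <- function(introns, coverage, index, n_bins = 1000L,
                                  pseudocount = 1) {
  introns <- as.data.table(introns)
  stopifnot(nrow(introns) >= 1L, n_bins >= 1L)
  covmat <- matrix(NA_real_, nrow = nrow(introns), ncol = n_bins)
  exonmat <- matrix(FALSE, nrow = nrow(introns), ncol = n_bins)
  for (k in seq_len(nrow(introns))) {
    s <- introns$start[k]; e <- introns$end[k]; L <- e - s
    v <- coverage_vector(coverage, introns$chrom[k], s, e)
    cum <- c(0, cumsum(v))
    # linear interpolation of the cumulative coverage at fractional bases
    cf <- function(x) {
      j <- pmin(floor(x), L - 1e-9)
      j0 <- floor(j)
      cum[j0 + 1] + (x - j0) * v[pmin(j0 + 1, L)]
    }
    edges <- L * (0:n_bins) / n_bins
    binsum <- cf(edges[-1]) - cf(edges[-(n_bins + 1)])
    covmat[k, ] <- binsum / (L / n_bins)
    ex <- query_exons(index, introns$chrom[k], s, e)
    if (nrow(ex)) {
      for (b in seq_len(n_bins)) {
        a0 <- s + edges[b]; a1 <- s + edges[b + 1]
        exonmat[k, b] <- any(pmin(ex$end, a1) - pmax(ex$start, a0) > 1e-9)
      }
    }
  }
  data.table(bin = seq_len(n_bins),
             log10_median_coverage =
               log10(apply(covmat, 2, stats::median) + pseudocount),
             exon_overlap_fraction = colMeans(exonmat))
}

#' LOESS presentation smoother
#'
#' Optional helper for smoothing binned outputs before plotting; all
#' quantitative results in the package are computed on unsmoothed bins.
#'
#' @param x,y numeric vectors.
#' @param span LOESS span (default 0.5).
#' @return numeric vector of fitted values at `x`.
#' @export
loess_smooth <- function(x, y, span = 0.5) {
  keep <- !is.na(y)
  fit <- stats::loess(y[keep] ~ x[keep], span = span)
  out <- rep(NA_real_, length(x))
  out[keep] <- stats::predict(fit)
  out
}
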