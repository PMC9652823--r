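#' @importFrom data.table data.table setkey setorder rbindlist fread fwrite
#'   as.data.table copy setnames fifelse setcolorder tstrsplit := .N .SD
#' @import IRanges
NULL

# All genomic intervals inside the package are 0-based half-open [start, end)
# on the forward genomic strand.  GTF is converted from 1-based closed at
# parse time; BED and bedGraph are already 0-based half-open.  IRanges (1-based
# closed) is used only as an overlap engine behind to_iranges().

#' Validate a genomic-interval table
#'
#' Checks the package-wide interval invariants: required columns present,
#' `start < end`, and strand in `{+, -}` (when a strand column exists).
#'
#' @param x data.frame/data.table with columns `chrom`, `start`, `end` and
#'   optionally `strand`.
#' @param what label used in error messages.
#' @return `x` as a data.table, invisibly-validated.
#' @export
validate_intervals <- function(x, what = "interval table") {
  x <- as.data.table(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(x) && any(x$start >= x$end))
    stop(what, ": found interval with start >= end (0-based half-open convention)")
  if ("strand" %in% names(x) && nrow(x) && !all(x$strand %in% c("+", "-")))
    stop(what, ": strand must be '+' or '-'")
  x
}

# 0-based half-open -> IRanges (1-based closed)
to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# overlap width between [s1,e1) and [s2,e2), 0 if disjoint
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Build an exon overlap index
#'
#' Interval index over all annotated exons, keyed by chromosome, each entry
#' carrying its source transcript id.  Used for the intron/exon overlap
#' statistics and for bin-level exon overlap in coverage profiles.
#'
#' @param exons data.table with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id` (0-based half-open).
#' @return object of class `exon_index`.
#' @export
exon_index <- function(exons) {
  exons <- validate_intervals(exons, "exon table")
  if (!"transcript_id" %in% names(exons))
    stop("exon table: missing column transcript_id")
  by_chrom <- split(exons, by = "chrom", keep.by = TRUE)
  idx <- lapply(by_chrom, function(dt) {
    list(ranges = to_iranges(dt$start, dt$end), table = dt)
  })
  structure(list(chrom = idx), class = "exon_index")
}

# exons intersecting [start, end) on chrom; returns data.table (possibly empty)
query_exons <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "exon_index"))
  entry <- index$chrom[[chrom]]
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), transcript_id = character())
  if (is.null(entry)) return(empty)
  hits <- IRanges::findOverlaps(to_iranges(start, end), entry$ranges)
  entry$table[S4Vectors::subjectHits(hits)]
}

#' @export
print.exon_index <- function(x, ...) {
  n <- sum(vapply(x$chrom, function(e) nrow(e$table), integer(1)))
  cat("exon_index:", n, "exons on", length(x$chrom), "chromosome(s)\n")
  invisible(x)
}
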