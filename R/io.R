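# Table output with provenance headers and atomic writes.
#
# Every table the pipeline writes starts with a single comment line carrying
# the package version and a hash of the run configuration, and is written to
# a temporary file in the destination directory then renamed, so a failing
# run never leaves a partial table behind.

pkg_version <- function() {
  as.character(utils::packageVersion("ripbench"))
}

# stable md5 of an R object (via its deparsed form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result table atomically with a provenance header
#'
#' @param dt data.table/data.frame.
#' @param path destination path.
#' @param config run configuration embedded (hashed) in the header line.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(dt, path, config = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  header <- sprintf("# ripbench %s config=%s", pkg_version(),
                    config_hash(config))
  writeLines(header, tmp)
  fwrite(dt, tmp, sep = "\t", append = TRUE, col.names = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path table path.
#' @return data.table.
#' @export
read_result_table <- function(path) {
  fread(path, sep = "\t", skip = 1L, header = TRUE)
}

#' Read a run configuration file
#'
#' Plain `key: value` lines (comments with `#`); keys use the CLI flag names
#' with underscores, e.g. `min_reads: 5`.  Values are parsed as numbers when
#' numeric.
#'
#' @param path config path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
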