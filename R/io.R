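# Reading and writing the long observation CSV dialect.

#' Read a long-format observation table
#'
#' Reads a UTF-8 comma-separated file with the exact header
#' `dam_id,group,ppd,period,slot,code,aux` into a validated [beh_dataset].
#' `aux` is a semicolon-joined list of auxiliary event symbols or empty.
#' Validation errors (missing or duplicate slots, unknown codes, a dam
#' appearing under two groups) name the offending row.
#'
#' @param path Path to an observation CSV.
#' @return A [beh_dataset].
#' @seealso [write_observations()]
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, .OBS_HEADER))
    stop("unexpected header in ", path, "; expected '",
         paste(.OBS_HEADER, collapse = ","), "'")
  x <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (nrow(x) == 0)
    return(structure(
      data.frame(dam_id = character(), group = character(),
                 ppd = integer(), period = character(), slot = integer(),
                 code = character(), aux = character(),
                 stringsAsFactors = FALSE),
      metadata = list(source = path),
      class = c("beh_dataset", "data.frame")))
  beh_dataset(x, metadata = list(source = path))
}

#' Write an observation dataset to CSV
#'
#' Writes the canonical long CSV (header `dam_id,group,ppd,period,slot,code,aux`)
#' in canonical row order (dam, day, period, slot), so
#' `read_observations(write_observations(d, f))` reproduces `d` exactly.
#'
#' @param dataset A [beh_dataset].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(dataset, path) {
  x <- as.data.frame(dataset)
  lines <- c(paste(.OBS_HEADER, collapse = ","),
             if (nrow(x) > 0)
               paste(x$dam_id, x$group, x$ppd, x$period, x$slot, x$code, x$aux,
                     sep = ","))
  write_atomic(lines, path)
  invisible(path)
}

# Write lines to `path` via a temporary file in the same directory, then
# rename, so no output file is ever partially written.
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con)
    close(con)
    ok <- TRUE
  }, finally = {
    if (!ok) {
      try(close(con), silent = TRUE)
      unlink(tmp)
    }
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("cannot write to ", path)
  }
  invisible(path)
}

# TSV writer used by the pipeline exports (atomic).
write_tsv <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0)
               do.call(paste, c(lapply(df, format_tsv_col), sep = "\t")))
  write_atomic(lines, path)
}

format_tsv_col <- function(v) {
  if (is.double(v)) formatC(v, digits = 10, format = "g") else as.character(v)
}
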