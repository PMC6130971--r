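#' Build a trace set
#'
#' A trace set is a long-form tibble of per-frame two-channel intensities
#' (`molecule_id`, `field_id`, `frame`, `donor`, `acceptor`) carrying the
#' shared acquisition metadata (`frame_rate`, `condition`) as attributes.
#' All traces of a set share one frame rate.
#'
#' @param traces Long tibble with the columns above (a `time` column is
#'   tolerated and recomputed on read).
#' @param frame_rate Acquisition rate in Hz.
#' @param condition Free-text condition label.
#' @return The validated tibble with class `trace_set` prepended.
#' @export
trace_set <- function(traces, frame_rate, condition = "") {
  stopifnot(frame_rate > 0)
  req <- c("molecule_id", "field_id", "frame", "donor", "acceptor")
  missing_cols <- setdiff(req, names(traces))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(traces) > 0) {
    check <- traces |>
      dplyr::group_by(.data$molecule_id) |>
      dplyr::summarise(
        contiguous = all(sort(.data$frame) == seq(0L, dplyr::n() - 1L)),
        complete = !anyNA(.data$donor) && !anyNA(.data$acceptor),
        .groups = "drop"
      )
    if (any(!check$contiguous)) {
      stop("frames must be contiguous 0-based integers per molecule; offending molecule(s): ",
           paste(check$molecule_id[!check$contiguous], collapse = ", "))
    }
    if (any(!check$complete)) {
      stop("donor/acceptor values missing for molecule(s): ",
           paste(check$molecule_id[!check$complete], collapse = ", "))
    }
  }
  out <- tibble::as_tibble(traces)[, intersect(c(req, "time"), names(traces))]
  attr(out, "frame_rate") <- frame_rate
  attr(out, "condition") <- condition
  class(out) <- c("trace_set", class(out))
  out
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d molecules, %d frames total, %g Hz%s\n",
              length(unique(x$molecule_id)), nrow(x), attr(x, "frame_rate"),
              if (nzchar(attr(x, "condition") %||% "")) paste0(" [", attr(x, "condition"), "]") else ""))
  NextMethod()
}

io_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("csv", "tsv", "parquet")))
  switch(tolower(tools::file_ext(path)),
         csv = "csv", tsv = "tsv", parquet = "parquet",
         stop("cannot infer format from extension of ", path))
}

#' Write a trace set to disk
#'
#' CSV/TSV are the canonical interchange formats (UTF-8, header row, '.'
#' decimal point; a `# frame_rate=... condition=...` comment line precedes
#' the header). Parquet (via the arrow package) is the bulk format and
#' round-trips the metadata through column attributes.
#'
#' @param ts A [trace_set()].
#' @param path Output file path.
#' @param format `"csv"`, `"tsv"` or `"parquet"`; inferred from the
#'   extension when omitted.
#' @param overwrite Must be `TRUE` to replace an existing file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path, format = NULL, overwrite = FALSE) {
  format <- io_format(path, format)
  if (file.exists(path) && !overwrite) {
    stop("file exists and overwrite = FALSE: ", path)
  }
  fr <- attr(ts, "frame_rate")
  cond <- attr(ts, "condition") %||% ""
  cols <- c("molecule_id", "field_id", "frame", "donor", "acceptor")
  flat <- tibble::as_tibble(as.data.frame(ts)[, cols])
  if (format %in% c("csv", "tsv")) {
    txt <- if (format == "csv") readr::format_csv(flat) else readr::format_tsv(flat)
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# frame_rate=%.10g condition=%s", fr, cond), con)
    writeLines(sub("\n+$", "", txt), con)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for parquet output")
    }
    attr(flat, "frame_rate") <- fr
    attr(flat, "condition") <- cond
    arrow::write_parquet(flat, path)
  }
  invisible(path)
}

#' Read a trace set from disk
#'
#' Inverse of [write_traces()]. Validates that the required columns are
#' present, that every molecule's frames are contiguous 0-based integers,
#' and that no per-frame values are missing. An empty file yields an empty
#' trace set with a warning.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"parquet"`; inferred from the
#'   extension when omitted.
#' @param frame_rate Frame rate override; by default read from the file's
#'   metadata (comment line or parquet attributes).
#' @return A [trace_set()].
#' @export
read_traces <- function(path, format = NULL, frame_rate = NULL) {
  format <- io_format(path, format)
  if (!file.exists(path)) stop("no such file: ", path)
  cond <- ""
  if (format %in% c("csv", "tsv")) {
    first <- readLines(path, n = 1, encoding = "UTF-8")
    if (length(first) == 1 && startsWith(first, "#")) {
      m <- regmatches(first, regexec("frame_rate=([0-9.eE+-]+)", first))[[1]]
      if (length(m) == 2 && is.null(frame_rate)) frame_rate <- as.numeric(m[2])
      mc <- regmatches(first, regexec("condition=(.*)$", first))[[1]]
      if (length(mc) == 2) cond <- mc[2]
    }
    delim <- if (format == "csv") "," else "\t"
    tb <- readr::read_delim(path, delim = delim, comment = "#",
                            show_col_types = FALSE, progress = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required for parquet input")
    }
    tb <- tibble::as_tibble(arrow::read_parquet(path))
    if (is.null(frame_rate)) frame_rate <- attr(tb, "frame_rate")
    cond <- attr(tb, "condition") %||% ""
  }
  if (nrow(tb) == 0) {
    warning("empty trace file: ", path)
    tb <- tibble::tibble(molecule_id = character(0), field_id = character(0),
                         frame = integer(0), donor = numeric(0),
                         acceptor = numeric(0))
  }
  if (is.null(frame_rate)) {
    stop("frame_rate not found in file metadata; supply it explicitly")
  }
  ts <- trace_set(tb, frame_rate = frame_rate, condition = cond)
  ts$time <- ts$frame / frame_rate
  ts
}

#' Write a results table with provenance header
#'
#' Writes a CSV preceded by a comment line recording the package version
#' and a hash of the run configuration, so every output table is
#' attributable to the exact parameters that produced it.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param config Optional configuration list to hash into the header.
#' @param overwrite Must be `TRUE` to replace an existing file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, config = NULL, overwrite = TRUE) {
  if (file.exists(path) && !overwrite) {
    stop("file exists and overwrite = FALSE: ", path)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("fretkin"))
  hash <- if (is.null(config)) "none" else rlang::hash(config)
  writeLines(sprintf("# fretkin %s config_hash=%s", ver, hash), con)
  writeLines(sub("\n+$", "", readr::format_csv(tibble::as_tibble(x))), con)
  invisible(path)
}
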