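#' Raw signal reads and SLOW5 ASCII I/O
#'
#' A `raw_read` holds the integer DAC samples of one nanopore read plus the
#' standard calibration constants; `pA = (s + offset) * range / digitisation`.
#'
#' @param read_id read identifier.
#' @param samples integer DAC values.
#' @param digitisation,offset,range calibration constants.
#' @param sampling_rate sampling rate in Hz.
#' @return object of class `raw_read`.
#' @export
raw_read <- function(read_id, samples, digitisation = 8192, offset = 10,
                     range = 1500, sampling_rate = 4000) {
  if (length(samples) == 0) stop("samples must be non-empty")
  stopifnot(is.finite(digitisation), is.finite(offset), is.finite(range),
            is.finite(sampling_rate))
  structure(list(read_id = read_id, samples = as.integer(samples),
                 digitisation = digitisation, offset = offset, range = range,
                 sampling_rate = sampling_rate),
            class = "raw_read")
}

#' Calibrate DAC samples to picoamps
#' @param read a [raw_read()].
#' @return numeric vector of pA values.
#' @export
calibrate_signal <- function(read) {
  (read$samples + read$offset) * read$range / read$digitisation
}

SLOW5_COLS <- c("read_id", "read_group", "digitisation", "offset", "range",
                "sampling_rate", "len_raw_signal", "raw_signal")

#' Read a SLOW5 ASCII file
#'
#' Parses the plain-text SLOW5 dialect: `@` metadata lines, `#`-prefixed type
#' and column-name header lines, and one tab-separated record per read with a
#' comma-separated `raw_signal` column. Reads whose declared
#' `len_raw_signal` disagrees with the parsed sample count are skipped with a
#' warning. Binary raw-signal formats (BLOW5/POD5/FAST5) are not parsed; see
#' [read_raw_reads()].
#'
#' @param path SLOW5 file path.
#' @return list of [raw_read()] objects in file order.
#' @export
read_slow5 <- function(path) {
  lines <- readLines(path)
  colline <- grep("^#read_id", lines)
  if (length(colline) != 1)
    stop("SLOW5 format error: missing '#read_id ...' column header in ", path)
  cols <- strsplit(sub("^#", "", lines[colline]), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(SLOW5_COLS, cols)
  if (length(missing))
    stop("SLOW5 format error: missing mandatory column(s) ",
         paste(missing, collapse = ", "))
  data <- lines[-seq_len(colline)]
  data <- data[nzchar(data) & !grepl("^[#@]", data)]
  reads <- list()
  for (ln in data) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    names(f) <- cols[seq_along(f)]
    sig <- as.integer(strsplit(f[["raw_signal"]], ",", fixed = TRUE)[[1]])
    declared <- as.integer(f[["len_raw_signal"]])
    if (length(sig) != declared) {
      warning("read ", f[["read_id"]], ": declared length ", declared,
              " != ", length(sig), " parsed samples; read skipped")
      next
    }
    reads[[length(reads) + 1L]] <-
      raw_read(f[["read_id"]], sig,
               digitisation = as.numeric(f[["digitisation"]]),
               offset = as.numeric(f[["offset"]]),
               range = as.numeric(f[["range"]]),
               sampling_rate = as.numeric(f[["sampling_rate"]]))
  }
  reads
}

#' Write a SLOW5 ASCII file
#' @param reads list of [raw_read()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slow5 <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#slow5_version\t0.2.0", "#num_read_groups\t1",
               "@asic_id\t0",
               paste0("#", paste(c("char*", "uint32_t", "double", "double",
                                   "double", "double", "uint64_t", "int16_t*"),
                                 collapse = "\t")),
               paste0("#", paste(SLOW5_COLS, collapse = "\t"))), con)
  for (r in reads) {
    writeLines(paste(r$read_id, 0, format(r$digitisation, digits = 17),
                     format(r$offset, digits = 17), format(r$range, digits = 17),
                     format(r$sampling_rate, digits = 17), length(r$samples),
                     paste(r$samples, collapse = ","), sep = "\t"), con)
  }
  invisible(path)
}

#' Fetch one read from a SLOW5 file by id
#'
#' Returns the same record a sequential scan would yield; if the id occurs
#' more than once the first occurrence is returned with a warning.
#'
#' @param path SLOW5 file path.
#' @param read_id read identifier to fetch.
#' @return a [raw_read()].
#' @export
get_read <- function(path, read_id) {
  reads <- read_slow5(path)
  ids <- vapply(reads, `[[`, "", "read_id")
  hit <- which(ids == read_id)
  if (length(hit) == 0)
    stop("read id not found in ", path, ": ", read_id)
  if (length(hit) > 1)
    warning("duplicate entries for read id ", read_id, "; first returned")
  reads[[hit[1]]]
}

#' Raw-read input dispatch
#'
#' Entry point for raw signal input. The SLOW5 ASCII dialect is implemented;
#' the binary formats are declared adapter interfaces and report themselves
#' as unavailable via `raw_format_supported()`.
#'
#' @param path signal file path (`.slow5` implemented).
#' @return list of [raw_read()] objects.
#' @export
read_raw_reads <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!isTRUE(raw_format_supported(ext)))
    stop("raw signal format '", ext, "' is a declared adapter interface ",
         "without an implementation; use SLOW5 ASCII")
  read_slow5(path)
}

#' @rdname read_raw_reads
#' @param format file extension (e.g. `"slow5"`, `"pod5"`).
#' @export
raw_format_supported <- function(format) {
  c(slow5 = TRUE, blow5 = FALSE, pod5 = FALSE, fast5 = FALSE)[tolower(format)]
}
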