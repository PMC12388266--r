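#' Signal file input/output
#'
#' Two dialects cover the acquisition chain's export formats: RIFF WAV
#' (PCM16, scaled to `[-1, 1)` by `1/32768`, or IEEE float32 passthrough)
#' and plain comma-separated text with one or two numeric columns and an
#' optional single header line. Two-channel files are returned as two
#' separate series so they can be fused explicitly by
#' [superpose_channels()].
#'
#' @name io
NULL

read_u32 <- function(con) readBin(con, "integer", 1L, 4L, signed = TRUE,
                                  endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1L, 2L, signed = FALSE,
                                  endian = "little")

read_wav_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop(sprintf("%s: not a RIFF file (leading bytes '%s')", path, riff),
         call. = FALSE)
  invisible(read_u32(con))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("%s: RIFF file is not WAVE data", path), call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- read_u32(con)
    if (identical(id, "fmt ")) {
      fmt <- list(audio_format = read_u16(con),
                  channels = read_u16(con),
                  rate = read_u32(con))
      invisible(read_u32(con))        # byte rate
      invisible(read_u16(con))        # block align
      fmt$bits <- read_u16(con)
      if (size > 16L) invisible(readBin(con, "raw", size - 16L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop(sprintf("%s: missing fmt or data chunk", path), call. = FALSE)
  if (!fmt$channels %in% 1:2)
    stop(sprintf("%s: %d channels unsupported (expect 1 or 2)", path,
                 fmt$channels), call. = FALSE)
  samples <-
    if (fmt$audio_format == 1L && fmt$bits == 16L) {
      readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
              signed = TRUE, endian = "little") / 32768
    } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
      readBin(data_raw, "double", length(data_raw) %/% 4L, 4L,
              endian = "little")
    } else {
      stop(sprintf("%s: unsupported WAV encoding (format %d, %d bits); expect PCM16 or float32",
                   path, fmt$audio_format, fmt$bits), call. = FALSE)
    }
  chans <- lapply(seq_len(fmt$channels), function(c_)
    time_series(samples[seq.int(c_, length(samples), fmt$channels)],
                fmt$rate))
  if (fmt$channels == 1L) chans[[1L]] else chans
}

read_csv_file <- function(path, rate) {
  if (file.size(path) == 0L)
    stop(sprintf("%s: empty file", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1L]])))
  df <- tryCatch(
    utils::read.csv(path, header = has_header,
                    colClasses = "numeric", strip.white = TRUE),
    error = function(e)
      stop(sprintf("%s: cannot parse CSV (%s)", path, conditionMessage(e)),
           call. = FALSE))
  if (ncol(df) < 1L || ncol(df) > 2L)
    stop(sprintf("%s: expected 1 or 2 numeric columns, found %d", path,
                 ncol(df)), call. = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("%s: no sample rows", path), call. = FALSE)
  chans <- lapply(df, function(col) {
    if (anyNA(col))
      stop(sprintf("%s: non-numeric or missing values (first bad row: %d)",
                   path, which(is.na(col))[1L]), call. = FALSE)
    time_series(col, rate)
  })
  if (length(chans) == 1L) chans[[1L]] else unname(chans)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("wav", "wave")) "wav"
  else if (ext %in% c("csv", "txt")) "csv"
  else stop(sprintf("cannot infer format of '%s'; pass format = \"wav\" or \"csv\"",
                    path), call. = FALSE)
}

#' Read a one- or two-channel signal file
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @param rate sampling rate used for CSV files (WAV files carry their own).
#' @return a [time_series], or a list of two for two-channel files.
#' @export
read_signal <- function(path, format = c("auto", "wav", "csv"), rate = 8000) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  if (format == "wav") read_wav_file(path) else read_csv_file(path, rate)
}

write_wav_file <- function(channels, path, type) {
  rate <- channels[[1L]]$rate
  n_ch <- length(channels)
  inter <- numeric(n_ch * length(channels[[1L]]$samples))
  for (c_ in seq_len(n_ch))
    inter[seq.int(c_, length(inter), n_ch)] <- channels[[c_]]$samples
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (type == "pcm16") 16L else 32L
  bytes <- bits %/% 8L
  data_size <- length(inter) * bytes
  w_u32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(if (type == "pcm16") 1L else 3L); w_u16(n_ch); w_u32(rate)
  w_u32(rate * n_ch * bytes); w_u16(n_ch * bytes); w_u16(bits)
  writeChar("data", con, eos = NULL); w_u32(data_size)
  if (type == "pcm16") {
    q <- as.integer(pmin(pmax(round(inter * 32768), -32768), 32767))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(inter, con, 4L, endian = "little")
  }
  invisible(path)
}

#' Write a signal (or channel pair) to WAV or CSV
#'
#' @param x a [time_series] or list of two with equal length and rate.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @param type WAV sample encoding: `"float"` (IEEE float32) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, format = c("auto", "wav", "csv"),
                         type = c("float", "pcm16")) {
  format <- match.arg(format); type <- match.arg(type)
  channels <- if (inherits(x, "time_series")) list(x) else x
  stopifnot(length(channels) %in% 1:2,
            all(vapply(channels, inherits, TRUE, "time_series")))
  if (length(channels) == 2L &&
      length(channels[[1L]]$samples) != length(channels[[2L]]$samples))
    stop("channels must have equal length", call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  if (format == "wav") return(write_wav_file(channels, path, type))
  df <- as.data.frame(lapply(channels, `[[`, "samples"))
  names(df) <- if (length(channels) == 1L) "amplitude"
               else c("channel_1", "channel_2")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
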