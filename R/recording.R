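#' Construct a multichannel extracellular recording
#'
#' A recording holds a channels x samples voltage matrix together with its
#' sampling rate, stimulus onset times and slice/animal metadata. Voltages are
#' volts at the electrode unless `meta$gain` says otherwise; times are seconds
#' from trace start; sample indices are 0-based in the on-disk format.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate, Hz.
#' @param stim_times Strictly increasing stimulus onsets, seconds.
#' @param meta Named list of metadata. Recognized fields: `slice_id`,
#'   `animal_id`, `group`, `gain` (amplifier gain, default 10000),
#'   `band` (length-2 Hz, default `c(100, 6000)`), `precision`
#'   (`"float32"` or `"float64"` payload precision, default `"float64"`).
#' @return An object of class `mua_recording`.
#' @export
new_recording <- function(data, fs, stim_times = numeric(),
                          meta = list()) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  defaults <- list(slice_id = "slice1", animal_id = "animal1",
                   group = "unknown", gain = 10000,
                   band = c(100, 6000), precision = "float64")
  meta <- modifyList(defaults, meta)
  rec <- structure(
    list(data = data, fs = fs, stim_times = as.numeric(stim_times),
         channel_count = nrow(data), meta = meta),
    class = "mua_recording"
  )
  validate_recording(rec)
}

validate_recording <- function(rec) {
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0) {
    abort("fs must be > 0")
  }
  if (length(rec$data) == 0 || ncol(rec$data) == 0) abort("empty recording")
  if (rec$channel_count != nrow(rec$data)) {
    abort("channel_count does not match number of data rows")
  }
  dur <- ncol(rec$data) / rec$fs
  st <- rec$stim_times
  if (length(st)) {
    if (any(st < 0) || any(st >= dur)) {
      abort("all stim_times must lie within [0, duration)")
    }
    if (any(diff(st) <= 0)) abort("stim_times must be strictly increasing")
  }
  if (!rec$meta$precision %in% c("float32", "float64")) {
    abort("precision must be float32 or float64")
  }
  rec
}

#' @export
print.mua_recording <- function(x, ...) {
  cat(sprintf(
    "<mua_recording> %d channels x %d samples @ %g Hz (%.3f s), %d stimuli\n",
    x$channel_count, ncol(x$data), x$fs, ncol(x$data) / x$fs,
    length(x$stim_times)))
  cat(sprintf("  slice %s / animal %s / group %s; band %g-%g Hz; %s payload\n",
              x$meta$slice_id, x$meta$animal_id, x$meta$group,
              x$meta$band[1], x$meta$band[2], x$meta$precision))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `mua_recording`.
#' @return Scalar seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

MUA_MAGIC <- "MUATRACE1"

#' Write a recording to a self-describing binary trace file
#'
#' The format is a magic line (`MUATRACE1`), a decimal header byte length on
#' its own line, a UTF-8 JSON header (fs, channel_count, n_samples,
#' stim_times, precision, metadata), then the channel-major little-endian
#' float payload at the precision declared in `rec$meta$precision`
#' (`float32` or `float64`). A `float64` payload round-trips R doubles
#' bit-for-bit; `float32` round-trips data that is already
#' single-precision-representable (the simulator quantizes its output so
#' that this holds).
#'
#' @param rec A valid `mua_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  header <- list(
    fs = rec$fs,
    channel_count = rec$channel_count,
    n_samples = ncol(rec$data),
    stim_times = as.numeric(rec$stim_times),
    precision = rec$meta$precision,
    meta = rec$meta[setdiff(names(rec$meta), "precision")]
  )
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hjson))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    abort(paste0("cannot open for writing: ", path))
  })
  on.exit(close(con))
  writeLines(c(MUA_MAGIC, as.character(length(hraw))), con)
  writeBin(hraw, con)
  size <- if (rec$meta$precision == "float32") 4L else 8L
  # channel-major: each channel's samples contiguous
  writeBin(as.numeric(t(rec$data)), con, size = size, endian = "little")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to a trace file.
#' @return An `mua_recording`; values identical to what was written (at the
#'   declared payload precision).
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, MUA_MAGIC)) {
    abort("format error: missing MUATRACE1 magic")
  }
  hlen <- suppressWarnings(as.integer(readLines(con, n = 1)))
  if (is.na(hlen) || hlen <= 0) abort("format error: bad header length")
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen))),
    error = function(e) abort("format error: corrupt JSON header"))
  for (f in c("fs", "channel_count", "n_samples", "precision")) {
    if (is.null(header[[f]])) {
      abort(paste0("format error: header missing field '", f, "'"))
    }
  }
  if (header$fs <= 0) abort("fs must be > 0")
  size <- if (header$precision == "float32") 4L else 8L
  n <- header$channel_count * header$n_samples
  payload <- readBin(con, "double", n = n, size = size, endian = "little")
  if (length(payload) != n) {
    abort(sprintf(
      "integrity error: payload has %d values, header declares %d",
      length(payload), n))
  }
  data <- matrix(payload, nrow = header$channel_count, byrow = TRUE)
  meta <- as.list(header$meta)
  meta$band <- as.numeric(meta$band)
  meta$precision <- header$precision
  new_recording(data, header$fs,
                stim_times = as.numeric(header$stim_times %||% numeric()),
                meta = meta)
}

# quantize a numeric vector/matrix to what an IEEE float32 payload preserves
quantize_float32 <- function(x) {
  d <- dim(x)
  q <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               "double", n = length(x), size = 4L, endian = "little")
  dim(q) <- d
  q
}
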