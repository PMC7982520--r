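#' Epoch a continuous EDF recording
#'
#' Reads a European Data Format (EDF) file and cuts stimulus-locked epochs
#' from it using an event table. The reader supports the plain EDF layout
#' (16-bit integer samples with per-signal physical/digital scaling,
#' identical sampling rate across the selected signals); EDF+ annotation
#' streams are not parsed, which is why events are supplied as a table.
#'
#' @param path EDF file.
#' @param events a `data.frame` with columns `onset_sample` (1-based sample
#'   index of stimulus onset in the continuous recording) and `label`
#'   (`"accept"`/`"reject"`), or a path to a delimited file with those
#'   columns.
#' @param epoch_window `(start_ms, end_ms)` window to cut around each onset.
#' @param channels optional subset of signal labels to keep (default: all).
#' @param subject_id subject identifier stored in the result.
#' @return an [epoch_set].
#' @export
read_edf_epochs <- function(path, events, epoch_window = c(-200, 800),
                            channels = NULL, subject_id = "S01") {
  rec <- read_edf(path)
  if (is.character(events)) {
    events <- read.table(events, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
  }
  if (!all(c("onset_sample", "label") %in% names(events)))
    stop2("event table needs columns 'onset_sample' and 'label'")
  if (!is.null(channels)) {
    miss <- setdiff(channels, rec$channel_names)
    if (length(miss) > 0)
      stop2("channel(s) not in EDF: %s", paste(miss, collapse = ", "))
    keep <- match(channels, rec$channel_names)
    rec$data <- rec$data[keep, , drop = FALSE]
    rec$channel_names <- channels
  }
  fs <- rec$sampling_rate
  off0 <- round(epoch_window[1] / 1000 * fs)
  n_sa <- round(diff(epoch_window) / 1000 * fs)
  n_tr <- nrow(events)
  n_ch <- nrow(rec$data)
  data <- array(0, dim = c(n_tr, n_ch, n_sa))
  for (t in seq_len(n_tr)) {
    i0 <- events$onset_sample[t] + off0
    if (i0 < 1 || i0 + n_sa - 1 > ncol(rec$data))
      stop2("epoch %d (samples %d..%d) falls outside the recording",
            t, i0, i0 + n_sa - 1)
    data[t, , ] <- rec$data[, i0:(i0 + n_sa - 1)]
  }
  epoch_set(data, labels = events$label, channel_names = rec$channel_names,
            sampling_rate = fs, epoch_window = epoch_window,
            subject_id = subject_id)
}

# Minimal EDF reader: 256-byte fixed header, field-major signal headers,
# int16 little-endian data records, physical = affine(digital).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                       # version
  hdr(80); hdr(80)             # patient / recording id
  hdr(8); hdr(8)               # start date / time
  hdr(8)                       # header byte count
  hdr(44)                      # reserved
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  n_sig <- as.integer(hdr(4))
  if (!is_count(n_sig)) stop2("'%s' does not look like an EDF file", path)
  field <- function(w) vapply(seq_len(n_sig), function(i) hdr(w), character(1))
  labels <- field(16)
  field(80)                    # transducer
  field(8)                     # physical dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                    # prefiltering
  spr <- as.integer(field(8))  # samples per record
  field(32)                    # reserved
  if (length(unique(spr)) != 1)
    stop2("EDF signals have differing sampling rates; not supported")
  data <- matrix(0, nrow = n_sig, ncol = n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      data[s, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        pmin[s] + (dig - dmin[s]) * scale[s]
    }
  }
  list(data = data, channel_names = labels,
       sampling_rate = spr[1] / rec_dur)
}

# Minimal EDF writer. Fixture generator for tests and a convenience for
# exporting synthetic recordings; quantizes to the int16 digital range.
write_edf <- function(data, channel_names, sampling_rate, path,
                      physical_range = c(-1000, 1000)) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names))
  spr <- as.integer(sampling_rate)   # one-second records
  if (ncol(data) %% spr != 0)
    stop2("sample count must be a whole number of 1 s records")
  n_rec <- ncol(data) / spr
  n_sig <- nrow(data)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf("%-*s", w, as.character(x))
    writeChar(substr(s, 1, w), con, eos = NULL)
  }
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 * (1 + n_sig), 8); pad("", 44)
  pad(n_rec, 8); pad("1", 8); pad(n_sig, 4)
  for (ch in channel_names) pad(ch, 16)
  for (i in seq_len(n_sig)) pad("", 80)
  for (i in seq_len(n_sig)) pad("uV", 8)
  for (i in seq_len(n_sig)) pad(physical_range[1], 8)
  for (i in seq_len(n_sig)) pad(physical_range[2], 8)
  for (i in seq_len(n_sig)) pad(-32768, 8)
  for (i in seq_len(n_sig)) pad(32767, 8)
  for (i in seq_len(n_sig)) pad("", 80)
  for (i in seq_len(n_sig)) pad(spr, 8)
  for (i in seq_len(n_sig)) pad("", 32)
  scale <- 65535 / diff(physical_range)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      x <- data[s, ((r - 1) * spr + 1):(r * spr)]
      dig <- as.integer(round((x - physical_range[1]) * scale) - 32768)
      dig <- pmax(pmin(dig, 32767L), -32768L)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
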