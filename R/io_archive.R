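#' Read and write epoch archives
#'
#' The package's on-disk epoch format is deliberately language-neutral and
#' diffable: a directory holding one delimited numeric matrix per trial
#' (channels x samples, comma separated, full 17-significant-digit
#' precision so 64-bit round trips are lossless) plus a JSON manifest with
#' the sampling rate, epoch window, channel names, labels and subject.
#'
#' @param epochs an [epoch_set].
#' @param path directory to create/read.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   an [epoch_set].
#' @seealso [read_edf_epochs()] for epoching continuous EDF recordings.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop2("cannot create archive directory '%s'", path)
  d <- dim(epochs$data)
  manifest <- list(
    format = "erpdecode-epochs-v1",
    n_trials = d[1],
    n_channels = d[2],
    n_samples = d[3],
    sampling_rate = epochs$sampling_rate,
    epoch_window = epochs$epoch_window,
    channel_names = as.list(epochs$channel_names),
    labels = if (is.null(epochs$labels)) NULL else as.list(as.character(epochs$labels)),
    subject_id = epochs$subject_id,
    subjects = if (is.null(epochs$subjects)) NULL else as.list(epochs$subjects)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  for (t in seq_len(d[1])) {
    m <- matrix(epochs$data[t, , ], nrow = d[2])
    lines <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = ","))
    writeLines(lines, file.path(path, sprintf("trial_%04d.csv", t)))
  }
  invisible(path)
}

#' @param format `"archive"` for the package epoch archive. EDF input goes
#'   through [read_edf_epochs()].
#' @rdname write_epochs
#' @export
read_epochs <- function(path, format = "archive") {
  format <- match.arg(format, "archive")
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    stop2("not an epoch archive: missing manifest at '%s'", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  n_tr <- man$n_trials; n_ch <- man$n_channels; n_sa <- man$n_samples
  data <- array(0, dim = c(n_tr, n_ch, n_sa))
  for (t in seq_len(n_tr)) {
    f <- file.path(path, sprintf("trial_%04d.csv", t))
    if (!file.exists(f)) stop2("archive inconsistent: missing '%s'", f)
    m <- as.matrix(read.table(f, sep = ",", header = FALSE))
    if (nrow(m) != n_ch || ncol(m) != n_sa)
      stop2("trial %d shape (%d x %d) disagrees with manifest (%d x %d)",
            t, nrow(m), ncol(m), n_ch, n_sa)
    data[t, , ] <- m
  }
  labels <- man$labels
  if (!is.null(labels) && length(labels) != n_tr)
    stop2("manifest labels length (%d) disagrees with n_trials (%d)",
          length(labels), n_tr)
  epoch_set(data,
            labels = labels,
            channel_names = unlist(man$channel_names),
            sampling_rate = as.numeric(man$sampling_rate),
            epoch_window = as.numeric(man$epoch_window),
            subject_id = man$subject_id %||% "S01",
            subjects = if (is.null(man$subjects)) NULL else unlist(man$subjects))
}
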