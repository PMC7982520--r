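#' Electrode montages
#'
#' A montage is a named, ordered set of electrode labels in 10-20/10-10
#' nomenclature. Four built-in presets of 4, 16, 32 and 60 electrodes are
#' provided for channel-subset experiments; they are strictly nested
#' (`active4` is a subset of `active16`, and so on) so that reduced-channel
#' runs use nested information. The exact preset memberships follow standard
#' symmetric 10-20/10-10 coverage and can be overridden by loading a montage
#' from a file (one electrode label per line).
#'
#' The montage's listed order is the sequence order fed to the recurrent
#' classifier, so montages are ordered, not sets.
#'
#' @param name_or_path one of `"active4"`, `"active16"`, `"active32"`,
#'   `"active60"`, or a path to a text file with one electrode label per
#'   line.
#' @return an object of class `montage`: a character vector of electrode
#'   labels with a `name` attribute.
#' @examples
#' length(load_montage("active4"))   # 4
#' length(load_montage("active60"))  # 60
#' @export
load_montage <- function(name_or_path) {
  stopifnot(is.character(name_or_path), length(name_or_path) == 1)
  if (name_or_path %in% names(.montage_presets)) {
    labels <- .montage_presets[[name_or_path]]
    name <- name_or_path
  } else if (file.exists(name_or_path)) {
    labels <- readLines(name_or_path, warn = FALSE)
    labels <- trimws(labels)
    labels <- labels[nzchar(labels)]
    name <- basename(name_or_path)
  } else {
    stop2("unknown montage preset or missing file: '%s'", name_or_path)
  }
  montage(labels, name = name)
}

#' @param channels ordered character vector of electrode labels.
#' @param name montage name.
#' @rdname load_montage
#' @export
montage <- function(channels, name = "custom") {
  channels <- as.character(channels)
  if (length(channels) == 0) stop2("montage must be non-empty")
  if (anyDuplicated(channels))
    stop2("duplicate electrode label(s): %s",
          paste(unique(channels[duplicated(channels)]), collapse = ", "))
  structure(channels, name = name, class = c("montage", "character"))
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage '%s'> %d electrodes: %s\n", attr(x, "name"),
              length(x), paste(head(unclass(x), 8), collapse = " ")),
      if (length(x) > 8) "  ...\n" else "")
  invisible(x)
}

# Nested presets: each larger set extends the previous one.
.montage_presets <- local({
  a4 <- c("Fz", "Cz", "Pz", "Oz")
  a16 <- c(a4, "Fp1", "Fp2", "F3", "F4", "F7", "F8",
           "C3", "C4", "T7", "T8", "P3", "P4")
  a32 <- c(a16, "FC1", "FC2", "FC5", "FC6", "CP1", "CP2", "CP5", "CP6",
           "P7", "P8", "O1", "O2", "FT9", "FT10", "TP9", "TP10")
  a60 <- c(a32, "AF3", "AF4", "AF7", "AF8", "F1", "F2", "F5", "F6",
           "FC3", "FC4", "FT7", "FT8", "C1", "C2", "C5", "C6",
           "CP3", "CP4", "TP7", "TP8", "P1", "P2", "P5", "P6",
           "PO3", "PO4", "PO7", "PO8")
  list(active4 = a4, active16 = a16, active32 = a32, active60 = a60)
})
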