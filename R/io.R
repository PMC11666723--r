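#' Epoched multichannel signal container
#'
#' The canonical in-memory container for epoched signals: a
#' channel x time x trial array plus its sampling rate, event-relative
#' time axis, alignment event and channel metadata. Mirrors the role an
#' MNE `Epochs` / FieldTrip `timelock` structure plays in EEG pipelines.
#'
#' @param data numeric array, channel x time x trial.
#' @param srate sampling rate (Hz).
#' @param time numeric time axis (s), strictly increasing and uniformly
#'   spaced at `1/srate`; length must match `dim(data)[2]`.
#' @param alignment name of the event the time axis is relative to
#'   (`"cue"`, `"stimulus"`, `"probe"`, `"response"`).
#' @param channels character channel labels, length `dim(data)[1]`.
#' @param neighbors optional named list mapping each channel to its
#'   spatial neighbors (used by cluster tests and simulators).
#' @param trial_info optional data.frame of per-trial metadata (load etc.).
#' @return an object of class `maat_epochs`.
#' @export
maat_epochs <- function(data, srate, time, alignment, channels,
                        neighbors = NULL, trial_info = NULL) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(channels),
            dim(data)[2] == length(time))
  dt <- diff(time)
  if (any(dt <= 0) || max(abs(dt - 1 / srate)) > 1e-6) {
    stop("time axis must be strictly increasing with spacing 1/srate")
  }
  if (!is.null(neighbors)) {
    if (!all(names(neighbors) %in% channels)) {
      stop("neighbor map names channels absent from the montage")
    }
  }
  structure(list(data = data, srate = srate, time = time,
                 alignment = alignment, channels = channels,
                 neighbors = neighbors, trial_info = trial_info),
            class = "maat_epochs")
}

#' @export
print.maat_epochs <- function(x, ...) {
  cat(sprintf("<maat_epochs> %d ch x %d samples x %d trials @ %g Hz, %s-locked [%g, %g] s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$srate,
              x$alignment, min(x$time), max(x$time)))
  invisible(x)
}

#' @export
dim.maat_epochs <- function(x) dim(x$data)

#' Write / read an epoched container as a plain-text bundle
#'
#' Serializes a [maat_epochs] object to a directory holding a JSON
#' attribute file (`attrs.json`: srate, time origin, alignment, channel
#' labels, dims) and a flat TSV payload of the array in channel-major
#' order. A plain-text stand-in for an HDF5 container, chosen because no
#' HDF5 R binding is available in the target environment; the attribute
#' contract is the same.
#'
#' @param x a [maat_epochs] object.
#' @param path directory to create/read.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   the reconstructed [maat_epochs].
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "maat_epochs"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  attrs <- list(srate = x$srate, t0 = x$time[1], alignment = x$alignment,
                channels = x$channels, dims = dim(x$data),
                neighbors = x$neighbors)
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(matrix(as.vector(x$data), nrow = 1),
                     file.path(path, "data.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  if (!is.null(x$trial_info)) {
    write_tsv(x$trial_info, file.path(path, "trial_info.tsv"))
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"),
                               simplifyVector = TRUE)
  vals <- scan(file.path(path, "data.tsv"), quiet = TRUE)
  data <- array(vals, dim = attrs$dims)
  time <- attrs$t0 + seq(0, by = 1 / attrs$srate,
                         length.out = attrs$dims[2])
  ti <- NULL
  tif <- file.path(path, "trial_info.tsv")
  if (file.exists(tif)) ti <- read_tsv(tif)
  nb <- attrs$neighbors
  if (length(nb) == 0) nb <- NULL
  maat_epochs(data, attrs$srate, time, attrs$alignment, attrs$channels,
              neighbors = nb, trial_info = ti)
}

#' Tab-separated table I/O with stable conventions
#'
#' Thin wrappers fixing the TSV dialect used throughout the package
#' (tab separator, header row, no quoting, no row names).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Load a stimulus/effect/pipeline configuration file
#'
#' Reads a YAML (or JSON) mapping and merges it over the package defaults
#' produced by [stimulus_config()], [effect_config()] or
#' [pipeline_config()]. Unknown top-level keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @param type one of `"stimulus"`, `"effects"`, `"pipeline"`.
#' @return the merged configuration list.
#' @export
load_config <- function(path, type = c("stimulus", "effects", "pipeline")) {
  type <- match.arg(type)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- switch(type,
                 stimulus = stimulus_config(),
                 effects = effect_config(),
                 pipeline = pipeline_config())
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  merged <- utils::modifyList(base, raw)
  class(merged) <- class(base)
  merged
}
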