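#' Multichannel recording container
#'
#' A `recording` holds one subject's one-modality multichannel time series as
#' a time-by-channel numeric matrix together with its sampling rate, channel
#' labels, modality tag and units. All feature-extraction functions accept and
#' return this container.
#'
#' @param data numeric matrix, time points in rows, channels in columns.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector, one label per channel. Defaults to
#'   the column names of `data`, or `ch1..chN`.
#' @param modality free-text tag (e.g. `"eeg"`, `"od_760"`).
#' @param units free-text unit label (e.g. `"uV"`, `"OD"`).
#' @return an object of class `recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(200), 100, 2), fs = 100)
#' rec
recording <- function(data, fs, channel_labels = NULL, modality = "eeg",
                      units = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(data)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(data)))
    }
  }
  if (length(channel_labels) != ncol(data)) {
    stop("`channel_labels` must have one entry per channel", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("recording data must be finite", call. = FALSE)
  }
  colnames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         modality = modality, units = units),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %.4f Hz (%.1f s)%s\n",
              x$modality, ncol(x$data), nrow(x$data), x$fs,
              nrow(x$data) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$data)
n_channels <- function(rec) ncol(rec$data)

#' Oxy-/deoxyhemoglobin concentration series
#'
#' Container for band-limited concentration-change time series of both
#' chromophores, in micromolar units, sharing channels and sampling rate.
#'
#' @param hbo,hbr numeric time-by-channel matrices of oxy- and deoxyhemoglobin
#'   concentration changes (uM).
#' @param fs sampling rate in Hz.
#' @param channel_labels channel labels shared by both chromophores.
#' @return an object of class `hb_series`.
#' @export
hb_series <- function(hbo, hbr, fs, channel_labels = NULL) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr))) {
    stop("hbo and hbr must have identical dimensions", call. = FALSE)
  }
  if (!all(is.finite(hbo)) || !all(is.finite(hbr))) {
    stop("hb_series values must be finite", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- colnames(hbo)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(ncol(hbo)))
  }
  colnames(hbo) <- channel_labels; colnames(hbr) <- channel_labels
  structure(list(hbo = hbo, hbr = hbr, fs = fs,
                 channel_labels = channel_labels, units = "uM"),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> %d channels x %d samples @ %.4f Hz [uM]\n",
              ncol(x$hbo), nrow(x$hbo), x$fs))
  invisible(x)
}
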