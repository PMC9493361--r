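# Recording I/O: delimited text (canonical), minimal EDF, minimal SNIRF.

#' Write a recording to disk
#'
#' Three formats are supported. `"delimited"` (canonical, lossless): a
#' tab-separated table with `#key value` metadata header lines. `"edf"`:
#' a minimal single-record European Data Format file (16-bit samples, so
#' values round-trip only to the per-channel quantisation step).
#' `"snirf"`: a minimal SNIRF (HDF5) file carrying the time series, time
#' axis and wavelength table.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @param format `"delimited"`, `"edf"` or `"snirf"`.
#' @param wavelengths for SNIRF: wavelength table in nm (default 760, 850).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path,
                            format = c("delimited", "edf", "snirf"),
                            wavelengths = c(760, 850)) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  switch(format,
         delimited = write_recording_delim(rec, path),
         edf = write_recording_edf(rec, path),
         snirf = write_recording_snirf(rec, path, wavelengths))
  invisible(path)
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]. Malformed files raise a format error
#' describing what is missing.
#'
#' @param path input file path.
#' @param format `"delimited"`, `"edf"` or `"snirf"`.
#' @return a [recording()].
#' @export
read_recording <- function(path, format = c("delimited", "edf", "snirf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  switch(format,
         delimited = read_recording_delim(path),
         edf = read_recording_edf(path),
         snirf = read_recording_snirf(path))
}

write_recording_delim <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#fs\t%.10g", rec$fs),
               sprintf("#modality\t%s", rec$modality),
               sprintf("#units\t%s", rec$units)), con)
  close(con); on.exit()
  data.table::fwrite(as.data.frame(rec$data), path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  path
}

read_recording_delim <- function(path) {
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3 || !all(startsWith(hdr, "#"))) {
    stop(sprintf("malformed delimited recording %s: expected 3 '#key\\tvalue' header lines",
                 path), call. = FALSE)
  }
  kv <- strsplit(sub("^#", "", hdr), "\t")
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "\t"),
                                 character(1)),
                          vapply(kv, `[[`, character(1), 1))
  if (!"fs" %in% names(meta)) {
    stop(sprintf("malformed delimited recording %s: missing #fs", path),
         call. = FALSE)
  }
  dt <- data.table::fread(path, sep = "\t", skip = 3, header = TRUE)
  recording(as.matrix(dt), as.numeric(meta[["fs"]]),
            channel_labels = colnames(dt),
            modality = if ("modality" %in% names(meta)) meta[["modality"]] else "",
            units = if ("units" %in% names(meta)) meta[["units"]] else "")
}

# ---- minimal EDF (single data record, 16-bit) ------------------------------

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

write_recording_edf <- function(rec, path) {
  X <- rec$data
  ns <- ncol(X); n <- nrow(X)
  pmin_ <- apply(X, 2, min); pmax_ <- apply(X, 2, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round(sweep(sweep(X, 2, pmin_), 2, (pmax_ - pmin_) / (dmax - dmin), `/`)) + dmin
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)                                  # version
  wr("synthetic subject", 80)                 # patient id (synthetic data)
  wr(paste("neurocpm", rec$modality), 80)     # recording id
  wr(format(Sys.Date(), "01.01.00"), 8)       # fixed date: reproducible files
  wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8)         # header bytes
  wr("", 44)
  wr("1", 8)                                  # one data record
  wr(sprintf("%.6g", n / rec$fs), 8)          # record duration (s)
  wr(as.character(ns), 4)
  labels <- substr(rec$channel_labels, 1, 16)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)  # transducer
  for (i in seq_len(ns)) wr(rec$units, 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmin_[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", pmax_[i]), 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)           # prefiltering
  for (i in seq_len(ns)) wr(as.character(n), 8)
  for (i in seq_len(ns)) wr("", 32)
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  path
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) {
    stop(sprintf("malformed EDF %s: bad signal count at offset 252", path),
         call. = FALSE)
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop(sprintf("EDF %s: differing samples-per-record not supported", path),
         call. = FALSE)
  }
  n <- spr[1] * nrec
  X <- matrix(0, n, ns)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      phys <- (d - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) + pmin_[i]
      X[((r - 1) * spr[1] + 1):(r * spr[1]), i] <- phys
    }
  }
  modality <- sub("^neurocpm ?", "", rec_id)
  recording(X, spr[1] * nrec / (dur * nrec), channel_labels = labels,
            modality = if (nzchar(modality)) modality else "eeg",
            units = units[1])
}

# ---- minimal SNIRF (HDF5) --------------------------------------------------

write_recording_snirf <- function(rec, path, wavelengths) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5write(rec$data, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(nrow(rec$data)) - 1) / rec$fs, path,
                 "nirs/data1/time")
  rhdf5::h5write(as.numeric(wavelengths), path, "nirs/probe/wavelengths")
  rhdf5::h5write(rec$channel_labels, path, "nirs/probe/channelLabels")
  rhdf5::h5closeAll()
  path
}

read_recording_snirf <- function(path) {
  contents <- rhdf5::h5ls(path)
  paths <- file.path(contents$group, contents$name)
  need <- c("/nirs/data1/dataTimeSeries", "/nirs/data1/time")
  miss <- setdiff(need, paths)
  if (length(miss)) {
    stop(sprintf("malformed SNIRF %s: missing dataset %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"/nirs/probe/wavelengths" %in% paths) {
    stop(sprintf("malformed SNIRF %s: missing wavelength table /nirs/probe/wavelengths",
                 path), call. = FALSE)
  }
  X <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  tm <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  labels <- if ("/nirs/probe/channelLabels" %in% paths) {
    as.character(rhdf5::h5read(path, "nirs/probe/channelLabels"))
  } else NULL
  rhdf5::h5closeAll()
  fs <- 1 / stats::median(diff(tm))
  recording(X, fs, channel_labels = labels, modality = "fnirs")
}

#' Write a synthetic cohort to a directory
#'
#' One delimited recording per subject and stream, a `performance.csv` table
#' (subject_id, performance) and a `ground_truth.json` sidecar.
#'
#' @param cohort a `synthetic_cohort` generated with signals.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    if (is.null(subj$eeg)) {
      stop("cohort was generated without signals; nothing to write",
           call. = FALSE)
    }
    write_recording(subj$eeg, file.path(dir, paste0(subj$id, "_eeg.tsv")))
    fn <- subj$fnirs
    if (inherits(fn, "hb_series")) {
      write_recording(recording(fn$hbo, fn$fs, fn$channel_labels, "hbo", "uM"),
                      file.path(dir, paste0(subj$id, "_hbo.tsv")))
      write_recording(recording(fn$hbr, fn$fs, fn$channel_labels, "hbr", "uM"),
                      file.path(dir, paste0(subj$id, "_hbr.tsv")))
    } else {
      write_recording(fn$od_760, file.path(dir, paste0(subj$id, "_od760.tsv")))
      write_recording(fn$od_850, file.path(dir, paste0(subj$id, "_od850.tsv")))
    }
  }
  perf <- data.frame(subject_id = names(cohort$subjects),
                     performance = cohort$truth$performance)
  data.table::fwrite(perf, file.path(dir, "performance.csv"))
  jsonlite::write_json(
    list(planted_edges = cohort$truth$planted_edges,
         planted_edge_targets = cohort$truth$planted_edge_targets,
         performance = cohort$truth$performance,
         spec = unclass(cohort$spec)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
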