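# Per-subject, per-modality Pearson functional connectivity.

#' Connectivity matrix container
#'
#' @param values symmetric channel-by-channel Pearson correlation matrix.
#' @param modality one of `"hbo"`, `"hbr"`, `"beta_m_alpha"`,
#'   `"gamma_m_alpha"` (other labels are allowed but the CPM stage expects
#'   these four).
#' @param subject_id subject label.
#' @param channel_labels channel labels; default from `values` dimnames.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, modality, subject_id = NA_character_,
                                channel_labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(abs(values) > 1 + 1e-8)) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  values[values > 1] <- 1; values[values < -1] <- -1
  diag(values) <- 1
  if (is.null(channel_labels)) {
    channel_labels <- rownames(values)
    if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(values)))
  }
  dimnames(values) <- list(channel_labels, channel_labels)
  structure(list(values = values, channel_labels = channel_labels,
                 modality = modality, subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %dx%d, subject %s\n",
              x$modality, nrow(x$values), ncol(x$values), x$subject_id))
  invisible(x)
}

#' Pearson functional connectivity over the resting block
#'
#' Entry (i, j) is the Pearson correlation of channels i and j over the
#' analysed block. For `am_series` inputs the first/last `trim_s` seconds
#' (filter and Hilbert transients) are excluded; hemoglobin series are used
#' untrimmed. A constant channel makes the correlation undefined and raises
#' an error naming the channel.
#'
#' @param x an `am_series`, [hb_series()], [recording()] or plain
#'   time-by-channel matrix.
#' @param component for `hb_series` input: `"hbo"` or `"hbr"`.
#' @param block optional `c(start_s, end_s)` restricting the analysed block
#'   (seconds from record start); default the whole record.
#' @param modality modality tag for the result; inferred when possible.
#' @param subject_id subject label for the result.
#' @return a [connectivity_matrix()].
#' @export
pearson_connectivity <- function(x, component = c("hbo", "hbr"), block = NULL,
                                 modality = NULL, subject_id = NA_character_) {
  trim_s <- 0
  fs <- NULL
  if (inherits(x, "hb_series")) {
    component <- match.arg(component)
    if (is.null(modality)) modality <- component
    fs <- x$fs
    labels <- x$channel_labels
    mat <- x[[component]]
  } else if (inherits(x, "recording")) {
    if (inherits(x, "am_series")) trim_s <- x$trim_s
    if (is.null(modality)) modality <- x$modality
    fs <- x$fs
    labels <- x$channel_labels
    mat <- x$data
  } else {
    mat <- as.matrix(x)
    labels <- colnames(mat)
    if (is.null(modality)) modality <- "unknown"
  }
  if (!is.null(block)) {
    stopifnot(length(block) == 2, !is.null(fs))
    i0 <- max(1L, floor(block[1] * fs) + 1L)
    i1 <- min(nrow(mat), ceiling(block[2] * fs))
    if (i1 <= i0) stop("requested block lies outside the record", call. = FALSE)
    mat <- mat[i0:i1, , drop = FALSE]
  }
  if (trim_s > 0 && !is.null(fs)) {
    k <- round(trim_s * fs)
    if (nrow(mat) <= 2 * k + 2) {
      stop("record too short after edge trimming", call. = FALSE)
    }
    mat <- mat[(k + 1):(nrow(mat) - k), , drop = FALSE]
  }
  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    bad <- if (is.null(labels)) which(sds == 0) else labels[sds == 0]
    stop(sprintf("constant channel(s) %s: correlation undefined",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cc <- cor(mat)
  connectivity_matrix(cc, modality, subject_id, labels)
}

#' Canonical edge list of a connectivity matrix
#'
#' Strict upper triangle (`i < j`) in row-major order; this ordering is used
#' consistently for masks and summary scores. An n-channel matrix yields
#' `n * (n - 1) / 2` edges.
#'
#' @param m a [connectivity_matrix()] or square symmetric matrix.
#' @return data.frame with columns `i`, `j`, `value`.
#' @export
edge_list <- function(m) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
  n <- nrow(v)
  idx <- edge_index(n)
  data.frame(i = idx[, 1], j = idx[, 2],
             value = v[idx], stringsAsFactors = FALSE)
}

# upper-triangle (i < j) indices in row-major order, as a 2-column matrix
edge_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i, j)
}

#' Rebuild a symmetric matrix from an edge list
#'
#' Inverse of [edge_list()] given the channel count; diagonal set to 1.
#'
#' @param edges data.frame with columns `i`, `j`, `value` (or a plain vector
#'   of edge values in canonical order).
#' @param n channel count.
#' @return symmetric n-by-n matrix.
#' @export
edges_to_matrix <- function(edges, n) {
  v <- if (is.data.frame(edges)) edges$value else as.numeric(edges)
  idx <- edge_index(n)
  stopifnot(length(v) == nrow(idx))
  m <- diag(n)
  m[idx] <- v
  m[idx[, c(2, 1)]] <- v
  m
}
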