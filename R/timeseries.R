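#' Parcellated BOLD time series
#'
#' Container for one scan's frames-by-parcels signal matrix together with its
#' repetition time, optional motion parameters, framewise-displacement (FD)
#' trace, and the per-frame retention mask used by scrubbing.
#'
#' @param data Numeric matrix, frames x parcels.
#' @param tr_seconds Repetition time in seconds (time between frames).
#' @param parcel_ids Character vector of parcel identifiers (one per column).
#'   Defaults to the column names of `data`, or `"p0001"`-style ids.
#' @param motion Optional frames x 6 matrix of rigid-body motion parameters
#'   (3 translations, 3 rotations).
#' @param fd Optional numeric vector of framewise displacement in mm, one per
#'   frame.
#' @param frame_mask Logical vector, `TRUE` for frames retained in analysis.
#'   Defaults to all `TRUE`.
#' @param noise_signals Optional frames x m matrix of nuisance channels (e.g.
#'   physiological-compartment proxies) used by [acompcor_components()].
#'
#' @return An object of class `parcel_ts`.
#' @seealso [denoise_scan()], [fc_matrix()]
#' @export
parcel_ts <- function(data, tr_seconds, parcel_ids = NULL, motion = NULL,
                      fd = NULL, frame_mask = NULL, noise_signals = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n_frames <- nrow(data)
  n_parcels <- ncol(data)
  if (n_frames < 10L)
    stop("a scan needs at least 10 frames; got ", n_frames)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (is.null(parcel_ids)) {
    parcel_ids <- colnames(data)
    if (is.null(parcel_ids))
      parcel_ids <- sprintf("p%04d", seq_len(n_parcels))
  }
  if (length(parcel_ids) != n_parcels)
    stop("parcel_ids length (", length(parcel_ids),
         ") does not match parcel count (", n_parcels, ")")
  if (anyDuplicated(parcel_ids))
    stop("duplicate parcel id: ",
         parcel_ids[duplicated(parcel_ids)][1L])
  colnames(data) <- parcel_ids
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L)
      stop("motion must have 6 columns; got ", ncol(motion))
    if (nrow(motion) != n_frames)
      stop("motion has ", nrow(motion), " rows but the scan has ",
           n_frames, " frames")
  }
  if (!is.null(fd)) {
    fd <- as.numeric(fd)
    if (length(fd) != n_frames)
      stop("fd has length ", length(fd), " but the scan has ",
           n_frames, " frames")
    if (any(fd < 0)) stop("fd values must be nonnegative")
  }
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, n_frames)
  if (length(frame_mask) != n_frames || !is.logical(frame_mask))
    stop("frame_mask must be a logical vector with one entry per frame")
  if (!is.null(noise_signals)) {
    noise_signals <- as.matrix(noise_signals)
    if (nrow(noise_signals) != n_frames)
      stop("noise_signals row count must equal the frame count")
  }
  structure(
    list(data = data, tr_seconds = tr_seconds, parcel_ids = parcel_ids,
         motion = motion, fd = fd, frame_mask = frame_mask,
         noise_signals = noise_signals),
    class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat("<parcel_ts> ", nrow(x$data), " frames x ", ncol(x$data),
      " parcels, TR = ", x$tr_seconds, " s\n", sep = "")
  cat("  retained frames: ", sum(x$frame_mask), "/", nrow(x$data), "\n",
      sep = "")
  if (!is.null(x$fd))
    cat("  FD: mean ", signif(mean(x$fd), 3), " mm, max ",
        signif(max(x$fd), 3), " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.parcel_ts <- function(x) dim(x$data)

# Retained-frame data matrix; errors if too few frames survive scrubbing.
retained_frames <- function(ts, min_frames = 10L) {
  x <- ts$data[ts$frame_mask, , drop = FALSE]
  if (nrow(x) < min_frames)
    stop("only ", nrow(x), " retained frames; at least ", min_frames,
         " are required")
  x
}
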