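#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body motion parameters into the 24-regressor set used for
#' motion artifact regression: the 6 parameters, their one-frame-lagged
#' copies, and the squares of both sets. The first frame of each lagged
#' column is backfilled with 0.
#'
#' @param motion Numeric frames x 6 matrix of motion parameters.
#' @return A `confound_set` with 24 columns.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion must have exactly 6 columns; got ", ncol(motion))
  n <- nrow(motion)
  lagged <- rbind(rep(0, 6L), motion[-n, , drop = FALSE])
  out <- cbind(motion, lagged, motion^2, lagged^2)
  base <- if (!is.null(colnames(motion))) colnames(motion)
          else sprintf("mot%d", 1:6)
  labels <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
              paste0(base, "_lag_sq"))
  degenerate <- all(out == 0)
  confound_set(out, labels,
               provenance = rep("friston24", 24L),
               degenerate = degenerate)
}

#' Component-based physiological noise regressors
#'
#' Principal components of column-demeaned noise-compartment signals; keeps
#' the smallest number of leading components whose cumulative explained
#' variance reaches `variance_fraction` (default: half the variance per scan,
#' the aCompCor50 rule).
#'
#' @param noise_signals Numeric frames x m matrix of noise channels.
#' @param variance_fraction Target cumulative explained-variance fraction.
#' @return A `confound_set` of principal-component scores.
#' @export
acompcor_components <- function(noise_signals, variance_fraction = 0.5) {
  x <- as.matrix(noise_signals)
  if (ncol(x) < 1L) stop("need at least one noise channel")
  if (!(variance_fraction > 0 && variance_fraction <= 1))
    stop("variance_fraction must be in (0, 1]")
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(xc) < .Machine$double.eps * 100))
    stop("noise signals are constant: no variance to decompose")
  pc <- stats::prcomp(xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= variance_fraction - 1e-12)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  confound_set(scores, sprintf("acompcor%d", seq_len(k)),
               provenance = rep("acompcor", k),
               explained_variance = frac[k])
}

#' Motion-spike (scrubbing) regressors
#'
#' One indicator column per frame whose framewise displacement strictly
#' exceeds `threshold_mm`. Also returns the retained-frame mask (flagged
#' frames are deleted from correlation estimation after confound regression).
#'
#' @param fd Nonnegative numeric vector of framewise displacement (mm).
#' @param threshold_mm Scrubbing threshold; frames with FD > threshold are
#'   flagged.
#' @return A `confound_set` (possibly with zero columns) whose
#'   `frame_mask` element marks retained frames.
#' @export
spike_regressors <- function(fd, threshold_mm = 0.5) {
  fd <- as.numeric(fd)
  if (any(fd < 0)) stop("fd values must be nonnegative")
  flagged <- which(fd > threshold_mm)
  n <- length(fd)
  mat <- matrix(0, n, length(flagged))
  if (length(flagged))
    mat[cbind(flagged, seq_along(flagged))] <- 1
  cs <- confound_set(mat, sprintf("spike_frame%04d", flagged),
                     provenance = rep("spike", length(flagged)))
  cs$frame_mask <- !(seq_len(n) %in% flagged)
  cs
}

#' Bundle of nuisance regressors
#'
#' @param regressors Numeric frames x k matrix.
#' @param labels Column labels.
#' @param provenance Which rule produced each column.
#' @param ... Extra metadata stored on the object.
#' @return An object of class `confound_set`.
#' @export
confound_set <- function(regressors, labels = NULL, provenance = NULL, ...) {
  regressors <- as.matrix(regressors)
  k <- ncol(regressors)
  if (is.null(labels)) labels <- sprintf("conf%d", seq_len(k))
  if (length(labels) != k) stop("labels length must match column count")
  colnames(regressors) <- labels
  r <- if (k > 0L) qr(regressors)$rank else 0L
  structure(c(list(regressors = regressors, labels = labels,
                   provenance = provenance, rank = r), list(...)),
            class = "confound_set")
}

#' Combine confound sets column-wise
#' @param ... `confound_set` objects (NULLs are dropped).
#' @return A single `confound_set`.
#' @export
bind_confounds <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  stopifnot(all(vapply(sets, inherits, TRUE, "confound_set")))
  confound_set(do.call(cbind, lapply(sets, `[[`, "regressors")),
               unlist(lapply(sets, `[[`, "labels")),
               provenance = unlist(lapply(sets, `[[`, "provenance")))
}

#' @export
print.confound_set <- function(x, ...) {
  cat("<confound_set> ", ncol(x$regressors), " regressors (rank ", x$rank,
      ")\n", sep = "")
  if (!is.null(x$provenance))
    print(table(x$provenance))
  invisible(x)
}

#' Nuisance regression
#'
#' Removes confound variance from every parcel by ordinary least squares:
#' each parcel series is replaced by its residual against an intercept, the
#' confound columns and, when `gsr = TRUE`, the global mean signal
#' (pre-regression mean over parcels). Rank-deficient designs are solved by
#' the Moore-Penrose pseudoinverse, so residuals are orthogonal to every
#' regressor regardless of collinearity.
#'
#' @param ts A [parcel_ts()].
#' @param confounds A `confound_set` (or NULL for intercept/GSR only).
#' @param gsr Include global signal regression?
#' @return A `parcel_ts` of residuals.
#' @export
regress_confounds <- function(ts, confounds = NULL, gsr = FALSE) {
  stopifnot(inherits(ts, "parcel_ts"))
  n <- nrow(ts$data)
  x <- cbind(intercept = rep(1, n))
  if (!is.null(confounds)) {
    stopifnot(inherits(confounds, "confound_set"))
    if (ncol(confounds$regressors) > 0L) {
      if (nrow(confounds$regressors) != n)
        stop("confound frame count (", nrow(confounds$regressors),
             ") does not match the scan (", n, " frames)")
      x <- cbind(x, confounds$regressors)
    }
  }
  if (gsr) x <- cbind(x, global_signal = rowMeans(ts$data))
  # pseudoinverse fit: residuals exactly orthogonal to the column space
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * max(dim(x)) * .Machine$double.eps
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% ts$data) / sv$d[pos])
  resid <- ts$data - x %*% beta
  out <- ts
  out$data <- resid
  out
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain masking with unit gain inside `[low_hz, high_hz]`, zero
#' gain outside, and a 2-bin raised-cosine taper at each band edge. The DC
#' component is always removed. Zero-phase by construction (a real gain
#' applied symmetrically in the frequency domain).
#'
#' @param ts A [parcel_ts()].
#' @param low_hz,high_hz Pass-band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return A filtered `parcel_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.008, high_hz = 0.09) {
  stopifnot(inherits(ts, "parcel_ts"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyquist)
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency (",
         signif(nyquist, 4), " Hz) for TR = ", ts$tr_seconds, " s")
  out <- ts
  out$data <- bandpass_matrix(ts$data, ts$tr_seconds, low_hz, high_hz)
  colnames(out$data) <- ts$parcel_ids
  out
}

# column-wise zero-phase frequency masking shared by bandpass() and the
# frequency-matched confound filtering in denoise_scan()
bandpass_matrix <- function(mat, tr_seconds, low_hz, high_hz) {
  n <- nrow(mat)
  df <- 1 / (n * tr_seconds)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * df   # folded bin frequencies
  gain <- band_gain(f, low_hz, high_hz, 2 * df)
  gain[1L] <- 0                                # DC always removed
  spec <- stats::mvfft(as.matrix(mat))
  Re(stats::mvfft(spec * gain, inverse = TRUE)) / n
}

# Raised-cosine band-edge gain: 1 inside [low, high], tapering to 0 over a
# `width`-Hz transition outside each edge.
band_gain <- function(f, low, high, width) {
  g <- numeric(length(f))
  inside <- f >= low & f <= high
  g[inside] <- 1
  lo_t <- f < low & f > low - width
  g[lo_t] <- 0.5 * (1 + cos(pi * (low - f[lo_t]) / width))
  hi_t <- f > high & f < high + width
  g[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - high) / width))
  g
}

#' Full scan-level denoising chain
#'
#' Applies the resting-state denoising recipe in a fixed order: flag motion
#' spikes (FD strictly above `fd_threshold_mm`), regress confounds (Friston-24
#' motion expansion when motion parameters are present, principal components
#' of the noise channels, the spike indicators, and optionally the global
#' signal), band-pass filter, and finally mark flagged frames for deletion so
#' that downstream correlation estimation uses retained frames only.
#'
#' Continuous confound regressors are band-pass filtered with the same
#' filter before regression (frequency-matched nuisance regression); spike
#' indicator columns stay raw. Without this, the later filtering step
#' reintroduces nuisance variance in the pass band and the chain stops being
#' idempotent on clean data.
#'
#' @param ts A [parcel_ts()] with `motion`/`fd`/`noise_signals` as available.
#' @param gsr Include global signal regression?
#' @param fd_threshold_mm Scrubbing threshold in mm.
#' @param low_hz,high_hz Band-pass edges in Hz.
#' @param variance_fraction aCompCor cumulative-variance target.
#' @return A denoised `parcel_ts` with `frame_mask` updated. QC counts
#'   (scrubbed frames, confound rank) are attached as attribute `qc`.
#' @export
denoise_scan <- function(ts, gsr = FALSE, fd_threshold_mm = 0.5,
                         low_hz = 0.008, high_hz = 0.09,
                         variance_fraction = 0.5) {
  stopifnot(inherits(ts, "parcel_ts"))
  sets <- list()
  spikes <- NULL
  if (!is.null(ts$fd)) {
    spikes <- spike_regressors(ts$fd, fd_threshold_mm)
    if (ncol(spikes$regressors) > 0L) sets <- c(sets, list(spikes))
  }
  filt <- function(cs) {   # frequency-match continuous regressors
    if (ncol(cs$regressors) > 0L)
      cs$regressors <- bandpass_matrix(cs$regressors, ts$tr_seconds,
                                       low_hz, high_hz)
    cs
  }
  if (!is.null(ts$motion)) sets <- c(sets, list(filt(friston24(ts$motion))))
  if (!is.null(ts$noise_signals))
    sets <- c(sets, list(filt(acompcor_components(ts$noise_signals,
                                                  variance_fraction))))
  confounds <- if (length(sets)) do.call(bind_confounds, sets) else NULL
  ts_for_reg <- ts
  if (gsr) {
    gs <- bandpass_matrix(cbind(rowMeans(ts$data)), ts$tr_seconds,
                          low_hz, high_hz)
    confounds <- if (is.null(confounds))
      confound_set(gs, "global_signal", provenance = "gsr")
    else bind_confounds(confounds,
                        confound_set(gs, "global_signal",
                                     provenance = "gsr"))
  }
  out <- regress_confounds(ts_for_reg, confounds, gsr = FALSE)
  out <- bandpass(out, low_hz, high_hz)
  if (!is.null(spikes)) out$frame_mask <- ts$frame_mask & spikes$frame_mask
  attr(out, "qc") <- list(
    n_scrubbed = if (is.null(spikes)) 0L else sum(!spikes$frame_mask),
    n_confounds = if (is.null(confounds)) 0L else ncol(confounds$regressors),
    confound_rank = if (is.null(confounds)) 0L else confounds$rank)
  out
}
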