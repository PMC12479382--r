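#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlation between all parcel series over retained
#' frames, capped at `|r| <= 1 - cap_epsilon` and Fisher z-transformed
#' (`atanh`). The cap keeps z finite for degenerate (duplicated) parcels and
#' is surfaced in the result's metadata together with the number of capped
#' entries.
#'
#' @param ts A [parcel_ts()].
#' @param cap_epsilon Correlation cap before `atanh`.
#' @return An object of class `fc_matrix` with elements `values` (symmetric
#'   parcels x parcels Fisher-z matrix, diagonal `NA`), `parcel_ids`,
#'   `cap_epsilon` and `n_capped`.
#' @export
fc_matrix <- function(ts, cap_epsilon = 1e-5) {
  stopifnot(inherits(ts, "parcel_ts"))
  x <- retained_frames(ts)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant parcel series: ",
         ts$parcel_ids[which(sds == 0)[1L]])
  r <- stats::cor(x)
  z <- atanh(cap_correlation(r, cap_epsilon))
  n_capped <- sum(abs(r[upper.tri(r)]) > 1 - cap_epsilon)
  diag(z) <- NA_real_
  dimnames(z) <- list(ts$parcel_ids, ts$parcel_ids)
  structure(list(values = z, parcel_ids = ts$parcel_ids,
                 cap_epsilon = cap_epsilon, n_capped = n_capped),
            class = "fc_matrix")
}

#' Construct an `fc_matrix` from an existing Fisher-z matrix
#'
#' Used by the connectome simulators and file readers; validates symmetry
#' and finiteness.
#' @param values Symmetric numeric matrix of Fisher-z values.
#' @param parcel_ids Parcel identifiers.
#' @param cap_epsilon Cap recorded in metadata.
#' @return An `fc_matrix`.
#' @export
as_fc_matrix <- function(values, parcel_ids = NULL, cap_epsilon = 1e-5) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("fc matrix must be square")
  off <- values
  diag(off) <- 0
  if (!all(is.finite(off))) stop("fc matrix has non-finite off-diagonal values")
  if (max(abs(off - t(off))) > 1e-12)
    stop("fc matrix is not symmetric to 1e-12")
  if (is.null(parcel_ids)) {
    parcel_ids <- rownames(values)
    if (is.null(parcel_ids)) parcel_ids <- sprintf("p%04d", seq_len(nrow(values)))
  }
  diag(values) <- NA_real_
  dimnames(values) <- list(parcel_ids, parcel_ids)
  structure(list(values = values, parcel_ids = parcel_ids,
                 cap_epsilon = cap_epsilon, n_capped = NA_integer_),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  p <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat("<fc_matrix> ", p, " x ", p, " Fisher-z, range [",
      signif(min(off), 3), ", ", signif(max(off), 3), "]\n", sep = "")
  if (!is.na(x$n_capped) && x$n_capped > 0)
    cat("  capped entries: ", x$n_capped, " (|r| > 1 - ",
        format(x$cap_epsilon), ")\n", sep = "")
  invisible(x)
}

cap_correlation <- function(r, cap_epsilon) {
  pmin(pmax(r, -(1 - cap_epsilon)), 1 - cap_epsilon)
}

#' Network seed-to-parcel connectivity map
#'
#' The seed series is the unweighted mean of the network's parcel series; the
#' map is the Fisher-z Pearson correlation of every parcel with that seed
#' series. Optional per-frame weights generalize to a weighted correlation.
#'
#' @param ts A [parcel_ts()].
#' @param atlas A [network_atlas()].
#' @param network Seed network label.
#' @param weights Optional nonnegative per-retained-frame weights (defaults
#'   to uniform).
#' @param cap_epsilon Correlation cap before `atanh`.
#' @return An object of class `seed_map`: per-parcel Fisher-z values plus
#'   metadata.
#' @export
network_seed_map <- function(ts, atlas, network, weights = NULL,
                             cap_epsilon = 1e-5) {
  stopifnot(inherits(ts, "parcel_ts"))
  members <- network_members(atlas, network)
  x <- retained_frames(ts)
  idx <- parcel_index(ts, members)
  seed <- rowMeans(x[, idx, drop = FALSE])
  if (is.null(weights)) {
    r <- as.vector(stats::cor(seed, x))
  } else {
    if (length(weights) != nrow(x) || any(weights < 0))
      stop("weights must be nonnegative with one entry per retained frame")
    r <- apply(x, 2L, weighted_cor, y = seed, w = weights)
  }
  z <- atanh(cap_correlation(r, cap_epsilon))
  names(z) <- ts$parcel_ids
  structure(list(network = network, values = z, cap_epsilon = cap_epsilon),
            class = "seed_map")
}

weighted_cor <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2); syy <- sum(w * (y - my)^2)
  sxy / sqrt(sxx * syy)
}

#' Within-network functional connectivity
#'
#' Unweighted mean of a network's seed-map values over the parcels belonging
#' to the seed network itself (own-network parcels included).
#'
#' @param seed_map A [network_seed_map()] result.
#' @param atlas The same [network_atlas()] the map was computed with.
#' @return A single Fisher-z value.
#' @export
within_network_fc <- function(seed_map, atlas) {
  stopifnot(inherits(seed_map, "seed_map"))
  members <- network_members(atlas, seed_map$network)
  idx <- match(members, names(seed_map$values))
  if (anyNA(idx)) stop("seed map does not cover the atlas parcels")
  mean(seed_map$values[idx])
}

#' Between-network functional connectivity
#'
#' Fisher-z Pearson correlation between the mean series of each pair of
#' analyzed networks.
#'
#' @param ts A [parcel_ts()].
#' @param atlas A [network_atlas()].
#' @param cap_epsilon Correlation cap before `atanh`.
#' @return A symmetric networks x networks Fisher-z matrix with `NA`
#'   diagonal.
#' @export
between_network_fc <- function(ts, atlas, cap_epsilon = 1e-5) {
  stopifnot(inherits(ts, "parcel_ts"))
  x <- retained_frames(ts)
  nets <- atlas$networks
  means <- vapply(nets, function(nw) {
    idx <- parcel_index(ts, network_members(atlas, nw))
    rowMeans(x[, idx, drop = FALSE])
  }, numeric(nrow(x)))
  sds <- apply(means, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant network mean series: ", nets[which(sds == 0)[1L]])
  z <- atanh(cap_correlation(stats::cor(means), cap_epsilon))
  diag(z) <- NA_real_
  dimnames(z) <- list(nets, nets)
  z
}

#' Global connectivity
#'
#' Per-parcel mean Fisher-z correlation with all other parcels (row mean of
#' the connectivity matrix excluding the diagonal).
#'
#' @param fc An [fc_matrix()].
#' @return Named numeric vector, one value per parcel.
#' @export
global_fc <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  rowMeans(fc$values, na.rm = TRUE)
}
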