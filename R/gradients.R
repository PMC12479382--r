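#' Row-wise sparsification of a connectivity matrix
#'
#' Per row, keeps the `ceiling(density * (P - 1))` largest off-diagonal
#' entries and zeroes the rest (including the diagonal). Ties are broken by
#' lower parcel index. The result is generally asymmetric and is passed as-is
#' to [cosine_affinity()].
#'
#' @param fc An [fc_matrix()] or a plain square numeric matrix.
#' @param density Fraction of off-diagonal entries retained per row.
#' @return A square numeric matrix of the same size.
#' @export
threshold_rows <- function(fc, density = 0.10) {
  m <- if (inherits(fc, "fc_matrix")) fc$values else as.matrix(fc)
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  p <- nrow(m)
  keep_n <- ceiling(density * (p - 1))
  out <- matrix(0, p, p, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    row <- m[i, ]
    row[i] <- NA_real_
    cand <- which(!is.na(row))
    # stable order: decreasing value, ties at lower index first
    ord <- cand[order(-row[cand], cand)]
    keep <- ord[seq_len(min(keep_n, length(ord)))]
    out[i, keep] <- m[i, keep]
  }
  out
}

#' Cosine-similarity affinity matrix
#'
#' Entry (i, j) is the cosine similarity of rows i and j of the (thresholded)
#' connectivity matrix. Negative similarities are clipped to 0 to keep the
#' kernel nonnegative for the Markov normalization; the clipped count is
#' recorded.
#'
#' @param m Square numeric matrix (typically from [threshold_rows()]).
#' @return An object of class `affinity_matrix` with `values` (symmetric,
#'   nonnegative) and `n_clipped`.
#' @export
cosine_affinity <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0))
    stop("all-zero row in thresholded matrix: row ", which(norms == 0)[1L])
  a <- tcrossprod(m) / outer(norms, norms)
  a <- (a + t(a)) / 2                     # exact symmetry
  n_clipped <- sum(a < 0)
  a[a < 0] <- 0
  structure(list(values = a, n_clipped = n_clipped),
            class = "affinity_matrix")
}

#' Diffusion map embedding
#'
#' Spectral embedding of a nonnegative affinity matrix via the
#' density-normalized diffusion operator. With `alpha = 0.5` the kernel is
#' `W' = D^-alpha W D^-alpha`; the transition operator `M = D'^-1 W'` is
#' diagonalized through its symmetric conjugate, the trivial constant
#' eigenvector is dropped, and each retained component is scaled by
#' `lambda / (1 - lambda)` (the `diffusion_time = 0` convention) or by
#' `lambda^t` for `diffusion_time = t > 0`.
#'
#' @param affinity An [cosine_affinity()] result or a symmetric nonnegative
#'   matrix.
#' @param n_components Number of gradients to compute.
#' @param alpha Density-normalization exponent in `[0, 1]`; 0.5 balances
#'   local and global geometry.
#' @param diffusion_time Diffusion time (0 selects the `lambda/(1-lambda)`
#'   scaling).
#' @return An object of class `gradient_set`: `scores` (parcels x
#'   `n_components`), `eigenvalues` (nontrivial, descending),
#'   `variance_explained` (eigenvalue fractions over the retained
#'   components), `alpha`, and `aligned_to` (`NA` until alignment).
#' @export
diffusion_embedding <- function(affinity, n_components = 10, alpha = 0.5,
                                diffusion_time = 0) {
  w <- if (inherits(affinity, "affinity_matrix")) affinity$values
       else as.matrix(affinity)
  if (any(w < 0)) stop("affinity entries must be nonnegative")
  if (max(abs(w - t(w))) > 1e-10) stop("affinity must be symmetric")
  if (!is_connected(w))
    stop("affinity graph is disconnected; increase the row-threshold ",
         "density or check the input connectivity matrix")
  p <- nrow(w)
  d <- rowSums(w)
  wa <- w / outer(d^alpha, d^alpha)
  da <- rowSums(wa)
  s <- wa / outer(sqrt(da), sqrt(da))     # symmetric conjugate of M
  eig <- eigen(s, symmetric = TRUE)
  # eigenvectors of M = D'^-1 W':  v = D'^-1/2 u ; leading v is constant
  v <- eig$vectors / sqrt(da)
  lam <- eig$values
  keep <- seq_len(min(n_components, p - 1L)) + 1L   # drop trivial lambda = 1
  lam_k <- lam[keep]
  v_k <- v[, keep, drop = FALSE]
  # unit-norm eigenvectors before diffusion scaling
  v_k <- sweep(v_k, 2L, sqrt(colSums(v_k^2)), `/`)
  scale_fac <- if (diffusion_time == 0) lam_k / (1 - lam_k)
               else lam_k^diffusion_time
  scores <- sweep(v_k, 2L, scale_fac, `*`)
  rownames(scores) <- rownames(w)
  lam_pos <- pmax(lam_k, 0)
  gradient_set(scores, eigenvalues = lam_pos,
               variance_explained = if (sum(lam_pos) > 0)
                 lam_pos / sum(lam_pos) else rep(0, length(lam_pos)),
               alpha = alpha)
}

# connectivity of the weighted graph (edges where w > 0), simple BFS
is_connected <- function(w) {
  p <- nrow(w)
  seen <- logical(p)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    nb <- which(w[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Gradient set container
#' @param scores Parcels x k matrix of gradient scores.
#' @param eigenvalues Nonnegative, descending eigenvalues (one per component).
#' @param variance_explained Per-component eigenvalue fraction.
#' @param alpha Normalization exponent used.
#' @param aligned_to Template identifier, or `NA` if unaligned.
#' @return An object of class `gradient_set`.
#' @export
gradient_set <- function(scores, eigenvalues = NULL,
                         variance_explained = NULL, alpha = 0.5,
                         aligned_to = NA_character_) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  if (!is.null(eigenvalues)) {
    if (length(eigenvalues) != k)
      stop("need one eigenvalue per component")
    if (any(diff(eigenvalues) > 1e-10))
      stop("eigenvalues must be descending")
    if (any(eigenvalues < 0)) stop("eigenvalues must be nonnegative")
  }
  colnames(scores) <- sprintf("g%d", seq_len(k))
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 variance_explained = variance_explained,
                 alpha = alpha, aligned_to = aligned_to),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("<gradient_set> ", nrow(x$scores), " parcels x ", ncol(x$scores),
      " gradients", sep = "")
  if (!is.na(x$aligned_to)) cat(" (aligned to ", x$aligned_to, ")", sep = "")
  cat("\n")
  if (!is.null(x$variance_explained))
    cat("  variance explained (first 3): ",
        paste(signif(100 * x$variance_explained[1:min(3, ncol(x$scores))], 3),
              collapse = "% / "), "%\n", sep = "")
  invisible(x)
}

#' Cumulative variance explained by the first k gradients
#'
#' Sum of the first `k` eigenvalues over the sum of all computed
#' eigenvalues.
#'
#' @param eigenvalues Nonnegative, descending eigenvalues, or a
#'   `gradient_set`.
#' @param k Number of leading components.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(eigenvalues, k = 3) {
  if (inherits(eigenvalues, "gradient_set"))
    eigenvalues <- eigenvalues$eigenvalues
  ev <- as.numeric(eigenvalues)
  if (any(ev < 0)) stop("eigenvalues must be nonnegative")
  if (any(diff(ev) > 1e-10)) stop("eigenvalues must be descending")
  if (sum(ev) == 0) stop("all-zero eigenvalue spectrum")
  if (k < 1 || k > length(ev)) stop("k out of range")
  sum(ev[seq_len(k)]) / sum(ev)
}

#' Procrustes alignment of gradient sets to a group template
#'
#' Aligns each scan's gradient scores to a template by an orthogonal
#' (rotation/reflection) transform without scaling, after column
#' mean-centering. When no template is supplied, a group template is built
#' iteratively: starting from the mean of the baseline scans, all scans are
#' aligned to the current template and the template is recomputed as the mean
#' of the aligned scores, for `n_iter` iterations. The summed squared
#' Frobenius disparity to the template is non-increasing over iterations.
#'
#' @param gradients A list of `gradient_set` objects (or score matrices).
#' @param template Optional template `gradient_set`/matrix; when `NULL` the
#'   iterative group template is built.
#' @param n_iter Template-building iterations.
#' @param baseline Indices of the scans used to seed the template (defaults
#'   to all scans; in cohort analyses, the pre-intervention scans).
#' @return A list with `aligned` (list of aligned `gradient_set`s),
#'   `template` (matrix), `disparity` (per-scan Frobenius distance to the
#'   final template) and `objective` (per-iteration summed squared
#'   disparity, when the template was built here).
#' @export
procrustes_align <- function(gradients, template = NULL, n_iter = 10,
                             baseline = NULL) {
  mats <- lapply(gradients, function(g)
    if (inherits(g, "gradient_set")) g$scores else as.matrix(g))
  dims <- vapply(mats, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all gradient sets must share parcel and component counts")
  mats <- lapply(mats, scale, center = TRUE, scale = FALSE)
  objective <- NULL
  if (is.null(template)) {
    if (is.null(baseline)) baseline <- seq_along(mats)
    tmpl <- Reduce(`+`, mats[baseline]) / length(baseline)
    objective <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      aligned <- lapply(mats, orthogonal_procrustes, template = tmpl)
      tmpl <- Reduce(`+`, aligned) / length(aligned)
      objective[it] <- sum(vapply(aligned, function(a)
        sum((a - tmpl)^2), numeric(1L)))
    }
  } else {
    tmpl <- if (inherits(template, "gradient_set")) template$scores
            else as.matrix(template)
    if (!all(dim(tmpl) == dims[, 1])) stop("template shape mismatch")
    tmpl <- scale(tmpl, center = TRUE, scale = FALSE)
    aligned <- lapply(mats, orthogonal_procrustes, template = tmpl)
  }
  disparity <- vapply(aligned, function(a) sqrt(sum((a - tmpl)^2)),
                      numeric(1L))
  out <- Map(function(g, a) {
    if (inherits(g, "gradient_set")) {
      g$scores <- a
      g$aligned_to <- "group_template"
      g
    } else gradient_set(a, aligned_to = "group_template")
  }, gradients, aligned)
  list(aligned = out, template = tmpl, disparity = disparity,
       objective = objective)
}

# Orthogonal Procrustes: the rotation/reflection Q minimizing ||X Q - T||_F.
orthogonal_procrustes <- function(x, template) {
  sv <- svd(crossprod(x, template))
  x %*% (sv$u %*% t(sv$v))
}

#' Within- and between-network gradient dispersion
#'
#' In the space of the first `k` gradients, each network's centroid is the
#' mean of its parcels' scores. Within-network dispersion is the sum of
#' squared Euclidean distances of the network's parcels to that centroid;
#' between-network dispersion is the Euclidean distance between network
#' centroids.
#'
#' @param gradients A `gradient_set` (aligned scores recommended).
#' @param atlas A [network_atlas()]; parcel order must match the score rows.
#' @param k Number of gradient dimensions used (default 3).
#' @return An object of class `dispersion_summary` with `within` (named
#'   vector), `between` (symmetric matrix, zero diagonal) and `centroids`
#'   (networks x k matrix).
#' @export
dispersion <- function(gradients, atlas, k = 3) {
  stopifnot(inherits(gradients, "gradient_set"),
            inherits(atlas, "network_atlas"))
  if (k > ncol(gradients$scores))
    stop("k exceeds the number of computed components")
  sc <- gradients$scores[, seq_len(k), drop = FALSE]
  ids <- rownames(sc)
  if (is.null(ids)) ids <- atlas$parcels$parcel_id
  nets <- atlas$networks
  centroids <- matrix(NA_real_, length(nets), k,
                      dimnames = list(nets, colnames(sc)))
  within <- stats::setNames(numeric(length(nets)), nets)
  for (nw in nets) {
    members <- network_members(atlas, nw)
    idx <- match(members, ids)
    if (anyNA(idx)) stop("gradient scores missing parcels of network ", nw)
    pts <- sc[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    centroids[nw, ] <- ctr
    within[nw] <- sum(sweep(pts, 2L, ctr)^2)
  }
  between <- as.matrix(stats::dist(centroids))
  structure(list(within = within, between = between, centroids = centroids,
                 k = k),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat("<dispersion_summary> ", length(x$within), " networks in ", x$k,
      "-D gradient space\n  within: ", sep = "")
  cat(paste(names(x$within), signif(x$within, 4), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
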