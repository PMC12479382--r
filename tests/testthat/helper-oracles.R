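# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (double loops, textbook formulas, nonsymmetric eigen)
# so they share no code path with the package implementation.

tiny_sizes <- c(VIS = 10, ASM = 10, DAN = 10, SAL = 10, FPN = 10, DMN = 10)

tiny_config <- function(seed = 1, n_per_group = 3, n_frames = 60, ...) {
  sim_config(n_drug = n_per_group, n_placebo = n_per_group,
             network_sizes = tiny_sizes, n_frames = n_frames,
             seed = seed, ...)
}

white_scan <- function(n_frames, n_parcels, tr = 1.8, seed = 1) {
  set.seed(seed)
  parcel_ts(matrix(rnorm(n_frames * n_parcels), n_frames, n_parcels), tr)
}

# textbook pairwise Pearson + Fisher z, double loop
brute_fisher_z <- function(x, cap = 1e-5) {
  p <- ncol(x)
  z <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    xi <- x[, i] - mean(x[, i]); xj <- x[, j] - mean(x[, j])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    r <- max(min(r, 1 - cap), -(1 - cap))
    z[i, j] <- atanh(r)
  }
  z
}

# step-up BH straight from the definition
brute_bh_reject <- function(p, q_level) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * q_level)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# dense diffusion-operator eigendecomposition via nonsymmetric eigen()
brute_diffusion_scores <- function(w, alpha = 0.5, k = 3) {
  d <- rowSums(w)
  wa <- w / outer(d^alpha, d^alpha)
  m <- wa / rowSums(wa)
  eig <- eigen(m)
  lam <- Re(eig$values)
  ord <- order(lam, decreasing = TRUE)
  vecs <- Re(eig$vectors[, ord, drop = FALSE])
  list(scores = vecs[, 1 + seq_len(k), drop = FALSE],
       eigenvalues = lam[ord][1 + seq_len(k)])
}

# normal-equations least squares
brute_ols <- function(x, y) solve(t(x) %*% x, t(x) %*% y)

# FFT amplitude of a single frequency component
fft_amplitude <- function(x, freq_hz, tr) {
  n <- length(x)
  bin <- round(freq_hz * n * tr) + 1L
  2 * Mod(fft(x)[bin]) / n
}

# design on the VIS-SAL pair of between-network FC with FD scrubbing active;
# used by the calibration and effect-recovery simulations
pair_scrubbed_design <- function(n_per_group, effect_map = list(), seed,
                                 pair = c("VIS", "SAL"), n_frames = 240) {
  cfg <- sim_config(n_drug = n_per_group, n_placebo = n_per_group,
                    network_sizes = tiny_sizes, n_frames = n_frames,
                    effect_map = effect_map, seed = seed)
  co <- simulate_cohort(cfg)
  subjects <- names(co$scans)
  val <- function(ses) vapply(subjects, function(s) {
    ts <- co$scans[[s]][[ses]]
    ts$frame_mask <- spike_regressors(ts$fd, 0.5)$frame_mask
    between_network_fc(ts, co$atlas)[pair[1L], pair[2L]]
  }, numeric(1L))
  list(design = fc_design(subjects, co$group_assignment[subjects],
                          val("pre"), val("post")),
       truth = co$truth)
}
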