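#' Simulation configuration for a synthetic resting-state cohort
#'
#' Defines a two-group (drug / placebo), two-session (pre / post) cohort of
#' parcellated BOLD scans with block-structured covariance. Couplings are
#' specified on interpretable scales: `within_coupling` is the Pearson
#' correlation between any two parcels of the same network, and
#' `between_coupling` is the Pearson correlation between the *mean series*
#' of two networks. Parcel-level between-network entries are calibrated as
#' `c_ab = rho_ab * sqrt(v_a * v_b)` with `v = (1 + (n - 1) w) / n` (the
#' variance of a network mean of `n` unit-variance parcels with
#' within-coupling `w`), so the planted network-pair correlation is exact in
#' closed form and recoverable by [between_network_fc()].
#'
#' @param n_drug,n_placebo Subjects per arm (defaults mirror a 39-subject
#'   randomized cohort: 19 drug, 20 placebo).
#' @param network_sizes Named integer vector of parcels per network (the six
#'   analyzed networks); must sum to the parcel count.
#' @param n_frames Frames per scan (default 240).
#' @param tr_seconds Repetition time in seconds (default 1.8).
#' @param within_coupling Scalar or named per-network parcel-parcel
#'   correlation in (0, 1).
#' @param between_coupling Scalar or networks x networks matrix of
#'   network-mean correlations in (-1, 1).
#' @param effect_map List of injections; each element is a list with fields
#'   `target` (one network label for a within-network change, or a pair of
#'   labels for a network-pair change), `group` (`"drug"` or `"placebo"`),
#'   `session` (`"pre"` or `"post"`), and `delta` (additive change on the
#'   correlation scale).
#' @param ar1_coefficient Temporal AR(1) smoothness in `[0, 1)`, applied
#'   identically to all parcels (preserves the planted cross-correlations).
#' @param fd_params List with `mean`, `sd` (of the FD trace, mm),
#'   `spike_prob` and `spike_magnitude` (mm added on spike frames).
#' @param n_noise_channels Nuisance channels emitted per scan for
#'   component-based noise regression.
#' @param questionnaire_model List with `questionnaires` (names),
#'   `intercept`, `slope` (named list per group) and `noise_sd`; day-2 scores
#'   are linear-Gaussian in the subject's planted Fisher-z connectivity
#'   change.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_drug = 19, n_placebo = 20,
                       network_sizes = c(VIS = 66, ASM = 82, DAN = 49,
                                         SAL = 50, FPN = 56, DMN = 97),
                       n_frames = 240, tr_seconds = 1.8,
                       within_coupling = 0.25, between_coupling = 0.05,
                       effect_map = list(), ar1_coefficient = 0.3,
                       fd_params = list(mean = 0.15, sd = 0.05,
                                        spike_prob = 0.03,
                                        spike_magnitude = 0.7),
                       n_noise_channels = 5,
                       questionnaire_model = list(
                         questionnaires = c("MEQ", "EBI", "NADA-S", "PIS",
                                            "TMS"),
                         intercept = 50,
                         slope = list(drug = 40, placebo = 40),
                         noise_sd = 10),
                       seed = 1L) {
  nets <- names(network_sizes)
  if (is.null(nets) || any(nets == ""))
    stop("network_sizes must be a named vector")
  if (any(network_sizes < 2)) stop("each network needs at least 2 parcels")
  if (n_drug < 2 || n_placebo < 2) stop("need at least 2 subjects per group")
  if (n_frames < 10) stop("n_frames must be at least 10")
  if (!(ar1_coefficient >= 0 && ar1_coefficient < 1))
    stop("ar1_coefficient must be in [0, 1)")
  w <- expand_within(within_coupling, nets)
  b <- expand_between(between_coupling, nets)
  for (inj in effect_map) validate_injection(inj, nets)
  cfg <- structure(
    list(n_drug = as.integer(n_drug), n_placebo = as.integer(n_placebo),
         network_sizes = network_sizes, n_parcels = sum(network_sizes),
         n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
         within_coupling = w, between_coupling = b,
         effect_map = effect_map, ar1_coefficient = ar1_coefficient,
         fd_params = fd_params, n_noise_channels = n_noise_channels,
         questionnaire_model = questionnaire_model, seed = as.integer(seed)),
    class = "sim_config")
  # build-time PD check of every implied condition covariance
  for (g in c("drug", "placebo"))
    for (s in c("pre", "post"))
      condition_couplings(cfg, g, s)
  cfg
}

expand_within <- function(w, nets) {
  if (length(w) == 1L && is.null(names(w)))
    w <- stats::setNames(rep(w, length(nets)), nets)
  if (!all(nets %in% names(w))) stop("within_coupling missing networks")
  w <- w[nets]
  if (any(w <= 0 | w >= 1)) stop("within_coupling must lie in (0, 1)")
  w
}

expand_between <- function(b, nets) {
  k <- length(nets)
  if (length(b) == 1L) b <- matrix(b, k, k)
  b <- as.matrix(b)
  if (!all(dim(b) == k)) stop("between_coupling must be ", k, " x ", k)
  dimnames(b) <- list(nets, nets)
  b <- (b + t(b)) / 2
  diag(b) <- NA_real_
  off <- b[upper.tri(b)]
  if (any(abs(off) >= 1)) stop("between_coupling must lie in (-1, 1)")
  b
}

validate_injection <- function(inj, nets) {
  need <- c("target", "group", "session", "delta")
  if (!all(need %in% names(inj)))
    stop("injection must have fields target, group, session, delta")
  if (!all(inj$target %in% nets))
    stop("injection targets unknown network: ",
         paste(setdiff(inj$target, nets), collapse = ", "))
  if (!length(inj$target) %in% 1:2)
    stop("injection target must be one network or a network pair")
  if (!inj$group %in% c("drug", "placebo"))
    stop("injection group must be 'drug' or 'placebo'")
  if (!inj$session %in% c("pre", "post"))
    stop("injection session must be 'pre' or 'post'")
  invisible(inj)
}

injection_label <- function(inj) {
  sprintf("%s/%s %s delta=%+g", inj$group, inj$session,
          paste(inj$target, collapse = "-"), inj$delta)
}

# Couplings for one (group, session) condition after applying injections,
# with a positive-definiteness check that names the offending injection.
condition_couplings <- function(cfg, group, session) {
  w <- cfg$within_coupling
  b <- cfg$between_coupling
  applied <- character(0)
  check_pd <- function(stage) {
    sig <- block_covariance(cfg$network_sizes, w, b)
    ok <- tryCatch({ chol(sig); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("implied covariance is not positive definite after injection ",
           stage, call. = FALSE)
    sig
  }
  sig <- check_pd("(none: baseline couplings)")
  for (inj in cfg$effect_map) {
    if (inj$group != group || inj$session != session) next
    if (length(inj$target) == 1L) {
      nw <- inj$target
      new_w <- w[nw] + inj$delta
      if (new_w <= 0 || new_w >= 1)
        stop("injection ", injection_label(inj),
             " drives within-coupling of ", nw, " outside (0, 1)")
      w[nw] <- new_w
    } else {
      a <- inj$target[1L]; d <- inj$target[2L]
      new_b <- b[a, d] + inj$delta
      if (abs(new_b) >= 1)
        stop("injection ", injection_label(inj),
             " drives coupling ", a, "-", d, " outside (-1, 1)")
      b[a, d] <- b[d, a] <- new_b
    }
    applied <- c(applied, injection_label(inj))
    sig <- check_pd(injection_label(inj))
  }
  list(within = w, between = b, sigma = sig, injections = applied)
}

# Parcel-level block correlation matrix: diag 1, within blocks w_n, between
# blocks calibrated so the network-mean correlation equals b[a, d] exactly.
block_covariance <- function(network_sizes, within, between) {
  nets <- names(network_sizes)
  p <- sum(network_sizes)
  v <- (1 + (network_sizes - 1) * within) / network_sizes  # var of net mean
  sig <- matrix(0, p, p)
  offs <- c(0, cumsum(network_sizes))
  for (i in seq_along(nets)) {
    ia <- (offs[i] + 1):offs[i + 1]
    sig[ia, ia] <- within[nets[i]]
    for (j in seq_along(nets)) {
      if (j == i) next
      ja <- (offs[j] + 1):offs[j + 1]
      sig[ia, ja] <- between[nets[i], nets[j]] *
        sqrt(v[nets[i]] * v[nets[j]])
    }
  }
  diag(sig) <- 1
  sig
}

#' Simulate a synthetic resting-state cohort
#'
#' Draws every scan from a zero-mean multivariate normal with the
#' block-structured covariance implied by the configured couplings plus any
#' injected group-by-session effects, optionally smooths it with a common
#' AR(1) filter (which preserves all planted cross-correlations), and
#' generates motion parameters, framewise-displacement traces with scrubbing
#' spikes, nuisance noise channels, and questionnaire scores. The returned
#' `truth` record carries every planted parameter needed for recovery tests.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort`: `scans` (nested list,
#'   `scans[[subject]][[session]]` is a [parcel_ts()]), `group_assignment`,
#'   `atlas` ([network_atlas()]), `scores` (long data.frame), and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nets <- names(config$network_sizes)
  parcel_ids <- sprintf("parcel_%03d", seq_len(config$n_parcels))
  atlas <- network_atlas(parcel_ids,
                         rep(nets, times = config$network_sizes))
  conds <- list()
  for (g in c("drug", "placebo"))
    for (s in c("pre", "post"))
      conds[[paste(g, s, sep = ".")]] <- condition_couplings(config, g, s)
  chols <- lapply(conds, function(cc) chol(cc$sigma))

  subjects <- sprintf("sub%02d", seq_len(config$n_drug + config$n_placebo))
  groups <- stats::setNames(
    rep(c("drug", "placebo"), c(config$n_drug, config$n_placebo)), subjects)

  scans <- list()
  for (subj in subjects) {
    scans[[subj]] <- list()
    for (ses in c("pre", "post")) {
      r <- chols[[paste(groups[[subj]], ses, sep = ".")]]
      z <- matrix(stats::rnorm(config$n_frames * config$n_parcels),
                  config$n_frames, config$n_parcels)
      x <- z %*% r
      if (config$ar1_coefficient > 0)
        x <- ar1_filter(x, config$ar1_coefficient)
      fdp <- config$fd_params
      fd <- abs(stats::rnorm(config$n_frames, fdp$mean, fdp$sd))
      spikes <- stats::runif(config$n_frames) < fdp$spike_prob
      fd[spikes] <- fd[spikes] + fdp$spike_magnitude
      motion <- apply(matrix(stats::rnorm(config$n_frames * 6, 0, 0.02),
                             config$n_frames, 6), 2L, cumsum)
      noise <- matrix(stats::rnorm(config$n_frames *
                                     config$n_noise_channels),
                      config$n_frames, config$n_noise_channels)
      scans[[subj]][[ses]] <- parcel_ts(x, config$tr_seconds, parcel_ids,
                                        motion = motion, fd = fd,
                                        noise_signals = noise)
    }
  }

  planted <- planted_changes(conds, nets)
  subj_change <- vapply(subjects, function(subj) {
    rows <- planted[planted$group == groups[[subj]], , drop = FALSE]
    if (nrow(rows)) sum(rows$delta_z) else 0
  }, numeric(1L))

  qm <- config$questionnaire_model
  scores <- do.call(rbind, lapply(subjects, function(subj) {
    g <- groups[[subj]]
    do.call(rbind, lapply(qm$questionnaires, function(qn) {
      base <- qm$intercept + stats::rnorm(1L, 0, qm$noise_sd)
      day2 <- qm$intercept + qm$slope[[g]] * subj_change[[subj]] +
        stats::rnorm(1L, 0, qm$noise_sd)
      data.frame(subject = subj, group = g,
                 day = c("baseline", "day2"), questionnaire = qn,
                 value = c(base, day2), stringsAsFactors = FALSE)
    }))
  }))

  truth <- list(
    config = config,
    conditions = lapply(conds, function(cc)
      list(within = cc$within, between = cc$between,
           between_z = atanh(cc$between), injections = cc$injections)),
    planted_changes = planted,
    subject_change = subj_change)

  structure(list(scans = scans, group_assignment = groups, atlas = atlas,
                 scores = scores, truth = truth),
            class = "cohort")
}

# post-minus-pre planted changes per group, on correlation and Fisher-z
# scales of the network-mean coupling (and within-coupling for single nets)
planted_changes <- function(conds, nets) {
  out <- list()
  for (g in c("drug", "placebo")) {
    pre <- conds[[paste(g, "pre", sep = ".")]]
    post <- conds[[paste(g, "post", sep = ".")]]
    for (i in seq_along(nets)) {
      dw <- post$within[nets[i]] - pre$within[nets[i]]
      if (abs(dw) > 0)
        out[[length(out) + 1L]] <- data.frame(
          group = g, net_a = nets[i], net_b = nets[i],
          pre_r = unname(pre$within[nets[i]]),
          delta_r = unname(dw),
          delta_z = unname(atanh(post$within[nets[i]]) -
                             atanh(pre$within[nets[i]])),
          stringsAsFactors = FALSE)
      for (j in seq_along(nets)) {
        if (j <= i) next
        db <- post$between[nets[i], nets[j]] - pre$between[nets[i], nets[j]]
        if (abs(db) > 0)
          out[[length(out) + 1L]] <- data.frame(
            group = g, net_a = nets[i], net_b = nets[j],
            pre_r = pre$between[nets[i], nets[j]],
            delta_r = db,
            delta_z = atanh(post$between[nets[i], nets[j]]) -
              atanh(pre$between[nets[i], nets[j]]),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(group = character(0), net_a = character(0),
                  net_b = character(0), pre_r = numeric(0),
                  delta_r = numeric(0), delta_z = numeric(0))
}

# common recursive AR(1) smoothing across all parcels; contemporaneous
# cross-correlations are exactly preserved
ar1_filter <- function(x, phi) {
  for (t in 2:nrow(x)) x[t, ] <- x[t, ] + phi * x[t - 1L, ]
  x
}

#' @export
print.cohort <- function(x, ...) {
  n <- length(x$scans)
  cat("<cohort> ", n, " subjects (",
      sum(x$group_assignment == "drug"), " drug / ",
      sum(x$group_assignment == "placebo"), " placebo), 2 sessions, ",
      nrow(x$scans[[1L]][[1L]]$data), " frames x ",
      ncol(x$scans[[1L]][[1L]]$data), " parcels\n", sep = "")
  if (nrow(x$truth$planted_changes))
    cat("  planted changes: ", nrow(x$truth$planted_changes), "\n", sep = "")
  invisible(x)
}

#' Simulate a connectome with planted gradient geometry
#'
#' Ground-truth inputs for the gradient pipeline. `"line"` geometry places
#' parcels on a 1-D coordinate and lets connectivity decay exponentially
#' with distance, planting a principal axis; `"two_block"` plants two
#' communities with strong within-block and weak between-block connectivity.
#' A small seeded jitter breaks exact ties while keeping the matrix
#' symmetric.
#'
#' @param n_parcels Number of parcels (at least 10).
#' @param geometry `"line"` or `"two_block"`.
#' @param decay Positive decay rate of connectivity with distance (line
#'   geometry).
#' @param seed Integer seed.
#' @param within,between Block correlations for `"two_block"`.
#' @param jitter_sd Standard deviation of the symmetric tie-breaking jitter.
#' @return A list with `fc` (an `fc_matrix` of Fisher-z values) and either
#'   `axis` (planted coordinate, line) or `labels` (block membership,
#'   two_block).
#' @export
simulate_gradient_connectome <- function(n_parcels,
                                         geometry = c("line", "two_block"),
                                         decay = 5, seed = 1L,
                                         within = 0.6, between = 0.05,
                                         jitter_sd = 0.005) {
  geometry <- match.arg(geometry)
  if (n_parcels < 10) stop("n_parcels must be at least 10")
  set.seed(seed)
  p <- n_parcels
  if (geometry == "line") {
    if (!(is.numeric(decay) && decay > 0))
      stop("decay must be a positive rate")
    axis <- seq(0, 1, length.out = p)
    r <- exp(-decay * abs(outer(axis, axis, `-`)))
    extra <- list(axis = axis)
  } else {
    labels <- rep(1:2, c(ceiling(p / 2), floor(p / 2)))
    r <- ifelse(outer(labels, labels, `==`), within, between)
    extra <- list(labels = labels)
  }
  jit <- matrix(stats::rnorm(p * p, 0, jitter_sd), p, p)
  jit <- (jit + t(jit)) / 2
  r <- r + jit
  diag(r) <- 1
  r <- cap_correlation(r, 1e-5)
  z <- atanh(r)
  ids <- sprintf("parcel_%03d", seq_len(p))
  c(list(fc = as_fc_matrix(z, ids)), extra)
}
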