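#' End-to-end run configuration
#'
#' Bundles every stage parameter with its default: row-threshold density
#' 0.10, diffusion-map `alpha` 0.5, 10 computed / 3 analyzed gradients, FD
#' scrubbing threshold 0.5 mm, 0.008-0.09 Hz band-pass, FDR level 0.05,
#' correlation cap 1e-5, 10 Procrustes template iterations, GSR off.
#'
#' @param sim A [sim_config()] describing the cohort to simulate.
#' @param gsr Include global signal regression in denoising?
#' @param fd_threshold_mm Scrubbing threshold (mm).
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param density Row-threshold density for the gradient pipeline.
#' @param alpha Diffusion-map density-normalization exponent.
#' @param n_components Gradients computed per scan.
#' @param k_analyzed Gradients analyzed (dispersion space).
#' @param procrustes_iter Template-building iterations.
#' @param q_level BH-FDR level.
#' @param cap_epsilon Correlation cap before Fisher z.
#' @param run_gradients Compute the gradient/dispersion stage? (The most
#'   expensive stage; can be disabled for FC-only runs.)
#' @param out_dir Optional output directory; when set, all stage outputs,
#'   the machine-readable summary and the resolved configuration are
#'   written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), gsr = FALSE,
                       fd_threshold_mm = 0.5, low_hz = 0.008,
                       high_hz = 0.09, density = 0.10, alpha = 0.5,
                       n_components = 10, k_analyzed = 3,
                       procrustes_iter = 10, q_level = 0.05,
                       cap_epsilon = 1e-5, run_gradients = TRUE,
                       out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  nyquist <- 1 / (2 * sim$tr_seconds)
  if (high_hz >= nyquist)
    stop("denoise: high_hz (", high_hz,
         " Hz) must be below the Nyquist frequency (", signif(nyquist, 4),
         " Hz)")
  structure(list(sim = sim, gsr = gsr, fd_threshold_mm = fd_threshold_mm,
                 low_hz = low_hz, high_hz = high_hz, density = density,
                 alpha = alpha, n_components = n_components,
                 k_analyzed = k_analyzed, procrustes_iter = procrustes_iter,
                 q_level = q_level, cap_epsilon = cap_epsilon,
                 run_gradients = run_gradients, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> denoise -> connectivity -> gradients/dispersion ->
#' contrasts -> brain-behavior association in order. Identical configuration
#' and seed give bit-identical results.
#'
#' @param config A [run_config()].
#' @return A report list: `cohort` truth summary, tidy tables of
#'   within-network, between-network and dispersion contrasts (with BH q per
#'   family), variance explained, association results, and QC counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$sim)
  atlas <- cohort$atlas
  nets <- atlas$networks
  subjects <- names(cohort$scans)
  groups <- cohort$group_assignment
  log <- list(n_subjects = length(subjects),
              networks = nets, seed = config$sim$seed)

  # denoise + connectivity metrics per scan
  qc_scrubbed <- integer(0)
  between <- list(); within <- list(); gfc <- list(); grads <- list()
  for (subj in subjects) {
    for (ses in c("pre", "post")) {
      key <- paste(subj, ses, sep = ".")
      den <- denoise_scan(cohort$scans[[subj]][[ses]], gsr = config$gsr,
                          fd_threshold_mm = config$fd_threshold_mm,
                          low_hz = config$low_hz, high_hz = config$high_hz)
      qc_scrubbed[key] <- attr(den, "qc")$n_scrubbed
      between[[key]] <- between_network_fc(den, atlas, config$cap_epsilon)
      within[[key]] <- vapply(nets, function(nw)
        within_network_fc(network_seed_map(den, atlas, nw,
                                           cap_epsilon = config$cap_epsilon),
                          atlas), numeric(1L))
      fc <- fc_matrix(den, config$cap_epsilon)
      gfc[[key]] <- global_fc(fc)
      if (config$run_gradients) {
        aff <- cosine_affinity(threshold_rows(fc, config$density))
        grads[[key]] <- diffusion_embedding(aff, config$n_components,
                                            config$alpha)
      }
    }
  }

  key_of <- function(subj, ses) paste(subj, ses, sep = ".")

  # contrasts on each between-network pair (one BH family over the pairs)
  pair_rows <- list()
  for (i in seq_along(nets)) for (j in seq_along(nets)) {
    if (j <= i) next
    pre <- vapply(subjects, function(s)
      between[[key_of(s, "pre")]][nets[i], nets[j]], numeric(1L))
    post <- vapply(subjects, function(s)
      between[[key_of(s, "post")]][nets[i], nets[j]], numeric(1L))
    des <- fc_design(subjects, groups[subjects], pre, post)
    metric <- paste(nets[i], nets[j], sep = "-")
    syn <- synergy_rm_anova(des, metric)
    pair_rows[[metric]] <- rbind(
      syn[syn$effect == "interaction", ],
      ancova_group_post(des, metric),
      within_group_ancova(des, "placebo", metric),
      within_group_ancova(des, "drug", metric))
  }
  between_res <- bh_by_contrast(do.call(rbind, pair_rows), config$q_level)

  # contrasts on within-network FC (one BH family over the networks)
  net_rows <- list()
  for (nw in nets) {
    pre <- vapply(subjects, function(s) within[[key_of(s, "pre")]][nw],
                  numeric(1L))
    post <- vapply(subjects, function(s) within[[key_of(s, "post")]][nw],
                   numeric(1L))
    des <- fc_design(subjects, groups[subjects], pre, post)
    syn <- synergy_rm_anova(des, nw)
    net_rows[[nw]] <- rbind(
      syn[syn$effect == "interaction", ],
      ancova_group_post(des, nw),
      within_group_ancova(des, "placebo", nw),
      within_group_ancova(des, "drug", nw))
  }
  within_res <- bh_by_contrast(do.call(rbind, net_rows), config$q_level)

  # parcel-wise Synergy on global connectivity (BH family = parcels)
  gfc_pre <- t(vapply(subjects, function(s) gfc[[key_of(s, "pre")]],
                      gfc[[1L]]))
  gfc_post <- t(vapply(subjects, function(s) gfc[[key_of(s, "post")]],
                       gfc[[1L]]))
  global_res <- parcelwise_contrast(gfc_pre, gfc_post, groups[subjects],
                                    "synergy", config$q_level)

  # gradients: align to baseline template, dispersion contrasts
  gradient_res <- NULL
  dispersion_res <- NULL
  varexp <- NULL
  if (config$run_gradients) {
    keys <- names(grads)
    baseline_idx <- which(endsWith(keys, ".pre"))
    ali <- procrustes_align(grads, n_iter = config$procrustes_iter,
                            baseline = baseline_idx)
    varexp <- vapply(grads, variance_explained, numeric(1L),
                     k = config$k_analyzed)
    disp <- lapply(ali$aligned, dispersion, atlas = atlas,
                   k = config$k_analyzed)
    names(disp) <- keys
    disp_rows <- list()
    for (nw in nets) {
      pre <- vapply(subjects, function(s)
        disp[[key_of(s, "pre")]]$within[nw], numeric(1L))
      post <- vapply(subjects, function(s)
        disp[[key_of(s, "post")]]$within[nw], numeric(1L))
      des <- fc_design(subjects, groups[subjects], pre, post)
      syn <- synergy_rm_anova(des, paste0("within_disp_", nw))
      disp_rows[[nw]] <- syn[syn$effect == "interaction", ]
    }
    dispersion_res <- bh_by_contrast(do.call(rbind, disp_rows),
                                     config$q_level)
    gradient_res <- list(template = ali$template,
                         disparity = ali$disparity,
                         objective = ali$objective)
  }

  # brain-behavior association on the planted target pair (or VIS-SAL)
  planted <- cohort$truth$planted_changes
  tgt <- if (nrow(planted)) c(planted$net_a[1L], planted$net_b[1L])
         else c("VIS", "SAL")
  if (tgt[1L] == tgt[2L]) tgt <- c("VIS", "SAL")
  fc_change <- vapply(subjects, function(s)
    between[[key_of(s, "post")]][tgt[1L], tgt[2L]] -
      between[[key_of(s, "pre")]][tgt[1L], tgt[2L]], numeric(1L))
  association <- association_ols(fc_change, cohort$scores,
                                 groups, delta_mode = FALSE,
                                 q_level = config$q_level)
  association_delta <- association_ols(fc_change, cohort$scores,
                                       groups, delta_mode = TRUE,
                                       q_level = config$q_level)

  report <- list(config = config,
                 truth = cohort$truth$planted_changes,
                 between_network = between_res,
                 within_network = within_res,
                 global_fc = global_res,
                 variance_explained = varexp,
                 dispersion = dispersion_res,
                 gradient_alignment = gradient_res,
                 association = association,
                 association_delta = association_delta,
                 qc = list(scrubbed_frames = qc_scrubbed),
                 log = log)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# BH within each contrast family (Synergy/GroupPost/Meditation/PsychMed)
bh_by_contrast <- function(tab, q_level) {
  tab$q <- NA_real_
  tab$reject <- NA
  for (cn in unique(tab$contrast)) {
    sel <- tab$contrast == cn
    bh <- fdr_bh(tab$p[sel], q_level)
    tab$q[sel] <- bh$q
    tab$reject[sel] <- bh$reject
  }
  rownames(tab) <- NULL
  tab
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$between_network, "between_network_contrasts.tsv")
  wt(report$within_network, "within_network_contrasts.tsv")
  wt(report$global_fc, "global_fc_synergy.tsv")
  wt(report$association, "association_raw.tsv")
  wt(report$association_delta, "association_delta.tsv")
  if (!is.null(report$dispersion))
    wt(report$dispersion, "dispersion_contrasts.tsv")
  cfg <- report$config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  summary <- list(
    n_rejections = list(
      between = sum(report$between_network$reject),
      within = sum(report$within_network$reject),
      global = sum(report$global_fc$reject)),
    variance_explained_mean = if (!is.null(report$variance_explained))
      mean(report$variance_explained) else NULL,
    qc = list(total_scrubbed = sum(report$qc$scrubbed_frames)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
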