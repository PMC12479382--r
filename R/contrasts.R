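#' Pre/post two-group design table
#'
#' Wide per-subject table used by all contrast functions: one row per
#' subject with its group and the metric value at both sessions.
#'
#' @param subject Subject identifiers.
#' @param group `"drug"` / `"placebo"` per subject.
#' @param pre,post Metric values at the pre and post sessions.
#' @return A data.frame of class `fc_design`.
#' @export
fc_design <- function(subject, group, pre, post) {
  subject <- as.character(subject)
  group <- as.character(group)
  if (anyDuplicated(subject)) stop("duplicate subject id")
  if (!all(group %in% c("drug", "placebo")))
    stop("group must be 'drug' or 'placebo'")
  if (length(unique(group)) < 2L) stop("both groups must be present")
  if (any(table(group) < 2L)) stop("need at least 2 subjects per group")
  d <- data.frame(subject = subject, group = group,
                  pre = as.numeric(pre), post = as.numeric(post),
                  stringsAsFactors = FALSE)
  if (anyNA(d$pre) || anyNA(d$post))
    stop("every subject needs both sessions (missing value found)")
  class(d) <- c("fc_design", "data.frame")
  d
}

# Perfect-fit guard: with (numerically) zero residual variance the t ratio
# from summary.lm is noise; report t = 0 / p = 1 for a zero coefficient and
# a hard rejection otherwise. Returns NULL when the fit is regular.
degenerate_fit <- function(fit, response, estimate) {
  rss <- sum(stats::residuals(fit)^2)
  scale <- max(sum(response^2), .Machine$double.xmin)
  if (rss > 1e-18 * scale) return(NULL)
  if (abs(estimate) < 1e-9 * sqrt(scale / length(response)) ||
      estimate == 0)
    c(0, 1)
  else c(Inf, 0)
}

contrast_row <- function(contrast, effect, estimate, statistic, stat_type,
                         df1, df2, p, metric = NA_character_) {
  data.frame(metric = metric, contrast = contrast, effect = effect,
             estimate = estimate, statistic = statistic,
             stat_type = stat_type, df1 = df1, df2 = df2, p = p,
             stringsAsFactors = FALSE)
}

#' Synergy contrast: two-way repeated-measures ANOVA
#'
#' Mixed two-way ANOVA with group (drug vs placebo) as between-subject and
#' time (post vs pre) as within-subject factor, computed from
#' unweighted-cell (Type-III-style) sums of squares so mild group imbalance
#' is handled. On balanced data the interaction F equals the squared pooled
#' two-sample t on per-subject post-minus-pre differences; this identity is
#' used as an internal consistency oracle in the test suite.
#'
#' @param design An [fc_design()].
#' @param metric Optional metric label carried through to the result.
#' @return A data.frame with rows for the group and time main effects and
#'   the group-by-time interaction (the Synergy contrast). Columns:
#'   `metric, contrast, effect, estimate, statistic, stat_type, df1, df2, p`.
#' @export
synergy_rm_anova <- function(design, metric = NA_character_) {
  stopifnot(inherits(design, "fc_design"))
  d <- design$post - design$pre
  s <- (design$post + design$pre) / 2
  g1 <- design$group == "drug"
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  pooled_var <- function(x) {
    ((n1 - 1) * stats::var(x[g1]) + (n2 - 1) * stats::var(x[!g1])) / (n - 2)
  }
  se_fac <- sqrt(1 / n1 + 1 / n2)
  f_test <- function(est, se) {
    if (se == 0) {
      if (abs(est) < 1e-15) return(c(f = 0, p = 1))
      return(c(f = Inf, p = 0))
    }
    f <- (est / se)^2
    c(f = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
  }
  sp_d <- sqrt(pooled_var(d))
  sp_s <- sqrt(pooled_var(s))
  est_int <- mean(d[g1]) - mean(d[!g1])
  est_time <- (mean(d[g1]) + mean(d[!g1])) / 2
  est_grp <- mean(s[g1]) - mean(s[!g1])
  r_int <- f_test(est_int, sp_d * se_fac)
  r_time <- f_test(est_time, sp_d * se_fac / 2)
  r_grp <- f_test(est_grp, sp_s * se_fac)
  rbind(
    contrast_row("Synergy", "group", est_grp, r_grp["f"], "F", 1, n - 2,
                 r_grp["p"], metric),
    contrast_row("Synergy", "time", est_time, r_time["f"], "F", 1, n - 2,
                 r_time["p"], metric),
    contrast_row("Synergy", "interaction", est_int, r_int["f"], "F", 1,
                 n - 2, r_int["p"], metric))
}

#' Group-differences-post-retreat contrast: between-group ANCOVA
#'
#' Least-squares fit of the post-session values on group with the
#' pre-session values as covariate; the group coefficient (drug minus
#' placebo) is tested with `df = n - 3`.
#'
#' @inheritParams synergy_rm_anova
#' @return A one-row contrast data.frame (`GroupPost`, t statistic).
#' @export
ancova_group_post <- function(design, metric = NA_character_) {
  stopifnot(inherits(design, "fc_design"))
  if (stats::sd(design$pre) == 0)
    stop("pre-session values are constant: ANCOVA covariate is collinear ",
         "with the intercept")
  g <- factor(design$group, levels = c("placebo", "drug"))
  fit <- stats::lm(post ~ pre + g, data = cbind(design, g = g))
  cf <- suppressWarnings(summary(fit))$coefficients
  n <- nrow(design)
  est <- cf["gdrug", 1]
  deg <- degenerate_fit(fit, design$post, est)
  if (is.null(deg)) deg <- c(cf["gdrug", 3], cf["gdrug", 4])
  contrast_row("GroupPost", "group", est, deg[1], "t",
               NA_real_, n - 3, deg[2], metric)
}

#' Within-group change contrasts (Meditation / Psychedelic-augmented)
#'
#' Tests the post-minus-pre change within one group, adjusting for the
#' group's centered baseline: `change ~ 1 + (pre - mean(pre))`, with the
#' intercept t testing the baseline-adjusted mean change (`df = n_g - 2`).
#' `group = "placebo"` is the Meditation contrast; `group = "drug"` the
#' Psychedelic-augmented-meditation (PsychMed) contrast.
#'
#' @inheritParams synergy_rm_anova
#' @param group Which group to test.
#' @return A one-row contrast data.frame.
#' @export
within_group_ancova <- function(design, group = c("placebo", "drug"),
                                metric = NA_character_) {
  stopifnot(inherits(design, "fc_design"))
  group <- match.arg(group)
  sub <- design[design$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) stop("group absent from design: ", group)
  if (stats::sd(sub$pre) == 0)
    stop("baseline values are constant within group ", group,
         ": covariate carries no information")
  d <- sub$post - sub$pre
  b <- sub$pre - mean(sub$pre)
  fit <- stats::lm(d ~ b)
  cf <- suppressWarnings(summary(fit))$coefficients
  est <- cf["(Intercept)", 1]
  deg <- degenerate_fit(fit, d, est)
  if (is.null(deg)) deg <- c(cf["(Intercept)", 3], cf["(Intercept)", 4])
  name <- if (group == "placebo") "Meditation" else "PsychMed"
  contrast_row(name, "time", est, deg[1], "t", NA_real_, nrow(sub) - 2,
               deg[2], metric)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH procedure: q-values with enforced monotonicity and the
#' rejection set at level `q_level`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q_level FDR level.
#' @return A list with `q` (adjusted values) and `reject` (logical).
#' @export
fdr_bh <- function(p_values, q_level = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0L)
    return(list(q = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= q_level)
}

#' Apply a contrast independently to every parcel
#'
#' Runs one of the four predefined contrasts on a per-parcel metric (e.g.
#' global connectivity) across the cohort, treating all parcels as one
#' BH-FDR family. This parcel-level correction deliberately replaces
#' voxel-level Gaussian-Random-Field cluster inference, which is out of
#' scope at parcel resolution.
#'
#' @param pre,post Subjects x parcels matrices of the metric at each
#'   session (matching row order).
#' @param group Group label per subject.
#' @param contrast One of `"synergy"`, `"grouppost"`, `"meditation"`,
#'   `"psychmed"`.
#' @param q_level FDR level across parcels.
#' @return A data.frame with one row per parcel: estimate, statistic, p, q,
#'   reject.
#' @export
parcelwise_contrast <- function(pre, post, group,
                                contrast = c("synergy", "grouppost",
                                             "meditation", "psychmed"),
                                q_level = 0.05) {
  contrast <- match.arg(contrast)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post)))
    stop("pre and post matrices must have identical shape")
  if (length(group) != nrow(pre))
    stop("group must have one entry per subject row")
  parcels <- colnames(pre)
  if (is.null(parcels)) parcels <- sprintf("p%04d", seq_len(ncol(pre)))
  subjects <- rownames(pre)
  if (is.null(subjects)) subjects <- sprintf("sub%03d", seq_len(nrow(pre)))
  rows <- lapply(seq_len(ncol(pre)), function(j) {
    des <- fc_design(subjects, group, pre[, j], post[, j])
    res <- switch(contrast,
      synergy = {
        r <- synergy_rm_anova(des, metric = parcels[j])
        r[r$effect == "interaction", , drop = FALSE]
      },
      grouppost = ancova_group_post(des, metric = parcels[j]),
      meditation = within_group_ancova(des, "placebo", metric = parcels[j]),
      psychmed = within_group_ancova(des, "drug", metric = parcels[j]))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bh <- fdr_bh(out$p, q_level)
  out$q <- bh$q
  out$reject <- bh$reject
  out
}

#' Brain-behavior association models
#'
#' Ordinary-least-squares fit of a per-subject connectivity change on each
#' questionnaire score, group, and their interaction:
#' `fc_change ~ score + group + score:group`. With `delta_mode = TRUE` the
#' score is the day-2 minus baseline difference, otherwise the raw day-2
#' score. The interaction p-values are BH-corrected across the
#' questionnaire family, and per-group Pearson and Spearman follow-up
#' correlations are reported.
#'
#' @param fc_change Named numeric vector of per-subject connectivity
#'   changes.
#' @param scores Long data.frame with columns `subject`, `questionnaire`,
#'   `day` (`"baseline"`, `"day2"`) and `value` (as produced by
#'   [simulate_cohort()]).
#' @param group Named group vector (`"drug"`/`"placebo"`) per subject.
#' @param delta_mode Use day-2 minus baseline scores?
#' @param q_level FDR level across questionnaires.
#' @return A data.frame with one row per questionnaire: interaction
#'   estimate/t/p/q, score and group main effects, and per-group
#'   correlations.
#' @export
association_ols <- function(fc_change, scores, group, delta_mode = FALSE,
                            q_level = 0.05) {
  subjects <- names(fc_change)
  if (is.null(subjects)) stop("fc_change must be a named vector")
  g <- group[subjects]
  if (anyNA(g)) stop("group missing for some subjects")
  if (any(table(g) < 4L)) stop("need at least 4 subjects per group")
  qnames <- unique(scores$questionnaire)
  rows <- lapply(qnames, function(qn) {
    sq <- scores[scores$questionnaire == qn, , drop = FALSE]
    day2 <- sq$value[match(paste(subjects, "day2"),
                           paste(sq$subject, sq$day))]
    if (delta_mode) {
      base <- sq$value[match(paste(subjects, "baseline"),
                             paste(sq$subject, sq$day))]
      x <- day2 - base
    } else x <- day2
    if (anyNA(x)) stop("missing ", qn, " scores for some subjects")
    gf <- factor(g, levels = c("placebo", "drug"))
    mm <- stats::model.matrix(~ x * gf)
    if (qr(mm)$rank < ncol(mm))
      stop("collinear association design for ", qn,
           " (score constant within a group?)")
    fit <- stats::lm(fc_change ~ x * gf)
    cf <- summary(fit)$coefficients
    per_group <- lapply(c(placebo = "placebo", drug = "drug"), function(gg) {
      sel <- g == gg
      pe <- stats::cor.test(x[sel], fc_change[sel], method = "pearson")
      sp <- suppressWarnings(
        stats::cor.test(x[sel], fc_change[sel], method = "spearman"))
      c(r = unname(pe$estimate), r_p = pe$p.value,
        rho = unname(sp$estimate), rho_p = sp$p.value)
    })
    data.frame(questionnaire = qn, delta_mode = delta_mode,
               slope = cf["x", 1],
               interaction = cf["x:gfdrug", 1],
               interaction_t = cf["x:gfdrug", 3],
               df = fit$df.residual,
               interaction_p = cf["x:gfdrug", 4],
               pearson_placebo = per_group$placebo["r"],
               pearson_placebo_p = per_group$placebo["r_p"],
               pearson_drug = per_group$drug["r"],
               pearson_drug_p = per_group$drug["r_p"],
               spearman_placebo = per_group$placebo["rho"],
               spearman_drug = per_group$drug["rho"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bh <- fdr_bh(out$interaction_p, q_level)
  out$interaction_q <- bh$q
  out$reject <- bh$reject
  out
}
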