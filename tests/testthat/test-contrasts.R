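test_that("synergy ANOVA matches the hand-computed toy example", {
  des <- fc_design(paste0("s", 1:4), c("drug", "drug", "placebo", "placebo"),
                   pre = c(0, 0, 0, 0), post = c(2, 0, 0, -2))
  res <- synergy_rm_anova(des)
  int <- res[res$effect == "interaction", ]
  expect_equal(int$statistic, 2.0, tolerance = 1e-12)
  expect_equal(int$df1, 1)
  expect_equal(int$df2, 2)
  expect_equal(int$estimate, 2)          # mean drug diff 1 - placebo diff -1
  # all-identical values: F = 0, p = 1
  flat <- fc_design(paste0("s", 1:4),
                    c("drug", "drug", "placebo", "placebo"),
                    pre = rep(3, 4), post = rep(3, 4))
  res_flat <- synergy_rm_anova(flat)
  expect_true(all(res_flat$statistic == 0))
  expect_true(all(res_flat$p == 1))
})

test_that("interaction F equals squared difference-score t on balanced data", {
  set.seed(40)
  for (rep in 1:50) {
    n <- sample(c(4, 6, 10), 1)
    des <- fc_design(paste0("s", 1:(2 * n)),
                     rep(c("drug", "placebo"), each = n),
                     pre = rnorm(2 * n), post = rnorm(2 * n))
    d <- des$post - des$pre
    tt <- t.test(d[des$group == "drug"], d[des$group == "placebo"],
                 var.equal = TRUE)
    f_pkg <- synergy_rm_anova(des)
    int <- f_pkg[f_pkg$effect == "interaction", ]
    expect_equal(int$statistic, unname(tt$statistic)^2,
                 tolerance = 1e-8)
    expect_equal(int$p, tt$p.value, tolerance = 1e-8)
  }
})

test_that("synergy main effects agree with aov on balanced designs", {
  set.seed(41)
  n <- 8
  des <- fc_design(paste0("s", 1:(2 * n)),
                   rep(c("drug", "placebo"), each = n),
                   pre = rnorm(2 * n), post = rnorm(2 * n))
  long <- data.frame(
    subject = rep(des$subject, 2),
    group = factor(rep(des$group, 2)),
    session = factor(rep(c("pre", "post"), each = 2 * n),
                     levels = c("pre", "post")),
    value = c(des$pre, des$post))
  fit <- summary(aov(value ~ group * session + Error(subject / session),
                     data = long))
  f_between <- fit[["Error: subject"]][[1]]["group", "F value"]
  f_within <- fit[["Error: subject:session"]][[1]]
  res <- synergy_rm_anova(des)
  expect_equal(res$statistic[res$effect == "group"], f_between,
               tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "time"],
               f_within["session", "F value"], tolerance = 1e-8)
  expect_equal(res$statistic[res$effect == "interaction"],
               f_within["group:session", "F value"], tolerance = 1e-8)
})

test_that("group-post ANCOVA matches the normal-equations oracle", {
  set.seed(42)
  des <- fc_design(paste0("s", 1:6),
                   c("drug", "drug", "drug", "placebo", "placebo",
                     "placebo"),
                   pre = rnorm(6), post = rnorm(6))
  res <- ancova_group_post(des)
  x <- cbind(1, des$pre, as.numeric(des$group == "drug"))
  beta <- brute_ols(x, des$post)
  expect_equal(res$estimate, beta[3], tolerance = 1e-10)
  expect_equal(res$df2, 3)
  # post == pre with balanced groups: no group signal
  des2 <- fc_design(paste0("s", 1:6), des$group,
                    pre = c(1, 2, 3, 1, 2, 3), post = c(1, 2, 3, 1, 2, 3))
  expect_lt(abs(ancova_group_post(des2)$statistic), 1e-8)
  # shift equivariance: adding a constant to post changes intercept only
  des3 <- des
  des3$post <- des$post + 10
  expect_equal(ancova_group_post(des3)$estimate, res$estimate,
               tolerance = 1e-10)
  # constant covariate is rejected
  des4 <- fc_design(des$subject, des$group, pre = rep(1, 6),
                    post = des$post)
  expect_error(ancova_group_post(des4), "collinear")
})

test_that("within-group ANCOVA is null when post equals pre", {
  set.seed(43)
  pre <- rnorm(8)
  des <- fc_design(paste0("s", 1:8), rep(c("drug", "placebo"), each = 4),
                   pre = pre, post = pre)
  expect_lt(abs(within_group_ancova(des, "placebo")$statistic), 1e-8)
  expect_lt(abs(within_group_ancova(des, "drug")$statistic), 1e-8)
})

test_that("within-group ANCOVA detects a planted uniform shift", {
  set.seed(44)
  hits <- 0L
  signs <- 0L
  for (rep in 1:200) {
    pre <- rnorm(40, 0, 0.1)
    post <- pre + 0.3 + rnorm(40, 0, 0.1)
    des <- fc_design(paste0("s", 1:40),
                     rep(c("drug", "placebo"), each = 20),
                     pre = pre, post = post)
    res <- within_group_ancova(des, "drug")
    if (res$p < 0.05) hits <- hits + 1L
    if (res$estimate > 0) signs <- signs + 1L
  }
  expect_gte(hits / 200, 0.95)
  expect_equal(signs, 200L)
})

test_that("BH correction matches the brute-force step-up definition", {
  res <- fdr_bh(c(0.01, 0.02, 0.04), 0.05)
  expect_true(all(res$reject))
  expect_true(all(fdr_bh(rep(0.9, 10), 0.05)$reject == FALSE))
  set.seed(45)
  for (rep in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    bh <- fdr_bh(p, 0.05)
    expect_identical(bh$reject, brute_bh_reject(p, 0.05))
    expect_true(all(bh$q >= p - 1e-15))
    # BH rejects at least as much as Bonferroni
    expect_true(all(which(p <= 0.05 / length(p)) %in% which(bh$reject)))
  }
  expect_length(fdr_bh(numeric(0))$reject, 0L)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("parcelwise contrasts are exchangeable under parcel permutation", {
  set.seed(46)
  n <- 12; p <- 8
  pre <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("p", 1:p)))
  post <- pre + matrix(rnorm(n * p, 0.1), n)
  colnames(post) <- colnames(pre)
  grp <- rep(c("drug", "placebo"), each = n / 2)
  res <- parcelwise_contrast(pre, post, grp, "synergy")
  perm <- sample(p)
  res_perm <- parcelwise_contrast(pre[, perm], post[, perm], grp, "synergy")
  expect_equal(res_perm$p, res$p[perm], tolerance = 1e-12)
  expect_equal(res_perm$metric, res$metric[perm])
  expect_error(parcelwise_contrast(pre, post[, 1:3], grp, "synergy"),
               "identical shape")
})

test_that("parcelwise synergy recovers parcels carrying a planted effect", {
  set.seed(47)
  n <- 40; p <- 30
  grp <- rep(c("drug", "placebo"), each = 20)
  hits <- replicate(20, {
    pre <- matrix(rnorm(n * p, 0, 0.1), n)
    post <- pre + matrix(rnorm(n * p, 0, 0.1), n)
    post[grp == "drug", 1:5] <- post[grp == "drug", 1:5] + 0.5
    res <- parcelwise_contrast(pre, post, grp, "synergy")
    c(sens = mean(res$reject[1:5]), fp = mean(res$reject[6:p]))
  })
  expect_gte(mean(hits["sens", ]), 0.9)
  expect_lt(mean(hits["fp", ]), 0.2)
})

test_that("association OLS recovers a planted interaction slope", {
  set.seed(48)
  n <- 40
  subjects <- paste0("s", 1:n)
  grp <- setNames(rep(c("drug", "placebo"), each = n / 2), subjects)
  slopes <- c(drug = 0.7, placebo = 0.2)   # interaction 0.5
  x <- rnorm(n)
  fc <- slopes[grp] * x + rnorm(n, 0, 0.02)
  names(fc) <- subjects
  scores <- data.frame(subject = rep(subjects, each = 2),
                       questionnaire = "MEQ",
                       day = rep(c("baseline", "day2"), n),
                       value = as.vector(rbind(rnorm(n), x)))
  res <- association_ols(fc, scores, grp)
  expect_equal(res$interaction, 0.5, tolerance = 0.05)
  expect_true(res$reject[1])
  expect_gt(res$pearson_drug, 0.9)
})

test_that("association OLS errors on group-constant scores", {
  n <- 16
  subjects <- paste0("s", 1:n)
  grp <- setNames(rep(c("drug", "placebo"), each = n / 2), subjects)
  fc <- setNames(rnorm(n), subjects)
  scores <- data.frame(subject = rep(subjects, each = 2),
                       questionnaire = "MEQ",
                       day = rep(c("baseline", "day2"), n),
                       value = rep(c(0, 5), n))  # day2 constant everywhere
  expect_error(association_ols(fc, scores, grp), "collinear")
})

test_that("delta mode uses day-2 minus baseline scores", {
  set.seed(49)
  n <- 20
  subjects <- paste0("s", 1:n)
  grp <- setNames(rep(c("drug", "placebo"), each = n / 2), subjects)
  base <- rnorm(n)
  delta <- rnorm(n)
  fc <- setNames(0.9 * delta + rnorm(n, 0, 0.05), subjects)
  scores <- data.frame(subject = rep(subjects, each = 2),
                       questionnaire = "PIS",
                       day = rep(c("baseline", "day2"), n),
                       value = as.vector(rbind(base, base + delta)))
  res_delta <- association_ols(fc, scores, grp, delta_mode = TRUE)
  res_raw <- association_ols(fc, scores, grp, delta_mode = FALSE)
  expect_equal(res_delta$slope, 0.9, tolerance = 0.1)
  expect_gt(abs(res_delta$pearson_drug), abs(res_raw$pearson_drug))
})
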