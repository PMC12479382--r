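test_that("identical seeds give bit-identical cohorts", {
  a <- simulate_cohort(tiny_config(seed = 11))
  b <- simulate_cohort(tiny_config(seed = 11))
  expect_identical(a$scans$sub01$pre$data, b$scans$sub01$pre$data)
  expect_identical(a$scans$sub06$post$fd, b$scans$sub06$post$fd)
  expect_identical(a$scores, b$scores)
  c <- simulate_cohort(tiny_config(seed = 12))
  expect_false(identical(a$scans$sub01$pre$data, c$scans$sub01$pre$data))
})

test_that("every subject has exactly two sessions and truth echoes config", {
  co <- simulate_cohort(tiny_config(seed = 2))
  expect_true(all(vapply(co$scans, function(s)
    identical(sort(names(s)), c("post", "pre")), logical(1L))))
  expect_s3_class(co$atlas, "network_atlas")
  expect_identical(co$truth$config$seed, 2L)
  expect_equal(nrow(co$truth$planted_changes), 0L)
})

test_that("zero couplings yield near-zero empirical correlations", {
  cfg <- sim_config(n_drug = 2, n_placebo = 2,
                    network_sizes = tiny_sizes, n_frames = 2000,
                    within_coupling = 1e-9, between_coupling = 0,
                    ar1_coefficient = 0, seed = 5)
  co <- simulate_cohort(cfg)
  r <- cor(co$scans$sub01$pre$data)
  expect_lt(abs(mean(r[upper.tri(r)])), 0.02)
})

test_that("planted between-coupling is recovered on the Fisher-z scale", {
  # Monte-Carlo against the closed form atanh(0.3) over 100 scans at T=240
  bc <- matrix(0.05, 6, 6)
  dimnames(bc) <- list(names(tiny_sizes), names(tiny_sizes))
  bc["VIS", "SAL"] <- bc["SAL", "VIS"] <- 0.3
  zs <- vapply(1:50, function(i) {
    cfg <- sim_config(n_drug = 2, n_placebo = 2,
                      network_sizes = tiny_sizes, n_frames = 240,
                      between_coupling = bc, seed = 7000 + i)
    co <- simulate_cohort(cfg)
    mean(c(between_network_fc(co$scans$sub01$pre, co$atlas)["VIS", "SAL"],
           between_network_fc(co$scans$sub02$pre, co$atlas)["VIS", "SAL"]))
  }, numeric(1L))
  expect_lt(abs(mean(zs) - atanh(0.3)), 0.03)
})

test_that("injected deltas shift only the targeted condition", {
  inj <- list(list(target = c("VIS", "SAL"), group = "drug",
                   session = "post", delta = 0.3))
  cfg <- tiny_config(seed = 3, effect_map = inj)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  expect_equal(tr$conditions$drug.post$between["VIS", "SAL"], 0.35)
  expect_equal(tr$conditions$drug.pre$between["VIS", "SAL"], 0.05)
  expect_equal(tr$conditions$placebo.post$between["VIS", "SAL"], 0.05)
  pc <- tr$planted_changes
  expect_equal(nrow(pc), 1L)
  expect_equal(pc$delta_z, atanh(0.35) - atanh(0.05))
  # drug subjects carry the planted change; placebo subjects do not
  expect_equal(unname(tr$subject_change[["sub01"]]), pc$delta_z)
  expect_equal(unname(tr$subject_change[["sub04"]]), 0)
})

test_that("non-PD injections are rejected naming the injection", {
  # two high couplings sharing a network violate joint positive
  # definiteness even though each is a valid pairwise correlation
  inj <- list(
    list(target = c("VIS", "SAL"), group = "drug", session = "post",
         delta = 0.9),
    list(target = c("VIS", "DAN"), group = "drug", session = "post",
         delta = 0.9))
  expect_error(tiny_config(seed = 1, effect_map = inj),
               "positive definite.*VIS-DAN", ignore.case = TRUE)
  inj2 <- list(list(target = c("VIS", "SAL"), group = "drug",
                    session = "post", delta = 0.96))
  expect_error(tiny_config(seed = 1, effect_map = inj2),
               "outside")
})

test_that("AR(1) smoothing preserves the planted cross-correlations", {
  mk <- function(phi) {
    cfg <- sim_config(n_drug = 2, n_placebo = 2,
                      network_sizes = tiny_sizes, n_frames = 4000,
                      ar1_coefficient = phi, seed = 99)
    co <- simulate_cohort(cfg)
    between_network_fc(co$scans$sub01$pre, co$atlas)["VIS", "SAL"]
  }
  # same seed, different smoothness: both should estimate atanh(0.05)
  expect_lt(abs(mk(0) - atanh(0.05)), 0.05)
  expect_lt(abs(mk(0.6) - atanh(0.05)), 0.05)
})

test_that("gradient connectome simulator is deterministic and validates", {
  a <- simulate_gradient_connectome(50, "line", decay = 4, seed = 8)
  b <- simulate_gradient_connectome(50, "line", decay = 4, seed = 8)
  expect_identical(a$fc$values, b$fc$values)
  expect_error(simulate_gradient_connectome(50, "line", decay = -1),
               "decay")
  expect_error(simulate_gradient_connectome(5, "line"), "at least 10")
  tb <- simulate_gradient_connectome(40, "two_block", seed = 8)
  expect_length(tb$labels, 40)
  expect_equal(sort(unique(tb$labels)), 1:2)
})

test_that("questionnaire scores follow the planted linear model", {
  inj <- list(list(target = c("VIS", "SAL"), group = "drug",
                   session = "post", delta = 0.3))
  cfg <- sim_config(n_drug = 40, n_placebo = 40,
                    network_sizes = tiny_sizes, n_frames = 60,
                    effect_map = inj,
                    questionnaire_model = list(
                      questionnaires = "MEQ", intercept = 50,
                      slope = list(drug = 100, placebo = 100),
                      noise_sd = 1),
                    seed = 21)
  co <- simulate_cohort(cfg)
  day2 <- co$scores[co$scores$day == "day2", ]
  dz <- co$truth$planted_changes$delta_z
  expect_lt(abs(mean(day2$value[day2$group == "drug"]) - (50 + 100 * dz)),
            1.5)
  expect_lt(abs(mean(day2$value[day2$group == "placebo"]) - 50), 1.5)
})
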