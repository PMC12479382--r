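test_that("row thresholding keeps ceil(density*(P-1)) entries with tie rule", {
  set.seed(30)
  m <- matrix(rnorm(400 * 400), 400)
  thr <- threshold_rows(m, 0.10)
  expect_true(all(rowSums(thr != 0) == 40))     # ceil(0.1 * 399) = 40
  # ties broken by lower parcel index
  tie <- matrix(1, 5, 5)
  thr_tie <- threshold_rows(tie, 0.4)           # keep 2 per row
  expect_equal(which(thr_tie[1, ] != 0), c(2L, 3L))
  expect_equal(which(thr_tie[4, ] != 0), c(1L, 2L))
  # brute-force sort oracle on a small random matrix
  set.seed(31)
  m5 <- matrix(rnorm(25), 5)
  thr5 <- threshold_rows(m5, 0.4)
  for (i in 1:5) {
    vals <- m5[i, -i]
    keep <- which(thr5[i, ] != 0)
    expect_equal(length(keep), 2L)
    expect_true(all(m5[i, keep] >= sort(vals, decreasing = TRUE)[2]))
  }
  expect_error(threshold_rows(m5, 0), "density")
})

test_that("cosine affinity follows the direct formula and clips negatives", {
  m <- rbind(c(1, 0), c(1, 1))
  a <- cosine_affinity(m)
  expect_equal(a$values[1, 2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(diag(a$values), c(1, 1))
  # disjoint support -> 0; opposite rows -> clipped to 0 with count
  m2 <- rbind(c(1, 0, 0, 1), c(0, 1, 1, 0), c(-1, 0, 0, -1))
  a2 <- cosine_affinity(m2)
  expect_equal(a2$values[1, 2], 0)
  expect_equal(a2$values[1, 3], 0)
  expect_equal(a2$n_clipped, 2L)
  expect_error(cosine_affinity(rbind(c(1, 1), c(0, 0))), "all-zero row.*2")
})

test_that("diffusion embedding matches the dense nonsymmetric oracle", {
  set.seed(32)
  for (rep in 1:3) {
    w <- matrix(runif(60 * 60), 60)
    w <- (w + t(w)) / 2
    gr <- diffusion_embedding(w, n_components = 3)
    oracle <- brute_diffusion_scores(w, 0.5, 3)
    for (k in 1:3)
      expect_gt(abs(cor(gr$scores[, k], oracle$scores[, k])), 0.999)
    expect_equal(gr$eigenvalues, oracle$eigenvalues, tolerance = 1e-8)
  }
})

test_that("two-block affinity separates blocks; uniform affinity degenerates", {
  aff <- matrix(0.05, 40, 40)
  aff[1:20, 1:20] <- 0.6
  aff[21:40, 21:40] <- 0.6
  g1 <- diffusion_embedding(aff, 3)$scores[, 1]
  expect_true(all(sign(g1[1:20]) == sign(g1[1])))
  expect_true(all(sign(g1[21:40]) == -sign(g1[1])))
  unif <- matrix(1, 30, 30)
  gu <- diffusion_embedding(unif, 3)
  expect_lt(max(abs(gu$eigenvalues)), 1e-10)
  expect_lt(max(abs(gu$scores)), 1e-6)
})

test_that("disconnected affinities are rejected", {
  w <- diag(2) %x% matrix(1, 10, 10)   # two disconnected cliques
  expect_error(diffusion_embedding(w), "disconnected")
})

test_that("variance explained follows the partial-sum rule", {
  expect_equal(variance_explained(c(0.5, 0.3, 0.2, 0, 0), 3), 1.0)
  expect_equal(variance_explained(c(4, 3, 2, 1), 3), 0.9)
  ve <- vapply(1:4, function(k) variance_explained(c(4, 3, 2, 1), k),
               numeric(1L))
  expect_true(all(diff(ve) >= 0))
  expect_error(variance_explained(c(0, 0, 0), 2), "all-zero")
  expect_error(variance_explained(c(1, 2, 3), 2), "descending")
})

test_that("procrustes self-alignment is the identity", {
  set.seed(33)
  x <- matrix(rnorm(50 * 3), 50)
  res <- procrustes_align(list(x), template = x)
  expect_lt(res$disparity[1], 1e-12)
})

test_that("procrustes recovers constructed rotations and reflections", {
  set.seed(34)
  x <- scale(matrix(rnorm(50 * 3), 50), TRUE, FALSE)
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  res <- procrustes_align(list(x %*% rot), template = x)
  expect_lt(sqrt(sum((res$aligned[[1]]$scores - x)^2)), 1e-8)
  refl <- diag(c(1, -1, 1))
  res2 <- procrustes_align(list(x %*% refl), template = x)
  expect_lt(sqrt(sum((res2$aligned[[1]]$scores - x)^2)), 1e-12)
  expect_error(procrustes_align(list(x, matrix(0, 10, 3))), "share")
})

test_that("group-template disparity objective is non-increasing", {
  set.seed(35)
  base <- matrix(rnorm(40 * 3), 40)
  scans <- lapply(1:8, function(i)
    base + matrix(rnorm(40 * 3, 0, 0.3), 40))
  res <- procrustes_align(scans, n_iter = 10, baseline = 1:4)
  expect_true(all(diff(res$objective) <= 1e-10))
})

test_that("dispersion matches hand-computed closed forms", {
  atlas <- network_atlas(c("a", "b", "c", "d"),
                         c("VIS", "VIS", "SAL", "SAL"))
  sc <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0), c(3, 4, 0))
  rownames(sc) <- c("a", "b", "c", "d")
  g <- gradient_set(sc)
  d <- dispersion(g, atlas, 3)
  expect_equal(unname(d$within["VIS"]), 2)     # points at 0 and 2, centroid 1
  expect_equal(unname(d$centroids["VIS", ]), c(1, 0, 0))
  # centroids (1,0,0) and (1.5,2,0): check the planted 3-4-5 pair directly
  atlas2 <- network_atlas(c("a", "b"), c("VIS", "SAL"))
  sc2 <- rbind(c(0, 0, 0), c(3, 4, 0))
  rownames(sc2) <- c("a", "b")
  d2 <- dispersion(gradient_set(sc2), atlas2, 3)
  expect_equal(d2$between["VIS", "SAL"], 5)
  expect_equal(unname(d2$within), c(0, 0))     # single points: zero spread
})

test_that("dispersion is invariant under common rotation of all scores", {
  set.seed(36)
  atlas <- network_atlas(sprintf("p%02d", 1:30),
                         rep(c("VIS", "SAL", "DMN"), each = 10))
  sc <- matrix(rnorm(30 * 3), 30)
  rownames(sc) <- sprintf("p%02d", 1:30)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  sc_rot <- sc %*% q
  rownames(sc_rot) <- rownames(sc)
  d1 <- dispersion(gradient_set(sc), atlas, 3)
  d2 <- dispersion(gradient_set(sc_rot), atlas, 3)
  expect_equal(d1$within, d2$within, tolerance = 1e-10)
  expect_equal(d1$between, d2$between, tolerance = 1e-10)
})

test_that("full pipeline recovers planted line and block geometry", {
  line <- simulate_gradient_connectome(200, "line", decay = 5, seed = 37)
  g1 <- diffusion_embedding(
    cosine_affinity(threshold_rows(line$fc, 0.10)), 10)$scores[, 1]
  expect_gte(abs(cor(g1, line$axis, method = "spearman")), 0.95)
  tb <- simulate_gradient_connectome(100, "two_block", seed = 38)
  h1 <- diffusion_embedding(
    cosine_affinity(threshold_rows(tb$fc, 0.6)), 10)$scores[, 1]
  s1 <- sign(h1[tb$labels == 1])
  s2 <- sign(h1[tb$labels == 2])
  expect_true(all(s1 == s1[1]) && all(s2 == -s1[1]))
})
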