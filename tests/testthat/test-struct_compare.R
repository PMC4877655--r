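cloud <- function(n, seed) with_seed_helper(seed, matrix(stats::rnorm(n * 3, 0, 8), n, 3))

test_that("kabsch recovers exact rigid motions", {
  P <- cloud(12, 1)
  fit0 <- kabsch(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)

  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% t(R), 2, c(1, 2, 3), `+`)
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-6)
})

test_that("kabsch refuses reflections and degenerate input", {
  P <- cloud(10, 2)
  Q <- P %*% diag(c(1, 1, -1))  # mirror image
  fit <- kabsch(P, Q)
  expect_gt(fit$rmsd, 0.5)
  # a reflection-permitting fit would be exact: confirms the chirality guard
  H <- crossprod(scale(P, scale = FALSE), scale(Q, scale = FALSE))
  sv <- svd(H)
  refl <- sv$u %*% t(sv$v)
  expect_equal(det(refl), -1, tolerance = 1e-6)
  naive <- sqrt(mean(rowSums((scale(P, scale = FALSE) %*% refl -
                                scale(Q, scale = FALSE))^2)))
  expect_lt(naive, 1e-9)

  expect_error(kabsch(P[1:2, ], Q[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("tm_d0 follows the standard constants with a 0.5 A floor", {
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(16), 0.5)  # formula gives -0.56, floored
})

test_that("tm_score is exact on identity and lower-bounded by the closed form", {
  P <- cloud(30, 3)
  corr <- cbind(1:30, 1:30)
  expect_equal(tm_score(P, P, corr, 30), 1.0, tolerance = 1e-9)

  # displacements orthogonal to the rigid-motion generators leave the
  # single-shot optimum at the identity: every pair sits at exactly d0
  d0 <- tm_d0(64)
  P4 <- rbind(c(8, 0, 0), c(-8, 0, 0), c(0, 8, 0), c(0, -8, 0))
  D <- rbind(c(0, 0, d0), c(0, 0, d0), c(0, 0, -d0), c(0, 0, -d0))
  Q4 <- P4 + D
  one_shot <- ladderlens:::tm_optimize(P4, Q4, cbind(1:4, 1:4), 64, d0,
                                       max_iter = 1L)
  expect_equal(one_shot$tm, 4 / (2 * 64), tolerance = 1e-9)
  expect_gte(tm_score(P4, Q4, cbind(1:4, 1:4), 64), 4 / (2 * 64) - 1e-12)
})

test_that("tm_score warns when the normalization length hits the d0 floor", {
  P <- cloud(10, 4)
  expect_warning(tm_score(P, P, cbind(1:10, 1:10), 10), "floor")
})

test_that("tm_score degrades monotonically with coordinate noise", {
  P <- cloud(60, 5)
  noise <- with_seed_helper(6, matrix(stats::rnorm(180), 60, 3))
  corr <- cbind(1:60, 1:60)
  tm1 <- tm_score(P, P + 1 * noise, corr, 60)
  tm4 <- tm_score(P, P + 4 * noise, corr, 60)
  expect_gt(tm1, tm4)
})

test_that("tm_score is invariant under rigid motions of either input", {
  A <- simulate_horseshoe(10, seed = 8)
  B <- simulate_horseshoe(10, seed = 9)
  n <- min(nrow(A$xyz), nrow(B$xyz))
  corr <- cbind(1:n, 1:n)
  base <- tm_score(A$xyz, B$xyz, corr, n)
  for (seed in 1:20) {
    R <- random_rotation(seed)
    t <- with_seed_helper(seed + 50, stats::rnorm(3, 0, 20))
    moved <- sweep(B$xyz %*% t(R), 2, t, `+`)
    expect_lt(abs(tm_score(A$xyz, moved, corr, n) - base), 1e-6)
  }
})

test_that("equal lengths with full correspondence give tm_a = tm_b", {
  A <- simulate_horseshoe(12, seed = 10, noise_sd = 0.3)
  B <- rigid_move(A, random_rotation(3), c(5, -2, 1))
  res <- align_structures(A, B)
  expect_equal(res$comparison$tm_a, res$comparison$tm_b, tolerance = 1e-9)
  expect_equal(res$comparison$tm_avg, 1.0, tolerance = 1e-3)
  expect_equal(det(res$comparison$rotation), 1, tolerance = 1e-6)
})

test_that("alignment separates related folds from random walks", {
  A <- simulate_horseshoe(15, seed = 12)
  walk <- with_seed_helper(13, {
    steps <- matrix(stats::rnorm(nrow(A$xyz) * 3, 0, 3.8 / sqrt(3)),
                    nrow(A$xyz), 3)
    ca_trace("walk", seq_len(nrow(A$xyz)), A$aa, apply(steps, 2, cumsum))
  })
  res <- align_structures(A, walk)
  expect_lt(res$comparison$tm_avg, 0.3)
})

test_that("central distortion lowers the TM-score against intact horseshoes", {
  sd1 <- simulate_horseshoe(21, FALSE, noise_sd = 0.5, seed = 14)
  sd2 <- simulate_horseshoe(21, FALSE, noise_sd = 0.5, seed = 15)
  td <- simulate_horseshoe(21, TRUE, noise_sd = 0.5, seed = 16)
  tm_ss <- align_structures(sd1, sd2)$comparison$tm_avg
  tm_st <- align_structures(sd1, td)$comparison$tm_avg
  expect_gt(tm_ss, 0.8)
  expect_gt(tm_ss, tm_st)
})

test_that("class summaries aggregate means and SEMs per unordered pair", {
  df <- data.frame(class_a = c("SD", "SD", "TD", "SD"),
                   class_b = c("SD", "SD", "SD", "TD"),
                   tm_avg = c(0.8, 0.9, 0.5, 0.7))
  out <- class_summary(df)
  expect_equal(out$mean_tm[out$group == "SDxSD"], 0.85)
  expect_equal(out$n[out$group == "SDxTD"], 2L)
  expect_equal(out$mean_tm[out$group == "SDxTD"], 0.6)
  single <- class_summary(df[3, ])
  expect_equal(single$sem, 0)
  expect_equal(single$n, 1L)
})
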