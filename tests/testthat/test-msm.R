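test_that("tICA recovers the AR(1) autocorrelation at the lag", {
  set.seed(61)
  f <- 50000; a <- 0.9
  x <- numeric(f)
  for (t in 2:f) x[t] <- a * x[t - 1] + rnorm(1)
  for (lag in c(1L, 5L)) {
    tm <- tica(matrix(x, ncol = 1), lag = lag)
    expect_equal(tm$eigenvalues[1], a^lag, tolerance = 0.05)
  }
})

test_that("tICA aligns its first component with the slow coordinate", {
  set.seed(62)
  f <- 20000
  slow <- numeric(f); fast <- numeric(f)
  for (t in 2:f) {
    slow[t] <- 0.95 * slow[t - 1] + rnorm(1)
    fast[t] <- 0.5 * fast[t - 1] + rnorm(1)
  }
  tm <- tica(cbind(slow, fast), lag = 5)
  v <- tm$components[, 1]
  expect_gt(abs(v[1]) / sqrt(sum(v^2)), 0.95)
  # components are generalized-orthonormal w.r.t. the instantaneous covariance
  x0 <- sweep(cbind(slow, fast), 2, tm$mean)
  n <- f - tm$lag
  c00 <- (crossprod(x0[1:n, ]) + crossprod(x0[(tm$lag + 1):f, ])) / (2 * n)
  gram <- t(tm$components) %*% c00 %*% tm$components
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(abs(tm$eigenvalues) <= 1 + 1e-6))
})

test_that("constant feature columns are regularized out with a warning", {
  set.seed(63)
  x <- cbind(rnorm(500), 1)
  expect_warning(tm <- tica(x, lag = 1), "rank-deficient")
  expect_equal(ncol(tm$components), 1L)
  expect_error(tica(x[1:3, ], lag = 5), "more frames")
})

test_that("tICA eigenvalues are invariant under time reversal", {
  set.seed(64)
  f <- 5000
  x <- matrix(0, f, 2)
  for (t in 2:f) x[t, ] <- 0.8 * x[t - 1, ] + rnorm(2)
  expect_equal(tica(x, 3)$eigenvalues, tica(x[f:1, ], 3)$eigenvalues,
               tolerance = 1e-9)
})

test_that("k-means microstates are deterministic and respect structure", {
  set.seed(65)
  clouds <- rbind(matrix(rnorm(200, mean = 0, sd = 0.3), ncol = 2),
                  matrix(rnorm(200, mean = 10, sd = 0.3), ncol = 2))
  l1 <- kmeans_microstates(clouds, n_states = 2, seed = 9)
  l2 <- kmeans_microstates(clouds, n_states = 2, seed = 9)
  expect_identical(l1, l2)
  expect_equal(length(unique(l1[1:100])), 1L)
  expect_equal(length(unique(l1[101:200])), 1L)
  expect_false(l1[1] == l1[101])

  # n_states = F: every frame its own state
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(sort(kmeans_microstates(x, n_states = 10, seed = 1)), 1:10)
  expect_error(kmeans_microstates(x, n_states = 11, seed = 1), "exceeds")
})

test_that("MSM estimation recovers a known 2-state chain", {
  p01 <- 0.1; p10 <- 0.3
  T2 <- matrix(c(1 - p01, p01, p10, 1 - p10), 2, 2, byrow = TRUE)
  traj <- simulate_markov_chain(T2, 100000, seed = 66)
  m <- estimate_msm(traj, lag = 1)
  # closed form: pi = (p10, p01) / (p01 + p10), lambda2 = 1 - p01 - p10
  expect_equal(as.numeric(m$stationary), c(0.75, 0.25), tolerance = 0.02)
  expect_equal(m$timescales[1], -1 / log(1 - p01 - p10), tolerance = 0.05)
  expect_equal(rowSums(m$transition), rep(1, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(m$stationary %*% m$transition),
               as.numeric(m$stationary), tolerance = 1e-10)
  # detailed balance holds by construction in reversible mode
  pt <- m$stationary * m$transition
  expect_equal(pt, t(pt), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m$retained_fraction, 1)
})

test_that("a deterministic 3-cycle has a uniform stationary distribution", {
  traj <- rep(1:3, length.out = 3000)
  m <- estimate_msm(traj, lag = 1, reversible = FALSE)
  expect_equal(as.numeric(m$stationary), rep(1 / 3, 3), tolerance = 1e-3)
})

test_that("disconnected states are dropped to the most-visited component", {
  traj <- c(rep(1L, 800), rep(2L, 200))   # one crossing 1 -> 2, no return
  m <- expect_silent(estimate_msm(traj, lag = 1))
  # symmetrized counts connect the pair; force hard disconnection instead
  traj2 <- list(rep(1L, 800), rep(2L, 200))
  m2 <- estimate_msm(traj2, lag = 1)
  expect_equal(m2$active_set, 1L)
  expect_lt(m2$retained_fraction, 1)
})

test_that("implied timescales are flat for a Markov chain and follow the formula", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  traj <- simulate_markov_chain(T2, 80000, seed = 67)
  tab <- implied_timescales(traj, lags = c(1L, 2L, 4L), n_timescales = 1L)
  t_true <- -1 / log(1 - 0.1 - 0.2)
  expect_equal(tab$timescale, rep(t_true, 3), tolerance = 0.1)

  # direct formula: lambda2 = exp(-1) at lag 10 -> t2 = 10
  expect_equal(-10 / log(exp(-1)), 10)

  # i.i.d. labels: lambda2 near zero, timescale tiny or undefined
  set.seed(68)
  iid <- sample(1:3, 50000, replace = TRUE)
  m <- estimate_msm(iid, lag = 1)
  expect_true(all(is.na(m$timescales) | m$timescales < 0.5))
})

test_that("PCCA-style coarse-graining separates weakly coupled blocks", {
  eps <- 1e-3
  Tblock <- rbind(c(0.60 - eps / 2, 0.40 - eps / 2, eps / 2, eps / 2),
                  c(0.30 - eps / 2, 0.70 - eps / 2, eps / 2, eps / 2),
                  c(eps / 2, eps / 2, 0.50 - eps / 2, 0.50 - eps / 2),
                  c(eps / 2, eps / 2, 0.45 - eps / 2, 0.55 - eps / 2))
  traj <- simulate_markov_chain(Tblock, 60000, seed = 69)
  m <- estimate_msm(traj, lag = 1)
  mac <- pcca_macrostates(m, 2, seed = 1)
  a <- mac$macro_assignment
  expect_equal(a[["1"]], a[["2"]])
  expect_equal(a[["3"]], a[["4"]])
  expect_false(a[["1"]] == a[["3"]])
  expect_equal(sum(mac$macro_populations), 1, tolerance = 1e-10)
  expect_equal(rowSums(mac$coarse_transition), rep(1, 2), tolerance = 1e-10)

  # n_macro = k is the identity coarse-graining
  mac_k <- pcca_macrostates(m, length(m$active_set), seed = 1)
  expect_equal(sort(as.numeric(mac_k$macro_populations)),
               sort(as.numeric(m$stationary)), tolerance = 1e-12)
  expect_error(pcca_macrostates(m, 10), "exceeds")
})

test_that("the Chapman-Kolmogorov test passes Markovian and flags non-Markovian data", {
  T2 <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, 2, byrow = TRUE)
  traj <- simulate_markov_chain(T2, 100000, seed = 70)
  ck <- ck_test(traj, lag = 1, factors = c(1L, 2L, 5L))
  expect_equal(ck$results[[1]]$max_deviation, 0, tolerance = 1e-12)
  expect_lt(ck$max_deviation, 0.05)

  # deterministic alternation lumped through a 2->1 observation map is
  # strongly non-Markovian at even lags
  hidden <- rep(c(1L, 2L, 3L, 2L), length.out = 40000)
  observed <- c(1L, 2L, 2L)[hidden]
  ck2 <- ck_test(observed, lag = 1, factors = c(1L, 2L))
  expect_gt(ck2$max_deviation, 0.2)
})
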