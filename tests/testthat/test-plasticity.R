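test_that("grid specs cover the padded bounding box", {
  top <- toy_topology(1)
  ens <- ensemble(top, matrix(c(0, 0, 0), 1, 3))
  spec <- make_grid_spec(ens, spacing = 1.0, padding = 4.0)
  # single C atom: extent 2 * (1.7 + 4.0) = 11.4 -> 12 voxels per axis
  expect_equal(spec$dims, rep(12L, 3))
  expect_equal(spec$origin, rep(-5.7, 3))
  expect_error(make_grid_spec(ens, spacing = 0), "positive")

  shifted <- ensemble(top, matrix(c(20, 0, 0), 1, 3))
  spec2 <- make_grid_spec(list(ens, shifted), spacing = 1.0, padding = 4.0)
  expect_equal(spec2$dims[1], as.integer(ceiling(20 + 11.4)))
  expect_equal(spec2$dims[2:3], rep(12L, 2))
})

test_that("static ensembles give binary mean grids and an all-zero SD grid", {
  ens <- generate_ensemble(synthetic_spec(sigma_scaffold = 0, sigma_loop = 0,
                                          n_frames = 5, seed = 51))
  spec <- make_grid_spec(ens)
  occ <- occupancy_stats(ens, spec)
  expect_true(all(occ$mean$values %in% c(0, 1)))
  expect_equal(max(occ$sd$values), 0)
  expect_equal(global_plasticity(occ$sd), 0)
  expect_gt(sum(occ$mean$values), 0)
})

test_that("a half-occupied site has mean 0.5 and the binomial-extremum SD 0.5", {
  top <- toy_topology(1)
  co <- array(0, dim = c(1, 3, 4))
  co[1, 1, 3:4] <- 40    # atom jumps far away for half the frames
  ens <- ensemble(top, co)
  spec <- make_grid_spec(ens, spacing = 1.0, padding = 4.0)
  occ <- occupancy_stats(ens, spec)
  # the voxel at the first site is occupied in exactly half the frames
  home <- which(occ$mean$values == 0.5)
  expect_gt(length(home), 0)
  expect_equal(occ$sd$values[home], rep(0.5, length(home)))
  expect_equal(max(occ$sd$values), 0.5)
})

test_that("SD grid satisfies sd = sqrt(p(1-p)) voxelwise", {
  ens <- generate_ensemble(synthetic_spec(n_frames = 15, seed = 52))
  spec <- make_grid_spec(ens)
  occ <- occupancy_stats(ens, spec)
  p <- occ$mean$values
  expect_lt(max(abs(occ$sd$values - sqrt(p * (1 - p)))), 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(occ$sd$values <= 0.5 + 1e-15))
  # occupancy counts per frame are integers: p * F is integral
  expect_equal(p * 15, round(p * 15), tolerance = 1e-9)
})

test_that("occupancy statistics are invariant to frame order", {
  ens <- generate_ensemble(synthetic_spec(n_frames = 8, seed = 53))
  spec <- make_grid_spec(ens)
  occ1 <- occupancy_stats(ens, spec)
  perm <- ensemble(ens$topology, ens$coords[, , sample(8)], ens$frame_ids)
  occ2 <- occupancy_stats(perm, spec)
  expect_equal(occ1$mean$values, occ2$mean$values)
  expect_equal(occ1$sd$values, occ2$sd$values)
})

test_that("atoms outside the grid are reported with frame and atom", {
  top <- toy_topology(2)
  co <- array(0, dim = c(2, 3, 2))
  co[2, 1, 2] <- 500
  ens <- ensemble(top, co)
  spec <- grid_spec(c(-6, -6, -6), 1.0, c(12L, 12L, 12L))
  expect_error(occupancy_stats(ens, spec), "frame 2: atom 2")
})

test_that("Gaussian smoothing preserves mass, handles sigma 0, fixes constants", {
  spec <- grid_spec(c(0, 0, 0), 1.0, c(21L, 21L, 21L))
  delta <- array(0, dim = c(21, 21, 21)); delta[11, 11, 11] <- 1
  g <- occupancy_grid(spec, delta, "sd", 1L)

  expect_equal(gauss_filter(g, sigma = 0)$values, delta)

  sm <- gauss_filter(g, sigma = 1.5)
  expect_equal(sm$kind, "sd_smoothed")
  expect_equal(sum(sm$values), 1, tolerance = 1e-9)
  # smoothed delta is proportional to the sampled separable Gaussian kernel
  k <- exp(-((-6:6))^2 / (2 * 1.5^2)); k <- k / sum(k)
  expect_equal(sm$values[11 + (-6:6), 11, 11], k[7] * k[7] * k,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sm$values[11, 11, 11], k[7]^3, tolerance = 1e-12)

  const <- occupancy_grid(spec, array(0.37, dim = c(21, 21, 21)), "mean", 1L)
  expect_equal(gauss_filter(const, 2.0)$values, const$values, tolerance = 1e-12)
})

test_that("smoothing preserves the total of any interior-supported grid", {
  set.seed(54)
  spec <- grid_spec(c(0, 0, 0), 0.5, c(30L, 30L, 30L))
  v <- array(0, dim = c(30, 30, 30))
  v[13:18, 13:18, 13:18] <- runif(216)
  g <- occupancy_grid(spec, v, "sd", 2L)
  sm <- gauss_filter(g, sigma = 0.6)
  expect_equal(sum(sm$values), sum(v), tolerance = 1e-9)
})

test_that("global plasticity integrates supra-threshold SD volume", {
  spec <- grid_spec(c(0, 0, 0), 1.0, c(5L, 5L, 5L))
  v <- array(0, dim = c(5, 5, 5))
  g0 <- occupancy_grid(spec, v, "sd", 4L)
  expect_equal(global_plasticity(g0), 0)

  v[3, 3, 3] <- 0.5
  g1 <- occupancy_grid(spec, v, "sd", 4L)
  expect_equal(global_plasticity(g1, threshold = 0.05), 0.5)
  # spacing scales the volume element
  spec2 <- grid_spec(c(0, 0, 0), 2.0, c(5L, 5L, 5L))
  g2 <- occupancy_grid(spec2, v, "sd", 4L)
  expect_equal(global_plasticity(g2, threshold = 0.05), 0.5 * 8)
  # threshold excludes values at or below it
  expect_equal(global_plasticity(g1, threshold = 0.5), 0)
  expect_error(global_plasticity(g1, threshold = 0.7), "0, 0.5")
  expect_error(global_plasticity(occupancy_grid(spec, v, "mean", 4L)), "SD grid")
})

test_that("localization assigns SD mass to the nearest residue and conserves it", {
  ens <- generate_ensemble(synthetic_spec(sigma_scaffold = 0, sigma_loop = 0,
                                          n_frames = 2, seed = 55))
  spec <- make_grid_spec(ens)
  # an all-zero grid localizes to all-zero scores
  zero <- occupancy_grid(spec, array(0, dim = spec$dims), "sd", 2L)
  loc0 <- localize_plasticity(zero, ens)
  expect_true(all(loc0$per_residue == 0))
  expect_equal(loc0$global_score, 0)

  # place SD mass only at the CA of loop residue H:3
  top <- ens$topology
  ca <- which(top$atoms$chain == "H" & top$atoms$resseq == 3 & top$atoms$name == "CA")
  pos <- frame_coords(ens, 1)[ca, ]
  idx <- pmin(pmax(ceiling((pos - spec$origin) / spec$spacing), 1L), spec$dims)
  v <- array(0, dim = spec$dims)
  v[idx[1], idx[2], idx[3]] <- 0.4
  g <- occupancy_grid(spec, v, "sd", 2L)
  loc <- localize_plasticity(g, ens, max_dist = 4.0, threshold = 0.05)
  expect_gt(loc$per_residue[["H:3"]], 0)
  expect_equal(sum(loc$per_residue > 0), 1L)
  expect_equal(loc$global_score, global_plasticity(g, 0.05), tolerance = 1e-9)
})

test_that("per-residue scores plus unassigned reproduce the global integral", {
  ens <- align_ensemble(generate_ensemble(synthetic_spec(n_frames = 12, seed = 56)),
                        "chain S name CA", reference = "mean")
  spec <- make_grid_spec(ens)
  occ <- occupancy_stats(ens, spec)
  sm <- gauss_filter(occ$sd, 1.5)
  loc <- localize_plasticity(sm, ens, max_dist = 4.0, threshold = 0.05)
  expect_equal(sum(loc$per_residue) + loc$unassigned,
               global_plasticity(sm, 0.05), tolerance = 1e-9)
  expect_equal(loc$global_score, sum(loc$per_residue) + loc$unassigned)
  expect_true(all(loc$per_residue >= 0))
})

test_that("plasticity responds monotonically to the fluctuation magnitude", {
  scores <- vapply(c(0.2, 0.5, 1.0), function(sig) {
    ens <- generate_ensemble(synthetic_spec(sigma_scaffold = 0.2, sigma_loop = sig,
                                            n_frames = 40, seed = 57))
    spec <- make_grid_spec(ens)
    occ <- occupancy_stats(ens, spec)
    global_plasticity(gauss_filter(occ$sd, 1.5), 0.05)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("difference grids subtract elementwise and refuse mismatched specs", {
  spec <- grid_spec(c(0, 0, 0), 1.0, c(4L, 4L, 4L))
  a <- occupancy_grid(spec, array(runif(64), dim = c(4, 4, 4)), "sd_smoothed", 3L)
  d0 <- plasticity_difference(a, a)
  expect_equal(d0$kind, "difference")
  expect_equal(max(abs(d0$values)), 0)

  b <- occupancy_grid(spec, array(runif(64), dim = c(4, 4, 4)), "sd_smoothed", 3L)
  expect_equal(plasticity_difference(a, b)$values, a$values - b$values)

  spec2 <- grid_spec(c(1, 0, 0), 1.0, c(4L, 4L, 4L))
  b2 <- occupancy_grid(spec2, b$values, "sd_smoothed", 3L)
  expect_error(plasticity_difference(a, b2), "specs differ")
  m <- occupancy_grid(spec, b$values, "mean_smoothed", 3L)
  expect_error(plasticity_difference(a, m), "kinds differ")
})

test_that("the naive ensemble is more plastic than the matured one near the loop", {
  pair <- naive_matured_pair(seed = 6, n_frames = 60)
  al <- pair_align(pair$naive, pair$matured, "chain S name CA")
  spec <- make_grid_spec(list(al$a, al$b))
  sd_a <- gauss_filter(occupancy_stats(al$a, spec)$sd, 1.5)
  sd_b <- gauss_filter(occupancy_stats(al$b, spec)$sd, 1.5)
  expect_gt(global_plasticity(sd_a), global_plasticity(sd_b))
  diff <- plasticity_difference(sd_a, sd_b)
  # near the loop, positive (naive-heavier) differences dominate
  loop <- resolve_selection(al$a$topology, "chain H name CA")$indices
  mean_loop <- apply(al$a$coords[loop, , , drop = FALSE], c(1, 2), mean)
  idx <- which(diff$values != 0, arr.ind = TRUE)
  centers <- sweep(sweep(idx - 0.5, 2, rep(spec$spacing, 3), "*"), 2,
                   spec$origin, "+")
  near <- apply(centers, 1, function(p)
    min(sqrt(colSums((t(mean_loop) - p)^2)))) <= 6
  vals <- diff$values[idx][near]
  expect_gt(sum(vals[vals > 0]), -sum(vals[vals < 0]))
})
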