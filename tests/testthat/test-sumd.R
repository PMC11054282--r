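test_that("center-of-mass distance follows the mass-weighted formula", {
  expect_equal(com_distance(matrix(c(3, 4, 0), 1), c(0, 0, 0), 1), 5)
  coords <- matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(com_distance(coords, c(0, 0, 0), c(1, 1)), 0)
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(rnorm(18), 6, 3)
    m <- runif(6, 1, 20)
    ctr <- rnorm(3)
    oracle <- sqrt(sum((colSums(x * m) / sum(m) - ctr)^2))
    expect_equal(com_distance(x, ctr, m), oracle, tolerance = 1e-12)
  }
  expect_error(com_distance(coords, c(0, 0, 0), c(0, 0)), "mass")
})

test_that("distance slope equals the closed-form OLS fit", {
  expect_equal(fit_distance_slope(rep(4, 10)), 0)
  expect_equal(fit_distance_slope(10 - 0.5 * (0:9)), -0.5)
  expect_error(fit_distance_slope(3), "at least 2")
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(30, 10, 2)
    x <- 0:29
    # normal-equations oracle
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit_distance_slope(y), beta[2], tolerance = 1e-10)
  }
})

test_that("supervision verdicts follow the slope sign exactly (stubbed engine)", {
  sys <- default_sys()
  cfg <- sumd_config(step_window = 100, max_attempts_per_step = 4, seed = 1,
                     save_every = 10)
  st <- dyn_state(unbound_pose(sys, 14), temperature_set = 310)
  mk_traj <- function(dists) {
    # place the whole ligand rigidly so COM distance tracks `dists`
    nb <- nrow(sys$ligand)
    arr <- array(0, c(length(dists), nb, 3))
    for (k in seq_along(dists)) arr[k, , ] <- unbound_pose(sys, dists[k])
    structure(list(frames = arr, kinetic = rep(0, length(dists)),
                   frame_interval = 10L, temperature_set = 310, seed = 1),
              class = "toy_trajectory")
  }
  approach <- function(st_, seed_) list(
    trajectory = mk_traj(seq(14, 13, length.out = 11)), state = st_)
  out <- sumd_step(sys, st, cfg, step_id = 1, engine = approach)
  expect_equal(out$record$verdict, "productive")
  expect_equal(out$record$attempt_count, 1)
  expect_lt(out$record$slope, 0)
  retreat <- function(st_, seed_) list(
    trajectory = mk_traj(seq(14, 15, length.out = 11)), state = st_)
  out2 <- sumd_step(sys, st, cfg, step_id = 2, engine = retreat)
  expect_equal(out2$record$verdict, "unproductive")
  expect_equal(out2$record$attempt_count, cfg$max_attempts_per_step)
  expect_null(out2$trajectory)
  expect_identical(out2$state$positions, st$positions)  # positions reset
  flat <- function(st_, seed_) list(
    trajectory = mk_traj(rep(14, 11)), state = st_)
  out3 <- sumd_step(sys, st, cfg, step_id = 3, engine = flat)
  expect_equal(out3$record$verdict, "unproductive")  # slope 0 is not negative
})

test_that("acceptance fraction on a force-free system is consistent with 1/2", {
  # with no forces the COM random-walks, so window slopes are
  # sign-symmetric; first-attempt acceptance should be ~Binomial(n, 1/2)
  sys <- default_sys()
  free <- sys
  free$receptor$charge[] <- 0
  free$receptor$epsilon[] <- 0
  n <- 60
  acc <- 0
  cfg <- sumd_config(step_window = 1000, save_every = 50, seed = 3,
                     max_attempts_per_step = 1)
  for (k in seq_len(n)) {
    st0 <- randomize_velocities(dyn_state(unbound_pose(sys, 14)), free, 310,
                                derive_seed(77, k))
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(3, k)
    out <- sumd_step(free, st0, cfg_k, step_id = k)
    acc <- acc + (out$record$verdict == "productive")
  }
  ci <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
})

test_that("full SuMD runs bind, log verdicts coherently and reproduce bit-exactly", {
  sys <- default_sys()
  cfg <- sumd_config(seed = 11, max_total_steps = 60)
  res <- run_sumd(sys, unbound_pose(sys, 14), cfg)
  expect_true(res$bound)
  expect_true(all(res$steps$slope[res$steps$verdict == "productive"] < 0))
  expect_equal(tail(res$steps$verdict, 1), "supervision_off")
  # supervised portion of the distance series decreases across step seams
  expect_lt(min(res$distances), cfg$distance_threshold)
  expect_equal(nrow(res$energies), n_frames(res$trajectory))
  expect_length(res$rmsd_vs_native, n_frames(res$trajectory))
  res2 <- run_sumd(sys, unbound_pose(sys, 14), cfg)
  expect_identical(res$trajectory$frames, res2$trajectory$frames)
  expect_identical(res$steps, res2$steps)
})

test_that("a start already below threshold skips straight to the post phase", {
  sys <- default_sys()
  cfg <- sumd_config(seed = 2, post_phase_window = 2000)
  res <- run_sumd(sys, sys$native_pose, cfg)
  expect_true(res$bound)
  expect_equal(res$supervision_off_step, 0)
  expect_equal(sum(res$steps$verdict != "supervision_off"), 0)
  expect_gt(n_frames(res$trajectory), 1)
})

test_that("a purely repulsive ligand ends not-bound after the step budget", {
  sys <- default_sys()
  rep_sys <- sys
  rep_sys$receptor$charge <- abs(rep_sys$receptor$charge) + 0.3
  rep_sys$ligand$charge <- abs(rep_sys$ligand$charge) + 0.3
  rep_sys$receptor$epsilon[] <- 0
  rep_sys$ligand$epsilon[] <- 0
  cfg <- sumd_config(step_window = 300, save_every = 30,
                     max_attempts_per_step = 2, max_total_steps = 4, seed = 4)
  res <- run_sumd(rep_sys, unbound_pose(rep_sys, 14), cfg)
  expect_false(res$bound)
  expect_true(is.na(res$integration_steps_to_bind))
  expect_equal(sum(res$steps$verdict != "supervision_off"),
               cfg$max_total_steps)
})

test_that("per-site electrostatic heat map ranks, decomposes and handles edge cases", {
  sys <- default_sys()
  st <- randomize_velocities(dyn_state(sys$native_pose), sys, 300, 6)
  out <- run_md(sys, st, 2000, 300, seed = 7, save_every = 100)
  tr <- out$trajectory
  hm <- per_residue_ele_heatmap(tr, sys, top_k = 5)
  expect_equal(dim(hm), c(5, n_frames(tr)))
  # columns equal the per-site decomposition of each frame
  for (i in c(1, n_frames(tr))) {
    per <- interaction_energy(sys, traj_frame(tr, i))$per_receptor_site_ele
    expect_equal(hm[, i], per[rownames(hm)], tolerance = 1e-9)
  }
  # rows are the top-|contact| sites of the full matrix
  full <- per_residue_ele_heatmap(tr, sys, top_k = nrow(sys$receptor))
  expect_identical(rownames(hm), rownames(full)[1:5])
  expect_true(all(diff(rowSums(abs(full))) <= 1e-12))
  expect_error(per_residue_ele_heatmap(tr, sys,
                                       top_k = nrow(sys$receptor) + 1),
               "top_k")
  neutral <- sys
  neutral$receptor$charge[] <- 0
  expect_true(all(per_residue_ele_heatmap(out$trajectory, neutral, 3) == 0))
  single <- run_md(sys, st, 50, 300, seed = 8, save_every = 100)$trajectory
  expect_equal(n_frames(single), 1)
  hm1 <- per_residue_ele_heatmap(single, sys, 4)
  expect_equal(ncol(hm1), 1)
})
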