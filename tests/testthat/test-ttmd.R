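test_that("binding-loss rule is a strict window-mean threshold", {
  expect_false(binding_lost(rep(-1, 5), -0.2))
  expect_true(binding_lost(rep(0, 5), -0.2))
  expect_false(binding_lost(c(-0.1, -0.3), -0.2))  # mean exactly at threshold
  expect_true(binding_lost(c(-0.1, -0.25), -0.2))
  expect_error(binding_lost(numeric(0)), "empty")
})

test_that("titration profile points are per-window means of the frame scores", {
  # synthetic result object checked against a spreadsheet-style oracle
  frames <- data.frame(
    temperature = rep(c(300, 310, 320), times = c(4, 4, 4)),
    frame = rep(1:4, 3),
    ifp_cs = c(-1, -0.5, -1, -0.5, -0.9, -0.7, -0.8, -0.6, -0.2, 0, -0.1, -0.1))
  windows <- do.call(rbind, lapply(split(frames, frames$temperature),
    function(d) data.frame(temperature = d$temperature[1],
                           mean_ifp_cs = sum(d$ifp_cs) / nrow(d),
                           mean_kinetic_T = d$temperature[1], lost = FALSE)))
  res <- structure(list(windows = windows, frames = frames,
                        unbinding_T = NA_real_, binding_lost = FALSE),
                   class = "ttmd_result")
  prof <- titration_profile(res)
  expect_equal(prof$mean_ifp_cs, c(-0.75, -0.75, -0.1))
  expect_equal(prof$temperature, c(300, 310, 320))
  expect_equal(attr(prof, "ms_coefficient"), (-0.1 - -0.75) / 20)
})

test_that("MS coefficient is the endpoint chord, not an OLS slope", {
  prof <- data.frame(temperature = c(300, 320),
                     mean_ifp_cs = c(-1.0, 0.0))
  expect_equal(ms_coefficient(prof), 0.05)
  flat <- data.frame(temperature = c(300, 310, 320),
                     mean_ifp_cs = rep(-0.6, 3))
  expect_equal(ms_coefficient(flat), 0)
  # a profile where chord and OLS demonstrably differ
  bump <- data.frame(temperature = c(300, 310, 320, 330),
                     mean_ifp_cs = c(-1, -0.2, -0.9, -0.8))
  chord <- (-0.8 - -1) / 30
  x <- bump$temperature; y <- bump$mean_ifp_cs
  ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(ms_coefficient(bump), chord)
  expect_equal(ms_coefficient(bump, method = "ols"), ols)
  expect_false(isTRUE(all.equal(chord, ols)))
  expect_error(ms_coefficient(bump[1, , drop = FALSE]), "at least 2")
  same_T <- data.frame(temperature = c(300, 300), mean_ifp_cs = c(-1, 0))
  expect_error(ms_coefficient(same_T), "identical")
})

test_that("a short ladder runs, reports rungs in order, and reproduces bit-exactly", {
  sys <- default_sys()
  cfg <- ttmd_config(t_start = 300, t_increment = 10, t_max = 330,
                     window_steps = 2000, save_every = 50, seed = 9)
  res <- run_ttmd(sys, sys$native_pose, cfg)
  expect_s3_class(res, "ttmd_result")
  expect_equal(res$windows$temperature,
               seq(300, by = 10, length.out = nrow(res$windows)))
  expect_true(all(res$windows$mean_ifp_cs >= -1 &
                    res$windows$mean_ifp_cs <= 0))
  expect_true(all(res$frames$rmsd_receptor == 0))
  res2 <- run_ttmd(sys, sys$native_pose, cfg)
  expect_identical(res$frames, res2$frames)
  expect_identical(res$windows, res2$windows)
})

test_that("a deep well completes a short ladder unbroken; a null ligand is lost at once", {
  sys <- default_sys()
  cfg <- ttmd_config(t_max = 320, window_steps = 2000, save_every = 50,
                     seed = 10)
  res <- run_ttmd(sys, sys$native_pose, cfg)
  expect_false(res$binding_lost)
  expect_true(is.na(res$unbinding_T))
  expect_equal(nrow(res$windows), 3)
  # all interactions zeroed: nothing holds the ligand, so over a window
  # long enough for free diffusion to mix over the box the mean similarity
  # collapses and the first rung already reports the loss
  null_sys <- sys
  null_sys$receptor$charge[] <- 0
  null_sys$receptor$epsilon[] <- 0
  resn <- run_ttmd(null_sys, sys$native_pose,
                   ttmd_config(t_start = 600, t_max = 610,
                               window_steps = 3000000, save_every = 15000,
                               seed = 11))
  expect_true(resn$binding_lost)
  expect_equal(resn$unbinding_T, 600)
  # a start pose with no interactions at all is an invalid reference
  far_sys <- sys
  expect_error(run_ttmd(far_sys, sweep(sys$native_pose, 2, c(0, 0, 40), "+"),
                        ttmd_config(seed = 1)),
               "all-zero")
})

test_that("thermostat realizes the rung set points on ladder average", {
  sys <- default_sys()
  cfg <- ttmd_config(t_max = 400, window_steps = 5000, save_every = 25,
                     seed = 12)
  res <- run_ttmd(sys, sys$native_pose, cfg)
  ratio <- res$windows$mean_kinetic_T / res$windows$temperature
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("replicate summaries aggregate unbinding temperature and MS", {
  sys <- default_sys()
  cfg <- ttmd_config(t_max = 320, window_steps = 1000, save_every = 50,
                     n_replicates = 3, seed = 13)
  reps <- run_ttmd_replicates(sys, sys$native_pose, cfg)
  expect_length(reps$replicates, 3)
  expect_equal(nrow(reps$summary), 3)
  expect_true(all(reps$summary$unbinding_T <= cfg$t_max))
  expect_equal(reps$summary$ms_coefficient,
               vapply(reps$profiles, attr, 0, "ms_coefficient"))
  # censored ladders are reported at the ceiling
  expect_true(all(reps$summary$unbinding_T[reps$summary$censored] ==
                    cfg$t_max))
})

test_that("deeper anchor wells raise the unbinding temperature (monotone trend)", {
  # small version of the stability-vs-well-depth property: strengthen the
  # hinge charge and compare unbinding temperatures at matched seeds
  depths <- c(0.15, 0.45)
  ub <- sapply(depths, function(q) {
    sys <- make_pocket_system(default_system_config(hbond_charge = q),
                              seed = 2)
    mean(sapply(1:2, function(r) {
      res <- run_ttmd(sys, sys$native_pose,
                      ttmd_config(window_steps = 4000, save_every = 100,
                                  t_max = 700, seed = derive_seed(40, r)))
      if (res$binding_lost) res$unbinding_T else 700
    }))
  })
  expect_gt(ub[2], ub[1])
})
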