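test_that("rmsd satisfies identity, rigid-shift and superposition properties", {
  set.seed(61)
  a <- matrix(rnorm(18), 6, 3)
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, sweep(a, 2, c(3, 4, 0), "+")), 5.0)
  # exact rigid transform is undone by superposition
  ax <- c(2, -1, 1) / sqrt(6)
  th <- 1.1
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  b <- sweep(a %*% t(Rm), 2, c(1, -2, 3), "+")
  expect_gt(rmsd(a, b), 1)
  expect_lt(rmsd(a, b, superpose = TRUE), 1e-8)
  # symmetry and the superposed <= raw inequality on random pairs
  for (i in 1:20) {
    x <- matrix(rnorm(18), 6, 3)
    y <- matrix(rnorm(18), 6, 3)
    expect_equal(rmsd(x, y), rmsd(y, x))
    expect_lte(rmsd(x, y, superpose = TRUE), rmsd(x, y) + 1e-12)
  }
  expect_error(rmsd(a, a[1:3, ]), "equal-shape")
})

test_that("system serialization round-trips exactly through PDB + JSON sidecar", {
  sys <- default_sys()
  d <- withr::local_tempdir()
  p <- file.path(d, "sys.pdb")
  write_system(sys, p)
  back <- read_system(p)
  for (f in c("native_pose", "pocket_center", "anchor_ids", "water_ids",
              "box_half_width", "bond_r0", "k_bond", "seed"))
    expect_equal(back[[f]], sys[[f]], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$receptor, sys$receptor, tolerance = 1e-12)
  expect_equal(back$ligand, sys$ligand, tolerance = 1e-12)
  expect_equal(unname(back$bonds), unname(sys$bonds))
  # energies computed from the round-tripped system agree exactly
  expect_equal(native_energy(back), native_energy(sys), tolerance = 1e-12)
  # the PDB half is structurally validated against the sidecar
  lines <- readLines(p)
  expect_true(any(grepl("SYNTHETIC", lines)))
  writeLines(lines[-grep("^HETATM", lines)[1]], p)
  expect_error(read_system(p), "disagree")
})

test_that("multi-frame XYZ round-trips within fixed-point tolerance", {
  sys <- default_sys()
  st <- randomize_velocities(dyn_state(sys$native_pose), sys, 300, 3)
  tr <- run_md(sys, st, 5000, 300, seed = 5, save_every = 50)$trajectory
  expect_equal(n_frames(tr), 101)
  d <- withr::local_tempdir()
  p <- file.path(d, "traj.xyz")
  write_xyz(tr, p, labels = sys$ligand$label)
  back <- read_xyz(p)
  expect_length(back, 101)
  for (i in c(1, 50, 101))
    expect_lt(max(abs(back[[i]] - traj_frame(tr, i))), 1e-6)
  expect_identical(rownames(back[[1]]), sys$ligand$label)
})

test_that("malformed XYZ input raises errors naming the offending frame", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.xyz")
  f1 <- matrix(rnorm(9), 3, 3)
  writeLines(c("3", "frame 1",
               sprintf("A %f %f %f", f1[, 1], f1[, 2], f1[, 3]),
               "4", "frame 2",
               sprintf("A %f %f %f", f1[, 1], f1[, 2], f1[, 3])), p)
  expect_error(read_xyz(p), "frame 2")
  writeLines(c("2", "frame 1", "A 1 2 3", "B 4 x 6"), p)
  expect_error(read_xyz(p), "frame 1")
  writeLines(character(0), p)
  expect_error(read_xyz(p), "no frames")
})

test_that("profiles and heat maps round-trip through CSV", {
  prof <- structure(data.frame(temperature = c(300, 310, 320),
                               mean_ifp_cs = c(-0.9, -0.7, -0.1)),
                    class = c("titration_profile", "data.frame"),
                    ms_coefficient = 0.04, unbinding_T = 320)
  d <- withr::local_tempdir()
  p <- file.path(d, "prof.csv")
  write_profile_csv(prof, p)
  back <- read_profile_csv(p)
  expect_equal(back$temperature, prof$temperature)
  expect_equal(back$mean_ifp_cs, prof$mean_ifp_cs)
  expect_equal(attr(back, "ms_coefficient"), 0.04)
  expect_equal(attr(back, "unbinding_T"), 320)
  hm <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("A", "B", "C"), NULL))
  hp <- file.path(d, "hm.csv")
  write_heatmap_csv(hm, hp)
  back_hm <- read.csv(hp)
  expect_equal(back_hm$site, rownames(hm))
  expect_equal(as.matrix(back_hm[, -1]), hm, ignore_attr = TRUE)
})

test_that("run configurations load from YAML and JSON with a mandatory seed", {
  d <- withr::local_tempdir()
  py <- file.path(d, "run.yaml")
  writeLines(c("seed: 42", "sumd:", "  step_window: 100",
               "  temperature: 310"), py)
  cfg <- read_run_config(py)
  expect_identical(cfg$seed, 42L)
  expect_equal(cfg$sumd$step_window, 100)
  pj <- file.path(d, "run.json")
  jsonlite::write_json(list(seed = 7, ttmd = list(t_start = 300)), pj,
                       auto_unbox = TRUE)
  cfgj <- read_run_config(pj)
  expect_identical(cfgj$seed, 7L)
  pn <- file.path(d, "noseed.yaml")
  writeLines("ttmd:\n  t_start: 300", pn)
  expect_error(read_run_config(pn), "seed")
  expect_error(read_run_config(file.path(d, "run.txt")), "unsupported")
})

test_that("derived seeds are valid, deterministic and stream-separated", {
  expect_identical(derive_seed(42, 1), derive_seed(42, 1))
  s <- vapply(0:200, function(k) derive_seed(123, k), 1L)
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_false(anyDuplicated(s) > 0)
  expect_false(derive_seed(1, 1) == derive_seed(2, 1))
})

test_that("the shipped example configuration parses into protocol settings", {
  cfg <- read_run_config(system.file("extdata", "example_run.yaml",
                                     package = "toykd"))
  expect_identical(cfg$seed, 42L)
  sc <- do.call(sumd_config, c(cfg$sumd, list(seed = cfg$seed)))
  expect_s3_class(sc, "sumd_config")
  expect_equal(sc$step_window, 5000L)
  tc <- do.call(ttmd_config, c(cfg$ttmd, list(seed = cfg$seed)))
  expect_equal(tc$loss_threshold, -0.2)
})
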