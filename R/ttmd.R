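#' TTMD protocol configuration
#'
#' Defaults reproduce the thermal-titration protocol shape: windows start
#' at 300 K and the temperature rises by 10 K per TTMD-step (20000
#' integration steps standing in for 10 ns each), five replicates. The
#' loss criterion (window-mean IFP_CS above -0.2) and the ladder ceiling
#' are package policy: the underlying protocol states the loss event
#' qualitatively, and on a rigid receptor there is no native-fold ceiling,
#' so `t_max` simply bounds the ladder.
#'
#' @param t_start first rung temperature, K.
#' @param t_increment rung spacing, K (> 0).
#' @param window_steps integration steps per rung.
#' @param t_max last rung temperature, K (>= t_start).
#' @param loss_threshold window-mean IFP_CS above which the binding mode
#'   counts as lost; in `(-1, 0]`.
#' @param n_replicates number of replicate ladders in
#'   [run_ttmd_replicates()].
#' @param seed global seed.
#' @param save_every frame interval in integration steps.
#' @return named list of class `ttmd_config`.
#' @export
ttmd_config <- function(t_start = 300, t_increment = 10,
                        window_steps = 20000, t_max = 900,
                        loss_threshold = -0.2, n_replicates = 5, seed = 1,
                        save_every = 100) {
  stopifnot(t_increment > 0, t_max >= t_start,
            loss_threshold > -1, loss_threshold <= 0, n_replicates >= 1)
  structure(as.list(environment()), class = "ttmd_config")
}

#' Has the native binding mode been lost in a window?
#'
#' TRUE when the arithmetic mean of the window's per-frame IFP_CS scores
#' is strictly above the threshold, i.e. closer to 0 (interaction pattern
#' gone) than the tolerated retention level.
#'
#' @param window_scores per-frame IFP_CS values (nonempty).
#' @param threshold loss threshold.
#' @return logical flag.
#' @export
binding_lost <- function(window_scores, threshold = -0.2) {
  if (length(window_scores) == 0) stop("binding_lost: empty score series")
  mean(window_scores) > threshold
}

#' Run a thermal-titration (TTMD) ladder
#'
#' Computes the reference interaction fingerprint from the start pose, then
#' runs MD windows at stepwise-increasing temperature. Each rung continues
#' from the previous rung's final coordinates with velocities rescaled to
#' the new set point. Per frame it records the IFP_CS against the
#' reference, the ligand RMSD versus the start pose, and the receptor
#' RMSD (identically 0 for the rigid receptor, still reported). The ladder
#' stops at the first rung whose window-mean IFP_CS exceeds the loss
#' threshold, or at `t_max`.
#'
#' @param system a `toy_system`.
#' @param start_pose reference binding mode (coordinate matrix); must have
#'   a nonzero interaction fingerprint.
#' @param cfg a [ttmd_config()].
#' @return object of class `ttmd_result`: list with `windows` (one row per
#'   rung: `temperature`, `mean_ifp_cs`, `mean_kinetic_T`, `lost`),
#'   `frames` (per-frame table: `temperature`, `frame`, `ifp_cs`,
#'   `rmsd_ligand`, `rmsd_receptor`), `unbinding_T` (K, or NA when the
#'   ladder completes without loss), `binding_lost`, `reference_ifp`,
#'   `cfg`.
#' @export
run_ttmd <- function(system, start_pose, cfg = ttmd_config()) {
  start_pose <- .check_coords(system, start_pose)
  ref <- compute_ifp(system, start_pose)
  if (sum(ref) == 0)
    stop("start pose has an all-zero interaction fingerprint")
  temps <- seq(cfg$t_start, cfg$t_max, by = cfg$t_increment)
  state <- dyn_state(start_pose, temperature_set = cfg$t_start)
  state <- randomize_velocities(state, system, cfg$t_start,
                                derive_seed(cfg$seed, 11))
  m <- ligand_masses(system)
  n_dof <- 3 * length(m)
  windows <- list()
  frames <- list()
  unbinding_T <- NA_real_
  lost <- FALSE
  for (k in seq_along(temps)) {
    T_k <- temps[k]
    if (k > 1)  # continue the previous rung, rescaled to the new set point
      state$velocities <- state$velocities * sqrt(T_k / temps[k - 1])
    out <- run_md(system, state, cfg$window_steps, T_k,
                  derive_seed(cfg$seed, 500 + k), cfg$save_every)
    state <- out$state
    tr <- out$trajectory
    nf <- n_frames(tr)
    sc <- vapply(seq_len(nf), function(i)
      ifp_cs(compute_ifp(system, traj_frame(tr, i)), ref), 0)
    rl <- vapply(seq_len(nf), function(i)
      rmsd(traj_frame(tr, i), start_pose), 0)
    frames[[k]] <- data.frame(temperature = T_k, frame = seq_len(nf),
                              ifp_cs = sc, rmsd_ligand = rl,
                              rmsd_receptor = 0)
    kinT <- mean(tr$kinetic[-1]) / (0.5 * n_dof * .kB)
    lost_k <- binding_lost(sc, cfg$loss_threshold)
    windows[[k]] <- data.frame(temperature = T_k, mean_ifp_cs = mean(sc),
                               mean_kinetic_T = kinT, lost = lost_k)
    if (lost_k) {
      unbinding_T <- T_k
      lost <- TRUE
      break
    }
  }
  structure(list(windows = do.call(rbind, windows),
                 frames = do.call(rbind, frames),
                 unbinding_T = unbinding_T, binding_lost = lost,
                 reference_ifp = ref, cfg = cfg),
            class = "ttmd_result")
}

#' @export
print.ttmd_result <- function(x, ...) {
  cat(sprintf("ttmd_result: %d rungs from %g K; %s\n", nrow(x$windows),
              x$windows$temperature[1],
              if (x$binding_lost)
                sprintf("binding lost at %g K", x$unbinding_T)
              else "binding retained through the ladder"))
  invisible(x)
}

#' Titration profile of a TTMD run
#'
#' One point per completed rung: the rung temperature and the window-mean
#' IFP_CS. Also carries the MS stability coefficient (see
#' [ms_coefficient()]) and the unbinding temperature.
#'
#' @param result a `ttmd_result`.
#' @return object of class `titration_profile`: data frame with columns
#'   `temperature`, `mean_ifp_cs`; attributes `ms_coefficient` and
#'   `unbinding_T`.
#' @export
titration_profile <- function(result) {
  pts <- result$windows[, c("temperature", "mean_ifp_cs")]
  rownames(pts) <- NULL
  ms <- if (nrow(pts) >= 2 &&
              pts$temperature[nrow(pts)] != pts$temperature[1])
    ms_coefficient(pts) else NA_real_
  structure(pts, class = c("titration_profile", "data.frame"),
            ms_coefficient = ms, unbinding_T = result$unbinding_T)
}

#' MS stability coefficient of a titration profile
#'
#' Slope of the straight line joining the first and last points of the
#' titration profile (mean IFP_CS versus rung temperature) — the endpoint
#' chord, not a regression. A more negative (or less positive) value ranks
#' the complex as more stable: its interaction pattern degrades less per
#' kelvin. An OLS slope is available as an alternative but is not the
#' definition.
#'
#' @param profile a `titration_profile` or data frame with columns
#'   `temperature` and `mean_ifp_cs` (>= 2 points).
#' @param method `"chord"` (definition) or `"ols"`.
#' @return slope, per K.
#' @export
ms_coefficient <- function(profile, method = c("chord", "ols")) {
  method <- match.arg(method)
  n <- nrow(profile)
  if (is.null(n) || n < 2) stop("ms_coefficient: need at least 2 points")
  if (profile$temperature[n] == profile$temperature[1])
    stop("ms_coefficient: first and last temperatures are identical")
  if (method == "chord")
    (profile$mean_ifp_cs[n] - profile$mean_ifp_cs[1]) /
      (profile$temperature[n] - profile$temperature[1])
  else {
    x <- profile$temperature
    xc <- x - mean(x)
    sum(xc * (profile$mean_ifp_cs - mean(profile$mean_ifp_cs))) / sum(xc^2)
  }
}

#' Replicated TTMD ladders
#'
#' Runs `cfg$n_replicates` ladders differing only by derived seed and
#' summarizes the unbinding temperature and MS coefficient. A ladder that
#' completes without loss is censored at `t_max` and enters the unbinding
#' summary at that ceiling.
#'
#' @inheritParams run_ttmd
#' @return list with `replicates` (list of `ttmd_result`), `profiles`
#'   (list of `titration_profile`), and `summary` data frame
#'   (`replicate`, `unbinding_T`, `censored`, `ms_coefficient`).
#' @export
run_ttmd_replicates <- function(system, start_pose, cfg = ttmd_config()) {
  reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(cfg$seed, 9000 + r)
    run_ttmd(system, start_pose, cfg_r)
  })
  profiles <- lapply(reps, titration_profile)
  summary <- data.frame(
    replicate = seq_along(reps),
    unbinding_T = vapply(reps, function(r)
      if (r$binding_lost) r$unbinding_T else cfg$t_max, 0),
    censored = vapply(reps, function(r) !r$binding_lost, TRUE),
    ms_coefficient = vapply(profiles, function(p)
      attr(p, "ms_coefficient"), 0))
  list(replicates = reps, profiles = profiles, summary = summary)
}
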