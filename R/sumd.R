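#' Mass-weighted ligand center of mass
#' @param ligand_coords coordinate matrix (n x 3), Angstrom.
#' @param masses bead masses, amu (total > 0).
#' @return length-3 numeric vector.
#' @export
ligand_com <- function(ligand_coords, masses) {
  if (sum(masses) <= 0) stop("ligand_com: total mass must be positive")
  colSums(as.matrix(ligand_coords) * masses) / sum(masses)
}

#' Distance from the ligand center of mass to a site center
#' @inheritParams ligand_com
#' @param site_center length-3 vector, Angstrom.
#' @return distance, Angstrom.
#' @export
com_distance <- function(ligand_coords, site_center, masses) {
  sqrt(sum((ligand_com(ligand_coords, masses) - site_center)^2))
}

#' Ordinary least-squares slope of a distance series
#'
#' Fits distance against frame index (0, 1, 2, ...) and returns the slope.
#' The supervision rule only uses its sign, so fitting against frame index
#' rather than physical time is equivalent.
#'
#' @param series numeric vector of distances (>= 2 points).
#' @return slope, Angstrom per frame index.
#' @export
fit_distance_slope <- function(series) {
  n <- length(series)
  if (n < 2) stop("fit_distance_slope: need at least 2 points")
  x <- seq_len(n) - 1
  xc <- x - mean(x)
  sum(xc * (series - mean(series))) / sum(xc^2)
}

#' SuMD protocol configuration
#'
#' Defaults reproduce the protocol shape of supervised molecular dynamics:
#' short unbiased windows ("SuMD-steps", 5000 integration steps standing in
#' for 500 ps), an accept rule on the sign of the fitted ligand-site
#' distance slope, supervision switched off below 10 A, and an
#' unsupervised post phase (20000 steps standing in for 10 ns) at 310 K.
#' Retry and total-step budgets are artifact policy: unbounded retries
#' would never terminate on a pathological system.
#'
#' @param step_window integration steps per SuMD-step.
#' @param distance_threshold supervision switch-off distance, Angstrom.
#' @param max_attempts_per_step velocity-rerandomization retries per step.
#' @param max_total_steps budget of SuMD-steps before giving up.
#' @param post_phase_window integration steps of unsupervised MD after
#'   supervision switches off.
#' @param temperature thermostat set point, K.
#' @param seed global seed; all stage seeds derive from it.
#' @param save_every frame interval in integration steps.
#' @return named list of class `sumd_config`.
#' @export
sumd_config <- function(step_window = 5000, distance_threshold = 10,
                        max_attempts_per_step = 20, max_total_steps = 200,
                        post_phase_window = 20000, temperature = 310,
                        seed = 1, save_every = 50) {
  stopifnot(step_window >= 1, distance_threshold > 0,
            max_attempts_per_step >= 1, max_total_steps >= 1,
            post_phase_window >= 1)
  cfg <- as.list(environment())
  for (f in c("step_window", "max_attempts_per_step", "max_total_steps",
              "post_phase_window", "save_every"))
    cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "sumd_config")
}

# distance of every frame's ligand COM to the binding-site center
.frame_distances <- function(traj, system) {
  m <- ligand_masses(system)
  vapply(seq_len(n_frames(traj)), function(i)
    com_distance(traj_frame(traj, i), system$pocket_center, m), 0)
}

#' Run one supervised MD window
#'
#' Propagates one SuMD-step and applies the tabu-like rule: if the OLS
#' slope of the ligand-site center-of-mass distance over the window is
#' strictly negative the window is productive and kept; otherwise the
#' positions are reset to the window start, the velocities are
#' re-randomized, and the window is retried up to
#' `max_attempts_per_step` times.
#'
#' @param system a `toy_system`.
#' @param state starting `dyn_state`.
#' @param cfg a [sumd_config()].
#' @param step_id integer id of this SuMD-step (seeds derive from it).
#' @param engine window propagator, `function(state, seed)` returning
#'   `list(trajectory =, state =)`; defaults to [run_md()]. Swappable for
#'   testing the accept/reject logic with stubbed trajectories.
#' @return list with `trajectory` (the accepted window, or NULL if the
#'   step failed), `record` (one-row data frame: `step_id`,
#'   `attempt_count`, `slope`, `verdict`, `end_distance`) and `state`.
#' @export
sumd_step <- function(system, state, cfg, step_id = 1L, engine = NULL) {
  if (is.null(engine))
    engine <- function(st, seed)
      run_md(system, st, cfg$step_window, cfg$temperature, seed,
             cfg$save_every)
  start_state <- state
  for (attempt in seq_len(cfg$max_attempts_per_step)) {
    seed_a <- derive_seed(cfg$seed, step_id * 1000 + attempt)
    st <- start_state
    if (attempt > 1)
      st <- randomize_velocities(st, system, cfg$temperature, seed_a)
    out <- engine(st, seed_a)
    d <- .frame_distances(out$trajectory, system)
    slope <- fit_distance_slope(d)
    if (slope < 0) {
      rec <- data.frame(step_id = step_id, attempt_count = attempt,
                        slope = slope, verdict = "productive",
                        end_distance = d[length(d)])
      return(list(trajectory = out$trajectory, record = rec,
                  state = out$state))
    }
  }
  rec <- data.frame(step_id = step_id,
                    attempt_count = cfg$max_attempts_per_step,
                    slope = slope, verdict = "unproductive",
                    end_distance = com_distance(start_state$positions,
                                                system$pocket_center,
                                                ligand_masses(system)))
  list(trajectory = NULL, record = rec, state = start_state)
}

#' Run the supervised-binding (SuMD) protocol
#'
#' Iterates supervised windows from an unbound start pose until the
#' ligand-site center-of-mass distance drops below the threshold, then
#' switches supervision off and continues with an unsupervised post phase.
#' The result carries the concatenated accepted trajectory, the step log,
#' per-frame interaction energies (ele + vdw) and ligand RMSD against the
#' native pose.
#'
#' @param system a `toy_system`.
#' @param start ligand start coordinates; its center of mass should be
#'   farther from the site than `cfg$distance_threshold` (a closer start
#'   simply skips straight to the post phase).
#' @param cfg a [sumd_config()].
#' @return object of class `sumd_result`: list with `steps` (step log),
#'   `trajectory`, `bound` (logical), `supervision_off_step`,
#'   `integration_steps_to_bind` (NA when not bound), `energies`,
#'   `rmsd_vs_native`, `distances`, `cfg`.
#' @export
run_sumd <- function(system, start, cfg = sumd_config()) {
  state <- dyn_state(.check_coords(system, start),
                     temperature_set = cfg$temperature)
  state <- randomize_velocities(state, system, cfg$temperature,
                                derive_seed(cfg$seed, 1))
  records <- list()
  trajs <- list()
  bound <- FALSE
  sup_off <- NA_integer_
  steps_spent <- 0
  m <- ligand_masses(system)
  for (step_id in seq_len(cfg$max_total_steps)) {
    d_now <- com_distance(state$positions, system$pocket_center, m)
    if (d_now < cfg$distance_threshold) {
      bound <- TRUE
      sup_off <- step_id - 1L
      break
    }
    out <- sumd_step(system, state, cfg, step_id)
    out$record$integration_steps <- out$record$attempt_count * cfg$step_window
    steps_spent <- steps_spent + out$record$integration_steps
    records[[length(records) + 1]] <- out$record
    if (!is.null(out$trajectory)) {
      trajs[[length(trajs) + 1]] <- out$trajectory
      state <- out$state
    }
  }
  if (bound) {
    post <- run_md(system, state, cfg$post_phase_window, cfg$temperature,
                   derive_seed(cfg$seed, 900001), cfg$save_every)
    trajs[[length(trajs) + 1]] <- post$trajectory
    state <- post$state
  }
  steps <- if (length(records)) do.call(rbind, records) else
    data.frame(step_id = integer(), attempt_count = integer(),
               slope = numeric(), verdict = character(),
               end_distance = numeric(), integration_steps = numeric())
  if (bound) {
    off_row <- data.frame(step_id = sup_off + 1L, attempt_count = 0L,
                          slope = NA_real_, verdict = "supervision_off",
                          end_distance = com_distance(state$positions,
                                                      system$pocket_center, m),
                          integration_steps = cfg$post_phase_window)
    steps <- rbind(steps, off_row)
  }
  traj <- if (length(trajs)) .concat_trajectories(trajs) else NULL
  energies <- if (!is.null(traj)) trajectory_energies(traj, system) else NULL
  rmsd_vec <- if (!is.null(traj))
    vapply(seq_len(n_frames(traj)), function(i)
      rmsd(traj_frame(traj, i), system$native_pose), 0) else numeric(0)
  distances <- if (!is.null(traj)) .frame_distances(traj, system) else numeric(0)
  structure(list(steps = steps, trajectory = traj, bound = bound,
                 supervision_off_step = sup_off,
                 integration_steps_to_bind = if (bound) steps_spent else NA_real_,
                 energies = energies, rmsd_vs_native = rmsd_vec,
                 distances = distances, cfg = cfg),
            class = "sumd_result")
}

#' @export
print.sumd_result <- function(x, ...) {
  n_prod <- sum(x$steps$verdict == "productive")
  cat(sprintf("sumd_result: %s after %d SuMD-steps (%d productive)\n",
              if (x$bound) "bound" else "not bound",
              sum(x$steps$verdict != "supervision_off"), n_prod))
  if (x$bound)
    cat(sprintf("  supervision off after step %d; %g integration steps to bind\n",
                x$supervision_off_step, x$integration_steps_to_bind))
  invisible(x)
}

#' Unsupervised binding run (baseline for SuMD)
#'
#' Plain Langevin MD from the same start pose, stopped at the first saved
#' frame whose ligand-site distance falls below the threshold, or at the
#' same total integration-step budget a SuMD run may spend.
#'
#' @inheritParams run_sumd
#' @return list with `bound`, `integration_steps_to_bind` (NA when the
#'   budget is exhausted unbound).
#' @export
run_unsupervised_binding <- function(system, start, cfg = sumd_config()) {
  state <- dyn_state(.check_coords(system, start),
                     temperature_set = cfg$temperature)
  state <- randomize_velocities(state, system, cfg$temperature,
                                derive_seed(cfg$seed, 1))
  budget <- cfg$max_total_steps * cfg$step_window
  spent <- 0
  m <- ligand_masses(system)
  chunk_id <- 0
  while (spent < budget) {
    chunk_id <- chunk_id + 1
    out <- run_md(system, state, cfg$step_window, cfg$temperature,
                  derive_seed(cfg$seed, 700000 + chunk_id), cfg$save_every)
    d <- .frame_distances(out$trajectory, system)
    hit <- which(d < cfg$distance_threshold)
    if (length(hit)) {
      spent <- spent + (hit[1] - 1) * cfg$save_every
      return(list(bound = TRUE, integration_steps_to_bind = spent))
    }
    spent <- spent + cfg$step_window
    state <- out$state
  }
  list(bound = FALSE, integration_steps_to_bind = NA_real_)
}

#' Per-site electrostatic interaction heat-map matrix
#'
#' Per-frame electrostatic interaction energies on a per-receptor-site
#' basis, rows restricted to the `top_k` most contacted sites (ranked by
#' summed absolute electrostatic energy over the trajectory, ties broken
#' by site id). This is the matrix behind time-resolved per-residue
#' interaction heat maps (negative values: stabilizing).
#'
#' @param traj a `toy_trajectory` with at least one frame.
#' @param system the matching `toy_system`.
#' @param top_k number of rows to keep (<= number of receptor sites).
#' @return numeric matrix (`top_k` x frames, kcal/mol), rownames = site
#'   labels.
#' @export
per_residue_ele_heatmap <- function(traj, system, top_k = 15) {
  if (is.null(traj) || n_frames(traj) == 0) stop("empty trajectory")
  if (top_k > nrow(system$receptor))
    stop("top_k exceeds the number of receptor sites")
  nf <- n_frames(traj)
  mat <- matrix(0, nrow(system$receptor), nf,
                dimnames = list(system$receptor$label, NULL))
  for (i in seq_len(nf))
    mat[, i] <- interaction_energy(system, traj_frame(traj, i))$per_receptor_site_ele
  contact <- rowSums(abs(mat))
  ord <- order(-contact, system$receptor$id)
  mat[ord[seq_len(top_k)], , drop = FALSE]
}

#' Unbound start pose for binding runs
#'
#' The native pose rigidly translated along +z (the pocket opening) so its
#' center of mass sits `distance` Angstrom from the pocket center, outside
#' the nonbonded cutoff of every receptor site.
#'
#' @param system a `toy_system`.
#' @param distance target center-of-mass distance, Angstrom.
#' @return coordinate matrix.
#' @export
unbound_pose <- function(system, distance = 14) {
  com <- ligand_com(system$native_pose, ligand_masses(system))
  dxy2 <- sum((com[1:2] - system$pocket_center[1:2])^2)
  if (distance^2 <= dxy2) stop("requested distance too small")
  tz <- sqrt(distance^2 - dxy2) - (com[3] - system$pocket_center[3])
  sweep(system$native_pose, 2, c(0, 0, tz), "+")
}
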