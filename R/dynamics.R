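#' Create a dynamical state
#'
#' @param positions ligand coordinate matrix (n_beads x 3), Angstrom.
#' @param velocities matrix of the same shape (defaults to rest).
#' @param temperature_set thermostat set point, K.
#' @param step_index integration-step counter carried across windows.
#' @return object of class `dyn_state`.
#' @export
dyn_state <- function(positions, velocities = NULL, temperature_set = 300,
                      step_index = 0L) {
  positions <- as.matrix(positions)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  stopifnot(all(dim(positions) == dim(velocities)), all(is.finite(positions)))
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 temperature_set = temperature_set,
                 step_index = as.integer(step_index)),
            class = "dyn_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Replaces the state's velocities with a fresh Maxwell-Boltzmann draw at
#' temperature `T`: each Cartesian component of bead `i` is N(0, kB*T/m_i).
#' Positions are untouched. This is the thermostat "kick" used to restart a
#' rejected supervised window.
#'
#' @param state a `dyn_state`.
#' @param system the `toy_system` supplying bead masses.
#' @param T temperature, K (>= 0).
#' @param seed integer seed.
#' @return the updated `dyn_state`.
#' @export
randomize_velocities <- function(state, system, T, seed) {
  if (T < 0) stop("randomize_velocities: negative temperature")
  m <- ligand_masses(system)
  set.seed(derive_seed(seed, 303))
  sdv <- sqrt(.kB * T / m)
  state$velocities <- matrix(rnorm(length(m) * 3), length(m), 3) * sdv
  state$temperature_set <- T
  state
}

#' Propagate the ligand with BAOAB Langevin dynamics
#'
#' Integrates the mobile ligand in the fixed receptor field with the BAOAB
#' splitting of Langevin dynamics: friction `gamma` (per internal time
#' unit), switched Coulomb + Lennard-Jones receptor forces, stiff harmonic
#' restraints on all intra-ligand distances (keeping the ligand rigid-ish),
#' and reflecting walls at the box boundary. The receptor never moves.
#' Deterministic for a given seed.
#'
#' One internal time unit corresponds to 500 integration steps at the
#' default `dt = 0.002`; protocol windows below are expressed in
#' integration steps so desk-scale runs finish quickly.
#'
#' @param system a `toy_system`.
#' @param state a `dyn_state`.
#' @param n_steps number of integration steps (>= 1).
#' @param T thermostat temperature, K.
#' @param seed integer seed for the thermostat noise.
#' @param save_every save a frame every this many steps.
#' @param dt integration time step (internal units).
#' @param gamma Langevin friction (1 / internal time unit).
#' @return list with `trajectory` (a `toy_trajectory`: `frames` array of
#'   dim frames x beads x 3, `kinetic` energies per frame,
#'   `frame_interval`, `temperature_set`, `seed`) and `state`, the final
#'   `dyn_state`.
#' @export
run_md <- function(system, state, n_steps, T, seed, save_every = 50,
                   dt = 0.002, gamma = 1) {
  stopifnot(n_steps >= 1, save_every >= 1, T >= 0)
  out <- .cpp_run_md(.field_of(system), state$positions, state$velocities,
                     as.integer(n_steps), dt, gamma, T,
                     as.double(derive_seed(seed, 404)),
                     as.integer(save_every))
  traj <- structure(list(frames = out$frames, kinetic = out$kinetic,
                         frame_interval = as.integer(save_every),
                         temperature_set = T, seed = as.integer(seed)),
                    class = "toy_trajectory")
  new_state <- dyn_state(out$pos, out$vel, T,
                         state$step_index + as.integer(n_steps))
  list(trajectory = traj, state = new_state)
}

#' Number of frames in a trajectory
#' @param traj a `toy_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as a coordinate matrix
#' @param traj a `toy_trajectory`.
#' @param i frame index (1-based).
#' @return n_beads x 3 matrix, Angstrom.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  matrix(traj$frames[i, , ], dim(traj$frames)[2], 3)
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("toy_trajectory: %d frames x %d beads, frame interval %d steps, T = %g K\n",
              n_frames(x), dim(x$frames)[2], x$frame_interval,
              x$temperature_set))
  invisible(x)
}

# concatenate trajectories, dropping the duplicated seam frame of each
# continuation window
.concat_trajectories <- function(trajs, drop_first_after_1 = TRUE) {
  keep <- lapply(seq_along(trajs), function(k) {
    f <- trajs[[k]]$frames
    if (k > 1 && drop_first_after_1) {
      f <- f[-1, , , drop = FALSE]
      kin <- trajs[[k]]$kinetic[-1]
    } else kin <- trajs[[k]]$kinetic
    list(f = f, kin = kin)
  })
  frames <- do.call(abind3, lapply(keep, `[[`, "f"))
  structure(list(frames = frames,
                 kinetic = unlist(lapply(keep, `[[`, "kin")),
                 frame_interval = trajs[[1]]$frame_interval,
                 temperature_set = trajs[[length(trajs)]]$temperature_set,
                 seed = trajs[[1]]$seed),
            class = "toy_trajectory")
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 0L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 1
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at:(at + k - 1), , ] <- a
    at <- at + k
  }
  out
}

#' Per-frame interaction energies along a trajectory
#'
#' @param traj a `toy_trajectory`.
#' @param system the matching `toy_system`.
#' @return data frame with columns `frame`, `ele`, `vdw`, `total`
#'   (kcal/mol) and `kinetic`.
#' @export
trajectory_energies <- function(traj, system) {
  nf <- n_frames(traj)
  ele <- vdw <- numeric(nf)
  for (i in seq_len(nf)) {
    eb <- interaction_energy(system, traj_frame(traj, i))
    ele[i] <- eb$ele
    vdw[i] <- eb$vdw
  }
  data.frame(frame = seq_len(nf), ele = ele, vdw = vdw, total = ele + vdw,
             kinetic = traj$kinetic)
}
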