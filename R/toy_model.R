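#' Default configuration for the synthetic pocket generator
#'
#' The defaults define the study conditions used throughout: a hemispherical
#' pocket of radius 6 A opening along +z, mainly lined by hydrophobic sites
#' (mimicking an ATP-site cleft lined by Ile/Ala/Leu side chains), a hinge
#' donor/acceptor pair 3.0 A apart at the pocket floor (the bidentate
#' backbone hydrogen-bond anchor), two fixed positively polarized
#' "structural water" sites on the pocket wall, a buried salt-bridge
#' cation/anion pair, and two aromatic sites. Partial charges of 0.3 e on
#' the hinge pair and 0.35 e on the water dipole ends give hydrogen-bond
#' wells of a few kcal/mol each, comparable to their physical counterparts.
#'
#' @param pocket_radius pocket shell radius, Angstrom.
#' @param n_hydrophobic,n_aromatic number of hydrophobic / aromatic wall sites.
#' @param hinge,waters logical; include the hinge anchor pair / water sites.
#' @param salt_bridge logical; include the buried cation/anion pair.
#' @param jitter_sd positional jitter applied to wall sites, Angstrom.
#' @param hbond_charge partial charge on hinge sites and ligand polar beads, e.
#' @param water_charge partial-charge magnitude of each water dipole end, e.
#' @param cyano_charge partial-charge magnitude of the nitrile bead, e.
#' @param ion_charge formal-charge magnitude of the salt-bridge pair, e.
#' @param hydrophobic_epsilon,aromatic_epsilon,polar_epsilon LJ well depths,
#'   kcal/mol.
#' @param cyano_bead logical; append the extra hydrogen-bond-acceptor bead
#'   (the nitrile analogue) to the ligand.
#' @param box_half_width reflecting-wall half width, Angstrom.
#' @param k_bond stiffness of the intra-ligand distance restraints,
#'   kcal/(mol A^2).
#' @param ... overrides for any of the above.
#' @return named list of generator settings.
#' @export
default_system_config <- function(pocket_radius = 6, n_hydrophobic = 8,
                                  n_aromatic = 2, hinge = TRUE, waters = TRUE,
                                  salt_bridge = TRUE, jitter_sd = 0.15,
                                  hbond_charge = 0.3, water_charge = 0.35,
                                  cyano_charge = 0.45, ion_charge = 0.2,
                                  hydrophobic_epsilon = 0.3,
                                  aromatic_epsilon = 0.3,
                                  polar_epsilon = 0.15,
                                  cyano_bead = FALSE,
                                  box_half_width = 16, k_bond = 300, ...) {
  cfg <- c(as.list(environment()), list(...))
  cfg[["..."]] <- NULL
  cfg
}

.site_types <- c("hydrophobic", "hbond_donor", "hbond_acceptor",
                 "cation", "anion", "aromatic")

.make_site <- function(id, label, xyz, type, charge = 0, epsilon = 0.2,
                       sigma = 3.5, mass = NA_real_) {
  stopifnot(type %in% .site_types, sigma > 0, epsilon >= 0)
  data.frame(id = id, label = label, x = xyz[1], y = xyz[2], z = xyz[3],
             type = type, charge = charge, epsilon = epsilon, sigma = sigma,
             mass = mass, stringsAsFactors = FALSE)
}

# rigid 6-bead ligand template in local coordinates (COM near origin):
# 3 hydrophobic beads, 1 aromatic, 1 H-bond donor, 1 H-bond acceptor.
# The optional 7th bead is the nitrile analogue: an extra acceptor
# pointing toward the structural-water sites.
.ligand_template <- function(cfg) {
  q <- cfg$hbond_charge
  eps_p <- cfg$polar_epsilon
  rbind(
    .make_site(1L, "LIG_H1", c(0.0, -1.2, 0.4), "hydrophobic", 0,
               cfg$hydrophobic_epsilon, 4.2, 12),
    .make_site(2L, "LIG_H2", c(1.3, -0.6, 1.2), "hydrophobic", 0,
               cfg$hydrophobic_epsilon, 4.2, 12),
    .make_site(3L, "LIG_H3", c(-1.3, -0.6, 1.2), "hydrophobic", 0,
               cfg$hydrophobic_epsilon, 4.2, 12),
    .make_site(4L, "LIG_AR", c(0.0, 0.9, 0.8), "aromatic", 0,
               cfg$aromatic_epsilon, 4.2, 12),
    .make_site(5L, "LIG_DON", c(-1.5, 0.0, -1.7), "hbond_donor", +q,
               eps_p, 2.6, 14),
    .make_site(6L, "LIG_ACC", c(1.5, 0.0, -1.7), "hbond_acceptor", -q,
               eps_p, 2.6, 16),
    if (isTRUE(cfg$cyano_bead))
      .make_site(7L, "LIG_CN", c(0.0, 1.9, 1.67), "hbond_acceptor",
                 -cfg$cyano_charge, 0.05, 2.2, 14))
}

.radius_of_gyration <- function(xyz) {
  com <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, com)^2)))
}

#' Generate a coarse-grained pocket-plus-ligand system
#'
#' Builds a rigid receptor pocket and a mobile rigid-ish ligand whose
#' relaxed native pose is a local minimum of the interaction energy (the
#' generated template is relaxed by FIRE minimization under the same force
#' field the dynamics use). The pocket is a hemispherical shell opening
#' into bulk along +z, so an incoming ligand sees a funnel. Generation is a
#' pure function of `(cfg, seed)`.
#'
#' @param cfg configuration list from [default_system_config()].
#' @param seed integer seed controlling wall-site jitter.
#' @param validate run the post-generation energy checks (native pose lower
#'   than outward-shifted poses, contacts in range); disable only for
#'   debugging degenerate configurations.
#' @param start_pose optional ligand start arrangement overriding the
#'   built-in template (used when grafting a substituent onto an already
#'   relaxed scaffold).
#' @param jitter_stream internal: fix the jitter sub-stream instead of
#'   searching (used to rebuild a matched receptor).
#' @return an object of class `toy_system`: list with `receptor` and
#'   `ligand` site tables, `native_pose` (matrix, A), `pocket_center`,
#'   `anchor_ids` (hinge donor/acceptor site ids), `water_ids`,
#'   `box_half_width`, intra-ligand restraint table and the generating
#'   `cfg`/`seed`.
#' @export
#' @examples
#' sys <- make_pocket_system(default_system_config(), seed = 1)
#' interaction_energy(sys, sys$native_pose)
make_pocket_system <- function(cfg = default_system_config(), seed = 1,
                               validate = TRUE, start_pose = NULL,
                               jitter_stream = NULL) {
  R <- cfg$pocket_radius
  lig <- .ligand_template(cfg)
  lig_xyz <- .site_xyz(lig)
  rg <- .radius_of_gyration(lig_xyz)
  if (R < rg)
    stop(sprintf("pocket radius %.2f A cannot host the ligand (radius of gyration %.2f A)",
                 R, rg))
  # deterministic rejection sampling over the jitter stream: the generator
  # guarantees that the relaxed native pose keeps the bidentate hinge
  # anchor and stays centered, so downstream reference-based analyses are
  # always well-posed
  streams <- if (is.null(jitter_stream)) 101L + 7L * (0:19) else jitter_stream
  system <- NULL
  for (stream in streams) {
    cand <- .build_system(cfg, seed, stream, lig, lig_xyz, R, start_pose)
    if (.native_pose_ok(cand)) { system <- cand; break }
  }
  if (is.null(system))
    stop("could not generate a system with an intact hinge-anchored native pose")
  if (validate) .validate_generated(system)
  system
}

.build_system <- function(cfg, seed, jitter_stream, lig, lig_xyz, R,
                          start_pose = NULL) {
  set.seed(derive_seed(seed, jitter_stream))
  jit <- function(n, sd) matrix(rnorm(n * 3, 0, sd), n, 3)
  sites <- list()
  nid <- 0L
  add <- function(label, xyz, type, charge = 0, eps = 0.2, sig = 3.5) {
    nid <<- nid + 1L
    sites[[nid]] <<- .make_site(nid, label, xyz, type, charge, eps, sig)
  }
  zb <- 0.93 * R  # hinge depth: pair 3.0 A apart at the pocket floor
  if (isTRUE(cfg$hinge)) {
    hj <- jit(2, 0.05)
    add("HINGE_DON", c(1.5, 0, -zb) + hj[1, ], "hbond_donor",
        +cfg$hbond_charge, cfg$polar_epsilon, 2.6)
    add("HINGE_ACC", c(-1.5, 0, -zb) + hj[2, ], "hbond_acceptor",
        -cfg$hbond_charge, cfg$polar_epsilon, 2.6)
  }
  anchor_ids <- if (isTRUE(cfg$hinge)) c(1L, 2L) else integer(0)
  water_ids <- integer(0)
  if (isTRUE(cfg$waters)) {
    # each structural water is a fixed dipole: a donating H-end site (+q,
    # listed in water_ids) and an O-end counter site 1 A behind it in the
    # pocket wall, so the far field seen by the hinge-anchored ligand decays
    # dipolar while a bead in contact still sees a full hydrogen-bond well
    wj <- jit(2, 0.05)
    s <- R / 6
    wfront <- list(c(0.0, 4.4, -0.8), c(-1.9, 4.0, -1.6))
    for (k in 1:2) {
      f <- wfront[[k]] * s + wj[k, ]
      u <- f / sqrt(sum(f^2))
      add(c("W295", "W296")[k], f, "hbond_donor", +cfg$water_charge,
          0.12, 2.8)
      water_ids <- c(water_ids, nid)
      add(paste0(c("W295", "W296")[k], "_O"), f + u, "anion",
          -cfg$water_charge, 0.12, 2.8)
    }
  }
  # hydrophobic lining on a deterministic hemispherical spiral + jitter
  hyd_labels <- c("ILE15", "ILE23", "ALA36", "LEU135", "ILE147",
                  paste0("HPH", seq_len(max(0, cfg$n_hydrophobic - 5)) + 5L))
  if (cfg$n_hydrophobic > 0) {
    # mid-depth band only: the hinge floor and the water region stay clear
    hjit <- jit(cfg$n_hydrophobic, cfg$jitter_sd)
    for (i in seq_len(cfg$n_hydrophobic)) {
      zf <- -0.15 - (i - 0.5) / cfg$n_hydrophobic * 0.55
      phi <- i * 2.399963
      rho <- sqrt(1 - zf^2)
      add(hyd_labels[i],
          (R - 0.3) * c(rho * cos(phi), rho * sin(phi), zf) + hjit[i, ],
          "hydrophobic", 0, cfg$hydrophobic_epsilon, 3.8)
    }
  }
  if (cfg$n_aromatic > 0) {
    ajit <- jit(cfg$n_aromatic, cfg$jitter_sd)
    aro_pos <- list(c(0, 5.1, -1.2), c(0, -5.5, -1.3),
                    c(5.2, 0, -1.9), c(-5.2, 0, -1.9))
    for (i in seq_len(min(cfg$n_aromatic, 4)))
      add(c("TYR56", "ARO2", "ARO3", "ARO4")[i],
          aro_pos[[i]] * R / 6 + ajit[i, ], "aromatic", 0,
          cfg$aromatic_epsilon, 3.8)
  }
  if (isTRUE(cfg$salt_bridge)) {
    sjit <- jit(2, 0.05)
    s <- R / 6
    # tight buried ion pair; the anion end faces the ligand so the pair
    # repels, rather than captures, the ligand's acceptor bead
    add("LYS38", c(0.6, -4.6, -3.1) * s + sjit[1, ], "cation",
        +cfg$ion_charge, cfg$polar_epsilon, 3.2)
    add("GLU52", c(2.9, -3.3, -3.1) * s + sjit[2, ], "anion",
        -cfg$ion_charge, cfg$polar_epsilon, 3.2)
  }
  receptor <- do.call(rbind, sites)
  if (anyDuplicated(receptor$label)) stop("duplicate receptor site labels")

  # place the ligand so its polar beads sit one H-bond above the hinge pair
  tz <- -(zb - 2.71) + 1.7
  pose0 <- sweep(lig_xyz, 2, c(0, 0, -tz), "-")
  if (!is.null(start_pose)) {
    stopifnot(all(dim(start_pose) == dim(pose0)))
    pose0 <- unname(as.matrix(start_pose))
  }
  bonds <- t(utils::combn(nrow(lig), 2))
  bond_r0 <- sqrt(rowSums((lig_xyz[bonds[, 1], , drop = FALSE] -
                           lig_xyz[bonds[, 2], , drop = FALSE])^2))
  system <- structure(list(
    receptor = receptor, ligand = lig, native_pose = pose0,
    pocket_center = c(0, 0, 0), anchor_ids = anchor_ids,
    water_ids = water_ids, box_half_width = cfg$box_half_width,
    bonds = bonds, bond_r0 = bond_r0, k_bond = cfg$k_bond,
    cfg = cfg, seed = as.integer(seed)), class = "toy_system")
  system$template_pose <- pose0
  system$jitter_stream <- as.integer(jitter_stream)
  if (!is.null(start_pose) && nrow(pose0) > 6) {
    # grafted substituent: settle the new bead against the frozen scaffold
    # first so its restraint strain does not repack the whole ligand
    mask <- c(rep(FALSE, 6), rep(TRUE, nrow(pose0) - 6))
    pose0 <- .cpp_minimize(.field_of(system), pose0, 5000L, 1e-4, mask)$pos
  }
  rel <- .cpp_minimize(.field_of(system), pose0, 20000L, 1e-4)
  system$native_pose <- rel$pos
  dimnames(system$native_pose) <- list(lig$label, c("x", "y", "z"))
  # the binding-site center targeted by the protocols is the centroid of
  # the natively bound ligand, as in docking-derived site definitions
  system$pocket_center <- unname(ligand_com(system$native_pose, lig$mass))
  system
}

# relaxed pose acceptable: bidentate hinge intact (when present), COM
# within 2 A of the site center
.native_pose_ok <- function(system) {
  com_ok <- sqrt(sum((ligand_com(system$native_pose, system$ligand$mass) -
                        system$pocket_center)^2)) <= 2
  if (length(system$anchor_ids) != 2) return(com_ok)
  rec <- system$receptor
  hd <- unlist(rec[rec$type == "hbond_donor" &
                     rec$id %in% system$anchor_ids, c("x", "y", "z")])
  ha <- unlist(rec[rec$type == "hbond_acceptor" &
                     rec$id %in% system$anchor_ids, c("x", "y", "z")])
  don <- system$native_pose[system$ligand$type == "hbond_donor" &
                              system$ligand$label != "LIG_CN", , drop = FALSE]
  acc <- system$native_pose[system$ligand$label == "LIG_ACC", , drop = FALSE]
  cut <- .ifp_cutoffs[["hbond"]] - 0.1  # margin below the scoring cutoff
  com_ok &&
    min(sqrt(rowSums(sweep(don, 2, ha)^2))) <= cut &&
    min(sqrt(rowSums(sweep(acc, 2, hd)^2))) <= cut
}

.validate_generated <- function(system) {
  com <- ligand_com(system$native_pose, ligand_masses(system))
  if (sqrt(sum((com - system$pocket_center)^2)) > 2)
    stop("generated native pose drifted > 2 A from the pocket center")
  e0 <- native_energy(system)
  dirs <- rbind(c(0, 0, 1), c(0.5, 0, 1), c(-0.5, 0, 1), c(0, 0.5, 1),
                c(0, -0.5, 1))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (d in c(5, 8)) for (k in seq_len(nrow(dirs))) {
    shifted <- sweep(system$native_pose, 2, dirs[k, ] * d, "+")
    eb <- interaction_energy(system, shifted)
    if (eb$ele + eb$vdw <= e0)
      stop("native pose is not lower in energy than an outward-shifted pose")
  }
  if (isTRUE(system$cfg$cyano_bead) && length(system$water_ids) > 0) {
    cn <- system$native_pose[system$ligand$label == "LIG_CN", ]
    w <- .site_xyz(system$receptor[system$water_ids, ])
    if (min(sqrt(rowSums(sweep(w, 2, cn)^2))) > 3.5)
      stop("nitrile bead is not within hydrogen-bond range of a water site")
  }
  invisible(system)
}

#' Total nonbonded interaction energy of the native pose (ele + vdw)
#' @param system a `toy_system`.
#' @return kcal/mol.
#' @export
native_energy <- function(system) {
  eb <- interaction_energy(system, system$native_pose)
  eb$ele + eb$vdw
}

#' Ligand bead masses
#' @param system a `toy_system`.
#' @return numeric vector, amu.
#' @export
ligand_masses <- function(system) system$ligand$mass

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %d receptor sites, %d ligand beads (seed %d)\n",
              nrow(x$receptor), nrow(x$ligand), x$seed))
  cat(sprintf("  anchors: %s | waters: %s | box half-width %.1f A\n",
              if (length(x$anchor_ids)) paste(x$receptor$label[x$anchor_ids],
                                              collapse = "+") else "none",
              if (length(x$water_ids)) paste(x$receptor$label[x$water_ids],
                                             collapse = "+") else "none",
              x$box_half_width))
  cat(sprintf("  native-pose energy %.3f kcal/mol\n", native_energy(x)))
  invisible(x)
}

#' Generate a matched ligand pair differing by one polar bead
#'
#' Returns two systems built on the identical receptor: the base 6-bead
#' ligand and a variant carrying one extra hydrogen-bond-acceptor bead (the
#' nitrile analogue) positioned to contact a structural-water site in the
#' native pose. The pair reproduces, in coarse grain, an unsubstituted
#' inhibitor versus its 5-cyano analogue whose nitrile hydrogen-bonds to
#' conserved waters in the pocket.
#'
#' @inheritParams make_pocket_system
#' @return list with elements `base` and `variant`, both `toy_system`.
#' @export
make_ligand_pair <- function(cfg = default_system_config(), seed = 1) {
  cfg_base <- cfg; cfg_base$cyano_bead <- FALSE
  cfg_var <- cfg; cfg_var$cyano_bead <- TRUE
  base <- make_pocket_system(cfg_base, seed)
  # graft the nitrile bead onto the relaxed base scaffold (local frame
  # transferred by rigid superposition), so the pair is congeneric: the
  # two native poses differ only by the substituent and its relaxation
  tmpl_var <- .site_xyz(.ligand_template(cfg_var))
  fit <- .rigid_fit(tmpl_var[1:6, ], base$native_pose)
  start <- sweep(tmpl_var %*% fit$R, 2, fit$t, "+")
  start[1:6, ] <- base$native_pose
  variant <- make_pocket_system(cfg_var, seed, start_pose = start,
                                jitter_stream = base$jitter_stream)
  list(base = base, variant = variant)
}

# least-squares rigid map a -> b: returns rotation R (right-multiplied)
# and translation t
.rigid_fit <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  s <- svd(crossprod(sweep(a, 2, ca), sweep(b, 2, cb)))
  d <- sign(det(s$u %*% t(s$v)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = Rm, t = cb - as.vector(ca %*% Rm))
}

#' Generate a set of rigid-body perturbed poses
#'
#' Pose 1 is always the unperturbed native pose; the remaining `n - 1`
#' poses are the native pose rotated about its center of mass (random axis,
#' angle drawn from N(0, rotation_sd)) and translated by an isotropic
#' Gaussian displacement (per-component sd `translation_sd`). A stand-in
#' for a docking-pose ensemble.
#'
#' @param system a `toy_system`.
#' @param n number of poses (>= 1).
#' @param translation_sd per-component translation sd, Angstrom.
#' @param rotation_sd rotation-angle sd, degrees.
#' @param seed integer seed.
#' @return list of `n` coordinate matrices.
#' @export
generate_pose_set <- function(system, n, translation_sd = 1,
                              rotation_sd = 10, seed = 1) {
  stopifnot(n >= 1, translation_sd >= 0, rotation_sd >= 0)
  set.seed(derive_seed(seed, 202))
  ref <- system$native_pose
  com <- ligand_com(ref, ligand_masses(system))
  poses <- vector("list", n)
  poses[[1]] <- ref
  for (i in seq_len(n)[-1]) {
    ax <- rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    ang <- rnorm(1, 0, rotation_sd) * pi / 180
    Rm <- .rotation_matrix(ax, ang)
    shift <- rnorm(3, 0, translation_sd)
    poses[[i]] <- sweep(sweep(ref, 2, com) %*% t(Rm), 2, com + shift, "+")
  }
  poses
}

# Rodrigues rotation about unit axis u by angle theta
.rotation_matrix <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# force-field view of a system consumed by the C++ core
.field_of <- function(system) {
  rec <- system$receptor
  lig <- system$ligand
  list(rec_xyz = .site_xyz(rec), rec_q = rec$charge, rec_eps = rec$epsilon,
       rec_sig = rec$sigma, lig_q = lig$charge, lig_eps = lig$epsilon,
       lig_sig = lig$sigma, lig_m = lig$mass,
       bonds = matrix(as.integer(system$bonds - 1L), ncol = 2),
       bond_r0 = system$bond_r0, k_bond = system$k_bond,
       box_half = system$box_half_width)
}
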