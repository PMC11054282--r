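#' Root-mean-square deviation between two coordinate sets
#'
#' Plain RMSD over matched points, optionally after optimal rigid-body
#' least-squares superposition (Kabsch algorithm, including the proper
#' reflection correction). Ligand RMSD along a trajectory is conventionally
#' computed without superposition here, because the receptor frame is
#' fixed.
#'
#' @param coords_a,coords_b matrices of equal shape (n x 3), Angstrom.
#' @param superpose logical; superpose `coords_a` onto `coords_b` first.
#' @return RMSD, Angstrom.
#' @export
#' @examples
#' a <- matrix(rnorm(18), 6, 3)
#' rmsd(a, a + 1)                    # pure translation: sqrt(3)
#' rmsd(a, a + 1, superpose = TRUE)  # ~0
rmsd <- function(coords_a, coords_b, superpose = FALSE) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3 || nrow(a) < 1)
    stop("rmsd: coordinate sets must be equal-shape n x 3 matrices")
  if (superpose) a <- .superpose(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}

# Kabsch superposition of a onto b
.superpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$u %*% t(s$v)))
  Rm <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(a0 %*% Rm, 2, cb, "+")
}

# ---- system serialization: PDB-subset + JSON sidecar ----
#
# The PDB-subset file is for human inspection (HETATM records, %8.3f
# coordinates; occupancy column carries the partial charge, segment id the
# site type, chain R = receptor / L = ligand native pose). Full-precision
# numeric fields live in the JSON sidecar, which is authoritative on read,
# so write/read round-trips are exact.

.type_tag <- c(hydrophobic = "HYD", hbond_donor = "DON",
               hbond_acceptor = "ACC", cation = "CAT", anion = "ANI",
               aromatic = "ARO")

#' Write a toy system to a PDB-subset file with a JSON sidecar
#'
#' @param system a `toy_system`.
#' @param pdb_path output path; the sidecar is written next to it with a
#'   `.json` extension unless `json_path` is given.
#' @param json_path optional sidecar path.
#' @return invisibly, the two paths.
#' @export
write_system <- function(system, pdb_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.pdb$", ".json", pdb_path)
  if (identical(json_path, pdb_path)) json_path <- paste0(pdb_path, ".json")
  hdr <- c(
    "REMARK   1 SYNTHETIC coarse-grained pocket model; not legal PDB chemistry",
    "REMARK   2 columns: occupancy = partial charge (e); segid = site type",
    "REMARK   3 chain R = fixed receptor sites, chain L = ligand native pose",
    sprintf("REMARK   4 box_half_width %.6f A", system$box_half_width))
  fmt <- function(df, xyz, chain)
    sprintf("HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
            seq_len(nrow(df)), substr(df$label, 1, 4), "TOY", chain, df$id,
            xyz[, 1], xyz[, 2], xyz[, 3], df$charge, 0,
            .type_tag[df$type])
  lines <- c(hdr, fmt(system$receptor, .site_xyz(system$receptor), "R"),
             fmt(system$ligand, system$native_pose, "L"), "END")
  writeLines(lines, pdb_path)
  side <- list(
    receptor = system$receptor, ligand = system$ligand,
    native_pose = unname(system$native_pose),
    pocket_center = system$pocket_center, anchor_ids = system$anchor_ids,
    water_ids = system$water_ids, box_half_width = system$box_half_width,
    bonds = system$bonds, bond_r0 = system$bond_r0,
    k_bond = system$k_bond, cfg = system$cfg, seed = system$seed)
  jsonlite::write_json(side, json_path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(c(pdb = pdb_path, json = json_path))
}

#' Read a toy system written by [write_system()]
#'
#' The JSON sidecar is authoritative for all numeric fields; the PDB file
#' is validated structurally (record counts per chain) against it.
#'
#' @param pdb_path path of the PDB-subset file (sidecar looked up next to
#'   it) or of the sidecar itself.
#' @return a `toy_system`.
#' @export
read_system <- function(pdb_path) {
  json_path <- if (grepl("\\.json$", pdb_path)) pdb_path else
    sub("\\.pdb$", ".json", pdb_path)
  if (!file.exists(json_path)) stop("missing sidecar: ", json_path)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (!grepl("\\.json$", pdb_path) && file.exists(pdb_path)) {
    lines <- readLines(pdb_path)
    het <- grep("^HETATM", lines, value = TRUE)
    n_r <- sum(substr(het, 22, 22) == "R")
    n_l <- sum(substr(het, 22, 22) == "L")
    if (n_r != nrow(side$receptor) || n_l != nrow(side$ligand))
      stop(sprintf("PDB record counts (R %d, L %d) disagree with sidecar (R %d, L %d)",
                   n_r, n_l, nrow(side$receptor), nrow(side$ligand)))
  }
  side$receptor$mass <- as.numeric(side$receptor$mass)
  np <- as.matrix(side$native_pose)
  dimnames(np) <- list(side$ligand$label, c("x", "y", "z"))
  structure(list(receptor = side$receptor, ligand = side$ligand,
                 native_pose = np, pocket_center = side$pocket_center,
                 anchor_ids = as.integer(side$anchor_ids),
                 water_ids = as.integer(side$water_ids),
                 box_half_width = side$box_half_width,
                 bonds = matrix(as.integer(side$bonds), ncol = 2),
                 bond_r0 = side$bond_r0, k_bond = side$k_bond,
                 cfg = side$cfg, seed = as.integer(side$seed)),
            class = "toy_system")
}

# ---- multi-frame XYZ ----

#' Write frames to a multi-frame XYZ file
#'
#' Standard XYZ dialect: atom count line, comment line, then one
#' `label x y z` line per bead with 6-decimal fixed-point coordinates.
#'
#' @param frames a `toy_trajectory`, a list of coordinate matrices, or a
#'   single matrix.
#' @param path output path.
#' @param labels bead labels (recycled across frames).
#' @param comment comment-line prefix; the frame index is appended.
#' @return invisibly, the path.
#' @export
write_xyz <- function(frames, path, labels = NULL, comment = "frame") {
  if (inherits(frames, "toy_trajectory"))
    frames <- lapply(seq_len(n_frames(frames)), traj_frame, traj = frames)
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  if (is.null(labels)) labels <- sprintf("B%d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    writeLines(c(sprintf("%d", nrow(f)), sprintf("%s %d", comment, i),
                 sprintf("%-6s %12.6f %12.6f %12.6f", labels,
                         f[, 1], f[, 2], f[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path input path.
#' @return list of coordinate matrices (one per frame), with bead labels
#'   as rownames. Malformed frames raise errors naming the offending frame
#'   and line.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1; frame_id <- 0
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop(sprintf("XYZ parse error at line %d (frame %d): expected atom count, got '%s'",
                   i, frame_id + 1, lines[i]))
    n <- as.integer(lines[i])
    frame_id <- frame_id + 1
    if (i + 1 + n > length(lines))
      stop(sprintf("XYZ parse error: frame %d truncated (needs %d atom lines after line %d)",
                   frame_id, n, i + 1))
    body <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4)
    if (length(bad))
      stop(sprintf("XYZ parse error at line %d (frame %d): malformed atom record",
                   i + 1 + bad[1], frame_id))
    xyz <- suppressWarnings(
      t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))))
    if (any(!is.finite(xyz)))
      stop(sprintf("XYZ parse error in frame %d: non-numeric coordinate", frame_id))
    rownames(xyz) <- vapply(toks, `[[`, "", 1)
    colnames(xyz) <- c("x", "y", "z")
    frames[[frame_id]] <- xyz
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop("XYZ file contains no frames")
  nn <- vapply(frames, nrow, 0L)
  if (length(unique(nn)) > 1)
    stop(sprintf("XYZ frames have inconsistent atom counts (frame %d has %d, frame 1 has %d)",
                 which(nn != nn[1])[1], nn[which(nn != nn[1])[1]], nn[1]))
  frames
}

# ---- tabular outputs ----

#' Write / read a titration profile as CSV
#' @param profile a `titration_profile` (or compatible data frame).
#' @param path file path.
#' @return `read_profile_csv` returns a `titration_profile`;
#'   `write_profile_csv` returns the path invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  df$ms_coefficient <- attr(profile, "ms_coefficient")
  df$unbinding_T <- attr(profile, "unbinding_T")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path)
  structure(df[, c("temperature", "mean_ifp_cs")],
            class = c("titration_profile", "data.frame"),
            ms_coefficient = df$ms_coefficient[1],
            unbinding_T = df$unbinding_T[1])
}

#' Write a per-site heat-map matrix as CSV (sites x frames)
#' @param mat matrix from [per_residue_ele_heatmap()].
#' @param path file path.
#' @export
write_heatmap_csv <- function(mat, path) {
  df <- data.frame(site = rownames(mat), mat, check.names = FALSE)
  colnames(df) <- c("site", sprintf("frame_%d", seq_len(ncol(mat))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a nested run configuration (YAML or JSON)
#'
#' The file must carry an explicit integer `seed` field; every stochastic
#' stage of a protocol run derives its own seed from it (see
#' [derive_seed()]).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_run.yaml",
#'                                    package = "toykd"))
#' cfg$seed
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path))
           jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: ", path)
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("run configuration must carry a numeric 'seed' field")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
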