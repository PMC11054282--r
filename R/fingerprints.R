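.ifp_channels <- c("hydrophobic", "hbond_don", "hbond_acc", "ionic",
                   "aromatic")
.ifp_cutoffs <- c(hydrophobic = 4.5, hbond = 3.5, ionic = 4.0,
                  aromatic = 4.5)

#' Protein-ligand interaction fingerprint of one pose
#'
#' Binary vector indexed by (receptor site, channel) with channels
#' hydrophobic, hbond_don (receptor donates to a ligand acceptor),
#' hbond_acc (receptor accepts from a ligand donor), ionic (opposite formal
#' charges) and aromatic. A bit is set when a ligand bead of the
#' complementary type lies within the channel cutoff of the site
#' (hydrophobic and aromatic 4.5 A, hydrogen bonds 3.5 A, ionic 4.0 A;
#' distance-only criteria, the toy beads carry no angular geometry).
#'
#' @param system a `toy_system`.
#' @param ligand_coords coordinate matrix (n_beads x 3), Angstrom.
#' @param frame_id optional integer tag.
#' @return object of class `interaction_fingerprint`: named 0/1 integer
#'   vector of length `n_sites * 5`.
#' @export
compute_ifp <- function(system, ligand_coords, frame_id = NA_integer_) {
  ligand_coords <- .check_coords(system, ligand_coords)
  rec <- system$receptor
  lig <- system$ligand
  dmat <- .dist_matrix(.site_xyz(rec), ligand_coords)
  pair_bit <- function(rec_type, lig_type, cutoff)
    as.integer(rowSums((dmat <= cutoff) *
                         outer(rec$type %in% rec_type,
                               lig$type %in% lig_type)) > 0)
  bits <- cbind(
    hydrophobic = pair_bit("hydrophobic", "hydrophobic",
                           .ifp_cutoffs["hydrophobic"]),
    hbond_don = pair_bit("hbond_donor", "hbond_acceptor",
                         .ifp_cutoffs["hbond"]),
    hbond_acc = pair_bit("hbond_acceptor", "hbond_donor",
                         .ifp_cutoffs["hbond"]),
    ionic = as.integer(rowSums((dmat <= .ifp_cutoffs["ionic"]) *
      (outer(rec$type == "cation", lig$type == "anion") |
       outer(rec$type == "anion", lig$type == "cation"))) > 0),
    aromatic = pair_bit("aromatic", "aromatic", .ifp_cutoffs["aromatic"]))
  v <- as.integer(bits)
  names(v) <- as.vector(outer(rec$label, .ifp_channels, paste, sep = ":"))
  structure(v, class = "interaction_fingerprint", frame_id = frame_id)
}

#' Interaction-fingerprint similarity score (IFP_CS)
#'
#' Negated cosine similarity between two binary interaction fingerprints:
#' -1 means the frame reproduces the reference interaction pattern exactly,
#' 0 means the pattern is fully lost. A frame with an all-zero fingerprint
#' scores 0 by convention; an all-zero reference is an error.
#'
#' @param fp fingerprint of the frame under scrutiny.
#' @param ref reference fingerprint (nonzero).
#' @return score in `[-1, 0]`.
#' @export
ifp_cs <- function(fp, ref) {
  if (length(fp) == 0 || length(ref) == 0) stop("ifp_cs: zero-length fingerprint")
  if (length(fp) != length(ref)) stop("ifp_cs: fingerprint lengths differ")
  nref <- sum(ref != 0)
  if (nref == 0) stop("ifp_cs: reference fingerprint is all-zero")
  nfp <- sum(fp != 0)
  if (nfp == 0) return(0)
  -sum(fp != 0 & ref != 0) / sqrt(nfp * nref)
}

#' Build a pharmacophore model from a reference pose
#'
#' Places a donor and an acceptor feature on the ligand beads engaged in
#' the bidentate hinge hydrogen bond, and one aromatic feature on each
#' aromatic bead, all with the same feature-sphere radius (default 2.0 A).
#' A reference pose that does not satisfy both hinge contacts (ligand donor
#' within hydrogen-bond range of the hinge acceptor site and vice versa) is
#' rejected.
#'
#' @param system a `toy_system` with a hinge anchor.
#' @param reference_pose coordinate matrix, Angstrom.
#' @param radius feature-sphere radius, Angstrom (> 0).
#' @return object of class `pharmacophore_model`: data frame of features
#'   (`x`, `y`, `z`, `type`, `radius`) with attribute `required_all = TRUE`.
#' @export
pharmacophore_from_reference <- function(system, reference_pose,
                                         radius = 2.0) {
  stopifnot(radius > 0)
  reference_pose <- .check_coords(system, reference_pose)
  if (length(system$anchor_ids) != 2)
    stop("system has no hinge anchor pair")
  rec <- system$receptor
  lig <- system$ligand
  hinge_don <- .site_xyz(rec[rec$type == "hbond_donor" &
                               rec$id %in% system$anchor_ids, ])
  hinge_acc <- .site_xyz(rec[rec$type == "hbond_acceptor" &
                               rec$id %in% system$anchor_ids, ])
  cut <- .ifp_cutoffs["hbond"]
  don_idx <- which(lig$type == "hbond_donor")
  acc_idx <- which(lig$type == "hbond_acceptor")
  d_don <- sqrt(colSums((t(reference_pose[don_idx, , drop = FALSE]) -
                           as.vector(hinge_acc))^2))
  d_acc <- sqrt(colSums((t(reference_pose[acc_idx, , drop = FALSE]) -
                           as.vector(hinge_don))^2))
  if (!any(d_don <= cut) || !any(d_acc <= cut))
    stop("reference pose does not satisfy the bidentate hinge hydrogen bond")
  don_bead <- don_idx[which.min(d_don)]
  acc_bead <- acc_idx[which.min(d_acc)]
  aro_idx <- which(lig$type == "aromatic")
  feat <- rbind(
    data.frame(x = reference_pose[don_bead, 1],
               y = reference_pose[don_bead, 2],
               z = reference_pose[don_bead, 3], type = "hbond_donor"),
    data.frame(x = reference_pose[acc_bead, 1],
               y = reference_pose[acc_bead, 2],
               z = reference_pose[acc_bead, 3], type = "hbond_acceptor"),
    if (length(aro_idx) > 0)
      data.frame(x = reference_pose[aro_idx, 1],
                 y = reference_pose[aro_idx, 2],
                 z = reference_pose[aro_idx, 3], type = "aromatic"))
  feat$radius <- radius
  rownames(feat) <- NULL
  structure(feat, class = c("pharmacophore_model", "data.frame"),
            required_all = TRUE)
}

#' Filter poses against a pharmacophore model
#'
#' A pose is retained when every feature of the model is matched by at
#' least one ligand bead of the matching type inside the feature sphere;
#' with the default model this enforces the bidentate hinge hydrogen bond
#' and the placement of the aromatic scaffold.
#'
#' @param poses list of coordinate matrices.
#' @param model a `pharmacophore_model`.
#' @param system the `toy_system` supplying bead types.
#' @return integer vector of retained pose indices (1-based).
#' @export
pharmacophore_filter <- function(poses, model, system) {
  lig_type <- system$ligand$type
  centers <- as.matrix(model[, c("x", "y", "z")])
  ok <- vapply(poses, function(pose) {
    pose <- as.matrix(pose)
    all(vapply(seq_len(nrow(model)), function(f) {
      beads <- which(lig_type == model$type[f])
      if (length(beads) == 0) return(FALSE)
      d <- sqrt(colSums((t(pose[beads, , drop = FALSE]) - centers[f, ])^2))
      any(d <= model$radius[f])
    }, TRUE))
  }, TRUE)
  which(ok)
}
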