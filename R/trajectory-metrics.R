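# RMSD machinery: optimal (Kabsch) superposition, receptor-backbone RMSD,
# ligand-movement RMSD with the < 2.000 Angstrom stability rule, and
# docking-pose RMSD without fitting.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")
STABILITY_CUTOFF <- 2.000 # Angstrom; ligand considered stable below this

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` via singular
#' value decomposition of the cross-covariance matrix, with the usual
#' determinant correction so the returned rotation is proper. The fitted
#' RMSD is the minimum over all rigid transforms.
#'
#' @param mobile,reference Numeric matrices (n x 3), matched row order,
#'   n >= 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the fit is
#'   `mobile %*% rotation + translation` after centering conventions are
#'   folded in), `rmsd` (fitted RMSD), and `transform(xyz)` applying the fit
#'   to arbitrary coordinates.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort_geometry("superposition selections differ in size")
  }
  if (nrow(mobile) < 3) {
    abort_geometry("superposition needs at least 3 points")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  h <- t(a) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  transform <- function(xyz) {
    sweep(sweep(as.matrix(xyz), 2, cm) %*% t(rot), 2, cr, "+")
  }
  list(rotation = rot, translation = cr - as.vector(cm %*% t(rot)),
       rmsd = rmsd, transform = transform)
}

backbone_coords <- function(frame) {
  prot <- frame[toupper(frame$res_name) %in% STANDARD_AA, ]
  bb <- prot[prot$name %in% BACKBONE_ATOMS, ]
  keys <- unique(residue_key(prot))
  have <- table(factor(residue_key(bb), levels = keys))
  missing <- keys[have < length(BACKBONE_ATOMS)]
  if (length(missing) > 0) {
    abort_geometry(paste("missing backbone atoms (need N, CA, C, O) in:",
                         paste(missing, collapse = ", ")))
  }
  bb <- arrange(bb, .data$chain, .data$res_seq, .data$i_code,
                match(.data$name, BACKBONE_ATOMS))
  coords_mat(bb)
}

#' Receptor backbone RMSD after optimal superposition
#'
#' Kabsch-fits the frame's backbone (N, CA, C, O of every protein residue)
#' onto the reference backbone, then reports the RMSD over that same
#' selection. Zero for any rigid motion of the whole structure.
#'
#' @param frame,reference_frame Single-frame atom tibbles with matching
#'   residues.
#' @return RMSD in Angstrom.
#' @export
rmsd_backbone <- function(frame, reference_frame) {
  kabsch_superpose(backbone_coords(frame),
                   backbone_coords(reference_frame))$rmsd
}

#' Ligand-movement RMSD (binding-stability metric)
#'
#' Superposes the frame onto the reference using the protein backbone only,
#' then reports the RMSD over ligand heavy atoms without further fitting, so
#' genuine ligand displacement relative to the receptor is measured. The
#' companion stability rule flags the pose stable when the value is below
#' 2.000 Angstrom.
#'
#' @param frame,reference_frame Single-frame atom tibbles.
#' @param ligand Ligand selector (see [split_complex()]).
#' @return RMSD in Angstrom.
#' @export
rmsd_ligmove <- function(frame, reference_frame, ligand) {
  fit <- kabsch_superpose(backbone_coords(frame),
                          backbone_coords(reference_frame))
  lig <- split_complex(frame, ligand)$ligand
  lig_ref <- split_complex(reference_frame, ligand)$ligand
  lig <- lig[lig$element != "H", ]
  lig_ref <- lig_ref[lig_ref$element != "H", ]
  if (nrow(lig) != nrow(lig_ref)) {
    abort_geometry("ligand atom sets differ between frame and reference")
  }
  moved <- fit$transform(coords_mat(lig))
  sqrt(mean(rowSums((moved - coords_mat(lig_ref))^2)))
}

#' Is a ligand pose stable under the 2.000 Angstrom rule?
#' @param rmsd Ligand-movement RMSD value(s) in Angstrom.
#' @return Logical: `rmsd < 2.000`.
#' @export
is_stable <- function(rmsd) {
  rmsd < STABILITY_CUTOFF
}

#' Docking-pose RMSD (no superposition)
#'
#' Plain root-mean-square deviation over heavy atoms of two poses of the
#' same molecule in the same atom order -- the redocking validation metric.
#' The acceptance rule deems a redocked pose reliable when
#' `rmsd_pose <= 2.000` Angstrom ([pose_acceptable()]). No symmetry
#' correction (e.g. carboxylate oxygen swap) is applied.
#'
#' @param pose_a,pose_b Atom tibbles or n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_pose <- function(pose_a, pose_b) {
  xyz <- function(p) {
    if (is.data.frame(p)) coords_mat(p[p$element != "H", ]) else as.matrix(p)
  }
  a <- xyz(pose_a); b <- xyz(pose_b)
  if (nrow(a) != nrow(b)) {
    abort_geometry("pose atom counts differ")
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Redocking acceptance rule
#' @param rmsd Pose RMSD in Angstrom.
#' @return Logical: `rmsd <= 2.000`.
#' @export
pose_acceptable <- function(rmsd) {
  rmsd <= STABILITY_CUTOFF
}

#' Backbone and ligand-movement RMSD traces over a snapshot series
#'
#' Computes [rmsd_backbone()] and [rmsd_ligmove()] for every frame against
#' the reference frame (default frame 0, the docked starting pose), plus the
#' simulation time assuming a fixed snapshot interval (default 100 ps) and
#' the stability flag.
#'
#' @param series Multi-frame atom tibble.
#' @param ligand Ligand selector.
#' @param reference 0-based reference frame index (default 0).
#' @param dt_ps Time between snapshots in picoseconds (default 100).
#' @return Tibble: `frame_index`, `time_ps`, `backbone_rmsd`,
#'   `ligmove_rmsd`, `stable`.
#' @export
rmsd_traces <- function(series, ligand, reference = 0, dt_ps = 100) {
  frames <- sort(unique(series$frame))
  ref <- get_frame(series, reference)
  rows <- lapply(frames, function(f) {
    fr <- get_frame(series, f)
    lg <- rmsd_ligmove(fr, ref, ligand)
    tibble(frame_index = f, time_ps = f * dt_ps,
           backbone_rmsd = rmsd_backbone(fr, ref),
           ligmove_rmsd = lg, stable = is_stable(lg))
  })
  bind_rows(rows)
}
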