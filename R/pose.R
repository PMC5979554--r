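# Genotype -> Cartesian coordinates (the phenotype), and pose comparison.

# fast path on the raw gene vector (compiled kinematics)
build_pose_vec <- function(ligand, v, box) {
  nt <- ligand$n_torsions
  cpp_build_pose(ligand$coords, as.integer(ligand$root),
                 as.integer(vapply(ligand$branches, `[[`, 0, "axis_from")),
                 as.integer(vapply(ligand$branches, `[[`, 0, "axis_to")),
                 lapply(ligand$branches,
                        function(b) as.integer(b$subtree)),
                 if (nt > 0L) v[7L + seq_len(nt)] else numeric(0),
                 v[4:7], box$center + v[1:3])
}

#' Build the ligand pose encoded by a genotype
#'
#' Torsions are applied branch by branch (parents before children), each
#' rotating its subtree about the branch axis; the whole ligand is then
#' rotated by the orientation quaternion about the rigid-root centroid and
#' translated so that the root centroid lands at
#' `box$center + translation`.
#'
#' @param ligand A `ligand`.
#' @param g A `genotype` (or raw gene vector) with `ligand$n_torsions`
#'   torsion genes.
#' @param box A [search_box()].
#' @return N x 3 coordinate matrix in the ligand's atom order, Angstrom.
#' @export
build_pose <- function(ligand, g, box) {
  stopifnot(inherits(ligand, "ligand"))
  build_pose_vec(ligand, as_gvec(g, ligand$n_torsions), box)
}

#' Root-mean-square deviation between two poses
#'
#' Index-matched RMSD (no superposition, no symmetry correction):
#' \eqn{\sqrt{\mathrm{mean}_i \|a_i - b_i\|^2}} over the selected atoms.
#' With `heavy_only = TRUE`, atoms whose AutoDock type starts with `H`
#' (i.e. `H`, `HD`) are excluded; `types` must then be supplied.
#'
#' @param pose_a,pose_b N x 3 coordinate matrices in the same atom order.
#' @param heavy_only Exclude hydrogens.
#' @param types Atom type tokens, required when `heavy_only = TRUE`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(pose_a, pose_b, heavy_only = FALSE, types = NULL) {
  pose_a <- as.matrix(pose_a)
  pose_b <- as.matrix(pose_b)
  if (!all(dim(pose_a) == dim(pose_b))) {
    stop("pose atom counts differ: ", nrow(pose_a), " vs ", nrow(pose_b))
  }
  keep <- rep(TRUE, nrow(pose_a))
  if (heavy_only) {
    if (is.null(types)) stop("heavy_only = TRUE requires atom types")
    stopifnot(length(types) == nrow(pose_a))
    keep <- !startsWith(types, "H")
  }
  d <- pose_a[keep, , drop = FALSE] - pose_b[keep, , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}
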