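# Clamshell-closure order parameters (xi1, xi2, xi12) and the glycan-D2
# minimum-distance order parameter.
#
# xi1 and xi2 are mass-weighted center-of-mass distances between pairs of
# backbone (N, CA, C) residue groups spanning the mouth of the bi-lobed
# ligand-binding domain; small values mean a closed clamshell. xi12 is
# their arithmetic mean, a convenient single closure coordinate. The
# glycan-D2 order parameter is the minimum heavy-atom distance between a
# near-pocket glycan and the bottom-lobe (D2) C-alpha atoms.

#' Residue-range presets for the xi order parameters and D2 lobes
#'
#' Residue numbering follows the author (UniProt-style) convention of the
#' receptor subunits; override freely for other systems.
#' @export
lobe_presets <- list(
  GluN1 = list(
    xi1 = list(c(484, 485), c(688, 689)),
    xi2 = list(c(405, 406, 407), c(714, 715)),
    D2 = c(537:544, 663:754)
  ),
  GluN2A = list(
    xi1 = list(c(485, 486), c(689, 690)),
    xi2 = list(c(413, 414), c(713, 714)),
    D2 = c(533:539, 661:757)
  )
)

# mass-weighted (default) or geometric center of a coordinate block
.center_of_mass <- function(X, masses, weighted = TRUE) {
  if (!weighted) masses <- rep(1, nrow(X))
  colSums(X * masses) / sum(masses)
}

#' Center-of-mass distance pair (xi1, xi2) for one frame
#'
#' Each order parameter is the distance between the mass-weighted centers
#' of mass of two backbone residue groups.
#'
#' @param traj an [lp_trajectory()]
#' @param frame 0-based frame index
#' @param groups list with `xi1` and `xi2`, each a list of two atom-id
#'   vectors (resolve with [resolve_selection()], e.g.
#'   `"residues 485-486 backbone"`); defaults to the topology's
#'   `op_groups`
#' @param mass_weighted mass-weighted COM (default) or geometric center
#' @return named numeric `c(xi1=, xi2=)` (Angstrom)
#' @export
xi_pair <- function(traj, frame, groups = NULL, mass_weighted = TRUE) {
  top <- traj$top
  if (is.null(groups)) groups <- top$op_groups
  if (is.null(groups)) stop("no order-parameter groups defined")
  X <- frame_coords(traj, frame)
  one <- function(pair) {
    coms <- lapply(pair, function(ids) {
      if (length(ids) == 0) stop("selection error: empty order-parameter group")
      rows <- .atom_rows(top, ids)
      .center_of_mass(X[rows, , drop = FALSE], top$atoms$mass[rows], mass_weighted)
    })
    sqrt(sum((coms[[1]] - coms[[2]])^2))
  }
  c(xi1 = one(groups$xi1), xi2 = one(groups$xi2))
}

#' Closure projection xi12
#'
#' Arithmetic mean of xi1 and xi2; e.g. (16, 14) -> 15.
#' @param xi1,xi2 numeric (Angstrom), vectorized
#' @return numeric (Angstrom)
#' @export
xi12 <- function(xi1, xi2) (xi1 + xi2) / 2

#' Glycan-D2 order parameter for one frame
#'
#' Minimum pairwise distance between the glycan heavy atoms and the D2
#' lobe C-alpha atoms.
#'
#' @param traj an [lp_trajectory()]
#' @param frame 0-based frame index
#' @param glycan_atoms atom ids of the glycan heavy atoms (default: first
#'   glycan in the topology)
#' @param d2_calpha atom ids of the D2 C-alpha atoms (default: CA atoms of
#'   the topology's `lobe_D2` residues)
#' @return numeric minimum distance (Angstrom)
#' @export
glycan_d2 <- function(traj, frame, glycan_atoms = NULL, d2_calpha = NULL) {
  top <- traj$top
  if (is.null(glycan_atoms)) {
    if (length(top$glycan_atoms) == 0) stop("selection error: no glycan atoms")
    glycan_atoms <- top$glycan_atoms[[1]]
  }
  if (is.null(d2_calpha)) {
    if (length(top$lobe_D2) == 0) stop("selection error: no D2 lobe residues")
    d2_calpha <- top$atoms$atom_id[top$atoms$residue_id %in% top$lobe_D2 &
                                     top$atoms$name == "CA"]
  }
  if (length(glycan_atoms) == 0 || length(d2_calpha) == 0)
    stop("selection error: empty atom set for glycan-D2 order parameter")
  X <- frame_coords(traj, frame)
  min_dist(X[.atom_rows(top, glycan_atoms), , drop = FALSE],
           X[.atom_rows(top, d2_calpha), , drop = FALSE])
}

#' Per-frame order-parameter series
#'
#' @param traj an [lp_trajectory()]
#' @param groups see [xi_pair()]
#' @param glycans list of glycan atom-id vectors (default: the topology's)
#' @param mass_weighted see [xi_pair()]
#' @return data.frame `frame`, `time_ns`, `xi1`, `xi2`, `xi12`, and one
#'   `glycan_d2_<i>` column per glycan
#' @export
order_parameter_series <- function(traj, groups = NULL, glycans = NULL,
                                   mass_weighted = TRUE) {
  nf <- n_frames(traj)
  if (is.null(glycans)) glycans <- traj$top$glycan_atoms
  xi <- t(vapply(seq_len(nf) - 1L,
                 function(f) xi_pair(traj, f, groups, mass_weighted),
                 numeric(2)))
  df <- data.frame(frame = seq_len(nf) - 1L, time_ns = traj$times,
                   xi1 = xi[, 1], xi2 = xi[, 2], xi12 = xi12(xi[, 1], xi[, 2]))
  for (g in seq_along(glycans)) {
    df[[paste0("glycan_d2_", g - 1L)]] <-
      vapply(seq_len(nf) - 1L, function(f) glycan_d2(traj, f, glycans[[g]]),
             numeric(1))
  }
  df
}
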