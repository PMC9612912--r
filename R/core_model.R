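# Core domain model: topology, trajectory, selections, distance primitives.
# Unit conventions used throughout the package:
#   distances in Angstrom, times in ns, energies in kcal/mol, temperatures in K.
# Atom ids are 0-based and preserve topology order; residue ids preserve the
# author/topology numbering verbatim (never renumbered).

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
.kB <- 0.0019872041

#' Avogadro's number (1/mol)
#' @keywords internal
.NA_AVOGADRO <- 6.02214076e23

# Elements counted as polar for the association criterion. Heavy atoms only;
# carbon and hydrogen are never polar. Sulfur is included by choice (the
# criterion itself names only "polar heavy atoms"); override via the
# `polar_elements` argument of `lp_topology()`.
.default_polar_elements <- c("N", "O", "S")

.backbone_names <- c("N", "CA", "C")

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)

.mass_of <- function(element) {
  m <- .element_masses[element]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Build a topology object
#'
#' A topology is the static description of one structure: an ordered atom
#' table plus the named atom groups every downstream stage needs (ligand
#' copies, docking atoms, clamshell lobes, order-parameter groups, glycans).
#'
#' @param atoms data.frame with columns `atom_id` (0-based integer, unique),
#'   `name`, `element`, `residue_id` (integer), `residue_name`, `chain_id`.
#'   Optional columns `x`, `y`, `z` carry reference coordinates (Angstrom).
#' @param ligand_copies list of integer vectors of atom ids, one per ligand
#'   molecule. Atoms not in any copy are protein/glycan atoms.
#' @param ligand_ref_atom integer vector, one atom id per copy, used as the
#'   pathway trace reference point (conventionally the ligand CA).
#' @param docking_atoms list, one element per copy, each a named list/vector
#'   with atom ids `NH1`, `NH2` (the conserved arginine guanidinium nitrogens)
#'   and `OT1`, `OT2` (the ligand carboxylate oxygens of that copy).
#' @param lobe_D1,lobe_D2 integer vectors of residue ids for the upper (D1)
#'   and lower (D2) clamshell lobes.
#' @param op_groups list with elements `xi1` and `xi2`, each a list of two
#'   residue-id vectors; the order parameter is the backbone center-of-mass
#'   distance between the two groups.
#' @param glycan_atoms list of integer atom-id vectors, one per glycan
#'   (heavy atoms).
#' @param box numeric length-3 orthorhombic box dimensions (Angstrom), or NULL.
#' @param polar_elements element symbols treated as polar heavy atoms.
#' @return An object of class `lp_topology`.
#' @export
lp_topology <- function(atoms, ligand_copies = list(), ligand_ref_atom = integer(),
                        docking_atoms = list(), lobe_D1 = integer(),
                        lobe_D2 = integer(), op_groups = NULL,
                        glycan_atoms = list(), box = NULL,
                        polar_elements = .default_polar_elements) {
  stopifnot(is.data.frame(atoms))
  req <- c("atom_id", "name", "element", "residue_id", "residue_name", "chain_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique within a topology")
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$residue_id <- as.integer(atoms$residue_id)
  atoms$is_polar <- atoms$element %in% polar_elements & !(atoms$element %in% c("C", "H"))
  atoms$is_backbone <- atoms$name %in% .backbone_names
  atoms$mass <- .mass_of(atoms$element)

  lig_all <- unlist(ligand_copies, use.names = FALSE)
  if (anyDuplicated(lig_all))
    stop("ligand copies must not share atoms")
  if (!all(lig_all %in% atoms$atom_id))
    stop("ligand copy references unknown atom ids")
  for (d in docking_atoms) {
    d <- unlist(d)
    if (!all(c("NH1", "NH2", "OT1", "OT2") %in% names(d)))
      stop("docking_atoms entries need NH1, NH2, OT1, OT2")
    if (!all(d %in% atoms$atom_id))
      stop("docking atom id not present in topology")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0)) stop("box must be three positive lengths")
  }
  structure(list(
    atoms = atoms,
    ligand_copies = lapply(ligand_copies, as.integer),
    ligand_ref_atom = as.integer(ligand_ref_atom),
    docking_atoms = docking_atoms,
    lobe_D1 = as.integer(lobe_D1),
    lobe_D2 = as.integer(lobe_D2),
    op_groups = op_groups,
    glycan_atoms = lapply(glycan_atoms, as.integer),
    box = box,
    polar_elements = polar_elements
  ), class = "lp_topology")
}

#' @export
print.lp_topology <- function(x, ...) {
  cat(sprintf("<lp_topology> %d atoms, %d ligand copies, %d glycans\n",
              nrow(x$atoms), length(x$ligand_copies), length(x$glycan_atoms)))
  invisible(x)
}

# row indices (1-based) of the given 0-based atom ids
.atom_rows <- function(top, atom_ids) {
  idx <- match(as.integer(atom_ids), top$atoms$atom_id)
  if (anyNA(idx)) stop("unknown atom id(s): ",
                       paste(atom_ids[is.na(idx)], collapse = ", "))
  idx
}

# atom ids belonging to any ligand copy
.ligand_atom_ids <- function(top) unlist(top$ligand_copies, use.names = FALSE)

# protein = everything that is neither ligand nor glycan
.protein_atom_ids <- function(top) {
  setdiff(top$atoms$atom_id,
          c(.ligand_atom_ids(top), unlist(top$glycan_atoms, use.names = FALSE)))
}

#' Build a trajectory object
#'
#' @param coords numeric array `frames x atoms x 3` (Angstrom) or a single
#'   `atoms x 3` matrix for a one-frame trajectory.
#' @param times frame times in ns, strictly increasing; defaults to
#'   `0:(n_frames-1)`.
#' @param topology an [lp_topology()].
#' @return An object of class `lp_trajectory`.
#' @export
lp_trajectory <- function(coords, topology, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("coordinate array atom count (", dim(coords)[2],
         ") does not match topology (", nrow(topology$atoms), ")")
  nf <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf || (nf > 1 && any(diff(times) <= 0)))
    stop("frame_times must be strictly increasing, one per frame")
  structure(list(coords = coords, times = as.numeric(times), top = topology),
            class = "lp_trajectory")
}

#' @export
print.lp_trajectory <- function(x, ...) {
  cat(sprintf("<lp_trajectory> %d frames x %d atoms, %.4g-%.4g ns\n",
              dim(x$coords)[1], dim(x$coords)[2],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
dim.lp_trajectory <- function(x) dim(x$coords)

n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj an [lp_trajectory()]
#' @param frame 0-based frame index
#' @param atom_ids optional 0-based atom ids to extract (default: all atoms)
#' @return numeric matrix `n x 3`
#' @export
frame_coords <- function(traj, frame, atom_ids = NULL) {
  f <- as.integer(frame) + 1L
  if (f < 1L || f > n_frames(traj)) stop("frame index out of range: ", frame)
  m <- traj$coords[f, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  if (!is.null(atom_ids)) m <- m[.atom_rows(traj$top, atom_ids), , drop = FALSE]
  m
}

# Squared cross-distance matrix between point sets X (n x 3) and Y (m x 3).
# With `box` set, applies orthorhombic minimum-image convention per axis.
.cross_dist2 <- function(X, Y, box = NULL) {
  X <- matrix(as.numeric(X), ncol = 3)
  Y <- matrix(as.numeric(Y), ncol = 3)
  if (is.null(box)) {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    d2[d2 < 0] <- 0
    return(d2)
  }
  d2 <- matrix(0, nrow(X), nrow(Y))
  for (k in 1:3) {
    dk <- outer(X[, k], Y[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  d2
}

#' Minimum distance between two point sets
#'
#' @param X,Y numeric matrices `n x 3` / `m x 3` (Angstrom).
#' @param box optional orthorhombic box for minimum-image distances; by
#'   default no periodic wrapping is applied (solute assumed whole/centered).
#' @return minimum pairwise Euclidean distance (Angstrom)
#' @export
min_dist <- function(X, Y, box = NULL) {
  if (NROW(X) == 0 || NROW(Y) == 0) stop("min_dist: empty point set")
  sqrt(min(.cross_dist2(X, Y, box)))
}

#' Resolve an atom selection expression on a topology
#'
#' The selection mini-language is a whitespace-separated conjunction of
#' filters:
#' \describe{
#'   \item{`protein`}{non-ligand, non-glycan atoms}
#'   \item{`ligand <copy>`}{atoms of the 0-based ligand copy}
#'   \item{`glycan <index>`}{heavy atoms of the 0-based glycan}
#'   \item{`residues <spec>` / `residue <spec>`}{residue ids, e.g.
#'     `485-486` or `533-539,661-757`}
#'   \item{`chain <id>`}{chain/subunit label}
#'   \item{`names <n1> <n2> ...`}{atom names (consumes following tokens)}
#'   \item{`backbone`}{atoms named N, CA, C}
#'   \item{`calpha`}{atoms named CA}
#'   \item{`polar`}{polar heavy atoms (element N/O/S by default)}
#'   \item{`heavy`}{non-hydrogen atoms}
#' }
#' e.g. `"residues 485-486 backbone"`, `"ligand 0 polar heavy"`.
#'
#' @param topology an [lp_topology()]
#' @param spec selection string
#' @param allow_empty if FALSE (default) an empty result is an error
#' @return sorted integer vector of 0-based atom ids
#' @export
resolve_selection <- function(topology, spec, allow_empty = FALSE) {
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  toks <- strsplit(trimws(spec), "\\s+")[[1]]
  i <- 1L
  .parse_residues <- function(token) {
    out <- integer()
    for (part in strsplit(token, ",")[[1]]) {
      if (grepl("^-?\\d+--?\\d+$", part) && grepl("-", sub("^-", "", part))) {
        ab <- as.integer(strsplit(sub("^(-?\\d+)-(-?\\d+)$", "\\1 \\2", part), " ")[[1]])
        out <- c(out, ab[1]:ab[2])
      } else if (grepl("^-?\\d+$", part)) {
        out <- c(out, as.integer(part))
      } else stop("selection error: cannot parse residue range '", part, "'")
    }
    out
  }
  while (i <= length(toks)) {
    t <- tolower(toks[i])
    if (t == "protein") {
      keep <- keep & at$atom_id %in% .protein_atom_ids(topology)
    } else if (t == "ligand") {
      copy <- suppressWarnings(as.integer(toks[i + 1L]))
      if (is.na(copy) || copy < 0 || copy >= length(topology$ligand_copies))
        stop("selection error: unknown ligand copy '", toks[i + 1L], "'")
      keep <- keep & at$atom_id %in% topology$ligand_copies[[copy + 1L]]
      i <- i + 1L
    } else if (t == "glycan") {
      g <- suppressWarnings(as.integer(toks[i + 1L]))
      if (is.na(g) || g < 0 || g >= length(topology$glycan_atoms))
        stop("selection error: unknown glycan index '", toks[i + 1L], "'")
      keep <- keep & at$atom_id %in% topology$glycan_atoms[[g + 1L]]
      i <- i + 1L
    } else if (t %in% c("residues", "residue", "resid")) {
      rs <- .parse_residues(toks[i + 1L])
      missing_rs <- setdiff(rs, at$residue_id)
      if (length(missing_rs) == length(rs))
        stop("selection error: residue(s) not in topology: ",
             paste(utils::head(missing_rs, 5), collapse = ", "))
      keep <- keep & at$residue_id %in% rs
      i <- i + 1L
    } else if (t == "chain") {
      ch <- toks[i + 1L]
      if (!ch %in% at$chain_id) stop("selection error: unknown chain '", ch, "'")
      keep <- keep & at$chain_id == ch
      i <- i + 1L
    } else if (t %in% c("names", "name", "atoms")) {
      nm <- character()
      while (i + 1L <= length(toks) &&
             !tolower(toks[i + 1L]) %in% c("protein", "ligand", "glycan",
                                           "residues", "residue", "resid", "chain",
                                           "names", "name", "atoms", "backbone",
                                           "calpha", "polar", "heavy")) {
        nm <- c(nm, toks[i + 1L]); i <- i + 1L
      }
      if (length(nm) == 0) stop("selection error: 'names' needs atom names")
      unknown <- setdiff(nm, at$name)
      if (length(unknown) == length(nm))
        stop("selection error: unknown atom name(s): ", paste(unknown, collapse = ", "))
      keep <- keep & at$name %in% nm
    } else if (t == "backbone") {
      keep <- keep & at$is_backbone
    } else if (t == "calpha") {
      keep <- keep & at$name == "CA"
    } else if (t == "polar") {
      keep <- keep & at$is_polar
    } else if (t == "heavy") {
      keep <- keep & at$element != "H"
    } else {
      stop("selection error: unknown token '", toks[i], "'")
    }
    i <- i + 1L
  }
  ids <- sort(at$atom_id[keep])
  if (length(ids) == 0 && !allow_empty)
    stop("selection error: '", spec, "' matched no atoms")
  ids
}

#' Association states
#'
#' Three-state classification of each ligand copy per frame, following the
#' scheme P + L <-> PL_assoc <-> PL_docked.
#' @export
association_states <- c("BULK", "ASSOCIATED", "DOCKED")
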