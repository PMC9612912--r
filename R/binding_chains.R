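# Binding-chain detection and pathway splitting.
#
# A binding chain is one continuous association episode: it opens at the
# first frame where any polar ligand heavy atom comes within `assoc_cutoff`
# (6 A) of any polar protein heavy atom, and survives until the ligand
# diffuses beyond `dissoc_cutoff` (10 A) from the protein. The gap between
# the two cutoffs is a hysteresis band: a ligand rattling between 6 and
# 10 A neither opens a new chain nor closes the current one. Chains are
# filtered by docking (the carboxylate/guanidinium criterion) and split
# into binding and unbinding pathways.

#' Chain intervals from per-frame distance series
#'
#' Pure state machine over two precomputed distance series; exposed so the
#' detection logic can be tested against scalar oracles independent of any
#' geometry.
#'
#' @param d_assoc per-frame association distance (min polar ligand to polar
#'   protein heavy-atom distance, Angstrom)
#' @param d_dissoc per-frame dissociation distance (min ligand to protein
#'   heavy-atom distance); must be elementwise <= `d_assoc` in the standard
#'   atom-set convention, but any series is accepted
#' @param assoc_cutoff,dissoc_cutoff Angstrom; `assoc_cutoff < dissoc_cutoff`
#' @return data.frame with 0-based `start`, `end`, and `terminated`
#' @export
chain_intervals <- function(d_assoc, d_dissoc = d_assoc,
                            assoc_cutoff = 6, dissoc_cutoff = 10) {
  if (assoc_cutoff >= dissoc_cutoff)
    stop("assoc_cutoff must be smaller than dissoc_cutoff")
  stopifnot(length(d_assoc) == length(d_dissoc), length(d_assoc) > 0)
  starts <- integer(); ends <- integer(); terms <- logical()
  in_chain <- FALSE; s <- NA_integer_
  for (f in seq_along(d_assoc)) {
    if (in_chain && d_dissoc[f] > dissoc_cutoff) {
      starts <- c(starts, s); ends <- c(ends, f - 2L); terms <- c(terms, TRUE)
      in_chain <- FALSE
    }
    if (!in_chain && d_assoc[f] <= assoc_cutoff) {
      in_chain <- TRUE; s <- f - 1L
    }
  }
  if (in_chain) {
    starts <- c(starts, s); ends <- c(ends, length(d_assoc) - 1L)
    terms <- c(terms, FALSE)
  }
  data.frame(start = starts, end = ends, terminated = terms)
}

#' Docking criterion on four atom positions
#'
#' True when the conserved-arginine guanidinium engages the ligand
#' carboxylate in either orientation:
#' Condition 1 - NH1 within `dock_cutoff` of OT1 AND NH2 within it of OT2;
#' Condition 2 - the flipped pairing (NH1-OT2 AND NH2-OT1).
#'
#' @param nh1,nh2,ot1,ot2 numeric xyz positions (Angstrom)
#' @param dock_cutoff Angstrom, default 4
#' @return logical
#' @export
is_docked <- function(nh1, nh2, ot1, ot2, dock_cutoff = 4) {
  pos <- list(nh1, nh2, ot1, ot2)
  if (any(vapply(pos, function(p) length(p) != 3 || anyNA(p), logical(1))))
    stop("docking atoms unresolved: need four xyz positions")
  d <- function(a, b) sqrt(sum((a - b)^2))
  (d(nh1, ot1) <= dock_cutoff && d(nh2, ot2) <= dock_cutoff) ||
    (d(nh1, ot2) <= dock_cutoff && d(nh2, ot1) <= dock_cutoff)
}

# per-frame association / dissociation distance series for one ligand copy
.distance_series <- function(traj, copy, pbc = FALSE) {
  top <- traj$top
  box <- if (pbc) top$box else NULL
  lig_ids <- top$ligand_copies[[copy + 1L]]
  lig_rows <- .atom_rows(top, lig_ids)
  at <- top$atoms
  lig_pol_rows <- lig_rows[at$is_polar[lig_rows] & at$element[lig_rows] != "H"]
  lig_hvy_rows <- lig_rows[at$element[lig_rows] != "H"]
  prot_ids <- .protein_atom_ids(top)
  prot_rows <- .atom_rows(top, prot_ids)
  prot_pol_rows <- prot_rows[at$is_polar[prot_rows]]
  prot_hvy_rows <- prot_rows[at$element[prot_rows] != "H"]
  if (length(lig_pol_rows) == 0 || length(prot_pol_rows) == 0)
    stop("no polar heavy atoms available for the association criterion")
  nf <- n_frames(traj)
  d_assoc <- numeric(nf); d_dissoc <- numeric(nf)
  for (f in seq_len(nf)) {
    X <- traj$coords[f, , ]
    d_assoc[f] <- sqrt(min(.cross_dist2(X[lig_pol_rows, , drop = FALSE],
                                        X[prot_pol_rows, , drop = FALSE], box)))
    d_dissoc[f] <- sqrt(min(.cross_dist2(X[lig_hvy_rows, , drop = FALSE],
                                         X[prot_hvy_rows, , drop = FALSE], box)))
  }
  list(d_assoc = d_assoc, d_dissoc = d_dissoc,
       lig_pol_rows = lig_pol_rows, prot_pol_rows = prot_pol_rows)
}

# docking-atom positions for one copy at one (1-based) frame
.dock_positions <- function(traj, copy, f1) {
  da <- traj$top$docking_atoms[[copy + 1L]]
  if (is.null(da)) stop("topology error: no docking atoms defined for copy ", copy)
  rows <- .atom_rows(traj$top, unlist(da[c("NH1", "NH2", "OT1", "OT2")]))
  X <- traj$coords[f1, , ]
  list(nh1 = X[rows[1], ], nh2 = X[rows[2], ], ot1 = X[rows[3], ], ot2 = X[rows[4], ])
}

#' Detect binding chains for one ligand copy
#'
#' @param traj an [lp_trajectory()]
#' @param copy 0-based ligand copy index
#' @param assoc_cutoff association cutoff (Angstrom), default 6: min polar
#'   ligand heavy atom to polar protein heavy atom distance
#' @param dissoc_cutoff dissociation cutoff (Angstrom), default 10: min
#'   distance over all ligand/protein heavy atoms
#' @param dock_cutoff docking cutoff for [is_docked()], default 4
#' @param contact_cutoff residue-contact profiling cutoff; defaults to
#'   `assoc_cutoff` (polar-polar)
#' @param pbc apply orthorhombic minimum-image distances
#' @return list of `lp_chain` objects; each records `ligand_copy`,
#'   `start_frame`/`end_frame` (0-based), `docked_frames`,
#'   `per_frame_contacts` (list of residue-id vectors, one per chain frame)
#'   and `terminated`
#' @export
detect_chains <- function(traj, copy, assoc_cutoff = 6, dissoc_cutoff = 10,
                          dock_cutoff = 4, contact_cutoff = assoc_cutoff,
                          pbc = FALSE) {
  if (assoc_cutoff >= dissoc_cutoff)
    stop("assoc_cutoff must be smaller than dissoc_cutoff")
  ds <- .distance_series(traj, copy, pbc)
  iv <- chain_intervals(ds$d_assoc, ds$d_dissoc, assoc_cutoff, dissoc_cutoff)
  if (nrow(iv) == 0) return(list())
  at <- traj$top$atoms
  box <- if (pbc) traj$top$box else NULL
  has_dock <- length(traj$top$docking_atoms) > copy &&
    !is.null(traj$top$docking_atoms[[copy + 1L]])
  lapply(seq_len(nrow(iv)), function(i) {
    fr <- iv$start[i]:iv$end[i]
    contacts <- vector("list", length(fr))
    docked <- logical(length(fr))
    for (j in seq_along(fr)) {
      f1 <- fr[j] + 1L
      X <- traj$coords[f1, , ]
      d2 <- .cross_dist2(X[ds$lig_pol_rows, , drop = FALSE],
                         X[ds$prot_pol_rows, , drop = FALSE], box)
      hit <- which(apply(d2, 2, min) <= contact_cutoff^2)
      contacts[[j]] <- sort(unique(at$residue_id[ds$prot_pol_rows[hit]]))
      if (has_dock) {
        p <- .dock_positions(traj, copy, f1)
        docked[j] <- is_docked(p$nh1, p$nh2, p$ot1, p$ot2, dock_cutoff)
      }
    }
    structure(list(
      ligand_copy = copy, chain_id = i - 1L,
      start_frame = iv$start[i], end_frame = iv$end[i],
      frames = fr, docked_frames = fr[docked],
      per_frame_contacts = contacts, terminated = iv$terminated[i]
    ), class = "lp_chain")
  })
}

#' @export
print.lp_chain <- function(x, ...) {
  cat(sprintf("<lp_chain> copy %d frames %d-%d, %d docked, terminated=%s\n",
              x$ligand_copy, x$start_frame, x$end_frame,
              length(x$docked_frames), x$terminated))
  invisible(x)
}

# residue-id frame-count table over a set of chain frames
.contact_multiset <- function(chain, frames) {
  idx <- match(frames, chain$frames)
  tab <- table(unlist(chain$per_frame_contacts[idx]))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Split a docked chain into binding and unbinding pathways
#'
#' Chains that never dock are discarded (zero pathways). The binding
#' pathway runs from chain start through the FIRST docked frame; the
#' unbinding pathway runs from the LAST docked frame through chain end and
#' is stored time-reversed so all pathways share the same directionality.
#' No unbinding pathway is emitted for unterminated chains or when the last
#' docked frame is the chain end.
#'
#' @param chain an `lp_chain`
#' @param traj the trajectory the chain came from (for the reference-atom
#'   trace)
#' @return list of 0-2 `lp_pathway` objects
#' @export
split_chain <- function(chain, traj) {
  if (length(chain$docked_frames) == 0) return(list())
  top <- traj$top
  ref_id <- top$ligand_ref_atom[chain$ligand_copy + 1L]
  ref_row <- .atom_rows(top, ref_id)
  mk <- function(frames, direction) {
    trace <- traj$coords[frames + 1L, ref_row, , drop = FALSE]
    trace <- matrix(trace, ncol = 3)
    structure(list(
      chain_id = chain$chain_id, ligand_copy = chain$ligand_copy,
      direction = direction, frames = frames, trace = trace,
      contact_residues = .contact_multiset(chain, frames),
      per_frame_contacts = chain$per_frame_contacts[match(frames, chain$frames)],
      mechanism = NA_character_
    ), class = "lp_pathway")
  }
  first_dock <- min(chain$docked_frames)
  out <- list(mk(chain$start_frame:first_dock, "binding"))
  last_dock <- max(chain$docked_frames)
  if (chain$terminated && last_dock < chain$end_frame)
    out <- c(out, list(mk(chain$end_frame:last_dock, "unbinding-reversed")))
  out
}

#' @export
print.lp_pathway <- function(x, ...) {
  cat(sprintf("<lp_pathway> chain %d (%s), %d frames, %d contact residues\n",
              x$chain_id, x$direction, length(x$frames),
              length(x$contact_residues)))
  invisible(x)
}

#' Classify a pathway as guided or free diffusion
#'
#' A pathway is labeled "free" when the ligand contacted fewer than
#' `min_distinct_residues` distinct surface residues before its first
#' docked frame; otherwise "guided". The criterion is a configurable
#' stand-in (the counting rule is not uniquely fixed by the three-state
#' scheme); the threshold is echoed in the result attributes.
#'
#' @param path an `lp_pathway` (binding direction)
#' @param min_distinct_residues default 3
#' @param exclude_residues residue ids never counted as surface contacts
#'   (typically the docking arginine)
#' @return "guided" or "free", with attribute `n_surface_residues`
#' @export
classify_mechanism <- function(path, min_distinct_residues = 3,
                               exclude_residues = integer()) {
  # contacts strictly before the pathway's terminal (first docked) frame;
  # for reversed unbinding pathways the whole trace counts
  contacts <- path$per_frame_contacts
  if (path$direction == "binding" && length(contacts) > 1)
    contacts <- contacts[-length(contacts)]
  else if (path$direction == "binding")
    contacts <- list()
  res <- setdiff(unique(as.integer(unlist(contacts))),
                 as.integer(exclude_residues))
  lab <- if (length(res) < min_distinct_residues) "free" else "guided"
  structure(lab, n_surface_residues = length(res),
            threshold = min_distinct_residues)
}

#' Association census for a trajectory
#'
#' Counts associations and docked (successful) associations, per-residue
#' conditional success probabilities, and per-microsecond rates. Because
#' a chain may contain several docking episodes, both the chain count and
#' the docking-episode count are reported.
#'
#' @param traj an [lp_trajectory()]
#' @param copies 0-based ligand copy indices (default: all)
#' @param ... passed to [detect_chains()]
#' @return list with totals, rates and a per-residue data.frame
#'   (`residue_id`, `n_associations`, `n_success`, `success_pct`)
#' @export
association_census <- function(traj, copies = NULL, ...) {
  if (is.null(copies)) copies <- seq_along(traj$top$ligand_copies) - 1L
  duration_ns <- traj$times[length(traj$times)] - traj$times[1]
  if (duration_ns <= 0) stop("trajectory has zero duration")
  chains <- unlist(lapply(copies, function(cp) detect_chains(traj, cp, ...)),
                   recursive = FALSE)
  n_assoc <- length(chains)
  docked <- vapply(chains, function(ch) length(ch$docked_frames) > 0, logical(1))
  n_episodes <- sum(vapply(chains, function(ch) {
    if (length(ch$docked_frames) == 0) return(0L)
    length(unique(cumsum(c(1L, diff(ch$docked_frames) > 1L))))
  }, integer(1)))
  res_assoc <- new.env()
  for (i in seq_along(chains)) {
    rs <- unique(unlist(chains[[i]]$per_frame_contacts))
    for (r in rs) {
      key <- as.character(r)
      cur <- if (is.null(res_assoc[[key]])) c(0L, 0L) else res_assoc[[key]]
      res_assoc[[key]] <- cur + c(1L, as.integer(docked[i]))
    }
  }
  keys <- ls(res_assoc)
  per_res <- data.frame(
    residue_id = as.integer(keys),
    n_associations = vapply(keys, function(k) res_assoc[[k]][1], integer(1)),
    n_success = vapply(keys, function(k) res_assoc[[k]][2], integer(1))
  )
  per_res <- per_res[order(per_res$residue_id), , drop = FALSE]
  rownames(per_res) <- NULL
  per_res$success_pct <- 100 * per_res$n_success / per_res$n_associations
  us <- duration_ns / 1000
  list(
    n_associations = n_assoc,
    n_docked = sum(docked),
    n_docking_episodes = n_episodes,
    duration_ns = duration_ns,
    associations_per_us = n_assoc / us,
    docked_per_us = sum(docked) / us,
    per_residue = per_res,
    chains = chains
  )
}
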