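# Independent brute-force oracles and tiny fixtures shared across tests.
# These deliberately avoid the package's vectorized internals: plain
# double loops only, so they can arbitrate.

# naive double-loop minimum distance
oracle_min_dist <- function(X, Y) {
  best <- Inf
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
    best <- min(best, sqrt(sum((X[i, ] - Y[j, ])^2)))
  best
}

# naive one-sided summed Hausdorff
oracle_hausdorff_sum <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    s <- s + best
  }
  s
}

oracle_wavg_hausdorff <- function(A, B) {
  0.5 * (oracle_hausdorff_sum(A, B) / nrow(A) +
         oracle_hausdorff_sum(B, A) / nrow(B))
}

# Brute-force per-frame binding-chain oracle. Recomputes the polar-polar
# association distance, the all-heavy dissociation distance and the
# docking criterion frame by frame from raw coordinates, then scans the
# hysteresis rule with an explicit state walk.
oracle_detect <- function(traj, copy, assoc = 6, dissoc = 10, dock = 4) {
  top <- traj$top
  at <- top$atoms
  lig_ids <- top$ligand_copies[[copy + 1]]
  lig <- at[match(lig_ids, at$atom_id), ]
  prot_ids <- setdiff(at$atom_id, c(unlist(top$ligand_copies),
                                    unlist(top$glycan_atoms)))
  prot <- at[match(prot_ids, at$atom_id), ]
  lig_pol <- match(lig_ids[lig$is_polar & lig$element != "H"], at$atom_id)
  lig_hvy <- match(lig_ids[lig$element != "H"], at$atom_id)
  prot_pol <- match(prot_ids[prot$is_polar], at$atom_id)
  prot_hvy <- match(prot_ids[prot$element != "H"], at$atom_id)
  da <- top$docking_atoms[[copy + 1]]
  dock_rows <- match(c(da$NH1, da$NH2, da$OT1, da$OT2), at$atom_id)
  nf <- dim(traj$coords)[1]
  d_pol <- numeric(nf); d_all <- numeric(nf); docked <- logical(nf)
  for (f in seq_len(nf)) {
    X <- traj$coords[f, , ]
    d_pol[f] <- oracle_min_dist(X[lig_pol, , drop = FALSE],
                                X[prot_pol, , drop = FALSE])
    d_all[f] <- oracle_min_dist(X[lig_hvy, , drop = FALSE],
                                X[prot_hvy, , drop = FALSE])
    dd <- function(i, j) sqrt(sum((X[dock_rows[i], ] - X[dock_rows[j], ])^2))
    docked[f] <- (dd(1, 3) <= dock && dd(2, 4) <= dock) ||
      (dd(1, 4) <= dock && dd(2, 3) <= dock)
  }
  chains <- list(); inch <- FALSE; s <- NA
  for (f in seq_len(nf)) {
    if (inch && d_all[f] > dissoc) {
      chains[[length(chains) + 1]] <- list(start = s, end = f - 2L, terminated = TRUE)
      inch <- FALSE
    }
    if (!inch && d_pol[f] <= assoc) { inch <- TRUE; s <- f - 1L }
  }
  if (inch)
    chains[[length(chains) + 1]] <- list(start = s, end = nf - 1L, terminated = FALSE)
  for (i in seq_along(chains)) {
    fr <- chains[[i]]$start:chains[[i]]$end
    chains[[i]]$docked_frames <- fr[docked[fr + 1L]]
  }
  chains
}

# minimal topology: one docking-arginine-like residue plus a serine-like
# ligand, all coordinates supplied per frame by the caller
mini_system <- function(n_extra_residues = 0) {
  rows <- data.frame(
    name = c("CA", "NH1", "NH2", "OD1"),
    element = c("C", "N", "N", "O"),
    residue_id = 518L, residue_name = "ARG", chain_id = "A"
  )
  if (n_extra_residues > 0) {
    for (i in seq_len(n_extra_residues))
      rows <- rbind(rows, data.frame(name = c("CA", "OD1"),
                                     element = c("C", "O"),
                                     residue_id = 400L + i,
                                     residue_name = "ASP", chain_id = "A"))
  }
  lig <- data.frame(
    name = c("N", "CA", "CB", "OG", "OT1", "OT2"),
    element = c("N", "C", "C", "O", "O", "O"),
    residue_id = 901L, residue_name = "SER", chain_id = "L"
  )
  atoms <- rbind(rows, lig)
  atoms$atom_id <- seq_len(nrow(atoms)) - 1L
  n <- nrow(atoms)
  lig_ids <- (n - 6):(n - 1)
  lp_topology(atoms,
              ligand_copies = list(lig_ids),
              ligand_ref_atom = lig_ids[2],
              docking_atoms = list(list(NH1 = 1L, NH2 = 2L,
                                        OT1 = lig_ids[5], OT2 = lig_ids[6])),
              box = c(60, 60, 60))
}

# trajectory over mini_system with the ligand placed at per-frame offsets
# along +x (protein fixed near the origin); gap_x is the CA x of the ligand
mini_traj <- function(gaps, n_extra_residues = 0, dt = 1) {
  top <- mini_system(n_extra_residues)
  na <- nrow(top$atoms)
  nf <- length(gaps)
  coords <- array(0, dim = c(nf, na, 3))
  # protein: CA at origin, NH1/NH2 at x=1, OD1 at (0,3,0); extras far away
  base <- matrix(0, na, 3)
  base[2, ] <- c(1, 1.1, 0)   # NH1
  base[3, ] <- c(1, -1.1, 0)  # NH2
  base[4, ] <- c(0, 3, 0)     # OD1
  if (n_extra_residues > 0)
    for (i in seq_len(n_extra_residues)) {
      base[4 + 2 * i - 1, ] <- c(-20, 5 * i, 0)
      base[4 + 2 * i, ] <- c(-20, 5 * i, 1)
    }
  lig_rows <- (na - 5):na
  lig_rel <- rbind(c(0.5, 1.3, 0.4), c(0, 0, 0), c(0.9, -1.1, 0.3),
                   c(1.9, -1.0, 1.1), c(-1.6, 1.15, 0), c(-1.6, -1.15, 0))
  for (f in seq_len(nf)) {
    coords[f, , ] <- base
    coords[f, lig_rows, ] <- sweep(lig_rel, 2, -c(gaps[f], 0, 0))
  }
  lp_trajectory(coords, top, times = (seq_len(nf) - 1) * dt)
}

# straight-line path template with Gaussian noise, for planted clustering
make_noisy_path <- function(from, to, n = 12, sd = 0.4) {
  t <- seq(0, 1, length.out = n)
  base <- outer(1 - t, from) + outer(t, to)
  base + matrix(stats::rnorm(n * 3, 0, sd), n, 3)
}
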