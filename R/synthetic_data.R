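# Synthetic-data generators: a toy two-lobed receptor, scripted
# ligand-diffusion trajectories with a ground-truth event log, and exact
# Boltzmann samples from analytic 2D potentials under harmonic umbrella
# biases. Every generator is a pure function of (parameters, seed); the
# caller's RNG state is saved and restored.
#
# The toy receptor is a point-cloud stand-in (synthetic, not derived from
# any deposited structure): two lobe "blobs" of pseudo-residues with
# backbone + sidechain atoms, a protruding docking arginine whose NH1/NH2
# tips are the only polar atoms in the docking corridor, and an optional
# glycan chain. The ligand is a serine-like rigid 6-atom body
# (N, CA, CB, OG, OT1, OT2) translated without rotation, so the polar
# (6 A), dissociation (10 A) and carboxylate-guanidinium docking (4 A)
# criteria are exercised literally.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# rigid serine-like ligand template, CA at origin, carboxylate pointing -x
.ligand_template <- function() {
  data.frame(
    name = c("N", "CA", "CB", "OG", "OT1", "OT2"),
    element = c("N", "C", "C", "O", "O", "O"),
    x = c(0.5, 0, 0.9, 1.9, -1.6, -1.6),
    y = c(1.3, 0, -1.1, -1.0, 1.15, -1.15),
    z = c(0.4, 0, 0.3, 1.1, 0, 0)
  )
}

#' Build a synthetic two-lobed toy receptor
#'
#' @param seed RNG seed (the structure is deterministic per seed)
#' @param n_residues total pseudo-residues across both lobes (>= 10),
#'   docking arginine excluded
#' @param n_copies number of ligand copies to include in the topology
#' @param lobe_radius lobe blob radius (Angstrom)
#' @param lobe_offset half-distance between lobe centers along z
#' @param box orthorhombic box (Angstrom)
#' @param with_glycan attach a glycan heavy-atom chain to the D1 lobe
#' @return list with `topology` (an [lp_topology()]; atoms carry reference
#'   x/y/z) and `anchors` (internal geometry: box center, dock/staging
#'   poses, rail templates) used by [simulate_binding()]
#' @export
make_toy_receptor <- function(seed = 1, n_residues = 40, n_copies = 4,
                              lobe_radius = 7, lobe_offset = 7,
                              box = c(140, 110, 110), with_glycan = TRUE) {
  if (n_residues < 10) stop("need at least 10 residues")
  if (lobe_radius <= 0 || lobe_offset <= 0) stop("degenerate lobe geometry")
  .with_seed(seed, {
    cc <- box / 2
    n1 <- floor(n_residues / 2); n2 <- n_residues - n1
    rows <- list()
    add_residue <- function(resid, resname, chain, ca, sidechain_polar) {
      side_el <- if (sidechain_polar) "O" else "C"
      side_nm <- if (sidechain_polar) "OD1" else "CB"
      data.frame(
        name = c("N", "CA", "C", side_nm),
        element = c("N", "C", "C", side_el),
        residue_id = resid, residue_name = resname, chain_id = chain,
        x = ca[1] + c(-1.2, 0, 0, 0), y = ca[2] + c(0, 0, 1.2, 0),
        z = ca[3] + c(0, 0, 0, 1.2)
      )
    }
    sphere_point <- function(center, radius) {
      repeat {
        p <- stats::runif(3, -1, 1)
        if (sum(p^2) <= 1) return(center + p * radius)
      }
    }
    d1_ids <- 401:(400 + n1)
    d2_ids <- 601:(600 + n2)
    for (i in seq_len(n1))
      rows[[length(rows) + 1L]] <- add_residue(
        d1_ids[i], "GLY", "A", sphere_point(cc + c(0, 0, lobe_offset), lobe_radius),
        i %% 2 == 0)
    for (i in seq_len(n2))
      rows[[length(rows) + 1L]] <- add_residue(
        d2_ids[i], "GLY", "A", sphere_point(cc - c(0, 0, lobe_offset), lobe_radius),
        i %% 2 == 0)
    # docking arginine protruding along +x; NH1/NH2 are the corridor's
    # only polar protein atoms
    arg <- data.frame(
      name = c("N", "CA", "C", "CZ", "NH1", "NH2"),
      element = c("N", "C", "C", "C", "N", "N"),
      residue_id = 518L, residue_name = "ARG", chain_id = "A",
      x = cc[1] + c(7.0, 8.0, 8.5, 10.8, 12.0, 12.0),
      y = cc[2] + c(0, 0, 1.0, 0, 1.1, -1.1),
      z = cc[3] + c(0, 0, 0, 0, 0, 0)
    )
    rows[[length(rows) + 1L]] <- arg
    glycan_rows <- NULL
    if (with_glycan) {
      ng <- 8L
      glycan_rows <- data.frame(
        name = paste0(rep(c("C", "O"), length.out = ng), seq_len(ng)),
        element = rep(c("C", "O"), length.out = ng),
        residue_id = 700L, residue_name = "MAN", chain_id = "G",
        x = cc[1] + 2 + 0.8 * seq_len(ng),
        y = cc[2] + 0.5 * sin(seq_len(ng)),
        z = cc[3] + lobe_offset + lobe_radius + 1.5 + 0.9 * seq_len(ng)
      )
      rows[[length(rows) + 1L]] <- glycan_rows
    }
    lig_t <- .ligand_template()
    lig_rows <- lapply(seq_len(n_copies), function(i) {
      data.frame(name = lig_t$name, element = lig_t$element,
                 residue_id = 900L + i, residue_name = "SER", chain_id = "L",
                 x = lig_t$x, y = lig_t$y, z = lig_t$z)
    })
    rows <- c(rows, lig_rows)
    atoms <- do.call(rbind, rows)
    atoms$atom_id <- seq_len(nrow(atoms)) - 1L
    atoms <- atoms[, c("atom_id", "name", "element", "residue_id",
                       "residue_name", "chain_id", "x", "y", "z")]
    n_lig_atoms <- nrow(lig_t)
    first_lig <- nrow(atoms) - n_copies * n_lig_atoms
    ligand_copies <- lapply(seq_len(n_copies), function(i)
      (first_lig + (i - 1L) * n_lig_atoms):(first_lig + i * n_lig_atoms - 1L))
    aid <- function(resid, nm) atoms$atom_id[atoms$residue_id == resid &
                                               atoms$name == nm][1]
    ref_atoms <- vapply(seq_len(n_copies), function(i)
      atoms$atom_id[atoms$residue_id == 900L + i & atoms$name == "CA"], integer(1))
    docking <- lapply(seq_len(n_copies), function(i) list(
      NH1 = aid(518L, "NH1"), NH2 = aid(518L, "NH2"),
      OT1 = atoms$atom_id[atoms$residue_id == 900L + i & atoms$name == "OT1"],
      OT2 = atoms$atom_id[atoms$residue_id == 900L + i & atoms$name == "OT2"]))
    glycan_atoms <- if (with_glycan)
      list(atoms$atom_id[atoms$residue_id == 700L]) else list()
    top <- lp_topology(
      atoms, ligand_copies = ligand_copies, ligand_ref_atom = ref_atoms,
      docking_atoms = docking, lobe_D1 = d1_ids, lobe_D2 = d2_ids,
      op_groups = local({
        bb <- function(rid) atoms$atom_id[atoms$residue_id == rid &
                                            atoms$name %in% c("N", "CA", "C")]
        list(xi1 = list(bb(d1_ids[1]), bb(d2_ids[1])),
             xi2 = list(bb(d1_ids[2]), bb(d2_ids[2])))
      }),
      glycan_atoms = glycan_atoms, box = box)
    # anchor poses (ligand CA positions); carboxylate points -x toward NH
    nh_mid <- cc + c(12, 0, 0)
    anchors <- list(
      center = cc,
      dock_ca = cc + c(16.35, -0.05, 0),
      assoc_ca = cc + c(19.5, 0, 1.0),
      corridor_dir = c(1, 0, 0),
      rails = local({
        # arcs hugging each lobe (~2 A above the surface) so guided
        # approaches rack up surface-residue contacts before docking
        arc <- function(sign) {
          lc <- cc + c(0, 0, sign * lobe_offset)
          r <- lobe_radius + 2
          th <- c(15, 40, 65, 90, 115) * pi / 180
          pts <- t(vapply(th, function(a)
            lc + c(r * sin(a), 0, sign * r * cos(a)), numeric(3)))
          rbind(cc + c(0, 0, sign * 28), pts,
                cc + c(17, 0, sign * 4), cc + c(19.5, 0, 1.0))
        }
        list(arc(1), arc(-1))
      }),
      nh_mid = nh_mid
    )
    list(topology = top, anchors = anchors)
  })
}

# --- scripted ligand motion -------------------------------------------------

# generator-side criterion evaluation (kept separate from detect_chains on
# purpose: the ground-truth log must not be produced by the code it checks)
.gt_scan <- function(lig_xyz_by_frame, lig_t, prot_pol, prot_hvy, nh1, nh2,
                     assoc_cutoff, dissoc_cutoff, dock_cutoff) {
  lig_pol <- which(lig_t$element %in% c("N", "O", "S"))
  nf <- length(lig_xyz_by_frame)
  d_pol <- numeric(nf); d_all <- numeric(nf); docked <- logical(nf)
  for (f in seq_len(nf)) {
    L <- lig_xyz_by_frame[[f]]
    dp <- Inf
    for (a in lig_pol)
      dp <- min(dp, min(sqrt(colSums((t(prot_pol) - L[a, ])^2))))
    da <- Inf
    for (a in seq_len(nrow(L)))
      da <- min(da, min(sqrt(colSums((t(prot_hvy) - L[a, ])^2))))
    d_pol[f] <- dp; d_all[f] <- da
    ot1 <- L[lig_t$name == "OT1", ]; ot2 <- L[lig_t$name == "OT2", ]
    c1 <- sqrt(sum((nh1 - ot1)^2)) <= dock_cutoff &&
          sqrt(sum((nh2 - ot2)^2)) <= dock_cutoff
    c2 <- sqrt(sum((nh1 - ot2)^2)) <= dock_cutoff &&
          sqrt(sum((nh2 - ot1)^2)) <= dock_cutoff
    docked[f] <- c1 || c2
  }
  # interval scan (independent re-statement of the hysteresis rule)
  starts <- integer(); ends <- integer(); terms <- logical()
  inch <- FALSE; s <- NA_integer_
  for (f in seq_len(nf)) {
    if (inch && d_all[f] > dissoc_cutoff) {
      starts <- c(starts, s); ends <- c(ends, f - 2L); terms <- c(terms, TRUE)
      inch <- FALSE
    }
    if (!inch && d_pol[f] <= assoc_cutoff) { inch <- TRUE; s <- f - 1L }
  }
  if (inch) { starts <- c(starts, s); ends <- c(ends, nf - 1L); terms <- c(terms, FALSE) }
  list(intervals = data.frame(start = starts, end = ends, terminated = terms),
       docked_frames = which(docked) - 1L, d_pol = d_pol, d_all = d_all)
}

#' Simulate ligand binding trajectories with ground truth
#'
#' Ligand copies perform reflected random walks in the box; scripted
#' approach segments bring a copy to the docking arginine so that
#' association (polar-polar <= `assoc_cutoff`) and docking (the 4 A
#' guanidinium criterion) occur along the way, with exponential
#' (memoryless) waiting times at per-site rate `kon * [L]`. In guided mode
#' each approach follows one of the receptor's surface rail templates
#' (accumulating residue contacts and defining the planted cluster
#' identity); in free mode the ligand dives straight down the docking
#' corridor, touching essentially no surface residues.
#'
#' The ground-truth log is derived from the emitted coordinates by a
#' self-contained criterion scan inside the generator (shared with no
#' detection code), so it is exact by construction.
#'
#' @param receptor result of [make_toy_receptor()]
#' @param n_frames frames per copy (> 20)
#' @param dt frame spacing (ns), default 0.2
#' @param seed RNG seed
#' @param mode "guided" or "free"
#' @param kon planted association rate constant (M^-1 s^-1); the waiting
#'   rate is `kon * [L]` with `[L]` the nominal all-copies-free box
#'   concentration. Default 1e8.
#' @param rate_per_ns optional direct per-copy association attempt rate
#'   (1/ns), overriding `kon` (useful to densify events in short test
#'   trajectories; the implied kon is logged)
#' @param p_dock probability an association proceeds to docking
#' @param dock_frames mean docked duration (frames)
#' @param step_sd bulk random-walk step standard deviation (Angstrom)
#' @param assoc_cutoff,dissoc_cutoff,dock_cutoff criterion cutoffs
#' @return list with `trajectory` (an [lp_trajectory()]) and `log`
#'   (class `lp_ground_truth`): per-copy `intervals`
#'   (start/end/terminated), `docked_frames`, `template` (planted rail id
#'   per chain, NA for free mode/failed chains), plus `kon_planted`,
#'   `rate_per_ns`, `concentration_M`, `mode`
#' @export
simulate_binding <- function(receptor, n_frames = 400, dt = 0.2, seed = 1,
                             mode = c("guided", "free"), kon = 1e8,
                             rate_per_ns = NULL, p_dock = 0.7,
                             dock_frames = 12, step_sd = 1.5,
                             assoc_cutoff = 6, dissoc_cutoff = 10,
                             dock_cutoff = 4) {
  mode <- match.arg(mode)
  top <- receptor$topology
  anc <- receptor$anchors
  n_copies <- length(top$ligand_copies)
  box <- top$box
  if (n_frames <= 20) stop("n_frames must exceed 20")
  if (prod(box) < 1e4 * n_copies) stop("box too small for this many copies")
  lig_t <- .ligand_template()
  at <- top$atoms
  prot_ids <- .protein_atom_ids(top)
  prot_rows <- .atom_rows(top, prot_ids)
  prot_hvy <- as.matrix(at[prot_rows[at$element[prot_rows] != "H"],
                           c("x", "y", "z")])
  prot_pol <- as.matrix(at[prot_rows[at$is_polar[prot_rows]], c("x", "y", "z")])
  nh1 <- as.numeric(at[at$residue_id == 518L & at$name == "NH1", c("x", "y", "z")])
  nh2 <- as.numeric(at[at$residue_id == 518L & at$name == "NH2", c("x", "y", "z")])
  nh_mid <- (nh1 + nh2) / 2

  conc <- n_copies / (.NA_AVOGADRO * prod(box) * 1e-27)
  if (is.null(rate_per_ns)) rate_per_ns <- kon * conc * 1e-9
  kon_planted <- rate_per_ns / (conc * 1e-9)

  min_prot <- function(p) {
    # min distance of any ligand heavy atom (body at CA position p) to protein
    L <- sweep(as.matrix(lig_t[, c("x", "y", "z")]), 2, -p)
    min(sqrt(.cross_dist2(L, prot_hvy)))
  }
  ot_nh <- function(p) {
    ot1 <- p + as.numeric(lig_t[lig_t$name == "OT1", c("x", "y", "z")])
    ot2 <- p + as.numeric(lig_t[lig_t$name == "OT2", c("x", "y", "z")])
    min(sqrt(sum((ot1 - nh1)^2)), sqrt(sum((ot1 - nh2)^2)),
        sqrt(sum((ot2 - nh1)^2)), sqrt(sum((ot2 - nh2)^2)))
  }
  clamp_box <- function(p) pmin(pmax(p, 3), box - 3)
  push_out <- function(p, target) {
    # move radially from the box center until min protein distance > target
    dirv <- p - anc$center
    nrm <- sqrt(sum(dirv^2)); if (nrm < 1e-6) dirv <- c(1, 0, 0) else dirv <- dirv / nrm
    while (min_prot(p) <= target) p <- clamp_box(p + dirv * 1.0)
    p
  }
  away_from_dock <- function(p, floor_d = 4.5) {
    while (ot_nh(p) < floor_d) p <- p + c(0.4, 0, 0.4)
    p
  }

  .with_seed(seed, {
    coords <- array(NA_real_, dim = c(n_frames, nrow(at), 3))
    # protein and glycan are static
    static_rows <- setdiff(seq_len(nrow(at)), .atom_rows(top, .ligand_atom_ids(top)))
    for (k in 1:3) coords[, static_rows, k] <-
      matrix(at[[c("x", "y", "z")[k]]][static_rows], n_frames,
             length(static_rows), byrow = TRUE)

    per_copy <- vector("list", n_copies)
    for (cp in seq_len(n_copies)) {
      pos <- matrix(NA_real_, n_frames, 3)
      template_of_chain <- integer()
      f <- 1L
      # start well out in bulk
      cur <- clamp_box(anc$center +
                         c(stats::runif(1, -40, 40), stats::runif(1, -35, 35),
                           stats::runif(1, -35, 35)))
      cur <- push_out(cur, 13)
      while (f <= n_frames) {
        # --- bulk waiting ---
        wait_ns <- stats::rexp(1, rate = rate_per_ns)
        n_wait <- max(1L, ceiling(wait_ns / dt))
        for (i in seq_len(n_wait)) {
          if (f > n_frames) break
          ok <- FALSE
          for (try in 1:25) {
            cand <- clamp_box(cur + stats::rnorm(3, 0, step_sd))
            if (min_prot(cand) > 12) { cur <- cand; ok <- TRUE; break }
          }
          if (!ok) cur <- push_out(cur, 12)
          pos[f, ] <- cur; f <- f + 1L
        }
        if (f > n_frames) break
        # --- approach ---
        tmpl <- NA_integer_
        if (mode == "guided") {
          tmpl <- sample.int(length(anc$rails), 1)
          rail <- anc$rails[[tmpl]]
          # walk the rail with small jitter
          wp <- rail
          n_app <- nrow(wp)
          for (i in seq_len(n_app)) {
            if (f > n_frames) break
            p <- wp[i, ] + stats::rnorm(3, 0, 0.5)
            p <- away_from_dock(p)
            pos[f, ] <- p; cur <- p; f <- f + 1L
          }
        } else {
          # straight dive down the +x corridor
          start <- anc$center + c(30, stats::rnorm(1, 0, 1.5), stats::rnorm(1, 0, 1.5))
          targets <- rbind(start, anc$center + c(25, 0, 0.5), anc$assoc_ca)
          for (i in seq_len(nrow(targets))) {
            if (f > n_frames) break
            p <- targets[i, ] + stats::rnorm(3, 0, 0.3)
            p <- away_from_dock(p)
            pos[f, ] <- p; cur <- p; f <- f + 1L
          }
        }
        if (f > n_frames) break
        # --- associated, pre-dock wiggle ---
        n_pre <- sample(2:5, 1)
        for (i in seq_len(n_pre)) {
          if (f > n_frames) break
          ok <- FALSE
          for (try in 1:25) {
            cand <- anc$assoc_ca + stats::rnorm(3, 0, 0.6)
            if (min_prot(cand) <= 9 && ot_nh(cand) >= 4.4) {
              cur <- cand; ok <- TRUE; break
            }
          }
          if (!ok) cur <- anc$assoc_ca
          pos[f, ] <- cur; f <- f + 1L
        }
        if (f > n_frames) break
        # --- dock (with probability p_dock) ---
        if (stats::runif(1) < p_dock) {
          n_dock <- max(2L, stats::rpois(1, dock_frames))
          for (i in seq_len(n_dock)) {
            if (f > n_frames) break
            cand <- anc$dock_ca + stats::rnorm(3, 0, 0.1)
            pos[f, ] <- cand; cur <- cand; f <- f + 1L
          }
          template_of_chain <- c(template_of_chain, tmpl)
        } else {
          template_of_chain <- c(template_of_chain, NA_integer_)
        }
        if (f > n_frames) break
        # --- leave to bulk ---
        leave <- rbind(anc$assoc_ca + c(1, 0, 0.5),
                       anc$center + c(24, 1, 2),
                       anc$center + c(30, 2, 4))
        for (i in seq_len(nrow(leave))) {
          if (f > n_frames) break
          p <- away_from_dock(leave[i, ] + stats::rnorm(3, 0, 0.3))
          pos[f, ] <- p; cur <- p; f <- f + 1L
        }
        cur <- push_out(cur, 13)
      }
      # materialize ligand atoms
      lig_rows <- .atom_rows(top, top$ligand_copies[[cp]])
      lig_xyz <- vector("list", n_frames)
      for (fr in seq_len(n_frames)) {
        L <- sweep(as.matrix(lig_t[, c("x", "y", "z")]), 2, -pos[fr, ])
        coords[fr, lig_rows, ] <- L
        lig_xyz[[fr]] <- L
      }
      scan <- .gt_scan(lig_xyz, lig_t, prot_pol, prot_hvy, nh1, nh2,
                       assoc_cutoff, dissoc_cutoff, dock_cutoff)
      # attach planted templates to chains that actually docked
      docked_chain <- vapply(seq_len(nrow(scan$intervals)), function(i)
        any(scan$docked_frames >= scan$intervals$start[i] &
              scan$docked_frames <= scan$intervals$end[i]), logical(1))
      tm <- rep(NA_integer_, nrow(scan$intervals))
      tmpl_seq <- template_of_chain[!is.na(template_of_chain)]
      if (length(tmpl_seq) > 0 && any(docked_chain))
        tm[which(docked_chain)] <- tmpl_seq[seq_len(sum(docked_chain))]
      per_copy[[cp]] <- list(intervals = scan$intervals,
                             docked_frames = scan$docked_frames,
                             template = tm)
    }
    traj <- lp_trajectory(coords, top, times = (seq_len(n_frames) - 1L) * dt)
    log <- structure(list(copies = per_copy, kon_planted = kon_planted,
                          rate_per_ns = rate_per_ns, concentration_M = conc,
                          mode = mode, dt = dt, seed = seed),
                     class = "lp_ground_truth")
    list(trajectory = traj, log = log)
  })
}

#' @export
print.lp_ground_truth <- function(x, ...) {
  n_chain <- sum(vapply(x$copies, function(cp) nrow(cp$intervals), integer(1)))
  cat(sprintf("<lp_ground_truth> %d copies, %d chains, mode=%s, kon=%.3g\n",
              length(x$copies), n_chain, x$mode, x$kon_planted))
  invisible(x)
}

#' Analytic 2D double-well potential factory
#'
#' `U(x1, x2) = barrier ((x1 - m)^2 / hw^2 - 1)^2 + k2 (x2 - c2)^2`,
#' with minima of 0 at `x1 = m -+ hw` and a saddle of height `barrier`
#' at `x1 = m`. Non-negative everywhere, as [sample_umbrella()] requires.
#'
#' @param barrier saddle height (kcal/mol), default 2
#' @param minima numeric(2) x1 positions of the wells
#' @param x2_center,x2_k transverse harmonic confinement
#' @return function `U(x)` accepting an `n x 2` matrix or length-2 vector
#' @export
make_double_well <- function(barrier = 2, minima = c(13, 16), x2_center = 12,
                             x2_k = 1) {
  m <- mean(minima); hw <- diff(minima) / 2
  function(x) {
    x <- matrix(as.numeric(x), ncol = 2)
    barrier * ((x[, 1] - m)^2 / hw^2 - 1)^2 + x2_k * (x[, 2] - x2_center)^2
  }
}

#' Exact Boltzmann samples from an analytic potential under umbrella biases
#'
#' Rejection sampling of `exp(-(U + bias)/kT)` per window with a uniform
#' proposal over a window-local bounding box and an envelope certified on
#' a fine grid: proposals are accepted with probability `W(x) / M` where
#' `W = exp(-(U + bias)/kT)` and `M` is 1.05 times the grid maximum of
#' `W`. The box spans `span_sd` bias standard deviations around the
#' center, outside which the biased density is negligible (the implied
#' support truncation mirrors the flat-bottom restraint used to keep
#' umbrella simulations near their window). Deterministic per seed.
#'
#' @param potential function of an `n x 2` matrix returning kcal/mol
#' @param centers `m x 2` matrix of window centers
#' @param k harmonic force constant per axis (kcal/mol/A^2), default 2
#' @param n_per_window samples per window
#' @param temperature K, default 300
#' @param seed RNG seed
#' @param span_sd half-width of the proposal box in units of the bias
#'   standard deviation `sqrt(kT/k)`, default 8
#' @param grid_n envelope-certification grid resolution per axis
#' @return list of [umbrella_window()]s, deterministic per seed
#' @export
sample_umbrella <- function(potential, centers, k = 2, n_per_window = 2000,
                            temperature = 300, seed = 1, span_sd = 8,
                            grid_n = 201) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  kT <- .kB * temperature
  span <- span_sd * sqrt(kT / k)
  weight <- function(x, ctr) {
    bias <- 0.5 * k * (x[, 1] - ctr[1])^2 + 0.5 * k * (x[, 2] - ctr[2])^2
    exp(-(potential(x) + bias) / kT)
  }
  .with_seed(seed, {
    lapply(seq_len(nrow(centers)), function(w) {
      ctr <- centers[w, ]
      g <- seq(-span, span, length.out = grid_n)
      gx <- as.matrix(expand.grid(ctr[1] + g, ctr[2] + g))
      M <- 1.05 * max(weight(gx, ctr))
      if (!is.finite(M) || M <= 0)
        stop("biased density vanishes on the window support; ",
             "check the potential")
      out <- matrix(NA_real_, 0, 2)
      tried <- 0
      while (nrow(out) < n_per_window) {
        m <- max(2000L, 2L * (n_per_window - nrow(out)))
        prop <- cbind(stats::runif(m, ctr[1] - span, ctr[1] + span),
                      stats::runif(m, ctr[2] - span, ctr[2] + span))
        acc <- stats::runif(m) < weight(prop, ctr) / M
        out <- rbind(out, prop[acc, , drop = FALSE])
        tried <- tried + m
        if (tried > 10000 && nrow(out) / tried < 1e-4)
          stop("rejection acceptance below 1e-4; narrow the sampling support")
      }
      umbrella_window(ctr, k, out[seq_len(n_per_window), , drop = FALSE],
                      temperature)
    })
  })
}
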