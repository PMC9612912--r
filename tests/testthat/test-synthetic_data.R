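test_that("toy receptor construction is deterministic and well-formed", {
  r1 <- make_toy_receptor(seed = 17, n_residues = 26, n_copies = 2)
  r2 <- make_toy_receptor(seed = 17, n_residues = 26, n_copies = 2)
  expect_identical(r1$topology$atoms, r2$topology$atoms)
  r3 <- make_toy_receptor(seed = 18, n_residues = 26, n_copies = 2)
  expect_false(identical(r1$topology$atoms$x, r3$topology$atoms$x))
  top <- r1$topology
  # docking atoms resolvable and of the right names
  da <- top$docking_atoms[[1]]
  nm <- top$atoms$name[match(unlist(da[c("NH1", "NH2", "OT1", "OT2")]),
                             top$atoms$atom_id)]
  expect_equal(nm, c("NH1", "NH2", "OT1", "OT2"))
  expect_length(resolve_selection(top, "residue 518 names NH1 NH2"), 2)
  # ligand and protein atom sets disjoint
  expect_length(intersect(unlist(top$ligand_copies),
                          resolve_selection(top, "protein")), 0)
  # glycan toggle
  r_no <- make_toy_receptor(seed = 17, n_residues = 26, with_glycan = FALSE)
  expect_length(r_no$topology$glycan_atoms, 0)
  expect_error(make_toy_receptor(seed = 1, n_residues = 4), "at least 10")
  expect_error(make_toy_receptor(seed = 1, lobe_radius = -1), "degenerate")
})

test_that("simulate_binding is deterministic and leaves the RNG state alone", {
  rec <- make_toy_receptor(seed = 2, n_residues = 24, n_copies = 2)
  set.seed(999); before <- runif(1)
  set.seed(999)
  s1 <- simulate_binding(rec, n_frames = 120, seed = 5, rate_per_ns = 0.05)
  after <- runif(1)
  expect_equal(after, before)  # generator restored the caller's RNG stream
  s2 <- simulate_binding(rec, n_frames = 120, seed = 5, rate_per_ns = 0.05)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  expect_identical(s1$log$copies, s2$log$copies)
  expect_error(simulate_binding(rec, n_frames = 10, seed = 1), "exceed")
})

test_that("ground-truth log agrees with detection on fresh seeds", {
  rec <- make_toy_receptor(seed = 4, n_residues = 30, n_copies = 2)
  for (s in c(23, 24)) {
    sim <- simulate_binding(rec, n_frames = 250, seed = s, rate_per_ns = 0.06)
    for (cp in 0:1) {
      chains <- detect_chains(sim$trajectory, cp)
      gt <- sim$log$copies[[cp + 1]]
      expect_equal(length(chains), nrow(gt$intervals))
      for (i in seq_along(chains)) {
        expect_equal(chains[[i]]$start_frame, gt$intervals$start[i])
        expect_equal(chains[[i]]$end_frame, gt$intervals$end[i])
        expect_equal(chains[[i]]$terminated, gt$intervals$terminated[i])
      }
      got_dock <- sort(unlist(lapply(chains, `[[`, "docked_frames")))
      expect_equal(got_dock, sort(gt$docked_frames), ignore_attr = TRUE)
    }
  }
})

test_that("free-mode pathways are overwhelmingly unguided", {
  rec <- make_toy_receptor(seed = 4, n_residues = 30, n_copies = 3)
  labs <- character()
  for (s in 31:33) {
    sim <- simulate_binding(rec, n_frames = 300, seed = s, mode = "free",
                            rate_per_ns = 0.06)
    for (cp in 0:2) for (ch in detect_chains(sim$trajectory, cp))
      for (p in split_chain(ch, sim$trajectory))
        if (p$direction == "binding")
          labs <- c(labs, as.character(classify_mechanism(p,
                                                          exclude_residues = 518L)))
  }
  expect_gt(length(labs), 3)
  expect_gte(mean(labs == "free"), 0.9)
})

test_that("umbrella sampler matches closed-form Gaussians", {
  # U = 0: samples are exactly N(center, kT/k)
  kT <- 0.0019872041 * 300
  w0 <- sample_umbrella(function(x) rep(0, nrow(matrix(x, ncol = 2))),
                        centers = rbind(c(2, 3)), k = 2, n_per_window = 20000,
                        seed = 41)[[1]]
  expect_equal(colMeans(w0$samples), c(2, 3), tolerance = 0.02)
  expect_equal(apply(w0$samples, 2, var), rep(kT / 2, 2), tolerance = 0.03)
  # quadratic U + harmonic bias: biased minimum at (k c + 2a m)/(k + 2a)
  a <- 1.5; m <- 5
  Uq <- function(x) { x <- matrix(x, ncol = 2); a * (x[, 1] - m)^2 + a * (x[, 2] - m)^2 }
  wq <- sample_umbrella(Uq, rbind(c(7, 7)), k = 2, n_per_window = 20000,
                        seed = 42)[[1]]
  mu <- (2 * 7 + 2 * a * m) / (2 + 2 * a)
  expect_equal(colMeans(wq$samples), c(mu, mu), tolerance = 0.02)
  # determinism
  wq2 <- sample_umbrella(Uq, rbind(c(7, 7)), k = 2, n_per_window = 20000,
                         seed = 42)[[1]]
  expect_identical(wq$samples, wq2$samples)
  # a potential that kills the density everywhere is an error
  expect_error(sample_umbrella(function(x) rep(Inf, nrow(matrix(x, ncol = 2))),
                               rbind(c(0, 0)), n_per_window = 10, seed = 1),
               "vanishes")
})

test_that("trajectories round-trip through the PDB and DCD writers", {
  rec <- make_toy_receptor(seed = 9, n_residues = 24, n_copies = 1)
  sim <- simulate_binding(rec, n_frames = 60, seed = 3, rate_per_ns = 0.08)
  tmp <- withr::local_tempdir()
  dcd <- file.path(tmp, "t.dcd")
  write_dcd(sim$trajectory, dcd, dt = 0.2)
  rt <- read_dcd(dcd)
  expect_equal(rt$coords, sim$trajectory$coords, tolerance = 1e-5)
  expect_equal(rt$box, rec$topology$box)
  expect_equal(rt$dt, 0.2, tolerance = 1e-7)
  # multi-model PDB holds coordinates to format precision (1e-3 A)
  pdb <- file.path(tmp, "t.pdb")
  write_pdb(sim$trajectory, pdb)
  rp <- read_pdb(pdb)
  expect_equal(dim(rp$coords), dim(sim$trajectory$coords))
  expect_lt(max(abs(rp$coords - sim$trajectory$coords)), 5.1e-4)
  # chains detected on the round-tripped coordinates agree exactly
  traj2 <- lp_trajectory(rt$coords, rec$topology, times = sim$trajectory$times)
  c_orig <- detect_chains(sim$trajectory, 0)
  c_rt <- detect_chains(traj2, 0)
  expect_equal(lapply(c_rt, `[[`, "frames"), lapply(c_orig, `[[`, "frames"))
})
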