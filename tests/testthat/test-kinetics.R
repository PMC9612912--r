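# helper: fabricate a chain object for state bookkeeping tests
fake_chain <- function(start, end, docked = integer(), terminated = TRUE) {
  structure(list(ligand_copy = 0L, chain_id = 0L, start_frame = start,
                 end_frame = end, frames = start:end, docked_frames = docked,
                 per_frame_contacts = rep(list(integer()), end - start + 1),
                 terminated = terminated), class = "lp_chain")
}

dummy_traj <- function(n_frames, dt = 1) {
  top <- mini_system()
  lp_trajectory(array(0, c(n_frames, nrow(top$atoms), 3)), top,
                times = (seq_len(n_frames) - 1) * dt)
}

test_that("bulk time is total minus associated time", {
  traj <- dummy_traj(1000, dt = 1)  # 1 us
  expect_equal(bulk_time(traj, 0, chains = list()), 1e-6)
  ch <- list(fake_chain(100, 399))  # 300 frames associated
  expect_equal(bulk_time(traj, 0, chains = ch), 7e-7)
  st <- state_series(traj, 0, chains = list(fake_chain(0, 9, docked = 5:9)))
  expect_equal(sum(st == "DOCKED"), 5)
  expect_equal(sum(st == "ASSOCIATED"), 5)
  expect_equal(sum(st == "BULK"), 990)
})

test_that("free concentration follows N / (NA V)", {
  rec <- make_toy_receptor(seed = 2, n_residues = 20, n_copies = 10,
                           box = c(140, 110, 110))
  traj <- lp_trajectory(
    array(rep(as.matrix(rec$topology$atoms[, c("x", "y", "z")]), each = 2),
          c(2, nrow(rec$topology$atoms), 3)),
    rec$topology, times = c(0, 1))
  states <- replicate(10, rep("BULK", 2), simplify = FALSE)
  conc <- free_concentration(traj, states = states)
  expect_equal(conc, 10 / (6.02214076e23 * prod(c(140, 110, 110)) * 1e-27),
               tolerance = 1e-12)
  expect_equal(conc, 0.0098, tolerance = 0.01)
  # doubling the box volume halves the concentration
  rec2 <- make_toy_receptor(seed = 2, n_residues = 20, n_copies = 10,
                            box = c(280, 110, 110))
  traj2 <- lp_trajectory(traj$coords, rec2$topology, times = c(0, 1))
  expect_equal(free_concentration(traj2, states = states), conc / 2)
  # no free copies: 0 M with a warning
  states0 <- replicate(10, rep("DOCKED", 2), simplify = FALSE)
  expect_warning(c0 <- free_concentration(traj, states = states0), "kon undefined")
  expect_equal(c0, 0)
})

test_that("kon_estimate substitutes directly into the rate equation", {
  inp <- kinetics_input(residence_ns = c(150, 200), bulk_times_s = 1e-6,
                        concentrations_M = 0.01, sites = 1)
  k <- kon_estimate(inp, residence_thresholds = 0)
  expect_equal(k$kon, 2 / (1e-6 * 0.01))
  expect_equal(k$kon, 2e8)
  # residence filtering: {3, 56, 131, 236} ns at >100 ns keeps 2
  inp2 <- kinetics_input(c(3, 56, 131, 236), 1e-6, 0.01)
  k2 <- kon_estimate(inp2, residence_thresholds = c(0, 100))
  expect_equal(k2$n_b, c(4L, 2L))
  expect_equal(k2$kon[2], 2e8)
  expect_error(kon_estimate(kinetics_input(1, 0, 0.01)), "denominator")
  expect_warning(kon_estimate(inp2, residence_thresholds = 500), "survive")
})

test_that("raising the residence threshold never raises the estimate", {
  set.seed(81)
  for (i in 1:20) {
    inp <- kinetics_input(rexp(50, 1 / 80), bulk_times_s = runif(3, 1e-7, 1e-6),
                          concentrations_M = runif(3, 0.005, 0.02))
    ks <- kon_estimate(inp, residence_thresholds = c(0, 25, 50, 100, 200))
    expect_true(all(diff(ks$kon) <= 0))
  }
})

test_that("kon is additive under trajectory concatenation", {
  set.seed(91)
  r1 <- rexp(40, 1 / 120); r2 <- rexp(60, 1 / 120)
  t1 <- runif(2, 1e-7, 5e-7); t2 <- runif(3, 1e-7, 5e-7)
  L <- 0.0098
  ka <- kon_estimate(kinetics_input(r1, t1, L), 0)
  kb <- kon_estimate(kinetics_input(r2, t2, L), 0)
  kab <- kon_estimate(kinetics_input(c(r1, r2), c(t1, t2), L), 0)
  expect_equal(kab$kon,
               (ka$n_b + kb$n_b) / (attr(ka, "denominator") + attr(kb, "denominator")))
})

test_that("the estimator recovers a planted memoryless kon", {
  # event-level simulation of the P + L -> PL_assoc process: per-site
  # association is a Poisson process with rate kon * L, so bulk waiting
  # times are Exp(kon * L)
  kon_true <- 1e8; L <- 0.0098
  set.seed(101)
  waits <- rexp(1200, rate = kon_true * L)
  inp <- kinetics_input(residence_ns = rep(150, 1200),
                        bulk_times_s = sum(waits), concentrations_M = L)
  est <- kon_estimate(inp, 0)$kon
  expect_lt(abs(est - kon_true) / kon_true, 0.10)
})

test_that("kon_from_trajectory wires detection into the estimator", {
  rec <- make_toy_receptor(seed = 6, n_residues = 30, n_copies = 3)
  sim <- simulate_binding(rec, n_frames = 300, dt = 0.2, seed = 13,
                          mode = "free", rate_per_ns = 0.05)
  res <- kon_from_trajectory(sim$trajectory, count = "all",
                             residence_thresholds = 0)
  expect_equal(res$kon$n_b, nrow(res$events))
  # conservation: bulk + associated frames = copies x frames
  states <- lapply(0:2, function(cp) state_series(sim$trajectory, cp))
  expect_equal(sum(vapply(states, length, integer(1))), 3 * 300)
  expect_equal(sum(unlist(states) == "BULK") +
                 sum(unlist(states) != "BULK"), 900)
})
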