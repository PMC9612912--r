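kB <- 0.0019872041

test_that("histogram PMF recovers a harmonic well from exact samples", {
  # U(x) = kappa/2 x^2 sampled exactly: x ~ N(0, kT/kappa)
  kappa <- 1; Temp <- 300; kT <- kB * Temp
  set.seed(121)
  x <- rnorm(2e5, 0, sqrt(kT / kappa))
  pmf <- histogram_pmf(x, bin_width = 0.2, temperature = Temp)
  sel <- is.finite(pmf$F) & pmf$F < 3
  analytic <- 0.5 * kappa * pmf$mids[[1]]^2
  analytic <- analytic - min(analytic[sel])
  rms <- sqrt(mean((pmf$F[sel] - analytic[sel])^2))
  expect_lt(rms, 0.1)
  # min-zero gauge
  expect_equal(min(pmf$F[is.finite(pmf$F)]), 0)
  expect_true(all(pmf$std[sel] >= 0, na.rm = TRUE))
})

test_that("uniform samples give a flat PMF within block noise", {
  set.seed(131)
  x <- runif(1e5, 0, 5)
  pmf <- histogram_pmf(x, bin_width = 0.2, temperature = 300)
  sel <- is.finite(pmf$F) & !is.na(pmf$std)
  dev <- pmf$F[sel] - mean(pmf$F[sel])
  expect_true(all(abs(dev) <= 3 * pmf$std[sel] + 1e-12))
})

test_that("degenerate histograms behave", {
  p1 <- histogram_pmf(3.0, bin_width = 0.2, temperature = 300, n_blocks = 1)
  expect_equal(sum(is.finite(p1$F)), 1)
  expect_equal(p1$F[is.finite(p1$F)], 0)
  expect_error(histogram_pmf(numeric(0)), "empty")
  expect_error(histogram_pmf(1:5, bin_width = -1), "positive")
})

test_that("single-window WHAM reduces to the (re)weighted histogram", {
  set.seed(141)
  # negligible bias: WHAM equals plain -kT ln(counts)
  samples <- cbind(rnorm(4000, 14, 0.6), rnorm(4000, 12, 0.6))
  w <- umbrella_window(c(14, 12), k = 1e-9, samples = samples)
  pmf <- wham2d(list(w), bin_width = 0.25, n_blocks = 2)
  counts <- pmf$occupancy
  kT <- kB * 300
  Fref <- ifelse(counts > 0, -kT * log(counts), Inf)
  Fref <- Fref - min(Fref[counts > 0])
  expect_equal(pmf$F[counts > 0], Fref[counts > 0], tolerance = 1e-6)
  # finite bias: single-window closed form F = -kT ln n_i - bias (min-zeroed)
  wb <- umbrella_window(c(14, 12), k = 2, samples = samples)
  pmfb <- wham2d(list(wb), bin_width = 0.25, n_blocks = 2)
  cb <- pmfb$occupancy
  b1 <- pmfb$mids[[1]]; b2 <- pmfb$mids[[2]]
  bias <- outer(0.5 * 2 * (b1 - 14)^2, 0.5 * 2 * (b2 - 12)^2, "+")
  Fb <- ifelse(cb > 0, -kT * log(cb) - bias, Inf)
  Fb <- Fb - min(Fb[cb > 0])
  expect_equal(pmfb$F[cb > 0], Fb[cb > 0], tolerance = 1e-5)
})

test_that("WHAM recovers an analytic double-well barrier and is gauge invariant", {
  U <- make_double_well(barrier = 2, minima = c(13, 16), x2_center = 12, x2_k = 1)
  centers <- as.matrix(expand.grid(seq(12, 17, 0.5), seq(11, 13, 1)))
  wins <- sample_umbrella(U, centers, k = 2, n_per_window = 3000, seed = 151)
  pmf <- wham2d(wins, bin_width = 0.25, n_blocks = 5)
  kT <- kB * 300
  # marginalize out the transverse axis, then measure the x1 barrier
  marg <- function(p) {
    w <- exp(-p$F / kT); w[!is.finite(p$F)] <- 0
    F1 <- -kT * log(rowSums(w))
    F1 - min(F1, na.rm = TRUE)
  }
  F1 <- marg(pmf)
  m1 <- pmf$mids[[1]]
  barrier <- F1[which.min(abs(m1 - 14.5))] -
    min(F1[m1 < 14], F1[m1 > 15])
  expect_lt(abs(barrier - 2), 0.15)
  # both minima sit near the planted wells
  expect_lt(abs(m1[which.min(F1[m1 < 14.5])] - 13), 0.5)
  # gauge invariance: constant shift of the initial window constants
  pmf2 <- wham2d(wins, bin_width = 0.25, n_blocks = 5,
                 f_init = rep(3.7, length(wins)))
  expect_equal(pmf2$F[is.finite(pmf$F)], pmf$F[is.finite(pmf$F)],
               tolerance = 1e-4)
})

test_that("disconnected windows trigger the overlap warning", {
  set.seed(161)
  w1 <- umbrella_window(c(0, 0), 2, cbind(rnorm(200, 0, 0.3), rnorm(200, 0, 0.3)))
  w2 <- umbrella_window(c(50, 50), 2, cbind(rnorm(200, 50, 0.3), rnorm(200, 50, 0.3)))
  expect_warning(wham2d(list(w1, w2), bin_width = 0.5, n_blocks = 2),
                 "disconnected")
})

test_that("low-energy conformer extraction respects the threshold", {
  # constructed two-basin grid: basins at 0 and 0.8, barrier at 2.5
  edges <- seq(0, 5, 1)
  F <- c(0, 2.5, 0.8, 3, 4)
  pmf <- structure(list(edges = list(edges), mids = list(edges[-6] + 0.5),
                        F = F, std = rep(0.1, 5), occupancy = rep(10, 5),
                        temperature = 300, kT = kB * 300, ndim = 1L),
                   class = "lp_pmf")
  vals <- c(0.5, 1.5, 2.5, 3.5, 4.5, 0.2)
  expect_equal(low_energy_conformers(pmf, vals, threshold = 0), c(0L, 5L))
  expect_equal(low_energy_conformers(pmf, vals, threshold = 1), c(0L, 2L, 5L))
  expect_equal(low_energy_conformers(pmf, vals, threshold = 4), 0:5)
  expect_warning(low_energy_conformers(pmf, 10, threshold = 0.5), "no frames")
})

test_that("conditional PMFs stratify by the closure predicate", {
  set.seed(171)
  n <- 6000
  xi <- runif(n, 10, 20)
  closed <- xi < 15
  # plant the correlation: glycan distance small iff the clamshell is closed
  g <- ifelse(closed, rnorm(n, 6, 0.5), rnorm(n, 14, 0.8))
  cp <- conditional_pmf(g, closed, "xi12 < 15", bin_width = 0.2,
                        temperature = 310)
  min_closed <- cp$satisfied$mids[[1]][which.min(cp$satisfied$F)]
  min_open <- cp$failed$mids[[1]][which.min(cp$failed$F)]
  expect_lt(min_closed, min_open)
  # swapped predicate swaps the strata
  cp_swap <- conditional_pmf(g, !closed, "xi12 >= 15", bin_width = 0.2,
                             temperature = 310)
  expect_equal(cp_swap$satisfied$F, cp$failed$F)
  expect_equal(cp_swap$failed$F, cp$satisfied$F)
  # all-true condition: stratum equals the unconditioned PMF
  expect_warning(cp_all <- conditional_pmf(g, rep(TRUE, n), "always",
                                           bin_width = 0.2, temperature = 310),
                 "empty stratum")
  ref <- histogram_pmf(g, bin_width = 0.2, temperature = 310)
  expect_equal(cp_all$satisfied$F, ref$F)
  expect_null(cp_all$failed)
})
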