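# Free-energy surfaces: direct Boltzmann inversion of histograms along a
# 1D order parameter, self-consistent 2D WHAM unbiasing of harmonic
# umbrella windows, block-averaged uncertainties, and extraction of
# low-energy conformers.
#
# All PMFs are reported min-zeroed in kcal/mol: free energies are defined
# up to an additive constant, and anchoring the sampled minimum at zero is
# the gauge fix used throughout. Unsampled bins are +Inf, never zero.

# bin edges covering the data, aligned to multiples of the bin width
.make_edges <- function(values, width, support = NULL) {
  if (width <= 0) stop("bin width must be positive")
  if (is.null(support)) support <- range(values)
  lo <- floor(support[1] / width) * width
  hi <- ceiling(support[2] / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi + width / 2, by = width)
}

.bin_of <- function(values, edges) {
  b <- findInterval(values, edges, rightmost.closed = TRUE)
  b[b < 1 | b >= length(edges)] <- NA_integer_
  b
}

.counts_1d <- function(values, edges) {
  b <- .bin_of(values, edges)
  tabulate(b[!is.na(b)], nbins = length(edges) - 1L)
}

# -kT ln(counts), min-zeroed over sampled bins
.invert_counts <- function(counts, kT) {
  F <- rep(Inf, length(counts))
  s <- counts > 0
  F[s] <- -kT * log(counts[s])
  F - min(F[s])
}

.new_pmf <- function(edges, F, std, occupancy, temperature, ndim) {
  mids <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(list(edges = edges, mids = mids, F = F, std = std,
                 occupancy = occupancy, temperature = temperature,
                 kT = .kB * temperature, ndim = ndim),
            class = "lp_pmf")
}

#' @export
print.lp_pmf <- function(x, ...) {
  Fs <- x$F[is.finite(x$F)]
  cat(sprintf("<lp_pmf> %dD, %s bins (%d sampled), F in [0, %.3g] kcal/mol, %g K\n",
              x$ndim, paste(vapply(x$edges, function(e) length(e) - 1L, 1L),
                            collapse = " x "),
              length(Fs), max(Fs), x$temperature))
  invisible(x)
}

#' Histogram potential of mean force along a 1D order parameter
#'
#' `F(bin) = -kT ln p(bin)`, min-zeroed. Uncertainties come from block
#' averaging: the series is split into `n_blocks` contiguous blocks, a PMF
#' is computed per block and gauge-aligned to the full PMF by its mean
#' offset over shared bins, and the per-bin standard deviation is taken
#' over the blocks; blocks in which a bin is unsampled are omitted from
#' that bin's error (relevant only in sparsely visited tails).
#'
#' @param values time-ordered order-parameter series (Angstrom)
#' @param bin_width default 0.2 Angstrom
#' @param temperature K (default 310, the equilibrium-trajectory
#'   convention)
#' @param n_blocks default 5
#' @param support optional c(lo, hi) histogram support
#' @return an `lp_pmf` (fields `edges`, `mids`, `F`, `std`, `occupancy`,
#'   `kT`); unsampled bins have `F = Inf` and `std = NA`
#' @export
histogram_pmf <- function(values, bin_width = 0.2, temperature = 310,
                          n_blocks = 5, support = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty order-parameter series")
  edges <- .make_edges(values, bin_width, support)
  counts <- .counts_1d(values, edges)
  kT <- .kB * temperature
  F <- .invert_counts(counts, kT)
  nb <- min(n_blocks, length(values))
  block_id <- ceiling(seq_along(values) / (length(values) / nb))
  # block PMFs are gauge-aligned to the full PMF by their mean offset over
  # the bins they sample (the min is a noisy anchor; the mean offset is the
  # least-squares choice of the arbitrary additive constant)
  blockF <- matrix(unlist(lapply(seq_len(nb), function(b) {
    cb <- .counts_1d(values[block_id == b], edges)
    Fb <- rep(NA_real_, length(cb))
    s <- cb > 0
    if (any(s)) {
      Fb[s] <- -kT * log(cb[s])
      shared <- s & counts > 0
      Fb <- Fb - mean(Fb[shared] - F[shared])
    }
    Fb
  })), nrow = length(counts))
  std <- apply(blockF, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  std[counts == 0] <- NA_real_
  .new_pmf(list(edges), F, std, counts, temperature, 1L)
}

#' Construct an umbrella window
#'
#' The bias is harmonic and independent per axis:
#' `U_bias(x) = k/2 (x1 - c1)^2 + k/2 (x2 - c2)^2`.
#'
#' @param center numeric(2) window center (Angstrom)
#' @param k force constant (kcal/mol/A^2), applied to each axis
#' @param samples `n x 2` matrix of per-frame (xi1, xi2) values
#' @param temperature K (default 300, the umbrella production convention)
#' @return object of class `lp_umbrella`
#' @export
umbrella_window <- function(center, k, samples, temperature = 300) {
  samples <- matrix(as.numeric(samples), ncol = 2)
  if (k <= 0) stop("force constant must be positive")
  if (nrow(samples) == 0) stop("umbrella window without samples")
  structure(list(center = as.numeric(center), k = k, samples = samples,
                 temperature = temperature), class = "lp_umbrella")
}

# core WHAM iteration on precomputed per-bin counts
# counts_w: windows x bins matrix, c_w: windows x bins bias Boltzmann factors
.wham_solve <- function(counts_w, c_w, kT, tol, max_iter, f_init = NULL) {
  n_i <- colSums(counts_w)
  N_k <- rowSums(counts_w)
  keep <- N_k > 0
  counts_w <- counts_w[keep, , drop = FALSE]
  c_w <- c_w[keep, , drop = FALSE]
  N_k <- N_k[keep]
  f <- if (is.null(f_init)) rep(0, length(N_k)) else f_init[keep]
  for (it in seq_len(max_iter)) {
    # p_i propto n_i / sum_k N_k exp(f_k/kT) c_ki
    denom <- colSums((N_k * exp(f / kT)) * c_w)
    p <- ifelse(denom > 0, n_i / denom, 0)
    Z <- as.numeric(c_w %*% p)
    f_new <- -kT * log(Z)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      p <- p / sum(p)
      return(list(p = p, f = f, iterations = it, converged = TRUE))
    }
  }
  stop(sprintf("WHAM failed to converge in %d iterations (residual %.3g kcal/mol)",
               max_iter, delta))
}

#' Two-dimensional WHAM unbiasing of umbrella windows
#'
#' Solves the self-consistent WHAM equations for harmonically biased
#' windows on a regular (xi1, xi2) grid and returns the min-zeroed
#' unbiased PMF. Per-bin standard deviations come from block averaging:
#' each window's samples are split into `n_blocks` contiguous blocks and
#' WHAM is re-solved per block.
#'
#' @param windows list of [umbrella_window()]s (consistent temperature)
#' @param bin_width numeric 1 or 2, default 0.25 Angstrom per axis
#' @param tol convergence tolerance on window free-energy constants
#'   (kcal/mol), default 1e-7
#' @param max_iter default 1e5
#' @param n_blocks default 10
#' @param support optional list of two c(lo, hi) axis ranges
#' @param f_init optional initial per-window free-energy constants
#'   (kcal/mol); the converged PMF is invariant to any additive constant
#'   here (gauge freedom)
#' @return an `lp_pmf` with 2D `F`, `std` and `occupancy` matrices and
#'   extra fields `window_f` (converged per-window constants) and
#'   `iterations`
#' @export
wham2d <- function(windows, bin_width = 0.25, tol = 1e-7, max_iter = 1e5,
                   n_blocks = 10, support = NULL, f_init = NULL) {
  if (length(windows) == 0) stop("need at least one umbrella window")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9) stop("windows have inconsistent temperatures")
  kT <- .kB * temps[1]
  bw <- rep(bin_width, length.out = 2)
  all1 <- unlist(lapply(windows, function(w) w$samples[, 1]))
  all2 <- unlist(lapply(windows, function(w) w$samples[, 2]))
  e1 <- .make_edges(all1, bw[1], if (!is.null(support)) support[[1]])
  e2 <- .make_edges(all2, bw[2], if (!is.null(support)) support[[2]])
  m1 <- (e1[-1] + e1[-length(e1)]) / 2
  m2 <- (e2[-1] + e2[-length(e2)]) / 2
  nb1 <- length(m1); nb2 <- length(m2)
  centers <- cbind(rep(m1, times = nb2), rep(m2, each = nb1))  # bin-major x1

  W <- length(windows)
  hist_one <- function(samples) {
    b1 <- .bin_of(samples[, 1], e1); b2 <- .bin_of(samples[, 2], e2)
    ok <- !is.na(b1) & !is.na(b2)
    tabulate((b2[ok] - 1L) * nb1 + b1[ok], nbins = nb1 * nb2)
  }
  counts_w <- t(vapply(windows, function(w) hist_one(w$samples),
                       numeric(nb1 * nb2)))
  c_w <- t(vapply(windows, function(w) {
    bias <- 0.5 * w$k * (centers[, 1] - w$center[1])^2 +
            0.5 * w$k * (centers[, 2] - w$center[2])^2
    exp(-bias / kT)
  }, numeric(nb1 * nb2)))

  # histogram-overlap connectivity check
  sampled <- counts_w > 0
  adj <- tcrossprod(sampled * 1) > 0
  comp <- .connected_components(adj)
  if (max(comp) > 1)
    warning("umbrella windows form ", max(comp),
            " disconnected histogram groups; PMF offsets between groups are arbitrary")

  sol <- .wham_solve(counts_w, c_w, kT, tol, max_iter, f_init = f_init)
  F <- rep(Inf, nb1 * nb2)
  s <- sol$p > 0
  F[s] <- -kT * log(sol$p[s])
  F <- F - min(F[s])

  # block errors: block b takes the b-th contiguous slice of every window
  blockF <- matrix(NA_real_, nb1 * nb2, n_blocks)
  for (b in seq_len(n_blocks)) {
    cb <- t(vapply(windows, function(w) {
      n <- nrow(w$samples)
      id <- ceiling(seq_len(n) / (n / min(n_blocks, n)))
      hist_one(w$samples[id == b, , drop = FALSE])
    }, numeric(nb1 * nb2)))
    if (sum(cb) == 0) next
    sb <- tryCatch(.wham_solve(cb, c_w, kT, tol * 10, max_iter, f_init = sol$f),
                   error = function(e) NULL)
    if (is.null(sb)) next
    pos <- sb$p > 0
    Fb <- rep(NA_real_, nb1 * nb2)
    Fb[pos] <- -kT * log(sb$p[pos])
    shared <- pos & is.finite(F)
    blockF[, b] <- Fb - mean(Fb[shared] - F[shared])
  }
  std <- apply(blockF, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  occ <- colSums(counts_w)
  out <- .new_pmf(list(e1, e2),
                  matrix(F, nb1, nb2), matrix(std, nb1, nb2),
                  matrix(occ, nb1, nb2), temps[1], 2L)
  out$window_f <- sol$f
  out$iterations <- sol$iterations
  out
}

.connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    stack <- i
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Frames in low-energy bins of a PMF
#'
#' Maps per-frame order-parameter values onto the PMF grid and returns the
#' (0-based) frames whose bin lies within `threshold` kcal/mol of the
#' minimum. Intended to extract e.g. the <= 1 kcal/mol conformers feeding
#' bound-state contact profiling.
#'
#' @param pmf an `lp_pmf`
#' @param values numeric vector (1D PMF) or `n x 2` matrix (2D PMF) of
#'   per-frame order parameters
#' @param threshold kcal/mol, default 1.0
#' @return integer vector of 0-based frame indices (empty, with a warning,
#'   if no bin qualifies)
#' @export
low_energy_conformers <- function(pmf, values, threshold = 1.0) {
  if (pmf$ndim == 1) {
    b <- .bin_of(as.numeric(values), pmf$edges[[1]])
    Fv <- ifelse(is.na(b), Inf, pmf$F[b])
  } else {
    values <- matrix(as.numeric(values), ncol = 2)
    b1 <- .bin_of(values[, 1], pmf$edges[[1]])
    b2 <- .bin_of(values[, 2], pmf$edges[[2]])
    Fv <- rep(Inf, nrow(values))
    ok <- !is.na(b1) & !is.na(b2)
    Fv[ok] <- pmf$F[cbind(b1[ok], b2[ok])]
  }
  out <- which(Fv <= threshold) - 1L
  if (length(out) == 0)
    warning("no frames fall in bins within ", threshold, " kcal/mol of the minimum")
  out
}

#' Conditional PMFs under a closure predicate
#'
#' Splits the frames by a logical condition (e.g. `xi12 < c`, the closed
#' clamshell) and computes a PMF for each stratum, typically of the
#' glycan-D2 order parameter.
#'
#' @param values the order-parameter series to histogram
#' @param condition logical vector, same length; TRUE = first stratum
#' @param condition_name label used in error messages
#' @param ... passed to [histogram_pmf()]
#' @return list with `satisfied` and `failed` `lp_pmf`s
#' @export
conditional_pmf <- function(values, condition, condition_name = "condition",
                            ...) {
  stopifnot(length(values) == length(condition))
  if (length(values) == 0) stop("no frames to stratify by ", condition_name)
  one <- function(keep, label) {
    if (!any(keep)) {
      warning("empty stratum (", label, " ", condition_name, "); PMF omitted")
      return(NULL)
    }
    histogram_pmf(values[keep], ...)
  }
  list(satisfied = one(condition, "satisfying"),
       failed = one(!condition, "failing"))
}
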