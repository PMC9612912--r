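# Association kinetics: three-state bookkeeping (bulk / associated /
# docked), bulk-time and free-concentration accounting, and the
# association rate constant
#   kon = N_b / sum_i t_i [L_i] s_i         (M^-1 s^-1)
# where N_b counts association events surviving the residence-time
# threshold, t_i is time spent in bulk solvent (s), [L_i] the free-agonist
# concentration (M) and s_i the number of identical binding sites.

# uniform frame duration in ns (frame_times are strictly increasing)
.frame_dt <- function(traj) {
  if (n_frames(traj) < 2) return(1)
  stats::median(diff(traj$times))
}

#' Per-frame association state for one ligand copy
#'
#' @param traj an [lp_trajectory()]
#' @param copy 0-based ligand copy
#' @param chains optional precomputed [detect_chains()] result
#' @param ... passed to [detect_chains()] when `chains` is NULL
#' @return character vector, one of `"BULK"`, `"ASSOCIATED"`, `"DOCKED"`
#'   per frame
#' @export
state_series <- function(traj, copy, chains = NULL, ...) {
  if (is.null(chains)) chains <- detect_chains(traj, copy, ...)
  st <- rep("BULK", n_frames(traj))
  for (ch in chains) {
    st[ch$frames + 1L] <- "ASSOCIATED"
    st[ch$docked_frames + 1L] <- "DOCKED"
  }
  st
}

#' Time a ligand copy spends in bulk solvent
#'
#' Total trajectory time minus time in the ASSOCIATED or DOCKED states,
#' in seconds.
#' @inheritParams state_series
#' @return numeric seconds
#' @export
bulk_time <- function(traj, copy, chains = NULL, ...) {
  st <- state_series(traj, copy, chains, ...)
  dt_ns <- .frame_dt(traj)
  sum(st == "BULK") * dt_ns * 1e-9
}

#' Free-agonist concentration
#'
#' Mean number of ligand copies in the BULK state divided by Avogadro's
#' number times the box volume. Supply `constant` to bypass the
#' computation (e.g. a nominal 19.6 mM).
#'
#' @param traj an [lp_trajectory()]
#' @param frames optional 0-based frame subset
#' @param constant optional molar concentration returned verbatim
#' @param states optional precomputed list of per-copy state vectors
#' @param ... passed to [detect_chains()]
#' @return molar concentration; 0 M (with a warning) when no copy is free
#' @export
free_concentration <- function(traj, frames = NULL, constant = NULL,
                               states = NULL, ...) {
  if (!is.null(constant)) return(constant)
  box <- traj$top$box
  if (is.null(box)) stop("box dimensions unknown; supply `constant`")
  if (is.null(states))
    states <- lapply(seq_along(traj$top$ligand_copies) - 1L,
                     function(cp) state_series(traj, cp, ...))
  sel <- if (is.null(frames)) seq_len(n_frames(traj)) else frames + 1L
  n_bulk <- rowSums(vapply(states, function(s) s[sel] == "BULK",
                           logical(length(sel))))
  mean_free <- mean(n_bulk)
  vol_l <- prod(box) * 1e-27  # A^3 -> liters
  conc <- mean_free / (.NA_AVOGADRO * vol_l)
  if (conc == 0) warning("no free ligand copies; kon undefined at 0 M")
  conc
}

#' Assemble kinetics input terms
#'
#' @param residence_ns residence time (ns) of each association event
#' @param bulk_times_s per-segment (typically per-copy) bulk solvent
#'   times t_i in seconds
#' @param concentrations_M free-agonist concentration L_i per segment
#'   (recycled)
#' @param sites number of identical binding sites s_i per segment
#'   (recycled)
#' @return object of class `lp_kinetics_input`
#' @export
kinetics_input <- function(residence_ns, bulk_times_s, concentrations_M,
                           sites = 1L) {
  if (any(residence_ns < 0)) stop("residence times must be >= 0")
  if (any(bulk_times_s < 0)) stop("bulk times must be >= 0")
  if (any(concentrations_M <= 0)) stop("concentrations must be > 0")
  if (any(sites < 1)) stop("site counts must be >= 1")
  n <- length(bulk_times_s)
  structure(list(
    residence_ns = as.numeric(residence_ns),
    bulk_times_s = as.numeric(bulk_times_s),
    concentrations_M = rep_len(as.numeric(concentrations_M), n),
    sites = rep_len(as.integer(sites), n)
  ), class = "lp_kinetics_input")
}

#' Association rate constant with residence-time sensitivity band
#'
#' `kon = N_b / sum_i t_i L_i s_i`. The threshold-0 row (all events
#' included) is the upper bound; each positive threshold drops events with
#' residence time at or below it, giving lower bounds (the reference
#' choice is >100 ns).
#'
#' @param input an [kinetics_input()]
#' @param residence_thresholds ns; default `c(0, 100)`
#' @return data.frame `threshold_ns`, `n_b`, `kon` with attribute
#'   `denominator` (the sum of t_i L_i s_i, in M s)
#' @export
kon_estimate <- function(input, residence_thresholds = c(0, 100)) {
  stopifnot(inherits(input, "lp_kinetics_input"))
  denom <- sum(input$bulk_times_s * input$concentrations_M * input$sites)
  if (denom <= 0) stop("kon denominator is zero (no concentration-weighted bulk time)")
  rows <- lapply(sort(residence_thresholds), function(th) {
    nb <- if (th <= 0) length(input$residence_ns) else sum(input$residence_ns > th)
    if (nb == 0) warning("no events survive residence threshold ", th, " ns")
    data.frame(threshold_ns = th, n_b = nb, kon = nb / denom)
  })
  out <- do.call(rbind, rows)
  attr(out, "denominator") <- denom
  out
}

#' Binding-event records from a trajectory
#'
#' One record per detected chain: residence time (time in the
#' ASSOCIATED-or-DOCKED state by default, or docked frames only) and a
#' success flag (the chain docked).
#'
#' @param traj an [lp_trajectory()]
#' @param copies 0-based ligand copies (default all)
#' @param residence "chain" (default) or "docked"
#' @param ... passed to [detect_chains()]
#' @return data.frame `ligand_copy`, `chain_id`, `residence_ns`, `success`
#' @export
binding_events <- function(traj, copies = NULL, residence = c("chain", "docked"),
                           ...) {
  residence <- match.arg(residence)
  if (is.null(copies)) copies <- seq_along(traj$top$ligand_copies) - 1L
  dt_ns <- .frame_dt(traj)
  rows <- list()
  for (cp in copies) {
    for (ch in detect_chains(traj, cp, ...)) {
      nfr <- if (residence == "chain") length(ch$frames) else length(ch$docked_frames)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_copy = cp, chain_id = ch$chain_id,
        residence_ns = nfr * dt_ns,
        success = length(ch$docked_frames) > 0)
    }
  }
  if (length(rows) == 0)
    return(data.frame(ligand_copy = integer(), chain_id = integer(),
                      residence_ns = numeric(), success = logical()))
  do.call(rbind, rows)
}

#' End-to-end kon estimate from a trajectory
#'
#' Detects chains for every copy, accounts bulk times and free
#' concentration, and evaluates [kon_estimate()]. "Association event"
#' defaults to docked (successful) chains; `count = "all"` counts every
#' association.
#'
#' @param traj an [lp_trajectory()]
#' @param copies 0-based ligand copies (default all)
#' @param sites identical binding sites per copy segment
#' @param concentration optional constant molar concentration
#' @param count "docked" (default) or "all"
#' @param residence_thresholds ns, see [kon_estimate()]
#' @param ... passed to [detect_chains()]
#' @return list with `kon` (the [kon_estimate()] table), `events`,
#'   `input`, `concentration_M`
#' @export
kon_from_trajectory <- function(traj, copies = NULL, sites = 1L,
                                concentration = NULL,
                                count = c("docked", "all"),
                                residence_thresholds = c(0, 100), ...) {
  count <- match.arg(count)
  if (is.null(copies)) copies <- seq_along(traj$top$ligand_copies) - 1L
  states <- lapply(copies, function(cp) state_series(traj, cp, ...))
  conc <- free_concentration(traj, constant = concentration, states = states)
  dt_ns <- .frame_dt(traj)
  bulk_s <- vapply(states, function(s) sum(s == "BULK") * dt_ns * 1e-9, numeric(1))
  ev <- binding_events(traj, copies, ...)
  if (count == "docked") ev <- ev[ev$success, , drop = FALSE]
  input <- kinetics_input(ev$residence_ns, bulk_s, conc, sites)
  list(kon = kon_estimate(input, residence_thresholds), events = ev,
       input = input, concentration_M = conc)
}
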