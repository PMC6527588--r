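# Temperature replica exchange (parallel tempering) with Metropolis swaps.

#' Temperature ladder for replica exchange
#'
#' Linearly spaced ladder of reduced temperatures; the default reproduces the
#' production setup of 20 replicas spanning 0.5-0.72 simulation units.
#'
#' @param t_min,t_max endpoints (reduced temperature), `t_min < t_max`.
#' @param n number of replicas (>= 2).
#' @param exchange_interval time between swap attempts (reduced units).
#' @return object of class `pqd_ladder`: list(temperatures, exchange_interval).
#' @examples
#' make_ladder()$temperatures[c(1, 20)] # 0.5, 0.72
#' @export
make_ladder <- function(t_min = 0.5, t_max = 0.72, n = 20,
                        exchange_interval = 1000) {
  if (n < 2) stop("a ladder needs at least 2 temperatures", call. = FALSE)
  if (!(t_min < t_max)) stop("t_min must be < t_max", call. = FALSE)
  structure(list(temperatures = seq(t_min, t_max, length.out = n),
                 exchange_interval = exchange_interval),
            class = "pqd_ladder")
}

#' @export
print.pqd_ladder <- function(x, ...) {
  cat(sprintf("<pqd_ladder> %d temperatures in [%g, %g], swaps every %g t.u.\n",
              length(x$temperatures), min(x$temperatures), max(x$temperatures),
              x$exchange_interval))
  invisible(x)
}

#' Metropolis acceptance probability for a temperature swap
#'
#' `min(1, exp[(1/T_i - 1/T_j) (E_i - E_j)])` for exchanging the temperatures
#' of two replicas with potential energies `E_i`, `E_j`.
#'
#' @param t_i,t_j replica temperatures.
#' @param e_i,e_j replica potential energies.
#' @return acceptance probability in `[0, 1]`.
#' @export
swap_accept_prob <- function(t_i, t_j, e_i, e_j) {
  pmin(1, exp((1 / t_i - 1 / t_j) * (e_i - e_j)))
}

#' Attempt a replica swap
#'
#' Draws the Metropolis decision for exchanging the temperatures of two
#' replicas. Uses R's RNG stream (seed it for reproducibility).
#'
#' @inheritParams swap_accept_prob
#' @return logical: accept?
#' @export
attempt_swap <- function(t_i, t_j, e_i, e_j) {
  stats::runif(1) < swap_accept_prob(t_i, t_j, e_i, e_j)
}

#' Burn-in frame index
#'
#' Marks the initial non-equilibrated segment of an energy series: the first
#' retained index is where the running mean over `window` frames stops
#' changing by more than `tol` (relative to the series spread) between
#' consecutive windows; if the criterion never triggers (or `window` is
#' `NULL`) the first `frac` of the series is discarded.
#'
#' @param energy per-frame energies.
#' @param frac fallback fraction to discard (default 0.5).
#' @param window window length in frames for the running-mean rule.
#' @param tol tolerance on the running-mean change, as a fraction of the
#'   interquartile range of the series.
#' @return integer index of the first retained frame.
#' @export
burnin_index <- function(energy, frac = 0.5, window = NULL, tol = 0.1) {
  n <- length(energy)
  if (n == 0) return(1L)
  fallback <- min(n, floor(n * frac) + 1L)
  if (is.null(window) || n < 3 * window) return(as.integer(fallback))
  scale <- stats::IQR(energy)
  if (scale == 0) return(1L)
  rm <- stats::filter(energy, rep(1 / window, window), sides = 1)
  for (k in seq(2 * window, n - window)) {
    if (abs(rm[k] - rm[k - window]) < tol * scale) return(as.integer(k - window + 1L))
  }
  as.integer(fallback)
}

#' Run replica-exchange DMD
#'
#' Advances `length(ladder$temperatures)` replicas of the system between swap
#' attempts at regular intervals; at each attempt, adjacent-pair temperature
#' swaps (alternating even/odd parity) are accepted with the Metropolis
#' probability computed from the replica potential energies; on acceptance
#' velocities are rescaled by `sqrt(T_new/T_old)`. Trajectories are collected
#' per temperature (not per replica).
#'
#' @param system a `pqd_system`.
#' @param ladder a `pqd_ladder`.
#' @param t_total total simulation time per replica (multiple of the exchange
#'   interval; must be at least one interval).
#' @param dt_sample frame sampling interval.
#' @param thermostat ghost-collision rate per bead per time unit.
#' @param ff force field.
#' @param seed master seed: controls initial states, engine streams and swap
#'   decisions.
#' @param box_edge,spacing passed to [init_state()].
#' @param burnin_frac fraction of each per-temperature trajectory flagged as
#'   burn-in (see [burnin_index()]); stored in the result, frames are kept.
#' @return object of class `pqd_remd`: list with `trajectories` (one
#'   `pqd_traj` per ladder temperature), `acceptance` (data.frame: pair,
#'   t_low, t_high, attempts, accepts, rate), `replica_temps` (matrix: swap
#'   step x replica -> temperature index), `burnin` (first retained frame
#'   index per temperature), `ladder`.
#' @export
run_remd <- function(system, ladder = make_ladder(), t_total,
                     dt_sample = ladder$exchange_interval / 4,
                     thermostat = 0.5, ff = default_forcefield(), seed = 1L,
                     box_edge = NULL, spacing = 0.55, burnin_frac = 0.5) {
  stopifnot(inherits(ladder, "pqd_ladder"))
  ex <- ladder$exchange_interval
  if (t_total < ex)
    stop("t_total must be at least one exchange interval", call. = FALSE)
  temps <- ladder$temperatures
  nrep <- length(temps)
  nchunk <- floor(t_total / ex)
  set.seed(seed)
  states <- lapply(seq_len(nrep), function(r)
    init_state(system, temps[r], ff = ff, box_edge = box_edge,
               spacing = spacing, seed = sample.int(2^31 - 1, 1)))
  set.seed(seed + 1L)
  temp_of <- seq_len(nrep)           # temperature index held by each replica
  chunks <- rep(list(vector("list", nchunk)), nrep)  # per TEMPERATURE
  epot <- numeric(nrep)
  npair <- nrep - 1L
  attempts <- integer(npair); accepts <- integer(npair)
  temp_hist <- matrix(NA_integer_, nchunk, nrep)
  for (ck in seq_len(nchunk)) {
    for (r in seq_len(nrep)) {
      Tr <- temps[temp_of[r]]
      res <- advance(states[[r]], ex, dt_sample = dt_sample,
                     thermostat = thermostat, temperature = Tr,
                     seed = sample.int(2^31 - 1, 1))
      states[[r]] <- res$state
      epot[r] <- res$potential
      if (!is.null(res$trajectory)) {
        res$trajectory$temperature <- Tr
        chunks[[temp_of[r]]][[ck]] <- res$trajectory
      }
    }
    temp_hist[ck, ] <- temp_of
    # adjacent-pair swaps, alternating parity
    first <- if (ck %% 2L == 1L) 1L else 2L
    rep_of <- order(temp_of)         # which replica holds temperature k
    if (first <= npair) for (k in seq(first, npair, by = 2L)) {
      ri <- rep_of[k]; rj <- rep_of[k + 1L]
      attempts[k] <- attempts[k] + 1L
      if (attempt_swap(temps[k], temps[k + 1L], epot[ri], epot[rj])) {
        accepts[k] <- accepts[k] + 1L
        temp_of[ri] <- k + 1L; temp_of[rj] <- k
        states[[ri]]$v <- states[[ri]]$v * sqrt(temps[k + 1L] / temps[k])
        states[[rj]]$v <- states[[rj]]$v * sqrt(temps[k] / temps[k + 1L])
      }
    }
  }
  trajectories <- lapply(seq_len(nrep), function(k)
    bind_trajectories(Filter(Negate(is.null), chunks[[k]])))
  burnin <- vapply(trajectories, function(tr) {
    if (is.null(tr)) return(1L)
    burnin_index(tr$potential, frac = burnin_frac)
  }, integer(1))
  structure(list(
    trajectories = trajectories,
    acceptance = data.frame(pair = seq_len(npair),
                            t_low = temps[-nrep], t_high = temps[-1L],
                            attempts = attempts, accepts = accepts,
                            rate = ifelse(attempts > 0, accepts / attempts, NA)),
    replica_temps = temp_hist, burnin = burnin, ladder = ladder,
    final_states = states, seed = seed),
    class = "pqd_remd")
}

#' @export
print.pqd_remd <- function(x, ...) {
  cat(sprintf("<pqd_remd> %d temperatures, %d frames at T_min=%g\n",
              length(x$trajectories),
              length(x$trajectories[[1]]), x$ladder$temperatures[1]))
  cat(sprintf("mean swap acceptance: %.2f\n", mean(x$acceptance$rate, na.rm = TRUE)))
  invisible(x)
}

#' Replica exchange on a two-level toy system
#'
#' Each replica is a single two-level degree of freedom with energies
#' `{0, dE}`; between swap attempts the state is re-drawn from its Boltzmann
#' distribution at the replica's current temperature (heat-bath sweeps), then
#' the same adjacent-pair Metropolis swap machinery as [run_remd()] is
#' applied. The analytic occupancy of the excited state is
#' `p(T) = exp(-dE/T) / (1 + exp(-dE/T))`, giving an exact oracle for
#' per-temperature sampling and for swap-acceptance statistics.
#'
#' @param toy a toy from [make_two_level_toy()].
#' @param n_cycles number of swap cycles.
#' @param sweeps heat-bath resamplings between swap attempts.
#' @param seed RNG seed.
#' @return list(occupancy (per-temperature excited-state frequency),
#'   expected (analytic occupancy), acceptance (per-pair data.frame with
#'   empirical and expected rates), n_cycles).
#' @export
remd_toy <- function(toy, n_cycles = 2000, sweeps = 1, seed = 1L) {
  stopifnot(inherits(toy, "pqd_two_level"))
  temps <- toy$ladder$temperatures
  nrep <- length(temps)
  dE <- toy$dE
  set.seed(seed)
  temp_of <- seq_len(nrep)
  state <- integer(nrep)             # 0 ground, 1 excited (per replica)
  occ <- numeric(nrep); nocc <- 0L
  npair <- nrep - 1L
  attempts <- integer(npair); accepts <- integer(npair)
  # tally swap outcomes by (state_i, state_j) for the exact-rate comparison
  acc_by <- matrix(0L, npair, 4L); att_by <- matrix(0L, npair, 4L)
  for (ck in seq_len(n_cycles)) {
    for (s in seq_len(sweeps))
      state <- as.integer(stats::runif(nrep) < toy$p_excited(temps[temp_of]))
    occ[temp_of] <- occ[temp_of] + state
    nocc <- nocc + 1L
    first <- if (ck %% 2L == 1L) 1L else 2L
    rep_of <- order(temp_of)
    for (k in seq(first, npair, by = 2L)) {
      ri <- rep_of[k]; rj <- rep_of[k + 1L]
      attempts[k] <- attempts[k] + 1L
      cell <- state[ri] * 2L + state[rj] + 1L
      att_by[k, cell] <- att_by[k, cell] + 1L
      if (attempt_swap(temps[k], temps[k + 1L], state[ri] * dE, state[rj] * dE)) {
        accepts[k] <- accepts[k] + 1L
        acc_by[k, cell] <- acc_by[k, cell] + 1L
        temp_of[ri] <- k + 1L; temp_of[rj] <- k
      }
    }
  }
  list(occupancy = occ / nocc,
       expected = toy$p_excited(temps),
       acceptance = data.frame(pair = seq_len(npair), attempts = attempts,
                               accepts = accepts, rate = accepts / attempts),
       accept_by_state = list(attempts = att_by, accepts = acc_by),
       temps = temps, n_cycles = n_cycles)
}
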