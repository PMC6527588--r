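# R surface of the event-driven DMD engine.

#' Time to reach a pair separation
#'
#' Smallest positive root of |r + v t| = d for a pair with relative position
#' `r` and relative velocity `v` (minimal image already applied), i.e. the
#' ballistic flight time to a shell of radius `d`. Returns `NA` if the
#' separation is never reached (receding pair outside the shell, or
#' insufficient approach).
#'
#' @param r relative position vector (length 3, nm).
#' @param v relative velocity vector (length 3, nm per time unit).
#' @param d target separation (nm, > 0).
#' @return time in reduced units, or `NA_real_`.
#' @examples
#' next_event_time(c(1, 0, 0), c(-1, 0, 0), 0.5) # 0.5
#' @export
next_event_time <- function(r, v, d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0)
    stop("shell radius d must be a positive number", call. = FALSE)
  r2 <- sum(r * r); b <- sum(r * v); v2 <- sum(v * v)
  if (v2 == 0) return(NA_real_)
  c_ <- r2 - d * d
  if (c_ > 0) {                       # outside the shell: approach needs b < 0
    if (b >= 0) return(NA_real_)
    disc <- b * b - v2 * c_
    if (disc <= 0) return(NA_real_)
    (-b - sqrt(disc)) / v2
  } else {                            # inside: the outgoing root always exists
    (-b + sqrt(b * b - v2 * c_)) / v2
  }
}

#' Velocity jump for a pair event at a potential step
#'
#' Applies the standard DMD velocity-jump rule along the line of centers:
#' the radial component of the relative velocity changes so that kinetic
#' energy changes by exactly minus the potential step when the boundary is
#' crossed; if the radial kinetic energy is below the step the pair reflects
#' elastically (bounce) and energy is unchanged. Pair momentum is conserved
#' exactly.
#'
#' @param v1,v2 bead velocities (length 3).
#' @param m1,m2 bead masses.
#' @param nvec unit vector from bead 1 to bead 2.
#' @param dU potential step for the attempted crossing (target minus current
#'   shell energy; `Inf` for a hard wall).
#' @param outward logical: is the attempted crossing outward?
#' @return list(v1, v2, crossed, dK) with updated velocities, whether the
#'   boundary was crossed and the kinetic-energy change.
#' @export
collide_pair <- function(v1, v2, m1, m2, nvec, dU, outward) {
  mu <- m1 * m2 / (m1 + m2)
  vr <- sum((v2 - v1) * nvec)
  q <- vr * vr - 2 * dU / mu
  if (is.finite(dU) && q > 0) {
    vrp <- if (outward) sqrt(q) else -sqrt(q)
    crossed <- TRUE
  } else {
    vrp <- -vr
    crossed <- FALSE
  }
  dvr <- vrp - vr
  list(v1 = v1 - (mu / m1) * dvr * nvec,
       v2 = v2 + (mu / m2) * dvr * nvec,
       crossed = crossed,
       dK = 0.5 * mu * (vrp * vrp - vr * vr))
}

#' Maxwell-Boltzmann velocities
#'
#' @param n number of beads; @param temperature reduced temperature (k_B=1);
#' @param mass bead masses (recycled).
#' @param zero_momentum remove the centre-of-mass drift.
#' @return n x 3 matrix.
#' @export
maxwell_velocities <- function(n, temperature, mass = 1, zero_momentum = TRUE) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  m <- rep_len(mass, n)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(temperature / m)
  if (zero_momentum && n > 1) {
    p <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, p)
  }
  v
}

# Stretched zig-zag chain coordinates satisfying every bond window and hard
# core of the default force field: CA beads alternate laterally so that
# CA(i)-CA(i+1) = 0.38 nm while CA(i)-CA(i+2) = 0.72 nm stays inside the
# pseudo-bond well; side chains sit 0.26 nm above the backbone plane.
.stretched_chain <- function(nres, has_sc, origin) {
  a <- 0.35; b <- sqrt(0.38^2 - a^2) / 2
  ca <- cbind(origin[1] + (seq_len(nres) - 1) * a,
              origin[2] + b * (-1)^(seq_len(nres)),
              origin[3])
  xyz <- matrix(NA_real_, nres + sum(has_sc), 3)
  row <- 1L
  for (i in seq_len(nres)) {
    xyz[row, ] <- ca[i, ]; row <- row + 1L
    if (has_sc[i]) { xyz[row, ] <- ca[i, ] + c(0, 0, 0.26); row <- row + 1L }
  }
  xyz
}

#' Initial system state
#'
#' Builds the bead topology and interaction tables, places every chain as a
#' completely stretched conformation on parallel axes with seed-controlled
#' small offsets, and draws Maxwell-Boltzmann velocities at the requested
#' temperature. The cubic box defaults to the longest chain extent plus a
#' margin so that stretched chains never interact with their periodic images.
#'
#' @param system a `pqd_system`.
#' @param temperature reduced temperature for the initial velocities.
#' @param ff force field (default [default_forcefield()]).
#' @param box_edge cubic box edge (nm); default auto-sized.
#' @param spacing distance between chain axes (nm).
#' @param seed RNG seed for offsets and velocities.
#' @return Object of class `pqd_state`: list(x, v, mass, box, time, topology,
#'   tables, system, ff, meta).
#' @export
init_state <- function(system, temperature, ff = default_forcefield(),
                       box_edge = system$box_edge, spacing = 0.55, seed = 1L) {
  stopifnot(inherits(system, "pqd_system"))
  topo <- build_topology(system, ff)
  tables <- interaction_tables(topo)
  lens <- vapply(system$constructs, function(co) sum(co$layout$length), integer(1))
  extent <- (max(lens) - 1) * 0.35
  if (is.null(box_edge)) box_edge <- extent + 4 + spacing * length(lens)
  if (box_edge < extent + 2)
    stop("box edge too small for a stretched chain of ", max(lens), " residues",
         call. = FALSE)
  set.seed(seed)
  xs <- vector("list", system$n_chain)
  for (ch in seq_len(system$n_chain)) {
    res <- system$table$global_index[system$table$chain == ch]
    has_sc <- aa_class(system$table$aa[res]) != "G"
    origin <- c(2 + stats::runif(1, -0.1, 0.1),
                box_edge / 2 + (ch - (system$n_chain + 1) / 2) * spacing,
                box_edge / 2 + stats::runif(1, -0.05, 0.05))
    xs[[ch]] <- .stretched_chain(length(res), has_sc, origin)
  }
  x <- do.call(rbind, xs)
  v <- maxwell_velocities(nrow(x), temperature, topo$beads$mass)
  structure(list(x = x, v = v, mass = topo$beads$mass, box = box_edge,
                 time = 0, topology = topo, tables = tables,
                 system = system, ff = ff,
                 meta = list(seed = seed, ff_hash = forcefield_hash(ff),
                             temperature = temperature)),
            class = "pqd_state")
}

#' @export
print.pqd_state <- function(x, ...) {
  cat(sprintf("<pqd_state> %d beads, box %.2f nm, t = %.1f t.u.\n",
              nrow(x$x), x$box, x$time))
  invisible(x)
}

#' Assemble a state from raw pieces
#'
#' Low-level constructor used for toy systems and test fixtures: supply bead
#' coordinates/velocities, an interaction-type table and the pair-type matrix
#' directly, bypassing construct/topology building.
#'
#' @param x,v N x 3 coordinate and velocity matrices (nm, nm/t.u.).
#' @param box cubic box edge (nm).
#' @param types list of interaction records `list(radii, energies, bonded)`.
#' @param itab N x N integer matrix of 1-based type ids (0 = none).
#' @param mass bead masses (recycled).
#' @return a `pqd_state`.
#' @export
make_raw_state <- function(x, v, box, types, itab, mass = 1) {
  x <- as.matrix(x); v <- as.matrix(v)
  stopifnot(ncol(x) == 3, all(dim(x) == dim(v)),
            nrow(itab) == nrow(x), ncol(itab) == nrow(x))
  structure(list(x = x, v = v, mass = rep_len(mass, nrow(x)), box = box,
                 time = 0, topology = NULL,
                 tables = list(itab = itab, types = types),
                 system = NULL, ff = NULL,
                 meta = list(seed = NA_integer_, temperature = NA_real_)),
            class = "pqd_state")
}

#' Advance a system by event-driven dynamics
#'
#' Processes pair events (core bounces, well captures/escapes/bounces, bond
#' reflections) in time order through the C++ event queue, with an optional
#' Andersen-style ghost-collision thermostat. Between thermostat events total
#' energy is conserved to floating round-off; identical seeds give identical
#' trajectories.
#'
#' @param state a `pqd_state`.
#' @param t duration to advance (reduced time units).
#' @param dt_sample sampling interval for recorded frames (0 = no frames).
#' @param thermostat ghost-collision rate per bead per time unit (0 = NVE).
#' @param temperature thermostat temperature; defaults to the state's.
#' @param seed engine RNG seed (used only by the thermostat).
#' @param log_events keep a log of resolved events (for diagnostics/tests).
#' @param max_log log capacity.
#' @return list(state, trajectory, counts, n_events, log) where `trajectory`
#'   is a `pqd_traj` (empty if `dt_sample = 0`).
#' @export
advance <- function(state, t, dt_sample = 0, thermostat = 0,
                    temperature = state$meta$temperature, seed = 1L,
                    log_events = FALSE, max_log = 1e6) {
  stopifnot(inherits(state, "pqd_state"), t > 0)
  if (thermostat > 0 && temperature <= 0)
    stop("temperature must be > 0 when the thermostat is on", call. = FALSE)
  if (thermostat == 0 && all(abs(state$v) < .Machine$double.eps) )
    warning("event-queue starvation: zero velocities and no thermostat; ",
            "the system will not move", call. = FALSE)
  res <- dmd_advance_cpp(state$x, state$v, state$mass, state$box,
                         state$tables$itab, state$tables$types,
                         t, dt_sample, thermostat,
                         if (is.null(temperature)) 0 else temperature,
                         as.double(seed %% 2^31), log_events, as.integer(max_log))
  new_state <- state
  new_state$x <- res$x
  new_state$v <- res$v
  new_state$time <- state$time + t
  traj <- NULL
  nf <- length(res$frame_times)
  if (nf > 0) {
    arr <- res$frames
    frames <- lapply(seq_len(nf), function(f) arr[, , f, drop = TRUE])
    traj <- new_trajectory(frames, state$time + res$frame_times,
                           temperature = temperature, box = state$box,
                           topology = state$topology,
                           meta = c(state$meta, list(engine_seed = seed)),
                           potential = res$frame_potential,
                           kinetic = res$frame_kinetic)
  }
  lg <- NULL
  if (log_events && !is.null(res$log))
    lg <- data.frame(t = state$time + res$log$t, i = res$log$i, j = res$log$j,
                     kind = c("core_bounce", "well_capture", "well_escape",
                              "well_bounce", "bond_reflection", "thermostat")[res$log$kind],
                     bnd = res$log$bnd)
  list(state = new_state, trajectory = traj, counts = res$counts,
       n_events = res$n_events, potential = res$potential,
       kinetic = res$kinetic, log = lg)
}

#' Trajectory container
#'
#' @param frames list of N x 3 coordinate matrices (nm, unwrapped).
#' @param times frame times (reduced units, strictly increasing).
#' @param temperature replica temperature label.
#' @param box cubic box edge (nm).
#' @param topology the `pqd_topology` the coordinates refer to.
#' @param meta metadata list (seed, force-field hash, ...).
#' @param potential,kinetic optional per-frame energies.
#' @return object of class `pqd_traj`.
#' @export
new_trajectory <- function(frames, times, temperature = NA_real_, box = NA_real_,
                           topology = NULL, meta = list(),
                           potential = NULL, kinetic = NULL) {
  if (length(frames) != length(times))
    stop("frames and times lengths differ", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  structure(list(frames = frames, times = times, temperature = temperature,
                 box = box, topology = topology, meta = meta,
                 potential = potential, kinetic = kinetic),
            class = "pqd_traj")
}

#' @export
print.pqd_traj <- function(x, ...) {
  cat(sprintf("<pqd_traj> %d frames, %s beads, T = %s\n", length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0,
              format(x$temperature)))
  invisible(x)
}

#' @export
length.pqd_traj <- function(x) length(x$frames)

#' Concatenate trajectories
#' @param ... `pqd_traj` objects with increasing time ranges.
#' @return a `pqd_traj`.
#' @export
bind_trajectories <- function(...) {
  ts <- list(...)
  if (length(ts) == 1L && !inherits(ts[[1L]], "pqd_traj")) ts <- ts[[1L]]
  ts <- ts[!vapply(ts, is.null, logical(1))]
  if (!length(ts)) return(NULL)
  new_trajectory(unlist(lapply(ts, `[[`, "frames"), recursive = FALSE),
                 unlist(lapply(ts, `[[`, "times")),
                 temperature = ts[[1L]]$temperature, box = ts[[1L]]$box,
                 topology = ts[[1L]]$topology, meta = ts[[1L]]$meta,
                 potential = unlist(lapply(ts, `[[`, "potential")),
                 kinetic = unlist(lapply(ts, `[[`, "kinetic")))
}
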