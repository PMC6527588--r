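# Brute-force reference DMD engine (pure R).
#
# Independent oracle for the C++ event-queue engine: no priority queue, no
# lazy invalidation, no cell lists. After every event the next event is found
# by a linear scan over ALL interacting pairs; candidate times for pairs
# whose beads were untouched are ballistic and therefore unchanged, so they
# are recomputed only when a member bead's velocity changes (recomputing them
# would be a mathematical no-op). Thermostat-free by design, so that the
# comparison with the production engine involves no random numbers.
#
# Arithmetic deliberately mirrors the C++ engine operation-for-operation
# (explicit three-term dot products, minimal image via round()) so that event
# times agree to the last bit and the two engines can be compared over long
# event sequences.

.ref_predict <- function(eng, k) {
  i <- eng$ii[k]; j <- eng$jj[k]
  P <- eng$ptypes[[eng$tt[k]]]
  s <- eng$s[k]
  tnow <- eng$tnow
  dx1 <- (eng$x[j, 1] + eng$v[j, 1] * (tnow - eng$tloc[j])) -
         (eng$x[i, 1] + eng$v[i, 1] * (tnow - eng$tloc[i]))
  dx2 <- (eng$x[j, 2] + eng$v[j, 2] * (tnow - eng$tloc[j])) -
         (eng$x[i, 2] + eng$v[i, 2] * (tnow - eng$tloc[i]))
  dx3 <- (eng$x[j, 3] + eng$v[j, 3] * (tnow - eng$tloc[j])) -
         (eng$x[i, 3] + eng$v[i, 3] * (tnow - eng$tloc[i]))
  box <- eng$box
  dx1 <- dx1 - box * round(dx1 / box)
  dx2 <- dx2 - box * round(dx2 / box)
  dx3 <- dx3 - box * round(dx3 / box)
  dv1 <- eng$v[j, 1] - eng$v[i, 1]
  dv2 <- eng$v[j, 2] - eng$v[i, 2]
  dv3 <- eng$v[j, 3] - eng$v[i, 3]
  r2 <- dx1 * dx1 + dx2 * dx2 + dx3 * dx3
  b <- dx1 * dv1 + dx2 * dv2 + dx3 * dv3
  v2 <- dv1 * dv1 + dv2 * dv2 + dv3 * dv3
  tbest <- Inf; bbest <- -1L; dbest <- 0L
  if (s >= 1L) {
    cc <- r2 - P$r2[s]
    if (cc <= 0) {
      if (b < 0) { tbest <- 0; bbest <- s - 1L; dbest <- -1L }
    } else if (b < 0 && v2 > 0) {
      disc <- b * b - v2 * cc
      if (disc > 0) {
        tt <- (-b - sqrt(disc)) / v2
        if (tt < tbest) { tbest <- tt; bbest <- s - 1L; dbest <- -1L }
      }
    }
  }
  if (s < P$m && v2 > 0) {
    cc <- r2 - P$r2[s + 1L]
    if (cc > 0 && b >= 0) tt <- 0
    else {
      disc <- b * b - v2 * cc
      tt <- if (disc > 0) (-b + sqrt(disc)) / v2 else 0
    }
    if (tt < tbest) { tbest <- tt; bbest <- s; dbest <- 1L }
  }
  # minimal-image validity horizon (mirrors the production engine): the
  # prediction only holds while no relative-displacement component crosses
  # +-box/2; past that, re-predict instead (dir flag 0)
  timg <- Inf
  tmin_adv <- 1e-12 + 1e-14 * tnow    # relative clamp: the clock must advance
  for (dvk_dxk in list(c(dv1, dx1), c(dv2, dx2), c(dv3, dx3))) {
    dvk <- dvk_dxk[1]; dxk <- dvk_dxk[2]
    if (dvk == 0) next
    tt <- ((if (dvk > 0) box / 2 else -box / 2) - dxk) / dvk
    if (tt < tmin_adv) tt <- tmin_adv
    if (tt < timg) timg <- tt
  }
  if (!(bbest >= 0L && tbest <= timg)) {
    if (is.finite(timg)) return(c(tnow + timg, -1, 0L))
    return(c(Inf, -1, 0L))
  }
  c(tnow + tbest, bbest, dbest)
}

#' Brute-force reference DMD run
#'
#' Advances a `pqd_state` by event-driven dynamics using the all-pairs rescan
#' reference implementation (see the source header). Thermostat-free; used as
#' the independent oracle for [advance()] in tests.
#'
#' @param state a `pqd_state`.
#' @param t duration (reduced time units).
#' @param max_events stop after this many events (safety cap).
#' @param log_events keep the event log.
#' @return list(state, log, potential, n_events) where `log` has columns
#'   t, i, j, kind, bnd like the production engine's.
#' @export
reference_advance <- function(state, t, max_events = Inf, log_events = TRUE) {
  stopifnot(inherits(state, "pqd_state"), t > 0)
  it <- state$tables$itab
  n <- nrow(state$x)
  sel <- which(upper.tri(it) & it > 0L, arr.ind = TRUE)
  ord <- order(sel[, 1], sel[, 2])
  sel <- sel[ord, , drop = FALSE]
  ptypes <- lapply(state$tables$types, function(ty)
    list(m = length(ty$radii), rad = ty$radii, r2 = ty$radii^2,
         E = ty$energies, bonded = ty$bonded))
  eng <- new.env(parent = emptyenv())
  eng$ii <- sel[, 1]; eng$jj <- sel[, 2]
  eng$tt <- it[sel]
  eng$ptypes <- ptypes
  eng$x <- state$x; eng$v <- state$v
  eng$mass <- state$mass
  eng$tloc <- numeric(n)
  eng$box <- state$box
  eng$tnow <- 0
  np <- length(eng$ii)
  # initial shell indices (squared-radius comparison, right-continuous)
  eng$s <- integer(np)
  Upot <- 0
  for (k in seq_len(np)) {
    i <- eng$ii[k]; j <- eng$jj[k]
    d <- eng$x[j, ] - eng$x[i, ]
    d <- d - eng$box * round(d / eng$box)
    r2 <- d[1] * d[1] + d[2] * d[2] + d[3] * d[3]
    P <- ptypes[[eng$tt[k]]]
    s <- 0L
    while (s < P$m && P$r2[s + 1L] <= r2) s <- s + 1L
    if (!is.finite(P$E[s + 1L]))
      stop(sprintf("invalid initial state: pair (%d,%d)", i, j), call. = FALSE)
    eng$s[k] <- s
    Upot <- Upot + P$E[s + 1L]
  }
  pairs_of <- vector("list", n)
  for (k in seq_len(np)) {
    pairs_of[[eng$ii[k]]] <- c(pairs_of[[eng$ii[k]]], k)
    pairs_of[[eng$jj[k]]] <- c(pairs_of[[eng$jj[k]]], k)
  }
  tev <- numeric(np); bnd <- integer(np); dirv <- integer(np)
  for (k in seq_len(np)) {
    pr <- .ref_predict(eng, k)
    tev[k] <- pr[1]; bnd[k] <- pr[2]; dirv[k] <- pr[3]
  }
  cap <- if (is.finite(max_events)) as.integer(max_events) else 1048576L
  log_t <- numeric(cap); log_i <- integer(cap); log_j <- integer(cap)
  log_kind <- integer(cap); log_bnd <- integer(cap)
  n_events <- 0L
  kindnames <- c("core_bounce", "well_capture", "well_escape", "well_bounce",
                 "bond_reflection", "thermostat")
  while (n_events < max_events) {
    k <- which.min(tev)
    tk <- tev[k]
    if (tk > t) break
    eng$tnow <- tk
    if (dirv[k] == 0L) {               # minimal-image refresh, not an event
      pr <- .ref_predict(eng, k)
      tev[k] <- pr[1]; bnd[k] <- pr[2]; dirv[k] <- pr[3]
      next
    }
    i <- eng$ii[k]; j <- eng$jj[k]
    # advance the two beads
    for (bd in c(i, j)) {
      eng$x[bd, ] <- eng$x[bd, ] + eng$v[bd, ] * (tk - eng$tloc[bd])
      eng$tloc[bd] <- tk
    }
    P <- eng$ptypes[[eng$tt[k]]]
    dx1 <- eng$x[j, 1] - eng$x[i, 1]; dx2 <- eng$x[j, 2] - eng$x[i, 2]
    dx3 <- eng$x[j, 3] - eng$x[i, 3]
    box <- eng$box
    dx1 <- dx1 - box * round(dx1 / box)
    dx2 <- dx2 - box * round(dx2 / box)
    dx3 <- dx3 - box * round(dx3 / box)
    r2 <- dx1 * dx1 + dx2 * dx2 + dx3 * dx3
    rr <- sqrt(r2)
    # snap the separation onto the boundary radius (mirrors the production
    # engine's round-off correction, bit for bit)
    Rb <- P$rad[bnd[k] + 1L]
    factor <- Rb / rr
    eng$x[j, 1] <- eng$x[j, 1] + dx1 * (factor - 1)
    eng$x[j, 2] <- eng$x[j, 2] + dx2 * (factor - 1)
    eng$x[j, 3] <- eng$x[j, 3] + dx3 * (factor - 1)
    dx1 <- dx1 * factor; dx2 <- dx2 * factor; dx3 <- dx3 * factor
    rr <- Rb
    nv1 <- dx1 / rr; nv2 <- dx2 / rr; nv3 <- dx3 / rr
    dv1 <- eng$v[j, 1] - eng$v[i, 1]; dv2 <- eng$v[j, 2] - eng$v[i, 2]
    dv3 <- eng$v[j, 3] - eng$v[i, 3]
    vr <- dv1 * nv1 + dv2 * nv2 + dv3 * nv3
    mi <- eng$mass[i]; mj <- eng$mass[j]; mu <- mi * mj / (mi + mj)
    dir <- dirv[k]
    from <- if (dir > 0L) bnd[k] else bnd[k] + 1L
    to <- if (dir > 0L) bnd[k] + 1L else bnd[k]
    Eto <- P$E[to + 1L]
    if (!is.finite(Eto)) {
      vrp <- -vr
      kindlog <- if (P$bonded) 5L else 1L
    } else {
      dU <- Eto - P$E[from + 1L]
      q <- vr * vr - 2 * dU / mu
      if (q > 0) {
        vrp <- (if (dir > 0L) 1 else -1) * sqrt(q)
        eng$s[k] <- to
        Upot <- Upot + dU
        kindlog <- if (dir > 0L) 3L else 2L
      } else {
        vrp <- -vr
        kindlog <- 4L
      }
    }
    dvr <- vrp - vr
    eng$v[i, 1] <- eng$v[i, 1] - (mu / mi) * dvr * nv1
    eng$v[i, 2] <- eng$v[i, 2] - (mu / mi) * dvr * nv2
    eng$v[i, 3] <- eng$v[i, 3] - (mu / mi) * dvr * nv3
    eng$v[j, 1] <- eng$v[j, 1] + (mu / mj) * dvr * nv1
    eng$v[j, 2] <- eng$v[j, 2] + (mu / mj) * dvr * nv2
    eng$v[j, 3] <- eng$v[j, 3] + (mu / mj) * dvr * nv3
    n_events <- n_events + 1L
    if (log_events) {
      if (n_events > cap) {        # grow geometrically
        cap <- cap * 2L
        length(log_t) <- cap; length(log_i) <- cap; length(log_j) <- cap
        length(log_kind) <- cap; length(log_bnd) <- cap
      }
      log_t[n_events] <- tk; log_i[n_events] <- i; log_j[n_events] <- j
      log_kind[n_events] <- kindlog; log_bnd[n_events] <- bnd[k]
    }
    # rescan: recompute candidates for every pair touching i or j
    for (kk in unique(c(pairs_of[[i]], pairs_of[[j]]))) {
      pr <- .ref_predict(eng, kk)
      tev[kk] <- pr[1]; bnd[kk] <- pr[2]; dirv[kk] <- pr[3]
    }
  }
  # propagate everything to t (only if we ran to completion)
  if (n_events < max_events) {
    for (bd in seq_len(n)) {
      eng$x[bd, ] <- eng$x[bd, ] + eng$v[bd, ] * (t - eng$tloc[bd])
      eng$tloc[bd] <- t
    }
    eng$tnow <- t
  }
  new_state <- state
  new_state$x <- eng$x
  new_state$v <- eng$v
  new_state$time <- state$time + eng$tnow
  lg <- NULL
  if (log_events) {
    keep <- seq_len(n_events)
    lg <- data.frame(t = state$time + log_t[keep], i = log_i[keep],
                     j = log_j[keep], kind = kindnames[log_kind[keep]],
                     bnd = log_bnd[keep])
  }
  list(state = new_state, log = lg, potential = Upot, n_events = n_events)
}
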