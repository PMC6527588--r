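# Shared fixtures and independent oracles for the test suite.

# --- toy states -----------------------------------------------------------

# Free beads with a two-shell square-well attraction in a periodic box.
# box < 4 * 0.62 forces the engine into all-pairs mode (no cell lists).
toy_gas_state <- function(n, box = 2.3, temperature = 0.6, seed = 1,
                          radii = c(0.35, 0.45, 0.62),
                          energies = c(Inf, -1, -0.5, 0)) {
  set.seed(seed)
  types <- list(list(radii = radii, energies = energies, bonded = FALSE))
  itab <- matrix(1L, n, n); diag(itab) <- 0L
  x <- matrix(stats::runif(3 * n, 0, box), n, 3)
  mind <- function(x) {
    d <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dd <- x[j, ] - x[i, ]; dd <- dd - box * round(dd / box)
      d <- min(d, sqrt(sum(dd * dd)))
    }
    d
  }
  tries <- 0
  while (mind(x) < radii[1] + 0.05 && tries < 2000) {
    x <- matrix(stats::runif(3 * n, 0, box), n, 3)
    tries <- tries + 1
  }
  v <- maxwell_velocities(n, temperature)
  make_raw_state(x, v, box, types, itab)
}

# 20 beads: two 4-bead bonded chains plus free beads, three interaction
# types (bond, pseudo-bond, two-shell well). All-pairs mode (small box).
toy_mixed_state <- function(seed = 1, box = 2.3, temperature = 0.6) {
  set.seed(seed)
  n <- 20
  types <- list(
    list(radii = c(0.345, 0.415), energies = c(Inf, 0, Inf), bonded = TRUE),
    list(radii = c(0.48, 0.75), energies = c(Inf, 0, Inf), bonded = TRUE),
    list(radii = c(0.35, 0.45, 0.62), energies = c(Inf, -1, -0.5, 0),
         bonded = FALSE))
  itab <- matrix(3L, n, n); diag(itab) <- 0L
  chain_of <- c(1, 1, 1, 1, 2, 2, 2, 2, rep(NA, 12))
  for (c0 in c(1, 5)) {
    for (i in c0:(c0 + 2)) { itab[i, i + 1] <- itab[i + 1, i] <- 1L }
    for (i in c0:(c0 + 1)) { itab[i, i + 2] <- itab[i + 2, i] <- 2L }
  }
  # chains as zig-zags, free beads placed clash-free
  zig <- function(org) {
    a <- 0.36; b <- sqrt(0.38^2 - a^2) / 2
    cbind(org[1] + (0:3) * a, org[2] + b * (-1)^(1:4), org[3])
  }
  x <- rbind(zig(c(0.3, 0.6, 0.5)), zig(c(0.3, 1.7, 1.6)))
  while (nrow(x) < n) {
    cand <- stats::runif(3, 0, box)
    d <- apply(x, 1, function(p) {
      dd <- cand - p; dd <- dd - box * round(dd / box); sqrt(sum(dd * dd))
    })
    if (min(d) > 0.45) x <- rbind(x, cand)
  }
  v <- maxwell_velocities(n, temperature)
  make_raw_state(x, v, box, types, itab)
}

# Hand-crafted multi-chain system from raw sequences (one segment per
# chain), for stability-scan toys where the full exon-1 layout is overkill.
toy_system <- function(seqs, segment = "R17") {
  cs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    structure(list(layout = data.frame(segment = segment,
                                       length = nchar(s),
                                       start = 1L, end = nchar(s),
                                       stringsAsFactors = FALSE),
                   sequence = s, label = paste0("toy", i), n = 0L),
              class = "pqd_construct")
  })
  build_system(cs)
}

# Valid (finite-energy) structure: parallel stretched chains built with the
# same geometry the engine starts from.
toy_structure <- function(seqs, spacing = 0.5, ff = default_forcefield()) {
  sys <- toy_system(seqs)
  topo <- build_topology(sys, ff)
  xs <- lapply(seq_along(seqs), function(ch) {
    res <- sys$table$global_index[sys$table$chain == ch]
    has_sc <- aa_class(sys$table$aa[res]) != "G"
    polyqdmd:::.stretched_chain(length(res), has_sc,
                                c(2, 5 + (ch - 1) * spacing, 5))
  })
  structure(list(x = do.call(rbind, xs), topology = topo,
                 tables = interaction_tables(topo), box = 50),
            class = "pqd_structure")
}

# --- independent oracles --------------------------------------------------

# O(N^2) double-loop potential + kinetic energy, written independently of
# the package's vectorized implementation.
brute_energy <- function(state) {
  x <- state$x; box <- state$box
  it <- state$tables$itab; types <- state$tables$types
  pot <- 0
  n <- nrow(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    t <- it[i, j]
    if (t == 0) next
    ty <- types[[t]]
    d <- x[j, ] - x[i, ]
    d <- d - box * round(d / box)
    r <- sqrt(sum(d * d))
    s <- 0
    for (rad in ty$radii) if (rad <= r) s <- s + 1
    pot <- pot + ty$energies[s + 1]
  }
  kin <- 0
  for (i in seq_len(n)) kin <- kin + 0.5 * state$mass[i] * sum(state$v[i, ]^2)
  list(potential = pot, kinetic = kin, total = pot + kin)
}

# Exhaustive connected-components clustering oracle (BFS on the d < cutoff
# graph), independent of the union-find implementation.
bfs_components <- function(D, cutoff) {
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(D[u, ] < cutoff & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Dense time-stepped oracle for the flight time to |r + v t| = d: bisection
# on a fine scan of |r(t)| - d sign changes.
scan_event_time <- function(r, v, d, t_max = 20, dt = 1e-4) {
  f <- function(t) sqrt(sum((r + v * t)^2)) - d
  ts <- seq(0, t_max, by = dt)
  fs <- vapply(ts, f, numeric(1))
  sgn <- fs[-1] * fs[-length(fs)]
  k <- which(sgn <= 0)[1]
  if (is.na(k)) return(NA_real_)
  lo <- ts[k]; hi <- ts[k + 1]
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Rotation-search RMSD oracle: coarse Euler-angle grid followed by
# Nelder-Mead refinement of the best grid points (with optimal translation
# built in), cross-checking the closed-form SVD superposition without using
# it.
grid_rmsd <- function(A, B, n_grid = 16) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  euler <- function(p) {
    a <- p[1]; b <- p[2]; cc <- p[3]
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(cc), -sin(cc), 0, sin(cc), cos(cc), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((B %*% t(euler(p)) - A)^2)))
  ang <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  cand <- list(); vals <- numeric(0)
  for (a in ang) for (b in seq(0, pi, length.out = n_grid / 2)) for (cc in ang) {
    cand[[length(cand) + 1L]] <- c(a, b, cc)
    vals <- c(vals, obj(c(a, b, cc)))
  }
  best <- Inf
  for (k in order(vals)[1:5]) {
    r <- stats::optim(cand[[k]], obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

# Analytic in-well occupancy of an isolated pair in a periodic box: the
# relative displacement is uniform over the box cube weighted by the
# Boltzmann factor of the piecewise potential.
pair_well_occupancy <- function(box, sigma, lambda, eps, temperature) {
  v_well <- 4 / 3 * pi * (lambda^3 - sigma^3)
  v_free <- box^3 - 4 / 3 * pi * lambda^3
  w <- v_well * exp(eps / temperature)
  w / (w + v_free)
}
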