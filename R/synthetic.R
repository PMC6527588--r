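# Synthetic fixtures with known ground truth: planted beta-cross
# trajectories, cluster bundles, and the two-level replica-exchange toy.
#
# Planted trajectories place ideal antiparallel strand pairs (rise 0.36
# nm/residue, planar zig-zag, inter-strand CA-CA spacing set by `contact`)
# for chosen residue ranges, and a compact helix-like curl everywhere else so
# that the extended-dihedral criterion rejects non-planted residues
# deterministically; Gaussian positional noise is added on top. Chains are
# laid out far apart so the only inter-chain proximity is the planted one.

#' Specify a planted strand pairing
#'
#' Helper building one row of the `planted` table for
#' [make_planted_trajectory()]: pairs (part of) a named segment of one chain
#' with (part of) a named segment of another, centred in each segment.
#'
#' @param system a `pqd_system`.
#' @param chain_a,segment_a,chain_b,segment_b the two regions to pair.
#' @param contact inter-strand CA-CA distance in nm; must not equal the
#'   0.4 nm contact cutoff (below it the pairing shows up in cross-beta maps,
#'   above it only in the beta labels).
#' @param frac fraction of frames in which the pairing is present.
#' @param length run length (residues); default pairs as much of both
#'   segments as possible.
#' @return one-row data.frame (chain_a, start_a, chain_b, start_b, length,
#'   contact, frac) with chain-local 1-based start offsets.
#' @export
plant_segment_pair <- function(system, chain_a, segment_a, chain_b, segment_b,
                               contact = 0.35, frac = 1, length = NULL) {
  seg_range <- function(ch, seg) {
    lay <- system$constructs[[ch]]$layout
    row <- lay[lay$segment == seg, ]
    if (nrow(row) != 1L) stop("no segment ", seg, " in chain ", ch, call. = FALSE)
    c(row$start, row$end)
  }
  ra <- seg_range(chain_a, segment_a); rb <- seg_range(chain_b, segment_b)
  len <- min(ra[2] - ra[1], rb[2] - rb[1]) + 1L
  if (!is.null(length)) len <- min(len, as.integer(length))
  data.frame(chain_a = chain_a,
             start_a = ra[1] + (ra[2] - ra[1] + 1L - len) %/% 2L,
             chain_b = chain_b,
             start_b = rb[1] + (rb[2] - rb[1] + 1L - len) %/% 2L,
             length = len, contact = contact, frac = frac)
}

#' Generate a trajectory with planted beta-cross structure
#'
#' Every row of `planted` pairs `length` residues starting at chain-local
#' offset `start_a` of `chain_a` antiparallel with the corresponding range of
#' `chain_b`, at inter-strand CA-CA distance `contact`, in a Bernoulli
#' fraction `frac` of frames (the partner strand is displaced far away in
#' "off" frames, so the planted residues keep extended geometry but lose
#' their partner). All other residues follow a compact helical curl. The
#' ground truth (per-residue beta frequency, per-frame on/off draws, planted
#' region pairs) is returned alongside the trajectory.
#'
#' @param system a `pqd_system`.
#' @param n_frames number of frames.
#' @param planted data.frame as built by [plant_segment_pair()] (rows may be
#'   concatenated with `rbind`).
#' @param noise_sd Gaussian positional noise per coordinate (nm).
#' @param seed RNG seed.
#' @param ff force field used only to build the bead topology.
#' @return list(trajectory = `pqd_traj`, truth = list(planted, on,
#'   beta_freq, pairs)).
#' @export
make_planted_trajectory <- function(system, n_frames = 100, planted,
                                    noise_sd = 0.005, seed = 1L,
                                    ff = default_forcefield()) {
  stopifnot(inherits(system, "pqd_system"), n_frames >= 1)
  topo <- build_topology(system, ff)
  tab <- system$table
  if (any(planted$contact == 0.4))
    stop("planted contact distance must not equal the 0.4 nm cutoff",
         call. = FALSE)
  # global residue index ranges of each planted strand
  glob <- function(ch, start, len) {
    idx <- tab$global_index[tab$chain == ch]
    if (start < 1 || start + len - 1L > length(idx))
      stop("planted segment outside chain ", ch, call. = FALSE)
    idx[start:(start + len - 1L)]
  }
  ga <- mapply(glob, planted$chain_a, planted$start_a, planted$length,
               SIMPLIFY = FALSE)
  gb <- mapply(glob, planted$chain_b, planted$start_b, planted$length,
               SIMPLIFY = FALSE)
  all_planted <- c(unlist(ga), unlist(gb))
  if (anyDuplicated(all_planted))
    stop("planted segments overlap", call. = FALSE)
  for (k in seq_len(nrow(planted)))
    if (planted$chain_a[k] == planted$chain_b[k] &&
        min(abs(outer(ga[[k]], gb[[k]], "-"))) < 3)
      stop("intra-chain planted pairing needs >= 3 residues of separation",
           call. = FALSE)
  R <- nrow(tab)
  # --- base coil geometry (helix-like curl per chain) --------------------
  base <- matrix(0, nrow(topo$beads), 3)
  r_h <- 0.245; pitch <- 0.06
  for (ch in unique(tab$chain)) {
    res <- tab$global_index[tab$chain == ch]
    th <- seq_along(res) * (100 * pi / 180)
    cx <- ch * 8
    ca <- cbind(cx + r_h * cos(th), r_h * sin(th), pitch * seq_along(res))
    sc <- cbind(cx + (r_h + 0.30) * cos(th), (r_h + 0.30) * sin(th),
                pitch * seq_along(res))
    base[topo$ca_of[res], ] <- ca
    sc_idx <- topo$sc_of[res]
    base[sc_idx[!is.na(sc_idx)], ] <- sc[!is.na(sc_idx), , drop = FALSE]
  }
  # --- planted strand geometry ------------------------------------------
  # "on" coordinates per row: strand a and (antiparallel) strand b
  set_strand <- function(X, res_ids, x0, sc_off) {
    m <- seq_along(res_ids) - 1L
    ca <- cbind(x0, m * 0.36, 20 + 0.061 * (-1)^m)
    X[topo$ca_of[res_ids], ] <- ca
    sc_idx <- topo$sc_of[res_ids]
    ok <- !is.na(sc_idx)
    sc <- ca; sc[, 3] <- sc[, 3] + sc_off
    X[sc_idx[ok], ] <- sc[ok, , drop = FALSE]
    X
  }
  zone_x <- -5 - 5 * (seq_len(nrow(planted)) - 1L)
  on_template <- base; off_template <- base
  for (k in seq_len(nrow(planted))) {
    bk <- rev(gb[[k]])                     # antiparallel alignment
    on_template <- set_strand(on_template, ga[[k]], zone_x[k], +0.30)
    on_template <- set_strand(on_template, bk, zone_x[k] + planted$contact[k],
                              -0.30)
    off_template <- set_strand(off_template, ga[[k]], zone_x[k], +0.30)
    off_template <- set_strand(off_template, bk, zone_x[k] + 3, -0.30)
  }
  # --- frames ------------------------------------------------------------
  set.seed(seed)
  on <- matrix(stats::runif(n_frames * nrow(planted)) <
                 rep(planted$frac, each = n_frames),
               n_frames, nrow(planted))
  beads_of_row <- lapply(seq_len(nrow(planted)), function(k) {
    res <- rev(gb[[k]])
    c(topo$ca_of[res], stats::na.omit(topo$sc_of[res]))
  })
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    X <- on_template
    for (k in seq_len(nrow(planted))) if (!on[f, k]) {
      ids <- beads_of_row[[k]]
      X[ids, ] <- off_template[ids, , drop = FALSE]
    }
    frames[[f]] <- X + matrix(stats::rnorm(length(X), 0, noise_sd),
                              nrow(X), 3)
  }
  # Ground-truth beta frequency. A strand residue is beta only if its
  # dihedral quadruple CA(i-1)..CA(i+2) lies inside the strand, i.e. the
  # interior [start+1, end-2] of each planted range; the three fringe
  # residues (start, end-1, end) border coil geometry and their dihedral is
  # not controlled, so they are marked NA (excluded from recovery checks).
  beta_freq <- numeric(R)
  mark <- function(g, frac) {
    beta_freq[g[2:(length(g) - 2L)]] <<- frac
    beta_freq[g[c(1L, length(g) - 1L, length(g))]] <<- NA_real_
  }
  for (k in seq_len(nrow(planted))) {
    if (planted$length[k] < 6L)
      stop("planted pairings need length >= 6 for a recoverable beta run",
           call. = FALSE)
    mark(ga[[k]], planted$frac[k])
    mark(gb[[k]], planted$frac[k])
  }
  regions <- region_labels(system)
  maj <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
  # aligned residue pairs per row: a position start_a+m pairs with
  # end_b-m; both sides have a guaranteed full-strand dihedral quadruple
  # (hence deterministic beta) only for m in 2..len-3 ("interior" pairs,
  # len-4 of them); pairs touching a strand fringe depend on the incidental
  # coil-jump geometry and are recorded but not pinned
  aligned <- do.call(rbind, lapply(seq_len(nrow(planted)), function(k) {
    L <- planted$length[k]
    m <- 0:(L - 1L)
    data.frame(row = k, ra = ga[[k]][m + 1L], rb = rev(gb[[k]])[m + 1L],
               interior = m >= 2L & m <= L - 3L,
               sub_cutoff = planted$contact[k] < 0.4,
               frac = planted$frac[k])
  }))
  pairs <- data.frame(
    region_a = vapply(ga, function(g) maj(regions[g]), ""),
    region_b = vapply(gb, function(g) maj(regions[g]), ""),
    contact = planted$contact, frac = planted$frac,
    length = planted$length,
    # exact expected mean contact count over the interior-aligned pairs
    expected_contacts = ifelse(planted$contact < 0.4,
                               pmax(planted$length - 4L, 0L) * planted$frac,
                               0))
  traj <- new_trajectory(frames, seq_len(n_frames), temperature = NA_real_,
                         box = NA_real_, topology = topo,
                         meta = list(seed = seed, synthetic = TRUE))
  list(trajectory = traj,
       truth = list(planted = planted, on = on, beta_freq = beta_freq,
                    pairs = pairs, aligned = aligned))
}

#' Generate a single-linkage cluster fixture
#'
#' `k` bundles of conformations around well-separated reference structures:
#' within a bundle every pairwise RMSD is below `spread`, between bundles
#' above `separation`, so single linkage at any cutoff in
#' `(spread, separation)` recovers the bundles exactly.
#'
#' @param sizes bundle sizes (length k).
#' @param spread maximum intra-bundle pairwise RMSD (Angstrom).
#' @param separation minimum inter-bundle RMSD (Angstrom).
#' @param n_beads beads per conformation.
#' @param seed RNG seed.
#' @return list(frames, labels) with `labels[i]` the bundle of frame i.
#' @export
make_cluster_fixture <- function(sizes, spread = 2, separation = 10,
                                 n_beads = 30, seed = 1L) {
  if (spread >= separation)
    stop("spread must be smaller than separation", call. = FALSE)
  k <- length(sizes)
  set.seed(seed)
  ok <- TRUE
  for (attempt in seq_len(50)) {
    refs <- lapply(seq_len(k), function(i)
      matrix(stats::rnorm(n_beads * 3, 0, 1), n_beads, 3))  # nm (1 nm = 10 A)
    if (k == 1) break
    ok <- TRUE
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (10 * .kabsch_rmsd(refs[[i]], refs[[j]]) < separation + spread)
        ok <- FALSE
    if (ok) break
  }
  if (!ok && k > 1) stop("could not separate reference structures", call. = FALSE)
  frames <- list(); labels <- integer(0)
  for (i in seq_len(k)) {
    for (m in seq_len(sizes[i])) {
      noise <- matrix(stats::rnorm(n_beads * 3), n_beads, 3)
      cand <- refs[[i]] + noise
      r <- 10 * .kabsch_rmsd(refs[[i]], cand)
      cand <- refs[[i]] + noise * (0.45 * spread / r)  # RMSD ~ 0.45 spread
      frames[[length(frames) + 1L]] <- cand
      labels <- c(labels, i)
    }
  }
  list(frames = frames, labels = labels, spread = spread,
       separation = separation)
}

#' Two-level toy system for replica-exchange validation
#'
#' A single degree of freedom with energies `{0, dE}`. The exact excited
#' occupancy at temperature T is `exp(-dE/T) / (1 + exp(-dE/T))` (-> 1/2 as
#' T -> infinity, -> 0 as T -> 0; equals 1/4 when dE/T = ln 3), which serves
#' as the analytic oracle for [remd_toy()].
#'
#' @param dE level spacing (> 0, reduced energy).
#' @param ladder a `pqd_ladder`.
#' @return object of class `pqd_two_level`: list(dE, ladder, p_excited).
#' @export
make_two_level_toy <- function(dE, ladder = make_ladder()) {
  if (dE <= 0) stop("dE must be positive", call. = FALSE)
  structure(list(dE = dE, ladder = ladder,
                 p_excited = function(temp) {
                   w <- exp(-dE / temp)
                   w / (1 + w)
                 }),
            class = "pqd_two_level")
}
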