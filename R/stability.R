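# Point-mutation stability scanning on oligomer structures.
#
# The free-energy surrogate dG of a structure is its total contact (pair
# potential) energy under the coarse-grained force field; a mutation changes
# the side-chain interaction class (or removes the side-chain bead for
# glycine), the side chains around the mutated site are re-packed by
# Monte-Carlo simulated annealing with the backbone fixed, and
# ddG = dG_mutant - dG_WT. Positive ddG destabilizes, negative stabilizes.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Extract a structure from a trajectory frame
#'
#' @param traj a `pqd_traj` with a topology (engine or synthetic output).
#' @param frame frame index (e.g. a cluster medoid).
#' @return object of class `pqd_structure`: list(x, topology, tables, box).
#' @export
structure_from_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "pqd_traj"))
  if (frame < 1 || frame > length(traj$frames))
    stop("frame index out of range", call. = FALSE)
  topo <- traj$topology
  structure(list(x = traj$frames[[frame]], topology = topo,
                 tables = interaction_tables(topo), box = traj$box),
            class = "pqd_structure")
}

#' Build a structure from a state
#' @param state a `pqd_state`.
#' @return a `pqd_structure`.
#' @export
structure_from_state <- function(state) {
  stopifnot(inherits(state, "pqd_state"))
  structure(list(x = state$x, topology = state$topology,
                 tables = state$tables, box = state$box),
            class = "pqd_structure")
}

#' Contact energy of a structure (the dG surrogate)
#' @param struct a `pqd_structure`.
#' @return reduced energy; `Inf` if the structure violates a hard constraint.
#' @export
structure_energy <- function(struct) {
  .pot_energy(struct$x, struct$tables, struct$box)
}

#' Apply a point mutation to a structure
#'
#' Rebuilds the bead topology with the substituted amino acid: the side-chain
#' interaction class changes; mutating to glycine removes the side-chain
#' bead; mutating glycine to another residue adds one (placed near the CA,
#' clash-free if possible, to be refined by [repack()]).
#'
#' @param struct a `pqd_structure`.
#' @param position global residue index.
#' @param aa one-letter code of the substituting amino acid.
#' @param seed RNG seed for the placement of a newly created side chain.
#' @return a `pqd_structure` carrying the mutation.
#' @export
mutate_structure <- function(struct, position, aa, seed = 1L) {
  topo <- struct$topology
  sys <- topo$system
  if (position < 1 || position > sys$total_length)
    stop("position out of range", call. = FALSE)
  aa <- toupper(aa)
  aa_class(aa)                                  # validates the code
  sys$table$aa[position] <- aa
  new_topo <- build_topology(sys, topo$ff)
  # map coordinates by (residue, kind)
  old_key <- paste(topo$beads$res, topo$beads$kind)
  new_key <- paste(new_topo$beads$res, new_topo$beads$kind)
  idx <- match(new_key, old_key)
  x <- matrix(NA_real_, nrow(new_topo$beads), 3)
  x[!is.na(idx), ] <- struct$x[idx[!is.na(idx)], , drop = FALSE]
  tables <- interaction_tables(new_topo)
  if (anyNA(x)) {                               # a side chain was created
    set.seed(seed)
    for (b in which(is.na(x[, 1]))) {
      ca <- new_topo$ca_of[new_topo$beads$res[b]]
      r0 <- mean(topo$ff$bond_ca_sc)
      best <- NULL; best_e <- Inf
      for (try in seq_len(64)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u * u))
        cand <- x[ca, ] + r0 * u
        x[b, ] <- cand
        e <- .bead_energy(x, tables, struct$box, b)
        if (e < best_e) { best_e <- e; best <- cand }
        if (is.finite(e)) break
      }
      x[b, ] <- best
    }
  }
  structure(list(x = x, topology = new_topo, tables = tables,
                 box = struct$box),
            class = "pqd_structure")
}

# Interaction energy of bead b with all other beads at coordinates x.
.bead_energy <- function(x, tables, box, b) {
  tp <- tables$itab[b, ]
  e <- 0
  for (t in unique(tp[tp > 0L])) {
    sel <- which(tp == t)
    type <- tables$types[[t]]
    dx <- .mi(x[sel, 1] - x[b, 1], box)
    dy <- .mi(x[sel, 2] - x[b, 2], box)
    dz <- .mi(x[sel, 3] - x[b, 3], box)
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    ei <- .energy_at(r, type)
    if (any(!is.finite(ei))) return(Inf)
    e <- e + sum(ei)
  }
  e
}

#' Simulated-annealing repack parameters
#'
#' @param shell repack shell: side chains of residues whose CA lies within
#'   this distance (nm) of the mutated CA are re-placed.
#' @param n_steps annealing steps.
#' @param t0,tf initial and final annealing temperature (geometric cooling).
#' @param step_sd side-chain displacement proposal s.d. (nm).
#' @return list of class `pqd_repack_params`.
#' @export
repack_params <- function(shell = 0.8, n_steps = 500, t0 = 1.0, tf = 0.05,
                          step_sd = 0.04) {
  structure(list(shell = shell, n_steps = n_steps, t0 = t0, tf = tf,
                 step_sd = step_sd), class = "pqd_repack_params")
}

#' Repack side chains around a site
#'
#' Monte-Carlo simulated annealing over the side-chain beads of all residues
#' whose CA lies within the repack shell of the given position's CA. The
#' backbone is fixed; proposals are Gaussian bead displacements, rejected
#' outright when they break the CA-SC bond window or a hard core (infinite
#' energy); cooling is geometric. Deterministic for a fixed seed.
#'
#' @param struct a `pqd_structure`.
#' @param position global residue index at the centre of the repack shell.
#' @param seed RNG seed.
#' @param params a [repack_params()] list.
#' @return list(x = repacked coordinates, dG = best total contact energy
#'   seen, moved = bead indices that were free to move).
#' @export
repack <- function(struct, position, seed = 1L, params = repack_params()) {
  topo <- struct$topology
  sys <- topo$system
  if (position < 1 || position > sys$total_length)
    stop("position out of range", call. = FALSE)
  ca_pos <- topo$ca_of[position]
  ca_all <- topo$ca_of
  d <- sqrt(rowSums(sweep(struct$x[ca_all, , drop = FALSE], 2,
                          struct$x[ca_pos, ])^2))
  res_in <- which(d <= params$shell)
  moved <- topo$sc_of[res_in]
  moved <- moved[!is.na(moved)]
  x <- struct$x
  E <- .pot_energy(x, struct$tables, struct$box)
  if (!length(moved))
    return(list(x = x, dG = E, moved = integer(0)))
  set.seed(seed)
  best_E <- E
  best_x <- x
  sched <- params$t0 * (params$tf / params$t0)^
    (seq(0, 1, length.out = params$n_steps))
  for (k in seq_len(params$n_steps)) {
    b <- moved[sample.int(length(moved), 1L)]
    old <- x[b, ]
    e_old <- .bead_energy(x, struct$tables, struct$box, b)
    x[b, ] <- old + stats::rnorm(3, 0, params$step_sd)
    e_new <- .bead_energy(x, struct$tables, struct$box, b)
    dE <- e_new - e_old
    if (is.finite(dE) && (dE <= 0 || stats::runif(1) < exp(-dE / sched[k]))) {
      E <- E + dE
      if (E < best_E) { best_E <- E; best_x <- x }
    } else {
      x[b, ] <- old
    }
  }
  list(x = best_x, dG = best_E, moved = moved)
}

#' ddG point-mutation scan
#'
#' For every (position, substitution) pair: both the wild-type and the mutant
#' structure are re-packed around the site (paired re-annealing with fresh
#' seeds each iteration), and ddG is the mean over iterations of
#' `dG_mutant - dG_WT`, reported with its standard deviation. Identity
#' substitutions are exactly zero by construction; proline substitutions are
#' flagged `"proline-omitted"` and skipped (the rigid proline ring makes the
#' surrogate unreliable), unless `compute_proline = TRUE`.
#'
#' @param struct a `pqd_structure` (typically a cluster medoid).
#' @param positions global residue indices to scan.
#' @param substitutions one-letter codes (default: the 20 amino acids).
#' @param iterations repack iterations averaged per mutation (default 250).
#' @param seed master seed.
#' @param params a [repack_params()] list.
#' @param compute_proline also compute (not just flag) proline substitutions.
#' @return object of class `pqd_ddg`: data.frame with columns `position`,
#'   `wt`, `sub`, `ddg`, `sd`, `n_iter`, `flag`.
#' @export
ddg_scan <- function(struct, positions, substitutions = .AA20,
                     iterations = 250, seed = 1L, params = repack_params(),
                     compute_proline = FALSE) {
  if (!length(positions)) stop("empty position list", call. = FALSE)
  tab <- struct$topology$system$table
  rows <- list()
  set.seed(seed)
  for (pos in positions) {
    wt <- tab$aa[pos]
    for (sub in substitutions) {
      if (sub == wt) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = pos, wt = wt, sub = sub, ddg = 0, sd = 0,
          n_iter = 0L, flag = "identity")
        next
      }
      if (sub == "P" && !compute_proline) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = pos, wt = wt, sub = sub, ddg = NA_real_, sd = NA_real_,
          n_iter = 0L, flag = "proline-omitted")
        next
      }
      mut <- mutate_structure(struct, pos, sub,
                              seed = sample.int(2^31 - 1, 1))
      d <- numeric(iterations)
      for (it in seq_len(iterations)) {
        s_wt <- sample.int(2^31 - 1, 1)
        s_mut <- sample.int(2^31 - 1, 1)
        d[it] <- repack(mut, pos, seed = s_mut, params = params)$dG -
                 repack(struct, pos, seed = s_wt, params = params)$dG
      }
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, wt = wt, sub = sub, ddg = mean(d), sd = stats::sd(d),
        n_iter = iterations,
        flag = if (sub == "P") "proline-omitted" else "ok")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pqd_ddg", "data.frame")
  out
}

#' Classify scan results
#'
#' Destabilizing if `ddg > tau`, stabilizing if `ddg < -tau`, else neutral;
#' the default threshold is one standard deviation of the estimate (per row).
#'
#' @param x a `pqd_ddg`.
#' @param tau classification threshold (reduced energy); `NULL` = per-row sd.
#' @return character vector of classifications (`NA` for omitted rows).
#' @export
classify_ddg <- function(x, tau = NULL) {
  thr <- if (is.null(tau)) x$sd else rep_len(tau, nrow(x))
  ifelse(is.na(x$ddg), NA_character_,
         ifelse(x$ddg > thr, "destabilizing",
                ifelse(x$ddg < -thr, "stabilizing", "neutral")))
}

#' @export
print.pqd_ddg <- function(x, ...) {
  cat(sprintf("<pqd_ddg> %d mutations at %d position(s)\n", nrow(x),
              length(unique(x$position))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Heat-map of a ddG scan
#'
#' Positions along x, substitutions along y; red = destabilizing (positive),
#' blue = stabilizing (negative), white = omitted/identity.
#' @param x a `pqd_ddg`; @param ... passed to [graphics::image()].
#' @export
plot.pqd_ddg <- function(x, ...) {
  pos <- sort(unique(x$position)); subs <- sort(unique(x$sub))
  M <- matrix(NA_real_, length(pos), length(subs),
              dimnames = list(pos, subs))
  M[cbind(match(x$position, pos), match(x$sub, subs))] <- x$ddg
  lim <- max(abs(M), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(63)
  graphics::image(seq_along(pos), seq_along(subs), M, zlim = c(-lim, lim),
                  col = pal, xlab = "position", ylab = "substitution",
                  axes = FALSE, ...)
  graphics::axis(1, seq_along(pos), pos)
  graphics::axis(2, seq_along(subs), subs, las = 1)
  graphics::box()
  invisible(x)
}

#' Write a ddG scan as CSV
#' @param x a `pqd_ddg`; @param path output file.
#' @return the path, invisibly.
#' @export
write_ddg <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
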