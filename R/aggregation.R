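# Aggregation analysis: mean smallest-distance maps, cross-beta contact maps
# at the 0.4 nm rule, aggregate-precursor calls and region-block summaries.

# Per-frame residue-pair smallest bead-bead distance matrix. Residues carry a
# CA bead and (except glycine) one side-chain bead; the residue-pair distance
# is the minimum over the up-to-4 bead pairs. Minimal image applied when the
# box is finite.
.res_min_dist <- function(frame, topology, box = NA) {
  tab <- topology$system$table
  R <- nrow(tab)
  pd <- function(idx_a, idx_b) {
    a <- frame[idx_a, , drop = FALSE]; b <- frame[idx_b, , drop = FALSE]
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    dz <- outer(a[, 3], b[, 3], "-")
    if (is.finite(box) && box > 0) {
      dx <- .mi(dx, box); dy <- .mi(dy, box); dz <- .mi(dz, box)
    }
    sqrt(dx * dx + dy * dy + dz * dz)
  }
  ca <- topology$ca_of
  sc <- topology$sc_of
  has_sc <- !is.na(sc)
  D <- pd(ca, ca)
  if (any(has_sc)) {
    scs <- sc[has_sc]
    Dcs <- matrix(Inf, R, R); Dsc <- matrix(Inf, R, R); Dss <- matrix(Inf, R, R)
    Dcs[, has_sc] <- pd(ca, scs)
    Dsc[has_sc, ] <- pd(scs, ca)
    Dss[has_sc, has_sc] <- pd(scs, scs)
    D <- pmin(D, Dcs, Dsc, Dss)
  }
  D
}

#' Mean smallest-distance map
#'
#' For every residue pair, the smallest bead-bead distance in each frame
#' (minimal image), averaged over frames.
#'
#' @param traj a `pqd_traj` with at least one frame.
#' @param topology optional `pqd_topology` override.
#' @return object of class `pqd_distance_map`: symmetric matrix (nm) with a
#'   zero diagonal; attributes `system`, `n_frames`.
#' @export
min_distance_map <- function(traj, topology = traj$topology) {
  stopifnot(inherits(traj, "pqd_traj"))
  if (length(traj$frames) < 1) stop("empty trajectory", call. = FALSE)
  acc <- NULL
  for (f in traj$frames) {
    D <- .res_min_dist(f, topology, traj$box)
    acc <- if (is.null(acc)) D else acc + D
  }
  M <- acc / length(traj$frames)
  diag(M) <- 0
  structure(M, class = c("pqd_distance_map", "matrix", "array"),
            system = topology$system, n_frames = length(traj$frames))
}

# Per-frame residue-pair bead-contact counts below the cutoff (strict <).
.res_contact_count <- function(frame, topology, cutoff, box = NA) {
  tab <- topology$system$table
  R <- nrow(tab)
  pd2 <- function(idx_a, idx_b) {
    a <- frame[idx_a, , drop = FALSE]; b <- frame[idx_b, , drop = FALSE]
    dx <- outer(a[, 1], b[, 1], "-")
    dy <- outer(a[, 2], b[, 2], "-")
    dz <- outer(a[, 3], b[, 3], "-")
    if (is.finite(box) && box > 0) {
      dx <- .mi(dx, box); dy <- .mi(dy, box); dz <- .mi(dz, box)
    }
    dx * dx + dy * dy + dz * dz
  }
  c2 <- cutoff * cutoff
  ca <- topology$ca_of; sc <- topology$sc_of
  has_sc <- !is.na(sc)
  cnt <- (pd2(ca, ca) < c2) + 0
  if (any(has_sc)) {
    scs <- sc[has_sc]
    A <- matrix(0, R, R); A[, has_sc] <- pd2(ca, scs) < c2
    B <- matrix(0, R, R); B[has_sc, ] <- pd2(scs, ca) < c2
    S <- matrix(0, R, R); S[has_sc, has_sc] <- pd2(scs, scs) < c2
    cnt <- cnt + A + B + S
  }
  cnt
}

#' Cross-beta contact map
#'
#' For every residue pair on *different* chains, the number of bead-bead
#' contacts closer than the cutoff in frames where *both* residues carry a
#' beta label, averaged over all frames (frames without qualifying contacts
#' contribute zero to the mean). The cutoff is strict (`< 0.4 nm` by
#' default); intra-chain entries are zero by construction.
#'
#' @param traj a `pqd_traj`.
#' @param annotations logical frames x residues matrix
#'   (from [beta_annotations()]).
#' @param cutoff contact cutoff in nm.
#' @param topology optional `pqd_topology` override.
#' @return object of class `pqd_crossbeta_map`: matrix of mean contact
#'   counts; attributes `system`, `n_frames`, `cutoff`.
#' @export
cross_beta_map <- function(traj, annotations, cutoff = 0.4,
                           topology = traj$topology) {
  stopifnot(inherits(traj, "pqd_traj"))
  if (length(traj$frames) < 1) stop("empty trajectory", call. = FALSE)
  if (nrow(annotations) != length(traj$frames))
    stop("annotations and trajectory have different frame counts", call. = FALSE)
  tab <- topology$system$table
  inter <- outer(tab$chain, tab$chain, "!=")
  acc <- matrix(0, nrow(tab), nrow(tab))
  for (fi in seq_along(traj$frames)) {
    bb <- annotations[fi, ]
    mask <- inter & outer(bb, bb, "&")
    if (!any(mask)) next
    cnt <- .res_contact_count(traj$frames[[fi]], topology, cutoff, traj$box)
    acc <- acc + cnt * mask
  }
  M <- acc / length(traj$frames)
  structure(M, class = c("pqd_crossbeta_map", "matrix", "array"),
            system = topology$system, n_frames = length(traj$frames),
            cutoff = cutoff)
}

#' Call aggregate precursors in one frame
#'
#' An aggregate precursor is a conformation with a beta sheet involving both
#' proteins: a connected run (>= `run_min` residues on each side) of
#' inter-chain beta pairing. Paired residues are beta-labelled residues on
#' different chains with CA-CA distance within the pairing cutoff; pairs are
#' grouped into patches by sequence adjacency on both sides, and each patch
#' is reported as the (chain:segment, chain:segment) region pair of the
#' majority of its members.
#'
#' @param frame N x 3 bead coordinates.
#' @param annotation logical vector over residues (beta labels for this frame).
#' @param topology a `pqd_topology`.
#' @param box box edge for minimal-image distances.
#' @param params a [beta_params()] list (pairing cutoff and run length).
#' @return data.frame with columns `region_a`, `region_b`, `n_a`, `n_b`
#'   (residue counts on each side); zero rows if no precursor.
#' @export
call_precursors <- function(frame, annotation, topology, box = NA,
                            params = beta_params()) {
  tab <- topology$system$table
  R <- nrow(tab)
  ca <- frame[topology$ca_of, , drop = FALSE]
  dx <- outer(ca[, 1], ca[, 1], "-")
  dy <- outer(ca[, 2], ca[, 2], "-")
  dz <- outer(ca[, 3], ca[, 3], "-")
  if (is.finite(box) && box > 0) {
    dx <- .mi(dx, box); dy <- .mi(dy, box); dz <- .mi(dz, box)
  }
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  pairmat <- d <= params$pair_cut & outer(tab$chain, tab$chain, "<") &
    outer(annotation, annotation, "&")
  hits <- which(pairmat, arr.ind = TRUE)
  empty <- data.frame(region_a = character(0), region_b = character(0),
                      n_a = integer(0), n_b = integer(0))
  if (!nrow(hits)) return(empty)
  # group pairs into patches: (i,j) ~ (i',j') when both indices are adjacent
  np <- nrow(hits)
  comp <- seq_len(np)
  find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
  for (a in seq_len(np - 1L)) for (b in (a + 1L):np) {
    if (abs(hits[a, 1] - hits[b, 1]) <= 1L && abs(hits[a, 2] - hits[b, 2]) <= 1L) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) comp[rb] <- ra
    }
  }
  roots <- vapply(seq_len(np), find, integer(1))
  regions <- region_labels(topology$system)
  out <- lapply(unique(roots), function(rt) {
    m <- hits[roots == rt, , drop = FALSE]
    ia <- unique(m[, 1]); ib <- unique(m[, 2])
    if (length(ia) < params$run_min || length(ib) < params$run_min) return(NULL)
    maj <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
    data.frame(region_a = maj(regions[ia]), region_b = maj(regions[ib]),
               n_a = length(ia), n_b = length(ib))
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) empty else out[order(out$region_a, out$region_b), , drop = FALSE]
}

#' Precursor region pairs over a trajectory
#'
#' Applies [call_precursors()] to every frame and tallies how often each
#' region pair appears.
#'
#' @inheritParams cross_beta_map
#' @param params a [beta_params()] list.
#' @return data.frame: region_a, region_b, n_frames, fraction.
#' @export
precursor_summary <- function(traj, annotations, topology = traj$topology,
                              params = beta_params()) {
  tallies <- list()
  for (fi in seq_along(traj$frames)) {
    pc <- call_precursors(traj$frames[[fi]], annotations[fi, ], topology,
                          traj$box, params)
    if (nrow(pc))
      for (k in seq_len(nrow(pc))) {
        key <- paste(pc$region_a[k], pc$region_b[k], sep = "|")
        tallies[[key]] <- (tallies[[key]] %||% 0L) + 1L
      }
  }
  if (!length(tallies))
    return(data.frame(region_a = character(0), region_b = character(0),
                      n_frames = integer(0), fraction = numeric(0)))
  parts <- strsplit(names(tallies), "|", fixed = TRUE)
  data.frame(region_a = vapply(parts, `[[`, "", 1L),
             region_b = vapply(parts, `[[`, "", 2L),
             n_frames = unlist(tallies, use.names = FALSE),
             fraction = unlist(tallies, use.names = FALSE) / length(traj$frames))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Region-block summary of a residue-pair map
#'
#' Mean of the map entries within every (chain:segment) x (chain:segment)
#' block, the region-level reduction used for map figures.
#'
#' @param map a residue-pair matrix ([min_distance_map()] or
#'   [cross_beta_map()] output).
#' @param system a `pqd_system` (defaults to the map's).
#' @return symmetric matrix with region labels as dimnames.
#' @export
region_block_summary <- function(map, system = attr(map, "system")) {
  labs <- region_labels(system)
  u <- unique(labs)
  f <- factor(labs, levels = u)
  M <- unclass(map)
  S <- t(rowsum(t(rowsum(M, f)), f))         # S[gA, gB]: rows gA, cols gB
  n <- as.vector(table(f))
  structure(S / outer(n, n), dimnames = list(u, u))
}

#' Write a residue-pair map as CSV
#' @param map matrix; @param path output file.
#' @return the path, invisibly.
#' @export
write_map <- function(map, path) {
  utils::write.csv(as.data.frame(unclass(map)), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.pqd_distance_map <- function(x, ...) {
  cat(sprintf("<pqd_distance_map> %d residues, %d frames, mean %.3f nm\n",
              nrow(x), attr(x, "n_frames"), mean(x[upper.tri(x)])))
  invisible(x)
}

#' @export
print.pqd_crossbeta_map <- function(x, ...) {
  cat(sprintf("<pqd_crossbeta_map> %d residues, %d frames, total mass %.3f\n",
              nrow(x), attr(x, "n_frames"), sum(x) / 2))
  invisible(x)
}
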