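# Conformational clustering: pairwise CA-RMSD after optimal superposition,
# single-linkage clusters at a 4 A cutoff, medoid (central) structures.

# Kabsch optimal superposition of B onto A (both centred), via SVD.
.kabsch_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A <- sweep(A, 2, ca); B <- sweep(B, 2, cb)
  H <- crossprod(B, A)                        # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bf <- B %*% t(R)
  sqrt(mean(rowSums((Bf - A)^2)))
}

#' Pairwise RMSD matrix of trajectory frames
#'
#' CA-RMSD (in Angstrom) between every pair of frames after least-squares
#' rigid superposition of the whole multi-chain system (optimal rotation via
#' the SVD solution).
#'
#' @param traj a `pqd_traj` with >= 2 frames, or a list of N x 3 coordinate
#'   matrices in nm with identical dimensions.
#' @param topology optional `pqd_topology`; when given, only CA beads enter
#'   the superposition; otherwise all rows are used.
#' @return symmetric matrix of RMSDs in Angstrom, zero diagonal.
#' @export
pairwise_rmsd <- function(traj, topology = NULL) {
  frames <- if (inherits(traj, "pqd_traj")) {
    if (is.null(topology)) topology <- traj$topology
    traj$frames
  } else traj
  if (length(frames) < 2) stop("need at least two frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3))
    stop("frames have mismatched dimensions", call. = FALSE)
  if (!is.null(topology)) frames <- lapply(frames, function(f)
    f[topology$ca_of, , drop = FALSE])
  nf <- length(frames)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf)
    D[i, j] <- D[j, i] <- 10 * .kabsch_rmsd(frames[[i]], frames[[j]])
  D
}

#' Single-linkage clustering at a distance cutoff
#'
#' Clusters are the connected components of the graph joining structures at
#' distance strictly below the cutoff ("a structure joins a cluster when its
#' distance to any member is below the cutoff"); chaining is the intended
#' behaviour. Clusters are ordered by decreasing size, ties broken by the
#' smallest member frame id; the medoid of a cluster is the member with the
#' smallest mean distance to its co-members (ties again to the smallest id).
#'
#' @param dist_mat symmetric distance matrix (Angstrom).
#' @param cutoff linkage cutoff; structures closer than this are joined
#'   (default 4 Angstrom = 0.4 nm).
#' @return object of class `pqd_clusters`: list with `membership` (cluster id
#'   per structure), `sizes`, `medoids` (frame id per cluster), `cutoff`.
#' @export
single_linkage <- function(dist_mat, cutoff = 4) {
  D <- as.matrix(dist_mat)
  n <- nrow(D)
  if (n != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  parent <- seq_len(n)
  find <- function(a) { r <- a; while (parent[r] != r) r <- parent[r]; r }
  if (n > 1) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (D[i, j] < cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), root)
  sizes <- lengths(comp)
  ord <- order(-sizes, vapply(comp, min, integer(1)))
  comp <- comp[ord]
  membership <- integer(n)
  for (k in seq_along(comp)) membership[comp[[k]]] <- k
  medoids <- vapply(comp, function(m) {
    if (length(m) == 1L) return(m)
    md <- rowSums(D[m, m, drop = FALSE]) / (length(m) - 1L)  # mean over co-members
    m[which.min(md)]
  }, integer(1))
  structure(list(membership = membership, sizes = unname(lengths(comp)),
                 medoids = unname(medoids), cutoff = cutoff, n = n),
            class = "pqd_clusters")
}

#' @export
print.pqd_clusters <- function(x, ...) {
  cat(sprintf("<pqd_clusters> %d structures in %d clusters (cutoff %g A)\n",
              x$n, length(x$sizes), x$cutoff))
  k <- min(5, length(x$sizes))
  cat("largest:", paste(x$sizes[seq_len(k)], collapse = ", "),
      if (length(x$sizes) > k) "..." else "", "\n")
  invisible(x)
}

#' @export
plot.pqd_clusters <- function(x, ...) {
  graphics::barplot(x$sizes, names.arg = seq_along(x$sizes),
                    xlab = "cluster", ylab = "number of structures", ...)
  invisible(x)
}

#' Cluster a trajectory
#'
#' Convenience wrapper: pairwise CA-RMSD then single linkage.
#'
#' @param traj a `pqd_traj`.
#' @param cutoff linkage cutoff in Angstrom.
#' @param topology optional topology override.
#' @return a `pqd_clusters` with the RMSD matrix attached as attribute `dist`.
#' @export
cluster_conformations <- function(traj, cutoff = 4, topology = NULL) {
  D <- pairwise_rmsd(traj, topology)
  cl <- single_linkage(D, cutoff)
  attr(cl, "dist") <- D
  cl
}

#' Write a cluster report as CSV
#' @param clusters a `pqd_clusters`; @param path output file.
#' @return the path, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  utils::write.csv(data.frame(cluster = seq_along(clusters$sizes),
                              size = clusters$sizes,
                              medoid_frame = clusters$medoids),
                   path, row.names = FALSE)
  invisible(path)
}
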