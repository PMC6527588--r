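# Beta-structure assignment for the coarse-grained model and per-residue
# beta-probability profiles with binomial error bars.
#
# Atomistic secondary-structure tools (STRIDE/DSSP) need backbone atoms the
# two-bead model does not have, so beta is assigned from CA geometry: a
# residue is beta when its virtual CA dihedral is extended AND it has a
# cross-strand partner (another residue at least 3 positions away in
# sequence, or on another chain, with CA-CA distance within the pairing
# cutoff), in a run of at least 3 consecutive such residues.

#' Parameters of the beta-assignment criterion
#'
#' @param dihedral_min minimum |virtual dihedral| in degrees for the extended
#'   window (default 135; ideal strands are near 180, helices near +50).
#' @param pair_cut cross-strand CA-CA pairing cutoff in nm (default 0.55).
#' @param min_sep minimum sequence separation for an intra-chain partner.
#' @param run_min minimum run length of paired extended residues.
#' @return list of class `pqd_beta_params`.
#' @export
beta_params <- function(dihedral_min = 135, pair_cut = 0.55, min_sep = 3,
                        run_min = 3) {
  structure(list(dihedral_min = dihedral_min, pair_cut = pair_cut,
                 min_sep = min_sep, run_min = run_min),
            class = "pqd_beta_params")
}

# Virtual CA dihedrals along one chain (L x 3 matrix of CA coordinates).
# Returns a vector of length L with NA at positions 1, L-1, L (no quadruple):
# the value at position i is the torsion of CA(i-1), CA(i), CA(i+1), CA(i+2).
.ca_dihedrals <- function(ca) {
  L <- nrow(ca)
  out <- rep(NA_real_, L)
  if (L < 4) return(out)
  b1 <- ca[2:(L - 2), , drop = FALSE] - ca[1:(L - 3), , drop = FALSE]
  b2 <- ca[3:(L - 1), , drop = FALSE] - ca[2:(L - 2), , drop = FALSE]
  b3 <- ca[4:L, , drop = FALSE] - ca[3:(L - 1), , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  out[2:(L - 2)] <- atan2(y, x) * 180 / pi
  out
}

#' Assign beta labels to one frame
#'
#' @param frame N x 3 bead coordinate matrix (nm).
#' @param topology the `pqd_topology` describing the beads.
#' @param box cubic box edge for minimal-image distances (`NA` = open space).
#' @param params a [beta_params()] list.
#' @return logical vector over global residues: is the residue beta?
#' @export
assign_beta <- function(frame, topology, box = NA, params = beta_params()) {
  stopifnot(inherits(topology, "pqd_topology"))
  tab <- topology$system$table
  R <- nrow(tab)
  ca <- frame[topology$ca_of, , drop = FALSE]
  chain <- tab$chain
  # (a) extended virtual dihedral, computed per chain
  extended <- logical(R)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    if (length(idx) < 4) next                     # short chain: all "other"
    dh <- .ca_dihedrals(ca[idx, , drop = FALSE])
    extended[idx] <- !is.na(dh) & abs(dh) >= params$dihedral_min
  }
  # (b) cross-strand partner within the pairing cutoff
  dx <- outer(ca[, 1], ca[, 1], "-")
  dy <- outer(ca[, 2], ca[, 2], "-")
  dz <- outer(ca[, 3], ca[, 3], "-")
  if (is.finite(box) && box > 0) {
    dx <- .mi(dx, box); dy <- .mi(dy, box); dz <- .mi(dz, box)
  }
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  eligible <- outer(chain, chain, "!=") |
    abs(outer(seq_len(R), seq_len(R), "-")) >= params$min_sep
  paired <- rowSums(d <= params$pair_cut & eligible) > 0
  cond <- extended & paired
  # (c) runs of >= run_min consecutive residues, per chain
  beta <- logical(R)
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    r <- rle(cond[idx])
    keep <- r$values & r$lengths >= params$run_min
    beta[idx] <- rep(keep, r$lengths)
  }
  beta
}

#' Beta annotations for a whole trajectory
#'
#' @param traj a `pqd_traj` (its topology is used unless `topology` given).
#' @param topology optional `pqd_topology` override.
#' @param params a [beta_params()] list.
#' @return logical matrix, frames x residues.
#' @export
beta_annotations <- function(traj, topology = traj$topology,
                             params = beta_params()) {
  stopifnot(inherits(traj, "pqd_traj"))
  out <- vapply(traj$frames, assign_beta,
                logical(nrow(topology$system$table)),
                topology = topology, box = traj$box, params = params)
  t(out)
}

#' Binomial error half-width
#'
#' `z * sqrt(p (1 - p) / N)`, the normal-approximation half-width of a
#' binomial proportion at confidence level given by `z` (1.96 for 95%). At
#' N = 4000 the maximum over p is 0.0155, i.e. 0.015 to two significant
#' figures.
#'
#' @param p estimated probability (vectorized).
#' @param n number of sampled configurations.
#' @param z normal quantile (default 1.96).
#' @return half-width(s).
#' @export
binom_halfwidth <- function(p, n, z = 1.96) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  z * sqrt(p * (1 - p) / n)
}

#' Per-residue beta-probability profile
#'
#' @param annotations logical matrix frames x residues
#'   (from [beta_annotations()]).
#' @param system optional `pqd_system` for region labels.
#' @param z normal quantile for the error bars.
#' @return object of class `pqd_beta_profile`: data.frame with columns
#'   `residue`, `region` (if system given), `p`, `dp`, plus attribute
#'   `n_frames`.
#' @export
beta_profile <- function(annotations, system = NULL, z = 1.96) {
  if (is.null(dim(annotations)) || nrow(annotations) < 1)
    stop("need at least one frame of annotations", call. = FALSE)
  N <- nrow(annotations)
  p <- colMeans(annotations)
  out <- data.frame(residue = seq_along(p),
                    region = if (is.null(system)) NA_character_
                             else region_labels(system),
                    p = p, dp = binom_halfwidth(p, N, z))
  attr(out, "n_frames") <- N
  attr(out, "z") <- z
  class(out) <- c("pqd_beta_profile", "data.frame")
  out
}

#' @export
print.pqd_beta_profile <- function(x, ...) {
  cat(sprintf("<pqd_beta_profile> %d residues, %d frames, max dp = %.4f\n",
              nrow(x), attr(x, "n_frames"), max(x$dp)))
  invisible(x)
}

#' @export
plot.pqd_beta_profile <- function(x, ...) {
  graphics::plot(x$residue, x$p, type = "h", lwd = 2,
                 xlab = "residue", ylab = expression(beta ~ probability),
                 ylim = c(0, max(0.05, max(x$p + x$dp))), ...)
  graphics::arrows(x$residue, pmax(0, x$p - x$dp), x$residue, x$p + x$dp,
                   angle = 90, code = 3, length = 0.01, col = "grey40")
  invisible(x)
}

#' Write a beta profile as CSV
#' @param x a `pqd_beta_profile`; @param path output file.
#' @return the path, invisibly.
#' @export
write_beta_profile <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
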