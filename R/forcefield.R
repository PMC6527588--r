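# Coarse-grained bead model and discrete (stepwise) pair potentials.
#
# Two beads per residue: a backbone CA-like bead and one side-chain bead
# (absent for glycine). Geometry is maintained by infinite-well bonds
# (CA(i)-CA(i+1), CA(i)-SC(i)) plus a CA(i)-CA(i+2) pseudo-bond standing in
# for the virtual bond angle. Non-bonded interactions are piecewise-constant
# square wells: a backbone-backbone attraction acting as a hydrogen-bond
# surrogate (this is what lets strands pair into beta structure), and
# side-chain class-pair wells in which glutamine-glutamine attraction is the
# deepest, so polyQ tracts drive aggregation. All quantities are in reduced
# units (lengths nm, k_B = 1, bead mass 1).

.AA_CLASS <- local({
  cl <- c(Q = "Q", P = "P", G = "G")
  for (a in strsplit("AVLIMFWYC", "")[[1L]]) cl[[a]] <- "H"
  for (a in strsplit("STNDEKRHX", "")[[1L]]) cl[[a]] <- "O"
  cl
})

#' Amino-acid interaction class
#'
#' Maps one-letter codes to the side-chain classes of the coarse-grained
#' force field: `"Q"` (glutamine), `"P"` (proline), `"H"` (hydrophobic:
#' AVLIMFWYC), `"O"` (other/polar), `"G"` (glycine, no side-chain bead).
#' @param aa character vector of one-letter codes.
#' @return character vector of classes.
#' @export
aa_class <- function(aa) {
  cl <- .AA_CLASS[toupper(aa)]
  if (any(is.na(cl))) stop("unknown amino-acid code(s): ",
                           paste(unique(aa[is.na(cl)]), collapse = ", "),
                           call. = FALSE)
  unname(cl)
}

#' Default coarse-grained force field
#'
#' Returns the parameter set of the stepwise pair potentials. Well depths are
#' ordered so that Q-Q side-chain attraction (eps 0.55) and the
#' backbone-backbone hydrogen-bond surrogate (eps 0.33) dominate over
#' proline-involving contacts (eps 0.06): polyQ tracts and backbone pairing
#' drive beta-cross formation while polyproline stretches stay inert. These
#' defaults are declared, not fitted; see the package vignette.
#'
#' @return Object of class `pqd_forcefield` (a named list). Fields:
#' \describe{
#'   \item{bond_ca_ca, bond_ca_sc, pseudo_ca_ca2}{infinite-well bond windows
#'     `[d_min, d_max]` in nm.}
#'   \item{core}{hard-core diameters per bead-kind pair (nm).}
#'   \item{hb_shell, hb_eps}{outer radius and depth of the backbone-backbone
#'     well (applies to CA pairs separated by >= 3 residues or on different
#'     chains).}
#'   \item{sc_shells, sc_shell_frac}{outer radii of the two side-chain wells
#'     and their depth multipliers (inner shell full depth, outer half).}
#'   \item{class_eps}{symmetric matrix of side-chain pair depths by class.}
#' }
#' @export
default_forcefield <- function() {
  classes <- c("Q", "P", "H", "O")
  # The energy scale is set so that the simulated temperature window
  # (0.5-0.72 reduced units) brackets the dimer pairing/melting transition:
  # a zipped two-chain beta ribbon gains roughly one Q-Q well plus one
  # backbone well per residue, so short (23Q) pairings melt within the
  # window while long (74Q) ones survive at its cold end - the
  # length-dependent stability the model exists to express.
  eps <- matrix(0, 4, 4, dimnames = list(classes, classes))
  eps["Q", "Q"] <- 0.55
  eps["H", "H"] <- 0.40
  eps["Q", "H"] <- eps["H", "Q"] <- 0.28
  eps["Q", "O"] <- eps["O", "Q"] <- 0.22
  eps["H", "O"] <- eps["O", "H"] <- 0.17
  eps["O", "O"] <- 0.17
  eps["P", ] <- eps[, "P"] <- 0.06
  structure(list(
    mass = c(CA = 1, SC = 1),
    bond_ca_ca = c(0.345, 0.415),
    bond_ca_sc = c(0.200, 0.320),
    # virtual-angle surrogate biased to extended backbone geometry (tight
    # turns are disallowed), which is what lets strands pair into beta
    # structure at all in a two-bead model
    pseudo_ca_ca2 = c(0.620, 0.720),
    # 1-4 distance window (virtual-dihedral surrogate): keeps the backbone
    # trans-extended, forbidding the tight turns a two-bead chain would
    # otherwise make freely
    pseudo_ca_ca3 = c(0.980, 1.110),
    core = c(ca_ca = 0.38, ca_sc = 0.33, sc_sc = 0.35),
    hb_shell = 0.56, hb_eps = 0.33,
    sc_shells = c(0.45, 0.62), sc_shell_frac = c(1.0, 0.5),
    class_eps = eps,
    version = "cg-1.0"
  ), class = "pqd_forcefield")
}

#' Hash of a force-field parameter set
#'
#' Deterministic content hash recorded in run metadata so trajectories carry
#' the provenance of the parameters that produced them.
#' @param ff a `pqd_forcefield`.
#' @return character scalar.
#' @export
forcefield_hash <- function(ff) {
  s <- paste(utils::capture.output(utils::str(ff, digits.d = 12)), collapse = "\n")
  # polynomial rolling hash in double precision (exact below 2^53)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read / write a force-field parameter file
#'
#' Plain key: value text with vector fields space-separated and the class
#' matrix given row-wise as `eps_<A><B>` entries.
#' @param path file path.
#' @param ff a `pqd_forcefield` (for writing).
#' @return `read_forcefield` returns a `pqd_forcefield`.
#' @export
write_forcefield <- function(ff, path) {
  ln <- c(
    sprintf("version: %s", ff$version),
    sprintf("bond_ca_ca: %.6g %.6g", ff$bond_ca_ca[1], ff$bond_ca_ca[2]),
    sprintf("bond_ca_sc: %.6g %.6g", ff$bond_ca_sc[1], ff$bond_ca_sc[2]),
    sprintf("pseudo_ca_ca2: %.6g %.6g", ff$pseudo_ca_ca2[1], ff$pseudo_ca_ca2[2]),
    sprintf("pseudo_ca_ca3: %.6g %.6g", ff$pseudo_ca_ca3[1], ff$pseudo_ca_ca3[2]),
    sprintf("core: %.6g %.6g %.6g", ff$core[["ca_ca"]], ff$core[["ca_sc"]], ff$core[["sc_sc"]]),
    sprintf("hb: %.6g %.6g", ff$hb_shell, ff$hb_eps),
    sprintf("sc_shells: %.6g %.6g", ff$sc_shells[1], ff$sc_shells[2]),
    sprintf("sc_shell_frac: %.6g %.6g", ff$sc_shell_frac[1], ff$sc_shell_frac[2])
  )
  cls <- rownames(ff$class_eps)
  for (i in seq_along(cls)) for (j in i:length(cls))
    ln <- c(ln, sprintf("eps_%s%s: %.6g", cls[i], cls[j], ff$class_eps[i, j]))
  writeLines(ln, path)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ff <- default_forcefield()
  for (line in readLines(path, warn = FALSE)) {
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    kv <- strsplit(line, ":", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = ":"))
    if (key == "version") { ff$version <- val; next }
    nums <- as.numeric(strsplit(val, "\\s+")[[1L]])
    if (key == "core") ff$core[] <- nums
    else if (key == "hb") { ff$hb_shell <- nums[1]; ff$hb_eps <- nums[2] }
    else if (startsWith(key, "eps_")) {
      ab <- strsplit(sub("eps_", "", key), "")[[1L]]
      ff$class_eps[ab[1L], ab[2L]] <- ff$class_eps[ab[2L], ab[1L]] <- nums
    } else if (key %in% names(ff)) ff[[key]] <- nums
    else stop("unknown force-field key: ", key, call. = FALSE)
  }
  ff
}

#' Build the bead topology of a system
#'
#' Two beads per residue (CA + side chain), side-chain bead absent for
#' glycine; bead count per chain of length L is `2L - #G`. Covalent links are
#' CA(i)-CA(i+1), CA(i)-SC(i) and the CA(i)-CA(i+2) pseudo-bond.
#'
#' @param system a `pqd_system`.
#' @param ff a `pqd_forcefield`.
#' @return Object of class `pqd_topology`: list with `beads` (data.frame:
#'   bead, chain, res (global residue index), kind ("CA"/"SC"), aa, class,
#'   mass) and `bonds` (data.frame: i, j, dmin, dmax, kind).
#' @export
build_topology <- function(system, ff = default_forcefield()) {
  stopifnot(inherits(system, "pqd_system"))
  tab <- system$table
  cls <- aa_class(tab$aa)
  has_sc <- cls != "G"
  nres <- nrow(tab)
  kind <- unlist(lapply(seq_len(nres), function(i) if (has_sc[i]) c("CA", "SC") else "CA"),
                 use.names = FALSE)
  res <- rep(tab$global_index, ifelse(has_sc, 2L, 1L))
  beads <- data.frame(bead = seq_along(res), chain = tab$chain[res], res = res,
                      kind = kind, aa = tab$aa[res], class = cls[res],
                      mass = unname(ff$mass[ifelse(kind == "CA", "CA", "SC")]),
                      stringsAsFactors = FALSE)
  ca_of <- integer(nres); sc_of <- rep(NA_integer_, nres)
  ca_of[beads$res[beads$kind == "CA"]] <- beads$bead[beads$kind == "CA"]
  sc_of[beads$res[beads$kind == "SC"]] <- beads$bead[beads$kind == "SC"]
  bonds <- list()
  for (ch in unique(tab$chain)) {
    r <- tab$global_index[tab$chain == ch]
    if (length(r) > 1L)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = ca_of[r[-length(r)]], j = ca_of[r[-1L]],
        dmin = ff$bond_ca_ca[1], dmax = ff$bond_ca_ca[2], kind = "ca_ca")
    if (length(r) > 2L)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = ca_of[r[1:(length(r) - 2L)]], j = ca_of[r[-(1:2)]],
        dmin = ff$pseudo_ca_ca2[1], dmax = ff$pseudo_ca_ca2[2], kind = "ca_ca2")
    if (length(r) > 3L)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = ca_of[r[1:(length(r) - 3L)]], j = ca_of[r[-(1:3)]],
        dmin = ff$pseudo_ca_ca3[1], dmax = ff$pseudo_ca_ca3[2], kind = "ca_ca3")
  }
  rs <- which(has_sc)
  if (length(rs))
    bonds[[length(bonds) + 1L]] <- data.frame(
      i = ca_of[rs], j = sc_of[rs],
      dmin = ff$bond_ca_sc[1], dmax = ff$bond_ca_sc[2], kind = "ca_sc")
  bonds <- do.call(rbind, bonds)
  structure(list(beads = beads, bonds = bonds, ca_of = ca_of, sc_of = sc_of,
                 system = system, ff = ff),
            class = "pqd_topology")
}

#' @export
print.pqd_topology <- function(x, ...) {
  cat(sprintf("<pqd_topology> %d beads (%d CA, %d SC), %d bonds\n",
              nrow(x$beads), sum(x$beads$kind == "CA"), sum(x$beads$kind == "SC"),
              nrow(x$bonds)))
  invisible(x)
}

# Interaction type table: each type is a list(radii, energies, bonded, name)
# with energies[s] the energy for r in (radii[s-1], radii[s]] and
# energies[m+1] the energy beyond the outermost radius. Infinite entries are
# hard walls. The convention at a boundary is right-continuous: at exactly
# r = radii[k] the pair counts as outside shell k.
.make_type <- function(name, radii, energies, bonded = FALSE)
  list(name = name, radii = radii, energies = energies, bonded = bonded)

#' Interaction tables for a topology
#'
#' Precomputes, for every unordered bead pair, which discrete potential
#' applies: bond wells for bonded pairs, the backbone hydrogen-bond surrogate
#' for non-local CA pairs, class-pair side-chain wells, and pure hard cores
#' for local exclusions. The result drives both the event-driven engine and
#' all energy evaluations.
#'
#' @param topology a `pqd_topology`.
#' @return list with `itab` (NxN integer matrix of 1-based type ids, 0 on the
#'   diagonal) and `types` (list of type records).
#' @export
interaction_tables <- function(topology) {
  stopifnot(inherits(topology, "pqd_topology"))
  ff <- topology$ff
  b <- topology$beads
  n <- nrow(b)
  types <- list(
    .make_type("bond_ca_ca", ff$bond_ca_ca, c(Inf, 0, Inf), bonded = TRUE),
    .make_type("bond_ca_sc", ff$bond_ca_sc, c(Inf, 0, Inf), bonded = TRUE),
    .make_type("pseudo_ca_ca2", ff$pseudo_ca_ca2, c(Inf, 0, Inf), bonded = TRUE),
    .make_type("hb_ca_ca", c(ff$core[["ca_ca"]], ff$hb_shell), c(Inf, -ff$hb_eps, 0)),
    .make_type("core_ca_sc", ff$core[["ca_sc"]], c(Inf, 0)),
    .make_type("core_sc_sc", ff$core[["sc_sc"]], c(Inf, 0)),
    .make_type("core_ca_ca", ff$core[["ca_ca"]], c(Inf, 0)),
    .make_type("pseudo_ca_ca3", ff$pseudo_ca_ca3, c(Inf, 0, Inf), bonded = TRUE)
  )
  cls <- rownames(ff$class_eps)
  sc_type_id <- matrix(NA_integer_, length(cls), length(cls),
                       dimnames = list(cls, cls))
  for (a in seq_along(cls)) for (bb in a:length(cls)) {
    e <- ff$class_eps[a, bb]
    types[[length(types) + 1L]] <- .make_type(
      paste0("sc_", cls[a], cls[bb]),
      c(ff$core[["sc_sc"]], ff$sc_shells),
      c(Inf, -e * ff$sc_shell_frac, 0))
    sc_type_id[a, bb] <- sc_type_id[bb, a] <- length(types)
  }
  isCA <- b$kind == "CA"
  res <- b$res; chain <- b$chain
  same_chain <- outer(chain, chain, "==")
  dres <- abs(outer(res, res, "-"))
  bothCA <- outer(isCA, isCA, "&")
  bothSC <- outer(!isCA, !isCA, "&")
  mixed <- !(bothCA | bothSC)
  itab <- matrix(0L, n, n)
  itab[bothCA & same_chain & dres == 1L] <- 1L
  itab[bothCA & same_chain & dres == 2L] <- 3L
  # hydrogen-bond surrogate between chains only: intermolecular beta pairing
  # is the modelled phenomenon; an isotropic intra-chain backbone attraction
  # would collapse single chains into non-beta globules instead
  itab[bothCA & same_chain & dres == 3L] <- 8L
  itab[bothCA & same_chain & dres > 3L] <- 7L
  itab[bothCA & !same_chain] <- 4L
  itab[mixed & dres == 0L] <- 2L              # CA(i)-SC(i) bond
  itab[mixed & dres > 0L] <- 5L
  itab[bothSC & same_chain & dres <= 2L] <- 6L
  far_sc <- bothSC & (!same_chain | dres > 2L)
  if (any(far_sc)) {
    ci <- match(b$class, cls)
    pair_cls <- matrix(sc_type_id[cbind(rep(ci, n), rep(ci, each = n))], n, n)
    itab[far_sc] <- pair_cls[far_sc]
  }
  diag(itab) <- 0L
  list(itab = itab, types = types)
}

#' Discrete potential acting between two beads
#'
#' Returns the stepwise potential record for a bead pair: hard-core /
#' shell radii (nm, strictly increasing), the step energies per shell
#' (right-continuous at boundaries, 0 beyond the outermost radius) and
#' whether the pair is covalently bonded (infinite well).
#'
#' @param topology a `pqd_topology`.
#' @param tables result of [interaction_tables()] for it.
#' @param a,b bead indices.
#' @return list(name, radii, energies, bonded), or `NULL` for the self pair.
#' @export
pair_potential <- function(topology, tables, a, b) {
  n <- nrow(topology$beads)
  if (a < 1L || a > n || b < 1L || b > n)
    stop("bead index out of range", call. = FALSE)
  t <- tables$itab[a, b]
  if (t == 0L) return(NULL)
  tables$types[[t]]
}

# Piecewise-constant energy lookup, vectorized over r for one type.
# Right-continuous: at r == radius the outer value applies.
.energy_at <- function(r, type) {
  type$energies[findInterval(r, type$radii) + 1L]
}

# Minimal-image displacement components (vectorized)
.mi <- function(d, box) d - box * round(d / box)

#' Potential + kinetic energy of a system state
#'
#' Sums all pair step energies under the minimal-image convention plus the
#' kinetic energy. Errors on hard-core overlap or a bonded pair outside its
#' well (inconsistent state).
#'
#' @param state a `pqd_state` (see [init_state()]).
#' @param parts if TRUE return `list(potential, kinetic, total)`.
#' @return total energy (reduced units), or the parts list.
#' @export
system_energy <- function(state, parts = FALSE) {
  pot <- .pot_energy(state$x, state$tables, state$box, error_on_inf = TRUE)
  kin <- 0.5 * sum(state$mass * rowSums(state$v^2))
  if (parts) list(potential = pot, kinetic = kin, total = pot + kin)
  else pot + kin
}

# Total pair potential of a coordinate set; Inf (or an error) on hard-core
# overlap / a bonded pair outside its well.
.pot_energy <- function(x, tables, box, error_on_inf = FALSE) {
  it <- tables$itab
  pot <- 0
  ut <- upper.tri(it)
  for (t in seq_along(tables$types)) {
    sel <- which(ut & it == t, arr.ind = TRUE)
    if (!nrow(sel)) next
    type <- tables$types[[t]]
    dx <- .mi(x[sel[, 2], 1] - x[sel[, 1], 1], box)
    dy <- .mi(x[sel[, 2], 2] - x[sel[, 1], 2], box)
    dz <- .mi(x[sel[, 2], 3] - x[sel[, 1], 3], box)
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    e <- .energy_at(r, type)
    if (any(!is.finite(e))) {
      if (error_on_inf) {
        k <- which(!is.finite(e))[1L]
        nm <- if (is.null(type$name)) "pair" else type$name
        stop(sprintf("inconsistent state: pair (%d,%d) of type %s at r=%.4f nm",
                     sel[k, 1], sel[k, 2], nm, r[k]), call. = FALSE)
      }
      return(Inf)
    }
    pot <- pot + sum(e)
  }
  pot
}
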