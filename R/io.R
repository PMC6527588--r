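# Trajectory I/O: multi-model PDB (CA/CB pseudo-atoms, chain IDs, Angstrom)
# with a JSON sidecar carrying what PDB cannot (frame times, temperature,
# box, seeds, force-field hash, and the residue table needed to rebuild the
# system). Round-trips preserve coordinates at the written precision
# (3 decimals in Angstrom = 1e-4 nm).

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL", X = "UNK")
.AA1 <- stats::setNames(names(.AA3), .AA3)

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a trajectory as multi-model PDB + JSON sidecar
#'
#' @param traj a `pqd_traj` with a topology.
#' @param path output PDB path; the sidecar is written to `<path>.json`.
#' @param wrap wrap coordinates into the primary box image before writing
#'   (default FALSE: frames are stored unwrapped so whole-system RMSD and
#'   visual continuity are preserved; all distance analyses use minimal
#'   image regardless).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, wrap = FALSE) {
  stopifnot(inherits(traj, "pqd_traj"))
  topo <- traj$topology
  if (is.null(topo)) stop("trajectory has no topology", call. = FALSE)
  b <- topo$beads
  tab <- topo$system$table
  # chain-local residue numbering
  resseq <- stats::ave(tab$global_index, tab$chain, FUN = seq_along)[b$res]
  atname <- ifelse(b$kind == "CA", "CA", "CB")
  resname <- .AA3[b$aa]
  chainid <- LETTERS[b$chain]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    X <- traj$frames[[f]]
    if (wrap && is.finite(traj$box) && traj$box > 0)
      X <- X - traj$box * floor(X / traj$box)
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(X)), atname, resname, chainid, resseq,
      10 * X[, 1], 10 * X[, 2], 10 * X[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  meta <- traj$meta
  meta$seed <- if (is.null(meta$seed)) NA else meta$seed
  jsonlite::write_json(
    list(format = "polyqdmd-traj-1",
         n_frames = length(traj$frames),
         times = traj$times,
         temperature = traj$temperature,
         box = traj$box,
         potential = traj$potential,
         kinetic = traj$kinetic,
         meta = meta,
         labels = vapply(topo$system$constructs, `[[`, "", "label"),
         residue_table = tab),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(path)
}

# Rebuild a pqd_system from a sidecar residue table.
.system_from_table <- function(tab, labels = NULL) {
  cs <- lapply(unique(tab$chain), function(ch) {
    sub <- tab[tab$chain == ch, ]
    segs <- rle(sub$segment)
    lay <- data.frame(segment = segs$values, length = segs$lengths,
                      start = c(1L, utils::head(cumsum(segs$lengths), -1L) + 1L),
                      end = cumsum(segs$lengths), stringsAsFactors = FALSE)
    structure(list(layout = lay, sequence = paste(sub$aa, collapse = ""),
                   label = if (!is.null(labels) && length(labels) >= ch)
                     labels[ch] else sprintf("chain-%d", ch),
                   n = sum(sub$segment == "polyQ")),
              class = "pqd_construct")
  })
  build_system(cs)
}

#' Read a multi-model PDB trajectory (with its JSON sidecar)
#'
#' Parse errors report the offending line number. The sidecar is required;
#' its absence is an error naming the expected file.
#'
#' @param path the PDB path written by [write_trajectory()].
#' @param ff force field used to rebuild the bead topology.
#' @return a `pqd_traj`.
#' @export
read_trajectory <- function(path, ff = default_forcefield()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- .sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar: expected ", sc, call. = FALSE)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  lines <- readLines(path, warn = FALSE)
  model_at <- which(startsWith(lines, "MODEL"))
  end_at <- which(startsWith(lines, "ENDMDL"))
  if (!length(model_at)) stop("no MODEL records in ", path, call. = FALSE)
  if (length(model_at) != length(end_at))
    stop(sprintf("unbalanced MODEL/ENDMDL blocks in %s (%d vs %d)",
                 path, length(model_at), length(end_at)), call. = FALSE)
  frames <- vector("list", length(model_at))
  n_atoms <- NA_integer_
  for (m in seq_along(model_at)) {
    lo <- model_at[m] + 1L; hi <- end_at[m] - 1L
    if (hi < lo) stop("empty MODEL block at line ", model_at[m], call. = FALSE)
    blk <- lines[lo:hi]
    is_atom <- startsWith(blk, "ATOM")
    if (!all(is_atom))
      stop("malformed record at line ", lo + which(!is_atom)[1L] - 1L,
           call. = FALSE)
    xs <- suppressWarnings(cbind(as.numeric(substr(blk, 31, 38)),
                                 as.numeric(substr(blk, 39, 46)),
                                 as.numeric(substr(blk, 47, 54))))
    if (anyNA(xs))
      stop("unparseable coordinates at line ",
           lo + which(rowSums(is.na(xs)) > 0)[1L] - 1L, call. = FALSE)
    if (is.na(n_atoms)) n_atoms <- nrow(xs)
    else if (nrow(xs) != n_atoms)
      stop(sprintf("model %d has %d atoms, expected %d (line %d)",
                   m, nrow(xs), n_atoms, model_at[m]), call. = FALSE)
    frames[[m]] <- xs / 10                      # Angstrom -> nm
  }
  tab <- as.data.frame(side$residue_table)
  system <- .system_from_table(tab, side$labels)
  topo <- build_topology(system, ff)
  if (nrow(topo$beads) != n_atoms)
    stop(sprintf("sidecar residue table implies %d beads but PDB has %d",
                 nrow(topo$beads), n_atoms), call. = FALSE)
  new_trajectory(frames,
                 times = as.numeric(side$times),
                 temperature = if (is.null(side$temperature)) NA_real_
                               else as.numeric(side$temperature),
                 box = if (is.null(side$box)) NA_real_ else as.numeric(side$box),
                 topology = topo,
                 meta = as.list(side$meta),
                 potential = if (is.null(side$potential)) NULL
                             else as.numeric(side$potential),
                 kinetic = if (is.null(side$kinetic)) NULL
                           else as.numeric(side$kinetic))
}

#' Write a single structure as PDB
#' @param struct a `pqd_structure` (or a `pqd_traj` frame via
#'   [structure_from_frame()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure_pdb <- function(struct, path) {
  traj <- new_trajectory(list(struct$x), times = 0,
                         box = struct$box %||% NA_real_,
                         topology = struct$topology)
  write_trajectory(traj, path)
}

#' Parse a length with unit suffix
#'
#' Accepts e.g. `"0.4 nm"`, `"4 A"`, `"4 angstrom"`, or a bare number taken
#' to be nm. Returns nm.
#' @param x character or numeric scalar.
#' @return length in nm.
#' @export
parse_length <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  m <- regmatches(x, regexec("^([0-9.eE+-]+)\\s*([A-Za-z]*)$", x))[[1L]]
  if (length(m) != 3L || m[2] == "")
    stop("cannot parse length: ", x, call. = FALSE)
  val <- as.numeric(m[2])
  unit <- tolower(m[3])
  if (unit %in% c("", "nm")) val
  else if (unit %in% c("a", "ang", "angstrom")) val / 10
  else stop("unknown length unit: ", m[3], call. = FALSE)
}

#' Default run configuration
#'
#' All defaults equal the production protocol where one exists: 20 replicas
#' spanning temperatures 0.5-0.72, temperature swaps every 1000 time units,
#' 0.4 nm contact cutoff, 4 Angstrom cluster cutoff, 250 ddG repack
#' iterations, z = 1.96 error bars. Desk-scale overrides are passed as
#' arguments.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return list of class `pqd_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_replicas = 20, t_min = 0.5, t_max = 0.72,
    exchange_interval = 1000,
    t_total = 4e6,
    dt_sample = 1000,
    thermostat = 0.5,
    contact_cutoff = 0.4,          # nm
    cluster_cutoff = 4,            # Angstrom
    beta_pair_cut = 0.55,          # nm
    ddg_iterations = 250,
    z = 1.96,
    seed = 1L,
    box_edge = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  for (f in c("contact_cutoff", "beta_pair_cut"))
    cfg[[f]] <- parse_length(cfg[[f]])
  if (is.character(cfg$cluster_cutoff))
    cfg$cluster_cutoff <- 10 * parse_length(cfg$cluster_cutoff)
  structure(cfg, class = "pqd_config")
}
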