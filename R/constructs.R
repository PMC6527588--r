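# Construct building: exon-1-like chains assembled from named segments and
# residue-index bookkeeping across chains.

# Fixed segment lengths encoded by the segment names. polyQ length is the free
# parameter n.
.SEGMENT_LENGTHS <- c(N17 = 17L, P11 = 11L, R17 = 17L, P10 = 10L, R12 = 12L)

# Default placeholder sequences for segments whose true identities are not
# bundled with the package. N17 is the canonical
# huntingtin N-terminal 17-mer; R17/R12 are SYNTHETIC placeholder sequences
# flagged as such (see ?build_construct). They are laid out so that the
# field-named interface residues (L64/P65 in R17, L194 in R17 of a second
# chain) carry the expected amino acid under the default layout.
.DEFAULT_SEGMENT_SEQS <- c(
  N17 = "MATLEKLMKAFESLKSF",
  R17 = "ELAEKSALQEQFLPSAE", # synthetic placeholder: L at offsets 2 and 13, P at 14
  R12 = "EAVAEELAKSQA"       # synthetic placeholder
)

#' Segment layout of an exon-1-like construct
#'
#' Returns the ordered segment decomposition N17 -> polyQ(n) -> P11 -> R17 ->
#' P10 -> R12. This order is the unique one consistent with the regions in
#' which the eight interface residues named in the literature fall
#' (Q37/Q38 in chain-1 polyQ, L64/P65 in chain-1 R17, Q175 in chain-2 polyQ,
#' P191/P192 in chain-2 P11, L194 in chain-2 R17 for the 23Q+74Q dimer).
#'
#' @param n polyQ repeat count (positive integer).
#' @return A data.frame with columns `segment`, `length`, `start`, `end`
#'   (1-based residue positions within the chain).
#' @export
segment_layout <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("polyQ repeat count `n` must be a positive integer", call. = FALSE)
  segs <- c("N17", "polyQ", "P11", "R17", "P10", "R12")
  lens <- c(17L, n, 11L, 17L, 10L, 12L)
  end <- cumsum(lens)
  data.frame(segment = segs, length = lens,
             start = c(1L, head(end, -1L) + 1L), end = end,
             stringsAsFactors = FALSE)
}

#' Build an exon-1-like construct
#'
#' Assembles a chain of n + 67 residues in the order N17, polyQ(n), P11, R17,
#' P10, R12. The polyQ segment is all glutamine and P11/P10 are all proline by
#' construction. N17 defaults to the canonical huntingtin N-terminal sequence;
#' R17 and R12 default to bundled synthetic placeholder sequences (their true
#' identities are not distributed with the package) and can be
#' overridden per segment.
#'
#' @param n polyQ repeat count, e.g. 23 (wild-type-like) or 74 (expanded).
#' @param label construct label; default `"HTT-<n>Q"`.
#' @param segment_seqs optional named character vector overriding the default
#'   sequences of N17/R17/R12 (each must have the segment's fixed length).
#' @return An object of class `pqd_construct`: list with `layout` (see
#'   [segment_layout()]), `sequence` (one-letter string), `label`, `n`.
#' @examples
#' build_construct(23)$label
#' nchar(build_construct(74)$sequence) # 141
#' @export
build_construct <- function(n, label = NULL, segment_seqs = NULL) {
  layout <- segment_layout(n)
  seqs <- .DEFAULT_SEGMENT_SEQS
  if (!is.null(segment_seqs)) {
    bad <- setdiff(names(segment_seqs), c("N17", "R17", "R12"))
    if (length(bad)) stop("cannot override segment(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    seqs[names(segment_seqs)] <- segment_seqs
  }
  for (s in names(seqs)) {
    if (nchar(seqs[[s]]) != .SEGMENT_LENGTHS[[s]])
      stop(sprintf("sequence for %s must have length %d", s, .SEGMENT_LENGTHS[[s]]),
           call. = FALSE)
  }
  piece <- function(seg, len) {
    switch(seg,
           polyQ = strrep("Q", len),
           P11 = strrep("P", len),
           P10 = strrep("P", len),
           seqs[[seg]])
  }
  sequence <- paste0(mapply(piece, layout$segment, layout$length), collapse = "")
  stopifnot(nchar(sequence) == sum(layout$length))
  structure(list(layout = layout, sequence = sequence,
                 label = if (is.null(label)) sprintf("HTT-%dQ", as.integer(n)) else label,
                 n = as.integer(n)),
            class = "pqd_construct")
}

#' @export
print.pqd_construct <- function(x, ...) {
  cat(sprintf("<pqd_construct> %s: %d residues\n", x$label, nchar(x$sequence)))
  print(x$layout, row.names = FALSE)
  invisible(x)
}

#' Assemble a multi-chain system specification
#'
#' Combines 1-3 constructs into a system with continuous 1-based global
#' residue numbering across chains in the listed order, matching the
#' cross-chain residue indices used in the field (e.g. Q175 falls in the
#' polyQ tract of the second chain of a 23Q+74Q dimer).
#'
#' Note on ternary numbering: for a 23Q+23Q+74Q ternary system continuous
#' numbering spans 1-321 (chains cover 1-90, 91-180, 181-321). Reports that
#' cite "residue 270" are consistent with this scheme (270 falls in the
#' third chain's polyQ tract) but "residue 38" in the same breath can only
#' refer to chain-local numbering of one of the 23Q chains; both readings
#' are plausible and neither is guessed at by this package - `global_index()`
#' always uses the continuous scheme.
#'
#' @param ... constructs created by [build_construct()] (or a single list of
#'   them), 1 to 3 chains.
#' @param box_edge optional cubic box edge length (nm), stored for simulation
#'   setup; `NULL` lets the engine pick one from the chain extents.
#' @return Object of class `pqd_system`: list with `constructs`, `n_chain`,
#'   `chain_offsets` (global index preceding each chain), `total_length`,
#'   `box_edge`, and a residue `table` (global_index, chain, segment, offset, aa).
#' @export
build_system <- function(..., box_edge = NULL) {
  cs <- list(...)
  if (length(cs) == 1L && !inherits(cs[[1L]], "pqd_construct")) cs <- cs[[1L]]
  if (!length(cs) || length(cs) > 3L)
    stop("a system holds 1 to 3 constructs", call. = FALSE)
  if (!all(vapply(cs, inherits, logical(1), "pqd_construct")))
    stop("all arguments must be pqd_construct objects", call. = FALSE)
  lens <- vapply(cs, function(co) sum(co$layout$length), integer(1))
  offsets <- c(0L, cumsum(lens)[-length(lens)])
  tabs <- lapply(seq_along(cs), function(k) {
    co <- cs[[k]]
    lay <- co$layout
    seg <- rep(lay$segment, lay$length)
    off <- unlist(lapply(lay$length, seq_len), use.names = FALSE)
    data.frame(global_index = offsets[k] + seq_len(lens[k]),
               chain = k, segment = seg, offset = off,
               aa = strsplit(co$sequence, "")[[1L]],
               stringsAsFactors = FALSE)
  })
  structure(list(constructs = cs, n_chain = length(cs),
                 chain_offsets = offsets, total_length = sum(lens),
                 box_edge = box_edge,
                 table = do.call(rbind, tabs)),
            class = "pqd_system")
}

#' @export
print.pqd_system <- function(x, ...) {
  cat(sprintf("<pqd_system> %d chain(s), %d residues: %s\n", x$n_chain,
              x$total_length,
              paste(vapply(x$constructs, `[[`, "", "label"), collapse = " + ")))
  invisible(x)
}

#' Decompose a global residue index
#'
#' Maps a 1-based continuous global residue index to (chain, segment,
#' within-segment offset). The inverse is [residue_index()].
#'
#' @param system a `pqd_system`.
#' @param residue global residue index (vectorized).
#' @return data.frame with columns `chain`, `segment`, `offset`.
#' @examples
#' sys <- build_system(build_construct(23), build_construct(74))
#' global_index(sys, 175) # chain 2, polyQ, offset 68
#' @export
global_index <- function(system, residue) {
  stopifnot(inherits(system, "pqd_system"))
  residue <- as.integer(residue)
  if (any(is.na(residue)) || any(residue < 1L) || any(residue > system$total_length))
    stop(sprintf("residue index out of range 1..%d", system$total_length), call. = FALSE)
  system$table[residue, c("chain", "segment", "offset")]
}

#' Recompose a global residue index
#'
#' Inverse of [global_index()]: (chain, segment, offset) -> global index.
#' @param system a `pqd_system`.
#' @param chain chain number; @param segment segment name; @param offset
#'   1-based offset within the segment.
#' @return integer global index.
#' @export
residue_index <- function(system, chain, segment, offset) {
  stopifnot(inherits(system, "pqd_system"))
  tab <- system$table
  idx <- mapply(function(ch, sg, of) {
    hit <- which(tab$chain == ch & tab$segment == sg & tab$offset == of)
    if (length(hit) != 1L)
      stop(sprintf("no residue (chain %s, %s, offset %s)", ch, sg, of), call. = FALSE)
    tab$global_index[hit]
  }, chain, segment, offset)
  as.integer(idx)
}

#' Region label per residue
#'
#' Convenience: "chain:segment" label for every global residue index, used by
#' map block summaries and precursor calls.
#' @param system a `pqd_system`.
#' @return character vector of length `system$total_length`.
#' @export
region_labels <- function(system) {
  paste0(system$table$chain, ":", system$table$segment)
}

#' Read a construct specification file
#'
#' A minimal key:value format with fields `n` (required), `label` (optional)
#' and `fasta` (optional path to a FASTA file with records named N17/R17/R12
#' overriding the placeholder segment sequences).
#' @param path file path.
#' @return a `pqd_construct`.
#' @export
read_construct_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1L], collapse = ":"), ""))
  spec <- stats::setNames(as.list(vals), keys)
  if (is.null(spec$n)) stop("construct spec needs field `n`", call. = FALSE)
  overrides <- NULL
  if (!is.null(spec$fasta)) {
    fp <- spec$fasta
    if (!file.exists(fp)) fp <- file.path(dirname(path), spec$fasta)
    overrides <- read_fasta(fp)
  }
  build_construct(as.integer(spec$n),
                  label = spec$label,
                  segment_seqs = overrides)
}

#' Read a FASTA file into a named character vector
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- vapply(strsplit(names_, "\\s+"), `[[`, "", 1L)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) toupper(gsub("\\s", "", paste(x, collapse = ""))), "")
  stats::setNames(seqs, names_)
}
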