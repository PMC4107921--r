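#' Default van der Waals radii
#'
#' Bondi-type radii (Angstrom) by element; elements not in the table fall back
#' to the carbon-like default.
#'
#' @param default radius for unknown elements.
#' @return named numeric vector with a `default` attribute, class `vdw_table`.
#' @export
default_vdw_table <- function(default = 1.70) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  if (any(radii <= 0.5 | radii >= 3.0) || default <= 0.5 || default >= 3.0)
    stop("van der Waals radii must lie in (0.5, 3.0) Angstrom")
  structure(radii, default = default, class = "vdw_table")
}

.vdw_radius <- function(table, element) {
  r <- unname(table[element])
  r[is.na(r)] <- attr(table, "default")
  r
}

.mainchain_names <- c("N", "CA", "C", "O")

# Reduce alternate conformations to a single conformer per atom: for atoms
# sharing (residue, atom name), keep the highest occupancy (ties: first in
# file order, which favours conformer A).
.primary_conformer <- function(atoms) {
  key <- paste(residue_key(atoms$chain, atoms$seqnum, atoms$icode), atoms$name)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Detect interatomic van der Waals clashes
#'
#' Reports every unordered atom pair whose separation falls short of the sum
#' of the two van der Waals radii by more than `min_overlap`. Excluded pairs:
#' atoms in the same residue; pairs involving a main-chain atom (N, CA, C, O)
#' of sequence-adjacent residues of the same chain (bonded peptide contacts);
#' and atoms carrying different non-blank alternate-location codes. Alternate
#' conformations are first reduced to the highest-occupancy conformer. A
#' spatial binning grid keeps the cost near-linear in the atom count; no
#' crystallographic symmetry mates are considered.
#'
#' @param m an [xtal_model].
#' @param radii a [default_vdw_table]-style radius table.
#' @param min_overlap minimal overlap (Angstrom) to report; the default 0.10
#'   suppresses marginal contacts attributable to liberal restraint settings.
#' @return data.frame with one row per clash: chain/seqnum/icode/resname/atom
#'   for both partners, the distance and the overlap (Angstrom).
#' @export
detect_clashes <- function(m, radii = default_vdw_table(), min_overlap = 0.10) {
  atoms <- .primary_conformer(m$atoms)
  n <- nrow(atoms)
  empty <- data.frame(chain_a = character(0), seqnum_a = integer(0),
                      icode_a = character(0), resname_a = character(0),
                      atom_a = character(0), chain_b = character(0),
                      seqnum_b = integer(0), icode_b = character(0),
                      resname_b = character(0), atom_b = character(0),
                      distance = numeric(0), overlap = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  r <- .vdw_radius(radii, atoms$element)
  cut <- 2 * max(r)  # largest possible clashing distance

  cx <- floor(atoms$x / cut); cy <- floor(atoms$y / cut); cz <- floor(atoms$z / cut)
  cells <- split(seq_len(n), paste(cx, cy, cz))
  pairs_i <- integer(0); pairs_j <- integer(0)
  cell_of <- paste(cx, cy, cz)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  for (cname in names(cells)) {
    ijk <- as.integer(strsplit(cname, " ")[[1]])
    here <- cells[[cname]]
    for (o in seq_len(nrow(offsets))) {
      key <- paste(ijk[1] + offsets$dx[o], ijk[2] + offsets$dy[o],
                   ijk[3] + offsets$dz[o])
      there <- cells[[key]]
      if (is.null(there)) next
      grid_pairs <- expand.grid(i = here, j = there)
      keep <- grid_pairs$i < grid_pairs$j
      pairs_i <- c(pairs_i, grid_pairs$i[keep])
      pairs_j <- c(pairs_j, grid_pairs$j[keep])
    }
  }
  if (!length(pairs_i)) return(empty)
  dup <- duplicated(paste(pairs_i, pairs_j))
  pairs_i <- pairs_i[!dup]; pairs_j <- pairs_j[!dup]

  a <- atoms[pairs_i, ]; b <- atoms[pairs_j, ]
  dist <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  overlap <- r[pairs_i] + r[pairs_j] - dist

  same_res <- residue_key(a$chain, a$seqnum, a$icode) ==
    residue_key(b$chain, b$seqnum, b$icode)
  adjacent_mc <- a$chain == b$chain & abs(a$seqnum - b$seqnum) == 1L &
    (a$name %in% .mainchain_names | b$name %in% .mainchain_names)
  alt_mismatch <- nzchar(a$alt_loc) & nzchar(b$alt_loc) & a$alt_loc != b$alt_loc

  keep <- overlap > min_overlap & !same_res & !adjacent_mc & !alt_mismatch
  if (!any(keep)) return(empty)
  a <- a[keep, ]; b <- b[keep, ]
  out <- data.frame(chain_a = a$chain, seqnum_a = a$seqnum, icode_a = a$icode,
                    resname_a = a$resname, atom_a = a$name,
                    chain_b = b$chain, seqnum_b = b$seqnum, icode_b = b$icode,
                    resname_b = b$resname, atom_b = b$name,
                    distance = dist[keep], overlap = overlap[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap), ]
  rownames(out) <- NULL
  out
}

#' Weighted bump severity
#'
#' BS_w = 100 * sum(overlap_i^2) / n_residues. The quadratic weighting makes a
#' single 0.8 Angstrom clash count sixteen times a 0.2 Angstrom clash, so the
#' score is driven by severe clashes (actual fitting errors) and largely
#' ignores marginal contacts.
#'
#' @param clashes data.frame from [detect_clashes] (only the `overlap` column
#'   is used), or a numeric vector of overlaps.
#' @param n_residues number of residues in the model, >= 1.
#' @return the weighted bump severity score.
#' @export
weighted_bump_severity <- function(clashes, n_residues) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  overlaps <- if (is.data.frame(clashes)) clashes$overlap else as.numeric(clashes)
  if (!length(overlaps)) return(0)
  if (any(overlaps <= 0)) stop("clash overlaps must be positive")
  100 * sum(overlaps^2) / n_residues
}

#' Write a clash list as TSV
#' @param clashes data.frame from [detect_clashes].
#' @param path optional output path; when NULL the text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
clashes_tsv <- function(clashes, path = NULL) {
  cols <- c("chain_a", "seqnum_a", "atom_a", "chain_b", "seqnum_b", "atom_b",
            "overlap")
  txt <- paste(c(paste(cols, collapse = "\t"),
                 apply(clashes[, cols, drop = FALSE], 1, paste, collapse = "\t"),
                 ""),
               collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
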