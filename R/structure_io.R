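#' Residue keys
#'
#' A residue is identified by (chain, seqnum, icode); the residue name is a
#' property, not part of the identity. Two residues sharing a key but carrying
#' different names (and not related as alternate conformers) are a format
#' error in the input file.
#'
#' @param chain,seqnum,icode character/integer/character vectors.
#' @return character vector of keys.
#' @keywords internal
residue_key <- function(chain, seqnum, icode) {
  paste(chain, seqnum, icode, sep = "|")
}

#' Construct a coordinate model
#'
#' A model is a flat atom table plus optional crystallographic metadata. The
#' atom table preserves file order; each row is one atom record.
#'
#' @param atoms data.frame with columns `record`, `serial`, `name`, `alt_loc`,
#'   `resname`, `chain`, `seqnum`, `icode`, `x`, `y`, `z`, `occ`, `b`,
#'   `element`.
#' @param cell numeric(6) unit-cell parameters (a, b, c in Angstrom; alpha,
#'   beta, gamma in degrees) or NULL.
#' @param spacegroup space-group symbol or NULL.
#' @return object of class `xtal_model`.
#' @export
xtal_model <- function(atoms, cell = NULL, spacegroup = NULL) {
  required <- c("record", "serial", "name", "alt_loc", "resname", "chain",
                "seqnum", "icode", "x", "y", "z", "occ", "b", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0))
    stop("negative B factors in atom table")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6L || any(cell[1:3] <= 0) ||
        any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
      stop("cell must be (a, b, c, alpha, beta, gamma) with positive lengths and angles in (0, 180)")
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$seqnum <- as.integer(atoms$seqnum)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, spacegroup = spacegroup),
            class = "xtal_model")
}

#' @export
print.xtal_model <- function(x, ...) {
  keys <- residue_key(x$atoms$chain, x$atoms$seqnum, x$atoms$icode)
  cat(sprintf("<xtal_model> %d atoms, %d residues",
              nrow(x$atoms), length(unique(keys))))
  if (!is.null(x$cell))
    cat(sprintf(", cell %.2f %.2f %.2f / %.1f %.1f %.1f", x$cell[1], x$cell[2],
                x$cell[3], x$cell[4], x$cell[5], x$cell[6]))
  cat("\n")
  invisible(x)
}

#' Number of residues in a model
#' @param m an `xtal_model`.
#' @return integer count of distinct residues.
#' @export
n_residues <- function(m) {
  length(unique(residue_key(m$atoms$chain, m$atoms$seqnum, m$atoms$icode)))
}

# Fixed-column slices of ATOM/HETATM records (PDB format v3.3, 1-based).
.pdb_num <- function(s, what, lineno) {
  s <- trimws(s)
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & nzchar(s)
  bad <- bad | !nzchar(s)
  if (any(bad))
    stop(sprintf("malformed %s field on line %d", what, lineno[bad][1]),
         call. = FALSE)
  v
}

#' Read a coordinate model from PDB-format text
#'
#' Parses ATOM/HETATM records (fixed columns) and CRYST1 if present. Alternate
#' locations are kept as separate atom rows. Two residues that share a chain,
#' residue number and insertion code but have different residue names are
#' rejected: such records cannot be told apart downstream.
#'
#' @param pdb_text character scalar (possibly multi-line) or character vector
#'   of lines, or a path to a file.
#' @return an [xtal_model].
#' @export
read_model <- function(pdb_text) {
  lines <- .as_lines(pdb_text)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("no ATOM/HETATM records found")
  lineno <- which(is_atom)
  al <- lines[is_atom]
  al <- formatC(al, width = max(nchar(al), 80L), flag = "-")  # pad short lines

  atoms <- data.frame(
    record  = trimws(substr(al, 1, 6)),
    serial  = as.integer(.pdb_num(substr(al, 7, 11), "serial", lineno)),
    name    = trimws(substr(al, 13, 16)),
    alt_loc = trimws(substr(al, 17, 17)),
    resname = trimws(substr(al, 18, 20)),
    chain   = substr(al, 22, 22),
    seqnum  = as.integer(.pdb_num(substr(al, 23, 26), "residue number", lineno)),
    icode   = trimws(substr(al, 27, 27)),
    x       = .pdb_num(substr(al, 31, 38), "x coordinate", lineno),
    y       = .pdb_num(substr(al, 39, 46), "y coordinate", lineno),
    z       = .pdb_num(substr(al, 47, 54), "z coordinate", lineno),
    occ     = .pdb_num(substr(al, 55, 60), "occupancy", lineno),
    b       = .pdb_num(substr(al, 61, 66), "B factor", lineno),
    element = trimws(substr(al, 77, 78)),
    stringsAsFactors = FALSE
  )
  no_el <- !nzchar(atoms$element)
  atoms$element[no_el] <- .element_from_name(atoms$name[no_el])

  keys <- residue_key(atoms$chain, atoms$seqnum, atoms$icode)
  nm_per_key <- tapply(atoms$resname, keys, function(v) length(unique(v)))
  dup <- names(nm_per_key)[nm_per_key > 1]
  if (length(dup))
    stop("duplicate residue identifier with conflicting residue names: ",
         paste(gsub("\\|", " ", dup), collapse = "; "))

  cell <- NULL
  sg <- NULL
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr)) {
    cr <- formatC(cr[1], width = 70, flag = "-")
    cell <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                         substr(cr, 25, 33), substr(cr, 34, 40),
                         substr(cr, 41, 47), substr(cr, 48, 54)))
    sg <- trimws(substr(cr, 56, 66))
    if (!nzchar(sg)) sg <- NULL
  }
  xtal_model(atoms, cell = cell, spacegroup = sg)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    return(readLines(x, warn = FALSE))
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1]])
  x
}

# Heuristic fallback when element columns are blank: strip digits, take the
# leading character(s); two-letter elements only when the name starts in the
# first column slot (not implemented from raw text here, so single letter).
.element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  toupper(substr(stripped, 1, 1))
}

.pdb_atom_name_field <- function(name, element) {
  # Standard alignment: element right-justified into columns 13-14, so names
  # whose element symbol is a single character start at column 14 unless the
  # name already uses 4 characters.
  ifelse(nchar(name) >= 4L, substr(sprintf("%-4s", name), 1, 4),
         ifelse(nchar(element) >= 2L,
                sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a model as PDB-format text
#'
#' Emits CRYST1 (when a cell is present) followed by fixed-column ATOM/HETATM
#' records and END. Coordinates are written to 3 decimals, occupancy and B
#' factor to 2, matching PDB precision.
#'
#' @param m an [xtal_model].
#' @return character scalar of PDB text.
#' @export
write_model <- function(m) {
  out <- character(0)
  if (!is.null(m$cell)) {
    sg <- if (is.null(m$spacegroup)) "P 1" else m$spacegroup
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                          m$cell[1], m$cell[2], m$cell[3],
                          m$cell[4], m$cell[5], m$cell[6], sg, 1L))
  }
  a <- m$atoms
  if (nrow(a)) {
    recs <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    a$record, a$serial,
                    .pdb_atom_name_field(a$name, a$element),
                    a$alt_loc, a$resname, a$chain, a$seqnum, a$icode,
                    a$x, a$y, a$z, a$occ, a$b,
                    formatC(a$element, width = 2))
    out <- c(out, recs)
  }
  paste(c(out, "END", ""), collapse = "\n")
}

#' Resolution of a reflection from the unit cell
#'
#' General triclinic d-spacing via the reciprocal metric: 1/d^2 = h* G* h
#' where G* is the reciprocal metric tensor of the cell. Symmetric in +/-hkl.
#'
#' @param cell numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @param hkl integer(3) Miller indices, or an n x 3 matrix of them.
#' @return d-spacing(s) in Angstrom.
#' @export
compute_d <- function(cell, hkl) {
  cell <- as.numeric(cell)
  if (length(cell) != 6L || any(cell[1:3] <= 0) ||
      any(cell[4:6] <= 0) || any(cell[4:6] >= 180))
    stop("invalid unit cell")
  hkl <- if (is.matrix(hkl)) hkl else matrix(hkl, ncol = 3)
  if (any(rowSums(hkl != 0) == 0))
    stop("hkl = (0,0,0) has no resolution")
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga)
  sa <- sin(al); sb <- sin(be); sg <- sin(ga)
  V <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  as <- b * c * sa / V; bs <- a * c * sb / V; cs <- a * b * sg / V
  cas <- (cb * cg - ca) / (sb * sg)
  cbs <- (ca * cg - cb) / (sa * sg)
  cgs <- (ca * cb - cg) / (sa * sb)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  inv_d2 <- h^2 * as^2 + k^2 * bs^2 + l^2 * cs^2 +
    2 * k * l * bs * cs * cas + 2 * h * l * as * cs * cbs +
    2 * h * k * as * bs * cgs
  1 / sqrt(inv_d2)
}

#' Construct a reflection set
#'
#' @param data data.frame with columns `h`, `k`, `l`, `f`, `sigf`, `free`;
#'   a `d` column is added (or checked) from the cell.
#' @param cell numeric(6) unit-cell parameters.
#' @param test_value integer free-flag value that marks the test set.
#' @return object of class `reflection_set`.
#' @export
reflection_set <- function(data, cell, test_value) {
  key <- paste(data$h, data$k, data$l)
  if (anyDuplicated(key))
    stop("duplicate Miller indices: unmerged reflection data are not supported")
  if (any(data$h == 0 & data$k == 0 & data$l == 0))
    stop("hkl = (0,0,0) is not a reflection")
  if (any(data$sigf < 0, na.rm = TRUE))
    stop("negative sigma values")
  data$d <- compute_d(cell, as.matrix(data[, c("h", "k", "l")]))
  rownames(data) <- NULL
  structure(list(data = data, cell = as.numeric(cell),
                 test_value = as.integer(test_value)),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections, d %.2f-%.2f A, %d in test set (flag %d)\n",
              nrow(x$data), min(x$data$d), max(x$data$d),
              sum(x$data$free == x$test_value), x$test_value))
  invisible(x)
}

#' Logical mask of test-set reflections
#' @param rs a `reflection_set`.
#' @return logical vector along the reflection table.
#' @export
test_mask <- function(rs) rs$data$free == rs$test_value

# Column-label preference used when auto-selecting data columns: amplitude
# labels are tried before intensity labels; the matching sigma is SIG<label>
# or a lone SIGF/SIGI.
.amp_labels <- c("F", "FP", "FOBS", "F_OBS", "FO")
.int_labels <- c("I", "IP", "IOBS", "I_OBS", "IMEAN")

.pick_column <- function(labels, have) {
  hit <- labels[labels %in% have]
  if (length(hit)) hit[1] else NA_character_
}

#' Read reflection data from the CSV dialect
#'
#' The dialect is a comma-separated table with a header naming at least the
#' Miller index columns `h`, `k`, `l` (case-insensitive) plus an amplitude
#' (F-like) or intensity (I-like) column, optionally its sigma, and a
#' free-set flag column; a comment line `# cell a b c alpha beta gamma`
#' carries the unit cell. Column selection prefers amplitudes over
#' intensities; intensities are converted as F = sqrt(max(I, 0)) with a
#' warning. The free flag is the most-populated integer column (other than
#' h, k, l) whose minority-value fraction is below 50%; the minority value
#' becomes the test-set marker.
#'
#' @param source path to a CSV file (an `.mtz` path is rejected with a
#'   pointer to the dialect) or a character scalar of CSV text.
#' @return a [reflection_set].
#' @export
read_reflections <- function(source) {
  if (length(source) == 1L && grepl("\\.mtz$", source, ignore.case = TRUE))
    stop("binary MTZ is not supported; convert to the CSV dialect ",
         "(header h,k,l,F,SIGF,FREE plus a '# cell a b c alpha beta gamma' line)")
  lines <- .as_lines(source)
  cell_line <- grep("^#\\s*cell\\b", lines, ignore.case = TRUE, value = TRUE)
  if (!length(cell_line))
    stop("no '# cell a b c alpha beta gamma' line found")
  cell <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", cell_line[1],
                                         ignore.case = TRUE)), "[,\\s]+",
                              perl = TRUE)[[1]])
  cell <- cell[!is.na(cell)]
  if (length(cell) != 6L) stop("cell line must carry six numbers")

  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE, strip.white = TRUE)
  names(tab) <- trimws(names(tab))
  have <- toupper(names(tab))
  idx_cols <- match(c("H", "K", "L"), have)
  if (any(is.na(idx_cols)))
    stop("columns h, k, l are required; found: ",
         paste(names(tab), collapse = ", "))

  amp <- .pick_column(.amp_labels, have)
  int <- .pick_column(.int_labels, have)
  if (is.na(amp) && is.na(int))
    stop("no recognizable amplitude or intensity column; available labels: ",
         paste(names(tab), collapse = ", "))
  if (!is.na(amp)) {
    f <- tab[[match(amp, have)]]
    sig_lab <- .pick_column(c(paste0("SIG", amp), "SIGF", "SIGFP"), have)
  } else {
    ivals <- tab[[match(int, have)]]
    f <- sqrt(pmax(ivals, 0))
    sig_lab <- NA_character_
    warning("intensity column ", int,
            " converted as F = sqrt(max(I, 0)); no French-Wilson treatment")
  }
  sigf <- if (!is.na(sig_lab)) tab[[match(sig_lab, have)]] else rep(1, nrow(tab))

  # Free-flag: integer-valued candidate columns, excluding indices and data.
  used <- c(idx_cols, match(c(amp, int, sig_lab), have))
  cand <- setdiff(seq_along(tab), used[!is.na(used)])
  cand <- cand[vapply(cand, function(j) {
    v <- tab[[j]]
    is.numeric(v) && all(v == round(v), na.rm = TRUE)
  }, logical(1))]
  flag_col <- NA_integer_; test_value <- NA_integer_
  best_n <- -1L
  for (j in cand) {
    v <- as.integer(tab[[j]])
    tt <- sort(table(v), decreasing = TRUE)
    if (length(tt) < 2L) next
    minority <- sum(tt[-1])
    if (minority / length(v) >= 0.5) next
    if (length(v) > best_n) {
      best_n <- length(v)
      flag_col <- j
      # the least-populated value marks the test set
      test_value <- as.integer(names(tt)[length(tt)])
    }
  }
  if (is.na(flag_col)) {
    free <- rep(0L, nrow(tab))
    test_value <- 1L
    warning("no free-flag column recognized; all reflections marked as work set")
  } else {
    free <- as.integer(tab[[flag_col]])
  }

  reflection_set(
    data.frame(h = as.integer(tab[[idx_cols[1]]]),
               k = as.integer(tab[[idx_cols[2]]]),
               l = as.integer(tab[[idx_cols[3]]]),
               f = as.numeric(f), sigf = as.numeric(sigf), free = free),
    cell = cell, test_value = test_value)
}

#' Write a reflection set in the CSV dialect
#' @param rs a [reflection_set].
#' @param path optional output path; when NULL the text is returned.
#' @return the CSV text, invisibly when written to a file.
#' @export
write_reflections <- function(rs, path = NULL) {
  hdr <- sprintf("# cell %.4f %.4f %.4f %.3f %.3f %.3f",
                 rs$cell[1], rs$cell[2], rs$cell[3],
                 rs$cell[4], rs$cell[5], rs$cell[6])
  d <- rs$data
  body <- sprintf("%d,%d,%d,%.6g,%.6g,%d", d$h, d$k, d$l, d$f, d$sigf, d$free)
  txt <- paste(c(hdr, "h,k,l,F,SIGF,FREE", body, ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
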