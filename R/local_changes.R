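# Side-chain chi dihedral definitions (atom-name quadruples) per residue type.
.chi_atoms <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1")))

# Terminal dihedrals with a 180-degree chemical equivalence (symmetric end
# groups): chi index per residue type.
.chi_symmetric <- c(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)

.water_names <- c("HOH", "WAT", "DOD")

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 numeric(3) coordinates.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.atom_xyz <- function(res_atoms, name) {
  i <- which(res_atoms$name == name)
  if (!length(i)) return(NULL)
  c(res_atoms$x[i[1]], res_atoms$y[i[1]], res_atoms$z[i[1]])
}

# All defined chi angles (degrees) of one residue; NA where atoms are missing.
.chi_angles <- function(res_atoms) {
  defs <- .chi_atoms[[res_atoms$resname[1]]]
  if (is.null(defs)) return(numeric(0))
  vapply(defs, function(names4) {
    pts <- lapply(names4, .atom_xyz, res_atoms = res_atoms)
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
}

# Circular difference in degrees, optionally modulo 180 for symmetric ends.
.ang_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

#' Per-residue density-fit record
#'
#' @param chain,seqnum,icode,resname residue identity.
#' @param rsr real-space R factor (>= 0).
#' @param rscc real-space correlation coefficient in (-1, 1).
#' @param n_grid number of independent map grid points behind the RSCC.
#' @return list of class `residue_density_fit`.
#' @export
residue_density_fit <- function(chain, seqnum, icode = "", resname = "",
                                rsr = NA_real_, rscc = NA_real_, n_grid = 0L) {
  stopifnot(is.na(rsr) || rsr >= 0, n_grid >= 0)
  if (!is.na(rscc) && abs(rscc) >= 1) stop("rscc must lie inside (-1, 1)")
  structure(list(chain = chain, seqnum = as.integer(seqnum), icode = icode,
                 resname = resname, rsr = rsr, rscc = rscc,
                 n_grid = as.integer(n_grid)),
            class = "residue_density_fit")
}

#' Classify a per-residue change in real-space correlation
#'
#' Applies the Fisher-transform Z test of [zchange_cc] with the grid-point
#' counts as sample sizes: |Z| > 2.6 marks the residue green (improvement) or
#' red (deterioration); a defined but sub-threshold Z is grey; an undefined Z
#' (3 or fewer grid points on either side — small compounds such as waters or
#' ions at low resolution) is white.
#'
#' @param fit_i,fit_f [residue_density_fit] for the same residue in the
#'   initial and final model.
#' @param threshold significance threshold on |Z_change| (default 2.6).
#' @return a [verdict] with the Z_change as magnitude.
#' @export
classify_rscc_change <- function(fit_i, fit_f, threshold = 2.6) {
  if (residue_key(fit_i$chain, fit_i$seqnum, fit_i$icode) !=
      residue_key(fit_f$chain, fit_f$seqnum, fit_f$icode))
    stop("density fits refer to different residues")
  classify_cc_change(fit_i$rscc, fit_i$n_grid, fit_f$rscc, fit_f$n_grid,
                     threshold = threshold)
}

#' Estimate the number of independent map grid points of a residue
#'
#' Fallback for when no external density-statistics table is available:
#' counts the nodes of a cubic lattice with spacing d/3 (a conventional map
#' grid at resolution d) lying within 2.0 Angstrom of any atom centre of the
#' residue. Overlapping atom spheres are counted once (union volume).
#'
#' @param res_atoms atom table rows of one residue.
#' @param d map resolution in Angstrom (> 0).
#' @param mask_radius masking radius around atom centres (Angstrom).
#' @return integer count of lattice nodes.
#' @export
estimate_grid_points <- function(res_atoms, d, mask_radius = 2.0) {
  stopifnot(d > 0, nrow(res_atoms) >= 1)
  sp <- d / 3
  ax <- function(v) {
    seq(floor((min(v) - mask_radius) / sp), ceiling((max(v) + mask_radius) / sp)) * sp
  }
  nodes <- expand.grid(x = ax(res_atoms$x), y = ax(res_atoms$y),
                       z = ax(res_atoms$z))
  inside <- rep(FALSE, nrow(nodes))
  r2 <- mask_radius^2
  for (i in seq_len(nrow(res_atoms))) {
    inside <- inside | ((nodes$x - res_atoms$x[i])^2 +
                          (nodes$y - res_atoms$y[i])^2 +
                          (nodes$z - res_atoms$z[i])^2) <= r2
  }
  sum(inside)
}

.moved_centroid <- function(res_i, res_f, eps = 0.1) {
  common <- intersect(res_i$name, res_f$name)
  src <- if (nrow(res_f)) res_f else res_i
  if (length(common)) {
    ai <- res_i[match(common, res_i$name), ]
    af <- res_f[match(common, res_f$name), ]
    moved <- sqrt((ai$x - af$x)^2 + (ai$y - af$y)^2 + (ai$z - af$z)^2) > eps
    if (any(moved))
      return(c(mean(af$x[moved]), mean(af$y[moved]), mean(af$z[moved])))
  }
  c(mean(src$x), mean(src$y), mean(src$z))
}

.hnq_swaps <- list(
  ASN = list(c("OD1", "ND2")),
  GLN = list(c("OE1", "NE2")),
  HIS = list(c("ND1", "CD2"), c("NE2", "CE1")))

.pair_mismatch <- function(res_i, res_f, pairs, swapped) {
  total <- 0
  for (p in pairs) {
    a <- p[1]; b <- p[2]
    ia <- .atom_xyz(res_i, a); ib <- .atom_xyz(res_i, b)
    fa <- .atom_xyz(res_f, a); fb <- .atom_xyz(res_f, b)
    if (is.null(ia) || is.null(ib) || is.null(fa) || is.null(fb))
      return(NA_real_)
    if (swapped) { tmp <- fa; fa <- fb; fb <- tmp }
    total <- total + sqrt(sum((ia - fa)^2)) + sqrt(sum((ib - fb)^2))
  }
  total
}

#' Detect discrete model changes between two models
#'
#' Compares residues matched by (chain, seqnum, icode) and reports discrete
#' rebuilding events:
#' \itemize{
#'   \item `water-deleted`: a water present initially and absent finally;
#'   \item `side-chain-completed`: side-chain atoms beyond CB present finally
#'     but absent initially;
#'   \item `rotamer`: any side-chain chi dihedral differing by more than
#'     `chi_threshold` degrees (terminal 180-degree equivalences of
#'     Phe/Tyr/Asp/Glu are corrected);
#'   \item `hnq-flip`: a His/Asn/Gln residue whose terminal atom positions are
#'     matched better after swapping the ambiguous N/O (or ring) assignment;
#'   \item `peptide-flip`: a carbonyl O displaced more than `o_threshold`
#'     Angstrom while the flanking CA atoms each moved less than
#'     `ca_threshold`;
#'   \item `other`: a non-water residue present in only one model.
#' }
#' When several detectors fire for one residue the precedence is
#' peptide-flip > hnq-flip > rotamer. Each change carries a `site` (the
#' centroid of the residue's moved atoms) for recentring a viewer.
#'
#' @param initial,final [xtal_model]s sharing a residue-numbering frame.
#' @param chi_threshold rotamer detection threshold in degrees (default 30).
#' @param o_threshold,ca_threshold peptide-flip thresholds in Angstrom
#'   (defaults 2.0 and 0.5).
#' @return data.frame with columns `category`, `chain`, `seqnum`, `icode`,
#'   `resname`, `x`, `y`, `z`, `note` (model order; one row per change).
#' @export
diff_models <- function(initial, final, chi_threshold = 30,
                        o_threshold = 2.0, ca_threshold = 0.5) {
  ai <- .primary_conformer(initial$atoms)
  af <- .primary_conformer(final$atoms)
  res_i <- .split_by_residue(ai)
  res_f <- .split_by_residue(af)
  keys_i <- names(res_i); keys_f <- names(res_f)

  changes <- list()
  add <- function(category, res, site, note = "") {
    changes[[length(changes) + 1L]] <<- data.frame(
      category = category, chain = res$chain[1], seqnum = res$seqnum[1],
      icode = res$icode[1], resname = res$resname[1],
      x = site[1], y = site[2], z = site[3], note = note,
      stringsAsFactors = FALSE)
  }

  for (key in keys_i) {
    ri <- res_i[[key]]
    if (!(key %in% keys_f)) {
      site <- c(mean(ri$x), mean(ri$y), mean(ri$z))
      if (ri$resname[1] %in% .water_names)
        add("water-deleted", ri, site)
      else
        add("other", ri, site, note = "residue removed")
      next
    }
    rf <- res_f[[key]]
    site <- .moved_centroid(ri, rf)

    # peptide flip: carbonyl O swings while the local backbone stays put
    o_i <- .atom_xyz(ri, "O"); o_f <- .atom_xyz(rf, "O")
    ca_i <- .atom_xyz(ri, "CA"); ca_f <- .atom_xyz(rf, "CA")
    next_key <- residue_key(ri$chain[1], ri$seqnum[1] + 1L, ri$icode[1])
    ca2_moved <- 0
    if (next_key %in% keys_i && next_key %in% keys_f) {
      ca2_i <- .atom_xyz(res_i[[next_key]], "CA")
      ca2_f <- .atom_xyz(res_f[[next_key]], "CA")
      if (!is.null(ca2_i) && !is.null(ca2_f))
        ca2_moved <- sqrt(sum((ca2_i - ca2_f)^2))
    }
    if (!is.null(o_i) && !is.null(o_f) && !is.null(ca_i) && !is.null(ca_f)) {
      o_moved <- sqrt(sum((o_i - o_f)^2))
      ca_moved <- sqrt(sum((ca_i - ca_f)^2))
      if (o_moved > o_threshold && ca_moved < ca_threshold &&
          ca2_moved < ca_threshold) {
        add("peptide-flip", ri, site,
            note = sprintf("O moved %.1f A", o_moved))
        next
      }
    }

    # His/Asn/Gln flip: swapped terminal assignment fits better
    swaps <- .hnq_swaps[[ri$resname[1]]]
    if (!is.null(swaps)) {
      plain <- .pair_mismatch(ri, rf, swaps, swapped = FALSE)
      swapped <- .pair_mismatch(ri, rf, swaps, swapped = TRUE)
      if (!is.na(plain) && !is.na(swapped) && swapped < plain) {
        add("hnq-flip", ri, site)
        next
      }
    }

    # rotamer change: any chi dihedral beyond the threshold
    chi_i <- .chi_angles(ri); chi_f <- .chi_angles(rf)
    if (length(chi_i) && length(chi_f)) {
      sym_idx <- .chi_symmetric[ri$resname[1]]
      deltas <- vapply(seq_along(chi_i), function(j) {
        if (is.na(chi_i[j]) || is.na(chi_f[j])) return(NA_real_)
        period <- if (!is.na(sym_idx) && j == sym_idx) 180 else 360
        .ang_diff(chi_i[j], chi_f[j], period)
      }, numeric(1))
      if (any(deltas > chi_threshold, na.rm = TRUE)) {
        add("rotamer", ri, site,
            note = sprintf("max chi change %.0f deg", max(deltas, na.rm = TRUE)))
        next
      }
    }

    # side-chain completion: atoms beyond CB appear
    backbone <- c(.mainchain_names, "CB", "OXT")
    new_atoms <- setdiff(setdiff(rf$name, backbone), ri$name)
    if (length(new_atoms)) {
      add("side-chain-completed", rf, site,
          note = paste("added", paste(new_atoms, collapse = " ")))
      next
    }
  }
  for (key in setdiff(keys_f, keys_i)) {
    rf <- res_f[[key]]
    if (rf$resname[1] %in% .water_names) next  # added waters are not reported
    add("other", rf, c(mean(rf$x), mean(rf$y), mean(rf$z)),
        note = "residue added")
  }

  if (!length(changes))
    return(data.frame(category = character(0), chain = character(0),
                      seqnum = integer(0), icode = character(0),
                      resname = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), note = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, changes)
  rownames(out) <- NULL
  out
}

.coot_label <- function(changes) {
  sprintf("%s %s%d%s %s", changes$category, trimws(changes$chain),
          changes$seqnum, trimws(changes$icode), changes$resname)
}

#' Emit Coot scripts listing model changes
#'
#' Builds the Scheme and Python scripts that Coot reads directly: each opens
#' an "interesting things" dialog with one button per change, labelled with
#' the category and residue, recentring the view on the change site when
#' clicked. Entries appear in model order and both dialects always carry the
#' same entries.
#'
#' @param changes data.frame from [diff_models].
#' @param title dialog title.
#' @return list with `scm` and `py` character scalars.
#' @export
write_coot_scripts <- function(changes, title = "Model changes") {
  labels <- .coot_label(changes)
  scm_entries <- sprintf('    (list "%s" %.3f %.3f %.3f)',
                         labels, changes$x, changes$y, changes$z)
  scm <- paste(c(";; model-change button list; load in Coot",
                 sprintf('(interesting-things-gui "%s"', title),
                 "  (list",
                 scm_entries,
                 "  ))", ""), collapse = "\n")
  py_entries <- sprintf('    ["%s", %.3f, %.3f, %.3f],',
                        labels, changes$x, changes$y, changes$z)
  py <- paste(c("# model-change button list; load in Coot",
                sprintf('interesting_things_gui("%s", [', title),
                py_entries,
                "])", ""), collapse = "\n")
  list(scm = scm, py = py)
}

#' Read a per-residue density-fit table
#'
#' EDSTATS-style TSV with header columns `chain`, `seqnum`, `icode`,
#' `resname`, `rsr`, `rscc`, `n_grid`.
#'
#' @param path file path or TSV text.
#' @return data.frame of per-residue fits.
#' @export
read_density_fits <- function(path) {
  lines <- .as_lines(path)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE)
  needed <- c("chain", "seqnum", "resname", "rsr", "rscc", "n_grid")
  if (!all(needed %in% names(tab)))
    stop("density-fit table needs columns: ", paste(needed, collapse = ", "))
  if (is.null(tab$icode)) tab$icode <- ""
  tab$icode[is.na(tab$icode)] <- ""
  tab$chain <- as.character(tab$chain)
  tab
}

#' Write a per-residue density-fit table
#' @param fits data.frame as from [read_density_fits].
#' @param path optional output path; when NULL the text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
write_density_fits <- function(fits, path = NULL) {
  cols <- c("chain", "seqnum", "icode", "resname", "rsr", "rscc", "n_grid")
  txt <- paste(c(paste(cols, collapse = "\t"),
                 if (nrow(fits)) apply(fits[, cols, drop = FALSE], 1,
                                       function(r) paste(trimws(r), collapse = "\t")),
                 ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Classify RSCC changes for a residue table pair
#'
#' Merges the initial and final per-residue fit tables on residue identity
#' and classifies each residue with [classify_rscc_change]; also reports the
#' mean RSCC change over residues with a defined Z (the average-change line
#' of the per-residue plot).
#'
#' @param fits_i,fits_f data.frames as from [read_density_fits].
#' @param threshold significance threshold on |Z_change|.
#' @return list with `table` (merged data.frame with `z`, `label`, `color`,
#'   `delta_rscc`) and `mean_change` (mean delta over defined rows).
#' @export
rscc_change_table <- function(fits_i, fits_f, threshold = 2.6) {
  key_i <- residue_key(fits_i$chain, fits_i$seqnum, fits_i$icode)
  key_f <- residue_key(fits_f$chain, fits_f$seqnum, fits_f$icode)
  common <- intersect(key_i, key_f)
  ii <- match(common, key_i); ff <- match(common, key_f)
  rows <- lapply(seq_along(common), function(j) {
    v <- classify_cc_change(fits_i$rscc[ii[j]], fits_i$n_grid[ii[j]],
                            fits_f$rscc[ff[j]], fits_f$n_grid[ff[j]],
                            threshold = threshold)
    data.frame(chain = fits_i$chain[ii[j]], seqnum = fits_i$seqnum[ii[j]],
               icode = fits_i$icode[ii[j]], resname = fits_i$resname[ii[j]],
               rscc_i = fits_i$rscc[ii[j]], rscc_f = fits_f$rscc[ff[j]],
               delta_rscc = fits_f$rscc[ff[j]] - fits_i$rscc[ii[j]],
               z = if (is.na(v$magnitude)) NA_real_ else v$magnitude,
               label = v$label, color = v$color, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), seqnum = integer(0), icode = character(0),
               resname = character(0), rscc_i = numeric(0), rscc_f = numeric(0),
               delta_rscc = numeric(0), z = numeric(0), label = character(0),
               color = character(0), stringsAsFactors = FALSE)
  defined <- tab$label != "undefined"
  list(table = tab,
       mean_change = if (any(defined)) mean(tab$delta_rscc[defined]) else NA_real_)
}
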