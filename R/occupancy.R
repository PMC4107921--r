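# Residue names exempt from occupancy sanitization by default: standard
# amino acids and nucleotides. The suspicious occupancy patterns target
# ligands and nonstandard residues.
.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "A", "C", "G", "U", "DA", "DC", "DG", "DT")

.split_by_residue <- function(atoms) {
  key <- residue_key(atoms$chain, atoms$seqnum, atoms$icode)
  split(atoms, factor(key, levels = unique(key)))
}

# Alternate-conformer exemption for the >= 3 distinct occupancies rule:
# conformer groups that are each internally uniform and whose occupancies sum
# to ~1 are legitimate alternates, not ad hoc per-atom fiddling.
.legit_altloc_groups <- function(res_atoms, tol = 0.02) {
  alts <- res_atoms$alt_loc
  if (!any(nzchar(alts))) return(FALSE)
  grp <- split(res_atoms$occ, alts)
  uniform <- vapply(grp, function(o) diff(range(round(o, 2))) == 0, logical(1))
  if (!all(uniform)) return(FALSE)
  conf <- vapply(grp[nzchar(names(grp))], function(o) round(o[1], 2), numeric(1))
  length(conf) >= 2 && abs(sum(conf) - 1) <= tol
}

#' Find residues with implausible occupancy patterns
#'
#' Flags residues whose occupancies look like an artificial fit improvement
#' rather than chemical reality: (a) any atom with occupancy 0.00 or 0.01
#' ("not there" markers), or (b) at least three different occupancy values
#' among the residue's atoms (values compared after rounding to the 2-decimal
#' precision of the PDB format). Rule (b) does not fire for genuine alternate
#' conformations — conformer groups that are internally uniform and sum to
#' ~1. By default only non-standard residues (ligands, modified residues,
#' waters) are examined, since those are where the pattern occurs.
#'
#' @param m an [xtal_model].
#' @param only_nonstandard examine only residues outside the standard amino
#'   acid / nucleotide set (default TRUE).
#' @return data.frame with columns `chain`, `seqnum`, `icode`, `resname`,
#'   `reason` ("zero-like occupancy" or ">=3 distinct occupancies").
#' @export
find_suspect_residues <- function(m, only_nonstandard = TRUE) {
  out <- list()
  for (res in .split_by_residue(m$atoms)) {
    if (only_nonstandard && res$resname[1] %in% .standard_residues) next
    occ <- round(res$occ, 2)
    reason <- NULL
    if (any(abs(res$occ) < 1e-6 | abs(res$occ - 0.01) < 1e-6))
      reason <- "zero-like occupancy"
    else if (length(unique(occ)) >= 3 && !.legit_altloc_groups(res))
      reason <- ">=3 distinct occupancies"
    if (!is.null(reason))
      out[[length(out) + 1L]] <- data.frame(
        chain = res$chain[1], seqnum = res$seqnum[1], icode = res$icode[1],
        resname = res$resname[1], reason = reason, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain = character(0), seqnum = integer(0),
                      icode = character(0), resname = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assign a single occupancy per flagged residue
#'
#' Every atom of each target residue receives one common occupancy — the
#' value (at 2-decimal precision) held by the largest number of its atoms,
#' ties broken towards the largest value — clamped to [0.01, 1.0]. The value
#' is an initializer only; downstream refinement is expected to refine it.
#' Non-target residues are untouched.
#'
#' @param m an [xtal_model].
#' @param targets data.frame with `chain`, `seqnum`, `icode` columns (e.g.
#'   from [find_suspect_residues]).
#' @return list with `model` (the sanitized [xtal_model]) and `log`, a
#'   data.frame recording old occupancies and the new value per residue.
#' @export
assign_single_occupancy <- function(m, targets) {
  log_rows <- list()
  if (nrow(targets)) {
    target_keys <- residue_key(targets$chain, targets$seqnum, targets$icode)
    keys <- residue_key(m$atoms$chain, m$atoms$seqnum, m$atoms$icode)
    model_keys <- unique(keys)
    if (!all(target_keys %in% model_keys))
      stop("target residues not present in the model: ",
           paste(setdiff(target_keys, model_keys), collapse = "; "))
    for (tk in target_keys) {
      idx <- which(keys == tk)
      occ <- round(m$atoms$occ[idx], 2)
      tab <- table(occ)
      winners <- as.numeric(names(tab)[tab == max(tab)])
      new_occ <- min(max(max(winners), 0.01), 1.0)
      if (any(m$atoms$occ[idx] != new_occ)) {
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          chain = m$atoms$chain[idx[1]], seqnum = m$atoms$seqnum[idx[1]],
          icode = m$atoms$icode[idx[1]], resname = m$atoms$resname[idx[1]],
          old = paste(format(occ, nsmall = 2), collapse = " "),
          new = new_occ, stringsAsFactors = FALSE)
        m$atoms$occ[idx] <- new_occ
      }
    }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(chain = character(0), seqnum = integer(0), icode = character(0),
               resname = character(0), old = character(0), new = numeric(0),
               stringsAsFactors = FALSE)
  list(model = m, log = log_df)
}

#' Write an occupancy change log as TSV
#' @param log data.frame from [assign_single_occupancy].
#' @param path optional output path; when NULL the text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
occupancy_log_tsv <- function(log, path = NULL) {
  cols <- c("chain", "seqnum", "resname", "old", "new")
  txt <- paste(c(paste(cols, collapse = "\t"),
                 if (nrow(log)) apply(log[, cols, drop = FALSE], 1,
                                      function(r) paste(trimws(r), collapse = "\t")),
                 ""),
               collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
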