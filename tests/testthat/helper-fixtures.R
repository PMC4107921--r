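# Shared fixture builders and independent oracles.

make_atom <- function(serial, name, resname, chain, seqnum, x, y, z,
                      occ = 1.0, b = 20.0, alt_loc = "", icode = "",
                      record = "ATOM", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  data.frame(record = record, serial = serial, name = name, alt_loc = alt_loc,
             resname = resname, chain = chain, seqnum = seqnum, icode = icode,
             x = x, y = y, z = z, occ = occ, b = b, element = element,
             stringsAsFactors = FALSE)
}

# Independent d-spacing oracle: invert the direct metric tensor.
d_metric_tensor <- function(cell, hkl) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  G <- matrix(c(a * a, a * b * cos(ga), a * c * cos(be),
                a * b * cos(ga), b * b, b * c * cos(al),
                a * c * cos(be), b * c * cos(al), c * c), 3, 3)
  Gstar <- solve(G)
  h <- matrix(hkl, ncol = 3)
  1 / sqrt(rowSums((h %*% Gstar) * h))
}

random_cell <- function() {
  # angles kept away from degenerate extremes so the cell volume is real
  c(runif(3, 5, 100), runif(3, 70, 110))
}

# O(n^2) clash oracle with the same exclusion rules, written as plain loops.
clashes_bruteforce <- function(m, radii = default_vdw_table(),
                               min_overlap = 0.10) {
  a <- m$atoms
  rad <- function(el) {
    r <- radii[el]
    if (is.na(r)) attr(radii, "default") else unname(r)
  }
  mc <- c("N", "CA", "C", "O")
  hits <- list()
  n <- nrow(a)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    ov <- rad(a$element[i]) + rad(a$element[j]) - d
    if (ov <= min_overlap) next
    if (a$chain[i] == a$chain[j] && a$seqnum[i] == a$seqnum[j] &&
        a$icode[i] == a$icode[j]) next
    if (a$chain[i] == a$chain[j] && abs(a$seqnum[i] - a$seqnum[j]) == 1 &&
        (a$name[i] %in% mc || a$name[j] %in% mc)) next
    if (nzchar(a$alt_loc[i]) && nzchar(a$alt_loc[j]) &&
        a$alt_loc[i] != a$alt_loc[j]) next
    hits[[length(hits) + 1]] <- data.frame(i = i, j = j, overlap = ov)
  }
  if (!length(hits)) return(data.frame(i = integer(0), j = integer(0),
                                       overlap = numeric(0)))
  do.call(rbind, hits)
}

# Random altloc-free model: residues of 5 atoms with protein-like names.
random_model <- function(n_atoms = 200, box = 20, seed = 1) {
  set.seed(seed)
  names_pool <- c("N", "CA", "C", "O", "CB", "CG", "CD")
  rows <- lapply(seq_len(n_atoms), function(i) {
    res <- (i - 1) %/% 5 + 1
    slot <- (i - 1) %% 5 + 1
    make_atom(i, sample(names_pool, 7)[slot], "ALA",
              if (res %% 2) "A" else "B", res,
              runif(1, 0, box), runif(1, 0, box), runif(1, 0, box),
              element = sample(c("C", "N", "O", "S"), 1))
  })
  atoms <- do.call(rbind, rows)
  # make atom names unique within each residue
  key <- paste(atoms$chain, atoms$seqnum)
  for (k in unique(key)) {
    idx <- which(key == k)
    atoms$name[idx] <- make.unique(atoms$name[idx])
  }
  xtal_model(atoms)
}

# Rigid-body transform: rotate about a random axis and translate.
rigid_transform <- function(m, angle = 37, axis = c(1, 2, 3),
                            shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
  m$atoms$x <- xyz[, 1] + shift[1]
  m$atoms$y <- xyz[, 2] + shift[2]
  m$atoms$z <- xyz[, 3] + shift[3]
  m
}

# CSV reflection text builder for read_reflections tests.
reflection_csv <- function(df, cell = c(20, 20, 20, 90, 90, 90),
                           header = names(df)) {
  paste(c(sprintf("# cell %s", paste(cell, collapse = " ")),
          paste(header, collapse = ","),
          apply(df, 1, paste, collapse = ",")),
        collapse = "\n")
}
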