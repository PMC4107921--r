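# Rotation of points about an axis through `origin` along unit vector `u`
# by `angle` degrees (Rodrigues formula).
.rotate_about_axis <- function(xyz, origin, u, angle) {
  u <- u / sqrt(sum(u^2))
  th <- angle * pi / 180
  p <- sweep(xyz, 2, origin)
  cross <- cbind(u[2] * p[, 3] - u[3] * p[, 2],
                 u[3] * p[, 1] - u[1] * p[, 3],
                 u[1] * p[, 2] - u[2] * p[, 1])
  dot <- as.numeric(p %*% u)
  rotated <- p * cos(th) + cross * sin(th) + outer(dot * (1 - cos(th)), u)
  sweep(rotated, 2, origin, `+`)
}

.demo_atom <- function(serial, name, resname, chain, seqnum, x, y, z,
                       occ = 1.0, b = 20.0, record = "ATOM") {
  data.frame(record = record, serial = serial, name = name, alt_loc = "",
             resname = resname, chain = chain, seqnum = seqnum, icode = "",
             x = x, y = y, z = z, occ = occ, b = b,
             element = .element_from_name(name), stringsAsFactors = FALSE)
}

#' Demo model pair with known constructed changes
#'
#' A three-residue structure (LEU, ALA, one water) and a modified copy in
#' which the leucine side chain is rotated by 120 degrees about the CA-CB
#' bond (a rotamer change) and the water is deleted. [diff_models] on the
#' pair finds exactly these two changes, which makes the pair a convenient
#' end-to-end fixture and worked example.
#'
#' @return list with elements `initial` and `final` ([xtal_model]s).
#' @export
demo_model_pair <- function() {
  leu <- rbind(
    .demo_atom(1, "N",   "LEU", "A", 1, 0.000, 0.000, 0.000),
    .demo_atom(2, "CA",  "LEU", "A", 1, 1.458, 0.000, 0.000),
    .demo_atom(3, "C",   "LEU", "A", 1, 2.009, 1.420, 0.000),
    .demo_atom(4, "O",   "LEU", "A", 1, 1.251, 2.390, 0.000),
    .demo_atom(5, "CB",  "LEU", "A", 1, 1.980, -0.773, -1.220),
    .demo_atom(6, "CG",  "LEU", "A", 1, 3.480, -1.050, -1.280),
    .demo_atom(7, "CD1", "LEU", "A", 1, 3.810, -1.880, -2.510),
    .demo_atom(8, "CD2", "LEU", "A", 1, 4.280, 0.240, -1.310))
  ala <- rbind(
    .demo_atom(9,  "N",  "ALA", "A", 2, 3.332, 1.536, 0.000),
    .demo_atom(10, "CA", "ALA", "A", 2, 3.988, 2.840, 0.000),
    .demo_atom(11, "C",  "ALA", "A", 2, 5.500, 2.710, 0.100),
    .demo_atom(12, "O",  "ALA", "A", 2, 6.030, 1.600, 0.150),
    .demo_atom(13, "CB", "ALA", "A", 2, 3.530, 3.660, 1.210))
  wat <- .demo_atom(14, "O", "HOH", "W", 501, 8.000, 8.000, 8.000,
                    b = 30.0, record = "HETATM")
  cell <- c(30, 30, 30, 90, 90, 90)
  initial <- xtal_model(rbind(leu, ala, wat), cell = cell, spacegroup = "P 1")

  final_atoms <- rbind(leu, ala)
  side <- final_atoms$name %in% c("CG", "CD1", "CD2") &
    final_atoms$resname == "LEU"
  ca <- as.numeric(final_atoms[final_atoms$name == "CA" &
                                 final_atoms$resname == "LEU",
                               c("x", "y", "z")])
  cb <- as.numeric(final_atoms[final_atoms$name == "CB" &
                                 final_atoms$resname == "LEU",
                               c("x", "y", "z")])
  xyz <- as.matrix(final_atoms[side, c("x", "y", "z")])
  final_atoms[side, c("x", "y", "z")] <-
    .rotate_about_axis(xyz, cb, cb - ca, 120)
  final <- xtal_model(final_atoms, cell = cell, spacegroup = "P 1")
  list(initial = initial, final = final)
}

#' Generate a synthetic reflection set
#'
#' Enumerates Miller indices of a half-sphere for the given cell down to
#' `d_min`, draws Wilson-like amplitudes whose mean falls off with
#' resolution, attaches proportional sigmas, optionally adds Gaussian
#' measurement noise, and flags a random test set. Deterministic for a seed.
#'
#' @param cell numeric(6) unit cell (default a 40 Angstrom cube).
#' @param d_min high-resolution limit (Angstrom).
#' @param n_max optional cap on the reflection count (random subsample).
#' @param test_fraction fraction of reflections flagged as the test set.
#' @param noise_sd relative Gaussian noise added to the amplitudes.
#' @param seed integer seed.
#' @return a [reflection_set]; the noise-free amplitudes are attached as
#'   attribute `f_true` on the object.
#' @export
generate_synthetic_reflections <- function(cell = c(40, 40, 40, 90, 90, 90),
                                           d_min = 2.0, n_max = NULL,
                                           test_fraction = 0.05,
                                           noise_sd = 0, seed = 1L) {
  rng_state <- .capture_rng()
  on.exit(.restore_rng(rng_state))
  set.seed(seed)
  hmax <- ceiling(max(cell[1:3]) / d_min)
  grid <- expand.grid(h = 0:hmax, k = -hmax:hmax, l = -hmax:hmax)
  # half sphere: unique under Friedel symmetry
  grid <- grid[grid$h > 0 | (grid$h == 0 & (grid$k > 0 |
                                              (grid$k == 0 & grid$l > 0))), ]
  d <- compute_d(cell, as.matrix(grid))
  keep <- d >= d_min
  grid <- grid[keep, ]; d <- d[keep]
  if (!is.null(n_max) && nrow(grid) > n_max) {
    sel <- sample(nrow(grid), n_max)
    grid <- grid[sel, ]; d <- d[sel]
  }
  n <- nrow(grid)
  f_true <- stats::rlnorm(n, meanlog = log(100) - 1.5 / d, sdlog = 0.4)
  f <- f_true * (1 + stats::rnorm(n, 0, noise_sd))
  f <- pmax(f, 1e-3)
  free <- as.integer(stats::runif(n) < test_fraction)
  rs <- reflection_set(
    data.frame(h = grid$h, k = grid$k, l = grid$l, f = f,
               sigf = pmax(0.05 * f_true, 1e-4), free = free),
    cell = cell, test_value = 1L)
  attr(rs, "f_true") <- f_true
  rs
}
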