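test_that("per-residue RSCC changes map onto the colour scheme", {
  fit <- function(rscc, n) residue_density_fit("A", 1, resname = "LEU",
                                               rscc = rscc, n_grid = n)
  v <- classify_rscc_change(fit(0.85, 120), fit(0.85, 120))
  expect_equal(v$label, "insignificant")
  expect_equal(v$color, "grey")
  expect_equal(v$magnitude, 0)
  expect_equal(classify_rscc_change(fit(0.80, 103), fit(0.90, 103))$color,
               "green")
  expect_equal(classify_rscc_change(fit(0.90, 103), fit(0.80, 103))$color,
               "red")
  expect_equal(classify_rscc_change(fit(0.80, 3), fit(0.90, 103))$color,
               "white")
  other <- residue_density_fit("B", 1, rscc = 0.8, n_grid = 50)
  expect_error(classify_rscc_change(fit(0.8, 50), other), "different residues")
})

test_that("RSCC colour classes partition all defined and undefined cases", {
  cases <- expand.grid(cc_i = c(0.3, 0.8), cc_f = c(0.31, 0.9),
                       n_i = c(3, 200), n_f = c(2, 400))
  for (r in seq_len(nrow(cases))) {
    v <- classify_cc_change(cases$cc_i[r], cases$n_i[r],
                            cases$cc_f[r], cases$n_f[r])
    z <- zchange_cc(cases$cc_i[r], cases$n_i[r], cases$cc_f[r], cases$n_f[r])
    want <- if (is.na(z)) "white"
    else if (abs(z) <= 2.6) "grey"
    else if (z > 0) "green" else "red"
    expect_equal(v$color, want)
  }
})

test_that("grid-point estimation matches brute-force lattice enumeration", {
  one <- make_atom(1, "O", "HOH", "W", 1, 0, 0, 0, element = "O")
  got <- estimate_grid_points(one, d = 3)  # spacing 1 A, radius 2 A
  brute <- 0
  for (x in -3:3) for (y in -3:3) for (z in -3:3)
    if (x^2 + y^2 + z^2 <= 4) brute <- brute + 1
  expect_equal(got, brute)
  expect_equal(got, 33L)
})

test_that("coarser grids never gain points; distant atoms add disjointly", {
  res <- rbind(make_atom(1, "C1", "LIG", "A", 1, 0.3, 0.1, -0.2),
               make_atom(2, "C2", "LIG", "A", 1, 1.5, 0.4, 0.3))
  counts <- vapply(c(1.5, 2, 3, 4.5, 6), function(d)
    estimate_grid_points(res, d), numeric(1))
  expect_true(all(diff(counts) <= 0))
  a <- make_atom(1, "O", "HOH", "W", 1, 0, 0, 0, element = "O")
  b <- make_atom(2, "O", "HOH", "W", 2, 10, 0, 0, element = "O")
  expect_equal(estimate_grid_points(rbind(a, b), d = 3),
               2 * estimate_grid_points(a, d = 3))
})

test_that("identical models produce no change records", {
  m <- demo_model_pair()$initial
  expect_equal(nrow(diff_models(m, m)), 0L)
})

test_that("the demo pair yields exactly one rotamer change and one deleted water", {
  p <- demo_model_pair()
  ch <- diff_models(p$initial, p$final)
  expect_equal(nrow(ch), 2L)
  expect_setequal(ch$category, c("rotamer", "water-deleted"))
  rot <- ch[ch$category == "rotamer", ]
  expect_equal(rot$resname, "LEU")
  expect_equal(rot$seqnum, 1L)
})

test_that("chi dihedrals agree with an independent torsion routine", {
  p <- demo_model_pair()
  leu_i <- p$initial$atoms[p$initial$atoms$resname == "LEU", ]
  leu_f <- p$final$atoms[p$final$atoms$resname == "LEU", ]
  chi1 <- function(res) {
    xyz <- unlist(lapply(c("N", "CA", "CB", "CG"), function(nm) {
      r <- res[res$name == nm, ]
      c(r$x, r$y, r$z)
    }))
    bio3d::torsion.xyz(xyz, atm.inc = 4)
  }
  own <- function(res) dihedral_angle(
    as.numeric(res[res$name == "N", c("x", "y", "z")]),
    as.numeric(res[res$name == "CA", c("x", "y", "z")]),
    as.numeric(res[res$name == "CB", c("x", "y", "z")]),
    as.numeric(res[res$name == "CG", c("x", "y", "z")]))
  expect_equal(own(leu_i), as.numeric(chi1(leu_i)), tolerance = 1e-6)
  expect_equal(own(leu_f), as.numeric(chi1(leu_f)), tolerance = 1e-6)
  # the constructed rotation moved chi1 by 120 degrees (per the oracle too)
  delta <- (as.numeric(chi1(leu_f)) - as.numeric(chi1(leu_i))) %% 360
  expect_equal(min(delta, 360 - delta), 120, tolerance = 1e-6)
})

test_that("a His/Asn/Gln terminal swap is detected as a flip", {
  asn <- rbind(
    make_atom(1, "N",   "ASN", "A", 1, 0.0, 0.0, 0.0),
    make_atom(2, "CA",  "ASN", "A", 1, 1.46, 0.0, 0.0),
    make_atom(3, "C",   "ASN", "A", 1, 2.0, 1.42, 0.0),
    make_atom(4, "O",   "ASN", "A", 1, 1.25, 2.39, 0.0),
    make_atom(5, "CB",  "ASN", "A", 1, 2.0, -0.77, -1.22),
    make_atom(6, "CG",  "ASN", "A", 1, 3.5, -1.05, -1.28),
    make_atom(7, "OD1", "ASN", "A", 1, 4.2, -0.55, -2.15, element = "O"),
    make_atom(8, "ND2", "ASN", "A", 1, 4.0, -1.85, -0.35, element = "N"))
  flipped <- asn
  flipped[flipped$name == "OD1", c("x", "y", "z")] <- asn[asn$name == "ND2",
                                                          c("x", "y", "z")]
  flipped[flipped$name == "ND2", c("x", "y", "z")] <- asn[asn$name == "OD1",
                                                          c("x", "y", "z")]
  ch <- diff_models(xtal_model(asn), xtal_model(flipped))
  expect_equal(ch$category, "hnq-flip")
})

test_that("a swung carbonyl with a fixed backbone is a peptide flip", {
  p <- demo_model_pair()
  m2 <- p$initial
  o_row <- m2$atoms$name == "O" & m2$atoms$resname == "LEU"
  m2$atoms[o_row, c("x", "y", "z")] <- m2$atoms[o_row, c("x", "y", "z")] +
    c(0, -2.5, 1.5)
  ch <- diff_models(p$initial, m2)
  expect_equal(ch$category, "peptide-flip")
})

test_that("a completed side chain is reported once", {
  p <- demo_model_pair()
  stub <- p$initial
  stub$atoms <- stub$atoms[!(stub$atoms$resname == "LEU" &
                               stub$atoms$name %in% c("CG", "CD1", "CD2")), ]
  ch <- diff_models(stub, p$initial)
  leu_rows <- ch[ch$resname == "LEU", ]
  expect_equal(leu_rows$category, "side-chain-completed")
  # and the reverse direction reports nothing for the water-free pair
  expect_equal(nrow(diff_models(p$initial, stub)[
    diff_models(p$initial, stub)$category == "side-chain-completed", ]), 0L)
})

test_that("water deletion is reported only in the deleting direction", {
  p <- demo_model_pair()
  fwd <- diff_models(p$initial, p$final)
  rev <- diff_models(p$final, p$initial)
  expect_equal(sum(fwd$category == "water-deleted"), 1L)
  expect_equal(sum(rev$category == "water-deleted"), 0L)
})

test_that("change detection is invariant under a common rigid-body motion", {
  p <- demo_model_pair()
  ch0 <- diff_models(p$initial, p$final)
  mi <- rigid_transform(p$initial, angle = 23, axis = c(1, -2, 2),
                        shift = c(4, 4, -6))
  mf <- rigid_transform(p$final, angle = 23, axis = c(1, -2, 2),
                        shift = c(4, 4, -6))
  ch1 <- diff_models(mi, mf)
  expect_identical(ch1$category, ch0$category)
  expect_identical(ch1$seqnum, ch0$seqnum)
})

test_that("Coot scripts carry one button per change in both dialects", {
  p <- demo_model_pair()
  ch <- diff_models(p$initial, p$final)
  scripts <- write_coot_scripts(ch)
  expect_equal(length(gregexpr("(list \"", scripts$scm, fixed = TRUE)[[1]]),
               nrow(ch))
  expect_equal(length(gregexpr("[\"", scripts$py, fixed = TRUE)[[1]]),
               nrow(ch))
  expect_match(scripts$scm, "interesting-things-gui")
  expect_match(scripts$py, "interesting_things_gui")
  wat <- ch[ch$category == "water-deleted", ]
  expect_match(scripts$scm, sprintf("%.3f %.3f %.3f", wat$x, wat$y, wat$z),
               fixed = TRUE)
  expect_match(scripts$scm, "water-deleted W501 HOH", fixed = TRUE)
  # empty change list: a valid zero-button dialog
  empty <- write_coot_scripts(ch[0, ])
  expect_match(empty$scm, "interesting-things-gui")
  expect_false(grepl("(list \"", empty$scm, fixed = TRUE))
})

test_that("density-fit tables round-trip and classify as a batch", {
  fits_i <- data.frame(chain = "A", seqnum = 1:3, icode = "",
                       resname = c("LEU", "ALA", "HOH"),
                       rsr = c(0.1, 0.12, 0.3),
                       rscc = c(0.80, 0.95, 0.70),
                       n_grid = c(103, 80, 3))
  fits_f <- fits_i
  fits_f$rscc <- c(0.90, 0.95, 0.75)
  back <- read_density_fits(write_density_fits(fits_i))
  expect_equal(back$rscc, fits_i$rscc)
  res <- rscc_change_table(fits_i, fits_f)
  expect_equal(res$table$color, c("green", "grey", "white"))
  expect_equal(res$mean_change, mean(c(0.10, 0)))
})
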