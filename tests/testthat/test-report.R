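write_demo_inputs <- function(dir) {
  p <- demo_model_pair()
  writeLines(write_model(p$initial), file.path(dir, "initial.pdb"), sep = "")
  writeLines(write_model(p$final), file.path(dir, "final.pdb"), sep = "")
  metrics_i <- list(r = 0.22, r_free = 0.25, n_test = 1200, cc_free = 0.90,
                    n_free_obs = 1200, bond_rmsz = 0.7, angle_rmsz = 1.2,
                    rama_z = -2.0, rotamer_z = -1.5, packing_z = -0.5,
                    gibbs = -40, resolution = 2.0)
  metrics_f <- metrics_i
  metrics_f$r <- 0.19; metrics_f$r_free <- 0.21; metrics_f$cc_free <- 0.94
  metrics_f$angle_rmsz <- 1.0; metrics_f$rama_z <- -1.0
  metrics_f$rotamer_z <- -0.2
  jsonlite::write_json(metrics_i, file.path(dir, "metrics_i.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(metrics_f, file.path(dir, "metrics_f.json"),
                       auto_unbox = TRUE, digits = NA)
  write_databank(generate_synthetic_databank(2000, seed = 12),
                 file.path(dir, "databank.tsv"))
  fits_i <- data.frame(chain = "A", seqnum = 1:2, icode = "",
                       resname = c("LEU", "ALA"), rsr = c(0.12, 0.10),
                       rscc = c(0.80, 0.93), n_grid = c(103, 60))
  fits_f <- fits_i
  fits_f$rscc <- c(0.90, 0.94)
  write_density_fits(fits_i, file.path(dir, "fits_i.tsv"))
  write_density_fits(fits_f, file.path(dir, "fits_f.tsv"))
  invisible(dir)
}

test_that("identical inputs give an all-grey table and empty Coot scripts", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  res <- compare_models(file.path(dir, "initial.pdb"),
                        file.path(dir, "initial.pdb"),
                        file.path(dir, "metrics_i.json"),
                        file.path(dir, "metrics_i.json"),
                        file.path(dir, "databank.tsv"))
  expect_true(all(res$comparison$label %in% c("insignificant", "undefined")))
  expect_equal(nrow(res$changes), 0L)
  expect_false(grepl("(list \"", res$scripts$scm, fixed = TRUE))
})

test_that("the demo bundle detects the constructed changes end to end", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  out <- file.path(dir, "bundle")
  res <- compare_models(file.path(dir, "initial.pdb"),
                        file.path(dir, "final.pdb"),
                        file.path(dir, "metrics_i.json"),
                        file.path(dir, "metrics_f.json"),
                        file.path(dir, "databank.tsv"),
                        fits_i = file.path(dir, "fits_i.tsv"),
                        fits_f = file.path(dir, "fits_f.tsv"),
                        outdir = out)
  expect_gte(sum(res$changes$category == "rotamer"), 1L)
  expect_equal(sum(res$changes$category == "water-deleted"), 1L)
  for (f in c("comparison.json", "comparison.html", "boxplots.json",
              "residue_rscc.tsv", "rscc.json", "changes.scm", "changes.py",
              "decisions.log"))
    expect_true(file.exists(file.path(out, f)), label = f)
  box <- jsonlite::read_json(file.path(out, "boxplots.json"),
                             simplifyVector = TRUE)
  expect_true(all(c("r_free", "rama_z", "rotamer_z") %in% names(box)))
  expect_gt(box$r_free$n, 100)
  expect_true(box$r_free$q1 <= box$r_free$median &&
                box$r_free$median <= box$r_free$q3)
  # r_free dropped 0.25 -> 0.21 with sigma = 0.25/sqrt(1200): a green row
  cmp <- res$comparison
  expect_equal(cmp$label[cmp$metric == "r_free"], "improvement")
  # the JSON table is a pure view of the in-memory comparison
  js <- jsonlite::read_json(file.path(out, "comparison.json"),
                            simplifyVector = TRUE)
  expect_equal(js$metric, cmp$metric)
  expect_equal(js$label, cmp$label)
  expect_equal(js$final[js$metric == "r_free"], 0.21)
  # one structured decision line per comparison row
  log <- readLines(file.path(out, "decisions.log"))
  expect_equal(sum(grepl("^metric=", log)), nrow(cmp))
})

test_that("re-running the comparison is byte-for-byte deterministic", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  run <- function(out) {
    compare_models(file.path(dir, "initial.pdb"), file.path(dir, "final.pdb"),
                   file.path(dir, "metrics_i.json"),
                   file.path(dir, "metrics_f.json"),
                   file.path(dir, "databank.tsv"),
                   fits_i = file.path(dir, "fits_i.tsv"),
                   fits_f = file.path(dir, "fits_f.tsv"), outdir = out)
    out
  }
  a <- run(file.path(dir, "a")); b <- run(file.path(dir, "b"))
  for (f in list.files(a))
    expect_identical(readLines(file.path(a, f)), readLines(file.path(b, f)),
                     label = f)
})

test_that("omitting the density-fit tables drops the RSCC section with a notice", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  out <- file.path(dir, "partial")
  res <- compare_models(file.path(dir, "initial.pdb"),
                        file.path(dir, "final.pdb"),
                        file.path(dir, "metrics_i.json"),
                        file.path(dir, "metrics_f.json"),
                        file.path(dir, "databank.tsv"), outdir = out)
  expect_null(res$rscc)
  expect_false(file.exists(file.path(out, "residue_rscc.tsv")))
  expect_true(any(grepl("RSCC section omitted",
                        readLines(file.path(out, "decisions.log")))))
})

test_that("missing mandatory inputs raise an error naming the file", {
  dir <- withr::local_tempdir()
  write_demo_inputs(dir)
  expect_error(compare_models(file.path(dir, "nope.pdb"),
                              file.path(dir, "final.pdb"),
                              file.path(dir, "metrics_i.json"),
                              file.path(dir, "metrics_f.json"),
                              file.path(dir, "databank.tsv")),
               "nope.pdb")
})

test_that("every comparison metric has a bundled explanation", {
  base <- quality_scores(r = 0.2, r_free = 0.22, n_test = 100)
  for (metric in build_comparison(base, base)$metric) {
    txt <- explain(metric)
    expect_gt(nchar(txt), 40)
  }
  expect_match(explain("r_free"), "cross-validation")
  expect_error(explain("xyzzy"), "known metrics")
})
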