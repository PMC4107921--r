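make_rs <- function(d_values, f = NULL, sigf = NULL, free = NULL) {
  # synthetic set with prescribed d values on a fake cell: use a large cubic
  # cell and pick (h,0,0) indices, then overwrite d directly
  n <- length(d_values)
  rs <- reflection_set(data.frame(h = seq_len(n), k = 0L, l = 0L,
                                  f = if (is.null(f)) rep(100, n) else f,
                                  sigf = if (is.null(sigf)) rep(1, n) else sigf,
                                  free = if (is.null(free)) rep(0L, n) else free),
                       cell = c(1000, 1000, 1000, 90, 90, 90), test_value = 1L)
  rs$data$d <- d_values
  rs
}

test_that("binliner splits distinct-d reflections into near-equal bins", {
  rs <- make_rs(seq(10, 2, length.out = 100))
  bins <- binliner(rs, 4)
  expect_equal(vapply(bins, function(b) length(b$members), integer(1)),
               rep(25L, 4))
  rs10 <- make_rs(seq(10, 2, length.out = 10))
  expect_equal(vapply(binliner(rs10, 3), function(b) length(b$members),
                      integer(1)), c(4L, 3L, 3L))
  one <- binliner(rs10, 1)
  expect_equal(length(one), 1L)
  expect_equal(one[[1]]$d_low, 10)
  expect_equal(one[[1]]$d_high, 2)
  expect_error(binliner(rs10, 11), "more bins")
})

test_that("reflections with identical d never straddle a bin boundary", {
  rs <- make_rs(c(10, 9, 8, 7, 7, 7, 6, 5, 4, 3))
  bins <- binliner(rs, 3)
  for (b in bins) {
    inside <- rs$data$d[b$members]
    outside <- rs$data$d[-b$members]
    expect_equal(length(intersect(unique(inside), unique(outside))), 0L)
  }
})

test_that("binliner bins partition random reflection sets", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    rs <- make_rs(runif(n, 1.5, 30))
    nb <- sample(2:8, 1)
    bins <- binliner(rs, nb)
    members <- unlist(lapply(bins, `[[`, "members"))
    expect_equal(sort(members), seq_len(n))
    sizes <- vapply(bins, function(b) length(b$members), integer(1))
    expect_lte(diff(range(sizes)), 1L)  # all d distinct almost surely
    for (b in bins) expect_lt(b$d_high, b$d_low)
  }
})

test_that("free metrics match hand-evaluated values", {
  fm <- compute_free_metrics(c(10, 20), c(1, 1), c(11, 18), c(TRUE, TRUE))
  expect_equal(fm$r_free, 3 / 30)
  perfect <- compute_free_metrics(c(10, 20, 30), rep(1, 3), c(10, 20, 30),
                                  rep(TRUE, 3))
  expect_equal(perfect$r_free, 0)
  expect_equal(perfect$wr_free, 0)
  expect_equal(perfect$cc_free, 1)
  expect_error(compute_free_metrics(c(10, 20), c(1, 1), c(10, 20),
                                    c(TRUE, FALSE)), "2 test")
})

test_that("r_free and cc_free are invariant under a common amplitude scale", {
  set.seed(3)
  fo <- runif(20, 50, 150); fc <- fo + rnorm(20, 0, 5)
  fm1 <- compute_free_metrics(fo, rep(1, 20), fc, rep(TRUE, 20))
  fm2 <- compute_free_metrics(2 * fo, rep(1, 20), 2 * fc, rep(TRUE, 20))
  expect_equal(fm2$r_free, fm1$r_free)
  expect_equal(fm2$cc_free, fm1$cc_free)
})

test_that("resolute rejects iff two or more metrics deteriorate", {
  base <- structure(list(r_free = 0.2, wr_free = 0.22, cc_free = 0.9,
                         ll_free = -100, n_test = 50), class = "free_metrics")
  expect_true(resolute_decide(base, base)$accept)  # equally well: accept
  worse1 <- base; worse1$r_free <- 0.21
  expect_true(resolute_decide(base, worse1)$accept)
  worse2 <- worse1; worse2$cc_free <- 0.89
  expect_false(resolute_decide(base, worse2)$accept)
})

test_that("resolute matches enumeration of all 16 deterioration patterns", {
  base <- structure(list(r_free = 0.2, wr_free = 0.22, cc_free = 0.9,
                         ll_free = -100, n_test = 50), class = "free_metrics")
  for (pattern in 0:15) {
    bits <- as.logical(bitwAnd(pattern, c(1L, 2L, 4L, 8L)))
    high <- base
    if (bits[1]) high$r_free <- base$r_free + 0.01
    if (bits[2]) high$wr_free <- base$wr_free + 0.01
    if (bits[3]) high$cc_free <- base$cc_free - 0.01
    if (bits[4]) high$ll_free <- base$ll_free - 1
    dec <- resolute_decide(base, high)
    expect_equal(dec$n_worse, sum(bits))
    expect_equal(dec$accept, sum(bits) < 2)
  }
})

test_that("an identity engine extends the cutoff to the data limit", {
  rs <- generate_synthetic_reflections(d_min = 1.8, n_max = 1500,
                                       test_fraction = 0.1, seed = 21)
  m <- demo_model_pair()$initial
  res <- paired_refinement(m, rs, previous_d = 2.6, engine_identity(),
                           n_bins = 4)
  expect_equal(res$d_cutoff, min(rs$data$d))
  expect_true(all(res$report$decision == "accept"))
})

test_that("data extending no further than the previous cutoff change nothing", {
  rs <- generate_synthetic_reflections(d_min = 2.5, n_max = 500, seed = 22)
  m <- demo_model_pair()$initial
  res <- paired_refinement(m, rs, previous_d = 2.5, engine_identity())
  expect_equal(res$d_cutoff, 2.5)
  expect_equal(nrow(res$report), 0L)
})

test_that("a noise profile growing with resolution truncates the extension", {
  rs <- generate_synthetic_reflections(d_min = 1.6, n_max = 3000,
                                       test_fraction = 0.1, noise_sd = 0.02,
                                       seed = 23)
  m <- demo_model_pair()$initial
  noisy <- engine_mock_noise(seed = 5, base_error = 0.02, noise_scale = 0.5)
  res <- paired_refinement(m, rs, previous_d = 3.0, noisy, n_bins = 5)
  expect_lt(nrow(res$report), 6)
  if (nrow(res$report)) {
    expect_true(all(res$report$decision[-nrow(res$report)] == "accept"))
    expect_equal(res$report$decision[nrow(res$report)], "reject")
    expect_equal(res$d_cutoff, res$report$d_low_cutoff[nrow(res$report)])
  }
  # hand-traced consistency: the decision column follows resolute on the
  # reported metric pairs
  for (i in seq_len(nrow(res$report))) {
    row <- res$report[i, ]
    low <- structure(list(r_free = row$r_free_low, wr_free = row$wr_free_low,
                          cc_free = row$cc_free_low, ll_free = row$ll_free_low),
                     class = "free_metrics")
    high <- structure(list(r_free = row$r_free_high, wr_free = row$wr_free_high,
                           cc_free = row$cc_free_high, ll_free = row$ll_free_high),
                      class = "free_metrics")
    dec <- resolute_decide(low, high)
    expect_equal(row$decision, if (dec$accept) "accept" else "reject")
    expect_equal(row$n_worse, dec$n_worse)
  }
})

test_that("worsening the noise never extends the chosen cutoff", {
  rs <- generate_synthetic_reflections(d_min = 1.6, n_max = 3000,
                                       test_fraction = 0.1, noise_sd = 0.02,
                                       seed = 24)
  m <- demo_model_pair()$initial
  cutoffs <- vapply(c(0, 0.3, 3), function(scale) {
    eng <- engine_mock_noise(seed = 7, base_error = 0.02, noise_scale = scale)
    paired_refinement(m, rs, previous_d = 3.0, eng, n_bins = 5)$d_cutoff
  }, numeric(1))
  expect_true(all(diff(cutoffs) >= 0))  # d grows (or holds) as noise grows
})
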