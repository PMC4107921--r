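#' Should the free R factor be cross-validated?
#'
#' With a small test set, stochastic test-set selection can move the free R
#' factor by several percentage points, so a single value is unreliable.
#' k-fold cross-validation is triggered when the test set holds fewer than
#' 500 reflections.
#'
#' @param n_test number of test reflections.
#' @return TRUE when k-fold cross-validation should be used.
#' @export
needs_kfold <- function(n_test) {
  stopifnot(n_test >= 0)
  n_test < 500
}

#' Number of alternative test sets
#'
#' k is the number of disjoint alternative test sets that tile the data:
#' round(1 / test_fraction), e.g. 20 when the original test set is 5% of all
#' reflections; never fewer than 2.
#'
#' @param test_fraction fraction of reflections in the test set, in (0, 0.5].
#' @return integer k.
#' @export
infer_k <- function(test_fraction) {
  if (test_fraction <= 0 || test_fraction > 0.5)
    stop("test_fraction must lie in (0, 0.5]")
  max(2L, as.integer(round(1 / test_fraction)))
}

#' Build k disjoint test-set masks
#'
#' Reflections are assigned to k folds by a seeded random permutation within
#' thin resolution shells (consecutive blocks of k reflections in descending-d
#' order), so every fold samples all resolutions — the convention for free
#' sets. The masks are pairwise disjoint, cover all reflections, and fold
#' sizes differ by at most one within each shell. When the reflection file
#' already carries a multi-valued free flag covering values 0..k-1, those
#' deposited assignments are reused instead.
#'
#' @param rs a [reflection_set].
#' @param k number of folds, >= 2 and <= number of reflections.
#' @param seed integer seed.
#' @return list of k logical masks; the integer fold assignment is attached
#'   as attribute `fold`.
#' @export
make_kfold_sets <- function(rs, k, seed = 1L) {
  n <- nrow(rs$data)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("more folds than reflections")
  flags <- sort(unique(rs$data$free))
  deposited_kfold <- length(flags) == k && all(flags == seq_len(k) - 1L) &&
    min(table(rs$data$free)) >= n / (2 * k)  # balanced tiling, not a 0/1 flag
  if (deposited_kfold) {
    fold <- rs$data$free + 1L
  } else {
    rng_state <- .capture_rng()
    on.exit(.restore_rng(rng_state))
    set.seed(seed)
    fold <- integer(n)
    ord <- order(-rs$data$d)
    starts <- seq(1L, n, by = k)
    for (s in starts) {
      idx <- ord[s:min(s + k - 1L, n)]
      fold[idx] <- sample(k)[seq_along(idx)]
    }
  }
  masks <- lapply(seq_len(k), function(i) fold == i)
  attr(masks, "fold") <- fold
  masks
}

.capture_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Perturb a model before cross-validation
#'
#' A model refined against one test set is not "free" with respect to an
#' alternative test set; perturbing it decorrelates the model from earlier
#' selections. Two modes: `reset-b` sets every atomic B factor to a fixed
#' value (coordinates untouched; the default is the median input B rounded to
#' the nearest integer); `jiggle` displaces every atom by an isotropic
#' zero-mean Gaussian per axis (B factors untouched), for regimes where
#' individual atomic B factors are not refined.
#'
#' @param m an [xtal_model].
#' @param mode "reset-b" or "jiggle".
#' @param b_value fixed B factor (Angstrom^2) for reset-b; default median B.
#' @param shift_sd per-axis displacement standard deviation (Angstrom) for
#'   jiggle; 0.2 is small enough to preserve the structure.
#' @param seed integer seed for jiggle.
#' @return the perturbed [xtal_model].
#' @export
perturb_model <- function(m, mode = c("reset-b", "jiggle"),
                          b_value = NULL, shift_sd = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "reset-b") {
    if (is.null(b_value)) b_value <- round(stats::median(m$atoms$b))
    m$atoms$b <- rep(as.numeric(b_value), nrow(m$atoms))
  } else {
    rng_state <- .capture_rng()
    on.exit(.restore_rng(rng_state))
    set.seed(seed)
    n <- nrow(m$atoms)
    m$atoms$x <- m$atoms$x + stats::rnorm(n, 0, shift_sd)
    m$atoms$y <- m$atoms$y + stats::rnorm(n, 0, shift_sd)
    m$atoms$z <- m$atoms$z + stats::rnorm(n, 0, shift_sd)
  }
  m
}

#' k-fold cross-validation of the free R factor
#'
#' For each of k disjoint test sets: perturb the input model, run the
#' refinement engine with that fold as the test set, and compute the work R
#' (over the other folds) and free R (over the fold) after a single
#' least-squares amplitude scale fitted on the work reflections. Aggregates
#' means and standard deviations of R, R_free and their gap across folds.
#'
#' @param m an [xtal_model].
#' @param rs a [reflection_set].
#' @param k fold count, or NULL to infer from the current test-set fraction.
#' @param engine a refinement engine (see [engine_identity]).
#' @param mode perturbation mode passed to [perturb_model].
#' @param seed integer seed (drives fold construction and perturbations).
#' @param b_value,shift_sd perturbation parameters, see [perturb_model].
#' @return list of class `kfold_result`: `k`, `folds` (data.frame fold, r,
#'   r_free, gap) and `summary` (data.frame metric, mean, sd).
#' @export
kfold_rfree <- function(m, rs, k = NULL, engine = engine_identity(),
                        mode = "reset-b", seed = 1L,
                        b_value = NULL, shift_sd = 0.2) {
  if (is.null(k)) k <- infer_k(mean(test_mask(rs)))
  masks <- make_kfold_sets(rs, k, seed = seed)
  d_limit <- min(rs$data$d)
  rows <- lapply(seq_len(k), function(i) {
    mask <- masks[[i]]
    rs_i <- rs
    rs_i$data$free <- as.integer(mask)
    rs_i$test_value <- 1L
    m_i <- perturb_model(m, mode = mode, b_value = b_value,
                         shift_sd = shift_sd, seed = seed + i)
    res <- engine(m_i, rs_i, d_limit)
    fo <- rs$data$f; fc <- res$f_calc
    kscale <- .ls_scale(fo[!mask], fc[!mask])
    fc <- kscale * fc
    r_work <- sum(abs(fo[!mask] - fc[!mask])) / sum(fo[!mask])
    r_free <- sum(abs(fo[mask] - fc[mask])) / sum(fo[mask])
    data.frame(fold = i, r = r_work, r_free = r_free, gap = r_free - r_work)
  })
  folds <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("r", "r_free", "gap"),
    mean = c(mean(folds$r), mean(folds$r_free), mean(folds$gap)),
    sd = c(stats::sd(folds$r), stats::sd(folds$r_free), stats::sd(folds$gap)),
    stringsAsFactors = FALSE)
  structure(list(k = k, folds = folds, summary = summary),
            class = "kfold_result")
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(sprintf("<kfold_result> k = %d\n", x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
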