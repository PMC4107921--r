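#' Equal-count resolution binning
#'
#' Sorts reflections by descending d-spacing (low to high resolution) and
#' splits them into `n_bins` contiguous groups of near-equal reflection count
#' (sizes differ by at most one when all d values are distinct; leading bins
#' take the remainder). Reflections sharing an identical d value never
#' straddle a bin boundary — the earlier bin grows to keep them together.
#' Equal counts, rather than equal resolution steps, make the information
#' content of successive shells predictably decreasing.
#'
#' @param rs a [reflection_set].
#' @param n_bins number of bins, >= 1 and <= number of reflections.
#' @return list of bins; each bin is a list with `d_low`, `d_high` (edges from
#'   member extremes, d_high < d_low) and `members` (row indices into
#'   `rs$data`).
#' @export
binliner <- function(rs, n_bins) {
  n <- nrow(rs$data)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_bins > n) stop("more bins than reflections")
  ord <- order(-rs$data$d)
  d_sorted <- rs$data$d[ord]
  bins <- vector("list", n_bins)
  start <- 1L
  left <- n_bins
  for (b in seq_len(n_bins)) {
    remaining <- n - start + 1L
    size <- ceiling(remaining / left)  # remainder spread over leading bins
    end <- start + size - 1L
    # keep ties on d together: extend while the next reflection has the same d
    while (end < n && d_sorted[end + 1L] == d_sorted[end]) end <- end + 1L
    members <- ord[start:end]
    bins[[b]] <- list(d_low = max(rs$data$d[members]),
                      d_high = min(rs$data$d[members]),
                      members = members)
    start <- end + 1L
    left <- left - 1L
    if (start > n) { bins <- bins[seq_len(b)]; break }
  }
  bins
}

#' Free-set fit metrics
#'
#' The four statistics used to judge a refinement against the test set:
#' \itemize{
#'   \item `r_free` = sum(|Fo - Fc|) / sum(Fo)
#'   \item `wr_free` = sqrt(sum(w (Fo - Fc)^2) / sum(w Fo^2)), w = 1/sigma^2
#'   \item `cc_free` = Pearson correlation of Fo and Fc
#'   \item `ll_free` = Gaussian log-likelihood
#'     sum(-(Fo - Fc)^2 / (2 sigma^2) - log(sigma sqrt(2 pi))); larger is
#'     better. This is a Gaussian surrogate for a refinement engine's own
#'     likelihood; an engine may supply its own value, which takes precedence
#'     in [paired_refinement].
#' }
#' All four are computed over test reflections only.
#'
#' @param f_obs,sigma,f_calc numeric vectors over the same reflections.
#' @param test logical mask of test reflections (>= 2 TRUE values required).
#' @return list of class `free_metrics` with fields `r_free`, `wr_free`,
#'   `cc_free`, `ll_free`, `n_test`.
#' @export
compute_free_metrics <- function(f_obs, sigma, f_calc, test) {
  if (sum(test) < 2) stop("need at least 2 test reflections")
  fo <- f_obs[test]; fc <- f_calc[test]; s <- sigma[test]
  if (any(s <= 0)) stop("sigma must be positive for weighting and likelihood")
  w <- 1 / s^2
  structure(list(
    r_free = sum(abs(fo - fc)) / sum(fo),
    wr_free = sqrt(sum(w * (fo - fc)^2) / sum(w * fo^2)),
    cc_free = stats::cor(fo, fc),
    ll_free = sum(-(fo - fc)^2 / (2 * s^2) - log(s * sqrt(2 * pi))),
    n_test = sum(test)), class = "free_metrics")
}

#' Accept or reject a higher-resolution refinement
#'
#' Paired-refinement decision rule: comparing the higher-resolution model
#' against the lower-resolution model on their common lower-resolution test
#' data, count the metrics that numerically deteriorate — r_free up, wr_free
#' up, cc_free down, ll_free down, all strictly (a tie is not a
#' deterioration, so a model that fits equally well is accepted). The
#' higher-resolution model is rejected when two or more metrics deteriorate.
#'
#' @param lowres,highres `free_metrics` for the models refined at the lower
#'   and higher resolution cutoff, both evaluated on the lower-cutoff test
#'   set.
#' @return list with `accept` (logical), `n_worse` (deterioration count) and
#'   `worse` (named logical over the four metrics).
#' @export
resolute_decide <- function(lowres, highres) {
  worse <- c(r_free = highres$r_free > lowres$r_free,
             wr_free = highres$wr_free > lowres$wr_free,
             cc_free = highres$cc_free < lowres$cc_free,
             ll_free = highres$ll_free < lowres$ll_free)
  n_worse <- sum(worse)
  list(accept = n_worse < 2, n_worse = n_worse, worse = worse)
}

# Single least-squares scale k minimizing sum (Fo - k Fc)^2 over the given
# reflections; applied to Fc before metric computation so the two engines'
# outputs are compared on a common scale.
.ls_scale <- function(f_obs, f_calc) {
  denom <- sum(f_calc^2)
  if (denom == 0) return(1)
  sum(f_obs * f_calc) / denom
}

#' Refinement engines
#'
#' A refinement engine is a function `(model, rs, d_cutoff) -> list(model,
#' f_calc, ll_free = NULL)` returning the refined model and calculated
#' amplitudes for every reflection in `rs` (reflections beyond the cutoff are
#' still predicted; only data with d >= d_cutoff are "used"). Engines must be
#' deterministic for a fixed seed. Real reciprocal-space refinement is out of
#' scope; these engines exercise the decision layer.
#'
#' `engine_identity` leaves the model untouched and returns `f_calc = f_obs`
#' (a perfect fit at every cutoff).
#'
#' @return a function with the engine signature, classed
#'   `refinement_engine`.
#' @export
engine_identity <- function() {
  structure(function(model, rs, d_cutoff) {
    list(model = model, f_calc = rs$data$f)
  }, class = c("refinement_engine", "function"))
}

#' @describeIn engine_identity returns a fixed amplitude vector regardless of
#'   cutoff — models an engine converged to a known ground truth, useful when
#'   the observed amplitudes carry synthetic noise around that truth.
#' @param f_calc amplitude vector aligned with the reflection table.
#' @export
engine_fixed <- function(f_calc) {
  force(f_calc)
  structure(function(model, rs, d_cutoff) {
    list(model = model, f_calc = f_calc)
  }, class = c("refinement_engine", "function"))
}

#' @describeIn engine_identity a seeded mock whose model error depends on the
#'   cutoff it was "refined" at: the relative error level is
#'   `base_error * sqrt(n_ref / n_used) + noise_scale * s(d_cutoff)`, where
#'   the first term falls as more reflections constrain the model and the
#'   second grows with the noise of the included high-resolution shells
#'   (`s` is the mean of `(d_max / d)^noise_power - 1` over the used
#'   reflections). The error direction per reflection is one fixed
#'   standard-normal draw from the seed, shared by every cutoff, so two
#'   refinements of the same data differ only in error amplitude and the
#'   accept/reject sequence of [paired_refinement] is fully deterministic:
#'   extension continues exactly while the error level keeps falling.
#' @param seed integer seed for the shared error vector.
#' @param base_error relative model error at `n_ref` reflections.
#' @param n_ref reference reflection count for the data-volume term.
#' @param noise_scale weight of the high-resolution noise term.
#' @param noise_power exponent of the resolution-dependent noise profile.
#' @export
engine_mock_noise <- function(seed = 1L, base_error = 0.05, n_ref = 1000,
                              noise_scale = 0, noise_power = 2) {
  structure(function(model, rs, d_cutoff) {
    used <- rs$data$d >= d_cutoff - 1e-9
    n_used <- sum(used)
    if (n_used < 2) stop("no reflections at this cutoff")
    d_used <- rs$data$d[used]
    d_anchor <- max(rs$data$d)  # fixed low-resolution anchor of the data set
    shell_noise <- mean((d_anchor / d_used)^noise_power) - 1
    sigma_rel <- base_error * sqrt(n_ref / n_used) + noise_scale * shell_noise
    eps <- .seeded_rng(seed)(nrow(rs$data))  # shared across cutoffs
    list(model = model, f_calc = rs$data$f * (1 + sigma_rel * eps))
  }, class = c("refinement_engine", "function"))
}

# Local standard-normal generator that does not disturb the global RNG state.
.seeded_rng <- function(seed) {
  function(n) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    stats::rnorm(n)
  }
}

#' Paired refinement to choose a resolution cutoff
#'
#' When reflection data extend beyond the resolution previously used for
#' refinement, the cutoff is extended step by step. The unused
#' high-resolution reflections are split into equal-count bins; each step
#' refines one model at the current (lower) cutoff and one at the next
#' (higher) cutoff, evaluates both with [compute_free_metrics] on the test
#' reflections of the current cutoff's range (the common data), applies a
#' single least-squares amplitude scale per model first, and accepts or
#' rejects the extension with [resolute_decide]. Extension stops at the first
#' rejection.
#'
#' @param m an [xtal_model].
#' @param rs a [reflection_set].
#' @param previous_d previous resolution cutoff (Angstrom).
#' @param engine a refinement engine (see [engine_identity]).
#' @param n_bins number of extension steps; default one bin per ~1000
#'   reflections beyond `previous_d`, minimum 2.
#' @return list with `d_cutoff` (chosen cutoff: the last accepted bin edge)
#'   and `report`, a data.frame with one row per attempted step (cutoffs, the
#'   four metrics for both models, deterioration count, decision).
#' @export
paired_refinement <- function(m, rs, previous_d, engine, n_bins = NULL) {
  beyond <- which(rs$data$d < previous_d)
  report_cols <- c("step", "d_low_cutoff", "d_high_cutoff",
                   "r_free_low", "wr_free_low", "cc_free_low", "ll_free_low",
                   "r_free_high", "wr_free_high", "cc_free_high", "ll_free_high",
                   "n_worse", "decision")
  empty_report <- as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(report_cols)), report_cols))
  if (!length(beyond))
    return(list(d_cutoff = previous_d, report = empty_report))
  if (is.null(n_bins))
    n_bins <- max(2L, round(length(beyond) / 1000))
  sub <- rs
  sub$data <- rs$data[beyond, , drop = FALSE]
  bins <- binliner(sub, min(n_bins, length(beyond)))

  current_d <- previous_d
  rows <- list()
  for (step in seq_along(bins)) {
    next_d <- bins[[step]]$d_high
    low <- engine(m, rs, current_d)
    high <- engine(m, rs, next_d)
    common_test <- test_mask(rs) & rs$data$d >= current_d - 1e-9
    if (sum(common_test) < 2)
      stop("fewer than 2 test reflections within the common resolution range")
    eval_one <- function(res) {
      k <- .ls_scale(rs$data$f[rs$data$d >= current_d - 1e-9],
                     res$f_calc[rs$data$d >= current_d - 1e-9])
      fm <- compute_free_metrics(rs$data$f, rs$data$sigf, k * res$f_calc,
                                 common_test)
      if (!is.null(res$ll_free)) fm$ll_free <- res$ll_free
      fm
    }
    fm_low <- eval_one(low)
    fm_high <- eval_one(high)
    dec <- resolute_decide(fm_low, fm_high)
    rows[[step]] <- data.frame(
      step = step, d_low_cutoff = current_d, d_high_cutoff = next_d,
      r_free_low = fm_low$r_free, wr_free_low = fm_low$wr_free,
      cc_free_low = fm_low$cc_free, ll_free_low = fm_low$ll_free,
      r_free_high = fm_high$r_free, wr_free_high = fm_high$wr_free,
      cc_free_high = fm_high$cc_free, ll_free_high = fm_high$ll_free,
      n_worse = dec$n_worse,
      decision = if (dec$accept) "accept" else "reject",
      stringsAsFactors = FALSE)
    if (!dec$accept) break
    current_d <- next_d
  }
  list(d_cutoff = current_d, report = do.call(rbind, rows))
}

#' Write a paired-refinement report as TSV
#' @param result list from [paired_refinement].
#' @param path optional output path; when NULL the text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
paired_refinement_tsv <- function(result, path = NULL) {
  rep <- result$report
  txt <- paste(c(paste(names(rep), collapse = "\t"),
                 if (nrow(rep)) apply(rep, 1, function(r)
                   paste(trimws(r), collapse = "\t")),
                 ""),
               collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}
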