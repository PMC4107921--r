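#' Select the resolution neighbourhood of a model
#'
#' Sorts the databank by distance in resolution space from the working model
#' and takes the top `n` nearest neighbours, including every further entry
#' whose distance exactly ties the n-th nearest (so the neighbourhood can
#' exceed `n`). When the databank is no larger than `n` the whole databank is
#' returned.
#'
#' @param db data.frame of reference entries with a `resolution` column.
#' @param resolution working-model resolution (Angstrom).
#' @param n neighbourhood size (default 1000).
#' @return the selected rows of `db`, ordered by distance.
#' @export
nearest_by_resolution <- function(db, resolution, n = 1000) {
  if (!nrow(db)) stop("empty databank")
  if (n < 1) stop("n must be >= 1")
  dist <- abs(db$resolution - resolution)
  ord <- order(dist)
  if (nrow(db) <= n) return(db[ord, , drop = FALSE])
  cut <- dist[ord][n]
  keep <- ord[dist[ord] <= cut]
  db[keep, , drop = FALSE]
}

#' Percentile rank of a score against a databank
#'
#' The percentage of databank values strictly worse than the given value
#' (orientation set by `higher_is_better`): the worst possible score maps to
#' 0, a score better than every entry to 100, and tied values share a rank.
#'
#' @param value the model's score.
#' @param db_values databank scores (non-empty numeric).
#' @param higher_is_better TRUE when larger scores are better (e.g.
#'   Z-scores), FALSE when smaller are better (e.g. R factors, bump
#'   severity).
#' @return percentile rank in [0, 100].
#' @export
percentile_rank <- function(value, db_values, higher_is_better = TRUE) {
  db_values <- db_values[!is.na(db_values)]
  if (!length(db_values)) stop("no databank values")
  worse <- if (higher_is_better) sum(db_values < value) else sum(db_values > value)
  100 * worse / length(db_values)
}

#' Box-and-whisker statistics
#'
#' Quartiles by linear interpolation; whiskers extend to the most extreme
#' data points within 1.5 interquartile ranges of the box; points beyond the
#' whiskers are flagged as outliers (Tukey's criterion).
#'
#' @param values numeric vector, at least 4 values.
#' @return list of class `box_stats`: `q1`, `median`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values for box statistics")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(q1 = q[1], median = q[2], q3 = q[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = sort(values[!inside]), n = length(values)),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("<box_stats> n = %d, box [%.4g, %.4g, %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$n, x$q1, x$median, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

# Generative parameters of the synthetic databank: resolution is log-normal
# around 2.0 A; each score is normal with a resolution-dependent mean. The
# trends mimic well-known behaviour (R factors and clash scores worsen, and
# geometry Z-scores drift down, as resolution degrades).
.synthetic_db_params <- list(
  resolution = list(meanlog = log(2.0), sdlog = 0.25),
  r_free = list(mean = function(res) 0.05 + 0.07 * res, sd = 0.03, min = 0.01),
  rama_z = list(mean = function(res) 1.0 - 1.2 * res, sd = 1.5),
  rotamer_z = list(mean = function(res) 0.8 - 1.0 * res, sd = 1.5),
  packing_z = list(mean = function(res) 0.5 - 0.8 * res, sd = 1.2),
  bsw = list(meanlog = function(res) log(0.5 + 1.5 * res), sdlog = 0.8))

#' Generate a synthetic reference databank
#'
#' Stands in for a large databank of quality scores of re-refined PDB
#' entries. Resolutions follow a log-normal distribution centred on 2.0
#' Angstrom; each quality score follows a resolution-dependent distribution
#' (see the package vignette for parameters). Deterministic for a given
#' seed.
#'
#' @param n number of entries.
#' @param seed integer seed.
#' @return data.frame with columns `entry_id`, `resolution`, `r_free`,
#'   `rama_z`, `rotamer_z`, `packing_z`, `bsw`.
#' @export
generate_synthetic_databank <- function(n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  rng_state <- .capture_rng()
  on.exit(.restore_rng(rng_state))
  set.seed(seed)
  p <- .synthetic_db_params
  res <- stats::rlnorm(n, p$resolution$meanlog, p$resolution$sdlog)
  data.frame(
    entry_id = sprintf("syn%05d", seq_len(n)),
    resolution = res,
    r_free = pmax(p$r_free$min,
                  stats::rnorm(n, p$r_free$mean(res), p$r_free$sd)),
    rama_z = stats::rnorm(n, p$rama_z$mean(res), p$rama_z$sd),
    rotamer_z = stats::rnorm(n, p$rotamer_z$mean(res), p$rotamer_z$sd),
    packing_z = stats::rnorm(n, p$packing_z$mean(res), p$packing_z$sd),
    bsw = stats::rlnorm(n, p$bsw$meanlog(res), p$bsw$sdlog),
    stringsAsFactors = FALSE)
}

#' Read a reference databank TSV
#' @param path file path or TSV text.
#' @return data.frame of reference entries.
#' @export
read_databank <- function(path) {
  tab <- utils::read.delim(text = paste(.as_lines(path), collapse = "\n"),
                           stringsAsFactors = FALSE)
  needed <- c("entry_id", "resolution")
  if (!all(needed %in% names(tab)))
    stop("databank needs columns: entry_id, resolution plus score columns")
  if (any(tab$resolution <= 0)) stop("non-positive resolutions in databank")
  tab
}

#' Write a reference databank TSV
#' @param db data.frame as from [generate_synthetic_databank].
#' @param path optional output path; when NULL the text is returned.
#' @return TSV text, invisibly when written to a file.
#' @export
write_databank <- function(db, path = NULL) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(db, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  txt <- paste(c(out, ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

# Orientation of each databank metric: is a higher value better?
.metric_orientation <- c(r_free = FALSE, rama_z = TRUE, rotamer_z = TRUE,
                         packing_z = TRUE, bsw = FALSE)

#' Percentile ranks of a model's scores in a databank neighbourhood
#'
#' @param scores a [quality_scores].
#' @param neighbourhood data.frame of reference entries (e.g. from
#'   [nearest_by_resolution]).
#' @return named numeric vector of percentiles (`rama`, `rotamer`,
#'   `packing`, `bump`), NA where the model lacks the score.
#' @export
databank_percentiles <- function(scores, neighbourhood) {
  get_pct <- function(value, column, higher) {
    if (is.na(value) || is.null(neighbourhood[[column]])) return(NA_real_)
    percentile_rank(value, neighbourhood[[column]], higher_is_better = higher)
  }
  c(rama = get_pct(scores$rama_z, "rama_z", TRUE),
    rotamer = get_pct(scores$rotamer_z, "rotamer_z", TRUE),
    packing = get_pct(scores$packing_z, "packing_z", TRUE),
    bump = get_pct(scores$bsw, "bsw", FALSE))
}
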