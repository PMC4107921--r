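#' Verdict on a metric change
#'
#' The outcome of one significance rule: a label, the test statistic that
#' drove it, and the display colour. The label-to-colour map is fixed:
#' improvement = green, deterioration = red, insignificant = grey,
#' undefined = white.
#'
#' @param label one of "improvement", "deterioration", "insignificant",
#'   "undefined".
#' @param magnitude the statistic behind the call (sigma multiples, Z_change,
#'   r.m.s.Z delta or percentile delta); NA when undefined.
#' @return object of class `verdict`.
#' @export
verdict <- function(label, magnitude = NA_real_) {
  label <- match.arg(label, c("improvement", "deterioration",
                              "insignificant", "undefined"))
  colors <- c(improvement = "green", deterioration = "red",
              insignificant = "grey", undefined = "white")
  structure(list(label = label, magnitude = magnitude,
                 color = unname(colors[label])),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s (%s), magnitude %s\n", x$label, x$color,
              format(x$magnitude, digits = 4)))
  invisible(x)
}

#' Global quality scores of one model
#'
#' Container for the metrics that drive the model-pair comparison. External
#' Z-scores (Ramachandran, rotamer, fine packing) and the Gibbs folding
#' energy are pass-through fields computed by other programs; percentile
#' ranks are filled in against a reference databank.
#'
#' @param r,r_free work and free R factors (fractions).
#' @param n_test number of test-set reflections behind `r_free`.
#' @param cc_free free correlation coefficient in (-1, 1).
#' @param n_free_obs number of data points behind `cc_free`.
#' @param bond_rmsz,angle_rmsz restraint r.m.s. Z-scores.
#' @param rama_z,rotamer_z,packing_z external Z-scores (may be NA).
#' @param gibbs Gibbs folding energy, kcal/mol (may be NA).
#' @param bsw weighted bump severity (may be NA).
#' @param percentiles named numeric vector of percentile ranks in [0, 100].
#' @return object of class `quality_scores`.
#' @export
quality_scores <- function(r = NA_real_, r_free = NA_real_, n_test = 0L,
                           cc_free = NA_real_, n_free_obs = 0L,
                           bond_rmsz = NA_real_, angle_rmsz = NA_real_,
                           rama_z = NA_real_, rotamer_z = NA_real_,
                           packing_z = NA_real_, gibbs = NA_real_,
                           bsw = NA_real_, percentiles = numeric(0)) {
  stopifnot(is.na(r) || r >= 0, is.na(r_free) || r_free >= 0, n_test >= 0)
  if (!is.na(cc_free) && abs(cc_free) >= 1)
    stop("cc_free must lie strictly inside (-1, 1)")
  if (length(percentiles) && any(percentiles < 0 | percentiles > 100,
                                 na.rm = TRUE))
    stop("percentile ranks must lie in [0, 100]")
  structure(list(r = r, r_free = r_free, n_test = as.integer(n_test),
                 cc_free = cc_free, n_free_obs = as.integer(n_free_obs),
                 bond_rmsz = bond_rmsz, angle_rmsz = angle_rmsz,
                 rama_z = rama_z, rotamer_z = rotamer_z,
                 packing_z = packing_z, gibbs = gibbs, bsw = bsw,
                 percentiles = percentiles),
            class = "quality_scores")
}

#' Standard deviation of the free R factor
#'
#' The Kleywegt-Bruenger estimate sigma(Rfree) = Rfree / sqrt(Ntest): the
#' precision of a free R factor is limited by the size of the test set.
#'
#' @param r_free free R factor (fraction), >= 0.
#' @param n_test number of test reflections.
#' @return estimated standard deviation; NA when `n_test` is 0 (significance
#'   is then undefined).
#' @export
sigma_rfree <- function(r_free, n_test) {
  stopifnot(r_free >= 0, n_test >= 0)
  if (n_test == 0) return(NA_real_)
  r_free / sqrt(n_test)
}

#' Classify a change in the free R factor
#'
#' A change is significant when it exceeds 2.6 sigma(Rfree) of the initial
#' model (two-sided p = 0.01 under a normal distribution); the baseline model
#' defines the null. A decrease is an improvement.
#'
#' @param initial,final [quality_scores] of the two models, scored against the
#'   same test set.
#' @param threshold significance multiple (default 2.6).
#' @return a [verdict]; magnitude is the change in units of sigma(Rfree).
#' @export
classify_rfree_change <- function(initial, final, threshold = 2.6) {
  if (is.na(initial$r_free) || is.na(final$r_free) || initial$n_test == 0)
    return(verdict("undefined"))
  s <- sigma_rfree(initial$r_free, initial$n_test)
  delta <- final$r_free - initial$r_free
  if (s == 0)
    return(verdict(if (delta == 0) "insignificant" else
      if (delta < 0) "improvement" else "deterioration", Inf * sign(delta)))
  z <- delta / s
  if (abs(z) > threshold)
    verdict(if (delta < 0) "improvement" else "deterioration", z)
  else
    verdict("insignificant", z)
}

#' Fisher transformation of a correlation coefficient
#'
#' z = atanh(cc) = 0.5 * log((1 + cc) / (1 - cc)); variance-stabilizing, odd
#' and strictly increasing on (-1, 1).
#'
#' @param cc correlation coefficient(s), |cc| < 1.
#' @return transformed value(s).
#' @export
fisher_z <- function(cc) {
  if (any(abs(cc) >= 1))
    stop("|cc| must be < 1 for the Fisher transformation")
  atanh(cc)
}

#' Z score for the change between two correlation coefficients
#'
#' Difference of Fisher-transformed correlations scaled by the standard
#' two-sample variance 1/(N-3) per sample:
#' Z = (z(cc_f) - z(cc_i)) / sqrt(1/(n_i - 3) + 1/(n_f - 3)).
#' Positive when the correlation improves. Undefined (NA) when either sample
#' has 3 or fewer data points — for per-residue density fits this happens for
#' small compounds such as waters or ions at low resolution.
#'
#' @param cc_i,cc_f initial and final correlation coefficients.
#' @param n_i,n_f numbers of data points behind each.
#' @return Z_change, or NA when undefined.
#' @export
zchange_cc <- function(cc_i, n_i, cc_f, n_f) {
  if (is.na(cc_i) || is.na(cc_f) || n_i <= 3 || n_f <= 3) return(NA_real_)
  (fisher_z(cc_f) - fisher_z(cc_i)) / sqrt(1 / (n_i - 3) + 1 / (n_f - 3))
}

#' Classify a change in a correlation coefficient
#'
#' |Z_change| > 2.6 is significant; the sign decides improvement versus
#' deterioration; an undefined Z maps to an undefined verdict.
#'
#' @param cc_i,cc_f initial and final correlation coefficients.
#' @param n_i,n_f numbers of data points behind each.
#' @param threshold significance threshold on |Z_change| (default 2.6).
#' @return a [verdict] with the Z_change as magnitude.
#' @export
classify_cc_change <- function(cc_i, n_i, cc_f, n_f, threshold = 2.6) {
  z <- zchange_cc(cc_i, n_i, cc_f, n_f)
  if (is.na(z)) return(verdict("undefined"))
  if (abs(z) > threshold)
    verdict(if (z > 0) "improvement" else "deterioration", z)
  else
    verdict("insignificant", z)
}

#' Classify a change in a restraint r.m.s. Z-score
#'
#' Restraint r.m.s. Z-scores have no sharp target other than not exceeding
#' 1.0, so a rule scheme replaces a distributional test: if the initial value
#' exceeds 1.0, any strict decrease is an improvement and any strict increase
#' a deterioration; crossing from below 1.0 to above 1.0 is always a
#' deterioration; everything else is insignificant.
#'
#' @param rmsz_i,rmsz_f initial and final r.m.s. Z-scores (>= 0).
#' @return a [verdict] with the delta as magnitude.
#' @export
classify_rmsz_change <- function(rmsz_i, rmsz_f) {
  if (is.na(rmsz_i) || is.na(rmsz_f)) return(verdict("undefined"))
  stopifnot(rmsz_i >= 0, rmsz_f >= 0)
  delta <- rmsz_f - rmsz_i
  if (rmsz_i > 1.0 && rmsz_f > rmsz_i) return(verdict("deterioration", delta))
  if (rmsz_i > 1.0 && rmsz_f < rmsz_i) return(verdict("improvement", delta))
  if (rmsz_i <= 1.0 && rmsz_f > 1.0) return(verdict("deterioration", delta))
  verdict("insignificant", delta)
}

#' Classify a change in a percentile rank
#'
#' With a databank of roughly 70 000 entries, one percentile point spans about
#' 700 entries, so a change of one point or more is taken as significant.
#'
#' @param p_i,p_f initial and final percentile ranks in [0, 100].
#' @param threshold minimal significant change in points (default 1).
#' @return a [verdict] with the percentile delta as magnitude.
#' @export
classify_percentile_change <- function(p_i, p_f, threshold = 1) {
  if (is.na(p_i) || is.na(p_f)) return(verdict("undefined"))
  stopifnot(p_i >= 0, p_i <= 100, p_f >= 0, p_f <= 100)
  delta <- p_f - p_i
  if (abs(delta) >= threshold)
    verdict(if (delta > 0) "improvement" else "deterioration", delta)
  else
    verdict("insignificant", delta)
}

.pct_or_na <- function(qs, name) {
  if (!is.null(qs$percentiles) && name %in% names(qs$percentiles))
    unname(qs$percentiles[[name]])
  else NA_real_
}

#' Build the model-pair comparison table
#'
#' One row per global quality indicator: work R, free R, free correlation
#' coefficient, bond and angle r.m.s. Z, Gibbs folding energy, and the
#' Ramachandran, rotamer, bump-severity and fine-packing percentiles. Each row
#' is classified with the rule appropriate to its metric; work R and the Gibbs
#' energy carry no significance rule and are reported without a verdict
#' (undefined/white).
#'
#' @param initial,final [quality_scores] for the two models.
#' @return data.frame with columns `metric`, `initial`, `final`, `label`,
#'   `magnitude`, `color`.
#' @export
build_comparison <- function(initial, final) {
  rows <- list(
    list("r", initial$r, final$r, verdict("undefined")),
    list("r_free", initial$r_free, final$r_free,
         classify_rfree_change(initial, final)),
    list("cc_free", initial$cc_free, final$cc_free,
         classify_cc_change(initial$cc_free, initial$n_free_obs,
                            final$cc_free, final$n_free_obs)),
    list("bond_rmsz", initial$bond_rmsz, final$bond_rmsz,
         classify_rmsz_change(initial$bond_rmsz, final$bond_rmsz)),
    list("angle_rmsz", initial$angle_rmsz, final$angle_rmsz,
         classify_rmsz_change(initial$angle_rmsz, final$angle_rmsz)),
    list("gibbs", initial$gibbs, final$gibbs, verdict("undefined"))
  )
  for (p in c("rama", "rotamer", "bump", "packing")) {
    rows[[length(rows) + 1L]] <- list(
      paste0(p, "_percentile"), .pct_or_na(initial, p), .pct_or_na(final, p),
      classify_percentile_change(.pct_or_na(initial, p), .pct_or_na(final, p)))
  }
  data.frame(
    metric = vapply(rows, `[[`, character(1), 1),
    initial = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    final = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    label = vapply(rows, function(r) r[[4]]$label, character(1)),
    magnitude = vapply(rows, function(r) as.numeric(r[[4]]$magnitude),
                       numeric(1)),
    color = vapply(rows, function(r) r[[4]]$color, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Render a comparison table as an HTML fragment
#'
#' A pure view over [build_comparison] output: same values, one `<tr>` per
#' metric with the verdict colour as the row class.
#'
#' @param comparison data.frame from [build_comparison].
#' @return character scalar of HTML.
#' @export
comparison_html <- function(comparison) {
  fmt <- function(v) ifelse(is.na(v), "&ndash;", formatC(v, digits = 4,
                                                         format = "fg"))
  rows <- sprintf('  <tr class="%s"><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>',
                  comparison$color, comparison$metric,
                  fmt(comparison$initial), fmt(comparison$final),
                  comparison$label)
  paste(c('<table class="model-comparison">',
          "  <tr><th>metric</th><th>initial</th><th>final</th><th>verdict</th></tr>",
          rows, "</table>", ""), collapse = "\n")
}

#' Read quality scores from a JSON metrics file
#'
#' Key-value JSON; recognized keys match the [quality_scores] fields, plus an
#' optional `resolution` (Angstrom) used for databank neighbourhood lookups.
#'
#' @param path JSON file path.
#' @return list with elements `scores` ([quality_scores]) and `resolution`.
#' @export
read_metrics <- function(path) {
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(key) if (!is.null(kv[[key]])) as.numeric(kv[[key]]) else NA_real_
  int <- function(key) if (!is.null(kv[[key]])) as.integer(kv[[key]]) else 0L
  qs <- quality_scores(
    r = num("r"), r_free = num("r_free"), n_test = int("n_test"),
    cc_free = num("cc_free"), n_free_obs = int("n_free_obs"),
    bond_rmsz = num("bond_rmsz"), angle_rmsz = num("angle_rmsz"),
    rama_z = num("rama_z"), rotamer_z = num("rotamer_z"),
    packing_z = num("packing_z"), gibbs = num("gibbs"), bsw = num("bsw"))
  list(scores = qs, resolution = num("resolution"))
}
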