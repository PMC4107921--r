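# Bundled one-paragraph explanations of every metric in the comparison table.
.metric_docs <- list(
  r = paste("Work R factor: the conventional residual sum(|Fo - Fc|)/sum(Fo)",
            "over the working reflections used in refinement. Because the",
            "model is fitted to exactly these data, R can be lowered by",
            "overfitting, so no significance rule is attached to its change."),
  r_free = paste("Free R factor: the same residual computed over the test set",
                 "of reflections withheld from refinement (cross-validation).",
                 "Its precision is limited by the test-set size; a change is",
                 "significant when it exceeds 2.6 estimated standard",
                 "deviations (Rfree/sqrt(Ntest)) of the initial model,",
                 "a two-sided p of 0.01 under a normal distribution."),
  cc_free = paste("Free correlation coefficient between observed and",
                  "calculated amplitudes over the test set. Changes are",
                  "tested after the Fisher transformation; a Z score above",
                  "2.6 in magnitude is significant."),
  bond_rmsz = paste("Root-mean-square Z-score of bond-length restraint",
                    "deviations. Values near 1 match the restraint library;",
                    "values above 1 are too loose. From above 1.0 any",
                    "decrease is an improvement and any increase a",
                    "deterioration; crossing upwards through 1.0 is always a",
                    "deterioration."),
  angle_rmsz = paste("Root-mean-square Z-score of bond-angle restraint",
                     "deviations; judged with the same rule scheme as the",
                     "bond-length r.m.s. Z-score."),
  gibbs = paste("Gibbs folding energy (kcal/mol) computed by an external",
                "program; reported as a pass-through value. No significance",
                "rule is defined for its change."),
  rama_percentile = paste("Percentile rank of the Ramachandran-plot Z-score",
                          "against the reference databank neighbourhood; a",
                          "change of one point or more (roughly 700 entries",
                          "in a 70 000-entry databank) is significant."),
  rotamer_percentile = paste("Percentile rank of the side-chain rotamer",
                             "quality Z-score against the reference databank;",
                             "one point or more of change is significant."),
  bump_percentile = paste("Percentile rank of the weighted bump severity, a",
                          "quadratically weighted sum of van der Waals",
                          "overlaps per residue that emphasizes severe",
                          "clashes; one point or more of change is",
                          "significant."),
  packing_percentile = paste("Percentile rank of the fine (second-generation)",
                             "packing Z-score against the reference databank;",
                             "one point or more of change is significant."))

#' Explain a quality metric
#'
#' @param metric metric name as used in the comparison table.
#' @return one-paragraph plain-text explanation.
#' @export
explain <- function(metric) {
  if (!metric %in% names(.metric_docs))
    stop("unknown metric '", metric, "'; known metrics: ",
         paste(names(.metric_docs), collapse = ", "))
  .metric_docs[[metric]]
}

.read_if_path <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("input file not found: ", x)
    reader(x)
  } else x
}

.decision_log_lines <- function(comparison) {
  rule <- c(r = "none", r_free = "2.6 sigma(Rfree)", cc_free = "|Zchange| > 2.6",
            bond_rmsz = "rmsZ rule scheme", angle_rmsz = "rmsZ rule scheme",
            gibbs = "none", rama_percentile = ">= 1 percentile point",
            rotamer_percentile = ">= 1 percentile point",
            bump_percentile = ">= 1 percentile point",
            packing_percentile = ">= 1 percentile point")
  sprintf("metric=%s rule=%s initial=%s final=%s magnitude=%s verdict=%s",
          comparison$metric, unname(rule[comparison$metric]),
          format(comparison$initial, digits = 4),
          format(comparison$final, digits = 4),
          format(comparison$magnitude, digits = 4), comparison$label)
}

#' Compare two models and write the full report bundle
#'
#' The main workflow: reads the initial and final model with their global
#' metrics, fills in the bump-severity score from the coordinates when it is
#' absent, ranks both models in a resolution neighbourhood of the reference
#' databank, classifies every global indicator, classifies per-residue
#' density-fit changes when fit tables are given, detects discrete model
#' changes and emits Coot scripts. Writes to `outdir`:
#' \itemize{
#'   \item `comparison.json` and `comparison.html`: the verdict table;
#'   \item `boxplots.json`: box statistics of r_free and the geometry
#'     Z-scores over the databank neighbourhood, with the model's values;
#'   \item `residue_rscc.tsv` and `rscc.json`: per-residue classification
#'     and the mean-change line (omitted, with a logged notice, when no fit
#'     tables are supplied);
#'   \item `changes.scm` / `changes.py`: Coot button scripts;
#'   \item `decisions.log`: one structured line per verdict.
#' }
#'
#' @param model_i,model_f [xtal_model]s or PDB file paths.
#' @param metrics_i,metrics_f metric lists (as from [read_metrics]) or JSON
#'   paths.
#' @param databank reference databank data.frame or TSV path.
#' @param fits_i,fits_f optional per-residue density-fit tables or TSV paths.
#' @param outdir output directory (created if needed), or NULL to skip
#'   writing files.
#' @param n_neighbours databank neighbourhood size (default 1000).
#' @return (invisibly) list with `comparison`, `percentiles_i`,
#'   `percentiles_f`, `boxplots`, `rscc`, `changes`, `scripts`, `log`.
#' @export
compare_models <- function(model_i, model_f, metrics_i, metrics_f, databank,
                           fits_i = NULL, fits_f = NULL, outdir = NULL,
                           n_neighbours = 1000) {
  model_i <- .read_if_path(model_i, read_model)
  model_f <- .read_if_path(model_f, read_model)
  metrics_i <- .read_if_path(metrics_i, read_metrics)
  metrics_f <- .read_if_path(metrics_f, read_metrics)
  databank <- .read_if_path(databank, read_databank)
  if (!is.null(fits_i)) fits_i <- .read_if_path(fits_i, read_density_fits)
  if (!is.null(fits_f)) fits_f <- .read_if_path(fits_f, read_density_fits)

  log_lines <- character(0)
  scores_i <- metrics_i$scores
  scores_f <- metrics_f$scores
  if (is.na(scores_i$bsw)) {
    scores_i$bsw <- weighted_bump_severity(detect_clashes(model_i),
                                           n_residues(model_i))
    log_lines <- c(log_lines, sprintf(
      "bsw(initial)=%.4f computed from coordinates", scores_i$bsw))
  }
  if (is.na(scores_f$bsw)) {
    scores_f$bsw <- weighted_bump_severity(detect_clashes(model_f),
                                           n_residues(model_f))
    log_lines <- c(log_lines, sprintf(
      "bsw(final)=%.4f computed from coordinates", scores_f$bsw))
  }

  resolution <- metrics_i$resolution
  if (is.na(resolution)) resolution <- metrics_f$resolution
  boxplots <- NULL
  if (!is.na(resolution)) {
    nb <- nearest_by_resolution(databank, resolution, n = n_neighbours)
    scores_i$percentiles <- databank_percentiles(scores_i, nb)
    scores_f$percentiles <- databank_percentiles(scores_f, nb)
    log_lines <- c(log_lines, sprintf(
      "databank neighbourhood: %d entries around %.2f A", nrow(nb), resolution))
    box_of <- function(column, value_i, value_f) {
      if (is.null(nb[[column]])) return(NULL)
      b <- box_stats(nb[[column]])
      list(q1 = b$q1, median = b$median, q3 = b$q3,
           whisker_low = b$whisker_low, whisker_high = b$whisker_high,
           n_outliers = length(b$outliers), n = b$n,
           initial = value_i, final = value_f)
    }
    boxplots <- Filter(Negate(is.null), list(
      r_free = box_of("r_free", scores_i$r_free, scores_f$r_free),
      rama_z = box_of("rama_z", scores_i$rama_z, scores_f$rama_z),
      rotamer_z = box_of("rotamer_z", scores_i$rotamer_z, scores_f$rotamer_z)))
  } else {
    log_lines <- c(log_lines,
                   "no resolution given: databank percentiles skipped")
  }

  comparison <- build_comparison(scores_i, scores_f)
  log_lines <- c(log_lines, .decision_log_lines(comparison))

  rscc <- NULL
  if (!is.null(fits_i) && !is.null(fits_f)) {
    rscc <- rscc_change_table(fits_i, fits_f)
    log_lines <- c(log_lines, sprintf(
      "per-residue RSCC: %d residues classified, mean change %.4f",
      nrow(rscc$table), rscc$mean_change))
  } else {
    log_lines <- c(log_lines,
                   "no per-residue density-fit tables: RSCC section omitted")
  }

  changes <- diff_models(model_i, model_f)
  scripts <- write_coot_scripts(changes)
  log_lines <- c(log_lines, sprintf("%d model change(s) detected",
                                    nrow(changes)))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(comparison, file.path(outdir, "comparison.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    writeLines(comparison_html(comparison),
               file.path(outdir, "comparison.html"), sep = "")
    if (!is.null(boxplots))
      jsonlite::write_json(boxplots, file.path(outdir, "boxplots.json"),
                           auto_unbox = TRUE, digits = NA)
    if (!is.null(rscc)) {
      utils::write.table(rscc$table, file.path(outdir, "residue_rscc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(mean_change = rscc$mean_change,
                                residues = rscc$table),
                           file.path(outdir, "rscc.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA,
                           na = "null")
    }
    writeLines(scripts$scm, file.path(outdir, "changes.scm"), sep = "")
    writeLines(scripts$py, file.path(outdir, "changes.py"), sep = "")
    writeLines(paste(c(log_lines, ""), collapse = "\n"),
               file.path(outdir, "decisions.log"), sep = "")
  }

  invisible(list(comparison = comparison,
                 percentiles_i = scores_i$percentiles,
                 percentiles_f = scores_f$percentiles,
                 boxplots = boxplots, rscc = rscc, changes = changes,
                 scripts = scripts, log = log_lines))
}
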