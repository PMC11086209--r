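#' Run the full analysis pipeline on a cohort
#'
#' Convenience wrapper chaining the three stages: assemble the per-trial
#' metric table ([build_metric_table()]), correlate every metric against
#' the stress index ([correlation_report()]), and classify the binarized
#' workload targets from approximate-entropy features
#' ([build_feature_matrix()] + [classify_cohort()]).
#'
#' @param trials list of [trial_record()]s (e.g. from [generate_cohort()]
#'   or [read_cohort()]).
#' @param classifiers,schemes,grids,seed passed to [classify_cohort()].
#' @param grid_hz synchronization grid rate.
#' @return A list with `metrics` (metric table), `correlations`
#'   (correlation report), `features` (ApEn feature matrix) and `skill`
#'   (skill report).
#' @export
run_pipeline <- function(trials, classifiers = c("dt", "knn", "svm", "lr"),
                         schemes = list("loocv", 5, 10), grids = NULL,
                         seed = 7919, grid_hz = 10) {
  metrics <- build_metric_table(trials, grid_hz)
  correlations <- correlation_report(metrics)
  features <- build_feature_matrix(trials, grid_hz)
  kept <- attr(features, "trial")
  skill <- classify_cohort(features, metrics[kept, , drop = FALSE],
                           classifiers = classifiers, schemes = schemes,
                           grids = grids, seed = seed)
  list(metrics = metrics, correlations = correlations,
       features = features, skill = skill)
}
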