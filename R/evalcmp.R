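#' Score a REM decision against a manually scored hypnogram
#'
#' Compares the classifier's REM epoch set with expert stage labels.
#' Unscored epochs (`U`) are removed from both sides before any metric is
#' computed. Reported metrics follow the source field's usage:
#' `frac_rem_labels_correct` is the precision of the REM label (the
#' "specificity" of the detector), `frac_rem_identified` the recall, and
#' `minutes_rem_correct = 0.5 * TP` converts correctly identified 30 s
#' epochs to minutes.
#'
#' @param rem_epochs integer epoch indices the classifier labelled REM
#'   (or a `rem_decision`, whose `rem_epochs` field is used).
#' @param truth character vector of stage labels (`W`, `N1`, `N2`, `N3`,
#'   `REM`, `U`), one per epoch.
#' @return one-row data frame of class `performance_report`:
#'   `n_identified`, `n_true_rem`, `n_correct`, `minutes_rem_correct`,
#'   `frac_rem_labels_correct`, `frac_rem_identified`.
#' @export
score <- function(rem_epochs, truth) {
  if (inherits(rem_epochs, "rem_decision")) {
    if (is.null(rem_epochs$rem_epochs))
      stop_invalid("decision carries no epoch indices", "invalid_parameter")
    rem_epochs <- rem_epochs$rem_epochs
  }
  scored <- which(truth != "U")
  rem_epochs <- intersect(rem_epochs, scored)
  true_rem <- which(truth == "REM")
  tp <- length(intersect(rem_epochs, true_rem))
  n_id <- length(rem_epochs)
  if (n_id == 0)
    warning("no REM epochs identified among scored epochs; precision undefined")
  out <- data.frame(
    n_identified = n_id,
    n_true_rem = length(true_rem),
    n_correct = tp,
    minutes_rem_correct = 0.5 * tp,
    frac_rem_labels_correct = if (n_id > 0) tp / n_id else NA_real_,
    frac_rem_identified = if (length(true_rem) > 0)
      tp / length(true_rem) else NA_real_
  )
  class(out) <- c("performance_report", class(out))
  out
}

#' Matched-power alpha-threshold baseline detector
#'
#' The conventional competitor to the clustering classifier: a per-epoch
#' alpha-power statistic (the mean across contacts of the multitaper
#' 10 Hz estimate) thresholded so that exactly `n_match` epochs - as many
#' as the clustering classifier identified - are called REM. Low alpha
#' power means REM-like, so the `n_match` lowest-statistic epochs are
#' returned; ties are broken by epoch index.
#'
#' @param spectra per-epoch, per-contact power matrix ([spectrum_table()]).
#' @param n_match number of epochs to call REM.
#' @param aggregate `"mean"` (default) or `"median"` across contacts.
#' @return sorted integer vector of exactly `n_match` epoch indices.
#' @export
matched_alpha_detector <- function(spectra, n_match,
                                   aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (n_match < 1 || n_match > n)
    stop_invalid("n_match must lie in 1..n_epochs", "invalid_parameter")
  stat <- if (aggregate == "mean") rowMeans(spectra)
  else apply(spectra, 1, median)
  sort(order(stat, seq_len(n))[seq_len(n_match)])
}

#' Run the full classifier on a feature set
#'
#' Convenience composition used by the evaluation routines and the
#' command line: cluster-count sweep, REM-cluster identification, and
#' (when truth labels are supplied) scoring.
#'
#' @param features list of `eigen_features`.
#' @param truth optional stage labels for scoring.
#' @param k_min,k_max,seed,max_iter,variant,sum_over passed to
#'   [select_clustering()].
#' @return list with `selection` (`model_selection`), `alpha_power`,
#'   `decision` (`rem_decision`), `spectra`, and `report` (`NULL` without
#'   truth).
#' @export
classify_features <- function(features, truth = NULL, k_min = 2, k_max = 14,
                              seed = NULL, max_iter = 500,
                              variant = "standard", sum_over = "assigned") {
  sel <- select_clustering(features, k_min, k_max, seed = seed,
                           max_iter = max_iter, variant = variant,
                           sum_over = sum_over)
  labels <- sel$labelings[[as.character(sel$chosen_k)]]$labels
  spectra <- spectrum_table(features)
  pow <- cluster_alpha_power(spectra, labels, sel$chosen_k)
  dec <- select_rem_cluster(pow, labels)
  rep <- if (!is.null(truth)) score(dec, truth) else NULL
  list(selection = sel, alpha_power = pow, decision = dec,
       spectra = spectra, report = rep)
}

#' Stratified hold-out splits of a night
#'
#' Repeatedly splits the night's epochs into two disjoint parts -- REM
#' epochs, Wake epochs, and (by default) every other stage are each split
#' at random in proportion `split_fraction` and recombined -- then runs
#' the full unsupervised pipeline on each part independently and scores
#' it against that part's truth. With `split_fraction = 1` the single
#' part is the whole night, reproducing the full-data report.
#'
#' @param features list of `eigen_features` for the whole night.
#' @param truth stage labels, one per epoch.
#' @param split_fraction fraction of each stratum assigned to part A
#'   (default 0.5; part B receives the complement).
#' @param n_reps number of random splits (default 50).
#' @param seed integer seed; the whole set of repetitions is reproducible.
#' @param include_other keep non-REM, non-Wake epochs in the clustering
#'   input (default `TRUE`); they are split like the other strata. If
#'   `FALSE`, only REM and Wake epochs enter the pipeline.
#' @param k_min,k_max,max_iter,variant,sum_over passed to
#'   [classify_features()].
#' @return data frame with one row per repetition and part: `rep`, `part`,
#'   `n_epochs`, `chosen_k`, `rem_cluster`, `reliable`, and the
#'   [score()] columns. Parts that fail (too few epochs, no completed
#'   fit) are skipped with a warning.
#' @export
holdout_splits <- function(features, truth, split_fraction = 0.5,
                           n_reps = 50, seed = NULL, include_other = TRUE,
                           k_min = 2, k_max = 14, max_iter = 500,
                           variant = "standard", sum_over = "assigned") {
  stopifnot(length(features) == length(truth))
  if (split_fraction <= 0 || split_fraction > 1)
    stop_invalid("split_fraction must lie in (0, 1]", "invalid_parameter")
  pool <- if (include_other) seq_along(truth)
  else which(truth %in% c("REM", "W"))
  strata <- split(pool, truth[pool])
  with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_reps)) {
      a <- sort(unlist(lapply(strata, function(idx) {
        n_a <- round(split_fraction * length(idx))
        if (length(idx) == 1)
          return(if (runif(1) < split_fraction) idx else integer(0))
        sample(idx, n_a)
      }), use.names = FALSE))
      parts <- list(A = a, B = setdiff(pool, a))
      for (p in names(parts)) {
        idx <- parts[[p]]
        if (length(idx) == 0) next
        if (length(idx) < k_min) {
          warning(sprintf("rep %d part %s: fewer epochs than k_min; skipped",
                          r, p))
          next
        }
        res <- tryCatch(
          classify_features(features[idx], truth[idx], k_min, k_max,
                            seed = seed, max_iter = max_iter,
                            variant = variant, sum_over = sum_over),
          remalpha_error = function(e) {
            warning(sprintf("rep %d part %s failed: %s", r, p,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        rows[[length(rows) + 1]] <- cbind(
          data.frame(rep = r, part = p, n_epochs = length(idx),
                     chosen_k = res$selection$chosen_k,
                     rem_cluster = res$decision$rem_cluster,
                     reliable = res$decision$reliable),
          as.data.frame(res$report))
      }
    }
    do.call(rbind, rows)
  })
}

#' Summarise hold-out reports
#'
#' Median and interquartile range of each performance metric across
#' repetitions (the numbers behind box-plot style summaries).
#'
#' @param reports data frame from [holdout_splits()].
#' @return data frame with one row per metric.
#' @export
summarize_holdout <- function(reports) {
  metrics <- c("frac_rem_labels_correct", "frac_rem_identified",
               "minutes_rem_correct")
  do.call(rbind, lapply(metrics, function(m) {
    x <- reports[[m]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(metric = m, median = q[[2]], q25 = q[[1]], q75 = q[[3]],
               n = sum(!is.na(x)))
  }))
}
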