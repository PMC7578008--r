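#' Stimulus event set
#'
#' @param onsets event onset times, seconds, strictly increasing.
#' @param categories event labels (e.g. `"scream"`, `"aggressive_face"`),
#'   recycled to the onsets.
#' @return object of class `event_set`.
#' @export
event_set <- function(onsets, categories = "stimulus") {
  if (length(onsets) == 0L) stop("no events", call. = FALSE)
  if (any(diff(onsets) <= 0))
    stop("onsets must be strictly increasing", call. = FALSE)
  structure(list(onsets = as.numeric(onsets),
                 categories = rep_len(as.character(categories),
                                      length(onsets))),
            class = "event_set")
}

#' Read events from delimited text
#'
#' CSV with columns `onset_s,category` (header required).
#'
#' @param path CSV file path.
#' @return an [event_set].
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  event_set(df$onset_s, df$category)
}

#' Align a heart-rate series to stimulus events
#'
#' Extracts one peristimulus trace per event on a common time grid around
#' onset (0 s reference), by linear interpolation of the HR series. Events
#' whose window is not fully inside the series support are dropped with a
#' warning.
#'
#' @param hr an [hr_series] (typically the smoothed video- or ECG-derived
#'   rate).
#' @param events an [event_set].
#' @param window length-2 peristimulus window in seconds, default
#'   `c(-16, 16)`.
#' @param category restrict to one category (`NULL` = all).
#' @param dt_s grid step of the peristimulus time axis, seconds.
#' @return object of class `aligned_response`: `peri_times`, `trials`
#'   (trial x time matrix, BPM), `category`, `n_trials`, and
#'   `baseline` (the correction window once applied, else `NULL`).
#' @export
align_to_events <- function(hr, events, window = c(-16, 16),
                            category = NULL, dt_s = 0.1) {
  stopifnot(inherits(hr, "hr_series"), inherits(events, "event_set"))
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be increasing length-2", call. = FALSE)
  onsets <- events$onsets
  cats <- events$categories
  if (!is.null(category)) {
    keep <- cats == category
    onsets <- onsets[keep]; cats <- cats[keep]
  }
  lo <- min(hr$times); hi <- max(hr$times)
  usable <- onsets + window[1] >= lo & onsets + window[2] <= hi
  if (any(!usable))
    warning(sum(!usable), " event(s) dropped: window outside HR support")
  onsets <- onsets[usable]
  if (length(onsets) == 0L)
    stop("no usable events within the HR series support", call. = FALSE)
  peri <- seq(window[1], window[2], by = dt_s)
  trials <- t(vapply(onsets, function(on) {
    stats::approx(hr$times, hr$bpm, xout = on + peri, rule = 1)$y
  }, numeric(length(peri))))
  structure(list(peri_times = peri, trials = trials,
                 category = if (is.null(category)) "all" else category,
                 n_trials = length(onsets), onsets = onsets,
                 baseline = NULL),
            class = "aligned_response")
}

#' Baseline-correct peristimulus traces
#'
#' Subtracts each trial's mean over the baseline window, so every trial's
#' baseline mean is exactly zero afterwards. Idempotent.
#'
#' @param resp an [align_to_events()] result.
#' @param baseline length-2 window in peristimulus seconds, default
#'   `c(-13, -3)`.
#' @return the corrected `aligned_response`.
#' @export
baseline_correct <- function(resp, baseline = c(-13, -3)) {
  stopifnot(inherits(resp, "aligned_response"))
  sel <- resp$peri_times >= baseline[1] & resp$peri_times <= baseline[2]
  if (!any(sel))
    stop("baseline window does not overlap the peristimulus grid",
         call. = FALSE)
  if (is.null(resp$trials_raw)) resp$trials_raw <- resp$trials
  bl <- rowMeans(resp$trials_raw[, sel, drop = FALSE])
  resp$trials <- resp$trials_raw - bl
  resp$baseline <- baseline
  resp
}

#' Mean and standard-error traces across trials
#'
#' @param resp an `aligned_response` with at least 2 trials.
#' @return list with `peri_times`, `mean` and `se` (sd / sqrt(n)) vectors,
#'   and `n_trials`.
#' @export
summarize_response <- function(resp) {
  stopifnot(inherits(resp, "aligned_response"))
  if (resp$n_trials < 2L) stop("need >= 2 trials", call. = FALSE)
  m <- colMeans(resp$trials)
  s <- apply(resp$trials, 2, stats::sd) / sqrt(resp$n_trials)
  list(peri_times = resp$peri_times, mean = m, se = s,
       n_trials = resp$n_trials)
}

#' Pre/post stimulus comparison (Wilcoxon + effect size)
#'
#' Per-trial means over the pre- and post-stimulus windows are compared
#' with a Wilcoxon test — rank-sum (Mann–Whitney) by default, with a
#' paired signed-rank option since trials are naturally paired. Cohen's d
#' is the post-minus-pre mean difference divided by `run_sd`, the global
#' standard deviation of the heart rate during the run.
#'
#' Window means are always taken from the uncorrected traces: the default
#' baseline window coincides with the pre-stimulus window, so per-trial
#' baseline correction would make every pre mean exactly zero and
#' degenerate the rank statistic (inflating the false-positive rate). The
#' paired signed-rank variant is invariant to this choice, since a
#' per-trial constant cancels in post minus pre.
#'
#' @param resp an `aligned_response` (typically baseline-corrected).
#' @param pre,post length-2 windows in peristimulus seconds; defaults
#'   `c(-13, -3)` and `c(3, 13)`.
#' @param run_sd global run standard deviation for the effect size; when
#'   `NULL`, the pooled s.d. of the per-trial pre/post means is used as a
#'   fallback.
#' @param paired use the paired signed-rank variant?
#' @return list with `p_value`, `effect_d`, `effect_label` (small /
#'   medium / large per the 0.2 / 0.5 / 0.8 convention), `pre_means`,
#'   `post_means`, `n_trials`.
#' @export
pre_post_test <- function(resp, pre = c(-13, -3), post = c(3, 13),
                          run_sd = NULL, paired = FALSE) {
  stopifnot(inherits(resp, "aligned_response"))
  pt <- resp$peri_times
  isel <- pt >= pre[1] & pt <= pre[2]
  jsel <- pt >= post[1] & pt <= post[2]
  if (!any(isel) || !any(jsel))
    stop("pre/post windows do not overlap the peristimulus grid",
         call. = FALSE)
  trials <- if (!is.null(resp$trials_raw)) resp$trials_raw else resp$trials
  pre_means <- rowMeans(trials[, isel, drop = FALSE])
  post_means <- rowMeans(trials[, jsel, drop = FALSE])
  wt <- suppressWarnings(
    stats::wilcox.test(post_means, pre_means, paired = paired,
                       exact = FALSE))
  if (is.na(wt$p.value)) wt$p.value <- 1   # fully tied data: no evidence
  if (is.null(run_sd))
    run_sd <- stats::sd(c(pre_means, post_means))
  d <- cohens_d(pre_means, post_means, run_sd)
  list(p_value = wt$p.value, effect_d = d,
       effect_label = effect_label(d),
       pre_means = pre_means, post_means = post_means,
       n_trials = resp$n_trials)
}

#' Cohen's d against run variability
#'
#' `(mean(post) - mean(pre)) / run_sd`: the mean heart-rate difference
#' before vs after the stimulus, divided by the global standard deviation
#' of the rate during the run. Conventional interpretation thresholds:
#' 0.2 small, 0.5 medium, 0.8 large.
#'
#' @param pre_means,post_means per-trial window means, BPM.
#' @param run_sd global run standard deviation, BPM (> 0).
#' @return scalar effect size.
#' @export
cohens_d <- function(pre_means, post_means, run_sd) {
  if (!is.numeric(run_sd) || length(run_sd) != 1L || run_sd <= 0)
    stop("run_sd must be a single value > 0", call. = FALSE)
  (mean(post_means) - mean(pre_means)) / run_sd
}

effect_label <- function(d) {
  ad <- abs(d)
  if (ad >= 0.8) "large" else if (ad >= 0.5) "medium"
  else if (ad >= 0.2) "small" else "negligible"
}
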