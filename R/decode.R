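# Score-based decoding of visual scenes and participant identity from SSVEP
# waveforms.
#
# The core comparison: for each scene, a baseline Pearson correlation between
# the SSVEPs of two trials at that scene is compared against the correlation
# between the test trial's SSVEP and each other scene's baseline SSVEP; a
# point is scored when the baseline correlation is strictly higher. With 6
# scenes each electrode receives a score out of 5 per scene, 30 in total.
# Ties and undefined (zero-variance) correlations never score a point.

safe_cor_matrix <- function(a, b) {
  # cor(a[, i], b[, j]) with NA for zero-variance columns, no warnings
  sda <- apply(a, 2, stats::sd)
  sdb <- apply(b, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(a, b))
  cc[sda == 0, ] <- NA_real_
  cc[, sdb == 0] <- NA_real_
  cc
}

as_waveform_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(colnames(x))) stop("waveform matrix needs column names", call. = FALSE)
    return(x)
  }
  if (is.list(x)) {
    wf <- lapply(x, function(s) if (inherits(s, "ssvep")) s$waveform else as.numeric(s))
    return(do.call(cbind, wf))
  }
  stop("expected a samples-x-conditions matrix or a named list of SSVEPs",
       call. = FALSE)
}

new_score_table <- function(df, mode) {
  structure(df, class = c("score_table", class(df)), mode = mode)
}

#' Decoding accuracy of a score table, in percent
#'
#' @param x A `score_table`.
#' @return `100 * correct / (correct + incorrect)`.
#' @export
accuracy <- function(x) {
  stopifnot(inherits(x, "score_table"))
  100 * mean(x$correct)
}

#' Per-condition scores of a score table
#'
#' @param x A `score_table`.
#' @return A tibble with one row per condition: points scored and the number
#'   of comparisons (e.g. a score out of 5 per scene with 6 scenes).
#' @export
score_per_condition <- function(x) {
  stopifnot(inherits(x, "score_table"))
  agg <- stats::aggregate(correct ~ condition, data = as.data.frame(x),
                          FUN = function(v) c(score = sum(v), out_of = length(v)))
  tibble::tibble(
    condition = agg$condition,
    score = agg$correct[, "score"],
    out_of = agg$correct[, "out_of"]
  )
}

#' Correlation (waveform-shape) decoding of one trial pair
#'
#' For each scene L, the baseline correlation `r(t1[L], t2[L])` is compared
#' with the test correlations `r(t1[M], t2[L])` for every other scene M; a
#' point is awarded when the baseline correlation is strictly higher.
#' Pearson correlation makes the decision depend only on waveform shape:
#' scaling or offsetting any SSVEP leaves the outcome unchanged.
#'
#' @param ssveps_t1,ssveps_t2 Baseline- and test-trial SSVEPs: matrices
#'   (samples x scenes, same scene column names) or named lists of `ssvep`
#'   objects. Same electrode and flicker frequency in both.
#' @return A `score_table` with one row per ordered (scene, other-scene)
#'   comparison: `condition`, `comparison`, `metric_base`, `metric_test`,
#'   `correct`, `degenerate` (correlation undefined on a constant waveform;
#'   counted incorrect).
#' @export
correlation_decode <- function(ssveps_t1, ssveps_t2) {
  t1 <- as_waveform_matrix(ssveps_t1)
  t2 <- as_waveform_matrix(ssveps_t2)
  scenes <- colnames(t1)
  if (!identical(scenes, colnames(t2))) {
    stop("trial collections must cover the same scenes in the same order",
         call. = FALSE)
  }
  if (nrow(t1) != nrow(t2)) stop("SSVEP lengths differ between trials", call. = FALSE)
  cc <- safe_cor_matrix(t1, t2)
  grid <- expand.grid(comparison = scenes, condition = scenes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$comparison != grid$condition, ]
  r_base <- cc[cbind(grid$condition, grid$condition)]
  r_test <- cc[cbind(grid$comparison, grid$condition)]
  correct <- r_base > r_test
  correct[is.na(correct)] <- FALSE
  new_score_table(tibble::tibble(
    condition = grid$condition, comparison = grid$comparison,
    metric_base = r_base, metric_test = r_test,
    correct = correct,
    degenerate = is.na(r_base) | is.na(r_test)
  ), mode = "correlation")
}

# Shared scalar machinery: amplitude decoding and alpha-power decoding both
# award a point when the within-scene absolute difference is strictly
# smaller than the cross-scene difference.
scalar_distance_decode <- function(v1, v2, mode) {
  stopifnot(identical(names(v1), names(v2)), !is.null(names(v1)))
  scenes <- names(v1)
  grid <- expand.grid(comparison = scenes, condition = scenes,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$comparison != grid$condition, ]
  d_base <- abs(v1[grid$condition] - v2[grid$condition])
  d_test <- abs(v1[grid$comparison] - v2[grid$condition])
  correct <- d_base < d_test
  correct[is.na(correct)] <- FALSE
  new_score_table(tibble::tibble(
    condition = grid$condition, comparison = grid$comparison,
    metric_base = unname(d_base), metric_test = unname(d_test),
    correct = unname(correct),
    degenerate = is.na(d_base) | is.na(d_test)
  ), mode = mode)
}

#' Peak-to-peak amplitude decoding of one trial pair
#'
#' Same scoring as [correlation_decode()] but on the scalar peak-to-peak
#' amplitude: a point is awarded when the within-scene amplitude difference
#' is strictly smaller than the cross-scene difference. The contrast between
#' this decoder and correlation decoding quantifies how much information
#' lives in waveform shape beyond amplitude.
#'
#' @param ssveps_t1,ssveps_t2 Matrices / lists of SSVEPs (as in
#'   [correlation_decode()]) or named numeric vectors of peak-to-peak
#'   amplitudes.
#' @return A `score_table` (see [correlation_decode()]).
#' @export
amplitude_decode <- function(ssveps_t1, ssveps_t2) {
  to_ptp <- function(x) {
    if (is.numeric(x) && !is.matrix(x) && !is.null(names(x))) return(x)
    m <- as_waveform_matrix(x)
    apply(m, 2, peak_to_peak)
  }
  scalar_distance_decode(to_ptp(ssveps_t1), to_ptp(ssveps_t2), "amplitude")
}

#' Decoding from endogenous alpha power in the pre-flicker baseline
#'
#' Applies the amplitude scoring rule to the per-scene peak alpha amplitudes
#' of the two trials (from [baseline_alpha()]): a scene decodes correctly
#' when its alpha peak is more similar across trials than to any other
#' scene's.
#'
#' @param peaks_t1,peaks_t2 Named numeric vectors of peak alpha amplitudes
#'   per scene.
#' @return A `score_table`.
#' @export
alpha_power_decode <- function(peaks_t1, peaks_t2) {
  st <- scalar_distance_decode(peaks_t1, peaks_t2, "alpha_power")
  st
}

#' Participant-identity decoding (winner-take-all)
#'
#' For one scene and electrode, a participant's trial-2 SSVEP is decoded
#' correctly when its correlation with that participant's own trial-1 SSVEP
#' strictly exceeds its correlation with every other participant's trial-1
#' SSVEP. Chance level is `100 / n_participants` percent (5% for 20
#' participants).
#'
#' @param ssveps_t1,ssveps_t2 Matrices (samples x participants, same
#'   participant column names) or named lists of SSVEPs, all from the same
#'   scene and electrode.
#' @return A `score_table` with one row per participant (`condition`), with
#'   `metric_base` the self-correlation and `metric_test` the best rival
#'   correlation. Ties for the maximum are counted incorrect.
#' @export
identity_decode <- function(ssveps_t1, ssveps_t2) {
  t1 <- as_waveform_matrix(ssveps_t1)
  t2 <- as_waveform_matrix(ssveps_t2)
  ids <- colnames(t1)
  if (length(ids) < 2) stop("identity decoding needs >= 2 participants", call. = FALSE)
  if (!identical(ids, colnames(t2))) {
    stop("participant sets differ between trials", call. = FALSE)
  }
  cc <- safe_cor_matrix(t1, t2)
  r_self <- diag(cc)
  rivals <- cc
  diag(rivals) <- NA_real_
  best_rival <- suppressWarnings(apply(rivals, 2, max, na.rm = TRUE))
  best_rival[!is.finite(best_rival)] <- NA_real_ # all rivals undefined
  correct <- r_self > best_rival
  correct[is.na(correct)] <- FALSE
  new_score_table(tibble::tibble(
    condition = ids, comparison = "best_rival",
    metric_base = unname(r_self), metric_test = unname(best_rival),
    correct = unname(correct),
    degenerate = is.na(r_self) | is.na(best_rival)
  ), mode = "identity")
}
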