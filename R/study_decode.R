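# Study-level decoding: build SSVEPs for every (participant, session, trial,
# electrode), pair trials within or between sessions, run a decoder over all
# pairs, and aggregate to per-participant, per-electrode accuracies.

flicker_metadata <- function(study) {
  study$metadata[study$metadata$kind == "flicker", , drop = FALSE]
}

# Segment (and optionally filter / artifact-reject) every flicker recording.
# Returned list is keyed by recording index as character.
flicker_segments <- function(study, band = NULL, notch = FALSE, reject = FALSE) {
  md <- flicker_metadata(study)
  segs <- list()
  for (i in seq_len(nrow(md))) {
    rec <- study$recordings[[md$idx[i]]]
    if (notch) rec <- notch_filter(rec)
    if (!is.null(band)) rec <- bandpass_filter(rec, band[1], band[2])
    seg <- segment_recording(rec)
    if (reject) seg <- reject_artifacts(seg)
    segs[[as.character(md$idx[i])]] <- seg
  }
  segs
}

feat_key <- function(p, se, tr) paste(p, se, tr, sep = "/")

# SSVEP matrices per (participant, session, trial, electrode):
# feats[[key]][[electrode]] is a samples x scenes matrix.
ssvep_feature_tables <- function(segments, md, electrodes, scenes,
                                 max_duration = NULL) {
  feats <- list()
  for (i in seq_len(nrow(md))) {
    seg <- segments[[as.character(md$idx[i])]]
    key <- feat_key(md$participant[i], md$session[i], md$trial[i])
    for (el in electrodes) {
      wf <- average_segments(seg, el, max_duration)$waveform
      feats[[key]][[el]] <- cbind(feats[[key]][[el]],
                                  matrix(wf, ncol = 1,
                                         dimnames = list(NULL, md$scene[i])))
    }
  }
  # fix scene column order
  for (key in names(feats)) {
    for (el in names(feats[[key]])) {
      feats[[key]][[el]] <- feats[[key]][[el]][, scenes, drop = FALSE]
    }
  }
  feats
}

# Peak alpha amplitude per (participant, session, trial, electrode, scene)
# from the pre-flicker baseline of each unfiltered recording.
alpha_feature_tables <- function(study, electrodes, scenes) {
  md <- flicker_metadata(study)
  feats <- list()
  for (i in seq_len(nrow(md))) {
    rec <- study$recordings[[md$idx[i]]]
    key <- feat_key(md$participant[i], md$session[i], md$trial[i])
    for (el in electrodes) {
      pk <- baseline_alpha(rec, el)$peak_amp
      v <- feats[[key]][[el]] %||% stats::setNames(rep(NA_real_, length(scenes)), scenes)
      v[md$scene[i]] <- pk
      feats[[key]][[el]] <- v
    }
  }
  feats
}

# Ordered (baseline, test) trial pairs for a pairing scheme. Each element is
# list(base = c(session, trial), test = c(session, trial)).
trial_pairs <- function(n_sessions, trials_per_scene,
                        pairing = c("within_session", "between_session"),
                        pool_orderings = FALSE) {
  pairing <- match.arg(pairing)
  pairs <- list()
  if (pairing == "within_session") {
    for (se in seq_len(n_sessions)) {
      if (trials_per_scene < 2) {
        stop("within-session pairing needs >= 2 trials per scene", call. = FALSE)
      }
      for (a in seq_len(trials_per_scene)) {
        for (b in seq_len(trials_per_scene)) {
          if (a == b) next
          if (!pool_orderings && a > b) next
          pairs[[length(pairs) + 1]] <- list(base = c(se, a), test = c(se, b))
        }
      }
    }
  } else {
    if (n_sessions < 2) {
      stop("between-session pairing needs >= 2 sessions", call. = FALSE)
    }
    for (sa in seq_len(n_sessions - 1)) {
      for (sb in (sa + 1):n_sessions) {
        for (tr in seq_len(trials_per_scene)) {
          pairs[[length(pairs) + 1]] <- list(base = c(sa, tr), test = c(sb, tr))
          if (pool_orderings) {
            pairs[[length(pairs) + 1]] <- list(base = c(sb, tr), test = c(sa, tr))
          }
        }
      }
    }
  }
  pairs
}

#' Run a decoder over a whole synthetic or recorded study
#'
#' Builds one SSVEP per (participant, session, trial, scene, electrode),
#' pairs trials within or between sessions, runs the chosen decoder over all
#' pairs and aggregates the points to a per-participant, per-electrode
#' accuracy. Accuracies are then typically averaged across electrodes and
#' participants; [summarize_decoding()] does both.
#'
#' @param study An [make_study()] result (or any object with the same
#'   structure wrapping recorded data).
#' @param mode `"correlation"` (waveform shape), `"amplitude"` (peak-to-peak)
#'   or `"alpha_power"` (pre-flicker alpha peak).
#' @param pairing `"within_session"` (trial pairs from the same day) or
#'   `"between_session"` (corresponding trials across days).
#' @param electrodes Channels to decode from; default all EEG channels.
#' @param max_duration Use only the first `max_duration` seconds of flicker
#'   when averaging SSVEPs (both baseline and test trials).
#' @param band `c(center, half_width)` in Hz: band-pass the continuous data
#'   before segmentation.
#' @param notch Apply the 50 Hz notch before segmentation.
#' @param reject Apply EOG/accelerometer artifact rejection before averaging.
#'   Default `FALSE`: the main analysis uses no pre-processing; rejection is
#'   an explicit robustness comparison.
#' @param pool_orderings If `TRUE`, use both orderings of each trial pair
#'   (two comparison rounds per pair). Default `FALSE`: the earlier trial is
#'   the baseline and the later the test, giving the canonical score out of
#'   `n_scenes - 1` per scene (out of 5 with 6 scenes, 30 in total).
#' @param segments Pre-computed [flicker_segments()] output to reuse across
#'   sweep steps (internal optimisation).
#' @return A tibble with one row per (participant, electrode): `n_correct`,
#'   `n_total`, `accuracy` in percent, plus the decode settings.
#' @export
decode_study <- function(study,
                         mode = c("correlation", "amplitude", "alpha_power"),
                         pairing = c("within_session", "between_session"),
                         electrodes = NULL, max_duration = NULL, band = NULL,
                         notch = FALSE, reject = FALSE, pool_orderings = FALSE,
                         segments = NULL) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  cfg <- study$config
  md <- flicker_metadata(study)
  electrodes <- electrodes %||%
    channels_with_role(study$recordings[[md$idx[1]]], "EEG")
  scenes <- sort(unique(md$scene))

  if (mode == "alpha_power") {
    feats <- alpha_feature_tables(study, electrodes, scenes)
  } else {
    if (is.null(segments)) {
      segments <- flicker_segments(study, band = band, notch = notch,
                                   reject = reject)
    }
    feats <- ssvep_feature_tables(segments, md, electrodes, scenes, max_duration)
  }
  pairs <- trial_pairs(cfg$n_sessions, cfg$trials_per_scene, pairing,
                       pool_orderings)

  participants <- unique(md$participant)
  rows <- list()
  for (p in participants) {
    for (el in electrodes) {
      n_correct <- 0L
      n_total <- 0L
      for (pr in pairs) {
        f1 <- feats[[feat_key(p, pr$base[1], pr$base[2])]][[el]]
        f2 <- feats[[feat_key(p, pr$test[1], pr$test[2])]][[el]]
        st <- switch(mode,
          correlation = correlation_decode(f1, f2),
          amplitude = amplitude_decode(f1, f2),
          alpha_power = alpha_power_decode(f1, f2)
        )
        n_correct <- n_correct + sum(st$correct)
        n_total <- n_total + nrow(st)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = p, electrode = el, pairing = pairing, mode = mode,
        n_correct = n_correct, n_total = n_total,
        accuracy = 100 * n_correct / n_total
      )
    }
  }
  do.call(rbind, rows)
}

#' Group-level summary of decoding accuracies
#'
#' Averages per-participant, per-electrode accuracies across electrodes to
#' one score per participant, then reports the group mean and median.
#'
#' @param res A [decode_study()] result.
#' @param by Optional grouping columns kept in the summary (e.g.
#'   `"electrode"` for per-electrode group scores, or a sweep column).
#' @return A tibble with `mean_accuracy`, `median_accuracy` and `n`.
#' @export
summarize_decoding <- function(res, by = NULL) {
  df <- as.data.frame(res)
  if (is.null(by)) {
    per_part <- stats::aggregate(accuracy ~ participant, df, mean)
    return(tibble::tibble(
      mean_accuracy = mean(per_part$accuracy),
      median_accuracy = stats::median(per_part$accuracy),
      n = nrow(per_part)
    ))
  }
  form <- stats::as.formula(paste("accuracy ~ participant +",
                                  paste(by, collapse = "+")))
  per_part <- stats::aggregate(form, df, mean)
  agg <- stats::aggregate(
    stats::as.formula(paste("accuracy ~", paste(by, collapse = "+"))),
    per_part,
    function(v) c(mean = mean(v), median = stats::median(v), n = length(v))
  )
  out <- agg[, by, drop = FALSE]
  out$mean_accuracy <- agg$accuracy[, "mean"]
  out$median_accuracy <- agg$accuracy[, "median"]
  out$n <- agg$accuracy[, "n"]
  tibble::as_tibble(out)
}

#' Decoding accuracy as a function of the amount of flicker data
#'
#' Re-averages both the baseline and the test SSVEPs from truncated data and
#' re-runs the decoder for each duration. Durations shorter than one flicker
#' period are skipped with a warning. Segmentation is done once and reused.
#'
#' @param study A study object.
#' @param durations Seconds of flicker data to use, e.g.
#'   `c(30, 25, 20, 15, 10, 5, 4, 3, 2, 1, 0.9, ..., 0.1)`.
#' @param band,notch,reject Preprocessing applied once before the sweep, as
#'   in [decode_study()].
#' @param ... Passed to [decode_study()] (mode, pairing, electrodes, ...).
#' @return A tibble of [decode_study()] rows with a `duration` column.
#' @export
duration_sweep <- function(study, durations, band = NULL, notch = FALSE,
                           reject = FALSE, ...) {
  cfg <- study$config
  period <- 1 / cfg$flicker_freq
  segments <- flicker_segments(study, band = band, notch = notch,
                               reject = reject)
  out <- list()
  for (d in durations) {
    if (d < period) {
      warning(sprintf("duration %.3g s is below one flicker period; skipped", d))
      next
    }
    res <- decode_study(study, segments = segments, max_duration = d, ...)
    res$duration <- d
    out[[length(out) + 1]] <- res
  }
  do.call(rbind, out)
}

#' Decoding accuracy after band-pass filtering at each flicker harmonic
#'
#' Applies [bandpass_filter()] to the continuous data before segmentation,
#' then re-runs the decoder, for each centre frequency; the unfiltered
#' accuracy is included as a reference (`center = NA`). Invalid bands (edge
#' at or beyond Nyquist, or non-positive lower edge) are skipped with a
#' warning.
#'
#' @param study A study object.
#' @param centers Band centre frequencies in Hz, e.g. `seq(10, 240, by = 10)`.
#' @param half_width Band half-width in Hz: 1 for the narrow +/-1 Hz harmonic
#'   bands, 5 for the wide 10 Hz bands used with 1 Hz flicker.
#' @param ... Passed to [decode_study()].
#' @return A tibble of [decode_study()] rows with a `center` column.
#' @export
band_sweep <- function(study, centers, half_width = 1, ...) {
  fs <- study$config$fs
  ref <- decode_study(study, ...)
  ref$center <- NA_real_
  out <- list(ref)
  for (ctr in centers) {
    if (ctr - half_width <= 0 || ctr + half_width >= fs / 2) {
      warning(sprintf("band %g +/- %g Hz invalid at fs = %g Hz; skipped",
                      ctr, half_width, fs))
      next
    }
    res <- decode_study(study, band = c(ctr, half_width), ...)
    res$center <- ctr
    out[[length(out) + 1]] <- res
  }
  do.call(rbind, out)
}

#' Participant-identity decoding across a study
#'
#' For each scene and electrode, collects every participant's SSVEP from two
#' trials and runs the winner-take-all [identity_decode()]: trial-2 SSVEPs
#' are matched against all participants' trial-1 SSVEPs.
#'
#' @param study A study object with >= 2 participants.
#' @param electrodes Channels to decode from; default all EEG channels.
#' @param session Session whose trial pair is used (default 1).
#' @param trials Baseline and test trial indices (default `c(1, 2)`).
#' @param max_duration Optional truncation as in [decode_study()].
#' @return A tibble with one row per (scene, electrode): accuracy in percent
#'   and the chance level `100 / n_participants`.
#' @export
identity_decode_study <- function(study, electrodes = NULL, session = 1,
                                  trials = c(1, 2), max_duration = NULL) {
  md <- flicker_metadata(study)
  electrodes <- electrodes %||%
    channels_with_role(study$recordings[[md$idx[1]]], "EEG")
  scenes <- sort(unique(md$scene))
  participants <- unique(md$participant)
  if (length(participants) < 2) {
    stop("identity decoding needs >= 2 participants", call. = FALSE)
  }
  segments <- flicker_segments(study)
  feats <- ssvep_feature_tables(segments, md, electrodes, scenes, max_duration)
  rows <- list()
  for (sc in scenes) {
    for (el in electrodes) {
      t1 <- sapply(participants,
                   function(p) feats[[feat_key(p, session, trials[1])]][[el]][, sc])
      t2 <- sapply(participants,
                   function(p) feats[[feat_key(p, session, trials[2])]][[el]][, sc])
      st <- identity_decode(t1, t2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        scene = sc, electrode = el,
        n_correct = sum(st$correct), n_total = nrow(st),
        accuracy = accuracy(st),
        chance = 100 / length(participants)
      )
    }
  }
  do.call(rbind, rows)
}

#' Individual alpha frequency per participant and session
#'
#' Applies [estimate_iaf()] to every eyes-closed recording in a study.
#'
#' @param study A study object.
#' @return A tibble (participant, session, iaf_hz, true_alpha_hz when the
#'   study is synthetic).
#' @export
iaf_table <- function(study) {
  md <- study$metadata[study$metadata$kind == "eyes_closed", , drop = FALSE]
  rows <- lapply(seq_len(nrow(md)), function(i) {
    rec <- study$recordings[[md$idx[i]]]
    tibble::tibble(
      participant = md$participant[i], session = md$session[i],
      iaf_hz = estimate_iaf(rec),
      true_alpha_hz = study$noise[[md$participant[i]]]$alpha_freq %||% NA_real_
    )
  })
  do.call(rbind, rows)
}
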