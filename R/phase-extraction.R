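#' Valve-event frame set
#'
#' Validating constructor for the three event frames used by single-phase
#' quantitation: the frame just before mitral valve opening (LV end systole),
#' the frame immediately prior to atrial contraction, and the frame at mitral
#' valve closure (LV end diastole). Frames are 0-based and must be strictly
#' increasing within the cycle.
#'
#' @param mv_open,ac_onset,mv_close Frame indices (0-based).
#' @param n_frames Number of frames in the cycle.
#' @return Named list of class `la_events`.
#' @export
event_frames <- function(mv_open, ac_onset, mv_close, n_frames) {
  f <- c(mv_open = mv_open, ac_onset = ac_onset, mv_close = mv_close)
  if (any(f != round(f)) || any(f < 0) || any(f >= n_frames)) {
    abort_validation("event frames must be integers in [0, n_frames)")
  }
  if (!(mv_open < ac_onset && ac_onset < mv_close)) {
    abort_validation("event frames must satisfy mv_open < ac_onset < mv_close")
  }
  structure(list(mv_open = as.integer(mv_open), ac_onset = as.integer(ac_onset),
                 mv_close = as.integer(mv_close)),
            class = "la_events")
}

frame_volume <- function(curve, frame) curve$volumes[frame + 1L]

#' Single-phase phasic volumes from valve-event frames
#'
#' Reads the phasic volume triple directly at the reviewed valve-event
#' frames: `lav_max` just before mitral valve opening, `lav_ac` immediately
#' prior to atrial contraction, `lav_min` at mitral valve closure. Under
#' heavy measurement noise the triple read this way can violate the phasic
#' ordering; such records are returned flagged (with a warning) so the
#' caller can exclude and count them rather than silently propagate them.
#'
#' @param curve An `la_curve`.
#' @param events An `la_events` set (defaults to the curve's own
#'   `event_frames`).
#' @return A list of class `la_phasic_record`: `patient_id`, `lav_max`,
#'   `lav_ac`, `lav_min`, `method`, `flag` (`NA` when clean,
#'   `"ordering_violation"` otherwise).
#' @export
extract_single_phase <- function(curve, events = NULL) {
  if (!inherits(curve, "la_curve")) abort_validation("'curve' must be an la_curve")
  ev <- events %||% curve$event_frames
  if (is.null(ev)) abort_validation("no event frames supplied or stored on the curve")
  f <- c(ev$mv_open, ev$ac_onset, ev$mv_close)
  if (length(f) != 3L || any(f != round(f)) || any(f < 0) || any(f >= curve$n_frames)) {
    abort_validation("event frames must be integers in [0, n_frames)")
  }
  lav_max <- frame_volume(curve, ev$mv_open)
  lav_ac <- frame_volume(curve, ev$ac_onset)
  lav_min <- frame_volume(curve, ev$mv_close)
  flag <- NA_character_
  if (!(lav_min <= lav_ac && lav_ac <= lav_max)) {
    flag <- "ordering_violation"
    warning(sprintf("patient %s: single-phase triple violates phasic ordering; flagged",
                    curve$patient_id), call. = FALSE)
  }
  structure(
    list(patient_id = curve$patient_id, lav_max = lav_max, lav_ac = lav_ac,
         lav_min = lav_min, method = "single_phase", flag = flag),
    class = "la_phasic_record"
  )
}

# Locate the atrial-contraction landmark on a curve. Returns the frame of
# steepest negative slope in the final diastolic third (onset) and the last
# local maximum of late diastole at or before it (ac_frame, the
# pre-contractile peak whose volume is lav_ac). With smoothing enabled the
# whole search runs on the smoothed curve; window 1 (the noiseless default)
# makes it exact on generated curves.
locate_ac <- function(curve, smooth_frames = 1L) {
  n <- curve$n_frames
  t <- curve$times
  rr <- curve$rr_interval
  vs <- moving_average_cyclic(curve$volumes, smooth_frames)
  v <- vs

  late3 <- which(t >= (2 / 3) * rr) - 1L            # 0-based, final third
  late3 <- late3[late3 <= n - 2L]                   # forward differences only
  slopes <- (vs[late3 + 2L] - vs[late3 + 1L]) / (t[late3 + 2L] - t[late3 + 1L])

  is_local_max <- function(i) {                     # i is 0-based, raw curve
    i >= 1L && i <= n - 2L && v[i + 1L] >= v[i] && v[i + 1L] > v[i + 2L]
  }
  last_local_max_before <- function(upper, lower) {
    cand <- seq.int(upper, lower)
    for (i in cand) if (is_local_max(i)) return(i)
    NA_integer_
  }
  late_start <- min(which(t >= 0.5 * rr)) - 1L      # late-diastolic region

  if (length(slopes) && any(slopes < 0)) {
    onset <- late3[which.min(slopes)]               # earliest on exact ties
    ac_frame <- if (onset >= late_start) {
      last_local_max_before(onset, late_start)
    } else {
      NA_integer_
    }
    if (is.na(ac_frame)) {
      return(list(onset = onset, ac_frame = NA_integer_, flag = "no_atrial_kick"))
    }
    return(list(onset = onset, ac_frame = ac_frame, flag = NA_character_))
  }

  # Fallback: no negative slope in late diastole. Use the last local maximum
  # before the global minimum; if none exists the morphology has no
  # resolvable atrial kick.
  gmin <- which.min(vs) - 1L
  if (gmin >= 1L) {
    ac_frame <- last_local_max_before(gmin - 1L, 0L)
    if (!is.na(ac_frame)) {
      return(list(onset = NA_integer_, ac_frame = ac_frame, flag = "onset_fallback"))
    }
  }
  list(onset = NA_integer_, ac_frame = NA_integer_, flag = "no_atrial_kick")
}

#' Detect the atrial-contraction onset on a time-volume curve
#'
#' Returns the 0-based frame of steepest negative volume slope within the
#' final diastolic third of the cycle — the start of the contractile
#' emptying. If late diastole holds no negative slope the function falls
#' back to the last local maximum before the global minimum; if that also
#' fails it returns `NA` with a `flag` attribute.
#'
#' @param curve An `la_curve`, non-flat.
#' @param smooth_frames Odd window for cyclic moving-average smoothing of the
#'   slope estimate; 1 (default) disables smoothing. Use 3 for noisy data.
#' @return Integer frame index (0-based), possibly `NA`; attribute `flag`
#'   carries `"onset_fallback"` or `"no_atrial_kick"` when applicable.
#' @export
detect_ac_onset <- function(curve, smooth_frames = 1L) {
  if (!inherits(curve, "la_curve")) abort_validation("'curve' must be an la_curve")
  loc <- locate_ac(curve, smooth_frames)
  out <- if (is.na(loc$onset)) loc$ac_frame else loc$onset
  attr(out, "flag") <- loc$flag
  out
}

#' Multi-phase phasic volumes from time-volume curve landmarks
#'
#' Extracts the triple from the curve alone, with no knowledge of the
#' valve-event frames: `lav_max` is the maximum during ventricular systole
#' (first half of the RR interval), `lav_min` the minimum over the
#' end-diastolic window (final 15% of RR plus frame 0, cyclic), and `lav_ac`
#' the volume at the pre-contractile peak located by [detect_ac_onset()].
#' Ties are broken toward the earliest frame.
#'
#' Flat curves (range below `flat_tol` times the mean volume) have no
#' identifiable phases; a degenerate `(V, V, V)` triple is returned with a
#' `"flat"` flag. Curves without a resolvable atrial kick collapse `lav_ac`
#' to `lav_min` (`"no_atrial_kick"` flag): with no pre-contractile peak
#' there is no booster contribution to attribute.
#'
#' @param curve An `la_curve`.
#' @param smooth_frames Odd smoothing window for noisy curves (1 = off, the
#'   default; 3 recommended for noisy input). Smoothing steers the landmark
#'   search only — extracted volumes are always read off the raw curve at
#'   the located frames. This suppresses the extreme-value bias of taking a
#'   maximum over raw noisy frames without flattening the measurement.
#' @param flat_tol Relative flatness tolerance: the curve is declared flat
#'   when `max - min < flat_tol * mean`. Default 0.05.
#' @return An `la_phasic_record` (see [extract_single_phase()]); `flag` is
#'   `NA`, `"flat"`, `"no_atrial_kick"`, `"onset_fallback"` or
#'   `"ordering_violation"`.
#' @export
extract_multi_phase <- function(curve, smooth_frames = 1L, flat_tol = 0.05) {
  if (!inherits(curve, "la_curve")) abort_validation("'curve' must be an la_curve")
  if (curve$n_frames < 20L) abort_validation("curve must have at least 20 frames")
  v <- curve$volumes
  vs <- moving_average_cyclic(v, smooth_frames)
  t <- curve$times
  rr <- curve$rr_interval
  rec <- function(vmax, vac, vmin, flag) {
    structure(
      list(patient_id = curve$patient_id, lav_max = vmax, lav_ac = vac,
           lav_min = vmin, method = "multi_phase", flag = flag),
      class = "la_phasic_record"
    )
  }

  if (max(v) - min(v) < flat_tol * mean(v)) {
    vbar <- mean(v)
    return(rec(vbar, vbar, vbar, "flat"))
  }

  # Landmarks are located on the (optionally smoothed) curve; volumes are
  # read off the raw curve at the located frames, so smoothing steers the
  # search without flattening the measurement itself.
  sys_win <- which(t <= 0.5 * rr)                 # 1-based indices
  lav_max <- v[sys_win[which.max(vs[sys_win])]]

  ed_win <- sort(unique(c(1L, which(t >= 0.85 * rr))))
  lav_min <- v[ed_win[which.min(vs[ed_win])]]

  loc <- locate_ac(curve, smooth_frames)
  flag <- loc$flag
  lav_ac <- if (is.na(loc$ac_frame)) lav_min else v[loc$ac_frame + 1L]

  if (!(lav_min <= lav_ac && lav_ac <= lav_max)) {
    flag <- "ordering_violation"
    warning(sprintf("patient %s: multi-phase triple violates phasic ordering; flagged",
                    curve$patient_id), call. = FALSE)
  }
  rec(lav_max, lav_ac, lav_min, flag)
}

#' Quantify a set of curves by one or both extraction methods
#'
#' Convenience wrapper running [extract_single_phase()] and/or
#' [extract_multi_phase()] over a list of curves and assembling the phasic
#' table with emptying fractions. Flagged records are kept in the table with
#' their flag so callers can exclude and count them.
#'
#' @param curves List of `la_curve` objects.
#' @param method `"single"`, `"multi"` or `"both"`.
#' @param observer_id Label recorded per row.
#' @param smooth_frames Passed to [extract_multi_phase()].
#' @return `data.frame` with columns `patient_id`, `observer_id`, `method`,
#'   `lav_min`, `lav_ac`, `lav_max`, `laef_total`, `laef_passive`,
#'   `laef_contractile`, `flag`.
#' @export
quantify_curves <- function(curves, method = c("both", "single", "multi"),
                            observer_id = "obs1", smooth_frames = 1L) {
  method <- match.arg(method)
  recs <- list()
  for (cv in curves) {
    if (method %in% c("both", "single")) {
      recs[[length(recs) + 1L]] <- extract_single_phase(cv)
    }
    if (method %in% c("both", "multi")) {
      recs[[length(recs) + 1L]] <- extract_multi_phase(cv, smooth_frames = smooth_frames)
    }
  }
  out <- do.call(rbind, lapply(recs, function(r) {
    ok <- is.na(r$flag) || r$flag == "onset_fallback"
    ef <- if (ok && r$lav_min <= r$lav_ac && r$lav_ac <= r$lav_max) {
      ef0 <- emptying_fractions(data.frame(lav_max = r$lav_max, lav_ac = r$lav_ac,
                                           lav_min = r$lav_min))
      unlist(ef0)
    } else {
      c(laef_total = NA_real_, laef_passive = NA_real_, laef_contractile = NA_real_)
    }
    data.frame(
      patient_id = r$patient_id, observer_id = observer_id, method = r$method,
      lav_min = r$lav_min, lav_ac = r$lav_ac, lav_max = r$lav_max,
      laef_total = ef[["laef_total"]], laef_passive = ef[["laef_passive"]],
      laef_contractile = ef[["laef_contractile"]],
      flag = r$flag, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Rotate the frame origin of a curve
#'
#' Utility for robustness checks: shifts the volume sequence cyclically by
#' `k` frames and re-indexes the stored event frames. Times keep the same
#' grid (they are measured from the new origin). Note that multi-phase
#' landmark windows are anchored at the R-wave by design, so only
#' single-phase extraction is expected to be invariant under rotation.
#'
#' @param curve An `la_curve`.
#' @param k Number of frames to rotate by.
#' @return Rotated `la_curve`.
#' @export
rotate_curve <- function(curve, k) {
  n <- curve$n_frames
  k <- ((k %% n) + n) %% n
  idx <- ((seq_len(n) - 1L + k) %% n) + 1L
  ev <- curve$event_frames
  if (!is.null(ev)) {
    ev <- lapply(ev, function(f) ((f - k) %% n + n) %% n)
  }
  out <- curve
  out$volumes <- curve$volumes[idx]
  out$event_frames <- ev
  out
}
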