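#' Biplane area-length LA volume
#'
#' Chamber volume from two orthogonal long-axis planimetry areas and the
#' chamber long-axis length: `0.85 * a1 * a2 / length_l`.
#'
#' @param a1 Planimetry area in the 2-chamber view, cm^2.
#' @param a2 Planimetry area in the 4-chamber view, cm^2.
#' @param length_l LA length perpendicular to the mitral annulus center in
#'   the 4-chamber view, cm.
#' @return Absolute volume in mL. Vectorized.
#' @export
#' @examples
#' biplane_volume(20, 20, 5)  # 68 mL
biplane_volume <- function(a1, a2, length_l) {
  stopifnot_positive(a1 = a1, a2 = a2, length_l = length_l)
  0.85 * a1 * a2 / length_l
}

#' Index a volume to body surface area
#'
#' @param volume_ml Absolute volume, mL.
#' @param bsa Body surface area, m^2.
#' @return Indexed volume, mL/m^2.
#' @export
index_volume <- function(volume_ml, bsa) {
  if (!is.numeric(bsa) || any(!is.finite(bsa)) || any(bsa <= 0)) {
    abort_validation("'bsa' must be positive")
  }
  volume_ml / bsa
}

#' Phasic volume triple
#'
#' Validating constructor for the (LAVmax, LAVac, LAVmin) triple produced by
#' either extraction method. Fractions and downstream statistics assume the
#' phasic ordering `lav_min <= lav_ac <= lav_max`; violations name the
#' offending pair. Volumes below `floor_ml_m2` are rejected as implausible.
#'
#' @param patient_id Identifier.
#' @param lav_max,lav_ac,lav_min Indexed volumes, mL/m^2.
#' @param method `"single_phase"` or `"multi_phase"`.
#' @param floor_ml_m2 Minimum plausible indexed volume (default 1 mL/m^2).
#' @return Object of class `la_phasic` (named list).
#' @export
phasic_volumes <- function(patient_id, lav_max, lav_ac, lav_min,
                           method = c("single_phase", "multi_phase"),
                           floor_ml_m2 = 1) {
  method <- match.arg(method)
  for (nm in c("lav_max", "lav_ac", "lav_min")) {
    v <- get(nm)
    if (!is_number(v)) abort_validation(sprintf("'%s' must be a single number", nm))
    if (v < floor_ml_m2) {
      abort_validation(sprintf(
        "'%s' = %.3g mL/m^2 is below the plausibility floor (%g mL/m^2)", nm, v, floor_ml_m2
      ))
    }
  }
  if (lav_min > lav_ac) {
    abort_validation("phasic ordering violated: lav_min > lav_ac")
  }
  if (lav_ac > lav_max) {
    abort_validation("phasic ordering violated: lav_ac > lav_max")
  }
  structure(
    list(patient_id = patient_id, lav_max = lav_max, lav_ac = lav_ac,
         lav_min = lav_min, method = method),
    class = "la_phasic"
  )
}

#' @export
print.la_phasic <- function(x, ...) {
  cat(sprintf("<la_phasic> %s [%s] max/ac/min = %.1f/%.1f/%.1f mL/m^2\n",
              x$patient_id, x$method, x$lav_max, x$lav_ac, x$lav_min))
  invisible(x)
}

#' LA emptying fractions from a phasic volume triple
#'
#' Computes the three emptying indices, each normalized by the maximal
#' volume:
#' \deqn{LAEF_{Total} = (LAV_{max}-LAV_{min})/LAV_{max}}
#' \deqn{LAEF_{Passive} = (LAV_{max}-LAV_{ac})/LAV_{max}}
#' \deqn{LAEF_{Contractile} = (LAV_{ac}-LAV_{min})/LAV_{max}}
#' Because all three share the `LAV_max` denominator, passive + contractile
#' equals total (to floating-point rounding), and BSA indexing cancels, so
#' indexed and absolute volumes give identical fractions.
#'
#' Fractions are kept in `[0, 1)`; rendering as percentages is left to the
#' reporting layer.
#'
#' @param pv An `la_phasic` object, or a data.frame with columns `lav_max`,
#'   `lav_ac`, `lav_min` (vectorized).
#' @return Named list (for a single triple) or data.frame (for a table) with
#'   `laef_total`, `laef_passive`, `laef_contractile`.
#' @export
#' @examples
#' pv <- phasic_volumes("p1", lav_max = 60, lav_ac = 48, lav_min = 30)
#' emptying_fractions(pv)  # total 0.50, passive 0.20, contractile 0.30
emptying_fractions <- function(pv) {
  if (inherits(pv, "la_phasic")) {
    vmax <- pv$lav_max; vac <- pv$lav_ac; vmin <- pv$lav_min
    scalar <- TRUE
  } else if (is.data.frame(pv)) {
    need <- c("lav_max", "lav_ac", "lav_min")
    if (!all(need %in% names(pv))) {
      abort_validation("data.frame input needs columns lav_max, lav_ac, lav_min")
    }
    vmax <- pv$lav_max; vac <- pv$lav_ac; vmin <- pv$lav_min
    scalar <- FALSE
  } else {
    abort_validation("'pv' must be an la_phasic or a data.frame of triples")
  }
  if (any(vmax <= 0)) abort_validation("lav_max must be positive")
  if (any(vmin > vac)) abort_validation("phasic ordering violated: lav_min > lav_ac")
  if (any(vac > vmax)) abort_validation("phasic ordering violated: lav_ac > lav_max")
  total <- (vmax - vmin) / vmax
  passive <- (vmax - vac) / vmax
  contractile <- (vac - vmin) / vmax
  if (scalar) {
    list(laef_total = total, laef_passive = passive, laef_contractile = contractile)
  } else {
    data.frame(laef_total = total, laef_passive = passive,
               laef_contractile = contractile)
  }
}

# Reconstruct an indexed volume curve from one observer's biplane table.
# Inverse of project_biplane: volume per frame via the area-length formula,
# then BSA indexing. Returns an la_curve suitable for phase extraction.
#' Reconstruct an LA time-volume curve from biplane measurements
#'
#' Applies [biplane_volume()] and [index_volume()] frame by frame to one
#' patient/observer block of planimetry measurements.
#'
#' @param biplane `data.frame` with columns `frame`, `time_ms`, `a1_cm2`,
#'   `a2_cm2`, `l_cm` for a single patient and observer, frames 0..n-1.
#' @param bsa Body surface area, m^2.
#' @param rr_interval RR interval in ms; inferred from the frame spacing if
#'   omitted.
#' @param event_frames Optional landmark list carried through to the curve.
#' @return An `la_curve`.
#' @export
curve_from_biplane <- function(biplane, bsa, rr_interval = NULL,
                               event_frames = NULL) {
  need <- c("frame", "time_ms", "a1_cm2", "a2_cm2", "l_cm")
  if (!all(need %in% names(biplane))) {
    abort_validation(sprintf("biplane table needs columns: %s",
                             paste(need, collapse = ", ")))
  }
  b <- biplane[order(biplane$frame), , drop = FALSE]
  if (any(duplicated(b$frame))) {
    abort_validation("biplane table has duplicated frames; split by patient/observer first")
  }
  vol <- index_volume(biplane_volume(b$a1_cm2, b$a2_cm2, b$l_cm), bsa)
  n <- nrow(b)
  rr <- rr_interval %||% (n * (b$time_ms[2] - b$time_ms[1]))
  structure(
    list(
      patient_id = if ("patient_id" %in% names(b)) b$patient_id[1] else NA_character_,
      times = b$time_ms,
      volumes = vol,
      rr_interval = rr,
      n_frames = n,
      event_frames = event_frames
    ),
    class = "la_curve"
  )
}
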