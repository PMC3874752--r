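#' Bland-Altman agreement between two paired measurement sets
#'
#' Differences are `x - y` (by convention single-phase minus multi-phase
#' when comparing extraction methods). Reports the mean difference (bias),
#' SD of differences, and the conventional 1.96-SD limits of agreement.
#'
#' @param x,y Paired numeric vectors of equal length, `n >= 2`.
#' @param comparison_name Label carried into the result.
#' @return List of class `la_agreement`: `comparison_name`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_pairs`.
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(1, 2, 3))$mean_diff  # 0
bland_altman <- function(x, y, comparison_name = "x_vs_y") {
  if (length(x) != length(y)) abort_validation("paired vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  if (length(d) < 2L) abort_validation("need at least 2 complete pairs")
  m <- mean(d)
  s <- stats::sd(d)
  structure(
    list(comparison_name = comparison_name, mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n_pairs = length(d)),
    class = "la_agreement"
  )
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' computed with population (n-normalized) moments, following Lin's original
#' definition. Penalizes both scatter and systematic location/scale shifts,
#' so `|CCC| <= |r|` always, with equality only when means and variances
#' match.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, each with nonzero variance.
#' @param comparison_name Label carried into the result.
#' @return List of class `la_concordance`: `comparison_name`, `ccc`,
#'   `n_pairs`.
#' @export
lin_ccc <- function(x, y, comparison_name = "x_vs_y") {
  if (length(x) != length(y)) abort_validation("paired vectors must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort_validation("need at least 3 complete pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0) abort_validation("concordance undefined: zero variance")
  sxy <- mean((x - mx) * (y - my))
  structure(
    list(comparison_name = comparison_name,
         ccc = 2 * sxy / (sx2 + sy2 + (mx - my)^2), n_pairs = n),
    class = "la_concordance"
  )
}

#' Observer-variability replicate study
#'
#' Emulates the replicate design of observer-variability assessment: a few
#' randomly selected cases are re-measured by independent observers (fresh
#' planimetry noise draws), each replicate is quantified by both extraction
#' methods, and Lin's CCC between the first two observers is reported per
#' volume index and method. Landmark re-detection makes the multi-phase
#' method additionally sensitive to noise-induced jitter, which is why its
#' concordance is expected at or below the single-phase one.
#'
#' @param cohort An `la_cohort` data frame.
#' @param n_cases Number of randomly selected cases (default 5).
#' @param n_replicates Observers per case, `>= 2` (default 2).
#' @param noise_sd_rel Relative planimetry noise per observer measurement.
#' @param seed RNG seed or `NULL`.
#' @param smooth_frames Smoothing window for multi-phase landmark detection
#'   (default 3, the noisy-input setting).
#' @return `data.frame` with columns `method`, `index`, `ccc`, `n_pairs`
#'   for the inter-observer comparison (observers 1 vs 2).
#' @export
replicate_study <- function(cohort, n_cases = 5, n_replicates = 2,
                            noise_sd_rel = 0.03, seed = NULL,
                            smooth_frames = 3L) {
  if (!is_count(n_replicates) || n_replicates < 2) {
    abort_validation("'n_replicates' must be an integer >= 2")
  }
  if (!is_count(n_cases) || n_cases > nrow(cohort)) {
    abort_validation("'n_cases' must be a positive integer <= cohort size")
  }
  if (!is.null(seed)) set.seed(seed)
  picked <- cohort[sort(sample.int(nrow(cohort), n_cases)), , drop = FALSE]

  sm <- if (noise_sd_rel > 0) smooth_frames else 1L
  tabs <- list()
  for (i in seq_len(nrow(picked))) {
    p <- picked[i, ]
    cv <- build_curve(p)
    for (r in seq_len(n_replicates)) {
      bp <- project_biplane(cv, p$bsa_m2, noise_sd_rel = noise_sd_rel,
                            observer_id = sprintf("obs%d", r))
      rc <- curve_from_biplane(bp, p$bsa_m2, rr_interval = cv$rr_interval,
                               event_frames = cv$event_frames)
      rc$patient_id <- p$patient_id
      tabs[[length(tabs) + 1L]] <- quantify_curves(
        list(rc), method = "both",
        observer_id = sprintf("obs%d", r), smooth_frames = sm
      )
    }
  }
  phasic <- do.call(rbind, tabs)

  out <- list()
  for (meth in c("single_phase", "multi_phase")) {
    for (ix in c("lav_min", "lav_ac", "lav_max")) {
      a <- phasic[phasic$method == meth & phasic$observer_id == "obs1", ]
      b <- phasic[phasic$method == meth & phasic$observer_id == "obs2", ]
      b <- b[match(a$patient_id, b$patient_id), ]
      cc <- lin_ccc(a[[ix]], b[[ix]],
                    comparison_name = sprintf("inter_observer_%s_%s", meth, ix))
      out[[length(out) + 1L]] <- data.frame(
        method = meth, index = ix, ccc = cc$ccc, n_pairs = cc$n_pairs,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
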