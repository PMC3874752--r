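#' Dichotomize LVEDP at a threshold
#'
#' Labels a patient `"elevated"` when LVEDP is strictly greater than the
#' threshold (default 12 mmHg) and `"normal"` otherwise; the boundary value
#' itself is normal. Missing values propagate as `NA` and are excluded (and
#' counted) by the reporting layer.
#'
#' @param lvedp LVEDP in mmHg (vectorized).
#' @param threshold Dichotomization threshold, mmHg.
#' @return Character vector of `"elevated"` / `"normal"` (or `NA`).
#' @export
#' @examples
#' dichotomize_lvedp(c(12, 12.1, 22, 9))
dichotomize_lvedp <- function(lvedp, threshold = 12) {
  if (any(!is.na(lvedp) & lvedp <= 0)) abort_validation("LVEDP must be positive")
  ifelse(is.na(lvedp), NA_character_, ifelse(lvedp > threshold, "elevated", "normal"))
}

as_positive_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("elevated", "normal")
    if (any(bad)) abort_validation("labels must be 'elevated'/'normal' or logical")
    return(labels == "elevated")
  }
  abort_validation("labels must be 'elevated'/'normal' or logical")
}

# Orient scores so that larger oriented score = more disease-like.
orient_scores <- function(scores, direction) {
  switch(direction, ge = scores, le = -scores,
         abort_validation("direction must be 'ge' or 'le'"))
}

#' Empirical ROC area with DeLong inference
#'
#' AUC as the Mann-Whitney pair statistic: the probability that a random
#' positive outscores a random negative, ties counted one half. `direction`
#' states how the index is oriented toward disease: `"ge"` (higher values
#' more disease-like, used for volumes) or `"le"` (lower values more
#' disease-like, used for emptying fractions). The two-sided p-value against
#' AUC = 0.5 uses the DeLong placement variance.
#'
#' @param scores Numeric index values, one per patient.
#' @param labels `"elevated"`/`"normal"`, factor, or logical (TRUE = positive).
#' @param direction `"ge"` or `"le"`.
#' @return List with `auc`, `p`, `se`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' empirical_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE), "ge")$auc  # 1
empirical_auc <- function(scores, labels, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  pos <- as_positive_label(labels)
  keep <- !is.na(scores) & !is.na(pos)
  s <- orient_scores(scores[keep], direction)
  pos <- pos[keep]
  m <- sum(pos); n <- sum(!pos)
  if (m < 1L || n < 1L) abort_validation("need at least one patient in each class")
  x <- s[pos]; y <- s[!pos]

  # Placement values: V10[i] = P-hat(x_i beats a random negative), and the
  # transpose. AUC is their common mean; DeLong variance combines their
  # sample variances.
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  auc <- mean(psi)
  s10 <- if (m > 1L) stats::var(v10) else 0
  s01 <- if (n > 1L) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  p <- if (se == 0) {
    if (abs(auc - 0.5) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  }
  list(auc = auc, p = p, se = se, n_pos = m, n_neg = n)
}

#' Youden-optimal cutoff with sensitivity and specificity
#'
#' Scans the empirical ROC thresholds (midpoints between consecutive
#' distinct observed values) and returns the cutoff maximizing Youden's
#' J = sensitivity + specificity - 1. Classification semantics follow
#' `direction`: positive when `score >= cutoff` (`"ge"`, volumes) or
#' `score <= cutoff` (`"le"`, fractions). Ties in J are broken toward the
#' higher-specificity operating point.
#'
#' @inheritParams empirical_auc
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `direction`. When no threshold discriminates (max J = 0) the cutoff is
#'   `NA`.
#' @export
optimal_cutoff <- function(scores, labels, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  pos <- as_positive_label(labels)
  keep <- !is.na(scores) & !is.na(pos)
  scores <- scores[keep]; pos <- pos[keep]
  if (sum(pos) < 1L || sum(!pos) < 1L) {
    abort_validation("need at least one patient in each class")
  }
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    return(list(cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
                youden = 0, direction = direction))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- list(j = -Inf, spec = -Inf, cutoff = NA_real_, sens = NA_real_)
  for (c0 in cand) {
    called_pos <- if (direction == "ge") scores >= c0 else scores <= c0
    sens <- mean(called_pos[pos])
    spec <- mean(!called_pos[!pos])
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(j = j, spec = spec, cutoff = c0, sens = sens)
    }
  }
  if (best$j <= 1e-12) {
    return(list(cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
                youden = 0, direction = direction))
  }
  list(cutoff = best$cutoff, sensitivity = best$sens, specificity = best$spec,
       youden = best$j, direction = direction)
}

#' Two-group comparison of a continuous index
#'
#' Group means and SDs with a two-sided two-sample t test. The pooled
#' (Student) variant is the default; Welch is available.
#'
#' @param values Numeric vector.
#' @param labels `"elevated"`/`"normal"`, factor, or logical.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return List with `mean_elevated`, `sd_elevated`, `n_elevated`,
#'   `mean_normal`, `sd_normal`, `n_normal`, `p_value`.
#' @export
group_compare <- function(values, labels, var_equal = TRUE) {
  pos <- as_positive_label(labels)
  keep <- !is.na(values) & !is.na(pos)
  values <- values[keep]; pos <- pos[keep]
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    abort_validation("both groups need n >= 2 for a defined SD")
  }
  a <- values[pos]; b <- values[!pos]
  p <- if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    1
  } else {
    stats::t.test(a, b, var.equal = var_equal)$p.value
  }
  list(mean_elevated = mean(a), sd_elevated = stats::sd(a), n_elevated = length(a),
       mean_normal = mean(b), sd_normal = stats::sd(b), n_normal = length(b),
       p_value = p)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y Numeric vectors, `n >= 3`, nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort_validation("need n >= 3 for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_validation("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p from the hypergeometric distribution.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))  # 2/252
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) abort_validation("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    abort_validation("counts must be nonnegative integers")
  }
  stats::fisher.test(table)$p.value
}

# Index orientation toward elevated LVEDP: larger volumes, smaller fractions.
index_directions <- function() {
  c(lav_min = "ge", lav_max = "ge", lav_ac = "ge",
    laef_passive = "le", laef_contractile = "le", laef_total = "le")
}

#' Per-index diagnostic accuracy table
#'
#' For each LA index, runs [empirical_auc()] and [optimal_cutoff()] against
#' the dichotomized LVEDP label, with volume indices oriented `>=` and
#' emptying fractions `<=`. Mirrors the layout of a ROC summary table:
#' AUC, p, criterion cutoff, sensitivity, specificity.
#'
#' @param phasic `data.frame` with the six index columns (`lav_min`,
#'   `lav_ac`, `lav_max`, `laef_total`, `laef_passive`, `laef_contractile`).
#' @param labels `"elevated"`/`"normal"` per row of `phasic`.
#' @param indices Index columns to evaluate (default all six).
#' @return `data.frame` with one row per index: `index`, `auc`, `p_value`,
#'   `direction`, `cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
diagnostic_report <- function(phasic, labels, indices = names(index_directions())) {
  dirs <- index_directions()
  unknown <- setdiff(indices, names(dirs))
  if (length(unknown)) {
    abort_validation(sprintf("unknown index: %s", paste(unknown, collapse = ", ")))
  }
  rows <- lapply(indices, function(ix) {
    sc <- phasic[[ix]]
    if (is.null(sc)) abort_validation(sprintf("phasic table lacks column '%s'", ix))
    a <- empirical_auc(sc, labels, dirs[[ix]])
    oc <- optimal_cutoff(sc, labels, dirs[[ix]])
    data.frame(index = ix, auc = a$auc, p_value = a$p, direction = dirs[[ix]],
               cutoff = oc$cutoff, sensitivity = oc$sensitivity,
               specificity = oc$specificity, n_pos = a$n_pos, n_neg = a$n_neg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-comparison table for the six LA indices (plus LVEDP)
#'
#' @param data `data.frame` holding the index columns and `lvedp_mmhg`.
#' @param labels `"elevated"`/`"normal"` per row.
#' @param var_equal Passed to [group_compare()].
#' @return `data.frame` with per-variable group means, SDs and t-test p.
#' @export
group_table <- function(data, labels, var_equal = TRUE) {
  vars <- c(names(index_directions()), "lvedp_mmhg")
  vars <- intersect(vars, names(data))
  rows <- lapply(vars, function(v) {
    gc <- group_compare(data[[v]], labels, var_equal = var_equal)
    data.frame(variable = v,
               mean_elevated = gc$mean_elevated, sd_elevated = gc$sd_elevated,
               n_elevated = gc$n_elevated,
               mean_normal = gc$mean_normal, sd_normal = gc$sd_normal,
               n_normal = gc$n_normal,
               p_value = gc$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
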