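# Shared helpers and independent oracles for the test suite.

# Construct an la_curve directly from a volume vector (for degenerate
# morphologies the generator never produces).
make_curve <- function(volumes, heart_rate = 70, patient_id = "T001",
                       event_frames = NULL) {
  n <- length(volumes)
  rr <- 60000 / heart_rate
  structure(
    list(patient_id = patient_id, times = (seq_len(n) - 1) * rr / n,
         volumes = volumes, rr_interval = rr, n_frames = n,
         event_frames = event_frames),
    class = "la_curve"
  )
}

# Cosine-blended single-peak curve with no atrial kick: monotone rise to a
# peak at 40% of the cycle, monotone fall to the end.
make_single_peak_curve <- function(n = 25, vmin = 30, vmax = 60) {
  f_peak <- round(0.4 * n)
  up <- vmin + (vmax - vmin) * (1 - cos(pi * (0:f_peak) / f_peak)) / 2
  down_idx <- seq.int(f_peak + 1, n - 1)
  down <- vmin + (vmax - vmin) *
    (1 + cos(pi * (down_idx - f_peak) / (n - 1 - f_peak))) / 2
  make_curve(c(up, down))
}

# Brute-force AUC: count pairs, ties one half, oriented per direction.
oracle_auc <- function(scores, labels, direction = "ge") {
  s <- if (direction == "le") -scores else scores
  pos <- s[labels]
  neg <- s[!labels]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# Two-sided Fisher exact p by explicit hypergeometric enumeration with
# binomial coefficients (margins fixed at the observed table's).
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled-variance two-sample t-test p from summary statistics.
oracle_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = n1 + n2 - 2)
}

# Small noiseless cohort with curves, shared by extraction tests.
noiseless_patients <- function(n, seed) {
  co <- sample_cohort(cohort_config(n_patients = n, noise_sd_rel = 0, seed = seed))
  curves <- lapply(seq_len(n), function(i) build_curve(co[i, ]))
  list(cohort = co, curves = curves)
}

expect_quiet_flag <- function(rec, flag = NA_character_) {
  if (is.na(flag)) expect_true(is.na(rec$flag)) else expect_identical(rec$flag, flag)
}
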