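# Internal helpers shared across modules.

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "laphase_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_config <- function(msg) abort(msg, "laphase_config_error")
abort_validation <- function(msg) abort(msg, "laphase_validation_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
stopifnot_positive <- function(..., .fn = abort_validation) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      .fn(sprintf("'%s' must be positive and finite", nms[i]))
    }
  }
  invisible(TRUE)
}

# Truncated-normal sampling by rejection; truncation bounds are open/closed
# as supplied through the predicate. Used for LVEDP group truncation at the
# 12 mmHg boundary and for physiologic clamping of HR/BSA.
rnorm_trunc <- function(n, mean, sd, accept, max_tries = 10000L, what = "value") {
  if (sd == 0) {
    if (!accept(mean)) {
      abort_config(sprintf(
        "degenerate %s distribution (sd = 0) with mean outside its truncation region",
        what
      ))
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::rnorm(1L, mean, sd)
      if (accept(x)) {
        out[i] <- x
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort_config(sprintf("could not sample %s within its truncation region", what))
    }
  }
  out
}

# Centered cyclic moving average; window must be odd. Window 1 is identity.
moving_average_cyclic <- function(x, window = 3L) {
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) abort_validation("smoothing window must be odd")
  n <- length(x)
  half <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n) - 1L, -half:half, "+") %% n + 1L
  rowMeans(matrix(x[idx], nrow = n))
}

# Derive a per-stage seed from a global one, staying within 32-bit range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean and SD of a normal truncated to [lower, upper] (closed two-sided
# formulas). Used to standardize the LVEDP link by the realized group
# distribution so truncation does not shift the volume means.
trunc_norm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(c(mean = mean, sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z <= 0) abort_config("empty truncation region")
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (aa - bb) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_fixed_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
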