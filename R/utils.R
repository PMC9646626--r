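# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derived seed kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 1000003 + (as.numeric(p) * 97)) %% 2147483647
  }
  as.integer(floor(h))
}

# Strict local maxima of a numeric vector (plateau-free signals assumed;
# plateaus take the first sample). Returns indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) < 0) + 1L
}

# Greedy enforcement of a minimum index separation, keeping higher values
# first; returns the kept subset sorted ascending.
enforce_min_separation <- function(idx, height, min_sep) {
  if (length(idx) == 0) return(integer(0))
  ord <- order(height, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_sep)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

# Peak prominence relative to the higher of the two flanking minima between
# neighbouring higher points (standard topographic definition, vectorized
# enough for recording-length inputs).
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    left_bound <- 1L
    higher_left <- which(x[seq_len(p - 1L)] > h)
    if (length(higher_left)) left_bound <- max(higher_left)
    right_bound <- n
    if (p < n) {
      higher_right <- which(x[(p + 1L):n] > h)
      if (length(higher_right)) right_bound <- p + min(higher_right)
    }
    left_min <- if (left_bound < p) min(x[left_bound:p]) else h
    right_min <- if (right_bound > p) min(x[p:right_bound]) else h
    h - max(left_min, right_min)
  }, numeric(1))
}

stop_neckppg <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "neckppg_error")))
}
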