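# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded by `seed`; restores the caller's
# stream afterwards so stochastic stages never leak global state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
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

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = 0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Centered moving average with edge shrinkage (window truncated at the ends).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  k <- rep(1, width)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  half <- (width - 1L) %/% 2L
  # stats::filter leaves NA at the edges; recompute with truncated windows
  idx <- which(is.na(num))
  for (i in idx) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    num[i] <- sum(x[lo:hi])
    den[i] <- hi - lo + 1L
  }
  as.numeric(num / den)
}

# Runs of TRUE in a logical vector -> matrix of [start_idx, stop_idx].
logical_runs <- function(mask) {
  r <- rle(mask)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], stop = stops[keep])
}

# Wrap angles to (-pi, pi].
wrap_pi <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Merge sorted half-open intervals whose gap is below `gap` (gap <= 0 merges
# only overlapping/contiguous intervals).
merge_intervals <- function(start, stop, gap = 0) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = numeric(0), stop = numeric(0)))
  }
  o <- order(start)
  start <- start[o]
  stop <- stop[o]
  ms <- start[1L]
  me <- stop[1L]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] - me < gap || start[i] <= me) {
      me <- max(me, stop[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- stop[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), stop = c(out_e, me))
}

# Total length covered by a set of non-overlapping intervals.
interval_time <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  sum(intervals$stop - intervals$start)
}

# Membership of time points in a set of sorted non-overlapping [start, stop)
# intervals.
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  edges <- as.numeric(t(as.matrix(intervals[, c("start", "stop")])))
  findInterval(t, edges) %% 2L == 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Monte-Carlo threshold at level alpha: the ceiling((1-alpha)(n+1))-th order
# statistic of the surrogate draws, the exact-test convention for
# surrogate-based significance.
mc_threshold <- function(sims, alpha) {
  n <- length(sims)
  sort(sims)[min(n, ceiling((1 - alpha) * (n + 1)))]
}
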