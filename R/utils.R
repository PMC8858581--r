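# Internal numeric helpers shared across the pipeline.

# Centered running mean with shrinking windows at the edges.
# width must be odd; at position i the window is the intersection of
# [i - h, i + h] with the series.
running_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered running median with shrinking windows at the edges.
running_median <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  h <- (width - 1L) %/% 2L
  out <- if (n >= width) as.numeric(stats::runmed(x, width, endrule = "keep")) else x
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(n - h + 1L, 1L), n)))
  for (i in edge) {
    lo <- max(i - h, 1L)
    hi <- min(i + h, n)
    out[i] <- stats::median(x[lo:hi])
  }
  out
}

# Unwrap a sequence of angles in degrees (removes +-360 jumps).
unwrap_deg <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jump <- round(d / 360)
  theta - c(0, cumsum(jump)) * 360
}

# Wrap angles in degrees to (-180, 180].
wrap_deg <- function(theta) {
  w <- (theta + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Derive a child RNG seed from an experiment seed and an offset, staying
# inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

# Average a high-rate series into bins aligned to an output clock.
# Sample i of the input is at time (i-1)/rate_in; output bin k covers
# [(k-1)/rate_out, k/rate_out).
bin_average <- function(x, rate_in, rate_out) {
  if (is.matrix(x)) stop("bin_average expects a vector")
  n <- length(x)
  n_out <- as.integer(floor(n / rate_in * rate_out))
  bin <- as.integer(floor((seq_len(n) - 1L) / rate_in * rate_out)) + 1L
  bin <- pmin(bin, n_out)
  as.numeric(rowsum(x, bin)) / tabulate(bin, nbins = n_out)
}

# Indices (1-based) of samples falling in [start_s, end_s) on a clock where
# sample i sits at time (i - 1) / rate_hz.
interval_to_idx <- function(start_s, end_s, rate_hz, n) {
  eps <- 1e-9
  lo <- as.integer(ceiling(start_s * rate_hz - eps)) + 1L
  hi <- as.integer(ceiling(end_s * rate_hz - eps))
  if (lo > n || hi < 1L || hi < lo) return(integer(0))
  seq.int(max(lo, 1L), min(hi, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
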