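# Zero-phase FIR filtering primitives. The deployed sensor SDK's internal
# filtering is undocumented; the tracker needs (a) a low-pass that preserves
# respiration peak locations (symmetric kernel => zero phase) and (b) a
# smoothed derivative for respiratory-motion activity detection. Both use
# reflection padding so extrema at the trace edges are not displaced.

# Symmetric windowed-sinc (Hamming) low-pass. `cutoff` in Hz. Near-unity
# passband below ~cutoff - 0.25 Hz so double application changes a
# band-limited signal by well under 1% RMS.
fir_lowpass <- function(x, dt, cutoff) {
  n <- length(x)
  if (n < 5L || !is.finite(cutoff) || cutoff <= 0) return(x)
  fc <- cutoff * dt                     # cycles/sample
  if (fc >= 0.5) return(x)              # at/above Nyquist: nothing to remove
  trans <- min(0.025, (0.5 - fc) / 2)   # normalized transition width
  half <- ceiling(3.3 / (2 * trans))
  half <- min(half, n - 1L)
  k <- -half:half
  h <- 2 * fc * sinc(2 * fc * k) * hamming(k, half)
  h <- h / sum(h)
  conv_reflect(x, h)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

hamming <- function(k, half) 0.54 + 0.46 * cos(pi * k / max(half, 1))

# Smoothed first derivative (derivative-of-Gaussian), units of x per second.
dog_slope <- function(x, dt, sigma = 0.3) {
  n <- length(x)
  if (n < 5L) return(rep(0, n))
  half <- min(ceiling(4 * sigma / dt), n - 1L)
  tt <- (-half:half) * dt
  g <- exp(-tt^2 / (2 * sigma^2))
  k <- -(tt / sigma^2) * g * dt
  # normalize so a unit-slope ramp maps to slope 1 exactly
  k <- k / sum(k * (-tt))
  conv_reflect(x, rev(k))
}

# Convolve with a symmetric-length kernel under reflection padding; output
# aligned with the input (no phase shift for symmetric kernels).
conv_reflect <- function(x, h) {
  half <- (length(h) - 1L) %/% 2L
  n <- length(x)
  if (half >= 1L) {
    # odd (anti-symmetric) reflection preserves the slope through the
    # edges, so extrema near the ends are not flattened by the kernel;
    # pivot on a short local mean, not the single (noisy) edge sample
    pl <- mean(x[1:min(5L, n)])
    pr <- mean(x[max(1L, n - 4L):n])
    left <- 2 * pl - x[pmin(half + 1L, n):2L]
    right <- 2 * pr - x[(n - 1L):max(n - half, 1L)]
    if (length(left) < half) left <- rep(left, length.out = half)
    if (length(right) < half) right <- rep(right, length.out = half)
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

# Rolling peak-to-peak (max - min) over a trailing-inclusive window of `w`
# samples; result[i] covers samples i..i+w-1 (length n-w+1).
rolling_p2p <- function(x, w) {
  n <- length(x)
  if (w > n) return(numeric(0))
  mx <- run_extreme(x, w, max)
  mn <- run_extreme(x, w, min)
  mx - mn
}

run_extreme <- function(x, w, fun) {
  n <- length(x)
  out <- numeric(n - w + 1L)
  for (i in seq_len(n - w + 1L)) out[i] <- fun(x[i:(i + w - 1L)])
  out
}
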