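# Trajectory statistics: stationary moments, histograms, autocorrelation,
# power spectra and a bimodality call.

#' Stationary summary statistics of a trajectory
#'
#' Discards a burn-in fraction, then reports mean, variance, Fano factor
#' and a histogram per requested species.  Histograms use unit-width
#' integer bins for (near-)integer data and Freedman-Diaconis bins
#' otherwise.
#'
#' @param tr a \code{grn_trajectory}
#' @param species character vector (default: all species)
#' @param burn_in fraction of the trajectory discarded from the start
#' @return named list per species with elements \code{mean}, \code{var},
#'   \code{fano}, \code{hist} (list of \code{breaks}, \code{counts},
#'   \code{mids})
#' @export
trajectory_stats <- function(tr, species = colnames(tr$abundances),
                             burn_in = 0.2) {
  stopifnot(burn_in >= 0, burn_in < 1)
  keep <- tr$times >= burn_in * max(tr$times)
  out <- lapply(species, function(s) {
    x <- tr$abundances[keep, s]
    m <- mean(x); v <- stats::var(x)
    integerish <- all(abs(x - round(x)) < 1e-9)
    if (integerish) {
      breaks <- seq(min(x) - 0.5, max(x) + 0.5, by = 1)
    } else {
      h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
      if (h <= 0) h <- diff(range(x)) / 30 + 1e-12
      breaks <- seq(min(x), max(x) + h, by = h)
    }
    hh <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(mean = m, var = v, fano = if (m > 0) v / m else NA_real_,
         hist = list(breaks = hh$breaks, counts = hh$counts, mids = hh$mids))
  })
  names(out) <- species
  out
}

#' Normalized autocorrelation of a series
#'
#' Biased (divide-by-n) autocovariance estimator, normalized so that
#' \code{acf(0) = 1}.  A constant series returns 1 at every lag, with
#' attribute \code{constant = TRUE}.
#'
#' @param series numeric vector, uniformly sampled
#' @param max_lag largest lag in samples; the series must be at least
#'   twice as long
#' @return numeric vector of length \code{max_lag + 1} (lags 0..max_lag)
#' @export
autocorrelation <- function(series, max_lag) {
  n <- length(series)
  stopifnot(n >= 2 * max_lag, max_lag >= 1)
  x <- series - mean(series)
  c0 <- sum(x^2) / n
  if (c0 == 0) {
    out <- rep(1, max_lag + 1)
    attr(out, "constant") <- TRUE
    return(out)
  }
  vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n / c0
  }, numeric(1))
}

#' Periodogram of a uniformly sampled series
#'
#' Plain periodogram of the mean-subtracted signal; the zero frequency is
#' omitted.
#'
#' @param series numeric vector
#' @param dt sampling interval (s)
#' @return list with \code{freq} (1/s) and \code{power}
#' @export
power_spectrum <- function(series, dt) {
  n <- length(series)
  x <- series - mean(series)
  X <- stats::fft(x)
  half <- seq(2L, floor(n / 2) + 1L)
  list(freq = (half - 1) / (n * dt),
       power = Mod(X[half])^2 / n)
}

#' Averaged periodogram over non-overlapping segments
#'
#' Splits the series into \code{n_seg} segments, averages their
#' periodograms.  Coarser frequency bins, lower variance; used to compare
#' dominant oscillation frequencies between simulation methods.
#'
#' @inheritParams power_spectrum
#' @param n_seg number of segments
#' @return list with \code{freq} and \code{power}
#' @export
averaged_spectrum <- function(series, dt, n_seg = 8) {
  n <- length(series)
  len <- floor(n / n_seg)
  stopifnot(len >= 8)
  acc <- NULL
  for (k in seq_len(n_seg)) {
    seg <- series[((k - 1) * len + 1):(k * len)]
    ps <- power_spectrum(seg, dt)
    acc <- if (is.null(acc)) ps$power else acc + ps$power
    freq <- ps$freq
  }
  list(freq = freq, power = acc / n_seg)
}

#' Bimodality call on a histogram
#'
#' Smooths the counts with a moving average (window 5 bins) and reports
#' bimodality when two local maxima are separated by a dip of at least
#' 20\% relative to the lower of the two peaks.
#'
#' @param hist list with \code{counts} and \code{mids} (as produced by
#'   \code{\link{trajectory_stats}})
#' @return list with \code{is_bimodal} and \code{modes} (positions of the
#'   two dominant peaks, or the single mode)
#' @export
bimodality <- function(hist) {
  counts <- hist$counts
  stopifnot(length(counts) >= 2)
  k <- 5L
  pad <- floor(k / 2)
  padded <- c(rep(counts[1], pad), counts, rep(counts[length(counts)], pad))
  sm <- stats::filter(padded, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)[(pad + 1):(pad + length(counts))]
  # local maxima (strictly above both flat-adjacent neighbours)
  n <- length(sm)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    is_max[i] <- sm[i] > left && sm[i] >= right
  }
  # substantial peaks only (>= 5% of the tallest) so shot noise on a
  # broad mode does not masquerade as extra modes
  peaks <- which(is_max & sm >= 0.05 * max(sm))
  if (length(peaks) < 2)
    return(list(is_bimodal = FALSE,
                modes = hist$mids[which.max(sm)]))
  # any pair of substantial peaks separated by a dip of >= 20% of the
  # lower peak qualifies; report the pair with the deepest relative dip
  best <- NULL; best_ratio <- Inf
  for (a in seq_along(peaks)[-length(peaks)]) {
    for (b in seq(a + 1L, length(peaks))) {
      p1 <- peaks[a]; p2 <- peaks[b]
      dip <- min(sm[p1:p2])
      ratio <- dip / min(sm[p1], sm[p2])
      if (ratio < best_ratio) { best_ratio <- ratio; best <- c(p1, p2) }
    }
  }
  list(is_bimodal = is.finite(best_ratio) && best_ratio <= 0.8,
       modes = hist$mids[best])
}
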