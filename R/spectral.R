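#' Symmetric pairwise-metric matrix
#'
#' Light wrapper marking a symmetric species-by-species matrix with the
#' coupling measure it holds: `"C0"` (equal-time correlation), `"absC0"`,
#' `"total_cpsd"` (integrated CPSD magnitude), or `"total_coherence"`.
#'
#' @param values Symmetric numeric matrix.
#' @param metric One of the four metric names (or another label).
#' @return A `metric_matrix` (a matrix with a `metric` attribute).
#' @export
metric_matrix <- function(values, metric) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) ||
      max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop_ecoguilds("metric matrix must be symmetric",
                   class = "ecoguilds_data_error")
  structure(values, metric = metric, class = c("metric_matrix", class(values)))
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat("<metric_matrix>", attr(x, "metric"), "(", nrow(x), "x", ncol(x), ")\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' @describeIn metric_matrix Tidy to one row per unordered pair.
#' @param x A `metric_matrix`.
#' @param ... Unused.
#' @export
tidy.metric_matrix <- function(x, ...) {
  out <- pair_index(nrow(x), rownames(x))
  out$metric <- attr(x, "metric")
  out$value <- x[upper.tri(x)]
  out
}

as_scores <- function(s) {
  if (inherits(s, "zscore_series")) s$scores
  else as.matrix(s)
}

#' Equal-time correlation matrix
#'
#' `C_ij(0) = (1/T) sum_t s_i(t) s_j(t)` over z-scored series; with the
#' population z-scoring of [log_zscore()] the diagonal is exactly 1.
#'
#' @param s A [log_zscore()] result, or an N x T matrix of z-scores.
#' @return A `metric_matrix` with metric `"C0"`.
#' @export
equal_time_corr <- function(s) {
  S <- as_scores(s)
  if (ncol(S) < 2)
    stop_ecoguilds("need at least 2 time points", class = "ecoguilds_data_error")
  metric_matrix(tcrossprod(S) / ncol(S), "C0")
}

#' Time-delayed cross-correlation between two series
#'
#' `C_ij(tau) = mean_t s_i(t) s_j(t + tau)`, averaged over the overlapping
#' portion at each lag (so a lag-0 autocorrelation of a z-scored series is 1).
#'
#' @param s_i,s_j Equal-length numeric z-scored series.
#' @param max_lag Maximum lag (must be < length of the series).
#' @return A tibble with columns `lag` (from `-max_lag` to `max_lag`) and
#'   `correlation`.
#' @export
cross_correlation <- function(s_i, s_j, max_lag) {
  T <- length(s_i)
  if (length(s_j) != T)
    stop_ecoguilds("series lengths differ", class = "ecoguilds_data_error")
  if (max_lag >= T)
    stop_ecoguilds("max_lag must be smaller than the series length",
                   class = "ecoguilds_data_error")
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(tau) {
    if (tau >= 0) mean(s_i[seq_len(T - tau)] * s_j[seq_len(T - tau) + tau])
    else mean(s_i[seq_len(T + tau) - tau] * s_j[seq_len(T + tau)])
  }, numeric(1))
  tibble::tibble(lag = lags, correlation = vals)
}

#' Welch-averaged auto- and cross-spectra with coherence
#'
#' Estimates the one-sided cross power spectral density `P_ij(f)` for every
#' species pair by averaging windowed, 50%-overlapping segment periodograms,
#' and the magnitude-squared coherence
#' `Coh_ij(f) = |P_ij|^2 / (P_ii P_jj)` from the segment-averaged spectra.
#' The frequency grid runs from 0 (DC) to the Nyquist frequency
#' `f_max = 1/(2 sampling_interval)` in steps of `delta_f` (default
#' `f_max / 15`, i.e. 30-sample segments). Series are assumed zero-mean
#' (z-scored); segments are not individually detrended, so genuine
#' low-frequency structure is retained.
#'
#' @param s A [log_zscore()] result or N x T matrix of z-scores.
#' @param sampling_interval Time between samples.
#' @param n_freq Number of frequency steps up to Nyquist (default 15, the
#'   `delta_f = f_max/15` rule). Ignored when `delta_f` is given.
#' @param delta_f Optional explicit frequency resolution.
#' @param window `"hamming"` (default), `"hann"`, or `"rect"`.
#' @param overlap Fractional segment overlap (default 0.5).
#' @return An object of class `spectral_estimate` with `frequencies`, complex
#'   `cpsd` (N x N x F), `psd` (N x F), `coherence` (N x N x F), `delta_f`,
#'   `f_max`, `n_segments`, `segment_length`, `sampling_interval`.
#' @export
welch_spectra <- function(s, sampling_interval, n_freq = 15, delta_f = NULL,
                          window = c("hamming", "hann", "rect"),
                          overlap = 0.5) {
  window <- match.arg(window)
  S <- as_scores(s)
  N <- nrow(S); T <- ncol(S); dt <- sampling_interval
  f_max <- 1 / (2 * dt)
  if (is.null(delta_f)) delta_f <- f_max / n_freq
  L <- 2L * max(1L, round(1 / (2 * delta_f * dt)))   # even segment length
  if (T < 2 * L)
    stop_ecoguilds("insufficient data: ", T, " samples but the frequency ",
                   "resolution requires segments of ", L, " samples and at ",
                   "least twice that many points",
                   class = "ecoguilds_data_error")
  hop <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, T - L + 1L, by = hop)
  n_seg <- length(starts)
  w <- switch(window,
              hamming = 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1)),
              rect = rep(1, L))
  nf <- L %/% 2 + 1L
  idx <- outer(0:(L - 1L), starts, "+")     # L x n_seg sample indices
  X <- array(complex(real = 0), c(nf, n_seg, N))
  for (i in seq_len(N)) {
    seg <- matrix(S[i, idx], L, n_seg) * w
    X[, , i] <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
  }
  scale <- dt / sum(w^2) * c(1, rep(2, nf - 2), 1)   # one-sided density
  cpsd <- array(complex(real = 0), c(N, N, nf))
  for (i in seq_len(N)) {
    for (j in i:N) {
      p <- rowMeans(Conj(X[, , i, drop = FALSE][, , 1]) *
                    X[, , j, drop = FALSE][, , 1]) * scale
      cpsd[i, j, ] <- p
      cpsd[j, i, ] <- Conj(p)
    }
  }
  psd <- matrix(0, N, nf)
  for (i in seq_len(N)) psd[i, ] <- Re(cpsd[i, i, ])
  coh <- array(0, c(N, N, nf))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      coh[i, j, ] <- Mod(cpsd[i, j, ])^2 / (psd[i, ] * psd[j, ])
    }
  }
  freqs <- (seq_len(nf) - 1) / (L * dt)
  structure(list(frequencies = freqs, cpsd = cpsd, psd = psd, coherence = coh,
                 delta_f = 1 / (L * dt), f_max = f_max, n_segments = n_seg,
                 segment_length = L, sampling_interval = dt,
                 species = rownames(S)),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat("<spectral_estimate>", dim(x$cpsd)[1], "species,", length(x$frequencies),
      "frequencies up to f_max =", x$f_max, "( delta_f =", x$delta_f,
      ",", x$n_segments, "segments )\n")
  invisible(x)
}

#' Tidy a spectral estimate into one row per pair and frequency
#'
#' @param x A `spectral_estimate`.
#' @param ... Unused.
#' @return Tibble with pair indices, frequency, CPSD real/imaginary parts and
#'   coherence.
#' @export
tidy.spectral_estimate <- function(x, ...) {
  n <- dim(x$cpsd)[1]
  pairs <- pair_index(n, x$species)
  purrr::map_dfr(seq_along(x$frequencies), function(k) {
    out <- pairs
    out$frequency <- x$frequencies[k]
    p <- x$cpsd[, , k]
    out$cpsd_re <- Re(p)[upper.tri(p)]
    out$cpsd_im <- Im(p)[upper.tri(p)]
    ch <- x$coherence[, , k]
    out$coherence <- ch[upper.tri(ch)]
    out
  })
}

# Trapezoidal quadrature weights over the frequency grid, optionally dropping
# the DC bin; integrates exactly to f_max (or f_max - delta_f) for a constant.
freq_weights <- function(est, include_dc = TRUE) {
  nf <- length(est$frequencies)
  w <- rep(1, nf); w[1] <- w[nf] <- 0.5
  if (!include_dc) {
    w[1] <- 0
    w[2] <- 0.5
  }
  w * est$delta_f
}

#' Total CPSD magnitude
#'
#' Integrates the magnitude of the cross power spectral density over the
#' frequency grid up to Nyquist (trapezoidal rule, DC included by default):
#' the pairwise coupling measure robust to unknown time delays. Without the
#' magnitude the same integral recovers the equal-time correlation by
#' Parseval's theorem, up to windowing and frequency-resolution effects
#' (exact for tiling rectangular segments); exposed via `signed = TRUE`.
#'
#' @param est A [welch_spectra()] estimate.
#' @param include_dc Include the zero-frequency bin (default TRUE).
#' @param signed If TRUE, integrate the real part without taking the
#'   magnitude (Parseval check).
#' @return A `metric_matrix` with metric `"total_cpsd"` (or `"signed_cpsd"`).
#' @export
total_cpsd_magnitude <- function(est, include_dc = TRUE, signed = FALSE) {
  stopifnot(inherits(est, "spectral_estimate"))
  wq <- freq_weights(est, include_dc)
  n <- dim(est$cpsd)[1]
  vals <- matrix(0, n, n, dimnames = list(est$species, est$species))
  for (k in seq_along(wq)) {
    slab <- est$cpsd[, , k]
    vals <- vals + wq[k] * (if (signed) Re(slab) else Mod(slab))
  }
  metric_matrix(vals, if (signed) "signed_cpsd" else "total_cpsd")
}

#' Total coherence
#'
#' Integrates the magnitude-squared coherence over the frequency grid up to
#' Nyquist (trapezoidal rule); bounded in `[0, f_max]`, with the diagonal at
#' exactly `f_max`. Requires at least two Welch segments: coherence estimated
#' from a single segment is identically 1 and carries no information.
#'
#' @inheritParams total_cpsd_magnitude
#' @return A `metric_matrix` with metric `"total_coherence"`.
#' @export
total_coherence <- function(est, include_dc = TRUE) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (est$n_segments < 2)
    stop_ecoguilds("coherence from a single Welch segment is identically 1; ",
                   "provide a longer series", class = "ecoguilds_data_error")
  wq <- freq_weights(est, include_dc)
  n <- dim(est$coherence)[1]
  vals <- matrix(0, n, n, dimnames = list(est$species, est$species))
  for (k in seq_along(wq)) vals <- vals + wq[k] * est$coherence[, , k]
  metric_matrix(vals, "total_coherence")
}

#' All four pairwise coupling measures from one series
#'
#' Convenience wrapper computing the equal-time correlation `C(0)`, its
#' absolute value, the total CPSD magnitude, and the total coherence from a
#' z-scored abundance matrix.
#'
#' @param s A [log_zscore()] result or N x T z-score matrix.
#' @param sampling_interval Time between samples.
#' @param ... Passed to [welch_spectra()].
#' @return A named list of four `metric_matrix` objects (`C0`, `absC0`,
#'   `total_cpsd`, `total_coherence`) with the `spectral_estimate` attached as
#'   attribute `"estimate"`; class `pairwise_metrics`.
#' @export
#' @examples
#' s <- log_zscore(matrix(exp(sin(outer(1:3, 1:200 / 5))), 3))
#' m <- pairwise_metrics(s, sampling_interval = 1)
#' names(m)
pairwise_metrics <- function(s, sampling_interval, ...) {
  c0 <- equal_time_corr(s)
  est <- welch_spectra(s, sampling_interval, ...)
  out <- list(
    C0 = c0,
    absC0 = metric_matrix(abs(unclass(c0)), "absC0"),
    total_cpsd = total_cpsd_magnitude(est),
    total_coherence = total_coherence(est))
  attr(out, "estimate") <- est
  class(out) <- "pairwise_metrics"
  out
}

#' @export
print.pairwise_metrics <- function(x, ...) {
  cat("<pairwise_metrics> metrics:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pairwise_metrics Tidy to one row per pair and metric.
#' @param x A `pairwise_metrics` list.
#' @export
tidy.pairwise_metrics <- function(x, ...) {
  purrr::map_dfr(names(x), function(nm) tidy(x[[nm]]))
}
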