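#' Welch power spectral density of a single series
#'
#' One-sided Welch estimate: the series is split into overlapping segments,
#' each mean-centered, tapered (Hamming), zero-padded to `nfft` and
#' periodogram-averaged, with the `1 / (fs * sum(w^2))` scaling under which
#' the integral of the PSD over frequency matches the series variance.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param window_s segment length in seconds (default 2.0).
#' @param overlap fractional overlap (default 0.5).
#' @param nfft FFT length, zero-padded (default 1024).
#' @return list: `freq` (Hz, up to fs/2), `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 2.0, overlap = 0.5, nfft = 1024) {
  nseg <- round(window_s * fs)
  if (length(x) < nseg) stop("series shorter than one Welch window")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- signal::hamming(nseg)
  u <- sum(w^2)
  nfft <- max(nfft, nseg)
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - nseg)))
    acc <- acc + Mod(X)^2
  }
  p2 <- acc / (length(starts) * fs * u)
  half <- seq_len(nfft %/% 2 + 1)
  p1 <- p2[half]
  ## one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- 2:(length(half) - if (nfft %% 2 == 0) 1 else 0)
  p1[dbl] <- 2 * p1[dbl]
  list(freq = (half - 1) * fs / nfft, psd = p1)
}

#' Power spectrum of on/off state series
#'
#' For each trial and state, forms a mean-centered binary series marking the
#' time points in that state on a fine grid (default 10 ms bins, 100 Hz
#' sampling, so spectral estimates extend to 50 Hz), computes its Welch PSD
#' (2.0 s Hamming windows, 50% overlap, 1024-point zero-padded FFT), and
#' averages across trials. Rhythmic alternation of states shows up as a
#' spectral peak; aperiodic states give a flat, broadband spectrum.
#'
#' @param states a `wm_states`, or a trials x bins binary matrix already on
#'   the fine grid (then `bin_width` gives its resolution).
#' @param bin_width fine-grid bin width, seconds (default 0.010).
#' @param window_s,overlap,nfft Welch parameters.
#' @return list of class `state_psd`: `freq`, `psd` (named list with `on`
#'   and `off` trial-averaged spectra), `n_trials` (used per state).
#' @export
state_psd <- function(states, bin_width = 0.010, window_s = 2.0,
                      overlap = 0.5, nfft = 1024) {
  fs <- 1 / bin_width
  if (inherits(states, "wm_states")) {
    ## rasterize window-grid labels onto the fine grid by nearest window
    ctr <- states$window_centers
    grid <- seq(min(ctr), max(ctr), by = bin_width)
    nearest <- vapply(grid, function(g) which.min(abs(ctr - g)), integer(1))
    mats <- lapply(c(on = "on", off = "off"), function(s)
      (states$states == s)[, nearest, drop = FALSE] * 1)
  } else {
    mats <- list(on = states * 1, off = 1 - (states * 1))
  }
  out <- lapply(mats, function(m) {
    spectra <- list(); used <- 0
    for (t in seq_len(nrow(m))) {
      res <- tryCatch(welch_psd(m[t, ], fs, window_s, overlap, nfft),
                      error = function(e) NULL)   # trial shorter than a window
      if (!is.null(res)) { spectra[[length(spectra) + 1]] <- res$psd; used <- used + 1 }
    }
    if (!used) return(NULL)
    list(psd = Reduce(`+`, spectra) / used, n = used)
  })
  nfft_eff <- max(nfft, round(window_s * fs))
  freq <- (seq_len(nfft_eff %/% 2 + 1) - 1) * fs / nfft_eff
  structure(list(freq = freq,
                 psd = list(on = out$on$psd, off = out$off$psd),
                 n_trials = c(on = out$on$n %||% 0, off = out$off$n %||% 0)),
            class = "state_psd")
}

#' @export
print.state_psd <- function(x, ...) {
  cat(sprintf("<state_psd> %d frequencies up to %.1f Hz (on: %d trials, off: %d)\n",
              length(x$freq), max(x$freq), x$n_trials["on"], x$n_trials["off"]))
  if (!is.null(x$psd$on)) {
    pk <- x$freq[which.max(x$psd$on[x$freq > 0]) + sum(x$freq == 0)]
    cat(sprintf("  on-state spectral peak (excluding DC) at %.2f Hz\n", pk))
  }
  invisible(x)
}
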