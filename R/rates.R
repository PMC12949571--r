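#' Bin spikes into a trials x units x windows firing-rate array
#'
#' Firing rates are estimated in sliding windows (default 100 ms wide, stepped
#' by 50 ms). Windows are labeled by their centers; the first window is the
#' earliest whose full extent fits the requested span, and window membership
#' is half-open `[center - width/2, center + width/2)`. Optional z-scoring is
#' applied per (unit, window) across trials; units with zero across-trial SD
#' in a window get 0 there (not NaN), which keeps downstream classifiers
#' well defined for silent units.
#'
#' @param session a `wm_session`.
#' @param window_width window width in seconds (default 0.100).
#' @param window_step window step in seconds (default 0.050).
#' @param epoch epoch name (`"fixation"`, `"cue"`, `"delay"`, `"response"`,
#'   or `"all"` for the full recorded span), or a numeric `c(start, end)` span.
#' @param zscore logical; z-score across trials per (unit, window)?
#' @return A `rate_matrix`: numeric array `[trial, unit, window]` of rates in
#'   spikes/s with attributes `window_centers`, `window_width`, `window_step`,
#'   `zscored`, `cue_location_deg` (per-trial labels) and `epoch`.
#' @export
bin_firing_rates <- function(session, window_width = 0.100, window_step = 0.050,
                             epoch = "delay", zscore = FALSE) {
  stopifnot(inherits(session, "wm_session"))
  if (window_width <= 0 || window_step <= 0)
    stop("window_width and window_step must be positive")
  if (nrow(session$trials) == 0) stop("session has zero trials")
  full <- session_span(session$epochs)
  span <- if (is.numeric(epoch)) {
    epoch
  } else if (identical(epoch, "all")) {
    full
  } else {
    iv <- session$epochs[[epoch]]
    if (is.null(iv)) stop(sprintf("unknown epoch '%s'", epoch))
    iv
  }
  if (span[1] < full[1] - 1e-9 || span[2] > full[2] + 1e-9)
    stop("requested span lies outside the recorded trial span")
  centers <- window_centers(span, window_width, window_step)
  if (!length(centers)) stop("no window fits the requested span")

  trial_ids <- session$trials$trial_id
  unit_ids <- session$units$unit_id
  nt <- length(trial_ids); nu <- length(unit_ids); nw <- length(centers)

  ## group = (trial, unit); spikes are sorted by (unit, trial, time)
  sp <- session$spikes
  arr <- array(0, dim = c(nt, nu, nw),
               dimnames = list(trial_ids, unit_ids, sprintf("%.3f", centers)))
  if (nrow(sp)) {
    gi <- (match(sp$unit_id, unit_ids) - 1L) * nt + match(sp$trial_id, trial_ids)
    ## offset trick: one global sorted vector, bounds shifted per group
    big <- (full[2] - full[1]) + 2
    key <- sp$time_s + gi * big
    o <- order(key)
    key <- key[o]
    groups <- sort(unique(gi))
    for (w in seq_len(nw)) {
      lo <- centers[w] - window_width / 2 + groups * big
      hi <- centers[w] + window_width / 2 + groups * big
      cnt <- n_below(hi, key) - n_below(lo, key)
      idx <- cbind((groups - 1L) %% nt + 1L, (groups - 1L) %/% nt + 1L,
                   rep(w, length(groups)))
      arr[idx] <- cnt / window_width
    }
  }

  if (zscore) {
    for (w in seq_len(nw)) {
      m <- arr[, , w, drop = FALSE]
      dim(m) <- c(nt, nu)
      mu <- colMeans(m)
      s <- apply(m, 2, sd)
      z <- sweep(m, 2, mu)
      ok <- s > 0
      z[, ok] <- sweep(z[, ok, drop = FALSE], 2, s[ok], "/")
      z[, !ok] <- 0
      arr[, , w] <- z
    }
  }

  structure(arr,
            window_centers = centers, window_width = window_width,
            window_step = window_step, zscored = zscore,
            cue_location_deg = session$trials$cue_location_deg,
            epoch = if (is.numeric(epoch)) "custom" else epoch,
            class = c("rate_matrix", "array"))
}

#' @export
print.rate_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rate_matrix> %d trials x %d units x %d windows (%s epoch)\n",
              d[1], d[2], d[3], attr(x, "epoch")))
  cat(sprintf("  width %g s, step %g s, centers %.3f..%.3f s, zscored: %s\n",
              attr(x, "window_width"), attr(x, "window_step"),
              min(attr(x, "window_centers")), max(attr(x, "window_centers")),
              attr(x, "zscored")))
  invisible(x)
}

## trials x units slice at one window index, as a plain matrix
rate_slice <- function(rm, w) {
  m <- rm[, , w, drop = FALSE]
  dim(m) <- dim(rm)[1:2]
  dimnames(m) <- dimnames(rm)[1:2]
  m
}

## indices of windows whose center falls inside [start, end)
windows_in <- function(rm, interval) {
  ctr <- attr(rm, "window_centers")
  which(ctr >= interval[1] - 1e-9 & ctr < interval[2] - 1e-9)
}
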