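#' @useDynLib wmoff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov coef lm optim pf predict quantile rbinom rnorm rpois
#'   runif sd setNames var wilcox.test p.adjust pt rbeta dbeta complete.cases
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The eight canonical cue angles of the ODR task
#'
#' Cue locations are arranged on a circle at 45 degree spacing.
#' @return Numeric vector `c(0, 45, ..., 315)`.
#' @export
cue_angles <- function() seq(0, 315, by = 45)

## circular distance in degrees, result in [0, 180]
circ_dist_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

#' Snap angles to the nearest canonical cue location
#'
#' Exact midpoints between two cues round toward the smaller angle.
#' @param theta angles in degrees.
#' @param cues candidate cue angles (default the 8 task locations).
#' @return Vector of cue angles, one per input angle.
#' @export
snap_to_cue <- function(theta, cues = cue_angles()) {
  vapply(theta, function(th) {
    if (is.na(th)) return(NA_real_)
    d <- circ_dist_deg(th, cues)
    ## ties -> smaller cue angle: which.min takes the first, cues sorted
    cues[which.min(d)]
  }, numeric(1))
}

## Half-open [start, end) membership
in_interval <- function(x, start, end) x >= start & x < end

## Window grid: centers of width-w windows stepped by s whose full extent
## fits inside [span[1], span[2]). First window is the earliest that fits.
window_centers <- function(span, width, step) {
  stopifnot(width > 0, step > 0, span[2] > span[1])
  first <- span[1] + width / 2
  last <- span[2] - width / 2
  if (last < first - 1e-12) return(numeric(0))
  n <- floor((last - first) / step + 1e-9) + 1
  first + step * (0:(n - 1))
}

## Counts of sorted-vector elements strictly below x (half-open helper)
n_below <- function(x, sorted) findInterval(x, sorted, left.open = TRUE)

## Run-length segments of a logical vector: data.frame(start_idx, end_idx, len)
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             len = r$lengths[keep])
}

## Seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Derive a stream of sub-seeds from one master seed (keeps values < 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
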