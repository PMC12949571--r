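#' Test per-unit location selectivity in a task epoch
#'
#' A unit is selective if a one-way ANOVA of its per-trial mean epoch firing
#' rates across the 8 cue locations is significant at `alpha` AND its best
#' (highest mean rate) location reaches at least `min_rate` spikes/s; the
#' rate criterion guards against false positives among nearly silent units.
#'
#' @param session a `wm_session`.
#' @param epoch epoch name (default `"delay"`).
#' @param alpha significance level (default 0.05).
#' @param min_rate best-location rate threshold in spikes/s (default 2).
#' @return data.frame with one row per unit: `unit_id`, `p_value`,
#'   `best_location_rate`, `best_location_deg`, `is_selective`.
#' @export
test_selectivity <- function(session, epoch = "delay", alpha = 0.05,
                             min_rate = 2) {
  iv <- session$epochs[[epoch]]
  if (is.null(iv)) stop(sprintf("unknown epoch '%s'", epoch))
  dur <- iv[2] - iv[1]
  cnt <- epoch_count_matrix(session, epoch) / dur   # trials x units, spikes/s
  cue <- factor(session$trials$cue_location_deg)
  tab <- table(cue)
  if (any(tab < 2))
    stop(sprintf("location %s has fewer than 2 trials", names(tab)[tab < 2][1]))
  res <- lapply(seq_len(ncol(cnt)), function(u) {
    y <- cnt[, u]
    p <- oneway_anova_p(y, cue)
    mu <- tapply(y, cue, mean)
    best <- which.max(mu)
    data.frame(unit_id = colnames(cnt)[u], p_value = p,
               best_location_rate = unname(mu[best]),
               best_location_deg = as.numeric(names(mu)[best]))
  })
  out <- do.call(rbind, res)
  out$is_selective <- out$p_value < alpha & out$best_location_rate >= min_rate
  out
}

## one-way ANOVA p-value via explicit sums of squares (NaN -> 1 for constant y)
oneway_anova_p <- function(y, g) {
  n <- length(y); k <- nlevels(g)
  gm <- tapply(y, g, mean); gn <- tapply(y, g, length)
  ssb <- sum(gn * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  if (ssw <= 0) {
    if (ssb <= 0) return(1)
    return(0)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  pf(f, k - 1, n - k, lower.tail = FALSE)
}

#' Bias-corrected explained variance (omega squared) per time window
#'
#' For each window of a rate matrix, computes the percentage of firing-rate
#' variance attributable to cue location for each unit:
#' `omega^2 = (SS_between - df * MSE) / (SS_total + MSE) * 100`, with
#' `df = n_groups - 1` (7 for the 8 task locations). To avoid bias from
#' unequal group sizes, trials are stratified once per call by seeded random
#' subsampling to the lowest common trial count across groups, so all windows
#' share the same trials (set `per_window = TRUE` to resample per window).
#' Under the null the statistic is centered on 0 and can be negative.
#'
#' @param rate_matrix a `rate_matrix` (typically 100 ms / 50 ms grid).
#' @param cue_labels cue locations per trial; defaults to the labels carried
#'   by the rate matrix.
#' @param seed integer seed for stratification.
#' @param per_window resample the stratified trials per window?
#' @return list of class `pev_series`: `omega2` (units x windows matrix, %),
#'   `window_centers`, `df`, `stratified_trials_per_group`.
#' @export
compute_pev <- function(rate_matrix, cue_labels = NULL, seed = 1,
                        per_window = FALSE) {
  stopifnot(inherits(rate_matrix, "rate_matrix"))
  cue <- cue_labels %||% attr(rate_matrix, "cue_location_deg")
  cue <- factor(cue)
  if (any(table(cue) == 0)) stop("empty cue group")
  n_min <- min(table(cue))
  nw <- dim(rate_matrix)[3]
  seeds <- derive_seeds(seed, if (per_window) nw else 1)

  strat_idx <- function(s) {
    with_seed(s, {
      unlist(lapply(levels(cue), function(l) {
        i <- which(cue == l)
        if (length(i) > n_min) sample(i, n_min) else i
      }))
    })
  }
  idx0 <- strat_idx(seeds[1])
  om <- matrix(NA_real_, dim(rate_matrix)[2], nw,
               dimnames = list(dimnames(rate_matrix)[[2]],
                               dimnames(rate_matrix)[[3]]))
  for (w in seq_len(nw)) {
    idx <- if (per_window) strat_idx(seeds[w]) else idx0
    m <- rate_slice(rate_matrix, w)[idx, , drop = FALSE]
    om[, w] <- omega2_percent(m, droplevels(cue[idx]))
  }
  structure(list(omega2 = om,
                 window_centers = attr(rate_matrix, "window_centers"),
                 df = nlevels(cue) - 1,
                 stratified_trials_per_group = n_min),
            class = "pev_series")
}

## omega^2 (percent) for each column of trials x units matrix, grouped by g
omega2_percent <- function(m, g) {
  n <- nrow(m); k <- nlevels(g)
  df <- k - 1
  gi <- as.integer(g)
  gn <- tabulate(gi, k)
  gm <- rowsum(m, gi) / gn                     # k x units group means
  mu <- colMeans(m)
  ssb <- colSums(gn * sweep(gm, 2, mu)^2)
  sst <- colSums(sweep(m, 2, mu)^2)
  ssw <- sst - ssb
  mse <- ssw / (n - k)
  out <- (ssb - df * mse) / (sst + mse) * 100
  out[sst <= 0 & ssw <= 0] <- 0                # nothing to explain
  out
}

#' Explained-variance time course for a session
#'
#' Convenience wrapper: bins the session on the standard 100 ms / 50 ms grid
#' and computes the omega-squared series. Multi-units are excluded by
#' default, since spike sorting quality affects the variance decomposition.
#'
#' @param session a `wm_session`.
#' @param epoch epoch or `"all"` (default) for the full trial.
#' @param include_multiunits include units with `kind == "multi"`?
#' @param seed stratification seed.
#' @return A `pev_series` (units x windows), see [compute_pev()].
#' @export
session_pev <- function(session, epoch = "all", include_multiunits = FALSE,
                        seed = 1) {
  rm_ <- bin_firing_rates(session, epoch = epoch)
  if (!include_multiunits) {
    keep <- session$units$kind == "single"
    rm_ <- structure(rm_[, keep, , drop = FALSE],
                     window_centers = attr(rm_, "window_centers"),
                     window_width = attr(rm_, "window_width"),
                     window_step = attr(rm_, "window_step"),
                     zscored = attr(rm_, "zscored"),
                     cue_location_deg = attr(rm_, "cue_location_deg"),
                     epoch = attr(rm_, "epoch"),
                     class = class(rm_))
  }
  compute_pev(rm_, seed = seed)
}

#' @export
print.pev_series <- function(x, ...) {
  cat(sprintf("<pev_series> %d units x %d windows, df = %d, %d trials/group\n",
              nrow(x$omega2), ncol(x$omega2), x$df,
              x$stratified_trials_per_group))
  cat(sprintf("  mean omega^2 across units: %.2f%% (per-window range %.2f..%.2f)\n",
              mean(x$omega2), min(colMeans(x$omega2)), max(colMeans(x$omega2))))
  invisible(x)
}

#' Preferred location as a spike-count-weighted circular mean
#'
#' Computes the resultant `T = sum_j n_j exp(i theta_j) / sum_j n_j` over the
#' 8 cue angles, where `n_j` is the unit's mean delay spike count at cue
#' `theta_j`. The preferred angle is `arg(T)` in `[0, 360)` and the modulus
#' `|T|` in `[0, 1]` measures tuning strength. The estimate is flagged
#' undefined when all counts are zero or `|T|` is below tolerance.
#'
#' @param counts_by_cue named numeric vector of 8 mean spike counts; names are
#'   cue angles in degrees (defaults to the canonical 8 if unnamed).
#' @param tol modulus below which the direction is considered undefined.
#' @return list: `theta_pref` (degrees), `modulus`, `defined` (logical).
#' @export
preferred_location <- function(counts_by_cue, tol = 1e-9) {
  n <- as.numeric(counts_by_cue)
  if (length(n) != 8) stop("expected 8 per-cue mean counts")
  th <- if (!is.null(names(counts_by_cue))) as.numeric(names(counts_by_cue))
        else cue_angles()
  circ_mean_counts(n, th, tol = tol)
}

## count-weighted circular mean over arbitrary represented cue angles
circ_mean_counts <- function(n, th, tol = 1e-9) {
  if (any(n < 0)) stop("mean counts must be non-negative")
  if (sum(n) == 0)
    return(list(theta_pref = NA_real_, modulus = 0, defined = FALSE))
  z <- sum(n * exp(1i * th * pi / 180)) / sum(n)
  mod <- Mod(z)
  if (mod < tol)
    return(list(theta_pref = NA_real_, modulus = mod, defined = FALSE))
  list(theta_pref = (Arg(z) * 180 / pi) %% 360, modulus = mod, defined = TRUE)
}

#' Preferred locations for every unit of a session
#'
#' @param session a `wm_session`.
#' @param epoch epoch over which spike counts are taken (default delay).
#' @return data.frame: `unit_id`, `theta_pref`, `modulus`, `defined`,
#'   `snapped_cue` (nearest of the 8 cue angles; midpoints round down).
#' @export
session_preferred_locations <- function(session, epoch = "delay") {
  cnt <- epoch_count_matrix(session, epoch)
  present <- sort(unique(session$trials$cue_location_deg))
  cue <- factor(session$trials$cue_location_deg, levels = present)
  gm <- rowsum(cnt, cue, reorder = TRUE)
  gn <- as.integer(table(cue))
  mean_cnt <- gm / gn
  res <- lapply(seq_len(ncol(cnt)), function(u) {
    pl <- circ_mean_counts(mean_cnt[, u], present)
    data.frame(unit_id = colnames(cnt)[u], theta_pref = pl$theta_pref,
               modulus = pl$modulus, defined = pl$defined)
  })
  out <- do.call(rbind, res)
  out$snapped_cue <- ifelse(out$defined, snap_to_cue(out$theta_pref), NA_real_)
  out
}

#' Laminar class from recording depth
#'
#' Depth is measured from the shallowest contact with spiking activity
#' (0 mm). Bins are half-open on the left: `[0, 0.8)` superficial,
#' `[0.8, 1.2)` middle, `>= 1.2` deep (deep recordings mostly 1.2--2.0 mm).
#'
#' @param depth_mm numeric depth(s) in millimeters, >= 0.
#' @return character vector of layer classes.
#' @export
classify_depth <- function(depth_mm) {
  if (any(depth_mm < 0)) stop("depth_mm must be >= 0")
  cut(depth_mm, c(0, 0.8, 1.2, Inf), right = FALSE,
      labels = c("superficial", "middle", "deep")) |> as.character()
}

#' Proportion of delay-selective units per cortical layer
#'
#' @param session a `wm_session`.
#' @param selectivity optional result of [test_selectivity()] (computed if
#'   missing).
#' @return data.frame: `layer`, `n_units`, `n_selective`, `proportion`.
#' @export
layer_selectivity <- function(session, selectivity = NULL) {
  sel <- selectivity %||% test_selectivity(session)
  layer <- classify_depth(session$units$depth_mm)
  sel_flag <- sel$is_selective[match(session$units$unit_id, sel$unit_id)]
  out <- do.call(rbind, lapply(c("superficial", "middle", "deep"), function(l) {
    i <- layer == l
    data.frame(layer = l, n_units = sum(i), n_selective = sum(sel_flag[i]),
               proportion = if (sum(i)) sum(sel_flag[i]) / sum(i) else NA_real_)
  }))
  out
}

#' Paired per-bin comparison of two epochs with Benjamini-Hochberg correction
#'
#' Utility for testing, bin by bin, whether (for example) delay activity
#' exceeds fixation activity: a paired t-test per bin with BH/FDR adjustment
#' across bins.
#'
#' @param x,y numeric matrices, observations x bins, paired by row.
#' @param q FDR level (default 0.05).
#' @param alternative passed to [stats::t.test()]-style comparison
#'   ("two.sided", "greater", "less") of `x - y`.
#' @return data.frame per bin: `t`, `p`, `p_adj`, `significant`.
#' @export
paired_bin_test <- function(x, y, q = 0.05, alternative = "two.sided") {
  stopifnot(all(dim(x) == dim(y)))
  d <- x - y
  n <- nrow(d)
  mu <- colMeans(d)
  se <- apply(d, 2, sd) / sqrt(n)
  t <- mu / se
  p <- switch(alternative,
              two.sided = 2 * pt(abs(t), n - 1, lower.tail = FALSE),
              greater = pt(t, n - 1, lower.tail = FALSE),
              less = pt(t, n - 1))
  p_adj <- p.adjust(p, method = "BH")
  data.frame(bin = seq_along(t), t = t, p = p, p_adj = p_adj,
             significant = p_adj < q)
}
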