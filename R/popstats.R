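#' Construct pseudo-populations by within-condition trial shuffling
#'
#' For each replicate, every unit's single-trial responses (entire spike
#' trains) are independently permuted across trials of the same stimulus
#' condition, preserving each unit's per-condition response multiset and
#' every trial's stimulus identity while destroying within-trial (noise)
#' correlations between units.
#'
#' @param session a `wm_session` with >= 2 trials per condition.
#' @param n_replicates number of pseudo-populations (default 100).
#' @param seed integer seed; replicate k is reproducible given the seed.
#' @return list of `wm_session` pseudo-population replicates.
#' @export
build_pseudopopulations <- function(session, n_replicates = 100, seed = 1) {
  stopifnot(inherits(session, "wm_session"))
  cue <- session$trials$cue_location_deg
  if (any(table(cue) < 2)) stop("every condition needs at least 2 trials")
  seeds <- derive_seeds(seed, n_replicates)
  trial_ids <- session$trials$trial_id
  cond_trials <- split(trial_ids, cue)
  sp <- session$spikes
  lapply(seq_len(n_replicates), function(r) {
    new_tid <- sp$trial_id
    with_seed(seeds[r], {
      for (u in session$units$unit_id) {
        iu <- which(sp$unit_id == u)
        for (ct in cond_trials) {
          if (length(ct) < 2) next
          perm <- setNames(sample(ct), ct)
          sel <- iu[sp$trial_id[iu] %in% ct]
          new_tid[sel] <- perm[sp$trial_id[sel]]
        }
      }
    })
    sp2 <- sp
    sp2$trial_id <- unname(new_tid)
    wm_session(session$units, session$trials, sp2,
               session_id = sprintf("%s_pseudo%03d", session$session_id, r),
               epochs = session$epochs,
               provenance = sprintf("pseudo-population replicate %d of %s",
                                    r, session$session_id))
  })
}

#' Compare simultaneous and pseudo-population decoding
#'
#' Runs the same leave-one-out decoder (train = test window) on the source
#' session and on every pseudo-population replicate. Per window, the
#' simultaneous accuracy is compared to the empirical distribution of
#' replicate accuracies (two-sided rank test, add-one convention) with
#' Bonferroni correction across windows; a Wilcoxon signed-rank test across
#' windows compares the replicate-mean accuracy trace to the simultaneous
#' one; per-epoch mean differences (cue, delay, response) summarize the
#' effect.
#'
#' @param session source `wm_session`.
#' @param pseudos list from [build_pseudopopulations()].
#' @param scheme,pair,config decoder settings, see [decode_trace()].
#' @param window_width,window_step grid for the rate matrices.
#' @param span span to decode (default cue onset to end of response).
#' @param epochs named list of epoch intervals for the per-epoch summary
#'   (defaults to the session's cue/delay/response epochs).
#' @return list of class `decoding_comparison`: `simultaneous` (accuracy
#'   trace), `pseudo` (replicates x windows), `per_window` (data.frame with
#'   Bonferroni-corrected significance), `wilcoxon_p`, `epoch_diff` (mean
#'   pseudo - simultaneous per epoch), `window_centers`.
#' @export
compare_decoding <- function(session, pseudos, scheme = "8way",
                             pair = c(0, 180), config = decoder_config(),
                             window_width = 0.100, window_step = 0.050,
                             span = NULL, epochs = NULL) {
  span <- span %||% c(session$epochs$cue[1], session$epochs$response[2])
  epochs <- epochs %||% session$epochs[c("cue", "delay", "response")]
  rm0 <- bin_firing_rates(session, window_width, window_step, epoch = span,
                          zscore = FALSE)
  simult <- decode_trace(rm0, scheme = scheme, pair = pair, config = config)
  ps <- t(vapply(pseudos, function(p) {
    rmp <- bin_firing_rates(p, window_width, window_step, epoch = span,
                            zscore = FALSE)
    decode_trace(rmp, scheme = scheme, pair = pair, config = config)
  }, numeric(length(simult))))
  nw <- length(simult)
  nrep <- nrow(ps)
  ## two-sided rank position of the simultaneous value in the replicate
  ## distribution, add-one convention, Bonferroni across windows
  p_lo <- (1 + colSums(ps <= matrix(simult, nrep, nw, byrow = TRUE))) / (1 + nrep)
  p_hi <- (1 + colSums(ps >= matrix(simult, nrep, nw, byrow = TRUE))) / (1 + nrep)
  p_two <- pmin(1, 2 * pmin(p_lo, p_hi))
  per_window <- data.frame(window_center = as.numeric(names(simult)),
                           simultaneous = unname(simult),
                           pseudo_mean = colMeans(ps), p = p_two,
                           p_bonf = pmin(1, p_two * nw),
                           significant = pmin(1, p_two * nw) < 0.05)
  dvec <- colMeans(ps) - simult
  wil <- if (sd(dvec) > 0) wilcox.test(dvec, exact = FALSE)$p.value else 1
  ctr <- as.numeric(names(simult))
  epoch_diff <- vapply(epochs, function(iv) {
    w <- ctr >= iv[1] - 1e-9 & ctr < iv[2] - 1e-9
    if (!any(w)) return(NA_real_)
    mean(dvec[w])
  }, numeric(1))
  structure(list(simultaneous = simult, pseudo = ps, per_window = per_window,
                 wilcoxon_p = wil, epoch_diff = epoch_diff,
                 window_centers = ctr),
            class = "decoding_comparison")
}

#' @export
print.decoding_comparison <- function(x, ...) {
  cat(sprintf("<decoding_comparison> %d windows, %d pseudo replicates\n",
              length(x$simultaneous), nrow(x$pseudo)))
  cat(sprintf("  mean accuracy: simultaneous %.3f, pseudo %.3f; Wilcoxon p = %.3g\n",
              mean(x$simultaneous), mean(x$pseudo), x$wilcoxon_p))
  cat("  epoch mean difference (pseudo - simultaneous):\n")
  print(round(x$epoch_diff, 4))
  invisible(x)
}
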