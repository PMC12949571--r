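test_that("pseudo-populations conserve per-unit condition marginals exactly", {
  sim <- diametric_sim(n_units = 5, n_per_loc = 6, seed = 17,
                       shared_gain_sd = 0.4)
  s <- sim$session
  ps <- build_pseudopopulations(s, n_replicates = 3, seed = 2)
  for (p in ps) {
    expect_identical(p$trials, s$trials)
    for (u in s$units$unit_id) {
      for (cu in unique(s$trials$cue_location_deg)) {
        tid <- s$trials$trial_id[s$trials$cue_location_deg == cu]
        src <- sort(table(s$spikes$trial_id[s$spikes$unit_id == u &
                                            s$spikes$trial_id %in% tid]))
        new <- sort(table(p$spikes$trial_id[p$spikes$unit_id == u &
                                            p$spikes$trial_id %in% tid]))
        ## multiset of per-trial spike counts is preserved
        expect_identical(as.integer(src), as.integer(new))
      }
    }
  }
  ## seeded determinism
  ps2 <- build_pseudopopulations(s, n_replicates = 3, seed = 2)
  expect_identical(ps[[2]]$spikes, ps2[[2]]$spikes)
})

test_that("shuffling destroys within-trial noise correlations", {
  sim <- diametric_sim(n_units = 10, n_per_loc = 60, seed = 29,
                       shared_gain_sd = 0.5)
  mean_r <- function(s) {
    cnt <- wmoff:::epoch_count_matrix(s)
    cue <- s$trials$cue_location_deg
    resid <- cnt
    for (cu in unique(cue)) resid[cue == cu, ] <- scale(cnt[cue == cu, ],
                                                        scale = FALSE)
    cm <- cor(resid)
    mean(cm[upper.tri(cm)])
  }
  r_before <- mean_r(sim$session)
  ps <- build_pseudopopulations(sim$session, n_replicates = 1, seed = 7)
  r_after <- mean_r(ps[[1]])
  expect_gt(r_before, 0.1)
  expect_lt(abs(r_after), 3 / sqrt(choose(10, 2) * 120))
})

test_that("identity pseudo-populations yield exactly zero differences", {
  sim <- diametric_sim(n_units = 6, n_per_loc = 4, seed = 5)
  fake_pseudos <- replicate(4, sim$session, simplify = FALSE)
  cmp <- compare_decoding(sim$session, fake_pseudos, scheme = "binary",
                          pair = c(90, 270), window_width = 0.5,
                          window_step = 0.5,
                          span = sim$session$epochs$delay,
                          epochs = sim$session$epochs["delay"])
  expect_true(all(cmp$pseudo[1, ] == cmp$simultaneous))
  expect_equal(unname(cmp$epoch_diff["delay"]), 0)
  expect_false(any(cmp$per_window$significant))
})

test_that("beta mixture model selection recovers the generating model", {
  ## AIC/BIC arithmetic is wired to the stored log-likelihoods
  x <- with_seed_vec(101, rbeta(2000, 2, 5))
  fit1 <- fit_beta_mixture(x, n_restarts = 4, seed = 1)
  expect_equal(fit1$dAIC,
               (2 * 5 - 2 * fit1$two$loglik) - (2 * 2 - 2 * fit1$one$loglik))
  expect_equal(fit1$dBIC,
               (5 * log(2000) - 2 * fit1$two$loglik) -
                 (2 * log(2000) - 2 * fit1$one$loglik))
  ## single-beta data: BIC prefers one state
  expect_gt(fit1$dBIC, 0)
  ## one-component MLE agrees with fitdistrplus
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    fd <- fitdistrplus::fitdist(x, "beta")
    expect_equal(fit1$one$a, unname(fd$estimate["shape1"]), tolerance = 1e-3)
    expect_equal(fit1$one$b, unname(fd$estimate["shape2"]), tolerance = 1e-3)
  }

  ## clearly bimodal data: AIC prefers two states, parameters sane
  y <- with_seed_vec(7, c(rbeta(1000, 20, 4), rbeta(1000, 4, 20)))
  fit2 <- fit_beta_mixture(y, n_restarts = 6, seed = 2)
  expect_lt(fit2$dAIC, 0)
  expect_lt(fit2$dBIC, 0)
  expect_true(fit2$two$w > 0.3 && fit2$two$w < 0.7)

  ## EM never decreases the log-likelihood
  expect_true(all(diff(fit2$two$ll_trace) > -1e-6))

  expect_error(fit_beta_mixture(runif(10)), "at least 20")
  expect_error(fit_beta_mixture(rep(0.5, 50)), "degenerate")
})

test_that("Welch PSD localizes known rhythms and conserves power", {
  ## 2 Hz square wave sampled at 100 Hz: global PSD maximum at the 2 Hz bin
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  sq <- as.numeric((t %% 0.5) < 0.25)
  w <- welch_psd(sq, fs = fs)
  expect_equal(max(w$freq), 50)
  expect_equal(w$freq[which.max(w$psd)], 2, tolerance = 0.11)

  ## Parseval: integral of the PSD matches the variance within ~1%
  x <- with_seed_vec(3, rnorm(20000))
  wx <- welch_psd(x, fs = fs)
  df <- wx$freq[2] - wx$freq[1]
  expect_equal(sum(wx$psd) * df, var(x), tolerance = 0.02)

  ## constant series: mean-centered zeros, flat zero spectrum
  wc <- welch_psd(rep(1, 1000), fs = fs)
  expect_true(all(wc$psd < 1e-20))

  expect_error(welch_psd(rnorm(50), fs = fs), "shorter")
})

test_that("state PSD alternating on/off shows the alternation frequency", {
  ## 0.25 s on / 0.25 s off alternation over 4 s trials = 2 Hz rhythm
  nt <- 6
  centers <- seq(0.05, 4, by = 0.05)
  states <- matrix("off", nt, length(centers))
  states[, ((ceiling(centers / 0.25) %% 2) == 1)] <- "on"
  st <- structure(list(states = states, z = NULL,
                       on_clusters = data.frame(), off_runs = data.frame(),
                       trial_ids = sprintf("t%03d", 1:nt),
                       window_centers = centers),
                  class = "wm_states")
  ps <- state_psd(st)
  expect_equal(max(ps$freq), 50)
  pk <- ps$freq[ps$freq > 0.5][which.max(ps$psd$on[ps$freq > 0.5])]
  expect_equal(pk, 2, tolerance = 0.15)
  expect_true(all(ps$psd$on >= 0))
})

test_that("reaction-time state effects bootstrap over sessions", {
  mk <- function(sid, rt_on, rt_off, n = 20, seed = 1) {
    nw <- 10
    states <- matrix("neither", n, nw)
    on_tr <- seq_len(n) %% 2 == 0
    states[on_tr, nw] <- "on"; states[!on_tr, nw] <- "off"
    st <- structure(list(states = states, z = NULL,
                         on_clusters = data.frame(), off_runs = data.frame(),
                         trial_ids = sprintf("t%03d", 1:n),
                         window_centers = seq(0.55, by = 0.05, length.out = nw)),
                    class = "wm_states")
    tr <- trials_df(rep(c(90, 270), n / 2),
                    rt = ifelse(on_tr, rt_on, rt_off))
    un <- units_df(1)
    ses <- wm_session(un, tr, data.frame(unit_id = character(0),
                                         trial_id = character(0),
                                         time_s = numeric(0)),
                      session_id = sid)
    list(session = ses, states = st)
  }
  ## identical RTs: every beta 0, all bootstrap means >= 0 -> p = 1
  eq <- rt_state_effect(list(mk("a", 250, 250), mk("b", 250, 250)),
                        B = 500, seed = 3)
  expect_true(all(eq$beta == 0))
  expect_equal(eq$p, 1)
  ## RT_on = RT_off - 50 in every session: all bootstrap means -50 -> p = 0
  fast <- rt_state_effect(list(mk("a", 200, 250), mk("b", 200, 250),
                               mk("c", 200, 250)), B = 500, seed = 3)
  expect_true(all(abs(fast$beta + 50) < 1e-9))
  expect_equal(fast$p, 0)
  ## determinism
  fast2 <- rt_state_effect(list(mk("a", 200, 250), mk("b", 200, 250),
                                mk("c", 200, 250)), B = 500, seed = 3)
  expect_identical(fast$p, fast2$p)
  expect_identical(fast$boot_mean, fast2$boot_mean)
})

test_that("state counts by outcome reproduce a three-way ANOVA oracle", {
  ## build sessions whose last-0.5 s state segments are fully controlled
  mk_sess <- function(sid, pattern, seed) {
    ## pattern: named mean counts for correct/error x pref/nonpref x on/off
    nw <- 60
    centers <- seq(0.525, by = 0.05, length.out = nw)
    n_tr <- 32
    cues <- rep(c(90, 270), n_tr / 2)
    correct <- rep(c(TRUE, TRUE, FALSE, FALSE), n_tr / 4)
    states <- matrix("neither", n_tr, nw)
    idx_last <- which(centers >= max(centers) - 0.5 + 1e-9)
    withr::with_seed(seed, {
      for (i in seq_len(n_tr)) {
        pref <- if (cues[i] == 90) "preferred" else "nonpreferred"
        oc <- if (correct[i]) "correct" else "error"
        non <- pattern[[paste(oc, pref, "on", sep = ".")]] +
          stats::rbinom(1, 1, 0.3)   # session-to-session noise
        noff <- pattern[[paste(oc, pref, "off", sep = ".")]]
        ## single-window segments separated by gaps, inside the tail window
        pos <- idx_last[1]
        for (k in seq_len(non)) { states[i, pos] <- "on"; pos <- pos + 2 }
        for (k in seq_len(noff)) { states[i, pos] <- "off"; pos <- pos + 2 }
        stopifnot(pos - 2 <= nw)
      }
    })
    st <- structure(list(states = states, z = NULL,
                         on_clusters = data.frame(), off_runs = data.frame(),
                         trial_ids = sprintf("t%03d", seq_len(n_tr)),
                         window_centers = centers),
                    class = "wm_states")
    ## confidence ranks 90 as preferred, 270 as least preferred
    post <- matrix(0.5, n_tr, 4)
    post[cues == 90, ] <- 0.9
    conf <- structure(list(posterior = post, correct = post > 0.5,
                           trial_ids = sprintf("t%03d", seq_len(n_tr)),
                           labels = cues, pair = c(90, 270),
                           window_centers = centers[1:4],
                           trial_index = seq_len(n_tr)),
                      class = "confidence_series")
    list(session_id = sid, states = st, confidence = conf,
         trials = trials_df(cues, correct = correct))
  }
  ## crossover: on states frequent for preferred-correct and nonpref-error
  pattern <- list(correct.preferred.on = 2, correct.preferred.off = 0,
                  correct.nonpreferred.on = 0, correct.nonpreferred.off = 2,
                  error.preferred.on = 0, error.preferred.off = 2,
                  error.nonpreferred.on = 2, error.nonpreferred.off = 0)
  dat <- lapply(1:5, function(i) mk_sess(paste0("s", i), pattern, seed = i))
  res <- state_counts_by_outcome(dat)
  tab <- res$anova_table
  i3 <- grep("outcome:preference:state", rownames(tab))
  expect_lt(tab[i3, "Pr(>F)"], 0.01)

  ## oracle: explicit balanced three-way sums of squares on the same cells
  cc <- res$cells
  y <- cc$mean_count
  A <- factor(cc$outcome); B <- factor(cc$preference); C <- factor(cc$state)
  gm <- mean(y)
  eff <- function(f) tapply(y, f, mean) - gm
  ssA3 <- local({
    cellm <- tapply(y, list(A, B, C), mean)
    mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mC <- tapply(y, C, mean)
    mAB <- tapply(y, list(A, B), mean); mAC <- tapply(y, list(A, C), mean)
    mBC <- tapply(y, list(B, C), mean)
    s <- 0
    for (a in 1:2) for (b in 1:2) for (cix in 1:2) {
      d <- cellm[a, b, cix] - mAB[a, b] - mAC[a, cix] - mBC[b, cix] +
        mA[a] + mB[b] + mC[cix] - gm
      s <- s + 5 * d^2   # 5 sessions per cell
    }
    s
  })
  expect_equal(tab[i3, "Sum Sq"], unname(ssA3), tolerance = 1e-8)

  ## flat pattern with session noise: interaction far from significant
  flat <- as.list(setNames(rep(1, 8), names(pattern)))
  dat0 <- lapply(1:5, function(i) mk_sess(paste0("s", i), flat, seed = 10 + i))
  res0 <- state_counts_by_outcome(dat0)
  tab0 <- res0$anova_table
  expect_gt(tab0[grep("outcome:preference:state", rownames(tab0)), "Pr(>F)"],
            0.2)
  expect_true(all(res0$cells$mean_count >= 0))
})
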