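test_that("state labeling follows the z and cluster-mass rules", {
  nw <- 12
  ## z == 0 everywhere: no on clusters; one off run spanning the delay
  cs0 <- make_confidence(matrix(0.5, 4, nw))
  nl0 <- make_null(4, nw, mean = 0.5, sd = 0.1, cluster_masses = 5)
  st0 <- label_states(cs0, nl0)
  expect_true(all(st0$states == "off"))

  ## z == 5 with mass over the null 95th percentile: all on, no off
  cs5 <- make_confidence(matrix(0.5 + 5 * 0.1, 4, nw))
  st5 <- label_states(cs5, nl0)   # mass 60 >> null masses of 5
  expect_true(all(st5$states == "on"))
  expect_equal(nrow(st5$off_runs), 0)

  ## a 2-window z = 2 excursion whose mass (4) is below the null 95th
  ## percentile (5) stays unlabeled
  post <- matrix(0.5, 1, nw)
  post[1, 6:7] <- 0.5 + 2 * 0.1
  stx <- label_states(make_confidence(post), make_null(1, nw, sd = 0.1,
                                                       cluster_masses = 5))
  expect_true(all(stx$states[1, 6:7] == "neither"))
  expect_true(all(stx$states[1, c(1:5, 8:12)] == "off"))

  ## the same excursion passes when the null masses are small
  sty <- label_states(make_confidence(post), make_null(1, nw, sd = 0.1,
                                                       cluster_masses = 0.5))
  expect_true(all(sty$states[1, 6:7] == "on"))

  ## off runs must last >= 3 windows
  post2 <- matrix(0.5 + 0.1, 1, nw)   # z = 1: neither
  post2[1, 3:4] <- 0.5                # 2-window dip: too short
  post2[1, 8:11] <- 0.5               # 4-window dip: off
  st2 <- label_states(make_confidence(post2), make_null(1, nw, sd = 0.1,
                                                        cluster_masses = 50))
  expect_true(all(st2$states[1, 3:4] == "neither"))
  expect_true(all(st2$states[1, 8:11] == "off"))

  ## undefined z (null SD 0) breaks runs and stays neither
  nl_bad <- make_null(1, nw, sd = 0.1, cluster_masses = 50)
  nl_bad$sd[1, 6] <- 0
  st3 <- label_states(make_confidence(matrix(0.5, 1, nw)), nl_bad)
  expect_equal(unname(st3$states[1, 6]), "neither")
  expect_true(all(st3$states[1, -6] == "off"))
})

test_that("the state partition is exhaustive, exclusive and monotone in z_on", {
  withr::with_seed(11, {
    for (i in 1:10) {
      nw <- 20
      post <- matrix(0.5 + rnorm(nw, 0.1, 0.25) * 0.2, 1, nw)
      cs <- make_confidence(post)
      nl <- make_null(1, nw, sd = 0.2, cluster_masses = runif(20, 0, 4))
      st_lo <- label_states(cs, nl, z_on = 1.64)
      st_hi <- label_states(cs, nl, z_on = 2.5)
      expect_true(all(st_lo$states %in% c("on", "off", "neither")))
      ## raising z_on never creates a new on window
      expect_true(all(st_hi$states[st_lo$states != "on"] != "on"))
    }
  })
})

test_that("null confidence has the expected shape and chance center", {
  sim <- diametric_sim(n_units = 6, n_per_loc = 8, seed = 3)
  rm_ <- bin_firing_rates(sim$session, 0.5, 0.5, epoch = "delay")
  nl <- build_null(rm_, pair = c(90, 270), n_shuffles = 50, seed = 9)
  expect_equal(dim(nl$null), c(16, dim(rm_)[3], 50))
  expect_equal(dim(nl$cluster_null), c(16, 50))
  ## shuffled-label confidence is centered on chance
  expect_lt(abs(mean(nl$mean) - 0.5), 0.05)
})

test_that("ground-truth states mark windows inside off intervals", {
  sch <- state_schedule(off_rate_per_s = 0.5, off_duration = 0.5,
                        off_tuning_gain = 0)
  sim <- diametric_sim(n_units = 3, n_per_loc = 5, seed = 8, schedule = sch)
  gt <- ground_truth_states(sim)
  iv <- sim$ground_truth$off_intervals
  expect_gt(nrow(iv), 0)
  for (r in seq_len(min(5, nrow(iv)))) {
    t <- match(iv$trial_id[r], gt$trial_ids)
    inside <- gt$window_centers >= iv$start[r] & gt$window_centers < iv$end[r]
    expect_true(all(gt$states[t, inside] == "off"))
  }
})

test_that("state tuning aligns raw curves and debiases null units", {
  ## untuned homogeneous Poisson units: debiased curves average ~ 0
  sim <- simulate_tuned_session(
    n_units = 30, n_trials_per_location = 6, seed = 23,
    unit_specs = tuned_unit_specs(30, baseline_rate = 8, delay_gain = 1,
                                  kappa = 0))
  gt <- ground_truth_states(sim)   # no schedule: all windows "on"
  ## give every trial alternating on/off halves so both states exist
  half <- ncol(gt$states) %/% 2
  gt$states[, seq_len(half)] <- "off"
  tun <- state_tuning(sim$session, gt, n_shuffles = 300, seed = 4)
  ## raw aligned curves peak at the center index by construction
  sums <- tun$on + tun$off
  expect_true(all(apply(sums, 2, which.max) == 5))
  ## debiased expectation ~ 0 at every position
  m_on <- rowMeans(tun$on_debiased)
  se <- apply(tun$on_debiased, 1, sd) / sqrt(30)
  expect_true(all(abs(m_on) < 3.5 * se + 1e-8))
})

test_that("state tuning recovers an imposed off gain", {
  ## off state scales the tuned component by 0.25: off/on depth ratio
  ## should recover it (ground-truth labels isolate the tuning estimator)
  n <- 60
  sch <- state_schedule(off_rate_per_s = 0.4, off_duration = 0.6,
                        off_tuning_gain = 0.25)
  sim <- simulate_tuned_session(
    n_units = n, n_trials_per_location = 10, seed = 91,
    unit_specs = tuned_unit_specs(n, baseline_rate = 8, delay_gain = 5,
                                  kappa = 3,
                                  preferred_angle = rep(cue_angles(),
                                                        length.out = n)),
    schedule = sch)
  tun <- state_tuning(sim$session, ground_truth_states(sim),
                      n_shuffles = 200, seed = 6)
  ratio <- mean(tun$depth_off, na.rm = TRUE) / mean(tun$depth_on, na.rm = TRUE)
  expect_lt(abs(ratio - 0.25), 0.12)
})

test_that("population rate traces respect state conditioning", {
  ## single unit, every window "on": state trace equals the all-trial mean
  sim <- diametric_sim(n_units = 1, n_per_loc = 5, seed = 3)
  gt <- ground_truth_states(sim)
  pr <- population_rate_by_state(sim$session, gt,
                                 preferred = setNames(90, "u001"))
  expect_equal(pr$traces["on", ], pr$traces["all", ])
  expect_true(all(is.na(pr$traces["off", ])))

  ## suppressed tuned component: on-rate exceeds off-rate at preferred cue
  sch <- state_schedule(off_rate_per_s = 0.4, off_duration = 0.6,
                        off_tuning_gain = 0.2)
  sim2 <- diametric_sim(n_units = 20, n_per_loc = 10, seed = 41,
                        schedule = sch, gain = 5, kappa = 3)
  pr2 <- population_rate_by_state(sim2$session, ground_truth_states(sim2))
  d <- pr2$per_unit$on - pr2$per_unit$off
  d <- d[is.finite(d)]
  tt <- t.test(d, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("cross-areal evaluation matches within-area analysis for self", {
  sch <- state_schedule(off_rate_per_s = 0.4, off_duration = 0.6,
                        off_tuning_gain = 0.2)
  sim <- diametric_sim(n_units = 15, n_per_loc = 8, seed = 52, schedule = sch)
  gt <- ground_truth_states(sim)
  ca <- cross_areal_states(sim$session, gt, check_min_units = FALSE,
                           n_shuffles = 100, seed = 2)
  tun <- state_tuning(sim$session, gt, n_shuffles = 100, seed = 2)
  expect_equal(ca$tuning$depth_on, tun$depth_on)
  expect_equal(nrow(ca$per_unit), 15)
  expect_equal(ca$per_unit$depth_change_pct,
               100 * (1 - tun$depth_off / tun$depth_on))
  expect_equal(ca$depth_change_pct,
               100 * (1 - mean(tun$depth_off, na.rm = TRUE) /
                        mean(tun$depth_on, na.rm = TRUE)))
  expect_error(cross_areal_states(sim$session, gt), ">= 80")
})

test_that("shared off states transfer across areas, independent ones do not", {
  sch <- state_schedule(off_rate_per_s = 0.4, off_duration = 0.6,
                        off_tuning_gain = 0.1)
  specs <- tuned_unit_specs(30, baseline_rate = 8, delay_gain = 5, kappa = 3,
                            preferred_angle = rep(c(90, 270), 15))
  simA <- simulate_tuned_session(30, 10, unit_specs = specs, schedule = sch,
                                 seed = 61, cue_locations = c(90, 270),
                                 area = "PFC")
  ## area B shares A's trials and off intervals (globally coordinated states)
  simB_shared <- simulate_tuned_session(30, 10, unit_specs = specs,
                                        schedule = sch, seed = 62,
                                        cue_locations = c(90, 270),
                                        area = "PPC",
                                        trials = simA$session$trials,
                                        off_intervals = simA$ground_truth$off_intervals)
  ## area C has its own independent schedule
  simC_indep <- simulate_tuned_session(30, 10, unit_specs = specs,
                                       schedule = sch, seed = 63,
                                       cue_locations = c(90, 270),
                                       area = "PPC",
                                       trials = simA$session$trials)
  gtA <- ground_truth_states(simA)
  caB <- cross_areal_states(simB_shared$session, gtA,
                            check_min_units = FALSE, n_shuffles = 100, seed = 3)
  caC <- cross_areal_states(simC_indep$session, gtA,
                            check_min_units = FALSE, n_shuffles = 100, seed = 3)
  expect_gt(caB$depth_change_pct, 50)     # strong transfer when shared
  expect_lt(abs(caC$depth_change_pct), 25)  # none when independent
})
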