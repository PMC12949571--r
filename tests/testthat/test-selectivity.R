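test_that("selectivity requires both the ANOVA and the rate criterion", {
  ## all units identical across locations -> none selective
  flat <- matrix(5, 3, 8)
  s_flat <- regular_session(flat, trials_per_loc = 3)
  sel <- test_selectivity(s_flat)
  expect_false(any(sel$is_selective))

  ## 10 sp/s at one location, 0 elsewhere -> selective; the oracle is the
  ## textbook one-way ANOVA via stats::aov on the same per-trial rates
  rates <- rbind(c(10, rep(0, 7)),   # strong, passes both criteria
                 c(1, rep(0, 7)))    # tuned but sub-threshold rate
  s <- regular_session(rates, trials_per_loc = 10)
  sel <- test_selectivity(s)
  expect_true(sel$is_selective[1])
  expect_false(sel$is_selective[2])     # rate criterion gate
  expect_lt(sel$p_value[2], 0.05)       # still ANOVA-significant

  cnt <- wmoff:::epoch_count_matrix(s) / 3
  cue <- factor(s$trials$cue_location_deg)
  p_oracle <- summary(aov(cnt[, 1] ~ cue))[[1]][["Pr(>F)"]][1]
  expect_equal(sel$p_value[1], p_oracle, tolerance = 1e-12)

  expect_error(test_selectivity(regular_session(flat, trials_per_loc = 1)),
               "fewer than 2 trials")
})

test_that("omega squared reproduces hand-computed ANOVA arithmetic", {
  ## 8 groups each {1, 3}: SS_between 0, MSE 2, SS_total 16
  ## -> (0 - 7*2) / (16 + 2) * 100 = -77.78
  vals <- array(rep(c(1, 3), times = 8), dim = c(16, 1, 1))
  rm_ <- make_rate_matrix(vals, cues = rep(cue_angles(), each = 2))
  pev <- compute_pev(rm_, seed = 1)
  expect_equal(pev$df, 7)
  expect_equal(unname(pev$omega2[1, 1]), -700 / 9, tolerance = 1e-10)

  ## zero within-group variance, distinct means -> 100
  vals2 <- array(rep(1:8, each = 2), dim = c(16, 1, 1))
  rm2 <- make_rate_matrix(vals2, cues = rep(cue_angles(), each = 2))
  expect_equal(unname(compute_pev(rm2, seed = 1)$omega2[1, 1]), 100)

  ## degenerate: no variance at all -> 0 by convention
  vals3 <- array(2, dim = c(16, 1, 1))
  rm3 <- make_rate_matrix(vals3, cues = rep(cue_angles(), each = 2))
  expect_equal(unname(compute_pev(rm3, seed = 1)$omega2[1, 1]), 0)
})

test_that("omega squared matches an independent sums-of-squares oracle", {
  ## independent oracle: SS terms from stats::aov's decomposition
  withr::with_seed(77, {
    for (rep_ in 1:5) {
      n_per <- sample(3:6, 1)
      vals <- array(rnorm(8 * n_per * 2 * 4, mean = 10, sd = 3),
                    dim = c(8 * n_per, 2, 4))
      cues <- rep(cue_angles(), each = n_per)
      rm_ <- make_rate_matrix(vals, cues = cues)
      pev <- compute_pev(rm_, seed = 3)
      for (u in 1:2) for (w in 1:4) {
        y <- vals[, u, w]; g <- factor(cues)
        tab <- summary(aov(y ~ g))[[1]]
        ssb <- tab["g", "Sum Sq"]; ssw <- tab["Residuals", "Sum Sq"]
        mse <- tab["Residuals", "Mean Sq"]
        oracle <- (ssb - 7 * mse) / (ssb + ssw + mse) * 100
        expect_equal(unname(pev$omega2[u, w]), oracle, tolerance = 1e-10)
      }
    }
  })
})

test_that("omega squared is label-permutation unbiased and relabel-invariant", {
  ## under the null, the bias-corrected statistic is centered on 0
  withr::with_seed(13, {
    oms <- replicate(300, {
      vals <- array(rnorm(48, 10, 2), dim = c(48, 1, 1))
      rm_ <- make_rate_matrix(vals, cues = sample(rep(cue_angles(), 6)))
      compute_pev(rm_, seed = 1)$omega2[1, 1]
    })
  })
  expect_lt(abs(mean(oms)), 3 * sd(oms) / sqrt(length(oms)))

  ## permuting which group gets which label leaves omega^2 unchanged
  vals <- array(rnorm(24, 8, 2), dim = c(24, 1, 1))
  cues <- rep(cue_angles(), 3)
  om1 <- compute_pev(make_rate_matrix(vals, cues), seed = 2)$omega2[1, 1]
  remap <- setNames(sample(cue_angles()), cue_angles())
  om2 <- compute_pev(make_rate_matrix(vals, unname(remap[as.character(cues)])),
                     seed = 2)$omega2[1, 1]
  expect_equal(om1, om2, tolerance = 1e-12)
})

test_that("stratification balances unequal group sizes", {
  cues <- c(rep(cue_angles(), 3), rep(0, 4))   # location 0 over-represented
  vals <- array(rnorm(length(cues), 5, 1), dim = c(length(cues), 1, 2))
  pev <- compute_pev(make_rate_matrix(vals, cues), seed = 6)
  expect_equal(pev$stratified_trials_per_group, 3)
})

test_that("preferred location follows the complex resultant", {
  one_hot <- setNames(c(0, 0, 5, 0, 0, 0, 0, 0), cue_angles())
  pl <- preferred_location(one_hot)
  expect_equal(pl$theta_pref, 90)
  expect_equal(pl$modulus, 1)

  equal <- setNames(rep(2, 8), cue_angles())
  expect_false(preferred_location(equal)$defined)
  expect_false(preferred_location(setNames(rep(0, 8), cue_angles()))$defined)

  mixed <- setNames(c(3, 0, 1, 0, 0, 0, 0, 0), cue_angles())
  pl2 <- preferred_location(mixed)
  expect_equal(pl2$theta_pref, atan2(1, 3) * 180 / pi, tolerance = 1e-10)
  expect_equal(pl2$modulus, sqrt(10) / 4, tolerance = 1e-12)
})

test_that("preferred location is rotation-equivariant", {
  withr::with_seed(4, {
    for (i in 1:20) {
      n <- runif(8, 0, 5)
      base <- preferred_location(setNames(n, cue_angles()))
      shift <- sample(0:7, 1) * 45
      rot <- preferred_location(setNames(n, (cue_angles() + shift) %% 360))
      if (base$defined) {
        expect_equal(circ_dist_deg(rot$theta_pref,
                                   (base$theta_pref + shift) %% 360), 0,
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("depth bins are half-open and guarded", {
  expect_identical(classify_depth(c(0, 0.79, 0.8, 1.19, 1.2, 1.5, 2.0)),
                   c("superficial", "superficial", "middle", "middle",
                     "deep", "deep", "deep"))
  expect_error(classify_depth(-0.1), ">= 0")
  ## layer-wise selective proportions add up
  sim <- diametric_sim(n_units = 10, n_per_loc = 3, seed = 2)
  ls <- layer_selectivity(sim$session,
                          test_selectivity(sim$session, epoch = "delay"))
  expect_equal(sum(ls$n_units), 10)
  expect_true(all(ls$proportion >= 0 & ls$proportion <= 1, na.rm = TRUE))
})

test_that("session-level PEV excludes multi-units by default", {
  sim <- simulate_tuned_session(
    n_units = 6, n_trials_per_location = 2, seed = 12,
    unit_specs = tuned_unit_specs(6, baseline_rate = 5, delay_gain = 3,
                                  kind = c("single", "multi")))
  pv <- session_pev(sim$session, epoch = "delay")
  expect_equal(nrow(pv$omega2), 3)
  pv_all <- session_pev(sim$session, epoch = "delay",
                        include_multiunits = TRUE)
  expect_equal(nrow(pv_all$omega2), 6)
})

test_that("snapping picks the nearest cue and rounds midpoints down", {
  expect_equal(snap_to_cue(c(10, 44, 23, 350)), c(0, 45, 45, 0))
  ## exact midpoints resolve to the smaller of the two tied cue angles
  expect_equal(snap_to_cue(22.5), 0)
  expect_equal(snap_to_cue(337.5), 0)
  expect_equal(snap_to_cue(67.5), 45)
})

test_that("paired bin test flags elevated bins with BH control", {
  withr::with_seed(9, {
    x <- matrix(rnorm(40 * 6), 40)
    x[, 1:2] <- x[, 1:2] + 1.5
    y <- matrix(rnorm(40 * 6), 40)
    res <- paired_bin_test(x, y, alternative = "greater")
  })
  expect_true(all(res$significant[1:2]))
  expect_false(any(res$significant[3:6]))
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})
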