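test_that("rm_anova rows satisfy the ANOVA identities", {
  sim <- simulate_motion(build_phase(1, 23), sim_params(seed = 8), 300)
  res <- rm_anova(cell_means(sim$series))
  expect_s3_class(res, "anova_result")
  expect_equal(res$mean_sq * res$df, res$sum_sq, tolerance = 1e-12)
  eff <- res[res$effect != "Residual" & res$stratum != "unit", ]
  for (i in seq_len(nrow(eff))) {
    resid <- res[res$stratum == eff$stratum[i] & res$effect == "Residual", ]
    expect_equal(eff$f_value[i], eff$mean_sq[i] / resid$mean_sq,
                 tolerance = 1e-10)
    expect_equal(eff$partial_eta_sq[i],
                 eff$sum_sq[i] / (eff$sum_sq[i] + resid$sum_sq),
                 tolerance = 1e-12)
  }
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
})

test_that("rm_anova reproduces the printed within-subject df structure", {
  # 23 cycles: factor strata carry (23-1)*2 = 44 df, the cycle covariate
  # interaction takes 2, leaving 42 — the published residual df
  sim <- simulate_motion(build_phase(1, 23), sim_params(seed = 9), 600)
  res <- rm_anova(cell_means(sim$series))
  res_cond <- res[res$stratum == "unit:condition", ]
  expect_equal(res_cond$df[res_cond$effect == "condition"], 2)
  expect_equal(res_cond$df[res_cond$effect == "condition:cycle"], 2)
  expect_equal(res_cond$df[res_cond$effect == "Residual"], 42)
  res3 <- res[res$stratum == "unit:condition:interval", ]
  expect_equal(res3$df[res3$effect == "condition:interval"], 4)
  expect_equal(res3$df[res3$effect == "Residual"], 84)
  expect_equal(rm_error_df(22, 2), 42)  # the same arithmetic, unit count form
})

test_that("rm_anova needs >= 2 units and a complete table", {
  sim <- simulate_motion(build_phase(1, 1), sim_params(seed = 1), 600)
  expect_error(rm_anova(cell_means(sim$series)), class = "stats_error")
  sim2 <- simulate_motion(build_phase(1, 3), sim_params(seed = 1), 600)
  cells <- cell_means(sim2$series)
  cells$mean_motion[5] <- NA
  expect_error(rm_anova(cells), class = "stats_error")
})

test_that("day length can enter as a covariate in phase 3", {
  sched <- build_phase(3, 12, seed = 21)
  sim <- simulate_motion(sched, sim_params(seed = 22), 600)
  res <- rm_anova(cell_means(sim$series), covariates = c("cycle", "day_length"))
  expect_true("condition:day_length" %in% res$effect)
  # two 2-df covariate interactions leave (12-1)*2 - 4 residual df
  res_cond <- res[res$stratum == "unit:condition", ]
  expect_equal(res_cond$df[res_cond$effect == "Residual"], 18)
})

test_that("simple_effects analyses one interval's condition-by-cycle design", {
  sim <- simulate_motion(build_phase(1, 10), sim_params(seed = 12), 600)
  cells <- cell_means(sim$series)
  res <- simple_effects(cells, "pre-light")
  expect_true(all(c("condition", "condition:cycle", "Residual") %in%
                    res$effect))
  # built-in anticipation effect is detected in the pre-light stratum
  p <- res$p_value[res$effect == "condition"]
  expect_lt(p, 0.05)
  expect_error(simple_effects(cells, "noon"), class = "stats_error")
  one <- cells[cells$cycle == 1, ]
  expect_error(simple_effects(one, "pre-light"), class = "stats_error")
})

test_that("condition effect power and null F distribution behave", {
  # with the default anticipation curve the pre-light condition effect is
  # detected in at least 80% of replicates
  hits <- vapply(1:25, function(s) {
    sim <- simulate_motion(build_phase(1, 23), sim_params(seed = 3000 + s),
                           300)
    res <- simple_effects(cell_means(sim$series), "pre-light")
    res$p_value[res$effect == "condition"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # with no effect built in, p-values are roughly uniform
  p0 <- vapply(1:60, function(s) {
    sim <- simulate_motion(
      build_phase(1, 12),
      sim_params(a_true = 0, b_true = 0, light_boost = 0, spike_height = 0,
                 seed = 4000 + s),
      900
    )
    res <- simple_effects(cell_means(sim$series), "pre-light")
    res$p_value[res$effect == "condition"]
  }, numeric(1))
  expect_gt(stats::ks.test(p0, "punif")$p.value, 0.01)
})

test_that("stratify_by_day_length partitions inclusively at 12 and 24 h", {
  d <- tibble::tibble(cycle = 1:6,
                      day_length_h = c(10, 12, 18, 24, 26, 32),
                      motion_diff = c(-0.1, 0.2, 0.25, 0.15, -0.05, -0.2))
  s <- stratify_by_day_length(d)
  expect_equal(s$in_band$n_cycles, 3)
  expect_equal(sort(s$in_band$cycles), c(2, 3, 4))
  expect_equal(s$out_of_band$n_cycles, 3)
  expect_gt(s$in_band$mean_diff, 0)
  expect_lt(s$out_of_band$mean_diff, 0)
  expect_s3_class(s$in_band_fit, "learning_curve_fit")

  all_in <- stratify_by_day_length(
    tibble::tibble(cycle = 1:3, day_length_h = 20,
                   motion_diff = c(0.1, 0.2, 0.3)))
  expect_equal(all_in$out_of_band$n_cycles, 0)
  expect_true(is.na(all_in$out_of_band$mean_diff))
  expect_error(stratify_by_day_length(tibble::tibble()),
               class = "stats_error")
})

test_that("generator applies anticipation only inside the band", {
  # sign test over replicated phase-3 runs: in-band mean positive,
  # out-of-band mean ~ 0 (the generator zeroes delta outside the band)
  signs <- vapply(1:12, function(s) {
    sched <- build_phase(3, 16, seed = 500 + s)
    sim <- simulate_motion(sched, sim_params(b_true = 0.05, seed = 600 + s),
                           600)
    d <- motion_difference(cell_means(sim$series))
    st <- stratify_by_day_length(d)
    c(in_band = st$in_band$mean_diff, out = st$out_of_band$mean_diff)
  }, numeric(2))
  expect_gte(sum(signs["in_band", ] > 0), 11)
  binom_p <- stats::binom.test(sum(signs["out", ] > signs["in_band", ]),
                               ncol(signs))$p.value
  expect_lt(binom_p, 0.05)
})
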