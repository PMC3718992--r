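test_that("control growth reproduces the exponential and linear regimes", {
  g <- growth_params(w0 = 0.1, lambda0 = 0.1, lambda1 = 0.2, psi = 20)
  tt <- seq(0, 10, by = 0.5)
  w <- simulate_control(g, tt)$w
  expect_equal(w, 0.1 * exp(0.1 * tt), tolerance = 5e-3)  # w << lambda1/lambda0
  tt2 <- seq(0, 200, by = 1)
  w2 <- simulate_control(g, tt2)$w
  late <- diff(tail(w2, 5))
  expect_equal(late, rep(0.2, 4), tolerance = 1e-6)       # dw/dt -> lambda1
  expect_true(all(diff(w2) > 0))                          # monotone growth
})

test_that("psi = 20 growth stays within 2% of the sharp-switch closed form", {
  g <- growth_params(w0 = 0.05, lambda0 = 0.15, lambda1 = 0.15, psi = 20)
  tt <- seq(0, 80, by = 0.25)
  w <- simulate_control(g, tt)$w
  w_switch <- 0.15 / 0.15                  # lambda1 / lambda0
  t_switch <- log(w_switch / 0.05) / 0.15
  oracle <- ifelse(tt < t_switch, 0.05 * exp(0.15 * tt),
                   w_switch + 0.15 * (tt - t_switch))
  expect_lt(max(abs(w - oracle) / oracle), 0.02)
})

test_that("monotherapy model reduces to control without drug pressure", {
  g <- growth_params(w0 = 0.08, lambda0 = 0.2, lambda1 = 0.25)
  tt <- seq(0, 40, by = 1)
  ctrl <- simulate_control(g, tt)$w
  pk <- pk_model(1, volume = 1, elimination_rate = 5)
  pr <- conc_profile(pk, regimen("d", c(8, 12), 50))
  tight <- list(rtol = 1e-10, atol = 1e-12)
  ctrl_t <- simulate_control(g, tt, control = tight)$w
  ## k2 = 0: drug inert regardless of exposure
  w_k20 <- simulate_monotherapy(g, drug_params(1, 0), pr, tt,
                                control = tight)$w
  expect_equal(w_k20, ctrl_t, tolerance = 1e-8)
  ## no doses: identical to control
  w_c0 <- simulate_monotherapy(g, drug_params(1, 0.05),
                               conc_profile(pk, regimen("d")), tt,
                               control = tight)$w
  expect_equal(w_c0, ctrl_t, tolerance = 1e-8)
  ## active drug: treated never exceeds control, strictly below after dosing
  w_trt <- simulate_monotherapy(g, drug_params(1, 0.05), pr, tt)$w
  expect_true(all(w_trt <= ctrl * (1 + 1e-6)))
  expect_true(all(w_trt[tt > 9] < ctrl[tt > 9]))
})

test_that("combination model reduces to the single-agent margins", {
  skip_if_not_installed("withr")
  withr::local_seed(42)
  pk <- pk_model(1, volume = 1, elimination_rate = 4)
  pr_a <- conc_profile(pk, regimen("A", c(6, 9, 12), 30))
  none <- conc_profile(pk, regimen("B"))
  tt <- seq(0, 35, by = 0.5)
  tight <- list(rtol = 1e-10, atol = 1e-12)
  for (rep in 1:5) {
    spec <- random_spec(gamma = runif(1, -1, 1))
    comb <- simulate_combination(spec, pr_a, none, tt, control = tight)
    ## states with j > 0 stay identically zero
    off <- comb$states[, grep("x_[0-3][1-3]", colnames(comb$states))]
    expect_equal(max(abs(off)), 0)
    mono <- simulate_monotherapy(spec$growth, spec$drug_a, pr_a, tt,
                                 control = tight)
    mA <- tgicomb:::margin_a(comb)
    expect_equal(unname(mA), unname(mono$states), tolerance = 1e-8)
    expect_equal(comb$w, mono$w, tolerance = 1e-8)
  }
  ## both drugs absent: control, and all damaged states stay 0
  spec <- random_spec(gamma = 2)
  comb0 <- simulate_combination(spec, none, none, tt, control = tight)
  expect_equal(comb0$w, simulate_control(spec$growth, tt, control = tight)$w,
               tolerance = 1e-8)
  expect_equal(max(abs(comb0$states[, -1])), 0)
})

test_that("zero-interaction reference equals gamma = 0 and brackets w by sign(gamma)", {
  pr <- c1_profiles()
  spec <- default_truth(gamma = 1.5)
  tt <- seq(0, 50, by = 0.5)
  ptgc <- simulate_zero_interaction(spec, pr$a, pr$b, tt)
  spec0 <- spec; spec0$gamma <- 0
  expect_identical(ptgc$w,
                   simulate_combination(spec0, pr$a, pr$b, tt)$w)
  w_syn <- simulate_combination(spec, pr$a, pr$b, tt)$w
  expect_true(all(w_syn <= ptgc$w + 1e-10))
  spec_neg <- spec; spec_neg$gamma <- -0.2
  w_ant <- simulate_combination(spec_neg, pr$a, pr$b, tt)$w
  expect_true(all(w_ant >= ptgc$w - 1e-10))
})

test_that("w(t) is monotone in gamma and in k2a", {
  skip_if_not_installed("withr")
  withr::local_seed(7)
  pr <- c1_profiles()
  tt <- seq(0, 45, by = 0.5)
  for (rep in 1:3) {
    spec <- random_spec()
    gammas <- c(-0.5, 0, 0.4, 1.2)
    ws <- sapply(gammas, function(g) {
      spec$gamma <- g
      suppressWarnings(simulate_combination(spec, pr$a, pr$b, tt)$w)
    })
    for (k in seq_len(length(gammas) - 1))
      expect_true(all(ws[, k] >= ws[, k + 1] - 1e-9))
  }
  spec <- default_truth(gamma = 0.5)
  w_lo <- simulate_combination(spec, pr$a, pr$b, tt)$w
  spec_hi <- spec
  spec_hi$drug_a <- drug_params(spec$drug_a$k1, spec$drug_a$k2 * 3)
  w_hi <- simulate_combination(spec_hi, pr$a, pr$b, tt)$w
  expect_true(all(w_hi <= w_lo + 1e-9))
})

test_that("mass balance: dw/dt = f_p - k1a*sum(x_3j) - k1b*sum(x_i3)", {
  pr <- c1_profiles()
  for (spec in list(default_truth(gamma = 1), default_truth(gamma = -0.15))) {
    h <- 0.02
    tt <- seq(0, 40, by = h)
    traj <- simulate_combination(spec, pr$a, pr$b, tt)
    x <- traj$states
    w <- traj$w
    g <- spec$growth
    fp <- g$lambda0 * x[, "x_00"] /
      (1 + ((g$lambda0 / g$lambda1) * w)^g$psi)^(1 / g$psi)
    exit_a <- spec$drug_a$k1 *
      rowSums(x[, sprintf("x_3%d", 0:3)])
    exit_b <- spec$drug_b$k1 *
      rowSums(x[, sprintf("x_%d3", 0:3)])
    rhs <- fp - exit_a - exit_b
    mid <- 2:(length(tt) - 1)
    dwdt <- (w[mid + 1] - w[mid - 1]) / (2 * h)
    ## exclude points adjacent to dose discontinuities
    doses <- sort(unique(c(pr$a$dose_times, pr$b$dose_times)))
    ok <- sapply(tt[mid], function(t) all(abs(t - doses) > 2 * h))
    err <- abs(dwdt - rhs[mid])
    scale <- max(abs(rhs))
    expect_lt(max(err[ok]) / scale, 5e-3)
  }
})

test_that("states remain non-negative up to solver tolerance", {
  pr <- c1_profiles()
  spec <- default_truth(gamma = 2)
  tt <- seq(0, 60, by = 0.25)
  traj <- simulate_combination(spec, pr$a, pr$b, tt)
  expect_true(all(traj$states >= 0))        # clipped
  expect_lt(traj$max_clip, 1e-9)            # and the clip was tiny
})

test_that("strongly negative gamma triggers a model-validity warning", {
  pr <- c1_profiles()
  spec <- default_truth(gamma = -50)
  tt <- seq(0, 40, by = 0.5)
  expect_warning(simulate_combination(spec, pr$a, pr$b, tt),
                 "net kill rate")
})

test_that("cross-potency model nests the gamma = 0 combination model", {
  pr <- c1_profiles()
  base <- default_truth()
  fa <- first_attempt_spec(base$growth, base$drug_a, base$drug_b,
                           k2a_b = base$drug_a$k2,
                           k2b_a = base$drug_b$k2)
  tt <- seq(0, 45, by = 0.5)
  tight <- list(rtol = 1e-10, atol = 1e-12)
  w_fa <- simulate_first_attempt(fa, pr$a, pr$b, tt, control = tight)$w
  spec0 <- base; spec0$gamma <- 0
  w_g0 <- simulate_combination(spec0, pr$a, pr$b, tt, control = tight)$w
  expect_equal(w_fa, w_g0, tolerance = 1e-8)
  ## one drug absent: reduces to the single-agent model
  none <- conc_profile(pk_model(1, volume = 1, elimination_rate = 1),
                       regimen("none"))
  w_solo <- simulate_first_attempt(fa, pr$a, none, tt, control = tight)$w
  w_mono <- simulate_monotherapy(base$growth, base$drug_a, pr$a, tt,
                                 control = tight)$w
  expect_equal(w_solo, w_mono, tolerance = 1e-8)
})

test_that("total weight is nearly insensitive to the cross-potencies", {
  pr <- c1_profiles()
  base <- default_truth()
  fa <- first_attempt_spec(base$growth, base$drug_a, base$drug_b,
                           k2a_b = base$drug_a$k2,
                           k2b_a = base$drug_b$k2)
  tt <- seq(0, 45, by = 0.5)
  tab <- potency_sensitivity_study(fa, pr$a, pr$b, tt,
                                   folds = c(0.1, 1, 10))
  expect_equal(tab$max_rel_dev_cross[tab$fold == 1], 0)
  expect_equal(tab$max_rel_dev_k2a[tab$fold == 1], 0)
  ## deviations grow with |log fold|
  expect_true(all(diff(tab$max_rel_dev_cross[order(abs(log(tab$fold)))]) >=
                    -1e-12))
  ## ten-fold cross-potency change moves the curve by a few percent at most,
  ## an order of magnitude less than the same change of k2a itself
  big <- tab[tab$fold == 10, ]
  expect_lt(big$max_rel_dev_cross, 0.08)
  expect_gt(big$max_rel_dev_k2a / big$max_rel_dev_cross, 10)
})

test_that("trajectories export to CSV and round-trip", {
  g <- growth_params(0.05, 0.15, 0.15)
  tt <- seq(0, 20, by = 1)
  traj <- simulate_control(g, tt)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$time_days, tt)
  expect_equal(back$w_total_g, traj$w)
  expect_equal(ncol(back), 4 + 2)
})
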