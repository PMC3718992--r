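test_that("the WLS objective matches a hand-coded double loop", {
  pr <- c1_profiles()
  truth <- default_truth(gamma = 0.8)
  dat <- generate_tumor_dataset(truth, pr$regimens, pr$pk,
                                times = seq(8, 32, by = 4),
                                cv = 0.1, seed = 3)
  spec <- default_truth(gamma = 0.2)   # deliberately misfit
  obj <- wls_objective(dat, spec)
  ## brute force: simulate each arm, accumulate sum_arms (1/n) sum rel^2
  manual <- 0
  grid <- sort(unique(c(0, seq(8, 32, by = 4))))
  for (a in dat$arms) {
    prof <- switch(a$arm_type,
                   control = NULL,
                   single_a = list(spec$growth, spec$drug_a, pr$a),
                   single_b = list(spec$growth, spec$drug_b, pr$b),
                   combination = "comb")
    traj <- if (a$arm_type == "control")
      simulate_control(spec$growth, grid)
    else if (identical(prof, "comb"))
      simulate_combination(spec, pr$a, pr$b, grid)
    else simulate_monotherapy(prof[[1]], prof[[2]], prof[[3]], grid)
    pred <- traj$w[match(a$observations$time, grid)]
    y <- a$observations$weight
    manual <- manual + sum(((y - pred) / y)^2) / length(y)
  }
  expect_equal(obj, manual, tolerance = 1e-10)
  ## arms with identical relative misfit but different n contribute equally
  mk_arm <- function(id, n) {
    t <- seq(10, 10 + n - 1)
    w <- simulate_control(spec$growth, c(0, t))$w[-1]
    tumor_arm(id, "control",
              data.frame(time = t, weight = w * 1.1, se = 0))
  }
  d2 <- tumor_dataset(list(mk_arm("short", 4), mk_arm("long", 16)), pr$pk)
  r <- tgicomb:::wls_residuals(
    spec, d2$arms, lapply(d2$arms, tgicomb:::arm_profiles, data = d2))
  ssr <- tapply(r^2, rep(c("short", "long"), c(4, 16)), sum)
  expect_equal(unname(ssr["short"]), unname(ssr["long"]), tolerance = 1e-6)
})

test_that("rmse is the unweighted root mean square in grams", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2), c(1.1, 2.1)), 0.1)
  x <- c(0.3, 0.9, 2.2); y <- c(0.5, 0.7, 2.0)
  expect_equal(rmse(x, y), sqrt(mean((x - y)^2)))
})

test_that("parameter_cv matches the textbook linear-model closed form", {
  ## y = theta * x with unit-weight residuals: se = s / sqrt(sum x^2)
  set.seed(11)
  x <- seq(0.5, 5, by = 0.5)
  theta <- 2
  y <- theta * x + rnorm(length(x), sd = 0.1)
  theta_hat <- sum(x * y) / sum(x * x)
  r <- y - theta_hat * x
  J <- matrix(-x, ncol = 1)        # d(residual)/d(theta), residual = y_hat - y flipped sign convention
  out <- parameter_cv(J, r, c(theta = theta_hat))
  s2 <- sum(r^2) / (length(x) - 1)
  expect_equal(unname(out$se), sqrt(s2 / sum(x^2)), tolerance = 1e-10)
  expect_equal(unname(out$cv_percent),
               100 * sqrt(s2 / sum(x^2)) / abs(theta_hat),
               tolerance = 1e-10)
  ## a duplicated column destroys identifiability and is flagged
  bad <- parameter_cv(cbind(J, J), r, c(a = 1, b = 1))
  expect_false(bad$rank_ok)
  expect_true(all(is.na(bad$cv_percent)))
  ## CV shrinks roughly as 1/sqrt(n) with more observations
  x4 <- rep(x, 4)
  y4 <- theta * x4 + rnorm(length(x4), sd = 0.1)
  th4 <- sum(x4 * y4) / sum(x4 * x4)
  out4 <- parameter_cv(matrix(-x4, ncol = 1), y4 - th4 * x4,
                       c(theta = th4))
  expect_lt(out4$cv_percent / out$cv_percent, 0.75)
})

test_that("noise-free staged fitting recovers all parameters", {
  pr <- c1_profiles()
  truth <- default_truth(gamma = 2)
  dat <- generate_tumor_dataset(truth, pr$regimens, pr$pk, cv = 0)
  s1 <- fit_monotherapy(dat, n_starts = 2, seed = 1)
  truth7 <- c(w0 = 0.05, lambda0 = 0.15, lambda1 = 0.15,
              k1a = 0.9, k2a = 0.02, k1b = 0.6, k2b = 0.05)
  expect_equal(s1$estimates, truth7, tolerance = 0.01)
  expect_lt(s1$rmse, 1e-3)
  s2 <- fit_interaction(dat, s1)
  expect_equal(unname(s2$estimates["gamma"]), 2, tolerance = 0.01)
})

test_that("missing arms raise configuration errors", {
  pr <- c1_profiles()
  truth <- default_truth(gamma = 1)
  dat <- generate_tumor_dataset(truth, pr$regimens, pr$pk, cv = 0)
  ctrl_only <- tumor_dataset(dat$arms["control"], pr$pk)
  expect_error(fit_monotherapy(ctrl_only), "single_a")
  no_ctrl <- tumor_dataset(dat$arms[c("mono_DrugC2", "mono_CPT-11")],
                           pr$pk)
  expect_error(fit_monotherapy(no_ctrl), "control")
  expect_error(fit_interaction(ctrl_only, fixed = coef_named7()),
               "combination")
  expect_error(fit_interaction(dat, fixed = c(w0 = 0.05)), "missing")
  comb_only <- tumor_dataset(dat$arms["combination"], pr$pk)
  expect_error(fit_joint(comb_only), "control")
})

test_that("joint fitting agrees with the staged pipeline on clean data", {
  pr <- c1_profiles()
  truth <- default_truth(gamma = 1)
  dat <- generate_tumor_dataset(truth, pr$regimens, pr$pk, cv = 0)
  jf <- fit_joint(dat, n_starts = 2, seed = 5)
  expect_equal(unname(jf$estimates["gamma"]), 1, tolerance = 0.01)
  expect_equal(unname(jf$estimates["k2a"]), 0.02, tolerance = 0.01)
  ## on noisy data the staged and joint gamma agree within joint CIs
  datn <- generate_tumor_dataset(truth, pr$regimens, pr$pk, cv = 0.1,
                                 seed = 21)
  staged <- tgi_fit(datn, n_starts = 3, seed = 21)
  joint <- tgi_fit(datn, method = "joint", n_starts = 3, seed = 21)
  g_s <- staged$estimates[["gamma"]]; se_s <- staged$se[["gamma"]]
  g_j <- joint$estimates[["gamma"]]; se_j <- joint$se[["gamma"]]
  expect_lt(abs(g_s - g_j), 1.96 * sqrt(se_s^2 + se_j^2))
})

test_that("the staged pipeline is deterministic for a fixed seed", {
  pr <- c1_profiles()
  dat <- generate_tumor_dataset(default_truth(gamma = 1), pr$regimens,
                                pr$pk, cv = 0.1, seed = 9)
  f1 <- tgi_fit(dat, n_starts = 3, seed = 4)
  f2 <- tgi_fit(dat, n_starts = 3, seed = 4)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$se, f2$se)
})

test_that("tgi_fit methods expose the fit the standard way", {
  pr <- c1_profiles()
  dat <- generate_tumor_dataset(default_truth(gamma = 1), pr$regimens,
                                pr$pk, cv = 0.05, seed = 13)
  fit <- tgi_fit(dat, n_starts = 2, seed = 13)
  expect_s3_class(fit, "tgi_fit")
  expect_named(coef(fit), c("w0", "lambda0", "lambda1", "k1a", "k2a",
                            "k1b", "k2b", "gamma"))
  s <- summary(fit)
  expect_s3_class(s, "summary.tgi_fit")
  expect_equal(rownames(s$coefficients)[8], "gamma")
  r <- residuals(fit)
  expect_true(all(c("arm_id", "time", "residual") %in% names(r)))
  expect_equal(nrow(fitted(fit)), 4 * 11)
  expect_output(print(fit), "gamma")
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "tumor_dataset")
  spec <- as_combo_spec(fit)
  expect_s3_class(spec, "combo_spec")
  expect_equal(spec$gamma, unname(coef(fit)["gamma"]))
  ## plotting works headlessly
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("prediction transports the fitted gamma to a new regimen", {
  pr <- c1_profiles()
  dat <- generate_tumor_dataset(default_truth(gamma = 1), pr$regimens,
                                pr$pk, cv = 0.05, seed = 17)
  fit <- tgi_fit(dat, n_starts = 2, seed = 17)
  ## same regimen: prediction reproduces the fitted combination curve
  p_same <- predict(fit, times = seq(0, 38, by = 0.5))
  comb_fit <- fit$stages$interaction$fitted
  at <- match(comb_fit$time, p_same$trajectory$times)
  expect_equal(p_same$trajectory$w[at], comb_fit$fitted, tolerance = 1e-6)
  ## higher dose of drug A with gamma > 0 raises the predicted SC
  fx2 <- experiment_fixture("c2")   # same schedule, drug A dose 113 umol/kg
  p_new <- predict(fit, regimens = fx2$regimens)
  expect_gt(p_new$indexes$sc, p_same$indexes$sc)
})
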