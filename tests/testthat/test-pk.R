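test_that("single iv bolus follows the closed form", {
  pk <- pk_model(1, volume = 2, elimination_rate = 1)
  reg <- regimen("d", times = 0, amounts = 10)
  pr <- conc_profile(pk, reg)
  expect_equal(conc_at(pr, 0), 5)                     # D/V
  expect_equal(conc_at(pr, 1), 5 * exp(-1))
  expect_equal(conc_at(pr, -0.5), 0)                  # before first dose
})

test_that("multi-dose profiles superpose linearly and scale with dose", {
  pk <- pk_model(1, volume = 2, elimination_rate = 1)
  both <- conc_profile(pk, regimen("d", c(0, 1), 10))
  one <- conc_profile(pk, regimen("d", 0, 10))
  two <- conc_profile(pk, regimen("d", 1, 10))
  tt <- seq(0, 6, by = 0.01)
  expect_equal(conc_at(both, tt), conc_at(one, tt) + conc_at(two, tt),
               tolerance = 1e-12)
  dbl <- conc_profile(pk, regimen("d", c(0, 1), 20))
  expect_equal(conc_at(dbl, tt), 2 * conc_at(both, tt), tolerance = 1e-14)
  expect_equal(auc(dbl), 2 * auc(both), tolerance = 1e-14)
})

test_that("oral absorption matches a high-accuracy ODE integration", {
  pk <- pk_model(1, volume = 1, elimination_rate = 1,
                 absorption_rate = 2, bioavailability = 1)
  reg <- regimen("d", times = c(0, 2), amounts = c(10, 5), route = "oral")
  pr <- conc_profile(pk, reg)
  rhs <- function(t, y, p) {
    list(c(-2 * y[1], 2 * y[1] - 1 * y[2]))
  }
  tt <- seq(0, 10, by = 0.05)
  sol1 <- deSolve::lsoda(c(10, 0), tt, rhs, NULL, rtol = 1e-10,
                         atol = 1e-12)
  sol2 <- deSolve::lsoda(c(5, 0), tt, rhs, NULL, rtol = 1e-10,
                         atol = 1e-12)
  oracle <- sol1[, 3] + c(rep(0, sum(tt < 2)),
                          sol2[seq_len(sum(tt >= 2)), 3])
  ## superpose the second dose shifted by 2 days
  oracle <- sol1[, 3]
  shift <- tt >= 2
  oracle[shift] <- oracle[shift] +
    approx(tt, sol2[, 3], xout = tt[shift] - 2)$y
  expect_equal(conc_at(pr, tt), oracle, tolerance = 1e-8)
})

test_that("degenerate ka = k oral profile uses the t*exp(-kt) limit", {
  pk_lim <- pk_model(1, volume = 1, elimination_rate = 1,
                     absorption_rate = 1)
  pk_near <- pk_model(1, volume = 1, elimination_rate = 1,
                      absorption_rate = 1 + 1e-6)
  reg <- regimen("d", 0, 10, "oral")
  tt <- seq(0, 8, by = 0.1)
  lim <- conc_at(conc_profile(pk_lim, reg), tt)
  expect_equal(lim, 10 * tt * exp(-tt), tolerance = 1e-12)
  near <- conc_at(conc_profile(pk_near, reg), tt)
  expect_equal(near, lim, tolerance = 1e-5)
})

test_that("two-compartment profiles start at D/V and keep AUC = D/CL", {
  pk <- pk_model(2, volume = 0.5, elimination_rate = 4, k12 = 2, k21 = 1)
  reg <- regimen("d", 0, 10)
  pr <- conc_profile(pk, reg)
  expect_equal(conc_at(pr, 0), 20)                # D/V
  expect_equal(auc(pr), 10 / (4 * 0.5))           # D / (k10 V)
  ## oral tri-exponential: cross-check against ODE integration
  pko <- pk_model(2, volume = 0.5, elimination_rate = 4, k12 = 2, k21 = 1,
                  absorption_rate = 6, bioavailability = 0.8)
  pro <- conc_profile(pko, regimen("d", 0, 10, "oral"))
  rhs <- function(t, y, p)
    list(c(-6 * y[1],
           6 * y[1] - (4 + 2) * y[2] + 1 * y[3],
           2 * y[2] - 1 * y[3]))
  tt <- seq(0, 5, by = 0.02)
  sol <- deSolve::lsoda(c(0.8 * 10, 0, 0), tt, rhs, NULL, rtol = 1e-10,
                        atol = 1e-12)
  expect_equal(conc_at(pro, tt), sol[, 3] / 0.5, tolerance = 1e-8)
})

test_that("AUC is analytic, truncates correctly and matches quadrature", {
  pk <- pk_model(1, volume = 1, elimination_rate = 2)
  reg <- regimen("d", times = c(0, 1, 2), amounts = 10)
  pr <- conc_profile(pk, reg)
  expect_equal(auc(pr), 30 / 2)                   # total D / (k V)
  ## truncated AUC vs fine trapezoidal quadrature, segmented at the dose
  ## discontinuities so the quadrature error stays O(h^2)
  trap <- 0
  for (seg in list(c(0, 1), c(1, 2), c(2, 5))) {
    tt <- seq(seg[1], seg[2], length.out = 1e5)
    ## keep the right endpoint on the left limit of the jump
    cc <- conc_at(pr, pmin(tt, seg[2] - 1e-9))
    trap <- trap + sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  }
  expect_equal(auc(pr, horizon = 5), trap, tolerance = 1e-6)
  expect_error(auc(pr, horizon = 1.5), "horizon")
  ## oral bioavailability scales AUC
  pko <- pk_model(1, volume = 1, elimination_rate = 2,
                  absorption_rate = 3, bioavailability = 0.5)
  pro <- conc_profile(pko, regimen("d", c(0, 1, 2), 10, "oral"))
  expect_equal(auc(pro), 0.5 * 30 / 2, tolerance = 1e-12)
})

test_that("auc_product is symmetric and matches the closed form", {
  pk_a <- pk_model(1, volume = 1, elimination_rate = 2)
  pk_b <- pk_model(1, volume = 2, elimination_rate = 3)
  pa <- conc_profile(pk_a, regimen("a", 0, 10))
  pb <- conc_profile(pk_b, regimen("b", 0, 12))
  ## both dosed at t = 0: integral (Da/Va)(Db/Vb)/(ka+kb)
  expect_equal(auc_product(pa, pb), (10 / 1) * (12 / 2) / (2 + 3),
               tolerance = 1e-6)
  expect_equal(auc_product(pa, pb), auc_product(pb, pa), tolerance = 1e-10)
  ## zero profile annihilates the product
  p0 <- conc_profile(pk_b, regimen("b"))
  expect_equal(auc_product(pa, p0), 0)
  ## doubling one dose doubles the product AUC
  pa2 <- conc_profile(pk_a, regimen("a", 0, 20))
  expect_equal(auc_product(pa2, pb), 2 * auc_product(pa, pb),
               tolerance = 1e-9)
})

test_that("PK validation rejects inconsistent configurations", {
  expect_error(pk_model(1, volume = -1, elimination_rate = 1), "volume")
  expect_error(pk_model(1, volume = 1, elimination_rate = 0),
               "elimination_rate")
  expect_error(pk_model(2, volume = 1, elimination_rate = 1), "k12")
  expect_error(pk_model(1, volume = 1, elimination_rate = 1,
                        bioavailability = 1.4), "bioavailability")
  expect_error(regimen("d", times = 1, amounts = -2), "amount")
  ## oral event without absorption rate is a configuration error
  pk <- pk_model(1, volume = 1, elimination_rate = 1)
  expect_error(conc_profile(pk, regimen("d", 0, 1, "oral")),
               "absorption_rate")
})

test_that("regimen CSV round-trips", {
  regs <- list(A = regimen("A", c(1, 2.5), c(10, 10), "oral"),
               B = regimen("B", 3, 20, "iv_bolus"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_regimen_csv(regs, f)
  back <- read_regimen_csv(f)
  expect_equal(back$A$events, regs$A$events)
  expect_equal(back$B$events, regs$B$events)
})
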