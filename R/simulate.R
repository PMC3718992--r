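#' Tumor growth and drug effect parameter containers
#'
#' `growth_params()` holds the unperturbed-growth parameters of the
#' switched exponential/linear tumor growth law
#' \deqn{\dot w = \lambda_0 w / [1 + ((\lambda_0/\lambda_1) w)^\Psi]^{1/\Psi}}
#' (exponential at rate `lambda0` while `w` is small, linear at rate
#' `lambda1` once `w` exceeds `lambda1/lambda0`; `psi` sets the sharpness
#' of the switch).  `drug_params()` holds one drug's effect parameters:
#' the potency `k2` (kill rate per unit concentration on proliferating
#' cells) and the damage-cascade transit rate `k1` (its inverse is the
#' delay between drug hit and cell loss).
#'
#' @param w0 Initial tumor weight at t = 0, g (> 0).
#' @param lambda0 Exponential growth rate, day^-1 (> 0).
#' @param lambda1 Linear growth rate, g/day (> 0).
#' @param psi Switching sharpness (dimensionless, > 0); default 20.
#' @return An object of class `"growth_params"` / `"drug_params"`.
#' @export
growth_params <- function(w0, lambda0, lambda1, psi = 20) {
  vals <- c(w0 = w0, lambda0 = lambda0, lambda1 = lambda1, psi = psi)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all growth parameters must be finite and > 0", call. = FALSE)
  structure(as.list(vals), class = "growth_params")
}

#' @rdname growth_params
#' @param k1 Transit rate through the damage cascade, day^-1 (> 0).
#' @param k2 Drug potency, uM^-1 day^-1 (>= 0).
#' @export
drug_params <- function(k1, k2) {
  if (!is.finite(k1) || k1 <= 0) stop("'k1' must be > 0", call. = FALSE)
  if (!is.finite(k2) || k2 < 0) stop("'k2' must be >= 0", call. = FALSE)
  structure(list(k1 = k1, k2 = k2), class = "drug_params")
}

#' Full specification of the two-drug combination TGI model
#'
#' Bundles the shared tumor growth parameters, the per-drug effect
#' parameters and the interaction parameter `gamma` (uM^-2 day^-2, any
#' sign: > 0 synergistic, < 0 antagonistic, ~ 0 additive).
#'
#' @param growth A [growth_params()].
#' @param drug_a,drug_b [drug_params()] for the two drugs.
#' @param gamma Interaction parameter, uM^-2 day^-2.
#' @return An object of class `"combo_spec"`.
#' @export
combo_spec <- function(growth, drug_a, drug_b, gamma = 0) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(drug_a, "drug_params"),
            inherits(drug_b, "drug_params"))
  if (!is.finite(gamma)) stop("'gamma' must be finite", call. = FALSE)
  structure(list(growth = growth, drug_a = drug_a, drug_b = drug_b,
                 gamma = gamma),
            class = "combo_spec")
}

#' @export
print.combo_spec <- function(x, ...) {
  g <- x$growth
  cat("Two-drug combination TGI model specification\n")
  cat(sprintf("  growth: w0 = %g g, lambda0 = %g /day, lambda1 = %g g/day, psi = %g\n",
              g$w0, g$lambda0, g$lambda1, g$psi))
  cat(sprintf("  drug A: k1 = %g /day, k2 = %g /uM/day\n",
              x$drug_a$k1, x$drug_a$k2))
  cat(sprintf("  drug B: k1 = %g /day, k2 = %g /uM/day\n",
              x$drug_b$k1, x$drug_b$k2))
  cat(sprintf("  gamma = %g /uM^2/day^2\n", x$gamma))
  invisible(x)
}

#' Cross-potency ("first attempt") model specification
#'
#' Variant of the combination model without the concentration-product
#' interaction term: instead, drug A acts on cells already damaged by drug
#' B with a separate potency `k2a_b` (and symmetrically `k2b_a`).  The
#' total tumor weight is nearly insensitive to these cross-potencies
#' (see [potency_sensitivity_study()]), which is why the single
#' interaction parameter acting on the proliferating cells is used
#' instead.
#'
#' @inheritParams combo_spec
#' @param k2a_b Potency of drug A on cells damaged by B, uM^-1 day^-1 (>= 0).
#' @param k2b_a Potency of drug B on cells damaged by A, uM^-1 day^-1 (>= 0).
#' @return An object of class `"first_attempt_spec"`.
#' @export
first_attempt_spec <- function(growth, drug_a, drug_b, k2a_b, k2b_a) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(drug_a, "drug_params"),
            inherits(drug_b, "drug_params"))
  if (k2a_b < 0 || k2b_a < 0)
    stop("cross-potencies must be >= 0", call. = FALSE)
  structure(list(growth = growth, drug_a = drug_a, drug_b = drug_b,
                 k2a_b = k2a_b, k2b_a = k2b_a),
            class = "first_attempt_spec")
}

## ---- ODE plumbing -----------------------------------------------------

MAXTERMS <- 192L  # must match src/tgi_ode.c

default_solver <- function(control = list()) {
  utils::modifyList(list(rtol = 1e-8, atol = 1e-10, maxsteps = 50000L),
                    control)
}

pad_terms <- function(terms) {
  n <- nrow(terms)
  if (n > MAXTERMS)
    stop("regimen expands to more than ", MAXTERMS,
         " concentration terms", call. = FALSE)
  out <- numeric(4 * MAXTERMS)
  if (n) out[seq_len(4 * n)] <- as.numeric(t(terms[, c("t0", "coef",
                                                       "rate", "pow"),
                                                  drop = FALSE]))
  c(n, out)
}

empty_profile <- function(drug_id = "none") {
  conc_profile(pk_model(1, volume = 1, elimination_rate = 1),
               regimen(drug_id))
}

## integrate one compiled model piecewise, restarting at dose onsets
ode_piecewise <- function(y0, times, breaks, func, initfunc, parms,
                          control) {
  ctl <- default_solver(control)
  t0 <- times[1]
  tmax <- times[length(times)]
  brk <- sort(unique(breaks))
  brk <- brk[brk > t0 & brk < tmax]
  bounds <- c(t0, brk, tmax)
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  out[1, ] <- y0
  y <- y0
  for (s in seq_len(length(bounds) - 1)) {
    a <- bounds[s]; b <- bounds[s + 1]
    inside <- times[times > a & times < b]
    tt <- c(a, inside, b)
    sol <- deSolve::lsoda(y, tt, func = func, parms = parms,
                          dllname = "tgicomb", initfunc = initfunc,
                          rtol = ctl$rtol, atol = ctl$atol,
                          maxsteps = ctl$maxsteps)
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tt) ||
        anyNA(sol))
      stop("ODE integration failed between t = ", a, " and t = ", b,
           call. = FALSE)
    y <- as.numeric(sol[nrow(sol), -1])
    idx <- match(signif(c(inside, b), 14), signif(times, 14))
    keep <- !is.na(idx)
    out[idx[keep], ] <- sol[-1, -1, drop = FALSE][keep, , drop = FALSE]
  }
  out
}

make_trajectory <- function(times, states, names, model) {
  ## clip solver-tolerance negatives to zero, keeping the worst excursion;
  ## larger negative values (which arise structurally in x_11 when
  ## gamma < 0) are part of the model solution and are left intact
  tiny <- states < 0 & states > -1e-9
  max_clip <- max(c(0, -states[tiny]))
  states[tiny] <- 0
  colnames(states) <- names
  structure(list(times = times, states = states, w = rowSums(states),
                 model = model, max_clip = max_clip,
                 min_state = min(c(0, states))),
            class = "tgi_trajectory")
}

#' @export
print.tgi_trajectory <- function(x, ...) {
  cat(sprintf("TGI trajectory (%s model): %d states, %d time points in [%g, %g] days\n",
              x$model, ncol(x$states), length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  w(t): %g -> %g g", x$w[1], x$w[length(x$w)]))
  if (x$max_clip > 0)
    cat(sprintf("  (max negative state clipped: %.3g g)", x$max_clip))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.tgi_trajectory <- function(x, ...) {
  data.frame(time_days = x$times, x$states, w_total_g = x$w,
             check.names = FALSE)
}

#' Export a simulated trajectory to CSV
#'
#' Columns are `time_days`, one column per state, and `w_total_g`.
#' @param x A `tgi_trajectory`.
#' @param path Output file.
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "tgi_trajectory"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
}

#' @export
plot.tgi_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$w, type = "l", xlab = "time (days)",
                 ylab = "tumor weight (g)", ...)
  invisible(x)
}

check_times <- function(times) {
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing with at least 2 points",
         call. = FALSE)
  if (times[1] != 0)
    stop("'times' must start at 0 (the reference time of w0)",
         call. = FALSE)
}

#' Simulate unperturbed (control) tumor growth
#'
#' Integrates the exponential-then-linear growth law with no drug present.
#' The result is reported in the 4-state layout of the monotherapy model
#' (all mass in the proliferating state).
#'
#' @param growth A [growth_params()].
#' @param times Output grid, days, strictly increasing, starting at 0.
#' @param control Solver settings: `rtol` (default 1e-8), `atol` (1e-10),
#'   `maxsteps`.
#' @return A `tgi_trajectory` with states `x1..x4` and total `w`.
#' @export
simulate_control <- function(growth, times, control = list()) {
  stopifnot(inherits(growth, "growth_params"))
  check_times(times)
  simulate_monotherapy(growth, drug_params(k1 = 1, k2 = 0),
                       empty_profile(), times, control = control)
}

#' Simulate monotherapy tumor growth inhibition (4-state model)
#'
#' The proliferating compartment `x1` grows by the unperturbed growth law
#' and is killed at rate `k2 * c(t)`; hit cells traverse three damage
#' states at transit rate `k1` and then leave the tumor mass.
#'
#' @param growth A [growth_params()].
#' @param drug A [drug_params()].
#' @param conc A [conc_profile()] defined on the simulation window.
#' @inheritParams simulate_control
#' @return A `tgi_trajectory` with states `x1..x4`.
#' @export
simulate_monotherapy <- function(growth, drug, conc, times,
                                 control = list()) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(drug, "drug_params"),
            inherits(conc, "conc_profile"))
  check_times(times)
  parms <- c(growth$lambda0, growth$lambda1, growth$psi,
             drug$k1, drug$k2, pad_terms(conc$terms))
  y0 <- c(growth$w0, 0, 0, 0)
  states <- ode_piecewise(y0, times, conc$dose_times,
                          "tgi_deriv_single", "tgi_init_single",
                          parms, control)
  make_trajectory(times, states, paste0("x", 1:4), "monotherapy")
}

combo_parms <- function(growth, drug_a, drug_b, gamma, flag, k2a_b, k2b_a,
                        conc_a, conc_b) {
  c(growth$lambda0, growth$lambda1, growth$psi,
    drug_a$k1, drug_a$k2, drug_b$k1, drug_b$k2, gamma,
    flag, k2a_b, k2b_a,
    pad_terms(conc_a$terms), pad_terms(conc_b$terms))
}

state_names_16 <- as.vector(outer(0:3, 0:3,
                                  function(i, j) sprintf("x_%d%d", i, j)))
## outer fills column-major over i: reorder to row-major x_00, x_01, ...
state_names_16 <- sort(state_names_16)

#' Simulate the two-drug combination TGI model (16-state system)
#'
#' Cells are indexed `x_ij` by damage stage `i` under drug A and `j` under
#' drug B (0 = undamaged).  Undamaged cells `x_00` proliferate and are
#' killed at rate `k2a*c_a + k2b*c_b + gamma*c_a*c_b`; each drug moves
#' cells one step along its own damage axis at transit rate `k1`, and the
#' `gamma` interaction flux sends proliferating cells directly to `x_11`.
#' Cells leaving stage 3 of either cascade exit the tumor mass.
#'
#' A negative `gamma` is allowed; if it ever makes the total instantaneous
#' kill rate on `x_00` negative (drug exposure creating cells) a
#' model-validity warning reports the offending time span.
#'
#' @param spec A [combo_spec()].
#' @param conc_a,conc_b [conc_profile()] objects for the two drugs.
#' @inheritParams simulate_control
#' @return A `tgi_trajectory` with the 16 states `x_00 .. x_33` and total
#'   `w`.
#' @export
simulate_combination <- function(spec, conc_a, conc_b, times,
                                 control = list()) {
  stopifnot(inherits(spec, "combo_spec"),
            inherits(conc_a, "conc_profile"),
            inherits(conc_b, "conc_profile"))
  check_times(times)
  if (spec$gamma < 0) {
    ca <- conc_at(conc_a, times); cb <- conc_at(conc_b, times)
    net <- spec$drug_a$k2 * ca + spec$drug_b$k2 * cb + spec$gamma * ca * cb
    if (any(net < 0)) {
      bad <- range(times[net < 0])
      warning(sprintf(
        "negative gamma makes the net kill rate on x_00 negative over t in [%g, %g] days; model validity is questionable there",
        bad[1], bad[2]), call. = FALSE)
    }
  }
  parms <- combo_parms(spec$growth, spec$drug_a, spec$drug_b, spec$gamma,
                       0, 0, 0, conc_a, conc_b)
  y0 <- c(spec$growth$w0, rep(0, 15))
  states <- ode_piecewise(y0, times,
                          c(conc_a$dose_times, conc_b$dose_times),
                          "tgi_deriv_combo", "tgi_init_combo",
                          parms, control)
  make_trajectory(times, states, state_names_16, "combination")
}

#' Simulate the zero-interaction reference (PTGC)
#'
#' The predictive tumor growth curve under the no-interaction hypothesis:
#' the combination model with `gamma` forced to 0.  The interaction
#' time-shift `Delta` is the horizontal distance between the combination
#' curve and this reference.
#'
#' @inheritParams simulate_combination
#' @return A `tgi_trajectory`.
#' @export
simulate_zero_interaction <- function(spec, conc_a, conc_b, times,
                                      control = list()) {
  stopifnot(inherits(spec, "combo_spec"))
  spec$gamma <- 0
  out <- simulate_combination(spec, conc_a, conc_b, times,
                              control = control)
  out$model <- "zero_interaction"
  out
}

#' Simulate the cross-potency ("first attempt") model variant
#'
#' @param spec A [first_attempt_spec()].
#' @inheritParams simulate_combination
#' @return A `tgi_trajectory`.
#' @export
simulate_first_attempt <- function(spec, conc_a, conc_b, times,
                                   control = list()) {
  stopifnot(inherits(spec, "first_attempt_spec"),
            inherits(conc_a, "conc_profile"),
            inherits(conc_b, "conc_profile"))
  check_times(times)
  parms <- combo_parms(spec$growth, spec$drug_a, spec$drug_b, 0,
                       1, spec$k2a_b, spec$k2b_a, conc_a, conc_b)
  y0 <- c(spec$growth$w0, rep(0, 15))
  states <- ode_piecewise(y0, times,
                          c(conc_a$dose_times, conc_b$dose_times),
                          "tgi_deriv_combo", "tgi_init_combo",
                          parms, control)
  make_trajectory(times, states, state_names_16, "first_attempt")
}

## i-margin (sum over j) of a 16-state trajectory, as a 4-state layout
margin_a <- function(traj) {
  stopifnot(ncol(traj$states) == 16)
  m <- sapply(0:3, function(i)
    rowSums(traj$states[, sprintf("x_%d%d", i, 0:3), drop = FALSE]))
  colnames(m) <- paste0("x", 1:4)
  m
}

margin_b <- function(traj) {
  stopifnot(ncol(traj$states) == 16)
  m <- sapply(0:3, function(j)
    rowSums(traj$states[, sprintf("x_%d%d", 0:3, j), drop = FALSE]))
  colnames(m) <- paste0("x", 1:4)
  m
}

#' Sensitivity of the tumor growth curve to the cross-potencies
#'
#' Sweeps the cross-potency parameters of the [first_attempt_spec()] model
#' multiplicatively and reports, for each fold change, the maximum
#' relative deviation of the total-weight curve from the baseline.  For
#' comparison the same sweep applied to the primary potency `k2a` is
#' reported: the contrast demonstrates why an identifiable interaction
#' term must act on the proliferating-cell compartment.
#'
#' @param spec A [first_attempt_spec()].
#' @param conc_a,conc_b [conc_profile()] objects.
#' @param times Simulation grid (strictly increasing, from 0).
#' @param folds Positive multipliers to apply (default
#'   `c(0.1, 0.5, 1, 2, 10)`).
#' @param control Solver settings.
#' @return A data frame with columns `fold`, `max_rel_dev_cross`
#'   (perturbing `k2a_b` and `k2b_a`) and `max_rel_dev_k2a` (perturbing
#'   `k2a` in the gamma-free combination model).
#' @export
potency_sensitivity_study <- function(spec, conc_a, conc_b, times,
                                      folds = c(0.1, 0.5, 1, 2, 10),
                                      control = list()) {
  stopifnot(inherits(spec, "first_attempt_spec"), all(folds > 0))
  base <- simulate_first_attempt(spec, conc_a, conc_b, times,
                                 control = control)
  base0 <- combo_spec(spec$growth, spec$drug_a, spec$drug_b, gamma = 0)
  ref0 <- simulate_combination(base0, conc_a, conc_b, times,
                               control = control)
  rows <- lapply(folds, function(f) {
    sp <- spec
    sp$k2a_b <- spec$k2a_b * f
    sp$k2b_a <- spec$k2b_a * f
    wf <- simulate_first_attempt(sp, conc_a, conc_b, times,
                                 control = control)$w
    dev_cross <- max(abs(wf - base$w) / base$w)
    sp2 <- base0
    sp2$drug_a <- drug_params(spec$drug_a$k1, spec$drug_a$k2 * f)
    w2 <- simulate_combination(sp2, conc_a, conc_b, times,
                               control = control)$w
    dev_k2a <- max(abs(w2 - ref0$w) / ref0$w)
    data.frame(fold = f, max_rel_dev_cross = dev_cross,
               max_rel_dev_k2a = dev_k2a)
  })
  do.call(rbind, rows)
}
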