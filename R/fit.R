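## Staged weighted least-squares identification of the combination TGI
## model.  Stage 1 (monotherapy): the seven parameters (w0, lambda0,
## lambda1, k1a, k2a, k1b, k2b) are fitted simultaneously on the control
## and single-agent arms, with the tumor-related parameters shared across
## arms.  Stage 2 (interaction): with those seven fixed, gamma is fitted
## on the control and combination arms.

param_names7 <- c("w0", "lambda0", "lambda1", "k1a", "k2a", "k1b", "k2b")

spec_from_params <- function(p, psi = 20) {
  combo_spec(
    growth = growth_params(p[["w0"]], p[["lambda0"]], p[["lambda1"]], psi),
    drug_a = drug_params(p[["k1a"]], p[["k2a"]]),
    drug_b = drug_params(p[["k1b"]], p[["k2b"]]),
    gamma = if ("gamma" %in% names(p)) p[["gamma"]] else 0)
}

## predicted group-mean weights of one arm at its observation times
predict_arm <- function(spec, arm, profiles, control = list()) {
  obs_t <- arm$observations$time
  grid <- sort(unique(c(0, obs_t)))
  traj <- switch(
    arm$arm_type,
    control = simulate_control(spec$growth, grid, control),
    single_a = simulate_monotherapy(spec$growth, spec$drug_a,
                                    profiles$a, grid, control),
    single_b = simulate_monotherapy(spec$growth, spec$drug_b,
                                    profiles$b, grid, control),
    combination = suppressWarnings(
      simulate_combination(spec, profiles$a, profiles$b, grid, control)))
  traj$w[match(obs_t, grid)]
}

## total observation count of a set of arms
n_obs_total <- function(arms)
  sum(vapply(arms, function(a) nrow(a$observations), 0L))

## residual evaluation that survives pathological parameter regions
## (e.g. strongly negative gamma blowing up the ODE): integration
## failures map to a large finite misfit so optimizers move away
safe_residuals <- function(spec, arms, profiles_by_arm, control) {
  tryCatch(
    suppressWarnings(wls_residuals(spec, arms, profiles_by_arm, control)),
    error = function(e) rep(1e4, n_obs_total(arms)))
}

## weighted residual vector over a set of arms: per observation
## (pred - obs) / obs / sqrt(n_arm), so that sum of squares equals the
## per-arm-normalized 1/y^2 WLS objective
wls_residuals <- function(spec, arms, profiles_by_arm, control = list()) {
  unlist(lapply(names(arms), function(id) {
    a <- arms[[id]]
    pred <- predict_arm(spec, a, profiles_by_arm[[id]], control)
    obs <- a$observations$weight
    ((pred - obs) / obs) / sqrt(length(obs))
  }), use.names = FALSE)
}

#' Weighted least-squares objective of the combination TGI model
#'
#' The fitting criterion: observations are weighted by `1/y_obs^2`
#' (constant relative error) and each arm's summed squared residuals are
#' divided by its observation count so that every arm contributes equally
#' regardless of sampling density:
#' \deqn{\sum_{arms} \frac{1}{n_{arm}} \sum_{obs}
#'   \frac{(y_{obs} - y_{pred})^2}{y_{obs}^2}.}
#'
#' @param data A [tumor_dataset()].
#' @param spec A [combo_spec()] supplying all model parameters.
#' @param arms Optional character vector of arm ids (default: all arms).
#' @param control Solver settings.
#' @return The scalar objective value.
#' @export
wls_objective <- function(data, spec, arms = NULL, control = list()) {
  stopifnot(inherits(data, "tumor_dataset"), inherits(spec, "combo_spec"))
  use <- if (is.null(arms)) data$arms else data$arms[arms]
  profs <- lapply(use, arm_profiles, data = data)
  sum(wls_residuals(spec, use, profs, control)^2)
}

#' Asymptotic parameter uncertainty from the residual Jacobian
#'
#' Standard nonlinear-least-squares asymptotics on the weighted residual
#' vector `r(theta)` (weights, including the per-arm normalization,
#' already folded in): `cov = s^2 (J'J)^-1` with
#' `s^2 = sum(r^2) / (n - p)`, and `CV% = 100 * se / |estimate|`.  A
#' rank-deficient Jacobian yields `NA` CVs with a diagnostic.
#'
#' @param jacobian Numeric matrix, `n x p`, of derivatives of the
#'   weighted residuals with respect to the parameters at the optimum.
#' @param residuals Weighted residual vector at the optimum (length `n`).
#' @param estimates Named parameter estimates (length `p`).
#' @return A list with `se`, `cv_percent`, `cov`, `s2` and `rank_ok`.
#' @export
parameter_cv <- function(jacobian, residuals, estimates) {
  jacobian <- as.matrix(jacobian)
  n <- length(residuals)
  p <- ncol(jacobian)
  if (n <= p) stop("need more residuals than parameters", call. = FALSE)
  s2 <- sum(residuals^2) / (n - p)
  qrj <- qr(jacobian)
  if (qrj$rank < p) {
    return(list(se = stats::setNames(rep(NA_real_, p), names(estimates)),
                cv_percent = stats::setNames(rep(NA_real_, p),
                                             names(estimates)),
                cov = NULL, s2 = s2, rank_ok = FALSE,
                message = sprintf(
                  "Jacobian rank %d < %d parameters; parameters are not locally identifiable",
                  qrj$rank, p)))
  }
  cov <- s2 * chol2inv(qr.R(qrj))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(estimates)
  list(se = se, cv_percent = 100 * se / abs(estimates), cov = cov,
       s2 = s2, rank_ok = TRUE)
}

#' Root-mean-square error in grams
#'
#' Unweighted `sqrt(mean((observed - predicted)^2))`, the goodness-of-fit
#' summary reported for each fitted arm.
#'
#' @param observed,predicted Numeric vectors of equal length (g).
#' @return RMSE in grams.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

## central finite-difference Jacobian of the weighted residuals with
## respect to the natural parameters
fd_jacobian <- function(fn, par, rel_step = 1e-5) {
  r0 <- fn(par)
  J <- matrix(NA_real_, nrow = length(r0), ncol = length(par))
  for (k in seq_along(par)) {
    h <- rel_step * max(abs(par[k]), 1e-8)
    up <- par; up[k] <- par[k] + h
    dn <- par; dn[k] <- par[k] - h
    J[, k] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

start_ranges <- list(w0 = c(0.01, 0.5), lambda0 = c(0.02, 0.6),
                     lambda1 = c(0.03, 1), k1a = c(0.1, 10),
                     k2a = c(1e-4, 1), k1b = c(0.1, 10),
                     k2b = c(1e-4, 1))

## data-informed starting point for the monotherapy stage
smart_start <- function(data, profiles_by_arm) {
  ctrl <- arms_of_type(data, "control")[[1]]$observations
  clip <- function(x, r) min(max(x, r[1]), r[2])
  l0 <- clip(log(ctrl$weight[2] / ctrl$weight[1]) /
               (ctrl$time[2] - ctrl$time[1]), start_ranges$lambda0)
  nl <- nrow(ctrl)
  l1 <- clip((ctrl$weight[nl] - ctrl$weight[nl - 1]) /
               (ctrl$time[nl] - ctrl$time[nl - 1]), start_ranges$lambda1)
  w0 <- clip(ctrl$weight[1] * exp(-l0 * ctrl$time[1]), start_ranges$w0)
  k2_start <- function(type, which) {
    arms <- arms_of_type(data, type)
    if (!length(arms)) return(0.01)
    prof <- profiles_by_arm[[arms[[1]]$arm_id]][[which]]
    a <- auc(prof)
    if (a > 0) clip(1 / a, start_ranges$k2a) else 0.01
  }
  c(w0 = w0, lambda0 = l0, lambda1 = l1,
    k1a = 1, k2a = k2_start("single_a", "a"),
    k1b = 1, k2b = k2_start("single_b", "b"))
}

#' Monotherapy stage: fit the seven single-agent parameters
#'
#' Simultaneous weighted least-squares fit of the control and
#' single-agent arms: the tumor-related parameters (`w0`, `lambda0`,
#' `lambda1`) are shared across arms while each drug keeps its own
#' (`k1`, `k2`).  Optimization is bounded-free on the log scale with
#' Levenberg-Marquardt refinement from `n_starts` starting points (one
#' data-informed, the rest drawn log-uniformly from physiologic ranges;
#' seed-controlled).
#'
#' @param data A [tumor_dataset()] with a control arm and at least one
#'   single-agent arm per drug.
#' @param psi Switching sharpness of the growth law (fixed, not
#'   estimated).
#' @param n_starts Number of multi-start points.
#' @param seed Optional integer seed for the random starts.
#' @param control Solver settings.
#' @return An object of class `"tgi_stage_fit"` with the seven estimates,
#'   their CV%, the pooled RMSE (g), residuals, fitted values and
#'   convergence diagnostics.
#' @export
fit_monotherapy <- function(data, psi = 20, n_starts = 8, seed = NULL,
                            control = list()) {
  stopifnot(inherits(data, "tumor_dataset"))
  if (!length(arms_of_type(data, "control")))
    stop("monotherapy stage requires a control arm", call. = FALSE)
  for (side in c("a", "b")) {
    type <- paste0("single_", side)
    if (!length(arms_of_type(data, type)))
      stop("monotherapy stage requires a ", type, " arm to identify drug ",
           toupper(side), "'s parameters", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  use <- Filter(function(a) a$arm_type %in% c("control", "single_a",
                                              "single_b"), data$arms)
  profs <- lapply(use, arm_profiles, data = data)
  resid_nat <- function(p) {
    names(p) <- param_names7
    safe_residuals(spec_from_params(p, psi), use, profs, control)
  }
  resid_log <- function(theta) resid_nat(exp(theta))

  starts <- list(log(smart_start(data, profs)))
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- vapply(start_ranges, function(r)
        stats::runif(1, log(r[1]), log(r[2])), 0)
    }
  }
  fits <- lapply(starts, function(th0) {
    tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_log,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
  })
  dev <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance, 0)
  if (all(!is.finite(dev)))
    stop("all monotherapy-stage starts failed to converge", call. = FALSE)
  best <- which.min(dev)
  fit <- fits[[best]]
  est <- exp(fit$par)
  names(est) <- param_names7

  r <- resid_nat(est)
  J <- fd_jacobian(function(p) { names(p) <- param_names7; resid_nat(p) },
                   est)
  uncert <- parameter_cv(J, r, est)

  spec <- spec_from_params(est, psi)
  fitted_arms <- lapply(names(use), function(id) {
    pred <- predict_arm(spec, use[[id]], profs[[id]], control)
    data.frame(arm_id = id, time = use[[id]]$observations$time,
               observed = use[[id]]$observations$weight, fitted = pred,
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, fitted_arms)
  structure(
    list(stage = "monotherapy", estimates = est, se = uncert$se,
         cv_percent = uncert$cv_percent, cov = uncert$cov,
         rmse = rmse(pooled$observed, pooled$fitted),
         objective = fit$deviance, residuals = r, fitted = pooled,
         psi = psi,
         convergence = list(n_starts = n_starts, best_start = best,
                            deviances = dev, info = fit$info,
                            message = fit$message,
                            rank_ok = uncert$rank_ok),
         seed = seed),
    class = "tgi_stage_fit")
}

#' Interaction stage: fit gamma with the monotherapy parameters fixed
#'
#' With the seven single-agent parameters fixed, the interaction
#' parameter `gamma` is estimated by weighted least squares on the
#' control and combination arms (the control arm carries no information
#' on `gamma` but is included in the criterion as fitted).  A coarse
#' bounded scan locates the basin and Levenberg-Marquardt refines it.
#'
#' When `fixed` is a [fit_monotherapy()] result carrying a covariance
#' matrix, the reported standard error of `gamma` includes the
#' delta-method propagation of the stage-1 parameter uncertainty (the
#' purely conditional SE is kept as `se_conditional`); intervals built
#' from the conditional SE alone would be too narrow.
#'
#' @param data A [tumor_dataset()] with at least one combination arm.
#' @param fixed Either a `"tgi_stage_fit"` from [fit_monotherapy()] or a
#'   named vector with `w0, lambda0, lambda1, k1a, k2a, k1b, k2b`.
#' @param gamma_bounds Search interval for `gamma`, uM^-2 day^-2.
#' @param psi Switching sharpness (ignored when `fixed` is a stage fit).
#' @param control Solver settings.
#' @return An object of class `"tgi_stage_fit"` with the `gamma`
#'   estimate, its CV%, and the RMSE (g) on the combination arm(s).
#' @export
fit_interaction <- function(data, fixed, gamma_bounds = c(-100, 100),
                            psi = 20, control = list()) {
  stopifnot(inherits(data, "tumor_dataset"))
  stage1_cov <- NULL
  if (inherits(fixed, "tgi_stage_fit")) {
    psi <- fixed$psi
    if (isTRUE(fixed$convergence$rank_ok)) stage1_cov <- fixed$cov
    fixed <- fixed$estimates
  }
  miss <- setdiff(param_names7, names(fixed))
  if (length(miss))
    stop("'fixed' is missing parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!length(arms_of_type(data, "combination")))
    stop("interaction stage requires a combination arm", call. = FALSE)
  use <- Filter(function(a) a$arm_type %in% c("control", "combination"),
                data$arms)
  profs <- lapply(use, arm_profiles, data = data)
  resid_g <- function(gamma) {
    p <- c(fixed[param_names7], gamma = unname(gamma))
    safe_residuals(spec_from_params(p, psi), use, profs, control)
  }
  obj <- function(gamma) sum(resid_g(gamma)^2)
  grid <- seq(gamma_bounds[1], gamma_bounds[2], length.out = 41)
  vals <- vapply(grid, obj, 0)
  g0 <- grid[which.min(vals)]
  fit <- minpack.lm::nls.lm(par = c(gamma = g0), fn = resid_g,
                            lower = gamma_bounds[1],
                            upper = gamma_bounds[2],
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-13, ptol = 1e-12))
  g_hat <- unname(fit$par)
  if (min(abs(g_hat - gamma_bounds)) < 1e-6 * diff(gamma_bounds))
    warning("gamma estimate lies on the search bound; widen 'gamma_bounds'",
            call. = FALSE)
  r <- resid_g(g_hat)
  J <- fd_jacobian(function(g) resid_g(g), g_hat)
  est <- c(gamma = g_hat)
  uncert <- parameter_cv(J, r, est)
  se_conditional <- uncert$se
  ## propagate the stage-1 parameter uncertainty into se(gamma): the
  ## stage-2 estimator depends on the plugged-in monotherapy parameters,
  ## so var(gamma) = conditional var + (d gamma / d theta1)' Cov1 (...)
  if (!is.null(stage1_cov) && uncert$rank_ok) {
    resid_full <- function(theta7) {
      p <- c(theta7[param_names7], gamma = g_hat)
      safe_residuals(spec_from_params(p, psi), use, profs, control)
    }
    J7 <- fd_jacobian(function(th) {
      names(th) <- param_names7
      resid_full(th)
    }, fixed[param_names7])
    a <- sum(J^2)
    dg_dtheta <- -(crossprod(J, J7)) / a      # 1 x 7
    var_prop <- as.numeric(dg_dtheta %*% stage1_cov %*% t(dg_dtheta))
    total <- sqrt(uncert$se["gamma"]^2 + max(var_prop, 0))
    uncert$se["gamma"] <- total
    uncert$cv_percent["gamma"] <- 100 * total / abs(est["gamma"])
  }

  spec <- spec_from_params(c(fixed[param_names7], gamma = g_hat), psi)
  comb <- Filter(function(a) a$arm_type == "combination", use)
  fitted_arms <- lapply(names(comb), function(id) {
    pred <- predict_arm(spec, comb[[id]], profs[[id]], control)
    data.frame(arm_id = id, time = comb[[id]]$observations$time,
               observed = comb[[id]]$observations$weight, fitted = pred,
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, fitted_arms)
  structure(
    list(stage = "interaction", estimates = est, se = uncert$se,
         cv_percent = uncert$cv_percent, cov = uncert$cov,
         rmse = rmse(pooled$observed, pooled$fitted),
         objective = fit$deviance, residuals = r, fitted = pooled,
         psi = psi, fixed = fixed[param_names7],
         se_conditional = se_conditional,
         convergence = list(scan_minimum = g0, info = fit$info,
                            message = fit$message,
                            rank_ok = uncert$rank_ok),
         seed = NULL),
    class = "tgi_stage_fit")
}

#' @export
print.tgi_stage_fit <- function(x, digits = 4, ...) {
  cat(sprintf("TGI model fit, %s stage\n", x$stage))
  tab <- cbind(Estimate = x$estimates, `CV%` = x$cv_percent)
  print(round(tab, digits))
  cat(sprintf("objective = %s, RMSE = %s g\n",
              format(x$objective, digits = digits),
              format(x$rmse, digits = digits)))
  invisible(x)
}

#' Fit the combination TGI model to a xenograft dataset
#'
#' The modelling front-end.  `method = "staged"` (default, the
#' recommended strategy) first fits the seven single-agent parameters on
#' the control and monotherapy arms ([fit_monotherapy()]), then fixes
#' them and fits the interaction parameter `gamma` on the control and
#' combination arms ([fit_interaction()]), so that all of the drug-effect
#' interaction is captured by `gamma` alone.  `method = "joint"` fits all
#' eight parameters simultaneously on all arms (for comparison).
#'
#' @param data A [tumor_dataset()].
#' @param method `"staged"` or `"joint"`.
#' @param psi Switching sharpness of the growth law (fixed).
#' @param n_starts Multi-start points for the 7/8-parameter searches.
#' @param seed Optional integer seed (random starts).
#' @param gamma_bounds Search interval for `gamma`.
#' @param control Solver settings (`rtol`, `atol`, `maxsteps`).
#' @return An object of class `"tgi_fit"` with methods [print()],
#'   [summary()], [coef()], [predict.tgi_fit()], [plot.tgi_fit()],
#'   [residuals.tgi_fit()], [fitted.tgi_fit()] and [simulate.tgi_fit()].
#' @examples
#' \donttest{
#' fx <- experiment_fixture("c1")
#' dat <- generate_tumor_dataset(default_truth(gamma = 1), fx$regimens,
#'                               synthetic_pk_library(), seed = 1)
#' fit <- tgi_fit(dat, seed = 1, n_starts = 2)
#' summary(fit)
#' }
#' @export
tgi_fit <- function(data, method = c("staged", "joint"), psi = 20,
                    n_starts = 8, seed = NULL,
                    gamma_bounds = c(-100, 100), control = list()) {
  stopifnot(inherits(data, "tumor_dataset"))
  method <- match.arg(method)
  cl <- match.call()
  if (method == "staged") {
    s1 <- fit_monotherapy(data, psi = psi, n_starts = n_starts,
                          seed = seed, control = control)
    s2 <- fit_interaction(data, fixed = s1, gamma_bounds = gamma_bounds,
                          control = control)
    estimates <- c(s1$estimates, s2$estimates)
    se <- c(s1$se, s2$se)
    cv <- c(s1$cv_percent, s2$cv_percent)
    stages <- list(monotherapy = s1, interaction = s2)
    rmse_out <- c(monotherapy = s1$rmse, combination = s2$rmse)
    objective <- c(monotherapy = s1$objective,
                   interaction = s2$objective)
  } else {
    jf <- fit_joint_impl(data, psi = psi, n_starts = n_starts,
                         seed = seed, gamma_bounds = gamma_bounds,
                         control = control)
    estimates <- jf$estimates
    se <- jf$se
    cv <- jf$cv_percent
    stages <- list(joint = jf)
    rmse_out <- c(all_arms = jf$rmse)
    objective <- c(joint = jf$objective)
  }
  structure(
    list(call = cl, method = method, estimates = estimates, se = se,
         cv_percent = cv, rmse = rmse_out, objective = objective,
         stages = stages, data = data, psi = psi, seed = seed,
         classification = classify_interaction(estimates[["gamma"]],
                                               se[["gamma"]])),
    class = "tgi_fit")
}

#' Joint eight-parameter fit (all arms simultaneously)
#'
#' @inheritParams tgi_fit
#' @return A `"tgi_stage_fit"`.
#' @export
fit_joint <- function(data, psi = 20, n_starts = 8, seed = NULL,
                      gamma_bounds = c(-100, 100), control = list()) {
  fit_joint_impl(data, psi, n_starts, seed, gamma_bounds, control)
}

fit_joint_impl <- function(data, psi, n_starts, seed, gamma_bounds,
                           control) {
  if (!length(arms_of_type(data, "control")))
    stop("joint fit requires a control arm", call. = FALSE)
  for (side in c("a", "b")) {
    if (!length(arms_of_type(data, paste0("single_", side))))
      stop("joint fit requires a single_", side, " arm; the model is not ",
           "identifiable from a combination arm alone", call. = FALSE)
  }
  if (!length(arms_of_type(data, "combination")))
    stop("joint fit requires a combination arm to identify gamma",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  use <- data$arms
  profs <- lapply(use, arm_profiles, data = data)
  ## theta = (log of the 7 positive parameters, gamma on the natural scale)
  resid_theta <- function(theta) {
    p <- c(exp(theta[1:7]), theta[8])
    names(p) <- c(param_names7, "gamma")
    safe_residuals(spec_from_params(p, psi), use, profs, control)
  }
  starts <- list(c(log(smart_start(data, profs)), gamma = 0))
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      th <- vapply(start_ranges, function(r)
        stats::runif(1, log(r[1]), log(r[2])), 0)
      starts[[i + 1]] <- c(th, gamma = stats::runif(1, -2, 2))
    }
  }
  lower <- c(rep(-Inf, 7), gamma_bounds[1])
  upper <- c(rep(Inf, 7), gamma_bounds[2])
  fits <- lapply(starts, function(th0) {
    tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_theta, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-10)),
      error = function(e) NULL)
  })
  dev <- vapply(fits, function(f) if (is.null(f)) Inf else f$deviance, 0)
  if (all(!is.finite(dev)))
    stop("all joint-fit starts failed to converge", call. = FALSE)
  fit <- fits[[which.min(dev)]]
  est <- c(exp(fit$par[1:7]), fit$par[8])
  names(est) <- c(param_names7, "gamma")

  resid_nat <- function(p) {
    names(p) <- c(param_names7, "gamma")
    wls_residuals(spec_from_params(p, psi), use, profs, control)
  }
  r <- resid_nat(est)
  J <- fd_jacobian(resid_nat, est)
  uncert <- parameter_cv(J, r, est)
  spec <- spec_from_params(est, psi)
  fitted_arms <- lapply(names(use), function(id) {
    pred <- predict_arm(spec, use[[id]], profs[[id]], control)
    data.frame(arm_id = id, time = use[[id]]$observations$time,
               observed = use[[id]]$observations$weight, fitted = pred,
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, fitted_arms)
  structure(
    list(stage = "joint", estimates = est, se = uncert$se,
         cv_percent = uncert$cv_percent, cov = uncert$cov,
         rmse = rmse(pooled$observed, pooled$fitted),
         objective = fit$deviance, residuals = r, fitted = pooled,
         psi = psi,
         convergence = list(n_starts = n_starts,
                            best_start = which.min(dev),
                            deviances = dev, info = fit$info,
                            message = fit$message,
                            rank_ok = uncert$rank_ok),
         seed = seed),
    class = "tgi_stage_fit")
}

#' Extract the fitted model specification
#'
#' @param fit A `"tgi_fit"` (or a named 8-parameter vector).
#' @param psi Switching sharpness when `fit` is a bare vector.
#' @return A [combo_spec()].
#' @export
as_combo_spec <- function(fit, psi = 20) {
  if (inherits(fit, "tgi_fit"))
    spec_from_params(fit$estimates, fit$psi)
  else spec_from_params(fit, psi)
}

#' @export
coef.tgi_fit <- function(object, ...) object$estimates

#' @export
print.tgi_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Combination TGI model fit (%s)\n\n", x$method))
  print(round(x$estimates, digits))
  cat(sprintf("\ngamma = %s /uM^2/day^2 (CV = %s%%): %s interaction\n",
              format(x$estimates[["gamma"]], digits = digits),
              format(x$cv_percent[["gamma"]], digits = 3),
              x$classification))
  invisible(x)
}

#' @export
summary.tgi_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$estimates, `Std. Error` = object$se,
               `CV%` = object$cv_percent)
  out <- list(call = object$call, method = object$method,
              coefficients = tab, rmse = object$rmse,
              objective = object$objective,
              classification = object$classification,
              psi = object$psi)
  class(out) <- "summary.tgi_fit"
  out
}

#' @export
print.summary.tgi_fit <- function(x, digits = 4, ...) {
  cat("Combination tumor growth inhibition model\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Fitting strategy: %s (psi = %g)\n\n", x$method, x$psi))
  print(round(x$coefficients, digits))
  cat("\nRMSE (g):", paste(sprintf("%s = %s", names(x$rmse),
                                   format(x$rmse, digits = 3)),
                           collapse = ", "), "\n")
  cat(sprintf("Drug-effect interaction: %s\n", x$classification))
  invisible(x)
}

#' @export
residuals.tgi_fit <- function(object,
                              type = c("weighted", "relative", "raw"),
                              ...) {
  type <- match.arg(type)
  tabs <- lapply(object$stages, `[[`, "fitted")
  df <- unique(do.call(rbind, tabs))
  raw <- df$fitted - df$observed
  r <- switch(type,
              raw = raw,
              relative = raw / df$observed,
              weighted = {
                n_by_arm <- table(df$arm_id)
                raw / df$observed / sqrt(as.numeric(n_by_arm[df$arm_id]))
              })
  data.frame(arm_id = df$arm_id, time = df$time, residual = r,
             stringsAsFactors = FALSE)
}

#' @export
fitted.tgi_fit <- function(object, ...) {
  unique(do.call(rbind, lapply(object$stages, `[[`, "fitted")))
}

#' Predict a new combination arm from a fitted model
#'
#' Pure simulation (no refitting): the fitted parameters, including
#' `gamma`, are transported to a new dose/schedule of the same two drugs,
#' giving the predicted tumor growth curve and the predicted interaction
#' indexes for the new regimen.
#'
#' @param object A `"tgi_fit"`.
#' @param regimens Named list `list(a = , b = )` of [regimen()] objects
#'   for the new arm (defaults to the combination regimens of the fitted
#'   dataset).
#' @param times Output grid (default: day 0 to 1.5x the last dose or last
#'   observation, step 0.5).
#' @param control Solver settings.
#' @param ... Unused.
#' @return A list of class `"tgi_prediction"` with the predicted
#'   `trajectory` (and `ptgc`, the zero-interaction reference) and
#'   `indexes` ([interaction_indexes()], closed form).
#' @export
predict.tgi_fit <- function(object, regimens = NULL, times = NULL,
                            control = list(), ...) {
  spec <- as_combo_spec(object)
  data <- object$data
  if (is.null(regimens)) {
    comb <- arms_of_type(data, "combination")[[1]]
    ids <- data$drugs
    regimens <- list(a = comb$regimens[[ids["a"]]],
                     b = comb$regimens[[ids["b"]]])
  }
  pa <- conc_profile(data$pk_library[[regimens$a$drug_id]], regimens$a)
  pb <- conc_profile(data$pk_library[[regimens$b$drug_id]], regimens$b)
  if (is.null(times)) {
    tmax <- max(c(unlist(lapply(data$arms, function(a)
      a$observations$time)), 1.5 * max(c(pa$dose_times, pb$dose_times, 1))))
    times <- seq(0, tmax, by = 0.5)
  }
  traj <- simulate_combination(spec, pa, pb, times, control = control)
  ptgc <- simulate_zero_interaction(spec, pa, pb, times,
                                    control = control)
  idx <- interaction_indexes(spec, pa, pb, method = "closed_form",
                             gamma_se = object$se[["gamma"]])
  structure(list(trajectory = traj, ptgc = ptgc, indexes = idx,
                 regimens = regimens),
            class = "tgi_prediction")
}

#' @export
print.tgi_prediction <- function(x, ...) {
  cat("Predicted combination arm (no fitting)\n")
  print(x$trajectory)
  print(x$indexes)
  invisible(x)
}

#' Simulate new datasets from a fitted model
#'
#' Parametric-bootstrap style: generates synthetic group-mean datasets
#' from the fitted parameter values under the fitted dataset's
#' combination regimens, with proportional noise.
#'
#' @param object A `"tgi_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param cv,n_animals Noise settings (see [generate_tumor_dataset()]).
#' @param ... Unused.
#' @return A list of [tumor_dataset()] objects (length `nsim`).
#' @export
simulate.tgi_fit <- function(object, nsim = 1, seed = NULL, cv = 0.1,
                             n_animals = 8, ...) {
  if (!is.null(seed)) set.seed(seed)
  data <- object$data
  comb <- arms_of_type(data, "combination")[[1]]
  ids <- data$drugs
  regimens <- list(a = comb$regimens[[ids["a"]]],
                   b = comb$regimens[[ids["b"]]])
  times <- comb$observations$time
  lapply(seq_len(nsim), function(i)
    generate_tumor_dataset(as_combo_spec(object), regimens,
                           data$pk_library, times = times, cv = cv,
                           n_animals = n_animals))
}

#' @export
plot.tgi_fit <- function(x, ...) {
  df <- fitted(x)
  arms <- unique(df$arm_id)
  cols <- grDevices::hcl.colors(max(3, length(arms)), "Dark 3")
  obs_all <- do.call(rbind, lapply(x$data$arms, function(a)
    cbind(a$observations, arm_id = a$arm_id)))
  graphics::plot(NA, xlim = range(obs_all$time),
                 ylim = c(0, max(obs_all$weight + obs_all$se) * 1.05),
                 xlab = "time (days)", ylab = "tumor weight (g)",
                 main = "observed (points +/- SE) and fitted (lines)", ...)
  for (i in seq_along(arms)) {
    sub <- df[df$arm_id == arms[i], ]
    obs <- obs_all[obs_all$arm_id == arms[i], ]
    graphics::points(obs$time, obs$weight, col = cols[i], pch = 16)
    graphics::arrows(obs$time, obs$weight - obs$se, obs$time,
                     obs$weight + obs$se, angle = 90, code = 3,
                     length = 0.02, col = cols[i])
    graphics::lines(sub$time, sub$fitted, col = cols[i])
  }
  graphics::legend("topleft", legend = arms, col = cols[seq_along(arms)],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}
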