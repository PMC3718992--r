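#' Time efficacy index of a combination regimen (closed form)
#'
#' The time efficacy index (TEI) is the asymptotic horizontal delay
#' between the treated and control tumor growth curves.  For the
#' combination model it is well approximated by
#' \deqn{TEI_{comb} \approx (k_{2a} AUC_{c_a} + k_{2b} AUC_{c_b} +
#'   \gamma AUC_{c_a c_b}) / \lambda_0,}
#' the total log-growth lost to the kill terms on the proliferating cells
#' divided by the exponential growth rate.  With `gamma = 0` this is the
#' additive reference `TEI_add`.
#'
#' @param k2a,k2b Drug potencies, uM^-1 day^-1.
#' @param auc_a,auc_b AUC of each drug's concentration curve, uM day
#'   (full-washout horizon).
#' @param gamma Interaction parameter, uM^-2 day^-2.
#' @param auc_ab AUC of the product of the two concentration curves,
#'   uM^2 day.
#' @param lambda0 Exponential growth rate, day^-1 (> 0).
#' @return Delay in days.
#' @export
tei_combination <- function(k2a, auc_a, k2b, auc_b, gamma, auc_ab,
                            lambda0) {
  if (!is.finite(lambda0) || lambda0 <= 0)
    stop("'lambda0' must be > 0", call. = FALSE)
  if (any(c(auc_a, auc_b, auc_ab) < 0))
    stop("AUC quantities must be >= 0", call. = FALSE)
  (k2a * auc_a + k2b * auc_b + gamma * auc_ab) / lambda0
}

#' @rdname tei_combination
#' @export
tei_additive <- function(k2a, auc_a, k2b, auc_b, lambda0)
  tei_combination(k2a, auc_a, k2b, auc_b, 0, 0, lambda0)

#' Interaction time-shift between combination curve and PTGC (closed form)
#'
#' The signed horizontal shift of the combination growth curve with
#' respect to the zero-interaction reference (PTGC), attributable to the
#' interaction alone: `Delta ~ gamma * AUC_{c_a c_b} / lambda0`.
#'
#' @inheritParams tei_combination
#' @return Shift in days; positive for synergy, negative for antagonism.
#' @export
interaction_shift <- function(gamma, auc_ab, lambda0) {
  if (!is.finite(lambda0) || lambda0 <= 0)
    stop("'lambda0' must be > 0", call. = FALSE)
  gamma * auc_ab / lambda0
}

#' Synergistic and antagonistic combination indexes
#'
#' `synergy_index()` computes `SC = 100 * Delta / TEI_comb` (percentage of
#' the total efficacy delay attributable to the interaction; defined for
#' `Delta > 0`).  `antagonism_index()` computes
#' `AC = 100 * (-Delta) / TEI_add` (interaction loss as a percentage of
#' the additive delay; defined for `Delta < 0`).
#'
#' @param delta Interaction time-shift, days.
#' @param tei_comb,tei_add Combination / additive time efficacy index,
#'   days (> 0).
#' @return Percentage in (0, 100].
#' @export
synergy_index <- function(delta, tei_comb) {
  if (delta <= 0)
    stop("'delta' must be > 0 for the synergy index; use antagonism_index() for delta < 0",
         call. = FALSE)
  if (tei_comb <= 0 || delta > tei_comb)
    stop("need 0 < delta <= tei_comb", call. = FALSE)
  100 * delta / tei_comb
}

#' @rdname synergy_index
#' @export
antagonism_index <- function(delta, tei_add) {
  if (delta >= 0)
    stop("'delta' must be < 0 for the antagonism index; use synergy_index() for delta > 0",
         call. = FALSE)
  if (tei_add <= 0) stop("'tei_add' must be > 0", call. = FALSE)
  100 * (-delta) / tei_add
}

#' Numeric asymptotic delay between two growth curves
#'
#' Measures the horizontal distance between two trajectories at a
#' reference weight `w_ref` chosen in the post-washout regrowth phase:
#' `t_treated(w_ref) - t_reference(w_ref)`, with each time-at-weight
#' obtained by monotone interpolation of the last upcrossing.  This is
#' the operational counterpart of the closed-form [tei_combination()] and
#' [interaction_shift()] approximations.
#'
#' @param treated,reference `tgi_trajectory` objects on a common (dense)
#'   grid.
#' @param w_ref Reference weight, g; by default `2 * lambda1 / lambda0`
#'   should be used (well inside the linear growth regime).
#' @return Delay in days (positive when `treated` lags `reference`).
#' @export
asymptotic_delay <- function(treated, reference, w_ref) {
  stopifnot(inherits(treated, "tgi_trajectory"),
            inherits(reference, "tgi_trajectory"))
  t_at <- function(traj, label) {
    w <- traj$w; tt <- traj$times
    if (max(w) < w_ref) {
      ## estimate the extra follow-up needed, assuming linear-phase growth
      slope <- (w[length(w)] - w[length(w) - 1]) /
        (tt[length(tt)] - tt[length(tt) - 1])
      need <- if (slope > 0) (w_ref - max(w)) / slope else Inf
      stop(sprintf(
        "'%s' curve never reaches w_ref = %g g; extend the window by ~%.1f days",
        label, w_ref, need), call. = FALSE)
    }
    below <- which(w < w_ref)
    if (!length(below)) return(tt[1])
    i <- max(below)            # last upcrossing
    if (i == length(w))
      stop(sprintf("'%s' curve ends below w_ref", label), call. = FALSE)
    tt[i] + (w_ref - w[i]) / (w[i + 1] - w[i]) * (tt[i + 1] - tt[i])
  }
  t_at(treated, "treated") - t_at(reference, "reference")
}

#' Classify the drug-effect interaction from the gamma estimate
#'
#' Synergistic if the estimate is significantly above zero, antagonistic
#' if significantly below, additive otherwise, using the asymptotic
#' normal interval `gamma_est -/+ z * se`.
#'
#' @param gamma_est Estimated interaction parameter, uM^-2 day^-2.
#' @param gamma_se Its standard error (>= 0).
#' @param z Normal quantile for the interval (default 1.96, i.e. 95%).
#' @return One of `"synergistic"`, `"antagonistic"`, `"additive"`.
#' @export
classify_interaction <- function(gamma_est, gamma_se, z = 1.96) {
  if (!is.finite(gamma_se) || gamma_se < 0)
    stop("'gamma_se' must be >= 0", call. = FALSE)
  if (gamma_est - z * gamma_se > 0) "synergistic"
  else if (gamma_est + z * gamma_se < 0) "antagonistic"
  else "additive"
}

#' Interaction indexes of a fitted or specified combination model
#'
#' Computes the full set of interaction indexes for one combination
#' regimen: `TEI_comb`, `TEI_add`, the interaction shift `Delta`, and the
#' synergy (`SC`) or antagonism (`AC`) percentage, either from the
#' closed-form AUC approximations (`method = "closed_form"`, the default)
#' or numerically from simulated curves via [asymptotic_delay()]
#' (`method = "numeric"`).  `|Delta|` below `delta_eps` reports neither
#' SC nor AC (additive).
#'
#' @param spec A [combo_spec()] (e.g. from a fitted model via
#'   [as_combo_spec()]).
#' @param conc_a,conc_b [conc_profile()] objects for the combination
#'   regimen.
#' @param method `"closed_form"` or `"numeric"`.
#' @param gamma_se Optional standard error of `gamma` for the
#'   classification; when missing the classification uses the sign of
#'   `Delta` only (with `delta_eps` as the additivity band).
#' @param horizon AUC horizon, days (default `Inf`, full washout).
#' @param t_max Simulation horizon for `method = "numeric"`; defaults to
#'   five times the last dose time.
#' @param w_ref Reference weight for the numeric delay; default
#'   `2 * lambda1 / lambda0`.
#' @param delta_eps Additivity band on `Delta`, days.
#' @param control Solver settings (numeric method).
#' @return An object of class `"interaction_indexes"`: a list with
#'   `tei_comb`, `tei_add`, `delta`, `sc`, `ac` (exactly one of `sc`/`ac`
#'   is non-`NA` when `|delta| > delta_eps`), `gamma_used`,
#'   `classification` and `method`.
#' @export
interaction_indexes <- function(spec, conc_a, conc_b,
                                method = c("closed_form", "numeric"),
                                gamma_se = NULL, horizon = Inf,
                                t_max = NULL, w_ref = NULL,
                                delta_eps = 1e-6, control = list()) {
  stopifnot(inherits(spec, "combo_spec"))
  method <- match.arg(method)
  g <- spec$growth
  if (method == "closed_form") {
    auc_a <- auc(conc_a, horizon = horizon)
    auc_b <- auc(conc_b, horizon = horizon)
    auc_ab <- auc_product(conc_a, conc_b, horizon = horizon)
    tei_c <- tei_combination(spec$drug_a$k2, auc_a, spec$drug_b$k2, auc_b,
                             spec$gamma, auc_ab, g$lambda0)
    tei_a <- tei_additive(spec$drug_a$k2, auc_a, spec$drug_b$k2, auc_b,
                          g$lambda0)
    delta <- interaction_shift(spec$gamma, auc_ab, g$lambda0)
  } else {
    last_dose <- max(c(conc_a$dose_times, conc_b$dose_times, 1))
    if (is.null(t_max)) t_max <- 5 * last_dose
    if (is.null(w_ref)) w_ref <- 2 * g$lambda1 / g$lambda0
    tt <- seq(0, t_max, by = min(0.25, t_max / 400))
    ctrl <- simulate_control(g, tt, control = control)
    comb <- simulate_combination(spec, conc_a, conc_b, tt,
                                 control = control)
    ptgc <- simulate_zero_interaction(spec, conc_a, conc_b, tt,
                                      control = control)
    tei_c <- asymptotic_delay(comb, ctrl, w_ref)
    tei_a <- asymptotic_delay(ptgc, ctrl, w_ref)
    delta <- asymptotic_delay(comb, ptgc, w_ref)
  }
  sc <- ac <- NA_real_
  if (delta > delta_eps) sc <- synergy_index(delta, tei_c)
  else if (delta < -delta_eps) ac <- antagonism_index(delta, tei_a)
  classification <- if (!is.null(gamma_se))
    classify_interaction(spec$gamma, gamma_se)
  else if (delta > delta_eps) "synergistic"
  else if (delta < -delta_eps) "antagonistic"
  else "additive"
  structure(list(tei_comb = tei_c, tei_add = tei_a, delta = delta,
                 sc = sc, ac = ac, gamma_used = spec$gamma,
                 classification = classification, method = method),
            class = "interaction_indexes")
}

#' @export
print.interaction_indexes <- function(x, digits = 4, ...) {
  cat(sprintf("Drug-effect interaction indexes (%s)\n", x$method))
  cat(sprintf("  gamma    = %s /uM^2/day^2\n",
              format(x$gamma_used, digits = digits)))
  cat(sprintf("  TEI_comb = %s days   TEI_add = %s days\n",
              format(x$tei_comb, digits = digits),
              format(x$tei_add, digits = digits)))
  cat(sprintf("  Delta    = %s days\n", format(x$delta, digits = digits)))
  if (!is.na(x$sc))
    cat(sprintf("  SC = %s %% (synergistic contribution to TEI_comb)\n",
                format(x$sc, digits = digits)))
  if (!is.na(x$ac))
    cat(sprintf("  AC = %s %% (antagonistic loss relative to TEI_add)\n",
                format(x$ac, digits = digits)))
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

#' @export
as.data.frame.interaction_indexes <- function(x, ...) {
  data.frame(tei_comb = x$tei_comb, tei_add = x$tei_add, delta = x$delta,
             sc = x$sc, ac = x$ac, gamma = x$gamma_used,
             classification = x$classification, method = x$method,
             stringsAsFactors = FALSE)
}
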