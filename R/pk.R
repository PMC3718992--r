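#' Linear compartmental pharmacokinetic model of one drug
#'
#' Describes the plasma kinetics of a single drug with a standard one- or
#' two-compartment linear model, optionally with first-order oral
#' absorption.  All the drug concentration curves used by the tumor growth
#' models are closed-form superpositions of single-dose responses of such a
#' model.
#'
#' @param n_compartments 1 or 2.
#' @param volume Central volume of distribution, L/kg.
#' @param elimination_rate First-order elimination rate constant from the
#'   central compartment (`k10`), day^-1.
#' @param k12,k21 Inter-compartment rate constants, day^-1; required iff
#'   `n_compartments == 2`.
#' @param absorption_rate First-order oral absorption rate constant `ka`,
#'   day^-1; required for regimens containing oral doses.
#' @param bioavailability Oral bioavailability fraction in \[0, 1\].
#' @return An object of class `"pk_model"`.
#' @examples
#' pk <- pk_model(1, volume = 2, elimination_rate = 1)
#' reg <- regimen("drug", times = 0, amounts = 10, route = "iv_bolus")
#' conc_at(conc_profile(pk, reg), c(0, 1))
#' @seealso [regimen()], [conc_profile()], [auc()]
#' @export
pk_model <- function(n_compartments = 1, volume, elimination_rate,
                     k12 = NULL, k21 = NULL,
                     absorption_rate = NULL, bioavailability = 1) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(1L, 2L))
    stop("'n_compartments' must be 1 or 2", call. = FALSE)
  stopifnot(is.numeric(volume), length(volume) == 1L, is.finite(volume))
  if (volume <= 0) stop("'volume' must be > 0", call. = FALSE)
  if (!is.finite(elimination_rate) || elimination_rate <= 0)
    stop("'elimination_rate' must be > 0", call. = FALSE)
  if (n_compartments == 2L) {
    if (is.null(k12) || is.null(k21))
      stop("two-compartment model requires 'k12' and 'k21'", call. = FALSE)
    if (k12 <= 0 || k21 <= 0)
      stop("'k12' and 'k21' must be > 0", call. = FALSE)
  } else if (!is.null(k12) || !is.null(k21)) {
    stop("'k12'/'k21' are only meaningful for a two-compartment model",
         call. = FALSE)
  }
  if (!is.null(absorption_rate) && absorption_rate <= 0)
    stop("'absorption_rate' must be > 0", call. = FALSE)
  if (bioavailability < 0 || bioavailability > 1)
    stop("'bioavailability' must be in [0, 1]", call. = FALSE)
  structure(
    list(n_compartments = n_compartments, volume = volume,
         elimination_rate = elimination_rate, k12 = k12, k21 = k21,
         absorption_rate = absorption_rate,
         bioavailability = bioavailability),
    class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("Linear %d-compartment PK model\n", x$n_compartments))
  cat(sprintf("  V = %g L/kg, k10 = %g /day", x$volume, x$elimination_rate))
  if (x$n_compartments == 2L)
    cat(sprintf(", k12 = %g, k21 = %g /day", x$k12, x$k21))
  cat("\n")
  if (!is.null(x$absorption_rate))
    cat(sprintf("  oral: ka = %g /day, F = %g\n",
                x$absorption_rate, x$bioavailability))
  invisible(x)
}

#' Dosing regimen of one drug
#'
#' An ordered sequence of dose events (time, amount, route) for a single
#' drug.  An empty regimen (no events) means the drug is not given.
#'
#' @param drug_id Character label identifying the drug; used to look the
#'   drug up in a PK library.
#' @param times Administration times, days (>= 0).
#' @param amounts Dose amounts, micromol/kg (>= 0); recycled to
#'   `length(times)`.
#' @param route `"iv_bolus"` or `"oral"`; recycled likewise.
#' @return An object of class `"regimen"` carrying a data frame of events
#'   sorted by time.
#' @examples
#' regimen("CPT-11", times = c(9, 13, 17), amounts = 72.9, route = "iv_bolus")
#' @export
regimen <- function(drug_id, times = numeric(), amounts = numeric(),
                    route = "iv_bolus") {
  stopifnot(is.character(drug_id), length(drug_id) == 1L)
  n <- length(times)
  amounts <- rep_len(amounts, n)
  route <- rep_len(as.character(route), n)
  if (n > 0) {
    if (any(!is.finite(times)) || any(times < 0))
      stop("dose times must be finite and >= 0", call. = FALSE)
    if (any(!is.finite(amounts)) || any(amounts < 0))
      stop("dose amounts must be finite and >= 0 umol/kg", call. = FALSE)
    bad <- setdiff(unique(route), c("iv_bolus", "oral"))
    if (length(bad))
      stop("unknown route(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(times)
  structure(
    list(drug_id = drug_id,
         events = data.frame(time = as.numeric(times)[ord],
                             amount = as.numeric(amounts)[ord],
                             route = route[ord],
                             stringsAsFactors = FALSE)),
    class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Dosing regimen for '%s': %d dose(s)\n",
              x$drug_id, nrow(x$events)))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

n_doses <- function(reg) nrow(reg$events)

#' Read or write a dosing regimen as CSV
#'
#' The CSV schema is `drug_id, time_days, dose_umol_per_kg, route`.  A file
#' may hold several drugs (and, with an extra `arm_id` column, several
#' arms); `read_regimen_csv()` returns a named list of [regimen()] objects
#' (nested by arm when `arm_id` is present).
#'
#' @param path File path.
#' @param regimens A single [regimen()] or a (possibly named) list of them.
#' @return For `read_regimen_csv()`, a named list of regimens.
#' @export
read_regimen_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "time_days", "dose_umol_per_kg", "route")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("regimen CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  split_one <- function(d) {
    out <- lapply(split(d, d$drug_id), function(g)
      regimen(g$drug_id[1], g$time_days, g$dose_umol_per_kg, g$route))
    out[order(names(out))]
  }
  if ("arm_id" %in% names(df)) {
    lapply(split(df, df$arm_id), split_one)
  } else {
    split_one(df)
  }
}

#' @rdname read_regimen_csv
#' @export
write_regimen_csv <- function(regimens, path) {
  if (inherits(regimens, "regimen")) regimens <- list(regimens)
  rows <- lapply(regimens, function(r) {
    if (!nrow(r$events)) return(NULL)
    data.frame(drug_id = r$drug_id, time_days = r$events$time,
               dose_umol_per_kg = r$events$amount, route = r$events$route,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

## ---- closed-form concentration machinery ------------------------------

## Each dose contributes terms  coef * (t-t0)^pow * exp(-rate*(t-t0)), t>=t0.
## Near-degenerate rate pairs (relative gap < rate_gap_tol) are replaced by
## their analytic limit, which introduces pow = 1 terms.
rate_gap_tol <- 1e-8

## terms for one unit of the dose response; returns matrix cols t0,coef,rate,pow
single_dose_terms <- function(pk, t0, amount, route) {
  V <- pk$volume
  k10 <- pk$elimination_rate
  if (route == "oral") {
    if (is.null(pk$absorption_rate))
      stop("oral dose event but PK model has no 'absorption_rate'",
           call. = FALSE)
    ka <- pk$absorption_rate
    FD <- pk$bioavailability * amount
  }
  if (pk$n_compartments == 1L) {
    if (route == "iv_bolus") {
      return(cbind(t0 = t0, coef = amount / V, rate = k10, pow = 0))
    }
    ## oral, 1-compartment
    if (abs(ka - k10) / max(ka, k10) < rate_gap_tol) {
      ## limiting form  (F D ka / V) * t * exp(-k t)
      return(cbind(t0 = t0, coef = FD * ka / V, rate = k10, pow = 1))
    }
    K <- FD * ka / (V * (ka - k10))
    return(cbind(t0 = c(t0, t0), coef = c(K, -K), rate = c(k10, ka),
                 pow = c(0, 0)))
  }
  ## two compartments: hybrid rate constants alpha, beta
  s <- k10 + pk$k12 + pk$k21
  disc <- sqrt(s^2 - 4 * k10 * pk$k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  if (route == "iv_bolus") {
    if ((alpha - beta) / alpha < rate_gap_tol) {
      ## repeated root: c = (D/V) e^{-a t} [1 + (k21 - a) t]
      return(cbind(t0 = c(t0, t0),
                   coef = c(amount / V, amount / V * (pk$k21 - alpha)),
                   rate = c(alpha, alpha), pow = c(0, 1)))
    }
    A <- (alpha - pk$k21) / (alpha - beta)
    B <- (pk$k21 - beta) / (alpha - beta)
    return(cbind(t0 = c(t0, t0), coef = amount / V * c(A, B),
                 rate = c(alpha, beta), pow = c(0, 0)))
  }
  ## oral, 2-compartment: tri-exponential F D ka / V * sum A_r e^{-r t}
  P <- FD * ka / V
  rts <- c(alpha, beta, ka)
  gap <- function(r1, r2) abs(r1 - r2) / max(r1, r2)
  if (gap(ka, alpha) < rate_gap_tol || gap(ka, beta) < rate_gap_tol) {
    ## merge ka with the near-equal hybrid rate; say ka ~ r1, other root r2
    if (gap(ka, alpha) < rate_gap_tol) { r1 <- alpha; r2 <- beta }
    else { r1 <- beta; r2 <- alpha }
    ## lim_{ka->r1} [A1 e^{-r1 t} + A3 e^{-ka t}]
    ##   = e^{-r1 t} [ (r2-k21)/(r2-r1)^2 + (k21-r1) t / (r2-r1) ]
    A2 <- (pk$k21 - r2) / (r1 - r2)^2
    return(cbind(t0 = rep(t0, 3),
                 coef = P * c((r2 - pk$k21) / (r2 - r1)^2,
                              (pk$k21 - r1) / (r2 - r1),
                              A2),
                 rate = c(r1, r1, r2), pow = c(0, 1, 0)))
  }
  if (gap(alpha, beta) < rate_gap_tol) {
    ## repeated hybrid root with distinct ka: limit of A1 e^{-at}+A2 e^{-bt}
    ## as beta->alpha, with A3 unchanged
    a <- alpha
    A3 <- (pk$k21 - ka) / ((a - ka)^2)
    return(cbind(t0 = rep(t0, 3),
                 coef = P * c((ka - pk$k21) / (ka - a)^2,
                              (pk$k21 - a) / (ka - a),
                              A3),
                 rate = c(a, a, ka), pow = c(0, 1, 0)))
  }
  A1 <- (pk$k21 - alpha) / ((ka - alpha) * (beta - alpha))
  A2 <- (pk$k21 - beta) / ((ka - beta) * (alpha - beta))
  A3 <- (pk$k21 - ka) / ((alpha - ka) * (beta - ka))
  cbind(t0 = rep(t0, 3), coef = P * c(A1, A2, A3), rate = rts,
        pow = c(0, 0, 0))
}

profile_terms <- function(pk, reg) {
  ev <- reg$events
  if (!nrow(ev))
    return(matrix(numeric(), ncol = 4,
                  dimnames = list(NULL, c("t0", "coef", "rate", "pow"))))
  do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    single_dose_terms(pk, ev$time[i], ev$amount[i], ev$route[i])))
}

eval_terms <- function(terms, t) {
  if (!nrow(terms)) return(rep(0, length(t)))
  out <- numeric(length(t))
  for (m in seq_len(nrow(terms))) {
    tau <- t - terms[m, "t0"]
    on <- tau >= 0
    v <- terms[m, "coef"] * exp(-terms[m, "rate"] * tau[on])
    if (terms[m, "pow"] > 0.5) v <- v * tau[on]
    out[on] <- out[on] + v
  }
  ## closed forms can go microscopically negative through cancellation
  pmax(out, 0)
}

#' Plasma concentration profile under a multi-dose regimen
#'
#' Builds the concentration-time curve of a drug under a dosing regimen by
#' exact superposition of closed-form single-dose responses of its linear
#' compartmental model (no numerical ODE integration is involved).  The
#' returned object can be evaluated at arbitrary times with [conc_at()].
#'
#' @param pk A [pk_model()].
#' @param reg A [regimen()].
#' @param times Optional evaluation grid, days (sorted ascending); stored in
#'   the object for printing/plotting.
#' @return An object of class `"conc_profile"`.
#' @export
conc_profile <- function(pk, reg, times = NULL) {
  stopifnot(inherits(pk, "pk_model"), inherits(reg, "regimen"))
  if (!is.null(times) && is.unsorted(times))
    stop("'times' must be sorted ascending", call. = FALSE)
  terms <- profile_terms(pk, reg)
  structure(
    list(drug_id = reg$drug_id, terms = terms,
         dose_times = unique(reg$events$time),
         times = times,
         values = if (!is.null(times)) eval_terms(terms, times)),
    class = "conc_profile")
}

#' Evaluate a concentration profile
#'
#' @param profile A [conc_profile()].
#' @param t Times, days.
#' @return Concentrations in micromolar; 0 before the first dose.
#' @export
conc_at <- function(profile, t) {
  stopifnot(inherits(profile, "conc_profile"))
  eval_terms(profile$terms, t)
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile for '%s' (%d dose(s), %d terms)\n",
              x$drug_id, length(x$dose_times), nrow(x$terms)))
  if (!is.null(x$times))
    cat(sprintf("  evaluated on %d grid points in [%g, %g] days\n",
                length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.conc_profile <- function(x, tmax = NULL, n = 400, ...) {
  if (is.null(tmax))
    tmax <- if (length(x$dose_times)) max(x$dose_times) + 2 else 1
  tt <- seq(0, tmax, length.out = n)
  graphics::plot(tt, conc_at(x, tt), type = "l", xlab = "time (days)",
                 ylab = expression(paste("concentration (", mu, "M)")),
                 main = x$drug_id, ...)
  invisible(x)
}

#' Area under the concentration-time curve
#'
#' Computes AUC analytically from the exponential-term representation of
#' the profile: each term `coef * tau^p * exp(-rate*tau)` contributes
#' `coef/rate` (p = 0) or `coef/rate^2` (p = 1) to the infinite-horizon
#' AUC, with the standard incomplete-gamma truncation for a finite
#' horizon.  For a one-compartment model this reduces to the textbook
#' `AUC = F * total dose / (k10 * V)`.
#'
#' @param x A [conc_profile()] or a [pk_model()] (then `reg` is required).
#' @param horizon Upper limit of integration, days, or `Inf`.
#' @param reg A [regimen()] when `x` is a PK model.
#' @param ... Unused.
#' @return AUC in micromolar-days.
#' @export
auc <- function(x, horizon = Inf, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.pk_model <- function(x, horizon = Inf, reg, ...)
  auc(conc_profile(x, reg), horizon = horizon)

#' @rdname auc
#' @export
auc.conc_profile <- function(x, horizon = Inf, ...) {
  terms <- x$terms
  if (!nrow(terms)) return(0)
  if (any(terms[, "rate"] <= 0) && !is.finite(horizon))
    stop("infinite-horizon AUC diverges with a zero elimination rate",
         call. = FALSE)
  if (is.finite(horizon) && length(x$dose_times) &&
      horizon <= max(x$dose_times))
    stop("'horizon' must exceed the last dose time (or be Inf)",
         call. = FALSE)
  tot <- 0
  for (m in seq_len(nrow(terms))) {
    r <- unname(terms[m, "rate"])
    cf <- unname(terms[m, "coef"])
    p <- unname(terms[m, "pow"])
    tau <- unname(horizon - terms[m, "t0"])
    if (is.finite(horizon) && tau <= 0) next
    tot <- tot + if (p < 0.5) {
      if (is.finite(horizon)) cf * (1 - exp(-r * tau)) / r else cf / r
    } else {
      if (is.finite(horizon)) cf * (1 - exp(-r * tau) * (1 + r * tau)) / r^2
      else cf / r^2
    }
  }
  tot
}

#' Area under the product of two concentration curves
#'
#' Computes `integral of c_a(t) * c_b(t) dt`, the exposure quantity that
#' multiplies the interaction parameter `gamma` in the combination
#' time-efficacy index.  The integral is evaluated by adaptive quadrature
#' on the product evaluator, split at every dose-onset time where either
#' curve has a discontinuity or kink.
#'
#' @param profile_a,profile_b [conc_profile()] objects.
#' @param horizon Upper limit, days, or `Inf` (full washout).
#' @param rel.tol Quadrature relative tolerance.
#' @return AUC of the product, micromolar^2-days (>= 0).
#' @export
auc_product <- function(profile_a, profile_b, horizon = Inf,
                        rel.tol = 1e-10) {
  stopifnot(inherits(profile_a, "conc_profile"),
            inherits(profile_b, "conc_profile"))
  if (!nrow(profile_a$terms) || !nrow(profile_b$terms)) return(0)
  f <- function(t) eval_terms(profile_a$terms, t) * eval_terms(profile_b$terms, t)
  cuts <- sort(unique(c(profile_a$dose_times, profile_b$dose_times)))
  cuts <- cuts[cuts < horizon]
  lo <- min(cuts)
  bounds <- c(cuts, horizon)
  tot <- 0
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    if (b <= a) next
    q <- stats::integrate(f, a, b, rel.tol = rel.tol, abs.tol = 0,
                          subdivisions = 400L, stop.on.error = FALSE)
    tot <- tot + q$value
  }
  max(tot, 0)
}

#' Read a PK parameter library from a YAML or JSON configuration file
#'
#' The file maps drug ids to [pk_model()] arguments, e.g.
#' \preformatted{ CPT-11:
#'   n_compartments: 1
#'   volume: 2.0
#'   elimination_rate: 8.0 }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of [pk_model()] objects.
#' @export
read_pk_library <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!length(cfg) || is.null(names(cfg)))
    stop("PK library file must map drug ids to parameter lists",
         call. = FALSE)
  lapply(cfg, function(p) do.call(pk_model, p))
}
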