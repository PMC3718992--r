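#' Treatment arm of a xenograft experiment
#'
#' One group of animals: its dosing regimens (none for a control arm) and
#' the group-mean tumor weight time series.
#'
#' @param arm_id Character label.
#' @param arm_type One of `"control"`, `"single_a"`, `"single_b"`,
#'   `"combination"`.
#' @param observations Data frame with columns `time` (days, strictly
#'   increasing), `weight` (group-mean tumor weight, g, > 0) and `se`
#'   (standard error of the mean, g, >= 0).
#' @param regimens Named list of [regimen()] objects (names = drug ids);
#'   empty for control arms.
#' @return An object of class `"tumor_arm"`.
#' @export
tumor_arm <- function(arm_id, arm_type, observations, regimens = list()) {
  arm_type <- match.arg(arm_type,
                        c("control", "single_a", "single_b", "combination"))
  need <- c("time", "weight", "se")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("arm '", arm_id, "': observations are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs <- observations[need]
  obs[] <- lapply(obs, as.numeric)
  if (is.unsorted(obs$time, strictly = TRUE))
    stop("arm '", arm_id, "': observation times must be strictly increasing",
         call. = FALSE)
  if (any(obs$weight <= 0))
    stop("arm '", arm_id, "': tumor weights must be > 0 g",
         call. = FALSE)
  if (any(obs$se < 0))
    stop("arm '", arm_id, "': standard errors must be >= 0", call. = FALSE)
  if (arm_type == "control" && length(regimens) &&
      any(vapply(regimens, n_doses, 0L) > 0))
    stop("arm '", arm_id, "': a control arm cannot carry dose events",
         call. = FALSE)
  if (length(regimens)) {
    stopifnot(all(vapply(regimens, inherits, TRUE, "regimen")))
    names(regimens) <- vapply(regimens, `[[`, "", "drug_id")
  }
  structure(list(arm_id = arm_id, arm_type = arm_type,
                 observations = obs, regimens = regimens),
            class = "tumor_arm")
}

#' Tumor growth dataset of one combination experiment
#'
#' Bundles the arms (control, monotherapies, combination(s)) with the PK
#' parameter library resolving every drug id appearing in the regimens.
#' The two drugs of the experiment are identified as drug A and drug B in
#' the order they appear in the first combination arm (or in the
#' monotherapy arms when no combination arm is present).
#'
#' @param arms List of [tumor_arm()] objects.
#' @param pk_library Named list of [pk_model()] objects keyed by drug id.
#' @param drugs Optional explicit identification, a named character
#'   vector `c(a = "...", b = "...")`; by default drug A/B are inferred
#'   from the `single_a`/`single_b` arms, then from the first combination
#'   arm's regimen order.
#' @return An object of class `"tumor_dataset"` with elements `arms`,
#'   `pk_library` and `drugs` (named character vector `c(a = , b = )`).
#' @export
tumor_dataset <- function(arms, pk_library, drugs = NULL) {
  stopifnot(is.list(arms), length(arms) >= 1,
            all(vapply(arms, inherits, TRUE, "tumor_arm")))
  names(arms) <- vapply(arms, `[[`, "", "arm_id")
  if (anyDuplicated(names(arms)))
    stop("duplicated arm ids", call. = FALSE)
  used <- unique(unlist(lapply(arms, function(a) names(a$regimens))))
  miss <- setdiff(used, names(pk_library))
  if (length(miss))
    stop("PK library does not resolve drug id(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ## identify drug A / drug B: explicit > monotherapy arm types >
  ## combination-arm regimen order
  if (!is.null(drugs)) {
    drugs <- unlist(drugs)
    if (!all(c("a", "b") %in% names(drugs)))
      stop("'drugs' must be a named vector with elements 'a' and 'b'",
           call. = FALSE)
    drugs <- drugs[c("a", "b")]
    bad <- setdiff(drugs, names(pk_library))
    if (length(bad))
      stop("'drugs' not in the PK library: ", paste(bad, collapse = ", "),
           call. = FALSE)
  } else {
    drugs <- c(a = NA_character_, b = NA_character_)
    for (a in arms) {
      if (a$arm_type == "single_a" && is.na(drugs["a"]) &&
          length(a$regimens))
        drugs["a"] <- names(a$regimens)[1]
      if (a$arm_type == "single_b" && is.na(drugs["b"]) &&
          length(a$regimens))
        drugs["b"] <- names(a$regimens)[1]
    }
    comb <- Filter(function(a) a$arm_type == "combination", arms)
    if (length(comb)) {
      ids <- setdiff(names(comb[[1]]$regimens), stats::na.omit(drugs))
      if (is.na(drugs["a"]) && length(ids)) {
        drugs["a"] <- ids[1]
        ids <- ids[-1]
      }
      if (is.na(drugs["b"]) && length(ids)) drugs["b"] <- ids[1]
    }
  }
  structure(list(arms = arms, pk_library = pk_library, drugs = drugs),
            class = "tumor_dataset")
}

#' @export
print.tumor_dataset <- function(x, ...) {
  cat(sprintf("Tumor growth dataset: %d arm(s), drugs A = '%s', B = '%s'\n",
              length(x$arms), x$drugs["a"], x$drugs["b"]))
  for (a in x$arms)
    cat(sprintf("  %-12s %-12s %2d obs over [%g, %g] days\n",
                a$arm_id, a$arm_type, nrow(a$observations),
                min(a$observations$time), max(a$observations$time)))
  invisible(x)
}

arms_of_type <- function(data, type)
  Filter(function(a) a$arm_type == type, data$arms)

## concentration profiles of the two drugs in one arm; empty when not dosed
arm_profiles <- function(arm, data) {
  get_prof <- function(id) {
    if (!is.na(id) && id %in% names(arm$regimens))
      conc_profile(data$pk_library[[id]], arm$regimens[[id]])
    else empty_profile()
  }
  list(a = get_prof(data$drugs["a"]), b = get_prof(data$drugs["b"]))
}

#' Generate a synthetic xenograft combination experiment
#'
#' Simulates the true group-mean curves of a four-arm experiment
#' (control, each monotherapy following the combination schedule, and the
#' combination) from a known [combo_spec()], then emulates group-mean
#' observations: each of `n_animals` animals gets a proportional error
#' `truth * (1 + cv * N(0,1))` (truncated at 1e-4 g; a truncation count
#' is recorded as attribute `"n_truncated"`), and the reported values are
#' the group mean and the standard error `sd / sqrt(n)`.  With `cv = 0`
#' the means equal the model truth exactly and the SEs are 0.
#'
#' Proportional noise matches the 1/y^2 weighting of the estimator (a
#' constant relative error model).
#'
#' @param spec A [combo_spec()] (the ground truth).
#' @param regimens Named list `list(a = regimen, b = regimen)` giving the
#'   combination schedule of the two drugs.
#' @param pk_library Named list of [pk_model()] resolving both drug ids.
#' @param times Observation days (strictly increasing, > 0); default
#'   every third day from day 8 to day 38.
#' @param cv Proportional noise coefficient of variation (fraction).
#' @param n_animals Animals per group.
#' @param seed Optional integer seed for reproducibility.
#' @param control Solver settings.
#' @return A [tumor_dataset()] with attributes `"truth"` (the generating
#'   spec) and `"true_curves"` (list of noise-free weights per arm).
#' @export
generate_tumor_dataset <- function(spec, regimens, pk_library,
                                   times = seq(8, 38, by = 3),
                                   cv = 0.10, n_animals = 8, seed = NULL,
                                   control = list()) {
  stopifnot(inherits(spec, "combo_spec"), cv >= 0, n_animals >= 1)
  if (!all(c("a", "b") %in% names(regimens)))
    stop("'regimens' must be a named list with elements 'a' and 'b'",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ida <- regimens$a$drug_id
  idb <- regimens$b$drug_id
  miss <- setdiff(c(ida, idb), names(pk_library))
  if (length(miss))
    stop("PK library does not resolve: ", paste(miss, collapse = ", "),
         call. = FALSE)
  grid <- sort(unique(c(0, times)))
  pa <- conc_profile(pk_library[[ida]], regimens$a)
  pb <- conc_profile(pk_library[[idb]], regimens$b)
  none <- empty_profile()
  truth <- list(
    control = simulate_control(spec$growth, grid, control)$w,
    single_a = simulate_monotherapy(spec$growth, spec$drug_a, pa, grid,
                                    control)$w,
    single_b = simulate_monotherapy(spec$growth, spec$drug_b, pb, grid,
                                    control)$w,
    combination = simulate_combination(spec, pa, pb, grid, control)$w)
  at_obs <- match(times, grid)
  n_trunc <- 0L
  make_arm <- function(type, id, regs) {
    mu <- truth[[type]][at_obs]
    if (cv > 0) {
      draws <- matrix(mu, nrow = length(mu), ncol = n_animals) *
        (1 + cv * matrix(stats::rnorm(length(mu) * n_animals),
                         nrow = length(mu)))
      n_trunc <<- n_trunc + sum(draws < 1e-4)
      draws[draws < 1e-4] <- 1e-4
      m <- rowMeans(draws)
      se <- apply(draws, 1, stats::sd) / sqrt(n_animals)
    } else {
      m <- mu
      se <- rep(0, length(mu))
    }
    tumor_arm(id, type,
              data.frame(time = times, weight = m, se = se),
              regimens = regs)
  }
  arms <- list(
    make_arm("control", "control", list()),
    make_arm("single_a", paste0("mono_", ida),
             list(regimens$a)),
    make_arm("single_b", paste0("mono_", idb),
             list(regimens$b)),
    make_arm("combination", "combination",
             list(regimens$a, regimens$b)))
  out <- tumor_dataset(arms, pk_library)
  attr(out, "truth") <- spec
  attr(out, "true_curves") <- c(list(times = times),
                                lapply(truth, function(w) w[at_obs]))
  attr(out, "n_truncated") <- n_trunc
  out
}

## ---- Table-1 schedule fixtures ---------------------------------------

## Administration schedules of the eleven explored combination arms.
## Doses are in umol/kg as printed alongside the mg/kg dose levels.
fixture_table <- local({
  bid3x3 <- function(start) {
    cycles <- c(start, 14, 18)
    sort(unlist(lapply(cycles, function(d) d + seq(0, 2.5, by = 0.5))))
  }
  list(
    a1 = list(cell_line = "BxPC3",
              a = list(drug = "DrugC1", dose = 29.4, route = "iv_bolus",
                       days = bid3x3(10)),
              b = list(drug = "Gemcitabine", dose = 267, route = "iv_bolus",
                       days = c(9, 13, 17))),
    b1 = list(cell_line = "A2780",
              a = list(drug = "DrugC1", dose = 58.7, route = "iv_bolus",
                       days = seq(8, 12.5, by = 0.5)),
              b = list(drug = "Cisplatin", dose = 26.7, route = "iv_bolus",
                       days = 13)),
    b2 = list(cell_line = "A2780",
              a = list(drug = "DrugC1", dose = 58.7, route = "iv_bolus",
                       days = seq(9, 13.5, by = 0.5)),
              b = list(drug = "Cisplatin", dose = 26.7, route = "iv_bolus",
                       days = 8)),
    c1 = list(cell_line = "HT29",
              a = list(drug = "DrugC2", dose = 84.5, route = "oral",
                       days = c(10, 11, 12, 14, 15, 16)),
              b = list(drug = "CPT-11", dose = 72.9, route = "iv_bolus",
                       days = c(9, 13, 17))),
    c2 = list(cell_line = "HT29",
              a = list(drug = "DrugC2", dose = 113, route = "oral",
                       days = c(10, 11, 12, 14, 15, 16)),
              b = list(drug = "CPT-11", dose = 72.9, route = "iv_bolus",
                       days = c(9, 13, 17))),
    d1 = list(cell_line = "HT29",
              a = list(drug = "DrugC2", dose = 84.5, route = "oral",
                       days = c(10, 11, 12, 14, 15, 16)),
              b = list(drug = "5-FU", dose = 384, route = "iv_bolus",
                       days = c(9, 13, 17))),
    d2 = list(cell_line = "HT29",
              a = list(drug = "DrugC2", dose = 113, route = "oral",
                       days = c(10, 11, 12, 14, 15, 16)),
              b = list(drug = "5-FU", dose = 384, route = "iv_bolus",
                       days = c(9, 13, 17))),
    e1 = list(cell_line = "BxPC3",
              a = list(drug = "DrugC4", dose = 37.5, route = "oral",
                       days = bid3x3(10)),
              b = list(drug = "Gemcitabine", dose = 267, route = "iv_bolus",
                       days = c(9, 13, 17))),
    e2 = list(cell_line = "BxPC3",
              a = list(drug = "DrugC4", dose = 75, route = "oral",
                       days = bid3x3(10)),
              b = list(drug = "Gemcitabine", dose = 267, route = "iv_bolus",
                       days = c(9, 13, 17))),
    ## drug C5 is given 6 h (0.25 day) after CPT-11 on shared days
    f1 = list(cell_line = "HT29",
              a = list(drug = "DrugC5", dose = 25.1, route = "iv_bolus",
                       days = c(9, 10, 11, 12.25, 13, 14, 15, 16.25)),
              b = list(drug = "CPT-11", dose = 72.9, route = "iv_bolus",
                       days = c(8, 12, 16))),
    f2 = list(cell_line = "HT29",
              a = list(drug = "DrugC5", dose = 50.3, route = "iv_bolus",
                       days = c(9, 10, 11, 12.25, 13, 14, 15, 16.25)),
              b = list(drug = "CPT-11", dose = 72.9, route = "iv_bolus",
                       days = c(8, 12, 16))))
})

#' Dosing schedules of the explored combination arms
#'
#' Returns the dosing regimens (drug, umol/kg dose, route, administration
#' days) of one of the eleven combination arms of the six xenograft
#' experiments studied with this model (arms `a1`, `b1`, `b2`, `c1`,
#' `c2`, `d1`, `d2`, `e1`, `e2`, `f1`, `f2`).  In the `f` arms the
#' investigational drug was given 6 h (0.25 day) after CPT-11 on shared
#' administration days; the offset is encoded.
#'
#' @param name Arm name, e.g. `"c1"`.
#' @return A list with elements `name`, `cell_line` and `regimens`
#'   (`list(a = , b = )` of [regimen()] objects).
#' @examples
#' experiment_fixture("c1")$regimens$a
#' @export
experiment_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(fixture_table))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(fixture_table), collapse = ", "),
         call. = FALSE)
  fx <- fixture_table[[name]]
  mk <- function(x) regimen(x$drug, x$days, x$dose, x$route)
  list(name = name, cell_line = fx$cell_line,
       regimens = list(a = mk(fx$a), b = mk(fx$b)))
}

#' Synthetic PK parameter library for the fixture drugs
#'
#' The PK parameter values of the drugs in the original experiments are
#' not published in the main text, so this library provides *synthetic*
#' but physiologically plausible mouse PK parameters (short half-lives of
#' a few hours, volumes around 1 L/kg) for every drug id used by
#' [experiment_fixture()].  They are intended for simulation studies and
#' worked examples, not as estimates of the real drugs' kinetics.
#'
#' @return Named list of [pk_model()] objects.
#' @export
synthetic_pk_library <- function() {
  list(
    "DrugC1" = pk_model(1, volume = 1.0, elimination_rate = 8),
    "DrugC2" = pk_model(1, volume = 1.5, elimination_rate = 6,
                        absorption_rate = 15, bioavailability = 1),
    "DrugC4" = pk_model(1, volume = 1.2, elimination_rate = 7,
                        absorption_rate = 12, bioavailability = 1),
    "DrugC5" = pk_model(1, volume = 0.8, elimination_rate = 9),
    "Gemcitabine" = pk_model(1, volume = 1.5, elimination_rate = 12),
    "Cisplatin" = pk_model(2, volume = 0.5, elimination_rate = 4,
                           k12 = 2, k21 = 1),
    "CPT-11" = pk_model(1, volume = 2.0, elimination_rate = 8),
    "5-FU" = pk_model(1, volume = 1.5, elimination_rate = 14))
}

#' Default ground-truth parameters for synthetic studies
#'
#' Arbitrary but plausible xenograft parameter values used as the ground
#' truth of the package's simulation studies (they are not estimates from
#' any real experiment): a tumor that weighs about 0.17 g on day 8
#' (randomization) and switches from exponential to linear growth around
#' 1 g, drugs with damage-transit half-lives of about a day, and
#' potencies giving a moderate monotherapy effect under the `c1`-style
#' schedules.
#'
#' @param gamma Interaction parameter of the truth, uM^-2 day^-2.
#' @return A [combo_spec()].
#' @export
default_truth <- function(gamma = 1) {
  combo_spec(
    growth = growth_params(w0 = 0.05, lambda0 = 0.15, lambda1 = 0.15,
                           psi = 20),
    drug_a = drug_params(k1 = 0.9, k2 = 0.02),
    drug_b = drug_params(k1 = 0.6, k2 = 0.05),
    gamma = gamma)
}
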