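# Shared fixtures for the test suite, all built in code.

# slow-growing tumor with a long exponential phase: treatment confined to
# an early window, observation much longer (the regime in which the
# closed-form index approximations are derived)
oracle_growth <- function() growth_params(w0 = 0.05, lambda0 = 0.1,
                                          lambda1 = 0.2, psi = 20)

# three short-treatment/long-observation scenarios with different
# interaction strengths and schedules
oracle_scenarios <- function() {
  pk_a <- pk_model(1, volume = 1, elimination_rate = 2)
  pk_b <- pk_model(1, volume = 1.5, elimination_rate = 3)
  reg_a1 <- regimen("A", times = c(3, 4, 5), amounts = 5)
  reg_b1 <- regimen("B", times = c(3.5, 4.5), amounts = 6)
  reg_a2 <- regimen("A", times = c(2, 4, 6), amounts = 4)
  reg_b2 <- regimen("B", times = c(2.25, 4.25), amounts = 5)
  base <- list(growth = oracle_growth(),
               drug_a = drug_params(k1 = 1, k2 = 0.1),
               drug_b = drug_params(k1 = 1.2, k2 = 0.15))
  list(
    list(spec = combo_spec(base$growth, base$drug_a, base$drug_b,
                           gamma = 0.2),
         conc_a = conc_profile(pk_a, reg_a1),
         conc_b = conc_profile(pk_b, reg_b1)),
    list(spec = combo_spec(base$growth, base$drug_a, base$drug_b,
                           gamma = -0.05),
         conc_a = conc_profile(pk_a, reg_a1),
         conc_b = conc_profile(pk_b, reg_b1)),
    list(spec = combo_spec(base$growth, base$drug_a, base$drug_b,
                           gamma = 0.1),
         conc_a = conc_profile(pk_a, reg_a2),
         conc_b = conc_profile(pk_b, reg_b2)))
}

# random but well-behaved parameter draws for property-style tests
random_spec <- function(gamma = 0) {
  combo_spec(
    growth = growth_params(w0 = runif(1, 0.02, 0.1),
                           lambda0 = runif(1, 0.08, 0.3),
                           lambda1 = runif(1, 0.1, 0.4)),
    drug_a = drug_params(k1 = runif(1, 0.3, 2), k2 = runif(1, 0.005, 0.05)),
    drug_b = drug_params(k1 = runif(1, 0.3, 2), k2 = runif(1, 0.01, 0.08)),
    gamma = gamma)
}

coef_named7 <- function()
  c(w0 = 0.05, lambda0 = 0.15, lambda1 = 0.15, k1a = 0.9, k2a = 0.02,
    k1b = 0.6, k2b = 0.05)

c1_profiles <- function() {
  fx <- experiment_fixture("c1")
  pkl <- synthetic_pk_library()
  list(a = conc_profile(pkl$DrugC2, fx$regimens$a),
       b = conc_profile(pkl[["CPT-11"]], fx$regimens$b),
       regimens = fx$regimens, pk = pkl)
}
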