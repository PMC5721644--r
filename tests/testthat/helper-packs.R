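# Shared fixture builders: packs with controlled mortality and transitions so
# closed-form oracles apply.

# Replace the life table with a constant annual probability and set every
# mortality multiplier to 1, making cycle matrices time-homogeneous.
flat_mortality <- function(pack, p_annual = 0) {
  pack$mortality$life_table$annual_death_prob <- p_annual
  pack$mortality$diabetes_rr <- 1
  pack$mortality$severity_rr[] <- 1
  pack
}

# A pack whose living states never move (identity transitions, no treatment)
# under constant mortality.
identity_pack <- function(p_annual = 0) {
  pack <- make_pack(synthetic_scenario(
    progression_scale = 0, regression_scale = 0, csdmo_incidence = 0,
    treatment_effect = 1, complication_prob_dmo = 0, complication_prob_vh = 0
  ))
  ls <- living_states()
  for (arm in c("usual_care", "intervention")) {
    m <- diag(length(ls))
    dimnames(m) <- list(ls, ls)
    pack$transitions[[arm]]$matrix <- m
    pack$transitions[[arm]]$treatment_states <- character(0)
  }
  flat_mortality(pack, p_annual)
}

# Zero out every treatment- and complication-related payoff so arms differ
# only through disease dynamics.
zero_treatment_costs <- function(pack) {
  pack$costs$prp_laser <- 0
  pack$costs$focal_laser <- 0
  pack$costs$oct <- 0
  pack$costs$vitrectomy <- 0
  pack$utilities$complication_disutility <- 0
  pack
}

# A hand-buildable strategy result for comparison-level tests.
strategy <- function(arm, cost, qaly) {
  structure(list(arm = arm, cost = cost, qaly = qaly,
                 cost_undiscounted = cost, qaly_undiscounted = qaly),
            class = "strategy_result")
}
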