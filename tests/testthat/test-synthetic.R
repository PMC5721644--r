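test_that("parametric life table matches its closed form and is monotone", {
  # b = 0: constant annual probability
  lt0 <- make_life_table(c(a = 0.002, b = 0, c = 0.1))
  expect_true(all(lt0$annual_death_prob == 0.002))

  lt <- make_life_table(c(a = 5e-4, b = 1e-5, c = 0.11))
  expect_equal(lt$annual_death_prob[lt$age == 50],
               5e-4 + 1e-5 * exp(0.11 * 50))
  expect_true(all(diff(lt$annual_death_prob) > 0))
  expect_true(all(lt$annual_death_prob >= 0 & lt$annual_death_prob <= 1))

  # probabilities above 1 are an error naming the offending age
  expect_error(make_life_table(c(a = 0.5, b = 1e-2, c = 0.11)), "age")
})

test_that("generated transition rows have the documented structure", {
  # zero scales: identity off the treatment states
  sc0 <- synthetic_scenario(progression_scale = 0, regression_scale = 0,
                            csdmo_incidence = 0, complication_prob_dmo = 0)
  ts <- make_transition_set(sc0, "usual_care")
  untreated <- setdiff(living_states(), ts$treatment_states)
  expect_equal(ts$matrix[untreated, untreated],
               diag(length(untreated)) * 1,
               ignore_attr = TRUE)
  # treated states move with certainty to their post-treatment state
  expect_equal(ts$matrix["HR_PDR", "HR_PDR_PT"], 1)
  expect_equal(ts$matrix["HR_PDR_CSDMO", "HR_PDR_CSDMO_PT"], 1)

  # interior state: stay 0.75 / worse 0.2 / better 0.05
  sc <- synthetic_scenario(progression_scale = 0.2, regression_scale = 0.05,
                           csdmo_incidence = 0)
  m <- make_transition_set(sc, "usual_care")$matrix
  expect_equal(m["early_PDR", "early_PDR"], 0.75)
  expect_equal(m["early_PDR", "HR_PDR"], 0.2)
  expect_equal(m["early_PDR", "severe_NPDR"], 0.05)

  # CSDMO incidence is a sideways move at tiers with a CSDMO sibling
  sc2 <- synthetic_scenario(progression_scale = 0.1, regression_scale = 0.02,
                            csdmo_incidence = 0.03)
  m2 <- make_transition_set(sc2, "intervention")$matrix
  expect_equal(m2["early_PDR", "early_PDR_CSDMO"], 0.03)
  expect_equal(m2["early_PDR_PT", "early_PDR_CSDMO_PT"], 0.03)
  expect_equal(m2["moderate_NPDR", "severe_NPDR"], 0.1)
  expect_equal(sum(m2["moderate_NPDR", c("moderate_NPDR", "severe_NPDR")]), 1)

  # post-treatment progression is slowed by the treatment effect in both arms
  sc3 <- synthetic_scenario(progression_scale = 0.1, treatment_effect = 0.4)
  for (arm in c("usual_care", "intervention")) {
    m3 <- make_transition_set(sc3, arm)$matrix
    expect_equal(m3["early_PDR_PT", "HR_PDR_PT"], 0.04)
  }

  # a null treatment effect makes post-treatment rows identical across arms
  sc4 <- synthetic_scenario(treatment_effect = 1)
  pt <- grep("_PT$", living_states(), value = TRUE)
  expect_equal(make_transition_set(sc4, "usual_care")$matrix[pt, ],
               make_transition_set(sc4, "intervention")$matrix[pt, ])

  # oversized scales are rejected
  expect_error(synthetic_scenario(progression_scale = 0.6, regression_scale = 0.5),
               "sum")
})

test_that("generated packs are valid, deterministic and complete", {
  for (seed in 1:8) {
    pack <- make_pack(random_scenario(seed))
    expect_length(validate_pack(pack), 0)
    for (arm in c("usual_care", "intervention")) {
      m <- pack$transitions[[arm]]$matrix
      expect_true(all(abs(rowSums(m) - 1) < 1e-12))
      expect_true(all(m >= 0 & m <= 1))
    }
  }
  # same scenario, same pack, field for field
  p1 <- make_pack(random_scenario(42))
  p2 <- make_pack(random_scenario(42))
  expect_equal(p1[names(p1)], p2[names(p2)])
})

test_that("the generator recovers the direction of the treatment effect", {
  # Through the progression channel alone (post-PRP complications switched
  # off), effective earlier treatment never loses QALYs, for any structurally
  # valid scenario: the treated lane progresses no faster than the untreated
  # one and is otherwise payoff-identical tier by tier.
  for (seed in c(3, 14, 27, 58, 64, 88)) {
    sc <- random_scenario(seed)
    sc$treatment_effect <- min(sc$treatment_effect, 0.95)
    sc$complication_prob_dmo <- 0
    sc$complication_prob_vh <- 0
    run <- run_comparison(make_pack(sc))
    expect_gte(run$intervention$result$qaly, run$usual_care$result$qaly)
  }
  # with the base-case complication risk the benefit shrinks toward zero as
  # the effect weakens but stays non-negative across the study grid
  for (eff in c(0.4, 0.7, 0.95)) {
    run <- run_comparison(make_pack(synthetic_scenario(treatment_effect = eff)))
    expect_gte(run$intervention$result$qaly, run$usual_care$result$qaly)
  }
  # a near-null effect with a high complication risk genuinely reverses the
  # sign: treating everyone early buys nothing and costs the complication
  # disutility (the harm-benefit trade-off the model is built to weigh)
  sc_harm <- synthetic_scenario(treatment_effect = 0.999,
                                complication_prob_dmo = 0.3)
  run_harm <- run_comparison(make_pack(sc_harm))
  expect_lt(run_harm$intervention$result$qaly, run_harm$usual_care$result$qaly)
})

test_that("identical treatment policies yield exactly zero increments", {
  # arms with the same transition wiring are payoff-identical
  pack <- make_pack(synthetic_scenario())
  pack$transitions$intervention <- pack$transitions$usual_care
  pack$transitions$intervention$arm <- "intervention"
  cmp <- run_comparison(pack)$comparison
  expect_identical(cmp$delta_cost, 0)
  expect_identical(cmp$delta_qaly, 0)
  expect_equal(cmp$verdict, "equivalent")
})

test_that("a null treatment effect with zero treatment costs gives zero increments", {
  # with treatment_effect = 1 treatment only relabels the lane, and with all
  # treatment payoffs zeroed the two arms are payoff-identical tier by tier
  sc <- synthetic_scenario(treatment_effect = 1)
  pack <- zero_treatment_costs(make_pack(sc))
  cmp <- run_comparison(pack)$comparison
  expect_equal(cmp$delta_cost, 0, tolerance = 1e-12)
  expect_equal(cmp$delta_qaly, 0, tolerance = 1e-12)
})
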