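test_that("cycle matrices layer mortality onto survival-conditional rows", {
  # zero mortality: living rows equal the stored transition rows
  pack0 <- flat_mortality(base_case_pack(), 0)
  cm <- build_cycle_matrix(pack0, "usual_care", 0)$matrix
  ls <- living_states()
  expect_equal(cm[ls, ls], pack0$transitions$usual_care$matrix)
  expect_true(all(cm[ls, "dead"] == 0))
  # the dead row is the identity row
  expect_equal(unname(cm["dead", ]), c(rep(0, 18), 1))

  # stay-with-certainty state with 10% cycle mortality: 0.9 stay / 0.1 dead
  pack1 <- identity_pack(p_annual = 1 - 0.9^2) # half-year prob = 0.1
  cm1 <- build_cycle_matrix(pack1, "usual_care", 0)$matrix
  expect_equal(cm1["moderate_NPDR", "moderate_NPDR"], 0.9)
  expect_equal(cm1["moderate_NPDR", "dead"], 0.1)

  # hand-assembled row: 0.6 stay / 0.4 progress with 5% death
  pack2 <- identity_pack(p_annual = 1 - 0.95^2) # half-year prob = 0.05
  pack2$transitions$usual_care$matrix["moderate_NPDR", ] <- 0
  pack2$transitions$usual_care$matrix["moderate_NPDR", "moderate_NPDR"] <- 0.6
  pack2$transitions$usual_care$matrix["moderate_NPDR", "severe_NPDR"] <- 0.4
  cm2 <- build_cycle_matrix(pack2, "usual_care", 0)$matrix
  expect_equal(unname(cm2["moderate_NPDR", c("moderate_NPDR", "severe_NPDR", "dead")]),
               c(0.57, 0.38, 0.05))

  expect_error(build_cycle_matrix(pack1, "usual_care", 60), "horizon")

  # every cycle matrix of the base pack is row-stochastic
  pack <- base_case_pack()
  for (t in c(0, 17, 59)) {
    m <- build_cycle_matrix(pack, "intervention", t)$matrix
    expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  }
})

test_that("the cohort trace follows its closed-form oracles", {
  # identity transitions, zero mortality: every row equals row 0
  p0 <- identity_pack(0)
  tr0 <- run_cohort(p0, "usual_care")
  expect_true(all(tr0[, "moderate_NPDR"] == 1))

  # constant 10% cycle mortality: survival is 0.9^t
  p1 <- identity_pack(1 - 0.9^2)
  tr1 <- run_cohort(p1, "usual_care")
  expect_equal(tr1[3, "moderate_NPDR"], 0.81)
  expect_equal(unname(tr1[, "moderate_NPDR"]), 0.9^(0:60))

  # time-homogeneous pack: trace equals explicit matrix powers to 1e-12
  ph <- flat_mortality(base_case_pack(), 0.02)
  M <- build_cycle_matrix(ph, "intervention", 0)$matrix
  tr <- run_cohort(ph, "intervention")
  row <- c(moderate_NPDR = 1, rep(0, 18))
  names(row) <- health_states()
  pow <- row
  for (t in 1:60) {
    pow <- pow %*% M
    expect_equal(unname(tr[t + 1, ]), as.vector(pow), tolerance = 1e-12)
  }
})

test_that("traces conserve probability and death is absorbing on random packs", {
  for (seed in 1:10) {
    pack <- make_pack(random_scenario(seed))
    for (arm in c("usual_care", "intervention")) {
      tr <- run_cohort(pack, arm)
      expect_true(all(abs(rowSums(tr) - 1) < 1e-9))
      expect_true(all(tr >= 0))
      expect_true(all(diff(tr[, "dead"]) >= 0))
      expect_equal(unname(tr[1, pack$settings$start_state]), 1)
    }
  }
})

test_that("treatment and complication events follow the one-cycle tunnel rule", {
  # no treatment states: all event masses zero
  p0 <- identity_pack(0)
  tr0 <- run_cohort(p0, "usual_care")
  ev0 <- treatment_events(p0, "usual_care", tr0)
  expect_true(all(ev0$prp_starts == 0) && all(ev0$comp_dmo == 0))

  # unit mass treated once with complication probability 0.1 under zero
  # mortality: complication mass 0.1 in exactly the post-treatment entry cycle
  sc <- synthetic_scenario(progression_scale = 0, regression_scale = 0,
                           csdmo_incidence = 0, complication_prob_dmo = 0.1,
                           complication_prob_vh = 0)
  p1 <- flat_mortality(make_pack(sc), 0)
  p1$settings$start_state <- "severe_NPDR" # treated immediately (intervention)
  tr1 <- run_cohort(p1, "intervention")
  ev1 <- treatment_events(p1, "intervention", tr1)
  expect_equal(ev1$prp_starts, c(1, rep(0, 59)))
  expect_equal(ev1$comp_dmo, c(0, 0.1, rep(0, 58)))

  # summation oracle: total complication mass equals the sum over cycles of
  # surviving treated mass times the complication probability
  pack <- base_case_pack()
  tr <- run_cohort(pack, "intervention")
  ev <- treatment_events(pack, "intervention", tr)
  dp <- death_prob_matrix(pack)
  treated <- pack$transitions$intervention$treatment_states
  p_dmo <- pack$transitions$intervention$complication_probs$dmo
  expected <- sum(vapply(1:59, function(k) {
    sum(tr[k, treated] * (1 - dp[k, treated])) * p_dmo
  }, numeric(1)))
  expect_equal(sum(ev$comp_dmo), expected)
  # treated mass feeds the post-treatment entry in the following cycle
  expect_equal(ev$comp_dmo[-1] > 0, ev$prp_starts[-60] > 0)
})

test_that("faster progression never increases an arm's QALYs", {
  base <- synthetic_scenario(progression_scale = 0.05)
  for (p in c(0.08, 0.12, 0.2)) {
    sc <- base
    sc$progression_scale <- p
    slow <- run_arm(make_pack(base), "usual_care")$result$qaly
    fast <- run_arm(make_pack(sc), "usual_care")$result$qaly
    expect_lte(fast, slow)
  }
})
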