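test_that("base-case pack carries the published utilities, costs and settings", {
  pack <- base_case_pack()
  u <- pack$utilities$by_state
  expect_equal(u[["moderate_NPDR"]], 0.7915)
  expect_equal(u[["severe_NPDR"]], 0.7915)
  expect_equal(u[["severe_NPDR_CSDMO"]], 0.7365)
  expect_equal(u[["early_PDR"]], 0.7047)
  expect_equal(u[["severe_PDR"]], 0.7047)
  expect_equal(u[["early_PDR_CSDMO"]], 0.6930)
  expect_equal(u[["SVL_blind"]], 0.6218)
  # post-treatment states carry their tier's utility
  expect_equal(u[["severe_NPDR_PT"]], 0.7915)
  expect_equal(u[["HR_PDR_CSDMO_PT"]], 0.6930)
  expect_equal(pack$utilities$complication_disutility, -0.03)

  expect_equal(pack$costs$ophthalmology_visit, 106)
  expect_equal(pack$costs$monitoring_visit, 80)
  expect_equal(pack$costs$prp_laser, 131)
  expect_equal(pack$costs$oct, 117)
  expect_equal(pack$costs$vitrectomy, 989)
  expect_equal(pack$costs$blindness_annual, 1483)
  expect_equal(pack$costs$price_year, "2012/2013")

  s <- pack$settings
  expect_equal(s$cohort_size, 1000)
  expect_equal(s$start_age, 50)
  expect_equal(s$cycle_length, 0.5)
  expect_equal(s$horizon, 30)
  expect_equal(s$discount_rate, 0.035)
  expect_equal(s$start_state, "moderate_NPDR")

  v <- pack$resources$visits_per_cycle
  expect_equal(unname(v[c("moderate_NPDR", "early_PDR", "HR_PDR", "SVL_blind")]),
               c(1, 1.5, 2, 0.5))
  # CSDMO variants inherit their tier's visit count
  expect_equal(v[["early_PDR_CSDMO"]], 1.5)

  m <- pack$mortality
  expect_equal(m$diabetes_rr, 2.194)
  expect_equal(unname(m$severity_rr[c("moderate_NPDR", "severe_NPDR",
                                      "mild_PDR", "moderate_high_PDR")]),
               c(1.118, 1.422, 0.992, 1.705))
  expect_equal(m$state_to_severity[["early_PDR_CSDMO_PT"]], "mild_PDR")
  expect_equal(m$state_to_severity[["SVL_blind"]], "moderate_high_PDR")

  # transitions are flagged as synthetic placeholders for the unpublished set
  expect_match(pack$transitions$usual_care$source, "synthetic")
})

test_that("validation reports each violated invariant as data naming the field", {
  pack <- base_case_pack()
  expect_length(validate_pack(pack), 0)

  p1 <- pack
  p1$costs$vitrectomy <- -5
  v <- validate_pack(p1)
  expect_length(v, 1)
  expect_match(v, "costs.vitrectomy")

  p2 <- pack
  p2$transitions$usual_care$matrix["early_PDR", "early_PDR"] <-
    p2$transitions$usual_care$matrix["early_PDR", "early_PDR"] - 0.02
  v <- validate_pack(p2)
  expect_match(v, "usual_care.early_PDR")
  expect_match(v, "0.98")

  p3 <- pack
  p3$utilities$by_state[["SVL_blind"]] <- 1.2
  expect_match(validate_pack(p3), "utilities.SVL_blind")

  p4 <- pack
  p4$transitions$usual_care <- NULL
  expect_match(validate_pack(p4), "missing arm 'usual_care'")

  p5 <- pack
  p5$resources$prp_sittings <- 3
  expect_match(validate_pack(p5), "prp_sittings")

  p6 <- pack
  p6$mortality$life_table <- p6$mortality$life_table[1:5, ]
  expect_match(validate_pack(p6), "life_table")
})

test_that("pack files round-trip through write_pack and load_pack", {
  pack <- base_case_pack()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pack.yaml")
  write_pack(pack, path)
  expect_true(file.exists(file.path(dir, "life_table.csv")))

  p2 <- load_pack(path)
  expect_equal(p2$utilities$by_state, pack$utilities$by_state)
  expect_equal(p2$costs, pack$costs)
  expect_equal(p2$settings, pack$settings)
  expect_equal(p2$resources$visits_per_cycle, pack$resources$visits_per_cycle)
  expect_equal(p2$transitions$usual_care$matrix,
               pack$transitions$usual_care$matrix, tolerance = 1e-12)
  expect_equal(p2$transitions$intervention$treatment_states,
               pack$transitions$intervention$treatment_states)
  expect_equal(p2$mortality$life_table$annual_death_prob,
               pack$mortality$life_table$annual_death_prob, tolerance = 1e-12)

  # an invalid file refuses to load, naming the broken row
  doc <- yaml::read_yaml(path)
  doc$transitions$usual_care$rows$moderate_NPDR[[1]] <-
    doc$transitions$usual_care$rows$moderate_NPDR[[1]] - 0.02
  bad <- file.path(dir, "bad.yaml")
  yaml::write_yaml(doc, bad, precision = 15)
  expect_error(load_pack(bad), "moderate_NPDR")
  expect_error(load_pack(file.path(dir, "absent.yaml")), "no such pack")
})

test_that("the state space is structured as documented", {
  expect_length(health_states(), 19)
  expect_length(living_states(), 18)
  expect_identical(utils::tail(health_states(), 1), "dead")
  info <- state_info()
  expect_setequal(info$state, living_states())
  # PT naming round-trips
  expect_equal(origin_state(pt_state("severe_NPDR")), "severe_NPDR")
  expect_error(pt_state("moderate_NPDR"), "no post-treatment")
  expect_error(pt_state("SVL_blind"))
  # every PT state shares its origin's tier, CSDMO flag, severity and utility
  pt <- info[info$pt, ]
  orig <- info[origin_state(pt$state), ]
  expect_equal(pt$tier, orig$tier)
  expect_equal(pt$csdmo, orig$csdmo)
  expect_equal(pt$severity_class, orig$severity_class)
  expect_equal(pt$utility_group, orig$utility_group)
})
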