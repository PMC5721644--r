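# Economics: per-cycle payoffs, discounted accrual of costs and QALYs over a
# cohort trace, incremental comparison (ICER or dominance) and net monetary
# benefit. NHS/PSS perspective, GBP, annual discounting of both costs and
# outcomes at the pack's rate.

visit_unit_cost <- function(pack, state) {
  unlist(pack$costs[pack$resources$visit_type[state]])
}

prp_bundle_cost <- function(pack) {
  res <- pack$resources
  res$prp_sittings * (res$lasers_per_sitting * pack$costs$prp_laser +
                        res$visits_per_sitting * pack$costs$ophthalmology_visit)
}

dmo_bundle_cost <- function(pack) {
  pack$resources$dmo_focal_lasers * pack$costs$focal_laser +
    pack$resources$dmo_oct * pack$costs$oct
}

#' Per-cycle cost and QALY payoff of occupying a state
#'
#' Cost is the state's scheduled visits times the applicable visit unit cost,
#' plus (for severe visual loss/blindness only) the annual cost of blindness
#' pro-rated to the cycle length. QALYs are the state utility times the cycle
#' length. Treatment and complication costs are event payoffs added by
#' [accrue()] from [treatment_events()], not here; the dead state pays zero.
#'
#' @param state A health state name.
#' @param arm Arm label (payoffs are arm-independent; accepted for symmetry).
#' @param pack A validated `parameter_pack`.
#' @return Named numeric `c(cost=, qaly=)` for one cycle of unit occupancy.
#' @export
cycle_payoff <- function(state, arm = "usual_care", pack) {
  assert_states(state)
  if (state == "dead") return(c(cost = 0, qaly = 0))
  dt <- pack$settings$cycle_length
  cost <- pack$resources$visits_per_cycle[[state]] * visit_unit_cost(pack, state)
  if (state == "SVL_blind") cost <- cost + pack$costs$blindness_annual * dt
  c(cost = unname(cost), qaly = pack$utilities$by_state[[state]] * dt)
}

state_payoff_vectors <- function(pack) {
  ls <- living_states()
  dt <- pack$settings$cycle_length
  cost <- pack$resources$visits_per_cycle[ls] * visit_unit_cost(pack, ls)
  cost["SVL_blind"] <- cost["SVL_blind"] + pack$costs$blindness_annual * dt
  list(cost = cost, qaly = pack$utilities$by_state[ls] * dt)
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Cycle `k` (1-based) pays the occupancy-weighted state payoffs of row
#' `k - 1` plus that cycle's event payoffs (PRP sitting bundle and, for
#' treated CSDMO patients, the focal-laser + OCT bundle, costed in the
#' treatment cycle; complication treatment costs and the complication
#' disutility applied to the affected mass for one cycle), discounted by
#' `(1 + r)^(-k * cycle_length)` (end-of-cycle timing; set
#' `settings$discount_first_cycle = FALSE` for exponent `(k - 1)`, and
#' `settings$half_cycle_correction = TRUE` to average adjacent occupancy
#' rows). Results are per-patient means.
#'
#' @param trace A `cohort_trace`.
#' @param pack The pack it was produced from.
#' @param events Event table from [treatment_events()] for the same arm.
#' @return A `strategy_result`: list with `arm`, discounted `cost` and
#'   `qaly`, and `cost_undiscounted`, `qaly_undiscounted`.
#' @export
accrue <- function(trace, pack, events) {
  s <- pack$settings
  n <- n_cycles(pack)
  ls <- living_states()
  po <- state_payoff_vectors(pack)

  occ <- unclass(trace)[seq_len(n), ls, drop = FALSE]
  if (isTRUE(s$half_cycle_correction)) {
    occ <- (occ + unclass(trace)[seq_len(n) + 1, ls, drop = FALSE]) / 2
  }
  cost_t <- as.vector(occ %*% po$cost)
  qaly_t <- as.vector(occ %*% po$qaly)

  comp_mass <- events$comp_dmo + events$comp_vh
  cost_t <- cost_t +
    events$prp_starts * prp_bundle_cost(pack) +
    events$dmo_bundles * dmo_bundle_cost(pack) +
    events$comp_dmo * dmo_bundle_cost(pack) +
    events$comp_vh * pack$costs$vitrectomy
  qaly_t <- qaly_t +
    comp_mass * pack$utilities$complication_disutility * s$cycle_length

  expo <- if (isTRUE(s$discount_first_cycle)) seq_len(n) else seq_len(n) - 1
  df <- (1 + s$discount_rate)^(-expo * s$cycle_length)

  structure(
    list(arm = attr(trace, "arm"),
         cost = sum(cost_t * df),
         qaly = sum(qaly_t * df),
         cost_undiscounted = sum(cost_t),
         qaly_undiscounted = sum(qaly_t)),
    class = "strategy_result"
  )
}

#' Run one arm end to end
#'
#' @param pack A validated `parameter_pack`.
#' @param arm Arm label.
#' @return List with `trace`, `events` and the accrued `result`.
#' @export
run_arm <- function(pack, arm) {
  trace <- run_cohort(pack, arm)
  events <- treatment_events(pack, arm, trace)
  list(trace = trace, events = events, result = accrue(trace, pack, events))
}

#' Incremental comparison of intervention versus usual care
#'
#' Deltas are intervention minus usual care. The intervention dominates when
#' it is cheaper and more effective, is dominated when dearer and less
#' effective; otherwise the ICER `delta_cost / delta_qaly` is reported. With
#' equal QALYs the cheaper strategy wins and no ICER is defined.
#'
#' @param uc,int_ `strategy_result`s for usual care and intervention from the
#'   same settings.
#' @return A `comparison_result`: `delta_cost`, `delta_qaly`, `verdict`
#'   (`"intervention_dominant"`, `"intervention_dominated"`, `"icer"` or
#'   `"equivalent"`), `icer` (`NA` unless verdict is `"icer"`), and the two
#'   inputs.
#' @export
compare_strategies <- function(uc, int_) {
  dc <- int_$cost - uc$cost
  de <- int_$qaly - uc$qaly
  if (de > 0 && dc < 0) {
    verdict <- "intervention_dominant"; icer <- NA_real_
  } else if (de < 0 && dc > 0) {
    verdict <- "intervention_dominated"; icer <- NA_real_
  } else if (de == 0) {
    verdict <- if (dc < 0) "intervention_dominant"
               else if (dc > 0) "intervention_dominated"
               else "equivalent"
    icer <- NA_real_
  } else {
    verdict <- "icer"; icer <- dc / de
  }
  structure(
    list(delta_cost = dc, delta_qaly = de, verdict = verdict, icer = icer,
         usual_care = uc, intervention = int_),
    class = "comparison_result"
  )
}

#' Net monetary benefit of the intervention
#'
#' `NMB(lambda) = lambda * delta_qaly - delta_cost`; exactly affine in the
#' willingness-to-pay `lambda` with slope `delta_qaly`.
#'
#' @param cmpres A `comparison_result`.
#' @param wtp Willingness to pay per QALY (GBP; vectorised, must be >= 0).
#' @return NMB in GBP, one value per `wtp`.
#' @export
nmb <- function(cmpres, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  wtp * cmpres$delta_qaly - cmpres$delta_cost
}

#' Run both arms and compare them
#'
#' @param pack A validated `parameter_pack`.
#' @return List with per-arm runs (`usual_care`, `intervention`) and the
#'   `comparison`.
#' @export
run_comparison <- function(pack) {
  uc <- run_arm(pack, "usual_care")
  int_ <- run_arm(pack, "intervention")
  list(usual_care = uc, intervention = int_,
       comparison = compare_strategies(uc$result, int_$result))
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost £%.2f, %.4f QALYs (discounted)\n",
              x$arm, x$cost, x$qaly))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> ΔC = £%.2f, ΔE = %.4f QALYs: %s",
              x$delta_cost, x$delta_qaly, x$verdict))
  if (x$verdict == "icer") cat(sprintf(" (£%.0f/QALY)", x$icer))
  cat("\n")
  invisible(x)
}
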