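# Mortality: general-population life table, adjusted for diabetes and for
# retinopathy severity, converted from annual to per-cycle probabilities on
# the hazard (log-survival) scale.

#' Convert an annual death probability to a per-cycle probability
#'
#' Uses the constant-hazard convention: a cycle of length `cycle_length`
#' years carries probability `1 - (1 - p_annual)^cycle_length`.
#'
#' @param p_annual Annual death probability (vectorised), in `[0, 1]`.
#' @param cycle_length Cycle length in years (> 0).
#' @return Per-cycle death probability, same length as `p_annual`.
#' @export
#' @examples
#' annual_to_cycle_prob(0.04, 0.5) # 1 - 0.96^0.5
annual_to_cycle_prob <- function(p_annual, cycle_length) {
  if (!is.numeric(cycle_length) || length(cycle_length) != 1 || cycle_length <= 0) {
    stop("cycle_length must be a single positive number")
  }
  if (any(!is.finite(p_annual)) || any(p_annual < 0) || any(p_annual > 1)) {
    stop("p_annual must lie in [0, 1]")
  }
  1 - (1 - p_annual)^cycle_length
}

lookup_annual_prob <- function(age, life_table) {
  a <- floor(age)
  idx <- match(a, life_table$age)
  if (any(is.na(idx))) {
    stop("age ", paste(unique(a[is.na(idx)]), collapse = ", "),
         " outside the life table range [", min(life_table$age), ", ",
         max(life_table$age), "]")
  }
  life_table$annual_death_prob[idx]
}

#' Per-cycle death probability adjusted for diabetes and retinopathy severity
#'
#' The combined relative risk `rr` multiplies the hazard, so the cycle
#' probability is `1 - (1 - p_annual)^(rr * cycle_length)` (capped at 1 by
#' construction). With `mortality$compose_diabetes = TRUE` (the default)
#' `rr = diabetes_rr * severity_rr[class]`; with `FALSE` the severity
#' multipliers are taken as already relative to the general population and
#' used alone.
#'
#' @param age Age in years (single value; `floor(age)` indexes the life table).
#' @param state Living health state name(s).
#' @param mortality A `MortalityModel` list: `life_table` (data.frame with
#'   `age`, `annual_death_prob`), `diabetes_rr`, `severity_rr` (named vector),
#'   `state_to_severity` (named character), `compose_diabetes` (logical).
#' @param cycle_length Cycle length in years.
#' @return Per-cycle death probability for each state.
#' @export
adjusted_death_prob <- function(age, state, mortality, cycle_length) {
  assert_states(state)
  if (any(state == "dead")) stop("death probability is undefined for 'dead'")
  p_annual <- lookup_annual_prob(age, mortality$life_table)
  cls <- mortality$state_to_severity[state]
  if (any(is.na(cls))) {
    stop("no severity class mapped for state(s): ",
         paste(state[is.na(cls)], collapse = ", "))
  }
  sev <- mortality$severity_rr[cls]
  if (any(is.na(sev))) {
    stop("no severity multiplier for class(es): ",
         paste(unique(cls[is.na(sev)]), collapse = ", "))
  }
  rr <- if (isTRUE(mortality$compose_diabetes)) mortality$diabetes_rr * sev else sev
  p <- 1 - (1 - p_annual)^(rr * cycle_length)
  pmin(unname(p), 1)
}

#' Per-cycle death probabilities for every cycle and living state
#'
#' @param pack A validated parameter pack.
#' @return Matrix of dim `n_cycles x 18`: row `t` holds the death
#'   probabilities applying during cycle `t` (age = start_age + (t-1) * cycle
#'   length), columns named by living state.
#' @export
death_prob_matrix <- function(pack) {
  s <- pack$settings
  n <- n_cycles(pack)
  ls <- living_states()
  out <- matrix(NA_real_, n, length(ls), dimnames = list(NULL, ls))
  for (t in seq_len(n)) {
    age <- s$start_age + (t - 1) * s$cycle_length
    out[t, ] <- adjusted_death_prob(age, ls, pack$mortality, s$cycle_length)
  }
  out
}
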