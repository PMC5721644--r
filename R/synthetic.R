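# Synthetic-data generator: parametric life tables and structurally valid
# transition sets with the progression / regression / CSDMO-incidence /
# treatment-slowing structure the model assumes. These stand in for the
# trial-derived (ETDRS) per-cycle transition probabilities, which are not
# publicly available in machine-readable form; any externally sourced set
# with the same state space drops in via the pack config file.

#' Define a synthetic model scenario
#'
#' A scenario fixes every knob of the generator: the per-cycle probability of
#' progressing one disease tier, of regressing one tier, the CSDMO incidence,
#' the multiplicative slowing of progression after panretinal
#' photocoagulation (PRP), the post-PRP complication risks, and the
#' Gompertz-Makeham parameters `(a, b, c)` of the parametric life table
#' (annual death probability `a + b * exp(c * age)`). The generator is fully
#' deterministic given its parameters; `seed` is recorded for provenance and
#' for downstream stochastic analyses.
#'
#' @param seed Integer, recorded in the scenario.
#' @param progression_scale Per-cycle probability of moving one tier worse.
#' @param regression_scale Per-cycle probability of moving one tier better
#'   (where a better state exists).
#' @param csdmo_incidence Per-cycle probability of developing clinically
#'   significant macular oedema, at any tier with a CSDMO sibling state.
#' @param treatment_effect Multiplier in `(0, 1]` applied to the progression
#'   probability of post-treatment states (1 = PRP does nothing).
#' @param complication_prob_dmo Probability that a treated patient develops
#'   macular oedema in the cycle after PRP.
#' @param complication_prob_vh Probability of vitreous haemorrhage in the
#'   cycle after PRP, applicable only when PRP is given at a severe PDR tier.
#' @param makeham Named numeric `c(a=, b=, c=)` life-table parameters.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               progression_scale = 0.08,
                               regression_scale = 0.02,
                               csdmo_incidence = 0.02,
                               treatment_effect = 0.5,
                               complication_prob_dmo = 0.10,
                               complication_prob_vh = 0.02,
                               makeham = c(a = 5e-4, b = 1e-5, c = 0.11)) {
  probs <- c(progression = progression_scale, regression = regression_scale,
             csdmo = csdmo_incidence, dmo = complication_prob_dmo,
             vh = complication_prob_vh)
  if (any(probs < 0 | probs > 1)) stop("scenario probabilities must lie in [0, 1]")
  if (treatment_effect <= 0 || treatment_effect > 1) {
    stop("treatment_effect must lie in (0, 1]")
  }
  if (progression_scale + regression_scale + csdmo_incidence > 1) {
    stop("progression, regression and CSDMO scales sum to more than 1")
  }
  structure(
    list(seed = as.integer(seed),
         progression_scale = progression_scale,
         regression_scale = regression_scale,
         csdmo_incidence = csdmo_incidence,
         treatment_effect = treatment_effect,
         complication_prob_dmo = complication_prob_dmo,
         complication_prob_vh = complication_prob_vh,
         makeham = makeham),
    class = "synthetic_scenario"
  )
}

#' Draw a random but structurally valid scenario
#'
#' Used for property-style testing: parameters are sampled uniformly from
#' clinically plausible ranges, deterministically given `seed`.
#'
#' @param seed Integer seed.
#' @return A `synthetic_scenario`.
#' @export
random_scenario <- function(seed) {
  set.seed(seed)
  synthetic_scenario(
    seed = seed,
    progression_scale = stats::runif(1, 0.01, 0.15),
    regression_scale = stats::runif(1, 0, 0.05),
    csdmo_incidence = stats::runif(1, 0, 0.05),
    treatment_effect = stats::runif(1, 0.3, 1),
    complication_prob_dmo = stats::runif(1, 0, 0.3),
    complication_prob_vh = stats::runif(1, 0, 0.1)
  )
}

#' Parametric (Gompertz-Makeham) general-population life table
#'
#' Annual death probability at age `x` is `a + b * exp(c * x)`; with
#' `b, c > 0` this is strictly increasing in age.
#'
#' @param makeham Named numeric `c(a=, b=, c=)`.
#' @param ages Integer ages to tabulate (default 50..80, covering a 30-year
#'   horizon from start age 50).
#' @return data.frame with columns `age`, `annual_death_prob`.
#' @export
#' @examples
#' make_life_table()[1, ] # age 50: 5e-4 + 1e-5 * exp(5.5)
make_life_table <- function(makeham = c(a = 5e-4, b = 1e-5, c = 0.11),
                            ages = 50:80) {
  p <- makeham[["a"]] + makeham[["b"]] * exp(makeham[["c"]] * ages)
  bad <- which(p < 0 | p > 1)
  if (length(bad)) {
    stop("life-table probability outside [0, 1] at age ",
         paste(ages[bad], collapse = ", "))
  }
  data.frame(age = as.integer(ages), annual_death_prob = unname(p))
}

# Neighbour map for the generator: each living state's one-tier-worse and
# one-tier-better states within its own lane (plain / CSDMO / PT / PT+CSDMO),
# and its CSDMO sibling where one exists. Severe PDR tiers progress to
# SVL_blind; SVL_blind and absorbing lanes have no better state.
lane_chain <- function(csdmo, pt) {
  tiers <- c("severe_NPDR", "early_PDR", "HR_PDR", "severe_PDR")
  s <- tiers
  if (csdmo) s <- paste0(s, "_CSDMO")
  if (pt) s <- paste0(s, "_PT")
  # both plain lanes are anchored at moderate NPDR so that the treated and
  # untreated chains are topologically parallel (regression from the first
  # post-treatment tier returns to moderate NPDR, where a new progression
  # leads to re-treatment); the CSDMO lanes have no moderate tier to return to
  if (!csdmo) s <- c("moderate_NPDR", s)
  c(s, "SVL_blind")
}

#' Generate a synthetic per-arm transition set
#'
#' Each living state's row places `progression_scale` on the next-worse state
#' in its lane, `regression_scale` on the next-better state (where one
#' exists), `csdmo_incidence` on its CSDMO sibling (where one exists), and
#' the remainder on staying put. Post-treatment states progress at
#' `progression_scale * treatment_effect` in both arms: the arms differ in
#' when PRP fires, not in how well it works. The treated and untreated lanes
#' are topologically parallel: regression from the first post-treatment tier
#' returns to moderate NPDR (from where renewed progression leads to
#' re-treatment), so slowed progression can only help, whichever arm
#' administers it. Treatment is wired in by giving each treated state its
#' post-treatment counterpart's row: patients are treated during the cycle
#' in which they occupy the state and end it in the post-treatment lane
#' (in the corresponding post-treatment state unless the disease moved that
#' cycle). PRP fires at the severe NPDR tiers in the intervention arm and at
#' the HR-PDR tiers under usual care. Rows are conditional on surviving the
#' cycle; death is layered on by the engine.
#'
#' @param scenario A [synthetic_scenario()].
#' @param arm `"usual_care"` or `"intervention"`.
#' @param timing For the intervention arm, the tier at which PRP fires:
#'   `"severe_NPDR"` (default) or `"early_PDR"` (timing scenario).
#' @return A transition-set list: `arm`, `matrix` (18 x 18 row-stochastic over
#'   living states), `treatment_states`, `complication_probs`, `source`.
#' @export
make_transition_set <- function(scenario, arm = c("usual_care", "intervention"),
                                timing = c("severe_NPDR", "early_PDR")) {
  arm <- match.arg(arm)
  timing <- match.arg(timing)
  ls <- living_states()
  info <- state_info()
  p <- scenario$progression_scale
  r <- scenario$regression_scale
  d <- scenario$csdmo_incidence
  eff <- scenario$treatment_effect

  m <- matrix(0, length(ls), length(ls), dimnames = list(ls, ls))
  for (csdmo in c(FALSE, TRUE)) {
    for (pt in c(FALSE, TRUE)) {
      chain <- lane_chain(csdmo, pt)
      for (i in seq_along(chain)) {
        s <- chain[i]
        if (s == "SVL_blind") next
        # moderate NPDR appears in the post-treatment lane only as a
        # regression target; its own row belongs to the untreated lane
        if (pt && s == "moderate_NPDR") next
        prog <- if (pt) p * eff else p
        worse <- chain[i + 1]
        better <- if (i > 1) chain[i - 1] else NA
        sibling <- if (!csdmo && s != "moderate_NPDR") {
          sub("(_PT)?$", paste0("_CSDMO", if (pt) "_PT" else ""),
              s)
        } else NA
        row <- c(worse = prog,
                 better = if (!is.na(better)) r else 0,
                 sibling = if (!is.na(sibling)) d else 0)
        if (sum(row) > 1) {
          stop("transition scales sum to ", sum(row), " > 1 for state ", s)
        }
        m[s, worse] <- m[s, worse] + prog
        if (!is.na(better)) m[s, better] <- m[s, better] + r
        if (!is.na(sibling)) m[s, sibling] <- m[s, sibling] + d
        m[s, s] <- m[s, s] + 1 - sum(row)
      }
    }
  }
  m["SVL_blind", "SVL_blind"] <- 1

  treated <- if (arm == "usual_care") {
    c("HR_PDR", "HR_PDR_CSDMO")
  } else if (timing == "severe_NPDR") {
    c("severe_NPDR", "severe_NPDR_CSDMO")
  } else {
    c("early_PDR", "early_PDR_CSDMO")
  }
  # a treated state adopts its post-treatment counterpart's row: patients who
  # neither progress nor regress during the treatment cycle move to the
  # corresponding post-treatment state at cycle end, and treatment never
  # suspends the underlying disease dynamics (so slowing progression can only
  # help, whichever arm administers it)
  for (s in treated) {
    m[s, ] <- m[pt_state(s), ]
  }

  list(
    arm = arm,
    matrix = m,
    treatment_states = treated,
    complication_probs = list(dmo = scenario$complication_prob_dmo,
                              vh = scenario$complication_prob_vh),
    source = "synthetic placeholder"
  )
}

#' Build a full parameter pack from a synthetic scenario
#'
#' Combines the base-case settings, utilities, costs and resource use with
#' the scenario's synthetic transition sets and parametric life table.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A validated `parameter_pack` (zero violations by construction).
#' @export
make_pack <- function(scenario = synthetic_scenario()) {
  lt <- make_life_table(scenario$makeham)
  pack <- new_pack(
    transitions = list(
      usual_care = make_transition_set(scenario, "usual_care"),
      intervention = make_transition_set(scenario, "intervention")
    ),
    mortality = default_mortality(lt)
  )
  attr(pack, "scenario") <- scenario
  pack
}
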