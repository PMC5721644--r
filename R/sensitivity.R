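# Deterministic sensitivity analysis: one-way parameter variation with a
# tornado diagram on net monetary benefit, and the two structural scenarios
# (treatment timing; number of PRP sittings).

utility_group_states <- function(group) {
  info <- state_info()
  info$state[info$utility_group == group]
}

visit_group_states <- function(group) {
  info <- state_info()
  info$state[info$visit_group == group]
}

#' Addressable sensitivity parameters
#'
#' The one-way machinery addresses parameters by dotted path:
#' `utilities.<group>` (the five base-case utility values, `npdr`,
#' `npdr_csdmo`, `pdr`, `pdr_csdmo`, `svl`),
#' `utilities.complication_disutility`, `costs.<item>` (the seven unit
#' costs), and `visits.<group>` (the four per-tier visit counts).
#'
#' @return Character vector of all addressable parameter names.
#' @export
sensitivity_parameters <- function() {
  c(paste0("utilities.", names(UTILITY_GROUP_VALUES)),
    "utilities.complication_disutility",
    paste0("costs.", COST_ITEMS),
    paste0("visits.", names(VISIT_GROUP_COUNTS)))
}

get_parameter <- function(pack, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !name %in% sensitivity_parameters()) {
    stop("unknown sensitivity parameter: '", name, "'")
  }
  switch(parts[1],
    utilities = if (parts[2] == "complication_disutility") {
      pack$utilities$complication_disutility
    } else {
      unname(pack$utilities$by_state[[utility_group_states(parts[2])[1]]])
    },
    costs = pack$costs[[parts[2]]],
    visits = unname(pack$resources$visits_per_cycle[[visit_group_states(parts[2])[1]]])
  )
}

set_parameter <- function(pack, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !name %in% sensitivity_parameters()) {
    stop("unknown sensitivity parameter: '", name, "'")
  }
  if (parts[1] == "utilities") {
    if (parts[2] == "complication_disutility") {
      pack$utilities$complication_disutility <- min(value, 0)
    } else {
      # utilities are capped at 1.00 after scaling
      pack$utilities$by_state[utility_group_states(parts[2])] <- min(value, 1)
    }
  } else if (parts[1] == "costs") {
    pack$costs[[parts[2]]] <- value
  } else {
    pack$resources$visits_per_cycle[visit_group_states(parts[2])] <- value
  }
  pack
}

#' One-way sensitivity of net monetary benefit to a single parameter
#'
#' Reruns both arms deterministically with the parameter set to
#' `base * multipliers[1]` and `base * multipliers[2]` (utilities capped at
#' 1.00) and evaluates the intervention's net monetary benefit at the given
#' willingness to pay.
#'
#' @param pack A validated `parameter_pack`.
#' @param parameter A name from [sensitivity_parameters()].
#' @param multipliers Length-2 numeric, low and high multipliers on the base
#'   value (default ±50%).
#' @param wtp Willingness to pay per QALY (GBP).
#' @return One-row data.frame: `parameter`, `low_value`, `high_value`,
#'   `nmb_low`, `nmb_high`, `width` (= `|nmb_high - nmb_low|`).
#' @export
one_way <- function(pack, parameter, multipliers = c(0.5, 1.5), wtp = 20000) {
  stopifnot(length(multipliers) == 2)
  base <- get_parameter(pack, parameter)
  nmb_at <- function(mult) {
    p2 <- set_parameter(pack, parameter, base * mult)
    list(value = get_parameter(p2, parameter),
         nmb = nmb(run_comparison(p2)$comparison, wtp))
  }
  lo <- nmb_at(multipliers[1])
  hi <- nmb_at(multipliers[2])
  data.frame(parameter = parameter,
             low_value = lo$value, high_value = hi$value,
             nmb_low = lo$nmb, nmb_high = hi$nmb,
             width = abs(hi$nmb - lo$nmb),
             stringsAsFactors = FALSE)
}

#' Tornado analysis of net monetary benefit
#'
#' Runs [one_way()] for every parameter and returns the entries sorted by
#' descending bar width. The base-case NMB is attached as attribute
#' `base_nmb`.
#'
#' @param pack A validated `parameter_pack`.
#' @param parameters Parameter names (default: all of
#'   [sensitivity_parameters()] except the complication disutility, i.e. all
#'   utilities, unit costs and visit counts).
#' @param multipliers,wtp Passed to [one_way()].
#' @return data.frame of tornado entries, widest bar first.
#' @export
tornado <- function(pack,
                    parameters = setdiff(sensitivity_parameters(),
                                         "utilities.complication_disutility"),
                    multipliers = c(0.5, 1.5), wtp = 20000) {
  rows <- do.call(rbind, lapply(parameters, function(p) {
    one_way(pack, p, multipliers, wtp)
  }))
  rows <- rows[order(-rows$width), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "base_nmb") <- nmb(run_comparison(pack)$comparison, wtp)
  attr(rows, "wtp") <- wtp
  rows
}

#' Treatment-timing scenario: PRP at early PDR instead of severe NPDR
#'
#' Rewires the intervention arm so that PRP fires on occupancy of the early
#' PDR tiers: the severe NPDR tiers revert to their untreated (usual-care)
#' transition rows and the early PDR tiers adopt their post-treatment
#' counterparts' rows. The usual-care arm is unchanged.
#'
#' @param pack A validated `parameter_pack` whose intervention arm treats at
#'   the severe NPDR tiers.
#' @return As [run_comparison()] on the rewired pack.
#' @export
scenario_timing <- function(pack) {
  int_ <- pack$transitions$intervention
  old <- int_$treatment_states
  if (!all(old %in% c("severe_NPDR", "severe_NPDR_CSDMO"))) {
    stop("timing scenario expects an intervention arm treating at severe NPDR")
  }
  new <- c("early_PDR", "early_PDR_CSDMO")
  m <- int_$matrix
  m[old, ] <- pack$transitions$usual_care$matrix[old, ]
  m[new, ] <- m[pt_state(new), ]
  pack$transitions$intervention$matrix <- m
  pack$transitions$intervention$treatment_states <- new
  out <- run_comparison(pack)
  out$scenario <- "timing_early_PDR"
  out
}

#' PRP-sittings scenario: one, two or four sittings
#'
#' Scales the PRP cost bundle to the given number of sittings (each sitting
#' delivering the per-sitting lasers and visits); transition probabilities
#' and complication risks are unchanged, so QALYs equal the base case and
#' only costs move.
#'
#' @param pack A validated `parameter_pack`.
#' @param sittings 1, 2 or 4.
#' @return As [run_comparison()] on the modified pack.
#' @export
scenario_sittings <- function(pack, sittings) {
  if (!length(sittings) == 1 || !sittings %in% c(1, 2, 4)) {
    stop("sittings must be 1, 2 or 4")
  }
  pack$resources$prp_sittings <- sittings
  out <- run_comparison(pack)
  out$scenario <- sprintf("prp_%d_sitting%s", sittings, if (sittings > 1) "s" else "")
  out
}
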