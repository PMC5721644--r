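# Parameter pack: the full model specification (settings, utilities, costs,
# resource use, per-arm transition sets, mortality), its validation, and the
# bundled base-case pack. File format: one YAML document plus a two-column
# life-table CSV (`age,annual_death_prob`).

ARMS <- c("usual_care", "intervention")

UTILITY_GROUP_VALUES <- c(
  npdr       = 0.7915, # moderate / severe NPDR (and their PT copies)
  npdr_csdmo = 0.7365, # severe NPDR with CSDMO
  pdr        = 0.7047, # early / HR / severe PDR
  pdr_csdmo  = 0.6930, # PDR tiers with CSDMO
  svl        = 0.6218  # severe visual loss / blindness
)

VISIT_GROUP_COUNTS <- c(
  npdr = 1, early_pdr = 1.5, hr_severe_pdr = 2, svl = 0.5
)

COST_ITEMS <- c(
  "ophthalmology_visit", "monitoring_visit", "prp_laser", "focal_laser",
  "oct", "vitrectomy", "blindness_annual"
)

#' Per-state base-case utilities
#'
#' Expands the five base-case utility values (NPDR 0.7915; severe NPDR with
#' CSDMO 0.7365; PDR tiers 0.7047; PDR with CSDMO 0.6930; severe visual
#' loss/blindness 0.6218) over the 18 living states. Post-treatment states
#' carry the utility of their disease tier.
#'
#' @param group_values Named vector of utility values per group (defaults to
#'   the base case).
#' @return Named numeric vector over [living_states()].
#' @export
default_utilities <- function(group_values = UTILITY_GROUP_VALUES) {
  info <- state_info()
  u <- group_values[info$utility_group]
  names(u) <- info$state
  u
}

default_visits <- function(group_counts = VISIT_GROUP_COUNTS) {
  info <- state_info()
  v <- group_counts[info$visit_group]
  names(v) <- info$state
  v
}

default_settings <- function() {
  list(
    cycle_length = 0.5,        # years; 6-month cycles
    horizon = 30,              # years
    start_age = 50,            # years
    cohort_size = 1000,
    discount_rate = 0.035,     # annual, applied to costs and QALYs
    start_state = "moderate_NPDR",
    discount_first_cycle = TRUE,   # first cycle discounted at exponent 0.5y
    half_cycle_correction = FALSE  # transitions fire at cycle end
  )
}

default_costs <- function() {
  list(
    ophthalmology_visit = 106,  # WF01B
    monitoring_visit = 80,      # WF01A
    prp_laser = 131,            # OP BZ22B, per laser treatment (one eye)
    focal_laser = 131,          # OP BZ22B
    oct = 117,                  # OP BZ23Z
    vitrectomy = 989,           # DC BZ22B
    blindness_annual = 1483,    # per year; excludes residential care
    price_year = "2012/2013"
  )
}

default_resources <- function() {
  info <- state_info()
  list(
    visits_per_cycle = default_visits(),
    # which unit cost each state's visits are billed at; the split between
    # ophthalmology (106) and monitoring (80) visits is not pinned down, so
    # all visits default to ophthalmology
    visit_type = stats::setNames(rep("ophthalmology_visit", nrow(info)), info$state),
    prp_sittings = 2,              # both eyes treated together, over 2 sittings
    lasers_per_sitting = 2,        # one laser treatment per eye per sitting
    visits_per_sitting = 0,        # extra clinic visits per PRP sitting
    dmo_focal_lasers = 2,          # focal laser for both eyes before PRP
    dmo_oct = 1                    # one OCT with the DMO bundle
  )
}

default_severity_rr <- function() {
  c(moderate_NPDR = 1.118, severe_NPDR = 1.422,
    mild_PDR = 0.992, moderate_high_PDR = 1.705)
}

default_mortality <- function(life_table = NULL) {
  if (is.null(life_table)) life_table <- make_life_table()
  info <- state_info()
  list(
    life_table = life_table,
    diabetes_rr = 2.194,
    severity_rr = default_severity_rr(),
    state_to_severity = stats::setNames(info$severity_class, info$state),
    compose_diabetes = TRUE
  )
}

#' Assemble a parameter pack
#'
#' Low-level constructor; components default to the base case. The pack is
#' validated and construction fails if any invariant is violated.
#'
#' @param settings,utilities,costs,resources,transitions,mortality Components;
#'   see [base_case_pack()] for their shapes.
#' @return A validated object of class `parameter_pack`.
#' @export
new_pack <- function(settings = default_settings(),
                     utilities = list(by_state = default_utilities(),
                                      complication_disutility = -0.03),
                     costs = default_costs(),
                     resources = default_resources(),
                     transitions = NULL,
                     mortality = default_mortality()) {
  if (is.null(transitions)) {
    sc <- synthetic_scenario()
    transitions <- list(
      usual_care = make_transition_set(sc, "usual_care"),
      intervention = make_transition_set(sc, "intervention")
    )
  }
  pack <- structure(
    list(settings = settings, utilities = utilities, costs = costs,
         resources = resources, transitions = transitions,
         mortality = mortality),
    class = "parameter_pack"
  )
  viol <- validate_pack(pack)
  if (length(viol)) {
    stop("invalid parameter pack:\n  ", paste(viol, collapse = "\n  "))
  }
  pack
}

#' The bundled base-case parameter pack
#'
#' Settings (1000-patient cohort starting at age 50 in moderate NPDR,
#' 6-month cycles over 30 years, 3.5% annual discounting), health-state
#' utilities, unit costs (2012/2013 GBP), visit schedules and mortality
#' multipliers (diabetes 2.194; severity 1.118 / 1.422 / 0.992 / 1.705) are
#' the published base case. The trial-derived (ETDRS) transition
#' probabilities behind the original analysis are not publicly available in
#' machine-readable form and are not bundled: the pack
#' ships clearly-flagged synthetic placeholder transitions
#' (see [make_transition_set()]) and a parametric (Gompertz-Makeham) life
#' table, both swappable via the config file read by [load_pack()].
#'
#' @param scenario Synthetic scenario supplying the placeholder transitions
#'   and life table; see [synthetic_scenario()].
#' @return A validated `parameter_pack`.
#' @export
#' @examples
#' pack <- base_case_pack()
#' pack$utilities$by_state[["SVL_blind"]]
#' pack$costs$vitrectomy
base_case_pack <- function(scenario = synthetic_scenario()) {
  make_pack(scenario)
}

n_cycles <- function(pack) {
  as.integer(round(pack$settings$horizon / pack$settings$cycle_length))
}

#' Validate a parameter pack
#'
#' Checks every structural invariant: settings ranges, utilities in `[0, 1]`
#' with a non-positive complication disutilty, non-negative costs and visit
#' counts, both arms present with complete stochastic transition rows
#' (each summing to 1 within 1e-9), and a life table covering the whole
#' horizon. Violations are returned as data, not raised.
#'
#' @param pack A `parameter_pack` (or pack-shaped list).
#' @return Character vector of violation messages; empty if the pack is valid.
#' @export
validate_pack <- function(pack) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  ls <- living_states()

  s <- pack$settings
  if (!is.numeric(s$cycle_length) || s$cycle_length <= 0) {
    add("settings.cycle_length: must be > 0")
  } else if (abs(s$horizon / s$cycle_length - round(s$horizon / s$cycle_length)) > 1e-9) {
    add("settings.horizon: must be an integer multiple of cycle_length")
  }
  if (!is.numeric(s$discount_rate) || s$discount_rate < 0 || s$discount_rate >= 1) {
    add("settings.discount_rate: must lie in [0, 1)")
  }
  if (!isTRUE(s$start_state %in% ls)) {
    add(paste0("settings.start_state: unknown state '", s$start_state, "'"))
  }
  if (!is.numeric(s$cohort_size) || s$cohort_size < 1) {
    add("settings.cohort_size: must be >= 1")
  }

  u <- pack$utilities$by_state
  missing_u <- setdiff(ls, names(u))
  if (length(missing_u)) {
    add(paste0("utilities: missing state(s) ", paste(missing_u, collapse = ", ")))
  }
  bad_u <- names(u)[!is.na(u) & (u < 0 | u > 1)]
  for (nm in bad_u) {
    add(paste0("utilities.", nm, ": value ", u[[nm]], " outside [0, 1]"))
  }
  cd <- pack$utilities$complication_disutility
  if (!is.numeric(cd) || cd > 0) {
    add("utilities.complication_disutility: must be <= 0")
  }

  for (item in COST_ITEMS) {
    val <- pack$costs[[item]]
    if (is.null(val)) {
      add(paste0("costs.", item, ": missing"))
    } else if (!is.numeric(val) || val < 0) {
      add(paste0("costs.", item, ": must be a non-negative number"))
    }
  }

  res <- pack$resources
  missing_v <- setdiff(ls, names(res$visits_per_cycle))
  if (length(missing_v)) {
    add(paste0("resources.visits_per_cycle: missing state(s) ",
               paste(missing_v, collapse = ", ")))
  }
  if (any(res$visits_per_cycle < 0, na.rm = TRUE)) {
    add("resources.visits_per_cycle: negative visit count")
  }
  if (!res$prp_sittings %in% c(1, 2, 4)) {
    add("resources.prp_sittings: must be 1, 2 or 4")
  }
  bad_vt <- setdiff(unique(res$visit_type), c("ophthalmology_visit", "monitoring_visit"))
  if (length(bad_vt)) {
    add(paste0("resources.visit_type: unknown type(s) ", paste(bad_vt, collapse = ", ")))
  }

  for (arm in ARMS) {
    ts <- pack$transitions[[arm]]
    if (is.null(ts)) {
      add(paste0("transitions: missing arm '", arm, "'"))
      next
    }
    m <- ts$matrix
    if (!is.matrix(m) || !setequal(rownames(m), ls) || !setequal(colnames(m), ls)) {
      add(paste0("transitions.", arm, ": matrix must be over all living states"))
      next
    }
    if (any(m < 0 | m > 1)) {
      add(paste0("transitions.", arm, ": entries outside [0, 1]"))
    }
    rs <- rowSums(m)
    bad <- which(abs(rs - 1) > 1e-9)
    for (i in bad) {
      add(paste0("transitions.", arm, ".", rownames(m)[i],
                 ": row sums to ", format(rs[i], digits = 10), ", not 1"))
    }
    unknown_ts <- setdiff(ts$treatment_states, ls)
    if (length(unknown_ts)) {
      add(paste0("transitions.", arm, ".treatment_states: unknown state(s) ",
                 paste(unknown_ts, collapse = ", ")))
    }
    cp <- unlist(ts$complication_probs)
    if (any(cp < 0 | cp > 1)) {
      add(paste0("transitions.", arm, ".complication_probs: outside [0, 1]"))
    }
  }

  m <- pack$mortality
  lt <- m$life_table
  if (!all(c("age", "annual_death_prob") %in% names(lt))) {
    add("mortality.life_table: needs columns age, annual_death_prob")
  } else {
    if (any(lt$annual_death_prob < 0 | lt$annual_death_prob > 1)) {
      add("mortality.life_table: probabilities outside [0, 1]")
    }
    need <- seq(floor(s$start_age), floor(s$start_age + s$horizon))
    if (!all(need %in% lt$age)) {
      add("mortality.life_table: does not cover ages start_age .. start_age + horizon")
    }
  }
  if (!is.numeric(m$diabetes_rr) || m$diabetes_rr <= 0) {
    add("mortality.diabetes_rr: must be > 0")
  }
  if (any(m$severity_rr <= 0, na.rm = TRUE)) {
    add("mortality.severity_rr: multipliers must be > 0")
  }
  missing_map <- setdiff(ls, names(m$state_to_severity))
  if (length(missing_map)) {
    add(paste0("mortality.state_to_severity: missing state(s) ",
               paste(missing_map, collapse = ", ")))
  } else {
    unmapped <- setdiff(unique(m$state_to_severity), names(m$severity_rr))
    if (length(unmapped)) {
      add(paste0("mortality.severity_rr: no multiplier for class(es) ",
                 paste(unmapped, collapse = ", ")))
    }
  }

  v
}

transitions_to_list <- function(ts) {
  rows <- apply(ts$matrix, 1, function(r) as.list(r[r > 0]), simplify = FALSE)
  list(
    treatment_states = as.list(ts$treatment_states),
    complication_probs = ts$complication_probs,
    source = ts$source,
    rows = rows
  )
}

transitions_from_list <- function(x, arm) {
  ls <- living_states()
  m <- matrix(0, length(ls), length(ls), dimnames = list(ls, ls))
  for (from in names(x$rows)) {
    assert_states(from, paste0("transition origin in arm ", arm))
    row <- unlist(x$rows[[from]])
    assert_states(names(row), paste0("transition destination in arm ", arm))
    m[from, names(row)] <- row
  }
  list(
    arm = arm,
    matrix = m,
    treatment_states = as.character(unlist(x$treatment_states)),
    complication_probs = lapply(x$complication_probs, as.numeric),
    source = x$source %||% "file"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter pack to disk
#'
#' Emits a YAML document plus a separate life-table CSV
#' (`age,annual_death_prob`) next to it, so that transition sets and life
#' tables can be edited or replaced independently of the code.
#'
#' @param pack A validated `parameter_pack`.
#' @param path Path of the YAML file to write.
#' @param life_table_file Name of the life-table CSV, relative to `path`.
#' @return `path`, invisibly.
#' @export
write_pack <- function(pack, path, life_table_file = "life_table.csv") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  doc <- list(
    pack_version = 1L,
    settings = pack$settings,
    utilities = list(
      by_state = as.list(pack$utilities$by_state),
      complication_disutility = pack$utilities$complication_disutility
    ),
    costs = pack$costs,
    resources = list(
      visits_per_cycle = as.list(pack$resources$visits_per_cycle),
      visit_type = as.list(pack$resources$visit_type),
      prp_sittings = pack$resources$prp_sittings,
      lasers_per_sitting = pack$resources$lasers_per_sitting,
      visits_per_sitting = pack$resources$visits_per_sitting,
      dmo_focal_lasers = pack$resources$dmo_focal_lasers,
      dmo_oct = pack$resources$dmo_oct
    ),
    transitions = lapply(pack$transitions, transitions_to_list),
    mortality = list(
      life_table_file = life_table_file,
      diabetes_rr = pack$mortality$diabetes_rr,
      severity_rr = as.list(pack$mortality$severity_rr),
      state_to_severity = as.list(pack$mortality$state_to_severity),
      compose_diabetes = pack$mortality$compose_diabetes
    )
  )
  yaml::write_yaml(doc, path, precision = 15)
  utils::write.csv(pack$mortality$life_table,
                   file.path(dirname(path), life_table_file),
                   row.names = FALSE)
  invisible(path)
}

#' Load and validate a parameter pack from disk
#'
#' Reads the YAML config written by [write_pack()] (life table resolved
#' relative to the config file) and validates every invariant; loading fails
#' with the full list of violations if any is broken.
#'
#' @param path Path to the pack YAML file.
#' @return A validated `parameter_pack`.
#' @export
load_pack <- function(path) {
  if (!file.exists(path)) stop("no such pack file: ", path)
  doc <- yaml::read_yaml(path)
  lt_path <- file.path(dirname(path), doc$mortality$life_table_file)
  if (!file.exists(lt_path)) stop("life table file not found: ", lt_path)
  lt <- utils::read.csv(lt_path)
  settings <- doc$settings
  utilities <- list(
    by_state = unlist(doc$utilities$by_state),
    complication_disutility = doc$utilities$complication_disutility
  )
  resources <- doc$resources
  resources$visits_per_cycle <- unlist(resources$visits_per_cycle)
  resources$visit_type <- unlist(resources$visit_type)
  transitions <- lapply(
    stats::setNames(nm = intersect(ARMS, names(doc$transitions))),
    function(arm) transitions_from_list(doc$transitions[[arm]], arm)
  )
  mortality <- list(
    life_table = lt,
    diabetes_rr = doc$mortality$diabetes_rr,
    severity_rr = unlist(doc$mortality$severity_rr),
    state_to_severity = unlist(doc$mortality$state_to_severity),
    compose_diabetes = isTRUE(doc$mortality$compose_diabetes)
  )
  new_pack(settings = settings, utilities = utilities, costs = doc$costs,
           resources = resources, transitions = transitions,
           mortality = mortality)
}

#' @export
print.parameter_pack <- function(x, ...) {
  s <- x$settings
  cat("<parameter_pack>\n")
  cat(sprintf("  cohort %d, start age %g in %s; %g-year horizon, %g-year cycles\n",
              as.integer(s$cohort_size), s$start_age, s$start_state,
              s$horizon, s$cycle_length))
  cat(sprintf("  discount rate %.1f%%/year; prices %s\n",
              100 * s$discount_rate, x$costs$price_year))
  for (arm in names(x$transitions)) {
    ts <- x$transitions[[arm]]
    cat(sprintf("  %s: PRP at %s (transitions: %s)\n", arm,
                paste(ts$treatment_states, collapse = ", "), ts$source))
  }
  invisible(x)
}
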