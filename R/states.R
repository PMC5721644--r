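# Health-state space shared by every module. Disease severity runs
# moderate NPDR > severe NPDR > early PDR > HR-PDR > severe PDR > SVL/blindness,
# with clinically significant macular oedema (CSDMO) variants from severe NPDR
# onwards and post-treatment (PT) shadows of every treatable state.

#' Living (non-absorbing) health states of the retinopathy model
#'
#' States are ordered by disease tier, with CSDMO variants beside their base
#' tier, followed by the post-treatment (`_PT`) copies and severe visual
#' loss/blindness. Death is excluded; see [health_states()].
#'
#' @return Character vector of 18 state names.
#' @export
living_states <- function() {
  base <- c(
    "moderate_NPDR",
    "severe_NPDR", "severe_NPDR_CSDMO",
    "early_PDR", "early_PDR_CSDMO",
    "HR_PDR", "HR_PDR_CSDMO",
    "severe_PDR", "severe_PDR_CSDMO"
  )
  c(base, paste0(base[-1], "_PT"), "SVL_blind")
}

#' All health states, including the absorbing death state
#'
#' @return Character vector of 19 state names; `"dead"` is last.
#' @export
health_states <- function() c(living_states(), "dead")

#' Structural metadata for every living state
#'
#' @return A data.frame with one row per living state and columns:
#'   `state`; `tier` (1 = moderate NPDR ... 5 = severe PDR, 6 = SVL/blind);
#'   `csdmo`, `pt` (logicals); `severity_class` (mortality-multiplier class);
#'   `utility_group` (which base-case utility value the state carries);
#'   `visit_group` (which per-cycle visit count applies).
#' @export
state_info <- function() {
  st <- living_states()
  tier_of <- function(s) {
    if (grepl("^moderate_NPDR", s)) 1L
    else if (grepl("^severe_NPDR", s)) 2L
    else if (grepl("^early_PDR", s)) 3L
    else if (grepl("^HR_PDR", s)) 4L
    else if (grepl("^severe_PDR", s)) 5L
    else 6L # SVL_blind
  }
  tier <- vapply(st, tier_of, integer(1))
  csdmo <- grepl("CSDMO", st)
  pt <- grepl("_PT$", st)
  severity_class <- c(
    "moderate_NPDR", "severe_NPDR", "mild_PDR", "moderate_high_PDR",
    "moderate_high_PDR", "moderate_high_PDR"
  )[tier]
  utility_group <- ifelse(
    tier == 6L, "svl",
    ifelse(tier <= 2L,
      ifelse(csdmo, "npdr_csdmo", "npdr"),
      ifelse(csdmo, "pdr_csdmo", "pdr")
    )
  )
  visit_group <- c(
    "npdr", "npdr", "early_pdr", "hr_severe_pdr", "hr_severe_pdr", "svl"
  )[tier]
  data.frame(
    state = st, tier = tier, csdmo = csdmo, pt = pt,
    severity_class = severity_class,
    utility_group = utility_group,
    visit_group = visit_group,
    row.names = st, stringsAsFactors = FALSE
  )
}

#' Post-treatment counterpart of a treatable state
#'
#' @param state Character vector of non-PT living state names.
#' @return The corresponding `_PT` state names.
#' @export
pt_state <- function(state) {
  bad <- grepl("_PT$", state) | state %in% c("moderate_NPDR", "SVL_blind", "dead")
  if (any(bad)) {
    stop("no post-treatment counterpart for state(s): ",
         paste(state[bad], collapse = ", "))
  }
  paste0(state, "_PT")
}

#' Pre-treatment origin of a post-treatment state
#'
#' @param state Character vector of `_PT` state names.
#' @return The state names with the `_PT` suffix removed.
#' @export
origin_state <- function(state) {
  if (!all(grepl("_PT$", state))) stop("not post-treatment state(s)")
  sub("_PT$", "", state)
}

assert_states <- function(x, what = "state") {
  unknown <- setdiff(x, health_states())
  if (length(unknown)) {
    stop("unknown ", what, ": ", paste(unknown, collapse = ", "))
  }
  invisible(x)
}
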