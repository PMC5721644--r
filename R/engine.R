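# Cohort engine: per-cycle transition matrices (disease transitions layered
# with age- and state-dependent mortality) and the deterministic cohort trace.
# Death is applied first each cycle; the stored disease rows are conditional
# on survival and are scaled by (1 - p_death).

#' Full transition matrix for one cycle
#'
#' For each living state `s`, the probability of moving to `dead` is the
#' adjusted per-cycle death probability at the cohort's current age
#' (`start_age + cycle_index * cycle_length`); the surviving mass
#' `1 - p_death` is distributed over the arm's survival-conditional
#' transition row. The `dead` row is the identity row.
#'
#' @param pack A validated `parameter_pack`.
#' @param arm `"usual_care"` or `"intervention"`.
#' @param cycle_index 0-based cycle index within the horizon.
#' @return List with `cycle_index` and `matrix` (19 x 19 row-stochastic, over
#'   [health_states()]).
#' @export
build_cycle_matrix <- function(pack, arm, cycle_index) {
  arm <- match.arg(arm, ARMS)
  ls <- living_states()
  s <- pack$settings
  if (cycle_index < 0 || cycle_index >= n_cycles(pack)) {
    stop("cycle_index outside the horizon")
  }
  age <- s$start_age + cycle_index * s$cycle_length
  p_death <- adjusted_death_prob(age, ls, pack$mortality, s$cycle_length)
  live <- pack$transitions[[arm]]$matrix[ls, ls] * (1 - p_death)
  full <- cbind(live, dead = p_death)
  full <- rbind(full, dead = c(rep(0, length(ls)), 1))
  list(cycle_index = cycle_index, matrix = full)
}

#' Run the deterministic cohort trace for one arm
#'
#' Starting from the whole cohort in `start_state`, occupancy row `t + 1` is
#' row `t` multiplied by the cycle-`t` transition matrix; with the base
#' settings this is 60 half-year cycles over 30 years. The result is
#' deterministic given the pack.
#'
#' @inheritParams build_cycle_matrix
#' @return A `cohort_trace`: matrix of `n_cycles + 1` rows (cycle 0 =
#'   the starting distribution) by 19 state columns, rows summing to 1, with
#'   attributes `arm` and `ages`.
#' @export
run_cohort <- function(pack, arm) {
  arm <- match.arg(arm, ARMS)
  hs <- health_states()
  ls <- living_states()
  s <- pack$settings
  n <- n_cycles(pack)
  occ <- matrix(0, n + 1, length(hs), dimnames = list(0:n, hs))
  occ[1, s$start_state] <- 1
  trans <- pack$transitions[[arm]]$matrix[ls, ls]
  dp <- death_prob_matrix(pack)
  for (t in seq_len(n)) {
    cur <- occ[t, ls]
    surv <- cur * (1 - dp[t, ])
    occ[t + 1, ls] <- surv %*% trans
    occ[t + 1, "dead"] <- occ[t, "dead"] + sum(cur) - sum(surv)
  }
  structure(occ, class = c("cohort_trace", "matrix"),
            arm = arm,
            ages = s$start_age + (0:n) * s$cycle_length)
}

#' Per-cycle treatment and complication event masses
#'
#' For each cycle `k` (1-based; the cycle during which occupancy row `k - 1`
#' applies) this returns: the cohort mass occupying a PRP treatment state
#' (`prp_starts`; every such patient is treated that cycle and moves to the
#' post-treatment state at cycle end), the subset with CSDMO receiving the
#' focal-laser + OCT bundle (`dmo_bundles`), and the mass incurring a
#' one-cycle post-PRP complication in the following cycle: macular oedema
#' (`comp_dmo`, probability `complication_probs$dmo` among surviving treated
#' patients) and vitreous haemorrhage (`comp_vh`, only when PRP was given at
#' a severe PDR tier). Complications attach to the cycle in which the
#' post-treatment state is entered; treatment begun in the final cycle has
#' its complication fall beyond the horizon and is dropped.
#'
#' @param pack A validated `parameter_pack`.
#' @param arm Arm label.
#' @param trace The `cohort_trace` produced by [run_cohort()] on the same
#'   pack and arm.
#' @return data.frame with columns `cycle`, `prp_starts`, `dmo_bundles`,
#'   `comp_dmo`, `comp_vh`.
#' @export
treatment_events <- function(pack, arm, trace) {
  arm <- match.arg(arm, ARMS)
  n <- n_cycles(pack)
  ts <- pack$transitions[[arm]]
  treated <- ts$treatment_states
  info <- state_info()
  ev <- data.frame(cycle = seq_len(n), prp_starts = 0, dmo_bundles = 0,
                   comp_dmo = 0, comp_vh = 0)
  if (!length(treated)) return(ev)
  dp <- death_prob_matrix(pack)
  csdmo_states <- treated[info[treated, "csdmo"]]
  severe_pdr_states <- treated[info[treated, "tier"] == 5L]
  for (k in seq_len(n)) {
    occ <- trace[k, treated]
    ev$prp_starts[k] <- sum(occ)
    ev$dmo_bundles[k] <- sum(trace[k, csdmo_states])
    if (k < n) {
      survivors <- occ * (1 - dp[k, treated])
      ev$comp_dmo[k + 1] <- sum(survivors) * ts$complication_probs$dmo
      ev$comp_vh[k + 1] <- sum(trace[k, severe_pdr_states] *
                                 (1 - dp[k, severe_pdr_states])) *
        ts$complication_probs$vh
    }
  }
  ev
}

#' Write a cohort trace to CSV
#'
#' One row per cycle with the cohort age, the end-of-cycle discount factor
#' and the occupancy of every state.
#'
#' @param trace A `cohort_trace`.
#' @param pack The pack it was produced from.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, pack, path) {
  s <- pack$settings
  n <- nrow(trace) - 1
  df <- data.frame(
    cycle = 0:n,
    age = attr(trace, "ages"),
    discount_factor = (1 + s$discount_rate)^(-(0:n) * s$cycle_length),
    unclass(trace), check.names = FALSE
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
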