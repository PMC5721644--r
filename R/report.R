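# Report assembly: CSV writers for the base case, scenarios, tornado and PSA
# outputs, plus a JSON run manifest recording what was produced from which
# inputs. The numbered scripts under analysis/ are thin drivers over these.

#' Write a JSON run manifest
#'
#' Records the analysis name, package version, timestamp, seed, resolved
#' options and output files; fails if any listed output file is missing.
#'
#' @param out_dir Output directory.
#' @param analysis Short analysis label.
#' @param files Character vector of files (relative to `out_dir`) the run
#'   produced.
#' @param seed Seed used, or `NA` for deterministic runs.
#' @param options Named list of resolved option values to record.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, analysis, files, seed = NA_integer_,
                           options = list()) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing)) {
    stop("manifest lists missing output file(s): ", paste(missing, collapse = ", "))
  }
  manifest <- list(
    analysis = analysis,
    package_version = as.character(utils::packageVersion("prpcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    options = options,
    files = as.list(files)
  )
  path <- file.path(out_dir, paste0(analysis, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

strategy_row <- function(res) {
  data.frame(arm = res$arm, cost = res$cost, qaly = res$qaly,
             cost_undiscounted = res$cost_undiscounted %||% NA_real_,
             qaly_undiscounted = res$qaly_undiscounted %||% NA_real_)
}

comparison_row <- function(cmp, label = "base_case") {
  data.frame(scenario = label,
             cost_uc = cmp$usual_care$cost, qaly_uc = cmp$usual_care$qaly,
             cost_int = cmp$intervention$cost, qaly_int = cmp$intervention$qaly,
             delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
             verdict = cmp$verdict, icer = cmp$icer)
}

#' Run and write the deterministic base case
#'
#' Writes per-arm traces, the per-arm strategy results and the incremental
#' comparison, plus a manifest.
#'
#' @param pack A validated `parameter_pack`.
#' @param out_dir Output directory (created if needed).
#' @return The [run_comparison()] result, invisibly.
#' @export
report_base_case <- function(pack, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- run_comparison(pack)
  write_trace(run$usual_care$trace, pack, file.path(out_dir, "trace_usual_care.csv"))
  write_trace(run$intervention$trace, pack, file.path(out_dir, "trace_intervention.csv"))
  utils::write.csv(rbind(strategy_row(run$usual_care$result),
                         strategy_row(run$intervention$result)),
                   file.path(out_dir, "strategy_results.csv"), row.names = FALSE)
  utils::write.csv(comparison_row(run$comparison),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  write_manifest(out_dir, "base_case",
                 c("trace_usual_care.csv", "trace_intervention.csv",
                   "strategy_results.csv", "comparison.csv"),
                 options = list(discount_rate = pack$settings$discount_rate,
                                prp_sittings = pack$resources$prp_sittings))
  invisible(run)
}

#' Run and write the deterministic scenario analyses
#'
#' Timing (PRP at early PDR) and sittings (1 and 4) scenarios beside the
#' base case.
#'
#' @inheritParams report_base_case
#' @return data.frame of scenario comparisons, invisibly.
#' @export
report_scenarios <- function(pack, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- rbind(
    comparison_row(run_comparison(pack)$comparison, "base_case"),
    comparison_row(scenario_timing(pack)$comparison, "timing_early_PDR"),
    comparison_row(scenario_sittings(pack, 1)$comparison, "prp_1_sitting"),
    comparison_row(scenario_sittings(pack, 4)$comparison, "prp_4_sittings")
  )
  utils::write.csv(rows, file.path(out_dir, "scenarios.csv"), row.names = FALSE)
  write_manifest(out_dir, "scenarios", "scenarios.csv")
  invisible(rows)
}

#' Run and write the tornado analysis
#'
#' @inheritParams report_base_case
#' @param wtp Willingness to pay per QALY.
#' @param multipliers Low/high multipliers on each parameter.
#' @return The tornado data.frame, invisibly.
#' @export
report_tornado <- function(pack, out_dir, wtp = 20000, multipliers = c(0.5, 1.5)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tor <- tornado(pack, multipliers = multipliers, wtp = wtp)
  utils::write.csv(tor, file.path(out_dir, "tornado.csv"), row.names = FALSE)
  write_manifest(out_dir, "tornado", "tornado.csv",
                 options = list(wtp = wtp, multipliers = multipliers,
                                base_nmb = attr(tor, "base_nmb")))
  invisible(tor)
}

#' Run and write the probabilistic sensitivity analysis
#'
#' Writes the per-iteration draws and outcomes, the cost-effectiveness plane
#' points and the acceptability curve.
#'
#' @inheritParams report_base_case
#' @param spec A [psa_spec()].
#' @return The `psa_result`, invisibly.
#' @export
report_psa <- function(pack, out_dir, spec = psa_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- sample_psa(pack, spec)
  utils::write.csv(cbind(res$draws, res$outcomes[, -1]),
                   file.path(out_dir, "psa_draws.csv"), row.names = FALSE)
  utils::write.csv(ce_plane(res), file.path(out_dir, "ce_plane.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(res), file.path(out_dir, "ceac.csv"), row.names = FALSE)
  write_manifest(out_dir, "psa",
                 c("psa_draws.csv", "ce_plane.csv", "ceac.csv"),
                 seed = spec$seed,
                 options = list(iterations = spec$iterations,
                                cost_se_frac = spec$cost_se_frac,
                                utility_se_frac = spec$utility_se_frac))
  invisible(res)
}
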