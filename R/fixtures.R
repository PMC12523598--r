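# Packaged example-laboratory dataset: sigma assessments, plan
# assignments and the consolidated per-analyzer plans of a six-analyzer
# core laboratory (four spectrophotometric, two immunoassay), 35
# parameters in serum and urine. Censored "sigma >= 6" entries are
# encoded as 6.0 (a conservative lower bound for rule selection) with
# the censoring preserved in a flag; "-" marks sigma < 4 (not
# controllable) and "na" a procedure not available on that analyzer.

fixture_path <- function(file) {
  system.file("extdata", file, package = "bracketqc", mustWork = TRUE)
}

#' Example laboratory sigma table
#'
#' Mean sigma values per parameter and analyzer for the packaged
#' example laboratory.
#'
#' @return data frame with columns \code{parameter}, \code{specimen}
#'   (serum/urine), \code{platform}, \code{analyzer}, \code{mean_sigma}
#'   (6.0 for censored ">= 6" entries, NA when not available),
#'   \code{censored_ge6} and \code{available}.
#' @export
lab_sigma_fixture <- function() {
  read_table_csv(fixture_path("lab_sigma.csv"))
}

#' Example laboratory plan assignments
#'
#' Multistage QC plan ids (1-7, referencing
#' \code{\link{plan_catalogue}}) and workload categories per parameter
#' and analyzer. \code{status} distinguishes assigned plans
#' (\code{"ok"}) from procedures with sigma < 4
#' (\code{"not_controllable"}, no plan possible) and procedures absent
#' from an analyzer (\code{"not_available"}).
#'
#' @return data frame with columns \code{parameter}, \code{platform},
#'   \code{analyzer}, \code{plan_id}, \code{category}, \code{status}.
#' @export
lab_plan_fixture <- function() {
  read_table_csv(fixture_path("lab_plan_assignments.csv"))
}

#' Reference consolidation of the example laboratory
#'
#' The per-analyzer general plan and the individualized plans actually
#' adopted for the example laboratory; used to validate
#' \code{\link{consolidate}}.
#'
#' @return list (one element per analyzer) with \code{analyzer},
#'   \code{general_plan}, \code{individualized} (plan id ->
#'   parameters) and \code{uncovered}.
#' @export
lab_consolidation_reference <- function() {
  jsonlite::read_json(fixture_path("lab_consolidation_reference.json"))
}
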