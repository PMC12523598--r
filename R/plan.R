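# Multistage (startup/monitor) QC plan design and cross-analyzer
# consolidation.

CATEGORY_MAX <- c(A = 100L, B = 75L, C = 50L, D = 25L, E = 12L)

#' Workload category from daily workload
#'
#' The run size (patient samples between QC events) is a quarter of the
#' daily workload, rounded up. Each parameter is then assigned the
#' smallest-capacity run-size category whose maximum covers that run
#' size: A (100), B (75), C (50), D (25), E (12); run sizes above 100
#' are capped into category A.
#'
#' @param daily_workload patient samples per day (>= 1).
#' @return an object of class \code{workload_profile}: list with
#'   \code{daily_workload}, \code{run_size} and \code{category}.
#' @examples
#' categorize_workload(200) # run size 50, category C
#' @export
categorize_workload <- function(daily_workload) {
  if (length(daily_workload) != 1 || !is.finite(daily_workload) ||
      daily_workload < 1)
    stop("daily_workload must be a single value >= 1", call. = FALSE)
  run_size <- as.integer(ceiling(daily_workload / 4))
  fits <- CATEGORY_MAX[CATEGORY_MAX >= run_size]
  category <- if (length(fits)) names(fits)[which.min(fits)] else "A"
  structure(list(daily_workload = daily_workload, run_size = run_size,
                 category = category),
            class = "workload_profile")
}

#' Workload profile from a run-size category
#'
#' When only the category is known, the nominal daily workload is four
#' times the category's maximum run size.
#'
#' @param category one of \code{"A"} to \code{"E"}.
#' @return a \code{workload_profile}.
#' @export
workload_from_category <- function(category) {
  category <- match.arg(category, names(CATEGORY_MAX))
  rs <- CATEGORY_MAX[[category]]
  structure(list(daily_workload = 4L * rs, run_size = rs,
                 category = category),
            class = "workload_profile")
}

#' @export
print.workload_profile <- function(x, ...) {
  cat(sprintf("Workload %g/day -> run size %d, category %s\n",
              x$daily_workload, x$run_size, x$category))
  invisible(x)
}

#' Catalogue of multistage QC plans
#'
#' The seven startup/monitor rule pairs used across the supported sigma
#' bands and workload categories.
#'
#' @return data frame with columns \code{plan_id}, \code{startup_rule},
#'   \code{startup_n}, \code{monitor_rule}, \code{monitor_n}.
#' @export
plan_catalogue <- function() {
  data.frame(
    plan_id = 1:7,
    startup_rule = c("1_2.5s", "1_3s", "1_2s", "MR", "1_3s", "MR", "1_3s"),
    startup_n = c(1L, 2L, 1L, 4L, 4L, 4L, 4L),
    monitor_rule = c("1_3s", "1_3s", "1_3s", "1_3s", "1_2.5s", "1_3s", "1_3s"),
    monitor_n = c(1L, 1L, 1L, 2L, 1L, 4L, 1L),
    stringsAsFactors = FALSE)
}

# Match a (startup, monitor) rule pair to a catalogue plan id (NA when
# the pair is not one of the seven catalogued plans).
match_plan_id <- function(startup, monitor) {
  cat <- plan_catalogue()
  hit <- which(cat$startup_rule == startup$rule_id &
               cat$startup_n == startup$n_per_event &
               cat$monitor_rule == monitor$rule_id &
               cat$monitor_n == monitor$n_per_event)
  if (length(hit)) cat$plan_id[hit[1]] else NA_integer_
}

# Candidate rules scanned in simplicity order: fewest control
# measurements first; among single N1 rules the 2.5s limit is tried
# before 2s (it is the standardized startup choice when it reaches the
# detection target) and startup may fall back to the multirule.
startup_candidates <- function() {
  list(qc_rule("1_2.5s", 1), qc_rule("1_2s", 1), qc_rule("1_3s", 1),
       qc_rule("1_3s", 2), qc_rule("1_3s", 4), qc_rule("MR", 4))
}

# Monitor candidates: widest limits first to minimize false rejection;
# the 1_2s N1 rule is excluded outright (Pfr about 0.05 would compromise
# routine efficiency).
monitor_candidates <- function() {
  list(qc_rule("1_3s", 1), qc_rule("1_2.5s", 1), qc_rule("1_3s", 2),
       qc_rule("1_3s", 4), qc_rule("MR", 4))
}

#' Design the startup-stage QC rule
#'
#' The startup stage brackets (at least) a full daily workload and must
#' detect the critical systematic error with probability >= 0.9.
#' Fixed sigma-band choices apply first: sigma >= 6 uses the
#' standardized 1_2.5s N1 rule; sigma in [4, 5) requires the MR N4
#' multirule regardless of run size. In [5, 6) candidates are scanned in
#' simplicity order for the first rule with Ped(critical shift) >= 0.9
#' whose Max E(Nuf)-bounded run size covers the daily workload.
#'
#' @param sigma mean sigma of the procedure; must be >= 4 (below 4 no
#'   startup rule achieves Ped >= 0.9 and the procedure is not
#'   controllable).
#' @param workload a \code{\link{workload_profile}}.
#' @param ped_threshold required probability of error detection.
#' @param criterion Max E(Nuf) bound for the run-size constraint.
#' @param ... Monte Carlo controls passed down for MR power evaluation.
#' @return a \code{\link{qc_rule}}.
#' @export
design_startup <- function(sigma, workload, ped_threshold = 0.9,
                           criterion = 1, ...) {
  stopifnot(inherits(workload, "workload_profile"))
  if (sigma < 4)
    stop("sigma < 4: no startup rule achieves the detection target; ",
         "analytical performance must be improved", call. = FALSE)
  if (sigma >= 6) return(qc_rule("1_2.5s", 1))
  if (sigma < 5) return(qc_rule("MR", 4))
  dcrit <- critical_shift(sigma)
  for (r in startup_candidates()) {
    ped <- ped_function(r, ...)(dcrit)
    if (ped < ped_threshold) next
    if (max_run_size(r, sigma, criterion = criterion, ...) >=
        workload$daily_workload)
      return(r)
  }
  # no candidate covers the workload: fall back to the most powerful
  # rule so detection is still guaranteed, mirroring the 4-5 band
  qc_rule("MR", 4)
}

#' Design the monitor-stage QC rule
#'
#' The monitor stage brackets (at least) one run size and must keep the
#' false-rejection probability at or below 0.05. Candidates are scanned
#' widest limit first (1_2s N1 is excluded for its ~0.05 Pfr); the first
#' rule whose Pfr and Max E(Nuf)-bounded run size both qualify is
#' returned.
#'
#' @inheritParams design_startup
#' @param pfr_threshold maximum tolerated false-rejection probability.
#' @return a \code{\link{qc_rule}}, or \code{NULL} if no candidate
#'   covers the run size (with a warning).
#' @export
design_monitor <- function(sigma, workload, pfr_threshold = 0.05,
                           criterion = 1, ...) {
  stopifnot(inherits(workload, "workload_profile"))
  if (sigma < 4)
    stop("sigma < 4: procedure is not controllable", call. = FALSE)
  for (r in monitor_candidates()) {
    if (false_rejection_probability(r, ...) > pfr_threshold) next
    if (max_run_size(r, sigma, criterion = criterion, ...) >=
        workload$run_size)
      return(r)
  }
  warning(sprintf(
    "no monitor rule covers run size %d at sigma %.3g within the risk criterion",
    workload$run_size, sigma))
  NULL
}

#' Design a multistage QC plan for one procedure
#'
#' Combines \code{\link{design_startup}} and \code{\link{design_monitor}}
#' for a (parameter, analyzer) procedure. Procedures with sigma < 4 get
#' the \code{not_controllable} sentinel rather than an error: no startup
#' rule reaches Ped >= 0.9 and analytical improvement is required.
#'
#' @param parameter,analyzer labels.
#' @param sigma mean sigma of the procedure (NA for a procedure not
#'   available on this analyzer).
#' @param workload a \code{\link{workload_profile}}.
#' @param ... thresholds and Monte Carlo controls passed to the stage
#'   designers.
#' @return an object of class \code{plan_assignment}: list with
#'   \code{parameter}, \code{analyzer}, \code{sigma}, \code{category},
#'   \code{status} (\code{"ok"}, \code{"not_controllable"} or
#'   \code{"not_available"}), \code{startup}, \code{monitor} and
#'   \code{plan_id} (catalogue id or NA).
#' @export
design_plan <- function(parameter, analyzer, sigma, workload,
                        ped_threshold = 0.9, pfr_threshold = 0.05,
                        criterion = 1, ...) {
  stopifnot(inherits(workload, "workload_profile"))
  base <- list(parameter = parameter, analyzer = analyzer, sigma = sigma,
               category = workload$category, startup = NULL, monitor = NULL,
               plan_id = NA_integer_)
  if (is.na(sigma)) {
    base$status <- "not_available"
  } else if (sigma < 4) {
    base$status <- "not_controllable"
  } else {
    base$status <- "ok"
    base$startup <- design_startup(sigma, workload,
                                   ped_threshold = ped_threshold,
                                   criterion = criterion, ...)
    base$monitor <- design_monitor(sigma, workload,
                                   pfr_threshold = pfr_threshold,
                                   criterion = criterion, ...)
    if (!is.null(base$monitor))
      base$plan_id <- match_plan_id(base$startup, base$monitor)
  }
  structure(base, class = "plan_assignment")
}

#' @export
print.plan_assignment <- function(x, ...) {
  cat(sprintf("%s / %s (sigma %.3g, category %s): ", x$parameter,
              x$analyzer, x$sigma, x$category))
  if (x$status != "ok") {
    cat(x$status, "\n")
  } else {
    cat(sprintf("startup %s, monitor %s (plan %s)\n", x$startup$label,
                if (is.null(x$monitor)) "-" else x$monitor$label,
                if (is.na(x$plan_id)) "custom" else x$plan_id))
  }
  invisible(x)
}

#' Design plans for a table of procedures
#'
#' @param procedures data frame with columns \code{parameter},
#'   \code{analyzer}, \code{mean_sigma} and either \code{daily_workload}
#'   or \code{category}.
#' @param ... passed to \code{\link{design_plan}}.
#' @return data frame with one row per procedure: \code{parameter},
#'   \code{analyzer}, \code{sigma}, \code{category}, \code{status},
#'   \code{startup}, \code{monitor} (rule labels) and \code{plan_id}.
#' @export
design_plans <- function(procedures, ...) {
  procedures <- as.data.frame(procedures)
  rows <- lapply(seq_len(nrow(procedures)), function(i) {
    row <- procedures[i, ]
    wl <- if (!is.null(row$daily_workload) && !is.na(row$daily_workload))
      categorize_workload(row$daily_workload)
    else workload_from_category(row$category)
    pa <- design_plan(row$parameter, row$analyzer, row$mean_sigma, wl, ...)
    data.frame(parameter = pa$parameter, analyzer = pa$analyzer,
               sigma = pa$sigma, category = pa$category, status = pa$status,
               startup = if (is.null(pa$startup)) NA_character_
                         else pa$startup$label,
               monitor = if (is.null(pa$monitor)) NA_character_
                         else pa$monitor$label,
               plan_id = pa$plan_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Demand ordering of the "simple" plans (startup with at most 2 single
# control measurements): higher rank = more demanding startup, by Ped
# dominance over the sigma range where these plans are used.
SIMPLE_PLAN_RANK <- c("3" = 3, "2" = 2, "1" = 1)

#' Consolidate plan assignments for one analyzer
#'
#' To streamline management, the simple plan (startup using at most two
#' single-rule control measurements: plans 1, 2, 3) covering the
#' analyzer's most demanding need becomes the general plan, applied to
#' every parameter assigned a simple plan. Assignments based on 4
#' control measurements per event (plans 4-7) remain individualized.
#' Parameters with sigma < 4 are listed as uncovered.
#'
#' @param assignments data frame with columns \code{parameter} and
#'   \code{plan_id} (integer 1-7, or NA for a sigma < 4 sentinel); rows
#'   for one analyzer. A \code{status} column, when present, is used to
#'   distinguish \code{not_available} (dropped silently) from
#'   \code{not_controllable} (reported uncovered).
#' @param analyzer label for the result.
#' @return an object of class \code{consolidation_result}: list with
#'   \code{analyzer}, \code{general_plan} (plan id or NA),
#'   \code{general_parameters}, \code{individualized} (data frame
#'   parameter/plan_id) and \code{uncovered} (character).
#' @export
consolidate <- function(assignments, analyzer = "analyzer") {
  assignments <- as.data.frame(assignments)
  if (!all(c("parameter", "plan_id") %in% names(assignments)))
    stop("assignments needs parameter and plan_id columns", call. = FALSE)
  if ("status" %in% names(assignments))
    assignments <- assignments[assignments$status != "not_available", ,
                               drop = FALSE]
  uncovered <- assignments$parameter[is.na(assignments$plan_id)]
  covered <- assignments[!is.na(assignments$plan_id), , drop = FALSE]
  if (nrow(covered) == 0) {
    warning("no controllable parameters on ", analyzer)
    return(structure(list(analyzer = analyzer, general_plan = NA_integer_,
                          general_parameters = character(),
                          individualized = data.frame(
                            parameter = character(), plan_id = integer()),
                          uncovered = as.character(uncovered)),
                     class = "consolidation_result"))
  }
  simple <- covered[covered$plan_id %in% c(1L, 2L, 3L), , drop = FALSE]
  indiv <- covered[covered$plan_id %in% c(4L, 5L, 6L, 7L), , drop = FALSE]
  general <- if (nrow(simple)) {
    ids <- unique(as.character(simple$plan_id))
    as.integer(ids[which.max(SIMPLE_PLAN_RANK[ids])])
  } else NA_integer_
  structure(
    list(analyzer = analyzer, general_plan = general,
         general_parameters = as.character(simple$parameter),
         individualized = data.frame(
           parameter = as.character(indiv$parameter),
           plan_id = as.integer(indiv$plan_id), stringsAsFactors = FALSE),
         uncovered = as.character(uncovered)),
    class = "consolidation_result")
}

#' @export
print.consolidation_result <- function(x, ...) {
  cat(sprintf("%s: general plan %s (%d parameters)\n", x$analyzer,
              ifelse(is.na(x$general_plan), "-", x$general_plan),
              length(x$general_parameters)))
  if (nrow(x$individualized))
    for (pid in sort(unique(x$individualized$plan_id)))
      cat(sprintf("  individualized plan %d: %s\n", pid,
                  paste(x$individualized$parameter[
                    x$individualized$plan_id == pid], collapse = ", ")))
  if (length(x$uncovered))
    cat("  uncovered (sigma < 4):", paste(x$uncovered, collapse = ", "), "\n")
  invisible(x)
}

#' Consolidate plan assignments across analyzers
#'
#' @param assignments data frame with columns \code{parameter},
#'   \code{analyzer}, \code{plan_id} (and optionally \code{status}).
#' @return named list of \code{\link{consolidate}} results, one per
#'   analyzer (in order of first appearance).
#' @export
consolidate_all <- function(assignments) {
  assignments <- as.data.frame(assignments)
  analyzers <- unique(assignments$analyzer)
  out <- lapply(analyzers, function(a)
    consolidate(assignments[assignments$analyzer == a, , drop = FALSE], a))
  names(out) <- analyzers
  out
}
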