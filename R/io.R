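# Input validation, readers/writers, and the end-to-end pipeline:
# sigma assessment -> plan design -> consolidation -> report.

SCHEMA_VERSION <- "1.0"

IQC_COLUMNS <- c("parameter", "analyzer", "level_id", "target_value",
                 "observed_mean", "cv_pct", "n_obs", "is_low_concentration")
TEA_COLUMNS <- c("parameter", "tea_pct", "source_tier")
WORKLOAD_COLUMNS <- c("parameter", "analyzer", "daily_workload")

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

collect_errors <- function(table, rows, keys, messages) {
  data.frame(table = table, row = rows, key = keys, message = messages,
             stringsAsFactors = FALSE)
}

#' Validate an input bundle
#'
#' Schema- and sanity-checks the three pipeline inputs. Errors are
#' collected row by row rather than failing fast, so a whole bundle can
#' be fixed in one pass. Units are percent throughout; absolute-unit
#' mixups are caught by the sanity bounds (CV below 50 percent, TEa
#' below 100 percent).
#'
#' @param iqc,tea,workload data frames or CSV paths. \code{workload} may
#'   carry either a \code{daily_workload} column or a \code{category}
#'   column.
#' @return a list with \code{ok} (logical) and \code{errors} (data frame
#'   with columns table, row, key, message; zero rows when clean).
#' @export
validate_inputs <- function(iqc, tea, workload = NULL) {
  load_tab <- function(x) if (is.character(x)) read_table_csv(x) else
    as.data.frame(x)
  iqc <- load_tab(iqc); tea <- load_tab(tea)
  if (!is.null(workload)) workload <- load_tab(workload)
  errs <- collect_errors(character(), integer(), character(), character())
  add <- function(tab, rows, keys, msg)
    errs <<- rbind(errs, collect_errors(tab, rows, keys, msg))

  miss <- setdiff(IQC_COLUMNS, names(iqc))
  if (length(miss)) {
    add("iqc", NA_integer_, "", paste("missing columns:",
                                      paste(miss, collapse = ", ")))
  } else {
    key <- paste(iqc$parameter, iqc$analyzer, iqc$level_id, sep = "/")
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    if (length(dup))
      add("iqc", dup, key[dup], "duplicate (parameter, analyzer, level) key")
    bad <- which(!is.finite(iqc$cv_pct) | iqc$cv_pct <= 0)
    if (length(bad)) add("iqc", bad, key[bad], "cv_pct must be > 0")
    big <- which(is.finite(iqc$cv_pct) & iqc$cv_pct >= 50)
    if (length(big))
      add("iqc", big, key[big],
          "cv_pct >= 50: value does not look like a percent CV")
    badt <- which(!is.finite(iqc$target_value) | iqc$target_value <= 0)
    if (length(badt)) add("iqc", badt, key[badt], "target_value must be > 0")
    badn <- which(!is.na(iqc$n_obs) & iqc$n_obs < 0)
    if (length(badn)) add("iqc", badn, key[badn], "n_obs must be >= 0")
  }

  misst <- setdiff(TEA_COLUMNS, names(tea))
  if (length(misst)) {
    add("tea", NA_integer_, "", paste("missing columns:",
                                      paste(misst, collapse = ", ")))
  } else {
    badtea <- which(!is.finite(tea$tea_pct) | tea$tea_pct <= 0 |
                      tea$tea_pct >= 100)
    if (length(badtea))
      add("tea", badtea, tea$parameter[badtea],
          "tea_pct must be a percent in (0, 100)")
    badtier <- which(!tea$source_tier %in%
                       c("biological_variation", "state_of_the_art", "other"))
    if (length(badtier))
      add("tea", badtier, tea$parameter[badtier], "unknown source_tier")
    if (!length(miss)) {
      orphan <- setdiff(unique(iqc$parameter), unique(tea$parameter))
      if (length(orphan))
        add("tea", NA_integer_, orphan, "parameter has no TEa specification")
    }
  }

  if (!is.null(workload)) {
    if (!all(c("parameter", "analyzer") %in% names(workload)) ||
        !any(c("daily_workload", "category") %in% names(workload))) {
      add("workload", NA_integer_, "",
          "needs parameter, analyzer and daily_workload (or category)")
    } else if ("daily_workload" %in% names(workload)) {
      badw <- which(!is.finite(workload$daily_workload) |
                      workload$daily_workload < 1)
      if (length(badw))
        add("workload", badw,
            paste(workload$parameter[badw], workload$analyzer[badw],
                  sep = "/"),
            "daily_workload must be >= 1")
    }
  }
  list(ok = nrow(errs) == 0, errors = errs)
}

#' Run the end-to-end QC design pipeline
#'
#' Sigma assessment of every (parameter, analyzer) procedure, multistage
#' plan design from sigma and workload, per-analyzer consolidation into
#' general and individualized plans, the run-size nomogram for the
#' candidate rules, and a summary (sigma-band counts per analyzer, plan
#' usage). Deterministic for a given \code{mc_seed}.
#'
#' @param iqc,tea,workload input tables or CSV paths (see
#'   \code{\link{validate_inputs}}).
#' @param out_dir if non-NULL, outputs are written there:
#'   \code{sigma_report.csv}, \code{plan_assignments.csv},
#'   \code{nomogram.csv}, \code{consolidation.json},
#'   \code{summary.json}.
#' @param criterion Max E(Nuf) bound (default 1).
#' @param ped_threshold,pfr_threshold startup and monitor criteria.
#' @param nomogram_sigma sigma grid of the exported nomogram.
#' @param mc_reps,mc_seed Monte Carlo controls for multirule power.
#' @return (invisibly) a list with \code{sigma_report}, \code{plans},
#'   \code{consolidation}, \code{nomogram}, \code{summary} and
#'   \code{meta}.
#' @export
run_pipeline <- function(iqc, tea, workload, out_dir = NULL, criterion = 1,
                         ped_threshold = 0.9, pfr_threshold = 0.05,
                         nomogram_sigma = seq(4, 6.5, by = 0.5),
                         mc_reps = 2e5, mc_seed = MC_DEFAULT_SEED) {
  stopifnot(ped_threshold > 0, ped_threshold < 1,
            pfr_threshold > 0, pfr_threshold < 1, criterion > 0)
  val <- validate_inputs(iqc, tea, workload)
  if (!val$ok) {
    stop("input validation failed with ", nrow(val$errors), " error(s); ",
         "first: ", val$errors$message[1], call. = FALSE)
  }
  load_tab <- function(x) if (is.character(x)) read_table_csv(x) else
    as.data.frame(x)
  iqc <- load_tab(iqc); tea <- load_tab(tea); workload <- load_tab(workload)

  sigrep <- sigma_report(iqc, tea)
  procedures <- merge(sigrep, workload, by = c("parameter", "analyzer"),
                      sort = FALSE)
  plans <- design_plans(procedures, criterion = criterion,
                        ped_threshold = ped_threshold,
                        pfr_threshold = pfr_threshold,
                        mc_reps = mc_reps, mc_seed = mc_seed)
  consolidation <- consolidate_all(plans)
  rules <- list(qc_rule("1_3s", 1), qc_rule("1_2.5s", 1), qc_rule("1_2s", 1),
                qc_rule("1_3s", 2), qc_rule("1_3s", 4), qc_rule("MR", 4))
  nomogram <- build_nomogram(rules, nomogram_sigma, criterion = criterion,
                             mc_reps = mc_reps, mc_seed = mc_seed)
  summary <- pipeline_summary(sigrep, plans, consolidation)
  meta <- list(schema_version = SCHEMA_VERSION, criterion = criterion,
               ped_threshold = ped_threshold, pfr_threshold = pfr_threshold,
               mc_reps = mc_reps, mc_seed = mc_seed,
               enuf_convention = "uniform-onset, half-run exposure, bracketed release")
  out <- list(sigma_report = sigrep, plans = plans,
              consolidation = consolidation, nomogram = nomogram,
              summary = summary, meta = meta)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

#' Sigma performance band
#'
#' Classifies sigma values into the half-open performance bands used for
#' plan selection and reporting: below 4 (not controllable), 4-5, 5-6,
#' and 6 or more.
#'
#' @param sigma numeric vector of sigma values.
#' @return factor with levels \code{"<4"}, \code{"4-5"}, \code{"5-6"},
#'   \code{">=6"}.
#' @export
sigma_band <- function(sigma) {
  cut(sigma, breaks = c(-Inf, 4, 5, 6, Inf),
      labels = c("<4", "4-5", "5-6", ">=6"), right = FALSE)
}

pipeline_summary <- function(sigrep, plans, consolidation) {
  band_counts <- as.data.frame.matrix(
    table(sigrep$analyzer, sigma_band(sigrep$mean_sigma)))
  band_counts <- cbind(analyzer = rownames(band_counts), band_counts,
                       stringsAsFactors = FALSE)
  rownames(band_counts) <- NULL
  plan_use <- as.data.frame(table(plan_id = plans$plan_id[!is.na(plans$plan_id)]),
                            stringsAsFactors = FALSE)
  general <- vapply(consolidation, `[[`, integer(1), "general_plan")
  indiv <- do.call(rbind, lapply(consolidation, function(cr)
    if (nrow(cr$individualized))
      cbind(analyzer = cr$analyzer, cr$individualized) else NULL))
  list(
    n_procedures = nrow(sigrep),
    sigma_band_counts = band_counts,
    plan_usage = plan_use,
    general_plans = general,
    n_distinct_general_plans = length(unique(general[!is.na(general)])),
    n_individualized_plans =
      if (is.null(indiv)) 0L else length(unique(indiv$plan_id)),
    n_individualized_parameters =
      if (is.null(indiv)) 0L else length(unique(indiv$parameter)),
    n_uncovered = sum(vapply(consolidation,
                             function(cr) length(cr$uncovered), integer(1))))
}

consolidation_as_list <- function(consolidation) {
  lapply(consolidation, function(cr) {
    list(analyzer = cr$analyzer, general_plan = cr$general_plan,
         general_parameters = cr$general_parameters,
         individualized = lapply(
           split(cr$individualized$parameter, cr$individualized$plan_id),
           identity),
         uncovered = cr$uncovered)
  })
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$sigma_report, file.path(out_dir, "sigma_report.csv"),
                   row.names = FALSE)
  utils::write.csv(out$plans, file.path(out_dir, "plan_assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(out$nomogram),
                   file.path(out_dir, "nomogram.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(meta = out$meta,
         consolidation = consolidation_as_list(out$consolidation)),
    file.path(out_dir, "consolidation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(list(meta = out$meta, summary = out$summary),
                       file.path(out_dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
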