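# Sigma metrics from internal QC summaries and allowable total error.

#' Systematic error (bias) in percent
#'
#' \code{SE\% = (observed_mean - target_value) / target_value * 100}.
#' The sign is preserved: it records the direction of the bias, even
#' though the sigma metric uses only its magnitude.
#'
#' @param observed_mean observed IQC mean, in reporting units.
#' @param target_value assigned target of the control material, same
#'   units; must be nonzero.
#' @return signed percent bias.
#' @examples
#' systematic_error_pct(102, 100) # 2
#' systematic_error_pct(95, 100)  # -5
#' @export
systematic_error_pct <- function(observed_mean, target_value) {
  if (any(target_value == 0))
    stop("target_value must be nonzero", call. = FALSE)
  (observed_mean - target_value) / target_value * 100
}

#' Sigma metric of a measurement procedure
#'
#' \code{sigma = (TEa - |SE|) / CV}, all terms in percent. The bias
#' enters as a magnitude: a negative bias consumes the total-error
#' budget exactly as a positive one does. Sigma is negative when the
#' bias alone exceeds the allowable total error.
#'
#' @param tea_pct allowable total error, percent (> 0).
#' @param se_pct systematic error, percent (sign ignored).
#' @param cv_pct coefficient of variation, percent (> 0).
#' @return dimensionless sigma.
#' @examples
#' sigma_metric(10, 1, 1.5) # 6
#' @export
sigma_metric <- function(tea_pct, se_pct, cv_pct) {
  if (any(cv_pct <= 0)) stop("cv_pct must be positive", call. = FALSE)
  if (any(tea_pct <= 0)) stop("tea_pct must be positive", call. = FALSE)
  (tea_pct - abs(se_pct)) / cv_pct
}

#' Control-level IQC summary
#'
#' One control level's summary statistics on one analyzer: the raw
#' material of the sigma metric.
#'
#' @param level_id label of the control level.
#' @param target_value assigned target concentration (> 0).
#' @param observed_mean observed mean of the IQC results, same units.
#' @param cv_pct observed coefficient of variation, percent (> 0).
#' @param n_obs number of IQC results behind the summary.
#' @param is_low_concentration whether this level sits in a low
#'   concentration range where a sigma in [3, 4) is still tolerated.
#'   The flag is an input: there is no universal numeric cutoff.
#' @return a one-row data frame with the level's fields.
#' @export
control_level <- function(level_id, target_value, observed_mean, cv_pct,
                          n_obs = NA_integer_, is_low_concentration = FALSE) {
  stopifnot(target_value > 0, cv_pct > 0, is.na(n_obs) || n_obs >= 0)
  data.frame(level_id = as.character(level_id),
             target_value = target_value, observed_mean = observed_mean,
             cv_pct = cv_pct, n_obs = as.integer(n_obs),
             is_low_concentration = isTRUE(is_low_concentration),
             stringsAsFactors = FALSE)
}

#' Assess a measurement procedure's sigma on one analyzer
#'
#' Computes the sigma metric for every control level at a given TEa and
#' aggregates to an unweighted arithmetic mean. The procedure is
#' acceptable when every level reaches sigma >= 4, or when every
#' non-low level reaches 4 and every low-concentration level reaches at
#' least 3 (analytical performance is usually poorer at low
#' concentrations and concentration-dependent specifications are rarely
#' available, so a sigma in [3, 4) is tolerated there).
#'
#' @param levels a data frame of control levels (one or more rows as
#'   produced by \code{\link{control_level}}, or the same columns).
#' @param tea_pct allowable total error, percent.
#' @return an object of class \code{sigma_assessment}: a list with
#'   \code{per_level} (data frame: level_id, se_pct, cv_pct, sigma,
#'   is_low_concentration), \code{mean_sigma},
#'   \code{all_levels_acceptable}, \code{low_level_exception_used} and
#'   \code{acceptable}.
#' @export
assess_analyzer_sigma <- function(levels, tea_pct) {
  levels <- as.data.frame(levels)
  req <- c("level_id", "target_value", "observed_mean", "cv_pct",
           "is_low_concentration")
  missing_cols <- setdiff(req, names(levels))
  if (nrow(levels) < 1) stop("at least one control level is required",
                             call. = FALSE)
  if (length(missing_cols))
    stop("levels is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  se <- systematic_error_pct(levels$observed_mean, levels$target_value)
  sig <- sigma_metric(tea_pct, se, levels$cv_pct)
  low <- as.logical(levels$is_low_concentration)
  all_ok <- all(sig >= 4)
  exception <- !all_ok && all(sig[!low] >= 4) && all(sig[low] >= 3)
  structure(
    list(per_level = data.frame(level_id = levels$level_id, se_pct = se,
                                cv_pct = levels$cv_pct, sigma = sig,
                                is_low_concentration = low,
                                stringsAsFactors = FALSE),
         tea_pct = tea_pct,
         mean_sigma = mean(sig),
         all_levels_acceptable = all_ok,
         low_level_exception_used = exception,
         acceptable = all_ok || exception),
    class = "sigma_assessment")
}

#' @export
print.sigma_assessment <- function(x, ...) {
  cat(sprintf("Sigma assessment at TEa %.3g%%: mean sigma %.2f (%s)\n",
              x$tea_pct, x$mean_sigma,
              if (x$acceptable) "acceptable" else "not acceptable"))
  if (x$low_level_exception_used)
    cat("  low-concentration exception applied (sigma in [3,4) tolerated)\n")
  print(x$per_level, ...)
  invisible(x)
}

#' Select the most demanding workable TEa specification
#'
#' Scans candidate allowable-total-error specifications from the most
#' demanding (smallest TEa) upward and returns the first one under which
#' the procedure's sigma assessment is acceptable. If none qualifies,
#' the most permissive candidate is returned with
#' \code{acceptable = FALSE} so the failure is visible downstream.
#'
#' @param candidates data frame with columns \code{tea_pct} and
#'   \code{source_tier} (one of \code{"biological_variation"},
#'   \code{"state_of_the_art"}, \code{"other"}); order does not matter.
#' @param levels control-level data frame as in
#'   \code{\link{assess_analyzer_sigma}}.
#' @return a list with \code{spec} (the chosen candidate row) and
#'   \code{assessment} (its \code{sigma_assessment}).
#' @export
select_tea <- function(candidates, levels) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) < 1) stop("no TEa candidates supplied", call. = FALSE)
  if (!"tea_pct" %in% names(candidates))
    stop("candidates must have a tea_pct column", call. = FALSE)
  if (any(candidates$tea_pct <= 0))
    stop("tea_pct must be positive", call. = FALSE)
  candidates <- candidates[order(candidates$tea_pct), , drop = FALSE]
  assessments <- lapply(candidates$tea_pct,
                        function(tea) assess_analyzer_sigma(levels, tea))
  ok <- vapply(assessments, `[[`, logical(1), "acceptable")
  idx <- if (any(ok)) which(ok)[1] else nrow(candidates)
  list(spec = candidates[idx, , drop = FALSE], assessment = assessments[[idx]])
}

#' Per-parameter sigma report
#'
#' Applies \code{\link{select_tea}} / \code{\link{assess_analyzer_sigma}}
#' across a long-format IQC summary table, one (parameter, analyzer)
#' procedure at a time.
#'
#' @param iqc data frame with columns \code{parameter}, \code{analyzer},
#'   \code{level_id}, \code{target_value}, \code{observed_mean},
#'   \code{cv_pct}, \code{n_obs}, \code{is_low_concentration}.
#' @param tea data frame with columns \code{parameter}, \code{tea_pct},
#'   \code{source_tier}; several rows per parameter act as candidate
#'   specifications.
#' @return data frame with one row per (parameter, analyzer):
#'   \code{tea_pct}, \code{mean_sigma}, \code{min_sigma},
#'   \code{acceptable}, \code{low_level_exception_used}.
#' @export
sigma_report <- function(iqc, tea) {
  iqc <- as.data.frame(iqc); tea <- as.data.frame(tea)
  keys <- unique(iqc[c("parameter", "analyzer")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    p <- keys$parameter[i]; a <- keys$analyzer[i]
    levels <- iqc[iqc$parameter == p & iqc$analyzer == a, , drop = FALSE]
    cand <- tea[tea$parameter == p, , drop = FALSE]
    if (nrow(cand) == 0)
      stop("no TEa specification for parameter ", p, call. = FALSE)
    sel <- select_tea(cand, levels)
    data.frame(parameter = p, analyzer = a,
               tea_pct = sel$spec$tea_pct,
               source_tier = if ("source_tier" %in% names(sel$spec))
                 sel$spec$source_tier else NA_character_,
               mean_sigma = sel$assessment$mean_sigma,
               min_sigma = min(sel$assessment$per_level$sigma),
               acceptable = sel$assessment$acceptable,
               low_level_exception_used =
                 sel$assessment$low_level_exception_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
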