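# Westgard control rules and their event-level evaluation.

#' Construct a Westgard control rule
#'
#' A QC rule is either a single rule with a symmetric rejection limit in
#' SD units (\code{1_2s}, \code{1_2.5s}, \code{1_3s}) applied to each of
#' \code{n} control measurements in a QC event, or the \code{MR}
#' multirule (1_3s/2_2s/R_4s/4_1s) evaluated jointly on 4 control
#' measurements per event.
#'
#' @param rule_id one of \code{"1_2s"}, \code{"1_2.5s"}, \code{"1_3s"},
#'   \code{"MR"}.
#' @param n_per_event control measurements per QC event; 1, 2 or 4.
#'   \code{MR} requires 4.
#' @return an object of class \code{qc_rule} with elements
#'   \code{rule_id}, \code{n_per_event}, \code{limit} (SD units, \code{NA}
#'   for \code{MR}), \code{subrules} (character, empty unless \code{MR})
#'   and \code{label} (e.g. \code{"1_2.5s N1"}).
#' @examples
#' qc_rule("1_2.5s", 1)
#' qc_rule("MR") # implies N4
#' @export
qc_rule <- function(rule_id, n_per_event = NULL) {
  rule_id <- match.arg(rule_id, c("1_2s", "1_2.5s", "1_3s", "MR"))
  if (is.null(n_per_event)) n_per_event <- if (rule_id == "MR") 4L else 1L
  n_per_event <- as.integer(n_per_event)
  if (!n_per_event %in% c(1L, 2L, 4L))
    stop("n_per_event must be 1, 2 or 4", call. = FALSE)
  if (rule_id == "MR" && n_per_event != 4L)
    stop("the MR multirule requires 4 control measurements per event",
         call. = FALSE)
  limit <- switch(rule_id, "1_2s" = 2, "1_2.5s" = 2.5, "1_3s" = 3, "MR" = NA_real_)
  subrules <- if (rule_id == "MR") c("1_3s", "2_2s", "R_4s", "4_1s") else character()
  structure(
    list(rule_id = rule_id, n_per_event = n_per_event, limit = limit,
         subrules = subrules,
         label = paste0(rule_id, " N", n_per_event)),
    class = "qc_rule")
}

#' @export
print.qc_rule <- function(x, ...) {
  cat("QC rule:", x$label)
  if (length(x$subrules))
    cat(" (", paste(x$subrules, collapse = "/"), ")", sep = "")
  cat("\n")
  invisible(x)
}

is_qc_rule <- function(x) inherits(x, "qc_rule")

#' Evaluate a control rule on one QC event
#'
#' Applies the rule to the standardized control deviations (z-scores, in
#' units of the assay SD) observed in a single QC event. Observations at
#' exactly a rejection limit count as rejections. Multirule counting
#' rules are evaluated within the event only; there is no across-event
#' memory.
#'
#' @param rule a \code{\link{qc_rule}}.
#' @param z numeric vector of standardized control deviations; its length
#'   must equal \code{rule$n_per_event}.
#' @return a list with \code{reject} (logical) and \code{triggered}
#'   (character vector of fired subrule labels; for single rules the rule
#'   id itself when it fires).
#' @examples
#' evaluate_event(qc_rule("1_3s", 1), 2.9)          # accept
#' evaluate_event(qc_rule("MR"), c(2.1, 2.2, 0.1, -0.3)) # 2_2s fires
#' @export
evaluate_event <- function(rule, z) {
  stopifnot(is_qc_rule(rule))
  if (!is.numeric(z) || anyNA(z))
    stop("z must be numeric without missing values", call. = FALSE)
  if (length(z) != rule$n_per_event)
    stop(sprintf("event has %d observations but rule %s expects %d",
                 length(z), rule$label, rule$n_per_event), call. = FALSE)
  if (rule$rule_id != "MR") {
    fired <- any(abs(z) >= rule$limit)
    return(list(reject = fired,
                triggered = if (fired) rule$rule_id else character()))
  }
  triggered <- character()
  if (any(abs(z) >= 3)) triggered <- c(triggered, "1_3s")
  if (sum(z >= 2) >= 2 || sum(z <= -2) >= 2) triggered <- c(triggered, "2_2s")
  if (max(z) - min(z) >= 4) triggered <- c(triggered, "R_4s")
  if (all(z >= 1) || all(z <= -1)) triggered <- c(triggered, "4_1s")
  list(reject = length(triggered) > 0, triggered = triggered)
}

# Vectorized MR rejection over an events-by-4 matrix of z-scores.
mr_reject_matrix <- function(Z) {
  hi <- Z >= 2
  lo <- Z <= -2
  zmax <- pmax(Z[, 1], Z[, 2], Z[, 3], Z[, 4])
  zmin <- pmin(Z[, 1], Z[, 2], Z[, 3], Z[, 4])
  (zmax >= 3 | zmin <= -3) |
    (rowSums(hi) >= 2 | rowSums(lo) >= 2) |
    (zmax - zmin >= 4) |
    (rowSums(Z >= 1) == 4L | rowSums(Z <= -1) == 4L)
}

# Evaluate code inside a temporary RNG state; the caller's .Random.seed
# is restored on exit so simulation helpers never perturb user RNG flow.
with_preserved_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
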