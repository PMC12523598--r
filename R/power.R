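# Power functions: probability a QC event rejects under a persistent
# systematic shift of the assay mean, in SD units.

# Default seed and replicate count for Monte Carlo power estimation of
# the MR multirule, which has no convenient closed form.
MC_DEFAULT_REPS <- 1e6
MC_DEFAULT_SEED <- 20240915L

#' Probability that a QC event rejects under a systematic shift
#'
#' Control observations are modeled as independent Gaussian with unit SD
#' and mean equal to the shift. For single rules with limit \code{k} the
#' per-observation rejection probability is
#' \code{1 - pnorm(k - shift) + pnorm(-k - shift)} and the event rejects
#' if any of the N observations does. The MR multirule is estimated by
#' seeded Monte Carlo; the estimate carries its standard error and
#' replicate count as attributes.
#'
#' @param rule a \code{\link{qc_rule}}.
#' @param shift non-negative systematic error in SD units (vectorized).
#' @param mc_reps Monte Carlo events for the MR multirule.
#' @param mc_seed RNG seed for the Monte Carlo path; the caller's RNG
#'   state is untouched.
#' @return rejection probability (vector along \code{shift}); for MR,
#'   attributes \code{se} and \code{mc_reps}.
#' @examples
#' rejection_probability(qc_rule("1_3s", 1), 0)    # false-rejection rate
#' rejection_probability(qc_rule("1_2s", 1), 3.35) # Ped at a critical shift
#' @export
rejection_probability <- function(rule, shift, mc_reps = MC_DEFAULT_REPS,
                                  mc_seed = MC_DEFAULT_SEED) {
  stopifnot(is_qc_rule(rule))
  if (any(shift < 0)) stop("shift must be non-negative", call. = FALSE)
  if (rule$rule_id != "MR") {
    p1 <- pnorm(shift - rule$limit) + pnorm(-rule$limit - shift)
    return(1 - (1 - p1)^rule$n_per_event)
  }
  est <- with_preserved_rng(mc_seed, {
    Z <- matrix(rnorm(mc_reps * 4L), ncol = 4L)
    vapply(shift, function(d) mean(mr_reject_matrix(Z + d)), numeric(1))
  })
  structure(est, se = sqrt(pmax(est * (1 - est), 1e-12) / mc_reps),
            mc_reps = mc_reps)
}

#' False-rejection probability of a rule
#'
#' Rejection probability with no error present (shift = 0).
#'
#' @inheritParams rejection_probability
#' @export
false_rejection_probability <- function(rule, mc_reps = MC_DEFAULT_REPS,
                                        mc_seed = MC_DEFAULT_SEED) {
  as.numeric(rejection_probability(rule, 0, mc_reps, mc_seed))
}

#' Critical systematic shift for a sigma level
#'
#' The size of the persistent systematic error (in SD units) that drives
#' the defect rate -- the fraction of patient results whose total error
#' exceeds the allowable total error -- up to 5 percent:
#' \code{shift = sigma - 1.65}.
#'
#' @param sigma sigma metric of the measurement procedure; must exceed
#'   1.65, below which no shift keeps the defect rate at 5 percent and
#'   the procedure is not controllable in this framework.
#' @return critical shift in SD units.
#' @examples
#' critical_shift(5) # 3.35
#' @export
critical_shift <- function(sigma) {
  if (any(sigma <= 1.65))
    stop("sigma must exceed 1.65; the procedure is not controllable",
         call. = FALSE)
  sigma - 1.65
}

# Vectorized Ped(shift) evaluator for a rule. Single rules use the
# closed form. For MR, a common-random-numbers Monte Carlo estimate on a
# shift grid is smoothed with a monotone spline and cached per
# (reps, seed) so that downstream optimization over shift is cheap and
# deterministic.
.mr_cache <- new.env(parent = emptyenv())

ped_function <- function(rule, mc_reps = 2e5, mc_seed = MC_DEFAULT_SEED) {
  if (rule$rule_id != "MR") {
    k <- rule$limit
    n <- rule$n_per_event
    return(function(shift) {
      p1 <- pnorm(shift - k) + pnorm(-k - shift)
      1 - (1 - p1)^n
    })
  }
  key <- sprintf("mr_%g_%d", mc_reps, mc_seed)
  if (!is.null(.mr_cache[[key]])) return(.mr_cache[[key]])
  grid <- seq(0, 15, by = 0.1)
  est <- with_preserved_rng(mc_seed, {
    Z <- matrix(rnorm(mc_reps * 4L), ncol = 4L)
    vapply(grid, function(d) mean(mr_reject_matrix(Z + d)), numeric(1))
  })
  # common random numbers make the raw curve monotone up to ties
  est <- cummax(est)
  sf <- splinefun(grid, est, method = "hyman")
  f <- function(shift) pmin(1, pmax(0, ifelse(shift >= 15, 1, sf(shift))))
  .mr_cache[[key]] <- f
  f
}

#' Power curve of a control rule
#'
#' Rejection probability over a grid of systematic shifts. The entry at
#' shift 0 is the rule's false-rejection probability.
#'
#' @inheritParams rejection_probability
#' @param shift_grid non-negative, ascending shifts in SD units.
#' @return a data frame of class \code{power_curve} with columns
#'   \code{shift}, \code{ped}, \code{se_of_ped} (0 for closed forms) and
#'   \code{method}; Monte Carlo metadata (seed, replicates) is attached
#'   as attributes.
#' @export
power_curve <- function(rule, shift_grid = seq(0, 6, by = 0.1),
                        mc_reps = MC_DEFAULT_REPS, mc_seed = MC_DEFAULT_SEED) {
  stopifnot(is_qc_rule(rule))
  if (any(diff(shift_grid) <= 0) || any(shift_grid < 0))
    stop("shift_grid must be non-negative and strictly ascending",
         call. = FALSE)
  ped <- rejection_probability(rule, shift_grid, mc_reps, mc_seed)
  se <- attr(ped, "se")
  out <- data.frame(
    shift = shift_grid,
    ped = as.numeric(ped),
    se_of_ped = if (is.null(se)) 0 else se,
    method = if (rule$rule_id == "MR") "monte_carlo" else "closed_form",
    stringsAsFactors = FALSE)
  structure(out, class = c("power_curve", "data.frame"),
            rule = rule$label, pfr = out$ped[match(0, out$shift)],
            mc_seed = if (rule$rule_id == "MR") mc_seed else NA_integer_,
            mc_reps = if (rule$rule_id == "MR") mc_reps else NA_real_)
}

#' Plot a power function
#'
#' Rejection probability against systematic shift, in the style of the
#' power-function panels used to validate startup and monitor rules.
#'
#' @param x a \code{power_curve}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.power_curve <- function(x, ...) {
  graphics::plot(x$shift, x$ped, type = "l", ylim = c(0, 1),
                 xlab = "systematic shift (SD units)",
                 ylab = "probability of rejection",
                 main = paste("Power function:", attr(x, "rule")), ...)
  graphics::abline(h = c(0.05, 0.9), lty = 3, col = "grey40")
  invisible(x)
}
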