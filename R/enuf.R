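# Expected number of unreliable final patient results, E(Nuf), under
# bracketed QC, its maximum over error magnitude, and run-size bounds.
#
# Convention: a persistent systematic shift of magnitude delta (SD
# units) begins at a time uniformly distributed within an inter-QC
# interval and lasts until a QC event first rejects. A run's results
# become final only when its closing QC event passes; a rejection
# corrects the pending run (and only that run). The onset run then
# contributes n/2 expected exposed results released with probability
# q = 1 - Ped, and each subsequent fully exposed run is released while
# QC keeps passing, giving a geometric expectation q^2 / Ped of
# released full runs. Hence
#   E(Nuf) = dpE(sigma, delta) * n * (q/2 + q^2 / Ped).

#' Defect rate of patient results under a systematic shift
#'
#' Probability that a single patient result's total analytical error
#' exceeds the allowable total error when the procedure runs at a given
#' sigma with a persistent shift of \code{shift} SD units:
#' \code{1 - pnorm(sigma - shift) + pnorm(-sigma - shift)}.
#'
#' @param sigma sigma metric (> 0).
#' @param shift systematic error magnitude, SD units (>= 0).
#' @return defect probability.
#' @examples
#' defect_rate(5, 4) # 0.1587
#' @export
defect_rate <- function(sigma, shift) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  if (any(shift < 0)) stop("shift must be non-negative", call. = FALSE)
  pnorm(shift - sigma) + pnorm(-sigma - shift)
}

# E(Nuf) per patient sample; E(Nuf) = run_size * this quantity.
enuf_per_patient <- function(ped, sigma, shift) {
  q <- 1 - ped
  rate <- defect_rate(sigma, shift)
  out <- ifelse(ped <= 0, Inf, rate * (q / 2 + q^2 / ped))
  out
}

#' Expected number of unreliable final results for one error episode
#'
#' Closed-form E(Nuf) for a bracketed QC operation: \code{run_size}
#' patient samples between QC events, error onset uniform within an
#' interval, persistent shift until first detection, results final only
#' when the closing QC event passes. See the package vignette for the
#' accounting convention.
#'
#' @param rule a \code{\link{qc_rule}} applied at every QC event.
#' @param sigma sigma metric of the procedure.
#' @param run_size patient samples between consecutive QC events (>= 1).
#' @param shift systematic error magnitude in SD units.
#' @param ... passed to \code{\link{rejection_probability}} (Monte Carlo
#'   controls for the MR multirule).
#' @return expected unreliable final results; \code{Inf} if the rule can
#'   never detect (Ped = 0).
#' @export
expected_nuf <- function(rule, sigma, run_size, shift, ...) {
  stopifnot(is_qc_rule(rule))
  if (any(run_size < 1)) stop("run_size must be >= 1", call. = FALSE)
  ped <- ped_function(rule, ...)(shift)
  run_size * enuf_per_patient(ped, sigma, shift)
}

#' Maximize E(Nuf) over the error magnitude
#'
#' Scans the expected number of unreliable final results over a grid of
#' shift magnitudes (default step 0.01 SD on [0, sigma + 5]) and refines
#' the maximum by golden-section search in the bracketing interval. The
#' model is linear in \code{run_size}, so the maximum scales
#' proportionally.
#'
#' @inheritParams expected_nuf
#' @param grid_step grid resolution in SD units.
#' @param shift_max upper end of the scanned shift range.
#' @return an object of class \code{enuf_profile}: list with
#'   \code{rule}, \code{sigma}, \code{run_size}, \code{enuf_by_shift}
#'   (data frame shift/enuf on the grid), \code{max_enuf} and
#'   \code{argmax_shift}.
#' @export
max_enuf <- function(rule, sigma, run_size, grid_step = 0.01,
                     shift_max = sigma + 5, ...) {
  stopifnot(is_qc_rule(rule))
  ped <- ped_function(rule, ...)
  f <- function(d) enuf_per_patient(ped(d), sigma, d)
  grid <- seq(0, shift_max, by = grid_step)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
  best <- if (opt$objective >= vals[i]) opt else
    list(maximum = grid[i], objective = vals[i])
  structure(
    list(rule = rule, sigma = sigma, run_size = run_size,
         enuf_by_shift = data.frame(shift = grid, enuf = run_size * vals),
         max_enuf = run_size * best$objective,
         argmax_shift = best$maximum),
    class = "enuf_profile")
}

#' @export
print.enuf_profile <- function(x, ...) {
  cat(sprintf(
    "Max E(Nuf) = %.4g at shift %.2f SD (rule %s, sigma %.3g, run size %d)\n",
    x$max_enuf, x$argmax_shift, x$rule$label, x$sigma,
    as.integer(x$run_size)))
  invisible(x)
}

#' Largest run size keeping Max E(Nuf) within a risk criterion
#'
#' By linearity of E(Nuf) in the run size, the bound is
#' \code{floor(criterion / max_shift E(Nuf per patient))}. A value of 0
#' means even a single patient sample between QC events violates the
#' criterion.
#'
#' @inheritParams max_enuf
#' @param criterion Max E(Nuf) bound; the conventional risk criterion is
#'   1 unreliable result per error episode.
#' @return integer maximum run size (possibly 0).
#' @export
max_run_size <- function(rule, sigma, criterion = 1, grid_step = 0.01,
                         shift_max = sigma + 5, ...) {
  if (criterion <= 0) stop("criterion must be positive", call. = FALSE)
  prof <- max_enuf(rule, sigma, run_size = 1, grid_step = grid_step,
                   shift_max = shift_max, ...)
  if (!is.finite(prof$max_enuf)) return(0L)
  as.integer(floor(criterion / prof$max_enuf))
}

#' Sigma-metric run size nomogram
#'
#' Tabulates, for each control rule and sigma level, the largest run
#' size (patient samples between QC events) that keeps Max E(Nuf) within
#' the risk criterion.
#'
#' @param rules list of \code{\link{qc_rule}} objects.
#' @param sigma_grid ascending sigma values (> 1.65).
#' @param criterion Max E(Nuf) bound, default 1.
#' @param ... passed to \code{\link{max_run_size}}.
#' @return data frame of class \code{nomogram_table} with columns
#'   \code{sigma}, \code{rule_id}, \code{n_per_event}, \code{rule_label}
#'   and \code{max_run_size}; the criterion is attached as an attribute.
#' @export
build_nomogram <- function(rules, sigma_grid = seq(4, 6.5, by = 0.25),
                           criterion = 1, ...) {
  if (is_qc_rule(rules)) rules <- list(rules)
  if (!length(rules) || !length(sigma_grid))
    stop("rules and sigma_grid must be non-empty", call. = FALSE)
  if (is.unsorted(sigma_grid, strictly = TRUE))
    stop("sigma_grid must be strictly ascending", call. = FALSE)
  rows <- lapply(rules, function(r) {
    data.frame(sigma = sigma_grid, rule_id = r$rule_id,
               n_per_event = r$n_per_event, rule_label = r$label,
               max_run_size = vapply(sigma_grid, function(s)
                 max_run_size(r, s, criterion = criterion, ...), integer(1)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("nomogram_table", "data.frame"), criterion = criterion)
}

#' Plot a run-size nomogram
#'
#' Maximum allowed run size against sigma, one curve per rule, on a log
#' run-size axis.
#'
#' @param x a \code{nomogram_table}.
#' @param ... passed to \code{\link[graphics]{matplot}}.
#' @export
plot.nomogram_table <- function(x, ...) {
  labs <- unique(x$rule_label)
  sig <- sort(unique(x$sigma))
  m <- sapply(labs, function(l)
    x$max_run_size[x$rule_label == l][order(x$sigma[x$rule_label == l])])
  m[m < 1] <- NA
  graphics::matplot(sig, m, type = "l", lty = 1, col = seq_along(labs),
                    log = "y", xlab = "sigma metric",
                    ylab = "maximum run size (patient samples)",
                    main = sprintf("Run size nomogram, Max E(Nuf) <= %g",
                                   attr(x, "criterion")), ...)
  graphics::legend("topleft", legend = labs, col = seq_along(labs),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
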