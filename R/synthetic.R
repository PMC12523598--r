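# Synthetic inputs and stochastic test beds: Gaussian IQC streams,
# whole-laboratory input bundles, and a bracketed patient-flow
# simulator that counts unreliable final results empirically.

#' Simulation configuration
#'
#' Bundles the error model of one measurement procedure for the
#' simulators: imprecision (CV), bias (SE) and allowable total error in
#' percent, the injected persistent systematic shift in SD units, and
#' the bracketed operation settings. The implied sigma metric is
#' \code{(tea_pct - |bias_pct|) / cv_pct}.
#'
#' @param cv_pct imprecision, percent (> 0).
#' @param bias_pct systematic error, percent.
#' @param tea_pct allowable total error, percent.
#' @param shift_sd injected persistent shift, SD units.
#' @param run_size patient samples between QC events.
#' @param n_episodes error episodes to simulate.
#' @param seed RNG seed; the seed fully determines all output.
#' @return a list of class \code{sim_config} (with \code{sigma} added).
#' @export
sim_config <- function(cv_pct, bias_pct = 0, tea_pct = 10, shift_sd = 0,
                       run_size = 50, n_episodes = 1e4, seed = 1L) {
  stopifnot(cv_pct > 0, tea_pct > 0, shift_sd >= 0, run_size >= 1,
            n_episodes >= 1)
  structure(list(cv_pct = cv_pct, bias_pct = bias_pct, tea_pct = tea_pct,
                 shift_sd = shift_sd, run_size = as.integer(run_size),
                 n_episodes = as.integer(n_episodes), seed = as.integer(seed),
                 sigma = sigma_metric(tea_pct, bias_pct, cv_pct)),
            class = "sim_config")
}

#' Generate a stream of standardized IQC events
#'
#' Control deviations are Gaussian with unit SD; the mean is the
#' standardized bias \code{bias_pct / cv_pct}, plus \code{shift_sd} from
#' the onset event onward. The same seed always reproduces the same
#' stream.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_events number of QC events.
#' @param n_per_event control measurements per event.
#' @param onset_event first event index affected by the shift
#'   (default 1; use \code{Inf} for an in-control stream).
#' @return an \code{n_events x n_per_event} matrix of z-scores.
#' @export
generate_iqc_stream <- function(config, n_events, n_per_event = 1,
                                onset_event = 1) {
  stopifnot(inherits(config, "sim_config"), n_events >= 1)
  mu <- config$bias_pct / config$cv_pct
  with_preserved_rng(config$seed, {
    z <- matrix(rnorm(n_events * n_per_event, mean = mu), nrow = n_events)
    if (is.finite(onset_event) && onset_event <= n_events)
      z[seq(onset_event, n_events), ] <-
        z[seq(onset_event, n_events), , drop = FALSE] + config$shift_sd
    z
  })
}

#' Simulate bracketed patient flow through error episodes
#'
#' Empirical counterpart of \code{\link{expected_nuf}}. Each episode
#' starts with a persistent systematic shift whose onset is uniform
#' within an inter-QC interval; patient runs of \code{run_size} samples
#' are bracketed by QC events evaluated with \code{rule}, and a run's
#' results become final only when its closing event passes. The episode
#' ends at the first rejection, which corrects the pending run. For each
#' released run, the number of results whose total error exceeds the
#' allowable total error is drawn from the exact Gaussian defect
#' distribution (binomial with probability
#' \code{\link{defect_rate}(sigma, shift)}).
#'
#' @param rule a \code{\link{qc_rule}}.
#' @param config a \code{\link{sim_config}}; \code{shift_sd},
#'   \code{run_size}, \code{n_episodes}, \code{seed} and the implied
#'   \code{sigma} are used. Control deviations include the standardized
#'   bias only through \code{sigma}; the shift is the in-simulation
#'   error.
#' @return an object of class \code{patient_flow_result}: list with
#'   \code{episodes}, \code{mean_nuf}, \code{se_of_mean},
#'   \code{detection_event_histogram} (table of the QC event index at
#'   which the shift was caught) and \code{config}.
#' @export
simulate_bracketed_flow <- function(rule, config) {
  stopifnot(is_qc_rule(rule), inherits(config, "sim_config"))
  n <- config$run_size
  shift <- config$shift_sd
  dp <- defect_rate(config$sigma, shift)
  m <- config$n_episodes
  npe <- rule$n_per_event
  with_preserved_rng(config$seed, {
    # onset uniform in the bracket: exposed samples in the onset run
    exposed <- sample.int(n + 1L, m, replace = TRUE) - 1L
    nuf <- numeric(m)
    detected_at <- integer(m)
    active <- seq_len(m)
    event <- 0L
    while (length(active)) {
      event <- event + 1L
      z <- matrix(rnorm(length(active) * npe, mean = shift), ncol = npe)
      rej <- if (rule$rule_id == "MR") mr_reject_matrix(z)
             else rowSums(abs(z) >= rule$limit) > 0
      pass <- active[!rej]
      if (length(pass)) {
        n_exposed <- if (event == 1L) exposed[pass] else rep(n, length(pass))
        nuf[pass] <- nuf[pass] + rbinom(length(pass), n_exposed, dp)
      }
      detected_at[active[rej]] <- event
      active <- pass
      if (event > 1e6) stop("episode did not terminate; Ped is ~0")
    }
    structure(
      list(episodes = m, mean_nuf = mean(nuf),
           se_of_mean = sd(nuf) / sqrt(m),
           detection_event_histogram = table(detected_at),
           config = config),
      class = "patient_flow_result")
  })
}

#' @export
print.patient_flow_result <- function(x, ...) {
  cat(sprintf(
    "Bracketed flow: %d episodes, mean Nuf %.4g (SE %.2g)\n",
    x$episodes, x$mean_nuf, x$se_of_mean))
  invisible(x)
}

#' Generate a synthetic laboratory input bundle
#'
#' Draws a laboratory of \code{n_parameters} measurement procedures
#' spread over \code{n_analyzers} analyzers (each parameter available on
#' 1 to \code{n_analyzers} of them), with per-procedure sigma targets
#' from a band mixture spanning < 4 to >= 6, and emits the consistent
#' CSV-ready tables the pipeline consumes: IQC level summaries whose
#' computed sigmas reproduce the targets (the sigma formula is inverted,
#' \code{cv = (tea - |bias|) / sigma}), TEa specifications, and daily
#' workloads.
#'
#' @param seed RNG seed; the bundle is a deterministic function of it.
#' @param n_analyzers number of analyzers.
#' @param n_parameters number of parameters.
#' @param band_weights probabilities of a procedure falling in the
#'   sigma bands [3,4), [4,5), [5,6), [6,7.5).
#' @param workload_range daily-workload range (uniform, patients/day).
#' @param n_obs IQC results behind each level summary (about six months
#'   of daily QC by default).
#' @return list with data frames \code{iqc}, \code{tea},
#'   \code{workload}, and \code{truth} (parameter, analyzer, drawn
#'   sigma).
#' @export
generate_lab_fixture <- function(seed = 1L, n_analyzers = 4,
                                 n_parameters = 20,
                                 band_weights = c(0.1, 0.2, 0.4, 0.3),
                                 workload_range = c(40, 420),
                                 n_obs = 180L) {
  stopifnot(n_analyzers >= 1, n_parameters >= 1,
            length(band_weights) == 4)
  with_preserved_rng(seed, {
    pars <- sprintf("par%02d", seq_len(n_parameters))
    analyzers <- sprintf("an%d", seq_len(n_analyzers))
    tea <- data.frame(parameter = pars,
                      tea_pct = sample(c(6, 8, 10, 12, 15), n_parameters,
                                       replace = TRUE),
                      source_tier = sample(
                        c("biological_variation", "state_of_the_art"),
                        n_parameters, replace = TRUE, prob = c(0.7, 0.3)),
                      stringsAsFactors = FALSE)
    workload <- data.frame(parameter = character(), analyzer = character(),
                           daily_workload = numeric())
    iqc <- NULL
    truth <- NULL
    bands <- rbind(c(3, 4), c(4, 5), c(5, 6), c(6, 7.5))
    for (i in seq_len(n_parameters)) {
      on_k <- sample.int(n_analyzers, 1)
      on <- sample(analyzers, on_k)
      for (a in on) {
        band <- sample.int(4, 1, prob = band_weights)
        sig <- runif(1, bands[band, 1], bands[band, 2])
        bias <- runif(1, 0, 0.15 * tea$tea_pct[i]) *
          sample(c(-1, 1), 1)
        cv <- (tea$tea_pct[i] - abs(bias)) / sig
        # two control levels with sigmas straddling the target so the
        # unweighted mean reproduces it exactly
        eps <- runif(1, 0, min(0.3, (sig - 3) / 2))
        sig_lv <- c(sig - eps, sig + eps)
        cv_lv <- (tea$tea_pct[i] - abs(bias)) / sig_lv
        tgt <- round(runif(1, 20, 200), 1) * c(1, 2.5)
        iqc <- rbind(iqc, data.frame(
          parameter = pars[i], analyzer = a,
          level_id = c("L1", "L2"), target_value = tgt,
          observed_mean = tgt * (1 + bias / 100),
          cv_pct = cv_lv, n_obs = n_obs,
          is_low_concentration = c(sig < 4, FALSE),
          stringsAsFactors = FALSE))
        truth <- rbind(truth, data.frame(
          parameter = pars[i], analyzer = a, sigma = sig, bias_pct = bias,
          stringsAsFactors = FALSE))
        workload <- rbind(workload, data.frame(
          parameter = pars[i], analyzer = a,
          daily_workload = round(runif(1, workload_range[1],
                                       workload_range[2])),
          stringsAsFactors = FALSE))
      }
    }
    rownames(iqc) <- NULL
    list(iqc = iqc, tea = tea, workload = workload, truth = truth)
  })
}
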