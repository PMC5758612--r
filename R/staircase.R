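#' Settings of the 3-down/1-up adaptive staircase
#'
#' Three consecutive correct responses lower the target contrast by
#' `step_log10` log units and every error raises it by the same amount; the
#' track terminates after `max_reversals` reversals or `max_trials` trials,
#' whichever comes first, and the threshold is the mean of the last
#' `n_reversals_for_threshold` reversal contrasts. These defaults (0.1 log
#' steps, 120 trials, 14 reversals, last 6 reversals) target the
#' 79.37%-correct point of the psychometric function.
#'
#' Since the track moves in log-contrast steps, the default threshold
#' estimator averages reversal contrasts in log10 units and exponentiates;
#' `mean_type = "linear"` averages the raw Michelson values instead.
#'
#' @param step_log10 Step size in log10 contrast units.
#' @param n_down Consecutive correct responses required to step down.
#' @param n_up Errors required to step up (only 1 supported).
#' @param max_trials,max_reversals Termination limits.
#' @param n_reversals_for_threshold Number of final reversals averaged.
#' @param start_contrast Initial Michelson contrast; default 0.5 (a clearly
#'   visible starting level).
#' @param contrast_ceiling,contrast_floor Clamping bounds; the floor default
#'   of 1e-4 is far below any plausible threshold and keeps log arithmetic
#'   finite.
#' @param mean_type `"log10"` (default) or `"linear"` reversal averaging.
#' @return An object of class `staircase_settings`.
#' @export
staircase_settings <- function(step_log10 = 0.1, n_down = 3, n_up = 1,
                               max_trials = 120, max_reversals = 14,
                               n_reversals_for_threshold = 6,
                               start_contrast = 0.5,
                               contrast_ceiling = 1.0, contrast_floor = 1e-4,
                               mean_type = c("log10", "linear")) {
  mean_type <- match.arg(mean_type)
  if (step_log10 <= 0) stop("step_log10 must be positive", call. = FALSE)
  if (n_up != 1) stop("only 1-up rules are implemented", call. = FALSE)
  if (n_reversals_for_threshold > max_reversals)
    stop("n_reversals_for_threshold cannot exceed max_reversals", call. = FALSE)
  if (contrast_floor <= 0 || contrast_floor >= start_contrast ||
      start_contrast > contrast_ceiling)
    stop("need 0 < floor < start_contrast <= ceiling", call. = FALSE)
  structure(list(step_log10 = step_log10, n_down = n_down, n_up = n_up,
                 max_trials = max_trials, max_reversals = max_reversals,
                 n_reversals_for_threshold = n_reversals_for_threshold,
                 start_contrast = start_contrast,
                 contrast_ceiling = contrast_ceiling,
                 contrast_floor = contrast_floor,
                 mean_type = mean_type),
            class = "staircase_settings")
}

#' Run one adaptive staircase against a response oracle
#'
#' `respond_fn` is called once per trial with the current Michelson contrast
#' and must return `TRUE` for a correct response. The consecutive-correct
#' counter resets on every error and on every executed down-step (standard
#' transformed-staircase bookkeeping). A reversal is logged at each trial
#' whose step direction differs from the previous executed step; a step
#' fully blocked by the contrast floor or ceiling is not a step and cannot
#' create a phantom reversal.
#'
#' @param respond_fn Function `contrast -> logical`.
#' @param settings A [staircase_settings()].
#' @return A `staircase_result`: list with `trials` (data frame of
#'   `trial, contrast, correct, reversal`), `reversal_contrasts`,
#'   `threshold` (NA with a warning when fewer than
#'   `n_reversals_for_threshold` reversals occurred), `valid`,
#'   `n_trials_run` and `termination_reason`.
#' @export
#' @examples
#' oracle <- function(contrast) contrast >= 0.1
#' res <- run_staircase(oracle, staircase_settings())
#' res$threshold
run_staircase <- function(respond_fn, settings = staircase_settings()) {
  stopifnot(inherits(settings, "staircase_settings"))
  contrast <- settings$start_contrast
  streak <- 0L
  last_dir <- 0L
  reversals <- numeric(0)
  n <- 0L
  trial_contrast <- numeric(settings$max_trials)
  trial_correct <- logical(settings$max_trials)
  trial_reversal <- logical(settings$max_trials)
  reason <- "trials_exhausted"

  while (n < settings$max_trials) {
    n <- n + 1L
    correct <- isTRUE(respond_fn(contrast))
    trial_contrast[n] <- contrast
    trial_correct[n] <- correct

    dir <- 0L
    if (correct) {
      streak <- streak + 1L
      if (streak == settings$n_down) {
        dir <- -1L
        streak <- 0L
      }
    } else {
      dir <- +1L
      streak <- 0L
    }

    if (dir != 0L) {
      new_contrast <- contrast * 10^(dir * settings$step_log10)
      new_contrast <- min(max(new_contrast, settings$contrast_floor),
                          settings$contrast_ceiling)
      if (new_contrast != contrast) {       # clamp-blocked steps are no steps
        if (last_dir != 0L && dir != last_dir) {
          reversals <- c(reversals, contrast)
          trial_reversal[n] <- TRUE
        }
        last_dir <- dir
        contrast <- new_contrast
      }
    }
    if (length(reversals) >= settings$max_reversals) {
      reason <- "reversals_reached"
      break
    }
  }

  k <- settings$n_reversals_for_threshold
  if (length(reversals) >= k) {
    last_k <- utils::tail(reversals, k)
    threshold <- if (settings$mean_type == "log10")
      10^mean(log10(last_k)) else mean(last_k)
    valid <- TRUE
  } else {
    warning(sprintf("staircase terminated with %d reversal(s); %d required for a threshold",
                    length(reversals), k), call. = FALSE)
    threshold <- NA_real_
    valid <- FALSE
  }

  structure(list(trials = data.frame(trial = seq_len(n),
                                     contrast = trial_contrast[seq_len(n)],
                                     correct = trial_correct[seq_len(n)],
                                     reversal = trial_reversal[seq_len(n)]),
                 reversal_contrasts = reversals,
                 threshold = threshold, valid = valid,
                 n_trials_run = n, termination_reason = reason,
                 settings = settings),
            class = "staircase_result")
}

#' Measure one observer's threshold in one condition via a staircase
#'
#' Convenience wrapper tying [run_staircase()] to [respond()].
#'
#' @inheritParams p_correct
#' @param settings A [staircase_settings()].
#' @return A `staircase_result`.
#' @export
measure_threshold <- function(observer, condition,
                              settings = staircase_settings()) {
  run_staircase(function(contrast) respond(observer, condition, contrast),
                settings)
}

#' Monte-Carlo convergence check for the staircase
#'
#' Runs `n_runs` seeded staircases against a simulated observer and reports
#' the distribution of threshold estimates together with the empirical
#' percent correct over trials after each run's first reversal (the
#' post-convergence portion of the track), which for the 3-down/1-up rule
#' should sit near the analytic 79.37% equilibrium.
#'
#' @inheritParams measure_threshold
#' @param n_runs Number of staircase replicates.
#' @param seed RNG seed.
#' @return List with `n_runs`, `n_valid`, `estimates` (Michelson),
#'   `mean_log10_estimate`, `sd_log10_estimate`,
#'   `true_threshold` (the observer's generating 79.37% point),
#'   `bias_log10` and `percent_correct_post_first_reversal`.
#' @export
convergence_report <- function(observer, condition,
                               settings = staircase_settings(),
                               n_runs = 500, seed = 1) {
  stopifnot(n_runs >= 1)
  set.seed(seed)
  estimates <- rep(NA_real_, n_runs)
  pc_correct <- 0L
  pc_total <- 0L
  for (i in seq_len(n_runs)) {
    res <- measure_threshold(observer, condition, settings)
    if (res$valid) estimates[i] <- res$threshold
    first_rev <- match(TRUE, res$trials$reversal)
    if (!is.na(first_rev) && first_rev < nrow(res$trials)) {
      post <- res$trials$correct[(first_rev + 1):nrow(res$trials)]
      pc_correct <- pc_correct + sum(post)
      pc_total <- pc_total + length(post)
    }
  }
  truth <- true_threshold(observer, condition)
  valid <- !is.na(estimates)
  list(n_runs = n_runs, n_valid = sum(valid),
       estimates = estimates[valid],
       mean_log10_estimate = mean(log10(estimates[valid])),
       sd_log10_estimate = stats::sd(log10(estimates[valid])),
       true_threshold = truth,
       bias_log10 = mean(log10(estimates[valid])) - log10(truth),
       percent_correct_post_first_reversal = 100 * pc_correct / pc_total)
}
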