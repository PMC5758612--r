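#' Specification of a synthetic two-group lateral-masking cohort
#'
#' Describes the generating distribution of a simulated cohort: per-group,
#' per-separation orthogonal (baseline) thresholds and threshold-elevation
#' profiles, with between-subject variability on log10 thresholds
#' (thresholds are positive and the staircase steps in log units, so
#' lognormal individual thresholds are the natural choice).
#'
#' `cohort_spec_from_table()` derives the group means and SDs from a
#' measured threshold table (typically the packaged baseline-experiment
#' fixture), so the synthetic cohort reproduces the statistical structure of
#' the measured groups: macular-degeneration observers with higher baseline
#' thresholds, reduced collinear inhibition at 3 lambda and reduced
#' facilitation at 6-8 lambda relative to controls.
#'
#' @param n_md,n_control Observers per group (defaults 5 and 5).
#' @param orthogonal_log10_means List with `MD` and `control` named vectors
#'   of mean log10 orthogonal thresholds per separation.
#' @param te_profile_means List with `MD` and `control` named vectors of
#'   mean TE (log10 units) per separation.
#' @param between_subject_sd SD of individual log10 orthogonal thresholds
#'   around the group mean.
#' @param te_profile_sd SD of individual TE values around the group mean.
#' @param psychometric A [psychometric_params()].
#' @param seed RNG seed; a fixed seed yields an identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(orthogonal_log10_means, te_profile_means,
                        n_md = 5, n_control = 5,
                        between_subject_sd = 0.25, te_profile_sd = 0.12,
                        psychometric = psychometric_params(), seed = 1) {
  for (g in c("MD", "control")) {
    if (is.null(orthogonal_log10_means[[g]]) || is.null(te_profile_means[[g]]))
      stop("means must be given for both 'MD' and 'control'", call. = FALSE)
    if (!identical(names(orthogonal_log10_means[[g]]),
                   names(te_profile_means[[g]])))
      stop("separation names must agree between threshold and TE means",
           call. = FALSE)
  }
  if (n_md < 1 || n_control < 1) stop("need at least one observer per group",
                                      call. = FALSE)
  if (between_subject_sd < 0 || te_profile_sd < 0)
    stop("SDs must be non-negative", call. = FALSE)
  structure(list(n_md = n_md, n_control = n_control,
                 orthogonal_log10_means = orthogonal_log10_means,
                 te_profile_means = te_profile_means,
                 between_subject_sd = between_subject_sd,
                 te_profile_sd = te_profile_sd,
                 psychometric = psychometric, seed = seed),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param table Threshold table (see [compute_te()]) from which group means
#'   and SDs are estimated.
#' @param ... Passed on to [cohort_spec()]; explicitly given arguments
#'   (including `between_subject_sd`/`te_profile_sd`) override the values
#'   estimated from the table.
#' @export
cohort_spec_from_table <- function(table, ...) {
  validate_threshold_table(table)
  te <- compute_te(table)
  ort <- table[table$orientation == "orthogonal", ]
  lg <- function(g) {
    sub <- ort[ort$group == g, ]
    agg <- stats::aggregate(log10(sub$threshold), list(sub$separation), mean)
    stats::setNames(agg$x, agg$Group.1)
  }
  tg <- function(g) {
    sub <- te[te$group == g, ]
    agg <- stats::aggregate(sub$te, list(sub$separation), mean)
    stats::setNames(agg$x, agg$Group.1)
  }
  pooled_sd <- function(d, v) {
    agg <- stats::aggregate(d[[v]], list(d$group, d$separation), stats::sd)
    sqrt(mean(agg$x^2))
  }
  ort$log10_threshold <- log10(ort$threshold)
  args <- list(orthogonal_log10_means = list(MD = lg("MD"),
                                             control = lg("control")),
               te_profile_means = list(MD = tg("MD"), control = tg("control")),
               between_subject_sd = pooled_sd(ort, "log10_threshold"),
               te_profile_sd = pooled_sd(te, "te"))
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' Draw a cohort of simulated observers
#'
#' Each observer's log10 orthogonal thresholds and TE profile values are
#' drawn Normal around the group means of the spec; thresholds are capped at
#' a Michelson contrast of 1. With `between_subject_sd = 0` and
#' `te_profile_sd = 0` every observer equals the group means. Deterministic
#' under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of [observer_model()]s, named `MD01...`, `control01...`;
#'   each observer's `profile$te_by_separation` holds its own generating TE
#'   values.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  draw <- function(group, idx) {
    mu <- spec$orthogonal_log10_means[[group]]
    te_mu <- spec$te_profile_means[[group]]
    lth <- stats::rnorm(length(mu), mu, spec$between_subject_sd)
    te <- stats::rnorm(length(te_mu), te_mu, spec$te_profile_sd)
    ort <- pmin(10^lth, 1)
    names(ort) <- names(mu)
    names(te) <- names(te_mu)
    observer_model(orthogonal_threshold = ort,
                   profile = lateral_profile(te),
                   psychometric = spec$psychometric,
                   group = group)
  }
  cohort <- c(lapply(seq_len(spec$n_md), function(i) draw("MD", i)),
              lapply(seq_len(spec$n_control), function(i) draw("control", i)))
  names(cohort) <- c(sprintf("MD%02d", seq_len(spec$n_md)),
                     sprintf("control%02d", seq_len(spec$n_control)))
  cohort
}

#' Simulate the baseline experiment through the staircase engine
#'
#' Runs one 3-down/1-up staircase per observer per condition (2 orientations
#' x the spec's separations) and returns the resulting threshold table with
#' phase `"pre"`. Staircases that end with too few reversals for a
#' threshold are dropped with a warning (none occur under default settings).
#'
#' @param cohort Output of [make_cohort()].
#' @param settings A [staircase_settings()].
#' @param seed RNG seed for the trial-level response noise.
#' @return Threshold table (see [compute_te()]).
#' @export
simulate_experiment1 <- function(cohort, settings = staircase_settings(),
                                 seed = 1) {
  stopifnot(length(cohort) > 0)
  set.seed(seed)
  simulate_phase(cohort, settings, phase = "pre",
                 shift = function(obs, cond, thr) thr)
}

# run staircases for all observers x conditions; `shift` maps the generating
# threshold to the phase-specific one
simulate_phase <- function(cohort, settings, phase, shift) {
  rows <- list()
  n_invalid <- 0L
  for (nm in names(cohort)) {
    obs <- cohort[[nm]]
    seps <- as.numeric(names(obs$orthogonal_threshold))
    for (ori in c("collinear", "orthogonal")) {
      for (s in seps) {
        cond <- list(orientation = ori, separation_lambda = s)
        thr <- shift(nm, cond, true_threshold(obs, cond))
        oracle <- weibull_oracle(thr, obs$psychometric)
        res <- suppressWarnings(run_staircase(oracle, settings))
        if (!res$valid) { n_invalid <- n_invalid + 1L; next }
        rows[[length(rows) + 1L]] <-
          data.frame(participant = nm, group = obs$group, phase = phase,
                     orientation = ori, separation = s,
                     threshold = min(res$threshold, 1),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (n_invalid > 0)
    warning(sprintf("%d staircase(s) ended without enough reversals; rows dropped",
                    n_invalid), call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "n_invalid") <- n_invalid
  out
}

# response oracle for a Weibull observer parameterised by its 79.37% point
weibull_oracle <- function(threshold79, psychometric) {
  alpha <- alpha_from_threshold(threshold79, psychometric)
  function(contrast) {
    p <- 0.5 + (0.5 - psychometric$lapse) *
      (1 - exp(-(contrast / alpha)^psychometric$beta))
    stats::runif(1) < p
  }
}

#' Specification of a perceptual-learning training effect
#'
#' Per-group, per-orientation, per-separation mean change in Michelson
#' threshold after training (negative = improvement) and its between-subject
#' SD. `training_spec_from_table()` estimates both from a table of measured
#' training differences (the packaged training-experiment fixture), in which
#' macular-degeneration observers improve substantially in the collinear
#' conditions while controls change little. Training is modelled at the
#' pre/post level: effects are drawn per condition, not per session, and the
#' 12 training sessions are recorded as metadata only.
#'
#' @param deltas Data frame with columns `group`, `orientation`,
#'   `separation`, `mean_delta`, `sd_delta`.
#' @param n_sessions Number of training sessions (metadata).
#' @return An object of class `training_spec`.
#' @export
training_spec <- function(deltas, n_sessions = 12) {
  needed <- c("group", "orientation", "separation", "mean_delta", "sd_delta")
  miss <- setdiff(needed, names(deltas))
  if (length(miss))
    stop("deltas lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (n_sessions <= 0) stop("n_sessions must be positive", call. = FALSE)
  structure(list(deltas = deltas, n_sessions = n_sessions),
            class = "training_spec")
}

#' @rdname training_spec
#' @param delta_table Data frame with columns `participant`, `group`,
#'   `orientation`, `separation`, `delta` (threshold change in Michelson).
#' @export
training_spec_from_table <- function(delta_table, n_sessions = 12) {
  agg <- stats::aggregate(delta ~ group + orientation + separation,
                          data = delta_table,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(group = agg$group, orientation = agg$orientation,
                    separation = agg$separation,
                    mean_delta = agg$delta[, "mean"],
                    sd_delta = agg$delta[, "sd"],
                    stringsAsFactors = FALSE)
  training_spec(out, n_sessions = n_sessions)
}

#' Simulate a pre/post training experiment
#'
#' Measures every observer in every condition before training, shifts each
#' observer's generating thresholds by a per-condition training effect drawn
#' from the training spec, and re-measures; both phases go through the full
#' staircase procedure. Post-training thresholds are floored at the
#' staircase contrast floor.
#'
#' @param cohort Output of [make_cohort()].
#' @param training A [training_spec()].
#' @param settings A [staircase_settings()].
#' @param seed RNG seed.
#' @return Threshold table with phases `"pre"` and `"post"`.
#' @export
simulate_training <- function(cohort, training,
                              settings = staircase_settings(), seed = 1) {
  stopifnot(inherits(training, "training_spec"), length(cohort) > 0)
  set.seed(seed)
  pre <- simulate_phase(cohort, settings, phase = "pre",
                        shift = function(obs, cond, thr) thr)
  # draw per-observer, per-condition effects on the generating thresholds
  effects <- new.env(parent = emptyenv())
  for (nm in names(cohort)) {
    obs <- cohort[[nm]]
    seps <- as.numeric(names(obs$orthogonal_threshold))
    for (ori in c("collinear", "orthogonal")) {
      for (s in seps) {
        row <- training$deltas[training$deltas$group == obs$group &
                                 training$deltas$orientation == ori &
                                 training$deltas$separation == s, ]
        if (nrow(row) != 1)
          stop(sprintf("training spec has no delta for %s/%s/%g lambda",
                       obs$group, ori, s), call. = FALSE)
        assign(paste(nm, ori, s, sep = "|"),
               stats::rnorm(1, row$mean_delta, row$sd_delta), envir = effects)
      }
    }
  }
  post <- simulate_phase(cohort, settings, phase = "post",
                         shift = function(nm, cond, thr) {
                           d <- get(paste(nm, cond$orientation,
                                          cond$separation_lambda, sep = "|"),
                                    envir = effects)
                           min(max(thr + d, settings$contrast_floor * 10), 1)
                         })
  rbind(pre, post)
}
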