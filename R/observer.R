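#' Psychometric-function parameters for a 2AFC Weibull observer
#'
#' Detection probability follows a Weibull on linear contrast,
#' \deqn{P(c) = 0.5 + (0.5 - \lambda)\,(1 - e^{-(c/\alpha)^\beta})}
#' with guess rate fixed at 0.5 (two-alternative forced choice), slope
#' `beta` and lapse rate `lapse`. The scale `alpha` is not set directly:
#' observers are parameterised by their 79.37%-correct contrast (the
#' 3-down/1-up staircase equilibrium) and `alpha` is derived per condition,
#' so staircase recovery is unbiased by construction.
#'
#' @param beta Weibull slope; default 3, a typical empirical value for
#'   contrast detection.
#' @param lapse Lapse rate in `[0, 0.1]`; default 0.02.
#' @return An object of class `psychometric_params`.
#' @export
psychometric_params <- function(beta = 3, lapse = 0.02) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (lapse < 0 || lapse > 0.1)
    stop("lapse must lie in [0, 0.1]", call. = FALSE)
  structure(list(beta = beta, lapse = lapse, guess = 0.5),
            class = "psychometric_params")
}

#' Separation-dependent lateral-interaction profile
#'
#' Maps target-to-flanker separation (in multiples of lambda) to a
#' threshold-elevation (TE) shift in log10 units: positive TE is collinear
#' inhibition (flankers within the perceptual field), negative TE is
#' facilitation (flankers outside it). TE at intermediate separations is
#' piecewise-linear interpolated; the perceptual-field border is reported as
#' the separation at which the interpolated profile crosses zero.
#'
#' @param te_by_separation Named numeric vector, names are separations in
#'   lambda (e.g. `c("3" = 0.2, "4" = 0, "6" = -0.1, "8" = -0.15)`).
#' @return An object of class `lateral_profile` with fields
#'   `te_by_separation` and `pf_border_lambda` (NA when the profile never
#'   changes sign).
#' @export
lateral_profile <- function(te_by_separation) {
  seps <- as.numeric(names(te_by_separation))
  if (length(seps) == 0 || anyNA(seps))
    stop("te_by_separation must be a named vector with numeric separation names",
         call. = FALSE)
  ord <- order(seps)
  seps <- seps[ord]
  te <- unname(te_by_separation[ord])
  border <- NA_real_
  for (i in seq_len(length(seps) - 1)) {
    if (te[i] > 0 && te[i + 1] <= 0) {
      border <- seps[i] + (seps[i + 1] - seps[i]) * te[i] / (te[i] - te[i + 1])
      break
    }
  }
  structure(list(te_by_separation = stats::setNames(te, seps),
                 pf_border_lambda = border),
            class = "lateral_profile")
}

#' Evaluate a lateral profile at arbitrary separations
#'
#' @param profile A [lateral_profile()].
#' @param separation_lambda Separations in lambda units; values outside the
#'   tabulated range take the nearest endpoint's TE.
#' @return TE values in log10 units.
#' @export
profile_te <- function(profile, separation_lambda) {
  stopifnot(inherits(profile, "lateral_profile"))
  tab <- profile$te_by_separation
  seps <- as.numeric(names(tab))
  if (length(seps) == 1) return(rep(unname(tab), length(separation_lambda)))
  stats::approx(seps, unname(tab), xout = separation_lambda, rule = 2)$y
}

#' A simulated lateral-masking observer
#'
#' The observer's contrast threshold (the 79.37%-correct point, i.e. the
#' 3-down/1-up equilibrium) in the orthogonal baseline condition is given per
#' separation; the collinear threshold at separation d is
#' `orthogonal threshold * 10^TE(d)`, so the log10 collinear/orthogonal
#' threshold ratio equals the lateral-interaction profile exactly.
#'
#' @param orthogonal_threshold Named numeric vector of Michelson thresholds,
#'   names are separations in lambda.
#' @param profile A [lateral_profile()].
#' @param psychometric A [psychometric_params()].
#' @param group `"MD"` or `"control"` (bookkeeping label).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(orthogonal_threshold, profile,
                           psychometric = psychometric_params(),
                           group = c("control", "MD")) {
  group <- match.arg(group)
  if (any(orthogonal_threshold <= 0 | orthogonal_threshold > 1))
    stop("orthogonal thresholds must be Michelson values in (0, 1]", call. = FALSE)
  if (is.null(names(orthogonal_threshold)))
    stop("orthogonal_threshold must be named by separation", call. = FALSE)
  stopifnot(inherits(profile, "lateral_profile"),
            inherits(psychometric, "psychometric_params"))
  structure(list(orthogonal_threshold = orthogonal_threshold,
                 profile = profile, psychometric = psychometric,
                 group = group),
            class = "observer_model")
}

#' Percent-correct level targeted by an n-down/1-up staircase
#'
#' The transformed up/down staircase equilibrates where the expected rates of
#' up and down steps match: `p^n_down = 0.5`. For the 3-down/1-up rule this
#' is `0.5^(1/3) = 0.7937`, i.e. 79% correct.
#'
#' @param n_down Number of consecutive correct responses required to step
#'   down.
#' @param n_up Number of errors required to step up; only 1 is supported.
#' @return The equilibrium probability of a correct response.
#' @export
#' @examples
#' equilibrium_probability(3, 1)  # 0.7937...
equilibrium_probability <- function(n_down = 3, n_up = 1) {
  if (n_down < 1) stop("n_down must be at least 1", call. = FALSE)
  if (n_up != 1)
    stop("only 1-up rules are implemented", call. = FALSE)
  0.5^(1 / n_down)
}

# Weibull scale alpha such that P(threshold79) = 0.5^(1/3)
alpha_from_threshold <- function(threshold79, psychometric) {
  p_star <- equilibrium_probability(3, 1)
  frac <- (p_star - 0.5) / (0.5 - psychometric$lapse)
  if (frac >= 1)
    stop("lapse rate too large: the 79.37%-correct level is unreachable",
         call. = FALSE)
  threshold79 / (-log(1 - frac))^(1 / psychometric$beta)
}

resolve_condition <- function(observer, condition) {
  orientation <- match.arg(condition$orientation, c("collinear", "orthogonal"))
  sep_key <- as.character(condition$separation_lambda)
  if (!sep_key %in% names(observer$orthogonal_threshold))
    stop(sprintf("observer has no orthogonal threshold for separation %s lambda",
                 sep_key), call. = FALSE)
  list(orientation = orientation, sep = condition$separation_lambda,
       sep_key = sep_key)
}

#' True (generating) contrast threshold of a simulated observer
#'
#' Returns the contrast at which the observer's probability of a correct
#' response equals the 3-down/1-up equilibrium `0.5^(1/3)`. For the
#' orthogonal condition this is the observer's baseline threshold; for the
#' collinear condition it is the baseline scaled by `10^TE(separation)`.
#'
#' @param observer An [observer_model()].
#' @param condition List with `orientation` (`"collinear"`/`"orthogonal"`)
#'   and `separation_lambda`.
#' @return Michelson contrast threshold.
#' @export
true_threshold <- function(observer, condition) {
  stopifnot(inherits(observer, "observer_model"))
  cond <- resolve_condition(observer, condition)
  base <- unname(observer$orthogonal_threshold[cond$sep_key])
  if (cond$orientation == "orthogonal") return(base)
  base * 10^profile_te(observer$profile, cond$sep)
}

#' Probability of a correct 2AFC response
#'
#' Weibull psychometric function evaluated at a given contrast, for the
#' given condition. Deterministic in its inputs; `respond()` draws the
#' Bernoulli outcome.
#'
#' @inheritParams true_threshold
#' @param contrast Michelson contrast in `[0, 1]`.
#' @return Probability of a correct response, in `[0.5, 1 - lapse]`.
#' @export
p_correct <- function(observer, condition, contrast) {
  stopifnot(inherits(observer, "observer_model"))
  if (any(contrast < 0 | contrast > 1))
    stop("contrast must lie in [0, 1]", call. = FALSE)
  thr <- true_threshold(observer, condition)
  psy <- observer$psychometric
  alpha <- alpha_from_threshold(thr, psy)
  0.5 + (0.5 - psy$lapse) * (1 - exp(-(contrast / alpha)^psy$beta))
}

#' Draw one 2AFC response
#'
#' Bernoulli draw with probability [p_correct()]; reproducible under
#' `set.seed()`.
#'
#' @inheritParams p_correct
#' @return Logical: was the response correct.
#' @export
respond <- function(observer, condition, contrast) {
  stats::runif(1) < p_correct(observer, condition, contrast)
}
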