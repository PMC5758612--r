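#' Aligned Rank Transform factorial analysis
#'
#' Nonparametric factorial analysis for small-sample designs: for each
#' effect, every other estimated effect is stripped from the responses
#' (estimates taken from unweighted cell means; balanced designs only), the
#' aligned responses are ranked (midranks on ties), and an ANOVA is run on
#' the ranks; only the row for the aligned-for effect is interpreted.
#'
#' Designs with within-subject (repeated-measures) factors are analysed
#' with subject error strata ([stats::aov()] with `Error(subject)`), so a
#' mixed 2-group x 4-level design yields the familiar F(1, 8) for the
#' between factor and F(3, 24) for the within factor and interaction.
#'
#' The between x within interaction is tested with a repeated-measures
#' aligned-rank procedure: responses are aligned by removing subject means
#' (which absorb all between-subject variation, including the group effect)
#' and the within-factor level means, leaving interaction plus error; the
#' aligned values are ranked and the interaction F is read from the
#' within-subject stratum. This test is available for exactly one within
#' and one between factor; designs with two or more within factors support
#' main effects only, and requesting their interactions is an explicit
#' error rather than a silently wrong answer.
#'
#' @param data Data frame in long format, one row per observation.
#' @param dv Name of the response column.
#' @param between,within Character vectors of factor column names.
#' @param subject Name of the subject identifier column.
#' @param interactions Logical: also test interactions (default TRUE where
#'   supported; with more than one within factor the request is refused).
#' @return An `art_result`: list with `effects` (data frame of
#'   `effect, F, df1, df2, p`), `aligned` (named list of per-effect aligned
#'   responses and ranks), and the interaction error variance needed by
#'   [diff_of_diffs_posthoc()].
#' @export
art_analysis <- function(data, dv, between = character(),
                         within = character(), subject = "participant",
                         interactions = length(within) <= 1) {
  factors <- c(between, within)
  if (length(factors) == 0) stop("no factors given", call. = FALSE)
  miss <- setdiff(c(dv, factors, subject), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (interactions && length(within) > 1)
    stop("interaction tests are not supported with more than one within factor",
         call. = FALSE)
  if (interactions && length(factors) > 2 && length(within) == 1)
    stop("the repeated-measures interaction test supports exactly one within and one between factor",
         call. = FALSE)

  d <- data
  d$.y <- d[[dv]]
  d$.subj <- factor(d[[subject]])
  for (f in factors) d[[f]] <- factor(d[[f]])
  cell <- interaction(d[factors], drop = FALSE)
  counts <- table(cell)
  if (length(unique(counts)) != 1 || any(counts == 0))
    stop("design must be complete and balanced (equal cell counts)",
         call. = FALSE)

  has_within <- length(within) > 0
  fixed_formula <- paste(factors, collapse = " * ")

  fit_ranks <- function(r) {
    d$.r <- r
    if (has_within)
      stats::aov(stats::as.formula(paste(".r ~", fixed_formula, "+ Error(.subj)")),
                 data = d)
    else
      stats::aov(stats::as.formula(paste(".r ~", fixed_formula)), data = d)
  }

  aligned <- list()
  rows <- list()

  run_effect <- function(label, aligned_y) {
    r <- rank(aligned_y)
    fit <- fit_ranks(r)
    row <- extract_aov_row(fit, label)
    aligned[[label]] <<- list(aligned = aligned_y, ranks = r)
    rows[[label]] <<- row
  }

  # main effects (and, in purely between designs, all interactions) via
  # cell-mean alignment
  for (f in factors)
    run_effect(f, align_for_effect(d$.y, d[factors], f))
  if (interactions && length(between) >= 2 && !has_within) {
    prs <- utils::combn(between, 2, simplify = FALSE)
    for (pr in prs)
      run_effect(paste(pr, collapse = ":"),
                 align_for_effect(d$.y, d[factors], pr))
  }

  inter_error <- NULL
  if (interactions && length(within) == 1 && length(between) == 1) {
    label <- paste(between, within, sep = ":")
    subj_means <- stats::ave(d$.y, d$.subj)
    within_means <- stats::ave(d$.y, d[[within]])
    aligned_y <- d$.y - subj_means - within_means + mean(d$.y)
    r <- rank(aligned_y)
    fit <- fit_ranks(r)
    rows[[label]] <- extract_aov_row(fit, label)
    aligned[[label]] <- list(aligned = aligned_y, ranks = r)
    inter_error <- extract_within_error(fit)
    inter_error$cells <- stats::aggregate(r,
      by = list(d[[between]], d[[within]]), FUN = mean)
    names(inter_error$cells) <- c(between, within, "mean_rank")
    inter_error$n_per_cell <- unname(counts[1])
    inter_error$between <- between
    inter_error$within <- within
  }

  structure(list(effects = do.call(rbind, rows),
                 aligned = aligned,
                 interaction_error = inter_error,
                 between = between, within = within),
            class = "art_result")
}

# effect estimate from unweighted cell means for a subset of factors
# (inclusion-exclusion over marginal means), returned per observation
effect_estimate <- function(y, fac_df, which_factors) {
  est <- rep(0, length(y))
  k <- length(which_factors)
  for (m in 0:k) {
    subsets <- utils::combn(which_factors, m, simplify = FALSE)
    for (s in subsets) {
      marg <- if (length(s) == 0) rep(mean(y), length(y))
      else stats::ave(y, fac_df[s])
      est <- est + (-1)^(k - m) * marg
    }
  }
  est
}

align_for_effect <- function(y, fac_df, which_factors) {
  full_cell_mean <- stats::ave(y, fac_df)
  y - full_cell_mean + effect_estimate(y, fac_df, which_factors)
}

extract_aov_row <- function(fit, label) {
  tabs <- if (inherits(fit, "aovlist")) lapply(summary(fit), `[[`, 1)
  else summary(fit)
  for (tab in tabs) {
    tab <- as.data.frame(tab)
    idx <- match(label, trimws(rownames(tab)))
    if (!is.na(idx)) {
      res <- which(trimws(rownames(tab)) == "Residuals")
      return(data.frame(effect = label,
                        F = tab$`F value`[idx],
                        df1 = tab$Df[idx],
                        df2 = tab$Df[res],
                        p = tab$`Pr(>F)`[idx],
                        stringsAsFactors = FALSE))
    }
  }
  stop("effect '", label, "' not found in ANOVA table", call. = FALSE)
}

extract_within_error <- function(fit) {
  tabs <- lapply(summary(fit), `[[`, 1)
  tab <- as.data.frame(tabs[[length(tabs)]])   # innermost (within) stratum
  res <- which(trimws(rownames(tab)) == "Residuals")
  list(ms_error = tab$`Mean Sq`[res], df_error = tab$Df[res])
}

#' Differences-of-differences post-hoc contrasts on the interaction
#'
#' Direct pairwise comparison of factor-level combinations is not meaningful
#' on aligned-rank interaction data; the appropriate contrasts compare
#' differences of differences, e.g. (A - B at level C) vs (A - B at level
#' D). For each requested pair of within-factor levels this computes the
#' between-group difference of mean interaction-aligned ranks at each level,
#' tests their difference against the interaction stratum's error variance,
#' and Holm-adjusts the p-values within the family.
#'
#' @param art An [art_analysis()] result containing an interaction test.
#' @param level_pairs Optional list of 2-vectors of within-factor levels;
#'   default all pairs.
#' @return Data frame with one row per contrast: the two levels, the
#'   difference-of-differences estimate (in mean ranks), t, df, raw and
#'   Holm-adjusted p.
#' @export
diff_of_diffs_posthoc <- function(art, level_pairs = NULL) {
  stopifnot(inherits(art, "art_result"))
  err <- art$interaction_error
  if (is.null(err))
    stop("no interaction test present in this ART result", call. = FALSE)
  cells <- err$cells
  wlev <- unique(as.character(cells[[err$within]]))
  blev <- unique(as.character(cells[[err$between]]))
  if (length(blev) != 2)
    stop("differences-of-differences contrasts require exactly 2 between-group levels",
         call. = FALSE)
  if (is.null(level_pairs))
    level_pairs <- utils::combn(wlev, 2, simplify = FALSE)
  rows <- lapply(level_pairs, function(pr) {
    if (!all(pr %in% wlev))
      stop("unknown within-factor level(s): ",
           paste(setdiff(pr, wlev), collapse = ", "), call. = FALSE)
    gm <- function(b, w)
      cells$mean_rank[cells[[err$between]] == b & cells[[err$within]] == w]
    est <- (gm(blev[1], pr[1]) - gm(blev[2], pr[1])) -
           (gm(blev[1], pr[2]) - gm(blev[2], pr[2]))
    se <- sqrt(err$ms_error * 4 / err$n_per_cell)
    t <- est / se
    data.frame(level_a = pr[1], level_b = pr[2],
               estimate = est, t = t, df = err$df_error,
               p = 2 * stats::pt(-abs(t), err$df_error),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}
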