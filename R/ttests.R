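#' One-sample, pooled two-sample and paired t-tests
#'
#' Thin, uniformly structured wrappers around [stats::t.test()] returning a
#' `stat_report` record. All p-values are two-tailed. The two-sample test
#' uses the pooled-variance form (`var.equal = TRUE`), giving
#' `df = n1 + n2 - 2` — with two groups of five, the df = 8 reported for
#' between-group threshold-elevation comparisons. A zero-variance sample
#' whose mean differs from `mu` is reported with an infinite statistic and a
#' p-value of 0 rather than an error.
#'
#' @param values,a,b,pre,post Numeric vectors (finite, n >= 2 each; paired
#'   inputs must have equal length).
#' @param mu Null-hypothesis mean for the one-sample test.
#' @return A `stat_report`: list with `test`, `statistic`, `df`, `p`,
#'   `mean` (or `mean_diff`), `sd`, `n` fields.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3))$statistic  # 3.464
one_sample_t <- function(values, mu = 0) {
  check_sample(values)
  if (stats::sd(values) == 0) {
    if (mean(values) == mu)
      return(stat_report("one-sample t", 0, length(values) - 1, 1,
                         mean = mean(values), sd = 0, n = length(values)))
    return(stat_report("one-sample t", sign(mean(values) - mu) * Inf,
                       length(values) - 1, 0,
                       mean = mean(values), sd = 0, n = length(values)))
  }
  fit <- stats::t.test(values, mu = mu)
  stat_report("one-sample t", unname(fit$statistic), unname(fit$parameter),
              fit$p.value, mean = mean(values), sd = stats::sd(values),
              n = length(values))
}

#' @rdname one_sample_t
#' @export
two_sample_t <- function(a, b) {
  check_sample(a); check_sample(b)
  fit <- stats::t.test(a, b, var.equal = TRUE)
  stat_report("two-sample t (pooled)", unname(fit$statistic),
              unname(fit$parameter), fit$p.value,
              mean = mean(a) - mean(b), sd = NA_real_,
              n = length(a) + length(b))
}

#' @rdname one_sample_t
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("paired samples must have equal length", call. = FALSE)
  one_sample_t_relabel(post - pre)
}

one_sample_t_relabel <- function(diffs) {
  rep <- one_sample_t(diffs, mu = 0)
  rep$test <- "paired t"
  names(rep)[names(rep) == "mean"] <- "mean_diff"
  rep
}

check_sample <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  invisible(x)
}

stat_report <- function(test, statistic, df, p, ...) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p),
              list(...)),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("%s: t(%g) = %.3f, p = %.4g\n", x$test, x$df, x$statistic, x$p))
  invisible(x)
}
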