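# Independent oracles and small builders used across the suite. These
# deliberately re-derive results from first principles (explicit formulas,
# exhaustive loops) rather than calling the package's own code paths.

# naive t-test formulas ------------------------------------------------------

oracle_one_sample_t <- function(x, mu = 0) {
  n <- length(x)
  t <- (mean(x) - mu) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_pooled_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

oracle_paired_t <- function(pre, post) oracle_one_sample_t(post - pre, 0)

# step-down Holm adjustment applied literally ------------------------------

oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# ANOVA on aligned ranks for a purely between-subjects two-factor design,
# written out longhand (cell means, inclusion-exclusion alignment, rank,
# explicit sums of squares)
oracle_art_between_2x2 <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  gm <- mean(y)
  cell <- paste(A, B)
  cmean <- tapply(y, cell, mean)[cell]
  amean <- tapply(y, A, mean)[A]
  bmean <- tapply(y, B, mean)[B]
  aligned <- list(A = y - cmean + (amean - gm),
                  B = y - cmean + (bmean - gm),
                  `A:B` = y - cmean + (cmean - amean - bmean + gm))
  out <- list()
  for (eff in names(aligned)) {
    r <- rank(aligned[[eff]])
    rg <- mean(r)
    ra <- tapply(r, A, mean)[A]
    rb <- tapply(r, B, mean)[B]
    rc <- tapply(r, cell, mean)[cell]
    ss_a <- sum((ra - rg)^2)
    ss_b <- sum((rb - rg)^2)
    ss_ab <- sum((rc - ra - rb + rg)^2)
    ss_err <- sum((r - rc)^2)
    n_cells <- length(unique(cell))
    df_err <- length(y) - n_cells
    ss_eff <- switch(eff, A = ss_a, B = ss_b, `A:B` = ss_ab)
    df_eff <- switch(eff, A = length(unique(A)) - 1,
                     B = length(unique(B)) - 1,
                     `A:B` = (length(unique(A)) - 1) * (length(unique(B)) - 1))
    out[[eff]] <- (ss_eff / df_eff) / (ss_err / df_err)
  }
  out
}

# builders -------------------------------------------------------------------

toy_threshold_table <- function(col, ort, participant = "P1",
                                group = "control", phase = "pre",
                                separation = 3) {
  rbind(data.frame(participant = participant, group = group, phase = phase,
                   orientation = "collinear", separation = separation,
                   threshold = col, stringsAsFactors = FALSE),
        data.frame(participant = participant, group = group, phase = phase,
                   orientation = "orthogonal", separation = separation,
                   threshold = ort, stringsAsFactors = FALSE))
}

flat_observer <- function(threshold = 0.2, beta = 3, lapse = 0.02,
                          te = 0, separations = 3) {
  te_vec <- setNames(rep(te, length(separations)), separations)
  thr_vec <- setNames(rep(threshold, length(separations)), separations)
  observer_model(thr_vec, lateral_profile(te_vec),
                 psychometric_params(beta = beta, lapse = lapse))
}

cond_at <- function(separation = 3, orientation = "orthogonal")
  list(orientation = orientation, separation_lambda = separation)

# long-format balanced mixed design (2 groups x within levels), iid noise
null_mixed_design <- function(n_per_group = 5, levels = c(3, 4, 6, 8)) {
  d <- expand.grid(participant = sprintf("S%02d", seq_len(2 * n_per_group)),
                   separation = levels, stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(substr(d$participant, 2, 3)) <= n_per_group,
                    "MD", "control")
  d$y <- rnorm(nrow(d))
  d
}
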