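test_that("between-subjects ART matches a longhand aligned-rank ANOVA oracle", {
  set.seed(33)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:4,
                   stringsAsFactors = FALSE)
  d$participant <- sprintf("S%02d", seq_len(nrow(d)))
  d$y <- sample.int(40, nrow(d))   # integer responses, no ties
  res <- art_analysis(d, "y", between = c("A", "B"), subject = "participant")
  oracle <- oracle_art_between_2x2(d$y, d$A, d$B)
  for (eff in c("A", "B", "A:B"))
    expect_equal(res$effects$F[res$effects$effect == eff], oracle[[eff]],
                 tolerance = 1e-10)
})

test_that("single-factor ART collapses to an ANOVA on ranks", {
  set.seed(8)
  d <- data.frame(participant = sprintf("S%02d", 1:14),
                  g = rep(c("x", "y"), each = 7), y = rnorm(14))
  res <- art_analysis(d, "y", between = "g", subject = "participant")
  ref <- anova(lm(rank(y) ~ g, data = d))
  expect_equal(res$effects$F[1], ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$effects$p[1], ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("alignment strips every other effect: per-effect aligned sums vanish, ranks are complete", {
  set.seed(12)
  d <- null_mixed_design()
  d$y <- d$y + ifelse(d$group == "MD", 1, 0) + 0.2 * d$separation
  res <- art_analysis(d, "y", between = "group", within = "separation")
  for (al in res$aligned) {
    expect_equal(sum(al$aligned), 0, tolerance = 1e-9)
    expect_equal(sort(al$ranks), seq_len(nrow(d)), tolerance = 1e-12)
  }
})

test_that("a pure main effect leaves no interaction signal after alignment", {
  d <- expand.grid(participant = sprintf("S%02d", 1:10),
                   separation = c(3, 4, 6, 8), stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(substr(d$participant, 2, 3)) <= 5,
                    "MD", "control")
  d$y <- ifelse(d$group == "MD", 10, 2)            # pure between effect
  res <- art_analysis(d, "y", between = "group", within = "separation")
  inter <- res$aligned[["group:separation"]]
  # all aligned interaction responses identical -> maximal midrank tie
  expect_equal(diff(range(inter$aligned)), 0, tolerance = 1e-12)
  expect_true(all(inter$ranks == mean(inter$ranks)))
  expect_false(isTRUE(res$effects$p[res$effects$effect == "group:separation"] < 0.05))
})

test_that("the mixed-design ART reports the split-plot degrees of freedom", {
  set.seed(4)
  d <- null_mixed_design(n_per_group = 5, levels = c(3, 4, 6, 8))
  res <- art_analysis(d, "y", between = "group", within = "separation")
  eff <- res$effects
  expect_equal(unlist(eff[eff$effect == "group", c("df1", "df2")]),
               c(df1 = 1, df2 = 8))
  expect_equal(unlist(eff[eff$effect == "separation", c("df1", "df2")]),
               c(df1 = 3, df2 = 24))
  expect_equal(unlist(eff[eff$effect == "group:separation", c("df1", "df2")]),
               c(df1 = 3, df2 = 24))
})

test_that("unsupported designs are refused explicitly", {
  set.seed(2)
  d <- null_mixed_design()
  d$orientation <- "collinear"
  d2 <- d; d2$orientation <- "orthogonal"
  dd <- rbind(d, d2)
  dd$y <- rnorm(nrow(dd))
  expect_error(art_analysis(dd, "y", between = "group",
                            within = c("separation", "orientation"),
                            interactions = TRUE),
               "more than one within")
  # main effects remain available under the same restriction
  res <- art_analysis(dd, "y", between = "group",
                      within = c("separation", "orientation"))
  expect_setequal(res$effects$effect, c("group", "separation", "orientation"))
  expect_error(art_analysis(d[-1, ], "y", between = "group",
                            within = "separation"),
               "balanced")
})

test_that("differences-of-differences contrasts are null when group differences are parallel", {
  # identical noise pattern in both groups: (MD - control) equal at every
  # separation, so every difference-of-differences is exactly zero
  set.seed(19)
  noise <- matrix(rnorm(20), nrow = 5)
  d <- null_mixed_design()
  idx <- (as.integer(substr(d$participant, 2, 3)) - 1) %% 5 + 1
  d$y <- ifelse(d$group == "MD", 3, 0) + 0.5 * d$separation +
    noise[cbind(idx, match(d$separation, c(3, 4, 6, 8)))]
  res <- art_analysis(d, "y", between = "group", within = "separation")
  ph <- diff_of_diffs_posthoc(res)
  # floating-point alignment breaks exact rank ties between the duplicated
  # pairs, so the null contrasts are near zero on the rank scale (cells span
  # ranks 1..40; real effects move mean ranks by >> 1) rather than exact
  expect_lt(max(abs(ph$estimate)), 1)
  expect_gt(min(ph$p), 0.9)
  expect_error(diff_of_diffs_posthoc(res, list(c("3", "99"))), "99")
})

test_that("Holm adjustment follows the literal step-down rule", {
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"),
               oracle_holm(c(0.01, 0.04, 0.03)), tolerance = 1e-15)
  expect_equal(oracle_holm(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06),
               tolerance = 1e-15)
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    adj <- p.adjust(p, "holm")
    expect_equal(adj, oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  }
})
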