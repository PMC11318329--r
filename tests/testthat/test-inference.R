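test_that("one-way ANOVA matches the hand decomposition and stats::aov", {
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- anova_oneway(v, g)
  expect_equal(an$table$SS, c(6, 6, 12))
  expect_equal(an$table$df, c(2, 6, 8))
  expect_equal(an$F, 3.0)

  fit <- anova(stats::aov(v ~ g))
  expect_equal(an$F, fit$`F value`[1])
  expect_equal(an$p_value, fit$`Pr(>F)`[1])

  # translation invariance
  an2 <- anova_oneway(v + 17.3, g)
  expect_equal(an2$table$SS, an$table$SS)
  expect_equal(an2$F, an$F)
})

test_that("constant groups make F explicitly undefined", {
  an <- anova_oneway(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_false(an$f_defined)
  expect_true(is.na(an$F))
  expect_error(tukey_hsd(rep(5, 9), rep(c("a", "b", "c"), each = 3)), "undefined")
})

test_that("SS conservation and df additivity hold on fuzzed inputs", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    n_i <- sample(2:8, k, replace = TRUE)
    g <- rep(letters[1:k], n_i)
    v <- rnorm(sum(n_i), mean = rep(runif(k, -5, 5), n_i), sd = runif(1, 0.5, 3))
    an <- anova_oneway(v, g)
    expect_equal(an$table$SS[3], an$table$SS[1] + an$table$SS[2], tolerance = 1e-10)
    expect_equal(an$table$df[3], an$table$df[1] + an$table$df[2])
    expect_equal(an$table$SS[3], sum((v - mean(v))^2), tolerance = 1e-10)
    expect_true(all(an$table$SS >= 0))
  }
})

test_that("audited ANOVA tables recover the expected F from SS and df", {
  expect_equal(anova_table_from_ss(6.594, 2, 0.513, 6)$F, 38.56, tolerance = 1e-3)
  expect_equal(anova_table_from_ss(134.48, 2, 9.65, 12)$F, 83.61, tolerance = 1e-3)
  expect_equal(anova_table_from_ss(0, 2, 5, 6)$F, 0)
  expect_false(anova_table_from_ss(3, 2, 0, 6)$f_defined)
  expect_error(anova_table_from_ss(-1, 2, 5, 6), ">= 0")
})

test_that("studentized range tail probability: anchors, t-reduction, monotonicity", {
  expect_equal(studentized_range_sf(0, 3, 10), 1)
  # alpha = 0.05 critical value for k = 3, df = 6 is 4.339
  expect_equal(studentized_range_sf(4.34, 3, 6), 0.05, tolerance = 2e-3)

  # k = 2 collapses to a two-sided t probability: sf(q,2,df) = P(|T| > q/sqrt(2))
  for (df in c(3, 6, 12, 30)) {
    for (q in c(0.5, 1.5, 3, 4.5)) {
      expect_equal(studentized_range_sf(q, 2, df),
                   2 * stats::pt(q / sqrt(2), df, lower.tail = FALSE),
                   tolerance = 1e-5)
    }
  }

  qs <- seq(0.5, 6, by = 0.5)
  sf <- studentized_range_sf(qs, 4, 10)
  expect_true(all(diff(sf) < 0))
})

test_that("studentized range agrees with stats::ptukey on a grid", {
  # absolute bound: ptukey's own approximation drifts by ~1e-6 at small df
  for (k in c(2, 3, 5)) for (df in c(4, 10, 25)) for (q in c(1, 2.5, 4, 5.5)) {
    expect_lt(abs(studentized_range_sf(q, k, df) -
                    stats::ptukey(q, k, df, lower.tail = FALSE)),
              5e-6, label = sprintf("q=%g k=%d df=%d", q, k, df))
  }
})

test_that("Tukey HSD: degenerate and well-separated designs give the expected letters", {
  set.seed(59)
  g <- rep(letters[1:3], each = 4)

  # identical group means: all adjusted p near 1, single shared letter
  v_eq <- rep(c(1, 2, 3, 4), 3)
  tk_eq <- tukey_hsd(v_eq, g)
  expect_true(all(tk_eq$comparisons$p_adj > 0.999))
  expect_equal(unname(tk_eq$letters), c("a", "a", "a"))

  # gaps >> within-SD: all pairs significant, letters a/b/c
  v_sep <- c(rnorm(4, 0, 0.1), rnorm(4, 10, 0.1), rnorm(4, 20, 0.1))
  tk_sep <- tukey_hsd(v_sep, g)
  expect_true(all(tk_sep$comparisons$significant))
  expect_equal(unname(tk_sep$letters), c("a", "b", "c"))
})

test_that("Tukey HSD agrees with stats::TukeyHSD and dominates the pairwise t-test", {
  set.seed(61)
  for (i in 1:10) {
    k <- sample(3:4, 1)
    g <- rep(letters[1:k], each = 5)
    v <- rnorm(5 * k, mean = rep(runif(k, 0, 3), each = 5))
    tk <- tukey_hsd(v, g)
    ref <- stats::TukeyHSD(stats::aov(v ~ g))$g
    key <- paste(tk$comparisons$group_2, tk$comparisons$group_1, sep = "-")
    expect_equal(tk$comparisons$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-5)

    # multiplicity ordering: adjusted p >= the unadjusted pairwise t-test p
    # on the same pooled within-group variance and residual df
    ms_w <- tk$anova$table$MSS[2]
    df_w <- tk$anova$table$df[2]
    for (r in seq_len(nrow(tk$comparisons))) {
      t_stat <- abs(tk$comparisons$diff[r]) /
        sqrt(ms_w * (1 / 5 + 1 / 5))
      p_t <- 2 * stats::pt(t_stat, df_w, lower.tail = FALSE)
      expect_gte(tk$comparisons$p_adj[r] + 1e-12, p_t)
    }
  }
})

test_that("Tukey-Kramer handles unbalanced groups without error and stays symmetric", {
  set.seed(67)
  g <- c(rep("a", 3), rep("b", 6), rep("c", 4))
  v <- rnorm(13, rep(c(0, 1, 4), c(3, 6, 4)))
  tk <- tukey_hsd(v, g)
  expect_equal(nrow(tk$comparisons), 3)
  expect_true(all(is.finite(tk$comparisons$q)))
})

test_that("percent change arithmetic and labels", {
  expect_equal(percent_change(4, 2), 100)
  expect_equal(percent_change(2, 2), 0)
  expect_equal(percent_change(0.20 * 7, 7), -80)
  expect_equal(percent_change_label(-80), "80% reduction")
  expect_equal(percent_change_label(135), "135% increase")
  expect_error(percent_change(1, 0), "positive")
  expect_error(percent_change(1, -2), "positive")
})

test_that("compact letters: no differences, all different, and the chain case", {
  m <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(unname(compact_letters(m)), c("a", "a", "a"))

  all_diff <- !diag(3) > 0
  dimnames(all_diff) <- dimnames(m)
  diag(all_diff) <- FALSE
  expect_equal(unname(compact_letters(all_diff)), c("a", "b", "c"))

  chain <- m
  chain["A", "C"] <- chain["C", "A"] <- TRUE
  expect_equal(unname(compact_letters(chain)), c("a", "ab", "b"))

  asym <- m; asym["A", "B"] <- TRUE
  expect_error(compact_letters(asym), "symmetric")
})

test_that("compact letters satisfy the sharing property on random flag matrices", {
  set.seed(71)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    m <- matrix(FALSE, k, k)
    pairs <- which(upper.tri(m), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.4
    for (r in which(on)) {
      m[pairs[r, 1], pairs[r, 2]] <- TRUE
      m[pairs[r, 2], pairs[r, 1]] <- TRUE
    }
    lt <- compact_letters(m)
    share <- function(a, b) length(intersect(strsplit(a, "")[[1]],
                                             strsplit(b, "")[[1]])) > 0
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      expect_equal(share(lt[a], lt[b]), !m[a, b],
                   label = sprintf("i=%d pair %d-%d", i, a, b))
    }
  }
})
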