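test_that("product-limit estimate matches hand oracles", {
  # no events: flat at 1
  s0 <- make_survival("a", day = rep(10, 5), event = rep(0L, 5))
  km0 <- km_estimate(s0)
  expect_true(all(km0$survival == 1))

  # n = 4, deaths at t = 1 and t = 2: S(2) = (3/4)(2/3) = 1/2
  s1 <- make_survival("a", day = c(1, 2, 3, 3), event = c(1L, 1L, 0L, 0L))
  km1 <- km_estimate(s1)
  expect_equal(km_survival_at(km1, 2), 0.5)
  expect_equal(km_survival_at(km1, 0.5), 1)

  # scripted design, high-dose group: S(21) = (39/40)(37/39)(36/37) = 0.90
  s <- generate_survival(default_config(seed = 1))
  km <- km_estimate(s, "5")
  expect_equal(km_survival_at(km, 21), 0.90)
  expect_equal(km$n_risk[km$time == 17], 40L)
  expect_equal(km$n_event[km$time == 19], 2L)
})

test_that("the survival curve is a nonincreasing step function in [0, 1] with shrinking risk sets", {
  for (seed in 1:10) {
    cfg <- default_config(seed = 3000 + seed, survival_mode = "hazard")
    cfg$survival$hazard_per_day[] <- c(0.01, 0.02, 0.05)
    s <- generate_survival(cfg)
    for (g in unique(s$group)) {
      km <- km_estimate(s, g)
      expect_true(all(diff(km$survival) <= 1e-12))
      expect_true(all(km$survival >= 0 & km$survival <= 1))
      expect_true(all(diff(km$n_risk) < 0))
    }
  }
})

test_that("without censoring before the last event, KM equals the empirical survival fraction", {
  set.seed(77)
  day <- sample(1:15, 30, replace = TRUE)
  s <- make_survival("a", day = day, event = rep(1L, 30))
  km <- km_estimate(s)
  for (t in c(3, 8, 14)) {
    expect_equal(km_survival_at(km, t), mean(day > t))
  }
})

test_that("log-rank single-event hand oracle: two groups of two, one death", {
  s <- rbind(make_survival("A", c(1, 5), c(1L, 0L)),
             make_survival("B", c(5, 5), c(0L, 0L)))
  lr <- logrank_test(s)
  # at t=1: d=1, N=4, n_A=2 -> E_A = 0.5, V = 1*3/3 * (1/2)(1/2) = 0.25
  expect_equal(unname(lr$observed["A"]), 1)
  expect_equal(unname(lr$expected["A"]), 0.5)
  expect_equal(lr$chisq, 1.0)
  expect_equal(lr$df, 1)
})

test_that("log-rank statistic: O-E sums to zero, vanishes for exchangeable groups, and matches the two-sample formula", {
  s <- rbind(make_survival("A", c(3, 7, 10, 10), c(1L, 1L, 0L, 0L)),
             make_survival("B", c(3, 7, 10, 10), c(1L, 1L, 0L, 0L)))
  lr <- logrank_test(s)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)

  set.seed(42)
  s2 <- rbind(make_survival("A", sample(1:20, 25, TRUE), rbinom(25, 1, 0.6)),
              make_survival("B", sample(1:12, 25, TRUE), rbinom(25, 1, 0.6)))
  s2$event <- as.integer(s2$event)
  lr2 <- logrank_test(s2)
  expect_equal(sum(lr2$observed - lr2$expected), 0, tolerance = 1e-10)
  u <- (lr2$observed - lr2$expected)["A"]
  expect_equal(lr2$chisq, unname(u^2 / lr2$var["A", "A"]), tolerance = 1e-10)
})

test_that("log-rank agrees with survival::survdiff and is invariant to relabeling", {
  skip_if_not_installed("survival")
  cfg <- default_config(seed = 1)
  s <- generate_survival(cfg)
  lr <- logrank_test(s)
  sd <- survival::survdiff(survival::Surv(day, event) ~ group, data = s)
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
  expect_equal(round(lr$chisq, 1), 8.3)

  relabeled <- s
  relabeled$group <- c("0" = "x", "1" = "y", "5" = "z")[s$group]
  expect_equal(logrank_test(relabeled)$chisq, lr$chisq, tolerance = 1e-12)

  set.seed(9)
  s3 <- rbind(make_survival("A", sample(1:21, 30, TRUE), rbinom(30, 1, 0.4)),
              make_survival("B", sample(1:21, 30, TRUE), rbinom(30, 1, 0.2)),
              make_survival("C", sample(1:21, 30, TRUE), rbinom(30, 1, 0.3)))
  s3$event <- as.integer(s3$event)
  sd3 <- survival::survdiff(survival::Surv(day, event) ~ group, data = s3)
  expect_equal(logrank_test(s3)$chisq, sd3$chisq, tolerance = 1e-10)
})

test_that("degenerate survival inputs are rejected explicitly", {
  s <- make_survival("a", rep(21, 10), rep(0L, 10))
  expect_error(logrank_test(s), "two groups")
  s2 <- rbind(s, make_survival("b", rep(21, 10), rep(0L, 10)))
  expect_error(logrank_test(s2), "no events")
  expect_error(km_estimate(make_survival("a", 5, 2L)), "0 or 1")
  expect_error(km_estimate(s, group = "zzz"), "no records")
})
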