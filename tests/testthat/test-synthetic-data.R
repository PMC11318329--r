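test_that("scripted survival reproduces the fixed event history", {
  cfg <- default_config(seed = 1)
  s <- generate_survival(cfg)
  expect_equal(nrow(s), 120)
  expect_equal(sum(s$event), 4)
  expect_true(all(s$group[s$event == 1] == "5"))
  expect_equal(sort(s$day[s$event == 1]), c(17, 19, 19, 20))
  expect_true(all(s$day[s$event == 0] == 21))
  expect_equal(sum(s$event[s$group %in% c("0", "1")]), 0)
})

test_that("scripted survival refuses a non-default design", {
  cfg <- default_config(seed = 1)
  cfg$design <- study_design(aquaria_per_group = 4)
  expect_error(generate_survival(cfg), "default")
})

test_that("hazard-mode survival: zero hazard censors everyone, positive hazard matches the geometric closed form", {
  cfg <- default_config(seed = 3, survival_mode = "hazard")
  cfg$survival$hazard_per_day[] <- 0
  s0 <- generate_survival(cfg)
  expect_equal(sum(s0$event), 0)
  expect_true(all(s0$day == 21))

  # expected deaths per group of n over T days at daily hazard h:
  # n * (1 - (1 - h)^T)
  h <- 0.05; n <- 40; T <- 21
  expected <- n * (1 - (1 - h)^T)
  reps <- 400
  counts <- vapply(seq_len(reps), function(i) {
    cfg_i <- default_config(seed = 1000 + i, survival_mode = "hazard")
    cfg_i$survival$hazard_per_day[] <- c(0, 0, h)
    s <- generate_survival(cfg_i)
    sum(s$event[s$group == "5"])
  }, numeric(1))
  mc_se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * mc_se + 1e-9)
})

test_that("biomarker generator hits group means exactly at CV 0 and respects calibration", {
  cfg <- default_config(seed = 5)
  cfg$biomarkers$cv <- 0
  b <- generate_biomarkers(cfg)
  expect_equal(nrow(b), 3 * 4 * 3)
  ache <- b[b$analyte == "AChE", ]
  ctrl <- cfg$biomarkers$analytes$control_mean[4]
  expect_equal(unique(ache$value[ache$group == "0"]), ctrl)
  expect_equal(unique(ache$value[ache$group == "5"]), ctrl * 0.20)
  mda <- b[b$analyte == "MDA", ]
  expect_equal(unique(mda$value[mda$group == "1"]) /
                 unique(mda$value[mda$group == "0"]), 2.35)
  expect_true(all(b$value > 0))
})

test_that("all generators are deterministic given the seed", {
  a <- generate_all(default_config(seed = 42))
  b <- generate_all(default_config(seed = 42))
  expect_identical(a, b)
  c <- generate_all(default_config(seed = 43))
  expect_false(identical(a$biomarkers$value, c$biomarkers$value))
})

test_that("lesion scores stay on the 0/2/4/6 support and follow the group profile", {
  cfg <- default_config(seed = 9)
  l <- generate_lesion_scores(cfg)
  cats <- lesion_weights()$category
  expect_equal(nrow(l), 15)
  for (cat in cats) expect_true(all(l[[cat]] %in% c(0, 2, 4, 6)))

  # degenerate profiles pin the downstream index to its extremes
  cfg$lesions$profiles["0", ] <- c(1, 0, 0, 0)
  cfg$lesions$profiles["5", ] <- c(0, 0, 0, 1)
  l2 <- generate_lesion_scores(cfg)
  idx <- condition_index_table(l2)
  expect_true(all(idx$Ih[idx$group == "0"] == 0))
  expect_true(all(idx$Ih[idx$group == "5"] == 1))
})

test_that("morphometry draws satisfy the construction identity and the atrophy ordering", {
  cfg <- default_config(seed = 11)
  m <- generate_morphometry(cfg)
  expect_equal(nrow(m), 75)
  expect_equal(m$lumen_area_um2 + m$wall_area_um2, m$tubule_area_um2)

  ms <- morphometry_summary(m)$groups
  lum <- setNames(ms$mean_rel_lumen_pct, ms$group)
  expect_true(lum["5"] > lum["1"] && lum["1"] > lum["0"])

  # noiseless case: exact split of a 5000 um^2 tubule at lumen fraction 0.3
  cfg0 <- default_config(seed = 11)
  cfg0$morphometry$area_cv <- 0
  cfg0$morphometry$lumen_fraction_sd <- 0
  cfg0$morphometry$lumen_fraction[] <- 0.3
  m0 <- generate_morphometry(cfg0)
  expect_true(all(m0$lumen_area_um2 == 1500))
  expect_true(all(m0$wall_area_um2 == 3500))
})

test_that("comet generator: tailed fraction is binomial around the configured probability", {
  p <- 0.15
  reps <- 40
  frac <- vapply(seq_len(reps), function(i) {
    cfg <- default_config(seed = 2000 + i)
    cfg$comet$tailed_prob[] <- p
    cc <- generate_comet_cells(cfg)
    mean(cc$tailed)
  }, numeric(1))
  n_cells <- 1500 * reps
  mc_se <- sqrt(p * (1 - p) / n_cells)
  expect_lt(abs(mean(frac) - p), 3 * mc_se)
})

test_that("comet generator: zero tailed probability yields zero tail DNA downstream", {
  cfg <- default_config(seed = 13)
  cfg$comet$tailed_prob[] <- 0
  cc <- generate_comet_cells(cfg)
  met <- comet_metrics_table(cc)
  expect_true(all(met$tail_dna_pct == 0))
  expect_true(all(met$tail_length_um == 0))
  expect_false(any(met$tailed))
})

test_that("invalid configurations are rejected", {
  cfg <- default_config(seed = 1)
  cfg$biomarkers$analytes$control_mean[1] <- -1
  expect_error(validate_config(cfg), "positive")
  cfg <- default_config(seed = 1)
  cfg$lesions$profiles["0", ] <- c(0.5, 0.2, 0.2, 0.2)
  expect_error(validate_config(cfg), "probability")
  cfg <- default_config(seed = 1)
  colnames(cfg$lesions$profiles) <- c("0", "1", "2", "3")
  expect_error(validate_config(cfg), "score levels")
  cfg <- default_config(seed = 1)
  cfg$morphometry$lumen_fraction[1] <- 1.2
  expect_error(validate_config(cfg), "lumen")
  cfg <- default_config(seed = 1)
  cfg$survival$hazard_per_day[1] <- 1.5
  expect_error(validate_config(cfg), "hazard")
  expect_error(default_config(), "seed")
})
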