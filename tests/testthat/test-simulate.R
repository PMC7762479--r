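test_that("simulated betas respect their range and are seed-reproducible", {
  cfg <- small_config(seed = 21)
  a <- simulate_cohort(cfg, 1)
  b <- simulate_cohort(cfg, 1)
  expect_identical(a$dataset$beta, b$dataset$beta)
  expect_identical(a$sheet, b$sheet)
  expect_true(all(a$dataset$beta >= 0.001 & a$dataset$beta <= 0.999))
  # different cohorts of one study share probes but not samples
  c2 <- simulate_cohort(cfg, 2, a$truth)
  expect_identical(rownames(c2$dataset$beta), rownames(a$dataset$beta))
  expect_false(any(colnames(c2$dataset$beta) %in% colnames(a$dataset$beta)))
})

test_that("probe truth respects the configured fractions and exclusivity", {
  cfg <- sim_config(cohort_sizes = c(40L, 40L), n_probes = 1000L,
                    age_ranges = list(c(20, 90)),
                    frac_sex = 0.05, frac_age = 0.05, frac_both = 0.02,
                    frac_het_female = 0.01, frac_het_male = 0.1, seed = 4)
  tr <- probe_truth(cfg)
  expect_equal(sum(tr$role == "both"), 20)
  expect_equal(sum(tr$het_scenario == "female"), 10)
  expect_equal(sum(tr$het_scenario == "male"), 100)
  # scenarios only on effect-free probes; labels mutually exclusive
  expect_true(all(tr$role[tr$het_scenario != "none"] == "none"))
  expect_true(all(tr$sex_effect[tr$role %in% c("sex", "both")] != 0))
  expect_true(all(tr$sex_effect[!tr$role %in% c("sex", "both")] == 0))
})

test_that("a zero-effect configuration yields uniform age-association p-values", {
  cfg <- sim_config(cohort_sizes = 200L, age_ranges = list(c(20, 90)),
                    n_probes = 2000L,
                    frac_sex = 0, frac_age = 0, frac_both = 0,
                    frac_interaction = 0, frac_het_female = 0,
                    frac_het_male = 0, frac_cell_probes = 0,
                    cell_age_trend = 0, seed = 8)
  sim <- simulate_cohort(cfg, 1)
  p <- associate(sim$dataset$beta - rowMeans(sim$dataset$beta),
                 sim$sheet$age)$p
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("the injected sex effect is recovered empirically", {
  cfg <- sim_config(cohort_sizes = 400L, age_ranges = list(c(20, 90)),
                    n_probes = 500L, frac_sex = 0.2, frac_age = 0,
                    frac_both = 0, frac_interaction = 0,
                    delta_sex = 0.05, seed = 12)
  sim <- simulate_cohort(cfg, 1)
  tr <- sim$truth
  male <- sim$sheet$sex == "M"
  on <- tr$role == "sex"
  diff_obs <- rowMeans(sim$dataset$beta[on, male]) -
    rowMeans(sim$dataset$beta[on, !male])
  # signed effect sizes: observed difference tracks the truth within 3 SE
  se <- cfg$noise_sd * sqrt(1 / sum(male) + 1 / sum(!male))
  expect_true(all(abs(diff_obs - tr$sex_effect[on]) < 3.5 * se))
  expect_equal(mean(diff_obs * sign(tr$sex_effect[on])), 0.05,
               tolerance = 3 * se / sqrt(sum(on)) + 0.001)
})

test_that("the noiseless limit returns the configured age slope exactly", {
  cfg <- sim_config(cohort_sizes = 4L, age_ranges = list(c(40, 60)),
                    n_probes = 50L, frac_age = 1, frac_sex = 0,
                    frac_both = 0, frac_interaction = 0,
                    frac_het_female = 0, frac_het_male = 0,
                    frac_cell_probes = 0, cell_loading = 0,
                    age_slope = 0.001, noise_sd = 1e-12, seed = 3)
  sim <- simulate_cohort(cfg, 1)
  tr <- sim$truth
  i <- which(tr$role == "age")[1]
  fit <- lm(sim$dataset$beta[i, ] ~ sim$sheet$age)
  expect_equal(unname(coef(fit)[2]), tr$age_slope_f[i], tolerance = 1e-6)
})

test_that("epimutation injection honors its rate model and identity cases", {
  cfg <- small_config(seed = 33)
  sim <- simulate_cohort(cfg, 1)

  # rate ~ 0: dataset unchanged
  set.seed(1)
  none <- inject_epimutations(sim$dataset, sim$sheet, base = -30, age_coef = 0)
  expect_identical(none$dataset$beta, sim$dataset$beta)
  expect_equal(nrow(none$flags), 0L)

  # age_coef = 0: counts independent of age (slope not significant)
  set.seed(2)
  flat <- inject_epimutations(sim$dataset, sim$sheet, base = 1, age_coef = 0)
  counts <- table(factor(flat$flags$sample_id, levels = sim$sheet$sample_id))
  fit <- summary(lm(as.numeric(counts) ~ sim$sheet$age))$coefficients
  expect_gt(fit[2, 4], 0.01)
})

test_that("an age-increasing epimutation rate is recovered by regression", {
  cfg <- sim_config(cohort_sizes = 300L, age_ranges = list(c(20, 90)),
                    n_probes = 400L, seed = 14)
  sim <- simulate_cohort(cfg, 1)
  set.seed(99)
  inj <- inject_epimutations(sim$dataset, sim$sheet, base = -1, age_coef = 0.02)
  counts <- table(factor(inj$flags$sample_id, levels = sim$sheet$sample_id))
  fit <- summary(lm(log(as.numeric(counts) + 1) ~ sim$sheet$age))$coefficients
  expect_gt(fit[2, 1], 0)
  expect_lt(fit[2, 4], 0.01)
})

test_that("every injected value lies strictly outside the clean 3xIQR bounds", {
  cfg <- small_config(seed = 55)
  sim <- simulate_cohort(cfg, 1)
  set.seed(7)
  inj <- inject_epimutations(sim$dataset, sim$sheet, base = 0, age_coef = 0.01)
  expect_gt(nrow(inj$flags), 0)
  for (r in seq_len(nrow(inj$flags))) {
    b <- compute_bounds(sim$dataset$beta[inj$flags$probe_id[r], ], k = 3)
    v <- inj$flags$value[r]
    expect_true(v < b$lower || v > b$upper)
  }
})

test_that("synthetic annotation is deterministic with plausible composition", {
  probes <- sprintf("cg%05d", 1:2000)
  a1 <- simulate_annotation(probes, seed = 5)
  a2 <- simulate_annotation(probes, seed = 5)
  expect_identical(a1, a2)
  expect_s3_class(a1, "ProbeAnnotation")
  expect_identical(a1$probe_id, probes)
  expect_true(all(a1$island_relation %in%
                    c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")))
  expect_true(all(diff(a1$pos) > 0))
  # flagged fractions land near their expectations
  expect_lt(abs(mean(a1$chr %in% c("X", "Y")) - 0.03), 0.02)
  expect_lt(abs(mean(a1$blacklist) - 0.05), 0.02)
  # round trip through disk
  p <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(a1, p)
  expect_equal(read_annotation(p), a1)
})
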