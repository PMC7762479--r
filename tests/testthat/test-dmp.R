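test_that("association statistics handle perfect and degenerate probes", {
  n <- 30
  age <- seq(20, 78, length.out = n)
  m <- rbind(p1 = 0.2 + 0.005 * age,     # strictly increasing
             p2 = rep(0.5, n),           # constant
             p3 = 0.9 - 0.004 * age)     # strictly decreasing
  colnames(m) <- paste0("S", 1:n)
  tab <- associate(m, age)
  expect_equal(tab$r[1], 1, tolerance = 1e-12)
  expect_lt(tab$p[1], 1e-200)
  expect_true(tab$flagged[2])
  expect_equal(tab$p[2], 1)
  expect_equal(tab$sign[2], 0L)
  expect_equal(tab$sign[3], -1L)
})

test_that("null probes give uniform association p-values", {
  set.seed(77)
  n <- 100
  m <- matrix(rnorm(2000 * n), 2000, n,
              dimnames = list(paste0("p", 1:2000), paste0("S", 1:n)))
  tab <- associate(m, runif(n, 20, 90))
  expect_gt(ks.test(tab$p, "punif")$p.value, 0.001)
})

test_that("DMP calls demand both meta significance and full concordance", {
  universe <- paste0("cg", 1:5)
  mk <- function(p, s) {
    t <- data.frame(probe_id = universe, r = s * 0.5, p = p,
                    p_bh = p, sign = as.integer(s), n = 400L, flagged = FALSE)
    class(t) <- c("AssocStat", "data.frame")
    t
  }
  # probe 1: strong everywhere, concordant; probe 2: strong but one flipped
  # sign; probe 3: weak; probe 4: concordant but p_bonf lands just below the
  # threshold; probe 5: sign 0 in one dataset
  p_strong <- 1e-12
  # choose probe-4 p so the Bonferroni-corrected meta p lands at 0.009:
  # meta p = 0.009/5, combined Z = qnorm(1 - meta_p/2), each of the 4 equal-n
  # datasets contributes Z/2
  z_each <- qnorm(1 - (0.009 / 5) / 2) / 2
  p4 <- 2 * (1 - pnorm(z_each))
  tabs <- list(
    mk(c(p_strong, p_strong, 0.5, p4, p_strong), c(1, 1, 1, 1, 1)),
    mk(c(p_strong, p_strong, 0.5, p4, p_strong), c(1, 1, -1, 1, 1)),
    mk(c(p_strong, p_strong, 0.5, p4, p_strong), c(1, -1, 1, 1, 0)),
    mk(c(p_strong, p_strong, 0.5, p4, p_strong), c(1, 1, 1, 1, 1))
  )
  res <- call_dmps(tabs, threshold = 0.01)
  expect_true("cg1" %in% res$set)
  expect_false("cg2" %in% res$set)  # discordant
  expect_false("cg3" %in% res$set)  # not significant
  expect_true("cg4" %in% res$set)   # boundary: corrected p just under 0.01
  expect_false("cg5" %in% res$set)  # zero sign breaks concordance
  expect_lt(res$meta["cg4", "p_bonf"], 0.01)
  expect_gt(res$meta["cg4", "p_bonf"], 0.005)
})

test_that("shrinking the threshold never grows the called set", {
  sim <- simulate_study(small_config(seed = 71))
  tabs <- mapply(function(ds, sh) {
    associate(residualize_for("sex-assoc", ds, sh), sh$sex)
  }, sim$datasets, sim$sheets, SIMPLIFY = FALSE)
  sets <- lapply(c(0.05, 0.01, 0.001), function(th) call_dmps(tabs, th)$set)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("saDMP classification is exact set algebra with quadrants", {
  universe <- paste0("cg", 1:4)
  meta <- function(z) {
    m <- data.frame(z = z, p = 0.001, p_bonf = 0.004)
    rownames(m) <- universe
    class(m) <- c("MetaStat", "data.frame")
    m
  }
  sex_meta <- meta(c(3, -3, 2, 1))
  age_meta <- meta(c(-4, 5, 3, -1))
  cat <- classify_sadmps(c("cg1", "cg2"), c("cg2", "cg3"), sex_meta, age_meta)
  expect_equal(cat$class, c("snaDMP", "saDMP", "aDMP-only", "none"))
  expect_equal(cat$quadrant[2], "M-hypo/age-hyper")
  expect_equal(cat$quadrant[1], "n/a")

  # disjoint sets: no saDMP
  cat2 <- classify_sadmps("cg1", "cg3", sex_meta, age_meta)
  expect_false(any(cat2$class == "saDMP"))

  # classes partition the sDMP set
  expect_equal(sum(cat$class %in% c("saDMP", "snaDMP")), 2)
  expect_error(classify_sadmps("cg9", "cg1", sex_meta, age_meta), "subsets")
})

test_that("published catalog arithmetic: snaDMP complement and enrichment OR", {
  n_sdmp <- 38100; n_admp <- 87581; n_sadmp <- 16526; m <- 327905
  n_snadmp <- n_sdmp - n_sadmp
  expect_equal(n_snadmp, 21574)
  ct <- fisher_2x2(n_sadmp, n_sdmp - n_sadmp,
                   n_admp - n_sadmp, m - n_sdmp - n_admp + n_sadmp)
  expect_equal(ct$odds_ratio, 2.35, tolerance = 0.005)
  expect_lt(ct$p, 2e-16)
})

test_that("a noiseless sex-specific slope yields a tiny interaction p", {
  n <- 60
  sheet <- make_sheet(n, seed = 81)
  sexn <- ifelse(sheet$sex == "M", 1, 0)
  beta <- matrix(0.4 + 0.001 * sheet$age + 0.002 * sheet$age * sexn +
                   rnorm(n, sd = 1e-8), 1, n,
                 dimnames = list("p1", sheet$sample_id))
  sim <- list(methylation_dataset(beta), methylation_dataset(beta, "c2"))
  res <- interaction_scan(sim, list(sheet, sheet), threshold = 0.01)
  expect_equal(res$set, "p1")
  expect_lt(res$meta["p1", "p_bonf"], 1e-10)
})

test_that("interaction scan recovers simulated sex-specific slopes and stays
           quiet under the null", {
  cfg <- sim_config(cohort_sizes = c(250L, 250L),
                    age_ranges = list(c(20, 90), c(25, 85)),
                    n_probes = 500L, frac_interaction = 0.02,
                    interaction_slope = 0.002, frac_sex = 0, frac_age = 0,
                    frac_both = 0, seed = 19)
  sim <- simulate_study(cfg)
  res <- interaction_scan(sim$datasets, sim$sheets, threshold = 0.01)
  truth_set <- sim$truth$probe_id[sim$truth$interaction]
  expect_gte(length(intersect(res$set, truth_set)) / length(truth_set), 0.8)
  expect_lte(length(setdiff(res$set, truth_set)), 1)

  cfg0 <- sim_config(cohort_sizes = c(150L, 150L),
                     age_ranges = list(c(20, 90), c(25, 85)),
                     n_probes = 400L, frac_interaction = 0, frac_sex = 0,
                     frac_age = 0, frac_both = 0, seed = 23)
  sim0 <- simulate_study(cfg0)
  res0 <- interaction_scan(sim0$datasets, sim0$sheets, threshold = 0.01)
  expect_length(res0$set, 0)
})
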