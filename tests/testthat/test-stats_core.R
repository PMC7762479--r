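test_that("regress_out removes exactly-linear covariate effects", {
  age <- 1:20
  y <- rbind(2 * age, 0.5 - 0.01 * age)
  rownames(y) <- c("p1", "p2"); colnames(y) <- paste0("S", 1:20)
  res <- regress_out(y, data.frame(age = age))
  expect_lt(max(abs(res)), 1e-10)
})

test_that("residuals are orthogonal to every covariate column", {
  set.seed(5)
  n <- 120
  covs <- data.frame(matrix(rgamma(n * 5, 4), n, 5))
  names(covs) <- c("CD8T", "CD4T", "NK", "Bcell", "Gran")
  y <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(paste0("p", 1:50), paste0("S", 1:n)))
  res <- regress_out(y, covs)
  for (cc in covs) {
    dots <- abs(res %*% (cc - mean(cc)))
    expect_lt(max(dots), 1e-8 * n)
  }
  # a covariate orthogonal to centered y leaves y - mean(y)
  x <- rep(c(-1, 1), n / 2)
  y1 <- matrix(rep(c(2, 2), n / 2), 1, n,
               dimnames = list("p", paste0("S", 1:n)))
  expect_equal(as.vector(regress_out(y1, data.frame(x = x))),
               as.vector(y1 - mean(y1)))
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  n <- 30
  covs <- data.frame(a = rnorm(n))
  covs$b <- 2 * covs$a
  y <- matrix(rnorm(n), 1, n, dimnames = list("p", paste0("S", 1:n)))
  expect_error(regress_out(y, covs), "collinear.*b")
})

test_that("Stouffer meta-analysis reproduces its closed forms", {
  # single dataset is the identity on (z, p)
  m1 <- stouffer_meta(0.05, 1L, n = 100)
  expect_equal(m1$z, qnorm(0.975), tolerance = 1e-6)
  expect_equal(m1$p, 0.05, tolerance = 1e-10)

  # 4 equal-n concordant datasets at p = 0.05: Z = 2 * qnorm(0.975)
  m4 <- stouffer_meta(matrix(rep(0.05, 4), 1), matrix(rep(1L, 4), 1),
                      n = rep(250, 4))
  expect_equal(m4$z, 3.91993, tolerance = 1e-4)
  expect_true(m4$concordant)

  # opposite signs at equal p cancel exactly
  m0 <- stouffer_meta(matrix(c(0.02, 0.02), 1), matrix(c(1L, -1L), 1),
                      n = c(80, 80))
  expect_equal(m0$z, 0)
  expect_equal(m0$p, 1)
  expect_false(m0$concordant)
})

test_that("meta Z is invariant under dataset permutation and floors tiny p", {
  set.seed(9)
  p <- matrix(runif(40), 10, 4)
  s <- matrix(sample(c(-1L, 1L), 40, TRUE), 10, 4)
  n <- c(100, 200, 300, 400)
  perm <- c(3, 1, 4, 2)
  a <- stouffer_meta(p, s, n)
  b <- stouffer_meta(p[, perm], s[, perm], n[perm])
  expect_equal(a$z, b$z)
  # p = 0 is floored rather than producing infinities
  m <- stouffer_meta(matrix(c(0, 0), 1), matrix(c(1L, 1L), 1), n = c(10, 10))
  expect_true(is.finite(m$z))
})

test_that("multiple-testing corrections match hand-computed step-up values", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  # BH by hand: p * m / rank then monotone cap from the largest down
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.04, 5), "BH"), rep(0.04, 5))
  # monotone nondecreasing on sorted input
  set.seed(2)
  p <- sort(runif(100))
  expect_true(all(diff(adjust_pvalues(p, "BH")) >= 0))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "outside")
})

test_that("ANCOVA interaction recovers constructed slope differences", {
  age <- rep(20:69, 2)
  sex <- rep(c("F", "M"), each = 50)
  y <- ifelse(sex == "M", 0.1 + 0.003 * age, 0.1 + 0.001 * age)
  # noiseless construction: silence lm's perfect-fit warning
  fit <- suppressWarnings(ancova_interaction(y, age, sex))
  expect_equal(unname(fit$coefficients["age_sex"]), 0.002, tolerance = 1e-10)
  expect_equal(fit$df, 96L)

  # y = age for both sexes: interaction exactly zero
  fit0 <- suppressWarnings(ancova_interaction(age, age, sex))
  expect_equal(unname(fit0$coefficients["age_sex"]), 0, tolerance = 1e-10)

  expect_error(ancova_interaction(y[sex == "F"], age[sex == "F"],
                                  sex[sex == "F"]), "both sexes")
})

test_that("interaction p-values are uniform under the null", {
  set.seed(31)
  reps <- 2000
  age <- runif(60, 20, 80)
  sex <- rep(c("F", "M"), 30)
  pv <- replicate(reps, {
    ancova_interaction(rnorm(60), age, sex)$p_values[["age_sex"]]
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.001)
})

test_that("fisher_2x2 matches exhaustive hypergeometric enumeration", {
  # oracle: sum the probabilities of all tables with the observed margins
  # whose probability does not exceed the observed table's
  enum_p <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(support, c1, n - c1, r1)
    sum(probs[probs <= dhyper(a, c1, n - c1, r1) * (1 + 1e-7)])
  }
  cases <- list(c(1, 9, 11, 3), c(5, 5, 5, 5), c(0, 10, 10, 0), c(7, 2, 3, 8))
  for (cs in cases) {
    got <- fisher_2x2(cs[1], cs[2], cs[3], cs[4], method = "exact")
    expect_equal(got$p, enum_p(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-8)
  }
  sym <- fisher_2x2(5, 5, 5, 5)
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  expect_error(fisher_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("large-table approximation agrees with the exact Fisher p", {
  # tables with minimum expected cell between 50 and 1000
  set.seed(17)
  for (i in 1:20) {
    a <- rpois(1, 300); b <- rpois(1, 500)
    c <- rpois(1, 400); d <- rpois(1, 600)
    exact <- fisher_2x2(a, b, c, d, method = "exact")$p
    approx <- fisher_2x2(a, b, c, d, method = "approx")$p
    if (exact > 1e-8) {
      expect_lt(abs(approx - exact) / exact, 0.05)
    }
  }
})

test_that("odds ratio follows the sample convention with conditional MLE optional", {
  got <- fisher_2x2(20, 10, 5, 40, method = "exact", or_conditional = TRUE)
  expect_equal(got$odds_ratio, 20 * 40 / (10 * 5))
  expect_false(got$approximate)
  expect_true(abs(log(got$odds_ratio_cmle) - log(got$odds_ratio)) < 1)
})
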