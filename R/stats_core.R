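# p-values are floored here before normal-quantile inversion so that
# qnorm() never returns -Inf/Inf; 1e-300 is far below any attainable
# array-scale significance.
P_FLOOR <- 1e-300

#' Regress covariates out of a probe-by-sample matrix
#'
#' Per probe, fits ordinary least squares of the probe's values on an
#' intercept plus the given covariates and returns observed minus fitted.
#' Missing values are excluded pairwise: a probe's fit uses only its
#' non-missing samples, and residuals are `NA` where the input was.
#'
#' @param mat Numeric matrix, probes in rows, samples in columns.
#' @param covariates Data frame or matrix of per-sample covariates, rows
#'   aligned with the columns of `mat`. Character/factor columns are expanded
#'   via [stats::model.matrix()].
#' @return The residual matrix, same shape and dimnames as `mat`, with
#'   attribute `covariates` recording the design columns used.
#' @export
regress_out <- function(mat, covariates) {
  stopifnot(is.matrix(mat))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != ncol(mat)) {
    stop("covariate rows must align with matrix columns")
  }
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- mat
  has_na <- rowSums(is.na(mat)) > 0L
  if (any(!has_na)) {
    res[!has_na, ] <- t(qr.resid(qx, t(mat[!has_na, , drop = FALSE])))
  }
  for (i in which(has_na)) {
    ok <- !is.na(mat[i, ])
    if (sum(ok) > ncol(X)) {
      res[i, ok] <- qr.resid(qr(X[ok, , drop = FALSE]), mat[i, ok])
    } else {
      res[i, ok] <- NA_real_
    }
  }
  attr(res, "covariates") <- colnames(X)[-1L]
  res
}

#' Sample-size-weighted Stouffer meta-analysis
#'
#' Combines per-dataset p-values across cohorts with weights proportional to
#' the square root of the sample size, the scheme used by METAL's
#' sample-size-weighted mode. In the signed (two-sided) form each dataset
#' contributes z = qnorm(1 - p/2) * sign; in the unsigned (one-sided) form,
#' used for heteroscedasticity tests, z = qnorm(1 - p). The combined statistic
#' is Z = sum(w_i z_i) / sqrt(sum(w_i^2)).
#'
#' @param pvals Numeric matrix of p-values, probes in rows, one column per
#'   dataset (a vector is treated as a single probe).
#' @param signs Matrix of direction signs in \{-1, 0, 1\} matching `pvals`,
#'   or `NULL` for the unsigned one-sided combination.
#' @param n Vector of per-dataset sample sizes.
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of probes in `pvals`.
#' @return A data frame of class `MetaStat` with one row per probe: combined
#'   `z`, meta `p`, `p_bonf`, and (signed form) the `concordant` flag plus
#'   per-dataset sign columns.
#' @export
stouffer_meta <- function(pvals, signs = NULL, n, m = NULL) {
  if (is.vector(pvals)) pvals <- matrix(pvals, nrow = 1L)
  if (!is.null(signs) && is.vector(signs)) signs <- matrix(signs, nrow = 1L)
  if (length(n) != ncol(pvals)) stop("length(n) must match the number of datasets")
  if (!is.null(signs) && !identical(dim(signs), dim(pvals))) {
    stop("signs and pvals dimensions differ")
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  if (is.null(m)) m <- nrow(pvals)
  p <- pmax(pvals, P_FLOOR)
  w <- sqrt(n)
  if (is.null(signs)) {
    z <- stats::qnorm(p, lower.tail = FALSE)
    Z <- as.vector(z %*% w) / sqrt(sum(w^2))
    meta_p <- stats::pnorm(Z, lower.tail = FALSE)
  } else {
    z <- stats::qnorm(p / 2, lower.tail = FALSE) * signs
    Z <- as.vector(z %*% w) / sqrt(sum(w^2))
    meta_p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  }
  out <- data.frame(z = Z, p = meta_p, p_bonf = pmin(1, m * meta_p))
  if (!is.null(signs)) {
    out$concordant <- apply(signs, 1L, function(s) all(s == s[1L]) && s[1L] != 0)
    colnames(signs) <- paste0("sign_", seq_len(ncol(signs)))
    out <- cbind(out, signs)
  }
  if (!is.null(rownames(pvals))) rownames(out) <- rownames(pvals)
  class(out) <- c("MetaStat", "data.frame")
  out
}

#' Multiple-testing correction
#'
#' Thin, range-checked wrapper over [stats::p.adjust()] for the two
#' corrections used in the pipeline.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @param method `"BH"` (Benjamini-Hochberg step-up) or `"bonferroni"`.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  stats::p.adjust(p, method = method)
}

#' ANCOVA with an age-by-sex interaction
#'
#' Fits y ~ age + sex + age:sex by ordinary least squares (female = 0,
#' male = 1) and reports the coefficient table, with the interaction term
#' testing whether the age trend differs between sexes.
#'
#' @param y Per-sample response values.
#' @param age Ages in years.
#' @param sex Character `"F"`/`"M"` (or numeric 0/1).
#' @return A list of class `AncovaResult`: `coefficients` and `p_values`
#'   (named `intercept`, `age`, `sex`, `age_sex`), and residual `df` (n - 4).
#' @export
ancova_interaction <- function(y, age, sex) {
  if (is.character(sex) || is.factor(sex)) sex <- sex_code(as.character(sex))
  ok <- stats::complete.cases(y, age, sex)
  y <- y[ok]; age <- age[ok]; sex <- sex[ok]
  if (length(y) < 5L) stop("need at least 5 complete observations")
  if (length(unique(sex)) < 2L) stop("both sexes must be present")
  fit <- stats::lm(y ~ age * sex)
  ct <- summary(fit)$coefficients
  # Align to the 4-term model even if a coefficient is inestimable.
  terms <- c("(Intercept)", "age", "sex", "age:sex")
  coefs <- stats::setNames(rep(NA_real_, 4L), c("intercept", "age", "sex", "age_sex"))
  pv <- coefs
  hit <- match(rownames(ct), terms)
  coefs[hit] <- ct[, 1L]
  pv[hit] <- ct[, 4L]
  structure(list(coefficients = coefs, p_values = pv,
                 df = length(y) - 4L), class = "AncovaResult")
}

#' Fisher test on a 2x2 contingency table
#'
#' Reports the sample odds ratio (a*d)/(b*c) and a two-sided p-value. The
#' exact p comes from the hypergeometric distribution via
#' [stats::fisher.test()]; for very large tables (minimum expected cell above
#' 1000) a skewness-corrected (Edgeworth) normal approximation with
#' continuity correction is used instead, following the same minimum-
#' likelihood two-sided convention as the exact test, and flagged in the
#' result. Degenerate tables with a zero row or column margin get odds ratio
#' 1 when the contrast group is empty, otherwise 0 or Inf by the sign of the
#' association.
#'
#' @param a,b,c,d Nonnegative integer counts, row-wise:
#'   \preformatted{ a b
#'  c d}
#' @param method `"auto"` (approximate only when all expected cells exceed
#'   1000), `"exact"`, or `"approx"`.
#' @param or_conditional Also report the conditional-MLE odds ratio from
#'   `fisher.test` (exact path only).
#' @return A list of class `ContingencyResult`: `table`, `odds_ratio`,
#'   `p`, `approximate` flag, and optionally `odds_ratio_cmle`.
#' @export
fisher_2x2 <- function(a, b, c, d, method = c("auto", "exact", "approx"),
                       or_conditional = FALSE) {
  method <- match.arg(method)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  ntot <- sum(counts)
  expected <- outer(rowSums(tab), colSums(tab)) / ntot
  use_approx <- switch(method,
    auto = min(expected) > 1000,
    exact = FALSE,
    approx = TRUE
  )
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c
  or <- if (den > 0) num / den
        else if (num > 0) Inf
        else if (c + d == 0 || b + d == 0) 1  # no contrast group
        else 0
  res <- list(table = tab, odds_ratio = or, approximate = use_approx)
  if (use_approx) {
    res$p <- hypergeom_approx_p(a, b, c, d)
  } else {
    ft <- stats::fisher.test(tab)
    res$p <- ft$p.value
    if (or_conditional) res$odds_ratio_cmle <- unname(ft$estimate)
  }
  res$p <- max(res$p, .Machine$double.xmin)
  class(res) <- "ContingencyResult"
  res
}

# Two-sided p for the count in cell a of a 2x2 table under the central
# hypergeometric, from an Edgeworth (skewness-corrected) normal with
# continuity correction. The opposite-tail cutoff follows the same
# minimum-likelihood convention as the exact test, located with the
# approximated density, so no hypergeometric probabilities are evaluated.
hypergeom_approx_p <- function(a, b, c, d) {
  N <- as.numeric(a + b + c + d)
  n1 <- as.numeric(a + b)        # draws
  K <- as.numeric(a + c)         # successes in population
  mu <- n1 * K / N
  sigma <- sqrt(n1 * (N - n1) * K * (N - K) / (N^2 * (N - 1)))
  if (sigma == 0) return(1)
  skew <- (N - 2 * K) * sqrt(N - 1) * (N - 2 * n1) /
    (sqrt(n1 * K * (N - K) * (N - n1)) * (N - 2))
  ptail <- function(x, lower) {
    z <- if (lower) (x + 0.5 - mu) / sigma else (x - 0.5 - mu) / sigma
    base <- stats::pnorm(z, lower.tail = lower)
    corr <- -stats::dnorm(z) * (skew / 6) * (z^2 - 1)
    min(1, max(0, base + if (lower) corr else -corr))
  }
  logf <- function(x) {
    z <- (x - mu) / sigma
    stats::dnorm(z, log = TRUE) +
      log(pmax(1e-12, 1 + (skew / 6) * (z^3 - 3 * z)))
  }
  support <- max(0, n1 + K - N):min(n1, K)
  lo_side <- a < mu
  other <- support[if (lo_side) support > mu else support < mu]
  cand <- other[logf(other) <= logf(a)]
  if (lo_side) {
    p2 <- if (length(cand)) ptail(min(cand), lower = FALSE) else 0
    min(1, ptail(a, TRUE) + p2)
  } else {
    p2 <- if (length(cand)) ptail(max(cand), lower = TRUE) else 0
    min(1, ptail(a, FALSE) + p2)
  }
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("2x2 Fisher test: OR = %.4g, two-sided p = %.3g%s\n",
              x$odds_ratio, x$p,
              if (x$approximate) " (normal approximation)" else ""))
  invisible(x)
}
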