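#' Breusch-Pagan test for age-dependent variance
#'
#' Classic Lagrange-multiplier form of the Breusch-Pagan test applied to the
#' age mean model: the values (cell-adjusted betas) are regressed on age,
#' the squared residuals of that fit are regressed on age again, and the
#' statistic is `n * R^2` of the auxiliary regression, referred to a
#' chi-squared distribution with 1 df. The auxiliary slope's sign is kept:
#' positive means variance increasing with age.
#'
#' @param y Per-sample values for one probe (residualized betas).
#' @param age Per-sample ages.
#' @return A list: `statistic`, `p`, `slope` (auxiliary slope), `n`.
#' @export
bp_test <- function(y, age) {
  ok <- stats::complete.cases(y, age)
  y <- y[ok]; age <- age[ok]
  if (length(y) < 10L) stop("Breusch-Pagan test needs n >= 10")
  if (stats::sd(age) == 0) stop("constant age vector")
  res <- bp_test_matrix(matrix(y, nrow = 1L), age)
  list(statistic = res$statistic, p = res$p, slope = res$slope, n = length(y))
}

# Vectorized Breusch-Pagan over the rows of a probe-by-sample matrix
# (complete data). Returns one row per probe.
bp_test_matrix <- function(mat, age) {
  stopifnot(is.matrix(mat), ncol(mat) == length(age))
  n <- length(age)
  if (stats::sd(age) == 0) stop("constant age vector")
  X <- cbind(1, age)
  qx <- qr(X)
  E <- t(qr.resid(qx, t(mat)))        # residuals of the mean model
  S <- E^2
  age_c <- age - mean(age)
  ssx <- sum(age_c^2)
  slope <- as.vector(S %*% age_c) / ssx
  ssr <- slope^2 * ssx                # explained SS of the auxiliary fit
  sst <- rowSums((S - rowMeans(S))^2)
  r2 <- ifelse(sst > 0, ssr / sst, 0)
  stat <- n * r2
  data.frame(
    probe_id = if (is.null(rownames(mat))) as.character(seq_len(nrow(mat))) else rownames(mat),
    statistic = stat,
    p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
    slope = slope,
    stringsAsFactors = FALSE
  )
}

#' Per-sex Breusch-Pagan scan of one dataset
#'
#' Residualizes the betas for the variability axis (cell fractions only),
#' splits by sex, and runs [bp_test_matrix()] per sex against age.
#'
#' @param dataset A `MethylationDataset`.
#' @param sheet Matching `SampleSheet`.
#' @return A list with elements `F` and `M`, each a data frame of per-probe
#'   `statistic`, `p`, `slope`, with attribute `n` (per-sex sample size).
#' @export
bp_scan <- function(dataset, sheet) {
  res <- residualize_for("variability", dataset, sheet)
  out <- lapply(c(F_ = "F", M_ = "M"), function(s) {
    idx <- sheet$sex == s
    if (sum(idx) < 10L) stop("need >= 10 samples of sex ", s)
    tab <- bp_test_matrix(res[, idx, drop = FALSE], sheet$age[idx])
    attr(tab, "n") <- sum(idx)
    tab
  })
  names(out) <- c("F", "M")
  out
}

meta_bp <- function(tables) {
  universe <- check_universe(tables)
  pvals <- collect_col(tables, "p", length(universe))
  rownames(pvals) <- universe
  n <- vapply(tables, attr, numeric(1), "n")
  meta <- stouffer_meta(pvals, signs = NULL, n = n)
  slopes <- collect_col(tables, "slope", length(universe))
  dir <- ifelse(rowSums(slopes > 0) == ncol(slopes), "increase",
                ifelse(rowSums(slopes < 0) == ncol(slopes), "decrease", "none"))
  list(meta = meta, direction = dir)
}

#' Call sex-specific age-associated variably methylated positions
#'
#' Combines per-dataset Breusch-Pagan p-values separately for females and
#' males with unsigned sample-size-weighted meta-analysis, Bonferroni-corrects
#' over the probe universe, and classifies each probe into one of three
#' scenarios: `female-specific` (female corrected meta p below
#' `sig_threshold`, male corrected meta p above `homosced_threshold`),
#' `male-specific` (the mirror image), or `opposite` (both significant with
#' opposite, all-dataset-concordant variability directions). Probes in the
#' gray zone between the two thresholds get scenario `none`.
#'
#' @param bp_tables List over datasets of [bp_scan()] results (each with
#'   `F` and `M` tables).
#' @param sig_threshold Corrected meta p below which a sex is called
#'   heteroscedastic (default 0.01).
#' @param homosced_threshold Corrected meta p above which the other sex is
#'   called homoscedastic (default 0.05).
#' @return A data frame of class `VMPCatalog`: per-sex meta `z`, `p`,
#'   `p_bonf`, per-sex `direction` (`increase` / `decrease` / `none`,
#'   requiring all-dataset slope-sign agreement), and `scenario`.
#' @export
call_savmps <- function(bp_tables, sig_threshold = 0.01,
                        homosced_threshold = 0.05) {
  if (length(bp_tables) < 1L) stop("need >= 1 dataset")
  f <- meta_bp(lapply(bp_tables, `[[`, "F"))
  m <- meta_bp(lapply(bp_tables, `[[`, "M"))
  universe <- rownames(f$meta)
  f_sig <- f$meta$p_bonf < sig_threshold
  m_sig <- m$meta$p_bonf < sig_threshold
  f_homo <- f$meta$p_bonf > homosced_threshold
  m_homo <- m$meta$p_bonf > homosced_threshold
  opposite <- f_sig & m_sig & f$direction != "none" & m$direction != "none" &
    f$direction != m$direction
  scenario <- rep("none", length(universe))
  scenario[f_sig & m_homo] <- "female-specific"
  scenario[m_sig & f_homo] <- "male-specific"
  scenario[opposite] <- "opposite"
  out <- data.frame(
    probe_id = universe,
    f_z = f$meta$z, f_p = f$meta$p, f_p_bonf = f$meta$p_bonf,
    m_z = m$meta$z, m_p = m$meta$p, m_p_bonf = m$meta$p_bonf,
    f_direction = f$direction, m_direction = m$direction,
    scenario = scenario,
    stringsAsFactors = FALSE
  )
  class(out) <- c("VMPCatalog", "data.frame")
  out
}

#' Per-probe standard deviations by age class
#'
#' Splits the cohort into the configured age classes (default 14-39, 40-59,
#' 60-94 years) and reports each probe's beta SD per class, optionally per
#' sex — the summary behind SD density plots by age class.
#'
#' @param dataset A `MethylationDataset`.
#' @param sheet Matching `SampleSheet`.
#' @param bins Age bin edges, strictly increasing; bin b spans
#'   `(bins[b], bins[b+1]]`, with the first bin closed on the left.
#' @param by_sex Split each class by sex as well.
#' @return A list of class `SdByAgeClass`: `sd` — a list of probe-by-bin SD
#'   matrices keyed `"pooled"` or `"F"`/`"M"` — plus `bins`, bin `labels`
#'   and per-group sample counts `n`.
#' @export
sd_by_age_class <- function(dataset, sheet, bins = c(14, 39, 59, 94),
                            by_sex = FALSE) {
  stopifnot(inherits(dataset, "MethylationDataset"))
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  labels <- paste(c(bins[1L], utils::head(bins, -1L)[-1L] + 1),
                  bins[-1L], sep = "-")
  cls <- cut(sheet$age, breaks = bins, include.lowest = TRUE, labels = labels)
  groups <- if (by_sex) split(seq_len(nrow(sheet)), sheet$sex)
            else list(pooled = seq_len(nrow(sheet)))
  sds <- lapply(groups, function(idx) {
    out <- sapply(labels, function(lb) {
      cols <- idx[which(cls[idx] == lb)]
      if (length(cols) < 2L) {
        stop("age class ", lb, " has fewer than 2 samples")
      }
      apply(dataset$beta[, cols, drop = FALSE], 1L, stats::sd, na.rm = TRUE)
    })
    rownames(out) <- probe_ids(dataset)
    out
  })
  n <- lapply(groups, function(idx) table(cls[idx]))
  structure(list(sd = sds, bins = bins, labels = labels, n = n),
            class = "SdByAgeClass")
}
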